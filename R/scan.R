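#' Match the C-terminal pentapeptide motif xZxxZ
#'
#' Tests whether a protein sequence ends in the CheR/CheB-binding pentapeptide
#' pattern `xZxxZ`, where `x` is any residue and `Z` one of the aromatics
#' F, W or Y: positions 2 and 5 of the last five residues must be F/W/Y.
#' The `x` positions accept any letter, including ambiguity codes; the
#' constrained positions accept only the literal letters F, W, Y, so an `X`
#' there never matches. Sequences shorter than five residues return `FALSE`,
#' never an error.
#'
#' @param sequence Character vector of uppercase amino-acid sequences.
#' @return Logical vector, one element per sequence.
#' @examples
#' match_cterm_motif(c("MKTAYNWETF", "MKTAYWETFA", "WETF"))
#' @export
match_cterm_motif <- function(sequence) {
  stopifnot(is.character(sequence))
  n <- nchar(sequence)
  ok <- !is.na(n) & n >= 5
  res <- rep(FALSE, length(sequence))
  if (any(ok)) {
    z2 <- substr(sequence[ok], n[ok] - 3, n[ok] - 3)
    z5 <- substr(sequence[ok], n[ok], n[ok])
    res[ok] <- z2 %in% AROMATIC_Z & z5 %in% AROMATIC_Z
  }
  res
}

#' Extract the C-terminal pentapeptide
#'
#' Returns the last five residues of each sequence whose C-terminus matches
#' the `xZxxZ` motif (see [match_cterm_motif()]), and `NA` otherwise.
#'
#' @param sequence Character vector of uppercase amino-acid sequences.
#' @return Character vector of 5-mers, `NA` where the motif is absent.
#' @examples
#' extract_pentapeptide(c("MKTAYNWETF", "AAAAA"))
#' @export
extract_pentapeptide <- function(sequence) {
  hit <- match_cterm_motif(sequence)
  out <- rep(NA_character_, length(sequence))
  n <- nchar(sequence[hit])
  out[hit] <- substr(sequence[hit], n - 4, n)
  out
}

#' Linker length between a reference domain and the pentapeptide
#'
#' The pentapeptide sits at the extreme C-terminus, tethered to the last
#' structured domain by an unstructured linker (about 35 residues in the
#' Tar/Tsr archetypes). Its length is `sequence_length - 5 -
#' reference_domain_end`; a negative value indicates the domain annotation
#' overlaps the pentapeptide and yields `NA` with a warning.
#'
#' @param sequence_length Integer vector of protein lengths.
#' @param reference_domain_end Integer vector of 1-based end coordinates of
#'   the domain the pentapeptide is fused to (see [classify_architecture()]).
#' @return Integer vector of linker lengths (`NA` where undefined).
#' @examples
#' linker_length(550, 510) # 35
#' @export
linker_length <- function(sequence_length, reference_domain_end) {
  out <- as.integer(sequence_length) - 5L - as.integer(reference_domain_end)
  neg <- !is.na(out) & out < 0
  if (any(neg)) {
    warn(paste0(
      sum(neg),
      " linker length(s) negative (domain annotation overlaps the",
      " pentapeptide); returned as NA"
    ))
    out[neg] <- NA_integer_
  }
  out
}

#' Scan proteins for C-terminal pentapeptides
#'
#' Tibble-level wrapper over [match_cterm_motif()] and
#' [extract_pentapeptide()]. When a domain table is supplied, the linker
#' length is computed relative to the most C-terminal MCPsignal (PF00015)
#' hit of each protein; otherwise `linker_length` is `NA`.
#'
#' @param proteins A tibble from [read_fasta()] (columns `protein_id`,
#'   `sequence`; `proteome_id` carried through when present).
#' @param domains Optional domain tibble from [read_domain_table()].
#' @return A tibble with columns `protein_id`, (`proteome_id`,)
#'   `has_pentapeptide`, `pentapeptide`, `linker_length`.
#' @export
scan_pentapeptides <- function(proteins, domains = NULL) {
  stopifnot(is.data.frame(proteins), all(c("protein_id", "sequence") %in% names(proteins)))
  out <- tibble(
    protein_id = proteins$protein_id,
    has_pentapeptide = match_cterm_motif(proteins$sequence),
    pentapeptide = extract_pentapeptide(proteins$sequence)
  )
  if ("proteome_id" %in% names(proteins)) {
    out <- mutate(out, proteome_id = proteins$proteome_id, .after = "protein_id")
  }
  if (is.null(domains)) {
    out$linker_length <- NA_integer_
    return(out)
  }
  ref <- domains |>
    filter(.data$family_accession == MCP_SIGNAL_ACC) |>
    group_by(.data$protein_id) |>
    summarise(reference_domain_end = max(.data$end), .groups = "drop")
  out <- left_join(out, ref, by = "protein_id")
  len <- setNames(nchar(proteins$sequence), proteins$protein_id)
  ll <- rep(NA_integer_, nrow(out))
  idx <- which(out$has_pentapeptide & !is.na(out$reference_domain_end))
  if (length(idx) > 0) {
    ll[idx] <- linker_length(
      len[out$protein_id[idx]], out$reference_domain_end[idx]
    )
  }
  out$linker_length <- ll
  select(out, -"reference_domain_end")
}
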