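#' Read a protein FASTA file into a tibble
#'
#' Parses protein FASTA into one row per record. Sequences are uppercased,
#' whitespace inside sequence lines is dropped, and a single trailing stop
#' symbol `*` is stripped. The header name (the token before the first
#' whitespace) is split on `|`; by default the first field is the protein id
#' and the second, when present, the proteome id, so both plain headers
#' (`>p1 description`) and UniProt-style compound ids parse usefully.
#'
#' @param path Path to a FASTA file.
#' @param id_field 1-based index of the `|`-delimited header field holding the
#'   protein id. Default 1.
#' @param proteome_field 1-based index of the `|`-delimited header field
#'   holding the proteome id; records without that field get `""`. Default 2.
#' @return A tibble with columns `protein_id`, `proteome_id`, `sequence`,
#'   `description`.
#' @examples
#' path <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1|UP1 a receptor", "MKTAYIAKQRNWETF"), path)
#' read_fasta(path)
#' @export
read_fasta <- function(path, id_field = 1, proteome_field = 2) {
  stopifnot(length(path) == 1)
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(
      protein_id = character(), proteome_id = character(),
      sequence = character(), description = character()
    ))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    abort(paste0(
      "Malformed FASTA: sequence line before any header at line ",
      which(!cumsum(is_header) > 0)[1]
    ))
  }
  rec <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  seqs <- vapply(
    split(lines[!is_header], rec[!is_header]),
    function(x) paste(x, collapse = ""),
    character(1)
  )
  sequence <- rep("", length(headers))
  sequence[as.integer(names(seqs))] <- seqs
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  sequence <- sub("\\*$", "", sequence)

  name <- sub("[[:space:]].*$", "", headers)
  description <- ifelse(
    grepl("[[:space:]]", headers),
    sub("^[^[:space:]]+[[:space:]]+", "", headers),
    ""
  )
  fields <- strsplit(name, "|", fixed = TRUE)
  pick <- function(f, i) if (length(f) >= i) f[[i]] else ""
  protein_id <- vapply(fields, pick, character(1), i = id_field)
  proteome_id <- vapply(fields, pick, character(1), i = proteome_field)

  dup <- unique(protein_id[duplicated(protein_id)])
  if (length(dup) > 0) {
    abort(paste0(
      "Duplicate protein_id in FASTA: ",
      paste(head(dup, 10), collapse = ", ")
    ))
  }
  if (any(!nzchar(sequence))) {
    abort(paste0(
      "Empty sequence for record(s): ",
      paste(head(protein_id[!nzchar(sequence)], 10), collapse = ", ")
    ))
  }
  tibble(
    protein_id = protein_id, proteome_id = proteome_id,
    sequence = sequence, description = description
  )
}

#' Write protein records to FASTA
#'
#' Inverse of [read_fasta()] on the (`protein_id`, `sequence`) pair: headers
#' are `protein_id|proteome_id description` (the proteome field and
#' description are omitted when empty).
#'
#' @param proteins A data frame with columns `protein_id` and `sequence`;
#'   optional `proteome_id` and `description`.
#' @param path Output path.
#' @param width Sequence line wrap width. Default 70.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 70) {
  stopifnot(is.data.frame(proteins), all(c("protein_id", "sequence") %in% names(proteins)))
  proteome <- proteins$proteome_id %||% rep("", nrow(proteins))
  desc <- proteins$description %||% rep("", nrow(proteins))
  name <- ifelse(nzchar(proteome), paste0(proteins$protein_id, "|", proteome),
    proteins$protein_id
  )
  header <- paste0(">", ifelse(nzchar(desc), paste(name, desc), name))
  wrapped <- lapply(proteins$sequence, function(s) {
    n <- nchar(s)
    if (n == 0) return(character())
    substring(s, seq(1, n, width), pmin(seq(1, n, width) + width - 1, n))
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(
    unlist(purrr::map2(header, wrapped, c), use.names = FALSE),
    con
  )
  invisible(path)
}
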