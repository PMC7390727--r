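#' The default ligand-binding-domain catalogue
#'
#' The eighteen Pfam families used to classify chemoreceptor sensor
#' (ligand-binding) domains — the most abundant LBD families known in
#' methyl-accepting chemotaxis proteins. The catalogue is user-extensible:
#' pass `extra` to append families, keeping accessions unique.
#'
#' @param extra Optional tibble/data frame with columns `family_label`,
#'   `family_accession` to append.
#' @return A tibble with columns `family_label`, `family_accession`.
#' @examples
#' lbd_catalog()
#' @export
lbd_catalog <- function(extra = NULL) {
  cat <- tibble(
    family_label = c(
      "TarH", "CHASE3", "4HB_MCP_1", "PAS_9", "PAS_4", "PAS_3",
      "sCACHE_2", "sCACHE_3_3", "protoglobin", "CZB", "GAF", "PilJ",
      "dCACHE_2", "dCACHE_3", "HBM", "NIT", "Cache_3-Cache_2", "dCache_1"
    ),
    family_accession = c(
      "PF02203", "PF05227", "PF12729", "PF13426", "PF08448", "PF08447",
      "PF17200", "PF17202", "PF11563", "PF13682", "PF01590", "PF13675",
      "PF08269", "PF14827", "PF16591", "PF08376", "PF17201", "PF02743"
    )
  )
  if (!is.null(extra)) {
    stopifnot(all(c("family_label", "family_accession") %in% names(extra)))
    cat <- bind_rows(cat, as_tibble(extra[c("family_label", "family_accession")]))
  }
  if (anyDuplicated(cat$family_accession) > 0) {
    abort("LBD catalogue accessions must be unique")
  }
  cat
}

#' Is a protein a chemoreceptor?
#'
#' A chemoreceptor is operationally a protein carrying at least one
#' MCPsignal (Pfam PF00015) domain hit.
#'
#' @param hits Domain tibble for one protein (or any subset of a domain
#'   table; only `family_accession` is inspected).
#' @return `TRUE` iff some hit has accession PF00015.
#' @export
is_chemoreceptor <- function(hits) {
  any(hits$family_accession == MCP_SIGNAL_ACC)
}

#' Classify receptor topology from transmembrane annotation
#'
#' A receptor with at least one annotated membrane-spanning region is
#' transmembrane; one with none is cytosolic (soluble).
#'
#' @param tm TM-region tibble for one protein (row count is what matters).
#' @return `"transmembrane"` or `"cytosolic"`.
#' @export
classify_topology <- function(tm) {
  if (nrow(tm) >= 1) "transmembrane" else "cytosolic"
}

#' Assign ligand-binding-domain families to a protein
#'
#' Returns the set of catalogue families with at least one hit on the
#' protein. A receptor may carry several families and is counted in each
#' by the census aggregations.
#'
#' @param hits Domain tibble for one protein.
#' @param catalog An LBD catalogue, see [lbd_catalog()].
#' @return Character vector of family labels (possibly empty), sorted.
#' @export
assign_lbd_families <- function(hits, catalog = lbd_catalog()) {
  labels <- catalog$family_label[match(hits$family_accession, catalog$family_accession)]
  sort(unique(labels[!is.na(labels)]))
}

#' Resolve the domain architecture of a pentapeptide-bearing receptor
#'
#' The pentapeptide is always fused to the extreme C-terminus, but the last
#' structured domain before it can be either the MCPsignal domain (the
#' prototypal layout) or a sensor domain that follows the signaling domain
#' in sequence (as in receptors with a C-terminal CZB domain). Taking `M` as
#' the most C-terminal MCPsignal hit: if any catalogue LBD hit lies after
#' `M`, the architecture is `pentapeptide_on_cterminal_lbd` and the
#' reference domain is the most C-terminal such LBD; otherwise
#' `pentapeptide_on_signaling_domain` with reference `M`. Receptors without
#' a pentapeptide get `no_pentapeptide` (reference `M`, still useful for
#' linker-free geometry). An LBD hit overlapping `M`'s end counts as
#' C-terminal only when its midpoint lies beyond `M`'s midpoint; such
#' ambiguous overlaps are reported via a message.
#'
#' The decision uses domain coordinates only, never sequence content, and
#' ignores Pfam hits outside the catalogue.
#'
#' @param hits Domain tibble for one protein (must include a PF00015 hit).
#' @param has_pentapeptide Logical scalar.
#' @param catalog An LBD catalogue, see [lbd_catalog()].
#' @return A list with elements `architecture` (string) and
#'   `reference_domain_end` (integer).
#' @export
classify_architecture <- function(hits, has_pentapeptide, catalog = lbd_catalog()) {
  mcp <- hits[hits$family_accession == MCP_SIGNAL_ACC, ]
  if (nrow(mcp) == 0) {
    abort("classify_architecture() requires at least one PF00015 hit")
  }
  m <- mcp[which.max(mcp$end), ]
  if (!isTRUE(has_pentapeptide)) {
    return(list(architecture = "no_pentapeptide", reference_domain_end = m$end))
  }
  lbd <- hits[hits$family_accession %in% catalog$family_accession, ]
  after <- lbd$start > m$end
  overlap <- lbd$start <= m$end & lbd$end > m$end
  if (any(overlap)) {
    mid_m <- (m$start + m$end) / 2
    amb <- overlap & (lbd$start + lbd$end) / 2 > mid_m
    if (any(amb)) {
      inform(paste0(
        "LBD hit(s) overlapping the signaling domain treated as C-terminal",
        " by midpoint rule on protein ", hits$protein_id[1]
      ))
    }
    after <- after | amb
  }
  if (any(after)) {
    list(
      architecture = "pentapeptide_on_cterminal_lbd",
      reference_domain_end = max(lbd$end[after])
    )
  } else {
    list(
      architecture = "pentapeptide_on_signaling_domain",
      reference_domain_end = m$end
    )
  }
}

#' Annotate chemoreceptors: pentapeptide, topology, LBD families, architecture
#'
#' The per-protein classification stage. Proteins without an MCPsignal
#' (PF00015) hit are dropped — every emitted row is a chemoreceptor. For
#' each receptor the C-terminal pentapeptide is detected, topology decided
#' from the TM table, catalogue LBD families collected, the architecture
#' resolved from domain coordinates and the linker length measured against
#' the architecture's reference domain.
#'
#' @param proteins Protein tibble from [read_fasta()].
#' @param domains Domain tibble from [read_domain_table()].
#' @param tm TM tibble from [read_tm_table()]; `NULL` means no protein has
#'   transmembrane evidence.
#' @param catalog An LBD catalogue, see [lbd_catalog()].
#' @return A tibble with one row per chemoreceptor: `protein_id`,
#'   `proteome_id`, `is_chemoreceptor` (all `TRUE`), `has_pentapeptide`,
#'   `pentapeptide`, `topology`, `lbd_families` (list column of character
#'   vectors), `architecture`, `reference_domain_end`, `linker_length`.
#' @export
classify_receptors <- function(proteins, domains, tm = NULL, catalog = lbd_catalog()) {
  stopifnot(is.data.frame(proteins), is.data.frame(domains))
  receptor_ids <- unique(domains$protein_id[domains$family_accession == MCP_SIGNAL_ACC])
  receptor_ids <- receptor_ids[receptor_ids %in% proteins$protein_id]
  prot <- proteins[match(receptor_ids, proteins$protein_id), ]

  has_penta <- match_cterm_motif(prot$sequence)
  penta <- extract_pentapeptide(prot$sequence)

  tm_n <- if (is.null(tm) || nrow(tm) == 0) {
    integer(0)
  } else {
    table(tm$protein_id)
  }
  topology <- ifelse(
    receptor_ids %in% names(tm_n)[tm_n >= 1], "transmembrane", "cytosolic"
  )

  dom_split <- split(
    domains[domains$protein_id %in% receptor_ids, ],
    factor(domains$protein_id[domains$protein_id %in% receptor_ids], levels = receptor_ids)
  )
  lbd_families <- lapply(dom_split, assign_lbd_families, catalog = catalog)
  arch <- purrr::map2(dom_split, has_penta, classify_architecture, catalog = catalog)
  architecture <- vapply(arch, `[[`, character(1), "architecture")
  ref_end <- vapply(arch, function(a) as.integer(a$reference_domain_end), integer(1))

  out <- tibble(
    protein_id = receptor_ids,
    proteome_id = prot$proteome_id %||% rep("", length(receptor_ids)),
    is_chemoreceptor = TRUE,
    has_pentapeptide = has_penta,
    pentapeptide = penta,
    topology = topology,
    lbd_families = unname(lbd_families),
    architecture = unname(architecture),
    reference_domain_end = unname(ref_end)
  )
  ll <- rep(NA_integer_, nrow(out))
  idx <- which(out$has_pentapeptide)
  if (length(idx) > 0) {
    ll[idx] <- linker_length(
      nchar(prot$sequence[idx]), out$reference_domain_end[idx]
    )
  }
  out$linker_length <- ll
  out
}
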