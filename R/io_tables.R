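#' Read a domain-annotation table
#'
#' Two dialects are supported. `"native"` is a tab-separated table with a
#' header row `protein_id, family_accession, family_label, start, end,
#' evalue` (`evalue` optional). `"hmmscan_domtblout"` is the per-domain
#' tabular output of `hmmscan --domtblout`; there the envelope coordinates
#' (`env from`/`env to`) become `start`/`end` — HMMER's own recommended
#' estimate of the region a domain occupies — and a version suffix on the
#' accession (`PF00015.22`) is removed. Coordinates are 1-based inclusive
#' throughout the package.
#'
#' Rows violating `1 <= start <= end` are dropped with a warning; the number
#' dropped is attached as attribute `rejected_rows`.
#'
#' @param path Path to the table.
#' @param dialect `"native"` or `"hmmscan_domtblout"`.
#' @param max_evalue Optional numeric; rows with `evalue` above it are
#'   dropped. Domain rows are not e-value filtered by default.
#' @return A tibble with columns `protein_id`, `family_accession`,
#'   `family_label`, `start`, `end`, `evalue`, carrying attribute
#'   `rejected_rows`.
#' @export
read_domain_table <- function(path,
                              dialect = c("native", "hmmscan_domtblout"),
                              max_evalue = NULL) {
  dialect <- rlang::arg_match(dialect)
  if (!file.exists(path)) abort(paste0("Domain table not found: ", path))
  if (dialect == "native") {
    hits <- readr::read_tsv(
      path,
      col_types = readr::cols(
        protein_id = readr::col_character(),
        family_accession = readr::col_character(),
        family_label = readr::col_character(),
        start = readr::col_integer(),
        end = readr::col_integer(),
        .default = readr::col_double()
      ),
      progress = FALSE
    )
    required <- c("protein_id", "family_accession", "family_label", "start", "end")
    missing <- setdiff(required, names(hits))
    if (length(missing) > 0) {
      abort(paste0(
        "Native domain table lacks column(s): ", paste(missing, collapse = ", ")
      ))
    }
    if (!"evalue" %in% names(hits)) hits$evalue <- NA_real_
    hits <- hits[required_domain_cols()]
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    if (length(lines) == 0) {
      hits <- tibble(
        protein_id = character(), family_accession = character(),
        family_label = character(), start = integer(), end = integer(),
        evalue = double()
      )
    } else {
      fields <- stringi::stri_split_regex(lines, "\\s+", omit_empty = TRUE)
      short <- lengths(fields) < 22
      if (any(short)) {
        abort(paste0(
          "hmmscan domtblout row with fewer than 22 fields at data line ",
          which(short)[1]
        ))
      }
      f <- function(i) vapply(fields, `[[`, character(1), i)
      hits <- tibble(
        protein_id = f(4),
        family_accession = sub("\\.\\d+$", "", f(2)),
        family_label = f(1),
        start = as.integer(f(20)),
        end = as.integer(f(21)),
        evalue = as.numeric(f(13)) # per-domain independent e-value
      )
    }
  }
  bad <- is.na(hits$start) | is.na(hits$end) | hits$start < 1 | hits$start > hits$end
  if (any(bad)) {
    warn(paste0(
      sum(bad), " domain row(s) rejected (require 1 <= start <= end)"
    ))
    hits <- hits[!bad, ]
  }
  if (!is.null(max_evalue)) {
    hits <- filter(hits, is.na(.data$evalue) | .data$evalue <= max_evalue)
  }
  attr(hits, "rejected_rows") <- sum(bad)
  hits
}

required_domain_cols <- function() {
  c("protein_id", "family_accession", "family_label", "start", "end", "evalue")
}

#' Read a transmembrane-region table
#'
#' Tab-separated with header `protein_id, start, end`; 1-based inclusive
#' coordinates. Any listed region counts as transmembrane evidence — no
#' distinction is drawn between predicted and experimental annotation.
#' Rows with `start > end` or `start < 1` are dropped with a warning.
#'
#' @param path Path to the table.
#' @return A tibble with columns `protein_id`, `start`, `end`.
#' @export
read_tm_table <- function(path) {
  if (!file.exists(path)) abort(paste0("TM table not found: ", path))
  tm <- readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer()
    ),
    progress = FALSE
  )
  bad <- is.na(tm$start) | is.na(tm$end) | tm$start < 1 | tm$start > tm$end
  if (any(bad)) {
    warn(paste0(sum(bad), " TM row(s) rejected (require 1 <= start <= end)"))
    tm <- tm[!bad, ]
  }
  tm
}

#' Read proteome taxonomy metadata
#'
#' Tab-separated with header `proteome_id, superkingdom, phylum, class,
#' order, family, genus, species`. Blank rank cells are normalised to the
#' sentinel `"unclassified"`. Duplicate rows with identical lineage merge
#' silently; duplicate `proteome_id` with conflicting lineage is an error.
#'
#' @param path Path to the table.
#' @return A tibble with one row per proteome.
#' @export
read_proteome_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("Metadata table not found: ", path))
  meta <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("proteome_id", TAXON_RANKS)
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    abort(paste0("Metadata lacks column(s): ", paste(missing, collapse = ", ")))
  }
  meta <- meta |>
    mutate(across(
      dplyr::all_of(TAXON_RANKS),
      ~ ifelse(is.na(.x) | !nzchar(trimws(.x)), UNCLASSIFIED, trimws(.x))
    )) |>
    distinct()
  dup <- unique(meta$proteome_id[duplicated(meta$proteome_id)])
  if (length(dup) > 0) {
    abort(paste0(
      "Conflicting lineages for proteome_id: ",
      paste(head(dup, 10), collapse = ", ")
    ))
  }
  meta[c("proteome_id", TAXON_RANKS, setdiff(names(meta), required))]
}

#' Read a strain-to-habitat mapping
#'
#' Tab-separated with header `proteome_id, category`, one row per
#' (proteome, habitat category) pair; a strain may carry several categories.
#'
#' @param path Path to the table.
#' @return A tibble with columns `proteome_id`, `category`.
#' @export
read_habitat_table <- function(path) {
  if (!file.exists(path)) abort(paste0("Habitat table not found: ", path))
  hab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      proteome_id = readr::col_character(),
      category = readr::col_character()
    ),
    progress = FALSE
  ) |>
    distinct()
  if (any(is.na(hab$category) | !nzchar(hab$category))) {
    abort("Habitat table has empty categories")
  }
  hab
}

#' Write a census table
#'
#' Writes the rows produced by the abundance aggregations as a tab-separated
#' table with columns `group`, `total_receptors`, `pentapeptide_receptors`,
#' `abundance_percent`, the abundance printed with two decimals.
#'
#' @param census A census tibble (see [abundance_by_group()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  required <- c("group", "total_receptors", "pentapeptide_receptors", "abundance_percent")
  stopifnot(is.data.frame(census), all(required %in% names(census)))
  out <- census |>
    mutate(abundance_percent = sprintf("%.2f", .data$abundance_percent)) |>
    select(dplyr::all_of(required))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
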