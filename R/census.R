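#' Per-genome receptor counts
#'
#' Tallies, for every proteome present in the annotations, the total number
#' of chemoreceptors and the number carrying a C-terminal pentapeptide.
#'
#' @param annotations Receptor annotation tibble from [classify_receptors()].
#' @return A tibble with columns `proteome_id`, `total_receptors`,
#'   `pentapeptide_receptors`.
#' @export
per_genome_counts <- function(annotations) {
  stopifnot(is.data.frame(annotations))
  if (nrow(annotations) == 0) {
    return(tibble(
      proteome_id = character(), total_receptors = integer(),
      pentapeptide_receptors = integer()
    ))
  }
  annotations |>
    group_by(.data$proteome_id) |>
    summarise(
      total_receptors = dplyr::n(),
      pentapeptide_receptors = sum(.data$has_pentapeptide),
      .groups = "drop"
    )
}

#' Mean and standard deviation of receptors per genome
#'
#' Summarises the per-genome chemoreceptor totals as mean and sample
#' standard deviation (n - 1 denominator). With a single genome the sd is
#' `NA`; with none, an error.
#'
#' @param counts Tibble from [per_genome_counts()].
#' @return A tibble with columns `n_genomes`, `mean_receptors`,
#'   `sd_receptors`.
#' @export
genome_summary <- function(counts) {
  stopifnot(is.data.frame(counts), "total_receptors" %in% names(counts))
  if (nrow(counts) == 0) abort("genome_summary() needs at least one genome")
  tibble(
    n_genomes = nrow(counts),
    mean_receptors = mean(counts$total_receptors),
    sd_receptors = if (nrow(counts) >= 2) sd(counts$total_receptors) else NA_real_
  )
}

#' Histogram of pentapeptide receptors per genome
#'
#' Counts genomes by their number `k` of pentapeptide-containing receptors,
#' for `k >= 1`; genomes with none are excluded, so the counts sum to the
#' number of genomes with at least one such receptor.
#'
#' @param counts Tibble from [per_genome_counts()].
#' @return A tibble with columns `pentapeptide_receptors` (k) and
#'   `n_genomes`, ascending in k.
#' @export
pentapeptide_histogram <- function(counts) {
  stopifnot(is.data.frame(counts), "pentapeptide_receptors" %in% names(counts))
  counts |>
    filter(.data$pentapeptide_receptors >= 1) |>
    dplyr::count(.data$pentapeptide_receptors, name = "n_genomes") |>
    arrange(.data$pentapeptide_receptors)
}

#' Pentapeptide abundance by arbitrary grouping
#'
#' The workhorse aggregation: maps every receptor to zero, one or several
#' group keys and reports, per key, the total receptor count, the
#' pentapeptide receptor count, and the abundance (pentapeptide receptors
#' as a percentage of all receptors in the group). A receptor contributes
#' to every key it maps to (multi-membership, e.g. LBD families or habitat
#' categories); receptors mapping to no key fall into an explicit
#' `"unclassified"` row unless `drop_unmapped = TRUE`.
#'
#' @param annotations Receptor annotation tibble.
#' @param group_fn Either a function taking one annotation row (a one-row
#'   tibble) and returning a character vector of keys, or the name of a
#'   column holding keys (character or list-of-character column).
#' @param drop_unmapped Drop receptors with no key instead of pooling them
#'   as `"unclassified"`. Default `FALSE`.
#' @return A census tibble with columns `group`, `total_receptors`,
#'   `pentapeptide_receptors`, `abundance_percent`, sorted by descending
#'   abundance. Groups with zero receptors never appear, so
#'   `abundance_percent` is always defined and in \[0, 100\].
#' @examples
#' ann <- tibble::tibble(
#'   proteome_id = "UP1", has_pentapeptide = c(TRUE, FALSE),
#'   topology = c("transmembrane", "cytosolic")
#' )
#' abundance_by_group(ann, "topology")
#' @export
abundance_by_group <- function(annotations, group_fn, drop_unmapped = FALSE) {
  stopifnot(is.data.frame(annotations))
  keys <- resolve_group_keys(annotations, group_fn)
  if (!drop_unmapped) {
    keys <- lapply(keys, function(k) if (length(k) == 0) UNCLASSIFIED else k)
  }
  nk <- lengths(keys)
  long <- tibble(
    group = unlist(keys, use.names = FALSE) %||% character(),
    has_pentapeptide = rep(annotations$has_pentapeptide, nk)
  )
  long |>
    group_by(.data$group) |>
    summarise(
      total_receptors = dplyr::n(),
      pentapeptide_receptors = sum(.data$has_pentapeptide),
      .groups = "drop"
    ) |>
    mutate(
      abundance_percent = 100 * .data$pentapeptide_receptors / .data$total_receptors
    ) |>
    arrange(dplyr::desc(.data$abundance_percent), .data$group)
}

resolve_group_keys <- function(annotations, group_fn) {
  if (is.function(group_fn)) {
    lapply(seq_len(nrow(annotations)), function(i) {
      k <- group_fn(annotations[i, ])
      as.character(k[!is.na(k)])
    })
  } else if (is.character(group_fn) && length(group_fn) == 1) {
    if (!group_fn %in% names(annotations)) {
      abort(paste0("No column '", group_fn, "' in annotations"))
    }
    col <- annotations[[group_fn]]
    if (is.list(col)) {
      lapply(col, function(k) as.character(k[!is.na(k)]))
    } else {
      lapply(col, function(k) if (is.na(k)) character() else as.character(k))
    }
  } else {
    abort("group_fn must be a function or a column name")
  }
}

#' Pentapeptide abundance by taxonomic rank
#'
#' Aggregates receptor counts at one lineage rank (superkingdom, phylum,
#' class, order or family). Every receptor maps to exactly one key — the
#' lineage name of its proteome at that rank — so totals are conserved:
#' column sums over the rows (including `"unclassified"`) equal the global
#' totals. Proteomes lacking the rank pool into `"unclassified"`.
#'
#' @param annotations Receptor annotation tibble.
#' @param metadata Proteome metadata tibble from [read_proteome_metadata()].
#' @param rank One of `"superkingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`.
#' @return A census tibble (see [abundance_by_group()]).
#' @export
abundance_by_taxon <- function(annotations, metadata, rank) {
  if (!is.character(rank) || length(rank) != 1 || !rank %in% CENSUS_RANKS) {
    abort(paste0(
      "rank must be one of: ", paste(CENSUS_RANKS, collapse = ", ")
    ))
  }
  orphans <- setdiff(unique(annotations$proteome_id), metadata$proteome_id)
  if (length(orphans) > 0) {
    abort(paste0(
      "Proteome(s) in annotations missing from metadata: ",
      paste(head(orphans, 10), collapse = ", ")
    ))
  }
  key <- metadata[[rank]][match(annotations$proteome_id, metadata$proteome_id)]
  ann <- mutate(annotations, .taxon = dplyr::coalesce(key, UNCLASSIFIED))
  abundance_by_group(ann, ".taxon")
}

#' Pentapeptide abundance by LBD family
#'
#' Multi-membership aggregation over the `lbd_families` list column: a
#' receptor carrying several sensor families is counted in each. Receptors
#' with no catalogue family form the `"unclassified"` row (or are dropped).
#'
#' @inheritParams abundance_by_group
#' @return A census tibble.
#' @export
abundance_by_lbd <- function(annotations, drop_unmapped = FALSE) {
  abundance_by_group(annotations, "lbd_families", drop_unmapped = drop_unmapped)
}

#' Pentapeptide abundance by membrane topology
#'
#' @inheritParams abundance_by_group
#' @return A census tibble with (at most) rows `transmembrane` and
#'   `cytosolic`.
#' @export
abundance_by_topology <- function(annotations) {
  abundance_by_group(annotations, "topology")
}

#' Pentapeptide abundance by habitat category
#'
#' Joins receptors to their strain's habitat categories (a strain may carry
#' several; the receptor counts in each). Receptors of proteomes without a
#' habitat assignment are excluded by default — habitat databases cover only
#' a subset of strains, so pooling them as `"unclassified"` would dominate
#' the table; set `drop_unassigned = FALSE` to pool them instead.
#'
#' @param annotations Receptor annotation tibble.
#' @param habitat Habitat tibble from [read_habitat_table()].
#' @param drop_unassigned Exclude receptors with no habitat. Default `TRUE`.
#' @return A census tibble.
#' @export
abundance_by_habitat <- function(annotations, habitat, drop_unassigned = TRUE) {
  stopifnot(is.data.frame(habitat), all(c("proteome_id", "category") %in% names(habitat)))
  cats <- split(habitat$category, habitat$proteome_id)
  ann <- mutate(
    annotations,
    .habitat = unname(cats[.data$proteome_id])
  )
  ann$.habitat[vapply(ann$.habitat, is.null, logical(1))] <- list(character())
  abundance_by_group(ann, ".habitat", drop_unmapped = drop_unassigned)
}

#' Pentapeptide abundance as a function of receptor count per genome
#'
#' For every distinct per-genome receptor count `c` (with at least
#' `min_genomes` genomes), computes the pooled abundance — the summed
#' pentapeptide receptors over the summed receptors of those genomes, as a
#' percentage — and the Pearson correlation between `c` and abundance over
#' the retained points. Genomes above the `cap_quantile` quantile of
#' receptor counts are excluded so a handful of extreme genomes cannot
#' dominate the count axis (99.5% of bacterial genomes carry fewer than 60
#' chemoreceptor genes). `method = "mean"` averages per-genome ratios
#' instead of pooling.
#'
#' @param counts Tibble from [per_genome_counts()].
#' @param min_genomes Minimum genomes per retained count value. Default 1.
#' @param cap_quantile Quantile of receptor counts above which genomes are
#'   dropped; `1` disables the cap. Default 0.995.
#' @param method `"pooled"` (default) or `"mean"`.
#' @return An object of class `penta_trend`: a list with `points` (tibble
#'   of `receptor_count`, `pooled_abundance_percent`, `n_genomes`),
#'   `pearson_r` (`NA` when undefined: fewer than two points or zero
#'   variance), `method`, `min_genomes`, `cap_quantile`.
#' @export
abundance_vs_receptor_count <- function(counts, min_genomes = 1,
                                        cap_quantile = 0.995,
                                        method = c("pooled", "mean")) {
  method <- rlang::arg_match(method)
  stopifnot(min_genomes >= 1)
  kept <- counts
  if (cap_quantile < 1 && nrow(kept) > 0) {
    cap <- stats::quantile(kept$total_receptors, cap_quantile, type = 1)
    kept <- filter(kept, .data$total_receptors <= cap)
  }
  points <- kept |>
    group_by(receptor_count = .data$total_receptors) |>
    summarise(
      pooled_abundance_percent = if (method == "pooled") {
        100 * sum(.data$pentapeptide_receptors) / sum(.data$total_receptors)
      } else {
        mean(100 * .data$pentapeptide_receptors / .data$total_receptors)
      },
      n_genomes = dplyr::n(),
      .groups = "drop"
    ) |>
    filter(.data$n_genomes >= min_genomes) |>
    arrange(.data$receptor_count)
  r <- if (nrow(points) < 2 ||
    sd(points$receptor_count) == 0 ||
    sd(points$pooled_abundance_percent) == 0) {
    NA_real_
  } else {
    pearson_r(points$receptor_count, points$pooled_abundance_percent)
  }
  structure(
    list(
      points = points, pearson_r = r, method = method,
      min_genomes = min_genomes, cap_quantile = cap_quantile
    ),
    class = "penta_trend"
  )
}

#' Pearson product-moment correlation
#'
#' Thin validating wrapper: errors on unequal lengths, fewer than two
#' observations, or a constant vector (where the correlation is undefined)
#' instead of returning `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("pearson_r() needs at least two observations")
  if (anyNA(x) || anyNA(y)) abort("pearson_r() does not accept missing values")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("pearson_r() undefined for constant input")
  }
  cor(x, y)
}

#' @export
print.penta_trend <- function(x, ...) {
  cat(
    "Pentapeptide abundance vs. receptor count (", x$method, ")\n",
    nrow(x$points), " count values; Pearson r = ",
    ifelse(is.na(x$pearson_r), "undefined", sprintf("%.3f", x$pearson_r)),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the abundance-vs-count trend into its points
#'
#' @param x A `penta_trend` object.
#' @param ... Unused.
#' @return The points tibble (`receptor_count`,
#'   `pooled_abundance_percent`, `n_genomes`).
#' @export
tidy.penta_trend <- function(x, ...) x$points

#' One-row summary of the abundance-vs-count trend
#'
#' @param x A `penta_trend` object.
#' @param ... Unused.
#' @return A one-row tibble with `pearson_r`, `n_points`, `n_genomes`,
#'   `method`.
#' @export
glance.penta_trend <- function(x, ...) {
  tibble(
    pearson_r = x$pearson_r,
    n_points = nrow(x$points),
    n_genomes = sum(x$points$n_genomes),
    method = x$method
  )
}
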