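#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line
#'   geom_hline labs theme_minimal scale_fill_brewer
#' @export
ggplot2::autoplot

#' Sequence-logo style plot of a pentapeptide PWM
#'
#' Stacked letter heights per position on the information-content rule
#' (frequency times the position's IC, in bits). Residues below
#' `min_height` bits are pooled into an unlabelled remainder so the stacks
#' stay readable.
#'
#' @param object A `penta_pwm` from [build_pwm()].
#' @param min_height Minimum stack height (bits) for an own segment.
#'   Default 0.02.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.penta_pwm <- function(object, min_height = 0.02, ...) {
  dat <- logo_table(object) |>
    mutate(residue = ifelse(.data$stack_height >= min_height, .data$residue, "other")) |>
    group_by(.data$position, .data$residue) |>
    summarise(stack_height = sum(.data$stack_height), .groups = "drop")
  ggplot(dat, aes(
    x = factor(.data$position), y = .data$stack_height,
    fill = .data$residue
  )) +
    geom_col(colour = "grey30", linewidth = 0.2) +
    labs(
      x = "pentapeptide position", y = "information (bits)",
      fill = "residue",
      title = "Pentapeptide consensus logo (information-content heights)"
    ) +
    theme_minimal()
}

#' Plot abundance vs. receptor count per genome
#'
#' The pooled pentapeptide abundance at each per-genome receptor count,
#' with a dashed line at the global abundance.
#'
#' @param object A `penta_trend` from [abundance_vs_receptor_count()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.penta_trend <- function(object, ...) {
  pts <- object$points
  # receptor-weighted global abundance over the retained points
  global <- with(
    pts,
    sum(pooled_abundance_percent * receptor_count * n_genomes) /
      sum(receptor_count * n_genomes)
  )
  ggplot(pts, aes(x = .data$receptor_count, y = .data$pooled_abundance_percent)) +
    geom_hline(yintercept = global, linetype = "dashed", colour = "grey50") +
    geom_point(aes(size = .data$n_genomes), alpha = 0.7) +
    labs(
      x = "chemoreceptor genes per genome",
      y = "pentapeptide abundance (%)",
      size = "genomes",
      title = sprintf(
        "Abundance vs. receptor count (Pearson r = %s)",
        ifelse(is.na(object$pearson_r), "undefined",
          sprintf("%.2f", object$pearson_r)
        )
      )
    ) +
    theme_minimal()
}

#' Bar chart of a census table
#'
#' Abundance per group for any census tibble (taxon rank, LBD family,
#' topology or habitat), ordered by abundance.
#'
#' @param census A census tibble from the `abundance_by_*` functions.
#' @param label Axis label for the grouping. Default "group".
#' @return A ggplot.
#' @export
plot_census <- function(census, label = "group") {
  stopifnot(is.data.frame(census), "abundance_percent" %in% names(census))
  dat <- mutate(census, group = stats::reorder(.data$group, .data$abundance_percent))
  ggplot(dat, aes(x = .data$abundance_percent, y = .data$group)) +
    geom_col(fill = "steelblue") +
    labs(
      x = "pentapeptide abundance (%)", y = label,
      title = "Pentapeptide abundance by group"
    ) +
    theme_minimal()
}

#' Histogram of pentapeptide receptors per genome
#'
#' @param histogram Tibble from [pentapeptide_histogram()].
#' @return A ggplot.
#' @export
plot_pentapeptide_histogram <- function(histogram) {
  stopifnot(is.data.frame(histogram))
  ggplot(histogram, aes(x = .data$pentapeptide_receptors, y = .data$n_genomes)) +
    geom_col(fill = "steelblue") +
    labs(
      x = "pentapeptide chemoreceptors per genome", y = "genomes",
      title = "Genomes by pentapeptide receptor count"
    ) +
    theme_minimal()
}
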