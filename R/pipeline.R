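#' Build and validate a census run configuration
#'
#' Collects the input paths and tuning knobs of a full census run and
#' validates them up front: every referenced input must exist and the
#' output directory must be creatable, so a bad path fails before any
#' compute.
#'
#' @param fasta,domains,tm,metadata Paths to the protein FASTA, domain
#'   table, TM table and proteome metadata. `tm` may be `NULL` (every
#'   receptor then classifies as cytosolic).
#' @param habitat Optional path to a habitat table; `NULL` skips the
#'   habitat census.
#' @param out_dir Output directory.
#' @param dialect Domain-table dialect, see [read_domain_table()].
#' @param ranks Taxonomic ranks to report. Default phylum, class, order,
#'   family.
#' @param pseudocount PWM pseudocount, see [build_pwm()].
#' @param min_genomes Minimum genomes per abundance-vs-count point.
#' @param cap_quantile Receptor-count cap quantile, see
#'   [abundance_vs_receptor_count()].
#' @param max_evalue Optional domain e-value cutoff.
#' @param seed Optional integer recorded in the outputs when the inputs
#'   were simulated (the analysis itself draws no random numbers).
#' @return A validated list of class `census_config`.
#' @export
census_config <- function(fasta, domains, tm = NULL, metadata,
                          habitat = NULL, out_dir,
                          dialect = c("native", "hmmscan_domtblout"),
                          ranks = c("phylum", "class", "order", "family"),
                          pseudocount = 0.5, min_genomes = 1,
                          cap_quantile = 0.995, max_evalue = NULL,
                          seed = NULL) {
  dialect <- rlang::arg_match(dialect)
  bad_rank <- setdiff(ranks, CENSUS_RANKS)
  if (length(bad_rank) > 0) {
    abort(paste0("Unsupported rank(s): ", paste(bad_rank, collapse = ", ")))
  }
  paths <- list(fasta = fasta, domains = domains, tm = tm, metadata = metadata, habitat = habitat)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("Input '", nm, "' does not exist: ", p))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("Cannot create output dir: ", out_dir))
  structure(
    list(
      fasta = fasta, domains = domains, tm = tm, metadata = metadata,
      habitat = habitat, out_dir = out_dir, dialect = dialect,
      ranks = ranks, pseudocount = pseudocount, min_genomes = min_genomes,
      cap_quantile = cap_quantile, max_evalue = max_evalue, seed = seed
    ),
    class = "census_config"
  )
}

#' Read a census configuration from a YAML file
#'
#' The file holds the same keys as the arguments of [census_config()];
#' relative input paths are resolved against the file's directory.
#'
#' @param path YAML file.
#' @return A validated `census_config`.
#' @export
read_census_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (startsWith(p, "/")) p else file.path(base, p)
  }
  for (nm in c("fasta", "domains", "tm", "metadata", "habitat")) {
    raw[[nm]] <- resolve(raw[[nm]])
  }
  if (!is.null(raw$out_dir) && !startsWith(raw$out_dir, "/")) {
    raw$out_dir <- file.path(base, raw$out_dir)
  }
  do.call(census_config, raw)
}

#' Run the full pentapeptide census pipeline
#'
#' Orchestrates scan, classification, census and motif stages on the
#' configured inputs and writes every result table under the configured
#' output directory: per-protein annotations, per-genome counts, census
#' tables by taxon rank / LBD family / topology / habitat, the
#' abundance-vs-count points, the PWM in long form, the logo table, the
#' consensus and charge summary, and a one-page text summary (global
#' abundance, per-superkingdom abundance, mean +/- sd receptors per
#' proteome, histogram, Pearson r). Outputs carry the configuration hash
#' (and seed, when recorded) so reruns are attributable; the run is
#' deterministic — rerunning on the same inputs gives identical files.
#' Progress and stage failures are logged to standard error, never mixed
#' into result files.
#'
#' @param config A `census_config` from [census_config()] or
#'   [read_census_config()].
#' @return Invisibly, a list with the in-memory results: `annotations`,
#'   `genome_counts`, `genome_summary`, `histogram`, `trend`, `census`
#'   (named list of census tibbles), `pwm`, `consensus`, `charges`,
#'   `summary_path`.
#' @export
run_census <- function(config) {
  stopifnot(inherits(config, "census_config"))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)))
      }),
      message = function(m) {
        message("[", name, "] ", sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      }
    )
    message(sprintf(
      "[%s] done in %.1fs", name,
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ))
    res
  }

  inputs <- stage("read", {
    list(
      proteins = read_fasta(config$fasta),
      domains = read_domain_table(config$domains, config$dialect,
        max_evalue = config$max_evalue
      ),
      tm = if (is.null(config$tm)) NULL else read_tm_table(config$tm),
      metadata = read_proteome_metadata(config$metadata),
      habitat = if (is.null(config$habitat)) NULL else read_habitat_table(config$habitat)
    )
  })

  annotations <- stage("classify", {
    classify_receptors(inputs$proteins, inputs$domains, inputs$tm)
  })

  res <- stage("census", {
    counts <- per_genome_counts(annotations)
    census <- list(topology = abundance_by_topology(annotations))
    census$superkingdom <- abundance_by_taxon(annotations, inputs$metadata, "superkingdom")
    for (rank in config$ranks) {
      census[[rank]] <- abundance_by_taxon(annotations, inputs$metadata, rank)
    }
    census$lbd <- abundance_by_lbd(annotations)
    if (!is.null(inputs$habitat)) {
      census$habitat <- abundance_by_habitat(annotations, inputs$habitat)
    }
    list(
      counts = counts,
      summary = genome_summary(counts),
      histogram = pentapeptide_histogram(counts),
      trend = abundance_vs_receptor_count(
        counts,
        min_genomes = config$min_genomes, cap_quantile = config$cap_quantile
      ),
      census = census
    )
  })

  motif <- stage("motif", {
    peptides <- annotations$pentapeptide[annotations$has_pentapeptide]
    if (length(peptides) == 0) {
      list(pwm = NULL, consensus = NA_character_, charges = NULL)
    } else {
      pwm <- build_pwm(peptides, pseudocount = config$pseudocount)
      list(
        pwm = pwm,
        consensus = suppressMessages(consensus_string(pwm)),
        charges = charge_summary(peptides)
      )
    }
  })

  stage("write", {
    out <- config$out_dir
    cfg_json <- jsonlite::toJSON(
      config[setdiff(names(config), "out_dir")],
      auto_unbox = TRUE, null = "null"
    )
    cfg_path <- file.path(out, "config.json")
    writeLines(cfg_json, cfg_path)
    cfg_hash <- unname(tools::md5sum(cfg_path))

    ann_out <- annotations |>
      mutate(lbd_families = vapply(
        .data$lbd_families, paste, character(1), collapse = ";"
      ))
    readr::write_tsv(ann_out, file.path(out, "annotations.tsv"), progress = FALSE)
    readr::write_tsv(res$counts, file.path(out, "genome_counts.tsv"), progress = FALSE)
    readr::write_tsv(res$histogram, file.path(out, "pentapeptide_histogram.tsv"), progress = FALSE)
    readr::write_tsv(res$trend$points, file.path(out, "abundance_vs_count.tsv"), progress = FALSE)
    for (nm in names(res$census)) {
      write_census(res$census[[nm]], file.path(out, paste0("census_", nm, ".tsv")))
    }
    if (!is.null(motif$pwm)) {
      readr::write_tsv(tidy(motif$pwm), file.path(out, "pwm.tsv"), progress = FALSE)
      export_logo_table(motif$pwm, file.path(out, "logo.tsv"))
      readr::write_tsv(
        motif$charges$per_peptide_charge,
        file.path(out, "pentapeptide_charges.tsv"),
        progress = FALSE
      )
    }
    writeLines(
      census_summary_text(annotations, res, motif, cfg_hash, config$seed),
      file.path(out, "summary.txt")
    )
  })

  invisible(list(
    annotations = annotations,
    genome_counts = res$counts,
    genome_summary = res$summary,
    histogram = res$histogram,
    trend = res$trend,
    census = res$census,
    pwm = motif$pwm,
    consensus = motif$consensus,
    charges = motif$charges,
    summary_path = file.path(config$out_dir, "summary.txt")
  ))
}

census_summary_text <- function(annotations, res, motif, cfg_hash, seed) {
  total <- nrow(annotations)
  penta <- sum(annotations$has_pentapeptide)
  gsum <- res$summary
  sk <- res$census$superkingdom
  lines <- c(
    "Pentapeptide chemoreceptor census summary",
    paste0("config_hash: ", cfg_hash),
    if (!is.null(seed)) paste0("seed: ", seed),
    "",
    sprintf("total chemoreceptors: %d", total),
    sprintf("pentapeptide chemoreceptors: %d", penta),
    sprintf("global abundance: %.2f%%", 100 * penta / max(total, 1)),
    "",
    "abundance by superkingdom:",
    sprintf(
      "  %s: %.2f%% (%d / %d)",
      sk$group, sk$abundance_percent, sk$pentapeptide_receptors,
      sk$total_receptors
    ),
    "",
    sprintf(
      "receptors per proteome: mean %.1f +/- %.1f sd (%d proteomes)",
      gsum$mean_receptors, gsum$sd_receptors, gsum$n_genomes
    ),
    sprintf(
      "Pearson r (abundance vs receptor count): %s",
      ifelse(is.na(res$trend$pearson_r), "undefined",
        sprintf("%.3f", res$trend$pearson_r)
      )
    ),
    "",
    "genomes by pentapeptide receptor count:",
    sprintf(
      "  %d receptor(s): %d genome(s)",
      res$histogram$pentapeptide_receptors, res$histogram$n_genomes
    )
  )
  if (!is.null(motif$pwm)) {
    lines <- c(
      lines, "",
      paste0("pentapeptide consensus: ", motif$consensus),
      sprintf("mean pentapeptide net charge: %.2f", motif$charges$mean_charge),
      sprintf(
        "fraction net negative: %.3f", motif$charges$fraction_net_negative
      ),
      "logo height rule: information content (frequency x IC per position)"
    )
  }
  lines
}
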