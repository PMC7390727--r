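#' Specify a synthetic clade
#'
#' One clade of the synthetic proteome generator: a set of genomes sharing
#' a lineage, a per-genome receptor-count distribution (negative binomial,
#' zero-truncated — every simulated genome is chemoreceptor-containing),
#' a pentapeptide probability, a sensor-family composition, a membrane
#' topology fraction and optional habitat categories.
#'
#' @param name Clade name (used for the genus and in the ground truth).
#' @param phylum,class,order,family Lineage names; `family` may be `NA` to
#'   leave the rank unclassified.
#' @param n_genomes Number of genomes (>= 1).
#' @param receptor_mean Mean of the (untruncated) negative binomial
#'   receptor count per genome.
#' @param receptor_dispersion Negative binomial size parameter; small
#'   values give the overdispersed, variance ~ mean^2 regime typical of
#'   chemoreceptor gene counts.
#' @param pentapeptide_probability Probability in \[0, 1\] that a receptor
#'   carries a C-terminal pentapeptide.
#' @param pentapeptide_slope Change in that probability per receptor above
#'   `receptor_mean` in the genome (clamped to \[0, 1\]); a negative slope
#'   induces a within-clade negative abundance-vs-count trend. Default 0.
#' @param lbd_weights Named non-negative weights over catalogue family
#'   labels; the special name `"none"` is the weight of carrying no sensor
#'   domain from the catalogue. Each receptor draws one label.
#' @param tm_fraction Probability a receptor is transmembrane.
#' @param czb_cterminal_fraction For receptors drawn as CZB, the
#'   probability the CZB domain sits C-terminal to the signaling domain
#'   (so a pentapeptide, if present, is fused to the CZB extension).
#' @param habitat_categories Character vector of habitat categories for
#'   every genome of the clade (may be empty: strain not covered by the
#'   habitat database).
#' @return A list of class `clade_spec`.
#' @export
clade_spec <- function(name, phylum, class, order, family = NA_character_,
                       n_genomes, receptor_mean, receptor_dispersion,
                       pentapeptide_probability, pentapeptide_slope = 0,
                       lbd_weights = c(none = 1), tm_fraction = 0.75,
                       czb_cterminal_fraction = 0.39,
                       habitat_categories = character()) {
  stopifnot(
    is.character(name), nzchar(name),
    n_genomes >= 1,
    receptor_mean >= 0, receptor_dispersion > 0,
    pentapeptide_probability >= 0, pentapeptide_probability <= 1,
    tm_fraction >= 0, tm_fraction <= 1,
    czb_cterminal_fraction >= 0, czb_cterminal_fraction <= 1,
    is.numeric(lbd_weights), all(lbd_weights >= 0), sum(lbd_weights) > 0
  )
  known <- c(lbd_catalog()$family_label, "none")
  unknown <- setdiff(names(lbd_weights), known)
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown LBD label(s) in lbd_weights: ", paste(unknown, collapse = ", ")
    ))
  }
  structure(
    list(
      name = name, phylum = phylum, class = class, order = order,
      family = family, n_genomes = as.integer(n_genomes),
      receptor_mean = receptor_mean,
      receptor_dispersion = receptor_dispersion,
      pentapeptide_probability = pentapeptide_probability,
      pentapeptide_slope = pentapeptide_slope,
      lbd_weights = lbd_weights, tm_fraction = tm_fraction,
      czb_cterminal_fraction = czb_cterminal_fraction,
      habitat_categories = habitat_categories
    ),
    class = "clade_spec"
  )
}

#' Default pentapeptide letter distribution for the generator
#'
#' A 5 x 20 frequency matrix over the standard alphabet: tryptophan
#' dominates position 2 and phenylalanine position 5 (all mass at those
#' positions on the aromatics F/W/Y, as the motif demands), while the free
#' positions 1, 3 and 4 are enriched in the small/polar and acidic
#' residues seen around the NWETF archetype — giving most sampled
#' pentapeptides a negative net charge.
#'
#' @return A 5 x 20 row-stochastic matrix with residue column names.
#' @export
default_pentapeptide_pwm <- function() {
  m <- matrix(0, nrow = 5, ncol = 20, dimnames = list(position = 1:5, residue = AA_STANDARD))
  base <- setNames(rep(1, 20), AA_STANDARD)
  boost1 <- c(N = 12, D = 10, E = 8, S = 6, T = 5, G = 4, A = 3)
  boost3 <- c(E = 14, D = 8, T = 6, S = 6, N = 5, Q = 4, A = 3)
  boost4 <- c(T = 10, E = 10, D = 7, S = 6, N = 5, P = 3, A = 3)
  fill <- function(boost) {
    w <- base
    w[names(boost)] <- w[names(boost)] + boost
    w / sum(w)
  }
  m[1, ] <- fill(boost1)
  m[3, ] <- fill(boost3)
  m[4, ] <- fill(boost4)
  m[2, c("W", "F", "Y")] <- c(0.60, 0.25, 0.15)
  m[5, c("F", "W", "Y")] <- c(0.70, 0.18, 0.12)
  m
}

#' A shipped synthetic configuration emulating the published census regime
#'
#' Ten clades spanning high-abundance (~35–40% pentapeptide probability),
#' mid (~20%) and low (~0.2–3%) regimes, with overdispersed per-genome
#' receptor counts whose receptor-weighted mean is ~13.5 and variance of
#' the same order as the squared mean. High-probability clades are given
#' low receptor-count means and the low-probability clades high means, so
#' the pooled abundance falls with the receptor count per genome — the
#' between-clade structure behind the negative abundance-vs-count
#' correlation. Enteric-like and clostridial-like clades carry the
#' "human intestinal microflora" habitat; pseudomonad-like clades are
#' free-living; some clades carry no habitat at all (as with strains a
#' habitat database does not cover).
#'
#' @return A list of [clade_spec()] objects.
#' @export
make_paperlike_config <- function() {
  list(
    clade_spec("caulobacter_like",
      phylum = "Proteobacteria", class = "Alphaproteobacteria",
      order = "Caulobacterales", family = "Caulobacteraceae",
      n_genomes = 150, receptor_mean = 7, receptor_dispersion = 1.5,
      pentapeptide_probability = 0.382,
      lbd_weights = c(TarH = 0.20, "4HB_MCP_1" = 0.10, CZB = 0.05, dCache_1 = 0.10, none = 0.55),
      tm_fraction = 0.80,
      habitat_categories = "aquatic"
    ),
    clade_spec("xanthomonad_like",
      phylum = "Proteobacteria", class = "Gammaproteobacteria",
      order = "Xanthomonadales", family = "Xanthomonadaceae",
      n_genomes = 150, receptor_mean = 9, receptor_dispersion = 1.5,
      pentapeptide_probability = 0.374,
      lbd_weights = c(TarH = 0.25, CHASE3 = 0.10, dCache_1 = 0.10, none = 0.55),
      tm_fraction = 0.80,
      habitat_categories = "plant host"
    ),
    clade_spec("enterobacteria_like",
      phylum = "Proteobacteria", class = "Gammaproteobacteria",
      order = "Enterobacterales", family = "Enterobacteriaceae",
      n_genomes = 300, receptor_mean = 8, receptor_dispersion = 2,
      pentapeptide_probability = 0.364,
      lbd_weights = c(TarH = 0.47, "4HB_MCP_1" = 0.08, CZB = 0.05, dCache_1 = 0.05, none = 0.35),
      tm_fraction = 0.85,
      habitat_categories = c("human intestinal microflora", "host-associated")
    ),
    clade_spec("burkholderia_like",
      phylum = "Proteobacteria", class = "Betaproteobacteria",
      order = "Burkholderiales", family = "Burkholderiaceae",
      n_genomes = 250, receptor_mean = 14, receptor_dispersion = 1.2,
      pentapeptide_probability = 0.213,
      lbd_weights = c(TarH = 0.08, dCache_1 = 0.20, sCACHE_2 = 0.07, none = 0.65),
      tm_fraction = 0.78,
      habitat_categories = c("soil", "host-associated")
    ),
    clade_spec("rhizobium_like",
      phylum = "Proteobacteria", class = "Alphaproteobacteria",
      order = "Rhizobiales", family = "Rhizobiaceae",
      n_genomes = 250, receptor_mean = 12, receptor_dispersion = 1.2,
      pentapeptide_probability = 0.214,
      lbd_weights = c(dCache_1 = 0.20, CHASE3 = 0.05, PAS_3 = 0.05, none = 0.70),
      tm_fraction = 0.75,
      habitat_categories = c("soil", "plant host")
    ),
    clade_spec("sphingomonad_like",
      phylum = "Proteobacteria", class = "Alphaproteobacteria",
      order = "Sphingomonadales", family = NA,
      n_genomes = 100, receptor_mean = 10, receptor_dispersion = 1.5,
      pentapeptide_probability = 0.202,
      lbd_weights = c(TarH = 0.10, GAF = 0.05, none = 0.85),
      tm_fraction = 0.72
    ),
    clade_spec("vibrio_like",
      phylum = "Proteobacteria", class = "Gammaproteobacteria",
      order = "Vibrionales", family = "Vibrionaceae",
      n_genomes = 150, receptor_mean = 18, receptor_dispersion = 1.2,
      pentapeptide_probability = 0.016,
      lbd_weights = c(dCache_1 = 0.25, "Cache_3-Cache_2" = 0.05, PilJ = 0.05, none = 0.65),
      tm_fraction = 0.80,
      habitat_categories = "aquatic"
    ),
    clade_spec("pseudomonas_like",
      phylum = "Proteobacteria", class = "Gammaproteobacteria",
      order = "Pseudomonadales", family = "Pseudomonadaceae",
      n_genomes = 300, receptor_mean = 26, receptor_dispersion = 1.2,
      pentapeptide_probability = 0.012,
      lbd_weights = c(dCache_1 = 0.30, "4HB_MCP_1" = 0.08, PilJ = 0.08, GAF = 0.04, none = 0.50),
      tm_fraction = 0.77,
      habitat_categories = c("soil", "free-living")
    ),
    clade_spec("bacillus_like",
      phylum = "Firmicutes", class = "Bacilli",
      order = "Bacillales", family = "Bacillaceae",
      n_genomes = 200, receptor_mean = 10, receptor_dispersion = 1.5,
      pentapeptide_probability = 0.002,
      lbd_weights = c(dCache_1 = 0.20, sCACHE_2 = 0.10, PAS_4 = 0.05, none = 0.65),
      tm_fraction = 0.70,
      habitat_categories = "soil"
    ),
    clade_spec("clostridium_like",
      phylum = "Firmicutes", class = "Clostridia",
      order = "Clostridiales", family = NA,
      n_genomes = 150, receptor_mean = 12, receptor_dispersion = 1.2,
      pentapeptide_probability = 0.029,
      lbd_weights = c(dCache_1 = 0.15, sCACHE_3_3 = 0.05, none = 0.80),
      tm_fraction = 0.65,
      habitat_categories = c("human intestinal microflora", "host-associated")
    )
  )
}

# Zero-truncated negative binomial draws (every genome keeps >= 1 receptor).
rtrunc_nbinom <- function(n, mu, size) {
  x <- rnbinom(n, mu = mu, size = size)
  while (any(x == 0)) {
    x[x == 0] <- rnbinom(sum(x == 0), mu = mu, size = size)
  }
  x
}

# Analytic mean of the zero-truncated negative binomial (test oracle hook).
trunc_nbinom_mean <- function(mu, size) {
  mu / (1 - stats::dnbinom(0, mu = mu, size = size))
}

aa_class <- function() paste0("[", paste(AA_STANDARD, collapse = ""), "]")

sample_pentapeptides <- function(n, pwm) {
  if (n == 0) return(character())
  cols <- lapply(1:5, function(i) {
    sample(AA_STANDARD, n, replace = TRUE, prob = pwm[i, ])
  })
  do.call(paste0, cols)
}

# 5-mers guaranteed NOT to match the xZxxZ motif (rejection sampling).
sample_negative_suffix <- function(n) {
  if (n == 0) return(character())
  s <- stringi::stri_rand_strings(n, 5, pattern = aa_class())
  bad <- match_cterm_motif(s)
  while (any(bad)) {
    s[bad] <- stringi::stri_rand_strings(sum(bad), 5, pattern = aa_class())
    bad <- match_cterm_motif(s)
  }
  s
}

#' Generate a synthetic proteome bundle with known ground truth
#'
#' Simulates, genome by genome, a set of chemoreceptor-containing proteomes
#' whose statistical structure mirrors what the census assumes: clade-
#' specific pentapeptide prevalence, zero-truncated negative-binomial
#' receptor counts per genome, a sensor-family composition, membrane
#' topology flags, an unstructured linker (mean ~35 residues) before the
#' pentapeptide, and a configurable pentapeptide letter distribution.
#' Background residues are uniform over the 20 standard letters, so the
#' motif's analytic false-positive rate (3/20)^2 applies exactly. Domain
#' annotations are noise-free by construction (the census trusts its
#' annotation source); `domain_dropout` optionally removes a fraction of
#' non-defining domain rows for robustness experiments. Receptors drawn
#' without a pentapeptide get a C-terminus rejection-sampled to never
#' match the motif, so ground-truth labels are exact.
#'
#' Identical `seed` gives an identical bundle.
#'
#' @param clades List of [clade_spec()] objects. Default
#'   [make_paperlike_config()].
#' @param pwm 5 x 20 pentapeptide letter frequency matrix; must place all
#'   mass at positions 2 and 5 on F/W/Y (otherwise generated
#'   "pentapeptides" would not match the motif and the ground truth would
#'   be wrong — this is an error). Default [default_pentapeptide_pwm()].
#' @param linker_mean,linker_sd Normal linker-length parameters (rounded,
#'   floored at 8 residues). Defaults 35 and 5.
#' @param decoys_per_genome Non-chemoreceptor proteins added per genome
#'   (half of them carrying a catalogue sensor domain but no MCPsignal
#'   domain, so the chemoreceptor filter is exercised). Default 2.
#' @param domain_dropout Fraction of LBD domain rows dropped at random.
#'   Default 0 (noise-free).
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `penta_bundle`: list of tibbles `proteins`,
#'   `domains`, `tm`, `metadata`, `habitat`, `ground_truth`, plus `seed`.
#' @export
simulate_proteomes <- function(clades = make_paperlike_config(),
                               pwm = default_pentapeptide_pwm(),
                               linker_mean = 35, linker_sd = 5,
                               decoys_per_genome = 2,
                               domain_dropout = 0,
                               seed) {
  stopifnot(length(clades) >= 1, !missing(seed))
  if (!all(vapply(clades, inherits, logical(1), "clade_spec"))) {
    abort("clades must be a list of clade_spec objects")
  }
  validate_generator_pwm(pwm)
  withr::with_seed(as.integer(seed), {
    parts <- vector("list", length(clades))
    genome_offset <- 0L
    for (i in seq_along(clades)) {
      parts[[i]] <- simulate_clade(
        clades[[i]], pwm, linker_mean, linker_sd,
        decoys_per_genome, genome_offset
      )
      genome_offset <- genome_offset + clades[[i]]$n_genomes
    }
    bundle <- list(
      proteins = bind_rows(lapply(parts, `[[`, "proteins")),
      domains = bind_rows(lapply(parts, `[[`, "domains")),
      tm = bind_rows(lapply(parts, `[[`, "tm")),
      metadata = bind_rows(lapply(parts, `[[`, "metadata")),
      habitat = bind_rows(lapply(parts, `[[`, "habitat")),
      ground_truth = bind_rows(lapply(parts, `[[`, "ground_truth")),
      seed = as.integer(seed)
    )
    if (domain_dropout > 0) {
      droppable <- bundle$domains$family_accession != MCP_SIGNAL_ACC
      drop <- droppable & runif(nrow(bundle$domains)) < domain_dropout
      bundle$domains <- bundle$domains[!drop, ]
    }
    structure(bundle, class = "penta_bundle")
  })
}

validate_generator_pwm <- function(pwm) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 5, ncol(pwm) == 20)
  if (is.null(colnames(pwm)) || !identical(colnames(pwm), AA_STANDARD)) {
    abort("Generator pwm must have the standard residue column names")
  }
  if (any(abs(rowSums(pwm) - 1) > 1e-9) || any(pwm < 0)) {
    abort("Generator pwm rows must be non-negative and sum to 1")
  }
  off <- setdiff(AA_STANDARD, AROMATIC_Z)
  if (any(pwm[c(2, 5), off] > 0)) {
    abort(
      "Generator pwm must place all mass at positions 2 and 5 on F/W/Y"
    )
  }
  invisible(pwm)
}

simulate_clade <- function(clade, pwm, linker_mean, linker_sd,
                           decoys_per_genome, genome_offset) {
  g <- clade$n_genomes
  proteome_id <- sprintf("SYNUP%05d", genome_offset + seq_len(g))
  counts <- rtrunc_nbinom(g, clade$receptor_mean, clade$receptor_dispersion)

  n <- sum(counts)
  rec_proteome <- rep(proteome_id, counts)
  rec_count <- rep(counts, counts)
  p_eff <- pmin(1, pmax(
    0,
    clade$pentapeptide_probability +
      clade$pentapeptide_slope * (rec_count - clade$receptor_mean)
  ))
  has_penta <- runif(n) < p_eff

  labels <- names(clade$lbd_weights)
  fam <- sample(labels, n, replace = TRUE, prob = clade$lbd_weights)
  czb_cterm <- fam == "CZB" & runif(n) < clade$czb_cterminal_fraction
  tm_flag <- runif(n) < clade$tm_fraction

  # Coordinate layout (1-based inclusive): optional N-terminal LBD after a
  # 30-residue N-terminal segment, a 25-residue gap, the 180-residue
  # MCPsignal block, then either linker+pentapeptide, a C-terminal CZB (for
  # the czb_cterm fraction), or a short non-matching tail.
  has_nlbd <- fam != "none" & !czb_cterm
  lbd_start <- ifelse(has_nlbd, 31L, NA_integer_)
  lbd_end <- ifelse(has_nlbd, 140L, NA_integer_)
  mcp_start <- 30L + ifelse(has_nlbd, 110L, 0L) + 25L + 1L
  mcp_end <- mcp_start + 179L
  czb_start <- ifelse(czb_cterm, mcp_end + 9L, NA_integer_)
  czb_end <- ifelse(czb_cterm, mcp_end + 98L, NA_integer_)
  ref_end <- ifelse(czb_cterm, czb_end, mcp_end)

  linker <- pmax(8L, as.integer(round(rnorm(n, linker_mean, linker_sd))))
  tail_len <- 5L + stats::rpois(n, 10)
  seq_len_ <- ifelse(has_penta, ref_end + linker + 5L, ref_end + tail_len)

  penta <- rep(NA_character_, n)
  penta[has_penta] <- sample_pentapeptides(sum(has_penta), pwm)
  suffix <- character(n)
  suffix[has_penta] <- penta[has_penta]
  suffix[!has_penta] <- sample_negative_suffix(sum(!has_penta))
  body <- stringi::stri_rand_strings(n, seq_len_ - 5L, pattern = aa_class())
  rec_seq <- paste0(body, suffix)

  rec_id <- sprintf("%s_R%03d", rec_proteome, sequence(counts))

  proteins <- tibble(
    protein_id = rec_id, proteome_id = rec_proteome,
    sequence = rec_seq,
    description = paste0("synthetic chemoreceptor clade=", clade$name)
  )

  catalog <- lbd_catalog()
  acc_of <- setNames(catalog$family_accession, catalog$family_label)
  mcp_rows <- tibble(
    protein_id = rec_id, family_accession = MCP_SIGNAL_ACC,
    family_label = "MCPsignal", start = mcp_start, end = mcp_end,
    evalue = 1e-30
  )
  nlbd_rows <- tibble(
    protein_id = rec_id[has_nlbd],
    family_accession = unname(acc_of[fam[has_nlbd]]),
    family_label = fam[has_nlbd],
    start = lbd_start[has_nlbd], end = lbd_end[has_nlbd], evalue = 1e-12
  )
  czb_rows <- tibble(
    protein_id = rec_id[czb_cterm],
    family_accession = unname(acc_of["CZB"]),
    family_label = "CZB",
    start = czb_start[czb_cterm], end = czb_end[czb_cterm], evalue = 1e-12
  )

  tm1 <- tibble(
    protein_id = rec_id[tm_flag], start = 5L, end = 25L
  )
  tm2 <- tibble(
    protein_id = rec_id[tm_flag],
    start = ifelse(has_nlbd[tm_flag], 141L, 31L),
    end = ifelse(has_nlbd[tm_flag], 161L, 51L)
  )

  # Decoys: background proteins without the MCPsignal domain.
  nd <- g * decoys_per_genome
  decoys <- NULL
  decoy_dom <- NULL
  if (nd > 0) {
    decoy_proteome <- rep(proteome_id, each = decoys_per_genome)
    decoy_id <- sprintf(
      "%s_D%03d", decoy_proteome,
      rep(seq_len(decoys_per_genome), times = g)
    )
    dlen <- sample(150:400, nd, replace = TRUE)
    dseq <- stringi::stri_rand_strings(nd, dlen, pattern = aa_class())
    decoys <- tibble(
      protein_id = decoy_id, proteome_id = decoy_proteome,
      sequence = dseq,
      description = paste0("synthetic non-receptor clade=", clade$name)
    )
    with_dom <- seq_len(nd) %% 2 == 1
    decoy_dom <- tibble(
      protein_id = decoy_id[with_dom],
      family_accession = unname(acc_of["GAF"]), family_label = "GAF",
      start = 20L, end = 130L, evalue = 1e-8
    )
  }

  architecture <- ifelse(
    !has_penta, "no_pentapeptide",
    ifelse(czb_cterm, "pentapeptide_on_cterminal_lbd",
      "pentapeptide_on_signaling_domain"
    )
  )
  ground_truth <- tibble(
    protein_id = rec_id, proteome_id = rec_proteome, clade = clade$name,
    is_chemoreceptor = TRUE,
    has_pentapeptide = has_penta, pentapeptide = penta,
    topology = ifelse(tm_flag, "transmembrane", "cytosolic"),
    lbd_families = ifelse(fam == "none", "", fam),
    architecture = architecture,
    reference_domain_end = as.integer(ref_end),
    linker_length = ifelse(has_penta, linker, NA_integer_)
  )
  if (!is.null(decoys)) {
    ground_truth <- bind_rows(ground_truth, tibble(
      protein_id = decoys$protein_id, proteome_id = decoys$proteome_id,
      clade = clade$name, is_chemoreceptor = FALSE,
      has_pentapeptide = match_cterm_motif(decoys$sequence),
      pentapeptide = extract_pentapeptide(decoys$sequence),
      topology = "cytosolic", lbd_families = "",
      architecture = NA_character_,
      reference_domain_end = NA_integer_, linker_length = NA_integer_
    ))
  }

  metadata <- tibble(
    proteome_id = proteome_id,
    superkingdom = "Bacteria",
    phylum = clade$phylum, class = clade$class, order = clade$order,
    family = ifelse(is.na(clade$family), UNCLASSIFIED, clade$family),
    genus = paste0(clade$name, "_genus"),
    species = UNCLASSIFIED
  )
  habitat <- if (length(clade$habitat_categories) > 0) {
    tidyr::expand_grid(
      proteome_id = proteome_id, category = clade$habitat_categories
    )
  } else {
    tibble(proteome_id = character(), category = character())
  }

  list(
    proteins = bind_rows(proteins, decoys),
    domains = bind_rows(mcp_rows, nlbd_rows, czb_rows, decoy_dom),
    tm = bind_rows(tm1, tm2),
    metadata = metadata,
    habitat = habitat,
    ground_truth = ground_truth
  )
}

#' Write a synthetic bundle to disk
#'
#' Emits the five census input files plus the ground truth:
#' `proteins.fasta`, `domains.tsv`, `tm.tsv`, `metadata.tsv`,
#' `habitat.tsv`, `ground_truth.tsv`. Output is deterministic given the
#' bundle.
#'
#' @param bundle A `penta_bundle` from [simulate_proteomes()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "penta_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    fasta = file.path(dir, "proteins.fasta"),
    domains = file.path(dir, "domains.tsv"),
    tm = file.path(dir, "tm.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    habitat = file.path(dir, "habitat.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv")
  )
  write_fasta(bundle$proteins, paths$fasta)
  readr::write_tsv(bundle$domains, paths$domains, progress = FALSE)
  readr::write_tsv(bundle$tm, paths$tm, progress = FALSE)
  readr::write_tsv(bundle$metadata, paths$metadata, progress = FALSE)
  readr::write_tsv(bundle$habitat, paths$habitat, progress = FALSE)
  readr::write_tsv(bundle$ground_truth, paths$ground_truth, progress = FALSE)
  invisible(paths)
}

#' @export
print.penta_bundle <- function(x, ...) {
  cat(
    "Synthetic proteome bundle (seed ", x$seed, ")\n",
    nrow(x$metadata), " genomes, ", nrow(x$proteins), " proteins (",
    sum(x$ground_truth$is_chemoreceptor), " chemoreceptors, ",
    sum(x$ground_truth$is_chemoreceptor & x$ground_truth$has_pentapeptide),
    " with pentapeptide)\n",
    sep = ""
  )
  invisible(x)
}
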