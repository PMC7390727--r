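test_that("per_genome_counts tallies totals and pentapeptide receptors per proteome", {
  counts <- per_genome_counts(toy_annotations())
  expect_equal(nrow(counts), 3)
  expect_equal(
    counts[counts$proteome_id == "UP1", ]$total_receptors, 3L
  )
  expect_equal(
    counts[counts$proteome_id == "UP1", ]$pentapeptide_receptors, 1L
  )
  expect_equal(
    counts[counts$proteome_id == "UP2", ]$pentapeptide_receptors, 2L
  )
  expect_equal(nrow(per_genome_counts(toy_annotations()[0, ])), 0)
})

test_that("genome_summary reports mean and sample standard deviation", {
  counts3 <- tibble::tibble(proteome_id = c("a", "b", "c"), total_receptors = c(10L, 10L, 10L))
  gs <- genome_summary(counts3)
  expect_equal(gs$mean_receptors, 10)
  expect_equal(gs$sd_receptors, 0)

  counts2 <- tibble::tibble(proteome_id = c("a", "b"), total_receptors = c(1L, 3L))
  gs <- genome_summary(counts2)
  expect_equal(gs$mean_receptors, 2)
  expect_equal(gs$sd_receptors, sqrt(2)) # hand-computed sample sd, n - 1

  one <- genome_summary(counts2[1, ])
  expect_true(is.na(one$sd_receptors))
  expect_error(genome_summary(counts2[0, ]), "at least one genome")
})

test_that("pentapeptide_histogram excludes zero-count genomes and conserves totals", {
  counts <- tibble::tibble(
    proteome_id = paste0("g", 1:5),
    total_receptors = c(3L, 2L, 4L, 1L, 20L),
    pentapeptide_receptors = c(1L, 1L, 2L, 0L, 20L)
  )
  h <- pentapeptide_histogram(counts)
  expect_equal(h$pentapeptide_receptors, c(1L, 2L, 20L))
  expect_equal(h$n_genomes, c(2L, 1L, 1L))
  expect_equal(sum(h$n_genomes), sum(counts$pentapeptide_receptors >= 1))

  allzero <- dplyr::mutate(counts, pentapeptide_receptors = 0L)
  expect_equal(nrow(pentapeptide_histogram(allzero)), 0)
})

test_that("abundance_by_group supports single and multi membership and the unclassified pool", {
  ann <- toy_annotations()
  topo <- abundance_by_group(ann, "topology")
  tmrow <- topo[topo$group == "transmembrane", ]
  expect_equal(tmrow$total_receptors, 5L)
  expect_equal(tmrow$pentapeptide_receptors, 3L)
  expect_equal(tmrow$abundance_percent, 60)

  fam <- abundance_by_group(ann, "lbd_families")
  expect_equal(fam[fam$group == "TarH", ]$total_receptors, 3L)
  # a receptor with families {GAF, PAS_3} increments both rows
  expect_equal(fam[fam$group == "GAF", ]$total_receptors, 1L)
  expect_equal(fam[fam$group == "PAS_3", ]$total_receptors, 1L)
  expect_equal(fam[fam$group == "unclassified", ]$total_receptors, 2L)
  expect_equal(
    nrow(abundance_by_group(ann, "lbd_families", drop_unmapped = TRUE) |>
      dplyr::filter(group == "unclassified")),
    0
  )

  byfun <- abundance_by_group(ann, function(row) row$proteome_id)
  expect_equal(sum(byfun$total_receptors), nrow(ann))
  expect_true(all(byfun$abundance_percent >= 0 & byfun$abundance_percent <= 100))
})

test_that("abundance_by_taxon aggregates at a rank and conserves global totals", {
  ann <- toy_annotations()
  meta <- toy_metadata()
  orders <- abundance_by_taxon(ann, meta, "order")
  entero <- orders[orders$group == "Enterobacterales", ]
  expect_equal(entero$total_receptors, 3L)
  expect_equal(entero$pentapeptide_receptors, 1L)

  phyla <- abundance_by_taxon(ann, meta, "phylum")
  expect_equal(sum(phyla$total_receptors), nrow(ann))
  expect_equal(sum(phyla$pentapeptide_receptors), sum(ann$has_pentapeptide))

  # each order's totals sum into its phylum's totals
  order_to_phylum <- setNames(meta$phylum, meta$order)
  by_parent <- tapply(
    orders$total_receptors, order_to_phylum[orders$group], sum
  )
  expect_equal(
    as.numeric(by_parent[phyla$group]), phyla$total_receptors
  )

  expect_error(abundance_by_taxon(ann, meta, "genus"), "rank must be one of")
  expect_error(
    abundance_by_taxon(ann, meta[-1, ], "phylum"),
    "missing from metadata.*UP1"
  )
})

test_that("a proteome lacking a rank pools into the unclassified row", {
  ann <- toy_annotations()
  meta <- toy_metadata()
  fams <- abundance_by_taxon(ann, meta, "family")
  expect_equal(
    fams[fams$group == "unclassified", ]$total_receptors, 2L # UP2 receptors
  )
})

test_that("abundance_by_habitat counts strains in every category and can exclude unassigned", {
  ann <- toy_annotations()
  hab <- tibble::tibble(
    proteome_id = c("UP1", "UP1", "UP2"),
    category = c("human intestinal microflora", "host-associated", "soil")
  )
  res <- abundance_by_habitat(ann, hab)
  expect_equal(
    res[res$group == "human intestinal microflora", ]$total_receptors, 3L
  )
  expect_equal(res[res$group == "host-associated", ]$total_receptors, 3L)
  expect_false("unclassified" %in% res$group) # UP3 excluded by default

  pooled <- abundance_by_habitat(ann, hab, drop_unassigned = FALSE)
  expect_equal(pooled[pooled$group == "unclassified", ]$total_receptors, 3L)
})

test_that("abundance_vs_receptor_count pools by count value and correlates", {
  perfect <- tibble::tibble(
    proteome_id = paste0("g", 1:8),
    total_receptors = rep(c(10L, 20L, 40L, 80L), each = 2),
    pentapeptide_receptors = rep(c(9L, 8L, 6L, 2L), each = 2)
  )
  tr <- abundance_vs_receptor_count(perfect, cap_quantile = 1)
  # abundance = 100 - c * 1.? -> here pooled abundance is exactly 90, 40, 15, 2.5
  expect_equal(tr$points$pooled_abundance_percent, c(90, 40, 15, 2.5))
  expect_lt(tr$pearson_r, 0)

  linear <- tibble::tibble(
    proteome_id = paste0("g", 1:3),
    total_receptors = c(10L, 20L, 50L),
    pentapeptide_receptors = c(9L, 16L, 25L)
  )
  tr <- abundance_vs_receptor_count(linear, cap_quantile = 1)
  expect_equal(tr$points$pooled_abundance_percent, c(90, 80, 50))
  expect_equal(tr$pearson_r, -1) # abundance = 100 - c on these points

  constant <- tibble::tibble(
    proteome_id = paste0("g", 1:4),
    total_receptors = c(2L, 4L, 8L, 10L),
    pentapeptide_receptors = c(1L, 2L, 4L, 5L)
  )
  tr <- abundance_vs_receptor_count(constant, cap_quantile = 1)
  expect_true(is.na(tr$pearson_r)) # zero variance in abundance

  # min_genomes filters sparsely supported count values
  tr <- abundance_vs_receptor_count(perfect, min_genomes = 3, cap_quantile = 1)
  expect_equal(nrow(tr$points), 0)

  g <- glance(abundance_vs_receptor_count(perfect, cap_quantile = 1))
  expect_equal(g$n_points, 4L)
  expect_equal(g$n_genomes, 8L)
  expect_equal(
    tidy(abundance_vs_receptor_count(perfect, cap_quantile = 1)),
    abundance_vs_receptor_count(perfect, cap_quantile = 1)$points
  )
})

test_that("the mean method averages per-genome ratios instead of pooling", {
  counts <- tibble::tibble(
    proteome_id = c("a", "b"),
    total_receptors = c(10L, 10L),
    pentapeptide_receptors = c(0L, 10L)
  )
  pooled <- abundance_vs_receptor_count(counts, cap_quantile = 1)
  meaned <- abundance_vs_receptor_count(counts, cap_quantile = 1, method = "mean")
  expect_equal(pooled$points$pooled_abundance_percent, 50)
  expect_equal(meaned$points$pooled_abundance_percent, 50)

  uneven <- tibble::tibble(
    proteome_id = c("a", "b"),
    total_receptors = c(1L, 1L),
    pentapeptide_receptors = c(1L, 0L)
  )
  expect_equal(
    abundance_vs_receptor_count(uneven, cap_quantile = 1, method = "mean")$points$pooled_abundance_percent,
    50
  )
})

test_that("pearson_r matches hand-derived values and validates its input", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(pearson_r(1, 2), "at least two")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("pearson_r agrees with a direct-formula oracle on random vectors", {
  withr::local_seed(104)
  for (i in 1:25) {
    n <- sample(3:50, 1)
    x <- rnorm(n)
    y <- rnorm(n) + 0.5 * x
    expect_equal(pearson_r(x, y), pearson_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("conservation holds for single-membership groupings on synthetic data", {
  b <- get_bundle("small")
  ann <- classify_receptors(b$proteins, b$domains, b$tm)
  for (rank in c("superkingdom", "phylum", "class", "order", "family")) {
    cens <- abundance_by_taxon(ann, b$metadata, rank)
    expect_equal(sum(cens$total_receptors), nrow(ann))
    expect_equal(sum(cens$pentapeptide_receptors), sum(ann$has_pentapeptide))
    expect_true(all(cens$abundance_percent >= 0 & cens$abundance_percent <= 100))
    expect_true(all(cens$total_receptors > 0))
  }
  topo <- abundance_by_topology(ann)
  expect_equal(sum(topo$total_receptors), nrow(ann))
})
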