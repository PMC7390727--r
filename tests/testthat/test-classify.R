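dom_row <- function(protein_id, acc, label, start, end) {
  tibble::tibble(
    protein_id = protein_id, family_accession = acc, family_label = label,
    start = as.integer(start), end = as.integer(end), evalue = 1e-20
  )
}

test_that("a chemoreceptor is a protein with an MCPsignal hit", {
  expect_true(is_chemoreceptor(dom_row("p1", "PF00015", "MCPsignal", 200, 380)))
  expect_false(is_chemoreceptor(dom_row("p1", "PF02203", "TarH", 10, 150)))
  expect_false(is_chemoreceptor(dom_row("p1", "PF00015", "x", 1, 1)[0, ]))
})

test_that("one or more TM regions makes a receptor transmembrane", {
  tm2 <- tibble::tibble(protein_id = "p1", start = c(5L, 150L), end = c(25L, 170L))
  expect_equal(classify_topology(tm2), "transmembrane")
  expect_equal(classify_topology(tm2[1, ]), "transmembrane")
  expect_equal(classify_topology(tm2[0, ]), "cytosolic")
})

test_that("LBD families come from the 18-family catalogue, multi-membership allowed", {
  cat18 <- lbd_catalog()
  expect_equal(nrow(cat18), 18)
  expect_equal(cat18$family_accession[cat18$family_label == "TarH"], "PF02203")
  expect_equal(cat18$family_accession[cat18$family_label == "dCache_1"], "PF02743")

  hits <- rbind(
    dom_row("p1", "PF00015", "MCPsignal", 200, 380),
    dom_row("p1", "PF02203", "TarH", 10, 150)
  )
  expect_equal(assign_lbd_families(hits), "TarH")
  hits2 <- rbind(
    dom_row("p1", "PF00015", "MCPsignal", 300, 480),
    dom_row("p1", "PF01590", "GAF", 10, 120),
    dom_row("p1", "PF08447", "PAS_3", 130, 230)
  )
  expect_equal(assign_lbd_families(hits2), c("GAF", "PAS_3"))
  expect_equal(
    assign_lbd_families(dom_row("p1", "PF00015", "MCPsignal", 200, 380)),
    character(0)
  )

  extra <- lbd_catalog(extra = tibble::tibble(
    family_label = "MyLBD", family_accession = "PF99999"
  ))
  expect_equal(nrow(extra), 19)
  expect_error(
    lbd_catalog(extra = tibble::tibble(
      family_label = "Dup", family_accession = "PF02203"
    )),
    "unique"
  )
})

test_that("architecture follows the position of the LBD relative to the signaling domain", {
  nterm <- rbind(
    dom_row("p1", "PF13682", "CZB", 10, 150),
    dom_row("p1", "PF00015", "MCPsignal", 200, 380)
  )
  res <- classify_architecture(nterm, has_pentapeptide = TRUE)
  expect_equal(res$architecture, "pentapeptide_on_signaling_domain")
  expect_equal(res$reference_domain_end, 380)

  cterm <- rbind(
    dom_row("p2", "PF00015", "MCPsignal", 50, 250),
    dom_row("p2", "PF13682", "CZB", 300, 420)
  )
  res <- classify_architecture(cterm, has_pentapeptide = TRUE)
  expect_equal(res$architecture, "pentapeptide_on_cterminal_lbd")
  expect_equal(res$reference_domain_end, 420)

  only <- dom_row("p3", "PF00015", "MCPsignal", 50, 250)
  res <- classify_architecture(only, has_pentapeptide = TRUE)
  expect_equal(res$architecture, "pentapeptide_on_signaling_domain")

  res <- classify_architecture(cterm, has_pentapeptide = FALSE)
  expect_equal(res$architecture, "no_pentapeptide")
  expect_equal(res$reference_domain_end, 250)

  expect_error(
    classify_architecture(
      dom_row("p4", "PF13682", "CZB", 10, 150), TRUE
    ),
    "PF00015"
  )
})

test_that("an LBD overlapping the signaling domain is C-terminal only past the midpoint", {
  overlap_cterm <- rbind(
    dom_row("p1", "PF00015", "MCPsignal", 100, 300),
    dom_row("p1", "PF13682", "CZB", 290, 400)
  )
  expect_message(
    res <- classify_architecture(overlap_cterm, TRUE),
    "midpoint"
  )
  expect_equal(res$architecture, "pentapeptide_on_cterminal_lbd")

  overlap_nterm <- rbind(
    dom_row("p2", "PF00015", "MCPsignal", 100, 300),
    dom_row("p2", "PF13682", "CZB", 20, 190) # midpoint 105 < 200
  )
  res <- classify_architecture(overlap_nterm, TRUE)
  expect_equal(res$architecture, "pentapeptide_on_signaling_domain")

  # non-catalogue Pfam hits after the signaling domain are ignored
  stranger <- rbind(
    dom_row("p3", "PF00015", "MCPsignal", 100, 300),
    dom_row("p3", "PF00001", "7tm_1", 350, 450)
  )
  res <- classify_architecture(stranger, TRUE)
  expect_equal(res$architecture, "pentapeptide_on_signaling_domain")
})

test_that("classify_receptors drops non-receptors and annotates the rest consistently", {
  proteins <- tibble::tibble(
    protein_id = c("r1", "r2", "d1"),
    proteome_id = "UP1",
    sequence = c(
      paste0(strrep("A", 380), strrep("G", 35), "NWETF"),
      strrep("A", 300),
      strrep("A", 120)
    )
  )
  domains <- rbind(
    dom_row("r1", "PF00015", "MCPsignal", 200, 380),
    dom_row("r1", "PF02203", "TarH", 10, 150),
    dom_row("r2", "PF00015", "MCPsignal", 80, 260),
    dom_row("d1", "PF01590", "GAF", 10, 110)
  )
  tm <- tibble::tibble(protein_id = "r1", start = 5L, end = 25L)
  ann <- classify_receptors(proteins, domains, tm)

  expect_equal(sort(ann$protein_id), c("r1", "r2"))
  expect_true(all(ann$is_chemoreceptor))
  expect_equal(ann$topology[ann$protein_id == "r1"], "transmembrane")
  expect_equal(ann$topology[ann$protein_id == "r2"], "cytosolic")
  expect_equal(ann$lbd_families[ann$protein_id == "r1"][[1]], "TarH")
  expect_equal(ann$linker_length[ann$protein_id == "r1"], 35L)
  # type invariants
  expect_equal(ann$has_pentapeptide, !is.na(ann$pentapeptide))
  expect_equal(
    ann$architecture == "no_pentapeptide", !ann$has_pentapeptide
  )
})

test_that("architecture classes partition any receptor set", {
  b <- get_bundle("small")
  ann <- classify_receptors(b$proteins, b$domains, b$tm)
  arch_counts <- table(ann$architecture)
  expect_equal(sum(arch_counts), nrow(ann))
  expect_equal(
    sum(arch_counts[c(
      "pentapeptide_on_signaling_domain", "pentapeptide_on_cterminal_lbd"
    )], na.rm = TRUE),
    sum(ann$has_pentapeptide)
  )
})
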