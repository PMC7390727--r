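# Shared fixtures, built in code. Bundles are cached per test run so the
# generator executes once per size.

.bundle_cache <- new.env(parent = emptyenv())

# Scaled-down clade configuration (same regimes, ~1/10 of the genomes).
small_clades <- function() {
  lapply(make_paperlike_config(), function(cl) {
    cl$n_genomes <- max(5L, cl$n_genomes %/% 10L)
    cl
  })
}

get_bundle <- function(key = c("small", "paperlike")) {
  key <- match.arg(key)
  if (!exists(key, envir = .bundle_cache)) {
    b <- switch(key,
      small = simulate_proteomes(clades = small_clades(), seed = 7),
      paperlike = simulate_proteomes(seed = 1)
    )
    assign(key, b, envir = .bundle_cache)
  }
  get(key, envir = .bundle_cache)
}

receptor_truth <- function(bundle) {
  bundle$ground_truth[bundle$ground_truth$is_chemoreceptor, ]
}

# Independent regular-expression oracle for the C-terminal motif.
motif_oracle <- function(sequence) {
  grepl(".[FWY]..[FWY]$", sequence)
}

# Random sequences over an alphabet including ambiguity codes.
random_sequences <- function(n, min_len = 0, max_len = 50) {
  len <- sample(min_len:max_len, n, replace = TRUE)
  stringi::stri_rand_strings(n, len, pattern = "[ACDEFGHIKLMNPQRSTVWYBJOUXZ]")
}

# Direct two-pass Pearson correlation (oracle independent of stats::cor).
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

write_native_domains <- function(rows, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(rows, path, progress = FALSE)
  path
}

# Assemble an hmmscan --domtblout text for the same hits (env coords carry
# the start/end; accessions get a fake version suffix).
write_domtblout <- function(rows, path = tempfile(fileext = ".txt")) {
  lines <- c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    sprintf(
      "%-20s %s.%d %5d %-20s - %6d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f some description text",
      rows$family_label, rows$family_accession, 22L, 200L,
      rows$protein_id, 600L, rows$evalue, 120.5, 0.1, 1L, 1L,
      rows$evalue, rows$evalue, 119.0, 0.1, 1L, 178L,
      rows$start + 1L, rows$end - 1L, rows$start, rows$end, 0.98
    ),
    "#"
  )
  writeLines(lines, path)
  path
}

# A hand-sized annotation table for census unit tests.
toy_annotations <- function() {
  tibble::tibble(
    protein_id = paste0("p", 1:8),
    proteome_id = c("UP1", "UP1", "UP1", "UP2", "UP2", "UP3", "UP3", "UP3"),
    is_chemoreceptor = TRUE,
    has_pentapeptide = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
    pentapeptide = ifelse(
      c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE), "NWETF", NA
    ),
    topology = c(
      "transmembrane", "transmembrane", "cytosolic", "cytosolic",
      "transmembrane", "cytosolic", "transmembrane", "transmembrane"
    ),
    lbd_families = list(
      "TarH", c("GAF", "PAS_3"), character(), "TarH",
      "CZB", character(), "dCache_1", "TarH"
    ),
    architecture = ifelse(
      c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
      "pentapeptide_on_signaling_domain", "no_pentapeptide"
    )
  )
}

toy_metadata <- function() {
  tibble::tibble(
    proteome_id = c("UP1", "UP2", "UP3"),
    superkingdom = "Bacteria",
    phylum = c("Proteobacteria", "Proteobacteria", "Firmicutes"),
    class = c("Gammaproteobacteria", "Alphaproteobacteria", "Bacilli"),
    order = c("Enterobacterales", "Rhizobiales", "Bacillales"),
    family = c("Enterobacteriaceae", "unclassified", "Bacillaceae"),
    genus = "unclassified",
    species = "unclassified"
  )
}
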