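---
title: "The pentapeptide census: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pentapeptide census: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentacensus)
```

## The procedure

`pentacensus` implements a census of chemoreceptors that carry the
C-terminal CheR/CheB-binding pentapeptide. The pipeline has four stages,
each a plain function over tibbles:

1. **Scan.** A chemoreceptor's C-terminus is tested against the pattern
   `xZxxZ` with `Z ∈ {F, W, Y}`: of the last five residues, positions 2
   and 5 must be literal aromatics; the `x` positions accept anything,
   including ambiguity codes. No constraint is placed on the linker
   sequence or its length — the motif alone decides. The assumption
   behind scanning only the extreme C-terminus is that the docking site
   functions there; internal `xZxxZ` occurrences are never counted.
2. **Classify.** A protein is a chemoreceptor iff it has an MCPsignal
   (PF00015) domain hit — annotation is trusted, no HMM search is run.
   Topology is transmembrane iff at least one TM region is annotated
   (any TM row counts as evidence; predicted and experimental regions are
   not distinguished, since annotation sources rarely say which they
   are). Sensor families come from an 18-family Pfam catalogue of the
   most abundant chemoreceptor ligand-binding domains; a receptor may
   carry several and is counted in each. Architecture — whether the
   pentapeptide is fused to the signaling domain or to a sensor domain
   C-terminal to it — is decided from domain coordinates only, never from
   sequence content, which keeps the stage testable against synthetic
   annotations.
3. **Census.** For any stratum, abundance is the percentage of receptors
   in the stratum that carry the pentapeptide. All aggregations are
   receptor-level (pooled), not genome-level averages; a stratum with
   zero receptors is never emitted, so abundance is always defined.
4. **Motif.** The pentapeptides are summarised as a 5 × 20 position
   weight matrix. Because every pentapeptide has exactly five residues,
   the multiple alignment underlying the matrix is the identity map and
   needs no aligner; the logo is computed in-package rather than through
   an external profile-HMM toolchain, preserving exactly the information
   a logo renderer needs.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `pseudocount` | `build_pwm()` | 0.5 | Jeffreys-style additive smoothing: keeps unobserved residues at small nonzero frequency without distorting populated columns. Frequencies are `(count + pc) / (n + 20·pc)`. |
| `small_sample_correction` | `build_pwm()` | off | Miller–Madow entropy correction `(20−1)/(2 ln2 · n)` bits. At the census scale (n in the thousands) it is negligible; exposed for small sets. |
| `max_evalue` | `read_domain_table()` | none | Domain rows are **not** e-value filtered by default — the census trusts its annotation source; the knob exists for raw `hmmscan` output. |
| `min_genomes` | `abundance_vs_receptor_count()` | 1 | Minimum genomes supporting a receptor-count value before it becomes a trend point. |
| `cap_quantile` | `abundance_vs_receptor_count()` | 0.995 | Genomes above this quantile of receptor counts are dropped from the trend so a handful of extreme genomes cannot dominate the count axis (99.5% of bacterial genomes carry fewer than 60 chemoreceptor genes). |
| `method` | `abundance_vs_receptor_count()` | `"pooled"` | The y value per count is pooled abundance (Σ pentapeptide / Σ receptors). Pooling matches the receptor-level abundance definition used everywhere else; `"mean"` (average of per-genome ratios) is available since both readings of a per-genome abundance plot are defensible. |
| `drop_unassigned` | `abundance_by_habitat()` | `TRUE` | Habitat databases cover only a subset of strains; pooling uncovered strains into "unclassified" would swamp the table. Configurable. |
| `linker_mean`, `linker_sd` | `simulate_proteomes()` | 35, 5 | The unstructured Tar/Tsr linker is about 35 residues; lengths are rounded normals floored at 8. |

Coordinates are 1-based inclusive throughout (the Pfam/HMMER convention);
conversion happens nowhere. For `hmmscan --domtblout` input the envelope
coordinates are used, HMMER's own recommended estimate of the region a
domain occupies, and accession version suffixes are stripped.

## Numerical choices and degenerate inputs

* Sequences shorter than five residues never match the motif (no error).
  Ambiguity codes (B, J, O, U, X, Z) are retained at parse time; they
  match `x` positions but never the constrained aromatic positions —
  conservative, so ambiguous translations cannot inflate counts. At the
  PWM stage, peptides containing non-standard letters are dropped with a
  logged count; in `net_charge()` non-standard letters count as zero
  charge with a warning. Histidine is counted neutral (pH-dependent
  protonation is out of scope).
* Consensus ties break alphabetically, with a message.
* When several MCPsignal hits exist, the most C-terminal one anchors the
  architecture decision — the signaling domain relevant to pentapeptide
  fusion is the one nearest the C-terminus. An LBD hit overlapping that
  anchor counts as C-terminal only if its midpoint lies beyond the
  anchor's midpoint; such overlaps are logged as ambiguous. Non-catalogue
  Pfam hits are ignored for architecture.
* A linker length that comes out negative (domain annotation overlapping
  the pentapeptide) is returned as `NA` with a warning rather than
  clamped.
* `genome_summary()` uses the sample (n − 1) standard deviation; with one
  genome the sd is `NA`, with none it errors. `pearson_r()` errors on
  constant input instead of silently returning `NA`; the trend object
  reports an absent correlation (`NA`) when fewer than two points remain
  or either coordinate is constant.
* Abundance tables print with two decimals in `write_census()`.

## What the generator emulates — and what it does not

`simulate_proteomes()` produces a fully self-consistent bundle (FASTA,
domain, TM, metadata and habitat tables) with exact per-protein ground
truth:

* **Clade structure.** Each `clade_spec()` fixes a lineage, a pentapeptide
  probability, a sensor-family mix, a topology fraction and optional
  habitat categories. The shipped `make_paperlike_config()` spans ten
  clades from high-abundance (~35–40%) through mid (~20%) to low
  (~0.2–3%) pentapeptide regimes, receptor-weighted mean receptor count
  ≈ 13.7 per genome.
* **Overdispersed receptor counts.** Counts are negative binomial
  (dispersion ≈ 1.2–2, i.e. variance of the order of the squared mean),
  zero-truncated because every simulated genome is by construction
  chemoreceptor-containing. Truncation shifts the realised mean to
  `μ / (1 − P(X = 0))`; the generator's law-of-large-numbers test checks
  against that analytic truncated mean.
* **The negative abundance-count trend.** In the shipped configuration
  the trend arises *between* clades: high-probability clades are given
  low receptor-count means and the ~1%-probability clades high means, so
  pooled abundance falls with receptor count while each clade's expected
  abundance remains exactly its configured probability. A per-clade
  `pentapeptide_slope` additionally allows count-dependent probabilities
  within a clade.
* **Sequence content.** Background residues are uniform over the 20
  standard letters, making the motif's false-positive rate exactly
  (3/20)² — a useful analytic check. Pentapeptides are drawn from a
  configurable 5 × 20 letter distribution whose constrained positions
  must put all mass on F/W/Y (anything else is rejected, since it would
  corrupt the ground truth); receptors drawn without a pentapeptide get a
  C-terminus rejection-sampled to never match.
* **Noise-free annotation.** Domain and TM rows are exact: the census
  trusts its annotation source, so annotation error is out of scope. A
  `domain_dropout` hook removes a fraction of non-defining domain rows
  for robustness experiments.

What passing the round-trip tests therefore shows: the scan,
classification and aggregation stages are mutually consistent and
calibrated under known truth. What it does **not** show: robustness to
annotation error, compositional bias, phylogenetic correlation between
related genomes, or archaeal contamination — real-data features the
generator deliberately omits.

## Problem sizes

The validation suite runs the generator at about 2,000 genomes
(~28,000 receptors) for the round-trip, calibration and conservation
checks, 10⁵ random sequences against an independent regular-expression
oracle for the motif matcher, 10⁶ uniform 5-mers for the analytic
false-positive rate, and 5,000 sampled pentapeptides for PWM recovery —
sizes at which every binomial check has comfortable power while the whole
suite stays fast on a single CPU.

## Known limitations

* The chemoreceptor definition is purely annotation-driven (PF00015);
  proteins missing that annotation are invisible to the census.
* Habitat assignments are taken as given and multi-valued; no attempt is
  made to resolve a preferred habitat per strain.
* The logo uses information-content stack heights (recorded in the output
  metadata); frequency-height logos can be built from the same
  `logo_table()` but are not the default.
* Taxonomic aggregation supports superkingdom through family; genus- and
  species-level strata are deliberately rejected as too sparse for
  abundance percentages to be meaningful.
* No significance testing of abundance differences is performed, and no
  figures beyond the provided `autoplot`/`plot_*` helpers.
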