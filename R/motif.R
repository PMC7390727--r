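#' Build a position weight matrix from pentapeptides
#'
#' Tallies residue counts at each of the five pentapeptide positions over
#' the standard 20-letter alphabet, derives frequencies with an additive
#' pseudocount — `(count + pseudocount) / (n + 20 * pseudocount)` — and the
#' per-position information content in bits, `IC[i] = log2(20) - H(column
#' i)` with `H` the Shannon entropy of the frequency column. Since every
#' pentapeptide has exactly five residues, the underlying multiple
#' alignment is the identity map and needs no aligner. Peptides containing
#' non-standard letters are dropped with a message.
#'
#' @param pentapeptides Character vector of 5-mers.
#' @param pseudocount Non-negative additive pseudocount; the default 0.5 is
#'   the Jeffreys-style choice that keeps rare residues visible without
#'   distorting well-populated columns.
#' @param small_sample_correction Apply the Miller–Madow correction
#'   `(20 - 1) / (2 ln(2) n)` bits to the entropy (subtracting it from IC,
#'   clamped at 0)? Off by default: the census operates at n in the
#'   thousands, where the correction is negligible.
#' @return An object of class `penta_pwm`: list with `counts` (5 x 20
#'   integer matrix), `pseudocount`, `frequencies` (5 x 20, rows sum to 1),
#'   `information_content` (length-5, bits), `n` (peptides used),
#'   `n_dropped`.
#' @examples
#' pwm <- build_pwm(rep("NWETF", 10), pseudocount = 0)
#' pwm$information_content
#' @export
build_pwm <- function(pentapeptides, pseudocount = 0.5,
                      small_sample_correction = FALSE) {
  stopifnot(is.character(pentapeptides), pseudocount >= 0)
  pentapeptides <- pentapeptides[!is.na(pentapeptides)]
  if (length(pentapeptides) == 0) abort("No pentapeptides supplied")
  if (any(nchar(pentapeptides) != 5)) {
    abort("All pentapeptides must have exactly 5 residues")
  }
  letters5 <- matrix(
    unlist(strsplit(pentapeptides, "", fixed = TRUE), use.names = FALSE),
    ncol = 5, byrow = TRUE
  )
  standard <- rowSums(matrix(letters5 %in% AA_STANDARD, ncol = 5)) == 5
  if (any(!standard)) {
    inform(paste0(
      sum(!standard), " pentapeptide(s) with non-standard letters dropped"
    ))
    letters5 <- letters5[standard, , drop = FALSE]
  }
  n <- nrow(letters5)
  if (n == 0) abort("No pentapeptides left after filtering")
  counts <- vapply(
    seq_len(5),
    function(i) table(factor(letters5[, i], levels = AA_STANDARD)),
    integer(20)
  )
  counts <- t(counts) # 5 x 20
  dimnames(counts) <- list(position = 1:5, residue = AA_STANDARD)
  freqs <- (counts + pseudocount) / (n + 20 * pseudocount)
  entropy <- apply(freqs, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  if (small_sample_correction) {
    entropy <- entropy + (20 - 1) / (2 * log(2) * n)
  }
  ic <- pmax(0, pmin(log2(20), log2(20) - entropy))
  structure(
    list(
      counts = counts, pseudocount = pseudocount, frequencies = freqs,
      information_content = unname(ic), n = n,
      n_dropped = sum(!standard)
    ),
    class = "penta_pwm"
  )
}

#' Consensus pentapeptide of a PWM
#'
#' The modal residue at each position; ties are broken alphabetically, with
#' a message noting the tie.
#'
#' @param pwm A `penta_pwm` from [build_pwm()].
#' @return A 5-character string.
#' @export
consensus_string <- function(pwm) {
  stopifnot(inherits(pwm, "penta_pwm"))
  picks <- apply(pwm$frequencies, 1, function(p) {
    top <- names(p)[p == max(p)]
    if (length(top) > 1) {
      inform(paste0(
        "Consensus tie between ", paste(top, collapse = "/"),
        "; broken alphabetically"
      ))
    }
    sort(top)[1]
  })
  paste(picks, collapse = "")
}

#' Net charge of a pentapeptide
#'
#' Counts basic minus acidic residues: `(#K + #R) - (#D + #E)`. Histidine
#' is counted as neutral (pH-dependent protonation is out of scope), as is
#' any non-standard letter (with a warning).
#'
#' @param pentapeptide Character vector of 5-mers.
#' @return Integer vector of net charges.
#' @examples
#' net_charge(c("NWETF", "KWKRF", "DWEDF"))
#' @export
net_charge <- function(pentapeptide) {
  stopifnot(is.character(pentapeptide))
  if (any(nchar(pentapeptide) != 5, na.rm = TRUE)) {
    abort("net_charge() expects 5-residue peptides")
  }
  nonstd <- stringr::str_detect(
    pentapeptide, paste0("[^", paste(AA_STANDARD, collapse = ""), "]")
  )
  if (any(nonstd, na.rm = TRUE)) {
    warn(paste0(
      sum(nonstd, na.rm = TRUE),
      " peptide(s) contain non-standard letters; those letters count as 0"
    ))
  }
  pos <- stringr::str_count(pentapeptide, "[KR]")
  neg <- stringr::str_count(pentapeptide, "[DE]")
  as.integer(pos - neg)
}

#' Charge summary over a pentapeptide set
#'
#' Per-peptide net charges plus their mean and the fraction that is net
#' negative (charge strictly below zero).
#'
#' @param pentapeptides Non-empty character vector of 5-mers.
#' @return A list with `per_peptide_charge` (tibble `pentapeptide`,
#'   `charge`), `mean_charge`, `fraction_net_negative`.
#' @export
charge_summary <- function(pentapeptides) {
  pentapeptides <- pentapeptides[!is.na(pentapeptides)]
  if (length(pentapeptides) == 0) abort("charge_summary() needs peptides")
  ch <- net_charge(pentapeptides)
  list(
    per_peptide_charge = tibble(pentapeptide = pentapeptides, charge = ch),
    mean_charge = mean(ch),
    fraction_net_negative = mean(ch < 0)
  )
}

#' Logo table of a PWM
#'
#' One row per (position, residue) with the letter's stack height in an
#' information-content sequence logo: `frequency x IC[position]`, so the
#' heights at a position sum to that position's information content.
#'
#' @param pwm A `penta_pwm`.
#' @return A tibble with columns `position`, `residue`, `frequency`,
#'   `stack_height`.
#' @export
logo_table <- function(pwm) {
  stopifnot(inherits(pwm, "penta_pwm"))
  tibble(
    position = rep(1:5, each = 20),
    residue = rep(AA_STANDARD, times = 5),
    frequency = as.vector(t(pwm$frequencies)),
    stack_height = as.vector(t(pwm$frequencies)) *
      rep(pwm$information_content, each = 20)
  )
}

#' Export the logo table as TSV
#'
#' Writes `(position, residue, stack_height)` rows consumable by any logo
#' renderer, heights on the information-content rule.
#'
#' @param pwm A `penta_pwm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_logo_table <- function(pwm, path) {
  readr::write_tsv(
    logo_table(pwm)[c("position", "residue", "stack_height")],
    path,
    progress = FALSE
  )
  invisible(path)
}

#' @export
print.penta_pwm <- function(x, ...) {
  cat(
    "Pentapeptide position weight matrix (n = ", x$n,
    ", pseudocount = ", x$pseudocount, ")\n",
    "consensus: ", suppressMessages(consensus_string(x)), "\n",
    "information content (bits): ",
    paste(sprintf("%.2f", x$information_content), collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a PWM into long form
#'
#' @param x A `penta_pwm`.
#' @param ... Unused.
#' @return A tibble with one row per (position, residue): `position`,
#'   `residue`, `count`, `frequency`, `information_content`,
#'   `stack_height`.
#' @export
tidy.penta_pwm <- function(x, ...) {
  logo_table(x) |>
    mutate(
      count = as.vector(t(x$counts)),
      information_content = rep(x$information_content, each = 20)
    ) |>
    select(
      "position", "residue", "count", "frequency",
      "information_content", "stack_height"
    )
}

#' One-row summary of a PWM
#'
#' @param x A `penta_pwm`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_dropped`, `pseudocount`, `consensus`,
#'   `total_information_content`.
#' @export
glance.penta_pwm <- function(x, ...) {
  tibble(
    n = x$n,
    n_dropped = x$n_dropped,
    pseudocount = x$pseudocount,
    consensus = suppressMessages(consensus_string(x)),
    total_information_content = sum(x$information_content)
  )
}
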