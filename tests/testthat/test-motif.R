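test_that("build_pwm tallies counts, frequencies and information content", {
  pwm <- build_pwm(rep("NWETF", 100), pseudocount = 0)
  expect_equal(pwm$n, 100)
  expect_equal(pwm$counts[2, "W"], c(W = 100L), ignore_attr = TRUE)
  expect_equal(pwm$frequencies[2, "W"], c(W = 1), ignore_attr = TRUE)
  expect_equal(pwm$information_content[2], log2(20))
  expect_equal(unname(rowSums(pwm$frequencies)), rep(1, 5), tolerance = 1e-9)

  # uniform column: every residue once at position 1 -> zero information
  uni <- build_pwm(paste0(AA_STANDARD, "WAAF"), pseudocount = 0)
  expect_equal(uni$information_content[1], 0)
  expect_true(all(uni$information_content >= 0 &
    uni$information_content <= log2(20) + 1e-12))

  mix <- build_pwm(c(rep("NWETF", 50), rep("DWDDF", 50)), pseudocount = 0)
  expect_equal(mix$frequencies[2, "W"], c(W = 1), ignore_attr = TRUE)
  expect_equal(mix$frequencies[1, "N"], c(N = 0.5), ignore_attr = TRUE)
  expect_equal(mix$frequencies[1, "D"], c(D = 0.5), ignore_attr = TRUE)
})

test_that("pseudocounts enter frequencies as (count + pc) / (n + 20 pc)", {
  pwm <- build_pwm(rep("NWETF", 10), pseudocount = 0.5)
  expect_equal(
    pwm$frequencies[2, "W"], c(W = 10.5 / 20), ignore_attr = TRUE
  )
  expect_equal(
    pwm$frequencies[2, "A"], c(A = 0.5 / 20), ignore_attr = TRUE
  )
  expect_equal(unname(rowSums(pwm$frequencies)), rep(1, 5), tolerance = 1e-9)
})

test_that("peptides with non-standard letters are dropped with a note", {
  expect_message(
    pwm <- build_pwm(c("NWETF", "NWXTF", "AWAAY"), pseudocount = 0),
    "1 pentapeptide"
  )
  expect_equal(pwm$n, 2)
  expect_equal(pwm$n_dropped, 1)
  expect_error(build_pwm(character()), "No pentapeptides")
  expect_error(suppressMessages(build_pwm("NWXTF")), "No pentapeptides")
  expect_error(build_pwm("NWET"), "exactly 5")
})

test_that("consensus takes the modal residue, breaking ties alphabetically", {
  expect_equal(
    consensus_string(build_pwm(rep("NWETF", 5), pseudocount = 0)), "NWETF"
  )
  uniform <- build_pwm(
    vapply(AA_STANDARD, function(a) strrep(a, 5), character(1)),
    pseudocount = 0
  )
  expect_message(cons <- consensus_string(uniform), "tie")
  expect_equal(cons, "AAAAA")
})

test_that("net charge counts basics minus acidics, histidine and non-standard neutral", {
  expect_equal(net_charge("NWETF"), -1L)
  expect_equal(net_charge("KWKRF"), 3L)
  expect_equal(net_charge("DWEDF"), -3L)
  expect_equal(net_charge("HWHHF"), 0L)
  expect_warning(expect_equal(net_charge("XWKRF"), 2L), "non-standard")
  expect_error(net_charge("NWET"), "5-residue")
  # permutation invariance
  withr::local_seed(105)
  for (i in 1:20) {
    p <- paste(sample(AA_STANDARD, 5, replace = TRUE), collapse = "")
    q <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
    expect_equal(net_charge(p), net_charge(q))
  }
})

test_that("charge_summary reports mean charge and the net-negative fraction", {
  cs <- charge_summary(c("NWETF", "DWEDF"))
  expect_equal(cs$mean_charge, -2)
  expect_equal(cs$fraction_net_negative, 1)
  expect_equal(cs$per_peptide_charge$charge, c(-1L, -3L))
  expect_equal(charge_summary("KWKRF")$fraction_net_negative, 0)
  expect_equal(charge_summary("NWATF")$fraction_net_negative, 0) # zero not negative
  expect_error(charge_summary(character()), "needs peptides")
})

test_that("logo heights are frequency times IC and sum to IC per position", {
  pwm <- build_pwm(rep("NWETF", 20), pseudocount = 0)
  lt <- logo_table(pwm)
  expect_equal(
    lt$stack_height[lt$position == 2 & lt$residue == "W"],
    log2(20)
  )
  sums <- tapply(lt$stack_height, lt$position, sum)
  expect_equal(as.numeric(sums), pwm$information_content, tolerance = 1e-9)

  mixed <- build_pwm(
    c(rep("NWETF", 30), rep("DWDDY", 10), rep("AFAAW", 5)),
    pseudocount = 0.5
  )
  lt <- logo_table(mixed)
  sums <- tapply(lt$stack_height, lt$position, sum)
  expect_equal(as.numeric(sums), mixed$information_content, tolerance = 1e-9)

  path <- withr::local_tempfile(fileext = ".tsv")
  export_logo_table(mixed, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back), c("position", "residue", "stack_height"))
  expect_equal(nrow(back), 100)
})

test_that("the small-sample entropy correction lowers IC and vanishes at large n", {
  peps <- c(rep("NWETF", 8), rep("DWDTF", 2))
  raw <- build_pwm(peps, pseudocount = 0)
  corr <- build_pwm(peps, pseudocount = 0, small_sample_correction = TRUE)
  expect_true(all(corr$information_content <= raw$information_content + 1e-12))
  big <- build_pwm(rep(peps, 500), pseudocount = 0)
  bigc <- build_pwm(rep(peps, 500), pseudocount = 0, small_sample_correction = TRUE)
  expect_equal(
    big$information_content, bigc$information_content,
    tolerance = 1e-2
  )
})

test_that("tidy and glance expose the PWM in broom style", {
  pwm <- build_pwm(c(rep("NWETF", 6), rep("DWETF", 4)), pseudocount = 0)
  td <- tidy(pwm)
  expect_equal(nrow(td), 100)
  expect_equal(
    names(td),
    c("position", "residue", "count", "frequency", "information_content", "stack_height")
  )
  expect_equal(sum(td$count), 50)
  gl <- glance(pwm)
  expect_equal(gl$n, 10)
  expect_equal(gl$consensus, "NWETF")
})

test_that("PWM recovery: sampled frequencies match the generating table", {
  withr::local_seed(106)
  gen <- default_pentapeptide_pwm()
  n <- 2000
  peps <- pentacensus:::sample_pentapeptides(n, gen)
  est <- build_pwm(peps, pseudocount = 0)
  se <- sqrt(gen * (1 - gen) / n)
  ok <- abs(est$frequencies - gen) <= 3 * se + 1e-12
  expect_gte(mean(ok), 0.99)
  cons <- suppressMessages(consensus_string(est))
  expect_equal(substr(cons, 2, 2), "W")
  expect_equal(substr(cons, 5, 5), "F")
})
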