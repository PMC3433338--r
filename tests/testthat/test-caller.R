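exon21 <- builtin_assays()[["EGFR_exon21"]]
braf <- builtin_assays()[["BRAF_codon600"]]
kras <- builtin_assays()[["KRAS_codon12_13"]]

test_that("the L858R quantification formula matches its algebra", {
  expect_equal(quant_l858r(A = 0, B = 1, C = 1, D = 2, E = 2), 0)
  expect_equal(quant_l858r(A = 3, B = 1, C = 0, D = 0, E = 2), 100)
  expect_equal(quant_l858r(A = 330, B = 200, C = 90, D = 180, E = 400), 55)
  # output clipped to [0, 100]
  expect_equal(quant_l858r(A = 0, B = 1, C = 2, D = 4, E = 2), 0)
  expect_error(quant_l858r(1, 0, 1, 1, 1), class = "pyromut_invalid_input")
  expect_error(quant_l858r(1, 1, 1, 1, 0), class = "pyromut_invalid_input")
})

test_that("fit_candidate recovers noiseless mixture fractions", {
  h <- c(0, 1, 0, 0.5, 0.5, 0, 1, 1, 1, 1, 1, 1)
  fit <- fit_candidate(h, braf, "V600E")
  expect_equal(fit$fraction, 0.5)
  expect_equal(fit$rms_residual, 0)
  # pure wildtype against any variant
  wt <- simulate_pyrogram(exon21$wildtype, 1, exon21$order)
  for (v in names(exon21$variants))
    expect_equal(fit_candidate(wt, exon21, v)$fraction, 0)
})

test_that("fit_candidate rejects a pattern-degenerate variant", {
  a <- pyro_assay("toy", target = "ACGT", order = "AC",
                  variants = list(pyro_variant("X", "substitution",
                                               pos = 4, bases = "G")))
  expect_error(fit_candidate(c(1, 1), a, "X"),
               class = "pyromut_undefined_fraction")
})

test_that("fraction estimates outside [0,1] are clipped and flagged", {
  wt <- simulate_pyrogram(exon21$wildtype, 1, exon21$order)
  mut <- simulate_pyrogram(apply_variant(exon21, "L858R"), 1, exon21$order)
  over <- wt + 1.4 * (mut - wt)  # beyond the pure-mutant pattern
  fit <- fit_candidate(over, exon21, "L858R")
  expect_equal(fit$fraction, 1)
  expect_gt(fit$fraction_raw, 1)
  expect_true(fit$clipped)
})

test_that("closed-form fit agrees with a 1e-4 grid-search oracle on noisy data", {
  set.seed(2024)
  pat <- assay_patterns(exon21)
  for (i in 1:25) {
    v <- sample(names(exon21$variants), 1)
    f <- runif(1)
    h <- (1 - f) * pat[, "wildtype"] + f * pat[, v] + rnorm(nrow(pat), 0, 0.05)
    h <- pmax(h, 0)
    fit <- fit_candidate(h, exon21, v)
    expect_lt(abs(fit$fraction -
                    oracle_grid_fit(h, pat[, "wildtype"], pat[, v])), 1e-4)
  }
})

test_that("the printed formula, the 1-D fit and the ranked fit agree on ideal exon-21 mixtures", {
  pat <- assay_patterns(exon21)
  for (f in seq(0, 1, by = 0.1)) {
    p <- noiseless_pyrogram(exon21, "L858R", fraction = f, scale = 200)
    h <- p$height
    pct <- quant_l858r(A = h[3], B = mean(h[c(2, 9, 11, 12, 14)]),
                       C = h[4], D = h[5], E = h[7])
    expect_equal(pct, 100 * f, tolerance = 1e-9)
    norm <- h / mean(h[c(2, 9, 11, 12, 14)])
    expect_equal(fit_candidate(norm, exon21, "L858R")$fraction, f,
                 tolerance = 1e-9)
    expect_equal(call_pyrogram(p, exon21)$best$fraction, f, tolerance = 1e-9)
  }
})

test_that("candidate ranking identifies noiseless mixtures", {
  fits <- rank_candidates(noiseless_pyrogram(exon21, "L858R", 0.30)$height / 100,
                          exon21)
  expect_identical(fits[[1]]$variant, "L858R")
  expect_equal(fits[[1]]$fraction, 0.30)
  expect_false(attr(fits, "ambiguous"))

  fits <- rank_candidates(noiseless_pyrogram(braf, "V600K", 0.20)$height / 100,
                          braf)
  expect_identical(fits[[1]]$variant, "V600K")
  expect_equal(fits[[1]]$fraction, 0.20)

  # pure wildtype: every candidate fits exactly with fraction 0, ambiguous
  fits <- rank_candidates(simulate_pyrogram(braf$wildtype, 1, braf$order), braf)
  expect_true(all(vapply(fits, function(f) f$fraction, 1) == 0))
  expect_true(all(vapply(fits, function(f) f$rms_residual, 1) < 1e-12))
  expect_true(attr(fits, "ambiguous"))
})

test_that("the V600K discriminator applies the B - 2*SD rule", {
  # noiseless 30% V600K mixture; reference SD as if sigma = 0.02*B
  p <- noiseless_pyrogram(braf, "V600K", fraction = 0.30, scale = 100)
  rs <- reference_stats(p, braf$reference_positions)
  rs$SD <- 0.02 * rs$B
  expect_equal(p$height[7] / rs$B, 0.70)
  expect_true(v600k_discriminator(p, rs))
  # pure V600E keeps dispensations 7 and 8 at B
  pe <- noiseless_pyrogram(braf, "V600E", fraction = 1, scale = 100)
  rse <- reference_stats(pe, braf$reference_positions)
  rse$SD <- 0.02 * rse$B
  expect_false(v600k_discriminator(pe, rse))
  # pure wildtype has no dispensation-4 T signal
  pw <- noiseless_pyrogram(braf, scale = 100)
  expect_false(v600k_discriminator(pw, reference_stats(pw, c(9, 10, 12))))
})

test_that("the 5% rule is strict: 6% is called, 4% is not", {
  p6 <- noiseless_pyrogram(exon21, "L858R", fraction = 0.06)
  r6 <- call_pyrogram(p6, exon21)
  expect_identical(r6$call, "mutation_detected")
  expect_identical(r6$variant, "L858R")
  p4 <- noiseless_pyrogram(exon21, "L858R", fraction = 0.04)
  r4 <- call_pyrogram(p4, exon21)
  expect_identical(r4$call, "wildtype")
  expect_null(r4$variant)
  expect_equal(r4$mutant_percent, 4, tolerance = 1e-9)
  # equality is not called
  p5 <- noiseless_pyrogram(exon21, "L858R", fraction = 0.05)
  expect_identical(call_pyrogram(p5, exon21)$call, "wildtype")
})

test_that("the specified noiseless KRAS pyrogram is called G12C at 47%", {
  h <- c(0, 0, 40.89, 133.11, 87, 0, 0, 174, 0, 0, 0, 0,
         87, 87, 87, 87, 174, 87, 0, 0, 0, 0, 0)
  r <- call_pyrogram(pyrogram(h, kras), kras)
  expect_identical(r$call, "mutation_detected")
  expect_identical(r$variant, "G12C")
  expect_equal(r$mutant_percent, 47, tolerance = 1e-9)
  expect_equal(r$qc$reference$B, 87)
})

test_that("unanalyzable and unexplainable pyrograms are reported as such", {
  expect_error(call_pyrogram(pyrogram(rep(0, 14), exon21), exon21),
               class = "pyromut_degenerate_signal")
  # flat signal: unlike wildtype and unlike any catalog mixture
  expect_identical(call_pyrogram(pyrogram(rep(100, 14), exon21), exon21)$call,
                   "indeterminate")
  expect_error(call_pyrogram(pyrogram(rep(1, 12), braf), exon21),
               class = "pyromut_invalid_input")
})

test_that("noiseless exact recovery holds across assays on a fraction grid", {
  for (nm in c("EGFR_exon19_del", "KRAS_codon61", "BRAF_codon600")) {
    a <- builtin_assays()[[nm]]
    for (vid in names(a$variants)) for (f in c(0.05, 0.30, 0.80)) {
      r <- call_pyrogram(noiseless_pyrogram(a, vid, fraction = f, scale = 77), a)
      expect_identical(r$best$variant, vid)
      expect_equal(r$best$fraction, f, tolerance = 1e-9)
    }
  }
})

test_that("call objects support the standard modelling methods", {
  p <- synth_pyrogram(exon21, "L858R", fraction = 0.55, scale = 200,
                      noise_sd = 0.02, nonspecific = c(0.01, 0.03), seed = 9)
  r <- call_pyrogram(p, exon21)
  expect_s3_class(r, "pyro_call")
  expect_output(print(r), "mutation detected \\(L858R\\)")
  expect_output(summary(r), "Candidates")
  expect_named(coef(r), c("mutant_fraction", "scale"))
  expect_equal(coef(r)[["mutant_fraction"]], 0.55, tolerance = 0.05)
  expect_length(fitted(r), 14L)
  expect_equal(residuals(r), p$height - fitted(r))
  expect_equal(predict(r, fraction = 0, scale = 1),
               simulate_pyrogram(exon21$wildtype, 1, exon21$order))
  sims <- simulate(r, nsim = 2, seed = 4)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "pyrogram")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(r))
})
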