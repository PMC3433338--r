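#' EGFR exon-21 L858R quantification formula
#'
#' The closed-form mutant-percentage rule for the exon-21 assay,
#' `[1/3 x A/B + (1 - C/B) + (1 - D/E)] / 3 x 100`, where
#' `A` is the mutant-signature G peak (dispensation 3), `B` the average of
#' the single-copy reference peaks (dispensations 2, 9, 11, 12, 14), `C` the
#' T peak (dispensation 4), `D` the G peak (dispensation 5) and `E` the C
#' peak (dispensation 7).  The 1/3 factor reflects the three-base mutant run
#' collapsing into the dispensation-3 G peak.  On ideal data the three terms
#' are each equal to the mutant fraction, and the formula agrees exactly with
#' the general least-squares estimator ([fit_candidate()]).
#'
#' @param A,B,C,D,E Peak heights (any consistent units); `B` and `E` must be
#'   positive.
#' @return Mutant percentage, clipped to `[0, 100]`.
#' @examples
#' quant_l858r(A = 330, B = 200, C = 90, D = 180, E = 400)  # 55
#' @export
quant_l858r <- function(A, B, C, D, E) {
  v <- c(A = A, B = B, C = C, D = D, E = E)
  if (anyNA(v) || any(v < 0)) stop_invalid("peak heights must be non-negative")
  if (B <= 0 || E <= 0) stop_invalid("reference peaks B and E must be positive")
  pct <- ((A / B) / 3 + (1 - C / B) + (1 - D / E)) / 3 * 100
  min(max(pct, 0), 100)
}

rms <- function(x) sqrt(mean(x^2))

#' Fit one mutant-mixture hypothesis to a normalized pyrogram
#'
#' Models the normalized heights as the convex mixture
#' `h_i = (1 - f) * wt_i + f * mut_i` and estimates the mutant fraction `f`
#' by one-dimensional linear least squares (closed form), clipped to
#' `[0, 1]`.  This generalises the per-mutation quantification formulas to
#' any catalog variant.
#'
#' @param norm_heights Numeric vector of per-copy (normalized) heights, one
#'   per dispensation (see [normalize_pyrogram()]).
#' @param assay A `pyro_assay` (or built-in assay name).
#' @param variant A `pyro_variant` or variant id in the assay catalog.
#' @param scale Instrument units per copy used for the normalization
#'   (recorded in the fit; default 1).
#' @return A list of class `pyro_fit`: `variant`, `fraction` (clipped),
#'   `fraction_raw`, `clipped`, `scale`, `rms_residual` (normalized units),
#'   `fitted` (per-copy fitted heights), `wt_pattern`, `mut_pattern`.
#' @examples
#' a <- builtin_assays()[["BRAF_codon600"]]
#' h <- simulate_pyrogram(c(a$wildtype, apply_variant(a, "V600E")),
#'                        c(0.5, 0.5), a$order)
#' fit_candidate(h, a, "V600E")$fraction  # 0.5
#' @export
fit_candidate <- function(norm_heights, assay, variant, scale = 1) {
  assay <- get_assay(assay)
  h <- as_heights(norm_heights)
  if (length(h) != nchar(assay$order))
    stop_invalid("need one height per dispensation of assay '", assay$name, "'")
  if (is.character(variant)) {
    if (!variant %in% names(assay$variants))
      stop_invalid("assay '", assay$name, "' has no variant '", variant, "'")
    variant <- assay$variants[[variant]]
  }
  wt <- incorporation_walk(assay$wildtype, assay$order)
  mut <- incorporation_walk(apply_edit(assay$wildtype, variant), assay$order)
  d <- mut - wt
  if (all(d == 0))
    stop(errorCondition(
      paste0("variant '", variant$id,
             "' has the same expected pattern as wildtype: fraction undefined"),
      class = c("pyromut_undefined_fraction", "pyromut_invalid_input", "error")))
  f_raw <- sum(d * (h - wt)) / sum(d * d)
  f <- min(max(f_raw, 0), 1)
  fitted <- (1 - f) * wt + f * mut
  structure(list(variant = variant$id, fraction = f, fraction_raw = f_raw,
                 clipped = (f != f_raw), scale = scale,
                 rms_residual = rms(h - fitted), fitted = fitted,
                 wt_pattern = wt, mut_pattern = mut),
            class = "pyro_fit")
}

joint_mixture_fit <- function(h, wt, mut, variant_id, denom = NULL) {
  # minimise ||h - u*wt - v*mut||^2 over u, v >= 0; u = s(1-f), v = s*f.
  # Profiling the instrument scale out of each candidate keeps the ranking
  # free of reference-peak calibration noise.
  gww <- sum(wt * wt); gwm <- sum(wt * mut); gmm <- sum(mut * mut)
  det <- gww * gmm - gwm * gwm
  bw <- sum(wt * h); bm <- sum(mut * h)
  if (det <= .Machine$double.eps * gww * gmm) {
    stop(errorCondition(
      paste0("variant '", variant_id,
             "' has the same expected pattern as wildtype: fraction undefined"),
      class = c("pyromut_undefined_fraction", "pyromut_invalid_input", "error")))
  }
  u <- (gmm * bw - gwm * bm) / det
  v <- (gww * bm - gwm * bw) / det
  if (u < 0) { u <- 0; v <- max(0, bm / gmm) }
  if (v < 0) { v <- 0; u <- max(0, bw / gww) }
  s <- u + v
  f <- if (s > 0) v / s else 0
  fitted_raw <- u * wt + v * mut
  denom <- denom %||% (if (s > 0) s else 1)
  structure(list(variant = variant_id, fraction = f, fraction_raw = f,
                 clipped = FALSE, scale = s,
                 rms_residual = rms(h - fitted_raw) / denom,
                 fitted = if (s > 0) fitted_raw / s else fitted_raw,
                 wt_pattern = wt, mut_pattern = mut),
            class = "pyro_fit")
}

#' Rank all catalog variants against a pyrogram
#'
#' Fits every variant in the assay catalog as a wildtype/mutant mixture and
#' orders the fits by ascending root-mean-square residual (ties broken by
#' variant id).  Each candidate is fitted with the instrument scale profiled
#' out: `h ~ u * wt + v * mut` with `u, v >= 0` by closed-form least squares,
#' giving the mutant fraction `f = v / (u + v)` and per-copy scale
#' `s = u + v`.  This reduces exactly to [fit_candidate()] on noiseless
#' normalized data, but keeps candidate ranking independent of
#' reference-peak calibration noise, and automatically re-calibrates
#' candidates that alter a reference peak (e.g. exon-19 deletions).
#'
#' @param pyro A `pyrogram` (raw instrument units) or a normalized numeric
#'   height vector.
#' @param assay A `pyro_assay` or built-in assay name.
#' @param stats Optional `pyro_refstats`; when given, residuals are expressed
#'   in per-copy units of its `B` so they are comparable across candidates
#'   and with the wildtype residual.
#' @param noise Optional `pyro_noise`; flagged peaks are zeroed before
#'   fitting.
#' @param ambiguity_rtol Relative residual difference under which the two
#'   best candidates are flagged ambiguous (default 0.10).
#' @return List of `pyro_fit` objects, ascending by residual, with attribute
#'   `ambiguous` (logical).
#' @export
rank_candidates <- function(pyro, assay, stats = NULL, noise = NULL,
                            ambiguity_rtol = 0.10) {
  assay <- get_assay(assay)
  if (length(assay$variants) == 0L)
    stop_invalid("assay '", assay$name, "' has an empty variant catalog")
  h <- as_heights(pyro)
  if (length(h) != nchar(assay$order))
    stop_invalid("need one height per dispensation of assay '", assay$name, "'")
  if (!is.null(noise)) h[noise$flagged] <- 0
  denom <- if (is.null(stats)) NULL else stats$B
  patterns <- assay_patterns(assay)
  wt <- patterns[, "wildtype"]
  fits <- lapply(names(assay$variants), function(vid)
    joint_mixture_fit(h, wt, patterns[, vid], vid, denom = denom))
  res <- vapply(fits, function(f) f$rms_residual, numeric(1))
  ids <- vapply(fits, function(f) f$variant, character(1))
  fits <- fits[order(res, ids)]
  res <- sort(res)
  ambiguous <- length(fits) > 1L &&
    (res[2] - res[1]) < ambiguity_rtol * max(res[2], .Machine$double.eps)
  structure(fits, ambiguous = ambiguous,
            names = vapply(fits, function(f) f$variant, character(1)))
}

#' BRAF V600K discriminator
#'
#' The V600E and V600K patterns share the mutant T signal at dispensation 4;
#' V600K additionally lowers the wildtype C and T peaks at dispensations 7
#' and 8.  Because that lowering must be separated from normal peak-height
#' variation, the rule compares those peaks against `B - 2 * SD` of the
#' reference peaks (dispensations 9, 10 and 12) rather than a fixed
#' percentage: the discriminator is `TRUE` iff both peaks fall below
#' `B - 2 * SD` (instrument units) while a T signal above the artifact
#' cutoff is present at dispensation 4.
#'
#' @param pyro A `pyrogram` (or raw height vector) in instrument units.
#' @param stats `pyro_refstats` computed from the BRAF reference
#'   dispensations `{9, 10, 12}`.
#' @param noise Optional `pyro_noise`; its cutoff qualifies the
#'   dispensation-4 T signal (0 when absent).
#' @param low_positions Dispensations that V600K lowers (default `c(7, 8)`).
#' @param mutant_position Dispensation of the mutant T signal (default 4).
#' @return Logical.
#' @export
v600k_discriminator <- function(pyro, stats, noise = NULL,
                                low_positions = c(7, 8), mutant_position = 4) {
  h <- as_heights(pyro)
  if (!inherits(stats, "pyro_refstats"))
    stop_invalid("stats must come from reference_stats()")
  cutoff <- if (is.null(noise)) 0 else noise$cutoff
  lowered <- all(h[low_positions] < stats$B - 2 * stats$SD)
  mutant_signal <- h[mutant_position] > cutoff && h[mutant_position] > 0
  isTRUE(lowered && mutant_signal)
}

#' Analyse a pyrogram: recognise and quantify a hotspot mutation
#'
#' The full calling pipeline.  Non-specific peaks are flagged with the
#' unexpected-position artifact cutoff; the reference peaks calibrate the
#' per-copy scale `B`; every catalog variant is fitted by least-squares
#' mixture deconvolution and ranked by residual; for the BRAF assay the
#' V600K discriminator resolves the V600E/V600K choice; and the mutant
#' percentage of the best candidate is compared against the calling
#' threshold: strictly above it the specimen is called
#' `"mutation_detected"`, otherwise `"wildtype"`.  A pyrogram explained by
#' the wildtype pattern at least as well as by any candidate (within
#' `wildtype_residual_tol`) is called wildtype; one explained by nothing
#' (best residual above three times the tolerance) is `"indeterminate"`.
#'
#' @param pyro A `pyrogram` (instrument units) or numeric height vector.
#' @param assay A `pyro_assay` or built-in assay name.
#' @param threshold_percent Calling threshold; mutant percentages strictly
#'   above it are called (default 5, the validated test sensitivity).
#' @param wildtype_residual_tol RMS tolerance (per-copy units) for "fits the
#'   wildtype pattern" (default 0.15).
#' @param noise_multiplier Artifact-cutoff multiplier (default 2).
#' @return An object of class `pyro_call`; see [print.pyro_call()],
#'   [summary.pyro_call()], [coef.pyro_call()].
#' @examples
#' a <- builtin_assays()[["EGFR_exon21"]]
#' p <- synth_pyrogram(a, "L858R", fraction = 0.3, scale = 150,
#'                     noise_sd = 0, nonspecific = c(0, 0), seed = 1)
#' call_pyrogram(p, a)
#' @export
call_pyrogram <- function(pyro, assay, threshold_percent = 5,
                          wildtype_residual_tol = 0.15,
                          noise_multiplier = 2) {
  assay <- get_assay(assay)
  if (!inherits(pyro, "pyrogram")) pyro <- pyrogram(as_heights(pyro), assay)
  if (nrow(pyro) != nchar(assay$order) ||
      !all(pyro$base == chars(assay$order)))
    stop_invalid("pyrogram does not match the dispensation order of assay '",
                 assay$name, "'")

  noise <- artifact_cutoff(pyro, assay$unexpected_positions,
                           multiplier = noise_multiplier)
  stats <- reference_stats(pyro, assay$reference_positions)
  # The artifact cutoff qualifies small peaks (reporting, discriminator);
  # the mixture fits use the unmasked heights so that genuine low-fraction
  # mutant signature peaks near the cutoff are not erased.
  norm <- normalize_pyrogram(pyro, stats)

  wt_pattern <- incorporation_walk(assay$wildtype, assay$order)
  wildtype_rms <- rms(norm - wt_pattern)

  fits <- rank_candidates(pyro, assay, stats = stats)
  ambiguous <- attr(fits, "ambiguous")
  best <- fits[[1]]

  # BRAF: when the V600E and V600K fits are not clearly separated by
  # residual, the two-SD reference rule arbitrates between them.
  discriminator <- NA
  if (all(c("V600E", "V600K") %in% names(fits))) {
    discriminator <- v600k_discriminator(pyro, stats, noise)
    if (best$variant %in% c("V600E", "V600K")) {
      rE <- fits[["V600E"]]$rms_residual
      rK <- fits[["V600K"]]$rms_residual
      if (abs(rE - rK) < 0.10 * max(rE, rK, .Machine$double.eps))
        best <- fits[[if (discriminator) "V600K" else "V600E"]]
    }
  }

  mutant_percent <- 100 * best$fraction
  tol <- wildtype_residual_tol
  call <- if (wildtype_rms <= tol && wildtype_rms <= best$rms_residual) {
    "wildtype"
  } else if (best$rms_residual > 3 * tol) {
    if (wildtype_rms <= tol) "wildtype" else "indeterminate"
  } else if (mutant_percent > threshold_percent) {
    "mutation_detected"
  } else {
    "wildtype"
  }

  result <- structure(
    list(call = call,
         variant = if (call == "mutation_detected") best$variant else NULL,
         mutant_percent = mutant_percent,
         threshold_percent = threshold_percent,
         best = best, fits = fits, ambiguous = ambiguous,
         v600k_discriminator = discriminator,
         wildtype_rms = wildtype_rms,
         wildtype_residual_tol = wildtype_residual_tol,
         qc = list(noise = noise, reference = stats,
                   clipped_fraction = best$clipped),
         assay = assay, pyrogram = pyro),
    class = "pyro_call")
  result$attributions <- attribute_peaks(
    if (call == "mutation_detected") best else zero_fraction_fit(best),
    assay, stats, noise, observed = pyro$height)
  result
}

zero_fraction_fit <- function(fit) {
  fit$fraction <- 0
  fit$fitted <- fit$wt_pattern
  fit
}
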