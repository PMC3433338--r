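#' @export
print.pyro_call <- function(x, ...) {
  cat("Pyrosequencing call -", x$assay$name, "\n")
  cat("  call:          ",
      switch(x$call,
             mutation_detected = paste0("mutation detected (", x$variant, ")"),
             wildtype = "wildtype",
             indeterminate = "indeterminate"), "\n")
  cat(sprintf("  mutant percent: %.1f%% (best candidate %s, threshold %.1f%%)\n",
              x$mutant_percent, x$best$variant, x$threshold_percent))
  cat(sprintf("  best residual:  %.4g (rms, per-copy units); wildtype rms %.4g\n",
              x$best$rms_residual, x$wildtype_rms))
  if (isTRUE(x$ambiguous))
    cat("  note: two candidates fit almost equally well (ambiguous)\n")
  if (isTRUE(x$qc$clipped_fraction))
    cat("  note: raw fraction estimate fell outside [0,1] and was clipped\n")
  invisible(x)
}

#' Summarise a pyrosequencing call
#'
#' @param object,x A `pyro_call`.
#' @param ... Unused.
#' @return `object`, invisibly, after printing the call, QC values, the
#'   candidate ranking and the per-peak attribution table.
#' @export
summary.pyro_call <- function(object, ...) {
  print(object)
  cat(sprintf("  qc: B = %.4g, SD = %.4g, noise cutoff = %.4g (%d flagged)\n",
              object$qc$reference$B, object$qc$reference$SD,
              object$qc$noise$cutoff, length(object$qc$noise$flagged)))
  cat("\nCandidates (ascending residual):\n")
  tab <- data.frame(
    variant = vapply(object$fits, function(f) f$variant, character(1)),
    fraction = vapply(object$fits, function(f) f$fraction, numeric(1)),
    rms_residual = vapply(object$fits, function(f) f$rms_residual, numeric(1)))
  print(tab, row.names = FALSE, digits = 4)
  cat("\nPer-peak attribution:\n")
  print.data.frame(object$attributions, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.pyro_call <- function(object, ...) {
  c(mutant_fraction = object$best$fraction, scale = object$best$scale)
}

#' @export
fitted.pyro_call <- function(object, ...) {
  object$best$fitted * object$best$scale
}

#' @export
residuals.pyro_call <- function(object, ...) {
  object$pyrogram$height - fitted(object)
}

#' Expected pyrogram under the called mixture
#'
#' @param object A `pyro_call`.
#' @param fraction Mutant fraction at which to predict (defaults to the
#'   estimated fraction).
#' @param scale Instrument scale (defaults to the estimated per-copy scale).
#' @param ... Unused.
#' @return Numeric vector of expected heights.
#' @export
predict.pyro_call <- function(object, fraction = object$best$fraction,
                              scale = object$best$scale, ...) {
  ((1 - fraction) * object$best$wt_pattern +
     fraction * object$best$mut_pattern) * scale
}

#' Plot observed peaks against the fitted wildtype/mutant split
#'
#' @param x A `pyro_call`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.pyro_call <- function(x, ...) {
  att <- x$attributions
  m <- rbind(wildtype = att$wildtype, mutant = att$mutant)
  bp <- graphics::barplot(m, names.arg = paste0(att$disp, "\n", att$base),
                          col = c("grey70", "firebrick"), border = NA,
                          ylab = "peak height (instrument units)",
                          xlab = "dispensation",
                          main = paste0(x$assay$name, ": ",
                                        if (x$call == "mutation_detected")
                                          sprintf("%s at %.1f%%", x$variant,
                                                  x$mutant_percent)
                                        else x$call), ...)
  graphics::points(bp, x$pyrogram$height, pch = 16, cex = 0.7)
  graphics::legend("topright", bty = "n", pch = c(15, 15, 16),
                   col = c("grey70", "firebrick", "black"),
                   legend = c("wildtype share", "mutant share", "observed"))
  invisible(x)
}

#' Simulate replicate pyrograms under the fitted model
#'
#' Draws synthetic pyrograms at the estimated mutant fraction and scale,
#' with Gaussian peak noise matched to the observed residual spread.
#'
#' @param object A `pyro_call` with `call == "mutation_detected"` or a
#'   wildtype call.
#' @param nsim Number of replicates.
#' @param seed Seed passed to [synth_pyrogram()].
#' @param ... Unused.
#' @return List of `pyrogram` objects.
#' @export
simulate.pyro_call <- function(object, nsim = 1, seed = 1, ...) {
  sd_rel <- rms(residuals(object)) / object$best$scale
  lapply(seq_len(nsim), function(i)
    synth_pyrogram(object$assay,
                   variant = if (object$best$fraction > 0) object$best$variant,
                   fraction = object$best$fraction,
                   scale = object$best$scale,
                   noise_sd = sd_rel, nonspecific = c(0, 0),
                   seed = seed + i - 1L))
}
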