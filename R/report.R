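#' Per-peak wildtype/mutant attribution
#'
#' Splits each fitted peak into its wildtype and mutant contributions —
#' `(1 - f) * wt_i * s` and `f * mut_i * s` (instrument units, `s` = per-copy
#' scale) — and labels every dispensation: `WT` (wildtype signal only), `Mut`
#' (mutant signal only), `Mixed` (both), `Noise` (artifact-flagged) or
#' `Absent` (no expected signal).  This is the per-peak readout showing which
#' peak, or which portion of a peak, comes from the wildtype or mutant gene.
#'
#' @param fit A `pyro_fit` (typically the best candidate of a call).
#' @param assay The `pyro_assay` fitted.
#' @param stats Optional `pyro_refstats`; its `B` is used as the scale when
#'   the fit carries none.
#' @param noise Optional `pyro_noise`; flagged dispensations are labelled
#'   `Noise`.
#' @param observed Optional numeric vector of observed instrument-unit
#'   heights to include in the table.
#' @return Data frame with columns `disp`, `base`, `observed`, `wildtype`,
#'   `mutant`, `label`.
#' @export
attribute_peaks <- function(fit, assay, stats = NULL, noise = NULL,
                            observed = NULL) {
  stopifnot(inherits(fit, "pyro_fit"))
  assay <- get_assay(assay)
  s <- fit$scale
  if ((is.null(s) || is.na(s) || identical(s, 1)) && !is.null(stats)) s <- stats$B
  if (is.null(s) || is.na(s)) s <- 1
  f <- fit$fraction
  wt_c <- (1 - f) * fit$wt_pattern * s
  mut_c <- f * fit$mut_pattern * s
  label <- ifelse(wt_c > 0 & mut_c > 0, "Mixed",
           ifelse(wt_c > 0, "WT",
           ifelse(mut_c > 0, "Mut", "Absent")))
  if (!is.null(noise)) label[noise$flagged] <- "Noise"
  data.frame(disp = seq_along(wt_c), base = chars(assay$order),
             observed = if (is.null(observed)) NA_real_ else as_heights(observed),
             wildtype = wt_c, mutant = mut_c, label = label,
             stringsAsFactors = FALSE)
}

#' Serialize a call result
#'
#' Deterministic rendering of a [call_pyrogram()] result as machine-readable
#' JSON (`{assay, call, variant, mutant_percent, threshold_percent,
#' qc:{B, SD, noise_cutoff}, attributions:[...]}`), a TSV attribution table,
#' or a human-readable text report.
#'
#' @param result A `pyro_call`.
#' @param format `"json"`, `"tsv"` or `"text"`.
#' @return Character scalar (the document).
#' @export
render_report <- function(result, format = c("json", "tsv", "text")) {
  stopifnot(inherits(result, "pyro_call"))
  if (!is.character(format) || !all(format %in% c("json", "tsv", "text")))
    stop(errorCondition(paste0("unknown report format '",
                               paste(format, collapse = ","), "'"),
                        class = c("pyromut_usage_error", "error")))
  format <- match.arg(format)
  att <- result$attributions
  if (format == "json") {
    doc <- list(
      assay = result$assay$name,
      call = result$call,
      variant = result$variant,
      mutant_percent = result$mutant_percent,
      threshold_percent = result$threshold_percent,
      qc = list(B = result$qc$reference$B, SD = result$qc$reference$SD,
                noise_cutoff = result$qc$noise$cutoff),
      attributions = att)
    return(paste0(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                   dataframe = "rows", null = "null"), "\n"))
  }
  if (format == "tsv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.table(att, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  lines <- c(
    paste0("assay: ", result$assay$name),
    if (result$call == "mutation_detected")
      paste0("mutation: ", result$variant)
    else if (result$call == "wildtype") "mutation: not detected"
    else "mutation: indeterminate",
    sprintf("mutant percent: %.1f", result$mutant_percent),
    sprintf("threshold percent: %.1f", result$threshold_percent),
    "qc:",
    sprintf("  reference B: %.4g", result$qc$reference$B),
    sprintf("  reference SD: %.4g", result$qc$reference$SD),
    sprintf("  noise cutoff: %.4g", result$qc$noise$cutoff),
    sprintf("  wildtype rms: %.4g", result$wildtype_rms),
    "attribution:",
    paste0("  ", utils::capture.output(
      print.data.frame(att, row.names = FALSE, digits = 4))))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Pearson chi-square for a 2x2 concordance table
#'
#' Utility for comparing two raters' positive/negative call counts (e.g.
#' manual review vs software), as a Pearson chi-square test without
#' continuity correction on the 2x2 table (df = 1).
#'
#' @param table 2x2 matrix (or object coercible to one) of non-negative
#'   integer counts with positive margins.
#' @return List with `statistic` (chi-square) and `p.value` (two-tailed).
#' @examples
#' concordance_chisq(matrix(c(10, 0, 0, 10), 2))
#' @export
concordance_chisq <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)))
    stop_invalid("concordance table must be 2x2")
  if (anyNA(m) || any(m < 0) || any(m != round(m)))
    stop_invalid("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop_invalid("concordance table has a zero margin")
  ct <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ct$statistic), p.value = unname(ct$p.value))
}
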