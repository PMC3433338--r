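#' Construct a pyrogram
#'
#' An ordered table of (dispensation index, dispensed base, peak height)
#' records in instrument units, as measured by the instrument or produced by
#' [synth_pyrogram()].
#'
#' @param heights Numeric vector of peak heights (>= 0), one per dispensation.
#' @param order Dispensation order: a character scalar, or a `pyro_assay`
#'   (whose order and name are used).
#' @param assay_name Optional assay name to attach.
#' @return A data frame of class `pyrogram` with columns `disp`, `base`,
#'   `height`.
#' @examples
#' a <- builtin_assays()[["BRAF_codon600"]]
#' pyrogram(100 * simulate_pyrogram(a$wildtype, 1, a$order), a)
#' @export
pyrogram <- function(heights, order, assay_name = NULL) {
  if (is.character(order) && length(order) == 1L &&
      order %in% names(builtin_assays()))
    order <- get_assay(order)
  if (inherits(order, "pyro_assay")) {
    assay_name <- assay_name %||% order$name
    order <- order$order
  }
  bases <- check_acgt(order, "dispensation order")
  heights <- as.numeric(heights)
  if (length(heights) != length(bases))
    stop_invalid("need one height per dispensation (", length(bases),
                 "), got ", length(heights))
  if (anyNA(heights) || any(heights < 0))
    stop_invalid("peak heights must be non-negative and non-missing")
  structure(data.frame(disp = seq_along(bases), base = bases,
                       height = heights, stringsAsFactors = FALSE),
            class = c("pyrogram", "data.frame"),
            assay_name = assay_name)
}

as_heights <- function(pyro) {
  if (inherits(pyro, "pyrogram") || is.data.frame(pyro)) pyro$height
  else as.numeric(pyro)
}

#' @export
print.pyrogram <- function(x, ...) {
  cat("Pyrogram",
      if (!is.null(attr(x, "assay_name"))) paste0("(", attr(x, "assay_name"), ")"),
      "-", nrow(x), "dispensations\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Non-specific peak cutoff from unexpected positions
#'
#' Peaks observed at dispensations where no signal is expected under wildtype
#' or any catalog variant are non-specific background.  Twice their average
#' height is used as the artifact cutoff: any peak strictly lower than the
#' cutoff is flagged as non-specific (artifact).
#'
#' @param pyro A `pyrogram` (or numeric height vector).
#' @param unexpected Integer vector of unexpected dispensation indices
#'   (see [unexpected_positions()]).
#' @param multiplier Cutoff multiplier; default 2.
#' @return A list of class `pyro_noise` with elements `unexpected_mean`,
#'   `multiplier`, `cutoff` and `flagged` (indices of artifact peaks).
#' @export
artifact_cutoff <- function(pyro, unexpected, multiplier = 2) {
  h <- as_heights(pyro)
  unexpected <- as.integer(unexpected)
  if (any(unexpected < 1L) || any(unexpected > length(h)))
    stop_invalid("unexpected positions outside the pyrogram")
  if (length(unexpected) == 0L) {
    warning("no unexpected positions: artifact cutoff is 0, nothing flagged",
            call. = FALSE)
    m <- 0
  } else {
    m <- mean(h[unexpected])
  }
  cutoff <- multiplier * m
  structure(list(unexpected_mean = m, multiplier = multiplier,
                 cutoff = cutoff, positions = unexpected,
                 flagged = which(h < cutoff)),
            class = "pyro_noise")
}

#' Reference-peak statistics
#'
#' The reference peaks each arise from a single nucleotide incorporation;
#' their average height `B` calibrates the per-copy instrument scale, and
#' their sample standard deviation `SD` measures normal run-to-run peak
#' variation (used e.g. by the V600K discriminator).
#'
#' @param pyro A `pyrogram` (or numeric height vector).
#' @param positions Integer vector of reference dispensation indices.
#' @return A list of class `pyro_refstats` with elements `B`, `SD`,
#'   `positions`.
#' @export
reference_stats <- function(pyro, positions) {
  h <- as_heights(pyro)
  positions <- as.integer(positions)
  if (length(positions) == 0L)
    stop_invalid("reference position set must be non-empty")
  if (any(positions < 1L) || any(positions > length(h)))
    stop_invalid("reference positions outside the pyrogram")
  B <- mean(h[positions])
  SD <- if (length(positions) > 1L) stats::sd(h[positions]) else 0
  structure(list(B = B, SD = SD, positions = positions),
            class = "pyro_refstats")
}

#' Normalize a pyrogram to per-copy units
#'
#' Divides every peak height by the reference average `B` (instrument units
#' per single incorporation) and zeroes artifact-flagged peaks, yielding
#' heights comparable to simulated expected patterns.
#'
#' @param pyro A `pyrogram` (or numeric height vector).
#' @param stats A `pyro_refstats` from [reference_stats()].
#' @param noise Optional `pyro_noise` from [artifact_cutoff()]; its flagged
#'   peaks are set to 0.
#' @return Numeric vector of per-copy heights.
#' @export
normalize_pyrogram <- function(pyro, stats, noise = NULL) {
  h <- as_heights(pyro)
  if (!inherits(stats, "pyro_refstats")) stop_invalid("stats must come from reference_stats()")
  if (stats$B <= 0)
    stop(errorCondition(
      "degenerate signal: reference peak average B is zero; pyrogram unanalyzable",
      class = c("pyromut_degenerate_signal", "error")))
  if (!is.null(noise)) h[noise$flagged] <- 0
  h / stats$B
}
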