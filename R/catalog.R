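#' Define a mutation variant
#'
#' A catalog entry: an identifier plus an edit applied to the assay's
#' wildtype read, in read-space 1-based coordinates.
#'
#' @param id Short label, e.g. `"L858R"`, `"G12C"`, `"E746_A750del"`.
#' @param type One of `"substitution"`, `"deletion"`, `"insertion"`.
#' @param pos For a substitution, the first edited position; for a deletion,
#'   the first deleted position; for an insertion, the position after which
#'   the bases are inserted.
#' @param bases Replacement bases (substitution; may span several adjacent
#'   positions) or inserted bases (insertion).
#' @param length Number of deleted bases (deletion only).
#' @param notes Optional free text.
#' @return An object of class `pyro_variant`.
#' @examples
#' pyro_variant("L858R", "substitution", pos = 2, bases = "G")
#' pyro_variant("E746_A750del", "deletion", pos = 7, length = 15)
#' @export
pyro_variant <- function(id, type = c("substitution", "deletion", "insertion"),
                         pos, bases = NULL, length = NULL, notes = "") {
  type <- match.arg(type)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_invalid("variant id must be a non-empty string")
  pos <- as.integer(pos)
  if (is.na(pos) || pos < if (type == "insertion") 0L else 1L)
    stop_invalid("variant '", id, "': invalid position")
  if (type == "deletion") {
    length <- as.integer(length)
    if (is.na(length) || length < 1L)
      stop_invalid("variant '", id, "': deletion length must be >= 1")
    bases <- NULL
  } else {
    if (is.null(bases) || !nzchar(bases))
      stop_invalid("variant '", id, "': bases required for a ", type)
    check_acgt(bases, paste0("variant '", id, "' bases"))
    length <- NULL
  }
  structure(list(id = id, type = type, pos = pos, bases = bases,
                 length = length, notes = notes),
            class = "pyro_variant")
}

apply_edit <- function(wildtype, variant) {
  b <- chars(wildtype)
  n <- length(b)
  v <- variant
  out <- switch(v$type,
    substitution = {
      rep_b <- chars(v$bases)
      if (v$pos + length(rep_b) - 1L > n)
        stop_invalid("variant '", v$id, "': substitution runs past the read")
      b[v$pos + seq_along(rep_b) - 1L] <- rep_b
      b
    },
    deletion = {
      if (v$pos + v$length - 1L > n)
        stop_invalid("variant '", v$id, "': deletion runs past the read")
      b[-(v$pos + seq_len(v$length) - 1L)]
    },
    insertion = {
      if (v$pos > n)
        stop_invalid("variant '", v$id, "': insertion point past the read")
      append(b, chars(v$bases), after = v$pos)
    })
  if (length(out) == 0L)
    stop_invalid("variant '", v$id, "': edit deletes the whole read")
  paste(out, collapse = "")
}

#' Apply a catalog variant to an assay's wildtype read
#'
#' @param assay A `pyro_assay`.
#' @param variant A `pyro_variant`, or the id of a variant in the assay's
#'   catalog.
#' @return The mutant read (character scalar, read space).
#' @examples
#' a <- builtin_assays()[["EGFR_exon21"]]
#' apply_variant(a, "L858R")  # "CGGGCCAAACTGCTGGGT"
#' @export
apply_variant <- function(assay, variant) {
  stopifnot(inherits(assay, "pyro_assay"))
  if (is.character(variant)) {
    if (!variant %in% names(assay$variants))
      stop_invalid("assay '", assay$name, "' has no variant '", variant, "'")
    variant <- assay$variants[[variant]]
  }
  apply_edit(assay$wildtype, variant)
}

#' Expected per-copy patterns of an assay's templates
#'
#' @param assay A `pyro_assay`.
#' @return Matrix of expected per-copy heights, one row per dispensation, one
#'   column per template (`"wildtype"` first, then each catalog variant id).
#' @export
assay_patterns <- function(assay) {
  stopifnot(inherits(assay, "pyro_assay"))
  reads <- c(wildtype = assay$wildtype,
             vapply(assay$variants, function(v) apply_edit(assay$wildtype, v),
                    character(1)))
  vapply(reads, incorporation_walk, integer(nchar(assay$order)),
         order = assay$order)
}

derive_reference_positions <- function(patterns) {
  which(apply(patterns == 1L, 1L, all))
}

derive_unexpected_positions <- function(patterns) {
  which(apply(patterns == 0L, 1L, all))
}

#' Define a pyrosequencing assay
#'
#' An assay bundles the targeted wildtype read, the instrument's dispensation
#' order, the catalog of recognisable mutations, and the dispensation indices
#' used for calibration: *reference positions* (expected height exactly one
#' incorporation under wildtype, used to estimate the per-copy instrument
#' scale B) and *unexpected positions* (expected height zero under wildtype
#' and every catalog variant, used to estimate non-specific background).
#' When not supplied, both sets are derived from the simulated patterns.
#'
#' @param name Assay name.
#' @param target Targeted sequence, possibly IUPAC-degenerate at the hotspot
#'   positions, in read space.
#' @param wildtype_assignment Named character vector resolving the degenerate
#'   positions of `target` to the wildtype bases (see [expand_iupac()]).
#' @param order Dispensation order.
#' @param orientation `"forward"` or `"reverse"` (reverse-sequencing assays
#'   store the read already reverse-complemented, exactly as analysed).
#' @param variants List of [pyro_variant()] objects.
#' @param reference_positions Optional integer vector of reference
#'   dispensations; derived when `NULL`.
#' @param unexpected_positions Optional integer vector; derived when `NULL`.
#' @param description Free text.
#' @return An object of class `pyro_assay`.
#' @export
pyro_assay <- function(name, target, wildtype_assignment = character(),
                       order, orientation = c("forward", "reverse"),
                       variants = list(),
                       reference_positions = NULL,
                       unexpected_positions = NULL,
                       description = "") {
  orientation <- match.arg(orientation)
  problems <- character()
  note <- function(...) problems <<- c(problems, paste0(...))

  wildtype <- NULL
  nd <- 0L
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    note("assay name must be a non-empty string")
  if (!is.character(order) || length(order) != 1L || !nzchar(order)) {
    note("missing dispensation order")
  } else if (!all(chars(order) %in% c("A", "C", "G", "T"))) {
    note("dispensation order must use only A/C/G/T")
  } else {
    nd <- nchar(order)
  }
  wildtype <- tryCatch(expand_iupac(target, wildtype_assignment),
                       error = function(e) { note(conditionMessage(e)); NULL })

  if (length(variants)) {
    ids <- vapply(variants, function(v) v$id, character(1))
    if (anyDuplicated(ids)) note("duplicate variant ids")
    names(variants) <- ids
    if (!is.null(wildtype)) {
      for (v in variants) {
        tryCatch(check_acgt(apply_edit(wildtype, v),
                            paste0("variant '", v$id, "' read")),
                 error = function(e) note(conditionMessage(e)))
      }
    }
  }
  if (length(problems))
    stop(errorCondition(
      paste0("invalid assay definition", if (nzchar(name %||% "")) paste0(" '", name, "'"),
             ":\n- ", paste(problems, collapse = "\n- ")),
      class = c("pyromut_validation_error", "pyromut_invalid_input", "error")))

  assay <- structure(list(name = name, target = toupper(target),
                          wildtype_assignment = wildtype_assignment,
                          wildtype = wildtype, order = toupper(order),
                          orientation = orientation, variants = variants,
                          reference_positions = NULL,
                          unexpected_positions = NULL,
                          description = description),
                     class = "pyro_assay")
  patterns <- assay_patterns(assay)

  if (is.null(reference_positions)) {
    reference_positions <- derive_reference_positions(patterns)
  } else {
    reference_positions <- sort(unique(as.integer(reference_positions)))
    if (any(reference_positions < 1L) || any(reference_positions > nd))
      note("reference positions outside the dispensation order")
    rp_ok <- reference_positions[reference_positions >= 1L &
                                   reference_positions <= nd]
    bad <- rp_ok[patterns[rp_ok, "wildtype"] != 1L]
    if (length(bad))
      note("reference position(s) ", paste(bad, collapse = ", "),
           " do not have expected wildtype height 1")
    reference_positions <- rp_ok
  }
  if (length(reference_positions) == 0L)
    note("assay has no single-copy reference position")
  for (v in names(assay$variants)) {
    if (length(reference_positions) &&
        !any(patterns[reference_positions, v] == 1L))
      note("no reference position is single-copy under variant '", v, "'")
  }

  if (is.null(unexpected_positions)) {
    unexpected_positions <- derive_unexpected_positions(patterns)
  } else {
    unexpected_positions <- sort(unique(as.integer(unexpected_positions)))
    if (any(unexpected_positions < 1L) || any(unexpected_positions > nd))
      note("unexpected positions outside the dispensation order")
    bad <- unexpected_positions[
      apply(patterns[unexpected_positions, , drop = FALSE] != 0L, 1L, any)]
    if (length(bad))
      note("unexpected position(s) ", paste(bad, collapse = ", "),
           " have non-zero expected height under some template")
  }
  if (length(problems))
    stop(errorCondition(
      paste0("invalid assay definition '", name, "':\n- ",
             paste(problems, collapse = "\n- ")),
      class = c("pyromut_validation_error", "pyromut_invalid_input", "error")))

  assay$reference_positions <- as.integer(reference_positions)
  assay$unexpected_positions <- as.integer(unexpected_positions)
  assay
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unexpected dispensation positions of an assay
#'
#' Dispensations where no signal is expected under wildtype or any catalog
#' variant; observed signal there estimates non-specific background.
#'
#' @param assay A `pyro_assay`.
#' @return Integer vector of 1-based dispensation indices.
#' @examples
#' unexpected_positions(builtin_assays()[["BRAF_codon600"]])  # 1 3 6
#' @export
unexpected_positions <- function(assay) {
  stopifnot(inherits(assay, "pyro_assay"))
  assay$unexpected_positions
}

#' @export
print.pyro_assay <- function(x, ...) {
  cat("Pyrosequencing assay:", x$name,
      if (x$orientation == "reverse") "(reverse sequencing)", "\n")
  cat("  target:            ", x$target, "\n")
  cat("  wildtype read:     ", x$wildtype, "\n")
  cat("  dispensation order:", x$order, "\n")
  cat("  reference positions: ", paste(x$reference_positions, collapse = ", "),
      "\n", sep = "")
  cat("  unexpected positions:", paste(x$unexpected_positions, collapse = ", "),
      "\n")
  cat("  variants (", length(x$variants), "): ",
      paste(names(x$variants), collapse = ", "), "\n", sep = "")
  invisible(x)
}

variant_to_json <- function(v) {
  edit <- switch(v$type,
    substitution = list(type = "substitution", pos = v$pos, bases = v$bases),
    deletion = list(type = "deletion", pos = v$pos, length = v$length),
    insertion = list(type = "insertion", after = v$pos, bases = v$bases))
  out <- list(id = v$id, edit = edit)
  if (nzchar(v$notes %||% "")) out$notes <- v$notes
  out
}

variant_from_json <- function(x) {
  e <- x$edit
  if (is.null(e) || is.null(e$type))
    stop_invalid("variant '", x$id %||% "?", "': missing edit")
  pyro_variant(x$id, e$type,
               pos = e$pos %||% e$after,
               bases = e$bases, length = e$length,
               notes = x$notes %||% "")
}

#' Read and write assay catalogs (JSON)
#'
#' The catalog file is a JSON list of assay objects with fields `name`,
#' `target` (IUPAC string), `wildtype_assignment`, `dispensation_order`,
#' `orientation`, `variants` (`{id, edit:{type, ...}}`), `reference_positions`
#' and optionally `unexpected_positions`.  Loading validates every assay and
#' reports all violations at once; save-then-load reproduces the assays
#' exactly.
#'
#' @param path File path.
#' @param assays Named list of `pyro_assay` objects.
#' @return `read_catalog()` returns a named list of `pyro_assay` objects;
#'   `write_catalog()` returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.list(raw) || length(raw) == 0L)
    stop_invalid("catalog file must contain a non-empty list of assays")
  assays <- lapply(raw, function(a) {
    wa <- unlist(a$wildtype_assignment) %||% character()
    if (length(wa)) wa <- stats::setNames(as.character(wa), names(wa))
    pyro_assay(
      name = a$name %||% "",
      target = a$target %||% "",
      wildtype_assignment = wa,
      order = a$dispensation_order %||% "",
      orientation = a$orientation %||% "forward",
      variants = lapply(a$variants %||% list(), variant_from_json),
      reference_positions = unlist(a$reference_positions),
      unexpected_positions = unlist(a$unexpected_positions),
      description = a$description %||% "")
  })
  stats::setNames(assays, vapply(assays, function(a) a$name, character(1)))
}

#' @rdname read_catalog
#' @export
write_catalog <- function(assays, path) {
  if (inherits(assays, "pyro_assay")) assays <- list(assays)
  out <- lapply(assays, function(a) {
    x <- list(name = a$name, target = a$target,
              wildtype_assignment = as.list(a$wildtype_assignment),
              dispensation_order = a$order, orientation = a$orientation,
              variants = lapply(unname(a$variants), variant_to_json),
              reference_positions = a$reference_positions,
              unexpected_positions = a$unexpected_positions)
    if (nzchar(a$description %||% "")) x$description <- a$description
    x
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
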