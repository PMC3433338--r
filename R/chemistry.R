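#' @keywords internal
"_PACKAGE"

# IUPAC nucleotide codes -> allowed concrete bases
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("pyromut_invalid_input", "error")))
}

check_acgt <- function(seq, what = "sequence") {
  b <- chars(seq)
  if (length(b) == 0L) stop_invalid(what, " must be non-empty")
  bad <- which(!b %in% c("A", "C", "G", "T"))
  if (length(bad)) {
    stop_invalid("non-ACGT character '", b[bad[1]], "' in ", what,
                 " at position ", bad[1])
  }
  invisible(b)
}

#' Walk a template read along a dispensation order
#'
#' Models the deterministic chemistry of sequencing-by-synthesis: nucleotides
#' are dispensed one at a time in a fixed order, and each dispensation
#' incorporates the maximal run of complementary template bases starting at
#' the current synthesis position.  The emitted light — and hence the pyrogram
#' peak height — is proportional to the number of bases incorporated, so the
#' returned run lengths are the expected per-copy peak heights.
#'
#' @param read Character scalar, the analysed (synthesised-strand) sequence in
#'   read space, using only A/C/G/T.
#' @param order Character scalar, the dispensation order (A/C/G/T), 1-based.
#' @return Integer vector with one run length per dispensation.  A cursor
#'   starts at read position 1; at each dispensation of base X the length of
#'   the maximal run of X at the cursor is emitted (0 if the next base
#'   differs) and the cursor advances by that length.  Read bases left after
#'   the last dispensation contribute nothing.
#' @examples
#' incorporation_walk("AACG", "ACG")                       # 2 1 1
#' incorporation_walk("CTGGCCAAACTGCTGGGT", "ACGTGTCACATGTC")
#' @export
incorporation_walk <- function(read, order) {
  rb <- check_acgt(read, "read")
  ob <- check_acgt(order, "dispensation order")
  n <- length(rb)
  out <- integer(length(ob))
  pos <- 1L
  for (i in seq_along(ob)) {
    k <- 0L
    while (pos + k <= n && rb[pos + k] == ob[i]) k <- k + 1L
    out[i] <- k
    pos <- pos + k
  }
  out
}

#' Expected pyrogram pattern of a template mixture
#'
#' Expected per-dispensation peak heights for a mixture of template reads,
#' in per-copy units (a single-base incorporation has height 1.0).  The signal
#' is exactly linear in the mixture fractions: each component contributes
#' `fraction * incorporation_walk(read, order)`.
#'
#' @param reads Character vector of reads (A/C/G/T, read space).
#' @param fractions Numeric vector of mixture fractions, one per read;
#'   non-negative and summing to 1 (within 1e-12).  Defaults to a pure
#'   single-template simulation when one read is given.
#' @param order Dispensation order (character scalar).
#' @return Numeric vector of expected heights, one per dispensation.
#' @examples
#' simulate_pyrogram("CGGGCCAAACTGCTGGGT", 1, "ACGTGTCACATGTC")
#' simulate_pyrogram(c("CTGGCCAAACTGCTGGGT", "CGGGCCAAACTGCTGGGT"),
#'                   c(0.5, 0.5), "ACGTGTCACATGTC")
#' @export
simulate_pyrogram <- function(reads, fractions = NULL, order) {
  if (length(reads) == 0L) stop_invalid("empty template mixture")
  if (is.null(fractions)) {
    if (length(reads) != 1L)
      stop_invalid("fractions must be given for a multi-component mixture")
    fractions <- 1
  }
  if (length(fractions) != length(reads))
    stop_invalid("reads and fractions must have equal length")
  if (any(fractions < 0)) stop_invalid("mixture fractions must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-12)
    stop_invalid("mixture fractions must sum to 1 (got ", sum(fractions), ")")
  pat <- vapply(reads, incorporation_walk, integer(nchar(order)),
                order = order)
  if (is.null(dim(pat))) pat <- matrix(pat, ncol = length(reads))
  as.numeric(pat %*% fractions)
}

#' Reverse complement of a nucleotide sequence
#'
#' Standard reverse complement in IUPAC space; degenerate codes map to their
#' complements (R<->Y, K<->M, B<->V, D<->H; S, W, N are self-complementary).
#' Used for reverse-sequencing assays, where the analysed read is the reverse
#' complement of the sense-strand context.
#'
#' @param seq Character scalar of IUPAC nucleotide codes.
#' @return Character scalar.
#' @examples
#' reverse_complement("ACAGTG")  # "CACTGT"
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop_invalid("sequence must be a non-empty character scalar")
  b <- chars(toupper(seq))
  bad <- which(!b %in% names(IUPAC_CODES))
  if (length(bad))
    stop_invalid("non-IUPAC character '", b[bad[1]], "' at position ", bad[1])
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", paste(rev(b), collapse = ""))
  comp
}

#' Resolve a degenerate IUPAC sequence to a concrete read
#'
#' Assay target sequences are printed with IUPAC degenerate codes at the
#' mutation hotspots (e.g. `CKGGCCAAACDGCTGGGT`); resolving each degenerate
#' position to one allowed base yields a concrete template read.
#'
#' @param seq Degenerate IUPAC nucleotide string.
#' @param assignment Named character vector mapping 1-based positions (names)
#'   to concrete bases, e.g. `c("2" = "T", "11" = "T")`.  Each assigned base
#'   must be allowed by the IUPAC code at that position; non-degenerate
#'   positions need no assignment.
#' @return Character scalar, a concrete A/C/G/T read.
#' @examples
#' expand_iupac("CWCTGTAG", c("2" = "A"))  # "CACTGTAG"
#' @export
expand_iupac <- function(seq, assignment = character()) {
  b <- chars(toupper(seq))
  bad <- which(!b %in% names(IUPAC_CODES))
  if (length(bad))
    stop_invalid("non-IUPAC character '", b[bad[1]], "' at position ", bad[1])
  if (length(assignment)) {
    pos <- as.integer(names(assignment))
    if (anyNA(pos) || any(pos < 1L) || any(pos > length(b)))
      stop_invalid("assignment positions must name positions within the sequence")
    for (i in seq_along(pos)) {
      allowed <- IUPAC_CODES[[b[pos[i]]]]
      base <- toupper(assignment[[i]])
      if (!base %in% allowed)
        stop_invalid("base '", base, "' not allowed by IUPAC code '",
                     b[pos[i]], "' at position ", pos[i])
      b[pos[i]] <- base
    }
  }
  left <- which(!b %in% c("A", "C", "G", "T"))
  if (length(left))
    stop_invalid("degenerate position ", left[1], " ('", b[left[1]],
                 "') has no assignment")
  paste(b, collapse = "")
}
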