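with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  } else {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_parse <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("pyromut_parse_error",
                                "pyromut_invalid_input", "error")))
}

#' Read and write pyrogram TSV files
#'
#' The interchange format is a tab-separated table with header
#' `disp	base	height`: 1-based consecutive dispensation indices, the
#' dispensed base (A/C/G/T) and the non-negative peak height (dot decimal,
#' instrument units).  `col_map` renames columns of permissive instrument
#' exports onto this dialect.  Writing then reading reproduces the pyrogram
#' exactly.
#'
#' @param path File path.
#' @param assay Optional `pyro_assay` or built-in assay name; when given,
#'   the base column is validated against the assay's dispensation order.
#' @param col_map Named character vector mapping the canonical names
#'   (`disp`, `base`, `height`) to the column names present in the file.
#' @param pyro A `pyrogram`.
#' @return `read_pyrogram()` returns a `pyrogram`; `write_pyrogram()`
#'   returns `path` invisibly.
#' @export
read_pyrogram <- function(path, assay = NULL,
                          col_map = c(disp = "disp", base = "base",
                                      height = "height")) {
  if (!file.exists(path)) stop_parse("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(c("disp", "base", "height"),
                          names(col_map)[col_map %in% names(df)])
  if (length(missing_cols))
    stop_parse("missing column(s) in ", path, ": ",
               paste(col_map[missing_cols], collapse = ", "))
  df <- data.frame(disp = df[[col_map[["disp"]]]],
                   base = toupper(df[[col_map[["base"]]]]),
                   height = df[[col_map[["height"]]]],
                   stringsAsFactors = FALSE)
  n <- nrow(df)
  if (n == 0L) stop_parse("empty pyrogram file: ", path)
  for (i in seq_len(n)) {
    line <- i + 1L  # header is line 1
    d <- suppressWarnings(as.integer(df$disp[i]))
    h <- suppressWarnings(as.numeric(df$height[i]))
    if (is.na(d) || d != i)
      stop_parse("parse error at line ", line, " of ", path,
                 ": dispensation indices must be consecutive from 1 (got '",
                 df$disp[i], "')")
    if (!df$base[i] %in% c("A", "C", "G", "T"))
      stop_parse("parse error at line ", line, " of ", path,
                 ": base must be A/C/G/T (got '", df$base[i], "')")
    if (is.na(h) || h < 0)
      stop_parse("parse error at line ", line, " of ", path,
                 ": height must be a non-negative number (got '",
                 df$height[i], "')")
  }
  assay_name <- NULL
  if (!is.null(assay)) {
    assay <- get_assay(assay)
    if (paste(df$base, collapse = "") != assay$order)
      stop_parse("base column of ", path,
                 " does not match the dispensation order of assay '",
                 assay$name, "' (", assay$order, ")")
    assay_name <- assay$name
  }
  pyrogram(as.numeric(df$height),
           paste(df$base, collapse = ""), assay_name = assay_name)
}

#' @rdname read_pyrogram
#' @export
write_pyrogram <- function(pyro, path) {
  stopifnot(inherits(pyro, "pyrogram"))
  utils::write.table(as.data.frame(pyro)[, c("disp", "base", "height")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic pyrogram
#'
#' Simulates a measured pyrogram for a wildtype/mutant template mixture:
#' `scale` times the expected per-copy pattern, plus i.i.d. Gaussian peak
#' noise (standard deviation `noise_sd * scale`), plus uniform non-specific
#' peaks at the assay's unexpected positions, truncated at zero (peak
#' heights are physical light intensities).  Identical seeds give identical
#' pyrograms; the global RNG state is left untouched.
#'
#' The defaults emulate a routine clinical run: per-copy scale 100
#' instrument units, peak noise 3% of a single-copy peak, and non-specific
#' background between 1% and 5% of a single-copy peak.
#'
#' @param assay A `pyro_assay` or built-in assay name.
#' @param variant Variant id (or `pyro_variant`) to mix in; `NULL` or
#'   `"wildtype"` for pure wildtype.
#' @param fraction Mutant fraction in `[0, 1]`.
#' @param scale Instrument units per single-base incorporation (> 0).
#' @param noise_sd Gaussian peak noise, as a fraction of `scale`.
#' @param nonspecific Length-2 range (fractions of `scale`) for uniform
#'   non-specific peak amplitudes at unexpected positions; `c(0, 0)`
#'   disables them.
#' @param seed Integer seed; required whenever noise or non-specific peaks
#'   are drawn.
#' @return A `pyrogram`.
#' @examples
#' synth_pyrogram("BRAF_codon600", "V600E", fraction = 0.3, scale = 120,
#'                seed = 42)
#' @export
synth_pyrogram <- function(assay, variant = NULL, fraction = 0, scale = 100,
                           noise_sd = 0.03, nonspecific = c(0.01, 0.05),
                           seed = NULL) {
  assay <- get_assay(assay)
  if (is.na(fraction) || fraction < 0 || fraction > 1)
    stop_invalid("fraction must be in [0, 1]")
  if (is.na(scale) || scale <= 0) stop_invalid("scale must be positive")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (length(nonspecific) != 2L || any(nonspecific < 0) ||
      nonspecific[1] > nonspecific[2])
    stop_invalid("nonspecific must be an increasing non-negative range")
  if (is.null(variant) || identical(variant, "wildtype")) {
    if (fraction > 0)
      stop_invalid("a variant must be named when fraction > 0")
    expected <- simulate_pyrogram(assay$wildtype, 1, assay$order)
  } else {
    mut <- apply_variant(assay, variant)
    expected <- simulate_pyrogram(c(assay$wildtype, mut),
                                  c(1 - fraction, fraction), assay$order)
  }
  h <- scale * expected
  needs_rng <- noise_sd > 0 || nonspecific[2] > 0
  if (needs_rng) {
    if (is.null(seed))
      stop_invalid("seed is required when noise or non-specific peaks are drawn")
    h <- with_seed(seed, {
      out <- h + stats::rnorm(length(h), 0, noise_sd * scale)
      un <- assay$unexpected_positions
      if (length(un) && nonspecific[2] > 0)
        out[un] <- out[un] +
          stats::runif(length(un), nonspecific[1], nonspecific[2]) * scale
      out
    })
  }
  pyrogram(pmax(h, 0), assay)
}

cli_usage <- function() {
  paste(
    "usage: pyromut <command> [options]",
    "",
    "commands:",
    "  analyze  --assay NAME --input FILE.tsv [--out FILE] [--format json|tsv|text]",
    "           [--min-call-percent 5] [--noise-multiplier 2]",
    "  synth    --assay NAME [--variant ID] [--fraction F] [--scale S]",
    "           [--noise-sd SD] [--seed N] --out FILE.tsv",
    "  catalog  list | show --assay NAME | validate --file CATALOG.json",
    sep = "\n")
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop(errorCondition(paste0("unexpected argument '", a, "'"),
                          class = c("pyromut_usage_error", "error")))
    if (i == length(args))
      stop(errorCondition(paste0("option ", a, " needs a value"),
                          class = c("pyromut_usage_error", "error")))
    opts[[substring(a, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line interface
#'
#' Subcommands: `analyze` (read a pyrogram TSV, run the caller, write a
#' report), `synth`/`simulate` (write a synthetic pyrogram TSV) and
#' `catalog` (`list`, `show`, `validate`).  Parameters and QC values are
#' logged to stderr.  A wrapper script ships at
#' `system.file("cli", "pyromut", package = "pyromut")`.
#'
#' @param args Character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code, invisibly: 0 on success, 1 on usage error,
#'   2 on unanalyzable input.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' pyro_cli(c("synth", "--assay", "BRAF_codon600", "--variant", "V600E",
#'            "--fraction", "0.4", "--seed", "7", "--out", tsv))
#' pyro_cli(c("analyze", "--assay", "BRAF_codon600", "--input", tsv,
#'            "--format", "text"))
#' @export
pyro_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  run <- function() {
    if (length(args) == 0L)
      stop(errorCondition("no command given", class = c("pyromut_usage_error", "error")))
    cmd <- args[1]
    rest <- args[-1]
    if (cmd %in% c("synth", "simulate")) {
      o <- parse_cli_opts(rest)
      if (is.null(o$assay) || is.null(o$out))
        stop(errorCondition("synth needs --assay and --out",
                            class = c("pyromut_usage_error", "error")))
      p <- synth_pyrogram(
        o$assay, variant = o$variant,
        fraction = as.numeric(o$fraction %||% 0),
        scale = as.numeric(o$scale %||% 100),
        noise_sd = as.numeric(o[["noise-sd"]] %||% 0.03),
        seed = if (!is.null(o$seed)) as.integer(o$seed))
      write_pyrogram(p, o$out)
      message("synth: assay=", o$assay, " variant=", o$variant %||% "wildtype",
              " fraction=", o$fraction %||% 0, " seed=", o$seed %||% "none",
              " -> ", o$out)
      return(0L)
    }
    if (cmd == "analyze") {
      o <- parse_cli_opts(rest)
      if (is.null(o$assay) || is.null(o$input))
        stop(errorCondition("analyze needs --assay and --input",
                            class = c("pyromut_usage_error", "error")))
      assay <- get_assay(o$assay)
      pyro <- read_pyrogram(o$input, assay = assay)
      res <- call_pyrogram(
        pyro, assay,
        threshold_percent = as.numeric(o[["min-call-percent"]] %||% 5),
        noise_multiplier = as.numeric(o[["noise-multiplier"]] %||% 2))
      message(sprintf(
        "analyze: assay=%s input=%s B=%.4g SD=%.4g cutoff=%.4g call=%s percent=%.1f",
        assay$name, o$input, res$qc$reference$B, res$qc$reference$SD,
        res$qc$noise$cutoff, res$call, res$mutant_percent))
      doc <- render_report(res, format = o$format %||% "json")
      if (is.null(o$out)) cat(doc) else writeLines(doc, o$out, sep = "")
      return(0L)
    }
    if (cmd == "catalog") {
      sub <- if (length(rest)) rest[1] else ""
      o <- parse_cli_opts(rest[-1])
      if (identical(sub, "list")) {
        cat(paste(names(builtin_assays()), collapse = "\n"), "\n", sep = "")
        return(0L)
      }
      if (identical(sub, "show")) {
        print(get_assay(o$assay %||%
                          stop(errorCondition("catalog show needs --assay",
                                              class = c("pyromut_usage_error", "error")))))
        return(0L)
      }
      if (identical(sub, "validate")) {
        if (is.null(o$file))
          stop(errorCondition("catalog validate needs --file",
                              class = c("pyromut_usage_error", "error")))
        assays <- read_catalog(o$file)
        message("catalog OK: ", length(assays), " assay(s): ",
                paste(names(assays), collapse = ", "))
        return(0L)
      }
      stop(errorCondition(paste0("unknown catalog subcommand '", sub, "'"),
                          class = c("pyromut_usage_error", "error")))
    }
    stop(errorCondition(paste0("unknown command '", cmd, "'"),
                        class = c("pyromut_usage_error", "error")))
  }
  code <- tryCatch(run(),
    pyromut_degenerate_signal = function(e) {
      message("error: ", conditionMessage(e)); 2L
    },
    pyromut_usage_error = function(e) {
      message("error: ", conditionMessage(e)); message(cli_usage()); 1L
    },
    error = function(e) {
      message("error: ", conditionMessage(e)); 1L
    })
  invisible(code)
}
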