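assays <- builtin_assays()

test_that("the built-in catalog ships the eight hotspot assays as printed", {
  expect_length(assays, 8L)
  expect_identical(assays[["BRAF_codon600"]]$order, "TCGTATCTGTAG")
  expect_identical(assays[["EGFR_exon21"]]$target, "CKGGCCAAACDGCTGGGT")
  expect_identical(assays[["KRAS_codon12_13"]]$target, "NNTGRCGTAGGC")
  expect_identical(assays[["KRAS_codon12_13"]]$order,
                   "ACTGTACGTGATCGTAGCAAGAG")
  expect_identical(assays[["EGFR_exon21"]]$reference_positions,
                   c(2L, 9L, 11L, 12L, 14L))
  expect_identical(assays[["BRAF_codon600"]]$reference_positions,
                   c(9L, 10L, 12L))
  # the analysed BRAF read is the reverse complement of the sense context
  expect_identical(assays[["BRAF_codon600"]]$wildtype,
                   reverse_complement("CTACAGTG"))
})

test_that("every wildtype read is one IUPAC resolution of its target", {
  for (a in assays) {
    expect_identical(nchar(a$wildtype), nchar(a$target))
    expect_identical(expand_iupac(a$target, a$wildtype_assignment), a$wildtype)
  }
})

test_that("apply_variant reproduces the expected mutant reads", {
  expect_identical(apply_variant(assays[["EGFR_exon21"]], "L858R"),
                   "CGGGCCAAACTGCTGGGT")
  expect_identical(apply_variant(assays[["BRAF_codon600"]], "V600E"),
                   "CTCTGTAG")
  expect_identical(apply_variant(assays[["BRAF_codon600"]], "V600K"),
                   "CTTTGTAG")
  # deleting the bracketed 15-base exon-19 block
  expect_identical(apply_variant(assays[["EGFR_exon19_del"]], "E746_A750del"),
                   paste0("TATCAA", "AACATCTCCGAAAGCCA"))
  expect_error(apply_variant(assays[["EGFR_exon21"]], "nope"),
               class = "pyromut_invalid_input")
})

test_that("variant edits change the read exactly as specified and nowhere else", {
  for (a in assays) for (v in a$variants) {
    wt <- strsplit(a$wildtype, "")[[1]]
    mut <- strsplit(apply_variant(a, v), "")[[1]]
    if (v$type == "substitution") {
      idx <- v$pos + seq_len(nchar(v$bases)) - 1L
      expect_identical(mut[idx], strsplit(v$bases, "")[[1]])
      expect_identical(mut[-idx], wt[-idx])
    } else if (v$type == "deletion") {
      expect_identical(mut, wt[-(v$pos + seq_len(v$length) - 1L)])
    } else {
      expect_identical(mut,
                       append(wt, strsplit(v$bases, "")[[1]], after = v$pos))
    }
  }
})

test_that("reference positions are single-copy under wildtype, and per variant where used", {
  for (a in assays) {
    pat <- assay_patterns(a)
    expect_true(all(pat[a$reference_positions, "wildtype"] == 1L))
    for (v in names(a$variants)) {
      usable <- a$reference_positions[pat[a$reference_positions, v] == 1L]
      expect_gt(length(usable), 0L)
    }
  }
})

test_that("no two catalog templates share an expected pattern", {
  for (a in assays) {
    pat <- assay_patterns(a)
    expect_false(anyDuplicated(t(pat)) > 0)
  }
})

test_that("unexpected positions are derived as jointly signal-free", {
  expect_identical(unexpected_positions(assays[["BRAF_codon600"]]),
                   c(1L, 3L, 6L))
  expect_identical(unexpected_positions(assays[["EGFR_exon21"]]),
                   c(1L, 6L, 13L))
  for (a in assays) {
    pat <- assay_patterns(a)
    un <- unexpected_positions(a)
    expect_true(all(pat[un, ] == 0L))
    # maximality for derived sets: no other dispensation is signal-free
    if (!a$name %in% c("EGFR_exon21", "BRAF_codon600"))
      expect_identical(un, which(apply(pat == 0L, 1L, all)))
  }
})

test_that("an assay fully consumed by every template has no unexpected positions", {
  a <- pyro_assay("toy", target = "AACG", order = "ACG",
                  variants = list(pyro_variant("X", "substitution",
                                               pos = 2, bases = "C")))
  expect_identical(unexpected_positions(a), integer(0))
})

test_that("catalog JSON round-trips exactly, including the shipped file", {
  tmp <- tempfile(fileext = ".json")
  write_catalog(assays, tmp)
  expect_equal(read_catalog(tmp), assays)
  shipped <- system.file("extdata", "assays.json", package = "pyromut")
  expect_equal(read_catalog(shipped), assays)
})

test_that("catalog validation reports all violations", {
  # reference position with expected height 2 (exon-21 dispensation 5)
  expect_error(
    pyro_assay("bad", target = "CTGGCCAAACTGCTGGGT",
               order = "ACGTGTCACATGTC",
               variants = list(pyro_variant("L858R", "substitution", 2, "G")),
               reference_positions = c(2, 5)),
    "expected wildtype height 1", class = "pyromut_validation_error")
  # missing dispensation order
  expect_error(
    pyro_assay("bad", target = "ACGT", order = ""),
    "dispensation order", class = "pyromut_validation_error")
  # several failures listed together
  err <- tryCatch(
    pyro_assay("bad", target = "ACGT", order = "QQ",
               variants = list(pyro_variant("V", "deletion", 3, length = 9))),
    error = function(e) conditionMessage(e))
  expect_match(err, "dispensation order")
  expect_match(err, "deletion runs past")
})

test_that("edits out of range are rejected", {
  a <- assays[["EGFR_exon20_790"]]
  expect_error(apply_variant(a, pyro_variant("bad", "substitution",
                                             pos = 6, bases = "GG")),
               "past the read", class = "pyromut_invalid_input")
})
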