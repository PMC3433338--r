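# Built-in assay definitions.
#
# All sequences are stored in read space: the analysed (synthesised-strand)
# sequence, 5'->3' in dispensation time.  Reverse-sequencing assays (KRAS
# codon 61, BRAF codon 600) are stored already reverse-complemented, exactly
# as the instrument analyses them.  Variant edits are read-space 1-based.

sub_ <- function(id, pos, bases, notes = "")
  pyro_variant(id, "substitution", pos = pos, bases = bases, notes = notes)
del_ <- function(id, pos, length, notes = "")
  pyro_variant(id, "deletion", pos = pos, length = length, notes = notes)
ins_ <- function(id, after, bases, notes = "")
  pyro_variant(id, "insertion", pos = after, bases = bases, notes = notes)

#' Built-in EGFR/KRAS/BRAF assay catalog
#'
#' The eight hotspot assays covered by the analysis software: EGFR codon 719
#' (exon 18), the common exon-19 deletions, exon-20 codon 768 (+ insertions),
#' codon 790, codon 858 (exon 21); KRAS codons 12 & 13 and codon 61; BRAF
#' codon 600.  Targeted sequences are IUPAC-degenerate at the hotspot
#' positions; the wildtype read is one resolution of the degenerate target.
#' Reference dispensations for the exon-21 and BRAF assays are the ones used
#' by the quantification rules (`{2,9,11,12,14}` and `{9,10,12}`); for the
#' other assays they are derived as the dispensations with expected height
#' exactly one incorporation under wildtype and every catalog variant.
#'
#' The same catalog ships as a JSON file at
#' `system.file("extdata", "assays.json", package = "pyromut")`.
#'
#' @return Named list of [pyro_assay()] objects.
#' @examples
#' names(builtin_assays())
#' builtin_assays()[["EGFR_exon21"]]
#' @export
builtin_assays <- function() {
  assays <- list(
    pyro_assay(
      name = "EGFR_exon18_719", target = "DSCTCCGGTGC",
      wildtype_assignment = c("1" = "G", "2" = "G"),
      order = "CATGTCACTCGTG", orientation = "forward",
      variants = list(
        sub_("G719S", 1, "A", "GGC>AGC"),
        sub_("G719C", 1, "T", "GGC>TGC"),
        sub_("G719A", 2, "C", "GGC>GCC")),
      description = "EGFR exon 18, codon 719"),
    pyro_assay(
      name = "EGFR_exon19_del",
      target = "TATCAAGGAATTAAGAGAAGCAACATCTCCGAAAGCCA",
      order = "CTATCACTGTCAGCTCGATCGTCATCGTCACGC", orientation = "forward",
      variants = list(
        del_("E746_A750del",   7, 15, "c.2235_2249del15"),
        del_("E746_A750del.2", 8, 15, "c.2236_2250del15"),
        del_("E746_T751>A",    9, 15, "c.2237_2251del15"),
        del_("E746_T751del",   8, 18, "c.2236_2253del18"),
        del_("E746_S752>V",   10, 18, "c.2238_2255del18"),
        del_("L747_E749del",  11,  9, "c.2239_2247del9"),
        del_("L747_T751>P",   12, 12, "c.2240_2251del12"),
        del_("L747_T751del",  11, 15, "c.2239_2253del15"),
        del_("L747_S752del",  11, 18, "c.2239_2256del18"),
        del_("L747_P753>S",   12, 18, "c.2240_2257del18")),
      description = "EGFR exon 19 common deletions (codons 746-753)"),
    pyro_assay(
      name = "EGFR_exon20_768", target = "CAGCGTGGACAACCCCCACG",
      order = "GCAGTACGTGTCGTGTACGTGACCACACTG", orientation = "forward",
      variants = list(
        sub_("S768I", 3, "T", "AGC>ATC"),
        ins_("V769_D770insASV", 7, "GCCAGCGTG"),
        ins_("D770_N771insSVD", 10, "AGCGTGGAC"),
        ins_("H773_V774insH", 19, "CAC")),
      description = "EGFR exon 20, codon 768 and insertions"),
    pyro_assay(
      name = "EGFR_exon20_790", target = "ATCAYG",
      wildtype_assignment = c("5" = "C"),
      order = "GATTCATCTG", orientation = "forward",
      variants = list(sub_("T790M", 5, "T", "ACG>ATG")),
      description = "EGFR exon 20, codon 790"),
    pyro_assay(
      name = "EGFR_exon21", target = "CKGGCCAAACDGCTGGGT",
      wildtype_assignment = c("2" = "T", "11" = "T"),
      order = "ACGTGTCACATGTC", orientation = "forward",
      variants = list(
        sub_("L858R", 2, "G", "CTG>CGG in read space"),
        sub_("L861Q", 11, "A", "CTG>CAG")),
      reference_positions = c(2, 9, 11, 12, 14),
      description = "EGFR exon 21, codons 858 and 861"),
    pyro_assay(
      name = "KRAS_codon12_13", target = "NNTGRCGTAGGC",
      wildtype_assignment = c("1" = "G", "2" = "G", "5" = "G"),
      order = "ACTGTACGTGATCGTAGCAAGAG", orientation = "forward",
      variants = list(
        sub_("G12S", 1, "A", "GGT>AGT"),
        sub_("G12C", 1, "T", "GGT>TGT"),
        sub_("G12R", 1, "C", "GGT>CGT"),
        sub_("G12D", 2, "A", "GGT>GAT"),
        sub_("G12V", 2, "T", "GGT>GTT"),
        sub_("G12A", 2, "C", "GGT>GCT"),
        sub_("G13D", 5, "A", "GGC>GAC")),
      description = "KRAS codons 12 and 13"),
    pyro_assay(
      name = "KRAS_codon61", target = "CTCDTGACCTG",
      wildtype_assignment = c("4" = "T"),
      order = "GCTCGATACGACCT", orientation = "reverse",
      variants = list(
        sub_("Q61H.1", 4, "G", "CAA>CAC"),
        sub_("Q61H.2", 4, "A", "CAA>CAT"),
        sub_("Q61L", 5, "A", "CAA>CTA"),
        sub_("Q61R", 5, "C", "CAA>CGA"),
        sub_("Q61K", 6, "T", "CAA>AAA")),
      description = "KRAS codon 61 (reverse sequencing)"),
    pyro_assay(
      name = "BRAF_codon600", target = "CWCTGTAG",
      wildtype_assignment = c("2" = "A"),
      order = "TCGTATCTGTAG", orientation = "reverse",
      variants = list(
        sub_("V600E", 2, "T", "GTG>GAG (sense)"),
        sub_("V600K", 2, "TT", "GTG>AAG (sense)"),
        sub_("V600R", 2, "CT", "GTG>AGG (sense)")),
      reference_positions = c(9, 10, 12),
      description = "BRAF codon 600 (reverse sequencing)")
  )
  stats::setNames(assays, vapply(assays, function(a) a$name, character(1)))
}

get_assay <- function(assay) {
  if (inherits(assay, "pyro_assay")) return(assay)
  all <- builtin_assays()
  if (!is.character(assay) || length(assay) != 1L || !assay %in% names(all))
    stop_invalid("unknown assay '", paste(assay, collapse = ","),
                 "'; built-in assays: ", paste(names(all), collapse = ", "))
  all[[assay]]
}
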