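test_that("group_sv_records maps every SyRI type to its major category", {
  recs <- data.table::data.table(
    ref_chrom = "c1", ref_start = 0L, ref_end = 100L,
    qry_chrom = "c1", qry_start = 0L, qry_end = 100L,
    raw_type = c("SYN", "SNP", "TRANS", "INVTR", "INV", "CPL", "CPG",
                 "DUP", "DUP", "INVDP", "INVDP", "INS", "INS", "DEL", "DEL"),
    copy_status = c(".", ".", ".", ".", ".", ".", ".",
                    "gain", "loss", "gain", "loss", ".", ".", ".", "."),
    length = c(100L, 1L, 100L, 100L, 100L, 100L, 100L,
               100L, 100L, 100L, 100L, 50L, 51L, 50L, 51L))
  got <- group_sv_records(recs)
  expect_identical(got$grouped_category,
                   c("SYN", "SNP", "TRANS", "TRANS", "INV", "AV", "PV",
                     "PV", "AV", "PV", "AV", "short", "PV", "short", "AV"))
  bad <- data.table::copy(recs)[1L, "raw_type" := "XX"]
  expect_error(group_sv_records(bad), "unknown SV type")
  nodup <- data.table::copy(recs)[8L, "copy_status" := "."]
  expect_error(group_sv_records(nodup), "copy_status")
})

test_that("summarize_sv_categories totals the four major categories", {
  got <- summarize_sv_categories(c(TRANS = 5, INV = 2, AV = 7, PV = 3,
                                   short = 99))
  expect_equal(got$total, 17)
  expect_equal(unname(got$counts), c(5, 2, 7, 3))
  recs <- data.table::data.table(
    grouped_category = c("TRANS", "AV", "AV", "short", "SYN", "PV"))
  got2 <- summarize_sv_categories(recs)
  expect_equal(got2$total, 4)
  expect_equal(got2$counts[["AV"]], 2)
})

test_that("allele_pair_bins aligns bins 5' to 3' on both haplotypes", {
  cfg <- hm_config(window_size = 100L, step_size = 100L, flank_size = 200L)
  pairs <- data.table::data.table(pair_id = "pair_1", maternal_id = "gM",
                                  paternal_id = "gP")
  genes_m <- data.table::data.table(gene_id = "gM", chrom = "h1",
                                    strand = "+", start = 2000L,
                                    end = 2400L)
  genes_p <- data.table::data.table(gene_id = "gP", chrom = "h2",
                                    strand = "-", start = 3000L,
                                    end = 3400L)
  # one CG site per 100-bp window; the k-th bin along transcription carries
  # c_meth = k on both alleles, so aligned bins must agree exactly
  m_sites <- data.table::data.table(
    chrom = "h1", pos = 1800L + 100L * (0:7) + 50L, strand = "+",
    context = "CG", c_meth = 1:8, c_total = 10L)
  # the paternal gene is on the minus strand: its bin k sits in the
  # (9-k)-th genomic window of the span [2800, 3600)
  p_sites <- data.table::data.table(
    chrom = "h2", pos = 2800L + 100L * (0:7) + 50L, strand = "+",
    context = "CG", c_meth = 8:1, c_total = 10L)
  bins <- allele_pair_bins(list(m_sites), list(p_sites), pairs,
                           genes_m, genes_p, cfg)
  expect_identical(nrow(bins), 8L)
  expect_identical(bins$bin, 1:8)
  expect_equal(bins$m_meth, as.numeric(1:8))
  expect_equal(bins$p_meth, as.numeric(1:8))
  # genomically, paternal bin 1 is the rightmost window
  expect_identical(bins$p_start[bins$bin == 1L], 3500L)
  expect_identical(bins$p_start[bins$bin == 8L], 2800L)
  expect_identical(bins$m_start[bins$bin == 1L], 1800L)
  # sub-threshold sites are excluded
  shallow <- data.table::copy(m_sites)[, "c_total" := 4L]
  bins2 <- allele_pair_bins(list(shallow), list(p_sites), pairs,
                            genes_m, genes_p, cfg)
  expect_identical(nrow(bins2), 0L)
})

test_that("detect_asmrs finds nothing when alleles are identical", {
  b <- data.table::data.table(
    pair_id = "pair_1", bin = 1:5, context = "CG",
    m_chrom = "h1", m_start = 0L, m_end = 100L,
    p_chrom = "h2", p_start = 0L, p_end = 100L,
    m_meth = c(10, 40, 80, 0, 55), m_total = 100,
    m_n_cyt = 10L,
    p_meth = c(10, 40, 80, 0, 55), p_total = 100,
    p_n_cyt = 10L)
  got <- detect_asmrs(b)
  expect_equal(got$delta, rep(0, 5L))
  expect_equal(got$p_value, rep(1, 5L))
  expect_false(any(got$is_asmr))
  expect_false(any(call_asmgs(got)$is_asmg))
})

test_that("detect_asmrs is antisymmetric under haplotype swap", {
  set.seed(41)
  n <- 40L
  b <- data.table::data.table(
    pair_id = paste0("pair_", 1:n), bin = 1L,
    context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
    m_chrom = "h1", m_start = 0L, m_end = 100L,
    p_chrom = "h2", p_start = 0L, p_end = 100L,
    m_meth = rbinom(n, 200, runif(n)), m_total = 200,
    m_n_cyt = 10L,
    p_meth = rbinom(n, 150, runif(n)), p_total = 150,
    p_n_cyt = 10L)
  sw <- data.table::copy(b)
  data.table::setnames(sw,
                       c("m_meth", "m_total", "m_n_cyt",
                         "p_meth", "p_total", "p_n_cyt"),
                       c("p_meth", "p_total", "p_n_cyt",
                         "m_meth", "m_total", "m_n_cyt"))
  fwd <- detect_asmrs(b)
  rev <- detect_asmrs(sw)
  data.table::setorderv(fwd, "pair_id")
  data.table::setorderv(rev, "pair_id")
  expect_equal(fwd$delta, -rev$delta)
  expect_equal(fwd$p_value, rev$p_value)
  expect_identical(fwd$is_asmr, rev$is_asmr)
  # bins with too few cytosines on either allele are dropped
  few <- data.table::copy(b)[1L, "m_n_cyt" := 5L]
  expect_identical(nrow(detect_asmrs(few)), n - 1L)
})

test_that("grade_delta enumerates the grade boundaries", {
  d <- c(24.9, 25, 49.9, 50, 74.9, 75, 99.9, 100, -60)
  expect_identical(grade_delta(d, "CG"),
                   c(NA, 1L, 1L, 2L, 2L, 3L, 3L, NA, 2L))
  expect_identical(grade_delta(d, "CHG"),
                   c(NA, 1L, 1L, 2L, 2L, 3L, 3L, NA, 2L))
  dh <- c(14.9, 15, 34.9, 35, 54.9, 55, -40)
  expect_identical(grade_delta(dh, "CHH"),
                   c(NA, 1L, 1L, 2L, 2L, NA, 2L))
})

test_that("fc_by_grade groups pairs by their ASMR grades", {
  asmrs <- data.table::data.table(
    pair_id = c("a", "b", "c", "d"), context = "CG", is_asmr = TRUE,
    delta = c(30, -60, 80, 10))  # grades 1, 2, 3, NA
  ase <- data.table::data.table(
    pair_id = c("a", "b", "c", "d"),
    log2fc = c(0.5, -1.5, 3, 9),
    bias_class = c("M", "P", "M", "U"))
  got <- fc_by_grade(ase, asmrs, "CG", aseg_only = TRUE)
  expect_equal(unname(got$medians), c(0.5, 1.5, 3))
  expect_identical(names(got$medians), c("1", "2", "3"))
  expect_identical(got$values$pair_id, c("a", "b", "c"))
  # with aseg_only = FALSE the ungraded pair d is still excluded
  got2 <- fc_by_grade(ase, asmrs, "CG", aseg_only = FALSE)
  expect_identical(got2$values$pair_id, c("a", "b", "c"))
  # rows of other contexts must not leak into the requested context
  mixed <- rbind(asmrs,
                 data.table::data.table(pair_id = c("a", "b"),
                                        context = "CHH", is_asmr = TRUE,
                                        delta = c(40, 40)))
  got_cg <- fc_by_grade(ase, mixed, "CG")
  expect_identical(got_cg$values, got$values)
  got_chh <- fc_by_grade(ase, mixed, "CHH")
  expect_identical(sort(got_chh$values$pair_id), c("a", "b"))
  expect_identical(unique(got_chh$values$grade), 2L)
})

test_that("overlap_sv_alleles tallies features with the exon-over-intron rule", {
  genes_m <- data.table::data.table(gene_id = "gA", chrom = "c1",
                                    strand = "+", start = 10000L,
                                    end = 12000L)
  genes_p <- data.table::data.table(gene_id = "gB", chrom = "c1q",
                                    strand = "+", start = 10000L,
                                    end = 12000L)
  exons_m <- data.table::data.table(
    gene_id = "gA", chrom = "c1",
    start = c(10000L, 11500L), end = c(10500L, 12000L))
  sv <- function(rs, re, qs, qe, cat) data.table::data.table(
    ref_chrom = "c1", ref_start = rs, ref_end = re,
    qry_chrom = "c1q", qry_start = qs, qry_end = qe,
    grouped_category = cat)
  svs <- rbind(
    sv(10100L, 10200L, 50000L, 50100L, "AV"),     # exon (maternal)
    sv(10800L, 10900L, 9000L, 9100L, "PV"),       # intron + qry promoter
    sv(10400L, 10600L, 70000L, 70100L, "TRANS"),  # exon AND intron span
    sv(10000L, 12000L, 10000L, 12000L, "short"))  # excluded category
  got <- overlap_sv_alleles(svs, genes_m, genes_p, exons_m, NULL,
                            flank = 2000L)
  fc <- got$feature_counts
  expect_identical(fc$n_sv_feature[fc$feature == "exon"], 2L)
  # sv3 spans exon and intron of gA but counts only as exonic
  expect_identical(fc$n_sv_feature[fc$feature == "intron"], 1L)
  expect_identical(fc$n_sv_feature[fc$feature == "promoter"], 1L)
  expect_false("downstream" %in% fc$feature)
  expect_identical(unique(fc$n_sv_distinct), 3L)
  gf <- got$gene_flags
  expect_identical(gf$gene_id[gf$haplotype == "maternal"], "gA")
  expect_identical(gf$gene_id[gf$haplotype == "paternal"], "gB")
  expect_true(all(gf$has_sv))
})

test_that("compare_asmr_sv splits bins by SV overlap on either haplotype", {
  mk <- function(i, m_start, delta) data.table::data.table(
    pair_id = paste0("pair_", i), bin = 1L, context = "CG",
    m_chrom = "c1", m_start = m_start, m_end = m_start + 200L,
    p_chrom = "c1q", p_start = 900000L + 1000L * i,
    p_end = 900000L + 1000L * i + 200L,
    delta = delta, is_asmr = TRUE)
  a <- data.table::rbindlist(c(
    lapply(1:3, function(i) mk(i, 10000L + 1000L * i, c(80, 70, 60)[i])),
    lapply(4:6, function(i) mk(i, 500000L + 1000L * i, c(30, 35, 40)[i - 3L]))))
  svs <- data.table::data.table(
    ref_chrom = "c1", ref_start = 10000L, ref_end = 14000L,
    qry_chrom = "other", qry_start = 0L, qry_end = 1L,
    grouped_category = "AV")
  got <- compare_asmr_sv(a, svs)
  cg <- got[got$context == "CG", ]
  expect_identical(cg$n_sv, 3L)
  expect_identical(cg$n_nonsv, 3L)
  expect_equal(cg$median_sv, 70)
  expect_equal(cg$median_nonsv, 35)
  expect_equal(cg$p_value,
               stats::wilcox.test(c(80, 70, 60), c(30, 35, 40))$p.value)
  expect_true(all(is.na(got$p_value[got$context != "CG"])))
})

test_that("sv_location_test matches the closed-form chi-square on a 2x3 table", {
  a <- c(gene_body = 30, upstream = 10, downstream = 10)
  b <- c(gene_body = 10, upstream = 20, downstream = 20)
  got <- sv_location_test(a, b)
  O <- rbind(a, b)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum((O - E)^2 / E)
  expect_equal(got$statistic, stat)
  expect_equal(unname(got$df), 2)
  expect_equal(got$p_value, stats::pchisq(stat, 2L, lower.tail = FALSE))
})

test_that("validate_breakpoints requires full coverage of breakpoint windows", {
  svs <- data.table::data.table(ref_chrom = "c1", ref_start = 30000L,
                                ref_end = 32000L)
  reads <- data.table::data.table(
    chrom = "c1",
    start = c(9000L, 29000L, 29900L),
    end = c(31000L, 39000L, 40000L))
  got <- validate_breakpoints(reads, svs, min_flank = 500L,
                              hc_length = 20000L)
  st <- got[got$breakpoint == "start", ]
  en <- got[got$breakpoint == "end", ]
  # start window [29500, 30500): covered by reads 1 and 2; read 1 is 22 kb
  expect_identical(st$n_support, 2L)
  expect_identical(st$n_high_confidence, 1L)
  # end window [31500, 32500): covered by reads 2 and 3, neither > 20 kb
  expect_identical(en$n_support, 2L)
  expect_identical(en$n_high_confidence, 0L)
})
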