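test_that("annotate_region applies the midpoint priority rules", {
  genes <- data.table::data.table(
    gene_id = c("g_plus", "g_minus"),
    chrom = c("chr1", "chr1"),
    strand = c("+", "-"),
    start = c(10000L, 40000L),
    end = c(14000L, 44000L))
  exons <- data.table::data.table(
    gene_id = c("g_plus", "g_plus", "g_minus"),
    chrom = "chr1",
    start = c(10000L, 13000L, 40000L),
    end = c(11000L, 14000L, 44000L))
  regions <- data.table::data.table(
    chrom = "chr1",
    #        promoter+  exon     intron     downstr+  intergenic
    start = c(9000L,    10200L,  11500L,    14500L,   20000L,
    #        promoter-  downstr-
              44500L,   39000L),
    end   = c(9200L,    10400L,  11700L,    14700L,   20200L,
              44700L,   39200L))
  ann <- annotate_region(regions, genes, exons, flank = 2000L)
  expect_identical(ann$feature,
                   c("promoter", "exon", "intron", "downstream", "intergenic",
                     "promoter", "downstream"))
  expect_identical(ann$gene_id,
                   c("g_plus", "g_plus", "g_plus", "g_plus", NA,
                     "g_minus", "g_minus"))
  # strand-aware distance to the TSS (negative upstream)
  expect_identical(ann$distance_to_tss[1L], 9100L - 10000L)
  expect_identical(ann$distance_to_tss[6L], -(44600L - 43999L))
})

test_that("annotate_region prefers promoter over exon at overlaps", {
  # two genes head-to-head: the promoter of g2 lies inside the exon of g1
  genes <- data.table::data.table(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = c("+", "+"),
    start = c(0L, 5000L), end = c(4000L, 9000L))
  reg <- data.table::data.table(chrom = "chr1", start = 3400L, end = 3600L)
  ann <- annotate_region(reg, genes, exons = NULL, flank = 2000L)
  expect_identical(ann$feature, "promoter")
  expect_identical(ann$gene_id, "g2")
})

test_that("call_dmgs uses gene body plus flanks with a hard boundary", {
  genes <- data.table::data.table(
    gene_id = "g1", chrom = "chr1", strand = "+",
    start = 10000L, end = 12000L)
  mk <- function(start, end) data.table::data.table(
    chrom = "chr1", start = start, end = end, context = "CG",
    direction = "hypo")
  # flank span is [8000, 14000): a DMR ending at 8000 does not touch it
  expect_identical(nrow(call_dmgs(mk(7800L, 8000L), genes)), 0L)
  expect_identical(call_dmgs(mk(7801L, 8001L), genes)$gene_id, "g1")
  expect_identical(call_dmgs(mk(13999L, 14100L), genes)$gene_id, "g1")
  expect_identical(nrow(call_dmgs(mk(14000L, 14200L), genes)), 0L)
  # duplicates collapse to one row per gene/context/direction
  two <- rbind(mk(10100L, 10300L), mk(11000L, 11200L))
  expect_identical(nrow(call_dmgs(two, genes)), 1L)
  expect_identical(nrow(call_dmgs(mk(0L, 0L)[0L], genes)), 0L)
})

test_that("dmr_feature_proportions fractions sum to one per stratum", {
  genes <- data.table::data.table(
    gene_id = "g1", chrom = "chr1", strand = "+",
    start = 10000L, end = 14000L)
  dmrs <- data.table::data.table(
    chrom = "chr1",
    start = c(9000L, 10500L, 20000L, 9100L),
    end = c(9200L, 10700L, 20200L, 9300L),
    context = c("CG", "CG", "CG", "CHH"),
    direction = c("hypo", "hypo", "hypo", "hyper"))
  fp <- dmr_feature_proportions(dmrs, genes)
  cg <- fp[fp$context == "CG", ]
  expect_equal(sum(cg$fraction), 1)
  expect_equal(cg$fraction[cg$feature == "promoter"], 1 / 3)
  expect_identical(fp$fraction[fp$context == "CHH"], 1)
})

test_that("metaprofile has 80 bins and mirrors minus-strand features", {
  # one plus-strand and one minus-strand gene with a methylation gradient
  # rising 5'->3' along each gene's own orientation: their profiles must
  # coincide bin for bin
  flank <- 200L
  mkgene <- function(strand, start) data.table::data.table(
    gene_id = paste0("g", strand), chrom = "chr1", strand = strand,
    start = start, end = start + 400L)
  g_plus <- mkgene("+", 1000L)
  g_minus <- mkgene("-", 5000L)
  mk_sites <- function(g) {
    pos <- seq(g$start - flank + 5L, g$end + flank - 5L, by = 10L)
    # fractional position along transcription direction
    relc <- (pos - (g$start - flank)) / (g$end - g$start + 2L * flank)
    if (g$strand == "-") relc <- 1 - relc
    data.table::data.table(
      chrom = "chr1", pos = pos, strand = "+", context = "CG",
      c_meth = as.integer(round(relc * 100)), c_total = 100L)
  }
  prof_p <- metaprofile(mk_sites(g_plus), g_plus, body_bins = 40L,
                        flank_bins = 20L, flank = flank)
  prof_m <- metaprofile(mk_sites(g_minus), g_minus, body_bins = 40L,
                        flank_bins = 20L, flank = flank)
  expect_identical(nrow(prof_p), 80L * 3L)
  expect_identical(prof_p$zone,
                   rep(rep(c("upstream", "body", "downstream"),
                           c(20L, 40L, 20L)), 3L))
  cg_p <- prof_p[prof_p$context == "CG", ]
  cg_m <- prof_m[prof_m$context == "CG", ]
  expect_equal(cg_p$level, cg_m$level, tolerance = 0.02)
  # the gradient rises monotonically across bins
  expect_true(all(diff(cg_p$level[!is.na(cg_p$level)]) >= 0))
})

test_that("metaprofile skips features shorter than the bin count", {
  short_gene <- data.table::data.table(gene_id = "tiny", chrom = "chr1",
                                       strand = "+", start = 100L,
                                       end = 130L)
  sites <- data.table::data.table(chrom = "chr1", pos = 110L, strand = "+",
                                  context = "CG", c_meth = 5L,
                                  c_total = 10L)
  prof <- metaprofile(sites, short_gene, body_bins = 40L, flank_bins = 20L,
                      flank = 200L)
  expect_true(all(prof$n_features == 0L))
})

test_that("gene_bin_levels agrees with metaprofile when aggregated", {
  set.seed(17)
  genes <- data.table::data.table(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = c("+", "-"),
    start = c(1000L, 8000L), end = c(3000L, 9500L))
  sites <- random_sites(2000L, span = 12000L, chroms = "chr1")
  gb <- gene_bin_levels(sites, genes, body_bins = 10L, flank_bins = 5L,
                        flank = 500L)
  mp <- metaprofile(sites, genes, body_bins = 10L, flank_bins = 5L,
                    flank = 500L)
  agg <- gb[, list(sum_c_meth = sum(sum_c_meth),
                   sum_c_total = sum(sum_c_total)),
            by = c("context", "bin")]
  m <- merge(agg, mp, by = c("context", "bin"))
  expect_gt(nrow(m), 0L)
  expect_equal(m$sum_c_meth.x, m$sum_c_meth.y)
  expect_equal(m$sum_c_total.x, m$sum_c_total.y)
  expect_true(all(gb$level >= 0 & gb$level <= 1))
})

test_that("find_telomeres needs ten copies in the terminal kilobase", {
  pad <- function(n) paste(rep("ACGT", n), collapse = "")
  mk <- function(copies_left, copies_right) {
    paste0(strrep("CCCTAAA", copies_left), pad(50L),
           strrep("GATTACA", 300L), pad(50L),
           strrep("TTTAGGG", copies_right))
  }
  seqs <- c(ten = mk(10L, 12L), nine = mk(9L, 0L))
  tel <- find_telomeres(seqs, window = 1000L, min_copies = 10L)
  expect_identical(tel$telomeric[tel$chrom == "ten" & tel$end == "left"],
                   TRUE)
  expect_identical(tel$telomeric[tel$chrom == "ten" & tel$end == "right"],
                   TRUE)
  expect_identical(tel$motif_count[tel$chrom == "ten" & tel$end == "right"],
                   12L)
  expect_identical(tel$telomeric[tel$chrom == "nine" & tel$end == "left"],
                   FALSE)
  expect_identical(tel$motif_count[tel$chrom == "nine" & tel$end == "left"],
                   9L)
})
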