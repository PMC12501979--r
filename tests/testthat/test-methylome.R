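test_that("classify_context matches hand-worked trinucleotides", {
  #       0123456789
  seq <- "CGACAGCTTC"
  # plus strand cytosines: pos 0 (CGA -> CG), 3 (CAG -> CHG), 6 (CTT -> CHH),
  # pos 9 is the last base (no downstream bases -> none)
  expect_identical(classify_context(seq, c(0L, 3L, 6L, 9L), "+"),
                   c("CG", "CHG", "CHH", "none"))
  # minus strand: G at pos 2 of ACGT reads 5'-C G ...-3' on the minus
  # strand -> CG; a G at pos 1 lacks two upstream bases -> none
  expect_identical(classify_context("ACGT", 2L, "-"), "CG")
  expect_identical(classify_context(seq, 1L, "-"), "none")
  # G at pos 5 on minus strand: complement upstream reads C T G -> CHG
  expect_identical(classify_context(seq, 5L, "-"), "CHG")
  # not a cytosine on the requested strand is an error
  expect_error(classify_context(seq, 1L, "+"), "not a cytosine")
})

test_that("classify_context is undefined near ends and at Ns", {
  expect_identical(classify_context("ACGNC", 1L, "+"), "none")  # CGN has N
  expect_identical(classify_context("ACGTC", 4L, "+"), "none")  # chromosome end
  expect_identical(classify_context("GGAAA", 1L, "-"), "none")  # start on minus
  expect_identical(classify_context("AATCG", 4L, "-"), "CG")
})

test_that("genome_cytosines enumerates both strands and agrees with classify_context", {
  seqs <- c(c1 = "ACGGTCCANCGTT")
  cyt <- genome_cytosines(seqs)
  # every reported site's context must equal the per-site classification
  for (i in seq_len(nrow(cyt))) {
    expect_identical(
      classify_context(seqs[["c1"]], cyt$pos[i], cyt$strand[i]),
      cyt$context[i])
  }
  # brute-force plus-strand enumeration
  bases <- strsplit(seqs[["c1"]], "")[[1L]]
  plus_c <- which(bases == "C") - 1L
  plus_expected <- plus_c[vapply(plus_c, function(p)
    classify_context(seqs[["c1"]], p, "+") != "none", logical(1L))]
  expect_identical(sort(cyt$pos[cyt$strand == "+"]), sort(plus_expected))
  minus_g <- which(bases == "G") - 1L
  minus_expected <- minus_g[vapply(minus_g, function(p)
    p >= 2L && classify_context(seqs[["c1"]], p, "-") != "none", logical(1L))]
  expect_identical(sort(cyt$pos[cyt$strand == "-"]), sort(minus_expected))
})

test_that("weighted level is depth-weighted, not a mean of per-site levels", {
  sites <- data.table::data.table(
    c_meth = c(10L, 1L), c_total = c(10L, 100L))
  got <- weighted_methylation_level(sites)
  expect_equal(got$level, 11 / 110)
  expect_false(got$undefined)
  # equal depths reduce to the mean of per-site levels
  eq <- data.table::data.table(c_meth = c(2L, 8L), c_total = c(10L, 10L))
  expect_equal(weighted_methylation_level(eq)$level, mean(c(0.2, 0.8)))
  # no covered sites -> undefined
  none <- data.table::data.table(c_meth = integer(), c_total = integer())
  expect_true(weighted_methylation_level(none)$undefined)
  expect_true(is.na(weighted_methylation_level(none)$level))
  # sub_threshold sites are excluded
  st <- data.table::data.table(c_meth = c(5L, 100L), c_total = c(10L, 100L),
                               sub_threshold = c(FALSE, TRUE))
  expect_equal(weighted_methylation_level(st)$level, 0.5)
})

test_that("estimate_conversion_error pools lambda counts", {
  lam <- data.table::data.table(
    context = c("CG", "CG", "CHH", "CHG"),
    c_meth = c(1L, 0L, 2L, 0L),
    c_total = c(100L, 50L, 150L, 0L))
  est <- estimate_conversion_error(lam)
  expect_equal(est$pooled, 3 / 300)
  expect_equal(est$conversion_rate, 1 - 3 / 300)
  expect_equal(unname(est$per_context[c("CG", "CHH")]),
               c(1 / 150, 2 / 150))
  expect_true(is.na(est$per_context[["CHG"]]))  # no covered CHG sites
  expect_error(estimate_conversion_error(lam[lam$c_total == 0L]),
               "no covered lambda sites")
})

test_that("call_methylated_sites handles depth threshold and validates inputs", {
  sites <- data.table::data.table(
    c_meth = c(4L, 4L, 0L), c_total = c(4L, 5L, 20L),
    context = "CG")
  got <- call_methylated_sites(sites, error_rate = 0.005)
  expect_identical(got$call[1L], "sub_threshold")
  expect_true(is.na(got$p_value[1L]))
  expect_identical(got$call[2L], "methylated")
  expect_identical(got$call[3L], "unmethylated")
  expect_error(call_methylated_sites(sites, error_rate = 0), "error_rate")
  expect_error(call_methylated_sites(sites, error_rate = 0.005, fdr = 1),
               "fdr")
})

test_that("histogram bins are half-open with the top bin closed", {
  sites <- data.table::data.table(
    context = "CG",
    c_meth = c(0L, 1L, 9L, 10L, 5L, 2L),
    c_total = c(10L, 10L, 10L, 10L, 10L, 4L))  # last site below depth 5
  h <- methylation_level_histogram(sites, n_levels = 10L, depth_min = 5L)
  cg <- h[h$context == "CG", ]
  expect_identical(nrow(cg), 10L)
  expect_identical(cg$count[cg$bin == 1L], 1L)   # level 0.0 -> [0, 0.1)
  expect_identical(cg$count[cg$bin == 2L], 1L)   # level 0.1 -> [0.1, 0.2)
  expect_identical(cg$count[cg$bin == 10L], 2L)  # 0.9 and 1.0 share top bin
  expect_identical(cg$count[cg$bin == 6L], 1L)   # level 0.5
  expect_identical(sum(cg$count), 5L)            # shallow site excluded
  expect_equal(cg$lower, seq(0, 0.9, by = 0.1))
  expect_equal(cg$upper, seq(0.1, 1, by = 0.1))
  # other contexts are present with zero counts
  expect_identical(sum(h$count[h$context != "CG"]), 0L)
})

test_that("context_share sums to one and flags the empty case", {
  sites <- data.table::data.table(
    context = c("CG", "CG", "CHG", "CHH"),
    call = c("methylated", "methylated", "methylated", "unmethylated"))
  sh <- context_share(sites)
  expect_equal(unname(sh), c(2 / 3, 1 / 3, 0))
  expect_equal(sum(sh), 1)
  empty <- context_share(sites[sites$call == "none", ])
  expect_true(all(is.na(empty)))
  expect_true(isTRUE(attr(empty, "undefined")))
})

test_that("region_methylation restricts to regions and matches the scalar form", {
  set.seed(7)
  sites <- random_sites(300L, span = 1000L)
  regions <- data.table::data.table(chrom = c("chr1", "chr2"),
                                    start = c(100L, 0L),
                                    end = c(400L, 250L))
  got <- region_methylation(sites, regions, by_context = FALSE,
                            drop_sub_threshold = FALSE)
  for (i in seq_len(nrow(regions))) {
    sub <- sites[sites$chrom == regions$chrom[i] &
                   sites$pos >= regions$start[i] &
                   sites$pos < regions$end[i], ]
    want <- weighted_methylation_level(sub)
    row <- got[got$region_idx == i, ]
    if (nrow(sub) == 0L) {
      expect_identical(nrow(row), 0L)
    } else {
      expect_identical(row$n_sites, want$n_sites)
      expect_equal(row$level, want$level)
    }
  }
})

test_that("genome_methylation_summary computes both denominators", {
  sites <- data.table::data.table(
    context = c("CG", "CG", "CG", "CHH"),
    c_meth = c(8L, 0L, 2L, 0L),
    c_total = c(10L, 10L, 4L, 10L),
    sub_threshold = c(FALSE, FALSE, TRUE, FALSE),
    call = c("methylated", "unmethylated", "sub_threshold", "unmethylated"))
  allc <- data.table::data.table(context = c(rep("CG", 5L), rep("CHH", 2L)))
  sm <- genome_methylation_summary(sites, allc)
  cg <- sm[sm$context == "CG", ]
  expect_equal(cg$level, 8 / 20)         # sub-threshold site excluded
  expect_identical(cg$n_methylated, 1L)
  expect_equal(cg$frac_of_covered, 1 / 2)  # 2 tested sites, 1 methylated
  expect_equal(cg$frac_of_all, 1 / 5)
})
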