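test_that("compact_letters satisfies the letter-display consistency property", {
  set.seed(51)
  for (rep in 1:20) {
    k <- sample(3:6, 1L)
    grps <- paste0("G", seq_len(k))
    pmat <- matrix(NA_real_, k, k, dimnames = list(grps, grps))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i < j) pmat[i, j] <- pmat[j, i] <- runif(1L)^2
    }
    med <- stats::setNames(runif(k), grps)
    ltr <- compact_letters(pmat, alpha = 0.05, medians = med)
    share <- function(a, b) {
      any(strsplit(ltr[[a]], "")[[1L]] %in% strsplit(ltr[[b]], "")[[1L]])
    }
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i < j) {
        if (pmat[i, j] < 0.05) {
          # significantly different groups never share a letter
          expect_false(share(grps[i], grps[j]))
        } else {
          # non-significant pairs must share at least one letter
          expect_true(share(grps[i], grps[j]))
        }
      }
    }
    expect_true(all(nzchar(ltr)))
  }
})

test_that("compact_letters gives distinct letters to separated groups", {
  grps <- c("lo", "mid", "hi")
  pmat <- matrix(c(NA, 1e-6, 1e-9,
                   1e-6, NA, 1e-6,
                   1e-9, 1e-6, NA), 3L, dimnames = list(grps, grps))
  ltr <- compact_letters(pmat, alpha = 0.01,
                         medians = c(lo = 0.1, mid = 0.5, hi = 0.9))
  expect_identical(unname(ltr["hi"]), "a")
  expect_identical(length(unique(ltr)), 3L)
})

test_that("meth_by_expression_rank orders groups and matches wilcox oracles", {
  set.seed(52)
  n <- 40L
  gene_levels <- data.table::data.table(
    gene_id = paste0("g", seq_len(3L * n)),
    level = c(runif(n, 0.7, 0.9), runif(n, 0.4, 0.6), runif(n, 0.05, 0.2)))
  rk <- stats::setNames(rep(c("N", "LM", "H"), each = n),
                        gene_levels$gene_id)
  got <- meth_by_expression_rank(gene_levels, rk, alpha = 0.01)
  expect_equal(got$medians[["N"]],
               stats::median(gene_levels$level[1:n]))
  oracle <- stats::wilcox.test(gene_levels$level[1:n],
                               gene_levels$level[(n + 1):(2 * n)],
                               exact = TRUE)$p.value
  expect_equal(got$pairwise["N", "LM"], oracle)
  expect_identical(unname(got$letters["N"]), "a")
  expect_identical(length(unique(got$letters)), 3L)
})

test_that("categorize_levels applies its closed boundaries", {
  got <- categorize_levels(c(0, 1e-6, 0.10, 0.100001, 0.20, 0.200001, 1))
  expect_identical(as.character(got),
                   c("zero", "LML", "LML", "MML", "MML", "HML", "HML"))
  expect_error(categorize_levels(c(0.5, 1.2)))
})

test_that("category_fractions sums to one within each rank group", {
  levels <- c(0, 0.05, 0.15, 0.5, 0, 0.9)
  rk <- c("N", "N", "N", "N", "H", "H")
  got <- category_fractions(levels, rk)
  sums <- got[, list(s = sum(fraction)), by = "rank_group"]
  expect_equal(sums$s, rep(1, 2L))
  expect_equal(got$fraction[got$rank_group == "N" &
                              got$category == "zero"], 1 / 4)
})

test_that("dmg_deg_enrichment equals the hypergeometric tail by enumeration", {
  set.seed(53)
  universe <- paste0("g", 1:60)
  dmg <- sample(universe, 18L)
  deg <- c(sample(dmg, 7L), sample(setdiff(universe, dmg), 5L))
  got <- dmg_deg_enrichment(dmg, deg, universe)
  N <- 60L; K <- 18L; n <- 12L; k <- 7L
  # direct enumeration of P(overlap >= k)
  p_enum <- sum(vapply(k:min(K, n), function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1L))) / choose(N, n)
  expect_equal(got$p_value, p_enum)
  expect_identical(got$table["deg", "dmg"], 7L)
  expect_identical(sum(got$table), 60L)
  expect_gt(got$odds_ratio, 1)
  expect_error(dmg_deg_enrichment(c(dmg, "absent"), deg, universe))
})

test_that("binwise_expression_correlation matches cor.test per bin", {
  set.seed(54)
  samples <- paste0("s", 1:8)
  tpm <- matrix(runif(16L, 1, 100), nrow = 2L,
                dimnames = list(c("gA", "gB"), samples))
  mk <- function(gene, bin, lv) data.table::data.table(
    gene_id = gene, bin = bin, context = "CG", sample = samples, level = lv)
  lv1 <- tpm["gA", ] / 100 + rnorm(8L, 0, 0.01)      # strongly positive
  lv2 <- 1 - tpm["gB", ] / 100 + rnorm(8L, 0, 0.01)  # strongly negative
  bl <- rbind(mk("gA", 1L, lv1), mk("gB", 1L, lv2),
              mk("gA", 2L, rep(0.5, 8L)))            # constant -> dropped
  got <- binwise_expression_correlation(bl, tpm, min_samples = 8L)
  res <- got$correlations
  expect_identical(nrow(res), 2L)
  oracle <- stats::cor.test(lv1, tpm["gA", ])
  rowA <- res[res$gene_id == "gA", ]
  expect_equal(rowA$r, unname(oracle$estimate))
  expect_equal(rowA$p_value, oracle$p.value)
  tal <- got$tallies
  expect_identical(tal$n_raw_pos, 1L)
  expect_identical(tal$n_raw_neg, 1L)
  # bins with fewer samples than min_samples are excluded
  got2 <- binwise_expression_correlation(bl[-1L], tpm, min_samples = 8L)
  expect_false("gA" %in%
                 got2$correlations$gene_id[got2$correlations$bin == 1L])
})

test_that("negative correlations dominate the tally under repressive coupling", {
  # with methylation repressing expression in most gene bodies, bins with a
  # significant negative methylation-expression correlation outnumber
  # positive ones at least two-fold
  set.seed(55)
  samples <- paste0("s", 1:8)
  n_neg <- 30L; n_pos <- 10L
  genes <- paste0("g", seq_len(n_neg + n_pos))
  expr <- matrix(runif((n_neg + n_pos) * 8L, 5, 120),
                 nrow = n_neg + n_pos, dimnames = list(genes, samples))
  bl <- data.table::rbindlist(lapply(seq_along(genes), function(i) {
    sgn <- if (i <= n_neg) -1 else 1
    data.table::rbindlist(lapply(1:3, function(b) {
      lv <- 0.5 + sgn * (expr[i, ] - mean(expr[i, ])) / 300 +
        rnorm(8L, 0, 0.02)
      data.table::data.table(gene_id = genes[i], bin = b, context = "CG",
                             sample = samples,
                             level = pmin(pmax(lv, 0), 1))
    }))
  }))
  got <- binwise_expression_correlation(bl, expr, min_samples = 8L)
  tal <- got$tallies
  expect_gte(tal$n_raw_neg, 2L * tal$n_raw_pos)
  expect_gt(tal$n_raw_neg, 0L)
})

test_that("te_fluctuation separates fluctuating TE genes from flat ones", {
  set.seed(56)
  mk <- function(gene, rvals) data.table::data.table(
    gene_id = gene, bin = seq_along(rvals), context = "CG", r = rvals)
  te_genes <- paste0("te", 1:8)
  flat_genes <- paste0("fl", 1:8)
  cc <- data.table::rbindlist(c(
    lapply(te_genes, function(g) mk(g, rnorm(10L, 0, 0.6))),
    lapply(flat_genes, function(g) mk(g, rnorm(10L, 0, 0.05)))))
  flags <- stats::setNames(rep(c(TRUE, FALSE), each = 8L),
                           c(te_genes, flat_genes))
  got <- te_fluctuation(cc, flags)
  expect_identical(got$n_te, 8L)
  expect_identical(got$n_nonte, 8L)
  expect_gt(got$median_te, got$median_nonte)
  expect_lt(got$p_value, 0.01)
  fl <- attr(got, "fluctuations")
  one <- fl[fl$gene_id == "te1", ]
  expect_equal(one$fluctuation, stats::sd(cc$r[cc$gene_id == "te1"]))
  # genes with fewer than min_bins bins are dropped
  got2 <- te_fluctuation(cc[cc$bin <= 2L], flags)
  expect_identical(nrow(got2), 0L)
})
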