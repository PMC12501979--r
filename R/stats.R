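# Methylation x expression intersection statistics and supporting tests.

#' Compact letter display from a pairwise p-value table
#'
#' Groups sharing a letter are pairwise non-significant at `alpha`, and any
#' two groups that are not significantly different share at least one
#' letter (insert-and-absorb construction: start from one all-group letter,
#' split it at every significant pair, and drop letters whose group set is
#' contained in another's). Letter 'a' attaches to the letter group
#' containing the highest median (ties by name).
#'
#' @param pmat symmetric matrix of pairwise p-values with group dimnames
#' @param alpha significance level
#' @param medians named vector of group medians used for ordering
#' @return named character vector of letter strings
#' @export
compact_letters <- function(pmat, alpha = 0.01, medians = NULL) {
  groups <- rownames(pmat)
  if (is.null(medians)) medians <- stats::setNames(rep(0, length(groups)),
                                                   groups)
  ord <- groups[order(-medians[groups], groups)]
  cliques <- list(ord)
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (i >= j) next
      a <- ord[i]; b <- ord[j]
      p <- pmat[a, b]
      if (is.na(p) || p >= alpha) next
      nxt <- list()
      for (cl in cliques) {
        if (a %in% cl && b %in% cl) {
          nxt <- c(nxt, list(setdiff(cl, a)), list(setdiff(cl, b)))
        } else {
          nxt <- c(nxt, list(cl))
        }
      }
      keep <- rep(TRUE, length(nxt))
      for (x in seq_along(nxt)) {
        for (y in seq_along(nxt)) {
          if (x == y || !keep[x] || !keep[y]) next
          if (all(nxt[[x]] %in% nxt[[y]]) &&
              (length(nxt[[x]]) < length(nxt[[y]]) || x > y)) {
            keep[x] <- FALSE
          }
        }
      }
      cliques <- nxt[keep]
    }
  }
  first_pos <- vapply(cliques, function(cl) min(match(cl, ord)), numeric(1L))
  cliques <- cliques[order(first_pos)]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(cliques)) {
    for (g in cliques[[k]]) {
      letters_out[g] <- paste0(letters_out[g], letters[k])
    }
  }
  letters_out[groups]
}

#' Methylation levels by expression rank group
#'
#' Per-gene region methylation levels are grouped by the gene's expression
#' rank (N/L/LM/MH/H); all pairwise two-sided Wilcoxon rank-sum tests are
#' summarized as a compact letter display at `alpha`.
#'
#' @param gene_levels data.frame with gene_id and level (fraction)
#' @param rank_groups named vector/factor of rank groups per gene_id
#' @param alpha significance level for the letter display
#' @return list with `distributions` (rank_group, gene_id, level),
#'   `pairwise` (p-value matrix), `letters`, `medians`
#' @export
meth_by_expression_rank <- function(gene_levels, rank_groups,
                                    alpha = 0.01) {
  g <- data.table::data.table(
    gene_id = gene_levels$gene_id,
    level = gene_levels$level,
    rank_group = as.character(rank_groups[gene_levels$gene_id]))
  g <- g[!is.na(g$level) & !is.na(g$rank_group), ]
  grps <- .rank_levels[.rank_levels %in% unique(g$rank_group)]
  pmat <- matrix(NA_real_, length(grps), length(grps),
                 dimnames = list(grps, grps))
  for (i in seq_along(grps)) for (j in seq_along(grps)) {
    if (i < j) {
      x <- g$level[g$rank_group == grps[i]]
      y <- g$level[g$rank_group == grps[j]]
      if (length(x) > 1L && length(y) > 1L) {
        p <- stats::wilcox.test(x, y,
                                exact = length(x) < 50 && length(y) < 50
                                )$p.value
        pmat[i, j] <- pmat[j, i] <- p
      }
    }
  }
  medians <- vapply(grps, function(gr) {
    stats::median(g$level[g$rank_group == gr])
  }, numeric(1L))
  list(distributions = g[order(g$rank_group, g$gene_id)],
       pairwise = pmat,
       letters = compact_letters(pmat, alpha, medians),
       medians = medians)
}

#' Categorize methylation levels
#'
#' zero (level = 0), LML (0 < level <= 10%), MML (10% < level <= 20%),
#' HML (level > 20%).
#'
#' @param levels numeric fractions in [0, 1]
#' @return factor with levels zero/LML/MML/HML
#' @export
categorize_levels <- function(levels) {
  stopifnot(all(levels >= 0 & levels <= 1, na.rm = TRUE))
  out <- rep(NA_character_, length(levels))
  out[levels == 0] <- "zero"
  out[levels > 0 & levels <= 0.10] <- "LML"
  out[levels > 0.10 & levels <= 0.20] <- "MML"
  out[levels > 0.20] <- "HML"
  factor(out, levels = c("zero", "LML", "MML", "HML"))
}

#' Fraction of genes per methylation category within rank groups
#'
#' @param levels numeric fractions per gene
#' @param rank_groups rank group per gene
#' @return data.table with rank_group, category, n, fraction (fractions sum
#'   to 1 within each rank group)
#' @export
category_fractions <- function(levels, rank_groups) {
  d <- data.table::data.table(rank_group = as.character(rank_groups),
                              category = categorize_levels(levels))
  d <- d[!is.na(d$category) & !is.na(d$rank_group), ]
  out <- d[, list(n = .N), by = c("rank_group", "category")]
  out[, "fraction" := n / sum(n), by = "rank_group"]
  data.table::setorderv(out, c("rank_group", "category"))
  out[]
}

#' Enrichment of DMGs among DEGs
#'
#' One-tailed Fisher's exact test (enrichment direction) on the 2x2 table of
#' DEG x DMG membership over a gene universe; the odds ratio is the
#' conditional maximum-likelihood estimate.
#'
#' @param dmg_set,deg_set character vectors of gene ids
#' @param universe character vector containing both sets
#' @return list with p_value, odds_ratio, table
#' @export
dmg_deg_enrichment <- function(dmg_set, deg_set, universe) {
  stopifnot(all(dmg_set %in% universe), all(deg_set %in% universe))
  is_dmg <- universe %in% dmg_set
  is_deg <- universe %in% deg_set
  tab <- matrix(c(sum(is_deg & is_dmg), sum(is_deg & !is_dmg),
                  sum(!is_deg & is_dmg), sum(!is_deg & !is_dmg)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(deg = c("deg", "non_deg"),
                                dmg = c("dmg", "non_dmg")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}

#' Per-bin correlation between methylation and expression across samples
#'
#' For every (gene, bin, context) with at least `min_samples` paired
#' observations and non-constant methylation, the Pearson correlation of
#' the bin's methylation level with the gene's expression (TPM) across
#' samples is computed; bins are tallied by correlation sign at p < 0.05
#' (raw, as is conventional for these counts; a BH-adjusted tally is also
#' reported).
#'
#' @param bin_levels data.table with gene_id, bin, context, sample, level
#' @param tpm matrix genes x samples
#' @param min_samples minimum paired samples per bin
#' @return list with `correlations` (gene_id, bin, context, r, p_value,
#'   q_value) and `tallies` (context, sign, n_raw, n_bh)
#' @export
binwise_expression_correlation <- function(bin_levels, tpm,
                                           min_samples = 6L) {
  b <- data.table::as.data.table(bin_levels)
  b <- b[!is.na(b$level) & b$gene_id %in% rownames(tpm) &
           b$sample %in% colnames(tpm), ]
  b[, "expr" := tpm[cbind(b$gene_id, b$sample)]]
  res <- b[, {
    ok <- !is.na(level) & !is.na(expr)
    if (sum(ok) >= min_samples && stats::sd(level[ok]) > 0 &&
        stats::sd(expr[ok]) > 0) {
      ct <- stats::cor.test(level[ok], expr[ok], method = "pearson")
      list(r = unname(ct$estimate), p_value = ct$p.value,
           n = sum(ok))
    } else {
      list(r = NA_real_, p_value = NA_real_, n = sum(ok))
    }
  }, by = c("gene_id", "bin", "context")]
  res <- res[!is.na(res$r), ]
  res[, "q_value" := stats::p.adjust(p_value, method = "BH"),
      by = "context"]
  tal <- res[, list(
    n_raw_pos = sum(p_value < 0.05 & r > 0),
    n_raw_neg = sum(p_value < 0.05 & r < 0),
    n_bh_pos = sum(q_value < 0.05 & r > 0),
    n_bh_neg = sum(q_value < 0.05 & r < 0)), by = "context"]
  list(correlations = res[], tallies = tal[order(tal$context)])
}

#' Methylation-profile fluctuation of gene-TE vs gene-non-TE genes
#'
#' Fluctuation is the standard deviation of a gene's per-bin methylation /
#' expression Pearson correlations along the gene body; distributions are
#' compared between genes containing TEs and genes without by a two-sided
#' Wilcoxon rank-sum test, per context.
#'
#' @param correlations per-bin correlation table (gene_id, bin, context, r),
#'   body bins only
#' @param te_flags named logical vector per gene_id (TRUE = contains TE)
#' @param min_bins minimum bins per gene to compute an SD
#' @return data.table with context, n_te, n_nonte, median_te, median_nonte,
#'   p_value, plus a `fluctuations` attribute table
#' @export
te_fluctuation <- function(correlations, te_flags, min_bins = 3L) {
  cc <- data.table::as.data.table(correlations)
  fl <- cc[, list(fluctuation = if (.N >= min_bins) stats::sd(r)
                  else NA_real_),
           by = c("gene_id", "context")]
  fl <- fl[!is.na(fl$fluctuation), ]
  fl[, "is_te" := te_flags[fl$gene_id]]
  fl <- fl[!is.na(fl$is_te), ]
  res <- fl[, {
    x <- fluctuation[is_te]
    y <- fluctuation[!is_te]
    if (length(x) > 1L && length(y) > 1L) {
      wt <- stats::wilcox.test(x, y, exact = FALSE)
      list(n_te = length(x), n_nonte = length(y),
           median_te = stats::median(x), median_nonte = stats::median(y),
           p_value = wt$p.value)
    } else {
      list(n_te = length(x), n_nonte = length(y),
           median_te = NA_real_, median_nonte = NA_real_,
           p_value = NA_real_)
    }
  }, by = "context"]
  data.table::setattr(res, "fluctuations", fl[])
  res[order(res$context)]
}
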