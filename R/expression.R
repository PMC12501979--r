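# Expression quantification (TPM), expression-rank groups, differential
# expression, and allele-specific expression classification.

.rank_levels <- c("N", "L", "LM", "MH", "H")
.bias_levels <- c("M", "P", "U")

#' Compute TPM from a count matrix
#'
#' Standard transcripts-per-million: per-gene rate = count / length (bp),
#' scaled so each sample column sums to 1e6.
#'
#' @param counts genes x samples count matrix (rownames = gene ids)
#' @param gene_lengths named vector of union-exon lengths in bp
#' @return TPM matrix of the same shape
#' @export
compute_tpm <- function(counts, gene_lengths) {
  len <- gene_lengths[rownames(counts)]
  if (anyNA(len)) stop_hm("missing gene length for %s",
                          rownames(counts)[which(is.na(len))[1L]])
  if (any(len <= 0)) stop_hm("zero-length gene %s",
                             rownames(counts)[which(len <= 0)[1L]])
  rate <- counts / len
  sweep(rate, 2L, colSums(rate), "/") * 1e6
}

#' Group genes by ranked expression level
#'
#' The five groups and their exact TPM boundaries: N (TPM = 0),
#' L (0 < TPM <= 1), LM (1 < TPM <= 7), MH (7 < TPM <= 100), H (TPM > 100).
#'
#' @param tpm TPM matrix or vector
#' @return factor (vector) or character matrix of group labels
#' @export
rank_expression <- function(tpm) {
  grp <- function(x) {
    out <- character(length(x))
    out[x == 0] <- "N"
    out[x > 0 & x <= 1] <- "L"
    out[x > 1 & x <= 7] <- "LM"
    out[x > 7 & x <= 100] <- "MH"
    out[x > 100] <- "H"
    out
  }
  if (is.matrix(tpm)) {
    out <- apply(tpm, 2L, grp)
    dimnames(out) <- dimnames(tpm)
    out
  } else {
    factor(grp(tpm), levels = .rank_levels)
  }
}

#' Call differentially expressed genes
#'
#' Counts are pooled within each group and compared with an exact
#' rate-ratio test (binomial conditional test, `poisson.test`) using
#' library-size totals as exposure. The fold change is computed on
#' library-size-normalized group means with a pseudocount of 1. A gene is a
#' DEG when BH q < `fdr` and |log2 fold change| > `lfc`.
#'
#' @param counts genes x samples count matrix
#' @param groups character/factor of length ncol(counts) with two levels;
#'   the first level is the test group, the second the control
#' @param lfc absolute log2 fold-change threshold
#' @param fdr q-value threshold
#' @return data.table with gene_id, log2fc, p_value, q_value, deg_status
#'   (up/down/ns)
#' @export
call_degs <- function(counts, groups, lfc = 1, fdr = 0.05) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, length(groups) == ncol(counts))
  g1 <- groups == levels(groups)[1L]
  g2 <- !g1
  lib <- colSums(counts)
  n1 <- sum(lib[g1]); n2 <- sum(lib[g2])
  x1 <- rowSums(counts[, g1, drop = FALSE])
  x2 <- rowSums(counts[, g2, drop = FALSE])
  # normalized means to a common scale (mean library size)
  scale_to <- mean(lib)
  m1 <- x1 / n1 * scale_to
  m2 <- x2 / n2 * scale_to
  log2fc <- log2((m1 + 1) / (m2 + 1))
  p <- vapply(seq_along(x1), function(i) {
    if (x1[i] + x2[i] == 0) return(1)
    stats::poisson.test(c(x1[i], x2[i]), c(n1, n2))$p.value
  }, numeric(1L))
  q <- stats::p.adjust(p, method = "BH")
  status <- rep("ns", length(p))
  sig <- q < fdr & abs(log2fc) > lfc
  status[sig & log2fc > 0] <- "up"
  status[sig & log2fc < 0] <- "down"
  hm_log(sprintf("call_degs: %d genes, %d DEGs (%d up, %d down) at |log2FC|>%g & FDR<%g",
                 length(p), sum(sig), sum(status == "up"),
                 sum(status == "down"), lfc, fdr))
  data.table::data.table(gene_id = rownames(counts), log2fc = log2fc,
                         p_value = p, q_value = q, deg_status = status)
}

#' Classify allele-specific expression
#'
#' For each maternal/paternal allele pair, counts are summed jointly over
#' samples and the maternal count is tested against the maternal proportion
#' expected from the library-size totals with an exact binomial test. The
#' log2 fold change (maternal vs paternal) is computed on
#' library-size-normalized totals with a pseudocount of 1. Bias class is M
#' or P when BH q < `fdr` and |log2fc| >= `lfc`, U otherwise; pairs with
#' zero total counts are U with an undefined log2fc flag. Relabeling the
#' haplotypes swaps M and P and negates every log2fc.
#'
#' @param pair_counts data.frame with pair_id and per-sample maternal /
#'   paternal count columns, or a list with elements `maternal` and
#'   `paternal` (matrices pairs x samples)
#' @param library_sizes list with `maternal` and `paternal` per-sample
#'   totals (summed allele counts per library); defaults to column sums
#' @param fdr q-value threshold
#' @param lfc absolute log2 fold-change threshold
#' @return data.table with pair_id, m_total, p_total, log2fc, p_value,
#'   q_value, bias_class, undefined_fc
#' @export
classify_ase <- function(pair_counts, library_sizes = NULL, fdr = 0.05,
                         lfc = 1) {
  mm <- pair_counts$maternal
  pp <- pair_counts$paternal
  stopifnot(is.matrix(mm), is.matrix(pp), all(dim(mm) == dim(pp)))
  if (is.null(library_sizes)) {
    library_sizes <- list(maternal = colSums(mm), paternal = colSums(pp))
  }
  Lm <- sum(library_sizes$maternal)
  Lp <- sum(library_sizes$paternal)
  p0 <- Lm / (Lm + Lp)
  m_tot <- rowSums(mm)
  p_tot <- rowSums(pp)
  n_tot <- m_tot + p_tot
  # normalized totals on a common scale
  scale_to <- (Lm + Lp) / 2
  m_norm <- m_tot / Lm * scale_to
  p_norm <- p_tot / Lp * scale_to
  log2fc <- log2((m_norm + 1) / (p_norm + 1))
  pv <- vapply(seq_along(m_tot), function(i) {
    if (n_tot[i] == 0) return(1)
    stats::binom.test(m_tot[i], n_tot[i], p = p0)$p.value
  }, numeric(1L))
  qv <- stats::p.adjust(pv, method = "BH")
  cls <- rep("U", length(m_tot))
  sig <- qv < fdr & abs(log2fc) >= lfc
  cls[sig & log2fc > 0] <- "M"
  cls[sig & log2fc < 0] <- "P"
  undef <- n_tot == 0
  log2fc[undef] <- NA_real_
  pair_id <- pair_counts$pair_id %||% rownames(mm) %||%
    paste0("pair_", seq_along(m_tot))
  hm_log(sprintf("classify_ase: %d pairs, %d M / %d P / %d U at FDR<%g & |log2FC|>=%g",
                 length(cls), sum(cls == "M"), sum(cls == "P"),
                 sum(cls == "U"), fdr, lfc))
  data.table::data.table(pair_id = pair_id, m_total = m_tot,
                         p_total = p_tot, log2fc = log2fc, p_value = pv,
                         q_value = qv, bias_class = cls,
                         undefined_fc = undef)
}

#' Cross-tabulate allele bias classes between two conditions
#'
#' 3x3 contingency of (epimutant class, control class) over the same pair
#' universe; margins equal the class totals of each condition.
#'
#' @param epimutant_classes character vector in {M,P,U}
#' @param control_classes character vector in {M,P,U}, same pairs same order
#' @return 3x3 integer matrix, rows = epimutant, cols = control
#' @export
crosstab_bias <- function(epimutant_classes, control_classes) {
  stopifnot(length(epimutant_classes) == length(control_classes))
  tab <- table(factor(epimutant_classes, levels = .bias_levels),
               factor(control_classes, levels = .bias_levels))
  m <- matrix(as.integer(tab), nrow = 3L,
              dimnames = list(epimutant = .bias_levels,
                              control = .bias_levels))
  m
}
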