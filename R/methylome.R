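# Per-site methylation calling and weighted methylation levels.
#
# A cytosine site is represented as one row of a data.table with columns
# chrom, pos (0-based), strand, context (CG/CHG/CHH), c_meth (reads
# supporting methylation), c_total (covering reads) and, after calling,
# p_value/q_value/call.

#' Classify the sequence context of cytosines
#'
#' Plant methylation contexts are read strand-aware from the trinucleotide
#' starting at the cytosine: CG when the next base is G, CHG for C-H-G and
#' CHH for C-H-H (H = A, C or T). When fewer than two downstream bases exist
#' (chromosome end) or the trinucleotide contains an N, the context is
#' undefined ("none") and the site is excluded from all statistics.
#'
#' @param seq a single chromosome sequence (character scalar, uppercase)
#' @param pos 0-based positions of cytosines (on the plus strand for
#'   `strand == "+"`; for `strand == "-"` the position of the G whose
#'   complement is the cytosine)
#' @param strand "+" or "-", recycled
#' @return character vector in {"CG","CHG","CHH","none"}
#' @export
classify_context <- function(seq, pos, strand) {
  n <- length(pos)
  strand <- rep_len(strand, n)
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(bases)
  p1 <- pos + 1L  # 1-based index
  base_here <- bases[p1]
  ok_c <- (strand == "+" & base_here == "C") |
    (strand == "-" & base_here == "G")
  if (any(!ok_c, na.rm = TRUE) || anyNA(base_here)) {
    stop_hm("classify_context: base at position %d is not a cytosine on strand %s",
            pos[which(!ok_c | is.na(base_here))[1L]],
            strand[which(!ok_c | is.na(base_here))[1L]])
  }
  nxt1 <- ifelse(strand == "+", p1 + 1L, p1 - 1L)
  nxt2 <- ifelse(strand == "+", p1 + 2L, p1 - 2L)
  in_range <- nxt2 >= 1L & nxt2 <= L
  b1 <- rep(NA_character_, n); b2 <- rep(NA_character_, n)
  b1[in_range] <- bases[nxt1[in_range]]
  b2[in_range] <- bases[nxt2[in_range]]
  minus <- strand == "-"
  b1[minus] <- chartr("ACGTN", "TGCAN", b1[minus])
  b2[minus] <- chartr("ACGTN", "TGCAN", b2[minus])
  out <- rep("none", n)
  valid <- in_range & b1 %in% c("A", "C", "G", "T") &
    b2 %in% c("A", "C", "G", "T")
  h <- c("A", "C", "T")
  out[valid & b1 == "G"] <- "CG"
  out[valid & b1 %in% h & b2 == "G"] <- "CHG"
  out[valid & b1 %in% h & b2 %in% h] <- "CHH"
  out
}

#' Enumerate all context-defined cytosines of a genome
#'
#' Scans both strands of every chromosome and returns each cytosine whose
#' trinucleotide context is defined.
#'
#' @param seqs named character vector of chromosome sequences
#' @return data.table with chrom, pos (0-based), strand, context,
#'   trinucleotide
#' @export
genome_cytosines <- function(seqs) {
  res <- vector("list", 2L * length(seqs))
  k <- 0L
  for (chrom in names(seqs)) {
    bases <- strsplit(seqs[[chrom]], "", fixed = TRUE)[[1L]]
    L <- length(bases)
    # plus strand: C at p with 2 downstream bases
    pc <- which(bases == "C")
    pc <- pc[pc + 2L <= L]
    if (length(pc)) {
      b1 <- bases[pc + 1L]; b2 <- bases[pc + 2L]
      ctx <- .tri_context(b1, b2)
      keep <- ctx != "none"
      k <- k + 1L
      res[[k]] <- data.table::data.table(
        chrom = chrom, pos = pc[keep] - 1L, strand = "+",
        context = ctx[keep],
        trinucleotide = paste0("C", b1[keep], b2[keep]))
    }
    # minus strand: G at p with 2 upstream bases
    pg <- which(bases == "G")
    pg <- pg[pg - 2L >= 1L]
    if (length(pg)) {
      b1 <- chartr("ACGTN", "TGCAN", bases[pg - 1L])
      b2 <- chartr("ACGTN", "TGCAN", bases[pg - 2L])
      ctx <- .tri_context(b1, b2)
      keep <- ctx != "none"
      k <- k + 1L
      res[[k]] <- data.table::data.table(
        chrom = chrom, pos = pg[keep] - 1L, strand = "-",
        context = ctx[keep],
        trinucleotide = paste0("C", b1[keep], b2[keep]))
    }
  }
  out <- data.table::rbindlist(res[seq_len(k)])
  data.table::setorderv(out, c("chrom", "pos", "strand"))
  out[]
}

.tri_context <- function(b1, b2) {
  out <- rep("none", length(b1))
  h <- c("A", "C", "T")
  acgt <- c("A", "C", "G", "T")
  valid <- b1 %in% acgt & b2 %in% acgt
  out[valid & b1 == "G"] <- "CG"
  out[valid & b1 %in% h & b2 == "G"] <- "CHG"
  out[valid & b1 %in% h & b2 %in% h] <- "CHH"
  out
}

#' Estimate the bisulfite conversion error from the lambda spike-in
#'
#' The unmethylated lambda control should read fully unmethylated; any
#' methylated calls measure incomplete conversion. The apparent methylation
#' rate sum(c_meth)/sum(c_total) equals 1 minus the conversion rate.
#'
#' @param lambda_sites cytosine site table from the lambda chromosome
#' @return list with `pooled` (fraction), `per_context` (named vector) and
#'   `conversion_rate` (1 - pooled)
#' @export
estimate_conversion_error <- function(lambda_sites) {
  cov <- lambda_sites[lambda_sites$c_total > 0, ]
  if (nrow(cov) == 0L) stop_hm("no covered lambda sites")
  pooled <- sum(cov$c_meth) / sum(cov$c_total)
  per_ctx <- vapply(.valid_contexts, function(ctx) {
    s <- cov[cov$context == ctx, ]
    if (nrow(s) == 0L) return(NA_real_)
    sum(s$c_meth) / sum(s$c_total)
  }, numeric(1L))
  list(pooled = pooled, per_context = per_ctx,
       conversion_rate = 1 - pooled)
}

#' Call methylated cytosines by binomial test
#'
#' Sites with depth >= `depth_min` are tested against the conversion error
#' rate with an upper-tail binomial test (P(X >= c_meth | c_total,
#' error_rate)); Benjamini-Hochberg correction is applied jointly over all
#' tested sites and a site is called methylated when q < `fdr`. Sites below
#' the depth threshold keep the call "sub_threshold" and are not tested.
#'
#' @param sites cytosine site table
#' @param error_rate apparent methylation rate of unmethylated DNA, from
#'   [estimate_conversion_error()]
#' @param depth_min minimum depth for a testable site
#' @param fdr q-value threshold
#' @return the table with p_value, q_value and call columns added
#' @export
call_methylated_sites <- function(sites, error_rate, depth_min = 5L,
                                  fdr = 0.05) {
  if (!(error_rate > 0 && error_rate < 1)) {
    stop_hm("error_rate must be in (0,1), got %g", error_rate)
  }
  if (!(fdr > 0 && fdr < 1)) stop_hm("fdr must be in (0,1), got %g", fdr)
  sites <- data.table::as.data.table(sites)
  tested <- sites$c_total >= as.integer(depth_min)
  p <- rep(NA_real_, nrow(sites))
  p[tested] <- stats::pbinom(sites$c_meth[tested] - 1L,
                             sites$c_total[tested], error_rate,
                             lower.tail = FALSE)
  q <- rep(NA_real_, nrow(sites))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  call <- rep("sub_threshold", nrow(sites))
  call[tested] <- ifelse(q[tested] < fdr, "methylated", "unmethylated")
  sites[, "p_value" := p]
  sites[, "q_value" := q]
  sites[, "call" := call]
  hm_log(sprintf("call_methylated_sites: %d sites in, %d tested (depth>=%d), %d methylated (FDR<%g)",
                 nrow(sites), sum(tested), depth_min,
                 sum(call == "methylated"), fdr), level = "debug")
  sites[]
}

#' Weighted methylation level of a set of sites
#'
#' The weighted level is sum(c_meth) / sum(c_total) over the cytosines of a
#' region, weighting each site by its read depth. Sites flagged
#' `sub_threshold` are excluded when the column is present.
#'
#' @param sites cytosine site table, already restricted to the region and
#'   context of interest
#' @return one-row data.table: n_sites, sum_c_meth, sum_c_total, level,
#'   undefined (TRUE when no covered sites)
#' @export
weighted_methylation_level <- function(sites) {
  if (!is.null(sites$sub_threshold)) {
    sites <- sites[!sites$sub_threshold, ]
  }
  sm <- sum(as.numeric(sites$c_meth))
  st <- sum(as.numeric(sites$c_total))
  data.table::data.table(
    n_sites = nrow(sites), sum_c_meth = sm, sum_c_total = st,
    level = if (st > 0) sm / st else NA_real_,
    undefined = st == 0)
}

#' Weighted methylation levels over many regions
#'
#' Vectorized companion of [weighted_methylation_level()]: assigns sites to
#' regions by overlap and aggregates counts per region (and per context when
#' `by_context`).
#'
#' @param sites cytosine site table
#' @param regions data.frame with chrom, start, end (0-based half-open)
#' @param by_context split levels by context (default TRUE)
#' @param drop_sub_threshold exclude sites flagged sub-threshold
#' @return data.table with region_idx, (context), n_sites, sum_c_meth,
#'   sum_c_total, level; regions without covered sites are absent
#' @export
region_methylation <- function(sites, regions, by_context = TRUE,
                               drop_sub_threshold = TRUE) {
  sites <- data.table::as.data.table(sites)
  if (drop_sub_threshold && !is.null(sites$sub_threshold)) {
    sites <- sites[!sites$sub_threshold, ]
  }
  # a site contributes to every region containing it, so overlapping
  # regions are each summarized from their full complement of sites
  hits <- overlap_pairs(
    data.table::data.table(chrom = sites$chrom, start = sites$pos,
                           end = sites$pos + 1L),
    regions)
  s <- sites[hits$qidx, ]
  s[, "region_idx" := hits$sidx]
  byv <- if (by_context) c("region_idx", "context") else "region_idx"
  out <- s[, list(n_sites = .N,
                  sum_c_meth = sum(as.numeric(c_meth)),
                  sum_c_total = sum(as.numeric(c_total))),
           by = byv]
  out[, "level" := ifelse(out$sum_c_total > 0,
                          out$sum_c_meth / out$sum_c_total, NA_real_)]
  data.table::setorderv(out, byv)
  out[]
}

#' Histogram of per-site methylation levels in ranked bins
#'
#' Per-site levels c_meth/c_total of sites at depth >= `depth_min` are
#' binned into `n_levels` equal bins, half-open except the last ([0,10%),
#' [10,20%), ..., [90,100%]).
#'
#' @param sites cytosine site table
#' @param n_levels number of bins (10)
#' @param depth_min minimum depth for inclusion
#' @return data.table with context, bin (1..n_levels), lower, upper, count
#' @export
methylation_level_histogram <- function(sites, n_levels = 10L,
                                        depth_min = 5L) {
  s <- data.table::as.data.table(sites)
  s <- s[s$c_total >= as.integer(depth_min), ]
  lev <- s$c_meth / s$c_total
  bin <- pmin(floor(lev * n_levels) + 1L, n_levels)  # level 1.0 -> top bin
  s[, "bin" := bin]
  grid <- data.table::CJ(context = .valid_contexts, bin = seq_len(n_levels))
  cnt <- s[, list(count = .N), by = c("context", "bin")]
  out <- merge(grid, cnt, by = c("context", "bin"), all.x = TRUE)
  out[is.na(out$count), "count" := 0L]
  out[, "lower" := (out$bin - 1L) / n_levels]
  out[, "upper" := out$bin / n_levels]
  data.table::setcolorder(out, c("context", "bin", "lower", "upper", "count"))
  data.table::setorderv(out, c("context", "bin"))
  out[]
}

#' Share of methylated sites by context
#'
#' Fractions of CG/CHG/CHH among sites called methylated.
#'
#' @param sites called site table (see [call_methylated_sites()])
#' @return named numeric vector (CG, CHG, CHH) summing to 1, or all NA with
#'   attribute `undefined = TRUE` when no site is methylated
#' @export
context_share <- function(sites) {
  m <- sites[sites$call == "methylated", ]
  if (nrow(m) == 0L) {
    out <- stats::setNames(rep(NA_real_, 3L), .valid_contexts)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  tab <- table(factor(m$context, levels = .valid_contexts))
  out <- as.numeric(tab) / nrow(m)
  names(out) <- .valid_contexts
  out
}

#' Genome-wide methylation summary
#'
#' Weighted level per context plus the fraction of methylated sites using
#' both denominators (all context-defined cytosines and covered cytosines
#' only).
#'
#' @param sites called site table
#' @param all_cytosines optional table of every context-defined cytosine in
#'   the genome (for the all-C denominator); when NULL that column is NA
#' @return data.table with context, level, n_methylated, frac_of_covered,
#'   frac_of_all
#' @export
genome_methylation_summary <- function(sites, all_cytosines = NULL) {
  s <- data.table::as.data.table(sites)
  if (is.null(s$sub_threshold)) s[, "sub_threshold" := FALSE]
  if (is.null(s$call)) s[, "call" := NA_character_]
  out <- s[, {
    cov <- c_total > 0
    tested <- !is.na(call) & call != "sub_threshold"
    meth <- call == "methylated"
    list(level = sum(as.numeric(c_meth[!sub_threshold])) /
           sum(as.numeric(c_total[!sub_threshold])),
         n_methylated = sum(meth),
         n_covered = sum(cov),
         frac_of_covered = sum(meth) / max(sum(tested), 1L))
  }, by = "context"]
  if (!is.null(all_cytosines)) {
    tot <- data.table::as.data.table(all_cytosines)[, list(n_all = .N),
                                                    by = "context"]
    out <- merge(out, tot, by = "context", all.x = TRUE)
    out[, "frac_of_all" := out$n_methylated / out$n_all]
  } else {
    out[, "frac_of_all" := NA_real_]
  }
  data.table::setorderv(out, "context")
  out[]
}
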