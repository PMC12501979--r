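# Allele-specific methylation (ASMR/ASMG), methylation-divergence grades,
# SyRI category grouping, and SV overlap statistics.

#' Group SyRI records into major SV categories
#'
#' TRANS and INVTR become TRANS; INV stays INV; CPL, DEL and DUP/INVDP
#' copy-loss become AV (absent variation); CPG, INS and DUP/INVDP copy-gain
#' become PV (present variation). INS/DEL records of length <= 50 bp are
#' short variations ("short"), excluded from SV sets. SYN and SNP records
#' pass through unchanged.
#'
#' @param records SV table from [read_syri_table()]
#' @return the table with `grouped_category` filled in
#' @export
group_sv_records <- function(records) {
  records <- data.table::as.data.table(records)
  raw <- records$raw_type
  bad <- setdiff(unique(raw), .valid_sv_types)
  if (length(bad)) stop_hm("unknown SV type code '%s'", bad[1L])
  grp <- rep(NA_character_, length(raw))
  grp[raw %in% c("SYN", "SNP")] <- raw[raw %in% c("SYN", "SNP")]
  grp[raw %in% c("TRANS", "INVTR")] <- "TRANS"
  grp[raw == "INV"] <- "INV"
  grp[raw == "CPL"] <- "AV"
  grp[raw == "CPG"] <- "PV"
  grp[raw == "DEL"] <- ifelse(records$length[raw == "DEL"] <= 50L,
                              "short", "AV")
  grp[raw == "INS"] <- ifelse(records$length[raw == "INS"] <= 50L,
                              "short", "PV")
  dup <- raw %in% c("DUP", "INVDP")
  if (any(dup)) {
    cs <- records$copy_status[dup]
    if (any(!cs %in% c("gain", "loss"))) {
      stop_hm("DUP/INVDP records need copy_status gain or loss")
    }
    grp[dup] <- ifelse(cs == "gain", "PV", "AV")
  }
  records[, "grouped_category" := grp]
  records[]
}

#' Per-category SV counts and total
#'
#' Counts records in the four major SV categories (TRANS, INV, AV, PV); the
#' total is their sum, the accounting used for headline SV totals.
#'
#' @param records grouped SV table, or a named numeric vector of per-category
#'   counts
#' @return list with `counts` (named vector TRANS/INV/AV/PV) and `total`
#' @export
summarize_sv_categories <- function(records) {
  cats <- c("TRANS", "INV", "AV", "PV")
  if (is.numeric(records)) {
    counts <- records[cats]
  } else {
    tab <- table(factor(records$grouped_category, levels = cats))
    counts <- stats::setNames(as.numeric(tab), cats)
  }
  list(counts = counts, total = sum(counts))
}

#' Aggregate haplotype-resolved methylation into allele-pair bins
#'
#' Each paired gene's span (gene body plus `flank` bp on both sides) is
#' tiled with the same window/step scheme as DMR detection, on each
#' haplotype separately; bin indices run 5' to 3' of the gene so bin k of
#' the maternal allele corresponds to bin k of the paternal allele. Only
#' bins defined on both alleles are kept (min of the two bin counts).
#' Cytosines below `depth_min` are excluded; replicates are pooled.
#'
#' @param maternal_reps list of cytosine site tables (hap1 coordinates), one
#'   per replicate
#' @param paternal_reps list for hap2
#' @param pairs allele-pair table (pair_id, maternal_id, paternal_id)
#' @param genes_maternal,genes_paternal gene tables for each haplotype
#' @param config an [hm_config()]
#' @return data.table with pair_id, bin, context, genomic intervals on both
#'   haplotypes, per-allele counts (m_meth, m_total, p_meth, p_total) and
#'   cytosine counts (m_n_cyt, p_n_cyt)
#' @export
allele_pair_bins <- function(maternal_reps, paternal_reps, pairs,
                             genes_maternal, genes_paternal,
                             config = hm_config()) {
  bins_m <- .gene_bins(pairs$maternal_id, genes_maternal, config)
  bins_p <- .gene_bins(pairs$paternal_id, genes_paternal, config)
  agg_m <- .aggregate_bins(maternal_reps, bins_m, config$depth_min)
  agg_p <- .aggregate_bins(paternal_reps, bins_p, config$depth_min)
  pid_m <- pairs$pair_id[match(agg_m$gene_id, pairs$maternal_id)]
  pid_p <- pairs$pair_id[match(agg_p$gene_id, pairs$paternal_id)]
  agg_m[, "pair_id" := pid_m]
  agg_p[, "pair_id" := pid_p]
  m <- merge(agg_m, agg_p, by = c("pair_id", "bin", "context"),
             suffixes = c("_m", "_p"))
  out <- data.table::data.table(
    pair_id = m$pair_id, bin = m$bin, context = m$context,
    m_chrom = m$chrom_m, m_start = m$start_m, m_end = m$end_m,
    p_chrom = m$chrom_p, p_start = m$start_p, p_end = m$end_p,
    m_meth = m$c_meth_m, m_total = m$c_total_m, m_n_cyt = m$n_cyt_m,
    p_meth = m$c_meth_p, p_total = m$c_total_p, p_n_cyt = m$n_cyt_p)
  data.table::setorderv(out, c("pair_id", "context", "bin"))
  out[]
}

# Tile gene spans (body +/- flank) into windows with 5'->3' bin indices.
.gene_bins <- function(gene_ids, genes, config) {
  gi <- match(gene_ids, genes$gene_id)
  if (anyNA(gi)) stop_hm("unknown gene id '%s'", gene_ids[which(is.na(gi))[1L]])
  res <- vector("list", length(gi))
  for (k in seq_along(gi)) {
    g <- genes[gi[k], ]
    s0 <- max(0L, g$start - config$flank_size)
    e0 <- g$end + config$flank_size
    w <- tile_windows(e0 - s0, config$window_size, config$step_size)
    bin <- seq_len(nrow(w))
    if (g$strand == "-") bin <- rev(bin)
    res[[k]] <- data.table::data.table(
      gene_id = g$gene_id, chrom = g$chrom,
      start = w$start + s0, end = w$end + s0, bin = bin)
  }
  data.table::rbindlist(res)
}

.aggregate_bins <- function(sites_reps, bins, depth_min) {
  s <- data.table::rbindlist(lapply(sites_reps, function(x) {
    x <- data.table::as.data.table(x)
    x[x$c_total >= depth_min,
      c("chrom", "pos", "strand", "context", "c_meth", "c_total"),
      with = FALSE]
  }))
  ov <- overlap_pairs(data.table::data.table(chrom = s$chrom, start = s$pos,
                                             end = s$pos + 1L), bins)
  x <- s[ov$qidx, ]
  x[, c("gene_id", "bin", "chrom_b", "start_b", "end_b") := list(
    bins$gene_id[ov$sidx], bins$bin[ov$sidx], bins$chrom[ov$sidx],
    bins$start[ov$sidx], bins$end[ov$sidx])]
  x[, "site_key" := paste0(x$pos, x$strand)]
  out <- x[, list(chrom = chrom_b[1L], start = start_b[1L], end = end_b[1L],
                  n_cyt = data.table::uniqueN(site_key),
                  c_meth = sum(as.numeric(c_meth)),
                  c_total = sum(as.numeric(c_total))),
           by = c("gene_id", "bin", "context")]
  out
}

#' Detect allele-specific methylated regions (ASMRs)
#'
#' Each allele-pair bin is tested maternal vs paternal with the same
#' logistic-regression likelihood-ratio statistic as DMR windows; q-values
#' are BH-adjusted per context. A bin is an ASMR when |delta| (maternal
#' level minus paternal level, percentage points) exceeds the context
#' threshold and q < `q_threshold`. Bins with too few cytosines or no
#' coverage on either allele are skipped.
#'
#' @param pair_bins output of [allele_pair_bins()]
#' @param thresholds named percentage-point thresholds (CG/CHG/CHH)
#' @param q_threshold q-value cutoff
#' @param min_cytosines minimum qualifying cytosines per allele per bin
#' @return data.table of tested bins with delta, p_value, q_value, is_asmr
#' @export
detect_asmrs <- function(pair_bins,
                         thresholds = c(CG = 25, CHG = 25, CHH = 15),
                         q_threshold = 0.05, min_cytosines = 6L) {
  b <- data.table::as.data.table(pair_bins)
  n_in <- nrow(b)
  b <- b[b$m_total > 0 & b$p_total > 0 &
           b$m_n_cyt >= min_cytosines & b$p_n_cyt >= min_cytosines, ]
  hm_log(sprintf("detect_asmrs: %d/%d pair bins testable (>=%d cytosines, coverage on both alleles)",
                 nrow(b), n_in, min_cytosines))
  b[, "delta" := (b$m_meth / b$m_total - b$p_meth / b$p_total) * 100]
  b[, "p_value" := .lrt_group(b$m_meth, b$m_total, b$p_meth, b$p_total)]
  b[, "q_value" := stats::p.adjust(p_value, method = "BH"), by = "context"]
  thr <- thresholds[b$context]
  b[, "is_asmr" := abs(b$delta) > thr & b$q_value < q_threshold]
  b[]
}

#' Flag allele pairs carrying at least one ASMR (ASMGs)
#'
#' @param asmrs output of [detect_asmrs()]
#' @return data.table with pair_id, n_asmr, is_asmg
#' @export
call_asmgs <- function(asmrs) {
  out <- asmrs[, list(n_asmr = sum(is_asmr)), by = "pair_id"]
  out[, "is_asmg" := out$n_asmr >= 1L]
  out[]
}

#' Grade methylation-divergence magnitudes
#'
#' CG/CHG bins are graded 1/2/3 for |delta| in [25,50), [50,75), [75,100);
#' CHH bins 1/2 for [15,35), [35,55). Values outside the grade ranges are
#' ungraded (NA).
#'
#' @param delta signed per-bin divergence in percentage points
#' @param context CG/CHG/CHH, recycled
#' @return integer grades (NA when ungraded)
#' @export
grade_delta <- function(delta, context) {
  context <- rep_len(context, length(delta))
  a <- abs(delta)
  g <- rep(NA_integer_, length(delta))
  cgchg <- context %in% c("CG", "CHG")
  g[cgchg & a >= 25 & a < 50] <- 1L
  g[cgchg & a >= 50 & a < 75] <- 2L
  g[cgchg & a >= 75 & a < 100] <- 3L
  chh <- context == "CHH"
  g[chh & a >= 15 & a < 35] <- 1L
  g[chh & a >= 35 & a < 55] <- 2L
  g
}

#' Expression fold change by methylation-divergence grade
#'
#' For each grade, the distribution of |log2 fold change| between alleles
#' over pairs owning at least one ASMR bin of that grade in the given
#' context; pairwise two-sided Wilcoxon rank-sum comparisons between grades
#' are reported. By default only biased pairs (ASEGs, class M or P) enter.
#'
#' @param ase ASE table from [classify_ase()]
#' @param asmrs ASMR table from [detect_asmrs()]
#' @param context one of CG/CHG/CHH
#' @param aseg_only restrict to pairs classed M or P
#' @return list with `values` (grade, pair_id, abs_log2fc), `medians` (named
#'   by grade), `pairwise` (grade1, grade2, p_value)
#' @export
fc_by_grade <- function(ase, asmrs, context = "CG", aseg_only = TRUE) {
  keep <- asmrs$is_asmr & asmrs$context == context
  a <- asmrs[keep, ]
  a <- data.table::data.table(pair_id = a$pair_id,
                              grade = grade_delta(a$delta, a$context))
  a <- a[!is.na(a$grade), ]
  e <- ase
  if (aseg_only) e <- e[e$bias_class %in% c("M", "P"), ]
  x <- merge(unique(a), e[, c("pair_id", "log2fc")], by = "pair_id")
  x <- x[!is.na(x$log2fc), ]
  vals <- data.table::data.table(grade = x$grade, pair_id = x$pair_id,
                                 abs_log2fc = abs(x$log2fc))
  data.table::setorderv(vals, c("grade", "pair_id"))
  grades <- sort(unique(vals$grade))
  medians <- vapply(grades, function(g) {
    stats::median(vals$abs_log2fc[vals$grade == g])
  }, numeric(1L))
  names(medians) <- as.character(grades)
  pw <- list()
  if (length(grades) >= 2L) {
    cmb <- utils::combn(grades, 2L)
    pw <- lapply(seq_len(ncol(cmb)), function(j) {
      g1 <- vals$abs_log2fc[vals$grade == cmb[1L, j]]
      g2 <- vals$abs_log2fc[vals$grade == cmb[2L, j]]
      p <- if (length(g1) > 1L && length(g2) > 1L) {
        stats::wilcox.test(g1, g2, exact = FALSE)$p.value
      } else NA_real_
      data.table::data.table(grade1 = cmb[1L, j], grade2 = cmb[2L, j],
                             p_value = p)
    })
  }
  list(values = vals, medians = medians,
       pairwise = data.table::rbindlist(pw))
}

#' Overlap SVs with allele gene features
#'
#' Each SV (major categories only) is assigned to every feature class it
#' overlaps in the gene space of paired alleles: exon, intron, promoter
#' (upstream `flank` bp) and downstream (`flank` bp), on the reference side
#' against maternal genes and on the query side against paternal genes.
#' Both a per-feature multi-label tally and a distinct-SV tally are
#' returned, together with per-gene SV flags.
#'
#' @param svs grouped SV table; records outside {TRANS, INV, AV, PV} are
#'   dropped
#' @param genes_maternal,genes_paternal gene tables restricted to paired
#'   alleles
#' @param exons_maternal,exons_paternal optional exon tables; when NULL each
#'   gene body counts as exon
#' @param flank flanking extent in bp
#' @return list with `feature_counts` (feature, n_sv_feature multi-label,
#'   n_sv_distinct), `gene_flags` (gene_id, haplotype, has_sv)
#' @export
overlap_sv_alleles <- function(svs, genes_maternal, genes_paternal,
                               exons_maternal = NULL, exons_paternal = NULL,
                               flank = 2000L) {
  svs <- data.table::as.data.table(svs)
  if (!is.null(svs$grouped_category)) {
    svs <- svs[svs$grouped_category %in% c("TRANS", "INV", "AV", "PV"), ]
  }
  svs[, "sv_id" := seq_len(nrow(svs))]
  one_side <- function(iv, genes, exons, hap) {
    if (is.null(exons)) {
      exons <- data.table::data.table(gene_id = genes$gene_id,
                                      chrom = genes$chrom,
                                      start = genes$start, end = genes$end)
    }
    plus <- genes$strand == "+"
    feats <- list(
      exon = data.table::data.table(chrom = exons$chrom,
                                    start = exons$start, end = exons$end,
                                    gene_id = exons$gene_id),
      intron = data.table::data.table(chrom = genes$chrom,
                                      start = genes$start, end = genes$end,
                                      gene_id = genes$gene_id),
      promoter = data.table::data.table(
        chrom = genes$chrom,
        start = ifelse(plus, genes$start - flank, genes$end),
        end = ifelse(plus, genes$start, genes$end + flank),
        gene_id = genes$gene_id),
      downstream = data.table::data.table(
        chrom = genes$chrom,
        start = ifelse(plus, genes$end, genes$start - flank),
        end = ifelse(plus, genes$end + flank, genes$start),
        gene_id = genes$gene_id))
    parts <- lapply(names(feats), function(fname) {
      ft <- feats[[fname]]
      ov <- overlap_pairs(iv, ft)
      if (nrow(ov) == 0L) {
        return(data.table::data.table(sv_id = integer(),
                                      feature = character(),
                                      gene_id = character()))
      }
      data.table::data.table(sv_id = iv$sv_id[ov$qidx], feature = fname,
                             gene_id = ft$gene_id[ov$sidx])
    })
    x <- data.table::rbindlist(parts)
    x[, "haplotype" := hap]
    x
  }
  ref_iv <- data.table::data.table(chrom = svs$ref_chrom,
                                   start = svs$ref_start, end = svs$ref_end,
                                   sv_id = svs$sv_id)
  qry_iv <- data.table::data.table(chrom = svs$qry_chrom,
                                   start = svs$qry_start, end = svs$qry_end,
                                   sv_id = svs$sv_id)
  hits <- data.table::rbindlist(list(
    one_side(ref_iv, genes_maternal, exons_maternal, "maternal"),
    one_side(qry_iv, genes_paternal, exons_paternal, "paternal")))
  # an SV in an exon is not additionally an intron hit for the same gene
  ex <- unique(hits[hits$feature == "exon",
                    c("sv_id", "gene_id", "haplotype")])
  if (nrow(ex)) {
    ex[, "is_exonic" := TRUE]
    hits <- merge(hits, ex, by = c("sv_id", "gene_id", "haplotype"),
                  all.x = TRUE)
    hits <- hits[!(hits$feature == "intron" & !is.na(hits$is_exonic) &
                     hits$is_exonic), ]
    hits[, "is_exonic" := NULL]
  }
  uh <- unique(hits[, c("sv_id", "feature")])
  feature_counts <- uh[, list(n_sv_feature = .N), by = "feature"]
  distinct <- data.table::uniqueN(uh$sv_id)
  feature_counts[, "n_sv_distinct" := distinct]
  gene_flags <- unique(hits[, c("gene_id", "haplotype")])
  gene_flags[, "has_sv" := TRUE]
  list(feature_counts = feature_counts[order(feature_counts$feature)],
       gene_flags = gene_flags[])
}

#' Compare ASMR methylation divergence with and without SV overlap
#'
#' ASMR bins are split per context into those overlapping an SV (on either
#' haplotype's genomic interval) and those not; |delta| distributions are
#' compared with a two-sided Wilcoxon rank-sum test.
#'
#' @param asmrs output of [detect_asmrs()] (only rows with is_asmr are
#'   used)
#' @param svs grouped SV table (major categories)
#' @return data.table with context, n_sv, n_nonsv, median_sv, median_nonsv,
#'   statistic, p_value
#' @export
compare_asmr_sv <- function(asmrs, svs) {
  a <- asmrs[asmrs$is_asmr, ]
  svs <- data.table::as.data.table(svs)
  if (!is.null(svs$grouped_category)) {
    svs <- svs[svs$grouped_category %in% c("TRANS", "INV", "AV", "PV"), ]
  }
  ov_m <- overlap_pairs(
    data.table::data.table(chrom = a$m_chrom, start = a$m_start,
                           end = a$m_end),
    data.table::data.table(chrom = svs$ref_chrom, start = svs$ref_start,
                           end = svs$ref_end))
  ov_p <- overlap_pairs(
    data.table::data.table(chrom = a$p_chrom, start = a$p_start,
                           end = a$p_end),
    data.table::data.table(chrom = svs$qry_chrom, start = svs$qry_start,
                           end = svs$qry_end))
  sv_flag <- seq_len(nrow(a)) %in% c(ov_m$qidx, ov_p$qidx)
  res <- lapply(.valid_contexts, function(ctx) {
    sel <- a$context == ctx
    x <- abs(a$delta[sel & sv_flag])
    y <- abs(a$delta[sel & !sv_flag])
    if (length(x) == 0L || length(y) == 0L) {
      return(data.table::data.table(context = ctx, n_sv = length(x),
                                    n_nonsv = length(y),
                                    median_sv = NA_real_,
                                    median_nonsv = NA_real_,
                                    statistic = NA_real_,
                                    p_value = NA_real_))
    }
    wt <- stats::wilcox.test(x, y, exact = length(x) < 50 &&
                               length(y) < 50)
    data.table::data.table(context = ctx, n_sv = length(x),
                           n_nonsv = length(y),
                           median_sv = stats::median(x),
                           median_nonsv = stats::median(y),
                           statistic = unname(wt$statistic),
                           p_value = wt$p.value)
  })
  data.table::rbindlist(res)
}

#' Chi-square test of SV feature-location proportions
#'
#' Compares the distribution of SV locations (gene body, upstream,
#' downstream) between two gene classes (typically ASEGs vs unbiased allele
#' pairs) with a chi-square test on the 2x3 table (df = 2, no continuity
#' correction).
#'
#' @param counts_a named counts for the first class (gene_body, upstream,
#'   downstream)
#' @param counts_b named counts for the second class
#' @return list with statistic, df, p_value, table
#' @export
sv_location_test <- function(counts_a, counts_b) {
  feats <- c("gene_body", "upstream", "downstream")
  tab <- rbind(a = as.numeric(counts_a[feats]),
               b = as.numeric(counts_b[feats]))
  colnames(tab) <- feats
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = tab)
}

#' Count read support at SV breakpoints
#'
#' For each SV the two reference-side breakpoints (start and end) are
#' checked: a read supports a breakpoint when its alignment interval covers
#' [breakpoint - min_flank, breakpoint + min_flank). Reads longer than
#' `hc_length` form the high-confidence subset.
#'
#' @param read_intervals data.frame with chrom, start, end (0-based
#'   half-open alignment spans)
#' @param svs SV table (ref coordinates used)
#' @param min_flank half-width of the required covered window, bp
#' @param hc_length minimum read length for high confidence, bp
#' @return data.table with sv_idx, breakpoint ("start"/"end"), pos,
#'   n_support, n_high_confidence
#' @export
validate_breakpoints <- function(read_intervals, svs, min_flank = 500L,
                                 hc_length = 20000L) {
  svs <- data.table::as.data.table(svs)
  reads <- data.table::as.data.table(read_intervals)
  bps <- data.table::rbindlist(list(
    data.table::data.table(sv_idx = seq_len(nrow(svs)),
                           breakpoint = "start", chrom = svs$ref_chrom,
                           pos = svs$ref_start),
    data.table::data.table(sv_idx = seq_len(nrow(svs)),
                           breakpoint = "end", chrom = svs$ref_chrom,
                           pos = svs$ref_end)))
  rlen <- reads$end - reads$start
  win_start <- bps$pos - as.integer(min_flank)
  win_end <- bps$pos + as.integer(min_flank)
  n_support <- integer(nrow(bps))
  n_hc <- integer(nrow(bps))
  if (nrow(reads) > 0L) {
    for (i in seq_len(nrow(bps))) {
      covers <- reads$chrom == bps$chrom[i] &
        reads$start <= win_start[i] & reads$end >= win_end[i]
      n_support[i] <- sum(covers)
      n_hc[i] <- sum(covers & rlen > hc_length)
    }
  }
  bps[, "n_support" := n_support]
  bps[, "n_high_confidence" := n_hc]
  data.table::setorderv(bps, c("sv_idx", "breakpoint"))
  bps[]
}
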