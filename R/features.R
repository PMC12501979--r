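# Feature annotation of regions, DMR-associated genes, metaplot binning and
# telomere detection.

#' Annotate regions with their genomic feature
#'
#' Each region is assigned exactly one feature by the position of its
#' midpoint, with priority promoter (upstream `flank` bp of the TSS,
#' strand-aware) > exon > intron > downstream (`flank` bp past the TTS) >
#' intergenic. The midpoint rule makes the single-label assignment
#' deterministic for the 200-bp windows the pipeline produces.
#'
#' @param regions data.frame with chrom, start, end
#' @param genes gene table (gene_id, chrom, strand, start, end)
#' @param exons exon table (gene_id, chrom, start, end); when NULL the whole
#'   gene body counts as exon
#' @param flank promoter/downstream extent in bp
#' @return data.table with feature, gene_id, distance_to_tss per region
#' @export
annotate_region <- function(regions, genes, exons = NULL, flank = 2000L) {
  n <- nrow(regions)
  mid <- as.integer(floor((as.numeric(regions$start) +
                             as.numeric(regions$end)) / 2))
  flank <- as.integer(flank)
  plus <- genes$strand == "+"
  promoters <- data.table::data.table(
    chrom = genes$chrom,
    start = ifelse(plus, genes$start - flank, genes$end),
    end = ifelse(plus, genes$start, genes$end + flank))
  downstreams <- data.table::data.table(
    chrom = genes$chrom,
    start = ifelse(plus, genes$end, genes$start - flank),
    end = ifelse(plus, genes$end + flank, genes$start))
  bodies <- genes[, c("chrom", "start", "end")]
  if (is.null(exons)) {
    exons <- data.table::data.table(gene_id = genes$gene_id,
                                    chrom = genes$chrom,
                                    start = genes$start, end = genes$end)
  }
  p_prom <- point_in_region(regions$chrom, mid, promoters)
  p_exon_row <- point_in_region(regions$chrom, mid, exons)
  p_exon <- match(exons$gene_id[p_exon_row], genes$gene_id)
  p_body <- point_in_region(regions$chrom, mid, bodies)
  p_down <- point_in_region(regions$chrom, mid, downstreams)
  feature <- rep("intergenic", n)
  gidx <- rep(NA_integer_, n)
  take <- function(cond, label, idx) {
    sel <- cond & feature == "intergenic"
    feature[sel] <<- label
    gidx[sel] <<- idx[sel]
  }
  take(!is.na(p_prom), "promoter", p_prom)
  take(!is.na(p_exon), "exon", p_exon)
  take(!is.na(p_body), "intron", p_body)
  take(!is.na(p_down), "downstream", p_down)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)[gidx]
  strand_sign <- ifelse(genes$strand == "+", 1L, -1L)[gidx]
  data.table::data.table(
    feature = feature,
    gene_id = genes$gene_id[gidx],
    distance_to_tss = as.integer((mid - tss) * strand_sign))
}

#' Feature-proportion table of a DMR set
#'
#' Convenience wrapper around [annotate_region()] producing the fraction of
#' DMRs per feature, split by context and direction. Fractions sum to 1
#' within each (context, direction).
#'
#' @param dmrs DMR table ([call_dmrs()])
#' @param genes,exons,flank passed to [annotate_region()]
#' @return data.table with context, direction, feature, n, fraction
#' @export
dmr_feature_proportions <- function(dmrs, genes, exons = NULL,
                                    flank = 2000L) {
  ann <- annotate_region(dmrs, genes, exons, flank)
  d <- data.table::data.table(context = dmrs$context,
                              direction = dmrs$direction,
                              feature = ann$feature)
  out <- d[, list(n = .N), by = c("context", "direction", "feature")]
  out[, "fraction" := n / sum(n), by = c("context", "direction")]
  data.table::setorderv(out, c("context", "direction", "feature"))
  out[]
}

#' Call differentially methylated genes
#'
#' A gene is a DMG when at least one DMR overlaps its gene body or `flank`
#' bp flanking regions ([start - flank, end + flank)).
#'
#' @param dmrs DMR table with chrom, start, end, context, direction
#' @param genes gene table
#' @param flank flanking extent in bp
#' @return data.table with gene_id, context, direction (one row per
#'   gene/context/direction combination with at least one supporting DMR)
#' @export
call_dmgs <- function(dmrs, genes, flank = 2000L) {
  if (nrow(dmrs) == 0L) {
    return(data.table::data.table(gene_id = character(),
                                  context = character(),
                                  direction = character()))
  }
  spans <- data.table::data.table(chrom = genes$chrom,
                                  start = genes$start - as.integer(flank),
                                  end = genes$end + as.integer(flank))
  ov <- overlap_pairs(dmrs[, c("chrom", "start", "end")], spans)
  out <- data.table::data.table(
    gene_id = genes$gene_id[ov$sidx],
    context = dmrs$context[ov$qidx],
    direction = dmrs$direction[ov$qidx])
  out <- unique(out)
  data.table::setorderv(out, c("gene_id", "context", "direction"))
  out[]
}

#' Metaplot profile over gene or TE bodies
#'
#' Feature bodies are mapped proportionally onto `body_bins` bins
#' (coordinates reversed on the minus strand); the `flank` bp up- and
#' downstream map onto `flank_bins` fixed-width bins each. The per-bin level
#' is the weighted methylation level over all sites of all features mapped
#' to the bin; flank sites contribute regardless of neighboring features
#' (profiles are feature-relative, not exclusive). Features shorter than
#' `body_bins` bp are skipped.
#'
#' @param sites cytosine site table (covered sites; sub-threshold sites are
#'   excluded when flagged)
#' @param features data.frame with chrom, start, end and optionally strand
#'   ("*" or missing treated as "+")
#' @param body_bins,flank_bins,flank binning parameters
#' @return data.table with context, bin (1..flank_bins+body_bins+flank_bins),
#'   zone (upstream/body/downstream), level, sum_c_meth, sum_c_total,
#'   n_features
#' @export
metaprofile <- function(sites, features, body_bins = 40L, flank_bins = 20L,
                        flank = 2000L) {
  body_bins <- as.integer(body_bins); flank_bins <- as.integer(flank_bins)
  flank <- as.integer(flank)
  f <- data.table::as.data.table(features)
  if (is.null(f$strand)) f[, "strand" := "+"]
  f[f$strand == "*", "strand" := "+"]
  short <- (f$end - f$start) < body_bins
  if (any(short)) {
    hm_log(sprintf("metaprofile: %d features shorter than %d bp skipped",
                   sum(short), body_bins), level = "debug")
    f <- f[!short, ]
  }
  s <- data.table::as.data.table(sites)
  if (!is.null(s$sub_threshold)) s <- s[!s$sub_threshold, ]
  s <- s[s$c_total > 0, ]
  x <- .feature_bin_map(s, f, body_bins, flank_bins, flank)
  n_bins <- flank_bins + body_bins + flank_bins
  grid <- data.table::CJ(context = .valid_contexts, bin = seq_len(n_bins))
  if (nrow(x)) {
    agg <- x[, list(sum_c_meth = sum(as.numeric(c_meth)),
                    sum_c_total = sum(as.numeric(c_total)),
                    n_features = data.table::uniqueN(fidx)),
             by = c("context", "bin")]
    out <- merge(grid, agg, by = c("context", "bin"), all.x = TRUE)
  } else {
    out <- grid
    out[, c("sum_c_meth", "sum_c_total", "n_features") :=
          list(NA_real_, NA_real_, 0L)]
  }
  out[is.na(out$n_features), "n_features" := 0L]
  out[, "level" := ifelse(!is.na(out$sum_c_total) & out$sum_c_total > 0,
                          out$sum_c_meth / out$sum_c_total, NA_real_)]
  out[, "zone" := ifelse(out$bin <= flank_bins, "upstream",
                         ifelse(out$bin <= flank_bins + body_bins, "body",
                                "downstream"))]
  data.table::setcolorder(out, c("context", "bin", "zone", "level",
                                 "sum_c_meth", "sum_c_total", "n_features"))
  data.table::setorderv(out, c("context", "bin"))
  out[]
}

# Map covered sites onto feature-relative bins (upstream/body/downstream);
# returns one row per site x feature hit with context, bin, zone, fidx and
# the site's counts.
.feature_bin_map <- function(s, f, body_bins, flank_bins, flank) {
  binw <- flank / flank_bins
  zones <- list(
    upstream = data.table::data.table(
      chrom = f$chrom,
      start = ifelse(f$strand == "+", f$start - flank, f$end),
      end = ifelse(f$strand == "+", f$start, f$end + flank)),
    body = data.table::data.table(chrom = f$chrom, start = f$start,
                                  end = f$end),
    downstream = data.table::data.table(
      chrom = f$chrom,
      start = ifelse(f$strand == "+", f$end, f$start - flank),
      end = ifelse(f$strand == "+", f$end + flank, f$start)))
  parts <- list()
  for (zone in names(zones)) {
    z <- zones[[zone]]
    ov <- overlap_pairs(data.table::data.table(chrom = s$chrom,
                                               start = s$pos,
                                               end = s$pos + 1L), z)
    if (nrow(ov) == 0L) next
    p <- s$pos[ov$qidx]
    fi <- ov$sidx
    plus <- f$strand[fi] == "+"
    if (zone == "body") {
      w <- f$end[fi] - f$start[fi]
      rel <- (p - f$start[fi]) / w
      b <- pmin(floor(rel * body_bins) + 1L, body_bins)
      b <- ifelse(plus, b, body_bins + 1L - b)
      bin <- flank_bins + b
    } else if (zone == "upstream") {
      off <- ifelse(plus, p - (f$start[fi] - flank),
                    (f$end[fi] + flank - 1L) - p)
      bin <- pmin(floor(off / binw) + 1L, flank_bins)
    } else {
      off <- ifelse(plus, p - f$end[fi], (f$start[fi] - 1L) - p)
      bin <- flank_bins + body_bins + pmin(floor(off / binw) + 1L,
                                           flank_bins)
    }
    parts[[zone]] <- data.table::data.table(
      context = s$context[ov$qidx],
      bin = as.integer(bin), zone = zone, fidx = fi,
      c_meth = s$c_meth[ov$qidx], c_total = s$c_total[ov$qidx])
  }
  data.table::rbindlist(parts)
}

#' Per-gene binned methylation levels
#'
#' Same binning as [metaprofile()], but levels are kept per feature
#' (gene) instead of averaged across features, giving one weighted level
#' per (gene, bin, context). Used to correlate bin methylation with
#' expression across samples.
#'
#' @param sites cytosine site table
#' @param genes gene table with gene_id, chrom, start, end, strand
#' @param body_bins,flank_bins,flank binning parameters
#' @return data.table with gene_id, bin, zone, context, level,
#'   sum_c_meth, sum_c_total
#' @export
gene_bin_levels <- function(sites, genes, body_bins = 40L, flank_bins = 20L,
                            flank = 2000L) {
  body_bins <- as.integer(body_bins); flank_bins <- as.integer(flank_bins)
  flank <- as.integer(flank)
  f <- data.table::as.data.table(genes)
  if (is.null(f$strand)) f[, "strand" := "+"]
  f <- f[(f$end - f$start) >= body_bins, ]
  s <- data.table::as.data.table(sites)
  if (!is.null(s$sub_threshold)) s <- s[!s$sub_threshold, ]
  s <- s[s$c_total > 0, ]
  x <- .feature_bin_map(s, f, body_bins, flank_bins, flank)
  if (nrow(x) == 0L) {
    return(data.table::data.table(gene_id = character(), bin = integer(),
                                  zone = character(), context = character(),
                                  level = numeric(), sum_c_meth = numeric(),
                                  sum_c_total = numeric()))
  }
  out <- x[, list(zone = zone[1L],
                  sum_c_meth = sum(as.numeric(c_meth)),
                  sum_c_total = sum(as.numeric(c_total))),
           by = c("fidx", "context", "bin")]
  out[, "gene_id" := f$gene_id[out$fidx]]
  out[, "level" := out$sum_c_meth / out$sum_c_total]
  out[, "fidx" := NULL]
  data.table::setcolorder(out, c("gene_id", "bin", "zone", "context",
                                 "level", "sum_c_meth", "sum_c_total"))
  data.table::setorderv(out, c("gene_id", "context", "bin"))
  out[]
}

#' Detect telomeric repeats at chromosome ends
#'
#' The plant telomere motif (TTTAGGG by default) is searched within the
#' terminal `window` bp of each chromosome end: the motif itself at the
#' downstream (right) end, its reverse complement (CCCTAAA) at the upstream
#' (left) end. An end is flagged telomeric when at least `min_copies`
#' occurrences are found.
#'
#' @param seqs named character vector of chromosome sequences
#' @param motif telomere repeat unit
#' @param window terminal window size in bp
#' @param min_copies minimum motif count to flag an end
#' @return data.table with chrom, end ("left"/"right"), motif_count,
#'   telomeric
#' @export
find_telomeres <- function(seqs, motif = "TTTAGGG", window = 1000L,
                           min_copies = 10L) {
  rc <- reverse_complement(motif)
  res <- lapply(names(seqs), function(ch) {
    sq <- seqs[[ch]]
    L <- nchar(sq)
    w <- min(window, L)
    left <- substr(sq, 1L, w)
    right <- substr(sq, L - w + 1L, L)
    nl <- Biostrings::countPattern(rc, Biostrings::DNAString(left))
    nr <- Biostrings::countPattern(motif, Biostrings::DNAString(right))
    data.table::data.table(chrom = ch, end = c("left", "right"),
                           motif_count = c(nl, nr),
                           telomeric = c(nl, nr) >= min_copies)
  })
  data.table::rbindlist(res)
}
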