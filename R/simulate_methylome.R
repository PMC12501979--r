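# Synthetic methylomes with implanted effects and full ground truth.

#' Simulate haplotype-resolved methylomes
#'
#' Site-level true methylation is drawn from a bimodal mixture whose
#' high-mode probability depends on context and on TE/gene-body overlap,
#' reproducing the canonical genome-wide level histograms (bimodal CG/CHG,
#' CHH dominated by low levels). On top of the shared baseline the
#' generator implants, and records as ground truth:
#'
#' * per-epimutant patchy demethylation (random 200-2000 bp patches per
#'   context, levels multiplied by 0.05) sized so the genome-wide weighted
#'   level drops by the sample's configured strength,
#' * per-epimutant step-aligned DMR windows with a fixed level difference
#'   per context (above threshold by a margin),
#' * per-pair maternal-paternal divergence over gene bodies, with
#'   SV-overlapping pairs drawn from an elevated CG/CHG (and reduced CHH)
#'   divergence range when `sv_divergence` is enabled.
#'
#' Observed counts are Poisson depths with binomial methylated counts at the
#' apparent level `level + (1 - level) * conversion_error`; a fully
#' unmethylated lambda spike-in is sequenced alongside every library.
#'
#' @param spec a [simulation_spec()]
#' @param genomes output of [simulate_genomes()]
#' @return object of class `hm_sim_methylome`: list with `template`
#'   (hap1 site table), `counts` (sample -> replicate -> c_meth/c_total),
#'   `true_levels` (per-sample numeric vectors), `hap2` (same three fields
#'   for gene-space hap2 sites; truth shared across samples), `lambda`
#'   (template + counts), `gene_levels` (per gene/sample/context true mean
#'   level), and `truth` (implants, patches, pair_divergence)
#' @export
simulate_methylome <- function(spec, genomes) {
  set.seed(spec$seed + 1L)
  tmpl <- genome_cytosines(genomes$hap1)
  lvl0 <- .draw_base_truth(tmpl, genomes$genes_h1, genomes$tes_h1)

  # --- pair divergence (shared across samples) ---------------------------
  div <- .assign_pair_divergence(spec, genomes)
  lvl0 <- .apply_divergence(tmpl, lvl0, div, genomes$genes_h1,
                            side = "maternal", genomes$pairs)

  # --- implanted DMR windows --------------------------------------------
  imp <- .plan_implants(spec, tmpl, genomes, div)
  lvl0 <- .set_interval_levels(tmpl, lvl0, imp, imp$control_level)

  # --- per-sample truth --------------------------------------------------
  samples <- spec$samples
  true_levels <- list()
  patches_all <- list()
  mean_ctx <- vapply(.valid_contexts, function(cx) {
    mean(lvl0[tmpl$context == cx])
  }, numeric(1L))
  L <- nchar(genomes$hap1[[1L]])
  for (i in seq_len(nrow(samples))) {
    nm <- samples$name[i]
    lvl <- lvl0
    if (samples$role[i] == "epimutant") {
      for (cx in .valid_contexts) {
        strength <- samples[[cx]][i]
        if (strength <= 0) next
        f <- min(0.9, (strength / 100) / (mean_ctx[[cx]] * 0.95))
        pat <- .draw_patches(names(genomes$hap1), L, f, imp)
        sel <- which(tmpl$context == cx)
        hit <- !is.na(point_in_region(tmpl$chrom[sel], tmpl$pos[sel], pat))
        lvl[sel[hit]] <- lvl[sel[hit]] * 0.05
        pat[, c("sample", "context") := list(nm, cx)]
        patches_all[[length(patches_all) + 1L]] <- pat
      }
      own <- imp[imp$sample == nm, ]
      lvl <- .set_interval_levels(tmpl, lvl, own, own$epimutant_level)
    }
    true_levels[[nm]] <- lvl
  }

  # --- observed counts ---------------------------------------------------
  counts <- lapply(stats::setNames(samples$name, samples$name), function(nm) {
    lapply(stats::setNames(seq_len(spec$replicates),
                           paste0("rep", seq_len(spec$replicates))),
           function(r) .sim_counts(true_levels[[nm]], spec$mean_depth,
                                   spec$conversion_error))
  })

  # --- lambda spike-in ---------------------------------------------------
  ltmpl <- genome_cytosines(genomes$lambda)
  lcounts <- lapply(stats::setNames(samples$name, samples$name), function(nm) {
    lapply(stats::setNames(seq_len(spec$replicates),
                           paste0("rep", seq_len(spec$replicates))),
           function(r) .sim_counts(rep(0, nrow(ltmpl)), spec$mean_depth,
                                   spec$conversion_error))
  })

  # --- hap2 gene-space methylome ----------------------------------------
  tmpl2 <- genome_cytosines(genomes$hap2)
  spans2 <- data.table::data.table(
    chrom = genomes$genes_h2$chrom,
    start = pmax(0L, genomes$genes_h2$start - 2000L),
    end = genomes$genes_h2$end + 2000L)
  keep2 <- !is.na(point_in_region(tmpl2$chrom, tmpl2$pos, spans2))
  tmpl2 <- tmpl2[keep2, ]
  lvl2 <- .draw_base_truth(tmpl2, genomes$genes_h2, genomes$tes_h2)
  lvl2 <- .apply_divergence(tmpl2, lvl2, div, genomes$genes_h2,
                            side = "paternal", genomes$pairs)
  counts2 <- lapply(stats::setNames(samples$name, samples$name), function(nm) {
    lapply(stats::setNames(seq_len(spec$replicates),
                           paste0("rep", seq_len(spec$replicates))),
           function(r) .sim_counts(lvl2, spec$mean_depth,
                                   spec$conversion_error))
  })

  gene_levels <- .gene_true_levels(tmpl, true_levels, genomes$genes_h1)
  patches <- if (length(patches_all)) data.table::rbindlist(patches_all)
             else data.table::data.table(chrom = character(),
                                         start = integer(), end = integer(),
                                         sample = character(),
                                         context = character())
  structure(list(
    template = tmpl, counts = counts, true_levels = true_levels,
    hap2 = list(template = tmpl2, counts = counts2, true_level = lvl2),
    lambda = list(template = ltmpl, counts = lcounts),
    gene_levels = gene_levels,
    truth = list(implants = imp, patches = patches,
                 pair_divergence = div)),
    class = "hm_sim_methylome")
}

#' Materialize one library's cytosine site table
#'
#' @param msim a `hm_sim_methylome`
#' @param sample sample name
#' @param rep replicate index or "repK" name
#' @param haplotype "hap1", "hap2" or "lambda"
#' @return data.table in cytosine-report layout (chrom, pos, strand,
#'   context, trinucleotide, c_meth, c_total)
#' @export
methylome_sites <- function(msim, sample, rep = 1L, haplotype = "hap1") {
  rep <- if (is.numeric(rep)) paste0("rep", rep) else rep
  src <- switch(haplotype,
                hap1 = list(t = msim$template, c = msim$counts),
                hap2 = list(t = msim$hap2$template, c = msim$hap2$counts),
                lambda = list(t = msim$lambda$template,
                              c = msim$lambda$counts),
                stop_hm("unknown haplotype '%s'", haplotype))
  cc <- src$c[[sample]][[rep]]
  if (is.null(cc)) stop_hm("no simulated library %s/%s", sample, rep)
  out <- data.table::copy(src$t)
  out[, c("c_meth", "c_total") := list(cc$c_meth, cc$c_total)]
  out[]
}

# Bimodal site-level baseline; high-mode probability by context and
# TE/gene-body membership (TE overrides gene body).
.draw_base_truth <- function(tmpl, genes, tes) {
  p_base <- c(CG = 0.40, CHG = 0.18, CHH = 0.03)
  p_gene <- c(CG = 0.55, CHG = 0.10, CHH = 0.02)
  p_te <- c(CG = 0.85, CHG = 0.60, CHH = 0.12)
  in_gene <- !is.na(point_in_region(tmpl$chrom, tmpl$pos,
                                    genes[, c("chrom", "start", "end")]))
  in_te <- !is.na(point_in_region(tmpl$chrom, tmpl$pos,
                                  tes[, c("chrom", "start", "end")]))
  ph <- p_base[tmpl$context]
  ph[in_gene] <- p_gene[tmpl$context[in_gene]]
  ph[in_te] <- p_te[tmpl$context[in_te]]
  n <- nrow(tmpl)
  high <- stats::runif(n) < ph
  lvl <- stats::runif(n, 0.005, 0.06)
  lvl[high] <- stats::runif(sum(high), 0.90, 0.99)
  lvl
}

# Divergence assignment: fraction asm_fraction of pairs, plus every pair
# whose gene overlaps a major SV when sv_divergence is on. Deltas are
# maternal minus paternal in percentage points.
.assign_pair_divergence <- function(spec, genomes) {
  pairs <- genomes$pairs
  n <- nrow(pairs)
  svs <- genomes$svs
  major <- svs[svs$raw_type %in% c("INS", "DEL", "INV", "TRANS") &
                 svs$length > 50L, ]
  gm <- genomes$genes_h1[match(pairs$maternal_id, genomes$genes_h1$gene_id), ]
  gp <- genomes$genes_h2[match(pairs$paternal_id, genomes$genes_h2$gene_id), ]
  ref_iv <- data.table::data.table(chrom = major$ref_chrom,
                                   start = major$ref_start,
                                   end = major$ref_end)
  qry_iv <- data.table::data.table(chrom = major$qry_chrom,
                                   start = major$qry_start,
                                   end = major$qry_end)
  span_m <- data.table::data.table(chrom = gm$chrom, start = gm$start - 2000L,
                                   end = gm$end + 2000L)
  span_p <- data.table::data.table(chrom = gp$chrom, start = gp$start - 2000L,
                                   end = gp$end + 2000L)
  sv_hit <- rep(FALSE, n)
  sv_hit[overlap_pairs(span_m, ref_iv)$qidx] <- TRUE
  sv_hit[overlap_pairs(span_p, qry_iv)$qidx] <- TRUE
  divergent <- sv_hit & spec$sv_divergence
  extra <- sample(which(!divergent), round(spec$asm_fraction * n))
  divergent[extra] <- TRUE
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  d_cg <- d_chg <- d_chh <- rep(0, n)
  hi <- divergent & sv_hit & spec$sv_divergence
  lo <- divergent & !hi
  d_cg[hi] <- sgn[hi] * stats::runif(sum(hi), 50, 90)
  d_chg[hi] <- sgn[hi] * stats::runif(sum(hi), 40, 80)
  d_chh[hi] <- sgn[hi] * stats::runif(sum(hi), 15, 30)
  d_cg[lo] <- sgn[lo] * stats::runif(sum(lo), 25, 60)
  d_chg[lo] <- sgn[lo] * stats::runif(sum(lo), 25, 55)
  d_chh[lo] <- sgn[lo] * stats::runif(sum(lo), 20, 50)
  data.table::data.table(pair_id = pairs$pair_id, divergent = divergent,
                         sv_linked = sv_hit, delta_cg = d_cg,
                         delta_chg = d_chg, delta_chh = d_chh)
}

# Set gene-body levels of divergent pairs so maternal - paternal equals the
# assigned delta: the higher allele sits at the context anchor, the lower at
# anchor - |d|. CG/CHG divergence covers the whole gene body at anchor 0.93;
# CHH uses a lower anchor (0.55) over only the central half of the body so
# the genome-wide CHH histogram stays dominated by low levels.
.apply_divergence <- function(tmpl, lvl, div, genes, side, pairs) {
  gid_col <- if (side == "maternal") "maternal_id" else "paternal_id"
  dd <- div[div$divergent, ]
  if (nrow(dd) == 0L) return(lvl)
  gids <- pairs[[gid_col]][match(dd$pair_id, pairs$pair_id)]
  gi <- match(gids, genes$gene_id)
  ok <- !is.na(gi)
  dd <- dd[ok, ]; gi <- gi[ok]
  glen <- genes$end[gi] - genes$start[gi]
  for (cx in .valid_contexts) {
    anchor <- if (cx == "CHH") 0.55 else 0.93
    spans <- if (cx == "CHH") {
      data.table::data.table(
        chrom = genes$chrom[gi],
        start = genes$start[gi] + glen %/% 4L,
        end = genes$end[gi] - glen %/% 4L)
    } else {
      data.table::data.table(chrom = genes$chrom[gi],
                             start = genes$start[gi], end = genes$end[gi])
    }
    sel <- which(tmpl$context == cx)
    ridx <- point_in_region(tmpl$chrom[sel], tmpl$pos[sel], spans)
    hit <- which(!is.na(ridx))
    d <- switch(cx, CG = dd$delta_cg, CHG = dd$delta_chg,
                CHH = dd$delta_chh)[ridx[hit]]
    val_here <- if (side == "maternal") {
      ifelse(d >= 0, anchor, anchor + d / 100)
    } else {
      ifelse(d >= 0, anchor - d / 100, anchor)
    }
    lvl[sel[hit]] <- pmax(0, val_here)
  }
  lvl
}

# Choose step-aligned windows with enough context cytosines, disjoint from
# each other and from divergent-pair gene bodies.
.plan_implants <- function(spec, tmpl, genomes, div) {
  step <- 100L
  window <- 200L
  L <- nchar(genomes$hap1[[1L]])
  chroms <- names(genomes$hap1)
  epis <- spec$samples[spec$samples$role == "epimutant", ]
  # cells of `step` bp; per-context site counts per cell
  n_cells <- L %/% step
  cell_counts <- list()
  for (cx in .valid_contexts) {
    cell_counts[[cx]] <- lapply(stats::setNames(chroms, chroms), function(ch) {
      sel <- tmpl$context == cx & tmpl$chrom == ch
      tabulate(tmpl$pos[sel] %/% step + 1L, nbins = n_cells)
    })
  }
  # cells blocked by divergent gene bodies (implants would be overwritten)
  blocked <- lapply(stats::setNames(chroms, chroms),
                    function(ch) logical(n_cells))
  dd <- div[div$divergent, ]
  gm <- genomes$genes_h1[
    match(genomes$pairs$maternal_id[match(dd$pair_id,
                                          genomes$pairs$pair_id)],
          genomes$genes_h1$gene_id), ]
  for (i in seq_len(nrow(gm))) {
    cs <- max(1L, gm$start[i] %/% step)
    ce <- min(n_cells, gm$end[i] %/% step + 1L)
    blocked[[gm$chrom[i]]][cs:ce] <- TRUE
  }
  tel_cells <- (nchar("TTTAGGG") * spec$telomere_copies) %/% step + 2L
  ctrl_val <- function(cx, hypo) {
    if (cx == "CHH") (if (hypo) 0.55 else 0.05) else (if (hypo) 0.85 else 0.10)
  }
  res <- list()
  for (i in seq_len(nrow(epis))) {
    for (cx in .valid_contexts) {
      need <- spec$n_dmr_implant[[cx]]
      delta <- spec$dmr_delta[[cx]]
      got <- 0L
      cand <- data.table::rbindlist(lapply(chroms, function(ch) {
        cnt <- cell_counts[[cx]][[ch]]
        k <- seq_len(n_cells - 1L)
        ok <- (cnt[k] + cnt[k + 1L]) >= 8L & k > tel_cells &
          k < n_cells - tel_cells
        data.table::data.table(chrom = ch, cell = k[ok])
      }))
      cand <- cand[sample(nrow(cand)), ]
      for (j in seq_len(nrow(cand))) {
        if (got >= need) break
        ch <- cand$chrom[j]; k <- cand$cell[j]
        if (blocked[[ch]][k] || blocked[[ch]][k + 1L]) next
        blocked[[ch]][c(k, k + 1L)] <- TRUE
        hypo <- stats::runif(1L) < spec$hypo_fraction
        cl <- ctrl_val(cx, hypo)
        el <- if (hypo) cl - delta / 100 else cl + delta / 100
        res[[length(res) + 1L]] <- data.table::data.table(
          sample = epis$name[i], context = cx, chrom = ch,
          start = (k - 1L) * step, end = (k - 1L) * step + window,
          control_level = cl, epimutant_level = el,
          direction = if (hypo) "hypo" else "hyper",
          delta = (el - cl) * 100)
        got <- got + 1L
      }
      if (got < need) {
        hm_log(sprintf("implants: only %d/%d %s windows placed for %s",
                       got, need, cx, epis$name[i]), level = "warn")
      }
    }
  }
  data.table::rbindlist(res)
}

# Overwrite levels of matching-context sites inside each interval.
.set_interval_levels <- function(tmpl, lvl, intervals, values) {
  if (nrow(intervals) == 0L) return(lvl)
  for (cx in unique(intervals$context)) {
    iv <- intervals[intervals$context == cx, ]
    v <- values[intervals$context == cx]
    sel <- which(tmpl$context == cx)
    ridx <- point_in_region(tmpl$chrom[sel], tmpl$pos[sel],
                            iv[, c("chrom", "start", "end")])
    hit <- !is.na(ridx)
    lvl[sel[hit]] <- v[ridx[hit]]
  }
  lvl
}

# Non-overlapping patches drawn from 2-kb slots, avoiding implant windows,
# until the requested genome fraction is covered.
.draw_patches <- function(chroms, L, fraction, implants) {
  slot <- 2000L
  n_slots <- L %/% slot
  slots <- data.table::CJ(chrom = chroms, k = seq_len(n_slots))
  slots[, c("start", "end") := list((k - 1L) * slot, k * slot)]
  if (nrow(implants)) {
    bad <- overlap_pairs(slots[, c("chrom", "start", "end")],
                         implants[, c("chrom", "start", "end")])$qidx
    if (length(bad)) slots <- slots[-unique(bad), ]
  }
  slots <- slots[sample(nrow(slots)), ]
  len <- as.integer(stats::runif(nrow(slots), 200, 2000))
  take <- which(cumsum(len) >= fraction * length(chroms) * L)[1L]
  if (is.na(take)) take <- nrow(slots)
  s <- slots[seq_len(take), ]
  plen <- len[seq_len(take)]
  off <- as.integer(stats::runif(take, 0, slot - plen))
  out <- data.table::data.table(chrom = s$chrom, start = s$start + off,
                                end = s$start + off + plen)
  data.table::setorderv(out, c("chrom", "start"))
  out[]
}

.sim_counts <- function(level, mean_depth, eps) {
  n <- length(level)
  d <- stats::rpois(n, mean_depth)
  apparent <- level + (1 - level) * eps
  data.table::data.table(c_meth = stats::rbinom(n, d, apparent),
                         c_total = d)
}

# Per gene x sample x context mean true level over gene-body sites.
.gene_true_levels <- function(tmpl, true_levels, genes) {
  ridx <- point_in_region(tmpl$chrom, tmpl$pos,
                          genes[, c("chrom", "start", "end")])
  hit <- which(!is.na(ridx))
  base <- data.table::data.table(gene_id = genes$gene_id[ridx[hit]],
                                 context = tmpl$context[hit])
  res <- lapply(names(true_levels), function(nm) {
    d <- data.table::copy(base)
    d[, "level" := true_levels[[nm]][hit]]
    out <- d[, list(level = mean(level)), by = c("gene_id", "context")]
    out[, "sample" := nm]
    out
  })
  out <- data.table::rbindlist(res)
  data.table::setcolorder(out, c("gene_id", "sample", "context", "level"))
  out[]
}
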