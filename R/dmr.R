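# Tiled-window differential methylation between a test (epimutant) sample
# and a control, and between haplotypes (allele-specific methylation uses
# the same machinery).

#' Tile a chromosome into sliding windows
#'
#' Windows of `window` bp every `step` bp: [0,window), [step, step+window),
#' ... A chromosome shorter than one window yields a single whole-chromosome
#' window. When the last full window does not reach the chromosome end, one
#' final partial window is emitted iff it is at least `step` bp long.
#'
#' @param chrom_length chromosome length in bp
#' @param window window size (>= step)
#' @param step step size
#' @return data.table with start, end (0-based half-open)
#' @export
tile_windows <- function(chrom_length, window = 200L, step = 100L) {
  window <- as.integer(window); step <- as.integer(step)
  L <- as.integer(chrom_length)
  stopifnot(step > 0L, window >= step)
  if (L <= window) {
    return(data.table::data.table(start = 0L, end = L))
  }
  n_full <- (L - window) %/% step + 1L
  starts <- (seq_len(n_full) - 1L) * step
  ends <- starts + window
  last_end <- ends[n_full]
  if (last_end < L) {
    pstart <- starts[n_full] + step
    if (L - pstart >= step) {
      starts <- c(starts, pstart)
      ends <- c(ends, L)
    }
  }
  data.table::data.table(start = starts, end = ends)
}

# Closed-form binomial log-likelihood, with 0*log(0) = 0
.binom_ll <- function(m, t, p) {
  term1 <- ifelse(m > 0, m * log(p), 0)
  term2 <- ifelse(t - m > 0, (t - m) * log(1 - p), 0)
  term1 + term2
}

# Vectorized logistic-regression likelihood-ratio test of group membership
# on methylated/unmethylated counts. With a single two-level covariate the
# binomial GLM maximum-likelihood fits are the group-pooled proportions, so
# the deviance has closed form and the test vectorizes over windows.
.lrt_group <- function(m1, t1, m2, t2) {
  p1 <- m1 / t1
  p2 <- m2 / t2
  p0 <- (m1 + m2) / (t1 + t2)
  g <- 2 * (.binom_ll(m1, t1, p1) + .binom_ll(m2, t2, p2) -
              .binom_ll(m1, t1, p0) - .binom_ll(m2, t2, p0))
  g <- pmax(g, 0)
  stats::pchisq(g, df = 1L, lower.tail = FALSE)
}

#' Differential methylation test for one window
#'
#' Per-replicate (c_meth, c_total) sums in the window for the two groups are
#' compared by a logistic-regression likelihood-ratio test of the group
#' factor (the methylKit-style default); when either group has only a single
#' replicate a two-sided Fisher's exact test on the pooled 2x2 table is used
#' instead. The difference is the gap between group-pooled weighted levels
#' in percentage points (test minus control).
#'
#' @param test_reps matrix-like with columns c_meth, c_total (one row per
#'   replicate) for the test group
#' @param control_reps same for the control group
#' @return list with diff (percentage points), p_value, test ("lrt" or
#'   "fisher")
#' @export
test_window <- function(test_reps, control_reps) {
  test_reps <- as.matrix(test_reps)
  control_reps <- as.matrix(control_reps)
  mt <- sum(test_reps[, 1L]); tt <- sum(test_reps[, 2L])
  mc <- sum(control_reps[, 1L]); tc <- sum(control_reps[, 2L])
  if (tt == 0 || tc == 0) {
    stop_hm("test_window: zero total counts in a group")
  }
  diff <- (mt / tt - mc / tc) * 100
  if (nrow(test_reps) < 2L || nrow(control_reps) < 2L) {
    tab <- matrix(c(mt, tt - mt, mc, tc - mc), nrow = 2L)
    p <- stats::fisher.test(tab)$p.value
    list(diff = diff, p_value = p, test = "fisher")
  } else {
    p <- .lrt_group(mt, tt, mc, tc)
    list(diff = diff, p_value = p, test = "lrt")
  }
}

# Aggregate per-replicate site tables into per-window, per-context counts.
# sites_reps: list of cytosine tables (one per replicate). Only sites with
# c_total >= depth_min enter; a window's cytosine count is the number of
# distinct qualifying sites (pooled over replicates).
.window_counts <- function(sites_reps, windows_by_chrom, depth_min) {
  agg <- vector("list", length(sites_reps))
  for (r in seq_along(sites_reps)) {
    s <- data.table::as.data.table(sites_reps[[r]])
    s <- s[s$c_total >= depth_min,
           c("chrom", "pos", "strand", "context", "c_meth", "c_total"),
           with = FALSE]
    s[, "rep" := r]
    agg[[r]] <- s
  }
  s <- data.table::rbindlist(agg)
  if (nrow(s) == 0L) return(NULL)
  win <- windows_by_chrom
  ridx <- overlap_pairs(
    data.table::data.table(chrom = s$chrom, start = s$pos,
                           end = s$pos + 1L),
    win)
  x <- s[ridx$qidx, ]
  x[, "widx" := ridx$sidx]
  # per-window pooled counts and distinct-site count
  x[, "site_key" := paste0(x$pos, x$strand)]
  out <- x[, list(
    n_cytosines = data.table::uniqueN(site_key),
    c_meth = sum(as.numeric(c_meth)),
    c_total = sum(as.numeric(c_total))), by = c("widx", "context")]
  out
}

#' Tiled-window DMR analysis between two samples
#'
#' Tiles every chromosome, aggregates per-replicate cytosine counts into
#' windows per context, requires at least `min_cytosines_per_window`
#' qualifying cytosines of the context in both groups' pooled coverage,
#' tests each window ([test_window()]'s statistic, vectorized) and adjusts
#' per context with Benjamini-Hochberg.
#'
#' @param test_reps list of cytosine site tables (one per replicate) for the
#'   test sample
#' @param control_reps list for the control sample
#' @param chrom_lengths named integer vector of chromosome lengths
#' @param config an [hm_config()]
#' @return data.table of tested windows: chrom, start, end, context,
#'   n_cytosines, level_test, level_control, diff, p_value, q_value
#' @export
dmr_test_windows <- function(test_reps, control_reps, chrom_lengths,
                             config = hm_config()) {
  wlist <- lapply(names(chrom_lengths), function(ch) {
    w <- tile_windows(chrom_lengths[[ch]], config$window_size,
                      config$step_size)
    w[, "chrom" := ch]
    w
  })
  windows <- data.table::rbindlist(wlist)
  data.table::setcolorder(windows, c("chrom", "start", "end"))
  wt <- .window_counts(test_reps, windows, config$depth_min)
  wc <- .window_counts(control_reps, windows, config$depth_min)
  if (is.null(wt) || is.null(wc)) {
    stop_hm("dmr_test_windows: no qualifying sites in one of the groups")
  }
  m <- merge(wt, wc, by = c("widx", "context"), suffixes = c("_t", "_c"))
  m <- m[m$n_cytosines_t >= config$min_cytosines_per_window &
           m$n_cytosines_c >= config$min_cytosines_per_window &
           m$c_total_t > 0 & m$c_total_c > 0, ]
  n_windows_total <- nrow(windows) * length(.valid_contexts)
  hm_log(sprintf("dmr_test_windows: %d windows tiled, %d window-contexts tested (>%d cytosines at depth>=%d in both groups)",
                 nrow(windows), nrow(m),
                 config$min_cytosines_per_window - 1L, config$depth_min))
  level_t <- m$c_meth_t / m$c_total_t * 100
  level_c <- m$c_meth_c / m$c_total_c * 100
  single_rep <- length(test_reps) < 2L || length(control_reps) < 2L
  if (single_rep) {
    p <- vapply(seq_len(nrow(m)), function(i) {
      tab <- matrix(c(m$c_meth_t[i], m$c_total_t[i] - m$c_meth_t[i],
                      m$c_meth_c[i], m$c_total_c[i] - m$c_meth_c[i]),
                    nrow = 2L)
      stats::fisher.test(round(tab))$p.value
    }, numeric(1L))
  } else {
    p <- .lrt_group(m$c_meth_t, m$c_total_t, m$c_meth_c, m$c_total_c)
  }
  out <- data.table::data.table(
    chrom = windows$chrom[m$widx],
    start = windows$start[m$widx],
    end = windows$end[m$widx],
    context = m$context,
    n_cytosines = pmin(m$n_cytosines_t, m$n_cytosines_c),
    level_test = level_t, level_control = level_c,
    diff = level_t - level_c, p_value = p)
  out[, "q_value" := stats::p.adjust(p_value, method = "BH"),
      by = "context"]
  data.table::setorderv(out, c("context", "chrom", "start"))
  out[]
}

#' Call DMRs from tested windows
#'
#' A window is a DMR when its absolute level difference exceeds the context
#' threshold (25/25/15 percentage points for CG/CHG/CHH by default) and its
#' BH q-value is below `q_threshold`. Direction is hyper when the test
#' sample is more methylated, hypo when less.
#'
#' @param windows output of [dmr_test_windows()] (q_value already computed
#'   per context)
#' @param thresholds named vector of percentage-point thresholds
#' @param q_threshold q-value cutoff
#' @return data.table of DMRs with a direction column
#' @export
call_dmrs <- function(windows, thresholds = c(CG = 25, CHG = 25, CHH = 15),
                      q_threshold = 0.05) {
  thr <- thresholds[windows$context]
  keep <- abs(windows$diff) > thr & windows$q_value < q_threshold
  out <- windows[keep, ]
  out[, "direction" := ifelse(out$diff < 0, "hypo", "hyper")]
  hm_log(sprintf("call_dmrs: %d/%d windows pass |diff|>threshold & q<%g (%d hyper, %d hypo)",
                 nrow(out), nrow(windows), q_threshold,
                 sum(out$direction == "hyper"), sum(out$direction == "hypo")))
  out[]
}

#' Intersect DMR sets across epimutants
#'
#' DMRs from different epimutants are treated as shared when their windows
#' overlap by at least 1 bp in the same context and direction. Overlapping
#' DMRs (within and across epimutants) are merged into clusters per
#' (context, direction); each cluster's membership pattern over epimutants
#' gives UpSet-style subset counts. Because the direction requirement is a
#' reading choice, the count of clusters shared by every epimutant is also
#' reported ignoring direction.
#'
#' @param dmr_sets named list of DMR tables (one per epimutant)
#' @return list with `clusters` (cluster intervals + membership flags),
#'   `subset_counts` (membership pattern -> count), `n_shared_by_all`,
#'   `frac_shared_by_all`, `n_shared_by_all_positional`
#' @export
intersect_dmr_sets <- function(dmr_sets) {
  stopifnot(length(dmr_sets) >= 2L, !is.null(names(dmr_sets)))
  all_dmrs <- data.table::rbindlist(
    lapply(names(dmr_sets), function(nm) {
      d <- data.table::as.data.table(dmr_sets[[nm]])
      d <- d[, c("chrom", "start", "end", "context", "direction"),
             with = FALSE]
      d[, "epimutant" := nm]
      d
    }))
  clusters <- .merge_clusters(all_dmrs, c("context", "direction"))
  pos_clusters <- .merge_clusters(all_dmrs, "context")
  members <- names(dmr_sets)
  pattern <- apply(clusters[, members, with = FALSE], 1L, function(fl) {
    paste(members[as.logical(fl)], collapse = "&")
  })
  subset_counts <- data.table::data.table(pattern = pattern)[
    , list(count = .N), by = "pattern"]
  data.table::setorderv(subset_counts, "pattern")
  all_flag <- rowSums(clusters[, members, with = FALSE]) == length(members)
  all_flag_pos <- rowSums(pos_clusters[, members, with = FALSE]) ==
    length(members)
  list(clusters = clusters,
       subset_counts = subset_counts,
       n_shared_by_all = sum(all_flag),
       frac_shared_by_all = sum(all_flag) / nrow(clusters),
       n_shared_by_all_positional = sum(all_flag_pos))
}

# Merge overlapping intervals into clusters within groups defined by `byv`,
# carrying per-epimutant membership flags.
.merge_clusters <- function(dmrs, byv) {
  members <- sort(unique(dmrs$epimutant))
  d <- data.table::copy(dmrs)
  data.table::setorderv(d, c(byv, "chrom", "start", "end"))
  d[, "grp" := do.call(paste, c(.SD, sep = "\r")), .SDcols = c(byv, "chrom")]
  # cluster id: new cluster when start > running max end within group
  d[, "cluster" := {
    cmax <- cummax(data.table::shift(end, fill = start[1L]))
    cumsum(start >= cmax & seq_len(.N) > 1L) + 1L
  }, by = "grp"]
  out <- d[, {
    fl <- lapply(members, function(mm) any(epimutant == mm))
    names(fl) <- members
    c(list(chrom = chrom[1L], start = min(start), end = max(end),
           context = context[1L],
           direction = if ("direction" %in% byv) direction[1L]
                       else NA_character_),
      fl)
  }, by = c("grp", "cluster")]
  out[, "grp" := NULL]
  out[]
}

#' Methylation-level distributions of common DMRs across samples
#'
#' Common DMRs (clusters shared by at least `min_shared` epimutants) are
#' re-measured in every sample with the weighted level; a DMR with no
#' coverage in a sample is excluded from that sample's distribution.
#'
#' @param intersections output of [intersect_dmr_sets()]
#' @param sample_sites named list of cytosine site tables (pooled
#'   replicates), one per sample
#' @param min_shared minimum number of epimutants sharing a cluster
#' @return data.table with sample, context, direction, chrom, start, end,
#'   level
#' @export
common_dmr_level_distributions <- function(intersections, sample_sites,
                                           min_shared = 2L) {
  cl <- intersections$clusters
  members <- setdiff(names(cl), c("cluster", "chrom", "start", "end",
                                  "context", "direction"))
  common <- cl[rowSums(cl[, members, with = FALSE]) >= min_shared, ]
  if (nrow(common) == 0L) {
    return(data.table::data.table(sample = character(), context = character(),
                                  direction = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  level = numeric()))
  }
  res <- lapply(names(sample_sites), function(sm) {
    rm <- region_methylation(sample_sites[[sm]], common, by_context = TRUE)
    rm <- rm[rm$context == common$context[rm$region_idx], ]
    skipped <- nrow(common) - length(unique(rm$region_idx))
    if (skipped > 0L) {
      hm_log(sprintf("common_dmr_level_distributions: %d/%d common DMRs without coverage in %s excluded",
                     skipped, nrow(common), sm), level = "debug")
    }
    data.table::data.table(
      sample = sm, context = common$context[rm$region_idx],
      direction = common$direction[rm$region_idx],
      chrom = common$chrom[rm$region_idx],
      start = common$start[rm$region_idx],
      end = common$end[rm$region_idx],
      level = rm$level)
  })
  data.table::rbindlist(res)
}
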