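# Run configuration: the analysis thresholds shared across pipeline stages.

#' Analysis run configuration
#'
#' Bundles the tunable thresholds of the methylome pipeline. The defaults are
#' the standard parameters for plant WGBS tiled-window analysis: 200-bp
#' windows sliding by 100 bp, at least 5 covering reads per cytosine, more
#' than 5 cytosines of the tested context per window, DMR level-difference
#' thresholds of 25/25/15 percentage points for CG/CHG/CHH, q < 0.05 after
#' Benjamini-Hochberg correction, and 2-kb flanks split into 20 bins around
#' a 40-bin gene body for metaplots.
#'
#' @param window_size tiled window width in bp
#' @param step_size window step in bp (must not exceed `window_size`)
#' @param min_cytosines_per_window minimum covered cytosines of the tested
#'   context required for a window to be tested (strictly more than 5 by
#'   default, i.e. at least 6)
#' @param dmr_diff_thresholds named numeric vector of minimum absolute
#'   methylation differences in percentage points, names CG/CHG/CHH
#' @param q_threshold BH-adjusted significance threshold
#' @param depth_min minimum read depth for a cytosine to be callable
#' @param flank_size flanking-region width in bp (promoters, DMG flanks,
#'   metaplot flanks)
#' @param body_bins number of proportional bins across a gene/TE body
#' @param flank_bins number of fixed-width bins across each flank
#' @param rng_seed integer seed used by stages that randomize
#' @return an object of class `hm_config` (a named list)
#' @export
hm_config <- function(window_size = 200L,
                      step_size = 100L,
                      min_cytosines_per_window = 6L,
                      dmr_diff_thresholds = c(CG = 25, CHG = 25, CHH = 15),
                      q_threshold = 0.05,
                      depth_min = 5L,
                      flank_size = 2000L,
                      body_bins = 40L,
                      flank_bins = 20L,
                      rng_seed = 1L) {
  stopifnot(window_size > 0, step_size > 0, step_size <= window_size,
            min_cytosines_per_window > 0,
            all(c("CG", "CHG", "CHH") %in% names(dmr_diff_thresholds)),
            all(dmr_diff_thresholds > 0),
            q_threshold > 0, q_threshold < 1,
            depth_min > 0, flank_size > 0, body_bins > 0, flank_bins > 0)
  structure(list(
    window_size = as.integer(window_size),
    step_size = as.integer(step_size),
    min_cytosines_per_window = as.integer(min_cytosines_per_window),
    dmr_diff_thresholds = dmr_diff_thresholds[c("CG", "CHG", "CHH")],
    q_threshold = q_threshold,
    depth_min = as.integer(depth_min),
    flank_size = as.integer(flank_size),
    body_bins = as.integer(body_bins),
    flank_bins = as.integer(flank_bins),
    rng_seed = as.integer(rng_seed)
  ), class = "hm_config")
}

#' @export
print.hm_config <- function(x, ...) {
  cat("hapmeth run configuration\n")
  cat(sprintf("  windows: %d bp, step %d bp, > %d cytosines/window\n",
              x$window_size, x$step_size, x$min_cytosines_per_window - 1L))
  cat(sprintf("  DMR thresholds (pp): CG %.0f, CHG %.0f, CHH %.0f; q < %g\n",
              x$dmr_diff_thresholds[["CG"]], x$dmr_diff_thresholds[["CHG"]],
              x$dmr_diff_thresholds[["CHH"]], x$q_threshold))
  cat(sprintf("  depth >= %d; flank %d bp; bins %d body + 2 x %d flank\n",
              x$depth_min, x$flank_size, x$body_bins, x$flank_bins))
  cat(sprintf("  seed: %d\n", x$rng_seed))
  invisible(x)
}

#' Read a flat key = value configuration file
#'
#' Lines are `key = value`; blank lines and `#` comments are ignored. Values
#' for `dmr_diff_thresholds` are given as `CG:25,CHG:25,CHH:15`. Keys not
#' present keep their defaults; CLI-style overrides can be layered with the
#' `overrides` argument, which wins over the file.
#'
#' @param path config file path
#' @param overrides named list applied after the file
#' @return an `hm_config`
#' @export
read_config <- function(path, overrides = list()) {
  args <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop_hm("malformed config line: '%s'", ln)
      key <- trimws(kv[1L]); val <- trimws(kv[2L])
      if (key == "dmr_diff_thresholds") {
        parts <- strsplit(strsplit(val, ",", fixed = TRUE)[[1L]], ":",
                          fixed = TRUE)
        v <- vapply(parts, function(p) as.numeric(trimws(p[2L])), numeric(1L))
        names(v) <- vapply(parts, function(p) trimws(p[1L]), character(1L))
        args[[key]] <- v
      } else {
        args[[key]] <- as.numeric(val)
      }
    }
  }
  args[names(overrides)] <- overrides
  do.call(hm_config, args)
}
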