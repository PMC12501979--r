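# Internal helpers: logging, coordinate conversion, interval overlap.
# All internal coordinates are 0-based half-open; files on disk follow their
# native conventions (GFF3/cytosine reports/SyRI 1-based inclusive, BED
# 0-based half-open).

.hm_env <- new.env(parent = emptyenv())
.hm_env$log_level <- "info"

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

#' Set the package log level
#'
#' Pipeline stages log record counts in and out together with the thresholds
#' applied, so that the number of records surviving each filter is auditable.
#'
#' @param level one of "debug", "info", "warn", "quiet"
#' @return the previous level, invisibly
#' @export
hm_log_level <- function(level = c("info", "debug", "warn", "quiet")) {
  level <- match.arg(level)
  old <- .hm_env$log_level
  .hm_env$log_level <- level
  invisible(old)
}

hm_log <- function(..., level = "info") {
  if (.log_levels[[level]] >= .log_levels[[.hm_env$log_level]]) {
    message(sprintf("[hapmeth] %s", paste0(...)))
  }
  invisible(NULL)
}

# 1-based inclusive -> 0-based half-open
from1based <- function(start1, end1 = start1) {
  list(start = start1 - 1L, end = end1)
}

# 0-based half-open -> 1-based inclusive
to1based <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}

# Index of the (first) interval in `regions` overlapping each query point,
# NA when none. `regions` is a data.frame with chrom/start/end (0-based
# half-open). Ties broken by first region in input order.
point_in_region <- function(chrom, pos, regions) {
  if (nrow(regions) == 0L || length(pos) == 0L) {
    return(rep(NA_integer_, length(pos)))
  }
  q <- data.table::data.table(chrom = chrom, start = as.integer(pos),
                              end = as.integer(pos), qidx = seq_along(pos))
  # regions converted to closed intervals [start, end-1]
  r <- data.table::data.table(chrom = regions$chrom,
                              start = as.integer(regions$start),
                              end = as.integer(regions$end) - 1L,
                              ridx = seq_len(nrow(regions)))
  r <- r[r$end >= r$start, ]
  if (nrow(r) == 0L) return(rep(NA_integer_, length(pos)))
  data.table::setkey(r, chrom, start, end)
  ov <- data.table::foverlaps(q, r, type = "any", nomatch = NA,
                              mult = "first")
  ov[order(ov$qidx)]$ridx
}

# All (query, subject) overlap pairs between two 0-based half-open interval
# tables. Returns a data.table with columns qidx, sidx.
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(data.table::data.table(qidx = integer(), sidx = integer()))
  }
  # half-open [s,e) recoded as closed [s, e-1]; empty intervals never overlap
  q <- data.table::data.table(chrom = query$chrom,
                              start = as.integer(query$start),
                              end = as.integer(query$end) - 1L,
                              qidx = seq_len(nrow(query)))
  s <- data.table::data.table(chrom = subject$chrom,
                              start = as.integer(subject$start),
                              end = as.integer(subject$end) - 1L,
                              sidx = seq_len(nrow(subject)))
  q <- q[q$end >= q$start, ]
  s <- s[s$end >= s$start, ]
  if (nrow(q) == 0L || nrow(s) == 0L) {
    return(data.table::data.table(qidx = integer(), sidx = integer()))
  }
  data.table::setkey(s, chrom, start, end)
  ov <- data.table::foverlaps(q, s, type = "any", nomatch = NULL)
  out <- ov[, c("qidx", "sidx"), with = FALSE]
  data.table::setorderv(out, c("qidx", "sidx"))
  out[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hm <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

reverse_complement <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE))
}
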