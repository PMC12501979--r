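# Shared fixtures. The default-scale simulation and pipeline run are
# expensive (~5 min), so they are computed once per session and reused by
# every test that needs them.

.fixtures <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(.fixtures$ds)) {
    .fixtures$ds <- simulate_dataset(simulation_spec())
  }
  .fixtures$ds
}

default_report <- function() {
  if (is.null(.fixtures$report)) {
    .fixtures$report <- run_pipeline(default_dataset())
  }
  .fixtures$report
}

default_report_dir <- function() {
  if (is.null(.fixtures$report_dir)) {
    dir <- file.path(tempdir(), "hapmeth-report-run1")
    build_report(default_report(), dir)
    .fixtures$report_dir <- dir
  }
  .fixtures$report_dir
}

# A down-scaled spec that still exercises every pipeline stage quickly.
tiny_spec <- function(seed = 11L, ...) {
  simulation_spec(
    n_chroms = 2L, chrom_length = 150000L, n_genes = 24L,
    te_fraction = 0.15,
    sv_counts = c(INS = 6L, DEL = 6L, INV = 2L, TRANS = 2L,
                  short_INS = 3L, short_DEL = 3L),
    samples = data.table::data.table(
      name = c("C1", "C2", "E1", "E2"),
      role = c("control", "control", "epimutant", "epimutant"),
      CG = c(0, 0, 5, 11), CHG = c(0, 0, 3, 6), CHH = c(0, 0, 1, 3)),
    n_dmr_implant = c(CG = 10L, CHG = 8L, CHH = 8L),
    telomere_copies = 15L, lambda_length = 5000L,
    seed = seed, ...)
}

tiny_dataset <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- simulate_dataset(tiny_spec())
  }
  .fixtures$tiny
}

tiny_report <- function() {
  if (is.null(.fixtures$tiny_report)) {
    .fixtures$tiny_report <- run_pipeline(tiny_dataset())
  }
  .fixtures$tiny_report
}

# Random cytosine site table for oracle tests.
random_sites <- function(n, max_depth = 50L, chroms = c("chr1", "chr2"),
                        span = 100000L) {
  ct <- sample.int(max_depth + 1L, n, replace = TRUE) - 1L
  data.table::data.table(
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(span, n, replace = TRUE) - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
    trinucleotide = "CGA",
    c_meth = vapply(ct, function(t) sample.int(t + 1L, 1L) - 1L,
                    integer(1L)),
    c_total = ct)
}
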