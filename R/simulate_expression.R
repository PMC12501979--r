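# Synthetic allele-resolved expression counts coupled to methylation.

#' Simulate allele-resolved expression counts
#'
#' Base expression per pair is a zero-inflated log-normal (about 10% silent
#' genes). A pair's expected allele log2 fold change is
#' `asm_ase_coupling * delta_CG + N(0, 0.25)`, fixed per pair so allelic
#' bias is stable across samples. Total gene expression additionally
#' responds to the gene's per-sample true methylation through
#' `expr_meth_coupling` (negative for CG/CHG, positive for CHH), so
#' epimutant hypomethylation induces differential expression. Counts are
#' negative binomial with the configured dispersion, scaled so the mean
#' per-allele count matches `mean_expr_depth` (with ~10% library-size
#' jitter).
#'
#' @param spec a [simulation_spec()]
#' @param genomes output of [simulate_genomes()]
#' @param msim output of [simulate_methylome()]
#' @return list with `maternal` / `paternal` (pairs x libraries count
#'   matrices, columns "sample.repK"), `gene_counts` (maternal gene ids),
#'   `gene_lengths` (union-exon bp), `truth` (per-pair expected log2fc and
#'   bias class)
#' @export
simulate_allele_counts <- function(spec, genomes, msim) {
  set.seed(spec$seed + 3L)
  pairs <- genomes$pairs
  n <- nrow(pairs)
  samples <- spec$samples$name
  libs <- as.vector(outer(paste0("rep", seq_len(spec$replicates)),
                          samples, function(r, s) paste0(s, ".", r)))
  libs <- sort(libs)

  ex <- genomes$exons_h1
  ex_len <- ex[, list(len = sum(end - start)), by = "gene_id"]
  gene_lengths <- stats::setNames(ex_len$len, ex_len$gene_id)

  base <- exp(stats::rnorm(n, log(8), 1.6))
  base[stats::runif(n) < 0.10] <- 0
  delta_cg <- msim$truth$pair_divergence$delta_cg[
    match(pairs$pair_id, msim$truth$pair_divergence$pair_id)]
  r <- spec$asm_ase_coupling * delta_cg + stats::rnorm(n, 0, 0.25)
  f_m <- 2^r / (1 + 2^r)

  # per-sample methylation effect on total expression (log2)
  gl <- msim$gene_levels
  ref <- gl[, list(ref = mean(level)), by = c("gene_id", "context")]
  gl <- merge(gl, ref, by = c("gene_id", "context"))
  gl[, "eff" := spec$expr_meth_coupling[gl$context] * (gl$level - gl$ref)]
  eff <- gl[, list(eff = sum(eff)), by = c("gene_id", "sample")]
  eff_mat <- matrix(0, n, length(samples),
                    dimnames = list(pairs$maternal_id, samples))
  eff_mat[cbind(eff$gene_id, eff$sample)[eff$gene_id %in% rownames(eff_mat), ,
                                         drop = FALSE]] <-
    eff$eff[eff$gene_id %in% rownames(eff_mat)]

  len_kb <- pmax(gene_lengths[pairs$maternal_id], 200) / 1000
  mm <- pp <- matrix(0L, n, length(libs),
                     dimnames = list(pairs$pair_id, libs))
  size <- 1 / spec$nb_dispersion
  for (j in seq_along(libs)) {
    sm <- sub("\\.rep[0-9]+$", "", libs[j])
    mu_tot <- base * len_kb * 2^eff_mat[, sm]
    mu_m <- mu_tot * f_m
    mu_p <- mu_tot * (1 - f_m)
    sf <- spec$mean_expr_depth * 2 * n / sum(mu_m + mu_p)
    u <- stats::runif(1L, 0.9, 1.1)
    mm[, j] <- stats::rnbinom(n, mu = mu_m * sf * u, size = size)
    pp[, j] <- stats::rnbinom(n, mu = mu_p * sf * u, size = size)
  }
  gene_counts <- mm + pp
  rownames(gene_counts) <- pairs$maternal_id

  cls <- rep("U", n)
  cls[r >= 1] <- "M"
  cls[r <= -1] <- "P"
  cls[base == 0] <- "U"
  truth <- data.table::data.table(pair_id = pairs$pair_id,
                                  base_expression = base,
                                  expected_log2fc = r,
                                  expected_bias = cls)
  list(maternal = mm, paternal = pp, gene_counts = gene_counts,
       gene_lengths = gene_lengths, truth = truth)
}

#' Simulate a complete study dataset
#'
#' Runs [simulate_genomes()], [simulate_methylome()] and
#' [simulate_allele_counts()] under the seed in `spec` and bundles their
#' outputs with the accumulated ground truth. When `out_dir` is given the
#' dataset is also written to disk in the package's native file formats
#' (FASTA genomes, GFF3 annotation, SyRI-style SV table, per-library
#' cytosine reports including lambda, allele-pair table, count matrices,
#' sample sheet, and the ground truth as JSON).
#'
#' @param spec a [simulation_spec()]
#' @param out_dir optional output directory
#' @return object of class `hm_sim_dataset`
#' @export
simulate_dataset <- function(spec = simulation_spec(), out_dir = NULL) {
  genomes <- simulate_genomes(spec)
  msim <- simulate_methylome(spec, genomes)
  expr <- simulate_allele_counts(spec, genomes, msim)
  truth <- c(genomes$truth, msim$truth, list(expression = expr$truth))
  ds <- structure(list(spec = spec, genomes = genomes, methylome = msim,
                       expression = expr, truth = truth),
                  class = "hm_sim_dataset")
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

#' Write a simulated dataset to disk
#'
#' @param ds a `hm_sim_dataset`
#' @param out_dir output directory (created if missing)
#' @return invisibly, the vector of written paths
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- ds$genomes
  p <- function(...) file.path(out_dir, ...)
  paths <- c(
    write_genome_fasta(g$hap1, p("hap1.fa")),
    write_genome_fasta(g$hap2, p("hap2.fa")),
    write_genome_fasta(g$lambda, p("lambda.fa")))
  write_gff3(g$genes_h1, g$exons_h1, g$tes_h1, p("hap1.gff3"))
  write_gff3(g$genes_h2, g$exons_h2, g$tes_h2, p("hap2.gff3"))
  write_syri_table(g$svs, p("sv.syri.tsv"))
  write_tsv(g$pairs, p("allele_pairs.tsv"))
  write_tsv(ds$spec$samples, p("samples.tsv"))
  dir.create(p("methylomes"), showWarnings = FALSE)
  for (nm in ds$spec$samples$name) {
    for (r in seq_len(ds$spec$replicates)) {
      write_cytosine_report(
        methylome_sites(ds$methylome, nm, r, "hap1"),
        p("methylomes", sprintf("%s_rep%d.hap1.CX_report.txt", nm, r)))
      write_cytosine_report(
        methylome_sites(ds$methylome, nm, r, "hap2"),
        p("methylomes", sprintf("%s_rep%d.hap2.CX_report.txt", nm, r)))
      write_cytosine_report(
        methylome_sites(ds$methylome, nm, r, "lambda"),
        p("methylomes", sprintf("%s_rep%d.lambda.CX_report.txt", nm, r)))
    }
  }
  write_count_matrix(ds$expression$maternal, p("counts_maternal.tsv"))
  write_count_matrix(ds$expression$paternal, p("counts_paternal.tsv"))
  write_count_matrix(ds$expression$gene_counts, p("counts_gene.tsv"))
  truth <- list(
    svs = ds$truth$svs, telomeres = ds$truth$telomeres,
    implants = ds$truth$implants, patches = ds$truth$patches,
    pair_divergence = ds$truth$pair_divergence,
    expression = ds$truth$expression)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       digits = NA, na = "null")
  invisible(paths)
}
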