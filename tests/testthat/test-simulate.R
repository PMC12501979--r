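test_that("simulation_spec validates its knobs", {
  expect_s3_class(simulation_spec(), "hm_sim_spec")
  expect_error(simulation_spec(replicates = 1L))
  expect_error(simulation_spec(conversion_error = 0))
  expect_error(simulation_spec(conversion_error = 0.1))
  expect_error(simulation_spec(te_fraction = 1))
  bad_samples <- data.table::data.table(
    name = "X", role = "mystery", CG = 0, CHG = 0, CHH = 0)
  expect_error(simulation_spec(samples = bad_samples))
})

test_that("default samples are two controls and four epimutants", {
  s <- default_samples()
  expect_identical(sum(s$role == "control"), 2L)
  expect_identical(sum(s$role == "epimutant"), 4L)
  expect_true(all(s$CG[s$role == "control"] == 0))
  # CG reductions dominate CHG which dominate CHH
  epi <- s[s$role == "epimutant", ]
  expect_true(all(epi$CG >= epi$CHG & epi$CHG >= epi$CHH))
})

test_that("the simulation is deterministic under a fixed seed", {
  ds1 <- tiny_dataset()
  ds2 <- simulate_dataset(tiny_spec())
  expect_identical(ds1$genomes$hap1, ds2$genomes$hap1)
  expect_identical(ds1$genomes$hap2, ds2$genomes$hap2)
  expect_identical(ds1$genomes$svs, ds2$genomes$svs)
  expect_identical(ds1$methylome$counts, ds2$methylome$counts)
  expect_identical(ds1$expression$maternal, ds2$expression$maternal)
  expect_identical(ds1$truth$implants, ds2$truth$implants)
  # a different seed changes the genome
  ds3 <- simulate_dataset(tiny_spec(seed = 12L))
  expect_false(identical(ds1$genomes$hap1, ds3$genomes$hap1))
})

test_that("simulated genomes carry telomeres, genes and a lambda spike-in", {
  ds <- tiny_dataset()
  g <- ds$genomes
  expect_identical(length(g$hap1), 2L)
  tel <- find_telomeres(g$hap1, min_copies = 10L)
  expect_true(all(tel$telomeric))
  expect_identical(nrow(g$genes_h1), 24L)
  expect_true(all(g$genes_h1$end > g$genes_h1$start))
  # genes do not overlap each other on hap1
  ov <- hapmeth:::overlap_pairs(g$genes_h1, g$genes_h1)
  expect_true(all(ov$qidx == ov$sidx))
  expect_identical(nchar(g$lambda[[1L]]), 5000L)
  # every allele pair resolves to genes on both haplotypes
  expect_true(all(g$pairs$maternal_id %in% g$genes_h1$gene_id))
  expect_true(all(g$pairs$paternal_id %in% g$genes_h2$gene_id))
})

test_that("the SV truth matches the requested counts and survives a disk round trip", {
  ds <- tiny_dataset()
  svs <- ds$genomes$svs
  raw <- table(svs$raw_type)
  expect_identical(unname(raw[["INV"]]), 2L)
  expect_identical(unname(raw[["TRANS"]]), 2L)
  # 6 long + 3 short insertions, same for deletions
  expect_identical(unname(raw[["INS"]]), 9L)
  expect_identical(unname(raw[["DEL"]]), 9L)
  grp <- group_sv_records(svs)
  tab <- table(grp$grouped_category)
  expect_identical(unname(tab[["short"]]), 6L)
  expect_identical(unname(tab[["PV"]]), 6L)
  expect_identical(unname(tab[["AV"]]), 6L)
  # round trip through the SyRI format preserves the grouping
  f <- tempfile(fileext = ".tsv")
  write_syri_table(svs, f)
  back <- group_sv_records(read_syri_table(f))
  expect_identical(back$grouped_category, grp$grouped_category)
  expect_identical(back$ref_start, svs$ref_start)
})

test_that("implanted DMR windows are step-aligned, disjoint and threshold-clearing", {
  ds <- tiny_dataset()
  imp <- ds$truth$implants
  spec <- tiny_spec()
  expect_true(all(imp$start %% 100L == 0L))
  expect_true(all(imp$end - imp$start == 200L))
  # no two implants overlap (cells are blocked globally)
  ov <- hapmeth:::overlap_pairs(imp, imp)
  expect_true(all(ov$qidx == ov$sidx))
  # direction, delta and level bookkeeping are mutually consistent
  expect_true(all(imp$delta[imp$direction == "hypo"] < 0))
  expect_true(all(imp$delta[imp$direction == "hyper"] > 0))
  expect_equal(imp$delta,
               (imp$epimutant_level - imp$control_level) * 100)
  expect_equal(abs(imp$delta), unname(spec$dmr_delta[imp$context]))
  expect_true(all(imp$control_level >= 0 & imp$control_level <= 1))
  expect_true(all(imp$epimutant_level >= 0 & imp$epimutant_level <= 1))
  # requested implant counts per epimutant and context
  cnt <- imp[, list(n = .N), by = c("sample", "context")]
  expect_true(all(cnt$n == spec$n_dmr_implant[cnt$context]))
  expect_identical(sort(unique(imp$sample)), c("E1", "E2"))
})

test_that("methylome libraries look like bisulfite data", {
  ds <- tiny_dataset()
  s <- methylome_sites(ds$methylome, "C1", 1L, "hap1")
  expect_true(all(c("chrom", "pos", "strand", "context", "trinucleotide",
                    "c_meth", "c_total") %in% names(s)))
  expect_true(all(s$c_meth <= s$c_total))
  expect_true(all(s$context %in% c("CG", "CHG", "CHH")))
  # depth is Poisson around the requested mean
  expect_equal(mean(s$c_total), 20, tolerance = 0.05)
  # replicates differ but share the template
  s2 <- methylome_sites(ds$methylome, "C1", 2L, "hap1")
  expect_identical(s2$pos, s$pos)
  expect_false(identical(s2$c_meth, s$c_meth))
  # lambda is unmethylated up to the conversion error
  lam <- methylome_sites(ds$methylome, "C1", 1L, "lambda")
  expect_lt(sum(lam$c_meth) / sum(lam$c_total), 0.02)
  # the epimutant E2 is globally hypomethylated relative to control in CG
  e2 <- methylome_sites(ds$methylome, "E2", 1L, "hap1")
  lev <- function(x) sum(x$c_meth[x$context == "CG"]) /
    sum(x$c_total[x$context == "CG"])
  expect_lt(lev(e2), lev(s) - 0.05)
})

test_that("allele counts are consistent across the three matrices", {
  ds <- tiny_dataset()
  e <- ds$expression
  expect_identical(dim(e$maternal), dim(e$paternal))
  expect_identical(ncol(e$maternal), 4L * 2L)  # samples x replicates
  expect_identical(rownames(e$maternal), ds$genomes$pairs$pair_id)
  expect_identical(unname(e$gene_counts), unname(e$maternal + e$paternal))
  expect_identical(rownames(e$gene_counts), ds$genomes$pairs$maternal_id)
  expect_true(all(rownames(e$gene_counts) %in% names(e$gene_lengths)))
  expect_true(all(e$maternal >= 0))
})

test_that("write_dataset produces the full file inventory", {
  ds <- tiny_dataset()
  dir <- file.path(tempdir(), "hapmeth-tiny-out")
  unlink(dir, recursive = TRUE)
  write_dataset(ds, dir)
  expected <- c("hap1.fa", "hap2.fa", "lambda.fa", "hap1.gff3", "hap2.gff3",
                "sv.syri.tsv", "allele_pairs.tsv", "samples.tsv",
                "counts_maternal.tsv", "counts_paternal.tsv",
                "counts_gene.tsv", "truth.json")
  for (f in expected) expect_true(file.exists(file.path(dir, f)), info = f)
  reports <- list.files(file.path(dir, "methylomes"))
  # 4 samples x 2 replicates x (hap1, hap2, lambda)
  expect_identical(length(reports), 4L * 2L * 3L)
  # spot-check one report round-trips against the in-memory library
  back <- read_cytosine_report(
    file.path(dir, "methylomes", "C1_rep1.hap1.CX_report.txt"))
  mem <- methylome_sites(ds$methylome, "C1", 1L, "hap1")
  expect_identical(back$pos, mem$pos)
  expect_identical(back$c_meth, as.integer(mem$c_meth))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_true(all(c("svs", "implants", "pair_divergence", "expression")
                  %in% names(tr)))
  unlink(dir, recursive = TRUE)
})
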