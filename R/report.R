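# Pipeline driver chaining every analysis stage, and the panel-TSV report.

#' Run the full analysis pipeline on a simulated dataset
#'
#' Chains every stage on an in-memory [simulate_dataset()] result:
#' conversion-error estimation from lambda, per-sample methylome summaries,
#' DMR detection per epimutant against the reference control, DMR
#' annotation/intersection/DMG calling, metaplots and telomere detection,
#' expression quantification with rank groups, DEG calling, DMG-in-DEG
#' enrichment, allele-specific expression, allele-pair methylation bins
#' with ASMR/ASMG detection and divergence grades, SV grouping and
#' SV-methylation/expression statistics, breakpoint support, and the
#' bin-wise methylation-expression correlation analysis. Every stage output
#' is returned under a stable name; [build_report()] serializes them.
#'
#' @param ds a `hm_sim_dataset`
#' @param config an [hm_config()]
#' @param reference_control name of the control sample used as the DMR/ASM
#'   reference; defaults to the last control in the sample sheet
#' @return object of class `hm_report` (named list of stage outputs)
#' @export
run_pipeline <- function(ds, config = hm_config(), reference_control = NULL) {
  g <- ds$genomes
  msim <- ds$methylome
  samples <- ds$spec$samples
  ctrls <- samples$name[samples$role == "control"]
  epis <- samples$name[samples$role == "epimutant"]
  if (is.null(reference_control)) reference_control <- ctrls[length(ctrls)]
  stopifnot(reference_control %in% ctrls)
  reps <- seq_len(ds$spec$replicates)

  # --- conversion error from lambda -------------------------------------
  hm_log("pipeline: estimating conversion error from lambda")
  conv <- data.table::rbindlist(lapply(samples$name, function(nm) {
    est <- estimate_conversion_error(.pooled_sites(msim, nm, "lambda"))
    data.table::data.table(sample = nm, apparent_rate = est$pooled,
                           conversion_rate = est$conversion_rate)
  }))

  # --- per-sample methylome summaries -----------------------------------
  hm_log("pipeline: per-sample methylome summaries")
  pooled <- lapply(stats::setNames(samples$name, samples$name),
                   function(nm) .pooled_sites(msim, nm, "hap1"))
  summaries <- list()
  histograms <- list()
  shares <- list()
  for (nm in samples$name) {
    err <- conv$apparent_rate[conv$sample == nm]
    called <- call_methylated_sites(pooled[[nm]], err,
                                    depth_min = config$depth_min,
                                    fdr = config$q_threshold)
    sm <- genome_methylation_summary(called, all_cytosines = msim$template)
    sm[, "sample" := nm]
    summaries[[nm]] <- sm
    hh <- methylation_level_histogram(called, depth_min = config$depth_min)
    hh[, "sample" := nm]
    histograms[[nm]] <- hh
    sh <- context_share(called)
    shares[[nm]] <- data.table::data.table(sample = nm,
                                           context = names(sh),
                                           share = as.numeric(sh))
  }
  summaries <- data.table::rbindlist(summaries)
  histograms <- data.table::rbindlist(histograms)
  shares <- data.table::rbindlist(shares)
  ref_lv <- summaries[summaries$sample == reference_control,
                      c("context", "level")]
  reductions <- merge(
    summaries[summaries$sample %in% epis,
              c("sample", "context", "level")],
    ref_lv, by = "context", suffixes = c("", "_control"))
  reductions[, "reduction_points" :=
               (reductions$level_control - reductions$level) * 100]
  data.table::setorderv(reductions, c("sample", "context"))

  # --- DMR detection per epimutant --------------------------------------
  chrom_lengths <- vapply(g$hap1, nchar, integer(1L))
  ctrl_reps <- lapply(reps, function(r) {
    methylome_sites(msim, reference_control, r, "hap1")
  })
  dmr_sets <- list()
  for (nm in epis) {
    hm_log(sprintf("pipeline: DMR testing %s vs %s", nm, reference_control))
    test_reps <- lapply(reps, function(r) methylome_sites(msim, nm, r, "hap1"))
    ws <- dmr_test_windows(test_reps, ctrl_reps, chrom_lengths, config)
    dmr_sets[[nm]] <- call_dmrs(ws, config$dmr_diff_thresholds,
                                config$q_threshold)
  }
  dmr_counts <- data.table::rbindlist(lapply(epis, function(nm) {
    d <- dmr_sets[[nm]]
    out <- d[, list(n = .N), by = c("context", "direction")]
    out[, "sample" := nm]
    out
  }))
  dmr_features <- data.table::rbindlist(lapply(epis, function(nm) {
    if (nrow(dmr_sets[[nm]]) == 0L) return(NULL)
    out <- dmr_feature_proportions(dmr_sets[[nm]], g$genes_h1, g$exons_h1,
                                   config$flank_size)
    out[, "sample" := nm]
    out
  }))
  intersections <- if (length(epis) >= 2L) intersect_dmr_sets(dmr_sets)
                   else NULL
  common_levels <- if (!is.null(intersections)) {
    common_dmr_level_distributions(intersections, pooled, min_shared = 2L)
  } else NULL
  dmgs <- lapply(dmr_sets, call_dmgs, genes = g$genes_h1,
                 flank = config$flank_size)
  dmg_counts <- data.table::rbindlist(lapply(epis, function(nm) {
    d <- dmgs[[nm]]
    out <- d[, list(n_genes = data.table::uniqueN(gene_id)),
             by = c("context", "direction")]
    out[, "sample" := nm]
    out
  }))

  # --- metaplots and telomeres ------------------------------------------
  hm_log("pipeline: metaprofiles and telomeres")
  metaprofiles <- data.table::rbindlist(lapply(samples$name, function(nm) {
    mg <- metaprofile(pooled[[nm]], g$genes_h1, config$body_bins,
                      config$flank_bins, config$flank_size)
    mg[, c("sample", "feature_type") := list(nm, "gene")]
    mt <- metaprofile(pooled[[nm]], g$tes_h1, config$body_bins,
                      config$flank_bins, config$flank_size)
    mt[, c("sample", "feature_type") := list(nm, "te")]
    rbind(mg, mt)
  }))
  telomeres <- rbind(
    cbind(find_telomeres(g$hap1), haplotype = "hap1"),
    cbind(find_telomeres(g$hap2), haplotype = "hap2"))

  # --- expression --------------------------------------------------------
  hm_log("pipeline: expression, DEGs, ASE")
  gene_counts <- ds$expression$gene_counts
  tpm_lib <- compute_tpm(gene_counts, ds$expression$gene_lengths)
  lib_sample <- sub("\\.rep[0-9]+$", "", colnames(tpm_lib))
  tpm_sample <- vapply(samples$name, function(nm) {
    rowMeans(tpm_lib[, lib_sample == nm, drop = FALSE])
  }, numeric(nrow(tpm_lib)))
  rownames(tpm_sample) <- rownames(tpm_lib)
  tpm_ctrl <- rowMeans(tpm_sample[, ctrls, drop = FALSE])
  ranks <- rank_expression(tpm_ctrl)
  names(ranks) <- rownames(tpm_lib)

  gene_meth <- region_methylation(pooled[[reference_control]],
                                  g$genes_h1, by_context = TRUE)
  gene_meth[, "gene_id" := g$genes_h1$gene_id[gene_meth$region_idx]]
  meth_by_rank <- lapply(stats::setNames(.valid_contexts, .valid_contexts),
                         function(cx) {
    gl <- gene_meth[gene_meth$context == cx, c("gene_id", "level")]
    meth_by_expression_rank(gl, ranks)
  })
  cat_fracs <- data.table::rbindlist(
    lapply(.valid_contexts, function(cx) {
      gl <- gene_meth[gene_meth$context == cx, ]
      out <- category_fractions(gl$level, ranks[gl$gene_id])
      out[, "context" := cx]
      out
    }))

  ctrl_libs <- colnames(gene_counts)[lib_sample %in% ctrls]
  degs <- lapply(stats::setNames(epis, epis), function(nm) {
    cols <- c(colnames(gene_counts)[lib_sample == nm], ctrl_libs)
    grp <- factor(ifelse(lib_sample[match(cols, colnames(gene_counts))]
                         == nm, "test", "control"),
                  levels = c("test", "control"))
    call_degs(gene_counts[, cols], grp)
  })
  deg_counts <- data.table::rbindlist(lapply(epis, function(nm) {
    d <- degs[[nm]]
    data.table::data.table(sample = nm,
                           n_up = sum(d$deg_status == "up"),
                           n_down = sum(d$deg_status == "down"))
  }))
  universe <- rownames(gene_counts)
  enrichment <- data.table::rbindlist(lapply(epis, function(nm) {
    dmg_set <- intersect(unique(dmgs[[nm]]$gene_id), universe)
    deg_set <- degs[[nm]]$gene_id[degs[[nm]]$deg_status != "ns"]
    en <- dmg_deg_enrichment(dmg_set, deg_set, universe)
    data.table::data.table(sample = nm, n_dmg = length(dmg_set),
                           n_deg = length(deg_set),
                           n_overlap = en$table["deg", "dmg"],
                           odds_ratio = en$odds_ratio,
                           p_value = en$p_value)
  }))

  # --- allele-specific expression ---------------------------------------
  pair_counts <- list(maternal = ds$expression$maternal,
                      paternal = ds$expression$paternal,
                      pair_id = rownames(ds$expression$maternal))
  ase_all <- classify_ase(pair_counts)
  ase_classes <- data.table::data.table(
    bias_class = .bias_levels,
    n = vapply(.bias_levels, function(b) sum(ase_all$bias_class == b),
               integer(1L)))
  sub_ase <- function(cols) {
    classify_ase(list(maternal = ds$expression$maternal[, cols],
                      paternal = ds$expression$paternal[, cols],
                      pair_id = rownames(ds$expression$maternal)))
  }
  ase_ctrl <- sub_ase(colnames(gene_counts)[lib_sample %in% ctrls])
  ase_crosstabs <- data.table::rbindlist(lapply(epis, function(nm) {
    ae <- sub_ase(colnames(gene_counts)[lib_sample == nm])
    m <- crosstab_bias(ae$bias_class, ase_ctrl$bias_class)
    out <- data.table::as.data.table(as.table(m))
    data.table::setnames(out, c("epimutant_class", "control_class", "n"))
    out[, "sample" := nm]
    out
  }))

  # --- allele-specific methylation and SVs ------------------------------
  hm_log("pipeline: allele-pair methylation and SV statistics")
  svs <- group_sv_records(g$svs)
  sv_summary <- summarize_sv_categories(svs)
  mat_reps <- lapply(reps, function(r) {
    methylome_sites(msim, reference_control, r, "hap1")
  })
  pat_reps <- lapply(reps, function(r) {
    methylome_sites(msim, reference_control, r, "hap2")
  })
  pair_bins <- allele_pair_bins(mat_reps, pat_reps, g$pairs,
                                g$genes_h1, g$genes_h2, config)
  asmrs <- detect_asmrs(pair_bins, config$dmr_diff_thresholds,
                        config$q_threshold,
                        config$min_cytosines_per_window)
  asmgs <- call_asmgs(asmrs)
  asmr_counts <- asmrs[asmrs$is_asmr,
                       list(n_asmr = .N,
                            n_pairs = data.table::uniqueN(pair_id)),
                       by = "context"]
  ase_named <- ase_all
  ase_named$pair_id <- rownames(ds$expression$maternal)
  fc_grades <- lapply(stats::setNames(.valid_contexts, .valid_contexts),
                      function(cx) fc_by_grade(ase_named, asmrs, cx))
  asmr_sv <- compare_asmr_sv(asmrs, svs)

  genes_m <- g$genes_h1[match(g$pairs$maternal_id, g$genes_h1$gene_id), ]
  genes_p <- g$genes_h2[match(g$pairs$paternal_id, g$genes_h2$gene_id), ]
  sv_features <- overlap_sv_alleles(svs, genes_m, genes_p,
                                    g$exons_h1, g$exons_h2,
                                    config$flank_size)
  aseg <- ase_named$pair_id[ase_named$bias_class != "U"]
  loc_a <- .sv_location_counts(svs, g$pairs[g$pairs$pair_id %in% aseg, ],
                               genes_m, genes_p, g$pairs,
                               config$flank_size)
  loc_b <- .sv_location_counts(svs, g$pairs[!g$pairs$pair_id %in% aseg, ],
                               genes_m, genes_p, g$pairs,
                               config$flank_size)
  sv_location <- if (sum(loc_a) > 0 && sum(loc_b) > 0) {
    sv_location_test(loc_a, loc_b)
  } else NULL
  breakpoints <- validate_breakpoints(g$hifi_reads, svs[
    svs$grouped_category %in% c("TRANS", "INV", "AV", "PV"), ])

  # --- bin-wise methylation x expression correlations -------------------
  hm_log("pipeline: bin-wise methylation/expression correlations")
  bin_levels <- data.table::rbindlist(lapply(samples$name, function(nm) {
    bl <- gene_bin_levels(pooled[[nm]], g$genes_h1, config$body_bins,
                          config$flank_bins, config$flank_size)
    bl[, "sample" := nm]
    bl
  }))
  binwise <- binwise_expression_correlation(bin_levels, tpm_sample,
                                            min_samples = length(samples$name))
  body_cors <- binwise$correlations[
    binwise$correlations$bin > config$flank_bins &
      binwise$correlations$bin <= config$flank_bins + config$body_bins, ]
  te_flags <- stats::setNames(g$genes_h1$is_te_overlapping,
                              g$genes_h1$gene_id)
  te_fluct <- te_fluctuation(body_cors, te_flags)

  manifest <- .run_manifest(ds, config, reference_control)
  structure(list(
    manifest = manifest,
    conversion = conv,
    methylome_summary = summaries,
    level_histograms = histograms,
    context_shares = shares,
    reductions = reductions,
    dmr_sets = dmr_sets,
    dmr_counts = dmr_counts,
    dmr_features = dmr_features,
    dmr_intersections = intersections,
    common_dmr_levels = common_levels,
    dmgs = dmgs,
    dmg_counts = dmg_counts,
    metaprofiles = metaprofiles,
    telomeres = telomeres,
    tpm = tpm_sample,
    rank_groups = ranks,
    meth_by_rank = meth_by_rank,
    category_fractions = cat_fracs,
    degs = degs,
    deg_counts = deg_counts,
    enrichment = enrichment,
    ase = ase_named,
    ase_classes = ase_classes,
    ase_crosstabs = ase_crosstabs,
    pair_bins = pair_bins,
    asmrs = asmrs,
    asmgs = asmgs,
    asmr_counts = asmr_counts,
    fc_grades = fc_grades,
    asmr_sv = asmr_sv,
    sv_summary = sv_summary,
    sv_features = sv_features,
    sv_location = sv_location,
    breakpoints = breakpoints,
    binwise = binwise,
    te_fluctuation = te_fluct), class = "hm_report")
}

# Pool a sample's replicate counts onto the template.
.pooled_sites <- function(msim, nm, hap) {
  t <- switch(hap, hap1 = msim$template, hap2 = msim$hap2$template,
              lambda = msim$lambda$template)
  cl <- switch(hap, hap1 = msim$counts, hap2 = msim$hap2$counts,
               lambda = msim$lambda$counts)[[nm]]
  if (is.null(cl)) stop_hm("no simulated sample '%s'", nm)
  cm <- Reduce(`+`, lapply(cl, function(x) x$c_meth))
  ct <- Reduce(`+`, lapply(cl, function(x) x$c_total))
  out <- data.table::copy(t)
  out[, c("c_meth", "c_total") := list(cm, ct)]
  out[]
}

# Distinct SVs overlapping gene bodies / upstream / downstream of a pair
# subset, on either haplotype.
.sv_location_counts <- function(svs, pair_subset, genes_m, genes_p,
                                pairs, flank) {
  svs <- svs[svs$grouped_category %in% c("TRANS", "INV", "AV", "PV"), ]
  svs <- data.table::copy(svs)
  svs[, "sv_id" := seq_len(nrow(svs))]
  sel <- pairs$pair_id %in% pair_subset$pair_id
  gm <- genes_m[sel, ]
  gp <- genes_p[sel, ]
  count_region <- function(mk) {
    iv <- rbind(mk(gm), mk(gp))
    ids <- c(
      svs$sv_id[overlap_pairs(
        data.table::data.table(chrom = svs$ref_chrom, start = svs$ref_start,
                               end = svs$ref_end), iv)$qidx],
      svs$sv_id[overlap_pairs(
        data.table::data.table(chrom = svs$qry_chrom, start = svs$qry_start,
                               end = svs$qry_end), iv)$qidx])
    length(unique(ids))
  }
  plus <- function(g) g$strand == "+"
  c(gene_body = count_region(function(g) {
      data.table::data.table(chrom = g$chrom, start = g$start, end = g$end)
    }),
    upstream = count_region(function(g) {
      data.table::data.table(
        chrom = g$chrom,
        start = ifelse(plus(g), g$start - flank, g$end),
        end = ifelse(plus(g), g$start, g$end + flank))
    }),
    downstream = count_region(function(g) {
      data.table::data.table(
        chrom = g$chrom,
        start = ifelse(plus(g), g$end, g$start - flank),
        end = ifelse(plus(g), g$end + flank, g$start))
    }))
}

.run_manifest <- function(ds, config, reference_control) {
  kv <- function(k, v) {
    d <- data.table::data.table(k, as.character(v))
    data.table::setnames(d, c("key", "value"))
    d
  }
  data.table::rbindlist(list(
    kv("package_version",
       as.character(utils::packageVersion("hapmeth"))),
    kv("r_version", R.version.string),
    kv("seed", ds$spec$seed),
    kv("reference_control", reference_control),
    kv("window_size", config$window_size),
    kv("step_size", config$step_size),
    kv("min_cytosines_per_window", config$min_cytosines_per_window),
    kv("dmr_diff_threshold_CG", config$dmr_diff_thresholds[["CG"]]),
    kv("dmr_diff_threshold_CHG", config$dmr_diff_thresholds[["CHG"]]),
    kv("dmr_diff_threshold_CHH", config$dmr_diff_thresholds[["CHH"]]),
    kv("q_threshold", config$q_threshold),
    kv("depth_min", config$depth_min),
    kv("flank_size", config$flank_size),
    kv("body_bins", config$body_bins),
    kv("flank_bins", config$flank_bins),
    kv("n_samples", nrow(ds$spec$samples)),
    kv("n_replicates", ds$spec$replicates),
    kv("n_cytosines_hap1", nrow(ds$methylome$template)),
    kv("n_genes", nrow(ds$genomes$genes_h1)),
    kv("n_allele_pairs", nrow(ds$genomes$pairs)),
    kv("n_sv_records", nrow(ds$genomes$svs))))
}

#' Write a report as one TSV per panel plus a manifest
#'
#' Serializes every panel of a [run_pipeline()] report into `out_dir`. A
#' panel whose stage output is missing (NULL) is skipped with a note in the
#' manifest, and the returned status is nonzero so script wrappers can
#' propagate a failing exit code.
#'
#' @param report a `hm_report`
#' @param out_dir output directory (created if missing)
#' @return invisibly, list with `status` (0 = all panels written), `written`
#'   and `skipped` file names
#' @export
build_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  flat_grades <- function() {
    data.table::rbindlist(lapply(names(report$fc_grades), function(cx) {
      fg <- report$fc_grades[[cx]]
      if (is.null(fg) || length(fg$medians) == 0L) return(NULL)
      data.table::data.table(context = cx,
                             grade = as.integer(names(fg$medians)),
                             n_pairs = vapply(names(fg$medians), function(g) {
                               sum(fg$values$grade == as.integer(g))
                             }, integer(1L)),
                             median_abs_log2fc = as.numeric(fg$medians))
    }))
  }
  panels <- list(
    conversion_rates = function() report$conversion,
    methylome_summary = function() report$methylome_summary,
    level_histograms = function() report$level_histograms,
    context_shares = function() report$context_shares,
    level_reductions = function() report$reductions,
    dmr_counts = function() report$dmr_counts,
    dmr_features = function() report$dmr_features,
    dmr_intersections = function() report$dmr_intersections$subset_counts,
    dmr_shared_by_all = function() {
      ix <- report$dmr_intersections
      if (is.null(ix)) return(NULL)
      data.table::data.table(
        n_shared_by_all = ix$n_shared_by_all,
        frac_shared_by_all = ix$frac_shared_by_all,
        n_shared_by_all_positional = ix$n_shared_by_all_positional)
    },
    common_dmr_levels = function() report$common_dmr_levels,
    dmg_counts = function() report$dmg_counts,
    gene_metaprofiles = function() {
      report$metaprofiles[report$metaprofiles$feature_type == "gene", ]
    },
    te_metaprofiles = function() {
      report$metaprofiles[report$metaprofiles$feature_type == "te", ]
    },
    telomeres = function() report$telomeres,
    meth_by_expression_rank = function() {
      data.table::rbindlist(lapply(names(report$meth_by_rank), function(cx) {
        mr <- report$meth_by_rank[[cx]]
        data.table::data.table(context = cx,
                               rank_group = names(mr$medians),
                               median_level = as.numeric(mr$medians),
                               letters = mr$letters[names(mr$medians)])
      }))
    },
    methylation_category_fractions = function() report$category_fractions,
    deg_counts = function() report$deg_counts,
    dmg_deg_enrichment = function() report$enrichment,
    binwise_correlation_tallies = function() report$binwise$tallies,
    te_fluctuation = function() report$te_fluctuation,
    ase_classes = function() report$ase_classes,
    ase_crosstabs = function() report$ase_crosstabs,
    asmr_counts = function() report$asmr_counts,
    ase_by_divergence_grade = flat_grades,
    sv_categories = function() {
      data.table::data.table(
        category = c(names(report$sv_summary$counts), "total"),
        n = c(as.numeric(report$sv_summary$counts),
              report$sv_summary$total))
    },
    sv_gene_features = function() report$sv_features$feature_counts,
    sv_location_test = function() {
      lt <- report$sv_location
      if (is.null(lt)) return(NULL)
      data.table::data.table(
        class = rownames(lt$table),
        gene_body = lt$table[, "gene_body"],
        upstream = lt$table[, "upstream"],
        downstream = lt$table[, "downstream"],
        statistic = lt$statistic, df = lt$df, p_value = lt$p_value)
    },
    asmr_sv_comparison = function() report$asmr_sv,
    sv_breakpoint_support = function() report$breakpoints)
  written <- character(0L)
  skipped <- character(0L)
  for (nm in names(panels)) {
    tab <- tryCatch(panels[[nm]](), error = function(e) NULL)
    if (is.null(tab) || (is.data.frame(tab) && nrow(tab) == 0L &&
                           ncol(tab) == 0L)) {
      skipped <- c(skipped, nm)
      hm_log(sprintf("build_report: panel %s skipped (missing stage output)",
                     nm), level = "warn")
      next
    }
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(tab, path)
    written <- c(written, basename(path))
  }
  manifest <- data.table::copy(report$manifest)
  if (length(skipped)) {
    extra <- data.table::data.table(paste0("skipped_panel_", skipped),
                                    "skipped")
    data.table::setnames(extra, c("key", "value"))
    manifest <- rbind(manifest, extra)
  }
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(status = as.integer(length(skipped) > 0L),
                 written = written, skipped = skipped))
}
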