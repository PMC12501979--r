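# Synthetic haplotype-resolved datasets with known ground truth.
#
# The generator emulates the statistical structure of a 5-Aza epimutant
# WGBS/RNA-seq study: bimodal CG/CHG site methylation, predominantly low
# CHH methylation, TE hypermethylation, region-wise (patchy) genome-wide
# hypomethylation of varying strength in epimutants, an unmethylated lambda
# spike-in, allele pairs with coupled methylation/expression bias, and
# structural variants with locally elevated inter-haplotype methylation
# divergence. Every implanted effect is recorded in a GroundTruth object so
# downstream detection can be scored.

#' Simulation specification
#'
#' Defaults define a toy-scale study: 2 chromosomes of 1 Mb per haplotype,
#' 200 genes, 2 controls plus 4 epimutants with context-wise demethylation
#' strengths (percentage points of genome-wide weighted level), 2 biological
#' replicates at mean depth 20, and an unmethylated lambda spike-in.
#'
#' @param n_chroms number of chromosomes
#' @param chrom_length core chromosome length in bp (telomeric arrays are
#'   appended on top)
#' @param n_genes total number of genes (split over chromosomes)
#' @param te_fraction fraction of the genome covered by TE intervals
#' @param snp_rate per-bp SNP probability between haplotypes
#' @param sv_counts named counts of structural edits applied to hap2
#'   (INS, DEL, INV, TRANS, short_INS, short_DEL)
#' @param samples data.frame with name, role (control/epimutant) and
#'   demethylation strengths per context in percentage points
#' @param replicates biological replicates per sample (>= 2)
#' @param mean_depth mean WGBS read depth per cytosine
#' @param conversion_error apparent methylation rate of unmethylated DNA
#'   (1 - bisulfite conversion rate), in (0, 0.05]
#' @param asm_ase_coupling slope linking a pair's methylation divergence
#'   (percentage points, CG) to its expected allele log2 fold change
#' @param expr_meth_coupling named per-context slopes linking a gene's
#'   methylation-level change (fraction) to its log2 expression change
#' @param mean_expr_depth target mean RNA-seq count per allele
#' @param nb_dispersion negative-binomial dispersion of expression counts
#' @param n_dmr_implant named per-context counts of implanted DMR windows
#'   per epimutant
#' @param dmr_delta named per-context implant differences (percentage
#'   points), each above the detection threshold by a margin
#' @param hypo_fraction fraction of implanted DMRs that are hypomethylated
#' @param asm_fraction fraction of allele pairs with implanted divergence
#' @param sv_divergence couple SV overlap to elevated CG/CHG divergence
#'   (and reduced CHH divergence)
#' @param telomere_copies telomere motif copies appended per chromosome end
#' @param lambda_length lambda spike-in length in bp
#' @param seed integer RNG seed
#' @return object of class `hm_sim_spec`
#' @export
simulation_spec <- function(n_chroms = 2L,
                            chrom_length = 1000000L,
                            n_genes = 200L,
                            te_fraction = 0.15,
                            snp_rate = 0.005,
                            sv_counts = c(INS = 25L, DEL = 25L, INV = 6L,
                                          TRANS = 6L, short_INS = 10L,
                                          short_DEL = 10L),
                            samples = default_samples(),
                            replicates = 2L,
                            mean_depth = 20,
                            conversion_error = 0.005,
                            asm_ase_coupling = 0.02,
                            expr_meth_coupling = c(CG = -3, CHG = -2,
                                                   CHH = 2),
                            mean_expr_depth = 30,
                            nb_dispersion = 0.1,
                            n_dmr_implant = c(CG = 60L, CHG = 40L,
                                              CHH = 40L),
                            dmr_delta = c(CG = 40, CHG = 40, CHH = 25),
                            hypo_fraction = 0.8,
                            asm_fraction = 0.25,
                            sv_divergence = TRUE,
                            telomere_copies = 30L,
                            lambda_length = 20000L,
                            seed = 1L) {
  samples <- data.table::as.data.table(samples)
  stopifnot(all(c("name", "role", "CG", "CHG", "CHH") %in% names(samples)),
            all(samples$role %in% c("control", "epimutant")),
            all(unlist(samples[, c("CG", "CHG", "CHH")]) >= 0),
            all(unlist(samples[, c("CG", "CHG", "CHH")]) <= 100),
            conversion_error > 0, conversion_error <= 0.05,
            replicates >= 2L,
            te_fraction >= 0, te_fraction < 1,
            asm_fraction >= 0, asm_fraction <= 1)
  structure(list(
    n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes), te_fraction = te_fraction,
    snp_rate = snp_rate, sv_counts = sv_counts, samples = samples,
    replicates = as.integer(replicates), mean_depth = mean_depth,
    conversion_error = conversion_error,
    asm_ase_coupling = asm_ase_coupling,
    expr_meth_coupling = expr_meth_coupling,
    mean_expr_depth = mean_expr_depth, nb_dispersion = nb_dispersion,
    n_dmr_implant = n_dmr_implant, dmr_delta = dmr_delta,
    hypo_fraction = hypo_fraction, asm_fraction = asm_fraction,
    sv_divergence = sv_divergence,
    telomere_copies = as.integer(telomere_copies),
    lambda_length = as.integer(lambda_length),
    seed = as.integer(seed)), class = "hm_sim_spec")
}

#' Default sample sheet: two controls, four epimutants
#'
#' Strengths are genome-wide weighted-level reductions in percentage points
#' per context; the strongest epimutant loses about 11 CG points, in the
#' regime observed for strongly hypomethylated 5-Aza lines.
#'
#' @return data.frame with name, role, CG, CHG, CHH
#' @export
default_samples <- function() {
  data.table::data.table(
    name = c("CTRL-1", "CTRL-2", "EPI-A", "EPI-B", "EPI-C", "EPI-D"),
    role = c("control", "control", rep("epimutant", 4L)),
    CG = c(0, 0, 4, 11, 3, 5),
    CHG = c(0, 0, 2, 6, 2, 3),
    CHH = c(0, 0, 1, 3, 1, 2))
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a haplotype-resolved genome pair
#'
#' hap1 is random DNA with telomeric TTTAGGG arrays at both chromosome
#' ends, annotated with non-overlapping genes (1-3 exons) and TE intervals.
#' hap2 is derived from hap1 by SNPs, insertions and deletions (both below
#' and above the 50-bp SV cutoff), inversions and translocations; a
#' SyRI-style table (including SYN blocks and SNP rows) records the truth.
#' Genes, exons and TEs are lifted onto hap2 through the edit map.
#'
#' @param spec a [simulation_spec()]
#' @return list with hap1, hap2, lambda (sequences), genes_h1/h2,
#'   exons_h1/h2, tes_h1/h2, pairs, svs, hifi_reads, truth
#' @export
simulate_genomes <- function(spec) {
  set.seed(spec$seed)
  tel <- paste(rep("TTTAGGG", spec$telomere_copies), collapse = "")
  tel_rc <- reverse_complement(tel)
  tel_len <- nchar(tel)
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  hap1 <- stats::setNames(vapply(chroms, function(ch) {
    paste0(tel_rc, .rand_dna(spec$chrom_length), tel)
  }, character(1L)), chroms)
  lambda <- c(lambda = .rand_dna(spec$lambda_length))
  L <- nchar(hap1[[1L]])

  genes <- .place_genes(spec, chroms, L, tel_len)
  exons <- .make_exons(genes)
  tes <- .place_tes(spec, chroms, L, tel_len)
  ov <- overlap_pairs(genes, tes)
  genes[, "is_te_overlapping" := seq_len(nrow(genes)) %in% ov$qidx]

  edits <- .place_sv_edits(spec, genes, chroms, L, tel_len)
  hap2 <- character(0L)
  sv_rows <- list()
  maps <- list()
  for (ch in chroms) {
    seq1 <- hap1[[ch]]
    # SNPs first, on the unedited copy
    n <- nchar(seq1)
    snp_pos <- which(stats::runif(n) < spec$snp_rate)
    b <- strsplit(seq1, "", fixed = TRUE)[[1L]]
    if (length(snp_pos)) {
      b[snp_pos] <- vapply(b[snp_pos], function(x) {
        sample(setdiff(c("A", "C", "G", "T"), x), 1L)
      }, character(1L), USE.NAMES = FALSE)
    }
    seq1_snp <- paste(b, collapse = "")
    ed <- edits[edits$chrom == ch, ]
    res <- .apply_sv_edits(seq1_snp, ed)
    hap2[ch] <- res$seq
    maps[[ch]] <- res$pieces
    rows <- res$sv_records
    if (length(snp_pos)) {
      qpos <- .map_ref_to_qry(snp_pos - 1L, res$pieces)
      keep <- !is.na(qpos)
      rows <- data.table::rbindlist(list(rows, data.table::data.table(
        ref_start = snp_pos[keep] - 1L, ref_end = snp_pos[keep],
        qry_start = qpos[keep], qry_end = qpos[keep] + 1L,
        raw_type = "SNP", copy_status = ".")))
    }
    rows[, "ref_chrom" := ch]
    rows[, "qry_chrom" := ch]
    sv_rows[[ch]] <- rows
  }
  svs <- data.table::rbindlist(sv_rows)
  len <- pmax(svs$ref_end - svs$ref_start, svs$qry_end - svs$qry_start)
  len[svs$raw_type == "SNP"] <- 1L
  svs[, "length" := as.integer(len)]
  svs[, "grouped_category" := NA_character_]
  data.table::setorderv(svs, c("ref_chrom", "ref_start"))

  lift <- function(tab) {
    out <- data.table::copy(tab)
    for (ch in chroms) {
      sel <- which(out$chrom == ch)
      if (!length(sel)) next
      out$start[sel] <- .map_ref_to_qry(tab$start[sel], maps[[ch]])
      out$end[sel] <- .map_ref_to_qry(tab$end[sel] - 1L, maps[[ch]]) + 1L
    }
    out[!is.na(out$start) & !is.na(out$end) & out$end > out$start, ]
  }
  genes_h2 <- lift(genes)
  genes_h2[, "gene_id" := paste0(genes_h2$gene_id, "_h2")]
  exons_h2 <- lift(exons)
  exons_h2[, "gene_id" := paste0(exons_h2$gene_id, "_h2")]
  # a gene can be lost in the lift (e.g. its span swallowed by a deletion)
  # while some of its exons survive; drop such orphan exons
  exons_h2 <- exons_h2[exons_h2$gene_id %in% genes_h2$gene_id, ]
  tes_h2 <- lift(tes)
  pairs <- data.table::data.table(
    pair_id = paste0("pair_", seq_len(nrow(genes))),
    maternal_id = genes$gene_id,
    paternal_id = paste0(genes$gene_id, "_h2"))
  pairs <- pairs[pairs$paternal_id %in% genes_h2$gene_id, ]
  pairs[, "pair_id" := paste0("pair_", seq_len(nrow(pairs)))]

  hifi_reads <- .simulate_long_reads(chroms, L, coverage = 3,
                                     mean_len = 20000, sd_len = 5000)
  telomeres <- data.table::CJ(chrom = chroms, end = c("left", "right"))
  telomeres[, "telomeric" := TRUE]
  truth <- list(svs = svs, telomeres = telomeres)
  list(hap1 = hap1, hap2 = hap2, lambda = lambda,
       genes_h1 = genes[], exons_h1 = exons[], tes_h1 = tes[],
       genes_h2 = genes_h2[], exons_h2 = exons_h2[], tes_h2 = tes_h2[],
       pairs = pairs[], svs = svs[], hifi_reads = hifi_reads,
       truth = truth)
}

# Non-overlapping genes in equal slots per chromosome, margins away from
# telomeres.
.place_genes <- function(spec, chroms, L, tel_len) {
  per_chrom <- rep(spec$n_genes %/% spec$n_chroms, spec$n_chroms)
  per_chrom[seq_len(spec$n_genes %% spec$n_chroms)] <-
    per_chrom[seq_len(spec$n_genes %% spec$n_chroms)] + 1L
  res <- list()
  gi <- 0L
  for (k in seq_along(chroms)) {
    n <- per_chrom[k]
    lo <- tel_len + 3000L
    hi <- L - tel_len - 3000L
    slot <- (hi - lo) %/% n
    glen <- pmin(as.integer(stats::runif(n, 1200, 5200)), slot - 600L)
    off <- as.integer(stats::runif(n, 0, slot - glen - 1L))
    start <- lo + (seq_len(n) - 1L) * slot + off
    res[[k]] <- data.table::data.table(
      gene_id = paste0("g", sprintf("%04d", gi + seq_len(n))),
      chrom = chroms[k],
      strand = sample(c("+", "-"), n, replace = TRUE),
      start = start, end = start + glen)
    gi <- gi + n
  }
  data.table::rbindlist(res)
}

# 1-3 exons per gene, alternating exon/intron, exons first and last.
.make_exons <- function(genes) {
  res <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    n_ex <- sample(1:3, 1L)
    if (n_ex == 1L) {
      res[[i]] <- data.table::data.table(gene_id = g$gene_id,
                                         chrom = g$chrom,
                                         start = g$start, end = g$end)
      next
    }
    len <- g$end - g$start
    cuts <- sort(sample(seq(200L, len - 200L, by = 50L),
                        2L * (n_ex - 1L)))
    bounds <- c(0L, cuts, len) + g$start
    starts <- bounds[seq(1L, length(bounds) - 1L, by = 2L)]
    ends <- bounds[seq(2L, length(bounds), by = 2L)]
    res[[i]] <- data.table::data.table(gene_id = g$gene_id, chrom = g$chrom,
                                       start = starts, end = ends)
  }
  data.table::rbindlist(res)
}

.place_tes <- function(spec, chroms, L, tel_len) {
  target <- spec$te_fraction * spec$n_chroms * L
  mean_len <- 1750
  n <- max(1L, as.integer(round(target / mean_len)))
  chrom <- sample(chroms, n, replace = TRUE)
  len <- as.integer(stats::runif(n, 500, 3000))
  start <- vapply(seq_len(n), function(i) {
    as.integer(stats::runif(1L, tel_len, L - tel_len - len[i]))
  }, integer(1L))
  out <- data.table::data.table(
    te_id = paste0(sample(c("LTR", "LINE", "DNA"), n, replace = TRUE),
                   "_", seq_len(n)),
    chrom = chrom, start = start, end = start + len)
  out[, "te_class" := sub("_[0-9]+$", "", out$te_id)]
  data.table::setorderv(out, c("chrom", "start"))
  out[]
}

# Sample non-overlapping structural-edit loci. TRANS origins/destinations
# stay clear of gene space (+/- 2 kb) so gene boundaries map monotonically;
# INS/DEL/INV may hit genes, which is what SV-gene overlap analyses need.
.place_sv_edits <- function(spec, genes, chroms, L, tel_len) {
  counts <- spec$sv_counts
  types <- c(rep("INS", counts[["INS"]] %||% 0),
             rep("DEL", counts[["DEL"]] %||% 0),
             rep("INV", counts[["INV"]] %||% 0),
             rep("TRANS", counts[["TRANS"]] %||% 0),
             rep("short_INS", counts[["short_INS"]] %||% 0),
             rep("short_DEL", counts[["short_DEL"]] %||% 0))
  lens <- vapply(types, function(tp) {
    switch(tp,
           INS = as.integer(stats::runif(1L, 60, 2000)),
           DEL = as.integer(stats::runif(1L, 60, 2000)),
           INV = as.integer(stats::runif(1L, 500, 5000)),
           TRANS = as.integer(stats::runif(1L, 500, 5000)),
           short_INS = as.integer(stats::runif(1L, 5, 50)),
           short_DEL = as.integer(stats::runif(1L, 5, 50)))
  }, integer(1L))
  raw <- sub("short_", "", types)
  gene_space <- data.table::data.table(chrom = genes$chrom,
                                       start = genes$start - 2000L,
                                       end = genes$end + 2000L)
  blocked <- data.table::data.table(chrom = character(), start = integer(),
                                    end = integer())
  # half the INS/DEL/INV edits are steered into gene space
  res <- list()
  for (i in seq_along(types)) {
    tp <- raw[i]
    len <- lens[i]
    want_gene <- tp %in% c("INS", "DEL", "INV") && (i %% 2L == 0L)
    for (try in 1:300) {
      if (want_gene) {
        g <- genes[sample(nrow(genes), 1L), ]
        span <- max(1L, g$end + 1500L - (g$start - 1500L) - len)
        pos <- as.integer(g$start - 1500L + stats::runif(1L, 0, span))
        ch <- g$chrom
      } else {
        ch <- sample(chroms, 1L)
        pos <- as.integer(stats::runif(1L, tel_len + 1000L,
                                       L - tel_len - 1000L - len))
      }
      iv <- data.table::data.table(chrom = ch, start = pos - 500L,
                                   end = pos + len + 500L)
      if (nrow(overlap_pairs(iv, blocked)) > 0L) next
      if (tp == "TRANS" &&
          nrow(overlap_pairs(iv, gene_space)) > 0L) next
      dest <- NA_integer_
      if (tp == "TRANS") {
        okd <- FALSE
        for (try2 in 1:300) {
          dest <- as.integer(stats::runif(1L, tel_len + 1000L,
                                          L - tel_len - 1000L))
          di <- data.table::data.table(chrom = ch, start = dest - 500L,
                                       end = dest + 500L)
          if (nrow(overlap_pairs(di, blocked)) == 0L &&
              nrow(overlap_pairs(di, gene_space)) == 0L) {
            blocked <- rbind(blocked, di)
            okd <- TRUE
            break
          }
        }
        if (!okd) next
      }
      blocked <- rbind(blocked, iv)
      res[[length(res) + 1L]] <- data.table::data.table(
        chrom = ch, type = tp,
        ref_start = if (tp == "INS") pos else pos,
        ref_end = if (tp == "INS") pos else pos + len,
        len = len, dest = dest)
      break
    }
  }
  out <- data.table::rbindlist(res)
  data.table::setorderv(out, c("chrom", "ref_start"))
  out[]
}

# Apply sorted, non-overlapping edits to one chromosome. Returns the edited
# sequence, a piece map (ref interval <-> qry interval) and SV records in
# 0-based half-open internal coordinates.
.apply_sv_edits <- function(seq1, edits) {
  L <- nchar(seq1)
  pieces <- list()
  recs <- list()
  if (nrow(edits) == 0L) {
    pieces <- data.table::data.table(ref_start = 0L, ref_end = L,
                                     qry_start = 0L, qry_end = L,
                                     kind = "SYN")
    return(list(seq = seq1, pieces = pieces,
                sv_records = .empty_sv_table()[, 1:8]))
  }
  # pre-extract segment sequences
  seg_seq <- substring(seq1, edits$ref_start + 1L, edits$ref_end)
  ins_seq <- vapply(seq_len(nrow(edits)), function(i) {
    if (edits$type[i] == "INS") .rand_dna(edits$len[i]) else ""
  }, character(1L))
  # events: edits at ref_start, TRANS destinations at dest
  ev <- data.table::data.table(
    pos = c(edits$ref_start, edits$dest[edits$type == "TRANS"]),
    idx = c(seq_len(nrow(edits)), which(edits$type == "TRANS")),
    what = c(rep("edit", nrow(edits)),
             rep("dest", sum(edits$type == "TRANS"))))
  data.table::setorderv(ev, "pos")
  out_seq <- character(0L)
  cur <- 0L
  qry <- 0L
  emit <- function(s, ref_start, ref_end, kind) {
    n <- nchar(s)
    out_seq[[length(out_seq) + 1L]] <<- s
    pieces[[length(pieces) + 1L]] <<- data.table::data.table(
      ref_start = ref_start, ref_end = ref_end,
      qry_start = qry, qry_end = qry + n, kind = kind)
    qry <<- qry + n
  }
  for (j in seq_len(nrow(ev))) {
    p <- ev$pos[j]
    i <- ev$idx[j]
    if (p > cur) {
      emit(substring(seq1, cur + 1L, p), cur, p, "SYN")
      cur <- p
    }
    if (ev$what[j] == "dest") {
      q0 <- qry
      emit(seg_seq[i], NA_integer_, NA_integer_, "TRANS")
      recs[[length(recs) + 1L]] <- data.table::data.table(
        ref_start = edits$ref_start[i], ref_end = edits$ref_end[i],
        qry_start = q0, qry_end = qry, raw_type = "TRANS",
        copy_status = ".")
    } else {
      tp <- edits$type[i]
      if (tp == "INS") {
        q0 <- qry
        emit(ins_seq[i], NA_integer_, NA_integer_, "INS")
        recs[[length(recs) + 1L]] <- data.table::data.table(
          ref_start = p, ref_end = p, qry_start = q0, qry_end = qry,
          raw_type = "INS", copy_status = ".")
      } else if (tp == "DEL") {
        recs[[length(recs) + 1L]] <- data.table::data.table(
          ref_start = p, ref_end = edits$ref_end[i], qry_start = qry,
          qry_end = qry, raw_type = "DEL", copy_status = ".")
        cur <- edits$ref_end[i]
      } else if (tp == "INV") {
        q0 <- qry
        emit(reverse_complement(seg_seq[i]), p, edits$ref_end[i], "INV")
        recs[[length(recs) + 1L]] <- data.table::data.table(
          ref_start = p, ref_end = edits$ref_end[i], qry_start = q0,
          qry_end = qry, raw_type = "INV", copy_status = ".")
        cur <- edits$ref_end[i]
      } else if (tp == "TRANS") {
        cur <- edits$ref_end[i]  # origin removed; emitted at dest
      }
    }
  }
  if (cur < L) emit(substring(seq1, cur + 1L, L), cur, L, "SYN")
  pieces <- data.table::rbindlist(pieces)
  recs <- data.table::rbindlist(recs)
  # SYN rows for the syntenic blocks
  syn <- pieces[pieces$kind == "SYN" &
                  (pieces$ref_end - pieces$ref_start) >= 100L, ]
  syn_rows <- data.table::data.table(
    ref_start = syn$ref_start, ref_end = syn$ref_end,
    qry_start = syn$qry_start, qry_end = syn$qry_end,
    raw_type = "SYN", copy_status = ".")
  recs <- data.table::rbindlist(list(recs, syn_rows))
  list(seq = paste(out_seq, collapse = ""), pieces = pieces,
       sv_records = recs)
}

# Map 0-based ref positions to qry through the piece map; positions inside
# deleted or translocated-away material map to NA.
.map_ref_to_qry <- function(pos, pieces) {
  pc <- pieces[!is.na(pieces$ref_start), ]
  out <- rep(NA_integer_, length(pos))
  idx <- point_in_region(rep("x", length(pos)), pos,
                         data.table::data.table(chrom = "x",
                                                start = pc$ref_start,
                                                end = pc$ref_end))
  ok <- !is.na(idx)
  out[ok] <- pc$qry_start[idx[ok]] + (pos[ok] - pc$ref_start[idx[ok]])
  out
}

.simulate_long_reads <- function(chroms, L, coverage, mean_len, sd_len) {
  res <- lapply(chroms, function(ch) {
    n <- as.integer(round(coverage * L / mean_len))
    len <- pmax(1000L, as.integer(stats::rnorm(n, mean_len, sd_len)))
    start <- as.integer(stats::runif(n, 0, pmax(1, L - len)))
    data.table::data.table(chrom = ch, start = start,
                           end = pmin(start + len, L))
  })
  data.table::rbindlist(res)
}
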