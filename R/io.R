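# Readers and writers for the external formats the pipeline touches.
#
# On-disk conventions follow each format's native one: cytosine reports,
# SyRI tables and GFF3 are 1-based inclusive; BED is 0-based half-open.
# Everything is converted to 0-based half-open on the way in and back on the
# way out.

.valid_contexts <- c("CG", "CHG", "CHH")
.valid_sv_types <- c("SYN", "INV", "TRANS", "INVTR", "DUP", "INVDP",
                     "CPL", "CPG", "INS", "DEL", "SNP")

#' Read a Bismark-style cytosine report
#'
#' Seven tab-separated columns: chromosome, 1-based position, strand,
#' methylated read count, unmethylated read count, context (CG/CHG/CHH) and
#' trinucleotide. Sites with total depth below `min_depth` are flagged
#' `sub_threshold` but kept; dropping them is the caller's decision.
#'
#' @param path file path
#' @param min_depth minimum total depth for a callable site
#' @return a `data.table` with columns chrom, pos (0-based), strand, c_meth,
#'   c_total, context, trinucleotide, sub_threshold
#' @export
read_cytosine_report <- function(path, min_depth = 5L) {
  cols <- c("chrom", "pos1", "strand", "c_meth", "c_unmeth", "context",
            "trinucleotide")
  empty <- data.table::data.table(
    chrom = character(), pos = integer(), strand = character(),
    c_meth = integer(), c_total = integer(), context = character(),
    trinucleotide = character(), sub_threshold = logical())
  if (file.exists(path) && file.size(path) == 0) return(empty)
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = FALSE, sep = "\t", col.names = cols,
                        colClasses = list(character = c(1L, 3L, 6L, 7L),
                                          integer = c(2L, 4L, 5L)))),
    error = function(e) stop_hm("cannot parse cytosine report '%s': %s",
                                path, conditionMessage(e)))
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) != 7L) {
    stop_hm("cannot parse cytosine report '%s': expected 7 columns, found %d",
            path, ncol(dt))
  }
  bad <- which(is.na(dt$pos1) | is.na(dt$c_meth) | is.na(dt$c_unmeth) |
                 dt$c_meth < 0L | dt$c_unmeth < 0L | dt$pos1 < 1L |
                 !dt$strand %in% c("+", "-"))
  if (length(bad)) {
    stop_hm("malformed cytosine report row at line %d of '%s'", bad[1L], path)
  }
  badctx <- which(!dt$context %in% .valid_contexts)
  if (length(badctx)) {
    stop_hm("unknown context token '%s' at line %d of '%s'",
            dt$context[badctx[1L]], badctx[1L], path)
  }
  out <- data.table::data.table(
    chrom = dt$chrom, pos = dt$pos1 - 1L, strand = dt$strand,
    c_meth = dt$c_meth, c_total = dt$c_meth + dt$c_unmeth,
    context = dt$context, trinucleotide = dt$trinucleotide)
  out[, "sub_threshold" := out$c_total < as.integer(min_depth)]
  hm_log(sprintf("read_cytosine_report: %d sites from %s (%d sub-threshold at depth<%d)",
                 nrow(out), basename(path), sum(out$sub_threshold), min_depth),
         level = "debug")
  out[]
}

#' Write a cytosine report
#'
#' Inverse of [read_cytosine_report()]; positions are written 1-based.
#'
#' @param sites data.frame with chrom, pos, strand, c_meth, c_total, context,
#'   trinucleotide
#' @param path output file
#' @export
write_cytosine_report <- function(sites, path) {
  out <- data.table::data.table(
    chrom = sites$chrom, pos1 = as.integer(sites$pos) + 1L,
    strand = sites$strand, c_meth = as.integer(sites$c_meth),
    c_unmeth = as.integer(sites$c_total) - as.integer(sites$c_meth),
    context = sites$context, trinucleotide = sites$trinucleotide)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a SyRI-style structural variant table
#'
#' Tab-separated with header: ref_chrom, ref_start, ref_end, qry_chrom,
#' qry_start, qry_end, type, copy_status. Coordinates are 1-based inclusive
#' on disk. `type` must be one of SYN, INV, TRANS, INVTR, DUP, INVDP, CPL,
#' CPG, INS, DEL, SNP; `copy_status` is gain/loss for DUP/INVDP records and
#' "." otherwise. The grouped category (TRANS/INV/AV/PV/short) is left unset;
#' see [group_sv_records()].
#'
#' @param path file path
#' @return a `data.table` of SV records with 0-based half-open coordinates,
#'   a `length` column and `grouped_category = NA`
#' @export
read_syri_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = c(1L, 4L, 7L, 8L)))
  if (nrow(dt) == 0L) {
    return(.empty_sv_table())
  }
  bad <- which(!dt$type %in% .valid_sv_types)
  if (length(bad)) {
    stop_hm("unknown SV type code '%s' at row %d of '%s'",
            dt$type[bad[1L]], bad[1L], path)
  }
  out <- data.table::data.table(
    ref_chrom = dt$ref_chrom,
    ref_start = as.integer(dt$ref_start) - 1L,
    ref_end = as.integer(dt$ref_end),
    qry_chrom = dt$qry_chrom,
    qry_start = as.integer(dt$qry_start) - 1L,
    qry_end = as.integer(dt$qry_end),
    raw_type = dt$type,
    copy_status = dt$copy_status)
  # record length: span on whichever side carries the material
  len <- pmax(out$ref_end - out$ref_start, out$qry_end - out$qry_start)
  len[out$raw_type == "SNP"] <- 1L
  out[, "length" := as.integer(len)]
  out[, "grouped_category" := NA_character_]
  out[]
}

.empty_sv_table <- function() {
  data.table::data.table(
    ref_chrom = character(), ref_start = integer(), ref_end = integer(),
    qry_chrom = character(), qry_start = integer(), qry_end = integer(),
    raw_type = character(), copy_status = character(), length = integer(),
    grouped_category = character())
}

#' Write a SyRI-style structural variant table
#'
#' Inverse of [read_syri_table()] (the derived `length` and
#' `grouped_category` columns are not written).
#'
#' @param records SV record table with 0-based half-open coordinates
#' @param path output file
#' @export
write_syri_table <- function(records, path) {
  out <- data.table::data.table(
    ref_chrom = records$ref_chrom,
    ref_start = as.integer(records$ref_start) + 1L,
    ref_end = as.integer(records$ref_end),
    qry_chrom = records$qry_chrom,
    qry_start = as.integer(records$qry_start) + 1L,
    qry_end = as.integer(records$qry_end),
    type = records$raw_type,
    copy_status = records$copy_status)
  data.table::fwrite(out, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Write intervals as BED
#'
#' 0-based half-open, sorted by (chrom, start); the score column carries the
#' methylation level scaled by 1000 and rounded (BED convention of a 0-1000
#' score). Intervals lacking a level get score 0.
#'
#' @param intervals data.frame with chrom, start, end and optionally `level`
#'   (fraction) or `diff` (percentage points, converted via |diff|/100)
#' @param path output file
#' @export
write_bed <- function(intervals, path) {
  n <- nrow(intervals)
  if (n == 0L) {
    file.create(path)
    return(invisible(path))
  }
  lev <- if (!is.null(intervals$level)) {
    intervals$level
  } else if (!is.null(intervals$diff)) {
    abs(intervals$diff) / 100
  } else rep(0, n)
  lev[is.na(lev)] <- 0
  out <- data.table::data.table(
    chrom = intervals$chrom, start = as.integer(intervals$start),
    end = as.integer(intervals$end), name = ".",
    score = as.integer(round(lev * 1000)))
  data.table::setorderv(out, c("chrom", "start", "end"))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#'
#' @param path file path
#' @return data.table with chrom, start, end, name, score and `level`
#'   (score/1000)
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), name = character(),
                                  score = integer(), level = numeric()))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "name",
                                        "score"))
  dt[, "level" := dt$score / 1000]
  dt[]
}

#' Read genome FASTA
#'
#' @param path FASTA file
#' @return named character vector of uppercase sequences
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write genome FASTA
#'
#' @param seqs named character vector of sequences
#' @param path output file
#' @export
write_genome_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read gene/TE models from GFF3
#'
#' Recognizes `gene` features (with `exon` children linked by `Parent`) and
#' TE features (`transposable_element` / `repeat_region`). Coordinates are
#' converted to 0-based half-open.
#'
#' @param path GFF3 file
#' @return list with `genes` (data.table: gene_id, chrom, strand, start, end,
#'   is_te_overlapping), `exons` (gene_id, chrom, start, end) and `tes`
#'   (te_id, chrom, start, end, te_class)
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  dt <- data.table::data.table(
    chrom = as.character(df$seqnames),
    start = as.integer(df$start) - 1L,
    end = as.integer(df$end),
    strand = as.character(df$strand),
    type = as.character(df$type),
    id = if (!is.null(df$ID)) as.character(df$ID) else NA_character_,
    parent = if (!is.null(df$Parent)) {
      vapply(df$Parent, function(p) if (length(p)) as.character(p[1L]) else NA_character_,
             character(1L))
    } else NA_character_)
  genes <- dt[dt$type == "gene",
              c("id", "chrom", "strand", "start", "end"), with = FALSE]
  data.table::setnames(genes, "id", "gene_id")
  exons <- dt[dt$type == "exon", c("parent", "chrom", "start", "end"),
              with = FALSE]
  data.table::setnames(exons, "parent", "gene_id")
  data.table::setorderv(exons, c("gene_id", "start"))
  tes <- dt[dt$type %in% c("transposable_element", "repeat_region"),
            c("id", "chrom", "start", "end"), with = FALSE]
  data.table::setnames(tes, "id", "te_id")
  tes[, "te_class" := sub("_[0-9]+$", "", tes$te_id)]
  if (nrow(genes)) {
    ov <- overlap_pairs(genes, tes)
    genes[, "is_te_overlapping" := seq_len(nrow(genes)) %in% ov$qidx]
  } else {
    genes[, "is_te_overlapping" := logical(0)]
  }
  list(genes = genes[], exons = exons[], tes = tes[])
}

#' Write gene/TE models to GFF3
#'
#' @param genes gene table (gene_id, chrom, strand, start, end)
#' @param exons exon table (gene_id, chrom, start, end); defaults to one exon
#'   spanning each gene
#' @param tes TE interval table (te_id, chrom, start, end), optional
#' @param path output file
#' @export
write_gff3 <- function(genes, exons = NULL, tes = NULL, path) {
  mk <- function(chrom, start, end, strand, type, attr) {
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(as.integer(start) + 1L,
                                            as.integer(end)),
                           strand = strand, type = type, ID = attr$ID,
                           Parent = attr$Parent)
  }
  if (is.null(exons)) {
    exons <- data.table::data.table(gene_id = genes$gene_id,
                                    chrom = genes$chrom,
                                    start = genes$start, end = genes$end)
  }
  g <- mk(genes$chrom, genes$start, genes$end, genes$strand, "gene",
          list(ID = genes$gene_id, Parent = NA_character_))
  ex_strand <- genes$strand[match(exons$gene_id, genes$gene_id)]
  e <- mk(exons$chrom, exons$start, exons$end, ex_strand, "exon",
          list(ID = paste0(exons$gene_id, ".e",
                           seq_len(nrow(exons))),
               Parent = exons$gene_id))
  grl <- c(g, e)
  if (!is.null(tes) && nrow(tes)) {
    t <- mk(tes$chrom, tes$start, tes$end, "*", "transposable_element",
            list(ID = tes$te_id, Parent = NA_character_))
    grl <- c(grl, t)
  }
  rtracklayer::export(sort(grl), path, format = "gff3")
  invisible(path)
}

#' Read an allele-pair table
#'
#' Two tab-separated columns with header: `maternal_id`, `paternal_id`.
#'
#' @param path file path
#' @return data.table with pair_id, maternal_id, paternal_id
#' @export
read_allele_pairs <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("maternal_id", "paternal_id") %in% names(dt))) {
    stop_hm("allele-pair table needs columns maternal_id, paternal_id")
  }
  out <- data.table::data.table(pair_id = paste0("pair_", seq_len(nrow(dt))),
                                maternal_id = dt$maternal_id,
                                paternal_id = dt$paternal_id)
  out[]
}

#' Write an allele-pair table
#' @param pairs data.frame with maternal_id, paternal_id
#' @param path output file
#' @export
write_allele_pairs <- function(pairs, path) {
  data.table::fwrite(pairs[, c("maternal_id", "paternal_id")], path,
                     sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Read a count matrix (genes x samples)
#'
#' Tab-separated with header; first column `gene_id`, remaining columns one
#' per sample library.
#'
#' @param path file path
#' @return numeric matrix with gene ids as rownames
#' @export
read_count_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1L, with = FALSE])
  rownames(m) <- as.character(dt[[1L]])
  storage.mode(m) <- "numeric"
  m
}

#' Write a count matrix
#' @param m numeric matrix with rownames
#' @param path output file
#' @export
write_count_matrix <- function(m, path) {
  dt <- data.table::data.table(gene_id = rownames(m))
  for (j in colnames(m)) dt[, (j) := m[, j]]
  data.table::fwrite(dt, path, sep = "\t", col.names = TRUE)
  invisible(path)
}

#' Write a generic TSV with header
#' @param dt data.frame
#' @param path output file
#' @export
write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", col.names = TRUE)
  invisible(path)
}
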