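#' @title Track input/output
#' @description Readers and writers for the four plain-text input
#'   formats (CGI track as BED4+4, per-CpG methylation as a
#'   bedGraph-like TSV, gene models as BED12, expression as TSV) plus
#'   result tables. All genomic coordinates are 0-based half-open
#'   internally and on disk; methylation is the fraction in `[0,1]`.
#' @name tracks_io
NULL

stop_line <- function(path, i, msg) {
  stop(sprintf("%s: line %d: %s", path, i, msg), call. = FALSE)
}

read_tsv_raw <- function(path, n_cols, what) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "",
                      quote = ""),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(NULL)
      stop(sprintf("%s: parse error: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  if (!is.null(df) && ncol(df) != n_cols)
    stop(sprintf("%s: expected %d %s columns, found %d", path, n_cols,
                 what, ncol(df)), call. = FALSE)
  df
}

#' Write / read a CGI track (BED4+4)
#'
#' Columns: chrom, start, end, name, length, cpgNum, gcFraction, obsExp;
#' tab-separated, no header, 0-based half-open.
#'
#' @param track data.frame as returned by [generate_cgi_track()].
#' @param path file path.
#' @return `read_cgi_track` returns the validated track sorted by
#'   chromosome and start.
#' @export
write_cgi_track <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "island_id",
                               "length", "cpg_count", "gc_fraction",
                               "obs_exp")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_cgi_track
#' @export
read_cgi_track <- function(path) {
  df <- read_tsv_raw(path, 8, "BED4+4")
  if (is.null(df))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), island_id = character(0),
                      length = integer(0), cpg_count = integer(0),
                      gc_fraction = numeric(0), obs_exp = numeric(0),
                      stringsAsFactors = FALSE))
  names(df) <- c("chrom", "start", "end", "island_id", "length",
                 "cpg_count", "gc_fraction", "obs_exp")
  for (i in seq_len(nrow(df))) {
    if (df$end[i] <= df$start[i])
      stop_line(path, i, "end must exceed start")
    if (df$length[i] != df$end[i] - df$start[i])
      stop_line(path, i, "length must equal end - start")
    if (df$cpg_count[i] < 1)
      stop_line(path, i, "cpg_count must be >= 1")
    if (df$gc_fraction[i] < 0 || df$gc_fraction[i] > 1)
      stop_line(path, i, "gc_fraction must be in [0,1]")
  }
  ord <- order(df$chrom, df$start)
  if (is.unsorted(ord)) warning(path, ": input unsorted; sorted on load")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write / read per-CpG methylation calls (bedGraph-like TSV)
#'
#' Columns: chrom, pos, pos+2, methylated_reads, coverage. Positions are
#' the 0-based coordinate of the CpG cytosine on the + strand; records
#' are assumed strand-collapsed per CpG.
#'
#' @param calls data.frame with `chrom, pos, coverage, methylated_reads`
#'   (one cell line / replica).
#' @param path file path.
#' @param cell_line,replica_id identifiers attached to the records on
#'   read (`replica_id` must be 1 or 2).
#' @return `read_methylation` returns a validated, position-sorted
#'   data.frame with columns `chrom, pos, coverage, methylated_reads,
#'   replica_id, cell_line`.
#' @export
write_methylation <- function(calls, path) {
  utils::write.table(
    data.frame(calls$chrom, calls$pos, calls$pos + 2L,
               calls$methylated_reads, calls$coverage),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_methylation
#' @export
read_methylation <- function(path, cell_line, replica_id) {
  stopifnot(replica_id %in% 1:2)
  df <- read_tsv_raw(path, 5, "methylation")
  if (is.null(df))
    return(data.frame(chrom = character(0), pos = integer(0),
                      coverage = integer(0), methylated_reads = integer(0),
                      replica_id = integer(0), cell_line = character(0),
                      stringsAsFactors = FALSE))
  names(df) <- c("chrom", "pos", "end", "methylated_reads", "coverage")
  for (i in seq_len(nrow(df))) {
    if (df$coverage[i] < 0)
      stop_line(path, i, "coverage must be >= 0")
    if (df$methylated_reads[i] < 0 || df$methylated_reads[i] > df$coverage[i])
      stop_line(path, i, "methylated_reads must lie in [0, coverage]")
  }
  ord <- order(df$chrom, df$pos)
  if (is.unsorted(ord)) warning(path, ": input unsorted; sorted on load")
  df <- df[ord, , drop = FALSE]
  data.frame(chrom = df$chrom, pos = df$pos, coverage = df$coverage,
             methylated_reads = df$methylated_reads,
             replica_id = as.integer(replica_id),
             cell_line = cell_line, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write / read gene models (BED12)
#'
#' Standard BED12 with thickStart/thickEnd holding the coding span and
#' blocks holding exons. The translational start is thickStart for `+`
#' genes and thickEnd for `-` genes.
#'
#' @param genes data.frame as returned by [generate_gene_models()].
#' @param path file path.
#' @return `read_gene_models` returns the validated gene-model
#'   data.frame (same columns as [generate_gene_models()]).
#' @export
write_gene_models <- function(genes, path) {
  starts <- strsplit(genes$exon_starts, ",")
  ends <- strsplit(genes$exon_ends, ",")
  n_ex <- lengths(starts)
  sizes <- mapply(function(s, e)
    paste(as.integer(e) - as.integer(s), collapse = ","), starts, ends)
  rel <- mapply(function(s, tx)
    paste(as.integer(s) - tx, collapse = ","), starts, genes$tx_start)
  utils::write.table(
    data.frame(genes$chrom, genes$tx_start, genes$tx_end, genes$gene_id,
               0L, genes$strand, genes$cds_start, genes$cds_end, 0L,
               n_ex, sizes, rel),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_raw(path, 12, "BED12")
  if (is.null(df))
    return(generate_gene_models(sim_config(n_genes = 0)))
  names(df) <- c("chrom", "tx_start", "tx_end", "gene_id", "score",
                 "strand", "cds_start", "cds_end", "rgb", "n_exons",
                 "sizes", "rel_starts")
  out <- df[, c("gene_id", "chrom", "strand", "tx_start", "tx_end",
                "cds_start", "cds_end")]
  out$exon_starts <- ""
  out$exon_ends <- ""
  for (i in seq_len(nrow(df))) {
    sizes <- as.integer(strsplit(as.character(df$sizes[i]), ",")[[1]])
    rel <- as.integer(strsplit(as.character(df$rel_starts[i]), ",")[[1]])
    if (length(sizes) != df$n_exons[i] || length(rel) != df$n_exons[i])
      stop_line(path, i, "block count mismatch")
    s <- df$tx_start[i] + rel
    e <- s + sizes
    if (is.unsorted(s, strictly = TRUE) || any(e[-length(e)] > s[-1]))
      stop_line(path, i, "exons must be sorted and non-overlapping")
    if (s[1] < df$tx_start[i] || e[length(e)] > df$tx_end[i])
      stop_line(path, i, "exons must lie within the transcript")
    if (df$cds_start[i] < df$tx_start[i] || df$cds_end[i] > df$tx_end[i] ||
        df$cds_start[i] >= df$cds_end[i])
      stop_line(path, i, "coding span must lie within the transcript")
    out$exon_starts[i] <- paste(s, collapse = ",")
    out$exon_ends[i] <- paste(e, collapse = ",")
  }
  rownames(out) <- NULL
  out
}

#' Write / read a two-replica expression table
#'
#' TSV with header `gene_id, expr1, expr2`; expression values must be
#' non-negative.
#'
#' @param expr data.frame `gene_id, expr1, expr2`.
#' @param path file path.
#' @return `read_expression` returns the validated table.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "expr1", "expr2") %in% names(df)))
    stop(path, ": expected header gene_id, expr1, expr2", call. = FALSE)
  bad <- which(df$expr1 < 0 | df$expr2 < 0)
  if (length(bad) > 0)
    stop_line(path, bad[1] + 1L, "expression values must be >= 0")
  df
}

#' Write a ground-truth table
#'
#' One row per (cell line, planted island id); TSV with header.
#'
#' @param ground_truth as returned by [generate_replica_reads()].
#' @param path file path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  rows <- do.call(rbind, lapply(names(ground_truth$planted), function(cl)
    if (length(ground_truth$planted[[cl]]) == 0) NULL else
      data.frame(cell_line = cl, island_id = ground_truth$planted[[cl]],
                 stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
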