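#' Construct a per-gene feature table
#'
#' The central data container: a numeric matrix of genes x named features
#' for one species, with a provenance tag per feature.
#'
#' @param values numeric matrix with gene ids as rownames and feature names
#'   as colnames; no duplicates in either.
#' @param species species tag.
#' @param provenance named character vector mapping feature name to a source
#'   tag; defaults to `"unknown"` for all features.
#' @return an object of class `"feature_table"` with elements `species`,
#'   `gene_ids`, `feature_names`, `values`, `provenance`.
#' @export
feature_table <- function(values, species = "?", provenance = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("feature table matrix needs gene ids as rownames and feature names as colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids in feature table")
  if (anyDuplicated(colnames(values))) stop("duplicate feature names in feature table")
  storage.mode(values) <- "double"
  if (is.null(provenance))
    provenance <- setNames(rep("unknown", ncol(values)), colnames(values))
  structure(list(species = species, gene_ids = rownames(values),
                 feature_names = colnames(values), values = values,
                 provenance = provenance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: species %s, %d genes x %d features\n",
              x$species, length(x$gene_ids), length(x$feature_names)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
as.matrix.feature_table <- function(x, ...) x$values

#' Read / write a feature table as TSV
#'
#' Tab-separated with a header row; first column `gene_id`, remaining
#' columns numeric features. The round trip `write` then `read` restores an
#' identical table.
#'
#' @param path file path.
#' @param species species tag attached to the result.
#' @return [read_feature_table()] returns a `feature_table`.
#' @export
read_feature_table <- function(path, species = "?") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(sprintf("%s: expected gene_id plus at least one feature column", path))
  if (anyDuplicated(df[[1]]))
    stop(sprintf("%s: duplicate gene id '%s'", path, df[[1]][duplicated(df[[1]])][1]))
  feats <- df[, -1, drop = FALSE]
  # a column that is entirely NA parses as logical; keep it numeric so the
  # imputation step can report it properly
  feats[] <- lapply(feats, function(col)
    if (is.logical(col) && all(is.na(col))) as.numeric(col) else col)
  m <- as.matrix(feats)
  if (!is.numeric(m)) stop(sprintf("%s: non-numeric feature values", path))
  rownames(m) <- df[[1]]
  impute_missing(feature_table(m, species = species))
}

#' Impute missing feature values by the within-species feature median
#'
#' Genes missing from one data source leave `NA` cells in a merged feature
#' table; each is replaced by the median of its feature column within the
#' species. The imputation is recorded per feature in the table's
#' `imputation_log` attribute (data.frame of feature, n_imputed, median
#' used). A feature that is entirely missing is an error.
#'
#' @param table a `feature_table` possibly containing `NA`s.
#' @return the table with all values finite and an `imputation_log`
#'   attribute.
#' @export
impute_missing <- function(table) {
  m <- table$values
  na_cols <- which(colSums(is.na(m)) > 0)
  log <- data.frame(feature = character(0), n_imputed = integer(0),
                    imputed_value = numeric(0), stringsAsFactors = FALSE)
  for (j in na_cols) {
    med <- median(m[, j], na.rm = TRUE)
    if (is.na(med))
      stop(sprintf("feature '%s' has no observed values to impute from",
                   colnames(m)[j]))
    n_na <- sum(is.na(m[, j]))
    m[is.na(m[, j]), j] <- med
    log <- rbind(log, data.frame(feature = colnames(m)[j], n_imputed = n_na,
                                 imputed_value = med))
  }
  out <- feature_table(m, species = table$species, provenance = table$provenance)
  attr(out, "imputation_log") <- log
  out
}

#' @rdname read_feature_table
#' @param table a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(gene_id = table$gene_ids, table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}

#' Read gene/exon annotations from GFF3
#'
#' Coordinates are kept in GFF3's native 1-based inclusive convention,
#' which is also the package's internal canonical convention. Gene
#' identifiers come from the `ID` attribute of `gene` records (overridable);
#' exons are attached to genes through their `Parent` attribute.
#'
#' @param path GFF3 file.
#' @param id_attribute attribute naming the stable gene identifier.
#' @return list with `genes` (data.frame `gene_id`, `chrom`, `start`,
#'   `end`, `strand`) and `exons` (data.frame `gene_id`, `start`, `end`).
#' @export
read_gff3 <- function(path, id_attribute = "ID") {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  if (any(md$start < 1)) stop(sprintf("%s: negative or zero coordinate", path))
  is_gene <- md$type == "gene"
  ids <- as.character(md[[id_attribute]][is_gene])
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicate gene id '%s'", path, ids[duplicated(ids)][1]))
  genes <- data.frame(gene_id = ids,
                      chrom = as.character(md$seqnames[is_gene]),
                      start = md$start[is_gene], end = md$end[is_gene],
                      strand = as.character(md$strand[is_gene]),
                      stringsAsFactors = FALSE)
  is_exon <- md$type == "exon"
  parent <- vapply(md$Parent[is_exon], function(p) as.character(p)[1], character(1))
  exons <- data.frame(gene_id = parent, start = md$start[is_exon],
                      end = md$end[is_exon], stringsAsFactors = FALSE)
  bad <- exons$start > exons$end
  if (any(bad)) stop(sprintf("%s: degenerate exon interval for gene %s", path, exons$gene_id[bad][1]))
  list(genes = genes, exons = exons)
}

write_gff3 <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$exons
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  gl <- sprintf("%s\tcrossess\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                g$chrom, as.integer(g$start), as.integer(g$end), g$strand, g$gene_id)
  chrom_of <- setNames(g$chrom, g$gene_id)
  strand_of <- setNames(g$strand, g$gene_id)
  el <- sprintf("%s\tcrossess\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                chrom_of[e$gene_id], as.integer(e$start), as.integer(e$end),
                strand_of[e$gene_id], e$gene_id,
                stats::ave(seq_len(nrow(e)), e$gene_id, FUN = seq_along), e$gene_id)
  # interleave genes before their exons by sorting on gene id then type
  writeLines(c(gl, el)[order(c(g$gene_id, e$gene_id), c(rep(0L, nrow(g)), rep(1L, nrow(e))))], con)
  invisible(path)
}

#' Read intervals from BED
#'
#' BED is 0-based half-open on disk; intervals are returned in that
#' convention (columns `chrom`, `start`, `end`, plus `name`/`score` when
#' present). Use [bed_to_1based()] to convert to the internal 1-based
#' inclusive convention.
#'
#' @param path BED file (3+ columns, no header).
#' @return data.frame of intervals, BED convention.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop(sprintf("%s: BED needs at least 3 columns", path))
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  if (!is.numeric(df$start) || !is.numeric(df$end))
    stop(sprintf("%s: non-numeric BED coordinates", path))
  if (any(df$start < 0)) {
    i <- which(df$start < 0)[1]
    stop(sprintf("%s: negative coordinate on line %d", path, i))
  }
  if (any(df$start >= df$end)) {
    i <- which(df$start >= df$end)[1]
    stop(sprintf("%s: empty interval on line %d", path, i))
  }
  df
}

#' Convert between BED (0-based half-open) and 1-based inclusive intervals
#'
#' `bed_to_1based` shifts starts by +1; `to_bed` is its inverse.
#'
#' @param intervals data.frame with `start`, `end`.
#' @return data.frame in the other convention.
#' @export
bed_to_1based <- function(intervals) {
  intervals$start <- intervals$start + 1
  intervals
}

#' @rdname bed_to_1based
#' @export
to_bed <- function(intervals) {
  intervals$start <- intervals$start - 1
  intervals
}

#' Read an undirected edge list (two-column TSV)
#'
#' @param path TSV with two columns of node ids (no header).
#' @return an undirected [igraph::graph] with self-loops and duplicate edges
#'   removed.
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(sprintf("%s: edge list needs two columns", path))
  igraph::simplify(igraph::graph_from_data_frame(df[, 1:2], directed = FALSE))
}

BLAST_TAB_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                    "gapopen", "qstart", "qend", "sstart", "send",
                    "evalue", "bitscore")

#' Read BLAST tabular output (outfmt 6, 12 columns)
#'
#' @param path tabular BLAST file.
#' @return data.frame with the standard 12 columns.
#' @export
read_blast_tab <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != length(BLAST_TAB_COLS))
    stop(sprintf("%s: expected %d tab-separated columns, found %d",
                 path, length(BLAST_TAB_COLS), ncol(df)))
  names(df) <- BLAST_TAB_COLS
  df
}

#' Read ortholog groups from a two-column group/gene TSV
#'
#' @param path TSV with columns group id, gene id (no header).
#' @return named list mapping group id to a character vector of gene ids.
#' @export
read_two_column_groups <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(sprintf("%s: expected two columns (group, gene)", path))
  split(as.character(df[[2]]), as.character(df[[1]]))
}
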