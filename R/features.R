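#' GC content of a DNA sequence
#'
#' Fraction (G+C)/(A+C+G+T); `N` bases are excluded from both numerator and
#' denominator.
#'
#' @param dna_sequence character scalar over `A,C,G,T,N` (case-insensitive).
#' @return fraction in `[0,1]`.
#' @export
gc_content <- function(dna_sequence) {
  if (!is.character(dna_sequence) || length(dna_sequence) != 1 || !nzchar(dna_sequence))
    stop("gc_content needs a single non-empty sequence")
  b <- strsplit(toupper(dna_sequence), "")[[1]]
  bad <- setdiff(unique(b), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop(sprintf("unexpected base(s): %s", paste(bad, collapse = ",")))
  n_acgt <- sum(b %in% c("A", "C", "G", "T"))
  if (n_acgt == 0) stop("GC content undefined: no unambiguous bases")
  sum(b %in% c("G", "C")) / n_acgt
}

#' Amino-acid composition of a protein sequence
#'
#' Fractions of each of the 20 canonical residues, named `AAC_A` ...
#' `AAC_Y`; non-canonical characters are ignored (with a message) and the
#' fractions sum to 1 over counted residues.
#'
#' @param protein_sequence character scalar.
#' @return named numeric vector of length 20 summing to 1.
#' @export
aa_composition <- function(protein_sequence) {
  if (!is.character(protein_sequence) || length(protein_sequence) != 1 ||
      !nzchar(protein_sequence))
    stop("aa_composition needs a single non-empty sequence")
  aa <- strsplit(toupper(protein_sequence), "")[[1]]
  keep <- aa %in% AA_STANDARD20
  if (!all(keep))
    message(sprintf("aa_composition: ignoring %d non-canonical residue(s)", sum(!keep)))
  aa <- aa[keep]
  if (!length(aa)) stop("no canonical residues in sequence")
  counts <- table(factor(aa, levels = AA_STANDARD20))
  setNames(as.numeric(counts) / length(aa), paste0("AAC_", AA_STANDARD20))
}

#' Kyte-Doolittle hydropathy scale (per residue)
#' @keywords internal
KYTE_DOOLITTLE <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                    H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                    P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
                    W = -0.9, Y = -1.3)

#' Normalized Moreau-Broto autocorrelation of a protein sequence
#'
#' `AC(d) = (1/(L-d)) * sum_i P(s_i) P(s_(i+d))` where `P` is a per-residue
#' physicochemical property scale standardized to mean 0 / sd 1 over the 20
#' canonical residues. Defaults to Kyte-Doolittle hydropathy at lags 1-3.
#'
#' @param protein_sequence character scalar; must be longer than `max_lag`.
#' @param property_scale named numeric vector over the 20 residues.
#' @param max_lag largest lag; values for lags `1..max_lag` are returned.
#' @return named numeric vector `AC_1 ... AC_<max_lag>`.
#' @export
autocorrelation <- function(protein_sequence, property_scale = KYTE_DOOLITTLE,
                            max_lag = 3) {
  if (max_lag < 1) stop("max_lag must be >= 1")
  aa <- strsplit(toupper(protein_sequence), "")[[1]]
  aa <- aa[aa %in% names(property_scale)]
  L <- length(aa)
  if (L <= max_lag) stop("sequence shorter than max_lag + 1")
  p <- (property_scale - mean(property_scale)) / sd(property_scale)
  v <- unname(p[aa])
  ac <- vapply(seq_len(max_lag), function(d)
    sum(v[seq_len(L - d)] * v[seq_len(L - d) + d]) / (L - d), numeric(1))
  setNames(ac, paste0("AC_", seq_len(max_lag)))
}

#' Exon count and total exonic length per gene
#'
#' @param annotation a list with `genes` and `exons` data.frames as
#'   returned by [read_gff3()]; coordinates 1-based inclusive.
#' @return data.frame with `gene_id`, `exons`, `exons_total_length`
#'   (bp; `sum(end - start + 1)`), one row per annotated gene (genes
#'   without exons get zeros).
#' @export
exon_features <- function(annotation) {
  g <- annotation$genes
  e <- annotation$exons
  out <- data.frame(gene_id = g$gene_id, exons = 0L, exons_total_length = 0,
                    stringsAsFactors = FALSE)
  if (nrow(e)) {
    cnt <- table(e$gene_id)
    len <- tapply(e$end - e$start + 1, e$gene_id, sum)
    i <- match(names(cnt), out$gene_id)
    out$exons[i] <- as.integer(cnt)
    out$exons_total_length[i] <- as.numeric(len[names(cnt)])
  }
  out
}

#' Relative distance of each gene from its chromosome centre
#'
#' `|midpoint - L/2| / (L/2)` with midpoint `(start + end)/2`; 0 at the
#' centre, ~1 at either end.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @return named numeric vector of fractions in `[0,1]`.
#' @export
distance_from_centre <- function(genes, chrom_lengths) {
  L <- chrom_lengths[genes$chrom]
  if (any(is.na(L))) stop("chromosome length missing for some genes")
  if (any(L <= 0)) stop("chromosome lengths must be positive")
  mid <- (genes$start + genes$end) / 2
  setNames(abs(mid - L / 2) / (L / 2), genes$gene_id)
}

#' Count peaks overlapping each gene span
#'
#' Counts intervals with at least 1 bp overlap with the full gene span
#' `[start, end]`, strand-blind. Peaks are supplied in BED convention
#' (0-based half-open) and converted internally.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param peaks data.frame with `chrom`, `start`, `end` in BED convention,
#'   e.g. from [read_bed()].
#' @return named integer vector of per-gene counts (0 for genes on
#'   chromosomes without peaks).
#' @export
count_peak_overlaps <- function(genes, peaks) {
  if (!nrow(peaks))
    return(setNames(integer(nrow(genes)), genes$gene_id))
  g <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start, genes$end))
  p1 <- bed_to_1based(peaks)
  p <- GenomicRanges::GRanges(p1$chrom, IRanges::IRanges(p1$start, p1$end))
  setNames(GenomicRanges::countOverlaps(g, p, ignore.strand = TRUE), genes$gene_id)
}

#' Degree, betweenness and closeness centrality per node
#'
#' Degree is the neighbour count after dropping self-loops and duplicate
#' edges; betweenness is Brandes' unnormalized accumulation over unordered
#' pairs; closeness is `(n_reachable - 1) / sum(distances)` within the
#' node's connected component, 0 for isolates.
#'
#' @param graph an undirected [igraph::graph].
#' @return data.frame with `node`, `degree`, `betweenness`, `closeness`.
#' @export
graph_centralities <- function(graph) {
  g <- igraph::simplify(igraph::as_undirected(graph))
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  d <- igraph::distances(g, weights = NA)
  clo <- apply(d, 1, function(row) {
    reach <- row[is.finite(row)]          # includes the node itself (0)
    if (length(reach) <= 1) return(0)
    (length(reach) - 1) / sum(reach)
  })
  data.frame(node = nodes, degree = as.numeric(deg), betweenness = as.numeric(btw),
             closeness = as.numeric(clo), row.names = NULL, stringsAsFactors = FALSE)
}

#' Ortholog-group size per gene
#'
#' Size of the ortholog group containing each gene; 0 for ungrouped genes.
#' A gene listed in several groups gets the size of its largest group (a
#' message reports how many genes this affected).
#'
#' @param groups named list mapping group id to gene ids, e.g. from
#'   [read_two_column_groups()].
#' @param gene_ids genes to report.
#' @return named integer vector.
#' @export
ortholog_group_sizes <- function(groups, gene_ids) {
  if (!length(groups)) return(setNames(integer(length(gene_ids)), gene_ids))
  long <- data.frame(gene = unlist(groups, use.names = FALSE),
                     size = rep(lengths(groups), lengths(groups)))
  best <- tapply(long$size, long$gene, max)
  multi <- sum(table(long$gene)[unique(long$gene)] > 1)
  if (multi > 0)
    message(sprintf("ortholog_group_sizes: %d gene(s) in multiple groups; using max size", multi))
  out <- setNames(integer(length(gene_ids)), gene_ids)
  hit <- intersect(gene_ids, names(best))
  out[hit] <- as.integer(best[hit])
  out
}

#' Count significant EST BLAST hits per gene
#'
#' ESTs are queries and genes subjects; a hit counts when
#' `evalue <= evalue_cutoff` (the boundary value is included).
#'
#' @param hits data.frame from [read_blast_tab()].
#' @param gene_ids genes to report (subject ids).
#' @param evalue_cutoff significance cutoff.
#' @return named integer vector of counts (0 for genes without hits).
#' @export
est_hit_counts <- function(hits, gene_ids, evalue_cutoff = 1e-10) {
  out <- setNames(integer(length(gene_ids)), gene_ids)
  if (!nrow(hits)) return(out)
  sig <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  cnt <- table(sig$sseqid)
  hit <- intersect(gene_ids, names(cnt))
  out[hit] <- as.integer(cnt[hit])
  out
}

#' Compute sequence/annotation-derived features and merge with passthrough
#' columns
#'
#' Derives the recomputable feature block for one species — amino-acid
#' composition (20 columns), hydropathy autocorrelation at lags 1-3, exon
#' count and total exonic length, and relative distance from the chromosome
#' centre — and binds it to an existing (passthrough) feature table.
#' Optional inputs add ChIP peak-overlap counts, PPI centralities, ortholog
#' group sizes and EST hit counts.
#'
#' @param passthrough a `feature_table` of precomputed columns.
#' @param proteins named character vector of protein sequences.
#' @param annotation gene/exon annotation list ([read_gff3()]).
#' @param chrom_lengths named chromosome lengths (bp).
#' @param peaks optional named list of BED-convention peak data.frames; one
#'   feature `ChIP_<name>` per element.
#' @param graph optional PPI graph; adds `degree`, `betweenness`,
#'   `closeness` (0 for genes absent from the graph).
#' @param ortholog_groups optional group list; adds `OMA_orthologs`.
#' @param est_hits optional BLAST tabular data.frame; adds `EST_BLAST`.
#' @param evalue_cutoff EST significance cutoff.
#' @return a `feature_table` with derived plus passthrough columns.
#' @export
featurize <- function(passthrough, proteins, annotation, chrom_lengths,
                      peaks = NULL, graph = NULL, ortholog_groups = NULL,
                      est_hits = NULL, evalue_cutoff = 1e-10) {
  ids <- passthrough$gene_ids
  aac <- t(vapply(proteins[ids], aa_composition, numeric(20)))
  ac <- t(vapply(proteins[ids], autocorrelation, numeric(3)))
  ex <- exon_features(annotation)
  ex <- ex[match(ids, ex$gene_id), ]
  dist <- distance_from_centre(annotation$genes, chrom_lengths)[ids]
  derived <- cbind(aac, ac, exons = ex$exons,
                   exons_total_length = ex$exons_total_length,
                   distance = dist)
  prov <- setNames(c(rep("sequence", 23), rep("annotation", 3)), colnames(derived))
  if (!is.null(peaks)) {
    for (nm in names(peaks)) {
      derived <- cbind(derived, count_peak_overlaps(annotation$genes, peaks[[nm]])[ids])
      colnames(derived)[ncol(derived)] <- paste0("ChIP_", nm)
      prov[paste0("ChIP_", nm)] <- "peaks"
    }
  }
  if (!is.null(graph)) {
    cen <- graph_centralities(graph)
    for (nm in c("degree", "betweenness", "closeness")) {
      v <- setNames(numeric(length(ids)), ids)
      hit <- intersect(ids, cen$node)
      v[hit] <- cen[[nm]][match(hit, cen$node)]
      derived <- cbind(derived, v)
      colnames(derived)[ncol(derived)] <- nm
      prov[nm] <- "graph"
    }
  }
  if (!is.null(ortholog_groups)) {
    derived <- cbind(derived, OMA_orthologs = ortholog_group_sizes(ortholog_groups, ids))
    prov["OMA_orthologs"] <- "orthologs"
  }
  if (!is.null(est_hits)) {
    derived <- cbind(derived, EST_BLAST = est_hit_counts(est_hits, ids, evalue_cutoff))
    prov["EST_BLAST"] <- "est_hits"
  }
  rownames(derived) <- ids
  combined <- cbind(derived, passthrough$values)
  feature_table(combined, species = passthrough$species,
                provenance = c(prov, setNames(rep("passthrough", ncol(passthrough$values)),
                                              colnames(passthrough$values))))
}
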