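#' Chromosome-level essentiality probability tracks
#'
#' Attaches each ranked gene's probability to its genomic midpoint, bins
#' gene density per chromosome, and can export one BedGraph record per
#' gene (0-based half-open gene span, probability as score). Genes without
#' an annotation are reported and skipped.
#'
#' @param ranked a `ranked_prediction`.
#' @param annotation gene/exon annotation list ([read_gff3()]).
#' @param chrom_lengths named chromosome lengths (bp).
#' @param bin_size density bin width in bp.
#' @return object of class `"chrom_track"`: list with `genes` (data.frame
#'   `gene_id`, `chrom`, `start`, `end`, `midpoint`, `probability`),
#'   `density` (data.frame `chrom`, `bin_start`, `bin_end`, `n_genes`),
#'   `bin_size`, `n_skipped`.
#' @export
probability_track <- function(ranked, annotation, chrom_lengths, bin_size = 1e6) {
  g <- annotation$genes
  hit <- ranked$gene_id %in% g$gene_id
  if (any(!hit))
    message(sprintf("probability_track: %d ranked gene(s) without annotation skipped", sum(!hit)))
  df <- merge(as.data.frame(ranked)[hit, c("gene_id", "probability")],
              g[, c("gene_id", "chrom", "start", "end")], by = "gene_id")
  df$midpoint <- (df$start + df$end) / 2
  dens <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    breaks <- seq(0, ceiling(L / bin_size) * bin_size, by = bin_size)
    mids <- df$midpoint[df$chrom == ch]
    counts <- if (length(mids)) tabulate(findInterval(mids, breaks, left.open = TRUE),
                                         nbins = length(breaks) - 1)
              else integer(length(breaks) - 1)
    data.frame(chrom = ch, bin_start = breaks[-length(breaks)],
               bin_end = breaks[-1], n_genes = counts, stringsAsFactors = FALSE)
  }))
  structure(list(genes = df[order(df$chrom, df$midpoint), ],
                 density = dens, bin_size = bin_size, n_skipped = sum(!hit)),
            class = "chrom_track")
}

#' @export
print.chrom_track <- function(x, ...) {
  cat(sprintf("chrom_track: %d genes on %d chromosomes (bin %g bp; %d skipped)\n",
              nrow(x$genes), length(unique(x$density$chrom)), x$bin_size, x$n_skipped))
  invisible(x)
}

#' Write a chromosome track as BedGraph
#'
#' One record per gene: chrom, 0-based start, end, probability.
#'
#' @param track a `chrom_track`.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  g <- track$genes
  writeLines(sprintf("%s\t%d\t%d\t%g", g$chrom, as.integer(g$start) - 1L,
                     as.integer(g$end), g$probability), path)
  invisible(path)
}

#' Heterochromatin summary of an essentiality landscape
#'
#' Classifies each gene as inside or outside heterochromatin by its
#' 1-based midpoint against the BED (0-based half-open) intervals, reports
#' the fraction of high-probability genes (probability > 0.5, the
#' landscape threshold) in each compartment, and a two-sided rank-sum test
#' (normal approximation) comparing probabilities inside vs outside.
#'
#' @param track a `chrom_track`.
#' @param het_intervals BED-convention data.frame (`chrom`, `start`,
#'   `end`), e.g. from [read_bed()].
#' @param hi_prob threshold defining "high probability" genes.
#' @return list of class `"het_summary"`: `n_inside`, `n_outside`,
#'   `frac_high_inside`, `frac_high_outside` (NA when a compartment is
#'   empty), `statistic`, `p_value`.
#' @export
heterochromatin_summary <- function(track, het_intervals, hi_prob = 0.5) {
  g <- track$genes
  if (is.null(het_intervals) || !nrow(het_intervals)) {
    return(structure(list(n_inside = 0L, n_outside = nrow(g),
                          frac_high_inside = NA_real_,
                          frac_high_outside = mean(g$probability > hi_prob),
                          statistic = NA_real_, p_value = NA_real_,
                          flagged = "no heterochromatin intervals"),
                     class = "het_summary"))
  }
  inside <- vapply(seq_len(nrow(g)), function(i) {
    h <- het_intervals[het_intervals$chrom == g$chrom[i], , drop = FALSE]
    any(g$midpoint[i] > h$start & g$midpoint[i] <= h$end)
  }, logical(1))
  hi <- g$probability > hi_prob
  stat <- p <- NA_real_
  if (any(inside) && any(!inside) &&
      (length(unique(g$probability)) > 1)) {
    wt <- suppressWarnings(wilcox.test(g$probability[inside], g$probability[!inside],
                                       alternative = "two.sided", exact = FALSE))
    stat <- unname(wt$statistic)
    p <- wt$p.value
  }
  structure(list(n_inside = sum(inside), n_outside = sum(!inside),
                 frac_high_inside = if (any(inside)) mean(hi[inside]) else NA_real_,
                 frac_high_outside = if (any(!inside)) mean(hi[!inside]) else NA_real_,
                 statistic = stat, p_value = p, flagged = NULL),
            class = "het_summary")
}

#' Plot an essentiality probability landscape
#'
#' One panel per chromosome: per-gene probability against genomic
#' midpoint, with heterochromatin intervals shaded when supplied.
#'
#' @param x a `chrom_track`.
#' @param het_intervals optional BED-convention intervals to shade.
#' @param ... passed to [graphics::plot()].
#' @export
plot.chrom_track <- function(x, het_intervals = NULL, ...) {
  chroms <- unique(x$density$chrom)
  old <- graphics::par(mfrow = c(length(chroms), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (ch in chroms) {
    g <- x$genes[x$genes$chrom == ch, ]
    plot(g$midpoint, g$probability, pch = 16, cex = 0.4,
         xlab = "", ylab = "P(essential)", main = ch, ylim = c(0, 1), ...)
    if (!is.null(het_intervals)) {
      h <- het_intervals[het_intervals$chrom == ch, ]
      if (nrow(h)) graphics::rect(h$start, 0, h$end, 1,
                                  col = grDevices::adjustcolor("grey", 0.3),
                                  border = NA)
    }
  }
  invisible(x)
}

#' Plot a cumulative lethal-ratio validation curve
#'
#' @param x a `validation_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.validation_curve <- function(x, ...) {
  plot(x$k, x$ratio, type = "l", xlab = "genes searched (ranked)",
       ylab = "cumulative lethal ratio",
       main = sprintf("direction: %s", attr(x, "direction")), ...)
  graphics::abline(h = x$ratio[nrow(x)], lty = 2, col = "grey40")
  invisible(x)
}

#' @export
print.het_summary <- function(x, ...) {
  cat(sprintf("het_summary: %d genes inside / %d outside heterochromatin\n",
              x$n_inside, x$n_outside))
  cat(sprintf("  high-probability fraction inside %.4f vs outside %.4f (rank-sum p = %.3g)\n",
              x$frac_high_inside, x$frac_high_outside, x$p_value))
  if (!is.null(x$flagged)) cat("  note:", x$flagged, "\n")
  invisible(x)
}
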