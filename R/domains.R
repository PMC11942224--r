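# Broad-domain classification: the top-fraction-broadest-domains-with-TSS
# selection rule and the descriptive narrow/broad width label.

#' Select the top broadest peaks containing a TSS
#'
#' Peaks of one sample are ranked by width, descending (ties broken by
#' genomic order: chromosome then start).  The top `ceiling(fraction * n)`
#' peaks are considered, and for each selected peak one call is emitted per
#' gene having at least one TSS coordinate inside the peak's half-open
#' interval.  Selection happens before the TSS filter, so selected peaks
#' containing no TSS contribute nothing.
#'
#' @param peakset a `PeakSet`.
#' @param annotation a `GenomeAnnotation`.
#' @param fraction fraction of broadest peaks to consider (0 < fraction
#'   <= 1); the study value is 0.05.
#' @return data.frame of class calls: `sample_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `width`, `width_rank` (1 = broadest),
#'   `width_percentile` (rank / n).
#' @export
top_broadest_with_tss <- function(peakset, annotation, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  empty <- data.frame(sample_id = character(), gene_id = character(),
                      chrom = character(), start = integer(), end = integer(),
                      width = integer(), width_rank = integer(),
                      width_percentile = numeric(), stringsAsFactors = FALSE)
  p <- peakset$peaks
  if (!nrow(p)) return(empty)
  p$width <- p$end - p$start
  ord <- order(-p$width, p$chrom, p$start, method = "radix")
  k <- ceiling(fraction * nrow(p))
  sel <- ord[seq_len(k)]
  tss <- annotation$tss
  if (!nrow(tss)) return(empty)
  pg <- GRanges(p$chrom[sel], IRanges(p$start[sel] + 1L, p$end[sel]))
  tg <- GRanges(tss$chrom, IRanges(tss$pos + 1L, tss$pos + 1L))
  hits <- suppressWarnings(findOverlaps(tg, pg))
  if (!length(hits)) return(empty)
  pair <- unique(data.frame(gene_id = tss$gene_id[queryHits(hits)],
                            sel_idx = subjectHits(hits),
                            stringsAsFactors = FALSE))
  idx <- sel[pair$sel_idx]
  out <- data.frame(sample_id = peakset$sample_id, gene_id = pair$gene_id,
                    chrom = p$chrom[idx], start = p$start[idx],
                    end = p$end[idx], width = p$width[idx],
                    width_rank = pair$sel_idx,
                    width_percentile = pair$sel_idx / nrow(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$width_rank, out$gene_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Descriptive narrow/broad domain label
#'
#' A domain is broad when its width is at least 4000 bp (the boundary is
#' inclusive), otherwise narrow.  This label is reporting only; the
#' analysis-driving selection is [top_broadest_with_tss()].
#'
#' @param width peak width(s) in bp, > 0.
#' @return character vector of `"narrow"`/`"broad"`.
#' @export
classify_domain <- function(width) {
  if (any(width <= 0)) stop("width must be positive")
  ifelse(width >= 4000, "broad", "narrow")
}

#' Deduplicated broad-domain gene sets per sample
#'
#' @param calls one or more call tables from [top_broadest_with_tss()]
#'   (row-bound across samples is fine).
#' @return named list, sample_id -> sorted character vector of gene ids.
#' @export
broad_gene_sets <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls)) calls <- do.call(rbind, calls)
  if (is.null(calls) || !nrow(calls)) return(structure(list(), names = character(0)))
  lapply(split(calls$gene_id, calls$sample_id), function(g) sort(unique(g)))
}
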