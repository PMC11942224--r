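# TSS-window annotation: assign peaks to genes whose TSS windows they
# overlap and build the genes x samples mark matrix.

#' Strand-aware TSS windows
#'
#' For a "+"-strand TSS `t` the window is `[t - up, t + down)`; for a "-"
#' strand TSS it is `[t - down, t + up)`.  Windows are clipped to the
#' chromosome; one window per distinct TSS.
#'
#' @param annotation a `GenomeAnnotation`.
#' @param up,down upstream/downstream extents (bp, both >= 0); default
#'   1000 bp each.
#' @return data.frame `gene_id`, `chrom`, `strand`, `tss`, `start`, `end`.
#' @export
tss_windows <- function(annotation, up = 1000, down = 1000) {
  stopifnot(up >= 0, down >= 0)
  tss <- annotation$tss
  if (!nrow(tss))
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), tss = integer(),
                      start = integer(), end = integer()))
  plus <- tss$strand == "+"
  start <- ifelse(plus, tss$pos - up, tss$pos - down)
  end <- ifelse(plus, tss$pos + down, tss$pos + up)
  lens <- annotation$chrom_sizes[tss$chrom]
  out <- data.frame(gene_id = tss$gene_id, chrom = tss$chrom,
                    strand = tss$strand, tss = tss$pos,
                    start = as.integer(pmax(start, 0)),
                    end = as.integer(pmin(end, lens)),
                    stringsAsFactors = FALSE)
  out <- out[out$start < out$end, , drop = FALSE]
  out <- out[order_genomic(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign peaks to genes via TSS-window overlap
#'
#' A peak is assigned to a gene when it overlaps (>= 1 bp intersection of
#' half-open intervals) at least one of the gene's TSS windows.  A peak may
#' be assigned to several genes; within one gene each peak is counted once
#' even if it overlaps several of the gene's windows.
#'
#' @param peakset a `PeakSet`.
#' @param windows TSS windows from [tss_windows()].
#' @return named list, gene_id -> data.frame of that gene's overlapping
#'   peaks (columns as in `PeakSet$peaks` plus `width`); genes with no
#'   overlap are absent.
#' @export
assign_tss_peaks <- function(peakset, windows) {
  p <- peakset$peaks
  if (!nrow(p) || !nrow(windows)) return(structure(list(), names = character(0)))
  pg <- GRanges(p$chrom, IRanges(p$start + 1L, p$end))
  wg <- GRanges(windows$chrom, IRanges(windows$start + 1L, windows$end))
  hits <- suppressWarnings(findOverlaps(pg, wg))
  if (!length(hits)) return(structure(list(), names = character(0)))
  pair <- unique(data.frame(peak = queryHits(hits),
                            gene = windows$gene_id[subjectHits(hits)],
                            stringsAsFactors = FALSE))
  p$width <- p$end - p$start
  lapply(split(pair$peak, pair$gene), function(idx) {
    d <- p[sort(idx), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}

#' Build the genes x samples mark matrix
#'
#' `marked[g, s]` is TRUE iff gene `g` has at least one peak assigned to a
#' TSS window in sample `s`.  `best_peak` records, per marked (gene,
#' sample), the widest overlapping peak (ties broken by leftmost genomic
#' position).  `domain_class` starts as `"none"` and is filled by
#' [classify_matrix_domains()].
#'
#' @param assignments named list, sample_id -> result of
#'   [assign_tss_peaks()] for that sample.
#' @param annotation a `GenomeAnnotation` (fixes the gene order).
#' @param sample_ids samples to include, in order; each must have an entry
#'   in `assignments`.
#' @return object of class `GeneMarkMatrix`: list with `genes`, `samples`,
#'   `marked` (logical matrix), `best_peak` (data.frame), `domain_class`
#'   (character matrix).
#' @export
gene_mark_matrix <- function(assignments, annotation, sample_ids = names(assignments)) {
  miss <- setdiff(sample_ids, names(assignments))
  if (length(miss)) stop("no assignment mapping for sample: ", miss[1])
  genes <- annotation$genes$gene_id
  marked <- matrix(FALSE, nrow = length(genes), ncol = length(sample_ids),
                   dimnames = list(genes, sample_ids))
  best_rows <- list()
  for (s in sample_ids) {
    asg <- assignments[[s]]
    for (g in names(asg)) {
      if (!g %in% genes) next
      marked[g, s] <- TRUE
      d <- asg[[g]]
      d <- d[order(-d$width, d$chrom, d$start, method = "radix"), , drop = FALSE]
      best_rows[[length(best_rows) + 1L]] <- data.frame(
        gene_id = g, sample_id = s, chrom = d$chrom[1], start = d$start[1],
        end = d$end[1], width = d$width[1], score = d$score[1],
        stringsAsFactors = FALSE)
    }
  }
  best_peak <- if (length(best_rows)) do.call(rbind, best_rows) else
    data.frame(gene_id = character(), sample_id = character(),
               chrom = character(), start = integer(), end = integer(),
               width = integer(), score = numeric())
  domain_class <- matrix("none", nrow = length(genes), ncol = length(sample_ids),
                         dimnames = list(genes, sample_ids))
  structure(list(genes = genes, samples = sample_ids, marked = marked,
                 best_peak = best_peak, domain_class = domain_class),
            class = "GeneMarkMatrix")
}

#' @export
print.GeneMarkMatrix <- function(x, ...) {
  cat(sprintf("GeneMarkMatrix: %d gene(s) x %d sample(s), %d marked cell(s)\n",
              length(x$genes), length(x$samples), sum(x$marked)))
  invisible(x)
}

#' Fill the domain class of every marked cell
#'
#' Applies [classify_domain()] to the best (widest) peak of each marked
#' (gene, sample) cell; unmarked cells stay `"none"`.
#'
#' @param matrix a `GeneMarkMatrix`.
#' @return the matrix with `domain_class` filled.
#' @export
classify_matrix_domains <- function(matrix) {
  bp <- matrix$best_peak
  for (i in seq_len(nrow(bp)))
    matrix$domain_class[bp$gene_id[i], bp$sample_id[i]] <- classify_domain(bp$width[i])
  matrix
}

#' Per-sample sets of marked genes
#' @param matrix a `GeneMarkMatrix`.
#' @return named list, sample_id -> character vector of marked gene ids.
#' @export
marked_gene_sets <- function(matrix) {
  setNames(lapply(matrix$samples, function(s)
    matrix$genes[matrix$marked[, s]]), matrix$samples)
}

#' Write a gene mark matrix as TSV
#'
#' One row per gene, one column per sample; cells contain the domain class
#' (`narrow`/`broad`) for marked cells and `.` for unmarked ones.
#'
#' @param matrix a `GeneMarkMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_mark_matrix <- function(matrix, path) {
  cls <- matrix$domain_class
  cls[!matrix$marked] <- "."
  cls[matrix$marked & cls == "none"] <- "marked"
  df <- data.frame(gene_id = matrix$genes, cls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene mark matrix written by [write_gene_mark_matrix()]
#'
#' `best_peak` is not serialized and comes back empty.
#'
#' @param path TSV path.
#' @return a `GeneMarkMatrix`.
#' @export
read_gene_mark_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  genes <- df$gene_id
  samples <- setdiff(names(df), "gene_id")
  cls <- as.matrix(df[samples])
  rownames(cls) <- genes
  marked <- cls != "."
  cls[!marked] <- "none"
  cls[cls == "marked"] <- "none"
  structure(list(genes = genes, samples = samples, marked = marked,
                 best_peak = data.frame(gene_id = character(),
                                        sample_id = character(),
                                        chrom = character(), start = integer(),
                                        end = integer(), width = integer(),
                                        score = numeric()),
                 domain_class = cls),
            class = "GeneMarkMatrix")
}
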