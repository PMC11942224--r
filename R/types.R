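# Core S3 containers: GenomeAnnotation, PeakSet, CoverageTrack, SampleSheet.
# All genomic intervals are 0-based half-open [start, end).

#' Construct a genome annotation
#'
#' A `GenomeAnnotation` bundles chromosome sizes with gene models and their
#' transcription start sites (TSS).  Each gene may carry several distinct
#' TSSs (one per transcript 5' end, deduplicated).
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param genes data.frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `start`, `end` (0-based half-open).
#' @param tss data.frame with columns `gene_id`, `chrom`, `strand`, `pos`
#'   (0-based TSS coordinate); one row per distinct (gene, TSS).
#' @return object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(chrom_sizes, genes, tss) {
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  tss <- as.data.frame(tss, stringsAsFactors = FALSE)
  need <- c("gene_id", "gene_name", "chrom", "strand", "start", "end")
  if (!all(need %in% names(genes))) stop("genes is missing columns: ",
    paste(setdiff(need, names(genes)), collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("gene identifiers must be unique")
  if (nrow(genes)) {
    if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(genes$start >= genes$end)) stop("gene start must be < end")
    bad <- !(genes$chrom %in% names(chrom_sizes))
    if (any(bad)) stop("gene on unknown chromosome: ", genes$chrom[bad][1])
    if (any(genes$end > chrom_sizes[genes$chrom]))
      stop("gene extends past its chromosome end")
  }
  if (nrow(tss)) {
    g <- match(tss$gene_id, genes$gene_id)
    if (anyNA(g)) stop("TSS for unknown gene: ", tss$gene_id[is.na(g)][1])
    if (any(tss$pos < genes$start[g] | tss$pos >= genes$end[g]))
      stop("every TSS must lie within its gene body [start, end)")
  }
  structure(list(chrom_sizes = chrom_sizes, genes = genes, tss = tss),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d gene(s), %d TSS(s), %d chromosome(s) (%.3g Mb)\n",
              nrow(x$genes), nrow(x$tss), length(x$chrom_sizes),
              sum(x$chrom_sizes) / 1e6))
  invisible(x)
}

#' Canonical (5'-most) TSS per gene
#'
#' For "+" genes the smallest TSS coordinate, for "-" genes the largest.
#'
#' @param annotation a `GenomeAnnotation`.
#' @return data.frame `gene_id`, `chrom`, `strand`, `pos`.
#' @export
canonical_tss <- function(annotation) {
  tss <- annotation$tss
  if (!nrow(tss)) return(tss)
  parts <- split(tss, tss$gene_id)
  out <- do.call(rbind, lapply(parts, function(d) {
    pos <- if (d$strand[1] == "+") min(d$pos) else max(d$pos)
    d[match(pos, d$pos), , drop = FALSE]
  }))
  rownames(out) <- NULL
  out[order_genomic(out$chrom, out$pos), , drop = FALSE]
}

empty_peaks_df <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             score = numeric(), summit = integer(), stringsAsFactors = FALSE)
}

#' Construct a peak set
#'
#' Half-open peak intervals for one sample, sorted by (chrom, start).
#' Peaks on the same chromosome must not overlap.  `score` is -log10 of the
#' adjusted significance (q-value); `summit` is the offset of the summit from
#' `start`, or `NA` when absent (broad peaks).
#'
#' @param sample_id sample identifier.
#' @param peaks data.frame with columns `chrom`, `start`, `end`, `score`, and
#'   optionally `summit`.
#' @param calling_params the [calling_params()] record that produced the
#'   peaks, or `NULL`.
#' @return object of class `PeakSet`.
#' @export
peak_set <- function(sample_id, peaks = empty_peaks_df(), calling_params = NULL) {
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  if (!nrow(peaks)) peaks <- empty_peaks_df()
  if (is.null(peaks$summit)) peaks$summit <- NA_integer_
  if (is.null(peaks$score)) peaks$score <- 0
  peaks <- peaks[c("chrom", "start", "end", "score", "summit")]
  peaks$start <- as.integer(peaks$start)
  peaks$end <- as.integer(peaks$end)
  peaks$summit <- as.integer(peaks$summit)
  peaks$score <- as.numeric(peaks$score)
  if (any(peaks$start >= peaks$end)) stop("peak start must be < end")
  if (any(peaks$score < 0, na.rm = TRUE)) stop("peak score must be >= 0")
  w <- peaks$end - peaks$start
  bad <- !is.na(peaks$summit) & (peaks$summit < 0 | peaks$summit >= w)
  if (any(bad)) stop("summit offset must lie in [0, width)")
  peaks <- peaks[order_genomic(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  if (nrow(peaks) > 1) {
    same <- peaks$chrom[-1] == peaks$chrom[-nrow(peaks)]
    if (any(same & peaks$start[-1] < peaks$end[-nrow(peaks)]))
      stop("peaks within a PeakSet must not overlap")
  }
  structure(list(sample_id = sample_id, peaks = peaks,
                 calling_params = calling_params),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  w <- x$peaks$end - x$peaks$start
  cat(sprintf("PeakSet '%s': %d peak(s)%s\n", x$sample_id, nrow(x$peaks),
              if (length(w)) sprintf(", widths %d-%d bp", min(w), max(w)) else ""))
  invisible(x)
}

#' Number of peaks in a PeakSet
#' @param x a `PeakSet`.
#' @return integer count.
#' @export
n_peaks <- function(x) nrow(x$peaks)

#' Construct a binned coverage track
#'
#' Per-chromosome fragment counts in fixed-width bins.  The last bin of each
#' chromosome may be truncated by the chromosome end but still counts as one
#' bin.  Counts may be fractional after length-weighted re-binning of
#' bedGraph input.
#'
#' @param bin_size bin width (bp).
#' @param counts named list, chromosome -> numeric vector of per-bin counts.
#' @param chrom_sizes named vector of chromosome lengths; bin-vector lengths
#'   are validated against it when supplied.
#' @return object of class `CoverageTrack` with `total_fragments` computed.
#' @export
coverage_track <- function(bin_size, counts, chrom_sizes = NULL) {
  stopifnot(is_count(bin_size), bin_size > 0, is.list(counts))
  if (any(vapply(counts, function(v) any(v < 0), logical(1))))
    stop("coverage counts must be non-negative")
  if (!is.null(chrom_sizes)) {
    for (chr in names(counts)) {
      if (!chr %in% names(chrom_sizes)) stop("unknown chromosome: ", chr)
      if (length(counts[[chr]]) != n_bins(chrom_sizes[[chr]], bin_size))
        stop("bin vector length mismatch on ", chr)
    }
  }
  structure(list(bin_size = as.integer(bin_size), counts = counts,
                 total_fragments = round(sum(vapply(counts, sum, numeric(1)))),
                 chrom_sizes = chrom_sizes),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack: %d chromosome(s), bin %d bp, %.4g fragments\n",
              length(x$counts), x$bin_size, x$total_fragments))
  invisible(x)
}

#' Construct a sample sheet
#'
#' @param entries data.frame with columns `sample_id`, `group` (one of
#'   `normal`, `cancer`, `reference_normal`) and optionally `chip_path`,
#'   `input_path`.
#' @return object of class `SampleSheet`.
#' @export
sample_sheet <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(entries)))
    stop("sample sheet needs 'sample_id' and 'group' columns")
  if (is.null(entries$chip_path)) entries$chip_path <- NA_character_
  if (is.null(entries$input_path)) entries$input_path <- NA_character_
  entries$chip_path[!is.na(entries$chip_path) & !nzchar(entries$chip_path)] <- NA_character_
  entries$input_path[!is.na(entries$input_path) & !nzchar(entries$input_path)] <- NA_character_
  if (anyDuplicated(entries$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         entries$sample_id[duplicated(entries$sample_id)][1])
  ok <- c("normal", "cancer", "reference_normal")
  if (!all(entries$group %in% ok))
    stop("unknown group label: ", setdiff(entries$group, ok)[1],
         " (expected normal/cancer/reference_normal)")
  structure(list(entries = entries[c("sample_id", "group", "chip_path",
                                     "input_path")]),
            class = "SampleSheet")
}

#' @export
print.SampleSheet <- function(x, ...) {
  tab <- table(x$entries$group)
  cat(sprintf("SampleSheet: %d sample(s) (%s)\n", nrow(x$entries),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Sample ids in a sheet belonging to given group(s)
#' @param sheet a `SampleSheet`.
#' @param groups character vector of group labels.
#' @return character vector of sample ids.
#' @export
samples_in_group <- function(sheet, groups) {
  sheet$entries$sample_id[sheet$entries$group %in% groups]
}
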