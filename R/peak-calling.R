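# Simplified MACS-style Poisson peak caller on binned coverage.
#
# The statistical skeleton follows the MACS family: per-bin Poisson
# significance against a local background rate (the max of the genome-wide
# rate and windowed local means, computed on the input control when one is
# available), Benjamini-Hochberg adjustment over all genome bins jointly,
# and either narrow merging (default mode) or strong-through-weak linking
# (broad mode).  Model building, fragment-shift estimation and read-level
# pileup are deliberately out of scope: the caller consumes binned coverage.

#' Peak-calling parameters
#'
#' @param mode `"default"` (narrow peaks with summits) or `"broad"`
#'   (strong bins linked through weak bins, no summits).
#' @param bin_size coverage bin width (bp).
#' @param q_strong adjusted-significance cutoff for significant bins.
#' @param q_weak broad-linking cutoff (must be >= `q_strong`).
#' @param min_peak_len minimum peak width (bp); shorter peaks are dropped.
#' @param broad_gap maximum gap (bp) bridged when linking weak bins in broad
#'   mode (must be >= `bin_size`).
#' @param local_windows window widths (bp) for the local background rate.
#' @param use_input whether to use the input control when supplied.
#' @return a list of class `CallingParams`.
#' @export
calling_params <- function(mode = c("default", "broad"), bin_size = 50,
                           q_strong = 0.05, q_weak = 0.10,
                           min_peak_len = 150, broad_gap = 1000,
                           local_windows = c(1000, 5000, 10000),
                           use_input = TRUE) {
  mode <- match.arg(mode)
  stopifnot(bin_size > 0, q_strong > 0, q_strong <= 1, min_peak_len >= 0)
  if (q_weak < q_strong) stop("q_weak must be >= q_strong")
  if (broad_gap < bin_size) stop("broad_gap must be >= bin_size")
  structure(list(mode = mode, bin_size = as.integer(bin_size),
                 q_strong = q_strong, q_weak = q_weak,
                 min_peak_len = as.integer(min_peak_len),
                 broad_gap = as.integer(broad_gap),
                 local_windows = local_windows, use_input = use_input),
            class = "CallingParams")
}

#' Poisson upper-tail probability P(X >= k)
#'
#' Survival-function form, numerically stable for rates up to at least 1e4.
#'
#' @param k observed count(s), non-negative integers.
#' @param lam Poisson rate(s), > 0.
#' @return `P(X >= k)` for `X ~ Poisson(lam)`, vectorized.
#' @export
poisson_upper_tail <- function(k, lam) {
  if (any(lam <= 0)) stop("lam must be > 0")
  if (any(k < 0) || any(k != floor(k))) stop("k must be a non-negative integer")
  ppois(k - 1, lam, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted significance values
#'
#' Step-up adjustment, monotone in p-value rank and capped at 1.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return q-values, same length and order as `pvalues`.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

check_track_compat <- function(chip, input) {
  if (!is.null(input)) {
    if (chip$bin_size != input$bin_size)
      stop("ChIP and input bin_size differ")
    if (!identical(sort(names(chip$counts)), sort(names(input$counts))) ||
        !all(lengths(chip$counts)[names(chip$counts)] ==
             lengths(input$counts)[names(chip$counts)]))
      stop("ChIP and input chromosomes differ")
  }
}

# truncated centered running mean (edge bins average over fewer bins)
window_mean <- function(x, wbins) {
  n <- length(x)
  h <- wbins %/% 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1)
  hi <- pmin(i + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Estimate the Poisson background model
#'
#' The genome-wide rate is `total ChIP fragments / total bins`.  The local
#' rate at a bin is the maximum of the genome-wide rate and centered window
#' means over the configured windows, computed on the depth-scaled input
#' when one is available, otherwise on the ChIP itself with windows below
#' 5 kb excluded (so true peaks do not inflate their own background).
#'
#' @param chip ChIP `CoverageTrack`.
#' @param input optional input-control `CoverageTrack` (scaled to ChIP
#'   depth before use).
#' @param params a [calling_params()] record.
#' @return list of class `LambdaModel` with `lambda_bg` and `local` (named
#'   list chromosome -> per-bin local rate).
#' @export
estimate_background <- function(chip, input = NULL, params = calling_params()) {
  check_track_compat(chip, input)
  if (!isTRUE(params$use_input)) input <- NULL
  total_bins <- sum(lengths(chip$counts))
  if (total_bins == 0) stop("empty coverage track")
  lambda_bg <- max(chip$total_fragments / total_bins, 1e-9)
  if (!is.null(input)) {
    scale <- if (input$total_fragments > 0)
      chip$total_fragments / input$total_fragments else 1
    source_counts <- lapply(input$counts, function(v) v * scale)
    windows <- params$local_windows
  } else {
    source_counts <- chip$counts
    windows <- params$local_windows[params$local_windows >= 5000]
  }
  wbins <- unique(pmax(1L, as.integer(round(windows / chip$bin_size))))
  local <- lapply(source_counts, function(v) {
    lam <- rep(lambda_bg, length(v))
    for (w in wbins) lam <- pmax(lam, window_mean(v, w))
    lam
  })
  structure(list(lambda_bg = lambda_bg, local = local,
                 used_input = !is.null(input)),
            class = "LambdaModel")
}

# per-chromosome q-values for a sample (BH over all genome bins jointly)
bin_qvalues <- function(chip, input, params) {
  lm <- estimate_background(chip, input, params)
  chroms <- names(chip$counts)
  p <- unlist(lapply(chroms, function(chr)
    poisson_upper_tail(chip$counts[[chr]], lm$local[[chr]])), use.names = FALSE)
  q <- bh_adjust(p)
  split_at <- cumsum(lengths(chip$counts)[chroms])
  out <- vector("list", length(chroms))
  names(out) <- chroms
  s <- 1L
  for (i in seq_along(chroms)) {
    out[[i]] <- q[s:split_at[i]]
    s <- split_at[i] + 1L
  }
  out
}

# merge sorted bin indices into [first, last] groups allowing index gaps
merge_bin_runs <- function(idx, max_idx_step) {
  if (!length(idx)) return(NULL)
  grp <- cumsum(c(TRUE, diff(idx) > max_idx_step))
  lapply(split(idx, grp), range)
}

#' Call peaks from binned coverage
#'
#' Per-bin Poisson p-values against the local background are BH-adjusted
#' over all genome bins.  Default mode merges significant bins
#' (`q <= q_strong`) across gaps of at most one bin, drops peaks shorter
#' than `min_peak_len`, and records the summit (leftmost maximum-count bin)
#' and score (max per-bin `-log10 q`).  Broad mode links weak bins
#' (`q <= q_weak`) across gaps up to `broad_gap` and keeps the linked
#' regions that contain at least one strong bin; broad peaks carry no
#' summit.  Output is sorted and non-overlapping.
#'
#' @param chip ChIP `CoverageTrack`.
#' @param input optional input `CoverageTrack`.
#' @param params a [calling_params()] record.
#' @param sample_id id recorded in the returned `PeakSet`.
#' @return a [peak_set()] (empty for empty or all-zero coverage).
#' @export
call_peaks <- function(chip, input = NULL, params = calling_params(),
                       sample_id = "sample") {
  if (sum(lengths(chip$counts)) == 0 || chip$total_fragments == 0)
    return(peak_set(sample_id, calling_params = params))
  bs <- params$bin_size
  if (bs != chip$bin_size)
    params$bin_size <- bs <- chip$bin_size
  q <- bin_qvalues(chip, input, params)
  rows <- list()
  for (chr in names(chip$counts)) {
    qc <- q[[chr]]
    counts <- chip$counts[[chr]]
    chrom_len <- if (!is.null(chip$chrom_sizes)) chip$chrom_sizes[[chr]]
                 else length(counts) * bs
    strong <- which(qc <= params$q_strong)
    if (!length(strong)) next
    if (params$mode == "default") {
      runs <- merge_bin_runs(strong, 2L)
    } else {
      weak <- which(qc <= params$q_weak)
      step <- params$broad_gap %/% bs + 1L
      runs <- merge_bin_runs(weak, step)
      has_strong <- vapply(runs, function(r)
        any(qc[r[1]:r[2]] <= params$q_strong), logical(1))
      runs <- runs[has_strong]
    }
    for (r in runs) {
      start <- (r[1] - 1L) * bs
      end <- min(r[2] * bs, chrom_len)
      if (end - start < params$min_peak_len) next
      bins <- r[1]:r[2]
      score <- max(-log10(pmax(qc[bins], 1e-300)))
      if (params$mode == "default") {
        mb <- bins[which.max(counts[bins])]
        summit <- (mb - 1L) * bs - start + bs %/% 2L
        summit <- min(summit, end - start - 1L)
      } else {
        summit <- NA_integer_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chr, start = as.integer(start), end = as.integer(end),
        score = score, summit = as.integer(summit), stringsAsFactors = FALSE)
    }
  }
  peaks <- if (length(rows)) do.call(rbind, rows) else empty_peaks_df()
  peak_set(sample_id, peaks, calling_params = params)
}

#' Order statistics of peak widths
#'
#' @param peakset a `PeakSet`.
#' @return list with `n` and, when `n > 0`, `min`, `q25`, `median`, `q75`,
#'   `max` of the peak widths (NA when the set is empty).
#' @export
peak_width_stats <- function(peakset) {
  w <- peakset$peaks$end - peakset$peaks$start
  if (!length(w))
    return(list(n = 0L, min = NA_real_, q25 = NA_real_, median = NA_real_,
                q75 = NA_real_, max = NA_real_))
  qs <- unname(quantile(w, c(0.25, 0.75), type = 7))
  list(n = length(w), min = min(w), q25 = qs[1], median = median(w),
       q75 = qs[2], max = max(w))
}
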