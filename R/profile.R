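# TSS-centred metagene profiles: mean coverage and peak density as a
# function of (strand-oriented) distance from the TSS.

profile_offsets <- function(flank, bin) {
  seq(-flank + bin / 2, flank - bin / 2, by = bin)
}

extract_tss_matrix <- function(per_chrom_values, annotation, flank, bin) {
  tss <- annotation$tss
  nb <- as.integer(2 * flank / bin)
  acc <- numeric(nb)
  n_used <- 0L
  n_dropped <- 0L
  for (i in seq_len(nrow(tss))) {
    v <- per_chrom_values[[tss$chrom[i]]]
    start_bin <- floor((tss$pos[i] - flank) / bin) + 1
    idx <- start_bin:(start_bin + nb - 1)
    if (idx[1] < 1 || idx[nb] > length(v)) {
      n_dropped <- n_dropped + 1L
      next
    }
    w <- v[idx]
    if (tss$strand[i] == "-") w <- rev(w)
    acc <- acc + w
    n_used <- n_used + 1L
  }
  list(acc = acc, n_used = n_used, n_dropped = n_dropped)
}

new_tss_profile <- function(flank, bin, values, n_tss, n_dropped) {
  structure(list(flank = flank, bin = bin,
                 offsets = profile_offsets(flank, bin), values = values,
                 n_tss = n_tss, n_dropped = n_dropped),
            class = "TssProfile")
}

#' @export
print.TssProfile <- function(x, ...) {
  imax <- which.max(x$values)
  cat(sprintf("TssProfile: +/-%d bp in %d bp bins, %d TSS(s) (%d dropped), max %.4g at %+d bp\n",
              x$flank, x$bin, x$n_tss, x$n_dropped, x$values[imax],
              as.integer(x$offsets[imax])))
  invisible(x)
}

#' TSS-centred mean coverage profile
#'
#' For every TSS the `+/- flank` coverage window is extracted at bin
#' resolution, reversed for "-"-strand genes so upstream maps to negative
#' offsets, and averaged across TSSs.  TSSs whose window crosses a
#' chromosome edge are dropped and counted in `n_dropped`.
#'
#' @param coverage a `CoverageTrack`; its `bin_size` must equal `bin`.
#' @param annotation a `GenomeAnnotation`.
#' @param flank half-window (bp), a multiple of `bin`; default 5000.
#' @param bin profile bin (bp); default 50.
#' @param normalize `"none"` (raw mean counts) or `"cpm"` (divide by total
#'   fragments per million).
#' @return a `TssProfile` (fields `offsets`, `values`, `n_tss`,
#'   `n_dropped`).
#' @export
tss_profile <- function(coverage, annotation, flank = 5000, bin = 50,
                        normalize = c("none", "cpm")) {
  normalize <- match.arg(normalize)
  stopifnot(flank > 0, flank %% bin == 0)
  if (bin != coverage$bin_size)
    stop("profile bin must equal the coverage bin_size (resampling is not supported)")
  ex <- extract_tss_matrix(coverage$counts, annotation, flank, bin)
  if (ex$n_used == 0) stop("no usable TSS (all windows cross chromosome edges)")
  values <- ex$acc / ex$n_used
  if (normalize == "cpm") values <- values / (coverage$total_fragments / 1e6)
  new_tss_profile(flank, bin, values, ex$n_used, ex$n_dropped)
}

#' TSS-centred peak density profile
#'
#' `values[j]` is the fraction of TSSs whose j-th offset bin is covered by
#' (overlaps >= 1 bp of) a peak; values lie in [0, 1].
#'
#' @param peakset a `PeakSet`.
#' @param annotation a `GenomeAnnotation`.
#' @param flank half-window (bp), a multiple of `bin`.
#' @param bin profile bin (bp).
#' @return a `TssProfile`.
#' @export
peak_density_profile <- function(peakset, annotation, flank = 5000, bin = 50) {
  stopifnot(flank > 0, flank %% bin == 0)
  covered <- lapply(names(annotation$chrom_sizes), function(chr) {
    v <- logical(n_bins(annotation$chrom_sizes[[chr]], bin))
    p <- peakset$peaks[peakset$peaks$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(p))) {
      b0 <- p$start[i] %/% bin + 1
      b1 <- min((p$end[i] - 1) %/% bin + 1, length(v))
      v[b0:b1] <- TRUE
    }
    as.numeric(v)
  })
  names(covered) <- names(annotation$chrom_sizes)
  ex <- extract_tss_matrix(covered, annotation, flank, bin)
  if (ex$n_used == 0) stop("no usable TSS (all windows cross chromosome edges)")
  new_tss_profile(flank, bin, ex$acc / ex$n_used, ex$n_used, ex$n_dropped)
}

#' Write a TSS profile as a two-column table
#'
#' @param profile a `TssProfile`.
#' @param path output path (TSV with `offset` and `value` columns).
#' @return `path`, invisibly.
#' @export
write_tss_profile <- function(profile, path) {
  write.table(data.frame(offset = profile$offsets, value = profile$values),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
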