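# Shared fixtures and brute-force oracles.  Fixtures are built in code; the
# oracles are deliberately naive (quadratic scans, direct summation) and
# independent of the implementation paths they check.

# --- tiny hand-built annotation -------------------------------------------

toy_annotation <- function() {
  genome_annotation(
    chrom_sizes = c(chrA = 100000, chrB = 50000),
    genes = data.frame(
      gene_id = c("gA1", "gA2", "gB1"),
      gene_name = c("ALPHA", "BETA", "GAMMA"),
      chrom = c("chrA", "chrA", "chrB"),
      strand = c("+", "-", "+"),
      start = c(5000L, 40000L, 10000L),
      end = c(15000L, 60000L, 20000L),
      stringsAsFactors = FALSE),
    tss = data.frame(
      gene_id = c("gA1", "gA1", "gA2", "gB1"),
      chrom = c("chrA", "chrA", "chrA", "chrB"),
      strand = c("+", "+", "-", "+"),
      pos = c(5000L, 5100L, 59999L, 10000L),
      stringsAsFactors = FALSE))
}

# flat coverage track over an annotation's chromosomes
flat_track <- function(chrom_sizes, value, bin_size = 50) {
  coverage_track(bin_size,
                 lapply(chrom_sizes, function(len)
                   rep(value, ceiling(len / bin_size))),
                 chrom_sizes)
}

# one-chromosome track with given per-bin counts
one_chrom_track <- function(counts, bin_size = 50, chrom = "chr1") {
  sizes <- setNames(length(counts) * bin_size, chrom)
  coverage_track(bin_size, setNames(list(counts), chrom), sizes)
}

# small planted-study fixture used across caller/differential tests
small_truth <- function(seed = 7, n_genes = 60, chrom_length = 2e6,
                        params = list(lambda0 = 2, enrichment = 8,
                                      depth = 1, bin_size = 50)) {
  ann <- generate_annotation(n_genes, n_chroms = 1,
                             chrom_length = chrom_length, seed = seed)
  des <- plant_marks(ann, default_group_design(), seed = seed + 1)
  synthetic_truth(ann, des, seed = seed, params = params)
}

random_peaks_df <- function(n, chrom_sizes, max_width = 5000) {
  rows <- list()
  for (chr in names(chrom_sizes)) {
    len <- chrom_sizes[[chr]]
    k <- ceiling(n / length(chrom_sizes))
    # non-overlapping by construction: slot the chromosome
    slot <- len %/% k
    start <- (seq_len(k) - 1) * slot + floor(runif(k, 0, slot / 2))
    width <- pmax(50, floor(runif(k, 50, min(max_width, slot / 2))))
    rows[[chr]] <- data.frame(chrom = chr, start = as.integer(start),
                              end = as.integer(start + width),
                              score = round(runif(k, 0, 100), 6),
                              summit = NA_integer_, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# --- brute-force oracles ---------------------------------------------------

# Poisson upper tail by direct summation of the pmf tail (small k,
# moderate lambda); summing the tail itself avoids cancellation
bf_poisson_upper_tail <- function(k, lam, kmax = 5000) {
  i <- k:(k + kmax)
  sum(exp(-lam + i * log(lam) - lgamma(i + 1)))
}

# all-pairs half-open interval overlap scan
bf_assign <- function(peaks_df, windows) {
  out <- structure(list(), names = character(0))
  for (i in seq_len(nrow(peaks_df))) {
    for (j in seq_len(nrow(windows))) {
      if (peaks_df$chrom[i] == windows$chrom[j] &&
          peaks_df$start[i] < windows$end[j] &&
          windows$start[j] < peaks_df$end[i]) {
        g <- windows$gene_id[j]
        out[[g]] <- union(out[[g]], i)
      }
    }
  }
  lapply(out, sort)
}

# sort widths, take ceiling(fraction * n) broadest (ties by genomic order),
# report genes with a TSS strictly inside a selected peak
bf_top_broad_genes <- function(peaks_df, tss, fraction) {
  if (!nrow(peaks_df)) return(character(0))
  w <- peaks_df$end - peaks_df$start
  ord <- order(-w, peaks_df$chrom, peaks_df$start, method = "radix")
  sel <- ord[seq_len(ceiling(fraction * nrow(peaks_df)))]
  genes <- character(0)
  for (i in sel) {
    for (j in seq_len(nrow(tss))) {
      if (tss$chrom[j] == peaks_df$chrom[i] &&
          tss$pos[j] >= peaks_df$start[i] && tss$pos[j] < peaks_df$end[i])
        genes <- union(genes, tss$gene_id[j])
    }
  }
  sort(genes)
}

# membership-enumeration set algebra over the universe of all mentioned genes
bf_unique_to <- function(sets, target, others) {
  universe <- sort(unique(unlist(sets)))
  keep <- vapply(universe, function(g)
    g %in% sets[[target]] && !any(vapply(others, function(s)
      g %in% sets[[s]], logical(1))), logical(1))
  universe[keep]
}

bf_common_absent <- function(sets, group, absent) {
  universe <- sort(unique(unlist(sets)))
  keep <- vapply(universe, function(g)
    all(vapply(group, function(s) g %in% sets[[s]], logical(1))) &&
      !any(vapply(absent, function(s) g %in% sets[[s]], logical(1))),
    logical(1))
  universe[keep]
}

random_gene_sets <- function(n_sets, universe_size = 100, p = 0.3) {
  universe <- sprintf("g%03d", seq_len(universe_size))
  setNames(lapply(seq_len(n_sets), function(i)
    universe[runif(universe_size) < p]),
    paste0("s", seq_len(n_sets)))
}

# Jaccard index of two half-open intervals on the same chromosome
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  inter / ((e1 - s1) + (e2 - s2) - inter)
}

# best Jaccard of a planted interval against a called peak set
best_jaccard <- function(peaks_df, chrom, start, end) {
  p <- peaks_df[peaks_df$chrom == chrom, , drop = FALSE]
  if (!nrow(p)) return(0)
  max(vapply(seq_len(nrow(p)), function(i)
    interval_jaccard(start, end, p$start[i], p$end[i]), numeric(1)))
}
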