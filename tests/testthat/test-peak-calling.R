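# peak_calling: statistical kernels, background model, caller behaviour

test_that("poisson_upper_tail matches closed forms and the summation oracle", {
  expect_equal(poisson_upper_tail(0, 0.5), 1.0)
  expect_equal(poisson_upper_tail(0, 100), 1.0)
  expect_equal(poisson_upper_tail(1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(poisson_upper_tail(10, 2), bf_poisson_upper_tail(10, 2),
               tolerance = 1e-12)
  # stable at large rates
  expect_equal(poisson_upper_tail(10100, 1e4),
               ppois(10099, 1e4, lower.tail = FALSE))
  expect_error(poisson_upper_tail(3, 0), "lam")
  expect_error(poisson_upper_tail(-1, 2), "k must")
})

test_that("bh_adjust reproduces the hand-computed step-up example", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 1.0)), c(0.04, 0.04, 0.04, 1.0))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("estimate_background: flat track gives flat lambda; input is depth-scaled", {
  flat <- one_chrom_track(rep(4, 2000))
  lm <- estimate_background(flat, params = calling_params())
  expect_equal(lm$lambda_bg, 4)
  expect_true(all(lm$local$chr1 == 4))

  # input at half ChIP depth: spike of 6/bin scales to 12/bin before windows
  chip <- one_chrom_track(rep(4, 2000))
  inp_counts <- rep(2, 2000); inp_counts[1001:1010] <- 6
  input <- one_chrom_track(inp_counts)
  scale <- chip$total_fragments / input$total_fragments
  lm2 <- estimate_background(chip, input, calling_params())
  # hand-computed 1 kb (20-bin) window mean at the spike centre
  centre <- 1005
  expect_equal(lm2$local$chr1[centre],
               max(4, mean(inp_counts[995:1015]) * scale,
                   mean(inp_counts[centre + (-50:50)]) * scale,
                   mean(inp_counts[centre + (-100:100)]) * scale))
})

test_that("estimate_background rejects mismatched tracks; local lambda >= lambda_bg", {
  chip <- one_chrom_track(rep(4, 100))
  expect_error(estimate_background(chip, one_chrom_track(rep(4, 100), bin_size = 25)),
               "bin_size")
  expect_error(estimate_background(chip, one_chrom_track(rep(4, 50))),
               "chromosomes")
  withr::local_seed(1)
  noisy <- one_chrom_track(rpois(5000, 3))
  lm <- estimate_background(noisy, params = calling_params())
  expect_true(all(lm$local$chr1 >= lm$lambda_bg))
})

test_that("call_peaks recovers a single planted narrow mark", {
  ann <- generate_annotation(1, 1, 1e6, gene_spacing = 1e6, seed = 5)
  des <- plant_marks(ann, default_group_design(
    fractions = c(all = 1, normal_only = 0, cancer_common = 0, one_cancer = 0),
    narrow_frac = 1), seed = 5)
  row <- des$table[des$table$sample_id == "N1", ]
  truth <- synthetic_truth(ann, des, seed = 8,
                           params = list(lambda0 = 2, enrichment = 8,
                                         depth = 1, bin_size = 50))
  cv <- simulate_coverage(truth, "N1")
  ps <- call_peaks(cv$chip, cv$input, calling_params("default"), "N1")
  expect_equal(n_peaks(ps), 1)
  expect_gte(best_jaccard(ps$peaks, "chr1", row$start, row$end), 0.5)
  expect_false(is.na(ps$peaks$summit[1]))
})

test_that("a planted 6 kb mark: broad mode one wide peak, default mode covers >= 80%", {
  ann <- generate_annotation(1, 1, 1e6, gene_spacing = 1e6, seed = 6)
  des <- plant_marks(ann, default_group_design(
    fractions = c(all = 1, normal_only = 0, cancer_common = 0, one_cancer = 0),
    narrow_frac = 0), seed = 6)
  row <- des$table[des$table$sample_id == "N1", ]
  row$end <- row$start + 6000  # pin the width at 6 kb
  truth <- synthetic_truth(ann, des, seed = 12,
                           params = list(lambda0 = 2, enrichment = 8,
                                         depth = 1, bin_size = 50))
  truth$design$table[truth$design$table$sample_id == "N1", "end"] <- row$end
  cv <- simulate_coverage(truth, "N1")

  broad <- call_peaks(cv$chip, cv$input, calling_params("broad"), "N1")
  expect_equal(n_peaks(broad), 1)
  expect_gte(broad$peaks$end[1] - broad$peaks$start[1], 4000)
  expect_true(is.na(broad$peaks$summit[1]))

  dflt <- call_peaks(cv$chip, cv$input, calling_params("default"), "N1")
  covered <- sum(pmin(dflt$peaks$end, row$end) - pmax(dflt$peaks$start, row$start))
  expect_gte(covered / (row$end - row$start), 0.8)
})

test_that("callable invariants: sorted non-overlapping peaks each containing a strong bin", {
  truth <- small_truth(seed = 21)
  cv <- simulate_coverage(truth, "C1")
  for (mode in c("default", "broad")) {
    params <- calling_params(mode)
    ps <- call_peaks(cv$chip, cv$input, params, "C1")
    p <- ps$peaks
    expect_true(all(diff(order(p$chrom, p$start, method = "radix")) == 1))
    same <- p$chrom[-1] == p$chrom[-nrow(p)]
    expect_true(all(p$start[-1][same] >= p$end[-nrow(p)][same]))
    expect_true(all(p$end - p$start >= params$min_peak_len))
    # every peak contains at least one strongly significant bin
    q <- broadmark:::bin_qvalues(cv$chip, cv$input, params)
    for (i in seq_len(nrow(p))) {
      bins <- (p$start[i] %/% 50 + 1):((p$end[i] - 1) %/% 50 + 1)
      expect_true(any(q[[p$chrom[i]]][bins] <= params$q_strong))
    }
  }
})

test_that("raising q_strong never removes called coverage", {
  truth <- small_truth(seed = 22)
  cv <- simulate_coverage(truth, "N1")
  covered_bins <- function(q) {
    ps <- call_peaks(cv$chip, cv$input, calling_params("default", q_strong = q,
                                                       q_weak = max(q, 0.1)), "N1")
    unlist(lapply(seq_len(nrow(ps$peaks)), function(i)
      paste(ps$peaks$chrom[i], seq(ps$peaks$start[i], ps$peaks$end[i] - 1, by = 50))))
  }
  loose <- covered_bins(0.2)
  strict <- covered_bins(0.05)
  expect_true(all(strict %in% loose))
})

test_that("degenerate coverage yields empty peak sets, not errors", {
  zero <- one_chrom_track(rep(0, 1000))
  expect_equal(n_peaks(call_peaks(zero, params = calling_params())), 0)
  empty <- coverage_track(50, setNames(list(), character(0)))
  expect_equal(n_peaks(call_peaks(empty, params = calling_params())), 0)
})

test_that("peak_width_stats equals a sort-based oracle", {
  expect_equal(peak_width_stats(peak_set("s"))$n, 0)
  df <- data.frame(chrom = "chr1", start = c(0, 1000, 10000),
                   end = c(100, 1400, 14000), score = 0)
  st <- peak_width_stats(peak_set("s", df))
  expect_equal(st[c("n", "min", "median", "max")],
               list(n = 3L, min = 100, median = 400, max = 4000))
  withr::local_seed(5)
  for (i in 1:5) {
    d <- random_peaks_df(30, c(chr1 = 1e6))
    w <- sort(d$end - d$start)
    st <- peak_width_stats(peak_set("s", d))
    expect_equal(st$min, w[1])
    expect_equal(st$max, w[length(w)])
    expect_equal(st$median, median(w))
    expect_equal(st$q25, unname(quantile(w, 0.25)))
  }
})
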