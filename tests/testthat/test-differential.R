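# differential: set algebra, relaxed-threshold validation, category runs

test_that("set operations match hand examples and reject bad inputs", {
  sets <- list(t = c("a", "b", "c"), o1 = "b", o2 = "c")
  expect_equal(unique_to_sample(sets, "t", c("o1", "o2")), "a")
  expect_equal(unique_to_sample(list(t = character(0), o = "x"), "t", "o"), character(0))
  expect_error(unique_to_sample(sets, "zz", "o1"), "unknown sample")
  expect_error(unique_to_sample(sets, "t", c("t", "o1")), "must not appear")

  gsets <- list(a = c("a", "b"), b = c("b", "c"), c = "b", z = character(0))
  expect_equal(common_to_group_absent(gsets, c("a", "b", "c"), "z"), "b")
  expect_equal(common_to_group_absent(list(a = "x", b = "x", all = "x"),
                                      c("a", "b"), "all"), character(0))
  expect_error(common_to_group_absent(gsets, character(0), "z"), "non-empty")
  expect_error(common_to_group_absent(gsets, c("a", "b"), "a"), "disjoint")

  expect_equal(cross_reference(c("a", "b"), c("b", "c")), "b")
  expect_equal(cross_reference(c("a", "b"), character(0)), character(0))
  expect_equal(cross_reference(c("a", "b"), c("a", "b", "c")), c("a", "b"))
})

test_that("set operations equal brute-force enumeration on random instances", {
  withr::local_seed(29)
  for (i in 1:25) {
    sets <- random_gene_sets(4)
    expect_equal(unique_to_sample(sets, "s1", c("s2", "s3", "s4")),
                 bf_unique_to(sets, "s1", c("s2", "s3", "s4")))
    expect_equal(common_to_group_absent(sets, c("s2", "s3", "s4"), "s1"),
                 bf_common_absent(sets, c("s2", "s3", "s4"), "s1"))
  }
})

test_that("validate_calls: empty relaxed sets validate everything; missing sets reject", {
  ann <- toy_annotation()
  w <- tss_windows(ann)
  res <- differential_result("normal_only", c("gA1", "gB1"),
                             absent_samples = c("C1", "C2"))
  relaxed <- list(C1 = peak_set("C1"), C2 = peak_set("C2"))
  out <- validate_calls(res, relaxed, w)
  expect_equal(out$validated, c("gA1", "gB1"))
  expect_length(out$flagged_false_positive, 0)
  expect_error(validate_calls(res, relaxed["C1"], w), "missing relaxed")

  # a relaxed peak at gA1's TSS in C1 flags gA1 but not gB1
  relaxed$C1 <- peak_set("C1", data.frame(chrom = "chrA", start = 4500L,
                                          end = 5200L, score = 1))
  out2 <- validate_calls(res, relaxed, w)
  expect_equal(out2$flagged_false_positive, "gA1")
  expect_equal(out2$validated, "gB1")
  expect_setequal(c(out2$validated, out2$flagged_false_positive), res$genes)
})

test_that("noiseless planted normal_only genes are recovered with 0 flagged", {
  truth <- small_truth(seed = 41)
  samples <- truth$design$samples$sample_id
  sheet <- sample_sheet(truth$design$samples)
  windows <- tss_windows(truth$annotation)
  peaks <- setNames(lapply(samples, function(s) truth_to_peaks(truth, s)), samples)
  assignments <- lapply(peaks, assign_tss_peaks, windows = windows)
  m <- gene_mark_matrix(assignments, truth$annotation, samples)
  res <- run_differential(m, sheet, "tss_peaks",
                          relaxed_peaksets = peaks, windows = windows)
  categ <- truth$design$gene_category
  expect_equal(res$normal_only$genes,
               sort(categ$gene_id[categ$category == "normal_only"]))
  expect_equal(res$cancer_common$genes,
               sort(categ$gene_id[categ$category == "cancer_common"]))
  expect_length(res$normal_only$flagged_false_positive, 0)
  expect_length(res$cancer_common$flagged_false_positive, 0)
  # one_cancer genes land in exactly one cancer sample's unique set
  one <- categ$gene_id[categ$category == "one_cancer"]
  uniq <- lapply(c("C1", "C2", "C3"), function(s) res[[paste0("unique_to_", s)]]$genes)
  expect_setequal(unlist(uniq), one)
})

test_that("swapping group labels swaps normal_only and cancer_common", {
  sets <- list(A = c("x", "y", "shared"), B = c("z", "shared"))
  sheet_ab <- sample_sheet(data.frame(sample_id = c("A", "B"),
                                      group = c("normal", "cancer")))
  sheet_ba <- sample_sheet(data.frame(sample_id = c("A", "B"),
                                      group = c("cancer", "normal")))
  r1 <- run_differential(sets, sheet_ab)
  r2 <- run_differential(sets, sheet_ba)
  expect_equal(r1$normal_only$genes, r2$cancer_common$genes)
  expect_equal(r1$cancer_common$genes, r2$normal_only$genes)
})

test_that("a sub-threshold planted mark is flagged by the relaxed pass (20 seeds)", {
  # world: one cancer sample carrying strong marks on half the genes plus one
  # weak (3-fold, 4 kb) broad mark on an otherwise unmarked gene -- the
  # false-positive shape of the broad-domain track inspection; the relaxed
  # re-call at q = 0.2 should see the weak mark in >= 90% of simulations
  ann <- generate_annotation(60, 1, 2e6, seed = 50)
  gd <- default_group_design(fractions = c(all = 0.5, normal_only = 0,
                                           cancer_common = 0, one_cancer = 0))
  des <- plant_marks(ann, gd, seed = 50)
  categ <- des$gene_category
  weak_gene <- categ$gene_id[categ$category == "none"][1]
  tssw <- tss_windows(ann)
  ct <- canonical_tss(ann)
  t0 <- ct$pos[ct$gene_id == weak_gene]
  strand <- ct$strand[ct$gene_id == weak_gene]
  i <- which(des$table$gene_id == weak_gene & des$table$sample_id == "C1")
  des$table$class[i] <- "broad"
  des$table$start[i] <- if (strand == "+") t0 else t0 - 3999L
  des$table$end[i] <- des$table$start[i] + 4000L
  des$table$enrichment[i] <- 3

  flagged <- 0L
  for (seed in 1:20) {
    truth <- synthetic_truth(ann, des, seed = seed,
                             params = list(lambda0 = 2, enrichment = 8,
                                           depth = 1, bin_size = 50))
    cv <- simulate_coverage(truth, "C1", seed = 1000 + seed)
    # broad-mode relaxed re-call: the matching mode for a broad false positive
    relaxed <- call_peaks(cv$chip, cv$input,
                          calling_params("broad", q_strong = 0.2, q_weak = 0.2),
                          "C1")
    res <- validate_calls(
      differential_result("normal_only", weak_gene, absent_samples = "C1"),
      list(C1 = relaxed), tssw)
    flagged <- flagged + (weak_gene %in% res$flagged_false_positive)
  }
  expect_gte(flagged, 18)
})

test_that("run_differential rejects sheets without both groups", {
  sheet <- sample_sheet(data.frame(sample_id = "N1", group = "normal"))
  expect_error(run_differential(list(N1 = "g1"), sheet), "cancer")
})
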