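# Multi-sample set algebra over marked-gene sets, plus the
# relaxed-threshold validation pass that formalizes manual track inspection.

#' Genes unique to one sample
#'
#' @param sets named list, sample_id -> character vector of gene ids.
#' @param target the sample of interest.
#' @param others samples whose genes are subtracted (must not include
#'   `target`).
#' @return `sets[[target]]` minus the union over `others`, sorted.
#' @export
unique_to_sample <- function(sets, target, others) {
  if (!target %in% names(sets)) stop("unknown sample id: ", target)
  miss <- setdiff(others, names(sets))
  if (length(miss)) stop("unknown sample id: ", miss[1])
  if (target %in% others) stop("target must not appear in others")
  sort(setdiff(sets[[target]], Reduce(union, sets[others], character(0))))
}

#' Genes common to one group and absent from another
#'
#' @param sets named list, sample_id -> gene ids.
#' @param group sample ids intersected (non-empty).
#' @param absent_group sample ids whose union is subtracted.
#' @return intersection over `group` minus union over `absent_group`, sorted.
#' @export
common_to_group_absent <- function(sets, group, absent_group) {
  if (!length(group)) stop("group must be non-empty")
  if (length(intersect(group, absent_group)))
    stop("group and absent_group must be disjoint")
  miss <- setdiff(c(group, absent_group), names(sets))
  if (length(miss)) stop("unknown sample id: ", miss[1])
  common <- Reduce(intersect, sets[group])
  sort(setdiff(common, Reduce(union, sets[absent_group], character(0))))
}

#' Intersect candidates with a reference gene set
#'
#' @param candidates character vector of gene ids.
#' @param reference_set character vector (e.g. genes marked in a reference
#'   normal tissue).
#' @return sorted intersection.
#' @export
cross_reference <- function(candidates, reference_set) {
  sort(intersect(candidates, reference_set))
}

#' Construct a differential category result
#'
#' @param category label, e.g. `"normal_only"`, `"cancer_common"` or
#'   `"unique_to_<sample>"`.
#' @param genes gene ids in the category.
#' @param absent_samples sample ids in which the genes are claimed absent
#'   (checked by [validate_calls()]).
#' @return object of class `DifferentialResult` with `validated` initially
#'   equal to `genes` and `flagged_false_positive` empty.
#' @export
differential_result <- function(category, genes, absent_samples = character(0)) {
  genes <- sort(unique(genes))
  structure(list(category = category, genes = genes,
                 absent_samples = absent_samples,
                 validated = genes,
                 flagged_false_positive = character(0)),
            class = "DifferentialResult")
}

#' @export
print.DifferentialResult <- function(x, ...) {
  cat(sprintf("DifferentialResult '%s': %d gene(s), %d validated, %d flagged\n",
              x$category, length(x$genes), length(x$validated),
              length(x$flagged_false_positive)))
  invisible(x)
}

#' Relaxed-threshold validation of a differential category
#'
#' A reproducible surrogate for visual track inspection: a gene is flagged
#' as a false positive iff any sample in which it is claimed absent shows a
#' relaxed-threshold peak overlapping one of the gene's TSS windows;
#' otherwise it is validated.  `validated` and `flagged_false_positive`
#' partition `genes`.
#'
#' @param result a `DifferentialResult` (its `absent_samples` field names
#'   the samples to check).
#' @param relaxed_peaksets named list, sample_id -> `PeakSet` re-called at
#'   the relaxed cutoff (e.g. `q_strong = 0.2`); must cover every absent
#'   sample.
#' @param windows TSS windows from [tss_windows()].
#' @return the result with `validated`/`flagged_false_positive` filled.
#' @export
validate_calls <- function(result, relaxed_peaksets, windows) {
  miss <- setdiff(result$absent_samples, names(relaxed_peaksets))
  if (length(miss)) stop("missing relaxed peak set for absent sample: ", miss[1])
  flagged <- character(0)
  for (s in result$absent_samples) {
    asg <- assign_tss_peaks(relaxed_peaksets[[s]], windows)
    flagged <- union(flagged, intersect(result$genes, names(asg)))
  }
  result$flagged_false_positive <- sort(flagged)
  result$validated <- sort(setdiff(result$genes, flagged))
  result
}

#' Differential presence/absence analysis across sample groups
#'
#' Computes, from per-sample marked-gene sets:
#' \itemize{
#'   \item `normal_only`: genes in every normal sample and no cancer
#'     sample, cross-referenced (intersected) with the union of
#'     reference-normal sets when the sheet has reference samples;
#'   \item `cancer_common`: genes in every cancer sample and absent from
#'     all normal and reference-normal samples;
#'   \item `unique_to_<s>`: for each core (normal or cancer) sample, genes
#'     present only in that sample among the core samples.
#' }
#' When `relaxed_peaksets` (and `windows`) are supplied, every category is
#' passed through [validate_calls()].
#'
#' @param x a `GeneMarkMatrix` (sets = marked genes per sample) or a named
#'   list of per-sample gene-id vectors (e.g. [broad_gene_sets()] output for
#'   the broad-domain mode).
#' @param sheet a `SampleSheet` with at least one normal and one cancer
#'   entry.
#' @param mode `"tss_peaks"` (TSS-marked genes) or `"broad_domains"`
#'   (label only; supply the broad gene sets as `x`).
#' @param relaxed_peaksets optional named list of relaxed-threshold
#'   `PeakSet`s covering all samples.
#' @param windows TSS windows (required with `relaxed_peaksets`).
#' @return named list of `DifferentialResult` objects
#'   (`normal_only`, `cancer_common`, `unique_to_<sample>`...).
#' @export
run_differential <- function(x, sheet, mode = c("tss_peaks", "broad_domains"),
                             relaxed_peaksets = NULL, windows = NULL) {
  mode <- match.arg(mode)
  normals <- samples_in_group(sheet, "normal")
  cancers <- samples_in_group(sheet, "cancer")
  refs <- samples_in_group(sheet, "reference_normal")
  if (!length(normals) || !length(cancers))
    stop("differential stage needs >= 1 normal and >= 1 cancer sample")
  sets <- if (inherits(x, "GeneMarkMatrix")) marked_gene_sets(x) else x
  if (!is.list(sets) || is.null(names(sets)))
    stop("x must be a GeneMarkMatrix or a named list of gene sets")
  core <- c(normals, cancers)
  miss <- setdiff(core, names(sets))
  if (length(miss)) stop("no gene set for sample: ", miss[1])

  normal_only <- common_to_group_absent(sets, normals, cancers)
  if (length(refs) && all(refs %in% names(sets))) {
    ref_set <- Reduce(union, sets[refs], character(0))
    normal_only <- cross_reference(normal_only, ref_set)
  }
  absent_ref <- intersect(refs, names(sets))
  results <- list(
    normal_only = differential_result("normal_only", normal_only,
                                      absent_samples = cancers),
    cancer_common = differential_result(
      "cancer_common",
      common_to_group_absent(sets, cancers, c(normals, absent_ref)),
      absent_samples = c(normals, absent_ref)))
  for (s in core) {
    results[[paste0("unique_to_", s)]] <- differential_result(
      paste0("unique_to_", s),
      unique_to_sample(sets, s, setdiff(core, s)),
      absent_samples = setdiff(core, s))
  }
  if (!is.null(relaxed_peaksets)) {
    if (is.null(windows)) stop("windows are required for validation")
    results <- lapply(results, validate_calls,
                      relaxed_peaksets = relaxed_peaksets, windows = windows)
  }
  results
}

#' Summarize differential results as a data.frame
#'
#' @param results list of `DifferentialResult` from [run_differential()].
#' @return data.frame `category`, `gene_id`, `validated` (logical).
#' @export
differential_table <- function(results) {
  rows <- lapply(results, function(r) {
    if (!length(r$genes))
      return(data.frame(category = character(), gene_id = character(),
                        validated = logical()))
    data.frame(category = r$category, gene_id = r$genes,
               validated = r$genes %in% r$validated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
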