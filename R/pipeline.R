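# Full study-shaped pipeline: simulate or ingest coverage, call peaks in
# both modes, annotate TSSs, select broad domains, run the differential
# analysis with relaxed-threshold validation, compute TSS profiles, and
# write a deterministic manifest.

#' Default run configuration
#'
#' @return nested list of pipeline defaults; see [run_pipeline()] for the
#'   meaning of each field.
#' @export
default_run_config <- function() {
  list(
    seed = 42,
    output_dir = "broadmark_out",
    simulate = NULL,
    input = NULL,
    calling = list(bin_size = 50, q_strong = 0.05, q_weak = 0.10,
                   min_peak_len = 150, broad_gap = 1000),
    window_up = 1000, window_down = 1000,
    broad_fraction = 0.05,
    relaxed_q = 0.2,
    profile_flank = 5000,
    write_tracks = FALSE)
}

#' Demo configuration: the bundled synthetic study
#'
#' One normal cell line, three cancer cell lines and one reference normal
#' tissue over 300 genes on two 5 Mb chromosomes, simulated at background
#' rate 2 fragments per 50 bp bin with 8-fold enrichment inside planted
#' marks, seed 42.
#'
#' @param output_dir where [run_pipeline()] should write its products.
#' @param seed study seed.
#' @return a run-configuration list.
#' @export
demo_config <- function(output_dir = tempfile("broadmark_demo_"), seed = 42) {
  cfg <- default_run_config()
  cfg$seed <- seed
  cfg$output_dir <- output_dir
  cfg$simulate <- list(
    n_genes = 300, n_chroms = 2, chrom_length = 5e6,
    fractions = c(all = 0.40, normal_only = 0.10,
                  cancer_common = 0.05, one_cancer = 0.05),
    narrow_frac = 0.5,
    lambda0 = 2, enrichment = 8, depth = 1,
    samples = data.frame(
      sample_id = c("N1", "C1", "C2", "C3", "REF1"),
      group = c("normal", "cancer", "cancer", "cancer", "reference_normal"),
      stringsAsFactors = FALSE))
  cfg
}

#' Read a run configuration from JSON
#'
#' Fields present in the file override [default_run_config()]; everything
#' else keeps its default.
#'
#' @param path JSON file.
#' @return a run-configuration list.
#' @export
read_run_config <- function(path) {
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- modifyList(default_run_config(), user)
  if (!is.null(cfg$simulate$fractions))
    cfg$simulate$fractions <- unlist(cfg$simulate$fractions)
  if (!is.null(cfg$simulate$samples))
    cfg$simulate$samples <- as.data.frame(cfg$simulate$samples,
                                          stringsAsFactors = FALSE)
  cfg
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    gd <- default_group_design(
      samples = sim$samples %||% default_group_design()$samples,
      fractions = sim$fractions %||% c(all = 0.40, normal_only = 0.10,
                                       cancer_common = 0.05, one_cancer = 0.05),
      narrow_frac = sim$narrow_frac %||% 0.5)
    truth <- simulate_study(
      n_genes = sim$n_genes %||% 300, n_chroms = sim$n_chroms %||% 2,
      chrom_length = sim$chrom_length %||% 5e6,
      gene_spacing = sim$gene_spacing,
      group_design = gd,
      params = list(lambda0 = sim$lambda0 %||% 2,
                    enrichment = sim$enrichment %||% 8,
                    depth = sim$depth %||% 1,
                    bin_size = config$calling$bin_size %||% 50),
      seed = config$seed)
    sheet <- sample_sheet(gd$samples)
    tracks <- setNames(lapply(gd$samples$sample_id, function(s)
      simulate_coverage(truth, s)), gd$samples$sample_id)
    list(annotation = truth$annotation, sheet = sheet, tracks = tracks,
         truth = truth)
  } else if (!is.null(config$input)) {
    inp <- config$input
    annotation <- read_gtf(inp$gtf, inp$chrom_sizes)
    sheet <- read_sample_sheet(inp$sample_sheet)
    bs <- config$calling$bin_size %||% 50
    tracks <- setNames(lapply(seq_len(nrow(sheet$entries)), function(i) {
      e <- sheet$entries[i, ]
      chip <- read_bedgraph(e$chip_path, annotation$chrom_sizes, bs)
      input <- if (!is.na(e$input_path) && nzchar(e$input_path))
        read_bedgraph(e$input_path, annotation$chrom_sizes, bs) else NULL
      list(chip = chip, input = input)
    }), sheet$entries$sample_id)
    list(annotation = annotation, sheet = sheet, tracks = tracks, truth = NULL)
  } else {
    stop("config must define either 'simulate' or 'input'")
  }
}

#' Run the full pipeline
#'
#' Stages: simulate (or ingest) coverage; call peaks per sample in default,
#' broad and relaxed (validation) settings; build TSS windows and the gene
#' mark matrix; select top-fraction broad domains; run the differential
#' analysis in both TSS-peak and broad-domain modes with relaxed-threshold
#' validation; compute per-sample TSS coverage and peak-density profiles;
#' and write every product plus a manifest (parameters, seed, per-stage
#' counts) under `output_dir`.  Reruns with the same configuration are
#' deterministic.
#'
#' @param config a run-configuration list ([demo_config()],
#'   [read_run_config()]) or a path to a JSON configuration.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- modifyList(default_run_config(), config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "peaks"), showWarnings = FALSE)
  dir.create(file.path(out, "broad_sets"), showWarnings = FALSE)
  dir.create(file.path(out, "differential"), showWarnings = FALSE)
  dir.create(file.path(out, "profiles"), showWarnings = FALSE)

  stage_log("inputs", "preparing inputs (seed %d)", config$seed)
  inp <- pipeline_inputs(config)
  sheet <- inp$sheet
  annotation <- inp$annotation
  sample_ids <- sheet$entries$sample_id
  if (!length(samples_in_group(sheet, "normal")) ||
      !length(samples_in_group(sheet, "cancer")))
    stop("differential stage needs >= 1 normal and >= 1 cancer sample")
  stage_log("inputs", "%d samples, %d genes, %d chromosomes",
            length(sample_ids), nrow(annotation$genes),
            length(annotation$chrom_sizes))
  if (isTRUE(config$write_tracks)) {
    dir.create(file.path(out, "tracks"), showWarnings = FALSE)
    for (s in sample_ids) {
      write_bedgraph(inp$tracks[[s]]$chip,
                     file.path(out, "tracks", paste0(s, "_chip.bedgraph")))
      if (!is.null(inp$tracks[[s]]$input))
        write_bedgraph(inp$tracks[[s]]$input,
                       file.path(out, "tracks", paste0(s, "_input.bedgraph")))
    }
  }

  cal <- config$calling
  p_default <- calling_params(mode = "default", bin_size = cal$bin_size,
                              q_strong = cal$q_strong, q_weak = cal$q_weak,
                              min_peak_len = cal$min_peak_len,
                              broad_gap = cal$broad_gap)
  p_broad <- calling_params(mode = "broad", bin_size = cal$bin_size,
                            q_strong = cal$q_strong, q_weak = cal$q_weak,
                            min_peak_len = cal$min_peak_len,
                            broad_gap = cal$broad_gap)
  # validation re-calls match the mode they validate: default-mode relaxed
  # peaks check the TSS-peak categories, broad-mode relaxed peaks the
  # broad-domain categories
  p_relaxed <- calling_params(mode = "default", bin_size = cal$bin_size,
                              q_strong = config$relaxed_q,
                              q_weak = max(config$relaxed_q, cal$q_weak),
                              min_peak_len = cal$min_peak_len,
                              broad_gap = cal$broad_gap)
  p_relaxed_broad <- p_relaxed
  p_relaxed_broad$mode <- "broad"
  default_peaks <- list(); broad_peaks <- list()
  relaxed_peaks <- list(); relaxed_broad_peaks <- list()
  for (s in sample_ids) {
    tr <- inp$tracks[[s]]
    default_peaks[[s]] <- call_peaks(tr$chip, tr$input, p_default, s)
    broad_peaks[[s]] <- call_peaks(tr$chip, tr$input, p_broad, s)
    relaxed_peaks[[s]] <- call_peaks(tr$chip, tr$input, p_relaxed, s)
    relaxed_broad_peaks[[s]] <- call_peaks(tr$chip, tr$input, p_relaxed_broad, s)
    write_peaks(default_peaks[[s]],
                file.path(out, "peaks", paste0(s, ".narrowPeak")), "narrowPeak")
    write_peaks(broad_peaks[[s]],
                file.path(out, "peaks", paste0(s, ".broadPeak")), "broadPeak")
    stage_log("callpeaks", "%s: %d default, %d broad, %d relaxed peaks",
              s, n_peaks(default_peaks[[s]]), n_peaks(broad_peaks[[s]]),
              n_peaks(relaxed_peaks[[s]]))
  }

  windows <- tss_windows(annotation, config$window_up, config$window_down)
  assignments <- lapply(default_peaks, assign_tss_peaks, windows = windows)
  matrix <- gene_mark_matrix(assignments, annotation, sample_ids)
  matrix <- classify_matrix_domains(matrix)
  write_gene_mark_matrix(matrix, file.path(out, "gene_mark_matrix.tsv"))
  stage_log("annotate", "%d TSS windows, %d marked gene-sample cells",
            nrow(windows), sum(matrix$marked))

  broad_calls <- lapply(sample_ids, function(s)
    top_broadest_with_tss(broad_peaks[[s]], annotation, config$broad_fraction))
  names(broad_calls) <- sample_ids
  broad_sets <- setNames(lapply(sample_ids, function(s)
    sort(unique(broad_calls[[s]]$gene_id))), sample_ids)
  for (s in sample_ids) {
    writeLines(broad_sets[[s]], file.path(out, "broad_sets", paste0(s, ".txt")))
    stage_log("broaddomains", "%s: %d genes in top %.3g%% broadest domains",
              s, length(broad_sets[[s]]), 100 * config$broad_fraction)
  }

  diff_tss <- run_differential(matrix, sheet, "tss_peaks",
                               relaxed_peaksets = relaxed_peaks,
                               windows = windows)
  diff_broad <- run_differential(broad_sets, sheet, "broad_domains",
                                 relaxed_peaksets = relaxed_broad_peaks,
                                 windows = windows)
  write.table(differential_table(diff_tss),
              file.path(out, "differential", "tss_peaks.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(differential_table(diff_broad),
              file.path(out, "differential", "broad_domains.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(diff_tss))
    stage_log("differential", "tss %s: %d genes (%d validated)", nm,
              length(diff_tss[[nm]]$genes), length(diff_tss[[nm]]$validated))

  profiles <- list()
  for (s in sample_ids) {
    pr <- tss_profile(inp$tracks[[s]]$chip, annotation,
                      flank = config$profile_flank, bin = cal$bin_size)
    pd <- peak_density_profile(default_peaks[[s]], annotation,
                               flank = config$profile_flank, bin = cal$bin_size)
    write_tss_profile(pr, file.path(out, "profiles", paste0(s, "_coverage.tsv")))
    write_tss_profile(pd, file.path(out, "profiles", paste0(s, "_peak_density.tsv")))
    profiles[[s]] <- list(n_tss = pr$n_tss, n_dropped = pr$n_dropped,
                          max_offset = pr$offsets[which.max(pr$values)])
  }
  stage_log("profile", "profiles written for %d samples", length(sample_ids))

  diff_counts <- function(res) lapply(res, function(r)
    list(n = length(r$genes), validated = length(r$validated),
         flagged = length(r$flagged_false_positive)))
  manifest <- list(
    tool = "broadmark",
    version = as.character(utils::packageVersion("broadmark")),
    seed = config$seed,
    params = list(calling = cal, window_up = config$window_up,
                  window_down = config$window_down,
                  broad_fraction = config$broad_fraction,
                  relaxed_q = config$relaxed_q,
                  simulate = if (!is.null(config$simulate))
                    config$simulate[setdiff(names(config$simulate), "samples")]
                  else NULL),
    samples = sheet$entries[c("sample_id", "group")],
    counts = list(
      genes = nrow(annotation$genes),
      tss = nrow(annotation$tss),
      tss_windows = nrow(windows),
      marked_cells = sum(matrix$marked),
      peaks_default = lapply(default_peaks, n_peaks),
      peaks_broad = lapply(broad_peaks, n_peaks),
      peaks_relaxed = lapply(relaxed_peaks, n_peaks),
      broad_sets = lapply(broad_sets, length),
      differential_tss = diff_counts(diff_tss),
      differential_broad = diff_counts(diff_broad)),
    profiles = profiles)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log("done", "outputs in %s", out)
  invisible(manifest)
}
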