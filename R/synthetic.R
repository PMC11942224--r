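# Synthetic-study generator: toy genomes, planted narrow/broad H3K4me3 mark
# designs, and Poisson ChIP/input coverage.  Everything is deterministic
# under a fixed seed so downstream recovery tests are reproducible.

#' Generate a toy genome annotation
#'
#' Genes are laid out on a regular grid of non-overlapping slots of
#' `gene_spacing` bp, with a jittered start inside each slot, random strand,
#' and 1-3 transcripts whose TSSs lie within 200 bp of the gene 5' end.
#'
#' @param n_genes number of genes.
#' @param n_chroms number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length length of every chromosome (bp).
#' @param gene_spacing slot width per gene (bp); default divides the genome
#'   evenly among the genes.
#' @param seed integer seed; identical inputs give identical annotations.
#' @return a [genome_annotation()].
#' @export
generate_annotation <- function(n_genes = 300, n_chroms = 2,
                                chrom_length = 5e6, gene_spacing = NULL,
                                seed = 1) {
  stopifnot(is_count(n_genes), is_count(n_chroms), n_chroms >= 1,
            chrom_length > 0)
  chrom_sizes <- setNames(rep(chrom_length, n_chroms),
                          paste0("chr", seq_len(n_chroms)))
  if (n_genes == 0) {
    return(genome_annotation(chrom_sizes,
      data.frame(gene_id = character(), gene_name = character(),
                 chrom = character(), strand = character(),
                 start = integer(), end = integer()),
      data.frame(gene_id = character(), chrom = character(),
                 strand = character(), pos = integer())))
  }
  gene_spacing <- gene_spacing %||% floor(n_chroms * chrom_length / n_genes)
  if (gene_spacing < 12000)
    stop("genome too small: gene_spacing must be >= 12000 bp, got ", gene_spacing)
  per_chrom <- chrom_length %/% gene_spacing
  if (per_chrom * n_chroms < n_genes)
    stop("genome too small: ", n_genes, " genes do not fit ",
         n_chroms, " x ", chrom_length, " bp at spacing ", gene_spacing)
  with_seed(seed, {
    chrom_idx <- rep(seq_len(n_chroms), each = per_chrom)[seq_len(n_genes)]
    slot_idx <- (seq_len(n_genes) - 1) %% per_chrom
    slot_start <- slot_idx * gene_spacing
    max_len <- min(20000, gene_spacing - 4000)
    jitter <- floor(runif(n_genes, 1000, 3000))
    len <- floor(runif(n_genes, 5000, max_len))
    start <- slot_start + jitter
    end <- start + len
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(n_genes)),
      gene_name = sprintf("GENE%04d", seq_len(n_genes)),
      chrom = names(chrom_sizes)[chrom_idx],
      strand = strand, start = as.integer(start), end = as.integer(end),
      stringsAsFactors = FALSE)
    n_tx <- sample(1:3, n_genes, replace = TRUE)
    tss <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      off <- c(0, sort(sample(0:200, n_tx[i] - 1, replace = TRUE)))
      pos <- if (strand[i] == "+") start[i] + off else end[i] - 1 - off
      unique(data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                        strand = strand[i], pos = as.integer(pos),
                        stringsAsFactors = FALSE))
    }))
    genome_annotation(chrom_sizes, genes, tss)
  })
}

#' Default group design for a planted study
#'
#' Mirrors the study shape: one normal cell line, three cancer cell lines
#' and one reference normal tissue.  Fractions give the share of genes
#' marked in every sample, only in normal samples, in all cancer samples,
#' and in exactly one cancer sample (round-robin); the remainder of genes
#' carry no mark.  `narrow_frac` is the narrow:broad split inside each
#' category.
#'
#' @param samples data.frame with `sample_id` and `group` columns.
#' @param fractions named numeric vector with entries `all`, `normal_only`,
#'   `cancer_common`, `one_cancer` summing to at most 1.
#' @param narrow_frac fraction of each category's genes receiving a narrow
#'   (rather than broad) mark.
#' @return a list usable as `group_design` in [plant_marks()].
#' @export
default_group_design <- function(
    samples = data.frame(
      sample_id = c("N1", "C1", "C2", "C3", "REF1"),
      group = c("normal", "cancer", "cancer", "cancer", "reference_normal"),
      stringsAsFactors = FALSE),
    fractions = c(all = 0.40, normal_only = 0.10,
                  cancer_common = 0.05, one_cancer = 0.05),
    narrow_frac = 0.5) {
  list(samples = samples, fractions = fractions, narrow_frac = narrow_frac)
}

mark_sample_groups <- function(category, samples) {
  switch(category,
    all = samples$sample_id,
    normal_only = samples$sample_id[samples$group %in% c("normal", "reference_normal")],
    cancer_common = samples$sample_id[samples$group == "cancer"],
    character(0))
}

#' Plant narrow and broad H3K4me3 marks on a toy genome
#'
#' Genes are shuffled (seeded) and assigned to categories in fixed order
#' (`all`, `normal_only`, `cancer_common`, `one_cancer`), each category
#' receiving exactly `floor(fraction * n_genes)` genes; the rest are
#' unmarked.  Within a category the first `floor(narrow_frac * k)` genes get
#' narrow marks (width uniform on [300, 700] bp), the rest broad marks
#' (uniform on [4000, 12000] bp).  Marks start at the gene's canonical TSS
#' and extend downstream (strand-aware) into the gene body, clipped to the
#' chromosome.
#'
#' @param annotation a `GenomeAnnotation`.
#' @param group_design see [default_group_design()].
#' @param seed integer seed.
#' @return object of class `MarkDesign`: list with `table` (data.frame over
#'   the full gene x sample grid: `gene_id`, `sample_id`, `class` in
#'   none/narrow/broad, `start`, `end`, `width`, `offset_from_tss`,
#'   `enrichment` (NA = study default)), `gene_category` (data.frame
#'   `gene_id`, `category`), and the design parameters.
#' @export
plant_marks <- function(annotation, group_design = default_group_design(),
                        seed = 1) {
  samples <- group_design$samples
  fr <- group_design$fractions
  need <- c("all", "normal_only", "cancer_common", "one_cancer")
  fr <- setNames(ifelse(need %in% names(fr), fr[need], 0), need)
  if (sum(fr) > 1 + 1e-9) stop("category fractions sum to more than 1")
  nf <- group_design$narrow_frac %||% 0.5
  genes <- annotation$genes
  n <- nrow(genes)
  cancer_ids <- samples$sample_id[samples$group == "cancer"]
  with_seed(seed, {
    perm <- sample(genes$gene_id)
    counts <- floor(fr * n)
    cat_of <- rep("none", n)
    i <- 1
    for (categ in need) {
      k <- counts[[categ]]
      if (k > 0) cat_of[i:(i + k - 1)] <- categ
      i <- i + k
    }
    gene_category <- data.frame(gene_id = perm, category = cat_of,
                                stringsAsFactors = FALSE)
    ctss <- canonical_tss(annotation)
    rows <- vector("list", n)
    one_cancer_counter <- 0
    for (j in seq_len(n)) {
      gid <- perm[j]
      categ <- cat_of[j]
      if (categ == "none") next
      g <- genes[genes$gene_id == gid, ]
      t0 <- ctss$pos[ctss$gene_id == gid][1]
      idx_in_cat <- sum(cat_of[seq_len(j)] == categ)
      k_cat <- counts[[categ]]
      cls <- if (idx_in_cat <= floor(nf * k_cat)) "narrow" else "broad"
      width <- if (cls == "narrow") round(runif(1, 300, 700)) else round(runif(1, 4000, 12000))
      if (categ == "one_cancer") {
        one_cancer_counter <- one_cancer_counter + 1
        marked_in <- cancer_ids[(one_cancer_counter - 1) %% length(cancer_ids) + 1]
      } else {
        marked_in <- mark_sample_groups(categ, samples)
      }
      if (!length(marked_in)) next  # category has no eligible samples
      chrom_len <- annotation$chrom_sizes[[g$chrom]]
      if (g$strand == "+") {
        s <- t0; e <- min(t0 + width, chrom_len)
      } else {
        s <- max(0, t0 - width + 1); e <- t0 + 1
      }
      rows[[j]] <- data.frame(gene_id = gid, sample_id = marked_in,
                              class = cls, start = as.integer(s),
                              end = as.integer(e),
                              stringsAsFactors = FALSE)
    }
    marked <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    grid <- expand.grid(gene_id = genes$gene_id,
                        sample_id = samples$sample_id,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    if (!is.null(marked)) {
      key <- paste(grid$gene_id, grid$sample_id)
      mkey <- paste(marked$gene_id, marked$sample_id)
      idx <- match(key, mkey)
      grid$class <- ifelse(is.na(idx), "none", marked$class[idx])
      grid$start <- marked$start[idx]
      grid$end <- marked$end[idx]
    } else {
      grid$class <- rep("none", nrow(grid))
      grid$start <- rep(NA_integer_, nrow(grid))
      grid$end <- rep(NA_integer_, nrow(grid))
    }
    grid$width <- grid$end - grid$start
    t_of <- if (nrow(ctss)) ctss$pos[match(grid$gene_id, ctss$gene_id)]
            else rep(NA_integer_, nrow(grid))
    grid$offset_from_tss <- ifelse(grid$class == "none", NA_integer_,
                                   grid$start - t_of)
    grid$enrichment <- rep(NA_real_, nrow(grid))
    structure(list(table = grid, gene_category = gene_category,
                   samples = samples, fractions = fr, narrow_frac = nf,
                   seed = seed),
              class = "MarkDesign")
  })
}

#' Bundle a synthetic study
#'
#' @param annotation a `GenomeAnnotation`.
#' @param design a `MarkDesign` from [plant_marks()].
#' @param seed study seed (drives the coverage simulation).
#' @param params list with `lambda0` (background fragments per bin),
#'   `enrichment` (fold change inside marks), `depth` (global depth
#'   multiplier) and `bin_size` (bp).
#' @return object of class `SyntheticTruth`.
#' @export
synthetic_truth <- function(annotation, design, seed = 1,
                            params = list(lambda0 = 2, enrichment = 8,
                                          depth = 1, bin_size = 50)) {
  stopifnot(params$lambda0 > 0, params$enrichment >= 1, params$depth > 0)
  structure(list(annotation = annotation, design = design, seed = seed,
                 params = params),
            class = "SyntheticTruth")
}

#' One-call synthetic study with the default design
#'
#' @param n_genes,n_chroms,chrom_length,gene_spacing passed to
#'   [generate_annotation()].
#' @param group_design passed to [plant_marks()].
#' @param params passed to [synthetic_truth()].
#' @param seed single study seed (annotation, design and coverage all derive
#'   from it deterministically).
#' @return a `SyntheticTruth`.
#' @export
simulate_study <- function(n_genes = 300, n_chroms = 2, chrom_length = 5e6,
                           gene_spacing = NULL,
                           group_design = default_group_design(),
                           params = list(lambda0 = 2, enrichment = 8,
                                         depth = 1, bin_size = 50),
                           seed = 42) {
  ann <- generate_annotation(n_genes, n_chroms, chrom_length, gene_spacing,
                             seed = seed)
  des <- plant_marks(ann, group_design, seed = seed + 1)
  synthetic_truth(ann, des, seed = seed, params = params)
}

# per-bin enrichment rate vector for one sample on one chromosome
sample_rate_vector <- function(truth, sample_id, chrom, depth) {
  p <- truth$params
  bs <- p$bin_size
  len <- truth$annotation$chrom_sizes[[chrom]]
  nb <- n_bins(len, bs)
  lam <- rep(p$lambda0 * depth, nb)
  tab <- truth$design$table
  rows <- tab[tab$sample_id == sample_id & tab$class != "none", , drop = FALSE]
  if (nrow(rows)) {
    gchrom <- truth$annotation$genes$chrom[match(rows$gene_id,
                                                 truth$annotation$genes$gene_id)]
    rows <- rows[gchrom == chrom, , drop = FALSE]
  }
  for (i in seq_len(nrow(rows))) {
    e <- rows$enrichment[i]
    if (is.na(e)) e <- p$enrichment
    s <- rows$start[i]; en <- rows$end[i]
    b0 <- s %/% bs + 1
    b1 <- min((en - 1) %/% bs + 1, nb)
    frac <- rep(1, b1 - b0 + 1)
    frac[1] <- frac[1] - (s - (b0 - 1) * bs) / bs
    frac[length(frac)] <- frac[length(frac)] - (b1 * bs - en) / bs
    frac[frac < 0] <- 0
    lam[b0:b1] <- lam[b0:b1] + (e - 1) * p$lambda0 * depth * frac
  }
  lam
}

#' Simulate ChIP and input coverage for one sample
#'
#' Input bins are independent Poisson(`lambda0 * depth`) draws.  ChIP bins
#' are Poisson with the same rate outside planted marks and
#' `enrichment * lambda0 * depth` inside; bins partially covered by a mark
#' get a length-interpolated rate.  A fixed seed gives bit-identical tracks.
#'
#' @param truth a `SyntheticTruth`.
#' @param sample_id which sample to simulate.
#' @param depth depth multiplier (defaults to the study's `params$depth`).
#' @param seed seed for this sample's draws (defaults to a value derived
#'   from the study seed and the sample index).
#' @return list with elements `chip` and `input`, both [coverage_track()]s.
#' @export
simulate_coverage <- function(truth, sample_id, depth = NULL, seed = NULL) {
  depth <- depth %||% truth$params$depth
  stopifnot(depth > 0)
  samples <- truth$design$samples$sample_id
  si <- match(sample_id, samples)
  if (is.na(si)) stop("unknown sample_id: ", sample_id)
  seed <- seed %||% ((truth$seed * 131 + si * 7) %% .Machine$integer.max)
  bs <- truth$params$bin_size
  sizes <- truth$annotation$chrom_sizes
  with_seed(seed, {
    chip <- lapply(names(sizes), function(chr)
      rpois(n_bins(sizes[[chr]], bs),
            sample_rate_vector(truth, sample_id, chr, depth)))
    input <- lapply(names(sizes), function(chr)
      rpois(n_bins(sizes[[chr]], bs), truth$params$lambda0 * depth))
    names(chip) <- names(input) <- names(sizes)
    list(chip = coverage_track(bs, chip, sizes),
         input = coverage_track(bs, input, sizes))
  })
}

#' Noiseless peaks from the planted design
#'
#' Converts the planted intervals of one sample directly into a `PeakSet`
#' (score set to the sentinel 1000), bypassing the peak caller, so
#' downstream stages can be tested against exact truth.
#'
#' @param truth a `SyntheticTruth` (or a `MarkDesign`).
#' @param sample_id sample to extract.
#' @return a [peak_set()].
#' @export
truth_to_peaks <- function(truth, sample_id) {
  design <- if (inherits(truth, "SyntheticTruth")) truth$design else truth
  ann <- if (inherits(truth, "SyntheticTruth")) truth$annotation else NULL
  tab <- design$table
  rows <- tab[tab$sample_id == sample_id & tab$class != "none", , drop = FALSE]
  chrom <- if (!is.null(ann)) ann$genes$chrom[match(rows$gene_id, ann$genes$gene_id)]
           else stop("truth_to_peaks needs a SyntheticTruth to resolve chromosomes")
  peak_set(sample_id, data.frame(chrom = chrom, start = rows$start,
                                 end = rows$end, score = 1000,
                                 summit = NA_integer_,
                                 stringsAsFactors = FALSE))
}

#' Write a complete synthetic study to disk
#'
#' Emits GTF, chrom.sizes, a sample sheet, per-sample ChIP/input bedGraphs
#' and a tab-separated truth table (`gene_id`, `sample_id`, `class`,
#' `start`, `end`, `category`), so a full file-based pipeline run needs only
#' generated files.
#'
#' @param truth a `SyntheticTruth`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic_study <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(truth$annotation, file.path(dir, "genes.gtf"))
  write_chrom_sizes(truth$annotation$chrom_sizes, file.path(dir, "chrom.sizes"))
  samples <- truth$design$samples
  entries <- data.frame(sample_id = samples$sample_id, group = samples$group,
                        chip_path = file.path(dir, paste0(samples$sample_id, "_chip.bedgraph")),
                        input_path = file.path(dir, paste0(samples$sample_id, "_input.bedgraph")),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(entries))) {
    cv <- simulate_coverage(truth, entries$sample_id[i])
    write_bedgraph(cv$chip, entries$chip_path[i])
    write_bedgraph(cv$input, entries$input_path[i])
  }
  write_sample_sheet(sample_sheet(entries), file.path(dir, "samples.tsv"))
  tab <- truth$design$table
  tab$category <- truth$design$gene_category$category[
    match(tab$gene_id, truth$design$gene_category$gene_id)]
  write.table(tab[tab$class != "none",
                  c("gene_id", "sample_id", "class", "start", "end", "category")],
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
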