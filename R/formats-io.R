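# Readers and writers for the plain-text genomic formats the pipeline
# touches: GTF (Ensembl dialect), chrom.sizes, BED/narrowPeak/broadPeak,
# bedGraph and the tab-separated sample sheet.  GTF coordinates (1-based
# closed) are converted to the internal 0-based half-open convention on read.

#' Read a two-column chrom.sizes file
#'
#' @param path file with `chrom<TAB>length` rows.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  if (anyDuplicated(df$chrom)) stop("duplicate chromosome in ", path)
  if (any(df$length <= 0)) stop("chromosome length must be positive")
  setNames(df$length, df$chrom)
}

#' Write a chrom.sizes file
#' @param chrom_sizes named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  write.table(data.frame(names(chrom_sizes), format(chrom_sizes, scientific = FALSE, trim = TRUE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
}

#' Read gene models and TSSs from a GTF file
#'
#' Parses `gene` and `transcript` features.  The strand-correct 5' position
#' of every transcript becomes a TSS (deduplicated per gene): for a "+"
#' transcript the 0-based start, for a "-" transcript the last base of the
#' interval.  When the GTF carries no `gene` features, gene extents are the
#' union of each gene's transcripts.
#'
#' @param path GTF file (Ensembl dialect attributes: `gene_id "x"; ...`).
#' @param chrom_sizes_path two-column chrom.sizes file.
#' @return a [genome_annotation()] object.
#' @export
read_gtf <- function(path, chrom_sizes_path) {
  chrom_sizes <- read_chrom_sizes(chrom_sizes_path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  if (!length(lineno)) {
    return(genome_annotation(chrom_sizes,
      data.frame(gene_id = character(), gene_name = character(),
                 chrom = character(), strand = character(),
                 start = integer(), end = integer()),
      data.frame(gene_id = character(), chrom = character(),
                 strand = character(), pos = integer())))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) stop_line(lineno[nf < 9][1], "expected 9 tab-separated GTF fields")
  tab <- data.frame(
    chrom = vapply(fields, `[[`, character(1), 1),
    feature = vapply(fields, `[[`, character(1), 3),
    start1 = as.integer(vapply(fields, `[[`, character(1), 4)),
    end1 = as.integer(vapply(fields, `[[`, character(1), 5)),
    strand = vapply(fields, `[[`, character(1), 7),
    attrs = vapply(fields, `[[`, character(1), 9),
    line = lineno, stringsAsFactors = FALSE)
  tab <- tab[tab$feature %in% c("gene", "transcript"), , drop = FALSE]
  bad <- !(tab$chrom %in% names(chrom_sizes))
  if (any(bad)) stop_line(tab$line[bad][1], "unknown chromosome '%s'", tab$chrom[bad][1])
  if (!all(tab$strand %in% c("+", "-")))
    stop_line(tab$line[!tab$strand %in% c("+", "-")][1], "strand must be '+' or '-'")
  tab$gene_id <- gtf_attr(tab$attrs, "gene_id")
  miss <- is.na(tab$gene_id)
  if (any(miss)) stop_line(tab$line[miss][1], "feature lacks a gene_id attribute")
  tab$gene_name <- gtf_attr(tab$attrs, "gene_name")
  # 1-based closed -> 0-based half-open
  tab$start <- tab$start1 - 1L
  tab$end <- tab$end1

  tx <- tab[tab$feature == "transcript", , drop = FALSE]
  gn <- tab[tab$feature == "gene", , drop = FALSE]
  if (nrow(gn)) {
    orphan <- !(tx$gene_id %in% gn$gene_id)
    if (any(orphan))
      stop_line(tx$line[orphan][1], "transcript without parent gene '%s'",
                tx$gene_id[orphan][1])
  }
  # transcripts without an explicit gene feature define the gene extent
  if (nrow(tx)) {
    agg <- do.call(rbind, lapply(split(tx, tx$gene_id), function(d) {
      data.frame(gene_id = d$gene_id[1],
                 gene_name = d$gene_name[1], chrom = d$chrom[1],
                 strand = d$strand[1], start = min(d$start), end = max(d$end),
                 stringsAsFactors = FALSE)
    }))
  } else {
    agg <- NULL
  }
  if (nrow(gn)) {
    genes <- gn[c("gene_id", "gene_name", "chrom", "strand", "start", "end")]
    extra <- agg[!agg$gene_id %in% genes$gene_id, , drop = FALSE]
    genes <- rbind(genes, extra)
  } else {
    genes <- agg
    if (is.null(genes))
      genes <- data.frame(gene_id = character(), gene_name = character(),
                          chrom = character(), strand = character(),
                          start = integer(), end = integer())
  }
  genes$gene_name <- ifelse(is.na(genes$gene_name), genes$gene_id, genes$gene_name)
  genes <- genes[order_genomic(genes$chrom, genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL

  if (nrow(tx)) {
    tx$pos <- ifelse(tx$strand == "+", tx$start, tx$end - 1L)
    tss <- unique(tx[c("gene_id", "chrom", "strand", "pos")])
  } else {
    tss <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), pos = integer())
  }
  tss <- tss[order_genomic(tss$chrom, tss$pos), , drop = FALSE]
  rownames(tss) <- NULL
  genome_annotation(chrom_sizes, genes, tss)
}

#' Write a GenomeAnnotation as GTF
#'
#' Emits one `gene` feature per gene and one `transcript` feature per
#' distinct TSS (spanning TSS to gene 3' end), converting back to 1-based
#' closed coordinates, so `read_gtf()` round-trips genes and TSS sets.
#'
#' @param annotation a `GenomeAnnotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  genes <- annotation$genes
  tss <- annotation$tss
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attr_g <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$gene_name)
    writeLines(sprintf("%s\tbroadmark\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       g$chrom, g$start + 1L, g$end, g$strand, attr_g), con)
    gt <- tss[tss$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(gt))) {
      pos <- gt$pos[j]
      if (g$strand == "+") { s1 <- pos + 1L; e1 <- g$end } else { s1 <- g$start + 1L; e1 <- pos + 1L }
      writeLines(sprintf('%s\tbroadmark\ttranscript\t%d\t%d\t.\t%s\t.\t%s transcript_id "%s.t%d";',
                         g$chrom, s1, e1, g$strand, attr_g, g$gene_id, j), con)
    }
  }
  invisible(path)
}

peak_dialects <- c("bed", "narrowPeak", "broadPeak")

#' Read peaks from a BED-family file
#'
#' Supported dialects: plain BED (3+ columns), ENCODE narrowPeak (10
#' columns) and broadPeak (9 columns).  The peak score is taken from the
#' qValue column (column 9, a -log10 adjusted significance) when present and
#' not -1, otherwise from the BED score column divided by 10 (the usual
#' 0-1000 encoding of 10 x -log10 q).  narrowPeak column 10 maps to the
#' summit offset; -1 means absent.
#'
#' @param path input file; an empty file yields an empty `PeakSet`.
#' @param dialect one of `"bed"`, `"narrowPeak"`, `"broadPeak"`.
#' @param sample_id sample id for the resulting set; defaults to the file
#'   name without extension.
#' @return a [peak_set()].
#' @export
read_peaks <- function(path, dialect = c("bed", "narrowPeak", "broadPeak"),
                       sample_id = NULL) {
  dialect <- match.arg(dialect)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) return(peak_set(sample_id))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- switch(dialect, bed = 3L, narrowPeak = 10L, broadPeak = 9L)
  if (dialect == "bed") {
    if (any(nf < 3L)) stop_line(which(nf < 3L)[1], "BED needs >= 3 columns")
    if (length(unique(nf)) != 1)
      stop_line(which(nf != nf[1])[1], "inconsistent column count")
  } else if (any(nf != need)) {
    stop_line(which(nf != need)[1], "%s needs exactly %d columns, found %d",
              dialect, need, nf[nf != need][1])
  }
  col <- function(i) vapply(fields, function(x) if (length(x) >= i) x[[i]] else NA_character_, character(1))
  chrom <- col(1)
  start <- as.integer(col(2))
  end <- as.integer(col(3))
  bad <- start >= end
  if (any(bad)) stop_line(which(bad)[1], "start >= end")
  score5 <- if (all(nf >= 5)) suppressWarnings(as.numeric(col(5))) else rep(0, length(chrom))
  score5[is.na(score5)] <- 0
  if (dialect == "bed") {
    score <- score5 / 10
    summit <- rep(NA_integer_, length(chrom))
  } else {
    qv <- as.numeric(col(9))
    score <- ifelse(qv >= 0, qv, score5 / 10)
    summit <- if (dialect == "narrowPeak") {
      s <- as.integer(col(10)); s[s < 0] <- NA_integer_; s
    } else rep(NA_integer_, length(chrom))
  }
  peak_set(sample_id, data.frame(chrom = chrom, start = start, end = end,
                                 score = score, summit = summit,
                                 stringsAsFactors = FALSE))
}

#' Write peaks to a BED-family file
#'
#' narrowPeak is the lossless carrier: the qValue column keeps full double
#' precision so `read_peaks(write_peaks(x))` reproduces intervals, scores and
#' summits bit-exactly.  broadPeak drops summits silently (the dialect has no
#' summit column); plain BED encodes the score as `round(10 * score)` capped
#' at 1000 and is therefore lossy for scores.
#'
#' @param peakset a `PeakSet`.
#' @param path output path.
#' @param dialect one of `"bed"`, `"narrowPeak"`, `"broadPeak"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peakset, path, dialect = c("bed", "narrowPeak", "broadPeak")) {
  dialect <- match.arg(dialect)
  p <- peakset$peaks
  if (!nrow(p)) { file.create(path); return(invisible(path)) }
  name <- sprintf("%s_peak_%d", peakset$sample_id, seq_len(nrow(p)))
  score5 <- pmin(1000L, as.integer(round(10 * p$score)))
  qcol <- sprintf("%.17g", p$score)
  rows <- switch(dialect,
    bed = sprintf("%s\t%d\t%d\t%s\t%d\t.", p$chrom, p$start, p$end, name, score5),
    broadPeak = sprintf("%s\t%d\t%d\t%s\t%d\t.\t0\t-1\t%s",
                        p$chrom, p$start, p$end, name, score5, qcol),
    narrowPeak = sprintf("%s\t%d\t%d\t%s\t%d\t.\t0\t-1\t%s\t%d",
                         p$chrom, p$start, p$end, name, score5, qcol,
                         ifelse(is.na(p$summit), -1L, p$summit)))
  writeLines(rows, path)
  invisible(path)
}

#' Read a bedGraph into a binned coverage track
#'
#' Interval values are interpreted as per-bin fragment counts.  Intervals
#' aligned to bin boundaries are copied; unaligned intervals are re-binned
#' with length weighting (each bin receives `value * overlap / bin_size`).
#' Bins not covered by any interval are zero.
#'
#' @param path bedGraph file (`chrom start end value`).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bin_size target bin width (bp).
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, chrom_sizes, bin_size = 50) {
  counts <- lapply(chrom_sizes, function(len) numeric(n_bins(len, bin_size)))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    chrom <- vapply(fields, `[[`, character(1), 1)
    start <- as.numeric(vapply(fields, `[[`, character(1), 2))
    end <- as.numeric(vapply(fields, `[[`, character(1), 3))
    value <- as.numeric(vapply(fields, `[[`, character(1), 4))
    if (any(value < 0)) stop_line(which(value < 0)[1], "negative bedGraph value")
    if (any(!chrom %in% names(chrom_sizes)))
      stop_line(which(!chrom %in% names(chrom_sizes))[1], "unknown chromosome")
    for (i in seq_along(chrom)) {
      v <- value[i]
      if (v == 0) next
      s <- start[i]; e <- end[i]
      b0 <- s %/% bin_size + 1
      b1 <- (e - 1) %/% bin_size + 1
      cv <- counts[[chrom[i]]]
      if (b1 > length(cv)) stop_line(i, "interval past chromosome end")
      len <- chrom_sizes[[chrom[i]]]
      # a chromosome's final bin may be shorter than bin_size; overlaps are
      # normalized by the true bin width so truncated bins round-trip
      bin_width <- function(b) min(bin_size, len - (b - 1) * bin_size)
      if (b0 == b1) {
        cv[b0] <- cv[b0] + v * (e - s) / bin_width(b0)
      } else {
        cv[b0] <- cv[b0] + v * (b0 * bin_size - s) / bin_width(b0)
        cv[b1] <- cv[b1] + v * (e - (b1 - 1) * bin_size) / bin_width(b1)
        if (b1 > b0 + 1) {
          mid <- (b0 + 1):(b1 - 1)
          cv[mid] <- cv[mid] + v
        }
      }
      counts[[chrom[i]]] <- cv
    }
  }
  coverage_track(bin_size, counts, chrom_sizes)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal bin values are collapsed into single intervals; zero-valued
#' runs are omitted (readers fill them back in).
#'
#' @param track a `CoverageTrack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (chr in names(track$counts)) {
    v <- track$counts[[chr]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    chrom_len <- if (!is.null(track$chrom_sizes)) track$chrom_sizes[[chr]] else length(v) * bs
    writeLines(sprintf("%s\t%s\t%s\t%s", chr,
                       format(starts[keep] * bs, scientific = FALSE, trim = TRUE),
                       format(pmin(ends[keep] * bs, chrom_len), scientific = FALSE, trim = TRUE),
                       format(r$values[keep], scientific = FALSE, trim = TRUE)), con)
  }
  invisible(path)
}

#' Read a tab-separated sample sheet
#'
#' Expected header columns: `sample_id`, `group` and optionally `chip_path`,
#' `input_path`.  Groups must be `normal`, `cancer` or `reference_normal`;
#' sample ids must be unique.
#'
#' @param path TSV file.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  sample_sheet(df)
}

#' Write a sample sheet as TSV
#' @param sheet a `SampleSheet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet$entries, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}
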