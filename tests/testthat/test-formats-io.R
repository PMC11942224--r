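# formats_io: GTF / BED-family / bedGraph / sample-sheet readers and writers

test_that("read_gtf converts 1-based closed GTF to 0-based half-open, both strands", {
  sizes <- withr::local_tempfile(lines = "chr1\t100000")
  gtf <- withr::local_tempfile(lines = c(
    'chr1\tx\ttranscript\t101\t500\t.\t+\t.\tgene_id "g1";',
    'chr1\tx\ttranscript\t101\t500\t.\t+\t.\tgene_id "g1";',
    'chr1\tx\ttranscript\t101\t500\t.\t-\t.\tgene_id "g2";'))
  ann <- read_gtf(gtf, sizes)
  expect_setequal(ann$genes$gene_id, c("g1", "g2"))
  g1 <- ann$tss[ann$tss$gene_id == "g1", ]
  g2 <- ann$tss[ann$tss$gene_id == "g2", ]
  expect_equal(g1$pos, 100)          # plus strand: interval start, 0-based
  expect_equal(nrow(g1), 1)          # identical TSSs collapse
  expect_equal(g2$pos, 499)          # minus strand: last base of interval
  expect_equal(ann$genes$start[ann$genes$gene_id == "g1"], 100)
  expect_equal(ann$genes$end[ann$genes$gene_id == "g1"], 500)
})

test_that("read_gtf rejects unknown chromosomes (with line number) and orphan transcripts", {
  sizes <- withr::local_tempfile(lines = "chr1\t100000")
  bad_chrom <- withr::local_tempfile(lines = c(
    'chr1\tx\ttranscript\t101\t500\t.\t+\t.\tgene_id "g1";',
    'chr9\tx\ttranscript\t101\t500\t.\t+\t.\tgene_id "g2";'))
  expect_error(read_gtf(bad_chrom, sizes), "line 2.*chr9")
  orphan <- withr::local_tempfile(lines = c(
    'chr1\tx\tgene\t101\t500\t.\t+\t.\tgene_id "g1";',
    'chr1\tx\ttranscript\t101\t500\t.\t+\t.\tgene_id "gX";'))
  expect_error(read_gtf(orphan, sizes), "without parent gene")
})

test_that("GTF writer round-trips genes and TSS sets", {
  ann <- toy_annotation()
  gtf <- withr::local_tempfile()
  sizes <- withr::local_tempfile()
  write_gtf(ann, gtf)
  write_chrom_sizes(ann$chrom_sizes, sizes)
  back <- read_gtf(gtf, sizes)
  expect_equal(back$genes[order(back$genes$gene_id), c("gene_id", "chrom", "strand", "start", "end")],
               ann$genes[order(ann$genes$gene_id), c("gene_id", "chrom", "strand", "start", "end")],
               ignore_attr = TRUE)
  key <- function(tss) sort(paste(tss$gene_id, tss$pos))
  expect_equal(key(back$tss), key(ann$tss))
})

test_that("read_peaks maps dialect columns, sorts, and handles empty files", {
  f <- withr::local_tempfile(lines = character(0))
  expect_equal(n_peaks(read_peaks(f, "narrowPeak")), 0)

  np <- withr::local_tempfile(lines = c(
    "chr2\t100\t700\tp2\t0\t.\t5.0\t4.0\t3.0\t250",
    "chr1\t900\t1200\tp1b\t0\t.\t5.0\t4.0\t2.0\t-1",
    "chr1\t100\t700\tp1\t0\t.\t5.0\t4.0\t3.5\t250"))
  ps <- read_peaks(np, "narrowPeak")
  expect_equal(ps$peaks$chrom, c("chr1", "chr1", "chr2"))   # sorted
  expect_equal(ps$peaks$start, c(100, 900, 100))
  expect_equal(ps$peaks$score, c(3.5, 2.0, 3.0))            # qValue column
  expect_equal(ps$peaks$summit, c(250L, NA, 250L))          # -1 -> absent

  bed <- withr::local_tempfile(lines = "chr1\t100\t700\tp\t55\t.")
  expect_equal(read_peaks(bed, "bed")$peaks$score, 5.5)     # score column / 10
})

test_that("read_peaks rejects malformed rows with line numbers", {
  bad_cols <- withr::local_tempfile(lines = c(
    "chr1\t100\t700\tp1\t0\t.\t5\t4\t3\t250",
    "chr1\t100\t700\tp1\t0"))
  expect_error(read_peaks(bad_cols, "narrowPeak"), "line 2")
  bad_coords <- withr::local_tempfile(lines = "chr1\t700\t700\tp\t0\t.\t0\t-1\t1\t-1")
  expect_error(read_peaks(bad_coords, "narrowPeak"), "line 1.*start >= end")
})

test_that("write_peaks/read_peaks round-trip is bit-exact for narrowPeak and broadPeak", {
  withr::local_seed(11)
  sizes <- c(chr1 = 2e5, chr2 = 1e5)
  for (rep in 1:10) {
    df <- random_peaks_df(20, sizes)
    with_summit <- runif(nrow(df)) < 0.5
    df$summit[with_summit] <- floor(runif(sum(with_summit)) * (df$end - df$start)[with_summit])
    ps <- peak_set("s1", df)
    f_np <- withr::local_tempfile()
    write_peaks(ps, f_np, "narrowPeak")
    back <- read_peaks(f_np, "narrowPeak", "s1")
    expect_identical(back$peaks, ps$peaks)
    ps_nosummit <- peak_set("s1", transform(df, summit = NA_integer_))
    f_bp <- withr::local_tempfile()
    write_peaks(ps_nosummit, f_bp, "broadPeak")  # summits silently dropped
    expect_identical(read_peaks(f_bp, "broadPeak", "s1")$peaks, ps_nosummit$peaks)
  }
  # empty set -> empty file -> empty set
  f <- withr::local_tempfile()
  write_peaks(peak_set("s1"), f, "narrowPeak")
  expect_equal(n_peaks(read_peaks(f, "narrowPeak")), 0)
})

test_that("bedGraph reading bins, re-bins with length weighting, and rejects negatives", {
  sizes <- c(chr1 = 100)
  f <- withr::local_tempfile(lines = "chr1\t0\t100\t0")
  expect_equal(read_bedgraph(f, sizes, 50)$counts$chr1, c(0, 0))

  f2 <- withr::local_tempfile(lines = c("chr1\t0\t50\t3", "chr1\t50\t100\t7"))
  tr <- read_bedgraph(f2, sizes, 50)
  expect_equal(tr$counts$chr1, c(3, 7))
  expect_equal(tr$total_fragments, 10)

  f3 <- withr::local_tempfile(lines = "chr1\t0\t100\t4")
  expect_equal(read_bedgraph(f3, sizes, 50)$counts$chr1, c(4, 4))

  # unaligned interval: value length-weighted into both bins
  f4 <- withr::local_tempfile(lines = "chr1\t25\t75\t2")
  expect_equal(read_bedgraph(f4, sizes, 50)$counts$chr1, c(1, 1))

  f5 <- withr::local_tempfile(lines = "chr1\t0\t50\t-1")
  expect_error(read_bedgraph(f5, sizes, 50), "negative")
})

test_that("bedGraph writer round-trips binned tracks (zero runs omitted)", {
  withr::local_seed(3)
  sizes <- c(chr1 = 5000, chr2 = 2130)  # chr2 has a truncated last bin
  counts <- lapply(sizes, function(len) rpois(ceiling(len / 50), 1))
  tr <- coverage_track(50, counts, sizes)
  f <- withr::local_tempfile()
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, sizes, 50)
  expect_equal(back$counts, tr$counts)
  expect_equal(back$total_fragments, tr$total_fragments)
})

test_that("sample sheets validate groups and uniqueness", {
  ok <- withr::local_tempfile(lines = c(
    "sample_id\tgroup\tchip_path\tinput_path",
    "N1\tnormal\tn1.bg\tn1i.bg",
    "C1\tcancer\tc1.bg\t",
    "C2\tcancer\tc2.bg\tc2i.bg",
    "C3\tcancer\tc3.bg\tc3i.bg",
    "REF1\treference_normal\tref.bg\t"))
  sheet <- read_sample_sheet(ok)
  expect_equal(nrow(sheet$entries), 5)
  expect_true(is.na(sheet$entries$input_path[2]))  # empty path -> NA
  expect_equal(samples_in_group(sheet, "cancer"), c("C1", "C2", "C3"))

  dup <- withr::local_tempfile(lines = c("sample_id\tgroup", "a\tnormal", "a\tcancer"))
  expect_error(read_sample_sheet(dup), "duplicate sample_id")
  badgrp <- withr::local_tempfile(lines = c("sample_id\tgroup", "a\ttumour"))
  expect_error(read_sample_sheet(badgrp), "unknown group")

  # cancer-only sheet is accepted here but rejected by the differential stage
  conly <- sample_sheet(data.frame(sample_id = "C1", group = "cancer"))
  expect_error(run_differential(list(C1 = "g1"), conly), "normal")
})
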