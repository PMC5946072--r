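test_that("BED12 coordinate arithmetic follows the half-open convention", {
  # single exon chr1 [100,600) +, CDS (thick) [200,500)
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t600\ttxA\t0\t+\t200\t500\t0\t1\t500,\t0,", tf)
  m <- read_transcript_models(tf, "bed12")[[1]]
  expect_equal(m$tx_length, 500L)
  expect_equal(m$cds_start, 100L)
  expect_equal(m$cds_end, 400L)
  expect_equal(m$biotype, "protein_coding")
})

test_that("minus-strand exons are reported 5'->3' (rightmost genomic first)", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t400\ttxB\t0\t-\t100\t100\t0\t2\t100,100\t0,200", tf)
  m <- read_transcript_models(tf, "bed12")[[1]]
  expect_equal(m$exons$start, c(300L, 100L))
  expect_equal(m$exons$end, c(400L, 200L))
  expect_true(is.na(m$cds_start))
})

test_that("GTF CDS spanning exons projects to contiguous transcript space", {
  tf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tt\texon\t101\t250\t.\t+\t.\tgene_id "gA"; transcript_id "tx1"; gene_biotype "protein_coding";',
    'chr1\tt\texon\t401\t600\t.\t+\t.\tgene_id "gA"; transcript_id "tx1";',
    'chr1\tt\tCDS\t201\t250\t.\t+\t.\tgene_id "gA"; transcript_id "tx1";',
    'chr1\tt\tCDS\t401\t500\t.\t+\t.\tgene_id "gA"; transcript_id "tx1";'), tf)
  m <- read_transcript_models(tf, "gtf")[[1]]
  expect_equal(m$tx_length, 350L)
  # transcript-space CDS length equals the summed CDS chunk lengths
  expect_equal(m$cds_end - m$cds_start, 50L + 100L)
  # cross-check both CDS boundaries with the per-base projection oracle
  or <- oracle_project(list(chrom = "chr1", start = 200L, end = 500L,
                            strand = "+"), m)
  expect_equal(unname(c(m$cds_start, m$cds_end)), unname(or))
})

test_that("genomic_to_transcript matches the per-base enumeration oracle", {
  set.seed(41)
  for (rep in 1:12) {
    m <- random_model(n_exons = sample(1:5, 1))
    span <- range(m$exons$start, m$exons$end)
    for (k in 1:50) {
      s <- sample(seq(span[1] - 100L, span[2] + 100L), 1L)
      iv <- list(chrom = "chrT", start = s,
                 end = s + sample.int(400L, 1L), strand = m$strand)
      got <- genomic_to_transcript(iv, m)
      want <- oracle_project(iv, m)
      expect_equal(got, want)
      if (!is.null(got)) {
        # projection never longer than the interval; equal iff fully exonic
        expect_lte(got[["end"]] - got[["start"]], iv$end - iv$start)
      }
    }
  }
})

test_that("projection is injective per exonic base and inverts cleanly", {
  set.seed(42)
  m <- random_model(n_exons = 4L)
  bmap <- oracle_base_map(m)
  tx_pos <- vapply(bmap, function(g) {
    genomic_to_transcript(list(chrom = "chrT", start = g, end = g + 1L,
                               strand = m$strand), m)[["start"]]
  }, integer(1))
  expect_equal(tx_pos, seq_along(bmap) - 1L)   # injective and ordered
  expect_false(anyDuplicated(tx_pos) > 0)
  # transcript_to_genomic inverts a single-exon slice
  sl <- transcript_to_genomic(m, 10L, 40L)
  back <- genomic_to_transcript(
    list(chrom = "chrT", start = min(sl$start), end = max(sl$end),
         strand = m$strand), m)
  expect_equal(unname(back), c(10L, 40L))
})

test_that("intronic and mismatched intervals project to nothing", {
  m <- transcript_model("t1", "chr1", "+",
                        data.frame(start = c(100, 300), end = c(200, 400)))
  expect_null(genomic_to_transcript(
    list(chrom = "chr1", start = 210L, end = 290L, strand = "+"), m))
  expect_null(genomic_to_transcript(
    list(chrom = "chr2", start = 110L, end = 150L, strand = "+"), m))
  expect_null(genomic_to_transcript(
    list(chrom = "chr1", start = 110L, end = 150L, strand = "-"), m))
  # exon 1 of a 2-exon plus-strand transcript maps to [0, len(exon1))
  expect_equal(unname(genomic_to_transcript(
    list(chrom = "chr1", start = 100L, end = 200L, strand = "+"), m)),
    c(0L, 100L))
})

test_that("BED12 write/read round-trips transcript models exactly", {
  cfg <- sim_config(seed = 11, n_transcripts = 30L,
                    n_shared_sites = 10L, n_young_only = 3L, n_old_only = 2L)
  sim <- simulate_transcriptome(cfg)
  tf <- withr::local_tempfile(fileext = ".bed")
  write_transcript_bed12(sim$models, tf)
  back <- read_transcript_models(tf, "bed12")
  ord <- order(names(sim$models))
  expect_identical(lapply(sim$models, unclass)[ord],
                   lapply(back, unclass)[order(names(back))])
})

test_that("malformed annotation input fails with a parse error", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\tnot_a_number\t600\ttx\t0\t+", tf)
  expect_error(read_transcript_models(tf, "bed12"))
  expect_error(transcript_model("t", "chr1", "+",
                                data.frame(start = 100, end = 50)))
  expect_error(transcript_model("t", "chr1", "+",
                                data.frame(start = c(0, 50), end = c(60, 100))),
               "overlap")
  expect_error(transcript_model("t", "chr1", "+",
                                data.frame(start = 0, end = 100),
                                cds_start = 50, cds_end = 150), "CDS")
})

test_that("gene sets are read as deduplicated ID sets", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "A", "B", "B", "", "  ", "C # trailing"), tf)
  expect_setequal(read_gene_set(tf), c("A", "B", "C"))

  tf2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# only", "# comments"), tf2)
  expect_warning(gs <- read_gene_set(tf2), "no IDs")
  expect_length(gs, 0L)

  set.seed(7)
  ids <- sprintf("G%04d", sample.int(500L, 1000L, replace = TRUE))
  tf3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(ids, tf3)
  expect_setequal(read_gene_set(tf3), unique(ids))
})
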