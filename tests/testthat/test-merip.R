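make_windows <- function(ip, input, start = NULL, width = 50L,
                         chrom = "chr1", strand = "+", tx = NULL) {
  n <- length(ip)
  if (is.null(start)) start <- seq(0L, by = 25L, length.out = n)
  w <- tibble::tibble(chrom = chrom, start = as.integer(start),
                      end = as.integer(start + width), strand = strand,
                      ip_count = ip, input_count = input)
  if (!is.null(tx)) w$transcript_id <- tx
  w
}

test_that("a strongly enriched window is called with a tiny tail p", {
  w <- make_windows(ip = c(100, 10, 9), input = c(10, 10, 10),
                    start = c(0, 1000, 2000))
  s <- call_m6a_sites(w, ip_libsize = 1e6, input_libsize = 1e6,
                      pseudocount = 0.5, dispersion = 0,
                      smooth_background = FALSE)
  expect_equal(nrow(s), 1L)
  expect_equal(s$enrichment, 100.5 / 10.5, tolerance = 1e-12)
  expect_lt(s$pvalue, 1e-10)
  # independent exact Poisson tail oracle bounds the call from below:
  # even the pure-Poisson tail admits this extreme a count
  expect_lt(ppois(99, 10.5, lower.tail = FALSE), 1e-10)
})

test_that("unenriched or empty count profiles yield no sites", {
  w <- make_windows(ip = rep(10, 20), input = rep(10, 20))
  expect_equal(nrow(call_m6a_sites(w, 1e6, 1e6)), 0L)
  w0 <- make_windows(ip = rep(0, 20), input = rep(0, 20))
  expect_equal(nrow(call_m6a_sites(w0, 1e6, 1e6)), 0L)
  expect_equal(nrow(call_m6a_sites(w[0, ], 1e6, 1e6)), 0L)
  expect_error(call_m6a_sites(w, 0, 1e6), "positive")
})

test_that("site calls are monotone in the q threshold and never overlap", {
  set.seed(101)
  n <- 400L
  ip <- rnbinom(n, mu = ifelse(seq_len(n) %% 20 == 0, 90, 10), size = 10)
  input <- rnbinom(n, mu = 10, size = 10)
  w <- make_windows(ip, input)
  counts <- vapply(c(1e-6, 0.01, 0.05, 0.5, 0.999),
                   function(q) nrow(call_m6a_sites(w, 1e6, 1e6, q_threshold = q)),
                   integer(1))
  expect_true(all(diff(counts) >= 0L))
  s <- call_m6a_sites(w, 1e6, 1e6, q_threshold = 0.999)
  if (nrow(s) > 1L) {
    o <- order(s$start)
    expect_true(all(s$start[o][-1L] >= s$end[o][-nrow(s)]))
  }
})

test_that("adjacent significant windows merge into one site carrying the best window", {
  # three overlapping hot windows, one isolated cold window
  w <- make_windows(ip = c(80, 120, 90, 10), input = c(10, 10, 10, 10),
                    start = c(0, 25, 50, 5000))
  s <- call_m6a_sites(w, 1e6, 1e6)
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 0L)
  expect_equal(s$end, 100L)
  expect_equal(s$n_windows, 3L)
  expect_equal(s$ip_count, 120)        # max-window counts
  expect_equal(s$n_fragments, 80 + 120 + 90)
})

test_that("motif classification follows longest-match priority", {
  expect_equal(classify_motif("AAGGACUAA"), "GGACU")
  expect_equal(classify_motif("AAGACUAA"), "GACU")
  expect_equal(classify_motif("UUUUU"), "none")
  expect_equal(classify_motif(""), "none")
  # T is read as U; case-insensitive; idempotent under repetition
  expect_equal(classify_motif("aaggactaa"), "GGACU")
  expect_equal(classify_motif(c("GACUGGACU", "ACUACU", "GACGAC")),
               c("GGACU", "ACU", "GAC"))
})

test_that("motif classes agree with the substring-enumeration oracle", {
  set.seed(33)
  seqs <- vapply(1:200, function(i) {
    paste(sample(c("A", "C", "G", "U"), 120, replace = TRUE), collapse = "")
  }, character(1))
  expect_equal(classify_motif(seqs), vapply(seqs, oracle_motif, character(1),
                                            USE.NAMES = FALSE))
  # hierarchy consistency: a GGACU sequence contains GACU and ACU
  gg <- seqs[classify_motif(seqs) == "GGACU"]
  expect_true(all(grepl("GACU", gg) & grepl("ACU", gg)))
})

test_that("FPKM closed form and scale invariance hold", {
  expect_identical(compute_fpkm(10, 1000, 1e6), 10)
  expect_identical(compute_fpkm(0, 1000, 1e6), 0)
  expect_equal(compute_fpkm(7, 850, 2e6), compute_fpkm(21, 850, 6e6))
  expect_error(compute_fpkm(1, 0, 1e6), "positive")
  expect_error(compute_fpkm(1, 100, 0), "positive")
})

test_that("site overlap respects the half-open boundary convention", {
  a <- make_sites(100, 150)
  expect_equal(overlap_sites(a, make_sites(140, 190))$shared, 1L)
  expect_equal(overlap_sites(a, make_sites(150, 200))$shared, 0L)  # abutting
  expect_equal(overlap_sites(a, make_sites(140, 190, strand = "-"))$shared, 0L)
  expect_equal(overlap_sites(a, make_sites(140, 190, chrom = "chr2"))$shared, 0L)
})

test_that("overlap of random site sets matches the all-pairs oracle", {
  set.seed(55)
  for (rep in 1:3) {
    a <- random_sites(200L); b <- random_sites(200L)
    ov <- overlap_sites(a, b)
    fa <- oracle_overlap_flags(a, b); fb <- oracle_overlap_flags(b, a)
    expect_identical(ov$shared_a, sum(fa))
    expect_identical(ov$shared_b, sum(fb))
    expect_identical(ov$a_only, sum(!fa))
    expect_identical(ov$b_only, sum(!fb))
    # invariants and swap symmetry of the overlap relation
    expect_equal(ov$a_only + ov$shared_a, nrow(a))
    expect_equal(ov$b_only + ov$shared_b, nrow(b))
    swapped <- overlap_sites(b, a)
    expect_identical(swapped$shared_a, ov$shared_b)
    expect_identical(swapped$shared_b, ov$shared_a)
  }
})

test_that("biotype tallies split sites by their transcript class", {
  models <- list(
    cod = transcript_model("cod", "chr1", "+", data.frame(start = 0, end = 500),
                           cds_start = 100, cds_end = 400),
    lnc = transcript_model("lnc", "chr1", "+", data.frame(start = 0, end = 500),
                           biotype = "lncRNA"))
  sites <- make_sites(c(10, 60, 110, 160), c(50, 100, 150, 200),
                      transcript_id = c("cod", "cod", "cod", "lnc"))
  tb <- tally_by_biotype(sites, models)
  expect_equal(tb$n_sites[tb$biotype == "protein_coding"], 3L)
  expect_equal(tb$n_sites[tb$biotype == "lncRNA"], 1L)
  expect_equal(sum(tb$n_sites), 4L)
  # empty site list gives all zeros; unknown transcripts are kept apart
  expect_true(all(tally_by_biotype(sites[0, ], models)$n_sites == 0L))
  sites$transcript_id[1] <- "mystery"
  expect_equal(tally_by_biotype(sites, models)$n_sites[5], 1L)
})

test_that("biotype tallies of a random assignment match a group-by oracle", {
  set.seed(77)
  bts <- sample(c("protein_coding", "lncRNA", "pseudogene", "other_noncoding"),
                40L, replace = TRUE)
  models <- lapply(seq_along(bts), function(i) {
    transcript_model(paste0("t", i), "chr1", "+",
                     data.frame(start = 0, end = 1000), biotype = bts[i])
  })
  names(models) <- paste0("t", seq_along(bts))
  tx <- sample(names(models), 500L, replace = TRUE)
  sites <- make_sites(rep(0, 500), rep(100, 500), transcript_id = tx)
  tb <- tally_by_biotype(sites, models)
  oracle <- table(factor(bts[match(tx, names(models))],
                         levels = c("protein_coding", "lncRNA", "pseudogene",
                                    "other_noncoding")))
  expect_equal(tb$n_sites[1:4], as.integer(oracle))
})

test_that("motif tallies report proportions over classified sites only", {
  sites <- make_sites(rep(0, 5), rep(100, 5),
                      motif_class = c("GGACU", "GGACU", "GACU", "ACU", "none"))
  tm <- tally_by_motif(sites)
  expect_equal(tm$proportion[tm$motif_class == "GGACU"], 0.5)
  expect_equal(tm$proportion[tm$motif_class == "GACU"], 0.25)
  expect_equal(sum(tm$proportion, na.rm = TRUE), 1)
  expect_equal(tm$n[tm$motif_class == "none"], 1L)
  single <- tally_by_motif(make_sites(0, 100, motif_class = "GAC"))
  expect_equal(single$proportion[single$motif_class == "GAC"], 1)
})

test_that("MeRIP-qPCR enrichment composes 2^-dCt quantities exactly", {
  expect_equal(merip_qpcr_enrichment(8, 1, 1, 1), 8)
  expect_equal(merip_qpcr_enrichment(3, 1.5, 6, 3), 1)
  # from Ct space: enrichment equals 2^-(dCt_target - dCt_control)
  ct <- c(ip = 20, input = 24, c_ip = 18, c_input = 19)
  got <- merip_qpcr_enrichment(2^-ct[["ip"]], 2^-ct[["input"]],
                               2^-ct[["c_ip"]], 2^-ct[["c_input"]])
  expect_equal(got, 2^-((ct[["ip"]] - ct[["input"]]) -
                          (ct[["c_ip"]] - ct[["c_input"]])))
  expect_error(merip_qpcr_enrichment(0, 1, 1, 1), "positive")
})

test_that("classify_sites pulls the planted motif out of the transcript sequence", {
  m <- transcript_model("tx", "chr1", "+", data.frame(start = 100, end = 400))
  seqs <- c(tx = paste(rep("A", 300), collapse = ""))
  substr(seqs[["tx"]], 151, 155) <- "GGACT"
  sites <- make_sites(220, 280, transcript_id = "tx")  # tx space [120,180)
  out <- classify_sites(sites, list(tx = m), seqs)
  expect_equal(out$motif_class, "GGACU")
  # a site with no transcript stays unclassified
  out2 <- classify_sites(make_sites(0, 50), list(tx = m), seqs)
  expect_equal(out2$motif_class, "none")
})
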