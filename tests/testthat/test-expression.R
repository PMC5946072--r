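expr_matrix <- function(n_genes, design, means = NULL, sd = 0) {
  n <- n_genes * nrow(design)
  m <- matrix(if (sd > 0) rnorm(n, 0, sd) else 0, nrow = n_genes)
  if (!is.null(means)) m <- m + means
  m <- pmax(m, 0)
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  colnames(m) <- design$subject_id
  m
}

test_that("log2 fold change arithmetic and pseudo-FPKM behave as documented", {
  design <- toy_design(2L)
  m <- rbind(g1 = c(4, 4, 8, 8), g2 = c(5, 5, 5, 5))
  colnames(m) <- design$subject_id
  rec <- log2_fold_changes(m, design, epsilon = 0.01)
  expect_equal(rec$log2fc[rec$gene_id == "g1"], log2(8.01 / 4.01),
               tolerance = 1e-12)
  expect_equal(rec$log2fc[rec$gene_id == "g2"], 0)
  # swapping group labels negates every fold change
  design_sw <- design; design_sw$group <- rev(design_sw$group)
  rec_sw <- log2_fold_changes(m, design_sw, epsilon = 0.01)
  expect_equal(rec_sw$log2fc, -rec$log2fc)
})

test_that("fold changes of a random table match per-gene recomputation", {
  set.seed(12)
  design <- toy_design(11L)
  m <- expr_matrix(100L, design, means = 5, sd = 2)
  rec <- log2_fold_changes(m, design, epsilon = 0.01,
                           methylated = c("g001", "g002"),
                           target_sets = list(auf1 = c("g002", "g003")))
  for (i in sample(100L, 20L)) {
    g <- sprintf("g%03d", i)
    my <- mean(m[g, design$subject_id[design$group == "young"]])
    mo <- mean(m[g, design$subject_id[design$group == "old"]])
    expect_equal(rec$log2fc[rec$gene_id == g], log2((mo + .01) / (my + .01)))
  }
  expect_equal(rec$methylated, rec$gene_id %in% c("g001", "g002"))
  expect_equal(rec$auf1, rec$gene_id %in% c("g002", "g003"))
})

test_that("ecdf_curve produces right-continuous step points ending at 1", {
  cc <- ecdf_curve(c(1, 2, 2, 4))
  expect_equal(cc$x, c(1, 2, 4))
  expect_equal(cc$F, c(0.25, 0.75, 1))
  expect_equal(ecdf_curve(3.7)$F, 1)
  expect_error(ecdf_curve(numeric()), "finite")
  expect_error(ecdf_curve(c(NA, Inf)), "finite")
  set.seed(13)
  v <- rnorm(500)
  cc2 <- ecdf_curve(v)
  expect_true(all(diff(cc2$F) > 0))
  # ECDF of standard normal draws tracks Phi within the 99% DKW band
  band <- sqrt(log(2 / 0.01) / (2 * 500))
  expect_lt(max(abs(cc2$F - pnorm(cc2$x))), band)
})

test_that("ks_compare returns the exact sup-distance and is symmetric", {
  a <- (0:999) / 1000
  r <- ks_compare(a, (500:1499) / 1000)   # exact half-unit shift
  expect_equal(r$D, 0.5, tolerance = 1e-12)
  # direct two-sided ECDF sweep oracle
  sweep_D <- function(x, y) {
    g <- sort(unique(c(x, y)))
    max(abs(ecdf(x)(g) - ecdf(y)(g)))
  }
  set.seed(14)
  x <- rnorm(80); y <- rnorm(120, 0.4)
  r2 <- ks_compare(x, y)
  expect_equal(r2$D, sweep_D(x, y), tolerance = 1e-12)
  r3 <- ks_compare(y, x)
  expect_equal(r2$D, r3$D)
  expect_equal(r2$p, r3$p)
  # location equivariance: shifting both samples changes nothing
  r4 <- ks_compare(x + 3.3, y + 3.3)
  expect_equal(r4$D, r2$D)
  expect_equal(r4$p, r2$p)
  # identical samples: D = 0, p = 1
  r5 <- ks_compare(x, x)
  expect_equal(r5$D, 0)
  expect_equal(r5$p, 1)
  expect_error(ks_compare(1, c(1, 2)), "finite values")
})

test_that("a planted half-sd shift is detected by the stratified KS report", {
  set.seed(15)
  n <- 300L
  records <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:(2 * n)),
    log2fc = c(rnorm(n, -0.5), rnorm(n, 0)),
    methylated = rep(c(TRUE, FALSE), each = n))
  rep1 <- stratified_cdf_report(
    records, strata = list(meth_target = records$methylated,
                           meth_nontarget = !records$methylated))
  expect_equal(nrow(rep1$ks), 1L)
  expect_lt(rep1$ks$p, 0.01)
  expect_named(rep1$ecdf, c("meth_target", "meth_nontarget"))
})

test_that("stratified reports cover all pairs and skip tiny strata", {
  set.seed(16)
  records <- tibble::tibble(gene_id = sprintf("g%d", 1:60),
                            log2fc = rnorm(60))
  three <- stratified_cdf_report(records, strata = list(
    a = rep(c(TRUE, FALSE), c(20, 40)),
    b = rep(c(FALSE, TRUE, FALSE), c(20, 20, 20)),
    c = rep(c(FALSE, TRUE), c(40, 20))))
  expect_equal(nrow(three$ks), 3L)   # all pairwise tests by default
  # identical multisets give D = 0
  same <- stratified_cdf_report(records, strata = list(
    u = rep(TRUE, 60), v = rep(TRUE, 60)))
  expect_equal(same$ks$D, 0)
  expect_warning(
    stratified_cdf_report(records, strata = list(
      big = rep(TRUE, 60), tiny = c(TRUE, rep(FALSE, 59)))),
    "fewer than 2")
  # predicates may be given as functions of the record tibble
  fun <- stratified_cdf_report(records, strata = list(
    pos = function(r) r$log2fc > 0, neg = function(r) r$log2fc <= 0))
  expect_equal(sum(fun$sizes), 60L)
})

test_that("methylation/abundance scatter reports a rank correlation", {
  x <- c(a = 1, b = 2, c = 3, d = 4)
  sc <- methylation_expression_scatter(x, x * 10)
  expect_equal(sc$rho, 1)
  sc2 <- methylation_expression_scatter(x, c(a = 2, b = 2, c = 2, d = 2))
  expect_equal(sc2$flag, "degenerate")
  expect_true(is.na(sc2$rho))
  expect_error(methylation_expression_scatter(x[1:2], x[1:2]), "at least 3")
  set.seed(17)
  y <- setNames(runif(500), sprintf("g%d", 1:500))
  z <- setNames(runif(500), sprintf("g%d", 1:500))
  expect_lt(abs(methylation_expression_scatter(y, z)$rho), 0.12)
})

test_that("vectorized Welch tests match stats::t.test per gene", {
  set.seed(18)
  design <- toy_design(6L)
  m <- expr_matrix(25L, design, means = 10, sd = 3)
  got <- group_t_tests(m, design)
  for (g in rownames(m)[sample(25L, 8L)]) {
    tt <- t.test(m[g, design$subject_id[design$group == "old"]],
                 m[g, design$subject_id[design$group == "young"]])
    row <- got[got$gene_id == g, ]
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(row$p, tt$p.value, tolerance = 1e-12)
  }
})
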