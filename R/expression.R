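#' Cohort expression comparison: fold changes, ECDFs and KS tests
#'
#' These functions implement the expression arm of the analysis: per-gene
#' log2 fold changes between cohorts, empirical cumulative distribution
#' curves, two-sample Kolmogorov-Smirnov comparisons, and stratified CDF
#' reports splitting genes by methylation status and RNA-binding-protein
#' target membership.
#'
#' @name cohort_expression
NULL

.split_design <- function(design) {
  .assert(all(c("subject_id", "group") %in% colnames(design)),
          "design needs subject_id and group columns")
  .assert(all(design$group %in% c("young", "old")),
          "design groups must be 'young' and 'old'")
  .assert(!anyDuplicated(design$subject_id), "subject_ids must be unique")
  split(design$subject_id, design$group)
}

#' Per-gene log2 fold changes between cohorts
#'
#' For each gene the group mean FPKM is computed and the fold change is
#' `log2((mean_old + epsilon) / (mean_young + epsilon))`; the pseudo-FPKM
#' `epsilon` keeps fold changes finite for genes unexpressed in one
#' cohort. Genes with no finite value in either group are dropped with a
#' message.
#'
#' @param expr numeric matrix (genes x subjects, rownames = gene IDs) or
#'   tibble with a `gene_id` column; values are FPKM (non-negative).
#' @param design tibble with `subject_id` and `group` (`young` / `old`);
#'   subjects must be columns of `expr`.
#' @param epsilon pseudo-FPKM added to both means (default 0.01).
#' @param methylated character vector of methylated gene IDs (genes
#'   owning at least one called m6A site), or `NULL`.
#' @param target_sets named list of character vectors of gene IDs; one
#'   logical membership column is added per set.
#' @return tibble: `gene_id`, `mean_fpkm_young`, `mean_fpkm_old`,
#'   `log2fc`, `methylated`, plus one logical column per target set.
#' @export
log2_fold_changes <- function(expr, design, epsilon = 0.01,
                              methylated = NULL, target_sets = list()) {
  .assert(epsilon > 0, "epsilon must be positive")
  if (!is.matrix(expr)) {
    expr <- as.data.frame(expr)
    .assert("gene_id" %in% colnames(expr), "expr needs a gene_id column")
    rn <- expr$gene_id
    expr <- as.matrix(expr[, setdiff(colnames(expr), "gene_id"), drop = FALSE])
    rownames(expr) <- rn
  }
  groups <- .split_design(design)
  .assert(all(unlist(groups) %in% colnames(expr)),
          "design subjects must all be expression columns")
  my <- rowMeans(expr[, groups$young, drop = FALSE], na.rm = TRUE)
  mo <- rowMeans(expr[, groups$old, drop = FALSE], na.rm = TRUE)
  bad <- !is.finite(my) | !is.finite(mo)
  if (any(bad)) {
    message(sum(bad), " gene(s) with no usable values excluded")
    my <- my[!bad]; mo <- mo[!bad]
  }
  out <- tibble::tibble(
    gene_id = names(my),
    mean_fpkm_young = unname(my),
    mean_fpkm_old = unname(mo),
    log2fc = log2((unname(mo) + epsilon) / (unname(my) + epsilon)),
    methylated = names(my) %in% (methylated %||% character()))
  for (nm in names(target_sets)) out[[nm]] <- out$gene_id %in% target_sets[[nm]]
  out
}

#' Empirical cumulative distribution curve
#'
#' Right-continuous step points of the ECDF: for each distinct value x,
#' `F(x)` is the fraction of observations `<= x`, so `F(max) = 1`.
#'
#' @param values numeric vector with at least one finite value
#'   (non-finite values are dropped).
#' @return tibble with columns `x` (sorted distinct values) and `F`.
#' @export
ecdf_curve <- function(values) {
  v <- values[is.finite(values)]
  .assert(length(v) >= 1L, "ecdf_curve needs at least one finite value")
  Fn <- stats::ecdf(v)
  x <- sort(unique(v))
  tibble::tibble(x = x, F = Fn(x))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Exact sup-distance between the two ECDFs with the asymptotic
#' two-sided p-value from the Kolmogorov distribution at effective sample
#' size `n1 * n2 / (n1 + n2)` (as in `stats::ks.test(exact = FALSE)`,
#' which performs the computation). Suitable for the hundreds-to-
#' thousands of genes per stratum this analysis compares.
#'
#' @param a,b numeric vectors, each with at least 2 finite values.
#' @return list of class `ks_result` with `D`, `p`, `n1`, `n2`.
#' @export
ks_compare <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  .assert(length(a) >= 2L && length(b) >= 2L,
          "ks_compare needs >= 2 finite values per sample")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  structure(list(D = unname(kt$statistic), p = unname(kt$p.value),
                 n1 = length(a), n2 = length(b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$D, x$p, x$n1, x$n2))
  invisible(x)
}

#' Stratified CDF report with pairwise KS tests
#'
#' Computes the ECDF of `log2fc` per stratum and a two-sample KS test for
#' every requested pair of strata (all pairs by default). A stratum is
#' defined by a logical vector over the records or by a predicate
#' function of the record tibble (e.g. methylated AUF1 targets versus
#' methylated non-targets). Strata with fewer than 2 members are dropped
#' from testing with a warning.
#'
#' @param records tibble from [log2_fold_changes()].
#' @param strata named list; each element is a logical vector of length
#'   `nrow(records)` or a function mapping the records tibble to one.
#' @param pairs optional 2-column character matrix of stratum names to
#'   test; default all pairwise combinations.
#' @return list of class `cdf_report`: `ecdf` (named list of tibbles),
#'   `sizes` (named integer vector), `ks` tibble (`stratum_a`,
#'   `stratum_b`, `D`, `p`, `n1`, `n2`).
#' @export
stratified_cdf_report <- function(records, strata, pairs = NULL) {
  .assert(length(strata) >= 1L && !is.null(names(strata)),
          "strata must be a non-empty named list")
  member <- lapply(strata, function(s) {
    v <- if (is.function(s)) s(records) else s
    .assert(is.logical(v) && length(v) == nrow(records),
            "each stratum must resolve to a logical vector over the records")
    v & !is.na(v)
  })
  values <- lapply(member, function(m) records$log2fc[m])
  sizes <- vapply(values, length, 0L)
  curves <- lapply(values[sizes >= 1L], ecdf_curve)
  if (is.null(pairs)) {
    nm <- names(strata)
    pairs <- if (length(nm) >= 2L) t(utils::combn(nm, 2L)) else
      matrix(character(), ncol = 2L)
  }
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    na <- pairs[i, 1L]; nb <- pairs[i, 2L]
    if (sizes[[na]] < 2L || sizes[[nb]] < 2L) {
      warning(sprintf("stratum pair (%s, %s) skipped: fewer than 2 members",
                      na, nb), call. = FALSE)
      next
    }
    ks <- ks_compare(values[[na]], values[[nb]])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      stratum_a = na, stratum_b = nb, D = ks$D, p = ks$p,
      n1 = ks$n1, n2 = ks$n2)
  }
  structure(list(ecdf = curves, sizes = sizes,
                 ks = if (length(rows)) dplyr::bind_rows(rows) else
                   tibble::tibble(stratum_a = character(), stratum_b = character(),
                                  D = numeric(), p = numeric(),
                                  n1 = integer(), n2 = integer())),
            class = "cdf_report")
}

#' Methylation level versus total expression
#'
#' Pairs per-gene m6A fragment FPKM with total-RNA FPKM and reports the
#' Spearman rank correlation (the analysis asks whether methylation
#' degree tracks transcript abundance at all, so a rank statistic is
#' appropriate). A constant vector makes the correlation undefined; the
#' result is then flagged `degenerate` with `rho = NA`.
#'
#' @param m6a_fpkm,total_fpkm named numeric vectors (names = gene IDs);
#'   at least 3 shared genes required.
#' @return list: `table` (tibble `gene_id`, `m6a_fpkm`, `total_fpkm`),
#'   `rho`, `p`, `n`, `flag` (`ok` or `degenerate`).
#' @export
methylation_expression_scatter <- function(m6a_fpkm, total_fpkm) {
  shared <- intersect(names(m6a_fpkm), names(total_fpkm))
  .assert(length(shared) >= 3L, "need at least 3 shared gene IDs")
  x <- m6a_fpkm[shared]; y <- total_fpkm[shared]
  tab <- tibble::tibble(gene_id = shared, m6a_fpkm = unname(x),
                        total_fpkm = unname(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(table = tab, rho = NA_real_, p = NA_real_,
                n = length(shared), flag = "degenerate"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(table = tab, rho = unname(ct$estimate), p = ct$p.value,
       n = length(shared), flag = "ok")
}

#' Per-gene Welch t-tests between cohorts
#'
#' Two-sided Welch (unequal-variance) t-test of each gene's per-subject
#' values between the young and old groups, vectorized over genes.
#'
#' @inheritParams log2_fold_changes
#' @return tibble: `gene_id`, `t`, `df`, `p`.
#' @export
group_t_tests <- function(expr, design) {
  if (!is.matrix(expr)) {
    expr <- as.data.frame(expr)
    rn <- expr$gene_id
    expr <- as.matrix(expr[, setdiff(colnames(expr), "gene_id"), drop = FALSE])
    rownames(expr) <- rn
  }
  groups <- .split_design(design)
  xy <- expr[, groups$young, drop = FALSE]
  xo <- expr[, groups$old, drop = FALSE]
  ny <- ncol(xy); no <- ncol(xo)
  .assert(ny >= 2L && no >= 2L, "need >= 2 subjects per group")
  my <- rowMeans(xy); mo <- rowMeans(xo)
  vy <- apply(xy, 1L, stats::var); vo <- apply(xo, 1L, stats::var)
  se2 <- vy / ny + vo / no
  tstat <- (mo - my) / sqrt(se2)
  df <- se2^2 / ((vy / ny)^2 / (ny - 1L) + (vo / no)^2 / (no - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  tibble::tibble(gene_id = rownames(expr), t = unname(tstat),
                 df = unname(df), p = unname(p))
}

#' Plot stratified ECDF curves
#'
#' Small ggplot2 helper for visualizing a [stratified_cdf_report()].
#'
#' @param report a `cdf_report` object.
#' @return a ggplot object.
#' @export
plot_cdf_report <- function(report) {
  .assert(requireNamespace("ggplot2", quietly = TRUE),
          "ggplot2 is required for plotting")
  df <- dplyr::bind_rows(lapply(names(report$ecdf), function(nm) {
    dplyr::mutate(report$ecdf[[nm]], stratum = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = F, colour = stratum)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "log2 fold change (old / young)",
                  y = "cumulative fraction") +
    ggplot2::theme_minimal()
}
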