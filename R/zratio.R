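#' miRNA microarray Z-ratio differential expression
#'
#' Raw array intensities are log10-transformed and z-scored per array
#' (column); the Z ratio of each miRNA is the difference of its mean
#' z-score between groups divided by the standard deviation of those
#' differences over all miRNAs (the standard microarray z-ratio
#' construction). Significance per miRNA comes from a two-sample z-test
#' on the per-subject z-scores, with BH FDR across miRNAs, and the final
#' call combines three thresholds: p < .05, |Z ratio| > 1.5, FDR < 0.3.
#'
#' @name mirna_zratio
NULL

#' Detectability filter for a miRNA intensity matrix
#'
#' A miRNA is detectable when its raw intensity exceeds `floor` in at
#' least half of the subjects of either group.
#'
#' @param m numeric intensity matrix (miRNA x subject).
#' @param design tibble with `subject_id`, `group` covering the columns.
#' @param floor intensity floor (default 50 fluorescence units).
#' @return logical vector over rows of `m`.
#' @export
detect_mirnas <- function(m, design, floor = 50) {
  groups <- .split_design(design)
  ok_in <- function(cols) {
    need <- ceiling(length(cols) / 2)
    rowSums(m[, cols, drop = FALSE] > floor) >= need
  }
  ok_in(groups$young) | ok_in(groups$old)
}

#' Per-array z-score normalization
#'
#' `z = (log10(intensity + 1) - column mean) / column sd`, computed per
#' array over the rows provided (detectable miRNAs). The `+1` offset
#' avoids `log(0)` for absent signals.
#'
#' @param m numeric intensity matrix (miRNA x subject), values >= 0; at
#'   least 2 rows.
#' @return numeric matrix of z-scores with the same dimnames; every
#'   column has mean 0 and sd 1.
#' @export
zscore_normalize <- function(m) {
  .assert(is.matrix(m) && nrow(m) >= 2L, "need a matrix with >= 2 miRNAs")
  .assert(all(m >= 0), "intensities must be non-negative")
  l <- log10(m + 1)
  mu <- colMeans(l)
  sdv <- apply(l, 2L, stats::sd)
  .assert(all(sdv > 0), "zero column sd: an array has constant intensities")
  sweep(sweep(l, 2L, mu, "-"), 2L, sdv, "/")
}

#' Z-ratio differential expression between cohorts
#'
#' For miRNA i, `dz_i = mean_z(old) - mean_z(young)` and
#' `z_ratio_i = dz_i / sd({dz_j over all miRNAs})`. The per-miRNA p-value
#' is a two-sample z-test on the per-subject z-scores (normal reference
#' for the standardized mean difference), BH-adjusted into an FDR.
#' `call` is `up` when `p < p_threshold`, `z_ratio > zratio_threshold`
#' and `fdr < fdr_threshold`; `down` symmetrically for
#' `z_ratio < -zratio_threshold`; otherwise `unchanged`.
#'
#' @param z z-score matrix from [zscore_normalize()] (miRNA x subject).
#' @param design tibble with `subject_id`, `group`; both groups need at
#'   least 2 subjects among the columns of `z`.
#' @param p_threshold,zratio_threshold,fdr_threshold the triple call
#'   thresholds (defaults .05, 1.5, 0.3).
#' @return tibble: `mirna_id`, `mean_z_young`, `mean_z_old`, `z_ratio`,
#'   `p`, `fdr`, `call`.
#' @export
z_ratio <- function(z, design, p_threshold = 0.05, zratio_threshold = 1.5,
                    fdr_threshold = 0.3) {
  groups <- .split_design(design)
  .assert(all(unlist(groups) %in% colnames(z)),
          "design subjects must all be z-score columns")
  zy <- z[, groups$young, drop = FALSE]
  zo <- z[, groups$old, drop = FALSE]
  ny <- ncol(zy); no <- ncol(zo)
  .assert(ny >= 2L && no >= 2L, "both groups need >= 2 subjects")
  my <- rowMeans(zy); mo <- rowMeans(zo)
  dz <- mo - my
  sd_dz <- stats::sd(dz)
  .assert(is.finite(sd_dz), "degenerate z-score differences")
  # all differences identical (e.g. no group effect at all): ratios are 0
  zr <- if (sd_dz > 0) dz / sd_dz else rep(0, length(dz))
  vy <- apply(zy, 1L, stats::var); vo <- apply(zo, 1L, stats::var)
  se <- sqrt(vy / ny + vo / no)
  zstat <- ifelse(se > 0, dz / se, 0)
  p <- 2 * stats::pnorm(-abs(zstat))
  fdr <- stats::p.adjust(p, method = "BH")
  call <- rep("unchanged", nrow(z))
  sig <- p < p_threshold & fdr < fdr_threshold
  call[sig & zr > zratio_threshold] <- "up"
  call[sig & zr < -zratio_threshold] <- "down"
  tibble::tibble(mirna_id = rownames(z) %||% as.character(seq_len(nrow(z))),
                 mean_z_young = unname(my), mean_z_old = unname(mo),
                 z_ratio = unname(zr), p = unname(p), fdr = unname(fdr),
                 call = call)
}

#' Top up- and down-regulated miRNAs by |Z ratio|
#'
#' Stable ordering by decreasing |Z ratio| with ties broken
#' lexicographically by miRNA ID; if fewer than `k` calls exist in a
#' direction, all are returned with a message.
#'
#' @param records tibble from [z_ratio()].
#' @param k number of miRNAs per direction (default 20).
#' @return tibble of at most `2k` rows with a `direction` column
#'   (`up` rows first).
#' @export
top_table <- function(records, k = 20L) {
  .assert(k >= 1L, "k must be >= 1")
  pick <- function(direction) {
    d <- records[records$call == direction, ]
    d <- d[order(-abs(d$z_ratio), d$mirna_id), ]
    if (nrow(d) < k)
      message(sprintf("only %d '%s' calls available (k = %d)",
                      nrow(d), direction, k))
    d <- utils::head(d, k)
    if (nrow(d)) d$direction <- direction else d$direction <- character()
    d
  }
  dplyr::bind_rows(pick("up"), pick("down"))
}
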