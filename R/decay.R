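#' mRNA decay kinetics from actinomycin-D RT-qPCR time courses
#'
#' After transcription shutoff with actinomycin D, remaining transcript
#' abundance is quantified by RT-qPCR relative to a reference gene (18S
#' rRNA) using the delta-delta-Ct method, and the half-life is the time
#' at which abundance reaches 50% of its t = 0 level.
#'
#' @name decay_kinetics
NULL

#' Relative abundance from Ct values (delta-delta-Ct)
#'
#' `dCt(t) = Ct_target(t) - Ct_reference(t)`;
#' `ddCt(t) = dCt(t) - dCt(0)`; `abundance(t) = 2^-ddCt(t)`, so the t = 0
#' abundance is exactly 1. Amplification efficiency is fixed at 2 per
#' cycle (classic delta-delta-Ct). Adding any constant to both target and
#' reference Ct leaves the result unchanged.
#'
#' @param time_h numeric hours since actinomycin D; must contain 0.
#' @param ct_target,ct_reference finite Ct values per timepoint.
#' @return tibble with `time_h` and `abundance`, sorted by time.
#' @export
relative_abundance <- function(time_h, ct_target, ct_reference) {
  .assert(length(time_h) == length(ct_target) &&
            length(time_h) == length(ct_reference),
          "time_h, ct_target and ct_reference must have equal length")
  .assert(all(is.finite(ct_target)) && all(is.finite(ct_reference)),
          "Ct values must be finite")
  i0 <- which(time_h == 0)
  .assert(length(i0) == 1L, "exactly one t = 0 measurement is required")
  dct <- ct_target - ct_reference
  ddct <- dct - dct[i0]
  out <- tibble::tibble(time_h = time_h, abundance = 2^(-ddct))
  out[order(out$time_h), ]
}

#' Fit an exponential decay half-life
#'
#' `method = "loglinear"` (default) fits `log(abundance) = -k * t` by
#' least squares with the intercept fixed at zero, since the t = 0
#' abundance is 1 by construction of the delta-delta-Ct normalization;
#' the half-life is the model-derived 50% crossing `t_half = log(2)/k`.
#' This uses every timepoint and is robust to noise.
#' `method = "interpolate"` instead returns the literal first
#' linear-interpolation crossing of abundance 0.5.
#'
#' A non-positive fitted decay rate is flagged `no_decay` with
#' `t_half = Inf`; an R-squared on the log scale below `r2_floor` (with
#' decay present) is flagged `poor_fit`.
#'
#' @param time_h numeric hours (at least 3 timepoints).
#' @param abundance normalized abundances (positive).
#' @param method `"loglinear"` or `"interpolate"`.
#' @param r2_floor flag threshold for fit quality (default 0.7).
#' @return list of class `half_life_fit`: `t_half` (h), `k` (per h),
#'   `r_squared`, `n_points`, `flag` (`ok`, `no_decay`, `poor_fit`),
#'   `method`.
#' @export
fit_half_life <- function(time_h, abundance,
                          method = c("loglinear", "interpolate"),
                          r2_floor = 0.7) {
  method <- match.arg(method)
  .assert(length(time_h) == length(abundance), "lengths differ")
  .assert(length(time_h) >= 3L, "need at least 3 timepoints")
  .assert(all(abundance > 0),
          "abundance must be positive (check upstream normalization)")
  o <- order(time_h)
  t <- as.numeric(time_h[o]); a <- as.numeric(abundance[o])
  y <- log(a)
  # zero-intercept least squares: k = -sum(t*y)/sum(t^2)
  k <- -sum(t * y) / sum(t^2)
  yhat <- -k * t
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum((y - yhat)^2) / sst else 1
  if (method == "interpolate") {
    t_half <- .interpolate_crossing(t, a, 0.5)
    k_rep <- if (is.finite(t_half)) log(2) / t_half else k
  } else {
    t_half <- if (k > 0) log(2) / k else Inf
    k_rep <- k
  }
  flag <- if (!is.finite(t_half) || k_rep <= 0) "no_decay"
  else if (r2 < r2_floor) "poor_fit" else "ok"
  structure(list(t_half = t_half, k = k_rep, r_squared = r2,
                 n_points = length(t), flag = flag, method = method),
            class = "half_life_fit")
}

.interpolate_crossing <- function(t, a, level) {
  below <- which(a <= level)
  if (length(below) == 0L) return(Inf)
  j <- below[1L]
  if (j == 1L) return(t[1L])
  # linear interpolation between the bracketing timepoints
  t[j - 1L] + (t[j] - t[j - 1L]) * (a[j - 1L] - level) / (a[j - 1L] - a[j])
}

#' @export
print.half_life_fit <- function(x, ...) {
  cat(sprintf("<half_life_fit> t1/2 = %.3g h (k = %.3g /h, R2 = %.3f, n = %d, %s, %s)\n",
              x$t_half, x$k, x$r_squared, x$n_points, x$flag, x$method))
  invisible(x)
}

#' Estimate half-lives for a table of decay series
#'
#' Applies [relative_abundance()] then [fit_half_life()] to each
#' condition x replicate series of a tidy Ct table.
#'
#' @param series tibble with columns `condition`, `replicate`, `time_h`,
#'   `ct_target`, `ct_reference`.
#' @inheritParams fit_half_life
#' @return tibble: `condition`, `replicate`, `t_half`, `k`, `r_squared`,
#'   `flag`.
#' @export
fit_decay_table <- function(series, method = c("loglinear", "interpolate")) {
  method <- match.arg(method)
  .assert(all(c("condition", "replicate", "time_h", "ct_target",
               "ct_reference") %in% colnames(series)),
          "series lacks required columns")
  keys <- unique(series[, c("condition", "replicate")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- series$condition == keys$condition[i] &
      series$replicate == keys$replicate[i]
    s <- series[sel, ]
    ab <- relative_abundance(s$time_h, s$ct_target, s$ct_reference)
    fit <- fit_half_life(ab$time_h, ab$abundance, method = method)
    tibble::tibble(condition = keys$condition[i],
                   replicate = keys$replicate[i],
                   t_half = fit$t_half, k = fit$k,
                   r_squared = fit$r_squared, flag = fit$flag)
  })
  dplyr::bind_rows(rows)
}

#' Compare half-lives across conditions
#'
#' Per-condition summary (mean and sd of replicate half-lives) plus a
#' two-sided Welch t-test for each condition pair on the replicate
#' half-life values. No multiplicity correction is applied by default
#' (a handful of planned comparisons, each reported on its own). Pairs
#' where either condition has fewer than 2 finite replicate values are
#' skipped with a warning.
#'
#' @param fits tibble with `condition`, `replicate`, `t_half` (e.g. from
#'   [fit_decay_table()]).
#' @return list of class `half_life_comparison`: `summary` tibble
#'   (`condition`, `n`, `mean_t_half`, `sd_t_half`), `tests` tibble
#'   (`condition_a`, `condition_b`, `t`, `p`).
#' @export
compare_half_lives <- function(fits) {
  .assert(all(c("condition", "replicate", "t_half") %in% colnames(fits)),
          "fits lacks required columns")
  vals <- split(fits$t_half[is.finite(fits$t_half)],
                fits$condition[is.finite(fits$t_half)])
  smry <- tibble::tibble(
    condition = names(vals),
    n = vapply(vals, length, 0L),
    mean_t_half = vapply(vals, mean, 0),
    sd_t_half = vapply(vals, function(v) if (length(v) > 1L) stats::sd(v)
                       else NA_real_, 0))
  conds <- names(vals)
  rows <- list()
  if (length(conds) >= 2L) {
    cmb <- utils::combn(conds, 2L)
    for (i in seq_len(ncol(cmb))) {
      a <- vals[[cmb[1L, i]]]; b <- vals[[cmb[2L, i]]]
      if (length(a) < 2L || length(b) < 2L) {
        warning(sprintf("comparison (%s, %s) skipped: fewer than 2 replicates",
                        cmb[1L, i], cmb[2L, i]), call. = FALSE)
        next
      }
      tt <- stats::t.test(a, b)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition_a = cmb[1L, i], condition_b = cmb[2L, i],
        t = unname(tt$statistic), p = tt$p.value)
    }
  }
  structure(list(summary = smry,
                 tests = if (length(rows)) dplyr::bind_rows(rows) else
                   tibble::tibble(condition_a = character(),
                                  condition_b = character(),
                                  t = numeric(), p = numeric())),
            class = "half_life_comparison")
}
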