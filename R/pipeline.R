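#' Run the full m6A profiling pipeline on a simulated study
#'
#' Orchestrates simulate -> site calling -> motif/biotype tallies and
#' cohort overlap -> metagene -> expression CDF/KS -> decay half-lives
#' -> miRNA Z-ratios from one configuration, in dependency order.
#' Outputs are written under `outdir/<stage>/` in plain-text formats and
#' hashed into a reproducible run manifest; with a fixed config and seed
#' two runs produce identical manifests.
#'
#' Stage toggles: the `merip` stage is a dependency of `metagene` and
#' `expression` and is added automatically when either is requested.
#'
#' @param config a [sim_config()]; holds the seed, all scenario and all
#'   stage parameters.
#' @param outdir output directory (default: a fresh temporary
#'   directory).
#' @param stages character subset of
#'   `c("merip", "metagene", "expression", "decay", "mirna")`.
#' @return list of class `m6a_run` with per-stage results, a `summary`
#'   list of headline numbers, and the `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = tempfile("m6a_run_"),
                         stages = c("merip", "metagene", "expression",
                                    "decay", "mirna")) {
  all_stages <- c("merip", "metagene", "expression", "decay", "mirna")
  .assert(all(stages %in% all_stages),
          sprintf("stages must be among: %s", paste(all_stages, collapse = ", ")))
  if (any(c("metagene", "expression") %in% stages) && !"merip" %in% stages) {
    message("adding 'merip' stage (required by metagene/expression)")
    stages <- c("merip", stages)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config, outdir = outdir, stages = stages)
  files <- character()

  sim <- simulate_transcriptome(config)
  files <- c(files, write_simulation(sim, file.path(outdir, "simulate")))
  res$sim <- sim

  if ("merip" %in% stages) {
    counts <- simulate_merip_counts(sim)
    sites <- list()
    for (cohort in c("young", "old")) {
      cc <- counts[[cohort]]
      s <- call_m6a_sites(cc$windows, cc$ip_libsize, cc$input_libsize,
                          q_threshold = config$q_threshold,
                          pseudocount = config$pseudocount,
                          dispersion = config$caller_dispersion)
      sites[[cohort]] <- classify_sites(s, sim$models, sim$sequences)
    }
    ov <- overlap_sites(sites$young, sites$old)
    tallies <- list(
      biotype_young = tally_by_biotype(sites$young, sim$models),
      biotype_old = tally_by_biotype(sites$old, sim$models),
      motif_young = tally_by_motif(sites$young),
      motif_old = tally_by_motif(sites$old))
    d <- file.path(outdir, "merip"); dir.create(d, showWarnings = FALSE)
    for (cohort in c("young", "old")) {
      f <- file.path(d, paste0("sites_", cohort, ".bed"))
      write_sites_bed(sites[[cohort]], f)
      files <- c(files, stats::setNames(f, paste0("sites_", cohort)))
    }
    for (nm in names(tallies)) {
      f <- file.path(d, paste0(nm, ".tsv"))
      readr::write_tsv(tallies[[nm]], f, progress = FALSE)
      files <- c(files, stats::setNames(f, nm))
    }
    res$counts <- counts; res$sites <- sites; res$overlap <- ov
    res$tallies <- tallies
  }

  if ("metagene" %in% stages) {
    prof <- list(
      young = metagene_profile(res$sites$young, sim$models,
                               bins = config$metagene_bins,
                               anchor_window = config$anchor_window),
      old = metagene_profile(res$sites$old, sim$models,
                             bins = config$metagene_bins,
                             anchor_window = config$anchor_window))
    d <- file.path(outdir, "metagene"); dir.create(d, showWarnings = FALSE)
    for (cohort in c("young", "old")) {
      f <- file.path(d, paste0("profile_", cohort, ".tsv"))
      readr::write_tsv(prof[[cohort]]$region_profile, f, progress = FALSE)
      files <- c(files, stats::setNames(f, paste0("metagene_", cohort)))
    }
    res$metagene <- prof
  }

  if ("expression" %in% stages) {
    ex <- simulate_expression(sim)
    methylated_genes <- unique(stats::na.omit(c(
      res$sites$young$transcript_id, res$sites$old$transcript_id)))
    records <- log2_fold_changes(ex$expression, ex$design,
                                 epsilon = config$epsilon,
                                 methylated = methylated_genes,
                                 target_sets = ex$target_sets)
    strata <- list(
      methylated = records$methylated,
      unmethylated = !records$methylated,
      methylated_auf1_target = records$methylated & records$auf1_like,
      methylated_auf1_nontarget = records$methylated & !records$auf1_like,
      methylated_hur_target = records$methylated & records$hur_like,
      methylated_hur_nontarget = records$methylated & !records$hur_like)
    pairs <- rbind(c("methylated", "unmethylated"),
                   c("methylated_auf1_target", "methylated_auf1_nontarget"),
                   c("methylated_hur_target", "methylated_hur_nontarget"))
    report <- stratified_cdf_report(records, strata, pairs = pairs)
    # m6A FPKM per gene (young sites) vs mean total FPKM in young
    m6a_fpkm <- tapply(res$sites$young$ip_fpkm,
                       res$sites$young$transcript_id, sum)
    young_cols <- ex$design$subject_id[ex$design$group == "young"]
    total <- rowMeans(as.matrix(ex$expression[, young_cols]))
    names(total) <- ex$expression$gene_id
    scatter <- methylation_expression_scatter(m6a_fpkm, total)
    d <- file.path(outdir, "expression"); dir.create(d, showWarnings = FALSE)
    f1 <- file.path(d, "fold_changes.tsv")
    readr::write_tsv(records, f1, progress = FALSE)
    f2 <- file.path(d, "ks_tests.tsv")
    readr::write_tsv(report$ks, f2, progress = FALSE)
    files <- c(files, fold_changes = f1, ks_tests = f2)
    res$expression <- list(simulated = ex, records = records,
                           report = report, scatter = scatter,
                           methylated_genes = methylated_genes)
  }

  if ("decay" %in% stages) {
    series <- simulate_decay(config)
    fits <- fit_decay_table(series, method = config$decay_method)
    comp <- compare_half_lives(fits)
    d <- file.path(outdir, "decay"); dir.create(d, showWarnings = FALSE)
    f1 <- file.path(d, "half_life_fits.tsv")
    readr::write_tsv(fits, f1, progress = FALSE)
    f2 <- file.path(d, "half_life_summary.tsv")
    readr::write_tsv(comp$summary, f2, progress = FALSE)
    files <- c(files, half_life_fits = f1, half_life_summary = f2)
    res$decay <- list(series = series, fits = fits, comparison = comp)
  }

  if ("mirna" %in% stages) {
    mi <- simulate_mirna(config)
    keep <- detect_mirnas(mi$intensity, mi$design, floor = config$mirna_floor)
    z <- zscore_normalize(mi$intensity[keep, , drop = FALSE])
    zr <- z_ratio(z, mi$design,
                  p_threshold = config$mirna_p_threshold,
                  zratio_threshold = config$mirna_zratio_threshold,
                  fdr_threshold = config$mirna_fdr_threshold)
    tt <- top_table(zr, k = config$top_k)
    d <- file.path(outdir, "mirna"); dir.create(d, showWarnings = FALSE)
    f1 <- file.path(d, "z_ratios.tsv")
    readr::write_tsv(zr, f1, progress = FALSE)
    f2 <- file.path(d, "top_table.tsv")
    readr::write_tsv(tt, f2, progress = FALSE)
    files <- c(files, z_ratios = f1, top_table = f2)
    res$mirna <- list(simulated = mi, records = zr, top = tt,
                      n_detectable = sum(keep))
  }

  res$summary <- .run_summary(res)
  manifest <- list(
    package = "m6aging",
    version = as.character(utils::packageVersion("m6aging")),
    seed = config$seed,
    stages = stages,
    config = unclass(config),
    files = as.list(unname(Map(function(nm, f) {
      list(name = nm, path = basename(f),
           md5 = unname(tools::md5sum(f)))
    }, names(files), files))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res$manifest <- manifest
  structure(res, class = "m6a_run")
}

.run_summary <- function(res) {
  s <- list()
  if (!is.null(res$sites)) {
    s$n_sites_young <- nrow(res$sites$young)
    s$n_sites_old <- nrow(res$sites$old)
    s$n_sites_shared <- res$overlap$shared
    truth <- res$sim$truth
    ago2_young <- any(res$sites$young$transcript_id == "AGO2like", na.rm = TRUE)
    ago2_old <- any(res$sites$old$transcript_id == "AGO2like", na.rm = TRUE)
    s$ago2_like_demethylated_in_old <- ago2_young && !ago2_old
  }
  if (!is.null(res$expression)) {
    ks <- res$expression$report$ks
    s$ks_p_methylated_vs_rest <-
      ks$p[ks$stratum_a == "methylated" & ks$stratum_b == "unmethylated"]
    rec <- res$expression$records
    s$ago2_like_log2fc <- rec$log2fc[rec$gene_id == "AGO2like"]
    s$scatter_rho <- res$expression$scatter$rho
  }
  if (!is.null(res$decay)) {
    smry <- res$decay$comparison$summary
    s$t_half <- stats::setNames(smry$mean_t_half, smry$condition)
  }
  if (!is.null(res$mirna)) {
    s$mirna_n_detectable <- res$mirna$n_detectable
    s$mirna_n_up <- sum(res$mirna$records$call == "up")
    s$mirna_n_down <- sum(res$mirna$records$call == "down")
  }
  s
}

#' @export
print.m6a_run <- function(x, ...) {
  s <- x$summary
  cat("<m6a_run> stages:", paste(x$stages, collapse = ", "), "\n")
  if (!is.null(s$n_sites_young))
    cat(sprintf("  m6A sites: young %d, old %d, shared %d\n",
                s$n_sites_young, s$n_sites_old, s$n_sites_shared))
  if (!is.null(s$ks_p_methylated_vs_rest))
    cat(sprintf("  KS methylated vs rest: p = %.3g\n",
                s$ks_p_methylated_vs_rest))
  if (!is.null(s$t_half))
    cat(sprintf("  half-lives (h): %s\n",
                paste(sprintf("%s = %.2f", names(s$t_half), s$t_half),
                      collapse = ", ")))
  if (!is.null(s$mirna_n_up))
    cat(sprintf("  miRNAs: %d detectable, %d up, %d down\n",
                s$mirna_n_detectable, s$mirna_n_up, s$mirna_n_down))
  cat("  outputs:", x$outdir, "\n")
  invisible(x)
}

#' Write called m6A sites as BED6+
#'
#' Name = motif class, score = `-10 log10(qvalue)` (capped at 1000),
#' with enrichment, q-value, FPKM and transcript columns appended.
#'
#' @param sites an `m6a_sites` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  score <- pmin(1000, round(-10 * log10(pmax(sites$qvalue, 1e-100))))
  df <- data.frame(sites$chrom, sites$start, sites$end,
                   ifelse(is.na(sites$motif_class), "none", sites$motif_class),
                   score, sites$strand, sites$transcript_id,
                   signif(sites$enrichment, 4), signif(sites$qvalue, 4),
                   signif(sites$ip_fpkm, 4), sites$n_fragments)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
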