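#' Simulation configuration for the full study design
#'
#' One configuration object drives every generator and the pipeline. The
#' defaults emulate the study conditions this package analyzes: two
#' cohorts of 11 subjects, roughly 1,000 planted methylated fragments in
#' the young cohort with about 75% shared with the old cohort (more
#' sites in young than old), 100-200 nt fragments, methylation
#' predominantly on protein-coding transcripts, three focal transcripts
#' with distinct methylation/stability behavior (an AGO2-like transcript
#' methylated and stable only in the young state, a DROSHA-like
#' transcript methylated in both cohorts with unchanged expression, and
#' a DICER1-like transcript unmethylated but reduced in old), decay
#' scenarios with half-lives 4.9 / 9.5 / 7.1 h, and an 887-miRNA array
#' scenario with 550 up- and 93 down-regulated species (7 of 12 let-7
#' family members down).
#'
#' All randomness is seeded: each generator derives its own stream from
#' `seed` with a fixed per-stage offset, so a fixed seed gives
#' byte-identical outputs.
#'
#' @param seed integer master seed.
#' @param ... overrides for any default field; unknown fields are
#'   rejected.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # transcriptome
    n_transcripts = 1500L,
    fraction_coding = 0.8,
    tx_length_meanlog = log(1500),
    tx_length_sdlog = 0.35,
    # planted m6A sites
    n_shared_sites = 750L,
    n_young_only = 250L,
    n_old_only = 50L,
    coding_site_fraction = 0.9,
    motif_mix = c(GGACU = 0.35, GACU = 0.30, ACU = 0.20, GAC = 0.15),
    fragment_length = c(100L, 200L),
    # MeRIP counts
    window = 50L,
    step = 25L,
    enrichment = 8,
    nb_dispersion = 0.1,
    depth_per_window = 10,
    expr_sdlog = 0.5,
    # caller parameters
    q_threshold = 0.05,
    pseudocount = 0.5,
    caller_dispersion = 0.1,
    # cohorts
    n_subjects = 11L,
    young_age_mean = 30.55, young_age_sd = 1.72,
    old_age_mean = 63.73, old_age_sd = 2.16,
    # expression
    epsilon = 0.01,
    base_log2_mean = 4, base_log2_sd = 1.5,
    lfc_sd = 0.4,
    subject_sd = 0.3,
    methylated_shift = 0.5,
    rbp_target_fraction = 0.15,
    rbp_target_shift = -0.4,
    focal_lfc = c(AGO2like = -1, DROSHAlike = 0, DICER1like = -0.8),
    # decay
    decay_t_half = c(empty_vector = 4.9, METTL3_OE = 9.5, METTL14_OE = 7.1),
    decay_replicates = 3L,
    decay_timepoints = c(0, 2, 4, 8),
    ct_noise_sd = 0.1,
    decay_method = "loglinear",
    # miRNA array
    mirna_n = 887L,
    mirna_n_up = 550L,
    mirna_n_down = 93L,
    mirna_effect = 1.0,
    mirna_noise_sd = 0.15,
    mirna_base_mean = 2.5,
    mirna_base_sd = 0.6,
    mirna_floor = 50,
    mirna_p_threshold = 0.05,
    mirna_zratio_threshold = 1.5,
    mirna_fdr_threshold = 0.3,
    top_k = 20L,
    # metagene
    metagene_bins = c(20L, 50L, 30L),
    anchor_window = 300L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  .assert(length(unknown) == 0L,
          sprintf("unknown sim_config field(s): %s", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  .assert(cfg$fraction_coding >= 0 && cfg$fraction_coding <= 1,
          "fraction_coding must be in [0,1]")
  .assert(abs(sum(cfg$motif_mix) - 1) < 1e-8, "motif_mix must sum to 1")
  .assert(cfg$mirna_n_up + cfg$mirna_n_down <= cfg$mirna_n,
          "mirna_n_up + mirna_n_down must not exceed mirna_n")
  .assert(all(cfg$decay_t_half > 0), "decay half-lives must be positive")
  .assert(0 %in% cfg$decay_timepoints, "decay timepoints must include 0")
  .assert(cfg$n_transcripts >= 10L, "n_transcripts must be >= 10")
  structure(cfg, class = "sim_config")
}

#' Load a simulation/pipeline configuration from YAML
#'
#' Unknown keys are rejected by [sim_config()].
#'
#' @param path YAML file path.
#' @return `sim_config` object.
#' @export
sim_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  .assert(is.list(y), "YAML config must be a mapping")
  # restore named-vector fields that YAML represents as maps
  for (nm in c("motif_mix", "decay_t_half", "focal_lfc")) {
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  }
  do.call(sim_config, y)
}

.FOCAL_IDS <- c("AGO2like", "DROSHAlike", "DICER1like")

# split `total` into n parts each >= min_len (reduces n if infeasible)
.split_lengths <- function(total, n, min_len = 60L) {
  n <- max(1L, min(n, total %/% (2L * min_len)))
  if (n == 1L) return(total)
  w <- stats::runif(n, 0.5, 1.5)
  len <- pmax(min_len, floor(total * w / sum(w)))
  len[1L] <- total - sum(len[-1L])
  if (len[1L] < min_len) return(.split_lengths(total, n - 1L, min_len))
  len
}

#' Simulate a transcriptome with planted m6A sites
#'
#' Generates random exon structures laid out without overlap on 22
#' chromosomes, random sequences, and a ground-truth registry of planted
#' methylation sites. Each planted site lies within a single exon, has a
#' fragment-scale width (100-200 nt), carries one motif from the
#' configured mix spliced into the sequence at its center, and is at
#' least two window widths away from any other site on the same
#' transcript. Cohort membership (young/old/shared) follows the
#' configured counts; the AGO2-like focal transcript gets a young-only
#' site, the DROSHA-like one a shared site, and the DICER1-like one none.
#'
#' @param cfg a [sim_config()].
#' @return list of class `m6a_simulation`: `config`, `models` (named
#'   list of [transcript_model()]), `sequences` (named character vector
#'   of mature transcript sequences, DNA alphabet), `truth` (tibble of
#'   planted sites with genomic and transcript coordinates, motif, and
#'   `in_young` / `in_old` flags).
#' @export
simulate_transcriptome <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_transcripts
  ids <- c(.FOCAL_IDS, sprintf("TX%05d", seq_len(n - length(.FOCAL_IDS))))
  coding <- c(rep(TRUE, 3L),
              stats::runif(n - 3L) < cfg$fraction_coding)
  nc_type <- sample(c("lncRNA", "pseudogene", "other_noncoding"), n,
                    replace = TRUE, prob = c(0.5, 0.3, 0.2))
  biotype <- ifelse(coding, "protein_coding", nc_type)
  tx_len <- pmin(6000L, pmax(400L, round(stats::rlnorm(
    n, cfg$tx_length_meanlog, cfg$tx_length_sdlog))))
  n_exons <- pmin(6L, 1L + stats::rpois(n, 1.2))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  chrom <- paste0("chr", (seq_len(n) - 1L) %% 22L + 1L)
  cursor <- stats::setNames(rep(0L, 22L), paste0("chr", 1:22))

  models <- vector("list", n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    ex_len <- .split_lengths(tx_len[i], n_exons[i])
    k <- length(ex_len)
    introns <- if (k > 1L) sample(200:1500, k - 1L, replace = TRUE) else integer()
    gstart <- cursor[[chrom[i]]] + sample(500:2000, 1L)
    starts <- gstart + cumsum(c(0L, ex_len[-k] + introns))
    exons <- data.frame(start = starts, end = starts + ex_len)
    cursor[[chrom[i]]] <- max(exons$end)
    cds_start <- NA_integer_; cds_end <- NA_integer_
    if (coding[i]) {
      u5 <- max(1L, round(tx_len[i] * stats::runif(1L, 0.10, 0.20)))
      u3 <- max(1L, round(tx_len[i] * stats::runif(1L, 0.25, 0.35)))
      cds_start <- u5; cds_end <- tx_len[i] - u3
    }
    models[[i]] <- transcript_model(ids[i], chrom[i], strand[i], exons,
                                    biotype = biotype[i], gene_id = ids[i],
                                    cds_start = cds_start, cds_end = cds_end)
    seqs[i] <- paste(sample(c("A", "C", "G", "T"), tx_len[i], replace = TRUE),
                     collapse = "")
  }
  names(models) <- ids; names(seqs) <- ids

  truth <- .plant_sites(cfg, models, seqs)
  seqs <- truth$sequences
  structure(list(config = cfg, models = models, sequences = seqs,
                 truth = truth$truth),
            class = "m6a_simulation")
}

.plant_sites <- function(cfg, models, seqs) {
  n_total <- cfg$n_shared_sites + cfg$n_young_only + cfg$n_old_only
  membership <- c(rep("shared", cfg$n_shared_sites),
                  rep("young_only", cfg$n_young_only),
                  rep("old_only", cfg$n_old_only))
  membership <- sample(membership)
  # focal transcripts take the first matching membership slots
  smry <- models_summary(models)
  coding_ids <- setdiff(smry$transcript_id[smry$biotype == "protein_coding"],
                        .FOCAL_IDS)
  noncoding_ids <- smry$transcript_id[smry$biotype != "protein_coding"]
  occupied <- new.env(parent = emptyenv())
  min_gap <- 2L * cfg$window
  rows <- list()
  motifs_rna <- names(cfg$motif_mix)

  out <- list(); seq_env <- seqs
  focal_member <- c(AGO2like = "young_only", DROSHAlike = "shared")
  assign_tx <- function() {
    if (stats::runif(1L) < cfg$coding_site_fraction || length(noncoding_ids) == 0L)
      sample(coding_ids, 1L) else sample(noncoding_ids, 1L)
  }
  queue <- membership
  # reserve focal memberships from the queue; a focal site is planted only
  # when the configuration provides a slot of its membership class
  reserved <- character()
  for (f in names(focal_member)) {
    j <- match(focal_member[[f]], queue)
    if (!is.na(j)) {
      queue <- queue[-j]
      reserved[f] <- focal_member[[f]]
    }
  }
  jobs <- c(reserved, stats::setNames(queue, rep("", length(queue))))
  motif_draw <- sample(motifs_rna, length(jobs), replace = TRUE,
                       prob = cfg$motif_mix)
  for (j in seq_along(jobs)) {
    member <- jobs[[j]]
    tx_id <- if (nzchar(names(jobs)[j])) names(jobs)[j] else assign_tx()
    motif <- motif_draw[j]
    m <- models[[tx_id]]
    width <- sample(seq(cfg$fragment_length[1L], cfg$fragment_length[2L]), 1L)
    offs <- .exon_offsets(m)
    ex_w <- m$exons$end - m$exons$start
    elig <- which(ex_w >= width + 10L)
    placed <- FALSE
    for (attempt in seq_len(25L)) {
      if (length(elig) == 0L) break
      e <- if (length(elig) == 1L) elig else sample(elig, 1L, prob = ex_w[elig])
      tx_start <- offs[e] + sample.int(ex_w[e] - width + 1L, 1L) - 1L
      tx_end <- tx_start + width
      occ <- occupied[[tx_id]] %||% matrix(numeric(), ncol = 2L)
      clash <- nrow(occ) > 0L &&
        any(tx_start < occ[, 2L] + min_gap & tx_end > occ[, 1L] - min_gap)
      if (clash) next
      occupied[[tx_id]] <- rbind(occ, c(tx_start, tx_end))
      g <- transcript_to_genomic(m, tx_start, tx_end)
      dna <- chartr("U", "T", motif)
      at <- tx_start + (width - nchar(dna)) %/% 2L
      substr(seq_env[[tx_id]], at + 1L, at + nchar(dna)) <- dna
      out[[length(out) + 1L]] <- tibble::tibble(
        site_id = sprintf("site%04d", length(out) + 1L),
        transcript_id = tx_id, gene_id = m$gene_id,
        chrom = g$chrom[1L], start = g$start[1L], end = g$end[1L],
        strand = m$strand, tx_start = tx_start, tx_end = tx_end,
        width = width, motif = motif,
        in_young = member %in% c("shared", "young_only"),
        in_old = member %in% c("shared", "old_only"))
      placed <- TRUE
      break
    }
    if (!placed && nzchar(names(jobs)[j]))
      stop("could not place a site on focal transcript ", tx_id)
  }
  list(truth = dplyr::bind_rows(out), sequences = seq_env)
}

#' Build sliding windows over the exons of transcript models
#'
#' Windows of fixed width are tiled along each exon (genomic
#' coordinates) with the given step; exons shorter than one window are
#' skipped.
#'
#' @param models named list of [transcript_model()].
#' @param window,step window width and stride in nt.
#' @return tibble: `chrom`, `start`, `end`, `strand`, `transcript_id`.
#' @export
build_windows <- function(models, window = 50L, step = 25L) {
  pieces <- lapply(models, function(m) {
    ex <- m$exons
    starts <- unlist(lapply(seq_len(nrow(ex)), function(i) {
      if (ex$end[i] - ex$start[i] < window) return(integer())
      seq.int(ex$start[i], ex$end[i] - window, by = step)
    }), use.names = FALSE)
    if (length(starts) == 0L) return(NULL)
    data.frame(chrom = m$chrom, start = starts, end = starts + window,
               strand = m$strand, transcript_id = m$transcript_id,
               stringsAsFactors = FALSE)
  })
  tibble::as_tibble(do.call(rbind, pieces))
}

#' Simulate per-cohort MeRIP window counts
#'
#' Input counts are negative binomial around a per-transcript expression
#' level (log-normal across transcripts); IP counts share that mean
#' scaled up by the configured enrichment over the fraction of the
#' window covered by a planted site of the cohort, and are background
#' (ratio 1) elsewhere. Subjects of a cohort are pooled into one library
#' pair, matching a per-cohort site-calling design.
#'
#' @param sim an [simulate_transcriptome()] result.
#' @param enrichment override of the configured IP enrichment at planted
#'   sites (e.g. 1 for a specificity control).
#' @return list with elements `young` and `old`, each a list of
#'   `windows` (tibble with `ip_count`, `input_count`), `ip_libsize`,
#'   `input_libsize`; plus `expression_lambda` (per-transcript mean) and
#'   the shared `window`/`step`.
#' @export
simulate_merip_counts <- function(sim, enrichment = NULL) {
  cfg <- sim$config
  enrichment <- enrichment %||% cfg$enrichment
  set.seed(cfg$seed + 1L)
  windows <- build_windows(sim$models, cfg$window, cfg$step)
  nw <- nrow(windows)
  lambda_tx <- stats::setNames(
    stats::rlnorm(length(sim$models), log(cfg$depth_per_window), cfg$expr_sdlog),
    names(sim$models))
  lam <- lambda_tx[windows$transcript_id]
  wgr <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start + 1L, windows$end),
                                strand = windows$strand)
  size <- 1 / cfg$nb_dispersion
  cohorts <- list()
  for (cohort in c("young", "old")) {
    truth_c <- sim$truth[sim$truth[[paste0("in_", cohort)]], ]
    f <- rep(0, nw)
    if (nrow(truth_c) > 0L) {
      sgr <- GenomicRanges::GRanges(truth_c$chrom,
                                    IRanges::IRanges(truth_c$start + 1L, truth_c$end),
                                    strand = truth_c$strand)
      hits <- GenomicRanges::findOverlaps(wgr, sgr)
      if (length(hits) > 0L) {
        ow <- GenomicRanges::width(IRanges::pintersect(
          wgr[S4Vectors::queryHits(hits)], sgr[S4Vectors::subjectHits(hits)]))
        frac <- ow / cfg$window
        agg <- tapply(frac, S4Vectors::queryHits(hits), max)
        f[as.integer(names(agg))] <- as.numeric(agg)
      }
    }
    mu_ip <- lam * (1 + (enrichment - 1) * f)
    w <- windows
    w$input_count <- stats::rnbinom(nw, mu = lam, size = size)
    w$ip_count <- stats::rnbinom(nw, mu = mu_ip, size = size)
    cohorts[[cohort]] <- list(windows = w,
                              ip_libsize = sum(w$ip_count),
                              input_libsize = sum(w$input_count))
  }
  c(cohorts, list(expression_lambda = lambda_tx,
                  window = cfg$window, step = cfg$step))
}

#' Deterministic cohort design (subjects, groups, ages)
#'
#' @param cfg a [sim_config()].
#' @return tibble: `subject_id`, `group`, `age`.
#' @export
cohort_design <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 9L)
  n <- cfg$n_subjects
  tibble::tibble(
    subject_id = c(sprintf("Y%02d", seq_len(n)), sprintf("O%02d", seq_len(n))),
    group = rep(c("young", "old"), each = n),
    age = round(c(stats::rnorm(n, cfg$young_age_mean, cfg$young_age_sd),
                  stats::rnorm(n, cfg$old_age_mean, cfg$old_age_sd)), 1))
}

#' Simulate the total-RNA expression table
#'
#' Per-gene baselines are log-normal; the old/young log2 fold change of
#' each gene is drawn around zero and shifted upward for methylated
#' genes (the planted CDF displacement), shifted further down for
#' methylated RBP-target genes (AUF1-like and HuR-like sets), and
#' overridden for the three focal transcripts (AGO2-like reduced in old,
#' DROSHA-like unchanged, DICER1-like reduced).
#'
#' @param sim an [simulate_transcriptome()] result.
#' @param methylated_shift override of the configured shift (0 for a
#'   null calibration run).
#' @return list: `expression` (tibble, `gene_id` x subject FPKM),
#'   `design` (see [cohort_design()]), `truth` (tibble `gene_id`,
#'   `true_lfc`, `methylated`, `auf1_like`, `hur_like`), `target_sets`
#'   (named list of gene ID vectors).
#' @export
simulate_expression <- function(sim, methylated_shift = NULL) {
  cfg <- sim$config
  shift <- methylated_shift %||% cfg$methylated_shift
  design <- cohort_design(cfg)
  set.seed(cfg$seed + 2L)
  genes <- names(sim$models)
  ng <- length(genes)
  methylated <- genes %in% sim$truth$gene_id
  auf1 <- stats::runif(ng) < cfg$rbp_target_fraction
  hur <- stats::runif(ng) < cfg$rbp_target_fraction
  base <- stats::rnorm(ng, cfg$base_log2_mean, cfg$base_log2_sd)
  lfc <- stats::rnorm(ng, 0, cfg$lfc_sd) +
    shift * methylated +
    cfg$rbp_target_shift * (methylated & (auf1 | hur))
  focal <- match(names(cfg$focal_lfc), genes)
  lfc[focal[!is.na(focal)]] <- cfg$focal_lfc[!is.na(focal)]
  n <- cfg$n_subjects
  is_old <- design$group == "old"
  vals <- matrix(stats::rnorm(ng * 2L * n, 0, cfg$subject_sd), nrow = ng)
  vals <- vals + base + outer(lfc, as.numeric(is_old))
  fpkm <- 2^vals
  colnames(fpkm) <- design$subject_id
  expression <- tibble::as_tibble(as.data.frame(fpkm))
  expression <- dplyr::bind_cols(tibble::tibble(gene_id = genes), expression)
  list(expression = expression, design = design,
       truth = tibble::tibble(gene_id = genes, true_lfc = lfc,
                              methylated = methylated,
                              auf1_like = auf1, hur_like = hur),
       target_sets = list(auf1_like = genes[auf1], hur_like = genes[hur]))
}

#' Simulate actinomycin-D decay RT-qPCR series
#'
#' The reference gene Ct is constant (plus noise); the target Ct rises
#' by one cycle per half-life elapsed (amplification efficiency 2), so
#' `ct_target(t) = ct0 + t / t_half + noise`.
#'
#' @param cfg a [sim_config()] (uses `decay_t_half`, `decay_replicates`,
#'   `decay_timepoints`, `ct_noise_sd`).
#' @return tibble: `condition`, `replicate`, `time_h`, `ct_target`,
#'   `ct_reference`.
#' @export
simulate_decay <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 3L)
  grid <- expand.grid(time_h = cfg$decay_timepoints,
                      replicate = seq_len(cfg$decay_replicates),
                      condition = names(cfg$decay_t_half),
                      stringsAsFactors = FALSE)
  t_half <- cfg$decay_t_half[grid$condition]
  n <- nrow(grid)
  tibble::tibble(
    condition = grid$condition,
    replicate = grid$replicate,
    time_h = grid$time_h,
    ct_target = 25 + grid$time_h / t_half + stats::rnorm(n, 0, cfg$ct_noise_sd),
    ct_reference = 15 + stats::rnorm(n, 0, cfg$ct_noise_sd))
}

.LET7_IDS <- c("hsa-let-7a-5p", "hsa-let-7b-5p", "hsa-let-7c-5p",
               "hsa-let-7d-5p", "hsa-let-7e-5p", "hsa-let-7f-5p",
               "hsa-let-7g-5p", "hsa-let-7i-5p", "hsa-miR-98-5p",
               "hsa-let-7a-3p", "hsa-let-7b-3p", "hsa-let-7f-1-3p")

#' Simulate a miRNA microarray intensity matrix
#'
#' Log-normal intensities with planted old/young shifts: `mirna_n_up`
#' species raised and `mirna_n_down` lowered in the old group by
#' `mirna_effect` column-sd units on the log10 scale. Seven of the
#' twelve let-7 family members are planted in the down set. Truth labels
#' accompany the matrix.
#'
#' @param cfg a [sim_config()].
#' @param effect override of `mirna_effect` (0 for a null run).
#' @return list: `intensity` (matrix miRNA x subject), `design`,
#'   `truth` (tibble `mirna_id`, `direction` in up/down/null).
#' @export
simulate_mirna <- function(cfg = sim_config(), effect = NULL) {
  effect <- effect %||% cfg$mirna_effect
  design <- cohort_design(cfg)
  set.seed(cfg$seed + 4L)
  n <- cfg$mirna_n
  .assert(n >= length(.LET7_IDS), "mirna_n too small for the let-7 family")
  ids <- c(.LET7_IDS, sprintf("hsa-miR-sim-%04d", seq_len(n - length(.LET7_IDS))))
  direction <- rep("null", n)
  if (effect != 0) {  # zero effect: every truth label stays null
    n_let7_down <- min(7L, cfg$mirna_n_down)
    direction[seq_len(n_let7_down)] <- "down"   # 7 of 12 let-7s down
    rest <- setdiff(seq_len(n), seq_len(length(.LET7_IDS)))
    down_rest <- sample(rest, cfg$mirna_n_down - n_let7_down)
    direction[down_rest] <- "down"
    up_pool <- setdiff(rest, down_rest)
    direction[sample(up_pool, cfg$mirna_n_up)] <- "up"
  }
  base <- stats::rnorm(n, cfg$mirna_base_mean, cfg$mirna_base_sd)
  delta <- effect * cfg$mirna_base_sd *
    (direction == "up") - effect * cfg$mirna_base_sd * (direction == "down")
  is_old <- design$group == "old"
  vals <- matrix(stats::rnorm(n * nrow(design), 0, cfg$mirna_noise_sd), nrow = n)
  vals <- vals + base + outer(delta, as.numeric(is_old))
  intensity <- round(10^vals)
  rownames(intensity) <- ids
  colnames(intensity) <- design$subject_id
  list(intensity = intensity, design = design,
       truth = tibble::tibble(mirna_id = ids, direction = direction))
}

#' Write simulated inputs to disk in standard formats
#'
#' Writes the transcript models (BED12), transcript sequences (FASTA),
#' the ground-truth site registry (TSV) and, when provided, window
#' counts (TSV) so that every stage of the pipeline can be re-run from
#' files.
#'
#' @param sim an [simulate_transcriptome()] result.
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(models = file.path(outdir, "transcripts.bed"),
             fasta = file.path(outdir, "transcripts.fa"),
             truth = file.path(outdir, "truth_sites.tsv"))
  write_transcript_bed12(sim$models, paths[["models"]])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$sequences),
                              paths[["fasta"]])
  readr::write_tsv(sim$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}
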