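#' m6A site calling, motif classification and quantification
#'
#' The site caller works on fixed-width sliding windows carrying IP and
#' input fragment counts. Per window the IP count is tested for enrichment
#' over the library-size-scaled input count with a one-sided
#' negative-binomial tail test; Benjamini-Hochberg correction is applied
#' across windows, and runs of significant windows are merged into sites.
#'
#' The null mean for window i is `lambda0 = (input_i + pseudocount) * rho`
#' with `rho = ip_libsize / input_libsize`. Because `lambda0` is itself a
#' plug-in estimate from a noisy input count, the test variance is
#' propagated: `Var = lambda0 * (1 + rho) + 2 * dispersion * lambda0^2`,
#' realized as a negative-binomial tail with effective size
#' `lambda0 / (rho + 2 * dispersion * lambda0)`. With `dispersion = 0` this
#' reduces to a Poisson-difference style test; the default 0.1 absorbs the
#' biological overdispersion typical of fragment counts.
#'
#' @param windows data.frame of sliding windows with columns `chrom`,
#'   `start`, `end`, `strand` (0-based half-open), `ip_count`,
#'   `input_count`, and optionally `transcript_id`.
#' @param ip_libsize,input_libsize total mapped fragments in the IP and
#'   input libraries (must be positive).
#' @param q_threshold BH-adjusted significance cutoff in (0, 1).
#' @param pseudocount added to both counts for enrichment and to the input
#'   for the null mean; avoids division by zero.
#' @param dispersion negative-binomial overdispersion assumed for fragment
#'   counts (0 = Poisson-like).
#' @param min_enrichment windows must exceed this IP/input enrichment
#'   ratio to be kept (default 1).
#' @param smooth_background when `TRUE` (default) and windows carry a
#'   `transcript_id`, the null mean of each window uses the larger of
#'   its own input count and the mean input count of its transcript, in
#'   the local-background tradition of genomic peak callers; this guards
#'   against spurious calls on windows whose single input draw
#'   undershoots the local coverage. Enrichment estimates still use the
#'   window's own counts.
#' @return tibble of class `m6a_sites` with one row per merged site:
#'   `chrom`, `start`, `end`, `strand`, `transcript_id`, `width`,
#'   `n_windows`, `ip_count`, `input_count` (best constituent window),
#'   `n_fragments` (sum of IP fragments over constituent windows),
#'   `enrichment`, `pvalue`, `qvalue`, `ip_fpkm`, `input_fpkm`,
#'   `motif_class` (`NA` until [classify_sites()] is run).
#' @seealso [classify_sites()], [overlap_sites()], [tally_by_motif()]
#' @export
call_m6a_sites <- function(windows, ip_libsize, input_libsize,
                           q_threshold = 0.05, pseudocount = 0.5,
                           dispersion = 0.1, min_enrichment = 1,
                           smooth_background = TRUE) {
  .assert(ip_libsize > 0 && input_libsize > 0, "library sizes must be positive")
  .assert(q_threshold > 0 && q_threshold < 1, "q_threshold must be in (0,1)")
  .assert(pseudocount >= 0, "pseudocount must be non-negative")
  empty <- .empty_sites()
  if (is.null(windows) || nrow(windows) == 0L) return(empty)
  w <- as.data.frame(windows)
  .assert(all(c("chrom", "start", "end", "strand", "ip_count", "input_count")
              %in% colnames(w)), "windows lack required columns")
  .assert(all(w$ip_count >= 0) && all(w$input_count >= 0),
          "window counts must be non-negative")
  widths <- w$end - w$start
  .assert(length(unique(widths)) <= 2L || stats::sd(widths) < max(widths),
          "windows must share a fixed width")

  rho <- ip_libsize / input_libsize
  enr <- ((w$ip_count + pseudocount) / ip_libsize) /
    ((w$input_count + pseudocount) / input_libsize)
  input_ref <- w$input_count
  if (smooth_background && "transcript_id" %in% colnames(w) &&
      !anyNA(w$transcript_id)) {
    tx_mean <- tapply(w$input_count, w$transcript_id, mean)
    input_ref <- pmax(input_ref, unname(tx_mean[w$transcript_id]))
  }
  lambda0 <- (input_ref + pseudocount) * rho
  size_eff <- lambda0 / (rho + 2 * dispersion * lambda0)
  p <- stats::pnbinom(w$ip_count - 1L, mu = lambda0, size = size_eff,
                      lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  sig <- q <= q_threshold & enr > min_enrichment
  if (!any(sig)) return(empty)

  ws <- w[sig, , drop = FALSE]
  gr <- GenomicRanges::GRanges(ws$chrom,
                               IRanges::IRanges(ws$start + 1L, ws$end),
                               strand = ws$strand)
  merged <- GenomicRanges::reduce(gr)   # merges overlapping and abutting runs
  hits <- GenomicRanges::findOverlaps(gr, merged)
  grp <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
  pv <- p[sig]; qv <- q[sig]
  site_rows <- lapply(split(seq_len(nrow(ws)), grp), function(idx) {
    best <- idx[order(-ws$ip_count[idx], qv[idx])][1L]
    data.frame(ip_count = ws$ip_count[best], input_count = ws$input_count[best],
               n_windows = length(idx), n_fragments = sum(ws$ip_count[idx]),
               pvalue = min(pv[idx]), qvalue = min(qv[idx]),
               transcript_id = if ("transcript_id" %in% colnames(ws))
                 ws$transcript_id[best] else NA_character_)
  })
  agg <- do.call(rbind, site_rows)
  site_width <- GenomicRanges::width(merged)
  sites <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    strand = as.character(GenomicRanges::strand(merged)),
    transcript_id = agg$transcript_id,
    width = site_width,
    n_windows = agg$n_windows,
    ip_count = agg$ip_count,
    input_count = agg$input_count,
    n_fragments = agg$n_fragments,
    enrichment = ((agg$ip_count + pseudocount) / ip_libsize) /
      ((agg$input_count + pseudocount) / input_libsize),
    pvalue = agg$pvalue,
    qvalue = agg$qvalue,
    ip_fpkm = compute_fpkm(agg$ip_count, site_width, ip_libsize),
    input_fpkm = compute_fpkm(agg$input_count, site_width, input_libsize),
    motif_class = NA_character_)
  class(sites) <- c("m6a_sites", class(sites))
  sites
}

.empty_sites <- function() {
  s <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), transcript_id = character(), width = integer(),
    n_windows = integer(), ip_count = numeric(), input_count = numeric(),
    n_fragments = numeric(), enrichment = numeric(), pvalue = numeric(),
    qvalue = numeric(), ip_fpkm = numeric(), input_fpkm = numeric(),
    motif_class = character())
  class(s) <- c("m6a_sites", class(s))
  s
}

sites_to_granges <- function(sites) {
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(sites$start + 1L, sites$end),
                         strand = sites$strand)
}

#' Classify an RNA sequence by its methylation motif hierarchy
#'
#' Sites are assigned to exactly one of the nested DRACH-derived motif
#' classes by longest-match priority: `GGACU` if present, else `GACU`,
#' else `ACU`, else `GAC`, else `none`. Matching is case-insensitive and
#' DNA input (`T`) is accepted and read as `U`. Vectorized.
#'
#' @param site_sequence character vector of RNA (or DNA) sequences.
#' @return character vector over `{GGACU, GACU, ACU, GAC, none}`.
#' @export
classify_motif <- function(site_sequence) {
  s <- chartr("T", "U", toupper(as.character(site_sequence)))
  out <- rep("none", length(s))
  remaining <- !is.na(s) & nzchar(s)
  for (motif in .MOTIF_CLASSES) {
    hit <- remaining & grepl(motif, s, fixed = TRUE)
    out[hit] <- motif
    remaining <- remaining & !hit
  }
  out
}

#' Attach motif classes to called sites from transcript sequences
#'
#' Each site is projected into transcript space and the underlying
#' transcript sequence is classified with [classify_motif()]. Sites that
#' do not project onto their transcript (or lack one) are classified from
#' no sequence and get `none`.
#'
#' @param sites an `m6a_sites` tibble from [call_m6a_sites()].
#' @param models named list of [transcript_model()] objects.
#' @param sequences named [Biostrings::DNAStringSet] (or character vector)
#'   of mature transcript sequences.
#' @return `sites` with `motif_class` filled in.
#' @export
classify_sites <- function(sites, models, sequences) {
  if (nrow(sites) == 0L) return(sites)
  seqs <- if (is.character(sequences)) sequences else
    stats::setNames(as.character(sequences), names(sequences))
  cls <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    tx <- sites$transcript_id[i]
    if (is.na(tx) || is.null(models[[tx]]) || !tx %in% names(seqs)) {
      cls[i] <- "none"; next
    }
    proj <- genomic_to_transcript(
      list(chrom = sites$chrom[i], start = sites$start[i],
           end = sites$end[i], strand = sites$strand[i]), models[[tx]])
    if (is.null(proj)) { cls[i] <- "none"; next }
    cls[i] <- classify_motif(substr(seqs[[tx]], proj[["start"]] + 1L,
                                    proj[["end"]]))
  }
  sites$motif_class <- cls
  sites
}

#' Fragments per kilobase of feature per million mapped fragments
#'
#' `FPKM = count * 1e9 / (feature_length * libsize)`; invariant under
#' joint scaling of count and library size.
#'
#' @param count fragment count(s) on the feature (non-negative).
#' @param feature_length feature length(s) in nt (positive).
#' @param libsize total mapped fragments in the library (positive).
#' @return numeric FPKM value(s).
#' @export
compute_fpkm <- function(count, feature_length, libsize) {
  .assert(all(feature_length > 0), "feature_length must be positive")
  .assert(all(libsize > 0), "libsize must be positive")
  .assert(all(count >= 0), "count must be non-negative")
  count * 1e9 / (feature_length * libsize)
}

#' Overlap two m6A site sets
#'
#' A site is shared when it intersects at least 1 nt of any site in the
#' other set on the same chromosome and strand (half-open convention, so
#' abutting sites do not overlap). Because one site may intersect several
#' sites of the other set, shared counts are reported from each side:
#' `shared_a` counts sites of `a` hit by `b` and vice versa; `shared` is
#' the a-side count. `a_only + shared_a = nrow(a)` and symmetrically.
#'
#' @param sites_a,sites_b `m6a_sites` tibbles (e.g. young and old cohorts).
#' @return list of class `m6a_overlap` with counts (`n_a`, `n_b`,
#'   `a_only`, `b_only`, `shared`, `shared_a`, `shared_b`) and the site
#'   subsets (`sites_a_only`, `sites_shared_a`, `sites_b_only`,
#'   `sites_shared_b`).
#' @export
overlap_sites <- function(sites_a, sites_b) {
  hit_a <- if (nrow(sites_a) == 0L || nrow(sites_b) == 0L)
    rep(FALSE, nrow(sites_a))
  else suppressWarnings(
    GenomicRanges::countOverlaps(sites_to_granges(sites_a),
                                 sites_to_granges(sites_b))) > 0L
  hit_b <- if (nrow(sites_a) == 0L || nrow(sites_b) == 0L)
    rep(FALSE, nrow(sites_b))
  else suppressWarnings(
    GenomicRanges::countOverlaps(sites_to_granges(sites_b),
                                 sites_to_granges(sites_a))) > 0L
  structure(list(
    n_a = nrow(sites_a), n_b = nrow(sites_b),
    shared = sum(hit_a), shared_a = sum(hit_a), shared_b = sum(hit_b),
    a_only = sum(!hit_a), b_only = sum(!hit_b),
    sites_a_only = sites_a[!hit_a, ], sites_shared_a = sites_a[hit_a, ],
    sites_b_only = sites_b[!hit_b, ], sites_shared_b = sites_b[hit_b, ]),
    class = "m6a_overlap")
}

#' @export
print.m6a_overlap <- function(x, ...) {
  cat(sprintf("<m6a_overlap> A: %d sites (%d unique, %d shared) | B: %d sites (%d unique, %d shared)\n",
              x$n_a, x$a_only, x$shared_a, x$n_b, x$b_only, x$shared_b))
  invisible(x)
}

#' Tally m6A sites by transcript biotype
#'
#' @param sites an `m6a_sites` tibble with `transcript_id` filled.
#' @param models named list of [transcript_model()] objects.
#' @return tibble with `biotype` (the four classes plus `unknown` for
#'   transcript IDs absent from `models`) and `n_sites`.
#' @export
tally_by_biotype <- function(sites, models) {
  bt <- vapply(sites$transcript_id, function(tx) {
    if (is.na(tx) || is.null(models[[tx]])) "unknown" else models[[tx]]$biotype
  }, character(1), USE.NAMES = FALSE)
  lv <- c(.BIOTYPES, "unknown")
  counts <- table(factor(bt, levels = lv))
  tibble::tibble(biotype = lv, n_sites = as.integer(counts))
}

#' Tally m6A sites by motif class
#'
#' Proportions are computed over the four motif classes; `none` sites are
#' reported separately and excluded from the denominator.
#'
#' @param sites an `m6a_sites` tibble with `motif_class` filled.
#' @param by `"site"` (default) tallies sites; `"transcript"` counts each
#'   transcript once per motif class.
#' @return tibble with `motif_class`, `n`, `proportion` (rows: the four
#'   classes then `none` with proportion `NA`).
#' @export
tally_by_motif <- function(sites, by = c("site", "transcript")) {
  by <- match.arg(by)
  df <- sites
  if (by == "transcript")
    df <- dplyr::distinct(as.data.frame(df)[, c("transcript_id", "motif_class")])
  counts <- table(factor(df$motif_class, levels = c(.MOTIF_CLASSES, "none")))
  n_classified <- sum(counts[.MOTIF_CLASSES])
  prop <- c(if (n_classified > 0) as.numeric(counts[.MOTIF_CLASSES]) / n_classified
            else rep(NA_real_, 4L), NA_real_)
  tibble::tibble(motif_class = c(.MOTIF_CLASSES, "none"),
                 n = as.integer(counts), proportion = prop)
}

#' MeRIP-qPCR fold enrichment over a nonspecific control
#'
#' Computes `(ip / input) / (control_ip / control_input)`, the fold
#' enrichment of a target transcript in the m6A immunoprecipitate relative
#' to a nonspecific binding control such as 18S rRNA. Quantities are
#' relative abundances (e.g. `2^-dCt` values) and must be positive.
#'
#' @param ip_quantity,input_quantity target quantities in IP and input.
#' @param control_ip,control_input control quantities in IP and input.
#' @return numeric fold enrichment.
#' @export
merip_qpcr_enrichment <- function(ip_quantity, input_quantity,
                                  control_ip, control_input) {
  vals <- c(ip_quantity, input_quantity, control_ip, control_input)
  .assert(all(is.finite(vals)) && all(vals > 0),
          "all quantities must be positive and finite")
  (ip_quantity / input_quantity) / (control_ip / control_input)
}
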