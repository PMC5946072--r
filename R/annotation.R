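#' Transcript models, coordinate projection and annotation I/O
#'
#' A transcript model records the exon structure of one mature transcript
#' together with its biotype and, for coding transcripts, the CDS span in
#' transcript-space coordinates. All coordinates are 0-based half-open
#' internally; BED input is native, GTF (1-based closed) is converted on
#' read. Exons are stored 5'->3' in transcript orientation, so for minus
#' strand transcripts the first exon is the genomically rightmost one.
#'
#' @param transcript_id,gene_id identifiers (gene defaults to transcript).
#' @param chrom,strand chromosome name and strand ("+" or "-").
#' @param exons data.frame with integer columns `start`, `end` (0-based
#'   half-open genomic coordinates), non-overlapping.
#' @param biotype one of `protein_coding`, `lncRNA`, `pseudogene`,
#'   `other_noncoding`.
#' @param cds_start,cds_end CDS span in transcript-space nt from the 5' end
#'   of the mature transcript (`NA` for noncoding transcripts).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons,
                             biotype = "protein_coding",
                             gene_id = transcript_id,
                             cds_start = NA_integer_, cds_end = NA_integer_) {
  .assert(is.character(transcript_id) && length(transcript_id) == 1L,
          "transcript_id must be a single string")
  .assert(strand %in% c("+", "-"), "strand must be '+' or '-'")
  .assert(biotype %in% .BIOTYPES,
          sprintf("biotype must be one of: %s", paste(.BIOTYPES, collapse = ", ")))
  exons <- as.data.frame(exons)[, c("start", "end")]
  .assert(all(exons$start < exons$end), "exon start must be < end")
  o <- order(exons$start)
  exons_sorted <- exons[o, , drop = FALSE]
  .assert(!anyNA(exons_sorted$start) && !anyNA(exons_sorted$end) &&
            all(exons_sorted$start >= 0), "exon coordinates must be non-negative")
  if (nrow(exons_sorted) > 1L) {
    .assert(all(exons_sorted$start[-1L] >= exons_sorted$end[-nrow(exons_sorted)]),
            sprintf("exons of %s overlap", transcript_id))
  }
  # 5'->3' transcript orientation
  if (strand == "-") exons_sorted <- exons_sorted[rev(seq_len(nrow(exons_sorted))), , drop = FALSE]
  rownames(exons_sorted) <- NULL
  exons_sorted$start <- as.integer(exons_sorted$start)
  exons_sorted$end <- as.integer(exons_sorted$end)
  len <- sum(exons_sorted$end - exons_sorted$start)
  if (!is.na(cds_start) || !is.na(cds_end)) {
    .assert(!is.na(cds_start) && !is.na(cds_end), "cds_start and cds_end must both be given")
    .assert(cds_start >= 0 && cds_start < cds_end && cds_end <= len,
            sprintf("CDS [%d,%d) outside transcript %s of length %d",
                    cds_start, cds_end, transcript_id, len))
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, biotype = biotype,
         chrom = chrom, strand = strand, exons = exons_sorted,
         tx_length = len,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cds <- if (is.na(x$cds_start)) "noncoding" else
    sprintf("CDS [%d,%d)", x$cds_start, x$cds_end)
  cat(sprintf("<transcript_model> %s (%s, %s) %s:%s %d exon(s), %d nt, %s\n",
              x$transcript_id, x$gene_id, x$biotype, x$chrom, x$strand,
              nrow(x$exons), x$tx_length, cds))
  invisible(x)
}

is_coding <- function(model) !is.na(model$cds_start)

# Cumulative transcript-space offset of each exon (5'->3' order)
.exon_offsets <- function(model) {
  w <- model$exons$end - model$exons$start
  cumsum(c(0L, w[-length(w)]))
}

#' Project a genomic interval into mature-transcript coordinates
#'
#' Projects the exonic part of a genomic interval into the coordinate
#' system of the mature transcript (nt from the 5' end, 0-based half-open).
#' On the minus strand the orientation is reversed so that positions count
#' from the transcript 5' end. Returns `NULL` when the interval has no
#' exonic overlap or lies on a different chromosome/strand.
#'
#' @param iv a list or one-row data.frame with `chrom`, `start`, `end`,
#'   `strand` (0-based half-open genomic interval).
#' @param model a [transcript_model()].
#' @return Integer vector `c(start, end)` in transcript space, or `NULL`.
#' @export
genomic_to_transcript <- function(iv, model) {
  if (!identical(as.character(iv$chrom), model$chrom) ||
      !identical(as.character(iv$strand), model$strand)) return(NULL)
  .assert(iv$start < iv$end, "interval start must be < end")
  offs <- .exon_offsets(model)
  ex <- model$exons
  lo <- NA_integer_; hi <- NA_integer_
  for (i in seq_len(nrow(ex))) {
    os <- max(iv$start, ex$start[i]); oe <- min(iv$end, ex$end[i])
    if (os >= oe) next
    if (model$strand == "+") {
      ts <- offs[i] + (os - ex$start[i]); te <- offs[i] + (oe - ex$start[i])
    } else {
      ts <- offs[i] + (ex$end[i] - oe);  te <- offs[i] + (ex$end[i] - os)
    }
    lo <- min(lo, ts, na.rm = TRUE); hi <- max(hi, te, na.rm = TRUE)
  }
  if (is.na(lo)) return(NULL)
  c(start = as.integer(lo), end = as.integer(hi))
}

#' Map a transcript-space interval back to genomic coordinates
#'
#' Inverse of [genomic_to_transcript()]: returns the genomic chunks (one
#' per exon touched) covering a transcript-space interval.
#'
#' @param model a [transcript_model()].
#' @param tx_start,tx_end transcript-space 0-based half-open interval.
#' @return data.frame with `chrom`, `start`, `end`, `strand`, ordered 5'->3'.
#' @export
transcript_to_genomic <- function(model, tx_start, tx_end) {
  .assert(tx_start >= 0 && tx_start < tx_end && tx_end <= model$tx_length,
          "transcript-space interval out of bounds")
  offs <- .exon_offsets(model)
  ex <- model$exons
  out <- list()
  for (i in seq_len(nrow(ex))) {
    w <- ex$end[i] - ex$start[i]
    s <- max(tx_start, offs[i]); e <- min(tx_end, offs[i] + w)
    if (s >= e) next
    if (model$strand == "+") {
      gs <- ex$start[i] + (s - offs[i]); ge <- ex$start[i] + (e - offs[i])
    } else {
      gs <- ex$end[i] - (e - offs[i]);   ge <- ex$end[i] - (s - offs[i])
    }
    out[[length(out) + 1L]] <- data.frame(chrom = model$chrom, start = gs,
                                          end = ge, strand = model$strand,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Collapse annotation biotypes into the four-class vocabulary.
.collapse_biotype <- function(x) {
  x <- ifelse(is.na(x), "other_noncoding", x)
  out <- rep("other_noncoding", length(x))
  out[x %in% "protein_coding"] <- "protein_coding"
  out[grepl("pseudogene", x)] <- "pseudogene"
  out[x %in% c("lncRNA", "lincRNA", "antisense", "processed_transcript",
               "sense_intronic", "sense_overlapping", "3prime_overlapping_ncRNA",
               "bidirectional_promoter_lncRNA", "macro_lncRNA")] <- "lncRNA"
  known <- x %in% c("protein_coding") | grepl("pseudogene", x) |
    out == "lncRNA" | x == "other_noncoding"
  if (any(!known)) {
    warning(sprintf("collapsing unrecognized biotype(s) to other_noncoding: %s",
                    paste(unique(x[!known]), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Read transcript models from GTF or BED12
#'
#' Parses transcript structures from a GTF (exon and CDS records, 1-based
#' closed, converted to the internal 0-based half-open convention) or a
#' BED12 file (native convention; `thickStart`/`thickEnd` taken as the
#' CDS). The BED12 `name` field may be plain `transcript_id` or
#' `transcript_id|gene_id|biotype` as written by
#' [write_transcript_bed12()]. Gzip-compressed files are accepted.
#'
#' @param path file path (optionally `.gz`).
#' @param format `"gtf"`, `"bed12"`, or `"auto"` (by file extension).
#' @return Named list of [transcript_model()] objects (names are
#'   transcript IDs).
#' @export
read_transcript_models <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.bed$", base, ignore.case = TRUE)) "bed12" else "gtf"
  }
  if (format == "bed12") .read_models_bed12(path) else .read_models_gtf(path)
}

.read_models_bed12 <- function(path) {
  g <- tryCatch(rtracklayer::import(path, format = "bed"),
                error = function(e) stop("BED12 parse error in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  mc <- S4Vectors::mcols(g)
  .assert(!is.null(mc$blocks), "BED input lacks block (BED12) columns")
  out <- vector("list", length(g))
  for (i in seq_along(g)) {
    feat_start <- GenomicRanges::start(g)[i] - 1L   # to 0-based
    blocks <- mc$blocks[[i]]                        # 1-based, feature-relative
    exons <- data.frame(start = feat_start + IRanges::start(blocks) - 1L,
                        end   = feat_start + IRanges::end(blocks))
    name <- mc$name[i] %||% sprintf("tx%06d", i)
    parts <- strsplit(name, "|", fixed = TRUE)[[1]]
    tx_id <- parts[1]
    gene <- if (length(parts) >= 2) parts[2] else tx_id
    bt <- if (length(parts) >= 3) .collapse_biotype(parts[3]) else NA_character_
    strand <- as.character(GenomicRanges::strand(g))[i]
    .assert(strand %in% c("+", "-"),
            sprintf("BED12 record %s lacks a strand", tx_id))
    thick <- mc$thick[i]
    cds_start <- NA_integer_; cds_end <- NA_integer_
    has_cds <- length(thick) == 1L && IRanges::width(thick) > 0L
    if (has_cds) {
      civ <- list(chrom = as.character(GenomicRanges::seqnames(g))[i],
                  start = IRanges::start(thick) - 1L, end = IRanges::end(thick),
                  strand = strand)
      m0 <- transcript_model(tx_id, civ$chrom, strand, exons,
                             biotype = "protein_coding", gene_id = gene)
      proj <- genomic_to_transcript(civ, m0)
      .assert(!is.null(proj), sprintf("CDS of %s falls outside its exons", tx_id))
      cds_start <- proj[["start"]]; cds_end <- proj[["end"]]
    }
    if (is.na(bt)) bt <- if (has_cds) "protein_coding" else "other_noncoding"
    out[[i]] <- transcript_model(tx_id, as.character(GenomicRanges::seqnames(g))[i],
                                 strand, exons, biotype = bt, gene_id = gene,
                                 cds_start = cds_start, cds_end = cds_end)
  }
  stats::setNames(out, vapply(out, `[[`, "", "transcript_id"))
}

.read_models_gtf <- function(path) {
  g <- tryCatch(rtracklayer::import(path, format = "gtf"),
                error = function(e) stop("GTF parse error in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  mc <- S4Vectors::mcols(g)
  .assert(!is.null(mc$transcript_id), "GTF lacks transcript_id attributes")
  bt_col <- intersect(c("transcript_biotype", "gene_biotype", "transcript_type",
                        "gene_type"), colnames(mc))[1]
  keep <- mc$type %in% c("exon", "CDS")
  g <- g[keep]; mc <- S4Vectors::mcols(g)
  ids <- unique(mc$transcript_id[mc$type == "exon"])
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    sel <- mc$transcript_id == ids[k]
    gi <- g[sel]; mi <- S4Vectors::mcols(gi)
    ex <- gi[mi$type == "exon"]
    exons <- data.frame(start = GenomicRanges::start(ex) - 1L,
                        end = GenomicRanges::end(ex))
    strand <- as.character(GenomicRanges::strand(ex))[1]
    chrom <- as.character(GenomicRanges::seqnames(ex))[1]
    gene <- mi$gene_id[mi$type == "exon"][1] %||% ids[k]
    bt_raw <- if (!is.na(bt_col)) mi[[bt_col]][1] else NA_character_
    cds <- gi[mi$type == "CDS"]
    cds_start <- NA_integer_; cds_end <- NA_integer_
    bt <- .collapse_biotype(bt_raw)
    if (length(cds) > 0) bt <- "protein_coding"
    m0 <- transcript_model(ids[k], chrom, strand, exons, biotype = bt,
                           gene_id = gene)
    if (length(cds) > 0) {
      lo <- Inf; hi <- -Inf; covered <- 0L
      for (j in seq_along(cds)) {
        proj <- genomic_to_transcript(
          list(chrom = chrom, start = GenomicRanges::start(cds)[j] - 1L,
               end = GenomicRanges::end(cds)[j], strand = strand), m0)
        .assert(!is.null(proj),
                sprintf("CDS chunk of %s falls outside its exons", ids[k]))
        lo <- min(lo, proj[["start"]]); hi <- max(hi, proj[["end"]])
        covered <- covered + (proj[["end"]] - proj[["start"]])
      }
      .assert(covered == hi - lo,
              sprintf("CDS chunks of %s are not exon-contiguous", ids[k]))
      cds_start <- lo; cds_end <- hi
      m0 <- transcript_model(ids[k], chrom, strand, exons,
                             biotype = bt, gene_id = gene,
                             cds_start = cds_start, cds_end = cds_end)
    }
    out[[k]] <- m0
  }
  stats::setNames(out, ids)
}

#' Write transcript models as BED12
#'
#' The `name` column encodes `transcript_id|gene_id|biotype` so that
#' [read_transcript_models()] round-trips models exactly.
#'
#' @param models named list of [transcript_model()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_transcript_bed12 <- function(models, path) {
  lines <- vapply(models, function(m) {
    ex <- m$exons
    if (m$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    chrom_start <- min(ex$start); chrom_end <- max(ex$end)
    if (is_coding(m)) {
      chunks <- transcript_to_genomic(m, m$cds_start, m$cds_end)
      thick_start <- min(chunks$start); thick_end <- max(chunks$end)
    } else {
      thick_start <- chrom_start; thick_end <- chrom_start
    }
    paste(m$chrom, chrom_start, chrom_end,
          paste(m$transcript_id, m$gene_id, m$biotype, sep = "|"),
          0L, m$strand, thick_start, thick_end, 0L, nrow(ex),
          paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - chrom_start, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene set (one ID per line)
#'
#' Lines starting with `#` and blank lines are ignored; IDs are
#' deduplicated. An empty result triggers a warning, not an error.
#'
#' @param path file path (optionally gzip-compressed).
#' @return Character vector of unique gene IDs.
#' @export
read_gene_set <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x <- unique(x[nzchar(x)])
  if (length(x) == 0L)
    warning("gene set file ", path, " contains no IDs", call. = FALSE)
  x
}

#' Summarize transcript models as a tibble
#'
#' @param models named list of [transcript_model()] objects.
#' @return tibble with one row per transcript.
#' @export
models_summary <- function(models) {
  tibble::tibble(
    transcript_id = vapply(models, `[[`, "", "transcript_id"),
    gene_id = vapply(models, `[[`, "", "gene_id"),
    biotype = vapply(models, `[[`, "", "biotype"),
    chrom = vapply(models, `[[`, "", "chrom"),
    strand = vapply(models, `[[`, "", "strand"),
    n_exons = vapply(models, function(m) nrow(m$exons), 0L),
    tx_length = vapply(models, `[[`, 0L, "tx_length"),
    cds_start = vapply(models, `[[`, NA_integer_, "cds_start"),
    cds_end = vapply(models, `[[`, NA_integer_, "cds_end"))
}

# Gene-level rollup: the longest isoform represents each gene.
longest_isoform <- function(models) {
  smry <- models_summary(models)
  keep <- unlist(lapply(split(seq_len(nrow(smry)), smry$gene_id), function(idx) {
    idx[which.max(smry$tx_length[idx])]
  }), use.names = FALSE)
  models[sort(keep)]
}
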