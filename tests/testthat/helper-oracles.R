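# Independent oracles and small fixture builders used across test files.
# Oracles are deliberately brute-force and share no code with the package
# implementations they check.

# Per-base projection oracle: enumerate every exonic base of the model in
# transcript order, then map an interval by looking its bases up.
oracle_base_map <- function(model) {
  ex <- model$exons   # already 5'->3' in transcript orientation
  bases <- integer()
  for (i in seq_len(nrow(ex))) {
    b <- seq.int(ex$start[i], ex$end[i] - 1L)
    if (model$strand == "-") b <- rev(b)
    bases <- c(bases, b)
  }
  bases  # bases[k] = genomic position of transcript base k-1
}

oracle_project <- function(iv, model) {
  if (!identical(iv$chrom, model$chrom) || !identical(iv$strand, model$strand))
    return(NULL)
  bmap <- oracle_base_map(model)
  hit <- which(bmap >= iv$start & bmap < iv$end)
  if (length(hit) == 0L) return(NULL)
  c(start = min(hit) - 1L, end = max(hit))
}

# O(n^2) all-pairs interval intersection oracle (half-open)
oracle_overlap_flags <- function(a, b) {
  flags <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && a$strand[i] == b$strand[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        flags[i] <- TRUE
        break
      }
    }
  }
  flags
}

# Motif oracle: enumerate all substrings of lengths 3..5 and pick the
# highest-priority motif present.
oracle_motif <- function(seq) {
  s <- toupper(seq)
  s <- gsub("T", "U", s)
  n <- nchar(s)
  found <- character()
  for (len in 3:5) {
    if (n < len) next
    for (i in seq_len(n - len + 1L)) {
      found <- c(found, substr(s, i, i + len - 1L))
    }
  }
  for (m in c("GGACU", "GACU", "ACU", "GAC")) if (m %in% found) return(m)
  "none"
}

# Random multi-exon transcript model for property tests
random_model <- function(n_exons = 5L, coding = TRUE) {
  ex_len <- sample(80:300, n_exons, replace = TRUE)
  introns <- sample(50:400, n_exons, replace = TRUE)
  starts <- 1000L + cumsum(c(0L, (ex_len + introns)[-n_exons]))
  strand <- sample(c("+", "-"), 1L)
  len <- sum(ex_len)
  cds_start <- NA_integer_; cds_end <- NA_integer_
  if (coding) {
    cds_start <- sample.int(len %/% 3L, 1L)
    cds_end <- cds_start + sample.int(len - cds_start - 1L, 1L)
  }
  transcript_model(paste0("rtx", sample.int(1e6, 1L)), "chrT", strand,
                   data.frame(start = starts, end = starts + ex_len),
                   biotype = if (coding) "protein_coding" else "lncRNA",
                   cds_start = cds_start, cds_end = cds_end)
}

# Minimal m6a_sites-like tibble for overlap/tally/metagene tests
make_sites <- function(start, end, chrom = "chr1", strand = "+",
                       transcript_id = NA_character_,
                       motif_class = NA_character_, ip_fpkm = 1) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 transcript_id = transcript_id, motif_class = motif_class,
                 ip_fpkm = ip_fpkm,
                 qvalue = 0.01, enrichment = 2, n_fragments = 1)
}

# Random site set on a couple of chromosomes/strands (for overlap oracle)
random_sites <- function(n, width_range = c(50L, 200L)) {
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  s <- sample.int(5000L, n, replace = TRUE)
  make_sites(s, s + w,
             chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE))
}

# Small two-group design
toy_design <- function(n = 4L) {
  tibble::tibble(
    subject_id = c(sprintf("Y%d", seq_len(n)), sprintf("O%d", seq_len(n))),
    group = rep(c("young", "old"), each = n))
}
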