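# The quantitative core: RPKM normalization, strand-aware overlap counting,
# 100-bin metagene repair profiles over genes and half-length flanks,
# per-gene normalized TS/NTS repair ratios, chromatin-state repair, and the
# two statistical analyses (Pearson correlation with expression, pairwise
# Welch tests across states).
#
# Strand convention: the excised oligonucleotide aligns to its strand of
# origin, so reads on the strand OPPOSITE a gene's annotated strand report
# template-strand (TS, transcription-coupled) repair; same-strand reads
# report non-transcribed-strand (NTS) repair.

#' Reads per kilobase per million mapped reads
#'
#' @param count Read count(s) on the feature.
#' @param length_bp Feature length(s) in bp (> 0).
#' @param library_total Total mapped reads in the library (> 0).
#' @return `count / ((length_bp / 1e3) * (library_total / 1e6))`.
#' @export
rpkm <- function(count, length_bp, library_total) {
  if (any(length_bp <= 0)) stop("rpkm: feature length must be > 0")
  if (any(library_total <= 0)) stop("rpkm: library total must be > 0")
  count / ((length_bp / 1e3) * (library_total / 1e6))
}

#' Count reads overlapping features, strand-aware
#'
#' A read counts toward every feature it overlaps by at least `min_overlap`
#' bp under the strand rule; no ambiguity resolution. `"same"` requires the
#' read strand to equal the feature strand, `"opposite"` the reverse,
#' `"ignore"` counts regardless of strand.
#'
#' @param features Data.frame with `chrom`, `start`, `end` and (for the
#'   stranded modes) `strand`.
#' @param reads Read data.frame.
#' @param strand_mode One of `"same"`, `"opposite"`, `"ignore"`.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return Integer vector of counts, one per feature row.
#' @export
count_overlaps <- function(features, reads,
                           strand_mode = c("same", "opposite", "ignore"),
                           min_overlap = 1L) {
  strand_mode <- match.arg(strand_mode)
  if (nrow(features) == 0L) return(integer(0))
  if (nrow(reads) == 0L) return(integer(nrow(features)))
  fgr <- .as_granges(features)
  rstrand <- reads$strand
  if (strand_mode == "opposite") {
    rstrand <- ifelse(reads$strand == "+", "-", "+")
  }
  rgr <- .as_granges(reads, strand = rstrand)
  GenomicRanges::countOverlaps(fgr, rgr, minoverlap = min_overlap,
                               ignore.strand = (strand_mode == "ignore"))
}

# Split an extended gene region into n equal bins (0-based half-open), bin 1
# at the 5' end of the gene. Returns a data.frame of bins for one gene.
.gene_bins <- function(chrom, start, end, strand, flank, n_bins) {
  r0 <- start - flank
  width <- (end + flank) - r0
  edges <- r0 + floor(width * (0:n_bins) / n_bins)
  b <- data.frame(
    chrom = chrom,
    start = edges[-(n_bins + 1L)],
    end = edges[-1L],
    strand = strand
  )
  b$bin <- if (strand == "+") seq_len(n_bins) else rev(seq_len(n_bins))
  b
}

#' Metagene repair profile over genes and flanks
#'
#' Each gene is extended by `flank_fraction` of its length on both sides
#' (default half-length, so the extended region is twice the gene length)
#' and the extended region is divided into `n_bins` equal bins; with the
#' defaults, bins 1-25 cover the upstream flank, 26-75 the gene body and
#' 76-100 the downstream flank. Bin 1 is always 5'-most (bin order reversed
#' for `-` genes). Counts are pooled over genes per bin index, separately
#' for TS (reads opposite the gene strand) and NTS (same strand) and for the
#' real and simulated libraries; each pooled count is RPKM-normalized with
#' the pooled bin length and the library total, and normalized repair is
#' real RPKM / simulated RPKM per bin. Genes whose extended region leaves
#' the chromosome are skipped and counted.
#'
#' @param genes Gene data.frame from [read_gene_annotation()].
#' @param real_reads,sim_reads Read data.frames (real and matched simulated
#'   library).
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param n_bins Number of bins (default 100).
#' @param flank_fraction Flank length as a fraction of gene length
#'   (default 0.5).
#' @param aggregate `"pooled"` (default) sums counts over genes per bin
#'   index and forms one ratio per bin; `"per_gene_mean"` forms the ratio
#'   per gene and bin (library-size corrected; undefined where the
#'   simulated count is 0) and averages the defined ratios across genes —
#'   a sensitivity mode, less robust in sparse bins.
#' @return An object of class `metagene_profile`: a long data.frame
#'   `profile` with one row per bin x strand-class (`bin`, `strand_class`,
#'   counts, pooled length, RPKMs, `normalized_repair`), plus bookkeeping
#'   (`n_genes_used`, `n_genes_skipped`, `undefined_bins`).
#' @export
metagene_profile <- function(genes, real_reads, sim_reads, chrom_sizes,
                             n_bins = 100L, flank_fraction = 0.5,
                             aggregate = c("pooled", "per_gene_mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(nrow(genes) > 0L)
  .check_reads(real_reads, what = "real_reads")
  .check_reads(sim_reads, what = "sim_reads")
  flank <- as.integer(round((genes$end - genes$start) * flank_fraction))
  usable <- genes$start - flank >= 0 &
    genes$end + flank <= chrom_sizes[genes$chrom]
  n_skipped <- sum(!usable)
  if (!any(usable)) stop("no usable genes: all extended regions leave their chromosome")
  g <- genes[usable, , drop = FALSE]
  flank <- flank[usable]
  bins <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    .gene_bins(g$chrom[i], g$start[i], g$end[i], g$strand[i], flank[i], n_bins)
  }))
  counts <- list(
    real_TS  = count_overlaps(bins, real_reads, "opposite"),
    real_NTS = count_overlaps(bins, real_reads, "same"),
    sim_TS   = count_overlaps(bins, sim_reads, "opposite"),
    sim_NTS  = count_overlaps(bins, sim_reads, "same")
  )
  width <- bins$end - bins$start
  pool <- function(x) as.numeric(rowsum(x, bins$bin)[as.character(1:n_bins), 1L])
  pooled_len <- pool(width)
  prof <- do.call(rbind, lapply(c("TS", "NTS"), function(sc) {
    real_all <- counts[[paste0("real_", sc)]]
    sim_all <- counts[[paste0("sim_", sc)]]
    real_c <- pool(real_all)
    sim_c <- pool(sim_all)
    real_rpkm <- rpkm(real_c, pooled_len, nrow(real_reads))
    sim_rpkm <- rpkm(sim_c, pooled_len, nrow(sim_reads))
    norm <- if (aggregate == "pooled") {
      ifelse(sim_c > 0, real_rpkm / sim_rpkm, NA_real_)
    } else {
      # per gene-bin ratio (bin lengths cancel within a gene-bin), averaged
      # over genes with a defined ratio
      r <- ifelse(sim_all > 0,
                  (real_all / sim_all) * (nrow(sim_reads) / nrow(real_reads)),
                  NA_real_)
      as.numeric(tapply(r, bins$bin, mean, na.rm = TRUE)[as.character(1:n_bins)])
    }
    data.frame(
      bin = 1:n_bins, strand_class = sc,
      real_count = real_c, sim_count = sim_c, pooled_length = pooled_len,
      real_rpkm = real_rpkm, sim_rpkm = sim_rpkm,
      normalized_repair = norm
    )
  }))
  rownames(prof) <- NULL
  structure(list(
    profile = prof,
    n_bins = as.integer(n_bins),
    flank_fraction = flank_fraction,
    aggregate = aggregate,
    body_bins = seq.int(floor(n_bins * flank_fraction / (1 + 2 * flank_fraction)) + 1L,
                        n_bins - floor(n_bins * flank_fraction / (1 + 2 * flank_fraction))),
    n_genes_used = nrow(g),
    n_genes_skipped = n_skipped,
    undefined_bins = sum(is.na(prof$normalized_repair))
  ), class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  body <- x$profile$bin %in% x$body_bins
  ts <- x$profile$strand_class == "TS"
  cat(sprintf(
    "metagene repair profile: %d bins x TS/NTS over %d genes (%d skipped)\n",
    x$n_bins, x$n_genes_used, x$n_genes_skipped))
  cat(sprintf("mean body-bin normalized repair: TS %.3f, NTS %.3f\n",
              mean(x$profile$normalized_repair[body & ts], na.rm = TRUE),
              mean(x$profile$normalized_repair[body & !ts], na.rm = TRUE)))
  invisible(x)
}

#' Per-gene normalized TS/NTS repair
#'
#' Counts real and simulated reads on each strand of each complete gene
#' region (no flanks), RPKM-normalizes with the gene length and library
#' totals, forms normalized repair (real RPKM / sim RPKM) per strand, and
#' the log2 of normalized TS over normalized NTS. Genes with a zero in any
#' of the four counts get `NA` ratios (flagged `defined = FALSE`) and are
#' excluded from summary statistics downstream.
#'
#' @inheritParams metagene_profile
#' @return Data.frame with one row per gene: counts, RPKMs, `norm_ts`,
#'   `norm_nts`, `log2_ts_nts`, `defined`.
#' @export
gene_ts_nts <- function(genes, real_reads, sim_reads) {
  stopifnot(nrow(genes) > 0L)
  .check_reads(real_reads, what = "real_reads")
  .check_reads(sim_reads, what = "sim_reads")
  len <- genes$end - genes$start
  real_ts <- count_overlaps(genes, real_reads, "opposite")
  real_nts <- count_overlaps(genes, real_reads, "same")
  sim_ts <- count_overlaps(genes, sim_reads, "opposite")
  sim_nts <- count_overlaps(genes, sim_reads, "same")
  nr <- nrow(real_reads); ns <- nrow(sim_reads)
  out <- data.frame(
    id = genes$id,
    length = len,
    real_ts = real_ts, real_nts = real_nts,
    sim_ts = sim_ts, sim_nts = sim_nts,
    rpkm_real_ts = rpkm(real_ts, len, nr),
    rpkm_real_nts = rpkm(real_nts, len, nr),
    rpkm_sim_ts = rpkm(sim_ts, len, ns),
    rpkm_sim_nts = rpkm(sim_nts, len, ns)
  )
  out$defined <- real_ts > 0 & real_nts > 0 & sim_ts > 0 & sim_nts > 0
  out$norm_ts <- ifelse(sim_ts > 0, out$rpkm_real_ts / out$rpkm_sim_ts, NA_real_)
  out$norm_nts <- ifelse(sim_nts > 0, out$rpkm_real_nts / out$rpkm_sim_nts, NA_real_)
  out$log2_ts_nts <- ifelse(out$defined,
                            log2(out$norm_ts / out$norm_nts), NA_real_)
  out
}

#' Summary of the TS/NTS ratio distribution
#'
#' Boxplot-ready summary (quartiles, median, n) of per-gene log2 normalized
#' TS/NTS ratios, optionally set against a comparison record set (e.g. a
#' second damage type), with a two-sample Wilcoxon comparison of the two
#' distributions.
#'
#' @param records Output of [gene_ts_nts()].
#' @param comparison Optional second [gene_ts_nts()] output.
#' @param labels Labels for the one or two record sets.
#' @return Data.frame with one row per record set (label, n, quartiles,
#'   median); if `comparison` is given, attribute `wilcox_p` holds the
#'   two-sided rank-sum p-value.
#' @export
ts_nts_distribution_summary <- function(records, comparison = NULL,
                                        labels = c("primary", "comparison")) {
  one <- function(rec, label) {
    x <- rec$log2_ts_nts[rec$defined]
    if (length(x) == 0L) stop("no genes with defined TS/NTS ratios")
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(label = label, n = length(x), q1 = q[1], median = q[2], q3 = q[3])
  }
  out <- one(records, labels[1])
  if (!is.null(comparison)) {
    out <- rbind(out, one(comparison, labels[2]))
    attr(out, "wilcox_p") <- stats::wilcox.test(
      records$log2_ts_nts[records$defined],
      comparison$log2_ts_nts[comparison$defined]
    )$p.value
  }
  out
}

#' Chromatin-state stratified normalized repair
#'
#' Counts real and simulated reads on each segment without respect to
#' strand, RPKM-normalizes with the segment length and library totals, and
#' forms per-segment normalized repair. Segments with zero simulated count
#' are excluded (reported); states left with no usable segments are dropped
#' with a warning.
#'
#' @param segments Chromatin segments from [read_chromatin_states()].
#' @param real_reads,sim_reads Read data.frames.
#' @return An object of class `state_repair`: data.frame `segments` (state,
#'   length, counts, normalized repair) and the per-state list `by_state`
#'   of segment-level normalized repair vectors.
#' @export
chromatin_state_repair <- function(segments, real_reads, sim_reads) {
  stopifnot(nrow(segments) > 0L)
  real_c <- count_overlaps(segments, real_reads, "ignore")
  sim_c <- count_overlaps(segments, sim_reads, "ignore")
  len <- segments$end - segments$start
  tab <- data.frame(
    state = segments$state,
    chrom = segments$chrom, start = segments$start, end = segments$end,
    length = len,
    real_count = real_c, sim_count = sim_c,
    real_rpkm = rpkm(real_c, len, nrow(real_reads)),
    sim_rpkm = rpkm(sim_c, len, nrow(sim_reads))
  )
  tab$normalized_repair <- ifelse(sim_c > 0, tab$real_rpkm / tab$sim_rpkm, NA_real_)
  n_excluded <- sum(sim_c == 0)
  usable <- tab[!is.na(tab$normalized_repair), , drop = FALSE]
  lost <- setdiff(unique(tab$state), unique(usable$state))
  if (length(lost)) {
    warning("state(s) with no usable segments dropped: ",
            paste(lost, collapse = ", "))
  }
  by_state <- split(usable$normalized_repair, usable$state)
  structure(list(segments = tab, by_state = by_state,
                 n_excluded = n_excluded),
            class = "state_repair")
}

#' @export
print.state_repair <- function(x, ...) {
  cat(sprintf("chromatin-state repair: %d segments, %d state(s), %d excluded (zero sim count)\n",
              nrow(x$segments), length(x$by_state), x$n_excluded))
  print(round(vapply(x$by_state, mean, numeric(1)), 3))
  invisible(x)
}

#' Significance stars for p-values
#'
#' Star notation: `ns` for p > 0.05, `*` for p <= 0.05, `**` for p <= 0.01,
#' `***` for p <= 0.001, `****` for p <= 0.0001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of labels.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"),
      right = TRUE) |> as.character()
}

#' Pairwise tests of normalized repair across chromatin states
#'
#' Two-sided Welch two-sample t-tests on segment-level normalized repair
#' between states, with the star notation of [p_stars()]. Raw p-values, no
#' multiple-testing correction. Pairs where either state has fewer than two
#' segments or zero variance in both are skipped with a reason.
#'
#' @param state_repair A [chromatin_state_repair()] result (or a named list
#'   of numeric vectors).
#' @param pairs Optional 2-column character matrix of state pairs; default
#'   all unordered pairs.
#' @return Data.frame with one row per pair: states, group sizes, mean
#'   difference, `t`, `df`, `p`, `stars` (NA rows carry `skipped_reason`).
#' @export
pairwise_state_tests <- function(state_repair, pairs = NULL) {
  by_state <- if (inherits(state_repair, "state_repair"))
    state_repair$by_state else state_repair
  states <- names(by_state)
  if (is.null(pairs)) {
    if (length(states) < 2L) stop("need at least two states")
    pairs <- t(utils::combn(states, 2L))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    x <- by_state[[a]]; y <- by_state[[b]]
    base <- data.frame(state_a = a, state_b = b,
                       n_a = length(x), n_b = length(y),
                       mean_a = mean(x), mean_b = mean(y),
                       t = NA_real_, df = NA_real_, p = NA_real_,
                       stars = NA_character_, skipped_reason = NA_character_)
    if (length(x) < 2L || length(y) < 2L) {
      base$skipped_reason <- "fewer than 2 segments in a state"
      return(base)
    }
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) {
        base$t <- 0; base$p <- 1; base$stars <- "ns"
        return(base)
      }
      base$skipped_reason <- "zero variance in both states"
      return(base)
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    base$t <- unname(tt$statistic)
    base$df <- unname(tt$parameter)
    base$p <- tt$p.value
    base$stars <- p_stars(tt$p.value)
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign gene-level expression from the longest isoform
#'
#' For each gene the longest transcript is the representative and its TPM
#' becomes the gene's expression; length ties break toward the
#' lexicographically smallest transcript id.
#'
#' @param transcripts Data.frame with columns `transcript_id`, `gene_id`,
#'   `length`, `tpm`.
#' @return Named numeric vector: gene id -> TPM.
#' @export
select_longest_isoform <- function(transcripts) {
  need <- c("transcript_id", "gene_id", "length", "tpm")
  miss <- setdiff(need, names(transcripts))
  if (length(miss)) stop("transcript table missing column(s): ",
                         paste(miss, collapse = ", "))
  tx <- transcripts[order(transcripts$gene_id, -transcripts$length,
                          transcripts$transcript_id), , drop = FALSE]
  top <- tx[!duplicated(tx$gene_id), , drop = FALSE]
  stats::setNames(top$tpm, top$gene_id)
}

#' Correlate TS/NTS repair with gene expression
#'
#' Pearson correlation between per-gene log2 normalized TS/NTS repair and
#' log10(TPM + pseudocount) over genes present in both inputs with defined
#' ratios.
#'
#' @param records Output of [gene_ts_nts()].
#' @param gene_tpm Named numeric vector from [select_longest_isoform()].
#' @param pseudocount Added to TPM before log10 (default 0.1); set
#'   `transform = "identity"` for raw TPM sensitivity analysis.
#' @param transform `"log10"` (default) or `"identity"`.
#' @return A list of class `repair_expression_cor`: `r`, `p`, `n`, the
#'   transform used, and the paired table (`gene`, `expression`,
#'   `log2_ts_nts`) for plotting.
#' @export
correlate_expression <- function(records, gene_tpm, pseudocount = 0.1,
                                 transform = c("log10", "identity")) {
  transform <- match.arg(transform)
  rec <- records[records$defined & records$id %in% names(gene_tpm), , drop = FALSE]
  if (nrow(rec) < 3L) stop("fewer than 3 genes with defined ratios and expression")
  tpm <- gene_tpm[rec$id]
  x <- if (transform == "log10") log10(tpm + pseudocount) else tpm
  y <- rec$log2_ts_nts
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(
    r = unname(ct$estimate), p = ct$p.value, n = nrow(rec),
    transform = transform, pseudocount = pseudocount,
    pairs = data.frame(gene = rec$id, expression = unname(x), log2_ts_nts = y)
  ), class = "repair_expression_cor")
}

#' @export
print.repair_expression_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation, expression vs log2 TS/NTS: r = %.3f, p = %.3g, n = %d\n",
              x$r, x$p, x$n))
  invisible(x)
}
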