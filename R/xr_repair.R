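# The central analysis object: one call takes a real XR-seq library, a gene
# annotation and a matched simulated background (supplied, or generated on
# the fly from the genome) and returns every normalized-repair quantity the
# package computes, with the usual modelling-style methods.

#' Fit a genome-wide normalized repair profile
#'
#' Runs the full quantification: optional coordinate deduplication, matched
#' background simulation (when `sim` is not supplied), the 100-bin metagene
#' TS/NTS profile over genes and half-length flanks, per-gene normalized
#' TS/NTS repair ratios, and — when the inputs are given — chromatin-state
#' repair with pairwise Welch tests and the Pearson correlation of TS/NTS
#' with expression.
#'
#' @param reads Real XR-seq read data.frame (BED6 columns; see
#'   [read_bed6()]).
#' @param genes Gene models (see [read_gene_annotation()]).
#' @param genome Genome from [read_genome_fasta()]; required when `sim` is
#'   `NULL` (to simulate the background) and for QC.
#' @param sim Matched simulated library; `NULL` simulates one from `genome`
#'   with [simulate_matched_library()].
#' @param states Optional chromatin segments (see
#'   [read_chromatin_states()]).
#' @param expression Optional transcript table (see
#'   [select_longest_isoform()]) or a named gene -> TPM vector.
#' @param chrom_sizes Chromosome lengths; derived from `genome` when
#'   omitted.
#' @param n_bins,flank_fraction Metagene geometry (see
#'   [metagene_profile()]).
#' @param dedup Deduplicate the real library first (coordinate key).
#' @param sim_cfg A [sim_config()] for background simulation; its seed
#'   controls the only stochastic step.
#' @return An object of class `xr_repair` with components `genes`
#'   (per-gene records from [gene_ts_nts()]), `metagene`, `qc` (length
#'   histogram and damage-site composition when `genome` is given),
#'   `states`/`state_tests`, `expression_cor`, `sim_report`, and the
#'   library sizes.
#' @seealso [summary.xr_repair()], [coef.xr_repair()], [plot.xr_repair()],
#'   [simulate.xr_repair()]
#' @export
xr_repair <- function(reads, genes, genome = NULL, sim = NULL, states = NULL,
                      expression = NULL, chrom_sizes = NULL,
                      n_bins = 100L, flank_fraction = 0.5,
                      dedup = TRUE, sim_cfg = sim_config(seed = 1L)) {
  .check_reads(reads)
  if (is.null(chrom_sizes)) {
    if (is.null(genome)) stop("supply either genome or chrom_sizes")
    chrom_sizes <- .genome_sizes(genome)
  }
  .check_chrom_names(reads, names(chrom_sizes))
  .check_chrom_names(genes, names(chrom_sizes), what = "genes")
  n_dup <- 0L
  if (dedup) {
    reads <- deduplicate_reads(reads)
    n_dup <- attr(reads, "n_removed")
  }
  sim_report <- NULL
  if (is.null(sim)) {
    if (is.null(genome)) stop("need a genome to simulate the background library")
    simlib <- simulate_matched_library(reads, genome, sim_cfg)
    sim <- simlib$reads
    sim_report <- simlib$report
  } else {
    .check_reads(sim, what = "sim")
  }
  qc <- NULL
  if (!is.null(genome)) {
    qc <- list(
      lengths = length_distribution(reads),
      damage_site = damage_site_composition(reads, genome, sim_cfg$damage_site)
    )
  }
  metagene <- metagene_profile(genes, reads, sim, chrom_sizes,
                               n_bins = n_bins, flank_fraction = flank_fraction)
  records <- gene_ts_nts(genes, reads, sim)
  state_tab <- NULL; state_tests <- NULL
  if (!is.null(states)) {
    state_tab <- chromatin_state_repair(states, reads, sim)
    if (length(state_tab$by_state) >= 2L) {
      state_tests <- pairwise_state_tests(state_tab)
    }
  }
  expr_cor <- NULL
  if (!is.null(expression)) {
    gene_tpm <- if (is.data.frame(expression))
      select_longest_isoform(expression) else expression
    expr_cor <- correlate_expression(records, gene_tpm)
  }
  structure(list(
    genes = records,
    metagene = metagene,
    qc = qc,
    states = state_tab,
    state_tests = state_tests,
    expression_cor = expr_cor,
    sim_report = sim_report,
    n_real = nrow(reads), n_sim = nrow(sim), n_duplicates_removed = n_dup,
    reads = reads, sim = sim, genome = genome, chrom_sizes = chrom_sizes,
    sim_cfg = sim_cfg,
    call = match.call()
  ), class = "xr_repair")
}

#' @export
print.xr_repair <- function(x, ...) {
  cat("Genome-wide normalized excision repair profile\n")
  cat(sprintf("  %d real reads (%d duplicates removed), %d simulated reads\n",
              x$n_real, x$n_duplicates_removed, x$n_sim))
  def <- x$genes$defined
  cat(sprintf("  %d genes, %d with defined TS/NTS ratios; median log2 TS/NTS = %.3f\n",
              nrow(x$genes), sum(def),
              stats::median(x$genes$log2_ts_nts[def])))
  if (!is.null(x$expression_cor)) {
    cat(sprintf("  expression correlation: r = %.3f (p = %.3g)\n",
                x$expression_cor$r, x$expression_cor$p))
  }
  if (!is.null(x$states)) {
    cat(sprintf("  chromatin states: %d\n", length(x$states$by_state)))
  }
  invisible(x)
}

#' Summarise a repair profile fit
#'
#' @param object An [xr_repair()] fit.
#' @param ... Unused.
#' @return An object of class `summary.xr_repair` collecting the TS/NTS
#'   distribution summary, mean body-bin metagene repair per strand class,
#'   per-state means and pairwise tests, QC headline numbers and the
#'   expression correlation.
#' @export
summary.xr_repair <- function(object, ...) {
  def <- object$genes$defined
  body <- object$metagene$profile$bin %in% object$metagene$body_bins
  ts <- object$metagene$profile$strand_class == "TS"
  nr <- object$metagene$profile$normalized_repair
  out <- list(
    n_real = object$n_real, n_sim = object$n_sim,
    ts_nts = ts_nts_distribution_summary(object$genes),
    mean_body_ts = mean(nr[body & ts], na.rm = TRUE),
    mean_body_nts = mean(nr[body & !ts], na.rm = TRUE),
    modal_length = if (!is.null(object$qc)) object$qc$lengths$modal_length,
    primary_fraction = if (!is.null(object$qc)) object$qc$lengths$primary_fraction,
    damage_top3 = if (!is.null(object$qc))
      sort(object$qc$damage_site, decreasing = TRUE)[1:3],
    state_means = if (!is.null(object$states))
      vapply(object$states$by_state, mean, numeric(1)),
    state_tests = object$state_tests,
    expression_cor = object$expression_cor
  )
  class(out) <- "summary.xr_repair"
  out
}

#' @export
print.summary.xr_repair <- function(x, ...) {
  cat("Normalized repair summary\n")
  cat(sprintf("  libraries: %d real / %d simulated reads\n", x$n_real, x$n_sim))
  with(x$ts_nts, cat(sprintf(
    "  log2 TS/NTS over %d genes: median %.3f [Q1 %.3f, Q3 %.3f]\n",
    n, median, q1, q3)))
  cat(sprintf("  mean body-bin normalized repair: TS %.3f, NTS %.3f (ratio %.3f)\n",
              x$mean_body_ts, x$mean_body_nts, x$mean_body_ts / x$mean_body_nts))
  if (!is.null(x$modal_length)) {
    cat(sprintf("  read lengths: mode %d nt, %.1f%% in the primary window\n",
                x$modal_length, 100 * x$primary_fraction))
    cat("  top damage-site dinucleotides: ",
        paste(sprintf("%s %.1f%%", names(x$damage_top3), 100 * x$damage_top3),
              collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$state_means)) {
    cat("  mean normalized repair by chromatin state:\n")
    print(round(x$state_means, 3))
  }
  if (!is.null(x$expression_cor)) {
    cat(sprintf("  expression vs log2 TS/NTS: Pearson r = %.3f, p = %.3g (n = %d)\n",
                x$expression_cor$r, x$expression_cor$p, x$expression_cor$n))
  }
  invisible(x)
}

#' Per-gene log2 TS/NTS repair coefficients
#'
#' @param object An [xr_repair()] fit.
#' @param ... Unused.
#' @return Named vector of per-gene log2 normalized TS/NTS ratios (NA where
#'   undefined).
#' @export
coef.xr_repair <- function(object, ...) {
  stats::setNames(object$genes$log2_ts_nts, object$genes$id)
}

#' Plot a repair profile fit
#'
#' Base-graphics views of the fit: the strand-specific metagene profile
#' (`which = "metagene"`), the per-gene log2 TS/NTS distribution
#' (`"tsnts"`), normalized repair by chromatin state (`"states"`), or
#' TS/NTS against expression (`"expression"`).
#'
#' @param x An [xr_repair()] fit.
#' @param which One of `"metagene"`, `"tsnts"`, `"states"`, `"expression"`.
#' @param ... Passed to the underlying plotting function.
#' @return Invisibly, `x`.
#' @export
plot.xr_repair <- function(x, which = c("metagene", "tsnts", "states", "expression"),
                           ...) {
  which <- match.arg(which)
  if (which == "metagene") {
    p <- x$metagene$profile
    ts <- p[p$strand_class == "TS", ]
    nts <- p[p$strand_class == "NTS", ]
    graphics::matplot(ts$bin, cbind(ts$normalized_repair, nts$normalized_repair),
                      type = "l", lty = 1, col = c("firebrick", "steelblue"),
                      xlab = "bin (1-100; body shaded)",
                      ylab = "normalized repair (real/sim RPKM)", ...)
    graphics::abline(v = range(x$metagene$body_bins), lty = 3)
    graphics::abline(h = 1, col = "grey60", lty = 2)
    graphics::legend("topright", c("TS", "NTS"), lty = 1,
                     col = c("firebrick", "steelblue"), bty = "n")
  } else if (which == "tsnts") {
    v <- x$genes$log2_ts_nts[x$genes$defined]
    graphics::boxplot(v, ylab = "log2 normalized TS/NTS", ...)
    graphics::abline(h = 0, col = "grey60", lty = 2)
  } else if (which == "states") {
    if (is.null(x$states)) stop("fit has no chromatin-state component")
    graphics::boxplot(x$states$by_state, ylab = "normalized repair", ...)
    graphics::abline(h = 1, col = "grey60", lty = 2)
  } else {
    if (is.null(x$expression_cor)) stop("fit has no expression component")
    p <- x$expression_cor$pairs
    graphics::plot(p$expression, p$log2_ts_nts,
                   xlab = sprintf("%s(TPM)", x$expression_cor$transform),
                   ylab = "log2 normalized TS/NTS", pch = 16,
                   col = grDevices::adjustcolor("black", 0.3), ...)
    graphics::abline(stats::lm(log2_ts_nts ~ expression, data = p),
                     col = "firebrick")
  }
  invisible(x)
}

#' Simulate matched background libraries from a fit
#'
#' Draws `nsim` fresh simulated libraries matched to the fit's (deduplicated)
#' real library, e.g. to gauge the sampling variability of normalized
#' repair under the background model.
#'
#' @param object An [xr_repair()] fit carrying its genome.
#' @param nsim Number of libraries.
#' @param seed Base seed; library i uses `seed + i - 1`.
#' @param ... Unused.
#' @return A list of read data.frames.
#' @export
simulate.xr_repair <- function(object, nsim = 1, seed = 1L, ...) {
  if (is.null(object$genome)) stop("fit carries no genome; cannot simulate")
  lapply(seq_len(nsim), function(i) {
    cfg <- object$sim_cfg
    cfg$seed <- seed + i - 1L
    simulate_matched_library(object$reads, object$genome, cfg)$reads
  })
}

#' Per-gene departures from strand-symmetric repair
#'
#' Residual-style diagnostics: the per-gene log2 normalized TS/NTS ratio is
#' zero under pure global (strand-symmetric) repair, so the defined ratios
#' double as residuals from that null.
#'
#' @param object An [xr_repair()] fit.
#' @param ... Unused.
#' @return Named numeric vector over genes with defined ratios.
#' @export
residuals.xr_repair <- function(object, ...) {
  def <- object$genes$defined
  stats::setNames(object$genes$log2_ts_nts[def], object$genes$id[def])
}
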