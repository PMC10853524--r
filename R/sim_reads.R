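# Simulated background reads for sequence-content normalization. The
# simulated library matches the real library's total read count and length
# histogram exactly, and its damage-site dinucleotide composition per length
# class by rejection sampling of uniform genomic windows. Dividing real by
# simulated read density then cancels damage-opportunity (sequence content)
# bias from repair signal.

#' Simulation configuration
#'
#' @param seed Integer seed; a fixed seed makes the output bit-identical
#'   across runs. `NULL` uses the current RNG state.
#' @param match_mode `"damage_dinuc"` (default) matches the damage-site
#'   dinucleotide per length class; `"per_position_mono"` additionally
#'   reweights candidate windows toward the real library's positional
#'   mononucleotide profile (slower, marginal gain).
#' @param max_tries Proposals per read before the fallback (accept the last
#'   window regardless) kicks in; fallbacks are counted, never silent.
#' @param damage_site A [damage_site_spec()].
#' @param exclude_n Reject candidate windows containing N.
#' @param fallback If `FALSE`, exhausting `max_tries` (e.g. the requested
#'   dinucleotide is absent from the genome) is an error instead of a
#'   counted fallback acceptance.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = NULL,
                       match_mode = c("damage_dinuc", "per_position_mono"),
                       max_tries = 10000L,
                       damage_site = damage_site_spec(),
                       exclude_n = TRUE,
                       fallback = TRUE) {
  match_mode <- match.arg(match_mode)
  stopifnot(max_tries >= 1L)
  structure(list(seed = seed, match_mode = match_mode,
                 max_tries = as.integer(max_tries),
                 damage_site = damage_site, exclude_n = exclude_n,
                 fallback = fallback),
            class = "sim_config")
}

#' Target profile of a real library
#'
#' Captures what the simulator must reproduce: exact read counts per length
#' class and the damage-site dinucleotide distribution of each class. A
#' length class whose reads all carry N at the damage site falls back to
#' the pooled all-length distribution, with a warning.
#'
#' @param reads Real read data.frame (non-empty).
#' @param genome Genome from [read_genome_fasta()].
#' @param config A [sim_config()].
#' @return An object of class `sim_target`: per-length counts `n` and
#'   dinucleotide distributions `q` (16 categories each), plus the pooled
#'   distribution.
#' @export
build_target_profile <- function(reads, genome, config = sim_config()) {
  .check_reads(reads)
  if (nrow(reads) == 0L) stop("empty read set")
  spec <- config$damage_site
  len <- reads$end - reads$start
  if (any(len < spec$offset + 2L)) {
    stop(sum(len < spec$offset + 2L),
         " read(s) too short to carry a damage site at offset ", spec$offset)
  }
  pooled <- damage_site_composition(reads, genome, spec)
  lengths <- sort(unique(len))
  n <- integer(length(lengths))
  q <- matrix(0, nrow = length(lengths), ncol = 16L,
              dimnames = list(lengths, DINUCS))
  for (i in seq_along(lengths)) {
    sel <- len == lengths[i]
    n[i] <- sum(sel)
    qi <- tryCatch(
      damage_site_composition(reads[sel, , drop = FALSE], genome, spec),
      error = function(e) NULL
    )
    if (is.null(qi)) {
      warning("length class ", lengths[i],
              " has no usable damage sites; using the pooled distribution")
      qi <- as.numeric(pooled)
    }
    q[i, ] <- as.numeric(qi)
  }
  structure(list(lengths = lengths, n = stats::setNames(n, lengths),
                 q = q, pooled = stats::setNames(as.numeric(pooled), DINUCS),
                 total = nrow(reads)),
            class = "sim_target")
}

#' @export
print.sim_target <- function(x, ...) {
  cat(sprintf("simulation target: %d reads in %d length class(es) (%s)\n",
              x$total, length(x$lengths),
              paste(range(x$lengths), collapse = "-")))
  invisible(x)
}

# --- internal simulator machinery ------------------------------------------

# Per-chromosome integer codes and N-prefix sums, computed once per run.
.genome_index <- function(genome) {
  codes <- lapply(genome, .seq_codes)
  ncum <- lapply(codes, function(cc) c(0L, cumsum(is.na(cc))))
  list(codes = codes, ncum = ncum,
       sizes = .genome_sizes(genome), chroms = names(genome))
}

# Damage-site dinucleotide index (1..16, NA if N) of proposed windows.
# For '+' windows [s, s+L): dinucleotide at genome coords (s+L-off-1, s+L-off)
# 0-based; for '-' windows the read dinucleotide is the reverse complement of
# the forward dinucleotide at (s+off-1, s+off).
.window_damage_dinuc <- function(gidx, chrom_i, s, L, strand, offset) {
  g <- ifelse(strand == "+", s + L - offset - 1L, s + offset - 1L)
  c1 <- integer(length(s)); c2 <- integer(length(s))
  for (ci in unique(chrom_i)) {
    sel <- chrom_i == ci
    cc <- gidx$codes[[ci]]
    c1[sel] <- cc[g[sel] + 1L]
    c2[sel] <- cc[g[sel] + 2L]
  }
  idx <- .dinuc_index(c1, c2)
  neg <- strand == "-"
  idx[neg] <- .dinuc_rc_index[idx[neg]]
  idx
}

# TRUE for windows containing any N.
.window_has_n <- function(gidx, chrom_i, s, L) {
  out <- logical(length(s))
  for (ci in unique(chrom_i)) {
    sel <- chrom_i == ci
    nc <- gidx$ncum[[ci]]
    out[sel] <- (nc[s[sel] + L + 1L] - nc[s[sel] + 1L]) > 0L
  }
  out
}

# Per-window log-likelihood-ratio of the real library's positional
# mononucleotide profile vs genome background, for every window start of
# one chromosome and strand (per_position_mono mode). `logw` is a 4 x L
# matrix indexed by FORWARD base code and forward offset within the window.
# Windows containing N get -Inf.
.window_logweights <- function(cc, L, logw) {
  n_starts <- length(cc) - L + 1L
  if (n_starts < 1L) return(numeric(0))
  acc <- numeric(n_starts)
  for (m in seq_len(L)) {
    idx <- cc[m:(m + n_starts - 1L)]
    v <- logw[cbind(idx, m)]
    v[is.na(idx)] <- -Inf
    acc <- acc + v
  }
  acc
}

# per_position_mono sampler for one length class: enumerate every window of
# length L on both strands, score it by the likelihood ratio of the real
# library's positional mononucleotide profile against the genome
# background, and draw each read's window from the windows carrying its
# damage dinucleotide with probability proportional to that weight — the
# same distribution the likelihood-ratio rejection sampler targets,
# computed exactly.
.simulate_class_mono <- function(gidx, L, want, bg, prof, config) {
  offset <- config$damage_site$offset
  logw_fwd <- log(pmax(prof, 1e-12) / bg)   # rows = read base = forward base
  # '-' windows: read base is the complement of the forward base and read
  # position p corresponds to forward offset L + 1 - p
  logw_minus <- logw_fwd[4:1, L:1, drop = FALSE]
  cand <- list()
  for (ci in seq_along(gidx$codes)) {
    cc <- gidx$codes[[ci]]
    n_starts <- length(cc) - L + 1L
    if (n_starts < 1L) next
    dplus <- .dinuc_index(cc[seq_len(n_starts) + L - offset - 1L],
                          cc[seq_len(n_starts) + L - offset])
    dminus <- .dinuc_rc_index[.dinuc_index(cc[seq_len(n_starts) + offset - 1L],
                                           cc[seq_len(n_starts) + offset])]
    cand[[length(cand) + 1L]] <- data.frame(
      chrom = ci, start0 = seq_len(n_starts) - 1L, strand = 1L,
      dinuc = dplus, lw = .window_logweights(cc, L, logw_fwd))
    cand[[length(cand) + 1L]] <- data.frame(
      chrom = ci, start0 = seq_len(n_starts) - 1L, strand = 2L,
      dinuc = dminus, lw = .window_logweights(cc, L, logw_minus))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[!is.na(cand$dinuc) & is.finite(cand$lw), , drop = FALSE]
  out_c <- integer(length(want)); out_s <- integer(length(want))
  out_st <- integer(length(want))
  for (d in unique(want)) {
    rows <- which(cand$dinuc == d)
    take <- which(want == d)
    if (!length(rows)) {
      if (!config$fallback) stop("no candidate window for dinucleotide ", DINUCS[d])
      rows <- seq_len(nrow(cand))
    }
    w <- exp(cand$lw[rows] - max(cand$lw[rows]))
    pick <- rows[sample.int(length(rows), length(take), replace = TRUE, prob = w)]
    out_c[take] <- cand$chrom[pick]
    out_s[take] <- cand$start0[pick]
    out_st[take] <- cand$strand[pick]
  }
  data.frame(
    chrom = gidx$chroms[out_c],
    start = out_s,
    end = out_s + L,
    strand = c("+", "-")[out_st]
  )
}

#' Simulate background reads matching a target profile
#'
#' For each length class L, each read is generated by sampling a damage
#' dinucleotide from the class distribution, then rejection-sampling a
#' uniform random genomic window of length L (chromosome weighted by length,
#' start uniform, strand equiprobable) until the window's damage-site
#' dinucleotide equals the sampled one and, if configured, the window is
#' N-free. After `max_tries` proposals the last window is accepted anyway
#' and a fallback counter incremented. Conditional on the accepted
#' dinucleotide, positions are uniform over all genomic windows carrying it.
#'
#' @param target A [build_target_profile()] result.
#' @param genome Genome from [read_genome_fasta()].
#' @param config A [sim_config()].
#' @param mono_profile Optional list of per-length 4 x L positional
#'   mononucleotide profiles (rows A,C,G,T), used in `per_position_mono`
#'   mode; computed from the real reads by [simulate_matched_library()].
#' @return Read data.frame with names `sim_1..sim_n`, with attribute
#'   `report` (per-length fallback counts and proposals).
#' @export
simulate_reads <- function(target, genome, config = sim_config(),
                           mono_profile = NULL) {
  stopifnot(inherits(target, "sim_target"))
  gidx <- .genome_index(genome)
  if (any(gidx$sizes < max(target$lengths))) {
    stop("chromosome(s) shorter than the maximum read length")
  }
  offset <- config$damage_site$offset
  # genome background base composition for per_position_mono weights
  bg <- tabulate(unlist(gidx$codes), nbins = 4L)
  bg <- pmax(bg / sum(bg), 1e-12)

  .with_seed(config$seed, {
    pieces <- vector("list", length(target$lengths))
    fallbacks <- stats::setNames(integer(length(target$lengths)), target$lengths)
    proposals <- fallbacks
    for (i in seq_along(target$lengths)) {
      L <- target$lengths[i]
      nL <- target$n[i]
      if (nL == 0L) next
      qL <- target$q[i, ]
      if (sum(qL) <= 0) stop("length class ", L, " has an empty dinucleotide distribution")
      want <- sample.int(16L, nL, replace = TRUE, prob = qL)

      use_mono <- config$match_mode == "per_position_mono" &&
        !is.null(mono_profile[[as.character(L)]])
      if (use_mono) {
        pieces[[i]] <- .simulate_class_mono(gidx, L, want, bg,
                                            mono_profile[[as.character(L)]],
                                            config)
        next
      }

      # start-position domain per chromosome: s in [0, size - L]
      navail <- pmax(gidx$sizes - L + 1L, 0L)
      chrom_prob <- navail / sum(navail)

      s_out <- integer(nL); chrom_out <- integer(nL); strand_out <- character(nL)
      pending <- seq_len(nL)
      tries <- integer(nL)
      while (length(pending)) {
        m <- length(pending)
        ci <- sample.int(length(navail), m, replace = TRUE, prob = chrom_prob)
        s <- floor(stats::runif(m) * navail[ci])
        st <- c("+", "-")[sample.int(2L, m, replace = TRUE)]
        tries[pending] <- tries[pending] + 1L
        proposals[i] <- proposals[i] + m
        din <- .window_damage_dinuc(gidx, ci, s, L, st, offset)
        ok <- !is.na(din) & din == want[pending]
        if (config$exclude_n) ok <- ok & !.window_has_n(gidx, ci, s, L)
        give_up <- tries[pending] >= config$max_tries
        if (any(give_up & !ok) && !config$fallback) {
          stop("max_tries exhausted for length class ", L,
               " (requested dinucleotide may be absent from the genome)")
        }
        fallbacks[i] <- fallbacks[i] + sum(give_up & !ok)
        take <- ok | give_up
        if (any(take)) {
          idx <- pending[take]
          s_out[idx] <- s[take]
          chrom_out[idx] <- ci[take]
          strand_out[idx] <- st[take]
          pending <- pending[!take]
        }
      }
      pieces[[i]] <- data.frame(
        chrom = gidx$chroms[chrom_out],
        start = s_out,
        end = s_out + L,
        strand = strand_out
      )
    }
    out <- do.call(rbind, pieces)
    out$name <- sprintf("sim_%d", seq_len(nrow(out)))
    out$score <- 0
    out <- out[, c("chrom", "start", "end", "name", "score", "strand")]
    rownames(out) <- NULL
    attr(out, "report") <- list(fallbacks = fallbacks, proposals = proposals)
    out
  })
}

#' Simulate a matched background library for a real library
#'
#' Composition of [build_target_profile()] and [simulate_reads()]: the
#' simulated library has the real library's exact size, exact length
#' histogram, and per-length damage-site dinucleotide content (up to
#' sampling noise), with strand drawn uniformly so the background is
#' strand-symmetric.
#'
#' @inheritParams build_target_profile
#' @return A list of class `sim_library`: `reads` (the simulated library),
#'   `target`, and `report` with per-length fallback counts, proposal
#'   totals, and the achieved total-variation distance between the
#'   simulated and target damage-site composition (pooled and per length).
#' @export
simulate_matched_library <- function(reads, genome, config = sim_config()) {
  target <- build_target_profile(reads, genome, config)
  mono <- NULL
  if (config$match_mode == "per_position_mono") {
    mono <- lapply(stats::setNames(nm = as.character(target$lengths)), function(l) {
      positional_nucleotide_frequencies(reads, genome, as.integer(l))
    })
  }
  sim <- simulate_reads(target, genome, config, mono_profile = mono)
  rep0 <- attr(sim, "report")
  attr(sim, "report") <- NULL
  sim_comp <- damage_site_composition(sim, genome, config$damage_site)
  tv_pooled <- sum(abs(as.numeric(sim_comp) - target$pooled)) / 2
  tv_len <- vapply(seq_along(target$lengths), function(i) {
    L <- target$lengths[i]
    qc <- damage_site_composition(sim, genome, config$damage_site,
                                  length_filter = L)
    sum(abs(as.numeric(qc) - target$q[i, ])) / 2
  }, numeric(1))
  structure(list(
    reads = sim,
    target = target,
    report = list(fallbacks = rep0$fallbacks,
                  proposals = rep0$proposals,
                  tv_pooled = tv_pooled,
                  tv_by_length = stats::setNames(tv_len, target$lengths))
  ), class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf(
    "simulated background library: %d reads, TV(damage-site composition) = %.4f, %d fallback(s)\n",
    nrow(x$reads), x$report$tv_pooled, sum(x$report$fallbacks)))
  invisible(x)
}
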