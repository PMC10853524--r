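# Synthetic dataset generator: a toy genome, non-overlapping stranded gene
# annotation with isoforms and expression, a disjoint chromatin-state cover,
# and an XR-seq-like read library with known (recorded) ground truth:
# damage-site dinucleotide spectrum, bimodal read-length mixture,
# expression-scaled transcription-coupled repair on template strands,
# chromatin-state repair multipliers and positional enrichment bumps around
# promoter/TSS/TES. Every pipeline stage is testable against the recorded
# truth without any external data.

#' Synthetic dataset specification
#'
#' Defaults describe a library with the statistical structure of a plant
#' (6-4)PP XR-seq experiment: a primary 25-28 nt read population peaking at
#' 27 plus a degraded 16-21 nt population, a damage-site dipyrimidine
#' spectrum led by TT (26.1%), TC (24.2%) and CT (15.9%) with the remaining
#' mass spread over the other dinucleotides in proportion to their genomic
#' availability, expression-ranked transcription-coupled repair on template
#' strands, and chromatin-state dependent repair rates.
#'
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the spec.
#' @param n_chroms,chrom_length Genome shape (default 2 x 500 kb).
#' @param gc GC fraction of the i.i.d. genome (default 0.36).
#' @param n_genes Number of non-overlapping genes (default 200).
#' @param gene_length_meanlog,gene_length_sdlog,gene_length_range Log-normal
#'   gene length law (median 2 kb) clipped to 500 bp - 8 kb.
#' @param tpm_meanlog,tpm_sdlog Log-normal expression law for gene-level TPM.
#' @param n_reads Library size (default 200,000).
#' @param primary_weights Named weights over primary read lengths 25-28
#'   (mode 27).
#' @param degraded_lengths Degraded (5'-shortened) product lengths, uniform.
#' @param primary_fraction Mixture weight of the primary population
#'   (default 0.8).
#' @param spectrum Named fractions for explicitly pinned damage-site
#'   dinucleotides; remaining mass is spread over the other dinucleotides
#'   proportional to genomic availability.
#' @param kappa TCR strength: the template-strand repair boost of gene g is
#'   `rho(g) = 1 + kappa * rank(TPM_g) / n_genes`.
#' @param state_multipliers Named repair-rate multipliers per chromatin
#'   state.
#' @param bump_amplitude,bump_width,promoter_offset Gaussian positional
#'   enrichment multipliers (peak `bump_amplitude`, s.d. `bump_width` bp)
#'   centred at the TSS, the TES, and `promoter_offset` bp upstream of the
#'   TSS.
#' @param damage_site A [damage_site_spec()]; lesions are placed so the
#'   damage dinucleotide sits at read positions (L-7, L-6) by default.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_chroms = 2L,
                           chrom_length = 5e5,
                           gc = 0.36,
                           n_genes = 200L,
                           gene_length_meanlog = log(2000),
                           gene_length_sdlog = 0.6,
                           gene_length_range = c(500L, 8000L),
                           tpm_meanlog = log(10),
                           tpm_sdlog = 1.5,
                           n_reads = 200000L,
                           primary_weights = c("25" = 0.15, "26" = 0.25,
                                               "27" = 0.40, "28" = 0.20),
                           degraded_lengths = 16:21,
                           primary_fraction = 0.8,
                           spectrum = c(TT = 0.261, TC = 0.242, CT = 0.159),
                           kappa = 1,
                           state_multipliers = c(open = 1.5, genic = 1.0,
                                                 hetAT = 0.5, hetGC = 0.6),
                           bump_amplitude = 1.5,
                           bump_width = 200,
                           promoter_offset = 500L,
                           damage_site = damage_site_spec()) {
  stopifnot(gc >= 0, gc <= 1,
            primary_fraction >= 0, primary_fraction <= 1,
            all(spectrum >= 0), sum(spectrum) <= 1,
            all(names(spectrum) %in% DINUCS),
            kappa >= 0, bump_amplitude >= 1,
            "genic" %in% names(state_multipliers))
  spec <- list(seed = seed, n_chroms = as.integer(n_chroms),
               chrom_length = as.integer(chrom_length), gc = gc,
               n_genes = as.integer(n_genes),
               gene_length_meanlog = gene_length_meanlog,
               gene_length_sdlog = gene_length_sdlog,
               gene_length_range = as.integer(gene_length_range),
               tpm_meanlog = tpm_meanlog, tpm_sdlog = tpm_sdlog,
               n_reads = as.integer(n_reads),
               primary_weights = primary_weights / sum(primary_weights),
               degraded_lengths = as.integer(degraded_lengths),
               primary_fraction = primary_fraction,
               spectrum = spectrum,
               kappa = kappa,
               state_multipliers = state_multipliers,
               bump_amplitude = bump_amplitude,
               bump_width = bump_width,
               promoter_offset = as.integer(promoter_offset),
               damage_site = damage_site)
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic XR-seq spec: %d x %d bp genome (GC %.2f), %d genes, %d reads, kappa = %g\n",
    x$n_chroms, x$chrom_length, x$gc, x$n_genes, x$n_reads, x$kappa))
  invisible(x)
}

#' Generate a synthetic genome
#'
#' I.i.d. bases at the spec's GC fraction.
#'
#' @param spec A [synthetic_spec()].
#' @return Named character vector of chromosome sequences (`chr1`, ...).
#' @export
generate_genome <- function(spec) {
  p <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
         G = spec$gc / 2, T = (1 - spec$gc) / 2)
  .with_seed(spec$seed, {
    stats::setNames(vapply(seq_len(spec$n_chroms), function(i) {
      paste(sample(BASES, spec$chrom_length, replace = TRUE, prob = p),
            collapse = "")
    }, character(1)), paste0("chr", seq_len(spec$n_chroms)))
  })
}

#' Generate a synthetic gene annotation with isoforms and expression
#'
#' Places exactly `n_genes` non-overlapping stranded genes with log-normal
#' lengths, keeping a margin at chromosome ends so half-length flanks stay
#' in bounds. Each gene carries 1-3 isoforms (nested, distinct lengths);
#' the gene-level TPM is assigned to the longest isoform and the remainder
#' is split across the others, so longest-isoform selection recovers the
#' gene-level expression exactly.
#'
#' @param spec A [synthetic_spec()].
#' @param genome Output of [generate_genome()].
#' @return A list: `genes` (data.frame as from [read_gene_annotation()]),
#'   `transcripts` (data.frame `transcript_id`, `gene_id`, `length`, `tpm`),
#'   `gene_tpm` (named vector of gene-level TPM).
#' @export
generate_annotation <- function(spec, genome) {
  sizes <- .genome_sizes(genome)
  .with_seed(spec$seed + 1L, {
    len <- round(stats::rlnorm(spec$n_genes, spec$gene_length_meanlog,
                               spec$gene_length_sdlog))
    len <- pmin(pmax(len, spec$gene_length_range[1]), spec$gene_length_range[2])
    # assign genes to chromosomes proportionally, then place left to right
    # with random gaps; margin = half of the longest gene so extended
    # metagene regions never leave the chromosome
    chrom_i <- sort(sample.int(spec$n_chroms, spec$n_genes, replace = TRUE))
    margin <- as.integer(ceiling(max(len) / 2)) + 10L
    # minimum intergenic gap: keeps every chromatin segment long relative to
    # the read length, so segment-level signal is not dominated by reads
    # spilling across segment boundaries
    min_gap <- 1000L
    starts <- integer(spec$n_genes); chroms <- character(spec$n_genes)
    for (ci in seq_len(spec$n_chroms)) {
      idx <- which(chrom_i == ci)
      if (!length(idx)) next
      total <- sum(len[idx])
      free <- sizes[ci] - 2L * margin - total - min_gap * length(idx)
      if (free < length(idx)) {
        stop("genes do not fit on chromosome ", ci,
             ": increase chrom_length or reduce n_genes")
      }
      # random extra gap sizes: stick-breaking over the remaining free space
      cuts <- sort(sample.int(free, length(idx)))
      gaps <- min_gap + diff(c(0L, cuts))
      pos <- margin
      for (k in seq_along(idx)) {
        pos <- pos + gaps[k]
        starts[idx[k]] <- as.integer(pos)
        pos <- pos + len[idx[k]]
      }
      chroms[idx] <- names(sizes)[ci]
    }
    strand <- c("+", "-")[sample.int(2L, spec$n_genes, replace = TRUE)]
    ids <- sprintf("SYNG%04d", seq_len(spec$n_genes))
    genes <- data.frame(id = ids, chrom = chroms, start = as.integer(starts),
                        end = as.integer(starts + len), strand = strand,
                        biotype = "protein_coding")
    gene_tpm <- stats::rlnorm(spec$n_genes, spec$tpm_meanlog, spec$tpm_sdlog)
    names(gene_tpm) <- ids
    n_iso <- sample.int(3L, spec$n_genes, replace = TRUE)
    tx <- do.call(rbind, lapply(seq_len(spec$n_genes), function(g) {
      # longest isoform spans the gene; extra isoforms are strictly shorter
      tl <- unique(c(len[g], round(len[g] * sort(stats::runif(n_iso[g] - 1L, 0.4, 0.95),
                                                 decreasing = TRUE))))
      tpms <- if (length(tl) == 1L) gene_tpm[g] else {
        w <- stats::runif(length(tl) - 1L, 0, 0.3)
        c(gene_tpm[g], gene_tpm[g] * w) # longest carries the gene TPM
      }
      data.frame(transcript_id = sprintf("%s.%d", ids[g], seq_along(tl)),
                 gene_id = ids[g], length = tl, tpm = unname(tpms))
    }))
    rownames(tx) <- NULL
    list(genes = genes, transcripts = tx, gene_tpm = gene_tpm)
  })
}

#' Generate a disjoint chromatin-state cover
#'
#' Gene bodies are labelled `genic`; intergenic space is chopped into
#' segments of roughly 2-10 kb, one third (at random) labelled `open`, and
#' the rest labelled `hetAT` or `hetGC` by whether their GC content falls
#' below or above the median of the remaining segments — so `hetAT`
#' segments have lower GC than `hetGC` by construction.
#'
#' @param spec A [synthetic_spec()].
#' @param genome Output of [generate_genome()].
#' @param annotation Output of [generate_annotation()].
#' @return Data.frame `chrom`, `start`, `end`, `state` forming a disjoint
#'   cover of the genome.
#' @export
generate_chromatin_states <- function(spec, genome, annotation) {
  sizes <- .genome_sizes(genome)
  genes <- annotation$genes
  .with_seed(spec$seed + 2L, {
    segs <- list()
    for (chr in names(sizes)) {
      g <- genes[genes$chrom == chr, , drop = FALSE]
      g <- g[order(g$start), , drop = FALSE]
      genic <- if (nrow(g)) data.frame(chrom = chr, start = g$start,
                                       end = g$end, state = "genic")
      # intergenic gaps
      gap_start <- c(0L, g$end)
      gap_end <- c(g$start, sizes[[chr]])
      keep <- gap_start < gap_end
      inter <- do.call(rbind, lapply(which(keep), function(k) {
        s <- gap_start[k]; e <- gap_end[k]
        n_pieces <- max(1L, ceiling((e - s) / stats::runif(1, 2000, 10000)))
        edges <- unique(round(seq(s, e, length.out = n_pieces + 1L)))
        data.frame(chrom = chr, start = edges[-length(edges)],
                   end = edges[-1L], state = NA_character_)
      }))
      segs[[chr]] <- rbind(genic, inter)
    }
    out <- do.call(rbind, segs)
    rownames(out) <- NULL
    inter_i <- which(is.na(out$state))
    is_open <- stats::runif(length(inter_i)) < 1 / 3
    out$state[inter_i[is_open]] <- "open"
    het_i <- inter_i[!is_open]
    gcont <- vapply(het_i, function(k) {
      s <- fetch_sequence(genome, out$chrom[k], out$start[k], out$end[k])
      mean(strsplit(s, "")[[1]] %in% c("C", "G"))
    }, numeric(1))
    out$state[het_i] <- ifelse(gcont < stats::median(gcont), "hetAT", "hetGC")
    out$start <- as.integer(out$start)
    out$end <- as.integer(out$end)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# Gaussian positional multiplier track (one per chromosome) for
# promoter/TSS/TES bumps; applied to both strands.
.bump_track <- function(spec, sizes, genes) {
  tracks <- lapply(sizes, function(n) rep(1, n))
  if (spec$bump_amplitude <= 1) return(tracks)
  halfspan <- ceiling(4 * spec$bump_width)
  for (g in seq_len(nrow(genes))) {
    chr <- genes$chrom[g]
    plus <- genes$strand[g] == "+"
    tss <- if (plus) genes$start[g] else genes$end[g] - 1L
    tes <- if (plus) genes$end[g] - 1L else genes$start[g]
    prom <- if (plus) tss - spec$promoter_offset else tss + spec$promoter_offset
    for (centre in c(prom, tss, tes)) {
      lo <- max(0L, centre - halfspan)
      hi <- min(sizes[[chr]] - 1L, centre + halfspan)
      if (lo > hi) next
      d <- (lo:hi) - centre
      idx <- (lo:hi) + 1L
      tracks[[chr]][idx] <- tracks[[chr]][idx] *
        (1 + (spec$bump_amplitude - 1) * exp(-d^2 / (2 * spec$bump_width^2)))
    }
  }
  tracks
}

#' Generate a synthetic XR-seq read library with ground truth
#'
#' Each read arises from a lesion: a genomic dinucleotide position and
#' strand. The damage dinucleotide class is drawn from the spec's spectrum
#' (an exact marginal); the position within the class is drawn with weight
#' proportional to chromatin-state multiplier x TCR boost (`rho(gene)` on
#' the gene's template strand) x promoter/TSS/TES bump. Read length is
#' drawn from the bimodal mixture and the read is placed so the lesion
#' occupies positions (L-7, L-6) of its 5'->3' sequence; reads that would
#' cross a chromosome end are rejected and resampled.
#'
#' @param spec A [synthetic_spec()].
#' @param genome,annotation,states Outputs of the paired generators.
#' @return A list of class `synthetic_library`: `reads` (BED6-style
#'   data.frame) and `truth` (spec, per-gene TPM/rank/rho, expected
#'   state-multiplier ratios, realized spectrum).
#' @export
generate_xrseq_library <- function(spec, genome, annotation, states) {
  sizes <- .genome_sizes(genome)
  genes <- annotation$genes
  gidx <- .genome_index(genome)
  offset <- spec$damage_site$offset

  # dinucleotide class of every (position, strand): forward dinuc code at
  # 0-based positions 0..size-2; minus strand is the reverse complement
  fwd_codes <- lapply(gidx$codes, function(cc) {
    n <- length(cc)
    .dinuc_index(cc[-n], cc[-1L])
  })

  # availability per dinucleotide over both strands
  avail <- numeric(16L)
  for (cc in fwd_codes) {
    tab <- tabulate(cc[!is.na(cc)], nbins = 16L)
    avail <- avail + tab + tab[.dinuc_rc_index]
  }

  # full 16-category spectrum: pinned categories + remaining mass spread
  # over the others proportional to availability
  q <- stats::setNames(numeric(16L), DINUCS)
  q[names(spec$spectrum)] <- spec$spectrum
  rest <- setdiff(DINUCS, names(spec$spectrum))
  rest_avail <- avail[match(rest, DINUCS)]
  if (any(q[rest] != 0) || sum(rest_avail) == 0) stop("invalid spectrum")
  q[rest] <- (1 - sum(spec$spectrum)) * rest_avail / sum(rest_avail)
  if (any(q > 0 & avail == 0)) {
    stop("spectrum dinucleotide absent from genome: ",
         paste(DINUCS[q > 0 & avail == 0], collapse = ", "))
  }

  # per-gene TCR boost rho = 1 + kappa * rank(TPM)/n
  tpm <- annotation$gene_tpm[genes$id]
  rho <- 1 + spec$kappa * rank(tpm, ties.method = "first") / nrow(genes)
  names(rho) <- genes$id

  # positional weight tracks per chromosome and strand (weights at
  # dinucleotide START positions 0..size-2, stored 1-based)
  bumps <- .bump_track(spec, sizes, genes)
  state_mult <- lapply(sizes, function(n) rep(1, n))
  for (k in seq_len(nrow(states))) {
    m <- spec$state_multipliers[[states$state[k]]]
    if (is.null(m) || is.na(m)) m <- 1
    state_mult[[states$chrom[k]]][(states$start[k] + 1L):states$end[k]] <- m
  }
  w_plus <- list(); w_minus <- list()
  for (chr in names(sizes)) {
    base <- state_mult[[chr]] * bumps[[chr]]
    wp <- base; wm <- base
    gsel <- which(genes$chrom == chr)
    for (g in gsel) {
      span <- (genes$start[g] + 1L):genes$end[g]
      if (genes$strand[g] == "+") {          # template strand of a + gene is -
        wm[span] <- wm[span] * rho[genes$id[g]]
      } else {
        wp[span] <- wp[span] * rho[genes$id[g]]
      }
    }
    n <- sizes[[chr]]
    w_plus[[chr]] <- wp[-n]  # weight of dinucleotide starting at each position
    w_minus[[chr]] <- wm[-n]
  }

  .with_seed(spec$seed + 3L, {
    # class sizes: exact multinomial draw from the spectrum
    class_n <- as.integer(stats::rmultinom(1L, spec$n_reads, q))

    # index of candidate lesions per dinucleotide class: (chrom, pos, strand).
    # Lesions within one maximal read length of a chromosome end are not
    # candidates (a read there could cross the end and would have to be
    # rejected); the exclusion zone is ~28 bp per end, negligible and
    # class-neutral on an i.i.d. genome.
    max_L <- max(as.integer(names(spec$primary_weights)), spec$degraded_lengths)
    les_chrom <- integer(0); les_pos <- integer(0); les_strand <- integer(0)
    for (d in which(class_n > 0L)) {
      cand_c <- integer(0); cand_p <- integer(0); cand_s <- integer(0); cand_w <- numeric(0)
      for (ci in seq_along(sizes)) {
        fc <- fwd_codes[[ci]]
        in_range <- function(p) p[p >= max_L + 1L & p <= sizes[[ci]] - max_L]
        pp <- in_range(which(!is.na(fc) & fc == d))                  # + strand
        pm <- in_range(which(!is.na(fc) & fc == .dinuc_rc_index[d])) # - strand
        cand_c <- c(cand_c, rep.int(ci, length(pp) + length(pm)))
        cand_p <- c(cand_p, pp, pm)
        cand_s <- c(cand_s, rep.int(1L, length(pp)), rep.int(2L, length(pm)))
        cand_w <- c(cand_w,
                    w_plus[[ci]][pp],
                    w_minus[[ci]][pm])
      }
      if (!length(cand_p)) stop("spectrum dinucleotide absent from genome: ", DINUCS[d])
      pick <- sample.int(length(cand_p), class_n[d], replace = TRUE, prob = cand_w)
      les_chrom <- c(les_chrom, cand_c[pick])
      les_pos <- c(les_pos, cand_p[pick] - 1L)  # back to 0-based
      les_strand <- c(les_strand, cand_s[pick])
    }
    ord <- sample.int(length(les_pos))          # shuffle classes together
    les_chrom <- les_chrom[ord]; les_pos <- les_pos[ord]; les_strand <- les_strand[ord]

    draw_lengths <- function(m) {
      primary <- stats::runif(m) < spec$primary_fraction
      out <- integer(m)
      pl <- as.integer(names(spec$primary_weights))
      out[primary] <- pl[sample.int(length(pl), sum(primary), replace = TRUE,
                                    prob = spec$primary_weights)]
      out[!primary] <- spec$degraded_lengths[
        sample.int(length(spec$degraded_lengths), sum(!primary), replace = TRUE)]
      out
    }
    n <- length(les_pos)
    L <- draw_lengths(n)
    # placement: lesion dinucleotide at 0-based genome position g occupies
    # read positions (L-offset, L-offset+1); read start is g-(L-offset-1) on
    # '+' and g-offset+1 on '-'
    start <- ifelse(les_strand == 1L, les_pos - (L - offset - 1L),
                    les_pos - (offset - 1L))
    end <- start + L
    stopifnot(all(start >= 0L), all(end <= sizes[les_chrom]))
    reads <- data.frame(
      chrom = names(sizes)[les_chrom],
      start = start, end = end,
      name = sprintf("synth_%d", seq_len(n)),
      score = 0,
      strand = c("+", "-")[les_strand]
    )
    truth <- list(
      spec = spec,
      spectrum16 = q,
      gene_tpm = tpm,
      gene_rho = rho,
      expected_mean_rho = mean(rho),
      state_multipliers = spec$state_multipliers,
      class_counts = stats::setNames(class_n, DINUCS)
    )
    structure(list(reads = reads, truth = truth), class = "synthetic_library")
  })
}

#' @export
print.synthetic_library <- function(x, ...) {
  cat(sprintf("synthetic XR-seq library: %d reads, kappa = %g, mean rho = %.3f\n",
              nrow(x$reads), x$truth$spec$kappa, x$truth$expected_mean_rho))
  invisible(x)
}

#' Generate a complete synthetic dataset
#'
#' Runs the four generators in order and optionally writes every artefact
#' to disk in its standard format (FASTA, chrom.sizes, GFF3, states BED,
#' expression TSV, reads BED, truth JSON).
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory; created if missing.
#' @return A list: `genome`, `chrom_sizes`, `annotation` (genes,
#'   transcripts, gene_tpm), `states`, `library` (reads + truth), and
#'   `paths` when `dir` is given.
#' @export
generate_synthetic_dataset <- function(spec = synthetic_spec(), dir = NULL) {
  genome <- generate_genome(spec)
  annotation <- generate_annotation(spec, genome)
  states <- generate_chromatin_states(spec, genome, annotation)
  lib <- generate_xrseq_library(spec, genome, annotation, states)
  out <- list(genome = genome, chrom_sizes = .genome_sizes(genome),
              annotation = annotation, states = states, library = lib)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      genome = file.path(dir, "genome.fa"),
      chrom_sizes = file.path(dir, "genome.chrom.sizes"),
      annotation = file.path(dir, "genes.gff3"),
      expression = file.path(dir, "expression.tsv"),
      states = file.path(dir, "states.bed"),
      reads = file.path(dir, "reads.bed"),
      truth = file.path(dir, "truth.json")
    )
    write_genome_fasta(genome, paths$genome)
    write_chrom_sizes(out$chrom_sizes, paths$chrom_sizes)
    write_gff3_genes(annotation, paths$annotation)
    utils::write.table(annotation$transcripts, paths$expression, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(states, paths$states, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    write_bed6(lib$reads, paths$reads)
    truth <- lib$truth
    truth$spec$damage_site <- unclass(truth$spec$damage_site)
    truth$spec <- unclass(truth$spec)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

#' Write a minimal gene/mRNA GFF3 from a synthetic annotation
#'
#' @param annotation Output of [generate_annotation()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3_genes <- function(annotation, path) {
  genes <- annotation$genes
  tx <- annotation$transcripts
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in seq_len(nrow(genes))) {
    writeLines(sprintf(
      "%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
      genes$chrom[g], genes$start[g] + 1L, genes$end[g], genes$strand[g],
      genes$id[g], genes$biotype[g]), con)
    txg <- tx[tx$gene_id == genes$id[g], , drop = FALSE]
    for (t in seq_len(nrow(txg))) {
      # isoforms share the gene 5' end (anchored at TSS)
      if (genes$strand[g] == "+") {
        ts <- genes$start[g]; te <- genes$start[g] + txg$length[t]
      } else {
        te <- genes$end[g]; ts <- genes$end[g] - txg$length[t]
      }
      writeLines(sprintf(
        "%s\tsynthetic\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        genes$chrom[g], ts + 1L, te, genes$strand[g],
        txg$transcript_id[t], genes$id[g]), con)
    }
  }
  invisible(path)
}
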