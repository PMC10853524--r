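# Fixtures and independent oracles, built in code at test time.

# Quick read data.frame constructor.
make_reads <- function(chrom, start, end, strand, name = NULL, score = 0) {
  n <- max(length(chrom), length(start), length(end), length(strand))
  data.frame(
    chrom = rep_len(chrom, n), start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    name = if (is.null(name)) sprintf("r%d", seq_len(n)) else rep_len(name, n),
    score = rep_len(score, n), strand = rep_len(strand, n)
  )
}

# Random i.i.d. genome as a named character vector.
random_genome <- function(sizes, gc = 0.4, seed = 1) {
  withr::with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    out <- vapply(sizes, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    names(out) <- names(sizes)
    out
  })
}

# Random stranded reads over a genome.
random_reads <- function(genome, n, len = 27L, seed = 1) {
  sizes <- nchar(genome)
  withr::with_seed(seed, {
    ci <- sample(seq_along(sizes), n, replace = TRUE)
    start <- floor(runif(n) * (sizes[ci] - len))
    make_reads(names(sizes)[ci], start, start + len,
               sample(c("+", "-"), n, replace = TRUE))
  })
}

# Slow string-level reverse complement, independent of the package's.
slow_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Slow per-read sequence fetch (substr + slow_revcomp), independent path.
slow_fetch <- function(genome, reads) {
  vapply(seq_len(nrow(reads)), function(i) {
    s <- substr(genome[[reads$chrom[i]]], reads$start[i] + 1L, reads$end[i])
    if (reads$strand[i] == "-") slow_revcomp(s) else s
  }, character(1))
}

# Brute-force O(n*m) overlap counting oracle.
oracle_count_overlaps <- function(features, reads, strand_mode, min_overlap = 1L) {
  vapply(seq_len(nrow(features)), function(i) {
    hits <- 0L
    for (j in seq_len(nrow(reads))) {
      if (features$chrom[i] != reads$chrom[j]) next
      ov <- min(features$end[i], reads$end[j]) -
        max(features$start[i], reads$start[j])
      if (ov < min_overlap) next
      keep <- switch(strand_mode,
        same = features$strand[i] == reads$strand[j],
        opposite = features$strand[i] != reads$strand[j],
        ignore = TRUE)
      if (keep) hits <- hits + 1L
    }
    hits
  }, integer(1))
}

# Brute-force per-read damage-site dinucleotide tally at (L-7, L-6).
oracle_damage_site <- function(genome, reads, offset = 7L) {
  seqs <- slow_fetch(genome, reads)
  din <- vapply(seqs, function(s) {
    L <- nchar(s)
    substr(s, L - offset, L - offset + 1L)
  }, character(1), USE.NAMES = FALSE)
  din <- din[!grepl("N", din)]
  table(factor(din, levels = excisr:::DINUCS)) / length(din)
}

# A small complete synthetic dataset shared across test files (cheap).
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(seed = 42, n_chroms = 2L, chrom_length = 100000L,
                             n_genes = 40L, n_reads = 20000L)
      cache <<- generate_synthetic_dataset(spec)
    }
    cache
  }
})
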