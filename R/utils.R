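# Internal helpers shared across modules.

# Canonical dinucleotide ordering used in every 16-category table.
DINUCS <- c(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
PYR_DINUCS <- c("CC", "CT", "TC", "TT")

BASES <- c("A", "C", "G", "T")

# Base -> integer code (A=1, C=2, G=3, T=4, N and anything else = NA).
# utf8ToInt is ASCII-safe for genome sequences.
.base_code_table <- local({
  tab <- rep(NA_integer_, 256L)
  tab[utf8ToInt("A")] <- 1L
  tab[utf8ToInt("C")] <- 2L
  tab[utf8ToInt("G")] <- 3L
  tab[utf8ToInt("T")] <- 4L
  tab
})

# Integer codes along one chromosome string.
.seq_codes <- function(seq) {
  .base_code_table[utf8ToInt(seq)]
}

# Dinucleotide index 1..16 from two base codes; NA if either base is N.
# Order matches DINUCS: index = code2*4 + code1 - 4 would be column-major of
# outer(first, second); DINUCS[i] has first base cycling fastest, so
# index(first c1, second c2) = (c2 - 1) * 4 + c1.
.dinuc_index <- function(c1, c2) {
  (c2 - 1L) * 4L + c1
}

# Reverse-complement dinucleotide index, precomputed: rc("AC") = "GT" etc.
.dinuc_rc_index <- local({
  idx <- integer(16L)
  comp <- c(4L, 3L, 2L, 1L) # A<->T, C<->G
  for (c1 in 1:4) {
    for (c2 in 1:4) {
      idx[(c2 - 1L) * 4L + c1] <- (comp[c1] - 1L) * 4L + comp[c2]
    }
  }
  idx
})

#' Reverse complement of DNA sequences
#'
#' Vectorised over a character vector; accepts A, C, G, T and N.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "TTAN"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate expr with a locally seeded RNG, restoring global RNG state after.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Validate a read/interval data.frame. Reads must be stranded (+/-).
.check_reads <- function(reads, stranded = TRUE, what = "reads") {
  stopifnot(is.data.frame(reads))
  need <- c("chrom", "start", "end", "strand")
  miss <- setdiff(need, names(reads))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")))
  }
  if (nrow(reads)) {
    if (any(reads$start >= reads$end)) {
      stop(sprintf("%s: start >= end in %d record(s)", what,
                   sum(reads$start >= reads$end)))
    }
    ok <- if (stranded) reads$strand %in% c("+", "-") else
      reads$strand %in% c("+", "-", ".")
    if (!all(ok)) {
      stop(sprintf("%s: invalid strand value(s): %s", what,
                   paste(unique(reads$strand[!ok]), collapse = ", ")))
    }
  }
  invisible(reads)
}

# Chromosome sizes from a genome (named character vector of sequences).
.genome_sizes <- function(genome) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  stats::setNames(nchar(genome), names(genome))
}

# Convert a 0-based half-open interval data.frame to GRanges (1-based).
.as_granges <- function(x, strand = x$strand) {
  if (is.null(strand)) strand <- "*"
  strand <- ifelse(strand == ".", "*", strand)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# Report read chromosomes absent from a reference name set; error if any.
.check_chrom_names <- function(reads, known, what = "reads") {
  bad <- setdiff(unique(reads$chrom), known)
  if (length(bad)) {
    stop(sprintf(
      "%s reference %d chromosome(s) absent from the genome: %s",
      what, length(bad), paste(bad, collapse = ", ")
    ))
  }
  invisible(TRUE)
}
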