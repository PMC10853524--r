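# QC of excision products: read-length distribution, positional mono- and
# dinucleotide frequencies, and the damage-site dinucleotide composition.
# Position indexing is 1-based along the read's 5'->3' sequence, so for a
# 27-mer the damage dinucleotide sits at positions 20-21.

#' Damage-site position specification
#'
#' The excised oligonucleotide carries the photoproduct a fixed distance
#' from its 3' end: for a read of length L the damage dinucleotide occupies
#' 1-based positions (L - offset, L - offset + 1). The default offset of 7
#' places it at positions 20-21 of a 27-mer, the geometry observed for
#' (6-4)PP excision products; it is configurable so the same code serves
#' CPD data.
#'
#' @param offset Distance of the first damaged base from the 3' end
#'   (default 7).
#' @return An object of class `damage_site_spec`.
#' @export
damage_site_spec <- function(offset = 7L) {
  offset <- as.integer(offset)
  stopifnot(offset >= 1L)
  structure(list(offset = offset), class = "damage_site_spec")
}

# 1-based positions (p1, p2) of the damage dinucleotide for read length L.
damage_site_positions <- function(spec, L) {
  p1 <- L - spec$offset
  cbind(p1 = p1, p2 = p1 + 1L)
}

#' @export
print.damage_site_spec <- function(x, ...) {
  cat(sprintf("damage site at read positions (L-%d, L-%d); L=27 -> (%d, %d)\n",
              x$offset, x$offset - 1L, 27L - x$offset, 28L - x$offset))
  invisible(x)
}

#' Read-length distribution
#'
#' @param reads Read data.frame.
#' @param primary_window Length range of primary (undegraded) excision
#'   products, default 25-28 nt.
#' @return An object of class `length_histogram`: integer counts and
#'   fractions per observed length, the modal length (ties break toward the
#'   smaller length) and the fraction of reads inside `primary_window`.
#' @export
length_distribution <- function(reads, primary_window = c(25L, 28L)) {
  .check_reads(reads)
  if (nrow(reads) == 0L) stop("empty read set")
  len <- reads$end - reads$start
  counts <- table(len)
  lengths <- as.integer(names(counts))
  counts <- as.integer(counts)
  fractions <- counts / sum(counts)
  mode_len <- lengths[which.max(counts)] # which.max takes the first maximum;
                                         # lengths ascend, so ties -> smaller
  structure(list(
    lengths = lengths,
    counts = stats::setNames(counts, lengths),
    fractions = stats::setNames(fractions, lengths),
    modal_length = mode_len,
    primary_window = primary_window,
    primary_fraction = sum(fractions[lengths >= primary_window[1] &
                                       lengths <= primary_window[2]]),
    n = nrow(reads)
  ), class = "length_histogram")
}

#' @export
print.length_histogram <- function(x, ...) {
  cat(sprintf("read length distribution: n = %d, mode = %d nt, %.1f%% in %d-%d nt\n",
              x$n, x$modal_length, 100 * x$primary_fraction,
              x$primary_window[1], x$primary_window[2]))
  print(round(x$fractions, 4))
  invisible(x)
}

# Fetch 5'->3' sequences of all reads of exact length L; errors if none.
.read_seqs_of_length <- function(reads, genome, L) {
  .check_reads(reads)
  sel <- (reads$end - reads$start) == L
  if (!any(sel)) stop("no reads of length ", L)
  fetch_sequence(genome, reads[sel, , drop = FALSE])
}

#' Positional mononucleotide frequencies
#'
#' Frequency of A, C, G, T at each position 1..L along the 5'->3' sequence
#' of reads of exact length `L`. Reads carrying N at a position are excluded
#' from that position's denominator only.
#'
#' @param reads Read data.frame.
#' @param genome Genome from [read_genome_fasta()].
#' @param L Read length to profile (e.g. 27).
#' @return A 4 x L matrix of fractions (rows A, C, G, T); each column sums
#'   to 1.
#' @export
positional_nucleotide_frequencies <- function(reads, genome, L) {
  seqs <- .read_seqs_of_length(reads, genome, L)
  codes <- matrix(.base_code_table[utf8ToInt(paste(seqs, collapse = ""))],
                  nrow = L)
  out <- matrix(0, nrow = 4L, ncol = L, dimnames = list(BASES, seq_len(L)))
  for (p in seq_len(L)) {
    cc <- codes[p, ]
    cc <- cc[!is.na(cc)]
    if (length(cc) == 0L) next
    out[, p] <- tabulate(cc, nbins = 4L) / length(cc)
  }
  out
}

#' Positional dinucleotide frequencies
#'
#' Frequency of each of the 16 dinucleotides starting at positions
#' 1..(L-1) along reads of exact length `L`. Reads with N at either base of
#' a position are excluded from that position's denominator.
#'
#' @inheritParams positional_nucleotide_frequencies
#' @return An object of class `dinuc_profile`: a 16 x (L-1) fraction matrix
#'   (`matrix`), its pyrimidine-dinucleotide rows CC, CT, TC, TT
#'   (`pyrimidine`, the subset usually plotted), the read length and n.
#' @export
positional_dinucleotide_frequencies <- function(reads, genome, L) {
  seqs <- .read_seqs_of_length(reads, genome, L)
  codes <- matrix(.base_code_table[utf8ToInt(paste(seqs, collapse = ""))],
                  nrow = L)
  mat <- matrix(0, nrow = 16L, ncol = L - 1L,
                dimnames = list(DINUCS, seq_len(L - 1L)))
  for (p in seq_len(L - 1L)) {
    idx <- .dinuc_index(codes[p, ], codes[p + 1L, ])
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) next
    mat[, p] <- tabulate(idx, nbins = 16L) / length(idx)
  }
  structure(list(
    matrix = mat,
    pyrimidine = mat[PYR_DINUCS, , drop = FALSE],
    read_length = L,
    n = length(seqs)
  ), class = "dinuc_profile")
}

#' @export
print.dinuc_profile <- function(x, ...) {
  cat(sprintf("positional dinucleotide profile of %d reads of length %d\n",
              x$n, x$read_length))
  cat("pyrimidine dinucleotides (CC/CT/TC/TT), fractions by position:\n")
  print(round(x$pyrimidine, 3))
  invisible(x)
}

#' Damage-site dinucleotide composition
#'
#' Distribution over the 16 dinucleotides at the damage site
#' (positions L-7, L-6 by default) of each read, pooled over reads. Reads
#' shorter than `offset + 2` nt (damage position would fall before the read
#' start) and reads with N in the damage window are skipped and counted in
#' the attached skip report.
#'
#' @param reads Read data.frame.
#' @param genome Genome from [read_genome_fasta()].
#' @param spec A [damage_site_spec()].
#' @param length_filter Optional single read length; only reads of that
#'   length contribute. Default `NULL` uses all reads (positions tracked per
#'   read length).
#' @return Named numeric vector of 16 dinucleotide fractions, with
#'   attributes `pyrimidine_share` (summed CC+CT+TC+TT fraction), `n_used`
#'   and `n_skipped`.
#' @export
damage_site_composition <- function(reads, genome, spec = damage_site_spec(),
                                    length_filter = NULL) {
  .check_reads(reads)
  if (nrow(reads) == 0L) stop("empty read set")
  len <- reads$end - reads$start
  sel <- rep(TRUE, nrow(reads))
  if (!is.null(length_filter)) sel <- len == length_filter
  too_short <- len < spec$offset + 2L # need p1 >= 1 and p2 <= L
  use <- sel & !too_short
  n_skipped <- sum(sel & too_short)
  if (!any(use)) stop("no usable reads for damage-site composition")
  rd <- reads[use, , drop = FALSE]
  L <- len[use]
  pos <- damage_site_positions(spec, L)
  # Genomic coordinates of the damage dinucleotide, strand-aware:
  # read position p maps to genome coordinate start + p - 1 on '+', end - p
  # on '-' (0-based). Fetch the two-base window on the read's strand.
  plus <- rd$strand == "+"
  g1 <- ifelse(plus, rd$start + pos[, "p1"] - 1L, rd$end - pos[, "p2"])
  din <- fetch_sequence(genome, data.frame(
    chrom = rd$chrom, start = g1, end = g1 + 2L, strand = rd$strand
  ))
  has_n <- grepl("N", din, fixed = TRUE)
  n_skipped <- n_skipped + sum(has_n)
  din <- din[!has_n]
  if (length(din) == 0L) stop("all damage windows contain N")
  counts <- table(factor(din, levels = DINUCS))
  frac <- as.numeric(counts) / length(din)
  names(frac) <- DINUCS
  structure(frac,
            pyrimidine_share = sum(frac[PYR_DINUCS]),
            n_used = length(din),
            n_skipped = n_skipped)
}
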