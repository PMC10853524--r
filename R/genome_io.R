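# Input/output for the standard formats the pipeline touches: FASTA genome,
# BED6 reads, GFF3/BED gene annotation, chromatin-state BED, chrom.sizes,
# bedGraph tracks. All coordinates are 0-based half-open (BED convention)
# internally; GFF3 (1-based inclusive) is converted at the boundary.

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and validated against the alphabet A, C, G, T, N.
#' Chromosome names are the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase sequence per chromosome.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  dup <- nm[duplicated(nm)]
  if (length(dup)) {
    stop("duplicate chromosome name(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  genome <- toupper(as.character(seqs))
  names(genome) <- nm
  for (i in seq_along(genome)) {
    bad <- regexpr("[^ACGTN]", genome[[i]])
    if (bad > 0L) {
      stop(sprintf(
        "illegal character '%s' in chromosome %s at position %d",
        substr(genome[[i]], bad, bad), nm[i], as.integer(bad)
      ))
    }
  }
  genome
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}

#' Read or write a two-column chrom.sizes table
#'
#' @param path Path to a two-column TSV (chromosome, length).
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "size"),
                         colClasses = c("character", "numeric"))
  stats::setNames(x$size, x$chrom)
}

#' @rdname read_chrom_sizes
#' @param sizes Named numeric vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(
    data.frame(chrom = names(sizes), size = as.integer(sizes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read aligned XR-seq reads from BED6
#'
#' Each record is one aligned excised-oligonucleotide. Strand must be `+` or
#' `-`: an excision product has a definite strand of origin, so `.` is an
#' error. File order is preserved.
#'
#' @param path Path to a tab-separated BED file with at least 6 columns.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (0-based half-open coordinates).
#' @export
read_bed6 <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0)))
  }
  x <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         comment.char = "", stringsAsFactors = FALSE)
  if (ncol(x) < 6L) stop("BED6 requires >= 6 columns, found ", ncol(x), ": ", path)
  x <- x[, 1:6]
  names(x) <- c("chrom", "start", "end", "name", "score", "strand")
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$name <- as.character(x$name)
  x$strand <- as.character(x$strand)
  bad <- which(!(x$strand %in% c("+", "-")))
  if (length(bad)) {
    stop(sprintf("invalid read strand '%s' at line %d of %s",
                 x$strand[bad[1]], bad[1], path))
  }
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    stop(sprintf("start >= end at line %d of %s", bad[1], path))
  }
  if (any(x$start < 0L)) stop("negative start coordinate in ", path)
  x
}

#' Write reads to BED6
#'
#' @param reads Read data.frame (see [read_bed6()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed6 <- function(reads, path) {
  .check_reads(reads)
  df <- data.frame(
    chrom = reads$chrom,
    start = format(reads$start, scientific = FALSE, trim = TRUE),
    end = format(reads$end, scientific = FALSE, trim = TRUE),
    name = if (is.null(reads$name)) "." else reads$name,
    score = if (is.null(reads$score)) 0 else reads$score,
    strand = reads$strand
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3 or BED6
#'
#' For GFF3, rows with feature type `gene` are used and 1-based inclusive
#' coordinates are converted to 0-based half-open. Genes without a definite
#' strand are dropped with a warning; duplicate gene ids are an error.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"bed6"`.
#' @param biotype_filter Keep only genes with this biotype; `NULL` keeps all.
#'   For BED input the biotype is unknown and the filter is ignored.
#' @param biotype_key GFF3 attribute holding the biotype (e.g. `"biotype"`,
#'   `"locus_type"`). If the attribute is absent from the file the filter is
#'   skipped with a warning.
#' @return A data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`.
#' @export
read_gene_annotation <- function(path, format = c("gff3", "bed6"),
                                 biotype_filter = "protein_coding",
                                 biotype_key = "biotype") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    if (length(gr) == 0L) stop("no 'gene' features in GFF3: ", path)
    bt <- if (biotype_key %in% names(S4Vectors::mcols(gr))) {
      as.character(S4Vectors::mcols(gr)[[biotype_key]])
    } else {
      rep(NA_character_, length(gr))
    }
    genes <- data.frame(
      id = as.character(gr$ID),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L, # GFF3 1-based -> BED 0-based
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      biotype = bt
    )
  } else {
    x <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
    if (ncol(x) < 6L) stop("BED6 annotation requires >= 6 columns: ", path)
    genes <- data.frame(
      id = as.character(x[[4]]),
      chrom = as.character(x[[1]]),
      start = as.integer(x[[2]]),
      end = as.integer(x[[3]]),
      strand = as.character(x[[6]]),
      biotype = NA_character_
    )
  }
  unstranded <- !(genes$strand %in% c("+", "-"))
  if (any(unstranded)) {
    warning(sum(unstranded), " gene(s) without strand dropped")
    genes <- genes[!unstranded, , drop = FALSE]
  }
  if (!is.null(biotype_filter) && format == "gff3") {
    if (all(is.na(genes$biotype))) {
      warning("biotype attribute '", biotype_key,
              "' absent from annotation; biotype filter skipped")
    } else {
      genes <- genes[!is.na(genes$biotype) & genes$biotype == biotype_filter, ,
                     drop = FALSE]
    }
  }
  dup <- genes$id[duplicated(genes$id)]
  if (length(dup)) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  }
  rownames(genes) <- NULL
  genes
}

#' Read a chromatin-state segmentation from BED
#'
#' Expects at least four columns: chrom, start, end, state label. Segments
#' must be non-overlapping (a segmentation is a disjoint labelled cover);
#' any overlap is an error.
#'
#' @param path Path to the BED file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `state`.
#' @export
read_chromatin_states <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         comment.char = "", stringsAsFactors = FALSE)
  if (ncol(x) < 4L) stop("state BED requires >= 4 columns: ", path)
  seg <- data.frame(
    chrom = as.character(x[[1]]),
    start = as.integer(x[[2]]),
    end = as.integer(x[[3]]),
    state = as.character(x[[4]])
  )
  if (any(seg$start >= seg$end)) stop("start >= end in state BED: ", path)
  gr <- .as_granges(transform(seg, strand = "."))
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(hits)) {
    i <- S4Vectors::queryHits(hits)[1]
    j <- S4Vectors::subjectHits(hits)[1]
    stop(sprintf("overlapping chromatin segments, e.g. records %d and %d (%s)",
                 i, j, seg$chrom[i]))
  }
  seg
}

#' Fetch the strand-of-origin sequence of genomic intervals
#'
#' Returns the 5'->3' sequence as read from the given strand: the forward
#' slice for `+` (or `.`), its reverse complement for `-`. Vectorised over
#' intervals.
#'
#' @param genome Named character vector from [read_genome_fasta()].
#' @param chrom,start,end,strand Parallel vectors describing 0-based
#'   half-open stranded intervals. Alternatively `chrom` may be a read
#'   data.frame, in which case the other arguments are taken from it.
#' @return Character vector of sequences.
#' @export
fetch_sequence <- function(genome, chrom, start = NULL, end = NULL, strand = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    chrom <- df$chrom; start <- df$start; end <- df$end; strand <- df$strand
  }
  if (is.null(strand)) strand <- rep(".", length(chrom))
  if (length(chrom) == 0L) return(character(0))
  .check_chrom_names(data.frame(chrom = chrom), names(genome), "intervals")
  sizes <- .genome_sizes(genome)
  if (any(start < 0L) || any(end > sizes[chrom])) {
    bad <- which(start < 0L | end > sizes[chrom])[1]
    stop(sprintf("interval out of bounds: %s:%d-%d (chromosome length %d)",
                 chrom[bad], start[bad], end[bad], sizes[chrom[bad]]))
  }
  if (any(start >= end)) stop("interval start >= end")
  out <- substring(genome[chrom], start + 1L, end)
  neg <- strand == "-"
  if (any(neg)) out[neg] <- revcomp(out[neg])
  unname(out)
}

#' Remove duplicate reads
#'
#' Coordinate-based duplicate elimination on aligned single-end reads: at
#' most one record is kept per (chrom, start, end, strand) key — the first
#' occurrence. Output is sorted by chrom, start, end, strand, so the result
#' does not depend on input order.
#'
#' @param reads Read data.frame.
#' @return The deduplicated data.frame, with attribute `n_removed` giving
#'   the number of duplicates dropped.
#' @export
deduplicate_reads <- function(reads) {
  .check_reads(reads)
  key <- paste(reads$chrom, reads$start, reads$end, reads$strand, sep = "\r")
  keep <- !duplicated(key)
  out <- reads[keep, , drop = FALSE]
  ord <- order(out$chrom, out$start, out$end, out$strand)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Write an RPM-normalized bedGraph coverage track
#'
#' Per-base coverage of the read intervals scaled by 1e6 / library size
#' (reads per million). Adjacent equal-value runs are merged and zero runs
#' omitted. With `split_strands = TRUE` two files are written, one per
#' strand, with suffixes `_plus`/`_minus` before the extension.
#'
#' @param reads Read data.frame (non-empty; RPM is undefined for an empty
#'   library).
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @param split_strands Write separate plus/minus tracks.
#' @return Invisibly, the path(s) written.
#' @export
write_bedgraph_rpm <- function(reads, chrom_sizes, path, split_strands = FALSE) {
  .check_reads(reads)
  if (nrow(reads) == 0L) stop("empty read set: RPM normalization is undefined")
  .check_chrom_names(reads, names(chrom_sizes))
  scale <- 1e6 / nrow(reads) # library total spans both strands even when split
  write_one <- function(rd, p) {
    gr <- .as_granges(rd)
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- chrom_sizes
    cov <- GenomicRanges::coverage(gr)
    con <- file(p, "w")
    on.exit(close(con))
    for (chr in names(cov)) {
      r <- cov[[chr]]
      val <- S4Vectors::runValue(r) * scale
      len <- S4Vectors::runLength(r)
      ends <- cumsum(len)
      starts <- ends - len
      nz <- val > 0
      if (any(nz)) {
        writeLines(sprintf("%s\t%d\t%d\t%.10g", chr, starts[nz], ends[nz], val[nz]), con)
      }
    }
    p
  }
  if (split_strands) {
    ext <- tools::file_ext(path)
    base <- if (nzchar(ext)) sub(paste0("\\.", ext, "$"), "", path) else path
    suffix <- function(s) if (nzchar(ext)) paste0(base, s, ".", ext) else paste0(base, s)
    paths <- c(
      write_one(reads[reads$strand == "+", , drop = FALSE], suffix("_plus")),
      write_one(reads[reads$strand == "-", , drop = FALSE], suffix("_minus"))
    )
    invisible(paths)
  } else {
    invisible(write_one(reads, path))
  }
}
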