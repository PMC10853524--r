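# Format IO, sequence access and deduplication.

test_that("FASTA reading normalizes case, keeps names and lengths, validates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 description text", "acgt"), f)
  g <- read_genome_fasta(f)
  expect_identical(g, c(chr1 = "ACGT"))

  writeLines(c(">a", strrep("A", 10), ">b", strrep("ACGT", 5)), f)
  g <- read_genome_fasta(f)
  expect_identical(nchar(g), c(a = 10L, b = 20L))

  writeLines(c(">chr1", "ACGU"), f)
  expect_error(read_genome_fasta(f), "chr1.*position 4|position 4.*chr1")

  writeLines(c(">chr1", "ACGT", ">chr1", "GGGG"), f)
  expect_error(read_genome_fasta(f), "duplicate")

  writeLines(character(0), f)
  expect_error(read_genome_fasta(f), "empty")

  # round trip
  writeLines(c(">chr1", "ACGTN"), f)
  g <- read_genome_fasta(f)
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, f2)
  expect_identical(read_genome_fasta(f2), g)
})

test_that("BED6 reading maps columns, preserves order, and validates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t37\tr1\t0\t+", f)
  r <- read_bed6(f)
  expect_identical(r$chrom, "chr1")
  expect_identical(r$start, 10L)
  expect_identical(r$end, 37L)
  expect_identical(r$end - r$start, 27L)
  expect_identical(r$strand, "+")

  file.create(f2 <- withr::local_tempfile(fileext = ".bed"))
  expect_identical(nrow(read_bed6(f2)), 0L)

  writeLines(c("chr1\t10\t37\tr1\t0\t+", "chr1\t5\t20\tr2\t0\t."), f)
  expect_error(read_bed6(f), "line 2")

  writeLines("chr1\t37\t10\tr1\t0\t+", f)
  expect_error(read_bed6(f), "start >= end")
})

test_that("BED6 write/read round-trips records exactly", {
  reads <- make_reads(c("chr2", "chr1", "chr1"), c(5, 0, 100),
                      c(32, 27, 127), c("-", "+", "-"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed6(reads, f)
  back <- read_bed6(f)
  expect_identical(back$chrom, reads$chrom)
  expect_identical(back$start, reads$start)
  expect_identical(back$end, reads$end)
  expect_identical(back$name, reads$name)
  expect_identical(back$strand, reads$strand)
})

test_that("gene annotation loads from GFF3 with coordinate conversion and from BED6", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t101\t200\t.\t-\t.\tID=g1;biotype=protein_coding",
    "chr1\tx\tgene\t301\t400\t.\t+\t.\tID=g2;biotype=lncRNA",
    "chr1\tx\texon\t101\t150\t.\t-\t.\tID=e1"
  ), f)
  g <- read_gene_annotation(f)
  expect_identical(nrow(g), 1L) # lncRNA filtered
  expect_identical(g$start, 100L) # 1-based inclusive -> 0-based half-open
  expect_identical(g$end, 200L)
  expect_identical(g$strand, "-")
  expect_identical(g$id, "g1")
  g_all <- read_gene_annotation(f, biotype_filter = NULL)
  expect_identical(g_all$id, c("g1", "g2"))

  fb <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tga\t0\t+",
               "chr1\t200\t300\tgb\t0\t-",
               "chr2\t0\t50\tgc\t0\t+"), fb)
  gb <- read_gene_annotation(fb, format = "bed6")
  expect_identical(nrow(gb), 3L)
  expect_identical(gb$id, c("ga", "gb", "gc"))
})

test_that("duplicate gene ids error and unstranded genes are dropped with warning", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t100\t.\t+\t.\tID=AT2G23430;biotype=protein_coding",
    "chr1\tx\tgene\t201\t300\t.\t-\t.\tID=AT2G23430;biotype=protein_coding"
  ), f)
  expect_error(read_gene_annotation(f), "AT2G23430")

  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t100\t.\t.\t.\tID=g1;biotype=protein_coding",
    "chr1\tx\tgene\t201\t300\t.\t-\t.\tID=g2;biotype=protein_coding"
  ), f)
  expect_warning(g <- read_gene_annotation(f), "without strand")
  expect_identical(g$id, "g2")
})

test_that("fetch_sequence is strand-aware and bounds-checked", {
  genome <- c(chr1 = "AACCGGTT")
  expect_identical(fetch_sequence(genome, "chr1", 0, 4, "+"), "AACC")
  expect_identical(fetch_sequence(genome, "chr1", 0, 4, "-"), "GGTT")
  expect_identical(fetch_sequence(genome, "chr1", 4, 8, "-"), "AACC")
  expect_error(fetch_sequence(genome, "chr1", 4, 9, "+"), "out of bounds")
  expect_error(fetch_sequence(genome, "chrX", 0, 4, "+"), "chrX")

  # plus and minus fetches of the same interval are reverse complements
  genome <- random_genome(c(chr1 = 500L), seed = 3)
  reads <- random_reads(genome, 50, seed = 4)
  plus <- fetch_sequence(genome, transform(reads, strand = "+"))
  minus <- fetch_sequence(genome, transform(reads, strand = "-"))
  expect_identical(minus, revcomp(plus))
  # and both match the slow independent path
  expect_identical(fetch_sequence(genome, reads), slow_fetch(genome, reads))
})

test_that("deduplication keeps one record per coordinate key, idempotently", {
  r <- make_reads("chr1", c(10, 10, 10), c(37, 37, 37), c("+", "+", "+"),
                  name = c("a", "b", "c"))
  d <- deduplicate_reads(r)
  expect_identical(nrow(d), 1L)
  expect_identical(attr(d, "n_removed"), 2L)
  expect_identical(d$name, "a") # first occurrence kept

  # strand is part of the key
  r2 <- make_reads("chr1", 10, 37, c("+", "-"))
  expect_identical(nrow(deduplicate_reads(r2)), 2L)

  # idempotent and order-independent output
  big <- random_reads(random_genome(c(chr1 = 1000L)), 200, seed = 5)
  d1 <- deduplicate_reads(big)
  d11 <- deduplicate_reads(d1)
  expect_identical(attr(d11, "n_removed"), 0L)
  attr(d11, "n_removed") <- attr(d1, "n_removed")
  expect_identical(d11, d1)
  shuf <- big[withr::with_seed(6, sample(nrow(big))), ]
  d2 <- deduplicate_reads(shuf)
  expect_identical(d1[c("chrom", "start", "end", "strand")],
                   d2[c("chrom", "start", "end", "strand")])
})

test_that("bedGraph output is RPM-scaled, merged and zero-omitted", {
  sizes <- c(chr1 = 100)
  f <- withr::local_tempfile(fileext = ".bedGraph")

  write_bedgraph_rpm(make_reads("chr1", 0, 10, "+"), sizes, f)
  expect_identical(readLines(f), "chr1\t0\t10\t1000000")

  write_bedgraph_rpm(make_reads("chr1", c(0, 0), c(10, 10), "+"), sizes, f)
  expect_identical(readLines(f), "chr1\t0\t10\t1000000") # 2 reads x 1e6/2

  write_bedgraph_rpm(make_reads("chr1", c(0, 50), c(10, 60), "+"), sizes, f)
  expect_identical(length(readLines(f)), 2L)

  expect_error(write_bedgraph_rpm(make_reads("chr1", 0, 10, "+")[0, ], sizes, f),
               "empty")
})

test_that("bedGraph mass equals 1e6 times the mean read length", {
  genome <- random_genome(c(chr1 = 2000L, chr2 = 1500L), seed = 7)
  reads <- random_reads(genome, 300, len = 27L, seed = 8)
  reads$end <- reads$start + withr::with_seed(9, sample(16:28, 300, replace = TRUE))
  f <- withr::local_tempfile(fileext = ".bedGraph")
  mass <- function(p) {
    x <- read.table(p, sep = "\t")
    sum(x$V4 * (x$V3 - x$V2))
  }
  write_bedgraph_rpm(reads, nchar(genome), f)
  expect_equal(mass(f), 1e6 * mean(reads$end - reads$start))
  # split by strand: the two files carry the same total mass
  write_bedgraph_rpm(reads, nchar(genome), f, split_strands = TRUE)
  plus <- sub("\\.bedGraph$", "_plus.bedGraph", f)
  minus <- sub("\\.bedGraph$", "_minus.bedGraph", f)
  expect_equal(mass(plus) + mass(minus), 1e6 * mean(reads$end - reads$start))
})

test_that("chrom.sizes round-trips and chromatin-state overlap is rejected", {
  sizes <- c(chr1 = 1000, chr2 = 500)
  f <- withr::local_tempfile(fileext = ".sizes")
  write_chrom_sizes(sizes, f)
  expect_equal(read_chrom_sizes(f), sizes)

  fb <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\topen", "chr1\t100\t200\tgenic"), fb)
  seg <- read_chromatin_states(fb)
  expect_identical(seg$state, c("open", "genic"))
  writeLines(c("chr1\t0\t100\topen", "chr1\t50\t200\tgenic"), fb)
  expect_error(read_chromatin_states(fb), "overlap")
})
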