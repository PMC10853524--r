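# RPKM, overlap counting, metagene profiles, TS/NTS, states, statistics.

test_that("rpkm evaluates the standard formula and rejects degenerate input", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(5, 500, 2e6), 5)
  expect_error(rpkm(1, 0, 1e6), "length")
  expect_error(rpkm(1, 100, 0), "library")
})

test_that("overlap counting respects the strand rule and minimum overlap", {
  feature <- make_reads("chr1", 0, 20, "+")
  read <- make_reads("chr1", 10, 37, "+")
  expect_identical(count_overlaps(feature, read, "same"), 1L)
  expect_identical(count_overlaps(feature, read, "opposite"), 0L)
  expect_identical(count_overlaps(feature, read, "ignore"), 1L)
  expect_identical(count_overlaps(feature, read, "same", min_overlap = 11L), 0L)
  expect_identical(count_overlaps(feature, read, "same", min_overlap = 10L), 1L)
  # a read overlapping two features counts in both
  two <- make_reads("chr1", c(0, 15), c(20, 40), "+")
  expect_identical(count_overlaps(two, read, "same"), c(1L, 1L))
})

test_that("overlap counting matches the nested-loop oracle on random instances", {
  genome <- random_genome(c(chr1 = 2000L, chr2 = 1000L), seed = 41)
  for (rep_i in 1:10) {
    reads <- random_reads(genome, 100, len = 27L, seed = 41 + rep_i)
    feats <- random_reads(genome, 20, len = 150L, seed = 141 + rep_i)
    for (mode in c("same", "opposite", "ignore")) {
      expect_identical(count_overlaps(feats, reads, mode),
                       oracle_count_overlaps(feats, reads, mode))
    }
  }
})

test_that("metagene with sim == real is exactly 1 and conserves counts", {
  ds <- small_dataset()
  reads <- ds$library$reads
  genes <- ds$annotation$genes
  mg <- metagene_profile(genes, reads, reads, ds$chrom_sizes)
  expect_identical(mg$n_genes_skipped, 0L)
  expect_true(all(mg$profile$normalized_repair[!is.na(mg$profile$normalized_repair)] == 1))
  expect_identical(mg$profile$real_count, mg$profile$sim_count)
  expect_identical(mg$body_bins, 26:75)

  # conservation: pooled bin counts sum to the count over full extended regions
  flank <- as.integer(round((genes$end - genes$start) * 0.5))
  extended <- transform(genes, start = start - flank, end = end + flank)
  full_ts <- sum(count_overlaps(extended, reads, "opposite"))
  ts_rows <- mg$profile$strand_class == "TS"
  # bin-level counts can exceed the region count only through double counting
  # of boundary-spanning reads; every read in the region appears at least once
  expect_gte(sum(mg$profile$real_count[ts_rows]), full_ts)
  expect_lte(sum(mg$profile$real_count[ts_rows]), 2 * full_ts)
})

test_that("minus-strand genes have bin 1 at their 5' end", {
  sizes <- c(chr1 = 10000)
  gene <- data.frame(id = "g1", chrom = "chr1", start = 4000L, end = 6000L,
                     strand = "-", biotype = "protein_coding")
  # reads piled just inside the gene 5' end (= high coordinates for '-')
  reads <- make_reads("chr1", seq(5900, 5960, by = 2), seq(5927, 5987, by = 2), "+")
  sim <- make_reads("chr1", seq(3000, 6990, by = 10), seq(3027, 7017, by = 10),
                    rep(c("+", "-"), 200))
  mg <- metagene_profile(gene, reads, sim, sizes)
  ts <- mg$profile[mg$profile$strand_class == "TS", ]
  hot <- ts$bin[which(ts$real_count > 0)]
  expect_true(all(hot >= 26 & hot <= 30)) # 5'-most body bins, not bins ~71-75
})

test_that("per-gene-mean aggregation agrees with pooling under identity", {
  ds <- small_dataset()
  reads <- ds$library$reads
  genes <- ds$annotation$genes
  mg <- metagene_profile(genes, reads, reads, ds$chrom_sizes,
                         aggregate = "per_gene_mean")
  vals <- mg$profile$normalized_repair
  expect_true(all(vals[!is.na(vals)] == 1)) # every defined gene-bin ratio is 1
  expect_identical(mg$aggregate, "per_gene_mean")
})

test_that("normalized repair is invariant to duplicating every read", {
  ds <- small_dataset()
  reads <- ds$library$reads[1:5000, ]
  sim <- ds$library$reads[5001:10000, ]
  sim$strand <- withr::with_seed(43, sample(c("+", "-"), 5000, replace = TRUE))
  genes <- ds$annotation$genes
  mg1 <- metagene_profile(genes, reads, sim, ds$chrom_sizes)
  mg2 <- metagene_profile(genes, rbind(reads, reads), rbind(sim, sim),
                          ds$chrom_sizes)
  expect_equal(mg1$profile$normalized_repair, mg2$profile$normalized_repair)
  g1 <- gene_ts_nts(genes, reads, sim)
  g2 <- gene_ts_nts(genes, rbind(reads, reads), rbind(sim, sim))
  expect_equal(g1$log2_ts_nts, g2$log2_ts_nts)
})

test_that("per-gene TS/NTS follows the normalized-ratio formula", {
  sizes <- c(chr1 = 1000)
  gene <- data.frame(id = "g1", chrom = "chr1", start = 100L, end = 600L,
                     strand = "+", biotype = "protein_coding")
  inside <- function(n, strand) make_reads("chr1", seq(150, 149 + 2 * n, by = 2),
                                           seq(177, 176 + 2 * n, by = 2), strand)
  # real: TS (opposite '+' gene = '-' reads) 20, NTS 10; sim: 15 and 15
  real <- rbind(inside(20, "-"), inside(10, "+"))
  sim <- rbind(inside(15, "-"), inside(15, "+"))
  rec <- gene_ts_nts(gene, real, sim)
  expect_true(rec$defined)
  expect_equal(rec$log2_ts_nts, 1.0) # log2((20/15)/(10/15)) = 1
  # RPKM bookkeeping: gene length 500 bp, library totals 30 each
  expect_equal(rec$rpkm_real_ts, rpkm(20, 500, 30))

  # zero counts flag the ratio undefined
  real0 <- inside(20, "-") # no NTS reads at all
  rec0 <- gene_ts_nts(gene, real0, sim)
  expect_false(rec0$defined)
  expect_true(is.na(rec0$log2_ts_nts))
})

test_that("TS/NTS distribution summary reduces correctly", {
  ds <- small_dataset()
  reads <- ds$library$reads
  rec_id <- gene_ts_nts(ds$annotation$genes, reads, reads)
  s <- ts_nts_distribution_summary(rec_id)
  expect_equal(c(s$q1, s$median, s$q3), c(0, 0, 0)) # identity -> all zeros

  one <- rec_id[which(rec_id$defined)[1], ]
  s1 <- ts_nts_distribution_summary(one)
  expect_equal(s1$median, one$log2_ts_nts)
  expect_identical(s1$n, 1L)

  # strong TCR dominates weak TCR
  spec_strong <- synthetic_spec(seed = 44, n_chroms = 1L, chrom_length = 200000L,
                                n_genes = 30L, n_reads = 15000L, kappa = 2)
  spec_weak <- synthetic_spec(seed = 44, n_chroms = 1L, chrom_length = 200000L,
                              n_genes = 30L, n_reads = 15000L, kappa = 0.2)
  mk <- function(spec) {
    d <- generate_synthetic_dataset(spec)
    sim <- simulate_matched_library(d$library$reads, d$genome,
                                    sim_config(seed = 45))$reads
    gene_ts_nts(d$annotation$genes, d$library$reads, sim)
  }
  s2 <- ts_nts_distribution_summary(mk(spec_strong), mk(spec_weak))
  expect_gt(s2$median[1], s2$median[2])
  expect_lt(attr(s2, "wilcox_p"), 0.01)
})

test_that("chromatin-state repair is exact under identity and recovers multipliers", {
  ds <- small_dataset()
  reads <- ds$library$reads
  st <- chromatin_state_repair(ds$states, reads, reads)
  vals <- unlist(st$by_state)
  expect_true(all(vals == 1))

  sim <- simulate_matched_library(reads, ds$genome, sim_config(seed = 46))$reads
  st2 <- chromatin_state_repair(ds$states, reads, sim)
  m <- vapply(st2$by_state, mean, numeric(1))
  expect_gt(m["open"], m["hetGC"])
  expect_gt(m["hetGC"], m["hetAT"] * 0.9) # 0.6 vs 0.5 multiplier, noisy

  # one-segment state survives as a length-1 vector
  seg1 <- rbind(ds$states[1:5, ],
                data.frame(chrom = "chr1", start = 99000L, end = 99500L,
                           state = "lonely"))
  st3 <- chromatin_state_repair(seg1, reads, sim)
  expect_identical(length(st3$by_state[["lonely"]]), 1L)
})

test_that("pairwise Welch tests map p-values to the star notation", {
  expect_identical(p_stars(c(0.2, 0.05, 0.03, 0.009, 0.0005, 0.00005)),
                   c("ns", "*", "*", "**", "***", "****"))
  x <- withr::with_seed(47, rnorm(30, 0, 1))
  tt <- pairwise_state_tests(list(a = x, b = x))
  expect_equal(tt$t, 0)
  expect_identical(tt$stars, "ns")

  # means 0 vs 1, sd 1, n = 50: essentially always below 1e-4
  y <- withr::with_seed(48, list(a = rnorm(50, 0, 1), b = rnorm(50, 1, 1)))
  t2 <- pairwise_state_tests(y)
  expect_identical(t2$stars, "****")
  # agrees with stats::t.test called directly
  expect_equal(t2$p, t.test(y$a, y$b)$p.value)

  t3 <- pairwise_state_tests(list(a = x, b = 1))
  expect_match(t3$skipped_reason, "fewer than 2")
})

test_that("longest-isoform selection applies the length and tie rules", {
  tx <- data.frame(
    transcript_id = c("t1.1", "t1.2", "t2.1", "t3.2", "t3.1"),
    gene_id = c("g1", "g1", "g2", "g3", "g3"),
    length = c(500, 800, 400, 800, 800),
    tpm = c(2, 5, 7, 1, 3)
  )
  tpm <- select_longest_isoform(tx)
  expect_equal(tpm[["g1"]], 5) # longer isoform wins
  expect_equal(tpm[["g2"]], 7) # single isoform
  expect_equal(tpm[["g3"]], 3) # tie -> lexicographically smaller id (t3.1)
  expect_error(select_longest_isoform(tx[, 1:3]), "tpm")
})

test_that("expression correlation returns exact and calibrated estimates", {
  rec <- data.frame(id = sprintf("g%d", 1:10), defined = TRUE,
                    log2_ts_nts = 2 * log10((1:10) + 0.1))
  tpm <- setNames(as.numeric(1:10), rec$id)
  ct <- correlate_expression(rec, tpm)
  expect_equal(ct$r, 1.0) # y is exactly linear in log10(TPM + 0.1)
  expect_identical(ct$n, 10L)

  rec$log2_ts_nts <- 1
  expect_error(correlate_expression(rec, tpm), "variance")
  expect_error(correlate_expression(rec[1:2, ], tpm), "fewer than 3")

  # seeded bivariate normal, rho = 0.5, n = 500: r within the Fisher-z 95% CI
  n <- 500
  xy <- withr::with_seed(49, {
    x <- rnorm(n); y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
    list(x = x, y = y)
  })
  rec2 <- data.frame(id = sprintf("g%d", 1:n), defined = TRUE,
                     log2_ts_nts = xy$y)
  tpm2 <- setNames(10^xy$x - 0.1, rec2$id) # so log10(tpm + 0.1) = x
  ct2 <- correlate_expression(rec2, tpm2)
  expect_gt(ct2$r, 0.41)
  expect_lt(ct2$r, 0.58)
  expect_lt(ct2$p, 1e-10)
})
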