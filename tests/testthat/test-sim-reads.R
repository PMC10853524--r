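# Background-read simulator: target profiles, the count/length/content
# contract, determinism, and conditional positional uniformity.

test_that("target profile captures exact length counts and per-class content", {
  genome <- c(chr1 = strrep("T", 2000))
  reads <- random_reads(genome, 100, len = 27L, seed = 21)
  reads$strand <- "+" # on an all-T genome, '-' reads would read all-A
  tp <- build_target_profile(reads, genome)
  expect_identical(unname(tp$n["27"]), 100L)
  expect_equal(unname(tp$q["27", "TT"]), 1.0)

  genome <- random_genome(c(chr1 = 5000L), seed = 22)
  reads <- random_reads(genome, 100, seed = 23)
  reads$end <- reads$start + rep(c(27L, 20L), c(60, 40))
  tp <- build_target_profile(reads, genome)
  expect_identical(unname(tp$n[c("20", "27")]), c(40L, 60L))
  # cross-module consistency with the QC composition, per length class
  expect_equal(tp$q["27", ],
               c(damage_site_composition(reads, genome, length_filter = 27L)))
  expect_equal(tp$pooled, c(damage_site_composition(reads, genome)))
})

test_that("simulated library matches count and length histogram exactly", {
  genome <- random_genome(c(chr1 = 30000L, chr2 = 20000L), gc = 0.4, seed = 24)
  reads <- random_reads(genome, 1000, seed = 25)
  reads$end <- reads$start + withr::with_seed(26, sample(c(16:21, 25:28), 1000,
                                                         replace = TRUE))
  sm <- simulate_matched_library(reads, genome, sim_config(seed = 27))
  expect_identical(nrow(sm$reads), nrow(reads))
  expect_identical(table(sm$reads$end - sm$reads$start),
                   table(reads$end - reads$start))
  # simulated reads never extend past chromosome ends
  expect_true(all(sm$reads$start >= 0))
  expect_true(all(sm$reads$end <= nchar(genome)[sm$reads$chrom]))
})

test_that("accepted windows carry the matched damage dinucleotide on both strands", {
  genome <- random_genome(c(chr1 = 30000L), seed = 28)
  reads <- random_reads(genome, 400, len = 27L, seed = 29)
  cfg <- sim_config(seed = 30)
  sm <- simulate_matched_library(reads, genome, cfg)
  # zero fallbacks here, so every damage site matched its sampled class;
  # check against sequence fetched through the slow independent path
  expect_identical(sum(sm$report$fallbacks), 0L)
  seqs <- slow_fetch(genome, sm$reads)
  din <- substr(seqs, 20, 21)
  expect_true(all(din %in% excisr:::DINUCS))
  minus <- sm$reads$strand == "-"
  expect_gt(sum(minus), 0)
  # pooled composition within multinomial noise of the target: for n = 400
  # over 16 categories E[TV] ~ 0.065, so 2x that is a generous sanity bound
  expect_lt(sm$report$tv_pooled, 0.13)
})

test_that("an all-T genome with a TT target needs no fallbacks and matches exactly", {
  genome <- c(chr1 = strrep("T", 5000), chr2 = strrep("T", 3000))
  reads <- random_reads(genome, 200, len = 27L, seed = 31)
  reads$strand <- "+" # target all TT; '+' proposals match instantly,
                      # '-' proposals (reading AA) are rejected
  sm <- simulate_matched_library(reads, genome, sim_config(seed = 32))
  expect_identical(sum(sm$report$fallbacks), 0L)
  expect_equal(sm$report$tv_pooled, 0)
  seqs <- slow_fetch(genome, sm$reads)
  expect_true(all(substr(seqs, 20, 21) == "TT"))
})

test_that("impossible targets fall back (counted) or error when fallback is off", {
  genome <- c(chr1 = strrep("AT", 2500)) # no CC anywhere on either strand
  target <- structure(list(
    lengths = 27L, n = c("27" = 50L),
    q = matrix(as.numeric(excisr:::DINUCS == "CC"), nrow = 1,
               dimnames = list("27", excisr:::DINUCS)),
    pooled = NULL, total = 50L), class = "sim_target")
  sim <- simulate_reads(target, genome, sim_config(seed = 33, max_tries = 5))
  expect_identical(nrow(sim), 50L) # count contract kept by fallback
  expect_identical(unname(attr(sim, "report")$fallbacks["27"]), 50L)
  expect_error(
    simulate_reads(target, genome,
                   sim_config(seed = 33, max_tries = 5, fallback = FALSE)),
    "max_tries")
})

test_that("simulation is bit-identical under a fixed seed", {
  ds <- small_dataset()
  reads <- ds$library$reads[1:2000, ]
  s1 <- simulate_matched_library(reads, ds$genome, sim_config(seed = 34))
  s2 <- simulate_matched_library(reads, ds$genome, sim_config(seed = 34))
  expect_identical(s1$reads, s2$reads)
  s3 <- simulate_matched_library(reads, ds$genome, sim_config(seed = 35))
  expect_false(identical(s1$reads, s3$reads))
  # byte-identical BED files
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_bed6(s1$reads, f1); write_bed6(s2$reads, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("positions are uniform over dinucleotide-carrying windows", {
  # uniform-composition toy genome, one length class; conditional on the
  # sampled dinucleotide, lesion positions must be uniform over the
  # positions carrying it, so tile counts follow tile-level availability
  genome <- random_genome(c(chr1 = 50000L), gc = 0.5, seed = 36)
  reads <- random_reads(genome, 2000, len = 27L, seed = 37)
  target <- build_target_profile(reads, genome)
  target$n[] <- 0L
  target$n["27"] <- 50000L
  sim <- simulate_reads(target, genome, sim_config(seed = 38))
  expect_identical(sum(attr(sim, "report")$fallbacks), 0L)

  # lesion (damage dinucleotide) 0-based start position per read
  g <- ifelse(sim$strand == "+", sim$start + 19L, sim$start + 6L)
  din <- substr(slow_fetch(genome, sim), 20, 21)
  tile <- factor(floor(g / 5000), levels = 0:9)

  # availability of each dinucleotide per tile, both strands
  codes <- strsplit(genome[[1]], "")[[1]]
  fwd <- paste0(codes[-length(codes)], codes[-1])
  fwd_tile <- floor((seq_along(fwd) - 1) / 5000)
  avail <- table(factor(fwd_tile, levels = 0:9),
                 factor(fwd, levels = excisr:::DINUCS)) # forward strand
  avail <- avail + avail[, excisr:::DINUCS[excisr:::.dinuc_rc_index]]
  n_d <- table(factor(din, levels = excisr:::DINUCS))
  expected <- as.numeric(avail %*% (as.numeric(n_d) / colSums(avail)))
  observed <- as.numeric(table(tile))
  X2 <- sum((observed - expected)^2 / expected)
  p <- pchisq(X2, df = 9, lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("per-position mononucleotide matching shifts composition toward the target", {
  genome <- random_genome(c(chr1 = 40000L), gc = 0.5, seed = 39)
  # real reads drawn only from T-rich windows: biased mono profile
  codes <- strsplit(genome[[1]], "")[[1]]
  tcount <- vapply(seq_len(40000L - 27L), function(s) {
    sum(codes[s:(s + 26)] == "T")
  }, numeric(1))
  top <- order(tcount, decreasing = TRUE)[1:500]
  reads <- make_reads("chr1", top - 1L, top + 26L, "+")
  cfg <- sim_config(seed = 40, match_mode = "per_position_mono")
  sm <- simulate_matched_library(reads, genome, cfg)
  real_t <- mean(positional_nucleotide_frequencies(reads, genome, 27L)["T", ])
  sim_t <- mean(positional_nucleotide_frequencies(sm$reads, genome, 27L)["T", ])
  base_t <- 0.25
  # reweighted simulation recovers most of the T enrichment over background
  expect_gt(sim_t, base_t + 0.5 * (real_t - base_t) - 0.05)
})
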