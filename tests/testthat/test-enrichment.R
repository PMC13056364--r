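# Genome binning, midpoint read counting, pseudocounted enrichment scores,
# distance profiles, and recovery summaries.

toy_binning <- function() bin_genome(c(chr1 = 250000), 100000)

test_that("binning tiles chromosomes into half-open windows", {
  b <- toy_binning()
  expect_equal(length(b$bins), 3)
  expect_equal(GenomicRanges::start(b$bins) - 1L, c(0, 100000, 200000))
  expect_equal(GenomicRanges::end(b$bins), c(100000, 200000, 250000))

  short <- bin_genome(c(tiny = 40000), 100000)
  expect_equal(length(short$bins), 1)
  expect_equal(GenomicRanges::width(short$bins), 40000)

  two <- bin_genome(data.frame(chrom = c("a", "b"),
                               size_bp = c(300000, 150000)), 100000)
  expect_equal(length(two$bins), 5)
  expect_error(bin_genome(c(a = 1e5), 0), "positive")
  expect_error(bin_genome(c(a = 1e5, a = 2e5), 1e5), "duplicate")
})

test_that("reads are assigned to bins by their interval midpoint", {
  b <- toy_binning()
  reads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(150001, 99951), end = c(150100, 100050)))  # 1-based closed
  counts <- count_reads(reads, b)
  # [150000,150100) -> midpoint 150050 -> bin 2; straddler [99950,100050)
  # -> midpoint 100000 -> bin 2, counted once
  expect_equal(counts$counts, c(0, 2, 0))
  expect_equal(counts$total_reads, 2)
})

test_that("reads on unknown chromosomes are skipped and counted", {
  b <- toy_binning()
  reads <- GenomicRanges::GRanges(
    c("chr1", "chrUn", "chr1"),
    IRanges::IRanges(start = c(1, 1, 200001), width = 50))
  expect_message(counts <- count_reads(reads, b), "skipped")
  expect_equal(sum(counts$counts), 2)
  expect_equal(attr(counts, "n_skipped"), 1)
})

test_that("random reads are conserved through counting", {
  set.seed(6)
  b <- bin_genome(c(c1 = 2e6, c2 = 1e6), 1e5)
  n <- 1000
  chrom <- sample(c("c1", "c2"), n, replace = TRUE)
  start0 <- floor(runif(n, 0, ifelse(chrom == "c1", 2e6, 1e6) - 100))
  reads <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
    start = start0 + 1, width = 100))
  counts <- count_reads(reads, b)
  expect_equal(sum(counts$counts), n)
})

test_that("identical libraries score 1 in every bin, either orientation", {
  b <- bin_genome(c(chrA = 1e6), 1e5)
  x <- binned_counts(b, c(5, 0, 12, 7, 0, 3, 9, 1, 2, 11), "input")
  y <- binned_counts(b, c(5, 0, 12, 7, 0, 3, 9, 1, 2, 11), "pulldown")
  expect_equal(enrichment_scores(x, y)$score, rep(1, 10))
  expect_equal(enrichment_scores(x, y, orientation = "inverted")$score,
               rep(1, 10))
})

test_that("the two-bin hand-computed case is reproduced exactly", {
  b <- bin_genome(c(chrA = 200000), 100000)
  input <- binned_counts(b, c(90, 10), "input")
  pulldown <- binned_counts(b, c(10, 90), "pulldown")
  p <- enrichment_scores(input, pulldown)  # pseudocount 10 per bin
  expect_equal(p$pseudocount_input, 10)
  expect_equal(p$score, c(5, 0.2))
  inv <- enrichment_scores(input, pulldown, orientation = "inverted")
  expect_equal(inv$score, c(0.2, 5))
})

test_that("pseudocounted fractions are normalized and scores positive", {
  set.seed(7)
  b <- bin_genome(c(chrA = 5e6), 1e5)
  input <- binned_counts(b, rpois(50, 20), "input")
  pulldown <- binned_counts(b, c(rep(0, 10), rpois(40, 40)), "pulldown")
  p <- enrichment_scores(input, pulldown)
  expect_lt(abs(sum(p$frac_input) - 1), 1e-12)
  expect_lt(abs(sum(p$frac_pulldown) - 1), 1e-12)
  expect_true(all(is.finite(p$score) & p$score > 0))
})

test_that("inverted and as-printed scores are exact reciprocals", {
  set.seed(8)
  b <- bin_genome(c(chrA = 3e6), 1e5)
  input <- binned_counts(b, rpois(30, 15), "input")
  pulldown <- binned_counts(b, rpois(30, 25), "pulldown")
  a <- enrichment_scores(input, pulldown)$score
  i <- enrichment_scores(input, pulldown, orientation = "inverted")$score
  expect_equal(a * i, rep(1, 30))
})

test_that("scores are invariant to common depth scaling", {
  b <- bin_genome(c(chrA = 2e6), 1e5)
  cin <- c(3, 9, 0, 5, 20, 1, 7, 2, 4, 6, 8, 10, 0, 2, 5, 9, 3, 1, 6, 4)
  cpd <- rev(cin)
  s1 <- enrichment_scores(binned_counts(b, cin, "input"),
                          binned_counts(b, cpd, "pulldown"))$score
  s7 <- enrichment_scores(binned_counts(b, 7 * cin, "input"),
                          binned_counts(b, 7 * cpd, "pulldown"))$score
  expect_equal(s1, s7)
})

test_that("growing pseudocounts shrink scores monotonically toward 1", {
  b <- bin_genome(c(chrA = 500000), 1e5)
  input <- binned_counts(b, c(50, 10, 0, 30, 10), "input")
  pulldown <- binned_counts(b, c(5, 25, 40, 10, 20), "pulldown")
  fracs <- c(0.05, 0.1, 0.5, 2, 10)
  dev <- sapply(fracs, function(f) {
    abs(log(enrichment_scores(input, pulldown,
                              pseudocount_fraction = f)$score))
  })
  for (i in seq_len(ncol(dev) - 1)) expect_true(all(dev[, i + 1] < dev[, i]))
})

test_that("distance profiles measure midpoint-to-target distances", {
  b <- bin_genome(c(chr1 = 1200000), 100000)
  input <- binned_counts(b, rep(10, 12), "input")
  pulldown <- binned_counts(b, rep(10, 12), "pulldown")
  p <- enrichment_scores(input, pulldown)
  targets <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(1000001, 1020000))
  dp <- distance_profile(p, targets)
  # last bin [1100000,1200000): midpoint 1150000, 130 kb past the target end
  last <- dp[dp$start == 1100000, ]
  expect_equal(last$distance_bp, 130000)
  expect_equal(last$log10_distance, 5.11394, tolerance = 1e-5)
  expect_false(last$on_target)
  # the bin overlapping the target is on-target at distance 0
  hit <- dp[dp$start == 1000000, ]
  expect_equal(hit$distance_bp, 0)
  expect_true(hit$on_target)
  expect_true(is.na(hit$log10_distance))
  expect_true(all(dp$on_target == (dp$distance_bp == 0)))
})

test_that("chromosomes without targets are excluded from the profile", {
  b <- bin_genome(c(chr1 = 300000, chr2 = 300000), 100000)
  input <- binned_counts(b, rep(5, 6), "input")
  pulldown <- binned_counts(b, rep(5, 6), "pulldown")
  p <- enrichment_scores(input, pulldown)
  targets <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  dp <- distance_profile(p, targets)
  expect_setequal(unique(dp$chrom), "chr1")
  expect_equal(nrow(dp), 3)
  expect_error(distance_profile(p, GenomicRanges::GRanges()), "target")
})

test_that("a strongly enriched target tops the genome-wide ranking", {
  sim <- simulate_libraries(c(chrA = 2.5e7), 1e5, target_bins = 100,
                            fold_enrichment = 20, depth_input = 1e5,
                            depth_pulldown = 1e5, seed = 13)
  p <- enrichment_scores(sim$input, sim$pulldown)
  rec <- summarize_recovery(p, 100L)
  expect_equal(rec$best_target_rank, 1)
  expect_equal(rec$n_bins, 250)
})

test_that("partner bins outrank background while the target leads", {
  sim <- simulate_libraries(c(chrA = 2.5e7), 1e5, target_bins = 60,
                            partner_bins = 180, fold_enrichment = 20,
                            depth_input = 1e5, depth_pulldown = 1e5,
                            seed = 14)
  p <- enrichment_scores(sim$input, sim$pulldown)
  rec <- summarize_recovery(p, 60L, 180L)
  expect_equal(rec$best_target_rank, 1)
  expect_lt(rec$median_partner_rank, rec$median_background_rank)
})

test_that("null libraries rank targets arbitrarily with unit background", {
  sim <- simulate_libraries(c(chrA = 2.5e7), 1e5, target_bins = 100,
                            fold_enrichment = 1, depth_input = 1e5,
                            depth_pulldown = 1e5, seed = 15)
  p <- enrichment_scores(sim$input, sim$pulldown)
  rec <- summarize_recovery(p, 100L)
  expect_equal(rec$median_background_score, 1, tolerance = 0.01)
  expect_gt(rec$best_target_rank, 1)
})

test_that("profiles round-trip through bedGraph and TSV", {
  tmp <- withr::local_tempdir()
  b <- bin_genome(c(chrA = 300000), 1e5)
  p <- enrichment_scores(binned_counts(b, c(10, 20, 30), "input"),
                         binned_counts(b, c(30, 20, 10), "pulldown"))
  bg <- file.path(tmp, "scores.bedGraph")
  tsv <- file.path(tmp, "scores.tsv")
  df <- write_profile(p, bg, tsv)
  reread <- read.delim(tsv)
  expect_equal(reread$score, df$score, tolerance = 1e-6)
  expect_equal(nrow(read.table(bg)), 3)
})

test_that("BED round trip preserves 0-based half-open intervals", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  gr <- GenomicRanges::GRanges("chr9", IRanges::IRanges(
    start = c(101, 5001), end = c(200, 5100)))
  write_bed(gr, tmp)
  raw <- read.table(tmp)
  expect_equal(raw$V2, c(100, 5000))
  expect_equal(raw$V3, c(200, 5100))
  back <- read_bed(tmp)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
})
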