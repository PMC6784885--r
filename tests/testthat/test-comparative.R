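test_that("ANI of a genome with itself is 100% over the full length", {
  g <- random_genome("a", 12000, seed = 1)
  r <- pairwise_ani(g, genome("b", g$sequence))
  expect_equal(r$ani, 100)
  expect_equal(r$aligned_fraction, 1)
  expect_equal(r$n_fragments_kept, r$n_fragments)
})

test_that("ANI tracks the planted divergence within binomial noise", {
  a <- random_genome("a", 20000, seed = 2)
  for (e in c(0.05, 0.10)) {
    b <- genome("b", mutate_seq(a$sequence, e, seed = round(1000 * e)))
    r <- pairwise_ani(a, b)
    sigma <- 100 * sqrt(e * (1 - e) / 1000 / r$n_fragments_kept)
    expect_lt(abs(r$ani - 100 * (1 - e)), 3 * sigma)
    expect_equal(r$n_fragments_kept, r$n_fragments)
  }
})

test_that("unrelated sequences yield no retained fragments", {
  a <- random_genome("a", 5000, seed = 3)
  b <- random_genome("b", 5000, seed = 4)
  r <- pairwise_ani(a, b)
  expect_true(is.na(r$ani))
  expect_equal(r$aligned_fraction, 0)
  expect_error(pairwise_ani(genome("s", "ACGT"), a), "fragment")
})

test_that("ANI is quasi-symmetric on diverged pairs", {
  a <- random_genome("a", 15000, seed = 5)
  for (seed in 1:3) {
    b <- genome("b", mutate_seq(a$sequence, 0.05, seed = seed))
    d <- abs(pairwise_ani(a, b)$ani - pairwise_ani(b, a)$ani)
    expect_lte(d, 1.0)
  }
})

test_that("rearrangement counting matches constructed events", {
  s <- random_genome("g1", 60000, seed = 6)$sequence
  g1 <- genome("g1", s)
  r0 <- find_rearrangements(list(g1, genome("same", s)))
  expect_equal(nrow(r0$blocks[[1]]), 1L)
  expect_equal(unname(r0$counts), 0L)

  inv <- paste0(substr(s, 1, 25000), revcomp(substr(s, 25001, 35000)),
                substr(s, 35001, 60000))
  r1 <- find_rearrangements(list(g1, genome("inv", inv)))
  expect_gte(nrow(r1$blocks[[1]]), 3L)
  expect_true(any(r1$blocks[[1]]$orient == -1L))
  expect_equal(unname(r1$counts), 1L)

  transpose <- function(x, from, len, to) {
    seg <- substr(x, from, from + len - 1)
    rest <- paste0(substr(x, 1, from - 1), substr(x, from + len, nchar(x)))
    paste0(substr(rest, 1, to), seg, substr(rest, to + 1, nchar(rest)))
  }
  t3 <- transpose(s, 5001, 6000, 40000)
  t3 <- transpose(t3, 15001, 6000, 50000)
  t3 <- transpose(t3, 25001, 6000, 57000)
  r3 <- find_rearrangements(list(g1, genome("t3", t3)))
  expect_equal(unname(r3$counts), 3L)

  expect_error(find_rearrangements(list(g1)), "two genomes")
})

test_that("identity blocks degenerate correctly and tile the alignment", {
  g <- random_genome("a", 5000, seed = 7)
  same <- list(g, genome("b", g$sequence), genome("c", g$sequence))
  bl <- segment_identity_blocks(same)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$n_classes, 1L)
  expect_equal(c(bl$start, bl$end), c(0L, 5000L))
  expect_error(
    segment_identity_blocks(list(g, genome("x", "ACGTACGTACGT"))),
    "pre-align")
})

test_that("constructed admixture gives the expected partitions", {
  base <- random_genome("base", 20000, seed = 8)$sequence
  altA <- mutate_seq(base, 0.02, seed = 9)
  # g1 = g2 on [0,10 kb), g2 = g3 on [10 kb, 20 kb)
  g1 <- genome("g1", paste0(substr(base, 1, 10000),
                            substr(altA, 10001, 20000)))
  g2 <- genome("g2", base)
  g3 <- genome("g3", paste0(substr(altA, 1, 10000),
                            substr(base, 10001, 20000)))
  bl <- segment_identity_blocks(list(g1, g2, g3))
  expect_equal(nrow(bl), 2L)
  expect_equal(bl$partition, c("1|1|2", "1|2|2"))
  # boundary within one informative-site spacing of 10,000
  expect_lt(abs(bl$end[1] - 10000), 20000 / sum(
    strsplit(base, "")[[1]] != strsplit(altA, "")[[1]]) + 1)
})

test_that("segmentation equals the brute-force per-column oracle", {
  ref <- random_genome("r", 8000, seed = 10)
  for (seed in 1:3) {
    mp <- generate_mosaic_population(ref, n_genomes = 4,
                                     block_mean = 1500, seed = seed)
    runs <- attr(segment_identity_blocks(mp$genomes), "runs")
    oracle <- blocks_oracle(mp$genomes)
    expect_equal(runs$start, oracle$start)
    expect_equal(runs$end, oracle$end)
    expect_equal(runs$partition, oracle$partition)
  }
})

test_that("absorbed micro-runs keep the tiling exact", {
  ref <- random_genome("r", 30000, seed = 11)
  mp <- generate_mosaic_population(ref, n_genomes = 5, block_mean = 2000,
                                   seed = 12)
  bl <- segment_identity_blocks(mp$genomes, min_block = 1000)
  expect_equal(bl$start[1], 0L)
  expect_equal(bl$end[nrow(bl)], 30000L)
  if (nrow(bl) > 1) {
    expect_equal(bl$start[-1], bl$end[-nrow(bl)])
  }
  expect_true(all(bl$end - bl$start >= 1000L | nrow(bl) == 1L))
})

test_that("the metagenome screen applies the length and identity filter", {
  ref <- random_genome("ref", 40000, seed = 13)
  slice <- function(at, len) substr(ref$sequence, at, at + len - 1)
  set.seed(14)
  grid <- expand.grid(len = c(1500, 2500, 4000), div = c(0, 0.2, 0.35))
  for (i in seq_len(nrow(grid))) {
    len <- grid$len[i]; div <- grid$div[i]
    ctg <- genome("c", mutate_seq(slice(2000, len), div))
    res <- screen_metagenome(ctg, ref)
    should <- len >= 2000 && div < 0.25
    expect_equal(res$present, should,
                 info = sprintf("len=%d div=%.2f", len, div))
    if (should) expect_equal(res$total_aligned, len)
  }
  # exact 5 kb slice: present with the full length aligned
  hit <- screen_metagenome(genome("h", slice(10000, 5000)), ref)
  expect_true(hit$present)
  expect_equal(hit$total_aligned, 5000)
  # reverse-complemented contigs are still found
  rc <- screen_metagenome(genome("r", revcomp(slice(9000, 3000))), ref)
  expect_true(rc$present)
})

test_that("marker profiles cluster identical markers and normalise depth", {
  m1 <- random_genome("m1", 600, seed = 15)
  m2 <- genome("m2", m1$sequence)
  m3 <- random_genome("m3", 600, seed = 16)
  reads <- generate_reads(m1, coverage = 20, read_len = 100,
                          error_rate = 0, seed = 17)
  prof <- marker_profile(list(m1, m2, m3), reads)
  expect_equal(nrow(prof), 2L)  # identical markers collapse
  src <- prof[grepl("m1", prof$members), ]
  other <- prof[!grepl("m1", prof$members), ]
  expect_gt(src$breadth_pct, 99)
  expect_equal(other$breadth_pct, 0)
  # duplicating every read leaves relative abundances unchanged
  prof2 <- marker_profile(list(m1, m2, m3), rbind(reads, reads))
  expect_equal(prof2$rel_abundance, prof$rel_abundance, tolerance = 1e-9)
})
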