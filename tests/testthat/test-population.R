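test_that("error-free reads map back to their exact origins", {
  ref <- random_genome("ref", 20000, seed = 1, circular = TRUE)
  rds <- generate_reads(ref, coverage = 3, read_len = 125,
                        error_rate = 0, seed = 2)
  pl <- map_reads(rds, ref)
  expect_equal(nrow(pl), nrow(rds))
  m <- match(pl$read_id, rds$id)
  expect_true(all(pl$start == rds$start[m]))
  expect_true(all(pl$n_mm == 0L))
  expect_true(all(pl$strand == rds$strand[m]))
  expect_length(attr(pl, "unmapped"), 0L)
})

test_that("the mapper is complete for every position of a small genome", {
  ref <- random_genome("ref", 600, seed = 3)
  L <- genome_length(ref)
  rl <- 50L
  reads <- substring(ref$sequence, 1:(L - rl + 1), rl:L)
  pl <- map_reads(reads, ref, k = 21L)
  expect_equal(nrow(pl), L - rl + 1L)
  expect_equal(sort(pl$start), 0:(L - rl))
  expect_true(all(pl$n_mm == 0L))
})

test_that("reads beyond the mismatch budget go unmapped", {
  ref <- random_genome("ref", 5000, seed = 4)
  rd <- substr(ref$sequence, 1000, 1124)
  ch <- strsplit(rd, "")[[1]]
  set.seed(5)
  pos <- sample(30:90, 6)
  ch[pos] <- vapply(ch[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, "")
  rd6 <- paste(ch, collapse = "")
  pl <- map_reads(rd6, ref, max_mm = 5L)
  expect_equal(nrow(pl), 0L)
  expect_length(attr(pl, "unmapped"), 1L)
  pl2 <- map_reads(rd6, ref, max_mm = 6L)
  expect_equal(pl2$start, 999L)
  expect_equal(pl2$n_mm, 6L)
})

test_that("reverse-complemented reads land on the same interval", {
  ref <- random_genome("ref", 5000, seed = 6)
  rd <- substr(ref$sequence, 2000, 2124)
  fwd <- map_reads(rd, ref)
  rev <- map_reads(revcomp(rd), ref)
  expect_equal(rev$start, fwd$start)
  expect_equal(rev$end, fwd$end)
  expect_true(fwd$strand != rev$strand)
})

test_that("zero-SNP fraction matches its closed-form expectation", {
  ref <- random_genome("ref", 30000, seed = 7, circular = TRUE)
  clonal <- generate_reads(ref, coverage = 4, error_rate = 0, seed = 8)
  expect_equal(zero_snp_fraction(map_reads(clonal, ref)), 1)

  e <- 0.004
  rds <- generate_reads(ref, coverage = 8, read_len = 125,
                        error_rate = e, seed = 9)
  pl <- map_reads(rds, ref)
  p <- (1 - e) ^ 125
  sigma <- sqrt(p * (1 - p) / nrow(pl))
  expect_lt(abs(zero_snp_fraction(pl) - p), 3 * sigma)
  expect_error(zero_snp_fraction(pl[0, ]), "no placements")
})

test_that("a diverged subpopulation shifts the zero-SNP fraction as a mixture", {
  ref <- random_genome("ref", 25000, seed = 10, circular = TRUE)
  minor <- genome("minor", mutate_seq(ref$sequence, 0.02, seed = 11),
                  circular = TRUE)
  rds <- generate_reads(list(ref, minor), weights = c(0.95, 0.05),
                        coverage = 10, read_len = 125, error_rate = 0,
                        seed = 12)
  pl <- map_reads(rds, ref, max_mm = 10L)
  expected <- 0.95 + 0.05 * (1 - 0.02) ^ 125
  n <- nrow(pl)
  expect_lt(abs(zero_snp_fraction(pl) - expected),
            3 * sqrt(expected * (1 - expected) / n) + 0.02)
})

test_that("variant calling sees a planted mixture and honours filters", {
  ref <- random_genome("ref", 20000, seed = 13, circular = TRUE)
  ch <- strsplit(ref$sequence, "")[[1]]
  set.seed(14)
  sites <- sort(sample(1000:19000, 20))
  ch[sites] <- vapply(ch[sites], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, "")
  hap2 <- genome("hap2", paste(ch, collapse = ""), circular = TRUE)
  rds <- generate_reads(list(ref, hap2), weights = c(0.7, 0.3),
                        coverage = 40, error_rate = 0, seed = 15)
  pl <- map_reads(rds, ref)
  v <- call_variants(pl, ref)
  called <- sort(unique(v$pos))
  expect_gte(length(intersect(called, sites - 1)), 18)
  freqs <- v$freq[v$pos %in% (sites - 1)]
  expect_lt(abs(mean(freqs) - 0.3), 0.05)

  clonal <- generate_reads(ref, coverage = 10, error_rate = 0, seed = 16)
  expect_equal(nrow(call_variants(map_reads(clonal, ref), ref)), 0L)
})

test_that("low-coverage sites are suppressed by min_cov", {
  ref <- random_genome("ref", 2000, seed = 17)
  # 9 identical reads carrying one substitution at position 500 (0-based)
  rd <- substr(ref$sequence, 401, 600)
  ch <- strsplit(rd, "")[[1]]
  ch[100] <- setdiff(c("A", "C", "G", "T"), ch[100])[1]
  reads <- rep(paste(ch, collapse = ""), 9)
  v9 <- call_variants(map_reads(reads, ref), ref, min_cov = 10)
  expect_equal(nrow(v9), 0L)
  v10 <- call_variants(map_reads(c(reads, reads[1]), ref), ref,
                       min_cov = 10)
  expect_equal(unique(v10$pos), 499L)  # 0-based: read base 100 of [400,600)
})

test_that("trajectories follow a moving mixture and report linkage", {
  ref <- random_genome("ref", 20000, seed = 18, circular = TRUE)
  ch <- strsplit(ref$sequence, "")[[1]]
  set.seed(19)
  sites <- sort(sample(2000:18000, 12))
  ch[sites] <- vapply(ch[sites], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, "")
  hap2 <- genome("hap2", paste(ch, collapse = ""), circular = TRUE)
  mixes <- c(0.2, 0.6)
  pls <- lapply(seq_along(mixes), function(i) {
    rds <- generate_reads(list(ref, hap2),
                          weights = c(1 - mixes[i], mixes[i]),
                          coverage = 40, error_rate = 0, seed = 20 + i)
    map_reads(rds, ref)
  })
  names(pls) <- c("day1", "day2")
  v <- call_variants(pls, ref)
  tr <- variant_trajectories(v, pls, ref)
  planted <- tr$trajectories[tr$trajectories$pos %in% (sites - 1), ]
  expect_gte(nrow(planted), 10)
  expect_lt(mean(abs(planted$day1 - 0.2)), 0.08)
  expect_lt(mean(abs(planted$day2 - 0.6)), 0.08)
  expect_gt(mean(planted$day2 - planted$day1), 0.25)
  # private sites of one subpopulation move together, i.e. are linked
  if (!is.null(tr$linkage) && nrow(tr$linkage) > 0) {
    expect_gt(mean(abs(tr$linkage$dprime)), 0.5)
  }
  expect_error(variant_trajectories(v[v$sample == "day1", ]),
               "two ordered samples")
})

test_that("independent sites show no linkage", {
  ref <- random_genome("ref", 6000, seed = 22, circular = TRUE)
  # two haplotypes recombined freely: alleles at two sites independent
  s1 <- 3000L; s2 <- 3050L
  ch <- strsplit(ref$sequence, "")[[1]]
  a1 <- setdiff(c("A", "C", "G", "T"), ch[s1])[1]
  a2 <- setdiff(c("A", "C", "G", "T"), ch[s2])[1]
  set.seed(23)
  reads <- vapply(1:400, function(i) {
    x <- ch[2950:3120]
    if (runif(1) < 0.5) x[s1 - 2949] <- a1
    if (runif(1) < 0.5) x[s2 - 2949] <- a2
    paste(x, collapse = "")
  }, "")
  pls <- list(t1 = map_reads(reads, ref), t2 = map_reads(reads, ref))
  v <- call_variants(pls, ref)
  tr <- variant_trajectories(v, pls, ref)
  expect_false(is.null(tr$linkage))
  expect_lt(max(abs(tr$linkage$dprime)), 0.5)
  expect_true(tr$unlinked)
})

test_that("recombinant reads are detected with a localised switch", {
  ref <- random_genome("B1", 20000, seed = 24)
  b2 <- genome("B2", mutate_seq(ref$sequence, 0.04, seed = 25))
  panel <- list(ref, b2)
  diff_pos <- which(strsplit(ref$sequence, "")[[1]] !=
                      strsplit(b2$sequence, "")[[1]])
  # chimeric read: left half B1 alleles, right half B2 alleles, 4+4 sites
  win <- NULL
  for (i in seq_len(length(diff_pos) - 7)) {
    if (diff_pos[i + 7] - diff_pos[i] < 110) { win <- i; break }
  }
  expect_false(is.null(win))
  js <- diff_pos[win + 3]   # junction after 4th diagnostic site
  je <- diff_pos[win + 4]
  s0 <- max(1, diff_pos[win] - 5)
  e0 <- min(20000, diff_pos[win + 7] + 5)
  chim <- paste0(substr(ref$sequence, s0, js),
                 substr(b2$sequence, js + 1, e0))
  pl <- map_reads(chim, ref, max_mm = 10L)
  rr <- find_recombinant_reads(pl, panel, ref)
  expect_equal(nrow(rr), 1L)
  expect_true(rr$recombinant)
  expect_equal(rr$n_switches, 1L)
  # switch interval covers the true junction
  expect_lte(rr$switch_start, js)
  expect_gte(rr$switch_end, js)

  # a pure B1 read over the same window is never flagged
  pure <- substr(ref$sequence, s0, e0)
  rp <- find_recombinant_reads(map_reads(pure, ref), panel, ref)
  expect_equal(nrow(rp), 1L)
  expect_false(rp$recombinant)

  # reads covering a single diagnostic site are uninformative
  gaps <- diff(c(0, diff_pos, 20000))
  iso <- which(gaps[-length(gaps)] > 80 & gaps[-1] > 80)[1]
  if (!is.na(iso)) {
    one <- substr(ref$sequence, diff_pos[iso] - 30, diff_pos[iso] + 30)
    r1 <- find_recombinant_reads(map_reads(one, ref), panel, ref)
    expect_equal(nrow(r1), 0L)
  }
  expect_error(find_recombinant_reads(pl, list(ref), ref), "two genomes")
})
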