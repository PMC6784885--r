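test_that("generators are pure functions of their seed", {
  a <- generate_phage_genome(length = 20000, code = 15, seed = 9)
  b <- generate_phage_genome(length = 20000, code = 15, seed = 9)
  expect_identical(a, b)
  expect_false(identical(
    a$genome$sequence,
    generate_phage_genome(length = 20000, code = 15, seed = 10)$genome$sequence))

  ref <- random_genome("ref", 15000, seed = 1)
  m1 <- generate_mosaic_population(ref, 3, seed = 5)
  m2 <- generate_mosaic_population(ref, 3, seed = 5)
  expect_identical(m1$truth$breakpoints, m2$truth$breakpoints)

  r1 <- generate_reads(ref, coverage = 2, seed = 6)
  r2 <- generate_reads(ref, coverage = 2, seed = 6)
  expect_identical(r1, r2)
})

test_that("planted genes translate cleanly under the planted code", {
  for (code in c(11, 15)) {
    sim <- generate_phage_genome(length = 30000, code = code, seed = 21)
    genes <- sim$truth$genes
    expect_gt(nrow(genes), 10)
    for (i in seq_len(nrow(genes))) {
      aa <- translate_seq(substr(sim$genome$sequence, genes$start[i] + 1,
                                 genes$end[i]), code)
      # exactly one stop, at the end; no internal stops under its own code
      expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
      expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
    }
    if (code == 11) expect_true(all(genes$n_TAG == 0L))
  }
})

test_that("planted in-frame TAG counts match the recorded truth", {
  sim <- generate_phage_genome(length = 40000, code = 15, tag_rate = 0.01,
                               seed = 33)
  genes <- sim$truth$genes
  for (i in seq_len(nrow(genes))) {
    cods <- substring(sim$genome$sequence,
                      seq(genes$start[i] + 1, genes$end[i], 3),
                      seq(genes$start[i] + 3, genes$end[i], 3))
    expect_equal(sum(cods == "TAG"), genes$n_TAG[i])
    if (genes$tag_free[i]) expect_equal(genes$n_TAG[i], 0L)
  }
  # total planted TAGs behave like the intended binomial rate
  perm_cod <- sum(((genes$end - genes$start) / 3 - 2)[!genes$tag_free])
  expect_gt(sum(genes$n_TAG), 0)
  expect_lt(abs(sum(genes$n_TAG) - 0.01 * perm_cod),
            4 * sqrt(perm_cod * 0.01 * 0.99))
})

test_that("realised GC stays within 0.02 of the specification", {
  for (seed in 1:3) {
    sim <- generate_phage_genome(length = 30000, gc = 0.26, seed = seed)
    expect_lt(abs(sim$truth$gc_realized - 0.26), 0.02)
  }
})

test_that("infeasible TAG-free spans are rejected", {
  expect_error(generate_phage_genome(length = 10000,
                                     tag_free_spans = rbind(c(0, 20000))),
               "within the genome")
  expect_error(generate_phage_genome(length = 20000,
                                     tag_free_spans = rbind(c(0, 10000),
                                                            c(5000, 15000))),
               "disjoint")
})

test_that("host scaffolds carry the planted array and protospacers", {
  phage <- generate_phage_genome(length = 20000, code = 15,
                                 seed = 2)$genome
  hs <- generate_host_scaffold(phage, n_spacers = 3, decoy_spacers = 0,
                               seed = 4)
  expect_equal(nrow(hs$truth$protospacers), 3L)
  expect_equal(hs$truth$repeat_seq, "GGTTTAATCGTACCTTTATGGAATTGAAAT")
  # every planted spacer occurs in the phage at its recorded interval,
  # reverse-complemented for minus-strand spacers
  for (i in seq_len(nrow(hs$truth$protospacers))) {
    pr <- hs$truth$protospacers[i, ]
    sp <- hs$truth$spacers$sequence[pr$spacer_index]
    at <- substr(phage$sequence, pr$start + 1, pr$end)
    expect_equal(if (pr$strand == "+") at else revcomp(at), sp)
  }
  expect_error(generate_host_scaffold(genome("tiny", "ACGTACGT"), 1),
               "shorter")
  expect_error(generate_host_scaffold(phage, 1, repeat_seq = "ACGT"),
               "23-50")
})

test_that("mosaic populations degrade gracefully and record truth", {
  ref <- random_genome("r", 10000, seed = 3)
  flat <- generate_mosaic_population(ref, 3, snp_rate = 0, seed = 1)
  for (g in flat$genomes) expect_equal(g$sequence, ref$sequence)

  single <- generate_mosaic_population(ref, 1, seed = 2)
  expect_length(single$truth$breakpoints, 1L)
  expect_true(all(diff(single$truth$breakpoints[[1]]) > 0))

  mp <- generate_mosaic_population(ref, 4, seed = 7)
  for (id in names(mp$genomes)) {
    expect_equal(genome_length(mp$genomes[[id]]), 10000L)
    bps <- mp$truth$breakpoints[[id]]
    expect_true(all(diff(bps) > 0) && all(bps > 0) && all(bps < 10000))
    # consecutive blocks always switch donor
    expect_true(all(diff(mp$truth$donors[[id]]) != 0))
  }
  expect_error(generate_mosaic_population(ref, 3, n_ancestors = 1),
               "admixture")
})

test_that("read counts, origins and error model behave as declared", {
  ref <- random_genome("r", 50000, seed = 8, circular = FALSE)
  rds <- generate_reads(ref, coverage = 10, read_len = 125,
                        error_rate = 0, seed = 1)
  expect_equal(nrow(rds), 4000L)  # 10 * 50000 / 125
  set.seed(99)
  for (i in sample(nrow(rds), 50)) {
    frag <- substr(ref$sequence, rds$start[i] + 1, rds$end[i])
    if (rds$strand[i] == "-") frag <- revcomp(frag)
    expect_equal(rds$mate1[i], frag)
  }
  expect_error(generate_reads(random_genome("s", 100, seed = 1),
                              read_len = 125),
               "exceeds")
})

test_that("genome weights shape read origins within binomial noise", {
  gs <- list(random_genome("a", 20000, seed = 11),
             random_genome("b", 20000, seed = 12))
  rds <- generate_reads(gs, weights = c(0.8, 0.2), coverage = 10,
                        seed = 13)
  n <- nrow(rds)
  n_a <- sum(rds$genome_id == "a")
  expect_lt(abs(n_a - 0.8 * n), 3 * sqrt(n * 0.8 * 0.2))
})

test_that("paired reads bracket the fragment with the declared insert", {
  ref <- random_genome("r", 30000, seed = 21)
  rds <- generate_reads(ref, coverage = 2, read_len = 100, paired = TRUE,
                        insert = 300, error_rate = 0, seed = 3)
  expect_true(all(rds$end - rds$start == 300))
  i <- 1L
  frag <- substr(ref$sequence, rds$start[i] + 1, rds$end[i])
  if (rds$strand[i] == "+") {
    expect_equal(rds$mate1[i], substr(frag, 1, 100))
    expect_equal(rds$mate2[i], revcomp(substr(frag, 201, 300)))
  } else {
    expect_equal(rds$mate1[i], revcomp(substr(frag, 201, 300)))
    expect_equal(rds$mate2[i], substr(frag, 1, 100))
  }
})
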