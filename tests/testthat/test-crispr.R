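test_that("planted arrays are recovered with repeat consensus and spacers", {
  phage <- generate_phage_genome(length = 20000, code = 15, seed = 2)$genome
  for (seed in c(3, 14, 27)) {
    hs <- generate_host_scaffold(phage, n_spacers = 5, decoy_spacers = 0,
                                 seed = seed)
    arr <- detect_arrays(hs$scaffold)
    expect_length(arr, 1L)
    cons <- arr[[1]]$repeat_consensus
    # when every repeat copy is followed (or preceded) by the same base
    # by chance, the repeat boundary is genuinely ambiguous and the
    # consensus may gain that column; allow one column of slack
    expect_true(startsWith(cons, hs$truth$repeat_seq) ||
                  startsWith(hs$truth$repeat_seq, cons) ||
                  endsWith(cons, hs$truth$repeat_seq))
    expect_lte(abs(nchar(cons) - nchar(hs$truth$repeat_seq)), 1L)
    expect_equal(nrow(arr[[1]]$spacers), 5L)
    got <- arr[[1]]$spacers$sequence
    planted <- hs$truth$spacers$sequence
    expect_true(all(mapply(function(r, p) grepl(r, p, fixed = TRUE),
                           got, planted)))
    expect_true(all(nchar(got) >= nchar(planted) - 2L))
  }
})

test_that("degenerate repeat structures are rejected", {
  set.seed(8)
  flank <- random_genome("f", 1500)$sequence
  rep30 <- "GGTTTAATCGTACCTTTATGGAATTGAAAT"
  # tandem perfect repeats: zero-length spacers
  tandem <- genome("tandem", paste0(flank, strrep(rep30, 6), flank))
  expect_length(detect_arrays(tandem), 0L)
  # two repeat copies only
  sp <- random_genome("s", 35)$sequence
  two <- genome("two", paste0(flank, rep30, sp, rep30, flank))
  expect_length(detect_arrays(two), 0L)
  # short scaffolds are skipped entirely
  expect_length(detect_arrays(genome("short", strrep("ACGT", 200))), 0L)
})

test_that("the spacer hit filter is exact: length > 24 and mismatches <= 1", {
  target <- random_genome("phage", 50000, gc = 0.4, seed = 99)
  set.seed(100)
  for (len in c(24, 25, 30, 40)) {
    for (mm in 0:2) {
      s0 <- sample(49000, 1)
      sp <- substr(target$sequence, s0, s0 + len - 1)
      if (mm > 0) {
        # spread substitutions so exact seeds remain
        pos <- round(seq(3, len - 2, length.out = mm))
        ch <- strsplit(sp, "")[[1]]
        ch[pos] <- vapply(ch[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, "")
        sp <- paste(ch, collapse = "")
      }
      hits <- match_spacers(stats::setNames(sp, "q"), target)
      should_hit <- len > 24 && mm <= 1
      expect_equal(nrow(hits) > 0, should_hit,
                   info = sprintf("len=%d mm=%d", len, mm))
      if (should_hit) {
        expect_equal(hits$start[1], s0 - 1)
        expect_equal(hits$mismatches[1], mm)
        expect_equal(hits$match_length[1], len)
      }
    }
  }
})

test_that("spacer matching is strand-symmetric", {
  target <- random_genome("t", 20000, seed = 55)
  set.seed(56)
  s0 <- sample(19000, 1)
  sp <- substr(target$sequence, s0, s0 + 29)
  fwd <- match_spacers(stats::setNames(sp, "q"), target)
  rc_target <- genome("t_rc", revcomp(target$sequence))
  rev <- match_spacers(stats::setNames(sp, "q"), rc_target)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(rev$start, genome_length(target) - fwd$end)
  expect_true(all(rev$strand != fwd$strand))
})

test_that("repeat hits void a scaffold's spacer evidence", {
  target <- random_genome("t", 20000, seed = 77)
  set.seed(78)
  sp <- substr(target$sequence, 500, 529)
  rep_in_target <- substr(target$sequence, 5000, 5029)
  out <- match_spacers(stats::setNames(sp, "q"), target,
                       repeats = rep_in_target)
  expect_equal(nrow(out), 0L)
  expect_true(attr(out, "voided_by_repeat"))
  ok <- match_spacers(stats::setNames(sp, "q"), target,
                      repeats = "GGTTTAATCGTACCTTTATGGAATTGAAAT")
  expect_gt(nrow(ok), 0L)
  expect_false(attr(ok, "voided_by_repeat"))
})

test_that("protospacer recovery is exact on error-free synthetic hosts", {
  phage <- generate_phage_genome(length = 30000, code = 15, seed = 6)$genome
  hs <- generate_host_scaffold(phage, n_spacers = 5, decoy_spacers = 5,
                               seed = 8)
  spacers <- stats::setNames(hs$truth$spacers$sequence,
                             paste0("sp", hs$truth$spacers$index))
  hits <- match_spacers(spacers, phage)
  truth <- hs$truth$protospacers
  got <- unique(hits[, c("start", "end", "strand")])
  expect_equal(nrow(got), nrow(truth))        # precision: no decoy hits
  key <- function(d) sort(paste(d$start, d$end, d$strand))
  expect_equal(key(got), key(truth))          # recall: all planted found
})

test_that("scaffold taxonomy walks ranks under the 50% rule", {
  mk <- function(genus, species = NA) {
    data.frame(domain = "Bacteria", phylum = "Bacteroidetes",
               class = "Bacteroidia", order = "Bacteroidales",
               family = NA, genus = genus, species = species,
               stringsAsFactors = FALSE)
  }
  gt <- rbind(mk(rep("Prevotella", 6), c(rep("P. copri", 4), NA, NA)),
              mk(c("Bacteroides", "Alistipes", "Alistipes", NA)))
  call <- assign_taxonomy(gt)
  expect_equal(call$rank, "genus")
  expect_equal(call$name, "Prevotella")
  expect_equal(call$support, 0.6)

  uni <- assign_taxonomy(mk(rep("Prevotella", 10), rep("P. copri", 10)))
  expect_equal(uni$rank, "species")
  expect_equal(uni$support, 1)

  # exactly half qualifies ("at least 50%")
  half <- assign_taxonomy(rbind(mk(rep("Prevotella", 5)),
                                mk(rep(NA_character_, 5))))
  expect_equal(half$rank, "genus")
  expect_equal(half$support, 0.5)

  none <- assign_taxonomy(mk(c("A", "B", "C")))
  expect_equal(none$rank, "order")  # shared lineage above genus
  expect_error(assign_taxonomy(gt[0, ]), "empty")
})

test_that("array comparison finds shared spacers and conserved order", {
  set.seed(123)
  sp <- replicate(8, random_genome("x", 32)$sequence)
  mkarr <- function(id, seqs) {
    structure(list(scaffold_id = id, repeat_consensus = "R",
                   repeat_intervals = data.frame(start = 0, end = 1),
                   spacers = data.frame(start = seq_along(seqs),
                                        end = seq_along(seqs) + 1,
                                        sequence = seqs)),
              class = "crispr_array")
  }
  a <- mkarr("a", sp[1:6])
  b <- mkarr("b", sp[1:6])
  cmp <- compare_arrays(list(a, b))
  expect_equal(cmp$sharing["a", "b"], 6L)
  expect_equal(cmp$lcs["a", "b"], 6L)

  # divergent leaders, shared 6-spacer trailer
  c1 <- mkarr("c1", c(replicate(2, random_genome("y", 30)$sequence), sp[3:8]))
  c2 <- mkarr("c2", c(replicate(3, random_genome("z", 30)$sequence), sp[3:8]))
  cmp2 <- compare_arrays(list(c1, c2))
  expect_equal(cmp2$sharing["c1", "c2"], 6L)
  expect_equal(cmp2$lcs["c1", "c2"], 6L)

  d <- mkarr("d", replicate(4, random_genome("w", 28)$sequence))
  cmp3 <- compare_arrays(list(a, d))
  expect_equal(cmp3$sharing["a", "d"], 0L)
  expect_error(compare_arrays(list(a)), "two arrays")
})
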