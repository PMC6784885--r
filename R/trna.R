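# Heuristic tRNA detection: a simplified cloverleaf scanner (not a
# covariance-model search), suppressor identification, and intron discovery
# by alignment offset. The scanner and the synthetic generator share one
# canonical cloverleaf layout; the scanner is validated on synthetic tRNAs
# only and is explicitly not a tRNAscan-SE replacement.

# Canonical layout, 1-based positions within an intron-free tRNA of 75 nt:
#   1-7    acceptor stem 5' arm          pairs 1<->71 .. 7<->65 (+CCA tail)
#   8-9    linker
#   10-13  D stem 5' arm                 pairs 10<->25 .. 13<->22
#   14-21  D loop (8 nt)
#   22-25  D stem 3' arm
#   26     linker
#   27-31  anticodon stem 5' arm         pairs 27<->43 .. 31<->39
#   32-38  anticodon loop (7 nt, anticodon at 34-36)
#          [intron, if any, inserted immediately 3' of position 36]
#   39-43  anticodon stem 3' arm
#   44-47  variable region
#   48-52  T stem 5' arm                 pairs 48<->64 .. 52<->60
#   53-59  T loop (7 nt)
#   60-64  T stem 3' arm
#   65-71  acceptor stem 3' arm
#   72-75  discriminator + CCA
TRNA_LEN <- 75L
TRNA_ANTICODON <- 34:36
TRNA_INTRON_AFTER <- 36L  # intron inserted after this position

# stem pair coordinates (1-based, intron-free); `shift` marks positions that
# move downstream when an intron of length l is inserted after position 36
trna_pairs <- function(intron_len = 0L) {
  l <- as.integer(intron_len)
  sh <- function(p) ifelse(p > TRNA_INTRON_AFTER, p + l, p)
  rbind(
    data.frame(arm = "acc", i = 1:7,   j = sh(71:65)),
    data.frame(arm = "D",   i = 10:13, j = 25:22),
    data.frame(arm = "AC",  i = 27:31, j = sh(43:39)),
    data.frame(arm = "T",   i = sh(48:52), j = sh(64:60))
  )
}

# Watson-Crick plus G.U wobble
PAIR_OK <- local({
  b5 <- c("A", "C", "G", "T", "N")
  m <- matrix(FALSE, 5, 5, dimnames = list(b5, b5))
  for (p in list(c("A", "T"), c("C", "G"), c("G", "T"))) {
    m[p[1], p[2]] <- TRUE
    m[p[2], p[1]] <- TRUE
  }
  m
})

# Build a canonical tRNA gene sequence with perfect stems.
# Returns list(seq, anticodon, intron = c(start0, end0) within the gene or
# NULL). Drawn from the current RNG stream.
build_trna <- function(anticodon, intron_len = 0L, gc = 0.45) {
  rnd <- function(n) seq_chars(random_dna(n, gc))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  acc5 <- rnd(7); d5 <- rnd(4); ac5 <- rnd(5); t5 <- rnd(5)
  dloop <- rnd(8); tloop <- rnd(7); var <- rnd(4)
  link1 <- rnd(2); link2 <- rnd(1)
  acl <- rnd(7)
  acl[2:4 + 1] <- seq_chars(toupper(anticodon))  # loop pos 3-5 = 34-36
  intron <- if (intron_len > 0L) rnd(intron_len) else character(0)
  body <- c(acc5, link1,
            d5, dloop, rev(unname(comp[d5])),
            link2,
            ac5, acl[1:5], intron, acl[6:7], rev(unname(comp[ac5])),
            var,
            t5, tloop, rev(unname(comp[t5])),
            rev(unname(comp[acc5])),
            rnd(1), "C", "C", "A")
  list(seq = paste(body, collapse = ""), anticodon = toupper(anticodon),
       intron = if (intron_len > 0L)
         c(TRNA_INTRON_AFTER, TRNA_INTRON_AFTER + intron_len) else NULL)
}

# Vectorised stem scores over all candidate start offsets of one strand.
# chars: character vector of the scanned sequence; returns a data.frame of
# candidate hits (start index 1-based in the scanned strand, intron_len,
# per-arm scores, total score).
scan_strand_trnas <- function(chars, min_score, max_intron) {
  n <- length(chars)
  hits <- list()
  arm_scores <- function(idx, l) {
    # idx: candidate start positions (1-based); returns matrix of arm scores
    pr <- trna_pairs(l)
    tot <- matrix(0L, length(idx), 4,
                  dimnames = list(NULL, c("acc", "D", "AC", "T")))
    for (r in seq_len(nrow(pr))) {
      a <- chars[idx + pr$i[r] - 1L]
      b <- chars[idx + pr$j[r] - 1L]
      ok <- PAIR_OK[cbind(match(a, rownames(PAIR_OK)),
                          match(b, rownames(PAIR_OK)))]
      ok[is.na(ok)] <- FALSE
      tot[, pr$arm[r]] <- tot[, pr$arm[r]] + ok
    }
    tot
  }
  gate <- function(sc) {
    sc[, "acc"] >= 6L & sc[, "D"] >= 3L & sc[, "AC"] >= 4L &
      sc[, "T"] >= 3L & rowSums(sc) >= min_score
  }
  # intron-free pass, fully vectorised
  t0 <- n - TRNA_LEN + 1L
  if (t0 >= 1L) {
    idx <- seq_len(t0)
    sc <- arm_scores(idx, 0L)
    keep <- gate(sc)
    if (any(keep)) {
      hits[["0"]] <- data.frame(start = idx[keep], intron_len = 0L,
                                score = rowSums(sc)[keep])
    }
    # D-stem gate (intron-independent) restricts the intron scan
    dcand <- idx[sc[, "D"] >= 3L]
  } else dcand <- integer(0)
  if (length(dcand)) {
    for (l in 5:max_intron) {
      ok_len <- dcand + TRNA_LEN + l - 1L <= n
      cand <- dcand[ok_len]
      if (!length(cand)) next
      sc <- arm_scores(cand, l)
      keep <- gate(sc)
      if (any(keep)) {
        hits[[as.character(l)]] <- data.frame(
          start = cand[keep], intron_len = l, score = rowSums(sc)[keep])
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), intron_len = integer(),
                      score = integer()))
  }
  do.call(rbind, hits)
}

#' Scan a genome for tRNA genes (simplified cloverleaf heuristic)
#'
#' Slides a fixed cloverleaf template over both strands: acceptor stem of 7
#' (>= 6 complementary pairs required, G-U allowed), 4-bp D stem (>= 3), 5-bp
#' anticodon stem (>= 4) with a 7-nt loop, 5-bp T stem (>= 3). The score is
#' the total number of paired bases (maximum 21). Candidates whose
#' downstream arms pair only after inserting 5--60 nt immediately 3' of the
#' anticodon are reported with that insertion as an intron. Overlapping
#' hits resolve to the highest score.
#'
#' @param g A [genome].
#' @param min_score Minimum total paired bases (default 20 of 21; the
#'   plain pairing-count score needs a strict cutoff to stay specific on
#'   AT-rich sequence).
#' @param max_intron Largest intron length considered.
#' @return Data.frame with `start`, `end` (0-based half-open), `strand`,
#'   `anticodon`, `isotype` (one-letter amino acid, `"SUP"` for anticodons
#'   reading a stop codon), `score`, `intron_start`, `intron_end` (NA when
#'   intron-free).
#' @export
scan_trnas <- function(g, min_score = 20L, max_intron = 60L) {
  L <- genome_length(g)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") g$sequence else revcomp(g$sequence)
    h <- scan_strand_trnas(seq_chars(s), min_score, max_intron)
    if (!nrow(h)) next
    s0 <- h$start - 1L
    e0 <- s0 + TRNA_LEN + h$intron_len
    is0 <- ifelse(h$intron_len > 0L, s0 + TRNA_INTRON_AFTER, NA_integer_)
    ie0 <- ifelse(h$intron_len > 0L, is0 + h$intron_len, NA_integer_)
    anticodon <- substring(s, s0 + TRNA_ANTICODON[1],
                           s0 + TRNA_ANTICODON[3])
    if (strand == "-") {
      fs <- L - e0; fe <- L - s0
      fis <- L - ie0; fie <- L - is0
    } else {
      fs <- s0; fe <- e0; fis <- is0; fie <- ie0
    }
    res[[strand]] <- data.frame(
      start = fs, end = fe, strand = strand, anticodon = anticodon,
      score = h$score, intron_start = fis, intron_end = fie,
      stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), anticodon = character(),
                      isotype = character(), score = integer(),
                      intron_start = integer(), intron_end = integer()))
  }
  hits <- do.call(rbind, res)
  # resolve overlaps to the highest score (then leftmost, shortest)
  hits <- hits[order(-hits$score, hits$start, hits$end - hits$start), ,
               drop = FALSE]
  kept <- logical(nrow(hits))
  occ_s <- integer(0); occ_e <- integer(0)
  for (i in seq_len(nrow(hits))) {
    if (!any(hits$start[i] < occ_e & hits$end[i] > occ_s)) {
      kept[i] <- TRUE
      occ_s <- c(occ_s, hits$start[i]); occ_e <- c(occ_e, hits$end[i])
    }
  }
  hits <- hits[kept, , drop = FALSE]
  codon <- revcomp(hits$anticodon)
  aa <- unname(Biostrings::getGeneticCode("11")[codon])
  hits$isotype <- ifelse(is.na(aa) | aa == "*", "SUP", aa)
  hits <- hits[order(hits$start), c("start", "end", "strand", "anticodon",
                                    "isotype", "score", "intron_start",
                                    "intron_end")]
  rownames(hits) <- NULL
  hits
}

#' Select suppressor tRNAs from a set of tRNA hits
#'
#' A suppressor tRNA carries the CTA anticodon that base-pairs with the TAG
#' codon and so enables its read-through as an amino acid -- the tRNA that
#' makes translation table 15 workable.
#'
#' @param trnas Output of [scan_trnas()].
#' @return The subset of rows with anticodon CTA, isotype set to `"SUP"`.
#' @export
find_suppressor <- function(trnas) {
  out <- trnas[trnas$anticodon == "CTA", , drop = FALSE]
  if (nrow(out)) out$isotype <- "SUP"
  rownames(out) <- NULL
  out
}

longest_common_prefix <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  d <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(d)) d[1] - 1L else n
}

#' Locate a tRNA intron by alignment offset
#'
#' Compares an intron-bearing tRNA locus with an intron-free copy of the
#' same isotype: the maximal exact prefix and suffix shared by the two
#' sequences pin down the inserted middle, which is reported as the intron.
#' When repeated bases at the insertion flanks make several placements
#' valid, the leftmost is chosen and the result flagged ambiguous. If a
#' structure-predicted intron start is supplied, the offset between the
#' structural and alignment-derived placements is reported.
#'
#' @param with_intron Sequence of the intron-bearing locus.
#' @param without_intron Sequence of the intron-free locus (shorter).
#' @param structural_start Optional 0-based intron start predicted from
#'   secondary structure (e.g. by [scan_trnas()]).
#' @return List with `intron` (0-based half-open interval within
#'   `with_intron`), `offset` (`structural_start` minus alignment start; NA
#'   when no structural prediction given) and `ambiguous`.
#' @export
#' @examples
#' detect_intron_by_offset("AAAGGGGTTTCCC", "AAATTTCCC",
#'                         structural_start = 4)
detect_intron_by_offset <- function(with_intron, without_intron,
                                    structural_start = NA) {
  w <- toupper(with_intron); wo <- toupper(without_intron)
  d <- nchar(w) - nchar(wo)
  if (d == 0L && w == wo) stop("sequences are identical: no intron",
                               call. = FALSE)
  if (d <= 0L) stop("`with_intron` must be the longer sequence",
                    call. = FALSE)
  P <- longest_common_prefix(w, wo)
  S <- longest_common_prefix(paste(rev(seq_chars(w)), collapse = ""),
                             paste(rev(seq_chars(wo)), collapse = ""))
  kmin <- max(0L, nchar(wo) - S)
  kmax <- min(P, nchar(wo))
  if (kmin > kmax) {
    stop("sequences do not differ by a single insertion", call. = FALSE)
  }
  k <- kmin  # leftmost placement
  list(intron = c(start = k, end = k + d),
       offset = if (is.na(structural_start)) NA_integer_
                else as.integer(structural_start) - k,
       ambiguous = kmax > kmin)
}
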