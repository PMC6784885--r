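# Shared fixtures and independent oracles, built in code at test time.

random_genome <- function(id, n, gc = 0.5, seed = NULL, circular = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  genome(id, paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = p),
                   collapse = ""), circular = circular)
}

# i.i.d. substitution of a sequence at rate e (every substitution changes
# the base), used to build diverged copies with known expected identity
mutate_seq <- function(s, e, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < e)
  ch[hit] <- vapply(ch[hit], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, "")
  paste(ch, collapse = "")
}

# Brute-force six-frame ORF oracle, deliberately structured differently
# from the scanner: enumerate EVERY start codon, walk codon by codon to
# the next stop, then keep the longest (first-start) ORF per stop.
orf_oracle <- function(g, code, min_len = 150L) {
  code <- genetic_code(code)
  L <- nchar(g$sequence)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") g$sequence else revcomp(g$sequence)
    for (f in 0:2) {
      cs <- seq.int(f + 1L, nchar(s) - 2L, by = 3L)
      if (length(cs) < 2L) next
      codons <- substring(s, cs, cs + 2L)
      is_stop <- codons %in% code$stops
      for (j in which(codons %in% code$starts)) {
        m <- j
        while (m <= length(codons) && !is_stop[m]) m <- m + 1L
        partial <- m > length(codons)
        if (partial) m <- length(codons)
        len <- (m - j + 1L) * 3L
        if (len < min_len) next
        out[[length(out) + 1L]] <- data.frame(
          strand = strand, frame = f, scan_start = cs[j] - 1L,
          scan_end = cs[m] + 2L, partial = partial,
          n_tag = sum(codons[j:m] == "TAG") -
            (!partial && codons[m] == "TAG"))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), n_internal_TAG = integer(),
                      partial = logical()))
  }
  o <- do.call(rbind, out)
  # longest ORF per stop-to-stop segment = smallest start per (strand,
  # frame, end)
  key <- paste(o$strand, o$frame, o$scan_end)
  o <- o[order(key, o$scan_start), ]
  o <- o[!duplicated(paste(o$strand, o$frame, o$scan_end)), ]
  fs <- ifelse(o$strand == "+", o$scan_start, L - o$scan_end)
  fe <- ifelse(o$strand == "+", o$scan_end, L - o$scan_start)
  res <- data.frame(start = fs, end = fe, strand = o$strand,
                    n_internal_TAG = o$n_tag, partial = o$partial)
  res <- res[order(res$start, res$end, res$strand), ]
  rownames(res) <- NULL
  res
}

# canonical comparable form of a find_orfs result
orf_key <- function(orfs) {
  with(orfs[order(orfs$start, orfs$end, orfs$strand), ],
       paste(start, end, strand, n_internal_TAG, partial))
}

# Brute-force identity-block oracle: explicit per-column partition
# run-length scan over the raw alignment matrix.
blocks_oracle <- function(genomes) {
  seqs <- lapply(genomes, function(g) strsplit(g$sequence, "")[[1]])
  L <- length(seqs[[1]])
  sig_prev <- NULL
  bounds <- integer(0)
  sigs <- character(0)
  for (p in seq_len(L)) {
    col <- vapply(seqs, `[[`, "", p)
    if (length(unique(col)) == 1L) next
    sig <- paste(match(col, unique(col)), collapse = "|")
    if (is.null(sig_prev) || sig != sig_prev) {
      bounds <- c(bounds, p - 1L)
      sigs <- c(sigs, sig)
      sig_prev <- sig
    }
  }
  if (!length(bounds)) {
    return(data.frame(start = 0L, end = L,
                      partition = paste(rep(1, length(seqs)),
                                        collapse = "|")))
  }
  data.frame(start = c(0L, bounds[-1]),
             end = c(bounds[-1], L), partition = sigs)
}
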