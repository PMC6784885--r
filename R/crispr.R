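# CRISPR array detection on host scaffolds, spacer extraction and
# spacer-to-protospacer matching. A spacer hit on a phage genome implicates
# the scaffold's organism as that phage's host; the accepted-hit filter
# (length strictly greater than 24 bp, at most one mismatch) is the exact
# rule used for the Lak host assignment, and repeat sequences are screened
# the same way so that a repeat match voids a scaffold's spacer evidence.

#' Detect CRISPR arrays on a scaffold
#'
#' A k-mer-seeded periodic-repeat finder: 11-mers recurring with a spacing
#' compatible with repeat+spacer periodicity seed candidate arrays; seeds
#' are extended to maximal repeat units by column-majority agreement, and
#' an array is accepted when at least `min_units` repeat copies each match
#' the majority consensus at `repeat_ident` identity or better, with all
#' spacer lengths in range.
#'
#' @param g Scaffold [genome]; scaffolds of 1 kb or shorter are skipped
#'   (empty result), matching the source screen.
#' @param repeat_len Allowed repeat length range in bp.
#' @param spacer_len Allowed spacer length range in bp.
#' @param min_units Minimum number of repeat copies.
#' @param repeat_ident Minimum identity of each repeat copy to the
#'   consensus.
#' @param k Seed k-mer length.
#' @return List of `crispr_array` objects, each with `scaffold_id`,
#'   `repeat_consensus`, `repeat_intervals` (data.frame, 0-based
#'   half-open), and `spacers` (data.frame with `start`, `end`,
#'   `sequence`).
#' @export
detect_arrays <- function(g, repeat_len = c(23L, 50L),
                          spacer_len = c(15L, 70L), min_units = 3L,
                          repeat_ident = 0.90, k = 11L) {
  L <- genome_length(g)
  if (L <= 1000L) return(list())
  chars <- seq_chars(g$sequence)
  period <- c(repeat_len[1] + spacer_len[1], repeat_len[2] + spacer_len[2])
  km <- kmers_of(g$sequence, k)
  tab <- table(km)
  cand_kmers <- names(tab)[tab >= min_units]
  cand_kmers <- cand_kmers[!grepl("N", cand_kmers, fixed = TRUE)]
  chains <- list()
  for (kk in cand_kmers) {
    p <- which(km == kk)
    d <- diff(p)
    inrange <- d >= period[1] & d <= period[2]
    r <- rle(inrange)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= (min_units - 1L))) {
      chains[[length(chains) + 1L]] <- p[starts[j]:(ends[j] + 1L)]
    }
  }
  if (!length(chains)) return(list())
  # prefer longer chains; drop chains overlapping an accepted one
  chains <- chains[order(-vapply(chains, length, 0L),
                         vapply(chains, min, 0L))]
  arrays <- list()
  claimed_s <- integer(0); claimed_e <- integer(0)
  col_agree <- function(pos) {
    b <- chars[pos]
    b <- b[pos >= 1L & pos <= L]
    if (length(b) < length(pos)) return(0)
    max(table(b)) / length(b)
  }
  for (ch in chains) {
    lo <- min(ch); hi <- max(ch) + k - 1L
    if (any(lo <= claimed_e & hi >= claimed_s)) next
    # extend seed to the maximal repeat unit
    left <- 0L
    while (nchar(g$sequence) && left < repeat_len[2] - k &&
           min(ch) - left - 1L >= 1L &&
           col_agree(ch - left - 1L) >= 0.9) {
      left <- left + 1L
    }
    right <- k - 1L
    while (right - (-left) + 1L < repeat_len[2] &&
           max(ch) + right + 1L <= L &&
           col_agree(ch + right + 1L) >= 0.9) {
      right <- right + 1L
    }
    rs <- ch - left
    re <- ch + right + 1L  # 0-based half-open needs -1 shift later
    rlen <- right + left + 1L
    if (rlen < repeat_len[1] || rlen > repeat_len[2]) next
    # consensus = majority base per column
    cols <- vapply(seq_len(rlen), function(o) {
      b <- chars[rs + o - 1L]
      names(sort(table(b), decreasing = TRUE))[1]
    }, "")
    consensus <- paste(cols, collapse = "")
    copies <- substring(g$sequence, rs, rs + rlen - 1L)
    idents <- 1 - vapply(copies, count_mismatches, 0L, b = consensus) / rlen
    if (sum(idents >= repeat_ident) < min_units) next
    # spacers between consecutive repeat copies
    sp_s <- (rs + rlen)[-length(rs)]
    sp_e <- rs[-1]
    sp_len <- sp_e - sp_s
    if (any(sp_len < spacer_len[1] | sp_len > spacer_len[2])) next
    spacers <- data.frame(
      start = sp_s - 1L, end = sp_e - 1L,
      sequence = substring(g$sequence, sp_s, sp_e - 1L),
      stringsAsFactors = FALSE)
    arrays[[length(arrays) + 1L]] <- structure(list(
      scaffold_id = g$id,
      repeat_consensus = consensus,
      repeat_intervals = data.frame(start = rs - 1L,
                                    end = rs + rlen - 1L),
      spacers = spacers
    ), class = "crispr_array")
    claimed_s <- c(claimed_s, lo); claimed_e <- c(claimed_e, hi)
  }
  arrays[order(vapply(arrays, function(a) a$repeat_intervals$start[1], 0))]
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("<crispr_array> %s: %d repeats (%d bp consensus), %d spacers\n",
              x$scaffold_id, nrow(x$repeat_intervals),
              nchar(x$repeat_consensus), nrow(x$spacers)))
  invisible(x)
}

#' Match CRISPR spacers against target genomes
#'
#' Emulates a short-sequence nucleotide search with exact 11-mer seeding
#' and ungapped extension over the full spacer on both strands. A hit is
#' accepted only when the aligned length exceeds `min_len` bp and carries
#' at most `max_mm` mismatches -- the filter used to call a spacer as
#' targeting a phage. When the array's repeat sequences are supplied they
#' are screened identically, and any repeat hit voids all spacer evidence
#' (result emptied and flagged), since repeat matches indicate the target
#' itself carries the array rather than being targeted by it.
#'
#' @param spacers Character vector of spacer sequences (names used as
#'   spacer ids; defaults to `spacer_1`, ...).
#' @param targets A [genome] or list of target genomes.
#' @param max_mm Maximum mismatches (default 1).
#' @param min_len Aligned length must be strictly greater than this
#'   (default 24 bp).
#' @param repeats Optional character vector of repeat sequences to screen.
#' @param k Seed length.
#' @return Data.frame with `spacer_id`, `target_id`, `start`, `end`
#'   (0-based half-open on the target forward strand), `strand`,
#'   `mismatches`, `match_length`; attribute `voided_by_repeat` is TRUE
#'   when a repeat hit suppressed the evidence.
#' @export
match_spacers <- function(spacers, targets, max_mm = 1L, min_len = 24L,
                          repeats = NULL, k = 11L) {
  targets <- as_genome_list(targets)
  if (is.null(names(spacers)) || !any(nzchar(names(spacers)))) {
    names(spacers) <- sprintf("spacer_%d", seq_along(spacers))
  }
  idx <- lapply(targets, function(g) kmer_index(g$sequence, k))
  hit_one <- function(qseq, qid, tid) {
    g <- targets[[tid]]
    L <- genome_length(g)
    res <- list()
    for (strand in c("+", "-")) {
      q <- if (strand == "+") qseq else revcomp(qseq)
      qlen <- nchar(q)
      if (qlen < k) next
      seeds <- kmers_of(q, k)
      cand <- integer(0)
      for (o in seq_along(seeds)) {
        p <- kmer_lookup(idx[[tid]], seeds[o])
        if (length(p)) cand <- c(cand, p - o + 1L)
      }
      for (s in unique(cand)) {
        # clip to the target ends; aligned length may shrink
        qs <- max(1L, 2L - s)
        ts <- s + qs - 1L
        te <- min(L, s + qlen - 1L)
        alen <- te - ts + 1L
        if (alen <= min_len) next
        mm <- count_mismatches(substr(q, qs, qs + alen - 1L),
                               substr(g$sequence, ts, te))
        if (mm > max_mm) next
        res[[length(res) + 1L]] <- data.frame(
          spacer_id = qid, target_id = tid, start = ts - 1L, end = te,
          strand = strand, mismatches = mm, match_length = alen,
          stringsAsFactors = FALSE)
      }
    }
    res
  }
  all_hits <- list()
  for (tid in names(targets)) {
    for (i in seq_along(spacers)) {
      all_hits <- c(all_hits, hit_one(toupper(spacers[[i]]),
                                      names(spacers)[i], tid))
    }
  }
  out <- if (length(all_hits)) do.call(rbind, all_hits) else
    data.frame(spacer_id = character(), target_id = character(),
               start = integer(), end = integer(), strand = character(),
               mismatches = integer(), match_length = integer())
  out <- unique(out)
  voided <- FALSE
  if (!is.null(repeats) && length(repeats)) {
    names(repeats) <- sprintf("repeat_%d", seq_along(repeats))
    rhits <- match_spacers(repeats, targets, max_mm = max_mm,
                           min_len = min_len, repeats = NULL, k = k)
    if (nrow(rhits)) {
      voided <- TRUE
      out <- out[0, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  attr(out, "voided_by_repeat") <- voided
  out
}

#' Consensus taxonomy of a scaffold from its per-gene lineages
#'
#' Walks ranks from most to least specific and returns the most specific
#' rank at which a single name is shared by at least half of the
#' scaffold's genes; unannotated genes stay in the denominator. Returns an
#' `unclassified` call when no rank reaches the threshold.
#'
#' @param gene_taxa Data.frame with one row per gene and one column per
#'   rank (most general first); `NA` marks missing annotation. A `gene_id`
#'   column, if present, is ignored.
#' @param ranks Rank columns to consider, most general first.
#' @param min_support Required fraction of genes sharing the name.
#' @return List with `rank`, `name`, `support` (fraction), `n_genes`.
#' @export
assign_taxonomy <- function(gene_taxa,
                            ranks = c("domain", "phylum", "class", "order",
                                      "family", "genus", "species"),
                            min_support = 0.5) {
  if (nrow(gene_taxa) == 0L) stop("empty gene table", call. = FALSE)
  ranks <- intersect(ranks, names(gene_taxa))
  n <- nrow(gene_taxa)
  for (r in rev(ranks)) {
    v <- gene_taxa[[r]]
    v <- v[!is.na(v) & nzchar(v)]
    if (!length(v)) next
    tab <- sort(table(v), decreasing = TRUE)
    if (tab[1] / n >= min_support) {
      return(list(rank = r, name = names(tab)[1],
                  support = unname(tab[1]) / n, n_genes = n))
    }
  }
  list(rank = "unclassified", name = NA_character_, support = 0,
       n_genes = n)
}

lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' Compare CRISPR arrays across scaffolds by shared spacer content
#'
#' Clusters all spacers across the arrays at `ident` identity (either
#' orientation), then reports, per array pair, the number of shared spacer
#' clusters and the order conservation (longest common subsequence of
#' cluster ids, computed in both relative orientations and the better one
#' taken, so arrays sharing one conserved end align). Divergence confined
#' to array ends is the signature of active, diversifying loci.
#'
#' @param arrays List of `crispr_array` objects (>= 2).
#' @param ident Spacer clustering identity threshold.
#' @return List with `spacer_clusters` (data.frame: array, position,
#'   cluster id), `sharing` (matrix of shared cluster counts) and `lcs`
#'   (matrix of longest-common-subsequence lengths).
#' @export
compare_arrays <- function(arrays, ident = 0.95) {
  if (length(arrays) < 2L) stop("need at least two arrays", call. = FALSE)
  ids <- vapply(arrays, `[[`, "", "scaffold_id")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  sp <- do.call(rbind, lapply(seq_along(arrays), function(i) {
    s <- arrays[[i]]$spacers
    if (!nrow(s)) return(NULL)
    data.frame(array = ids[i], position = seq_len(nrow(s)),
               sequence = s$sequence, stringsAsFactors = FALSE)
  }))
  if (is.null(sp) || !nrow(sp)) stop("arrays contain no spacers",
                                     call. = FALSE)
  seq_ident <- function(a, b) {
    if (abs(nchar(a) - nchar(b)) > 0L) {
      aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
      return(Biostrings::pid(aln, type = "PID4") / 100)
    }
    1 - count_mismatches(a, b) / nchar(a)
  }
  # greedy centroid clustering, longest spacer first
  ord <- order(-nchar(sp$sequence))
  centroid <- character(0)
  cluster <- integer(nrow(sp))
  for (i in ord) {
    s <- sp$sequence[i]
    assigned <- 0L
    for (cj in seq_along(centroid)) {
      if (seq_ident(s, centroid[cj]) >= ident ||
          seq_ident(revcomp(s), centroid[cj]) >= ident) {
        assigned <- cj
        break
      }
    }
    if (assigned == 0L) {
      centroid <- c(centroid, s)
      assigned <- length(centroid)
    }
    cluster[i] <- assigned
  }
  sp$cluster <- cluster
  n <- length(ids)
  sharing <- matrix(0L, n, n, dimnames = list(ids, ids))
  lcs <- matrix(0L, n, n, dimnames = list(ids, ids))
  per_array <- split(sp[order(sp$position), ], sp$array[order(sp$position)])
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ci <- per_array[[ids[i]]]$cluster
      cj <- per_array[[ids[j]]]$cluster
      sharing[i, j] <- length(intersect(ci, cj))
      lcs[i, j] <- max(lcs_length(ci, cj), lcs_length(ci, rev(cj)))
    }
  }
  list(spacer_clusters = sp[, c("array", "position", "cluster")],
       sharing = sharing, lcs = lcs)
}
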