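# Comparative genomics: fragment-recruitment ANI, anchor-chain synteny and
# rearrangement counting, identity-block segmentation of aligned genome
# populations (the recombination/admixture signal), and metagenome
# presence screening with the 2 kb / 70% identity rule.

NUC_MAT <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                    mismatch = -1,
                                                    baseOnly = TRUE)

# Locate the best target window for a query via exact k-mer seeding.
# Returns list(strand, start) (1-based window start on the target forward
# strand) or NULL when no seed matches.
seed_locate <- function(query, target_index, target_len, k) {
  best <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    seeds <- kmers_of(q, k)
    if (!length(seeds)) next
    # sparse sampling of seeds is enough to find the diagonal
    take <- unique(c(seq(1L, length(seeds), by = max(1L, k)),
                     length(seeds)))
    diags <- integer(0)
    for (o in take) {
      p <- kmer_lookup(target_index, seeds[o])
      if (length(p)) diags <- c(diags, p - o + 1L)
    }
    if (!length(diags)) next
    tab <- sort(table(diags), decreasing = TRUE)
    cand <- list(strand = strand,
                 start = as.integer(names(tab)[1]),
                 support = unname(tab[1]))
    if (is.null(best) || cand$support > best$support) best <- cand
  }
  best
}

# Align a query globally against a local window of the target around the
# seeded diagonal. Returns matches, aligned length and target interval.
window_align <- function(query, target_seq, at, pad = 50L) {
  qlen <- nchar(query)
  L <- nchar(target_seq)
  ws <- max(1L, at - pad)
  we <- min(L, at + qlen - 1L + pad)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query),
    Biostrings::DNAString(substr(target_seq, ws, we)),
    type = "global-local", substitutionMatrix = NUC_MAT,
    gapOpening = 5, gapExtension = 2)
  list(matches = Biostrings::nmatch(aln),
       target_start = ws + Biostrings::start(Biostrings::subject(aln)) - 1L,
       target_end = ws + Biostrings::end(Biostrings::subject(aln)) - 1L)
}

#' Fragment-based average nucleotide identity
#'
#' Genome `a` is cut into consecutive `frag`-length fragments; each
#' fragment is aligned (globally in the fragment, locally in the target)
#' to its best-matching locus of `b`, found by exact k-mer seeding.
#' Fragments are retained when their identity reaches `min_ident` over at
#' least `min_cov` of the fragment; ANI is the mean identity of retained
#' fragments, in percent. Fragments with more than 10% N are excluded.
#'
#' @param a,b [genome] objects, both at least `frag` long.
#' @param frag Fragment length in bp.
#' @param min_ident Minimum fragment identity for retention.
#' @param min_cov Minimum aligned fraction of a fragment for retention.
#' @param k Seed k-mer length.
#' @return List of class `ani_result` with `genome_a`, `genome_b`, `ani`
#'   (percent, `NA` when no fragment is retained), `aligned_fraction`,
#'   `n_fragments_kept`, `n_fragments`.
#' @export
pairwise_ani <- function(a, b, frag = 1000L, min_ident = 0.70,
                         min_cov = 0.70, k = 15L) {
  La <- genome_length(a)
  if (La < frag || genome_length(b) < frag) {
    stop("both genomes must be at least one fragment long", call. = FALSE)
  }
  starts <- seq(1L, La, by = frag)
  ends <- pmin(starts + frag - 1L, La)
  keep_frag <- (ends - starts + 1L) >= k
  starts <- starts[keep_frag]; ends <- ends[keep_frag]
  idx <- kmer_index(b$sequence, k)
  ident <- rep(NA_real_, length(starts))
  cov <- rep(0, length(starts))
  for (i in seq_along(starts)) {
    fseq <- substr(a$sequence, starts[i], ends[i])
    if (n_fraction(fseq) > 0.10) next
    loc <- seed_locate(fseq, idx, genome_length(b), k)
    if (is.null(loc)) next
    q <- if (loc$strand == "+") fseq else revcomp(fseq)
    al <- window_align(q, b$sequence, loc$start)
    flen <- nchar(fseq)
    ident[i] <- al$matches / flen
    cov[i] <- 1  # global-in-fragment: the whole fragment is aligned
  }
  retained <- !is.na(ident) & ident >= min_ident & cov >= min_cov
  structure(list(
    genome_a = a$id, genome_b = b$id,
    ani = if (any(retained)) mean(ident[retained]) * 100 else NA_real_,
    aligned_fraction = sum((ends - starts + 1L)[retained]) / La,
    n_fragments_kept = sum(retained),
    n_fragments = length(starts)
  ), class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> %s vs %s: ANI %s%% (%d/%d fragments, %.2f aligned)\n",
              x$genome_a, x$genome_b,
              ifelse(is.na(x$ani), "NA", sprintf("%.2f", x$ani)),
              x$n_fragments_kept, x$n_fragments, x$aligned_fraction))
  invisible(x)
}

# longest increasing subsequence length (O(n^2); block counts are small)
lis_length <- function(x) {
  n <- length(x)
  if (n == 0L) return(0L)
  best <- rep(1L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && best[j] + 1L > best[i]) best[i] <- best[j] + 1L
    }
  }
  max(best)
}

# canonical k-mer orientation: lexicographic min of kmer and its revcomp
canonical_kmers <- function(seq, k) {
  km <- kmers_of(seq, k)
  rc <- revcomp(km)
  fwd <- km <= rc
  data.frame(canon = ifelse(fwd, km, rc), pos = seq_along(km),
             orient = ifelse(fwd, 1L, -1L), stringsAsFactors = FALSE)
}

#' Synteny blocks and rearrangements between genomes
#'
#' Collects k-mers that occur exactly once in every genome (in either
#' orientation) and are shared by all, chains collinear anchors into
#' blocks (chains break at orientation flips, order violations or anchor
#' gaps above `max_gap`), and keeps blocks spanning at least `min_chain`.
#' The rearrangement count between a genome pair is an event count: blocks
#' inverted in place plus blocks displaced out of the longest conserved
#' order (a deliberate heuristic mirroring a by-eye count of large
#' rearrangements, not a minimal-distance computation).
#'
#' @param genomes List of at least two [genome]s; the first is the
#'   reference frame for block coordinates.
#' @param anchor_k Anchor k-mer length.
#' @param min_chain Minimum block span (bp in the reference genome).
#' @param max_gap Maximum gap between chained anchors (bp).
#' @return List with `blocks` (per-pair data.frames, reference vs each
#'   other genome) and `counts` (named rearrangement counts per pair;
#'   `NA` when no shared anchors exist).
#' @export
find_rearrangements <- function(genomes, anchor_k = 15L,
                                min_chain = 5000L, max_gap = 2000L) {
  genomes <- as_genome_list(genomes)
  if (length(genomes) < 2L) stop("need at least two genomes",
                                 call. = FALSE)
  per <- lapply(genomes, function(g) {
    ck <- canonical_kmers(g$sequence, anchor_k)
    tab <- table(ck$canon)
    ck[ck$canon %in% names(tab)[tab == 1L], , drop = FALSE]
  })
  shared <- Reduce(intersect, lapply(per, `[[`, "canon"))
  ids <- names(genomes)
  blocks <- list(); counts <- list()
  for (j in seq_along(genomes)[-1]) {
    key <- paste(ids[1], ids[j], sep = "|")
    if (!length(shared)) {
      blocks[[key]] <- NULL; counts[[key]] <- NA_integer_
      next
    }
    a <- per[[1]][match(shared, per[[1]]$canon), ]
    b <- per[[j]][match(shared, per[[j]]$canon), ]
    o <- order(a$pos)
    pa <- a$pos[o]; pb <- b$pos[o]
    rel <- a$orient[o] * b$orient[o]
    # chain collinear anchors
    n <- length(pa)
    brk <- logical(n)
    brk[1] <- TRUE
    if (n > 1L) {
      step_ok <- rel[-1] == rel[-n] &
        (pb[-1] - pb[-n]) * rel[-1] > 0 &
        abs(pb[-1] - pb[-n]) <= max_gap &
        (pa[-1] - pa[-n]) <= max_gap
      brk[-1] <- !step_ok
    }
    cid <- cumsum(brk)
    bl <- do.call(rbind, lapply(split(seq_len(n), cid), function(ix) {
      data.frame(a_start = pa[ix[1]] - 1L,
                 a_end = pa[ix[length(ix)]] + anchor_k - 1L,
                 b_start = min(pb[ix]) - 1L,
                 b_end = max(pb[ix]) + anchor_k - 1L,
                 orient = rel[ix[1]], n_anchors = length(ix))
    }))
    bl <- bl[bl$a_end - bl$a_start >= min_chain, , drop = FALSE]
    rownames(bl) <- NULL
    blocks[[key]] <- bl
    if (!nrow(bl)) {
      counts[[key]] <- NA_integer_
      next
    }
    displaced <- nrow(bl) - lis_length(bl$b_start)
    inverted <- sum(bl$orient == -1L)
    counts[[key]] <- displaced + inverted
  }
  list(blocks = blocks, counts = unlist(counts))
}

#' Segment an aligned genome set into identity blocks
#'
#' Operates on equal-length (gaplessly aligned) genomes, e.g. the output
#' of [generate_mosaic_population()]. Every polymorphic column induces a
#' partition of the genomes into identical-character classes; maximal runs
#' of columns with the same partition become blocks, so monomorphic
#' stretches never split a block. Adjacent runs with equal partitions
#' merge; runs spanning less than `min_block` are absorbed into their
#' longer flank (and retained, flagged, in the `runs` attribute), which
#' preserves the tiling property. Alternating partitions along the genome
#' are the admixture signature of homologous recombination.
#'
#' @param genomes List of equal-length [genome]s (>= 2).
#' @param min_block Minimum block span in bp after absorption.
#' @return Data.frame of blocks (`start`, `end`, `partition` as a
#'   `1|1|2|...` class string in genome order, `n_classes`, `absorbed`
#'   flag marking blocks that swallowed a micro-run), with attributes
#'   `runs` (the raw signature runs before absorption) and `genome_ids`.
#'   Blocks tile `[0, L)` exactly.
#' @export
segment_identity_blocks <- function(genomes, min_block = 1000L) {
  genomes <- as_genome_list(genomes)
  if (length(genomes) < 2L) stop("need at least two genomes",
                                 call. = FALSE)
  lens <- vapply(genomes, genome_length, 0L)
  if (length(unique(lens)) != 1L) {
    stop("genomes differ in length: pre-align them first (the analysis ",
         "expects a gapless alignment)", call. = FALSE)
  }
  L <- lens[1]
  G <- length(genomes)
  mat <- do.call(rbind, lapply(genomes, function(g) {
    charToRaw(g$sequence)
  }))
  poly <- which(colSums(mat != rep(mat[1, ], each = G)) > 0L)
  if (!length(poly)) {
    out <- data.frame(start = 0L, end = L,
                      partition = paste(rep(1L, G), collapse = "|"),
                      n_classes = 1L, absorbed = FALSE)
    attr(out, "runs") <- out[, 1:4]
    attr(out, "genome_ids") <- names(genomes)
    return(out)
  }
  sig <- vapply(poly, function(p) {
    v <- as.integer(mat[, p])
    paste(match(v, unique(v)), collapse = "|")
  }, "")
  r <- rle(sig)
  run_last <- cumsum(r$lengths)          # index into poly
  run_first <- run_last - r$lengths + 1L
  # block boundaries: start of block i+1 = first informative column of
  # run i+1 (0-based); first block starts at 0, last ends at L
  rs <- c(0L, poly[run_first[-1]] - 1L)
  re <- c(rs[-1], L)
  runs <- data.frame(start = rs, end = re, partition = r$values,
                     n_classes = vapply(strsplit(r$values, "|",
                                                 fixed = TRUE),
                                        function(x) max(as.integer(x)),
                                        0L))
  blocks <- runs
  blocks$absorbed <- FALSE
  repeat {
    small <- which(blocks$end - blocks$start < min_block)
    if (!length(small) || nrow(blocks) == 1L) break
    i <- small[which.min((blocks$end - blocks$start)[small])]
    left_w <- if (i > 1L) blocks$end[i - 1L] - blocks$start[i - 1L] else -1L
    right_w <- if (i < nrow(blocks))
      blocks$end[i + 1L] - blocks$start[i + 1L] else -1L
    into <- if (left_w >= right_w) i - 1L else i + 1L
    blocks$start[into] <- min(blocks$start[into], blocks$start[i])
    blocks$end[into] <- max(blocks$end[into], blocks$end[i])
    blocks$absorbed[into] <- TRUE
    blocks <- blocks[-i, , drop = FALSE]
    # re-merge adjacent equal partitions created by the absorption
    j <- 1L
    while (j < nrow(blocks)) {
      if (blocks$partition[j] == blocks$partition[j + 1L]) {
        blocks$end[j] <- blocks$end[j + 1L]
        blocks$absorbed[j] <- blocks$absorbed[j] || blocks$absorbed[j + 1L]
        blocks <- blocks[-(j + 1L), , drop = FALSE]
      } else j <- j + 1L
    }
  }
  rownames(blocks) <- NULL
  attr(blocks, "runs") <- runs
  attr(blocks, "genome_ids") <- names(genomes)
  blocks
}

#' Screen a metagenome assembly for a reference phage
#'
#' Aligns each contig to the reference (anchor-seeded, gapped extension)
#' and keeps alignments of at least `min_len` bp and `min_ident`
#' nucleotide identity; a metagenome is called positive when at least one
#' alignment survives the filter.
#'
#' @param contigs A [genome] or list of contigs.
#' @param reference Reference [genome].
#' @param min_len Minimum kept alignment length (bp).
#' @param min_ident Minimum kept alignment identity.
#' @param metagenome_id Label for the screened sample.
#' @param k Seed k-mer length.
#' @return List of class `screen_result`: `metagenome_id`,
#'   `kept_alignments` (data.frame contig, ref_start, ref_end, length,
#'   identity), `total_aligned` (bp) and `present`.
#' @export
screen_metagenome <- function(contigs, reference, min_len = 2000L,
                              min_ident = 0.70,
                              metagenome_id = "metagenome", k = 15L) {
  contigs <- as_genome_list(contigs)
  idx <- kmer_index(reference$sequence, k)
  kept <- list()
  for (ct in contigs) {
    loc <- seed_locate(ct$sequence, idx, genome_length(reference), k)
    if (is.null(loc)) next
    q <- if (loc$strand == "+") ct$sequence else revcomp(ct$sequence)
    al <- window_align(q, reference$sequence, loc$start, pad = 100L)
    alen <- nchar(ct$sequence)
    identity <- al$matches / alen
    if (alen >= min_len && identity >= min_ident) {
      kept[[length(kept) + 1L]] <- data.frame(
        contig = ct$id, ref_start = al$target_start - 1L,
        ref_end = al$target_end, length = alen, identity = identity,
        stringsAsFactors = FALSE)
    }
  }
  kept <- if (length(kept)) do.call(rbind, kept) else
    data.frame(contig = character(), ref_start = integer(),
               ref_end = integer(), length = integer(),
               identity = numeric())
  structure(list(metagenome_id = metagenome_id, kept_alignments = kept,
                 total_aligned = sum(kept$length),
                 present = nrow(kept) > 0L),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %s: %s (%d alignments, %d bp)\n",
              x$metagenome_id, if (x$present) "PRESENT" else "absent",
              nrow(x$kept_alignments), x$total_aligned))
  invisible(x)
}

#' Marker-gene community profile from reads
#'
#' Clusters marker sequences (e.g. ribosomal protein S3 genes) greedily at
#' `cluster_ident` identity, longest first; maps reads to the cluster
#' centroids; and reports per-cluster breadth of coverage (percent of
#' centroid positions covered), normalised by total sample bases, plus the
#' relative abundance across clusters (which is invariant to sequencing
#' depth).
#'
#' @param markers A [genome] or list of marker sequences (>= 200 bp each).
#' @param reads Read data.frame as from [generate_reads()] /
#'   [read_reads()].
#' @param cluster_ident Clustering identity threshold.
#' @param max_mm Maximum mismatches when placing a read on a centroid.
#' @return Data.frame per cluster: `centroid`, `members`, `breadth_pct`,
#'   `norm_abundance` (breadth / total sample bases) and `rel_abundance`.
#' @export
marker_profile <- function(markers, reads, cluster_ident = 0.90,
                           max_mm = 5L) {
  markers <- as_genome_list(markers)
  if (any(vapply(markers, genome_length, 0L) < 200L)) {
    stop("marker sequences must be at least 200 bp", call. = FALSE)
  }
  ord <- order(-vapply(markers, genome_length, 0L))
  centroids <- list()
  members <- list()
  for (i in ord) {
    m <- markers[[i]]
    hit <- 0L
    for (cj in seq_along(centroids)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(m$sequence),
        Biostrings::DNAString(centroids[[cj]]$sequence),
        type = "global", substitutionMatrix = NUC_MAT,
        gapOpening = 5, gapExtension = 2)
      if (Biostrings::pid(aln, type = "PID4") / 100 >= cluster_ident) {
        hit <- cj
        break
      }
    }
    if (hit == 0L) {
      centroids[[length(centroids) + 1L]] <- m
      members[[length(centroids)]] <- m$id
    } else {
      members[[hit]] <- c(members[[hit]], m$id)
    }
  }
  total_bases <- sum(nchar(reads$mate1)) +
    sum(nchar(reads$mate2), na.rm = TRUE)
  # place each read on its best centroid
  placements <- lapply(centroids, function(ce) map_reads(reads, ce,
                                                         max_mm = max_mm))
  best <- list()
  all_ids <- unique(unlist(lapply(placements, function(p) p$read_id)))
  if (length(all_ids)) {
    mm_tab <- sapply(placements, function(p) {
      p$n_mm[match(all_ids, p$read_id)]
    })
    mm_tab <- matrix(mm_tab, nrow = length(all_ids))
    assign_to <- apply(mm_tab, 1L, function(x) {
      if (all(is.na(x))) NA_integer_ else which.min(x)
    })
    for (cj in seq_along(centroids)) {
      sel <- !is.na(assign_to) & assign_to == cj
      best[[cj]] <- placements[[cj]][
        placements[[cj]]$read_id %in% all_ids[sel], , drop = FALSE]
    }
  }
  out <- do.call(rbind, lapply(seq_along(centroids), function(cj) {
    ce <- centroids[[cj]]
    Lc <- genome_length(ce)
    covered <- logical(Lc)
    if (length(best) >= cj && nrow(best[[cj]])) {
      for (r in seq_len(nrow(best[[cj]]))) {
        s <- best[[cj]]$start[r] + 1L
        e <- min(Lc, best[[cj]]$end[r])
        covered[s:e] <- TRUE
      }
    }
    breadth <- 100 * mean(covered)
    data.frame(centroid = ce$id,
               members = paste(members[[cj]], collapse = ","),
               breadth_pct = breadth,
               norm_abundance = if (total_bases > 0)
                 breadth / total_bases else 0,
               stringsAsFactors = FALSE)
  }))
  out$rel_abundance <- if (sum(out$norm_abundance) > 0)
    out$norm_abundance / sum(out$norm_abundance) else 0
  rownames(out) <- NULL
  out
}
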