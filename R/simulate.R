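# Seeded synthetic-data generators with full ground truth. Every generator
# is a pure function of its arguments plus `seed`; the returned `truth`
# object records every planted feature so downstream analyses can be scored
# against a known answer.

base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                             T = (1 - gc) / 2)

# n random codons at the given GC, avoiding the `forbidden` codon set.
draw_codons <- function(n, gc, forbidden) {
  if (n == 0L) return(character(0))
  p <- base_probs(gc)
  draw <- function(m) {
    b <- matrix(sample(DNA_BASES, 3L * m, replace = TRUE, prob = p),
                nrow = 3L)
    paste0(b[1, ], b[2, ], b[3, ])
  }
  out <- draw(n)
  repeat {
    bad <- which(out %in% forbidden)
    if (!length(bad)) break
    out[bad] <- draw(length(bad))
  }
  out
}

# Remove every TAG motif (and CTA, its minus-strand mirror) from a
# sequence, in any frame. The replacement pair (TAG->TAA, CTA->CCA) is
# GC-balanced and cannot create an in-frame stop inside a gene whose
# in-frame stop/TAG/CTA codons were already excluded; the loop guards
# against re-created motifs. Used to make TAG-free spans literally
# TAG-free on both strands, so ORF calls sweeping through intergenic
# sequence or neighbouring frames cannot pick up stray TAGs there.
scrub_tag_motifs <- function(s) {
  for (i in 1:50) {
    if (!grepl("TAG|CTA", s)) break
    s <- gsub("CTA", "CCA", gsub("TAG", "TAA", s, fixed = TRUE),
              fixed = TRUE)
  }
  s
}

#' Generate a phage genome with a planted genetic code and ground truth
#'
#' Tiles the genome with protein-coding genes separated by short intergenic
#' gaps. Under table 15 genes carry in-frame TAG codons at `tag_rate` per
#' codon -- except inside the designated TAG-free spans, where genes avoid
#' TAG entirely (the pattern seen along real recoded phage genomes, where
#' large regions shun the repurposed stop). A code-15 genome always carries
#' a suppressor tRNA with the CTA anticodon; additional tRNAs (optionally
#' intron-bearing) are planted per `trna_spec`.
#'
#' @param length Genome length in bp (>= 10 kb recommended).
#' @param gc Target GC content (default 0.26, the AT-rich composition of
#'   Lak-type genomes).
#' @param code Planted translation table, 11 or 15.
#' @param gene_density_target Fraction of the genome to cover with genes
#'   (in (0.5, 0.98)); realised via the gene/gap length ratio.
#' @param tag_free_spans Two-column matrix or list of `c(start, end)`
#'   0-based intervals that must stay free of in-frame TAG; `NULL` plants
#'   the default two spans at 10--20% and 55--65% of the genome.
#' @param tag_rate Per-codon probability of an in-frame TAG in TAG-permitted
#'   genes (code 15 only).
#' @param trna_spec Data.frame with columns `anticodon` and `intron_len`;
#'   `NULL` plants the default set (suppressor plus one intron-bearing tRNA
#'   under code 15, one plain tRNA under code 11).
#' @param gap_range Intergenic gap length range in bp.
#' @param circular Mark the genome circular.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return List with `genome` (a [genome]) and `truth` (list recording the
#'   planted `genes`, `code`, `trnas`, `tag_free_spans`, per-gene planted
#'   TAG counts and the realised GC).
#' @export
generate_phage_genome <- function(length = 50000L, gc = 0.26, code = 15,
                                  gene_density_target = 0.9,
                                  tag_free_spans = NULL, tag_rate = 0.01,
                                  trna_spec = NULL,
                                  gap_range = c(50L, 200L),
                                  circular = FALSE, seed = 1L) {
  length <- as.integer(length)
  code <- as.integer(code)
  stopifnot(code %in% c(11L, 15L), gc > 0, gc < 1,
            gene_density_target > 0.5, gene_density_target < 0.98)
  if (is.null(tag_free_spans)) {
    tag_free_spans <- rbind(c(0.10, 0.20), c(0.55, 0.65)) * length
  }
  tag_free_spans <- matrix(as.integer(unlist(tag_free_spans)),
                           ncol = 2, byrow = !is.matrix(tag_free_spans))
  if (nrow(tag_free_spans)) {
    o <- order(tag_free_spans[, 1])
    tag_free_spans <- tag_free_spans[o, , drop = FALSE]
    if (any(tag_free_spans[, 2] > length) ||
        any(tag_free_spans[, 1] < 0) ||
        any(tag_free_spans[-1, 1] < tag_free_spans[-nrow(tag_free_spans), 2])) {
      stop("tag_free_spans must be disjoint and lie within the genome",
           call. = FALSE)
    }
  }
  if (is.null(trna_spec)) {
    trna_spec <- if (code == 15L) {
      data.frame(anticodon = c("CTA", "TGC"), intron_len = c(0L, 20L))
    } else {
      data.frame(anticodon = "TGC", intron_len = 0L)
    }
  }
  if (code == 15L && !"CTA" %in% toupper(trna_spec$anticodon)) {
    trna_spec <- rbind(data.frame(anticodon = "CTA", intron_len = 0L),
                       trna_spec)
  }
  code_obj <- genetic_code(code)
  # gene length chosen so mean(gene)/(mean(gene)+mean(gap)) hits the target
  mean_gap <- mean(gap_range)
  mean_gene <- gene_density_target / (1 - gene_density_target) * mean_gap
  n_genes_est <- ceiling(length / (mean_gene + mean_gap))
  trna_tiles <- if (nrow(trna_spec)) {
    unique(pmax(1L, floor(seq(0.3, 0.9, length.out = nrow(trna_spec)) *
                            n_genes_est)))
  } else integer(0)
  if (base::length(trna_tiles) < nrow(trna_spec)) {
    trna_tiles <- seq_len(nrow(trna_spec))
  }

  with_seed(seed, {
    chunks <- character(0)
    pos <- 0L
    genes <- list(); trnas <- list()
    tile <- 0L; trna_i <- 0L
    overlaps_span <- function(s, e, margin = 0L) {
      nrow(tag_free_spans) > 0 &&
        any(s < tag_free_spans[, 2] + margin &
              e > tag_free_spans[, 1] - margin)
    }
    draw_gap <- function(n, from) {
      s <- random_dna(n, gc)
      if (overlaps_span(from, from + n, margin = 300L)) {
        s <- scrub_tag_motifs(s)
        # a gap ending in CT would form CTA against a following ATG
        if (endsWith(s, "CT")) s <- paste0(substr(s, 1, n - 1), "A")
      }
      s
    }
    while (pos < length) {
      gap_len <- sample(gap_range[1]:gap_range[2], 1L)
      if (pos + gap_len >= length) {
        chunks <- c(chunks, draw_gap(length - pos, pos))
        pos <- length
        break
      }
      chunks <- c(chunks, draw_gap(gap_len, pos))
      pos <- pos + gap_len
      tile <- tile + 1L
      due <- trna_i < nrow(trna_spec) &&
        tile >= trna_tiles[min(trna_i + 1L, base::length(trna_tiles))]
      if (due && !overlaps_span(pos, pos + 200L, margin = 300L)) {
        trna_i <- trna_i + 1L
        tr <- build_trna(trna_spec$anticodon[trna_i],
                         trna_spec$intron_len[trna_i], gc = 0.5)
        if (pos + nchar(tr$seq) >= length) {
          chunks <- c(chunks, random_dna(length - pos, gc))
          pos <- length
          break
        }
        trnas[[trna_i]] <- data.frame(
          start = pos, end = pos + nchar(tr$seq), strand = "+",
          anticodon = tr$anticodon,
          intron_start = if (is.null(tr$intron)) NA_integer_
                         else pos + tr$intron[1],
          intron_end = if (is.null(tr$intron)) NA_integer_
                       else pos + tr$intron[2],
          stringsAsFactors = FALSE)
        chunks <- c(chunks, tr$seq)
        pos <- pos + nchar(tr$seq)
        next
      }
      n_cod <- sample(200:550, 1L)  # internal codons
      gene_len <- 3L * (n_cod + 2L)  # + start and stop codons
      if (pos + gene_len >= length) {
        chunks <- c(chunks, random_dna(length - pos, gc))
        pos <- length
        break
      }
      in_span <- overlaps_span(pos, pos + gene_len)
      tag_free_gene <- code == 11L || in_span
      n_tag <- 0L
      if (in_span) {
        # genes touching a TAG-free span avoid the TAG motif in every
        # frame and on both strands (CTA is a minus-strand TAG), so that
        # overlapping ORF calls cannot pick up incidental TAGs
        repeat {
          cod <- draw_codons(n_cod, gc,
                             union(code_obj$stops, c("TAG", "CTA")))
          gene_seq <- paste0("ATG", paste(cod, collapse = ""),
                             sample(setdiff(code_obj$stops, "TAG"), 1L))
          gene_seq <- scrub_tag_motifs(gene_seq)
          aa <- translate_seq(gene_seq, code_obj$table_id)
          if (!grepl("TAG|CTA", gene_seq) &&
              !grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE) &&
              substr(aa, nchar(aa), nchar(aa)) == "*") break
        }
      } else {
        cod <- draw_codons(n_cod, gc, union(code_obj$stops, "TAG"))
        if (code == 15L && tag_rate > 0) {
          put_tag <- stats::runif(n_cod) < tag_rate
          cod[put_tag] <- "TAG"
          n_tag <- sum(put_tag)
        }
        gene_seq <- paste0("ATG", paste(cod, collapse = ""),
                           sample(code_obj$stops, 1L))
      }
      genes[[base::length(genes) + 1L]] <- data.frame(
        start = pos, end = pos + gene_len, strand = "+",
        frame = pos %% 3L, n_TAG = n_tag, tag_free = tag_free_gene)
      chunks <- c(chunks, gene_seq)
      pos <- pos + gene_len
    }
    seqn <- paste(chunks, collapse = "")
    # genes drawn at base composition `gc` but with fixed ATG/stop codons;
    # measured GC is reported in the truth channel
    g <- genome(sprintf("synthetic_phage_code%d_seed%d", code, seed), seqn,
                circular = circular)
    truth <- list(
      genes = if (base::length(genes)) do.call(rbind, genes) else
        data.frame(start = integer(), end = integer(), strand = character(),
                   frame = integer(), n_TAG = integer(),
                   tag_free = logical()),
      code = code,
      trnas = if (base::length(trnas)) do.call(rbind, trnas) else
        data.frame(start = integer(), end = integer(), strand = character(),
                   anticodon = character(), intron_start = integer(),
                   intron_end = integer()),
      tag_free_spans = tag_free_spans,
      gc_realized = gc_content(seqn),
      seed = seed
    )
    list(genome = g, truth = truth)
  })
}

#' Paper-reported CRISPR repeat of the Lak-targeting *Prevotella* arrays
#' @export
LAK_CRISPR_REPEAT <- "GGTTTAATCGTACCTTTATGGAATTGAAAT"

#' Generate a host scaffold carrying a CRISPR array targeting a phage
#'
#' Builds a scaffold with one repeat-spacer-repeat array whose true spacers
#' are copied (on either strand) from random positions of the supplied
#' phage genome; those source intervals are recorded as protospacers in the
#' truth channel. Decoy spacers are random sequence matching nothing. The
#' array is flanked by at least `flank` bp of random host sequence.
#'
#' @param phage A [genome] the true spacers are sampled from.
#' @param n_spacers Number of true (phage-derived) spacers (>= 1).
#' @param repeat_seq Repeat sequence, 23--50 bp; defaults to the 30-mer
#'   repeat of the Lak-targeting arrays.
#' @param decoy_spacers Number of random decoy spacers.
#' @param spacer_len_range Spacer length range (uniform; an assumption, the
#'   source arrays' empirical distribution being unknown).
#' @param flank Flank length in bp.
#' @param host_gc GC content of the host background sequence.
#' @param seed Integer seed.
#' @return List with `scaffold` (a [genome]) and `truth` (protospacer
#'   intervals on the phage, planted spacer order/strands, array interval,
#'   repeat).
#' @export
generate_host_scaffold <- function(phage, n_spacers,
                                   repeat_seq = LAK_CRISPR_REPEAT,
                                   decoy_spacers = 0L,
                                   spacer_len_range = c(25L, 40L),
                                   flank = 1000L, host_gc = 0.45,
                                   seed = 1L) {
  stopifnot(n_spacers >= 1L)
  repeat_seq <- toupper(repeat_seq)
  if (nchar(repeat_seq) < 23L || nchar(repeat_seq) > 50L) {
    stop("repeat length must be 23-50 bp", call. = FALSE)
  }
  L <- genome_length(phage)
  if (L < max(spacer_len_range)) {
    stop("phage genome shorter than the spacer length", call. = FALSE)
  }
  with_seed(seed, {
    n_total <- n_spacers + decoy_spacers
    lens <- sample(spacer_len_range[1]:spacer_len_range[2], n_total,
                   replace = TRUE)
    kind <- sample(rep(c("true", "decoy"), c(n_spacers, decoy_spacers)))
    sp <- vector("list", n_total)
    proto <- list()
    for (i in seq_len(n_total)) {
      if (kind[i] == "true") {
        s <- sample.int(L - lens[i] + 1L, 1L) - 1L
        strand <- sample(c("+", "-"), 1L)
        seqi <- substr(phage$sequence, s + 1L, s + lens[i])
        if (strand == "-") seqi <- revcomp(seqi)
        proto[[base::length(proto) + 1L]] <- data.frame(
          start = s, end = s + lens[i], strand = strand,
          spacer_index = i, stringsAsFactors = FALSE)
      } else {
        seqi <- random_dna(lens[i], host_gc)
      }
      sp[[i]] <- seqi
    }
    spacers <- unlist(sp)
    array_seq <- paste0(repeat_seq,
                        paste0(spacers, repeat_seq, collapse = ""))
    left <- random_dna(flank, host_gc)
    right <- random_dna(flank, host_gc)
    scaffold <- genome(paste0(phage$id, "_host_seed", seed),
                       paste0(left, array_seq, right))
    truth <- list(
      protospacers = if (base::length(proto)) do.call(rbind, proto) else
        data.frame(start = integer(), end = integer(),
                   strand = character(), spacer_index = integer()),
      spacers = data.frame(index = seq_len(n_total), sequence = spacers,
                           kind = kind, stringsAsFactors = FALSE),
      array_start = nchar(left),
      array_end = nchar(left) + nchar(array_seq),
      repeat_seq = repeat_seq,
      seed = seed
    )
    list(scaffold = scaffold, truth = truth)
  })
}

#' Generate a mosaic (recombinant) genome population
#'
#' First simulates `n_ancestors` haplotypes by substituting each reference
#' site independently with probability `snp_rate`; each output genome is
#' then a concatenation of ancestor blocks with exponentially distributed
#' lengths. A substitution-only model keeps all outputs the same length as
#' the reference, so the population is aligned by construction and block
#' segmentation needs no gapped aligner. Consecutive blocks always switch
#' ancestor, so every recorded breakpoint is a real donor change.
#'
#' @param ref Reference [genome].
#' @param n_genomes Number of mosaic genomes to emit.
#' @param n_ancestors Number of ancestral haplotypes (>= 2).
#' @param block_mean Mean block length in bp (exponential).
#' @param snp_rate Per-site substitution probability per ancestor.
#' @param seed Integer seed.
#' @return List with `genomes` (named list of [genome]s), and `truth`
#'   (ancestor sequences, per-genome `breakpoints` (strictly increasing
#'   0-based positions) and per-block donors).
#' @export
generate_mosaic_population <- function(ref, n_genomes, n_ancestors = 2L,
                                       block_mean = 5000L, snp_rate = 0.02,
                                       seed = 1L) {
  if (n_ancestors < 2L) {
    stop("n_ancestors must be >= 2: no admixture possible otherwise",
         call. = FALSE)
  }
  L <- genome_length(ref)
  with_seed(seed, {
    refc <- seq_chars(ref$sequence)
    ancestors <- lapply(seq_len(n_ancestors), function(a) {
      x <- refc
      mut <- which(stats::runif(L) < snp_rate)
      if (length(mut)) {
        x[mut] <- vapply(x[mut], function(b) {
          sample(setdiff(DNA_BASES, b), 1L)
        }, "")
      }
      x
    })
    genomes <- vector("list", n_genomes)
    breakpoints <- vector("list", n_genomes)
    donors <- vector("list", n_genomes)
    for (i in seq_len(n_genomes)) {
      pos <- 0L
      bps <- integer(0); dnr <- integer(0)
      cur <- sample.int(n_ancestors, 1L)
      out <- character(0)
      while (pos < L) {
        blen <- max(1L, as.integer(round(stats::rexp(1L, 1 / block_mean))))
        e <- min(L, pos + blen)
        out <- c(out, ancestors[[cur]][(pos + 1L):e])
        dnr <- c(dnr, cur)
        if (e < L) bps <- c(bps, e)
        pos <- e
        others <- setdiff(seq_len(n_ancestors), cur)
        cur <- others[sample.int(length(others), 1L)]
      }
      genomes[[i]] <- genome(sprintf("%s_mosaic%d", ref$id, i),
                             paste(out, collapse = ""),
                             circular = ref$circular)
      breakpoints[[i]] <- bps
      donors[[i]] <- dnr
    }
    names(genomes) <- vapply(genomes, `[[`, "", "id")
    names(breakpoints) <- names(genomes)
    names(donors) <- names(genomes)
    list(genomes = genomes,
         truth = list(ancestors = vapply(ancestors, paste, "",
                                         collapse = ""),
                      breakpoints = breakpoints, donors = donors,
                      snp_rate = snp_rate, seed = seed))
  })
}

#' Simulate shotgun reads with known origins
#'
#' Uniform start positions (wrapping the origin on circular genomes),
#' i.i.d. substitution errors, optional paired-end layout. The expected
#' number of reads is `coverage * total genome length / read_len`.
#'
#' @param genomes A [genome] or list of genomes.
#' @param weights Relative abundance per genome (recycled/normalised);
#'   default uniform.
#' @param coverage Fold coverage across the weighted collection.
#' @param read_len Read length in bp.
#' @param error_rate Per-base substitution error probability.
#' @param paired Emit read pairs.
#' @param insert Outer fragment length for paired reads.
#' @param seed Integer seed.
#' @return Data.frame with `id`, `genome_id`, `start`, `end` (0-based
#'   fragment interval on the source genome; `end` may exceed the genome
#'   length when the fragment wraps a circular origin), `strand`, `mate1`,
#'   `mate2` (NA for single-end).
#' @export
generate_reads <- function(genomes, weights = NULL, coverage = 10,
                           read_len = 125L, error_rate = 0.004,
                           paired = FALSE, insert = 350L, seed = 1L) {
  genomes <- as_genome_list(genomes)
  lens <- vapply(genomes, genome_length, 0L)
  frag <- if (paired) as.integer(insert) else as.integer(read_len)
  if (any(lens < frag)) {
    stop("read/fragment length exceeds a genome length", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(genomes))
  weights <- weights / sum(weights)
  n_reads <- round(coverage * sum(lens) / read_len)
  n_frags <- if (paired) as.integer(round(n_reads / 2)) else
    as.integer(n_reads)
  with_seed(seed, {
    gidx <- sample.int(length(genomes), n_frags, replace = TRUE,
                       prob = weights)
    starts <- integer(n_frags)
    for (i in seq_along(genomes)) {
      sel <- gidx == i
      hi <- if (genomes[[i]]$circular) lens[i] else lens[i] - frag + 1L
      starts[sel] <- sample.int(hi, sum(sel), replace = TRUE) - 1L
    }
    strand <- sample(c("+", "-"), n_frags, replace = TRUE)
    add_errors <- function(v) {
      if (error_rate <= 0 || !length(v)) return(v)
      nerr <- stats::rbinom(length(v), nchar(v), error_rate)
      for (r in which(nerr > 0L)) {
        pos <- sample.int(nchar(v[r]), nerr[r])
        ch <- seq_chars(v[r])
        ch[pos] <- vapply(ch[pos], function(b) {
          sample(setdiff(DNA_BASES, b), 1L)
        }, "")
        v[r] <- paste(ch, collapse = "")
      }
      v
    }
    fseqs <- vapply(seq_len(n_frags), function(r) {
      genome_subseq(genomes[[gidx[r]]], starts[r], starts[r] + frag)
    }, "")
    minus <- strand == "-"
    if (!paired) {
      mate1 <- fseqs
      if (any(minus)) mate1[minus] <- revcomp(fseqs[minus])
      mate1 <- add_errors(mate1)
      mate2 <- rep(NA_character_, n_frags)
    } else {
      left <- substr(fseqs, 1L, read_len)
      right <- substr(fseqs, frag - read_len + 1L, frag)
      right <- if (length(right)) revcomp(right) else right
      mate1 <- ifelse(minus, right, left)
      mate2 <- ifelse(minus, left, right)
      mate1 <- add_errors(mate1)
      mate2 <- add_errors(mate2)
    }
    data.frame(
      id = sprintf("read_%06d", seq_len(n_frags)),
      genome_id = names(genomes)[gidx],
      start = starts, end = starts + frag, strand = strand,
      mate1 = mate1, mate2 = mate2, stringsAsFactors = FALSE)
  })
}
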