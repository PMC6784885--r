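# Population analysis of reads against a reference: exact-seed ungapped
# read mapping, the zero-SNP read fraction (a clonality / chimerism
# diagnostic for curated genomes), SNP calling from pileups, variant
# trajectories over serial samples with a two-locus linkage report, and
# recombinant-read detection against a genotype panel.
#
# "SNP" here means a read-versus-reference mismatch, the read-level sense
# in which the zero-SNP fraction is defined. The mapper is ungapped by
# design (the synthetic data are indel-free), which keeps it exactly
# testable; placements from standard mappers can be imported as a
# data.frame with the same columns.

#' Map reads to a reference with exact seeds and mismatch verification
#'
#' Seeds on exact 21-mers taken at non-overlapping offsets along the read,
#' then verifies a full-length ungapped alignment with at most `max_mm`
#' mismatches, on both strands. The placement with the fewest mismatches
#' is reported; ties resolve to the leftmost position and are flagged
#' multi-mapping. Circular references admit placements wrapping the
#' origin. Both mates of paired input are placed independently (read ids
#' get `/1`, `/2` suffixes).
#'
#' @param reads Data.frame with `id`, `mate1` and optionally `mate2`
#'   columns (as produced by [generate_reads()] / [read_reads()]), or a
#'   character vector of read sequences.
#' @param ref Reference [genome].
#' @param max_mm Maximum mismatches per read.
#' @param k Seed length; reads shorter than `k` are unmappable.
#' @return Data.frame of class placements: `read_id`, `ref_id`, `start`,
#'   `end` (0-based half-open; `end` may exceed the reference length for
#'   origin-wrapping placements), `strand`, `n_mm`, `mm_pos` (list column
#'   of 0-based reference positions of mismatches), `mm_allele` (list
#'   column of read bases at those positions), `multi`. Unmapped read ids
#'   are kept in the `unmapped` attribute.
#' @export
map_reads <- function(reads, ref, max_mm = 5L, k = 21L) {
  if (is.character(reads)) {
    reads <- data.frame(id = sprintf("read_%06d", seq_along(reads)),
                        mate1 = reads, mate2 = NA_character_,
                        stringsAsFactors = FALSE)
  }
  L <- genome_length(ref)
  has2 <- "mate2" %in% names(reads) && any(!is.na(reads$mate2))
  seqs <- c(reads$mate1, if (has2) reads$mate2)
  ids <- if (has2) {
    c(paste0(reads$id, "/1"), paste0(reads$id, "/2"))
  } else reads$id
  keep <- !is.na(seqs)
  seqs <- seqs[keep]; ids <- ids[keep]
  max_rl <- if (length(seqs)) max(nchar(seqs)) else 0L
  if (max_rl >= L) stop("reads must be shorter than the reference",
                        call. = FALSE)
  ext <- if (ref$circular) {
    paste0(ref$sequence, substr(ref$sequence, 1L, max_rl - 1L))
  } else ref$sequence
  idx <- kmer_index(ext, k)
  seqs_rc <- if (length(seqs)) revcomp(seqs) else character(0)

  place_one <- function(s, s_rc) {
    rl <- nchar(s)
    if (rl < k) return(NULL)
    offs <- unique(c(seq(1L, rl - k + 1L, by = k), rl - k + 1L))
    best <- NULL
    for (strand in c("+", "-")) {
      q <- if (strand == "+") s else s_rc
      cand <- integer(0)
      for (o in offs) {
        p <- kmer_lookup(idx, substr(q, o, o + k - 1L))
        if (length(p)) cand <- c(cand, p - o + 1L)
      }
      cand <- unique(cand)
      cand <- cand[cand >= 1L & cand + rl - 1L <= nchar(ext)]
      if (ref$circular) cand <- cand[cand <= L]
      for (cc in cand) {
        mm <- count_mismatches(q, substr(ext, cc, cc + rl - 1L))
        if (mm > max_mm) next
        cnd <- list(start = cc - 1L, strand = strand, mm = mm)
        if (is.null(best) || mm < best$mm) {
          best <- cnd
          best$multi <- FALSE
        } else if (mm == best$mm &&
                   (cnd$start != best$start || cnd$strand != best$strand)) {
          best$multi <- TRUE
          if (cnd$start < best$start) {
            best[c("start", "strand", "mm")] <-
              cnd[c("start", "strand", "mm")]
          }
        }
      }
    }
    best
  }

  rows <- vector("list", length(seqs))
  unmapped <- character(0)
  for (i in seq_along(seqs)) {
    b <- place_one(seqs[i], seqs_rc[i])
    if (is.null(b)) {
      unmapped <- c(unmapped, ids[i])
      next
    }
    rl <- nchar(seqs[i])
    q <- if (b$strand == "+") seqs[i] else seqs_rc[i]
    mp <- mismatch_positions(q, substr(ext, b$start + 1L, b$start + rl))
    rows[[i]] <- list(read_id = ids[i], start = b$start,
                      strand = b$strand, n_mm = b$mm,
                      mm_pos = (b$start + mp - 1L) %% L,
                      mm_allele = if (length(mp)) substring(q, mp, mp)
                                  else character(0),
                      rl = rl, multi = b$multi)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- data.frame(read_id = character(), ref_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), n_mm = integer(),
                      multi = logical(), stringsAsFactors = FALSE)
    out$mm_pos <- list(); out$mm_allele <- list()
    attr(out, "unmapped") <- unmapped
    attr(out, "ref_len") <- L
    return(out)
  }
  out <- data.frame(
    read_id = vapply(rows, `[[`, "", "read_id"),
    ref_id = ref$id,
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, function(r) r$start + r$rl, 0L),
    strand = vapply(rows, `[[`, "", "strand"),
    n_mm = vapply(rows, `[[`, 0L, "n_mm"),
    multi = vapply(rows, `[[`, TRUE, "multi"),
    stringsAsFactors = FALSE)
  out$mm_pos <- lapply(rows, `[[`, "mm_pos")
  out$mm_allele <- lapply(rows, `[[`, "mm_allele")
  attr(out, "unmapped") <- unmapped
  attr(out, "ref_len") <- L
  out
}

#' Fraction of mapped reads carrying zero mismatches
#'
#' The proportion of placed reads whose alignment to the reference is
#' perfect. Values near 1 indicate a near-clonal population and argue
#' against the assembled genome being a chimera of population variants;
#' with a per-base error rate e and read length l the expectation for a
#' truly clonal population is (1-e)^l.
#'
#' @param placements Output of [map_reads()] against one reference.
#' @return Fraction in `[0, 1]`.
#' @export
zero_snp_fraction <- function(placements) {
  if (nrow(placements) == 0L) stop("no placements", call. = FALSE)
  if (length(unique(placements$ref_id)) > 1L) {
    stop("placements must come from a single reference", call. = FALSE)
  }
  mean(placements$n_mm == 0L)
}

# per-position coverage vector (1-based) from placements, wrap-aware
coverage_vector <- function(placements, L) {
  cov <- integer(L)
  if (!nrow(placements)) return(cov)
  s <- placements$start; e <- pmin(placements$end, L)
  w <- placements$end > L
  bump <- function(from, to) {
    d <- integer(L + 1L)
    t1 <- tabulate(from, nbins = L)
    t2 <- tabulate(to + 1L, nbins = L + 1L)
    cumsum(t1 - t2[seq_len(L)])
  }
  cov <- bump(s + 1L, e)
  if (any(w)) cov <- cov + bump(rep(1L, sum(w)), placements$end[w] - L)
  cov
}

#' Call single-nucleotide variants from read pileups
#'
#' Builds a substitution pileup per sample and reports every site with
#' coverage of at least `min_cov` and a non-reference allele at frequency
#' `min_freq` or higher in at least one sample, with per-sample counts
#' and frequencies for all samples.
#'
#' @param placements_list A placements data.frame (one sample) or a named
#'   list of them (ordered samples).
#' @param ref Reference [genome].
#' @param min_cov Minimum site coverage.
#' @param min_freq Minimum alternative-allele frequency.
#' @return Long-format data.frame: `sample`, `pos` (0-based), `ref_allele`,
#'   `alt_allele`, `alt_count`, `coverage`, `freq`.
#' @export
call_variants <- function(placements_list, ref, min_cov = 10L,
                          min_freq = 0.05) {
  if (is.data.frame(placements_list)) {
    placements_list <- list(sample1 = placements_list)
  }
  if (is.null(names(placements_list)) ||
      !all(nzchar(names(placements_list)))) {
    names(placements_list) <- sprintf("sample%d",
                                      seq_along(placements_list))
  }
  L <- genome_length(ref)
  per <- lapply(names(placements_list), function(sm) {
    pl <- placements_list[[sm]]
    cov <- coverage_vector(pl, L)
    pos <- unlist(pl$mm_pos)
    allele <- unlist(pl$mm_allele)
    if (is.null(pos) || !length(pos)) {
      return(data.frame(sample = character(), pos = integer(),
                        alt_allele = character(), alt_count = integer(),
                        coverage = integer(), freq = numeric()))
    }
    tab <- as.data.frame(table(pos = pos, alt = allele),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0L, , drop = FALSE]
    tab$pos <- as.integer(tab$pos)
    data.frame(sample = sm, pos = tab$pos, alt_allele = tab$alt,
               alt_count = tab$Freq, coverage = cov[tab$pos + 1L],
               freq = tab$Freq / pmax(1L, cov[tab$pos + 1L]),
               stringsAsFactors = FALSE)
  })
  allv <- do.call(rbind, per)
  if (!nrow(allv)) {
    return(data.frame(sample = character(), pos = integer(),
                      ref_allele = character(), alt_allele = character(),
                      alt_count = integer(), coverage = integer(),
                      freq = numeric()))
  }
  qual <- allv$coverage >= min_cov & allv$freq >= min_freq
  keys <- unique(paste(allv$pos, allv$alt_allele)[qual])
  out <- allv[paste(allv$pos, allv$alt_allele) %in% keys, , drop = FALSE]
  if (!nrow(out)) {
    return(data.frame(sample = character(), pos = integer(),
                      ref_allele = character(), alt_allele = character(),
                      alt_count = integer(), coverage = integer(),
                      freq = numeric()))
  }
  out$ref_allele <- substring(ref$sequence, out$pos + 1L, out$pos + 1L)
  out <- out[order(out$pos, out$alt_allele, out$sample),
             c("sample", "pos", "ref_allele", "alt_allele", "alt_count",
               "coverage", "freq")]
  rownames(out) <- NULL
  out
}

# read allele at a 0-based reference position, given its placement row
read_allele_at <- function(placement, pos, ref_base) {
  hit <- which(placement$mm_pos[[1]] == pos)
  if (length(hit)) placement$mm_allele[[1]][hit[1]] else ref_base
}

#' Variant-frequency trajectories and linkage across serial samples
#'
#' Joins variant sites across two or more ordered samples into per-site
#' frequency series, and reports two-locus linkage: for every pair of
#' reported sites co-covered by at least `min_pair_cov` reads, the
#' haplotype counts observed within individual reads and the normalised
#' disequilibrium D'. The population is summarised as "unlinked" when
#' |D'| stays below `dprime_max` for at least `unlinked_frac` of pairs --
#' shifting but unlinked site frequencies indicate changing relative
#' abundances of phage subpopulations rather than discrete strains.
#'
#' @param variants Output of [call_variants()] over >= 2 samples.
#' @param placements_list The named list of placements used for the calls
#'   (pooled for the linkage report); optional, `NULL` skips linkage.
#' @param ref Reference [genome].
#' @param min_pair_cov Minimum reads co-covering a site pair.
#' @param dprime_max |D'| threshold below which a pair counts as unlinked.
#' @param unlinked_frac Fraction of pairs required for the summary call.
#' @return List with `trajectories` (wide data.frame, one row per
#'   site/allele, one frequency column per sample), `linkage` (per-pair
#'   data.frame with haplotype counts and D') and `unlinked` (logical or
#'   NA when no pair qualifies).
#' @export
variant_trajectories <- function(variants, placements_list = NULL,
                                 ref = NULL, min_pair_cov = 20L,
                                 dprime_max = 0.5, unlinked_frac = 0.9) {
  samples <- unique(variants$sample)
  if (length(samples) < 2L) {
    stop("need at least two ordered samples", call. = FALSE)
  }
  key <- paste(variants$pos, variants$alt_allele)
  sites <- unique(variants[, c("pos", "ref_allele", "alt_allele")])
  sites <- sites[order(sites$pos, sites$alt_allele), , drop = FALSE]
  traj <- sites
  for (sm in samples) {
    v <- variants[variants$sample == sm, ]
    m <- match(paste(sites$pos, sites$alt_allele),
               paste(v$pos, v$alt_allele))
    traj[[sm]] <- ifelse(is.na(m), 0, v$freq[m])
  }
  rownames(traj) <- NULL
  if (!nrow(traj)) warning("no shared variant sites across samples")

  linkage <- NULL
  unlinked <- NA
  if (!is.null(placements_list) && nrow(traj) >= 2L && !is.null(ref)) {
    pooled <- do.call(rbind, placements_list)
    pos <- unique(traj$pos)
    refb <- substring(ref$sequence, pos + 1L, pos + 1L)
    altb <- traj$alt_allele[match(pos, traj$pos)]
    pairs <- utils::combn(seq_along(pos), 2L)
    rows <- list()
    for (pi in seq_len(ncol(pairs))) {
      i <- pairs[1, pi]; j <- pairs[2, pi]
      covers <- pooled$start <= pos[i] & pooled$end > pos[j] &
        pooled$start <= pos[j] & pooled$end > pos[i]
      n <- sum(covers)
      if (n < min_pair_cov) next
      sel <- which(covers)
      ai <- vapply(sel, function(r) {
        read_allele_at(pooled[r, ], pos[i], refb[i])
      }, "")
      aj <- vapply(sel, function(r) {
        read_allele_at(pooled[r, ], pos[j], refb[j])
      }, "")
      xi <- as.integer(ai == altb[i])
      xj <- as.integer(aj == altb[j])
      p1 <- mean(xi); p2 <- mean(xj)
      p11 <- mean(xi == 1L & xj == 1L)
      D <- p11 - p1 * p2
      dmax <- if (D >= 0) min(p1 * (1 - p2), (1 - p1) * p2) else
        min(p1 * p2, (1 - p1) * (1 - p2))
      dprime <- if (is.na(dmax) || dmax == 0) 0 else D / dmax
      rows[[length(rows) + 1L]] <- data.frame(
        pos_a = pos[i], pos_b = pos[j], n_reads = n,
        n11 = sum(xi & xj), n10 = sum(xi & !xj),
        n01 = sum(!xi & xj), n00 = sum(!xi & !xj),
        dprime = dprime)
    }
    if (length(rows)) {
      linkage <- do.call(rbind, rows)
      unlinked <- mean(abs(linkage$dprime) < dprime_max) >= unlinked_frac
    }
  }
  list(trajectories = traj, linkage = linkage, unlinked = unlinked)
}

#' Detect reads spanning a genotype switch (recombinant reads)
#'
#' Given placements on a reference and a panel of aligned genotype
#' genomes, each read's alleles at the panel's diagnostic sites are
#' assigned to the panel genomes they match. A read is recombinant when
#' no single panel genome explains all its covered diagnostic sites, i.e.
#' a minimal-switch parsimony needs at least two donors; the switch is
#' localised between the last site of one donor run and the first site of
#' the next. Adjacent single-read evidence of this kind is the direct
#' signature of allele reassortment via homologous recombination.
#'
#' @param placements Output of [map_reads()] against `ref`.
#' @param panel Named list of >= 2 [genome]s, each the same length as and
#'   aligned to `ref`.
#' @param ref Reference [genome] used for the mapping.
#' @param min_sites Minimum diagnostic sites a read must cover to be
#'   informative.
#' @return Data.frame per informative read: `read_id`, `n_sites`,
#'   `n_switches`, `recombinant`, `switch_start`, `switch_end` (0-based
#'   bounds of the first switch interval; NA for non-recombinants);
#'   attribute `diagnostic_sites` lists the panel's diagnostic positions.
#' @export
find_recombinant_reads <- function(placements, panel, ref,
                                   min_sites = 2L) {
  panel <- as_genome_list(panel)
  if (length(panel) < 2L) stop("panel needs at least two genomes",
                               call. = FALSE)
  L <- genome_length(ref)
  if (any(vapply(panel, genome_length, 0L) != L)) {
    stop("panel genomes must be aligned to the reference (equal length)",
         call. = FALSE)
  }
  pm <- do.call(rbind, lapply(panel, function(g) charToRaw(g$sequence)))
  diag_sites <- which(colSums(pm != rep(pm[1, ], each = nrow(pm))) > 0L) - 1L
  out <- list()
  # vectorised pre-filter: only reads covering >= min_sites diagnostic
  # sites are worth a row-level look
  n_in <- findInterval(placements$end - 1L, diag_sites) -
    findInterval(placements$start - 1L, diag_sites)
  for (r in which(n_in >= min_sites)) {
    pl <- placements[r, ]
    sites <- diag_sites[diag_sites >= pl$start & diag_sites < pl$end]
    if (length(sites) < min_sites) next
    refb <- substring(ref$sequence, sites + 1L, sites + 1L)
    donors_per_site <- lapply(seq_along(sites), function(si) {
      a <- read_allele_at(pl, sites[si], refb[si])
      which(rawToChar(pm[, sites[si] + 1L], multiple = TRUE) == a)
    })
    usable <- lengths(donors_per_site) > 0L
    sites <- sites[usable]
    donors_per_site <- donors_per_site[usable]
    if (length(sites) < min_sites) next
    cur <- seq_along(panel)
    n_sw <- 0L
    sw_s <- NA_integer_; sw_e <- NA_integer_
    last_site <- NA_integer_
    for (si in seq_along(sites)) {
      nxt <- intersect(cur, donors_per_site[[si]])
      if (!length(nxt)) {
        n_sw <- n_sw + 1L
        if (n_sw == 1L) {
          sw_s <- last_site
          sw_e <- sites[si]
        }
        cur <- donors_per_site[[si]]
      } else {
        cur <- nxt
      }
      last_site <- sites[si]
    }
    out[[length(out) + 1L]] <- data.frame(
      read_id = pl$read_id, n_sites = length(sites), n_switches = n_sw,
      recombinant = n_sw >= 1L, switch_start = sw_s, switch_end = sw_e,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(), n_sites = integer(),
               n_switches = integer(), recombinant = logical(),
               switch_start = integer(), switch_end = integer())
  rownames(res) <- NULL
  attr(res, "diagnostic_sites") <- diag_sites
  res
}
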