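# ORF prediction under alternative translation tables, the coding-density
# statistic that drives genetic-code inference, windowed codon usage and
# TAG-free region detection.
#
# The ORF model is deliberately simple (longest ORF per stop-to-stop
# segment, ATG/GTG/TTG starts): the decision statistic -- the coding-density
# gain when a stop codon is removed from the table -- is what matters for
# code inference, not the individual gene calls.

# Scan one strand of a sequence. `s` is the scan sequence (already
# reverse-complemented for the minus strand, already doubled for circular
# genomes); coordinates are mapped back by the caller.
scan_orfs_one <- function(s, code, min_len) {
  n <- nchar(s)
  out <- vector("list", 3L)
  for (f in 0:2) {
    cs <- seq.int(f + 1L, n - 2L, by = 3L)
    if (length(cs) < 2L) next
    codons <- substring(s, cs, cs + 2L)
    sp <- which(codons %in% code$stops)
    st <- which(codons %in% code$starts)
    tagcum <- c(0L, cumsum(codons == "TAG"))
    res <- list()
    if (length(sp) && length(st)) {
      prev <- c(0L, sp[-length(sp)])
      jidx <- findInterval(prev, st) + 1L
      ok <- jidx <= length(st)
      j <- rep(NA_integer_, length(sp))
      j[ok] <- st[jidx[ok]]
      keep <- !is.na(j) & j < sp & (sp - j + 1L) * 3L >= min_len
      if (any(keep)) {
        jk <- j[keep]; spk <- sp[keep]
        res$complete <- data.frame(
          start = cs[jk] - 1L, end = cs[spk] + 2L, frame = f,
          n_internal_TAG = tagcum[spk] - tagcum[jk],
          partial = FALSE
        )
      }
    }
    # trailing stop-less segment (meaningful for linear sequences only;
    # the caller discards these in circular mode)
    p <- if (length(sp)) sp[length(sp)] else 0L
    jidx <- findInterval(p, st) + 1L
    if (length(st) && jidx <= length(st)) {
      j <- st[jidx]
      m <- length(codons)
      if (j <= m && (m - j + 1L) * 3L >= min_len) {
        res$partial <- data.frame(
          start = cs[j] - 1L, end = cs[m] + 2L, frame = f,
          n_internal_TAG = tagcum[m + 1L] - tagcum[j],
          partial = TRUE
        )
      }
    }
    out[[f + 1L]] <- if (length(res)) do.call(rbind, res) else NULL
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      n_internal_TAG = integer(), partial = logical()))
  }
  do.call(rbind, out)
}

#' Predict open reading frames under a translation table
#'
#' Scans all six reading frames. Within each frame every stop-to-stop
#' segment yields at most one ORF, running from the segment's first start
#' codon (ATG/GTG/TTG) through its terminating stop codon. Segments that
#' run into the end of a linear sequence are reported with `partial = TRUE`;
#' on circular genomes the frames wrap the origin instead and wrapped ORFs
#' carry `wrap = TRUE` (their `end` then exceeds the genome length).
#'
#' @param g A [genome].
#' @param code A [genetic_code] or table number (11, 15 or 4).
#' @param min_len Minimum ORF length in bp (stop codon included); must be a
#'   multiple of 3.
#' @return A data.frame with columns `genome_id`, `start`, `end` (0-based
#'   half-open), `strand`, `frame`, `n_internal_TAG` (in-frame TAG codons,
#'   the terminal stop excluded), `partial`, `wrap` and `code`.
#' @export
#' @examples
#' g <- genome("demo", "ATGGCATAGGCATAA")
#' find_orfs(g, 15, min_len = 15)   # TAG read through as glutamine
find_orfs <- function(g, code = 11, min_len = 150L) {
  code <- as_genetic_code(code)
  min_len <- as.integer(min_len)
  if (min_len %% 3L != 0L) stop("min_len must be a multiple of 3",
                                call. = FALSE)
  L <- genome_length(g)
  empty <- data.frame(genome_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), n_internal_TAG = integer(),
                      partial = logical(), wrap = logical(),
                      code = integer())
  if (L < min_len) return(empty)

  collect <- function(s, strand) {
    scan_seq <- if (g$circular) paste0(s, s) else s
    orfs <- scan_orfs_one(scan_seq, code, min_len)
    if (g$circular && nrow(orfs)) {
      orfs <- orfs[!orfs$partial & orfs$start < L &
                     (orfs$end - orfs$start) <= L, , drop = FALSE]
    }
    if (!nrow(orfs)) return(NULL)
    if (strand == "+") {
      fs <- orfs$start; fe <- orfs$end
    } else {
      w <- orfs$end - orfs$start
      if (g$circular) {
        fs <- (2L * L - orfs$end) %% L
      } else {
        fs <- L - orfs$end
      }
      fe <- fs + w
    }
    data.frame(genome_id = g$id, start = fs, end = fe, strand = strand,
               frame = orfs$frame, n_internal_TAG = orfs$n_internal_TAG,
               partial = orfs$partial, wrap = fe > L,
               code = code$table_id, stringsAsFactors = FALSE)
  }

  res <- rbind(collect(g$sequence, "+"), collect(revcomp(g$sequence), "-"))
  if (is.null(res)) return(empty)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Coding density of an ORF set
#'
#' Fraction of the genome covered by the union of predicted ORF intervals
#' over both strands. A low value under the standard bacterial code
#' (table 11) combined with a large gain under table 15 is the diagnostic
#' for TAG reassignment.
#'
#' @param orfs Output of [find_orfs()] for a single genome.
#' @param genome_len Genome length in bp.
#' @return Fraction in `[0, 1]`.
#' @export
coding_density <- function(orfs, genome_len) {
  if (nrow(orfs) == 0L) return(0)
  if (length(unique(orfs$genome_id)) > 1L) {
    stop("coding_density expects ORFs from a single genome", call. = FALSE)
  }
  s <- orfs$start; e <- orfs$end
  wrapped <- if ("wrap" %in% names(orfs)) orfs$wrap else rep(FALSE, length(s))
  if (any(s < 0) || any(s >= genome_len) ||
      any(e > genome_len & !wrapped) ||
      any(e - genome_len > genome_len)) {
    stop("ORF interval out of range", call. = FALSE)
  }
  # split origin-wrapping ORFs into their two linear pieces
  wrapped <- wrapped & e > genome_len
  s2 <- c(s, rep(0L, sum(wrapped)))
  e2 <- c(pmin(e, genome_len), e[wrapped] - genome_len)
  ir <- IRanges::reduce(IRanges::IRanges(start = s2 + 1L, end = e2))
  sum(IRanges::width(ir)) / genome_len
}

#' Infer the genetic code of a genome from coding-density gain
#'
#' Predicts ORFs under each candidate translation table and compares coding
#' densities. An alternative table is called only when it buys at least
#' `delta` of absolute density over table 11; ties and small gains resolve
#' conservatively to the standard code. This operationalises the
#' observation that genuinely recoded genomes look gene-poor (<70% coding)
#' under table 11 and recover normal density once the reassigned stop is
#' read through.
#'
#' @param g A [genome] of at least 5 kb.
#' @param candidates Candidate table numbers; must include 11.
#' @param delta Minimum absolute density gain to call an alternative code.
#' @param min_len Minimum ORF length passed to [find_orfs()].
#' @return List of class `code_inference` with `table_id` (the call) and
#'   `densities` (named per-candidate coding densities).
#' @export
infer_genetic_code <- function(g, candidates = c(11, 15, 4), delta = 0.10,
                               min_len = 150L) {
  if (genome_length(g) < 5000L) {
    stop("genetic-code inference needs a genome of at least 5 kb",
         call. = FALSE)
  }
  candidates <- unique(as.integer(candidates))
  if (!11L %in% candidates) {
    stop("candidate set must include the standard table 11", call. = FALSE)
  }
  dens <- vapply(candidates, function(tid) {
    coding_density(find_orfs(g, tid, min_len = min_len), genome_length(g))
  }, numeric(1))
  names(dens) <- as.character(candidates)
  alt <- setdiff(candidates, 11L)
  call_id <- 11L
  if (length(alt)) {
    da <- dens[as.character(alt)]
    best <- alt[which.max(da)]
    if (max(da) >= dens[["11"]] + delta) call_id <- best
  }
  structure(list(table_id = call_id, densities = dens, delta = delta),
            class = "code_inference")
}

#' @export
print.code_inference <- function(x, ...) {
  cat(sprintf("<code_inference> table %d (densities: %s)\n", x$table_id,
              paste(sprintf("%s=%.3f", names(x$densities), x$densities),
                    collapse = ", ")))
  invisible(x)
}

# Genomic first-base position and sequence of every codon of every ORF.
# For minus-strand ORFs the recorded position is the leftmost base of the
# codon's genomic footprint. Origin-wrapping ORFs are skipped (windowed
# statistics assume a rotated, feature-free origin).
orf_codon_positions <- function(g, orfs) {
  keep <- !orfs$wrap
  orfs <- orfs[keep, , drop = FALSE]
  if (!nrow(orfs)) {
    return(data.frame(pos = integer(), codon = character()))
  }
  per <- lapply(seq_len(nrow(orfs)), function(i) {
    s <- orfs$start[i]; e <- orfs$end[i]
    ncod <- (e - s) %/% 3L
    if (orfs$strand[i] == "+") {
      pos <- s + 3L * (seq_len(ncod) - 1L)
      codon <- substring(g$sequence, pos + 1L, pos + 3L)
    } else {
      pos <- e - 3L * seq_len(ncod)
      codon <- revcomp(substring(g$sequence, pos + 1L, pos + 3L))
    }
    data.frame(pos = pos, codon = codon, stringsAsFactors = FALSE)
  })
  do.call(rbind, per)
}

#' Codon usage in consecutive fixed-width windows
#'
#' For each non-overlapping window the value is the percentage of the
#' target codon among all codons of all ORFs whose first base falls in the
#' window; windows containing no coding sequence (or more than 10% N) are
#' reported as `NA` rather than zero. Profiling TAG along a genome
#' annotated under table 15 exposes the regions that avoid the repurposed
#' stop entirely.
#'
#' @param g A [genome].
#' @param orfs Output of [find_orfs()] for `g`.
#' @param codon Target codon (3-mer), default `"TAG"`.
#' @param window Window width in bp (>= 300).
#' @return Data.frame with `window_start`, `window_end`, `n_codons`,
#'   `n_target` and `value` (percent, `NA` where undefined). The final
#'   window is reported at its true (possibly shorter) width.
#' @export
codon_usage_windows <- function(g, orfs, codon = "TAG", window = 1000L) {
  window <- as.integer(window)
  if (window < 300L) stop("window must be at least 300 bp", call. = FALSE)
  if (nchar(codon) != 3L) stop("codon must be a 3-mer", call. = FALSE)
  codon <- toupper(codon)
  L <- genome_length(g)
  nwin <- ceiling(L / window)
  ws <- (seq_len(nwin) - 1L) * window
  we <- pmin(ws + window, L)
  cp <- orf_codon_positions(g, orfs)
  widx <- cp$pos %/% window + 1L
  n_codons <- tabulate(widx, nbins = nwin)
  n_target <- tabulate(widx[cp$codon == codon], nbins = nwin)
  value <- ifelse(n_codons > 0L, 100 * n_target / n_codons, NA_real_)
  nfrac <- vapply(seq_len(nwin), function(i) {
    n_fraction(substr(g$sequence, ws[i] + 1L, we[i]))
  }, numeric(1))
  value[nfrac > 0.10] <- NA_real_
  data.frame(window_start = ws, window_end = we, n_codons = n_codons,
             n_target = n_target, value = value)
}

#' Reduce a six-frame ORF set to a primary non-overlapping gene set
#'
#' Six-frame scanning reports every qualifying ORF, including short
#' antisense ORFs nested inside real genes. For analyses that need one
#' gene model per locus (TAG-free region detection, summary gene counts)
#' this helper greedily keeps the longest ORFs whose mutual overlap does
#' not exceed `max_overlap` bp.
#'
#' @param orfs Output of [find_orfs()].
#' @param max_overlap Tolerated overlap between kept ORFs in bp.
#' @return The selected subset of `orfs`, ordered by `start`.
#' @export
primary_orfs <- function(orfs, max_overlap = 30L) {
  if (!nrow(orfs)) return(orfs)
  o <- orfs[order(-(orfs$end - orfs$start)), , drop = FALSE]
  kept_s <- integer(0); kept_e <- integer(0)
  keep <- logical(nrow(o))
  for (i in seq_len(nrow(o))) {
    ov <- pmin(o$end[i], kept_e) - pmax(o$start[i], kept_s)
    if (!length(ov) || max(ov) <= max_overlap) {
      keep[i] <- TRUE
      kept_s <- c(kept_s, o$start[i]); kept_e <- c(kept_e, o$end[i])
    }
  }
  out <- o[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Maximal regions free of in-frame TAG codons
#'
#' Given ORFs predicted under table 15 (where TAG is an ordinary sense
#' codon), returns all maximal intervals longer than `min_span` that
#' contain no in-frame TAG of any primary ORF -- the hallmark regions
#' where the repurposed stop codon is avoided. The ORF set is first
#' reduced with [primary_orfs()] (disable with `primary = FALSE`): TAGs
#' inside short antisense ORFs nested in real genes are calling
#' artifacts, not codon usage.
#'
#' @param g A [genome].
#' @param orfs Output of [find_orfs()] under table 15.
#' @param min_span Minimum region length in bp (regions must exceed it).
#' @param primary Reduce to a non-overlapping primary gene set first.
#' @return Data.frame with `start`, `end` (0-based half-open, clipped to
#'   the genome) and `width`.
#' @export
tag_free_regions <- function(g, orfs, min_span = 5000L, primary = TRUE) {
  L <- genome_length(g)
  if (primary) orfs <- primary_orfs(orfs)
  cp <- orf_codon_positions(g, orfs)
  tag_pos <- sort(unique(cp$pos[cp$codon == "TAG"]))
  gaps_s <- c(0L, tag_pos + 3L)
  gaps_e <- c(tag_pos, L)
  keep <- (gaps_e - gaps_s) > min_span
  data.frame(start = gaps_s[keep], end = gaps_e[keep],
             width = (gaps_e - gaps_s)[keep])
}
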