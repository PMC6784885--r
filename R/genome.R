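#' Genome objects
#'
#' A `genome` is the substrate of every analysis stage: a named nucleotide
#' sequence over \{A,C,G,T,N\} plus a circularity flag. Collections of genomes
#' are plain named lists (names equal to the genome ids), which is what
#' [read_fasta()] returns.
#'
#' @param id Single non-empty string; must be unique within any collection.
#' @param sequence Nucleotide sequence (upper-cased on construction).
#' @param circular Logical; `TRUE` for circularised genomes, where features
#'   may wrap the origin and read sampling wraps.
#' @return An object of class `genome` with fields `id`, `sequence`,
#'   `circular`.
#' @export
#' @examples
#' g <- genome("A1", "ACGTACGT", circular = TRUE)
#' genome_length(g)
genome <- function(id, sequence, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    stop(sprintf("genome '%s': empty sequence", id), call. = FALSE)
  }
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    stop(sprintf(
      "genome '%s': non-nucleotide character '%s' at position %d",
      id, substr(sequence, bad, bad), bad
    ), call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp%s\n", x$id,
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' @rdname genome
#' @param g A `genome`.
#' @export
genome_length <- function(g) nchar(g$sequence)

as_genome_list <- function(x) {
  if (inherits(x, "genome")) x <- list(x)
  ids <- vapply(x, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate genome ids: ", paste(unique(ids[duplicated(ids)]),
                                         collapse = ", "), call. = FALSE)
  }
  names(x) <- ids
  x
}

#' Read genomes from a FASTA file
#'
#' The header token before the first whitespace becomes the genome id;
#' sequences are upper-cased. Records with duplicate ids, empty sequences or
#' characters outside \{A,C,G,T,N\} are rejected with an informative error.
#'
#' @param path Path to a (optionally gzipped) FASTA file.
#' @param circular Logical, recycled over records: circularity flag to attach.
#' @return Named list of [genome] objects.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(ss) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  circular <- rep_len(circular, length(ss))
  gs <- lapply(seq_along(ss), function(i) {
    genome(ids[i], as.character(ss[[i]]), circular = circular[i])
  })
  as_genome_list(gs)
}

#' Write genomes to a FASTA file
#'
#' @param genomes A `genome` or list of genomes.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  genomes <- as_genome_list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    writeLines(paste0(">", g$id), con)
    n <- nchar(g$sequence)
    starts <- seq(1L, n, by = width)
    writeLines(substring(g$sequence, starts, pmin(starts + width - 1L, n)),
               con)
  }
  invisible(path)
}

#' Read short reads from FASTA or FASTQ
#'
#' Qualities in FASTQ input are ignored; only the sequences enter the
#' analyses. Mate pairing is by the conventional `/1`,`/2` id suffixes when
#' two files are given.
#'
#' @param path Path to reads (FASTA or FASTQ; format sniffed from the first
#'   character).
#' @param path2 Optional second file with mate-2 reads.
#' @return A data.frame with columns `id`, `mate1`, `mate2` (NA when
#'   unpaired); compatible with the output of [generate_reads()].
#' @export
read_reads <- function(path, path2 = NULL) {
  sniff <- function(p) {
    ch <- substr(readLines(p, n = 1L), 1, 1)
    if (ch == "@") "fastq" else "fasta"
  }
  rd <- function(p) {
    ss <- Biostrings::readBStringSet(p, format = sniff(p))
    data.frame(id = sub("\\s.*$", "", names(ss)),
               seq = toupper(as.character(ss)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  r1 <- rd(path)
  if (is.null(path2)) {
    return(data.frame(id = sub("/1$", "", r1$id), mate1 = r1$seq,
                      mate2 = NA_character_, stringsAsFactors = FALSE))
  }
  r2 <- rd(path2)
  if (nrow(r1) != nrow(r2)) stop("mate files differ in read count",
                                 call. = FALSE)
  data.frame(id = sub("/1$", "", r1$id), mate1 = r1$seq, mate2 = r2$seq,
             stringsAsFactors = FALSE)
}

#' Extract a subsequence, wrapping the origin of circular genomes
#'
#' @param g A [genome].
#' @param start 0-based start.
#' @param end 0-based exclusive end; may exceed the genome length for
#'   circular genomes, in which case the extraction wraps.
#' @return Character sequence of length `end - start`.
#' @export
genome_subseq <- function(g, start, end) {
  n <- genome_length(g)
  stopifnot(start >= 0, end > start)
  if (end <= n) return(substr(g$sequence, start + 1L, end))
  if (!g$circular) stop(sprintf(
    "interval [%d,%d) extends past the end of linear genome '%s'",
    start, end, g$id), call. = FALSE)
  if (end - start > n) stop("wrapped interval longer than genome",
                            call. = FALSE)
  paste0(substr(g$sequence, start + 1L, n), substr(g$sequence, 1L, end - n))
}
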