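# Feature tables and their on-disk formats.
#
# Internally every annotated interval lives in a plain data.frame with
# 0-based half-open coordinates; conversion to the 1-based inclusive GFF3
# convention happens only at the format boundary.

#' Construct a feature table
#'
#' @param genome_id Character vector of genome ids.
#' @param start,end 0-based half-open interval bounds (`end > start`).
#' @param strand One of `"+"`, `"-"`, `"."` per feature.
#' @param type Feature type tag (e.g. `"CDS"`, `"tRNA"`).
#' @param attributes Free-form `key=value;key=value` attribute string.
#' @param wrap Logical: feature wraps the origin of a circular genome, in
#'   which case `end` may exceed the genome length.
#' @return A `data.frame` with the columns above.
#' @export
feature_table <- function(genome_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          type = character(), attributes = character(),
                          wrap = logical()) {
  n <- length(start)
  if (n > 0L) {
    stopifnot(all(start >= 0), all(end > start),
              all(strand %in% c("+", "-", ".")))
  }
  rec <- function(x, default) {
    if (n == 0L) return(vector(typeof(default), 0L))
    if (!length(x)) x <- default
    rep_len(x, n)
  }
  data.frame(
    genome_id = as.character(rec(genome_id, NA_character_)),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(rec(strand, ".")),
    type = as.character(rec(type, "feature")),
    attributes = as.character(rec(attributes, "")),
    wrap = as.logical(rec(wrap, FALSE)),
    stringsAsFactors = FALSE
  )
}

FEATURE_COLS <- c("genome_id", "start", "end", "strand", "type",
                  "attributes", "wrap")

validate_features <- function(features, genomes = NULL) {
  stopifnot(all(FEATURE_COLS %in% names(features)))
  if (nrow(features) == 0L) return(invisible(features))
  stopifnot(all(features$end > features$start), all(features$start >= 0))
  if (!is.null(genomes)) {
    genomes <- as_genome_list(genomes)
    for (i in seq_len(nrow(features))) {
      g <- genomes[[features$genome_id[i]]]
      if (is.null(g)) next
      if (!g$circular && (features$wrap[i] ||
                          features$end[i] > genome_length(g))) {
        stop(sprintf(
          "feature %d ([%d,%d) on '%s') extends past the end of a linear genome",
          i, features$start[i], features$end[i], g$id), call. = FALSE)
      }
    }
  }
  invisible(features)
}

#' Write features to GFF3, BED or the internal TSV dialect
#'
#' GFF3 output uses 1-based inclusive coordinates, BED 0-based half-open;
#' the TSV dialect is a lossless dump of the internal table behind a
#' `#`-prefixed header and round-trips through [read_features()] exactly.
#'
#' @param features A feature table (see [feature_table()]).
#' @param path Output path.
#' @param format `"gff3"`, `"bed"` or `"tsv"`.
#' @param genomes Optional genome collection used to validate that no
#'   feature runs past the end of a linear genome.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, format = c("tsv", "gff3", "bed"),
                           genomes = NULL) {
  format <- match.arg(format)
  validate_features(features, genomes)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(paste0("#", paste(FEATURE_COLS, collapse = "\t")), con)
    if (nrow(features)) {
      utils::write.table(features[, FEATURE_COLS], con, sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  } else if (format == "gff3") {
    writeLines("##gff-version 3", con)
    if (nrow(features)) {
      attrs <- ifelse(nzchar(features$attributes), features$attributes, ".")
      attrs <- paste0(attrs, ifelse(features$wrap, ";wrap=true", ""))
      utils::write.table(
        data.frame(features$genome_id, "lakphage", features$type,
                   features$start + 1L, features$end, ".", features$strand,
                   ".", attrs),
        con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  } else {
    writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
    if (nrow(features)) {
      utils::write.table(
        data.frame(features$genome_id, features$start, features$end,
                   features$type, 0L, features$strand),
        con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read features from the internal TSV dialect or GFF3
#'
#' @param path Input path.
#' @param format `"tsv"` or `"gff3"`.
#' @return A feature table in internal (0-based half-open) coordinates.
#' @export
read_features <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(feature_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "tsv") {
    m <- do.call(rbind, fields)
    feature_table(genome_id = m[, 1], start = as.integer(m[, 2]),
                  end = as.integer(m[, 3]), strand = m[, 4], type = m[, 5],
                  attributes = m[, 6], wrap = as.logical(m[, 7]))
  } else {
    m <- do.call(rbind, fields)
    wrap <- grepl("wrap=true", m[, 9], fixed = TRUE)
    attrs <- sub(";?wrap=true", "", m[, 9])
    attrs <- ifelse(attrs == ".", "", attrs)
    feature_table(genome_id = m[, 1], start = as.integer(m[, 4]) - 1L,
                  end = as.integer(m[, 5]), strand = m[, 7], type = m[, 3],
                  attributes = attrs, wrap = wrap)
  }
}
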