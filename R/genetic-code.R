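#' Translation tables
#'
#' Builds the translation-table object the gene caller works with. Table 11
#' is the standard bacterial code (stops TAA/TAG/TGA); table 15 reassigns
#' the amber stop TAG to glutamine (Q), the signature of the Lak megaphage
#' genomes; table 4 reassigns TGA to tryptophan and is carried as a third
#' candidate so that code inference is a genuine model selection rather
#' than a binary switch.
#'
#' @param table_id One of 11, 15 or 4 (NCBI translation table numbers).
#' @return An object of class `genetic_code` with fields `table_id`,
#'   `stops`, `starts` (ATG/GTG/TTG throughout) and `codons` (codon to
#'   amino-acid map, stops as `"*"`).
#' @export
#' @examples
#' genetic_code(15)$stops      # TAA, TGA -- TAG now encodes Q
genetic_code <- function(table_id = 11) {
  table_id <- as.integer(table_id)
  if (!table_id %in% c(11L, 15L, 4L)) {
    stop("supported translation tables: 11, 15, 4", call. = FALSE)
  }
  map <- Biostrings::getGeneticCode(as.character(table_id))
  structure(list(
    table_id = table_id,
    stops = names(map)[map == "*"],
    starts = c("ATG", "GTG", "TTG"),
    codons = map
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> table %d; stops: %s\n", x$table_id,
              paste(x$stops, collapse = ", ")))
  invisible(x)
}

as_genetic_code <- function(x) {
  if (inherits(x, "genetic_code")) x else genetic_code(x)
}

#' Translate a nucleotide sequence under a given table
#'
#' @param seq In-frame nucleotide sequence (length a multiple of 3).
#' @param code A [genetic_code] or table number.
#' @return Single amino-acid string, stops as `"*"`.
#' @export
translate_seq <- function(seq, code = 11) {
  code <- as_genetic_code(code)
  stopifnot(nchar(seq) %% 3 == 0)
  cod <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  paste(unname(code$codons[cod]), collapse = "")
}
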