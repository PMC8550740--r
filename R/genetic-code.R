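#' Genetic code tables for barcode translation
#'
#' Returns a genetic code object for NCBI translation table 1 (standard) or
#' 5 (invertebrate mitochondrial). Table 5 is the default throughout the
#' package because whitefly mtCO1 is a mitochondrial locus: relative to the
#' standard code it reads ATA as Met, TGA as Trp and AGA/AGG as Ser, leaving
#' TAA and TAG as the only stop codons.
#'
#' @param table_id Integer NCBI translation table id, 1 or 5.
#' @return An object of class `genetic_code`: a list with `table_id`, a
#'   64-entry named character vector `codons` (stops encoded as `"*"`) and
#'   the character vector `stops` of stop codons.
#' @examples
#' gc5 <- genetic_code(5)
#' gc5$codons[["TGA"]]  # "W" under the invertebrate mitochondrial code
#' @export
genetic_code <- function(table_id = 5L) {
  table_id <- as.integer(table_id)
  if (!table_id %in% c(1L, 5L)) {
    stop("only NCBI translation tables 1 and 5 are shipped, got: ", table_id)
  }
  codons <- Biostrings::getGeneticCode(as.character(table_id))
  stopifnot(length(codons) == 64L)
  structure(
    list(
      table_id = table_id,
      codons = codons,
      stops = names(codons)[codons == "*"]
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code: NCBI translation table", x$table_id, "\n")
  cat("Stop codons:", paste(x$stops, collapse = ", "), "\n")
  invisible(x)
}

#' Translate a nucleotide sequence and locate stop codons
#'
#' Translates `nt` from the given reading-frame offset, dropping any trailing
#' partial codon. Codons containing any non-ACGT symbol (IUPAC ambiguity
#' codes, N, gaps) translate to `"X"`, never to a stop: a Sanger base-calling
#' ambiguity must not trigger the premature-stop pseudogene filter.
#'
#' All positions in this package are 0-based; stop positions index the
#' peptide, not the nucleotide sequence.
#'
#' @param nt Gap-free nucleotide string.
#' @param frame Frame offset (0, 1 or 2): number of leading nucleotides
#'   skipped before the first codon.
#' @param code A [genetic_code()] object. Defaults to table 5.
#' @return A list with `peptide` (character string, stops shown as `"*"`)
#'   and `stops` (integer vector of 0-based peptide indices of stop codons).
#' @examples
#' translate_nt("ATGTGA")$peptide          # "MW": TGA is Trp in table 5
#' translate_nt("ATGTAA")$stops            # 1
#' @export
translate_nt <- function(nt, frame = 0L, code = genetic_code(5L)) {
  stopifnot(is.character(nt), length(nt) == 1L)
  nt <- toupper(nt)
  if (grepl("-", nt, fixed = TRUE)) {
    stop("translate_nt() requires a gap-free sequence")
  }
  frame <- as.integer(frame)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  if (frame >= nchar(nt)) stop("frame offset beyond sequence length")
  eff <- substr(nt, frame + 1L, nchar(nt))
  n_codon <- nchar(eff) %/% 3L
  if (n_codon == 0L) stop("no complete codon to translate")
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  cod <- substring(eff, starts, starts + 2L)
  aa <- unname(code$codons[cod])
  aa[is.na(aa)] <- "X"  # any codon with a non-ACGT symbol
  list(
    peptide = paste(aa, collapse = ""),
    stops = which(aa == "*") - 1L
  )
}
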