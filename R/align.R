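# Pairwise global alignment of a query barcode against its nearest panel
# reference, with the barcode window mapped onto alignment columns.

# Ends-free Needleman-Wunsch via Biostrings (type "overlap": flanking
# primer sequence overhangs the reference at no cost, as appropriate for an
# amplicon against a barcode-window reference) with the package's scoring
# scheme: match +1, mismatch -1, gap open -5, gap extend -1 (penalties
# passed as positive costs, Biostrings convention). Ambiguity codes score
# via the IUPAC fuzzy matrix. The returned aligned rows are clipped to the
# overlapping region; pattern_start/subject_start give the 1-based
# coordinate of the first aligned position in each sequence.
.nw_align <- function(pattern, subject, gap_open = 5, gap_ext = 1) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = "overlap", substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_ext
  )
  p <- as.character(Biostrings::alignedPattern(al))
  s <- as.character(Biostrings::alignedSubject(al))
  list(
    pattern = p, subject = s,
    pattern_chars = strsplit(p, "")[[1L]],
    subject_chars = strsplit(s, "")[[1L]],
    pattern_start = Biostrings::start(Biostrings::pattern(al)),
    pattern_end = Biostrings::end(Biostrings::pattern(al)),
    subject_start = Biostrings::start(Biostrings::subject(al)),
    subject_end = Biostrings::end(Biostrings::subject(al)),
    score = Biostrings::score(al)
  )
}

# Columns of a clipped alignment covering subject window [ws, we)
# (0-based, half-open): first/last columns holding subject positions
# ws+1 .. we. `complete` records whether the full window is inside the
# aligned region. NULL when the window is entirely absent.
.window_columns <- function(al, ws, we) {
  sch <- al$subject_chars
  spos <- al$subject_start - 1L + cumsum(sch != "-")
  hit <- which(sch != "-" & spos > ws & spos <= we)
  if (length(hit) == 0L) return(NULL)
  list(first = hit[1L], last = hit[length(hit)],
       complete = al$subject_start <= ws + 1L && al$subject_end >= we)
}

.kmer_set <- function(nt, k) {
  n <- nchar(nt)
  if (n < k) return(character(0))
  unique(substring(nt, 1:(n - k + 1L), k:n))
}

#' Align a query barcode against its nearest panel reference
#'
#' Selects the panel reference sharing the most k-mers with the query (ties
#' broken by lexicographic reference id), aligns the pair globally
#' (Needleman-Wunsch: match +1, mismatch -1, gap open -5, gap extend -1) and
#' maps the panel's 651-nt barcode window onto the alignment columns.
#'
#' @param query Single nucleotide string (or length-1 named character
#'   vector), at least 400 nt.
#' @param panel A [build_panel()] object.
#' @param k K-mer length for nearest-reference selection (default 8).
#' @param min_identity Minimum fraction of identical window positions below
#'   which the query is reported unalignable (default 0.70).
#' @return An object of class `query_alignment`: aligned query/reference
#'   rows, the window column span, 0-based window-relative gap positions for
#'   each row, whether the query spans the full window, and window identity.
#' @export
align_query <- function(query, panel, k = 8L, min_identity = 0.70) {
  stopifnot(inherits(panel, "reference_panel"))
  query_id <- if (!is.null(names(query))) names(query)[1L] else NA_character_
  query <- toupper(as.character(query)[1L])
  if (nchar(query) < 400L) {
    stop("query shorter than 400 nt (", nchar(query), ")")
  }

  shared <- vapply(panel$entries$nt, function(ref) {
    length(intersect(.kmer_set(query, k), .kmer_set(ref, k)))
  }, integer(1))
  ord <- order(-shared, panel$entries$id)
  ref_i <- ord[1L]
  ref_id <- panel$entries$id[ref_i]

  al <- .nw_align(query, panel$entries$nt[ref_i])
  win <- panel$ref_window[[ref_id]]
  cols <- .window_columns(al, win[1L], win[2L])
  base <- list(
    query_id = query_id,
    ref_id = ref_id,
    ref_species = panel$entries$species[ref_i],
    aligned_query = al$pattern,
    aligned_ref = al$subject,
    query_start = al$pattern_start,
    ref_start = al$subject_start,
    window_cols = c(first = NA_integer_, last = NA_integer_),
    spans_window = FALSE,
    query_gaps = integer(0),
    ref_gaps = integer(0),
    identity = 0,
    unalignable = TRUE
  )
  if (is.null(cols)) {
    return(structure(base, class = "query_alignment"))
  }
  span <- seq.int(cols$first, cols$last)
  pch <- al$pattern_chars
  sch <- al$subject_chars

  # window-relative 0-based offsets of gap columns (either row)
  rel <- function(colidx) colidx - cols$first
  base$window_cols <- c(first = cols$first, last = cols$last)
  base$spans_window <- cols$complete
  base$query_gaps <- rel(span[pch[span] == "-"])
  base$ref_gaps <- rel(span[sch[span] == "-"])
  base$identity <- sum(pch[span] == sch[span] & pch[span] != "-") / 651
  base$unalignable <- base$identity < min_identity
  structure(base, class = "query_alignment")
}

#' @export
print.query_alignment <- function(x, ...) {
  cat("Query", x$query_id, "vs reference", x$ref_id,
      sprintf("(%s), window identity %.1f%%\n", x$ref_species, 100 * x$identity))
  cat("Window gaps: query", length(x$query_gaps),
      "| reference", length(x$ref_gaps),
      "| spans window:", x$spans_window, "\n")
  invisible(x)
}
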