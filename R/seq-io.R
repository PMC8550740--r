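#' Read nucleotide barcodes from a FASTA file
#'
#' Reads a (possibly wrapped) FASTA file of nucleotide sequences and returns
#' them as an uppercase named character vector, one element per entry, in
#' file order. Sequences may contain IUPAC ambiguity codes and gaps.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences; names are the
#'   full header lines (minus `>`), first whitespace-delimited token used
#'   as the id when headers carry descriptions.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) {
    stop("malformed FASTA at line 1: expected a '>' header, got: ",
         substr(lines[1L], 1, 40))
  }
  bad <- grep("[^ACGTRYSWKMBDHVN-]", toupper(lines[!hdr]))
  if (length(bad)) {
    # recover the original line number of the first offending sequence line
    seq_line_nos <- which(!hdr)
    stop("illegal sequence character at line ", seq_line_nos[bad[1L]],
         " of ", path)
  }
  grp <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  ids <- vapply(strsplit(ids, "[ \t]+"), `[`, character(1), 1L)
  seqs <- vapply(
    split(lines[!hdr], grp[!hdr]),
    function(x) toupper(paste(x, collapse = "")),
    character(1)
  )
  # entries with a header but no sequence line are empty strings
  out <- stats::setNames(character(length(ids)), ids)
  out[as.integer(names(seqs))] <- seqs
  if (any(!nzchar(out))) {
    stop("FASTA entry with empty sequence: ", ids[!nzchar(out)][1L])
  }
  if (anyDuplicated(ids)) {
    stop("duplicated sequence id in ", path, ": ", ids[duplicated(ids)][1L])
  }
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read whitefly collection records from a survey TSV
#'
#' A survey record describes one field sample: whiteflies aspirated from one
#' host plant at one site (by design three adult flies per sample). Required
#' columns: `sample_id`, `host_scientific`, `host_common`, `host_family`,
#' `region`, `lat`, `lon`, `whitefly_ids` (comma-separated sequence ids).
#' Hosts known only by a local common name may leave `host_scientific`
#' empty; it is recorded as `"Unknown"`.
#'
#' @param path Path to a tab-separated file with the documented header.
#' @return A data.frame with one row per sample and `whitefly_ids` as a
#'   list-column of character vectors.
#' @export
read_survey_records <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  required <- c("sample_id", "host_scientific", "host_common", "host_family",
                "region", "lat", "lon", "whitefly_ids")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("survey table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  for (cc in c("lat", "lon")) {
    v <- trimws(df[[cc]])
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & is.na(num))) {
      stop("non-numeric ", cc, " value: ", v[!is.na(v) & is.na(num)][1L])
    }
    df[[cc]] <- num
  }
  df$host_scientific[trimws(df$host_scientific) == ""] <- "Unknown"
  ids <- strsplit(df$whitefly_ids, ",[ \t]*")
  ids <- lapply(ids, function(x) x[nzchar(x)])
  if (any(lengths(ids) == 0L)) {
    stop("record with no whitefly ids: sample ",
         df$sample_id[lengths(ids) == 0L][1L])
  }
  all_ids <- unlist(ids)
  if (anyDuplicated(all_ids)) {
    stop("whitefly id linked to more than one sample: ",
         all_ids[duplicated(all_ids)][1L])
  }
  df$whitefly_ids <- I(ids)
  df
}

#' Write survey records to TSV
#'
#' Inverse of [read_survey_records()].
#'
#' @param records Data.frame as returned by [read_survey_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey_records <- function(records, path) {
  out <- records
  out$whitefly_ids <- vapply(records$whitefly_ids, paste, character(1),
                             collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
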