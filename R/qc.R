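# NUMT / pseudogene / PCR-artefact screening cascade.
#
# A candidate barcode passes only if, against its nearest reference, it
# (i) aligns over the full 651-nt barcode window with adequate identity,
# (ii) carries no indel inside the window, (iii) translates without a stop
# codon, and (iv) matches the panel consensus at every conserved amino-acid
# column. Failure statuses mirror the filter that caught the sequence.

.qc_statuses <- c("pass", "fail_indel", "fail_premature_stop",
                  "fail_conserved_violation", "fail_length")

#' Screen a windowed alignment for indels
#'
#' Fails iff any gap column (in either row) falls inside the barcode
#' window; gaps confined to the flanking primer regions are ignored,
#' since the barcode is trimmed to the window before translation.
#'
#' @param aln A [align_query()] result covering the barcode window.
#' @return List with `status` (`"pass"` or `"fail_indel"`) and `gap_positions`
#'   (0-based window-relative alignment columns).
#' @export
screen_indels <- function(aln) {
  stopifnot(inherits(aln, "query_alignment"))
  gaps <- sort(unique(c(aln$query_gaps, aln$ref_gaps)))
  list(
    status = if (length(gaps)) "fail_indel" else "pass",
    gap_positions = gaps
  )
}

#' Trim an aligned query to the 651-nt barcode
#'
#' Extracts the query nucleotides at the window columns. Requires an
#' indel-free window ([screen_indels()] passed) that the query fully spans.
#'
#' @param aln A [align_query()] result.
#' @return List with `nt` (651-nt string) and `frame` (always 0: the window
#'   starts on a codon boundary by construction).
#' @export
trim_to_barcode <- function(aln) {
  stopifnot(inherits(aln, "query_alignment"))
  if (!aln$spans_window) {
    stop("query does not span the full barcode window")
  }
  if (length(aln$query_gaps) || length(aln$ref_gaps)) {
    stop("window contains indels; run screen_indels() first")
  }
  cols <- seq.int(aln$window_cols["first"], aln$window_cols["last"])
  nt <- paste(strsplit(aln$aligned_query, "")[[1L]][cols], collapse = "")
  if (nchar(nt) != 651L) stop("trimmed barcode is not 651 nt")
  list(nt = nt, frame = 0L)
}

#' Screen a trimmed barcode's translation
#'
#' Translates the 651-nt barcode in frame 0 under the panel's genetic code
#' and checks for premature stop codons, then for substitutions at
#' conserved amino-acid columns of the reference profile.
#'
#' @param trimmed_nt 651-nt barcode string.
#' @param panel A [build_panel()] object.
#' @return List with `status`, `peptide` and `diagnostics` (data.frame of
#'   0-based peptide positions and details).
#' @export
screen_peptide <- function(trimmed_nt, panel) {
  stopifnot(inherits(panel, "reference_panel"), nchar(trimmed_nt) == 651L)
  tr <- translate_nt(trimmed_nt, 0L, panel$code)
  if (length(tr$stops)) {
    return(list(
      status = "fail_premature_stop",
      peptide = tr$peptide,
      diagnostics = data.frame(position = tr$stops, detail = "stop codon")
    ))
  }
  aa <- strsplit(tr$peptide, "")[[1L]]
  bad <- which(panel$conserved_mask & aa != panel$consensus_aa & aa != "X")
  if (length(bad)) {
    return(list(
      status = "fail_conserved_violation",
      peptide = tr$peptide,
      diagnostics = data.frame(
        position = bad - 1L,
        detail = paste0(panel$consensus_aa[bad], "->", aa[bad])
      )
    ))
  }
  list(status = "pass", peptide = tr$peptide,
       diagnostics = data.frame(position = integer(0), detail = character(0)))
}

#' Run the full QC cascade over a batch of candidate barcodes
#'
#' Each query receives exactly one status; per-sequence failures never abort
#' the batch. Sequences shorter than `min_length`, not spanning the window,
#' or below `min_identity` window identity are reported as `fail_length`.
#'
#' @param queries Named character vector of candidate barcode sequences.
#' @param panel A [build_panel()] object.
#' @param min_length Minimum query length (default 400 nt).
#' @param min_identity Window identity below which a query is unalignable
#'   (default 0.70).
#' @return An object of class `qc_report`: `results` data.frame (`seq_id`,
#'   `status`, `frame_offset`, `trimmed_nt`, `peptide`, `diagnostics`) and a
#'   `summary` named integer vector over all statuses.
#' @export
qc_pipeline <- function(queries, panel, min_length = 400L, min_identity = 0.70) {
  stopifnot(inherits(panel, "reference_panel"))
  n <- length(queries)
  ids <- names(queries)
  if (n > 0L && is.null(ids)) stop("queries must be named")
  res <- data.frame(
    seq_id = character(n), status = character(n),
    frame_offset = rep(NA_integer_, n), trimmed_nt = rep(NA_character_, n),
    peptide = rep(NA_character_, n), diagnostics = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    res$seq_id[i] <- ids[i]
    q <- queries[[i]]
    if (nchar(q) < min_length) {
      res$status[i] <- "fail_length"
      res$diagnostics[i] <- sprintf("length %d < %d", nchar(q), min_length)
      next
    }
    aln <- align_query(stats::setNames(q, ids[i]), panel,
                       min_identity = min_identity)
    if (aln$unalignable) {
      res$status[i] <- "fail_length"
      res$diagnostics[i] <- sprintf("window identity %.1f%% below threshold",
                                    100 * aln$identity)
      next
    }
    if (!aln$spans_window) {
      res$status[i] <- "fail_length"
      res$diagnostics[i] <- "query does not span full barcode window"
      next
    }
    ind <- screen_indels(aln)
    if (ind$status == "fail_indel") {
      res$status[i] <- "fail_indel"
      res$diagnostics[i] <- paste("gap at window offset",
                                  paste(ind$gap_positions, collapse = ","))
      next
    }
    trimmed <- trim_to_barcode(aln)
    pep <- screen_peptide(trimmed$nt, panel)
    res$status[i] <- pep$status
    res$frame_offset[i] <- trimmed$frame
    res$peptide[i] <- pep$peptide
    if (pep$status == "pass") {
      res$trimmed_nt[i] <- trimmed$nt
      res$diagnostics[i] <- ""
    } else {
      res$diagnostics[i] <- paste(pep$diagnostics$detail, "at",
                                  pep$diagnostics$position, collapse = "; ")
    }
  }
  summary <- stats::setNames(integer(length(.qc_statuses)), .qc_statuses)
  tab <- table(res$status)
  summary[names(tab)] <- as.integer(tab)
  structure(list(results = res, summary = summary), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", nrow(x$results), "sequences\n")
  for (s in names(x$summary)) {
    if (x$summary[s] > 0L) cat(sprintf("  %-26s %d\n", s, x$summary[s]))
  }
  invisible(x)
}

#' Extract passing trimmed barcodes from a QC report
#'
#' @param report A [qc_pipeline()] report.
#' @return Named character vector of 651-nt trimmed barcodes.
#' @export
qc_passing <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  ok <- report$results$status == "pass"
  stats::setNames(report$results$trimmed_nt[ok], report$results$seq_id[ok])
}

#' Write a QC report to disk
#'
#' Writes the per-sequence verdicts as JSON and the status summary as TSV.
#'
#' @param report A [qc_pipeline()] report.
#' @param json_path Path for the per-sequence JSON report.
#' @param summary_path Optional path for the TSV status summary.
#' @return `json_path`, invisibly.
#' @export
write_qc_report <- function(report, json_path, summary_path = NULL) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(report$results, json_path, dataframe = "rows",
                       na = "null", auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(summary_path)) {
    utils::write.table(
      data.frame(status = names(report$summary), n = unname(report$summary)),
      summary_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(json_path)
}
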