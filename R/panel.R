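#' Build a reference panel for barcode QC
#'
#' A reference panel holds species-labelled, gap-free reference sequences
#' (typically derived from high-throughput-sequenced full mitogenomes),
#' a fixed 651-nt barcode window anchored on one reference, the aligned
#' amino-acid profile of that window (217 residues) and the conserved-site
#' mask used by the pseudogene screen. A column of the amino-acid profile is
#' marked conserved when every panel member carries the same residue there;
#' query peptides must not deviate at conserved columns.
#'
#' Every reference is aligned to the anchor to map the window into its own
#' coordinates. References that cannot be aligned over at least
#' `min_coverage` of the window, that carry indels within the window, or
#' whose window translation contains a stop codon are rejected; rejections
#' are reported in the `rejected` attribute.
#'
#' @param refs Data.frame with columns `id`, `species`, `nt` and optionally
#'   `hlgg` (high-level genetic group of the reference, e.g. `"SSA"`,
#'   `"AMEA"`, `"NewWorld"`, `"Uganda"`).
#' @param window_anchor Id of the reference that fixes the barcode window.
#'   Defaults to the first reference.
#' @param window_start 0-based start of the 651-nt window on the anchor.
#' @param code Genetic code used for the amino-acid profile
#'   (default invertebrate mitochondrial, table 5).
#' @param min_coverage Minimum fraction of window positions a reference must
#'   align over (default 0.9).
#' @return An object of class `reference_panel`.
#' @export
build_panel <- function(refs, window_anchor = NULL, window_start = 0L,
                        code = genetic_code(5L), min_coverage = 0.9) {
  refs <- as.data.frame(refs, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "species", "nt") %in% names(refs)))
  if (nrow(refs) < 2L) {
    stop("a reference panel needs at least 2 entries to define a conserved mask")
  }
  if (anyDuplicated(refs$id)) stop("duplicated reference ids")
  if (any(!nzchar(refs$species))) stop("every species label must be non-empty")
  refs$nt <- toupper(refs$nt)
  if (any(grepl("-", refs$nt, fixed = TRUE))) {
    stop("reference sequences must be gap-free")
  }
  if (is.null(refs$hlgg)) refs$hlgg <- NA_character_
  if (is.null(window_anchor)) window_anchor <- refs$id[1L]
  if (!window_anchor %in% refs$id) stop("window anchor not in panel: ", window_anchor)

  window_start <- as.integer(window_start)
  window_end <- window_start + 651L
  anchor_nt <- refs$nt[refs$id == window_anchor]
  if (nchar(anchor_nt) < window_end) {
    stop("anchor shorter than window end (need ", window_end, " nt)")
  }

  window_nt <- stats::setNames(character(nrow(refs)), refs$id)
  ref_window <- stats::setNames(vector("list", nrow(refs)), refs$id)
  rejected <- data.frame(id = character(0), reason = character(0))
  reject <- function(id, reason) {
    rejected <<- rbind(rejected, data.frame(id = id, reason = reason))
  }

  for (i in seq_len(nrow(refs))) {
    id <- refs$id[i]
    if (id == window_anchor) {
      window_nt[id] <- substr(anchor_nt, window_start + 1L, window_end)
      ref_window[[id]] <- c(window_start, window_end)
      next
    }
    al <- .nw_align(refs$nt[i], anchor_nt)
    cols <- .window_columns(al, window_start, window_end)
    if (is.null(cols) || !cols$complete) { reject(id, "window not covered"); next }
    span <- seq.int(cols$first, cols$last)
    pch <- al$pattern_chars[span]
    sch <- al$subject_chars[span]
    covered <- sum(pch != "-" & sch != "-")
    if (covered < min_coverage * 651) { reject(id, "window coverage < 90%"); next }
    if (any(pch == "-") || any(sch == "-")) {
      reject(id, "indel within barcode window relative to anchor"); next
    }
    # map window to this reference's own coordinates (0-based half-open)
    ppos <- al$pattern_start - 1L + cumsum(al$pattern_chars != "-")
    ws_i <- ppos[cols$first] - 1L
    window_nt[id] <- substr(refs$nt[i], ws_i + 1L, ws_i + 651L)
    if (nchar(window_nt[id]) != 651L) { reject(id, "window truncated"); next }
    ref_window[[id]] <- c(ws_i, ws_i + 651L)
  }

  keep <- !refs$id %in% rejected$id
  refs <- refs[keep, , drop = FALSE]
  window_nt <- window_nt[refs$id]
  ref_window <- ref_window[refs$id]
  if (nrow(refs) < 2L) {
    stop("fewer than 2 references remain after window mapping; rejected: ",
         paste(rejected$id, rejected$reason, sep = ": ", collapse = "; "))
  }

  peptides <- lapply(window_nt, function(x) translate_nt(x, 0L, code))
  stops <- vapply(peptides, function(p) length(p$stops) > 0L, logical(1))
  if (any(stops)) {
    for (id in refs$id[stops]) reject(id, "stop codon in reference window")
    refs <- refs[!stops, , drop = FALSE]
    window_nt <- window_nt[refs$id]
    ref_window <- ref_window[refs$id]
    peptides <- peptides[refs$id]
    if (nrow(refs) < 2L) stop("fewer than 2 stop-free references remain")
  }

  aa_profile <- vapply(peptides, function(p) strsplit(p$peptide, "")[[1L]],
                       character(217L))
  conserved_mask <- apply(aa_profile, 1L, function(r) length(unique(r)) == 1L)
  consensus_aa <- apply(aa_profile, 1L, function(r) {
    names(sort(table(r), decreasing = TRUE))[1L]
  })

  structure(
    list(
      entries = refs[, c("id", "species", "hlgg", "nt")],
      anchor = window_anchor,
      window = c(start = window_start, end = window_end),
      window_nt = window_nt,
      ref_window = ref_window,
      aa_profile = aa_profile,
      conserved_mask = conserved_mask,
      consensus_aa = consensus_aa,
      code = code
    ),
    class = "reference_panel",
    rejected = rejected
  )
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("Reference panel:", nrow(x$entries), "entries,",
      length(unique(x$entries$species)), "species\n")
  cat("Barcode window: [", x$window[1], ", ", x$window[2], ") on anchor ",
      x$anchor, "\n", sep = "")
  cat("Conserved amino-acid columns:", sum(x$conserved_mask), "of 217\n")
  rej <- attr(x, "rejected")
  if (nrow(rej)) cat("Rejected references:", nrow(rej), "\n")
  invisible(x)
}

#' Read a reference panel FASTA
#'
#' Headers follow the convention `id|species|hlgg` (hlgg optional).
#'
#' @param path FASTA path.
#' @return Data.frame with columns `id`, `species`, `hlgg`, `nt`, suitable
#'   for [build_panel()].
#' @export
read_panel_fasta <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  data.frame(
    id = vapply(parts, `[`, character(1), 1L),
    species = vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_,
                     character(1)),
    hlgg = vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_,
                  character(1)),
    nt = unname(seqs),
    stringsAsFactors = FALSE
  )
}
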