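# Threshold-based species assignment: a QC-passing barcode is called as the
# species of its nearest reference when the minimum divergence is below the
# species threshold (default 4%), and otherwise delimited as a novel
# putative species. Novel sequences are grouped by single linkage at the
# same threshold and named by extending the SSA / B. Uganda numbering of
# the reference panel.

.divergence_to_refs <- function(query_nt, panel, metric) {
  vapply(seq_len(nrow(panel$entries)), function(i) {
    ref_win <- panel$window_nt[[panel$entries$id[i]]]
    tryCatch(
      switch(metric,
             p_distance = p_distance(query_nt, ref_win)$p,
             tajima_nei = tajima_nei(query_nt, ref_win)$d),
      error = function(e) NA_real_
    )
  }, numeric(1))
}

#' Assign one barcode to a known species or flag it as novel
#'
#' The nearest panel reference (by p-distance over the 651-nt barcode, with
#' pairwise deletion) determines the call: the reference's species when the
#' minimum divergence is strictly below `threshold`, `"novel"` otherwise
#' (a barcode at exactly the threshold is novel). Distance ties are broken
#' by lexicographic reference id and flagged.
#'
#' @param query Named (or unnamed) 651-nt QC-passing barcode.
#' @param panel A [build_panel()] object.
#' @param threshold Divergence threshold as a fraction (default 0.04).
#' @param metric `"p_distance"` (barcoding convention, default) or
#'   `"tajima_nei"`.
#' @return One-row data.frame: `seq_id`, `call`, `nearest_ref`,
#'   `min_divergence`, `hlgg` (inherited from the nearest reference),
#'   `tie` flag.
#' @export
assign_species <- function(query, panel, threshold = 0.04,
                           metric = c("p_distance", "tajima_nei")) {
  metric <- match.arg(metric)
  stopifnot(inherits(panel, "reference_panel"))
  seq_id <- if (!is.null(names(query))) names(query)[1L] else NA_character_
  d <- .divergence_to_refs(toupper(as.character(query)[1L]), panel, metric)
  if (all(is.na(d))) {
    stop("divergence undefined against every reference; query unassignable")
  }
  ord <- order(d, panel$entries$id, na.last = TRUE)
  best <- ord[1L]
  tie <- sum(d == d[best], na.rm = TRUE) > 1L
  known <- d[best] < threshold
  data.frame(
    seq_id = seq_id,
    call = if (known) panel$entries$species[best] else "novel",
    nearest_ref = panel$entries$id[best],
    min_divergence = d[best],
    hlgg = panel$entries$hlgg[best],
    tie = tie,
    stringsAsFactors = FALSE
  )
}

# single-linkage grouping at strictly-below-threshold divergence via
# union-find; exact ("< threshold") semantics, no dendrogram cut involved
.single_linkage_groups <- function(seqs, threshold) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (p_distance(seqs[[i]], seqs[[j]])$p < threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Group novel barcodes into putative species by single linkage
#'
#' Novel sequences (all at `>= threshold` divergence from every reference)
#' are linked whenever their pairwise p-distance is strictly below the
#' threshold; connected components form the putative species. Groups are
#' ordered canonically by their lexicographically smallest member id, so
#' labels are independent of input order. A group whose nearest reference
#' lies inside the *B. tabaci* complex (any HLGG except `"Uganda"`)
#' continues the SSA numbering (SSA14, SSA15, ...); other groups continue
#' the B. Uganda numbering.
#'
#' @param novel_seqs Named character vector of 651-nt novel barcodes.
#' @param panel A [build_panel()] object (provides naming context).
#' @param threshold Divergence threshold as a fraction (default 0.04).
#' @param tabaci_hlggs HLGG labels treated as inside the *B. tabaci*
#'   complex for naming purposes.
#' @return Data.frame `seq_id`, `group`, `nearest_ref`, `hlgg`.
#' @export
cluster_novel <- function(novel_seqs, panel, threshold = 0.04,
                          tabaci_hlggs = c("SSA", "AMEA", "NewWorld")) {
  if (length(novel_seqs) == 0L) {
    return(data.frame(seq_id = character(0), group = character(0),
                      nearest_ref = character(0), hlgg = character(0)))
  }
  stopifnot(!is.null(names(novel_seqs)))
  comp <- .single_linkage_groups(novel_seqs, threshold)
  # canonical order: by smallest member id within each component
  comp_ids <- split(names(novel_seqs), comp)
  first_member <- vapply(comp_ids, function(x) sort(x)[1L], character(1))
  comp_order <- names(comp_ids)[order(first_member)]

  next_number <- function(pattern, labels) {
    hits <- regmatches(labels, regexpr(pattern, labels))
    nums <- suppressWarnings(as.integer(sub("\\D+", "", hits)))
    if (length(nums) == 0L || all(is.na(nums))) 1L else max(nums, na.rm = TRUE) + 1L
  }
  ssa_next <- next_number("SSA\\d+", panel$entries$species)
  ug_next <- next_number("Uganda\\d+", panel$entries$species)

  out <- data.frame(seq_id = names(novel_seqs), group = NA_character_,
                    nearest_ref = NA_character_, hlgg = NA_character_,
                    stringsAsFactors = FALSE)
  for (cid in comp_order) {
    members <- comp_ids[[cid]]
    idx <- match(members, names(novel_seqs))
    # group-level nearest reference: the closest reference to any member
    d <- sapply(idx, function(i)
      .divergence_to_refs(novel_seqs[[i]], panel, "p_distance"))
    d <- matrix(d, nrow = nrow(panel$entries))
    best_ref <- which.min(apply(d, 1L, min, na.rm = TRUE))
    hlgg <- panel$entries$hlgg[best_ref]
    in_tabaci <- !is.na(hlgg) && hlgg %in% tabaci_hlggs
    if (in_tabaci) {
      label <- paste0("SSA", ssa_next); ssa_next <- ssa_next + 1L
    } else {
      label <- paste0("B. Uganda", ug_next); ug_next <- ug_next + 1L
    }
    out$group[idx] <- label
    out$nearest_ref[idx] <- panel$entries$id[best_ref]
    out$hlgg[idx] <- hlgg
  }
  out
}

#' Assign an SSA1 subgroup (or other within-species subgroup)
#'
#' Subgroups (~1-1.5% mtCO1 divergence apart, e.g. SSA1-SG1/SG2/SG3) are
#' called by nearest subgroup reference; ties go to the lexicographically
#' smallest label and are flagged. The margin to the second-best subgroup
#' is reported.
#'
#' @param query 651-nt barcode.
#' @param subgroup_refs Named character vector: subgroup label -> reference
#'   barcode sequence. `NULL` or empty yields subgroup `NA`.
#' @return One-row data.frame: `subgroup`, `margin`, `tie`.
#' @export
assign_subgroup <- function(query, subgroup_refs = NULL) {
  if (is.null(subgroup_refs) || length(subgroup_refs) == 0L) {
    return(data.frame(subgroup = NA_character_, margin = NA_real_, tie = FALSE))
  }
  q <- toupper(as.character(query)[1L])
  d <- vapply(subgroup_refs, function(r) p_distance(q, r)$p, numeric(1))
  ord <- order(d, names(subgroup_refs))
  best <- ord[1L]
  margin <- if (length(d) > 1L) d[ord[2L]] - d[best] else NA_real_
  data.frame(
    subgroup = names(subgroup_refs)[best],
    margin = margin,
    tie = sum(d == d[best]) > 1L,
    stringsAsFactors = FALSE
  )
}

#' Assign a full batch of QC-passing barcodes
#'
#' Runs [assign_species()] on every query, groups the novel ones with
#' [cluster_novel()], optionally refines calls with subgroup references,
#' and tallies calls.
#'
#' @param queries Named character vector of 651-nt barcodes.
#' @param panel A [build_panel()] object.
#' @param threshold Divergence threshold (default 0.04).
#' @param subgroup_refs Optional named list: species -> named vector of
#'   subgroup reference barcodes (e.g. `list(SSA1 = c(SG1 = ..., ...))`).
#' @param metric Divergence measure, see [assign_species()].
#' @return Object of class `assignment_set`: `assignments` data.frame
#'   (`seq_id`, `call`, `subgroup`, `nearest_ref`, `min_divergence`,
#'   `margin`, `hlgg`, `novel`, `tie`) and `tally` (named integer vector,
#'   rows summing to the number of queries).
#' @export
assign_all <- function(queries, panel, threshold = 0.04,
                       subgroup_refs = NULL,
                       metric = c("p_distance", "tajima_nei")) {
  metric <- match.arg(metric)
  if (length(queries) == 0L) {
    asn <- data.frame(seq_id = character(0), call = character(0),
                      subgroup = character(0), nearest_ref = character(0),
                      min_divergence = numeric(0), margin = numeric(0),
                      hlgg = character(0), novel = logical(0), tie = logical(0))
    return(structure(list(assignments = asn, tally = integer(0)),
                     class = "assignment_set"))
  }
  rows <- lapply(seq_along(queries), function(i) {
    assign_species(queries[i], panel, threshold, metric)
  })
  asn <- do.call(rbind, rows)
  asn$novel <- asn$call == "novel"
  asn$subgroup <- NA_character_
  asn$margin <- NA_real_

  if (any(asn$novel)) {
    grp <- cluster_novel(queries[asn$novel], panel, threshold)
    asn$call[asn$novel] <- grp$group[match(asn$seq_id[asn$novel], grp$seq_id)]
  }
  if (!is.null(subgroup_refs)) {
    for (sp in names(subgroup_refs)) {
      hit <- which(asn$call == sp)
      for (i in hit) {
        sg <- assign_subgroup(queries[[i]], subgroup_refs[[sp]])
        asn$subgroup[i] <- sg$subgroup
        asn$margin[i] <- sg$margin
        asn$tie[i] <- asn$tie[i] | sg$tie
      }
    }
  }
  tally_names <- asn$call
  has_sg <- !is.na(asn$subgroup)
  tally_names[has_sg] <- paste(asn$call[has_sg], asn$subgroup[has_sg],
                               sep = "-")
  tally <- table(tally_names)
  tally <- stats::setNames(as.integer(tally), names(tally))
  structure(list(assignments = asn, tally = tally), class = "assignment_set")
}

#' @export
print.assignment_set <- function(x, ...) {
  cat("Species assignments:", nrow(x$assignments), "barcodes,",
      sum(x$assignments$novel), "novel\n")
  print(x$tally)
  invisible(x)
}

#' Write assignments and tally to TSV
#'
#' @param aset An [assign_all()] result.
#' @param assignments_path,tally_path Output paths (either may be `NULL`).
#' @return `assignments_path`, invisibly.
#' @export
write_assignments <- function(aset, assignments_path, tally_path = NULL) {
  stopifnot(inherits(aset, "assignment_set"))
  utils::write.table(aset$assignments, assignments_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(tally_path)) {
    utils::write.table(
      data.frame(call = names(aset$tally), n = unname(aset$tally)),
      tally_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(assignments_path)
}
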