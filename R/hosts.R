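# Host-plant association analyses: host x species count matrices and the
# summaries derived from them (composition percentages, minimum-support
# association tables, mixed-sample fractions).

#' Build a host x species count matrix from records and assignments
#'
#' Tallies assigned whiteflies by `(host_scientific, call)`. Hosts declared
#' in the records but carrying no assigned fly appear as explicit all-zero
#' rows, and every assignment must trace back to exactly one record.
#'
#' @param records Survey records ([read_survey_records()]).
#' @param assignments An [assign_all()] result or its `assignments`
#'   data.frame.
#' @param split_subgroups If `TRUE` (default), species with subgroup calls
#'   get one column per subgroup (e.g. `SSA1-SG1`).
#' @return Integer matrix (hosts x species) with a `total_n` attribute.
#' @export
build_count_matrix <- function(records, assignments, split_subgroups = TRUE) {
  if (inherits(assignments, "assignment_set")) {
    assignments <- assignments$assignments
  }
  id2sample <- rep(records$sample_id, lengths(records$whitefly_ids))
  names(id2sample) <- unlist(records$whitefly_ids)
  orphan <- setdiff(assignments$seq_id, names(id2sample))
  if (length(orphan)) {
    stop("assignment(s) with no survey record: ",
         paste(orphan, collapse = ", "))
  }
  host_of <- stats::setNames(records$host_scientific, records$sample_id)
  hosts <- sort(unique(records$host_scientific))
  col_label <- assignments$call
  if (split_subgroups && !is.null(assignments$subgroup)) {
    has_sg <- !is.na(assignments$subgroup)
    col_label[has_sg] <- paste(assignments$call[has_sg],
                               assignments$subgroup[has_sg], sep = "-")
  }
  species <- sort(unique(col_label))
  m <- matrix(0L, length(hosts), length(species),
              dimnames = list(hosts, species))
  if (nrow(assignments)) {
    h <- host_of[id2sample[assignments$seq_id]]
    tab <- table(factor(h, hosts), factor(col_label, species))
    m[] <- as.integer(tab)
  }
  attr(m, "total_n") <- sum(m)
  m
}

#' Read a host x species count matrix from TSV
#'
#' Expects columns `host_scientific`, `host_common`, `host_family` followed
#' by one integer column per species.
#'
#' @param path TSV path.
#' @return Integer count matrix with host metadata in the `host_info`
#'   attribute and `total_n` set.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta_cols <- c("host_scientific", "host_common", "host_family")
  if (!all(meta_cols %in% names(df))) {
    stop("count matrix must carry columns: ", paste(meta_cols, collapse = ", "))
  }
  counts <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("species columns must be non-negative integer counts")
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$host_scientific
  attr(counts, "host_info") <- df[, meta_cols]
  attr(counts, "total_n") <- sum(counts)
  counts
}

#' The Uganda 2013 whitefly survey count matrix
#'
#' Host x species counts of the 870 classified whiteflies from the
#' 2013 Uganda field survey (previously described species plus the novel
#' SSA14-SSA16 and B. Uganda2-5 putative species), shipped with the package
#' as a plain-text fixture. SSA1 is split into its SG1/SG2/SG3 subgroups.
#'
#' @return Integer count matrix (hosts x species).
#' @export
uganda_counts <- function() {
  read_count_matrix(system.file("extdata", "uganda_survey_counts.tsv",
                                package = "whiteflyCOI", mustWork = TRUE))
}

#' High-level genetic group of each species in the Uganda survey
#'
#' Maps the species column labels of [uganda_counts()] to their high-level
#' genetic group: `SSA`, `AMEA` (Africa-Middle East-Asia Minor),
#' `NewWorld`, or `Uganda` (the non-*tabaci* clade).
#'
#' @return Named character vector: species label -> HLGG.
#' @export
uganda_hlgg <- function() {
  c(
    "SSA1-SG1" = "SSA", "SSA1-SG2" = "SSA", "SSA1-SG3" = "SSA",
    "SSA2" = "SSA", "SSA6" = "SSA", "SSA9" = "SSA", "SSA16" = "SSA",
    "SSA10" = "NewWorld", "SSA14" = "NewWorld", "SSA15" = "NewWorld",
    "SSA11" = "AMEA", "SSA12" = "AMEA", "SSA13" = "AMEA",
    "MED-ASL" = "AMEA", "MED-Q1" = "AMEA", "MEAM1" = "AMEA",
    "MEAM2" = "AMEA", "IO" = "AMEA", "EA1" = "AMEA",
    "B. Uganda1" = "Uganda", "B. Uganda2" = "Uganda",
    "B. Uganda3" = "Uganda", "B. Uganda4" = "Uganda",
    "B. Uganda5" = "Uganda"
  )
}

#' Percentage composition of species in a count matrix
#'
#' @param m Host x species count matrix.
#' @return Named numeric vector of percentages summing to 100 exactly
#'   (before any rounding).
#' @export
composition_percentages <- function(m) {
  total <- sum(m)
  if (total == 0) stop("empty count matrix: composition undefined")
  100 * colSums(m) / total
}

#' Minimum-support host-association table
#'
#' Keeps only host x species cells supported by at least `min_n`
#' whiteflies (the "at least 3" rule used to call host associations) and
#' drops hosts with no surviving cell.
#'
#' @param m Host x species count matrix.
#' @param min_n Minimum whiteflies per retained cell (default 3).
#' @return Matrix with unsupported cells zeroed and unsupported hosts
#'   dropped.
#' @export
min_support_table <- function(m, min_n = 3L) {
  keep <- m >= min_n
  out <- m
  out[!keep] <- 0L
  out[rowSums(keep) > 0L, , drop = FALSE]
}

#' Fraction of multi-fly samples containing more than one species
#'
#' Samples with at least two assigned flies are eligible; a sample counts
#' as mixed when its flies carry more than one distinct species call
#' (subgroups of one species do not make a sample mixed).
#'
#' @param records Survey records.
#' @param assignments An [assign_all()] result or its data.frame.
#' @return List: `fraction`, `n_mixed`, `n_eligible`.
#' @export
mixed_sample_fraction <- function(records, assignments) {
  if (inherits(assignments, "assignment_set")) {
    assignments <- assignments$assignments
  }
  id2sample <- rep(records$sample_id, lengths(records$whitefly_ids))
  names(id2sample) <- unlist(records$whitefly_ids)
  sample_of <- id2sample[assignments$seq_id]
  calls_by_sample <- split(assignments$call, sample_of)
  eligible <- calls_by_sample[lengths(calls_by_sample) >= 2L]
  if (length(eligible) == 0L) {
    stop("no samples with >= 2 assigned flies; mixed fraction undefined")
  }
  mixed <- vapply(eligible, function(x) length(unique(x)) > 1L, logical(1))
  list(fraction = mean(mixed), n_mixed = sum(mixed),
       n_eligible = length(eligible))
}
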