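# End-to-end orchestration: QC -> assignment -> host-association survey,
# driven by a single config object, with every parameter and seed logged to
# a run manifest so an identical analysis can be re-executed.

#' Assemble a pipeline configuration
#'
#' @param queries Path to the query FASTA.
#' @param panel Path to the reference panel FASTA (headers
#'   `id|species|hlgg`).
#' @param records Path to the survey TSV (optional; required by
#'   [run_survey()]).
#' @param outdir Output directory (created if missing).
#' @param threshold Species divergence threshold (default 0.04; must lie in
#'   (0, 0.5)).
#' @param window_start 0-based barcode window start on the panel anchor.
#' @param min_identity QC window identity floor (default 0.70).
#' @param metric,linkage Clustering distance and linkage.
#' @param k_range Candidate cluster counts (default 2:10).
#' @param scales,B Multiscale bootstrap scales and replicates.
#' @param au_cutoff Strong-support AU cutoff (default 0.83).
#' @param seed Seed for all stochastic steps (bootstrap).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(queries = NULL, panel = NULL, records = NULL,
                            outdir = ".", threshold = 0.04,
                            window_start = 0L, min_identity = 0.70,
                            metric = "euclidean", linkage = "average",
                            k_range = 2:10,
                            scales = seq(0.5, 1.4, by = 0.1), B = 1000L,
                            au_cutoff = 0.83, seed = 1L) {
  if (threshold <= 0 || threshold >= 0.5) stop("threshold must lie in (0, 0.5)")
  for (p in c(queries, panel, records)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(
    list(queries = queries, panel = panel, records = records,
         outdir = outdir, threshold = threshold,
         window_start = as.integer(window_start),
         min_identity = min_identity, metric = metric, linkage = linkage,
         k_range = k_range, scales = scales, B = as.integer(B),
         au_cutoff = au_cutoff, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

.ensure_outdir <- function(config) {
  if (!dir.exists(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE)
  }
  config$outdir
}

.write_manifest <- function(config, stage, extra = list()) {
  manifest <- c(list(stage = stage, timestamp = format(Sys.time())),
                config[!vapply(config, is.null, logical(1))], extra)
  path <- file.path(config$outdir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the QC stage of the pipeline
#'
#' Reads queries and panel from the config paths, runs [qc_pipeline()],
#' and writes the JSON report, TSV summary and passing-barcode FASTA to the
#' output directory.
#'
#' @param config A [pipeline_config()].
#' @return The `qc_report`, invisibly.
#' @export
run_qc <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  .ensure_outdir(config)
  queries <- read_fasta(config$queries)
  panel <- build_panel(read_panel_fasta(config$panel),
                       window_start = config$window_start)
  report <- qc_pipeline(queries, panel, min_identity = config$min_identity)
  write_qc_report(report,
                  file.path(config$outdir, "qc_report.json"),
                  file.path(config$outdir, "qc_summary.tsv"))
  passing <- qc_passing(report)
  if (length(passing)) {
    write_fasta(passing, file.path(config$outdir, "passing_barcodes.fasta"))
  }
  .write_manifest(config, "qc", list(n_input = length(queries),
                                     n_pass = length(passing)))
  message("QC: ", length(passing), "/", length(queries), " sequences passed")
  invisible(report)
}

#' Run the species-assignment stage
#'
#' Requires `run_qc()` outputs in the config output directory; writes the
#' assignments and tally TSVs.
#'
#' @param config A [pipeline_config()].
#' @return The `assignment_set`, invisibly.
#' @export
run_assign <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  passing_path <- file.path(config$outdir, "passing_barcodes.fasta")
  if (!file.exists(passing_path)) {
    stop("no QC output found in ", config$outdir, "; run run_qc() first")
  }
  passing <- read_fasta(passing_path)
  panel <- build_panel(read_panel_fasta(config$panel),
                       window_start = config$window_start)
  aset <- assign_all(passing, panel, threshold = config$threshold)
  write_assignments(aset,
                    file.path(config$outdir, "assignments.tsv"),
                    file.path(config$outdir, "species_tally.tsv"))
  .write_manifest(config, "assign",
                  list(n_assigned = nrow(aset$assignments),
                       n_novel = sum(aset$assignments$novel)))
  message("Assignment: ", nrow(aset$assignments), " barcodes, ",
          sum(aset$assignments$novel), " novel")
  invisible(aset)
}

#' Run the host-association survey stage
#'
#' Builds the host x species count matrix from the survey records and
#' assignments, then writes composition percentages, the minimum-support
#' association table, the mixed-sample fraction, dendrograms (Newick) with
#' optimal-k reports, and per-node AU support for both axes.
#'
#' @param config A [pipeline_config()].
#' @return List of stage results, invisibly.
#' @export
run_survey <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  asn_path <- file.path(config$outdir, "assignments.tsv")
  if (!file.exists(asn_path)) {
    stop("no assignment output found in ", config$outdir,
         "; run run_assign() first")
  }
  if (is.null(config$records)) stop("config$records is required for run_survey()")
  records <- read_survey_records(config$records)
  if (nrow(records) == 0L) stop("survey records are empty")
  assignments <- utils::read.delim(asn_path)

  m <- build_count_matrix(records, assignments)
  utils::write.table(m, file.path(config$outdir, "count_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  comp <- composition_percentages(m)
  utils::write.table(
    data.frame(species = names(comp), percent = round(comp, 1)),
    file.path(config$outdir, "composition.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  assoc <- min_support_table(m)
  utils::write.table(assoc, file.path(config$outdir, "associations_min3.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  mix <- tryCatch(mixed_sample_fraction(records, assignments),
                  error = function(e) NULL)

  cluster_out <- list()
  for (axis in c("hosts", "species")) {
    n_items <- if (axis == "hosts") nrow(m) else ncol(m)
    if (n_items < 3L) next
    hc <- hierarchical_cluster(m, axis, config$metric, config$linkage)
    write_dendrogram_newick(
      hc, file.path(config$outdir, paste0("dendrogram_", axis, ".nwk")))
    ok <- optimal_k(m, axis, config$k_range, config$metric, config$linkage)
    au <- au_bootstrap(m, axis, config$scales, config$B, config$seed,
                       config$metric, config$linkage, config$au_cutoff)
    write_node_support(
      au, file.path(config$outdir, paste0("node_support_", axis, ".tsv")))
    cluster_out[[axis]] <- list(hclust = hc, optimal_k = ok, au = au)
  }
  .write_manifest(config, "survey",
                  list(total_n = sum(m),
                       mixed_fraction = if (is.null(mix)) NA else mix$fraction))
  message("Survey: ", sum(m), " whiteflies across ", nrow(m), " hosts")
  invisible(list(matrix = m, composition = comp, associations = assoc,
                 mixed = mix, clustering = cluster_out))
}

#' Run the full pipeline (QC, assignment, survey)
#'
#' @param config A [pipeline_config()].
#' @return List with all stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  qc <- run_qc(config)
  aset <- run_assign(config)
  survey <- if (!is.null(config$records)) run_survey(config) else NULL
  invisible(list(qc = qc, assignments = aset, survey = survey))
}
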