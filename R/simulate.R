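# Ground-truthed synthetic data for every pipeline stage: species-structured
# reference panels and query barcodes, NUMT artefacts carrying planted
# defects, and host-survey records with known mixing and host-preference
# structure. All generators are deterministic under a fixed seed and return
# machine-readable truth tables.

.BASES <- c("A", "C", "G", "T")

# substitute one position, avoiding creation of an in-frame stop codon;
# with synonymous = TRUE the encoded amino acid must also be preserved.
# Returns the new character vector or NULL if no admissible base exists.
.substitute_base <- function(chars, pos, code, synonymous = FALSE) {
  old <- chars[pos]
  codon_i <- (pos - 1L) %/% 3L
  codon_idx <- codon_i * 3L + 1:3
  old_aa <- code$codons[[paste(chars[codon_idx], collapse = "")]]
  cand <- sample(setdiff(.BASES, old))
  for (nb in cand) {
    trial <- chars
    trial[pos] <- nb
    codon <- paste(trial[codon_idx], collapse = "")
    if (codon %in% code$stops) next
    if (synonymous && code$codons[[codon]] != old_aa) next
    return(trial)
  }
  NULL
}

# place exactly k substitutions drawn from `pool` positions, never hitting
# the same site twice and never creating a stop codon. synonymous_p is the
# probability each substitution is required to be synonymous (1 = strictly
# silent variation, as within-species barcode polymorphism mostly is).
.place_substitutions <- function(chars, k, pool, code, synonymous_p = 0) {
  used <- integer(0)
  tries <- 0L
  while (length(used) < k) {
    tries <- tries + 1L
    if (tries > 500L * max(k, 1L)) {
      stop("cannot place ", k, " admissible substitutions")
    }
    avail <- setdiff(pool, used)
    if (length(avail) == 0L) stop("substitution position pool exhausted")
    pos <- if (length(avail) == 1L) avail else sample(avail, 1L)
    want_syn <- stats::runif(1) < synonymous_p
    trial <- .substitute_base(chars, pos, code, synonymous = want_syn)
    if (is.null(trial)) next
    chars <- trial
    used <- c(used, pos)
  }
  list(chars = chars, positions = sort(used))
}

#' The synthetic 651-nt seed open reading frame
#'
#' A fixed, synthetic (not a real accession) 651-nt sequence with no stop
#' codon in frame 0 under the invertebrate mitochondrial code, shipped as a
#' plain-text fixture and used as the common ancestor for all simulated
#' panels.
#'
#' @return A single 651-nt string.
#' @export
seed_orf <- function() {
  unname(read_fasta(system.file("extdata", "synthetic_seed_orf.fasta",
                                package = "whiteflyCOI", mustWork = TRUE)))[1L]
}

#' Simulate a species-structured reference panel
#'
#' Each of `n_species` reference barcodes is derived from the seed ORF by
#' placing `round(inter_divergence * 651 / 2)` substitutions at positions
#' disjoint across species (and never creating a stop codon), so that every
#' species pair differs at `~ round(inter_divergence * 651)` sites and the
#' realised pairwise p-distance matches the target. Species are labelled
#' `SSA1 ... SSAn` with HLGG `"SSA"` by default so downstream novel-species
#' naming continues the panel's numbering.
#'
#' @param n_species Number of species (>= 2).
#' @param inter_divergence Target pairwise p-distance between species
#'   (default 0.08, twice the 4% species threshold).
#' @param seed Integer seed.
#' @param seed_sequence 651-nt stop-free ORF (default [seed_orf()]).
#' @param species_names Optional species labels.
#' @param hlgg HLGG label(s) for the references (default `"SSA"`).
#' @param code Genetic code (default table 5).
#' @return Object of class `sim_panel`: `refs` data.frame (`id`, `species`,
#'   `hlgg`, `nt`), the `seed_nt`, the set of `used_positions` (1-based)
#'   and the per-species substitution positions in `truth`.
#' @export
simulate_panel <- function(n_species, inter_divergence = 0.08, seed = 1L,
                           seed_sequence = seed_orf(),
                           species_names = NULL, hlgg = "SSA",
                           code = genetic_code(5L)) {
  stopifnot(n_species >= 1L, nchar(seed_sequence) == 651L)
  if (length(translate_nt(seed_sequence, 0L, code)$stops)) {
    stop("seed sequence must encode a stop-free ORF")
  }
  set.seed(as.integer(seed))
  k_each <- round(inter_divergence * 651 / 2)
  if (n_species * k_each > 651) stop("divergence target unattainable: too many species")
  if (is.null(species_names)) species_names <- paste0("SSA", seq_len(n_species))
  hlgg <- rep_len(hlgg, n_species)

  seed_chars <- strsplit(toupper(seed_sequence), "")[[1L]]
  used <- integer(0)
  refs <- data.frame(id = paste0("ref_", species_names),
                     species = species_names, hlgg = hlgg,
                     nt = NA_character_, stringsAsFactors = FALSE)
  truth <- vector("list", n_species)
  names(truth) <- species_names
  for (i in seq_len(n_species)) {
    res <- .place_substitutions(seed_chars, k_each,
                                setdiff(seq_len(651L), used), code,
                                synonymous_p = 0.5)
    used <- c(used, res$positions)
    truth[[i]] <- res$positions
    refs$nt[i] <- paste(res$chars, collapse = "")
  }
  structure(
    list(refs = refs, seed_nt = seed_sequence, used_positions = sort(used),
         truth = truth, inter_divergence = inter_divergence, code = code),
    class = "sim_panel"
  )
}

#' Simulate query barcodes around a panel's species
#'
#' Each query carries between 1 and `floor(intra_divergence * 651)`
#' synonymous (silent) substitutions relative to its species reference
#' (0 when `intra_divergence = 0`), placed outside the panel's
#' inter-species diagnostic positions, so queries stay within
#' `intra_divergence` of their own species, at least the full
#' inter-species distance from all others, and QC-clean (within-species
#' barcode polymorphism is modelled as silent variation: it can neither
#' introduce a stop codon nor touch a conserved amino-acid column).
#'
#' @param sim A [simulate_panel()] object.
#' @param per_species_n Queries per species.
#' @param intra_divergence Maximum within-species p-distance (default 0.01).
#' @param seed Integer seed.
#' @param species Subset of species to draw queries from (default all).
#' @param prefix Id prefix (default `"q"`).
#' @return List: `seqs` (named character vector) and `truth` data.frame
#'   (`seq_id`, `species`).
#' @export
simulate_queries <- function(sim, per_species_n, intra_divergence = 0.01,
                             seed = 1L, species = NULL, prefix = "q") {
  stopifnot(inherits(sim, "sim_panel"))
  set.seed(as.integer(seed))
  if (is.null(species)) species <- sim$refs$species
  max_sub <- floor(intra_divergence * 651)
  pool <- setdiff(seq_len(651L), sim$used_positions)
  seqs <- character(0)
  truth <- data.frame(seq_id = character(0), species = character(0))
  for (sp in species) {
    ref_chars <- strsplit(sim$refs$nt[sim$refs$species == sp], "")[[1L]]
    for (j in seq_len(per_species_n)) {
      k <- if (max_sub == 0L) 0L else sample.int(max_sub, 1L)
      chars <- if (k == 0L) ref_chars else {
        .place_substitutions(ref_chars, k, pool, sim$code,
                             synonymous_p = 1)$chars
      }
      id <- sprintf("%s_%s_%03d", prefix, gsub("[^A-Za-z0-9]", "", sp), j)
      seqs[id] <- paste(chars, collapse = "")
      truth <- rbind(truth, data.frame(seq_id = id, species = sp))
    }
  }
  list(seqs = seqs, truth = truth)
}

#' Simulate NUMT artefacts with planted defects
#'
#' Generates pseudogene-like sequences from random panel species, each
#' carrying at least one in-window defect: a 1-nt deletion (frameshift
#' indel) with probability `indel_p` and/or a premature stop codon
#' (a TAA codon planted away from the window ends) with probability
#' `stop_p`. Sequences with both defects are labelled `"both"`.
#'
#' @param sim A [simulate_panel()] object.
#' @param n Number of NUMTs.
#' @param indel_p,stop_p Defect probabilities; their sum must be positive.
#' @param seed Integer seed.
#' @return List: `seqs` and `truth` data.frame (`seq_id`, `species`,
#'   `defect`, `position` of the first planted defect, 0-based).
#' @export
simulate_numts <- function(sim, n, indel_p = 0.5, stop_p = 0.5, seed = 1L) {
  stopifnot(inherits(sim, "sim_panel"))
  if (indel_p + stop_p <= 0) stop("indel_p + stop_p must be positive")
  set.seed(as.integer(seed))
  seqs <- character(0)
  truth <- data.frame(seq_id = character(0), species = character(0),
                      defect = character(0), position = integer(0))
  for (j in seq_len(n)) {
    sp_i <- sample.int(nrow(sim$refs), 1L)
    chars <- strsplit(sim$refs$nt[sp_i], "")[[1L]]
    has_indel <- stats::runif(1) < indel_p
    has_stop <- stats::runif(1) < stop_p
    while (!has_indel && !has_stop) {
      has_indel <- stats::runif(1) < indel_p
      has_stop <- stats::runif(1) < stop_p
    }
    pos <- NA_integer_
    if (has_stop) {
      codon_i <- sample(2:215, 1L)  # interior codon, 0-based index
      chars[codon_i * 3L + 1:3] <- c("T", "A", "A")
      pos <- codon_i
    }
    if (has_indel) {
      del <- sample(50:600, 1L)
      if (is.na(pos)) pos <- del - 1L
      chars <- chars[-del]
    }
    defect <- if (has_indel && has_stop) "both" else if (has_indel) "indel" else "stop"
    id <- sprintf("numt_%03d", j)
    seqs[id] <- paste(chars, collapse = "")
    truth <- rbind(truth, data.frame(
      seq_id = id, species = sim$refs$species[sp_i],
      defect = defect, position = pos
    ))
  }
  list(seqs = seqs, truth = truth)
}

#' Simulate a host-plant survey with known mixing structure
#'
#' Emulates the field design: each sample is one host plant at one site
#' from which `flies_per_sample` adult whiteflies (3 by default) are
#' sequenced. With probability `mixing_p` a sample's flies are drawn from
#' two species (at least one fly from each); otherwise all flies belong to
#' one species. The sample's host is drawn from the primary species'
#' host-preference profile.
#'
#' @param sim A [simulate_panel()] object.
#' @param n_samples Number of samples.
#' @param flies_per_sample Flies sequenced per sample (default 3).
#' @param mixing_p Probability a sample mixes two species (default 0.4).
#' @param host_profiles Species x host matrix of preference probabilities
#'   (rows sum to 1). Defaults to one preferred host per species (weight
#'   0.7, remainder uniform over the other hosts).
#' @param intra_divergence Within-species query divergence (default 0.01).
#' @param seed Integer seed.
#' @return List: `records` (survey data.frame with `whitefly_ids`
#'   list-column), `seqs` (per-fly barcodes), `truth` data.frame
#'   (`seq_id`, `sample_id`, `species`, `host`), `truth_matrix`
#'   (host x species counts) and the realised `mixed_fraction`.
#' @export
simulate_survey <- function(sim, n_samples, flies_per_sample = 3L,
                            mixing_p = 0.4, host_profiles = NULL,
                            intra_divergence = 0.01, seed = 1L) {
  stopifnot(inherits(sim, "sim_panel"), n_samples >= 1L)
  species <- sim$refs$species
  if (is.null(host_profiles)) {
    n_sp <- length(species)
    hosts <- paste0("host_", seq_len(n_sp))
    host_profiles <- matrix((1 - 0.7) / (n_sp - 1), n_sp, n_sp,
                            dimnames = list(species, hosts))
    diag(host_profiles) <- 0.7
  }
  if (is.null(rownames(host_profiles)) ||
      !all(species %in% rownames(host_profiles))) {
    stop("host_profiles must have one row per panel species")
  }
  if (any(abs(rowSums(host_profiles) - 1) > 1e-8)) {
    stop("host_profiles rows must sum to 1")
  }
  hosts <- colnames(host_profiles)
  set.seed(as.integer(seed))
  mixed_draw <- stats::runif(n_samples) < mixing_p
  pool <- setdiff(seq_len(651L), sim$used_positions)
  max_sub <- floor(intra_divergence * 651)

  records <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    host_scientific = NA_character_, host_common = NA_character_,
    host_family = "Unknown", region = "synthetic",
    lat = NA_real_, lon = NA_real_, stringsAsFactors = FALSE
  )
  ids_by_sample <- vector("list", n_samples)
  seqs <- character(0)
  truth <- NULL
  fly_no <- 0L
  for (s in seq_len(n_samples)) {
    primary <- sample(species, 1L)
    host <- sample(hosts, 1L, prob = host_profiles[primary, ])
    records$host_scientific[s] <- host
    records$host_common[s] <- host
    fly_species <- rep(primary, flies_per_sample)
    if (mixed_draw[s] && length(species) > 1L && flies_per_sample >= 2L) {
      secondary <- sample(setdiff(species, primary), 1L)
      n_sec <- sample.int(flies_per_sample - 1L, 1L)
      fly_species[seq_len(n_sec)] <- secondary
    }
    fly_ids <- character(flies_per_sample)
    for (f in seq_len(flies_per_sample)) {
      fly_no <- fly_no + 1L
      id <- sprintf("fly_%05d", fly_no)
      fly_ids[f] <- id
      ref_chars <- strsplit(sim$refs$nt[sim$refs$species == fly_species[f]],
                            "")[[1L]]
      k <- if (max_sub == 0L) 0L else sample.int(max_sub, 1L)
      chars <- if (k == 0L) ref_chars else {
        .place_substitutions(ref_chars, k, pool, sim$code,
                             synonymous_p = 1)$chars
      }
      seqs[id] <- paste(chars, collapse = "")
      truth <- rbind(truth, data.frame(
        seq_id = id, sample_id = records$sample_id[s],
        species = fly_species[f], host = host
      ))
    }
    ids_by_sample[[s]] <- fly_ids
  }
  records$whitefly_ids <- I(ids_by_sample)
  truth_matrix <- table(factor(truth$host, sort(hosts)),
                        factor(truth$species, sort(species)))
  truth_matrix <- matrix(as.integer(truth_matrix), nrow(truth_matrix),
                         ncol(truth_matrix),
                         dimnames = dimnames(truth_matrix))
  list(records = records, seqs = seqs, truth = truth,
       truth_matrix = truth_matrix,
       mixed_fraction = mean(vapply(split(truth$species, truth$sample_id),
                                    function(x) length(unique(x)) > 1L,
                                    logical(1))))
}

#' Simulate a planted-block host x species count matrix
#'
#' Builds a matrix of `k` host blocks by `k` species blocks in which cells
#' of the diagonal blocks draw from `Poisson(lambda_in)` and all other
#' cells from `Poisson(lambda_out)`, giving well-separated host-preference
#' clusters with known membership.
#'
#' @param k Number of planted blocks.
#' @param hosts_per_block,species_per_block Block sizes.
#' @param lambda_in,lambda_out Poisson means inside and outside the
#'   diagonal blocks (defaults 50 and 1).
#' @param seed Integer seed.
#' @return Count matrix with attributes `host_block` and `species_block`
#'   (integer block memberships).
#' @export
simulate_block_matrix <- function(k, hosts_per_block = 4L,
                                  species_per_block = 4L,
                                  lambda_in = 50, lambda_out = 1,
                                  seed = 1L) {
  set.seed(as.integer(seed))
  nh <- k * hosts_per_block
  ns <- k * species_per_block
  host_block <- rep(seq_len(k), each = hosts_per_block)
  species_block <- rep(seq_len(k), each = species_per_block)
  lambda <- ifelse(outer(host_block, species_block, "=="), lambda_in,
                   lambda_out)
  m <- matrix(stats::rpois(nh * ns, lambda), nh, ns,
              dimnames = list(sprintf("host_%02d", seq_len(nh)),
                              sprintf("species_%02d", seq_len(ns))))
  attr(m, "host_block") <- host_block
  attr(m, "species_block") <- species_block
  m
}
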