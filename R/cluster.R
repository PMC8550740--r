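# Hierarchical clustering of host-range profiles and optimal-k selection
# by a majority vote of cluster validity indices.

.cluster_items <- function(m, axis = c("hosts", "species")) {
  axis <- match.arg(axis)
  x <- if (axis == "hosts") m else t(m)
  storage.mode(x) <- "double"
  x
}

.profile_dist <- function(x, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") return(stats::dist(x))
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant profile(s) under correlation distance: ",
         paste(rownames(x)[sds == 0], collapse = ", "))
  }
  stats::as.dist(1 - stats::cor(t(x)))
}

#' Hierarchical clustering of hosts or species profiles
#'
#' Clusters rows (hosts) or columns (species) of a count matrix by their
#' count profiles. Defaults: Euclidean distance, average linkage (UPGMA);
#' correlation distance is offered for shape-based profiles.
#'
#' @param m Host x species count matrix.
#' @param axis `"hosts"` (rows) or `"species"` (columns).
#' @param metric `"euclidean"` (default) or `"correlation"`.
#' @param linkage Any [stats::hclust()] method (default `"average"`).
#' @return An `hclust` object with the axis recorded in `$axis`.
#' @export
hierarchical_cluster <- function(m, axis = c("hosts", "species"),
                                 metric = c("euclidean", "correlation"),
                                 linkage = "average") {
  axis <- match.arg(axis)
  x <- .cluster_items(m, axis)
  if (nrow(x) < 2L) stop("need at least 2 items on axis ", axis)
  hc <- stats::hclust(.profile_dist(x, match.arg(metric)), method = linkage)
  hc$axis <- axis
  hc
}

#' Export a dendrogram as Newick with merge heights as branch lengths
#'
#' @param hc An `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

# ---- cluster validity indices -------------------------------------------
# Implemented directly from their definitions; each votes for the k in the
# searched range that optimises it (maximise CH, silhouette, Dunn;
# minimise Davies-Bouldin, C-index).

.idx_ch <- function(x, cl) {
  n <- nrow(x); k <- length(unique(cl))
  grand <- colMeans(x)
  centers <- rowsum(x, cl) / as.vector(table(cl))
  bgss <- sum(as.vector(table(cl)) * rowSums((centers - rep(grand, each = k))^2))
  wgss <- sum((x - centers[as.character(cl), , drop = FALSE])^2)
  if (wgss == 0) return(Inf)
  (bgss / (k - 1)) / (wgss / (n - k))
}

.idx_silhouette <- function(d, cl) {
  mean(cluster::silhouette(cl, d)[, "sil_width"])
}

.idx_dunn <- function(d, cl) {
  dm <- as.matrix(d)
  ks <- unique(cl)
  sep <- Inf; diam <- 0
  for (a in ks) {
    ia <- which(cl == a)
    if (length(ia) > 1L) diam <- max(diam, max(dm[ia, ia]))
    for (b in ks) {
      if (a < b) sep <- min(sep, min(dm[cl == a, cl == b]))
    }
  }
  if (diam == 0) return(Inf)
  sep / diam
}

.idx_db <- function(x, cl) {
  ks <- sort(unique(cl)); k <- length(ks)
  centers <- rowsum(x, cl) / as.vector(table(cl))
  s <- vapply(ks, function(a) {
    ia <- which(cl == a)
    mean(sqrt(rowSums((x[ia, , drop = FALSE] -
                         rep(centers[as.character(a), ], each = length(ia)))^2)))
  }, numeric(1))
  r <- vapply(seq_len(k), function(i) {
    max(vapply(seq_len(k)[-i], function(j) {
      mij <- sqrt(sum((centers[i, ] - centers[j, ])^2))
      if (mij == 0) Inf else (s[i] + s[j]) / mij
    }, numeric(1)))
  }, numeric(1))
  mean(r)
}

.idx_cindex <- function(d, cl) {
  dv <- as.vector(d)
  dm <- as.matrix(d)
  within <- unlist(lapply(unique(cl), function(a) {
    ia <- which(cl == a)
    if (length(ia) > 1L) dm[ia, ia][lower.tri(dm[ia, ia])] else numeric(0)
  }))
  nw <- length(within)
  if (nw == 0L) return(NA_real_)
  sw <- sum(within)
  sorted <- sort(dv)
  smin <- sum(sorted[seq_len(nw)])
  smax <- sum(sorted[seq.int(length(sorted) - nw + 1L, length(sorted))])
  if (smax == smin) return(0)
  (sw - smin) / (smax - smin)
}

#' Choose the number of clusters by a validity-index majority vote
#'
#' Cuts the hierarchical dendrogram at each k in `k_range` and scores the
#' partitions with five cluster validity indices (Calinski-Harabasz,
#' average silhouette width, Dunn, Davies-Bouldin, C-index). Each index
#' votes for its optimal k; the chosen k is the mode of the votes, with
#' ties resolved toward the smallest k and flagged.
#'
#' @param m Host x species count matrix.
#' @param axis `"hosts"` or `"species"`.
#' @param k_range Integer vector of candidate cluster counts (default 2:10),
#'   truncated to half the item count (partitions dominated by singleton
#'   clusters degenerate several indices -- Davies-Bouldin in particular
#'   rewards zero-scatter singletons -- so k beyond n/2 is not searched).
#' @param metric,linkage Passed to [hierarchical_cluster()].
#' @param indices Subset of
#'   `c("ch", "silhouette", "dunn", "db", "cindex")`.
#' @return List of class `optimal_k`: `chosen_k`, `index_votes` (named
#'   integer vector), `tie` flag, `scores` matrix (index x k) and the
#'   dendrogram `hclust`.
#' @export
optimal_k <- function(m, axis = c("hosts", "species"), k_range = 2:10,
                      metric = "euclidean", linkage = "average",
                      indices = c("ch", "silhouette", "dunn", "db", "cindex")) {
  axis <- match.arg(axis)
  x <- .cluster_items(m, axis)
  if (nrow(unique(as.data.frame(x))) < 2L) {
    stop("degenerate matrix: all profiles identical on axis ", axis)
  }
  k_range <- sort(unique(as.integer(k_range)))
  k_max <- max(2L, nrow(x) %/% 2L)
  k_range <- k_range[k_range >= 2L & k_range <= k_max]
  if (length(k_range) == 0L) stop("k_range empty after truncation to item count")
  d <- .profile_dist(x, metric)
  hc <- stats::hclust(d, method = linkage)
  hc$axis <- axis

  scores <- matrix(NA_real_, length(indices), length(k_range),
                   dimnames = list(indices, k_range))
  for (j in seq_along(k_range)) {
    cl <- stats::cutree(hc, k = k_range[j])
    for (idx in indices) {
      scores[idx, j] <- switch(idx,
        ch = .idx_ch(x, cl),
        silhouette = .idx_silhouette(d, cl),
        dunn = .idx_dunn(d, cl),
        db = .idx_db(x, cl),
        cindex = .idx_cindex(d, cl)
      )
    }
  }
  minimise <- c(db = TRUE, cindex = TRUE, ch = FALSE, silhouette = FALSE,
                dunn = FALSE)
  votes <- vapply(indices, function(idx) {
    s <- scores[idx, ]
    if (all(is.na(s))) return(NA_integer_)
    if (minimise[[idx]]) k_range[which.min(s)] else k_range[which.max(s)]
  }, integer(1))
  tab <- table(votes[!is.na(votes)])
  winners <- as.integer(names(tab)[tab == max(tab)])
  chosen <- min(winners)
  structure(
    list(chosen_k = chosen, index_votes = votes, tie = length(winners) > 1L,
         scores = scores, hclust = hc, k_range = k_range),
    class = "optimal_k"
  )
}

#' @export
print.optimal_k <- function(x, ...) {
  cat("Optimal k =", x$chosen_k,
      if (x$tie) "(tie, smallest k chosen)" else "", "\n")
  cat("Index votes:\n")
  print(x$index_votes)
  invisible(x)
}
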