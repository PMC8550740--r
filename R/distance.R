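# Pairwise nucleotide distances for aligned barcodes: p-distance, percent
# identity and the Tajima-Nei (1984) model-corrected distance. Alignment
# columns where either sequence carries a gap or non-ACGT symbol are
# excluded pair-by-pair ("pairwise deletion", the MEGA default), so each
# pair uses the maximum number of unambiguous sites.

.pair_sites <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1L]]
  b <- strsplit(toupper(b), "")[[1L]]
  if (length(a) != length(b)) {
    stop("sequences must be equal length (positional alignment implied)")
  }
  use <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  list(a = a[use], b = b[use], n = sum(use))
}

#' Proportion of differing sites (p-distance)
#'
#' @param a,b Equal-length aligned nucleotide strings.
#' @return List with `p` (mismatches / usable sites) and `n_sites_used`.
#' @examples
#' p_distance("AANA", "AATA")  # N-site excluded: p = 0 over 3 sites
#' @export
p_distance <- function(a, b) {
  s <- .pair_sites(a, b)
  if (s$n == 0L) stop("no usable sites: distance undefined")
  list(p = sum(s$a != s$b) / s$n, n_sites_used = s$n)
}

#' Percent nucleotide identity
#'
#' `100 * (1 - p)` under pairwise deletion.
#'
#' @inheritParams p_distance
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(a, b) {
  100 * (1 - p_distance(a, b)$p)
}

#' Tajima-Nei (1984) corrected distance
#'
#' Computes `d = -b * log(1 - p/b)` with
#' `b = (1 - sum(q_i^2) + p^2 / h) / 2` and
#' `h = sum_{i<j} x_ij^2 / (2 q_i q_j)`, where `q` are the four nucleotide
#' frequencies averaged over the pooled pair and `x_ij` the relative
#' frequencies of the six unordered mismatch types. With uniform base
#' composition and equally frequent mismatch types the estimate reduces to
#' the Jukes-Cantor form `-(3/4) log(1 - 4p/3)`.
#'
#' @inheritParams p_distance
#' @return List of class `tajima_nei` with components `p`, `q` (length 4),
#'   `x` (named length-6 vector of mismatch-pair frequencies), `h`, `b`,
#'   `d` and `n_sites_used`.
#' @export
tajima_nei <- function(a, b) {
  s <- .pair_sites(a, b)
  if (s$n == 0L) stop("no usable sites: distance undefined")
  bases <- c("A", "C", "G", "T")
  q <- (
    as.numeric(table(factor(s$a, bases))) +
    as.numeric(table(factor(s$b, bases)))
  ) / (2 * s$n)
  names(q) <- bases
  pairs <- utils::combn(bases, 2L)
  pair_names <- paste0(pairs[1L, ], pairs[2L, ])
  diff <- s$a != s$b
  key <- ifelse(s$a < s$b, paste0(s$a, s$b), paste0(s$b, s$a))
  x <- as.numeric(table(factor(key[diff], pair_names))) / s$n
  names(x) <- pair_names
  p <- sum(x)

  if (p == 0) {
    out <- list(p = 0, q = q, x = x, h = 0, b = NA_real_, d = 0,
                n_sites_used = s$n)
    class(out) <- "tajima_nei"
    return(out)
  }
  qi <- q[pairs[1L, ]]
  qj <- q[pairs[2L, ]]
  terms <- x^2 / (2 * qi * qj)
  terms[x == 0] <- 0  # pairs never observed contribute nothing
  h <- sum(terms)
  bb <- (1 - sum(q^2) + p^2 / h) / 2
  if (p >= bb) {
    stop(sprintf("Tajima-Nei saturation: p = %.4f >= b = %.4f", p, bb))
  }
  out <- list(p = p, q = q, x = x, h = h, b = bb,
              d = -bb * log(1 - p / bb), n_sites_used = s$n)
  class(out) <- "tajima_nei"
  out
}

#' @export
print.tajima_nei <- function(x, ...) {
  cat(sprintf("Tajima-Nei distance: d = %.6f (p = %.6f over %d sites)\n",
              x$d, x$p, x$n_sites_used))
  invisible(x)
}

#' Full pairwise distance matrix
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (at least 2).
#' @param metric One of `"p_distance"`, `"percent_identity"`, `"tajima_nei"`.
#' @return Object of class `distance_matrix`: `labels`, symmetric `values`
#'   matrix (diagonal 0, or 100 for percent identity), `metric`, and
#'   `n_sites_used` matrix of effective site counts.
#' @export
distance_matrix <- function(seqs,
                            metric = c("p_distance", "percent_identity",
                                       "tajima_nei")) {
  metric <- match.arg(metric)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  labels <- names(seqs)
  if (is.null(labels)) stop("sequences must be named")
  n <- length(seqs)
  vals <- matrix(if (metric == "percent_identity") 100 else 0,
                 n, n, dimnames = list(labels, labels))
  nsites <- matrix(NA_integer_, n, n, dimnames = list(labels, labels))
  diag(nsites) <- nchar(seqs)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      v <- tryCatch(
        switch(metric,
          p_distance = { r <- p_distance(seqs[[i]], seqs[[j]]); c(r$p, r$n_sites_used) },
          percent_identity = {
            r <- p_distance(seqs[[i]], seqs[[j]])
            c(100 * (1 - r$p), r$n_sites_used)
          },
          tajima_nei = { r <- tajima_nei(seqs[[i]], seqs[[j]]); c(r$d, r$n_sites_used) }
        ),
        error = function(e) stop("pair (", labels[i], ", ", labels[j], "): ",
                                 conditionMessage(e))
      )
      vals[i, j] <- vals[j, i] <- v[1L]
      nsites[i, j] <- nsites[j, i] <- as.integer(v[2L])
    }
  }
  structure(list(labels = labels, values = vals, metric = metric,
                 n_sites_used = nsites),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("Pairwise", x$metric, "matrix over", length(x$labels), "sequences\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Write a distance matrix as TSV (labels in first row and column)
#'
#' @param dm A [distance_matrix()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  stopifnot(inherits(dm, "distance_matrix"))
  utils::write.table(dm$values, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
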