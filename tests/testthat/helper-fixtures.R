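# Shared fixtures and independent oracles, built in code at test time.

# mutate positions (1-based) of a sequence to given bases
mutate_at <- function(nt, pos, base) {
  chars <- strsplit(nt, "")[[1L]]
  chars[pos] <- base
  paste(chars, collapse = "")
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A tiny fixed panel: three species derived from the shipped seed ORF.
toy_sim <- function(n_species = 3, seed = 42) {
  simulate_panel(n_species, inter_divergence = 0.08, seed = seed)
}

toy_panel <- function(n_species = 3, seed = 42) {
  build_panel(toy_sim(n_species, seed)$refs)
}

# Independent Needleman-Wunsch oracle: ends-free affine-gap alignment SCORE
# by dynamic programming (interior gap of length L costs open + L * extend,
# terminal overhangs free), coded directly from the recurrence, no
# Biostrings involved.
nw_score <- function(a, b, match = 1, mismatch = -1, open = 5, extend = 1) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # a[i] aligned to b[j]
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (a[i] aligned to '-')
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[, 1] <- 0; M[1, ] <- 0        # free leading overhang in either sequence
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend)
    }
  }
  best <- function(i, j) max(M[i, j], X[i, j], Y[i, j])
  # free trailing overhang: finish anywhere on the last row or column
  max(vapply(seq_len(m + 1), function(j) best(n + 1, j), numeric(1)),
      vapply(seq_len(n + 1), function(i) best(i, m + 1), numeric(1)))
}

# Independent straight-from-the-formula Tajima-Nei evaluation: tabulates
# site patterns with nested loops, no shared code with the package path.
tn_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  bases <- c("A", "C", "G", "T")
  keep <- a %in% bases & b %in% bases
  a <- a[keep]; b <- b[keep]; n <- length(a)
  q <- numeric(4); names(q) <- bases
  for (base in bases) q[base] <- (sum(a == base) + sum(b == base)) / (2 * n)
  h <- 0; p <- 0
  for (i in 1:3) {
    for (j in (i + 1):4) {
      xij <- sum((a == bases[i] & b == bases[j]) |
                 (a == bases[j] & b == bases[i])) / n
      p <- p + xij
      if (xij > 0) h <- h + xij^2 / (2 * q[i] * q[j])
    }
  }
  bb <- 0.5 * (1 - sum(q^2) + p^2 / h)
  -bb * log(1 - p / bb)
}

# Equal-length pair with uniform pooled base composition and all six
# mismatch types equally frequent, at exact p-distance p (n = 480 admits
# every p in {0.05, ..., 0.50}).
uniform_pair <- function(p, n = 480) {
  m <- round(p * n)
  stopifnot(m %% 6 == 0, (n - m) %% 4 == 0)
  bases <- c("A", "C", "G", "T")
  a <- c(rep(bases, (n - m) / 4), rep(c("A", "A", "A", "C", "C", "G"), m / 6))
  b <- c(rep(bases, (n - m) / 4), rep(c("C", "G", "T", "G", "T", "T"), m / 6))
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# write a small survey TSV and return its path
write_toy_survey <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}

survey_header <- paste("sample_id", "host_scientific", "host_common",
                       "host_family", "region", "lat", "lon", "whitefly_ids",
                       sep = "\t")
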