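# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can vouch for the vectorised implementations.

# Tanimoto similarity by explicit counting
oracle_tanimoto <- function(u, v) {
  inter <- 0; a <- 0; b <- 0
  for (k in seq_along(u)) {
    if (u[k] == 1 && v[k] == 1) inter <- inter + 1
    if (u[k] == 1) a <- a + 1
    if (v[k] == 1) b <- b + 1
  }
  if (a + b - inter == 0) return(0)
  inter / (a + b - inter)
}

# full pairwise weight matrix by double loop
oracle_weight_matrix <- function(x) {
  n <- nrow(x)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) w[i, j] <- oracle_tanimoto(x[i, ], x[j, ])
    }
  }
  w
}

# one-shot Eq.-style pipeline: raw weight matrices -> per-disease KL,
# composing the exponential row normalisation and the divergence sum
oracle_kl_from_weights <- function(w_pr, w_dr) {
  n <- nrow(w_pr)
  kl <- numeric(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    p <- exp(w_pr[i, others]); p <- p / sum(p)
    q <- exp(w_dr[i, others]); q <- q / sum(q)
    s <- 0
    for (j in seq_along(others)) s <- s + p[j] * log(p[j] / q[j])
    kl[i] <- s
  }
  kl
}

# SSL closed form via explicit dense matrix inversion (solve(A) %*% y),
# a different numerical path than the package's Cholesky backsolves
oracle_ssl <- function(w, labeled, mu) {
  n <- nrow(w)
  diag(w) <- 0
  lap <- diag(rowSums(w)) - w
  a_inv <- solve(diag(n) + mu * lap)
  y <- as.numeric(seq_len(n) == labeled)
  as.vector(a_inv %*% y)
}

# random binary disease x feature table with guaranteed nonzero rows
random_binary_table <- function(n_rows, n_cols, density = 0.3,
                                row_kind = "disease", col_kind = "protein",
                                prefix = c("D", "P")) {
  x <- matrix(rbinom(n_rows * n_cols, 1, density), n_rows, n_cols)
  for (i in seq_len(n_rows)) {
    if (sum(x[i, ]) == 0) x[i, sample.int(n_cols, 1)] <- 1
  }
  rows <- sprintf("%s%03d", prefix[1], seq_len(n_rows))
  cols <- sprintf("%s%03d", prefix[2], seq_len(n_cols))
  idx <- which(x == 1, arr.ind = TRUE)
  association_table(data.frame(row = rows[idx[, 1]], col = cols[idx[, 2]]),
                    row_kind, col_kind, row_ids = rows, col_ids = cols)
}

# random symmetric weight matrix in [0, 1] with zero diagonal
random_weights <- function(n, density = 0.5) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < density) w[i, j] <- w[j, i] <- runif(1)
    }
  }
  w
}

# write pairs to a tempfile as TSV
write_pairs_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

as_dense <- function(table) as.matrix(table$matrix)
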