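# Independent brute-force oracles used to validate the package's
# numerics. These are deliberately naive re-implementations that share no
# code with the package internals.

# Gotoh affine-gap dynamic programming, global. A gap of length L costs
# open + L * ext (the same convention as the package's aligner).
oracle_global_score <- function(a, b, mat, open = 10, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[A[i], B[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                             X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                             Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Gotoh affine-gap DP, local (Smith-Waterman); score floored at 0.
oracle_local_score <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[A[i], B[j]]
      M[i + 1, j + 1] <- max(0, max(M[i, j], X[i, j], Y[i, j]) + s)
      X[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                             X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                             Y[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Shannon entropy (nats) of one alignment column from raw symbol counts.
oracle_column_entropy <- function(chars) {
  tab <- table(chars)
  p <- as.numeric(tab) / length(chars)
  -sum(p * log(p))
}

# PSSM score by direct triple loop.
oracle_pssm <- function(msa_mat, blosum) {
  N <- nrow(msa_mat)
  aa <- efprf::aa_alphabet()
  out <- matrix(0, ncol(msa_mat), length(aa),
                dimnames = list(NULL, aa))
  for (i in seq_len(ncol(msa_mat))) {
    for (j in aa) {
      s <- 0
      for (k in aa) {
        c_ki <- sum(msa_mat[, i] == k)
        if (c_ki > 0) s <- s + log(c_ki + 1) / log(N + 1) * blosum[k, j]
      }
      out[i, j] <- s
    }
  }
  out
}

oracle_s_func <- function(ecs) {
  pref <- sub("\\.\\d+$", "", ecs)
  p <- as.numeric(table(pref)) / length(ecs)
  -sum(p * log(p))
}

# Exact two-sided rank-sum p by enumeration of all group assignments
# (tie-free samples only, where the exact distribution applies).
oracle_rank_sum_p <- function(g1, g2) {
  pooled <- c(g1, g2)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(g1)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# textbook paired t
oracle_paired_t <- function(a, b) {
  d <- a - b; n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}
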