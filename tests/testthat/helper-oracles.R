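# Independent oracles, kept deliberately naive and separate from the
# package's own code paths.

# Textbook (Deng) grey relational analysis: plain loops, per-element
# coefficients with global extreme differences, unweighted mean degree.
deng_gra_degree <- function(reference, x, rho = 0.5) {
  x <- as.matrix(x)
  m <- nrow(x)
  n <- ncol(x)
  delta <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) delta[i, j] <- abs(reference[i] - x[i, j])
  }
  dmin <- min(delta)
  dmax <- max(delta)
  deg <- numeric(n)
  for (j in seq_len(n)) {
    s <- (dmin + rho * dmax) / (delta[, j] + rho * dmax)
    deg[j] <- mean(s)
  }
  deg
}

# Power-iteration principal eigenvector of a positive matrix.
power_eigvec <- function(q, iters = 500) {
  v <- rep(1, nrow(q))
  for (i in seq_len(iters)) {
    v <- as.numeric(q %*% v)
    v <- v / sum(v)
  }
  v
}

# Brute-force one-vs-one vote counting with the package's stated
# tie-break: most votes, then largest summed signed decision value, then
# lowest class id.
brute_vote <- function(decisions, pairs, classes) {
  out <- character(nrow(decisions))
  for (i in seq_len(nrow(decisions))) {
    votes <- setNames(rep(0, length(classes)), classes)
    score <- setNames(rep(0, length(classes)), classes)
    for (p in seq_along(pairs)) {
      a <- pairs[[p]][1]; b <- pairs[[p]][2]
      d <- decisions[i, p]
      if (d >= 0) votes[a] <- votes[a] + 1 else votes[b] <- votes[b] + 1
      score[a] <- score[a] + d
      score[b] <- score[b] - d
    }
    cand <- classes[votes == max(votes)]
    if (length(cand) > 1) {
      cand <- cand[score[cand] == max(score[cand])]
    }
    out[i] <- sort(cand)[1]
  }
  out
}

# Random labelled dataset (uniform indicators, no class structure) for
# identity/property checks.
random_dataset <- function(m = 200, n = 7, seed = 1) {
  set.seed(seed)
  x <- as.data.frame(matrix(runif(m * n), m, n))
  names(x) <- paste0("ind", seq_len(n))
  x$label <- sample(1:6, m, replace = TRUE)
  x
}

# Tiny linearly separable two-class set with a wide margin.
toy_separable <- function(n = 20, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(runif(2 * n, 0, 0.2), ncol = 2),
             matrix(runif(2 * n, 0.8, 1.0), ncol = 2))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c(1L, 2L), each = n))
}
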