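#' Grey relational analysis settings
#'
#' @param rho Difference (distinguishing) coefficient in (0, 1]; the
#'   conventional value is 0.5.
#' @param denominator_form `"standard"` uses the classical coefficient
#'   denominator `delta + rho * delta_max`; `"literal"` uses
#'   `delta + delta_max` (a variant occasionally seen in print, in which
#'   `rho` acts on the numerator only).
#' @param normalize_reference Min-max normalize the reference (class)
#'   series before computing differences, so both sides live on \[0, 1\].
#' @return A `grey_config` list.
#' @export
grey_config <- function(rho = 0.5, denominator_form = c("standard", "literal"),
                        normalize_reference = TRUE) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho > 1) {
    stopf("rho must lie in (0, 1]")
  }
  structure(list(rho = rho,
                 denominator_form = match.arg(denominator_form),
                 normalize_reference = isTRUE(normalize_reference)),
            class = "grey_config")
}

#' Grey relational coefficients
#'
#' For a reference series `x0` and comparison series `x_j` (all on \[0, 1\]),
#' the absolute differences `delta_j(i) = |x0(i) - x_j(i)|` are formed and
#' the coefficient
#' `s_j(i) = (delta_min + rho * delta_max) / (delta_j(i) + rho * delta_max)`
#' is computed, with `delta_min`/`delta_max` the global extremes of the
#' difference matrix over all samples and series. When every series equals
#' the reference (`delta_max = 0`) all coefficients are 1 by convention.
#'
#' @param reference Numeric vector, length m.
#' @param subindices m x n matrix of comparison series.
#' @param cfg A [grey_config()].
#' @return m x n matrix of coefficients in (0, 1].
#' @export
#' @examples
#' ref <- c(0, 0.5, 1)
#' x <- cbind(a = c(0, 0.3, 0.6), b = c(0.2, 0.5, 0.8))
#' grey_coefficients(ref, x)
grey_coefficients <- function(reference, subindices, cfg = grey_config()) {
  x <- as.matrix(subindices)
  m <- length(reference)
  if (m < 2L) stopf("need at least 2 samples")
  if (nrow(x) != m) stopf("reference length and matrix rows disagree")
  if (!all(is.finite(reference)) || !all(is.finite(x))) {
    stopf("inputs must be finite")
  }
  delta <- abs(x - reference)
  dmax <- max(delta)
  dmin <- min(delta)
  if (dmax == 0) {
    s <- matrix(1, m, ncol(x), dimnames = dimnames(x))
    return(s)
  }
  num <- dmin + cfg$rho * dmax
  den <- switch(cfg$denominator_form,
                standard = delta + cfg$rho * dmax,
                literal  = delta + dmax)
  num / den
}

#' Pairwise comparison matrix for subjective (AHP) weighting
#'
#' Validates a positive reciprocal matrix of pairwise importance ratios on
#' the 1-9 scale. `comparison_matrix(n)` with a single count gives the
#' neutral all-ones matrix (equal subjective weights).
#'
#' @param q Square numeric matrix, or a single integer n for the neutral
#'   n x n matrix.
#' @return The validated matrix with class `comparison_matrix`.
#' @export
comparison_matrix <- function(q) {
  if (length(q) == 1L && is_count(q)) {
    q <- matrix(1, q, q)
  }
  q <- as.matrix(q)
  n <- nrow(q)
  if (ncol(q) != n) stopf("comparison matrix must be square")
  if (!all(is.finite(q)) || any(q <= 0)) {
    stopf("comparison matrix entries must be positive")
  }
  if (any(abs(diag(q) - 1) > 1e-9)) stopf("comparison matrix diagonal must be 1")
  if (any(abs(q * t(q) - 1) > 1e-6)) {
    stopf("comparison matrix must be reciprocal (q[j,l] == 1/q[l,j])")
  }
  if (any(q < 1 / 9 - 1e-9 | q > 9 + 1e-9)) {
    stopf("comparison ratios must lie on the 1-9 scale ([1/9, 9])")
  }
  structure(q, class = c("comparison_matrix", "matrix"))
}

# Saaty random consistency indices, n = 1..10.
saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' Subjective weights from a pairwise comparison matrix (AHP)
#'
#' Row-sum weighting: `alpha_j = sum_l q[j, l] / sum_{j, l} q[j, l]`. The
#' consistency ratio CR is computed from the principal eigenvalue
#' (`CI = (lambda_max - n) / (n - 1)`, `CR = CI / RI`) and a warning is
#' raised when CR exceeds 0.1 (incoherent judgments).
#'
#' @param q A [comparison_matrix()] (or coercible matrix).
#' @return Numeric weight vector summing to 1, with the consistency ratio
#'   attached as attribute `cr`.
#' @export
#' @examples
#' ahp_weights(comparison_matrix(3))          # equal weights, CR = 0
#' q <- matrix(c(1, 3, 1/3, 1), 2, 2, byrow = TRUE)
#' ahp_weights(q)                             # 0.75, 0.25
ahp_weights <- function(q) {
  q <- comparison_matrix(q)
  n <- nrow(q)
  alpha <- rowSums(q) / sum(q)
  lambda_max <- max(Re(eigen(q, only.values = TRUE)$values))
  cr <- if (n <= 2L) 0 else ((lambda_max - n) / (n - 1)) / saaty_ri[n]
  if (cr > 0.1) {
    warning(sprintf("AHP consistency ratio %.3f exceeds 0.1; judgments may be incoherent", cr),
            call. = FALSE)
  }
  names(alpha) <- colnames(q)
  attr(alpha, "cr") <- cr
  alpha
}

#' Objective weights by dispersion and conflict (CRITIC)
#'
#' `C_j = sigma_j * sum_l (1 - r_jl)` where `sigma_j` is the standard
#' deviation of (normalized) indicator column j and `r_jl` the Pearson
#' correlation between columns j and l; weights are `beta_j = C_j / sum C`.
#' High-information indicators are those that both vary and disagree with
#' the others.
#'
#' @param x m x n matrix of normalized indicator columns, m >= 3, no
#'   constant column.
#' @return Numeric weight vector summing to 1.
#' @export
critic_weights <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stopf("need at least 3 samples")
  sig <- apply(x, 2L, sd)
  if (any(sig == 0)) {
    stopf("degenerate column: constant indicator(s) %s",
          paste(colnames(x)[sig == 0], collapse = ", "))
  }
  r <- cor(x)
  info <- sig * rowSums(1 - r)
  if (all(info <= .Machine$double.eps^0.5 * max(sig))) {
    stopf("degeneracy: all indicators pairwise correlation 1, no information")
  }
  beta <- info / sum(info)
  names(beta) <- colnames(x)
  beta
}

#' Combine subjective and objective weights
#'
#' `omega_j = (alpha_j + beta_j) / sum(alpha + beta)`; with both inputs
#' normalized this is the simple average of the two weightings.
#'
#' @param alpha,beta Nonnegative weight vectors of equal length, each
#'   summing to 1.
#' @return Combined weight vector summing to 1.
#' @export
combine_weights <- function(alpha, beta) {
  if (length(alpha) != length(beta)) stopf("weight vectors differ in length")
  for (w in list(alpha, beta)) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-6) {
      stopf("weights must be nonnegative and sum to 1")
    }
  }
  (alpha + beta) / sum(alpha + beta)
}

#' Weighted grey relational degree
#'
#' `r(j) = omega_j * mean_i s_j(i)`: the per-indicator mean relational
#' coefficient scaled by the indicator's combined weight. With equal
#' weights `omega_j = 1/n` this reduces (up to the factor n) to the
#' classical unweighted relational degree.
#'
#' @param s m x n coefficient matrix from [grey_coefficients()].
#' @param omega Length-n weight vector.
#' @return Length-n vector of weighted degrees.
#' @export
weighted_degree <- function(s, omega) {
  s <- as.matrix(s)
  if (ncol(s) != length(omega)) stopf("coefficient columns and weights disagree")
  colMeans(s) * omega
}

#' Rank and select indicators by weighted grey relational degree
#'
#' Full selection pipeline: min-max normalize each indicator (orienting
#' benefit-type indicators such as DO to the pollution-severity direction),
#' normalize the ordinal class series as the reference, compute grey
#' relational coefficients, weight them with combined AHP + CRITIC weights
#' and rank indicators by descending weighted degree (ties broken by
#' original column order). The top `q` indicators are selected.
#'
#' @param data Data frame of indicator columns plus a `label` column
#'   (integer classes).
#' @param q Number of indicators to keep, 1 <= q <= n.
#' @param comparison [comparison_matrix()] of subjective judgments;
#'   defaults to the neutral all-ones matrix (equal subjective weights).
#' @param cfg A [grey_config()].
#' @param direction Named vector of +1/-1 severity directions per
#'   indicator; -1 entries are reversed after normalization. Defaults to
#'   the [water_schema()] directions for known indicators, +1 otherwise.
#' @return An `acgra_selection` object: data frame `ranking` (indicator,
#'   mean_s, alpha, beta, omega, degree, rank), character vector
#'   `selected`, and the inputs' dimensions.
#' @export
select_features <- function(data, q = 4L, comparison = NULL,
                            cfg = grey_config(), direction = NULL) {
  if (!"label" %in% names(data)) stopf("data must carry a 'label' column")
  ind_cols <- setdiff(names(data), "label")
  n <- length(ind_cols)
  if (!is_count(q) || q > n) stopf("q must be a count in 1..%d", n)
  x <- as.matrix(data[ind_cols])
  if (is.null(direction)) {
    direction <- setNames(rep(1, n), ind_cols)
    known <- intersect(ind_cols, wq_indicators())
    direction[known] <- water_schema()$direction[known]
  }
  xn <- apply(x, 2L, min_max_normalize)
  rev_cols <- ind_cols[direction[ind_cols] < 0]
  xn[, rev_cols] <- 1 - xn[, rev_cols]
  ref <- as.numeric(data$label)
  if (cfg$normalize_reference) ref <- min_max_normalize(ref)

  s <- grey_coefficients(ref, xn, cfg)
  if (is.null(comparison)) comparison <- comparison_matrix(n)
  alpha <- ahp_weights(comparison)
  beta <- critic_weights(xn)
  omega <- combine_weights(as.numeric(alpha), beta)
  degree <- weighted_degree(s, omega)

  ord <- order(-degree, seq_len(n))  # stable: ties by column order
  ranking <- data.frame(
    indicator = ind_cols[ord],
    mean_s = colMeans(s)[ord],
    alpha = as.numeric(alpha)[ord],
    beta = as.numeric(beta)[ord],
    omega = omega[ord],
    degree = degree[ord],
    rank = seq_len(n),
    row.names = NULL
  )
  structure(list(ranking = ranking,
                 selected = ranking$indicator[seq_len(q)],
                 q = q, n = n, m = nrow(data),
                 cr = attr(alpha, "cr")),
            class = "acgra_selection")
}

#' @export
print.acgra_selection <- function(x, ...) {
  cat(sprintf("ACGRA indicator ranking (m = %d samples, top %d selected)\n",
              x$m, x$q))
  df <- x$ranking
  df[2:6] <- lapply(df[2:6], function(v) round(v, 4))
  print(df, row.names = FALSE)
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
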