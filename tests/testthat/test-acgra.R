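test_that("grey relational coefficients follow the standard form", {
  ref <- c(0.5, 0.5, 0.5)
  x <- cbind(a = c(0.5, 0.7, 0.9))  # differences 0, 0.2, 0.4
  s <- grey_coefficients(ref, x)
  expect_equal(as.numeric(s), c(1, 0.5, 1 / 3))
  # difference equal to the global minimum gives coefficient 1
  expect_equal(unname(s[1, 1]), 1)
})

test_that("literal denominator form and the all-identical convention work", {
  ref <- c(0.5, 0.5, 0.5)
  x <- cbind(a = c(0.5, 0.7, 0.9))
  s <- grey_coefficients(ref, x, grey_config(denominator_form = "literal"))
  expect_equal(as.numeric(s), 0.2 / (c(0, 0.2, 0.4) + 0.4))
  same <- grey_coefficients(ref, cbind(ref, ref))
  expect_true(all(same == 1))
})

test_that("coefficients lie in (0, 1] and at least 1/3 for rho = 0.5", {
  for (seed in 1:10) {
    set.seed(seed)
    ref <- runif(40)
    x <- matrix(runif(40 * 5), 40, 5)
    s <- grey_coefficients(ref, x)
    expect_true(all(s > 0 & s <= 1))
    expect_true(all(s >= 1 / 3))
  }
})

test_that("AHP row-sum weights match the examples and the eigenvector on consistent matrices", {
  a <- ahp_weights(comparison_matrix(4))
  expect_equal(as.numeric(a), rep(0.25, 4))
  expect_equal(attr(a, "cr"), 0)

  q <- matrix(c(1, 3, 1 / 3, 1), 2, 2, byrow = TRUE)
  expect_equal(as.numeric(ahp_weights(q)), c(0.75, 0.25))

  # perfectly consistent matrix q[j,l] = w_j / w_l: row-sum weights equal
  # the principal eigenvector (power-iteration oracle)
  w <- c(0.4, 0.3, 0.2, 0.1)
  q <- outer(w, w, "/")
  a <- ahp_weights(q)
  expect_equal(as.numeric(a), power_eigvec(q), tolerance = 1e-9)
  expect_equal(as.numeric(a), w, tolerance = 1e-12)
  expect_equal(attr(a, "cr"), 0, tolerance = 1e-9)
})

test_that("AHP validates matrices and warns on inconsistent judgments", {
  bad <- matrix(c(1, 2, 3, 1), 2, 2)
  expect_error(ahp_weights(bad), "reciprocal")
  expect_error(ahp_weights(matrix(c(1, -1, -1, 1), 2, 2)), "positive")
  cyc <- matrix(c(1, 9, 1 / 9, 1 / 9, 1, 9, 9, 1 / 9, 1), 3, 3, byrow = TRUE)
  expect_warning(ahp_weights(cyc), "consistency ratio")
})

test_that("CRITIC weights reflect dispersion and conflict", {
  # two orthogonal centred columns with equal sd -> symmetric weights
  x2 <- cbind(c(-1, 0, 1), c(1, -2, 1) / sqrt(3))
  expect_equal(as.numeric(critic_weights(x2)), c(0.5, 0.5))
  # three pairwise-uncorrelated columns, sd ratio (1, 1, 2)
  x3 <- cbind(c(-1, -1, 1, 1), c(-1, 1, -1, 1), 2 * c(1, -1, -1, 1))
  expect_equal(as.numeric(critic_weights(x3)), c(0.25, 0.25, 0.5))
  # perfectly correlated columns carry no information
  x <- runif(10)
  expect_error(critic_weights(cbind(x, 2 * x)), "degenera")
  expect_error(critic_weights(cbind(x, rep(1, 10))), "constant")
})

test_that("weight combination averages normalized weight vectors", {
  a <- c(0.6, 0.4)
  expect_equal(combine_weights(a, a), a)
  expect_equal(combine_weights(c(1, 0), c(0, 1)), c(0.5, 0.5))
  expect_equal(combine_weights(c(0.6, 0.4), c(0.2, 0.8)), c(0.4, 0.6))
  expect_error(combine_weights(c(1, 0), c(1, 0, 0)), "length")
})

test_that("weighted degree scales the mean coefficient by the weight", {
  s <- cbind(c(1, 1, 1), c(1, 0.5, 1 / 3))
  expect_equal(weighted_degree(s, c(0.6, 0.6)),
               c(0.6, 0.6 * 11 / 18), ignore_attr = TRUE)
  expect_equal(weighted_degree(s, c(0.4, 0))[2], 0, ignore_attr = TRUE)
})

test_that("all weight vectors sum to one and selection is permutation-equivariant", {
  d <- random_dataset(m = 80, n = 6, seed = 3)
  sel <- select_features(d, q = 6)
  rk <- sel$ranking
  expect_equal(sum(rk$alpha), 1, tolerance = 1e-9)
  expect_equal(sum(rk$beta), 1, tolerance = 1e-9)
  expect_equal(sum(rk$omega), 1, tolerance = 1e-9)
  expect_lte(sum(rk$degree), 1)
  expect_true(all(rk$degree <= rk$omega + 1e-12))

  perm <- c(4, 1, 6, 2, 5, 3)
  dp <- d[c(paste0("ind", perm), "label")]
  selp <- select_features(dp, q = 6)
  m1 <- rk[order(rk$indicator), c("indicator", "degree", "omega")]
  m2 <- selp$ranking[order(selp$ranking$indicator),
                     c("indicator", "degree", "omega")]
  expect_equal(m1$degree, m2$degree, tolerance = 1e-12)
  expect_equal(m1$omega, m2$omega, tolerance = 1e-12)
})

test_that("selection is invariant to positive affine rescaling of a column", {
  d <- random_dataset(m = 60, n = 5, seed = 11)
  s1 <- select_features(d, q = 5)
  d$ind2 <- 100 * d$ind2 + 7
  s2 <- select_features(d, q = 5)
  expect_equal(s1$ranking$degree, s2$ranking$degree, tolerance = 1e-12)
  expect_identical(s1$ranking$indicator, s2$ranking$indicator)
})

test_that("equal weights reduce the weighted degree to classical Deng GRA", {
  for (seed in 1:5) {
    d <- random_dataset(m = 50, n = 7, seed = seed)
    xn <- apply(as.matrix(d[paste0("ind", 1:7)]), 2, min_max_normalize)
    ref <- min_max_normalize(d$label)
    s <- grey_coefficients(ref, xn)
    r_eq <- weighted_degree(s, rep(1 / 7, 7))
    expect_equal(7 * as.numeric(r_eq), deng_gra_degree(ref, xn),
                 tolerance = 1e-12)
  }
})

test_that("selection returns q indicators ranked by degree with stable ties", {
  d <- random_dataset(m = 40, n = 5, seed = 2)
  sel <- select_features(d, q = 3)
  expect_length(sel$selected, 3)
  expect_true(!is.unsorted(rev(sel$ranking$degree)))
  expect_error(select_features(d, q = 9), "q must")
  # duplicated columns tie exactly; original column order breaks the tie
  dd <- d
  dd$ind5 <- dd$ind1
  seld <- select_features(dd, q = 5)
  rk <- seld$ranking
  expect_lt(which(rk$indicator == "ind1"), which(rk$indicator == "ind5"))
})
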