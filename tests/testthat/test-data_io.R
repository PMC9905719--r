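make_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

full_row <- function(...) {
  base <- data.frame(do = 8, temp = 15, turbidity = 0.8, nh3n = 0.1,
                     codmn = 1.5, ph = 7.2, tds = 120, label = 1)
  over <- list(...)
  base[names(over)] <- over
  base
}

test_that("CSV reading preserves rows, drops incomplete ones and checks the schema", {
  df <- rbind(full_row(), full_row(do = 6.5, label = 2), full_row(codmn = 5, label = 3))
  d <- read_water_csv(make_csv(df))
  expect_equal(nrow(d), 3L)
  expect_equal(d$do, df$do)
  expect_equal(attr(d, "dropped"), 0L)

  df2 <- df
  df2$codmn[2] <- NA
  expect_message(d2 <- read_water_csv(make_csv(df2)), "1 row")
  expect_equal(nrow(d2), 2L)
  expect_equal(attr(d2, "dropped"), 1L)
  expect_equal(d2$label, c(1L, 3L))  # order preserved

  df3 <- df[setdiff(names(df), "ph")]
  expect_error(read_water_csv(make_csv(df3)), "schema error.*ph")

  empty <- make_csv(df[0, ])
  expect_error(read_water_csv(empty), "empty")
})

test_that("Roman class labels and custom column names map through the schema", {
  df <- rbind(full_row(), full_row(label = 2))
  names(df)[names(df) == "do"] <- "DO_mgL"
  df$label <- c("I", "poor V")
  d <- read_water_csv(make_csv(df), water_schema(do = "DO_mgL"))
  expect_equal(d$label, c(1L, 6L))
})

test_that("min-max normalization maps endpoints and rejects constant series", {
  expect_equal(min_max_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_error(min_max_normalize(c(5, 5, 5)), "degenerate")
  # observed DO min/max/mean: the mean lands at (9.03-0.5)/(25.67-0.5)
  expect_equal(min_max_normalize(c(0.5, 25.67, 9.03)),
               c(0, 1, 8.53 / 25.17))
})

test_that("min-max normalization is idempotent and affine-invariant", {
  set.seed(7)
  for (i in 1:10) {
    x <- runif(30, -5, 20)
    y <- min_max_normalize(x)
    expect_true(all(y >= 0 & y <= 1))
    expect_equal(min_max_normalize(y), y)
    expect_equal(min_max_normalize(3.7 * x + 11), y)
    expect_equal(order(x), order(y))
  }
})

test_that("standard classification matches the class limits", {
  s <- data.frame(do = 9, nh3n = 0.1, codmn = 1.5, tds = 100)
  expect_equal(classify_by_standard(s), 1L)
  s$codmn <- 12  # in (10, 15] -> class V
  expect_equal(classify_by_standard(s), 5L)
  s$codmn <- 1.5
  s$nh3n <- 6.47  # beyond the 2.0 class-V limit -> poor V
  expect_equal(classify_by_standard(s), 6L)
  # boundary values sit in the better class (<= / >= comparisons)
  b <- data.frame(do = 7.5, nh3n = 0.15, codmn = 2, tds = 150)
  expect_equal(classify_by_standard(b), 1L)
})

test_that("turbidity and pH only set advisory flags, never the class", {
  s <- full_row(turbidity = 2000, ph = 5)
  expect_equal(classify_by_standard(s), 1L)
  fl <- classify_by_standard(s, flags = TRUE)
  expect_false(fl$turbidity_ok)
  expect_false(fl$ph_ok)
  expect_true(classify_by_standard(full_row(), flags = TRUE)$ph_ok)
})

test_that("worsening any limited indicator never improves the class", {
  set.seed(42)
  rng <- indicator_ranges()
  rownames(rng) <- rng$indicator
  for (i in 1:50) {
    s <- data.frame(do = runif(1, 0.5, 25), nh3n = runif(1, 0.02, 6),
                    codmn = runif(1, 0.25, 22), tds = runif(1, 48, 600))
    c0 <- classify_by_standard(s)
    worse <- list(
      within(s, do <- do * 0.7),
      within(s, nh3n <- nh3n * 1.5),
      within(s, codmn <- codmn * 1.5),
      within(s, tds <- tds * 1.3)
    )
    for (w in worse) expect_gte(classify_by_standard(w), c0)
  }
})

test_that("stratified split preserves class proportions, is seeded and validates input", {
  d <- data.frame(x = runif(100), label = rep(1:2, each = 50))
  sp <- stratified_split(d, 0.2, seed = 9)
  expect_equal(unname(table(sp$test$label)), c(10L, 10L), ignore_attr = TRUE)
  expect_equal(nrow(sp$train) + nrow(sp$test), 100L)
  sp2 <- stratified_split(d, 0.2, seed = 9)
  expect_identical(attr(sp, "test_idx"), attr(sp2, "test_idx"))
  expect_identical(sp$train, sp2$train)
  expect_error(stratified_split(d, 0), "test_fraction")
  d1 <- data.frame(x = runif(3), label = c(1, 1, 2))
  expect_error(stratified_split(d1, 0.5), "stratification")
})
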