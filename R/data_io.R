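#' Column schema for monitoring CSV files
#'
#' Maps the canonical indicator names used throughout the package to the
#' column names found in a CSV file, plus the (optional) label column and
#' the severity direction of each indicator. Dissolved oxygen is the one
#' indicator for which *higher* values mean *better* water; all other
#' limited indicators worsen as they grow. The direction is consumed by the
#' grey relational stage, which compares indicator series to a pollution
#' severity reference.
#'
#' @param ... Named overrides, canonical name = CSV column name, e.g.
#'   `do = "DO_mgL"`.
#' @param label CSV column holding the quality class (Roman numerals
#'   I..V / "poor V", or integers 1..6). `NA` if the file is unlabelled.
#' @return A `water_schema` list with elements `columns`, `label`,
#'   `direction`.
#' @export
#' @examples
#' water_schema(do = "DO", nh3n = "NH3.N")
water_schema <- function(..., label = "label") {
  columns <- setNames(wq_indicators(), wq_indicators())
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), wq_indicators())
    if (length(bad)) stopf("unknown indicator(s) in schema: %s",
                           paste(bad, collapse = ", "))
    columns[names(over)] <- unlist(over)
  }
  direction <- setNames(rep(1, 7), wq_indicators())
  direction["do"] <- -1  # severity decreases as DO increases
  structure(list(columns = columns, label = label, direction = direction),
            class = "water_schema")
}

roman_labels <- function() c("I", "II", "III", "IV", "V", "poor V")

parse_labels <- function(x) {
  if (is.numeric(x)) {
    lab <- as.integer(x)
  } else {
    x <- trimws(as.character(x))
    lab <- match(x, roman_labels())
    num <- suppressWarnings(as.integer(x))
    lab[is.na(lab)] <- num[is.na(lab)]
  }
  if (any(is.na(lab) | lab < 1L | lab > 6L)) {
    stopf("labels must be I..V/'poor V' or integers in 1..6")
  }
  lab
}

#' Read a water-quality monitoring CSV
#'
#' Reads a comma-separated, header-bearing file, maps columns through the
#' schema, coerces indicators to numeric and drops (with a logged count)
#' any row with a missing or unparseable indicator value. Row order is
#' preserved.
#'
#' @param path CSV file path.
#' @param schema A [water_schema()].
#' @return Data frame with the seven canonical indicator columns and, when
#'   present in the file, an integer `label` column (1..6). The number of
#'   dropped rows is attached as attribute `dropped`.
#' @export
read_water_csv <- function(path, schema = water_schema()) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stopf("input file is empty: %s", path)
  miss <- setdiff(unname(schema$columns), names(raw))
  if (length(miss)) {
    stopf("schema error: missing column(s) %s", paste(miss, collapse = ", "))
  }
  out <- as.data.frame(lapply(setNames(wq_indicators(), wq_indicators()),
                              function(ind) {
                                suppressWarnings(as.numeric(raw[[schema$columns[[ind]]]]))
                              }))
  keep <- rowSums(is.na(out[wq_indicators()])) == 0L
  dropped <- sum(!keep)
  if (dropped > 0L) {
    wq_note("clean", dropped, " row(s) dropped (missing/unparseable indicator)")
  }
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) stopf("no complete rows after cleaning: %s", path)
  if (!is.na(schema$label) && schema$label %in% names(raw)) {
    out$label <- parse_labels(raw[[schema$label]][keep])
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Write a dataset in the CSV dialect the reader expects
#'
#' @param data Data frame of indicators (and optionally `label`).
#' @param path Output path.
#' @export
write_water_csv <- function(data, path) {
  write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Min-max normalization to \[0, 1\]
#'
#' Linear rescaling `(x - min x) / (max x - min x)`; the minimum maps to 0,
#' the maximum to 1, order is preserved. A constant series has no scale and
#' raises a degenerate-column error (the caller decides whether to drop the
#' indicator).
#'
#' @param x Numeric vector, length >= 2, not constant.
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' min_max_normalize(c(2, 4, 6))  # 0, 0.5, 1
min_max_normalize <- function(x) {
  if (length(x) < 2L) stopf("need at least 2 values to normalize")
  if (!all(is.finite(x))) stopf("values must be finite")
  rng <- range(x)
  if (rng[2] <= rng[1]) stopf("degenerate column: constant series (max == min)")
  (x - rng[1]) / (rng[2] - rng[1])
}

# Scaler fitted on training data only; applied unchanged to test data, so
# test values may fall outside [0, 1].
fit_scaler <- function(x) {
  x <- as.matrix(x)
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  if (any(maxs <= mins)) {
    stopf("degenerate column: constant feature(s) %s",
          paste(colnames(x)[maxs <= mins], collapse = ", "))
  }
  list(mins = mins, maxs = maxs, names = colnames(x))
}

apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  if (!identical(colnames(x), scaler$names)) {
    x <- x[, scaler$names, drop = FALSE]
  }
  sweep(sweep(x, 2L, scaler$mins, "-"), 2L,
        scaler$maxs - scaler$mins, "/")
}

#' Stratified train/test split
#'
#' Splits a labelled dataset so that per-class proportions are preserved
#' within rounding; the partition is disjoint, exhaustive and reproducible
#' for a given seed.
#'
#' @param data Data frame with a `label` column.
#' @param test_fraction Proportion assigned to the test set, in (0, 1).
#' @param seed Integer seed.
#' @return List with data frames `train` and `test`; row indices of the
#'   test set (relative to `data`) attached as `attr(, "test_idx")`.
#' @export
stratified_split <- function(data, test_fraction = 0.2, seed = 1L) {
  if (!"label" %in% names(data)) stopf("data must carry a 'label' column")
  if (!is.numeric(test_fraction) || length(test_fraction) != 1L ||
      test_fraction <= 0 || test_fraction >= 1) {
    stopf("test_fraction must lie strictly between 0 and 1")
  }
  tab <- table(data$label)
  if (any(tab < 2L)) {
    stopf("stratification error: class(es) %s have fewer than 2 samples",
          paste(names(tab)[tab < 2L], collapse = ", "))
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(data)), data$label), function(idx) {
      n_test <- max(1L, round(length(idx) * test_fraction))
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  out <- list(train = data[-test_idx, , drop = FALSE],
              test = data[test_idx, , drop = FALSE])
  rownames(out$train) <- rownames(out$test) <- NULL
  attr(out, "test_idx") <- test_idx
  out
}
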