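#' Canonical indicator set and observed ranges
#'
#' The seven routine monitoring indicators handled by the package, in
#' canonical column order, with the observed minimum/maximum of each over a
#' national river cross-section monitoring campaign (used as default
#' plausibility ranges and by the synthetic generator).
#'
#' Units: `do` mg/L, `temp` degrees C, `turbidity` NTU, `nh3n` mg/L,
#' `codmn` mg/L, `ph` dimensionless, `tds` mg/L.
#'
#' @return A data frame with columns `indicator`, `min`, `max`, `mean` and
#'   one row per indicator, in canonical order.
#' @export
#' @examples
#' indicator_ranges()
indicator_ranges <- function() {
  data.frame(
    indicator = c("do", "temp", "turbidity", "nh3n", "codmn", "ph", "tds"),
    min  = c(0.5, 0.04, 0.22, 0.02, 0.25, 6.14, 47.43),
    max  = c(25.67, 35.22, 2559.22, 6.47, 22.66, 9.98, 323.12),
    mean = c(9.03, 16.85, 47.03, 0.19, 3.20, 7.5, 185.07),
    stringsAsFactors = FALSE
  )
}

wq_indicators <- function() indicator_ranges()$indicator

#' Surface-water quality class limits (GB3838-2002)
#'
#' Per-class limits of the surface-water environmental quality standard for
#' the indicators that carry class bands: lower limits for dissolved oxygen
#' (compared with `>=`) and upper limits for ammonia nitrogen, permanganate
#' index and total dissolved solids (compared with `<=`), for classes
#' I through V. Samples beyond any class-V limit fall in class 6 ("poor V").
#' Turbidity and pH have only single advisory limits (1 NTU drinking-water
#' turbidity; pH range 6-9), so they never influence the class and are
#' reported as pass/fail flags instead.
#'
#' @param do_min,nh3n_max,codmn_max,tds_max Numeric length-5 vectors of
#'   class I-V limits. Defaults are the published standard values.
#' @param turbidity_limit,ph_range Advisory limits.
#' @return An object of class `class_standard`.
#' @export
#' @examples
#' std <- gb3838_standard()
#' std$nh3n_max
gb3838_standard <- function(do_min = c(7.5, 6, 5, 3, 1),
                            nh3n_max = c(0.15, 0.5, 1.0, 1.5, 2.0),
                            codmn_max = c(2, 4, 6, 10, 15),
                            tds_max = c(150, 300, 450, 550, 550),
                            turbidity_limit = 1,
                            ph_range = c(6, 9)) {
  for (v in list(do_min, nh3n_max, codmn_max, tds_max)) {
    if (length(v) != 5L || !all(is.finite(v))) {
      stopf("class limits must be finite length-5 vectors (classes I-V)")
    }
  }
  if (any(diff(do_min) > 0)) {
    stopf("DO lower limits must be non-increasing from class I to V")
  }
  for (nm in c("nh3n_max", "codmn_max", "tds_max")) {
    v <- get(nm)
    if (any(diff(v) < 0)) stopf("%s limits must be non-decreasing I to V", nm)
  }
  structure(
    list(do_min = do_min, nh3n_max = nh3n_max, codmn_max = codmn_max,
         tds_max = tds_max, turbidity_limit = turbidity_limit,
         ph_range = ph_range),
    class = "class_standard"
  )
}

# Per-indicator class for an "upper limit" indicator (<=); 6 beyond class V.
class_from_upper <- function(x, limits) {
  cls <- rep.int(6L, length(x))
  for (c in 5:1) cls[x <= limits[c]] <- c
  cls
}

# Per-indicator class for DO (lower limit, >=); 6 below the class-V limit.
class_from_do <- function(x, limits) {
  cls <- rep.int(6L, length(x))
  for (c in 5:1) cls[x >= limits[c]] <- c
  cls
}

#' Classify samples against the surface-water standard
#'
#' Single-factor assessment: each band-limited indicator (DO, NH3-N, CODMn,
#' TDS) is assigned the best (lowest) class whose limit it satisfies, and the
#' sample class is the worst (largest) of these per-indicator classes. An
#' indicator beyond its class-V limit puts the sample in class 6 ("poor V").
#' Turbidity and pH do not enter the class; they are advisory flags only.
#'
#' @param data Data frame with (at least) numeric columns `do`, `nh3n`,
#'   `codmn`, `tds`; `turbidity` and `ph` are used for the flags if present.
#' @param std A [gb3838_standard()] object.
#' @param flags If `TRUE`, return a data frame with the per-indicator
#'   classes and advisory flags alongside the class.
#' @return Integer vector of classes in 1..6, or a data frame when
#'   `flags = TRUE`.
#' @export
#' @examples
#' s <- data.frame(do = 9, nh3n = 0.1, codmn = 1.5, tds = 100)
#' classify_by_standard(s)            # class I
#' s$codmn <- 12
#' classify_by_standard(s)            # CODMn in (10, 15] -> class V
classify_by_standard <- function(data, std = gb3838_standard(),
                                 flags = FALSE) {
  need <- c("do", "nh3n", "codmn", "tds")
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("missing indicator column(s): %s",
                          paste(miss, collapse = ", "))
  vals <- data[need]
  if (!all(vapply(vals, function(v) all(is.finite(v)), logical(1)))) {
    stopf("indicator values must be finite")
  }
  per <- cbind(
    do    = class_from_do(data$do, std$do_min),
    nh3n  = class_from_upper(data$nh3n, std$nh3n_max),
    codmn = class_from_upper(data$codmn, std$codmn_max),
    tds   = class_from_upper(data$tds, std$tds_max)
  )
  cls <- as.integer(apply(per, 1L, max))
  if (!flags) return(cls)
  out <- data.frame(class = cls, per, check.names = FALSE)
  if ("turbidity" %in% names(data)) {
    out$turbidity_ok <- data$turbidity <= std$turbidity_limit
  }
  if ("ph" %in% names(data)) {
    out$ph_ok <- data$ph >= std$ph_range[1] & data$ph <= std$ph_range[2]
  }
  out
}

# Class band of one limited indicator, intersected with a plausibility
# range. For "upper" indicators class c occupies (limit_{c-1}, limit_c];
# for DO class c occupies [limit_c, limit_{c-1}). Returns c(lo, hi) or NULL
# when the band is empty under the range cap.
class_band <- function(indicator, cls, std = gb3838_standard(),
                       ranges = indicator_ranges()) {
  rng <- unlist(ranges[ranges$indicator == indicator, c("min", "max")])
  if (indicator == "do") {
    hi <- if (cls == 1L) rng[2] else std$do_min[cls - 1L]
    lo <- if (cls == 6L) rng[1] else max(std$do_min[cls], rng[1])
    hi <- min(hi, rng[2])
  } else {
    limits <- switch(indicator, nh3n = std$nh3n_max, codmn = std$codmn_max,
                     tds = std$tds_max,
                     stopf("indicator '%s' has no class bands", indicator))
    lo <- if (cls == 1L) rng[1] else max(limits[cls - 1L], rng[1])
    hi <- if (cls == 6L) rng[2] else min(limits[cls], rng[2])
  }
  if (hi <= lo) return(NULL)
  c(lo = unname(lo), hi = unname(hi))
}
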