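#' Synthetic dataset settings
#'
#' Configuration for [generate_water_data()]. Defaults emulate the
#' structure of a national river monitoring campaign: the seven indicators
#' span their observed ranges ([indicator_ranges()]), the four band-limited
#' indicators (DO, NH3-N, CODMn, TDS) carry the class information, and all
#' six standard classes are equally represented.
#'
#' @param n_per_class Samples per class, >= 1.
#' @param classes Integer classes to generate, subset of 1..6.
#' @param seed Integer seed.
#' @param ranges Plausibility ranges per indicator, as from
#'   [indicator_ranges()].
#' @param informative Indicator names that determine the label (drawn
#'   inside their class bands); the rest are label-independent noise drawn
#'   uniformly over their full range. Must be band-limited indicators.
#' @param noise_sd Standard deviation of optional Gaussian measurement
#'   noise added to the informative indicators *after* labelling (in units
#'   of each indicator's band width). The default 0 keeps generated labels
#'   exactly consistent with [classify_by_standard()].
#' @param nonlinear If `TRUE`, overwrite `temp` and `turbidity` with
#'   class-indexed annulus coordinates (radially separable, not linearly
#'   separable), for exercising nonlinear kernels.
#' @param std A [gb3838_standard()].
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_per_class = 100L, classes = 1:6, seed = 1L,
                         ranges = indicator_ranges(),
                         informative = c("do", "nh3n", "codmn", "tds"),
                         noise_sd = 0, nonlinear = FALSE,
                         std = gb3838_standard()) {
  if (!is_count(n_per_class)) stopf("n_per_class must be a count >= 1")
  classes <- as.integer(classes)
  if (length(classes) < 1L || any(!classes %in% 1:6)) {
    stopf("classes must be a non-empty subset of 1..6")
  }
  if (length(informative) == 0L) {
    stopf("config error: informative set must not be empty")
  }
  banded <- c("do", "nh3n", "codmn", "tds")
  if (!all(informative %in% banded)) {
    stopf("informative indicators must be band-limited (%s)",
          paste(banded, collapse = ", "))
  }
  if (any(ranges$max <= ranges$min)) stopf("ranges require min < max")
  structure(list(n_per_class = as.integer(n_per_class), classes = classes,
                 seed = seed, ranges = ranges, informative = informative,
                 noise_sd = noise_sd, nonlinear = isTRUE(nonlinear),
                 std = std),
            class = "synth_config")
}

# Band to draw an informative indicator from for class cls; when the exact
# band is empty under the range cap (possible for TDS, whose class IV/V
# limits coincide and exceed the observed maximum), fall back to the
# highest feasible band below, which cannot raise the sample's class.
draw_band <- function(indicator, cls, std, ranges) {
  for (c_try in cls:1) {
    b <- class_band(indicator, c_try, std, ranges)
    if (!is.null(b)) return(b)
  }
  stopf("no feasible band for %s at class %d", indicator, cls)
}

#' Generate a synthetic water-quality dataset
#'
#' For each requested class c, informative indicators are drawn uniformly
#' inside their class-c band (DO in `[limit_c, limit_{c-1})`, upper-limited
#' indicators in `(limit_{c-1}, limit_c]`; class 6 beyond the class-V
#' limit, capped at the observed maxima) and non-informative indicators
#' uniformly over their full observed range; the label is the generating
#' class. With the default configuration the labels are exactly
#' reproducible by [classify_by_standard()].
#'
#' With `nonlinear = TRUE`, `temp` and `turbidity` are replaced by points
#' on class-indexed annuli (common centre, radius growing with the class
#' position), a structure a linear kernel cannot separate.
#'
#' @param cfg A [synth_config()].
#' @return Data frame with the seven indicator columns and an integer
#'   `label` column, `n_per_class * length(classes)` rows.
#' @export
#' @examples
#' d <- generate_water_data(synth_config(n_per_class = 5, seed = 42))
#' table(d$label, classify_by_standard(d))
generate_water_data <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    rng <- cfg$ranges
    rownames(rng) <- rng$indicator
    label <- rep(cfg$classes, each = cfg$n_per_class)
    m <- length(label)
    out <- data.frame(matrix(NA_real_, m, 7,
                             dimnames = list(NULL, wq_indicators())))
    for (ind in wq_indicators()) {
      if (ind %in% cfg$informative) {
        for (cls in cfg$classes) {
          b <- draw_band(ind, cls, cfg$std, rng)
          sel <- label == cls
          out[[ind]][sel] <- runif(sum(sel), b["lo"], b["hi"])
        }
        if (cfg$noise_sd > 0) {
          width <- diff(range(out[[ind]])) / 6
          out[[ind]] <- pmin(pmax(out[[ind]] +
                                    rnorm(m, 0, cfg$noise_sd * width),
                                  rng[ind, "min"]), rng[ind, "max"])
        }
      } else {
        out[[ind]] <- runif(m, rng[ind, "min"], rng[ind, "max"])
      }
    }
    if (cfg$nonlinear) {
      pos <- match(label, cfg$classes)
      kk <- length(cfg$classes)
      radius <- runif(m, (pos - 0.8) / kk, (pos - 0.2) / kk)
      angle <- runif(m, 0, 2 * pi)
      u <- 0.5 + 0.5 * radius * cos(angle)   # in [0, 1]
      v <- 0.5 + 0.5 * radius * sin(angle)
      out$temp <- rng["temp", "min"] + u * (rng["temp", "max"] - rng["temp", "min"])
      out$turbidity <- rng["turbidity", "min"] +
        v * (rng["turbidity", "max"] - rng["turbidity", "min"])
    }
    out$label <- label
    out
  })
}
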