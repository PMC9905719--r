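# Internal helpers shared across modules.

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Stage-tagged progress note. Uses message() so callers can suppress or
# capture; never writes to stdout (keeps piped CLI output clean).
wq_note <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)

# Deterministic number formatting for report files (full double precision).
fmt_num <- function(x) formatC(x, digits = 15, format = "g")
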