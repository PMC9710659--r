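# Internal helpers shared across modules.

# Clamp x into [lo, hi].
clamp <- function(x, lo = -1, hi = 1) pmin(hi, pmax(lo, x))

# Clamp a cosine to [-1, 1] only when it overshoots by at most `tol`;
# larger overshoots indicate geometrically inconsistent inputs.
clamp_cosine <- function(x, tol = 1e-9) {
  bad <- is.finite(x) & (abs(x) > 1 + tol)
  if (any(bad)) {
    abort(
      sprintf(
        "cosine magnitude exceeds 1 by more than %g (max |cos| = %.12g); distances are not Euclidean-consistent",
        tol, max(abs(x[bad]))
      ),
      class = "geosec_geometry_inconsistency"
    )
  }
  clamp(x)
}

stop_validation <- function(msg) abort(msg, class = "geosec_validation_error")
stop_format <- function(msg) abort(msg, class = "geosec_format_error")
stop_degenerate <- function(msg) abort(msg, class = "geosec_degenerate_geometry")
stop_insufficient <- function(msg) abort(msg, class = "geosec_insufficient_structure")
stop_config <- function(msg) abort(msg, class = "geosec_config_error")

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == as.integer(x) && x >= min
}

is_number <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Deterministic local RNG: evaluate `expr` under `seed` without touching the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}
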