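#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage index to a new seed in
#' `[1, 2^31 - 2]`, so every stochastic stage of a pipeline run can be seeded
#' from one integer.
#'
#' @param master integer master seed.
#' @param k integer stage/repeat index.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, k) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(k), length(k) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- (abs(as.numeric(master)) %% m) * 48271 + (abs(as.numeric(k)) + 1) * 16807
  as.integer(s %% (m - 1) + 1)
}

# Evaluate expr with a locally set RNG seed, restoring global RNG state after.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Metadata columns of a feature table; everything else numeric is a feature.
.META_COLS <- c("spectrum_id", "patient_id", "point_id", "label")

feature_cols <- function(df) {
  cand <- setdiff(names(df), .META_COLS)
  cand[vapply(df[cand], is.numeric, logical(1))]
}

.TISSUE_CLASSES <- c("liver", "BT", "HCC", "MTS")

stop_with <- function(...) stop(sprintf(...), call. = FALSE)
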