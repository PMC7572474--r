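#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Assert that x is a square symmetric distance-like matrix with zero diagonal.
check_dist_matrix <- function(D, name = "D") {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop(name, " must be a square matrix", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8)
    stop(name, " must be symmetric", call. = FALSE)
  if (max(abs(diag(D))) > 1e-8)
    stop(name, " must have a zero diagonal", call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
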