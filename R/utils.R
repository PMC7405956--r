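#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map2 pmap map_dbl map_lgl
#' @importFrom stats approx integrate median pchisq pnorm pt qt rnorm runif
#'   rgamma sd var fft setNames rbinom complete.cases
NULL

# error function (needed for Gaussian integrals)
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Trapezoidal integral
#'
#' @param x abscissa, strictly increasing
#' @param y ordinate, same length
#' @return scalar integral
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
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
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# circular 2-D shift of a matrix: positive dy moves content down, dx right
circshift2 <- function(m, dy, dx) {
  nr <- nrow(m)
  nc <- ncol(m)
  dy <- ((dy %% nr) + nr) %% nr
  dx <- ((dx %% nc) + nc) %% nc
  if (dy != 0) m <- m[c((nr - dy + 1):nr, seq_len(nr - dy)), , drop = FALSE]
  if (dx != 0) m <- m[, c((nc - dx + 1):nc, seq_len(nc - dx)), drop = FALSE]
  m
}

boundary_names <- c("ILM", "RNFL_GCL", "GCL_IPL", "IPL_INL", "OPL", "RPE")
phantom_layers <- c("RNFL", "GCL", "IPL", "INL_OPL", "OUTER")
derived_layers <- c("TRT", "GCL", "IPL", "GCIPL")
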