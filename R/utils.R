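#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif aggregate convolve sd quantile
#' @importFrom utils read.csv write.csv head tail
NULL

# Internal assertion helper: stop with the caller's message if cond is FALSE.
abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(NULL)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

# 0-based pixel-centre coordinates of an image of given width/height.
# Convention used throughout: origin top-left, x grows rightwards (columns),
# y grows downwards (rows); the centre of matrix cell [i, j] is (j - 1, i - 1).
image_center <- function(width, height) {
  c(x = (width - 1) / 2, y = (height - 1) / 2)
}

# Local RNG scope: evaluates expr with a temporary seed without disturbing
# the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}
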