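# Internal helpers shared across modules.

#' Evaluate an expression with a temporarily seeded RNG
#'
#' Restores the caller's RNG state afterwards, so seeded package functions do
#' not perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a parent seed and a stream index,
# staying well inside 32-bit integer range.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103L + index * 12347L) %% 2147483562) + 1L
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

# Rotation matrix sending the camera to look from `eye` toward `target`,
# returning the world->camera rotation (camera z forward, x right, y down).
lookAtRotation <- function(eye, target, worldUp = c(0, 0, 1)) {
  zc <- unitv(target - eye)
  xc <- pracmaFreeCross(zc, worldUp)
  if (vnorm(xc) < 1e-9) xc <- pracmaFreeCross(zc, c(0, 1, 0))
  xc <- unitv(xc)
  yc <- pracmaFreeCross(zc, xc)
  rbind(xc, yc, zc, deparse.level = 0)
}

# 3-vector cross product (kept local; no dependency needed for one primitive).
pracmaFreeCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Signed angle (degrees, counter-clockwise positive) from 2D vector a to b.
signedAngleDeg <- function(a, b) {
  atan2(a[1] * b[2] - a[2] * b[1], a[1] * b[1] + a[2] * b[2]) * 180 / pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a
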