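# Internal helpers: classed error conditions, small vector algebra, seeding.

paStop <- function(msg, class, call. = FALSE, ...) {
  cond <- structure(
    class = c(class, "pipetteAimError", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

assertPoint3 <- function(p, what = "point") {
  if (!is.numeric(p) || length(p) != 3L || any(!is.finite(p)))
    paStop(sprintf("%s must be a finite numeric vector of length 3", what),
           "invalidParameter")
  as.numeric(p)
}

assertUnitAxis <- function(axis, tol = 1e-6) {
  axis <- assertPoint3(axis, "axis")
  n <- vnorm(axis)
  if (abs(n - 1) > tol)
    paStop(sprintf("axis must have unit norm (got %.8f)", n),
           "invalidParameter")
  axis / n
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

# Orthonormal basis {e1, e2} of the plane perpendicular to a unit axis.
#' Lateral basis of the plane perpendicular to the pipette axis
#'
#' Returns two orthonormal vectors spanning the plane perpendicular to
#' \code{axis}, used to draw lateral deflection/displacement vectors.
#'
#' @param axis unit 3-vector.
#' @return a 2-row matrix whose rows are the basis vectors.
#' @export
lateralBasis <- function(axis) {
  axis <- assertUnitAxis(axis)
  ref <- if (abs(axis[3L]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- cross3(ref, axis)
  e1 <- e1 / vnorm(e1)
  e2 <- cross3(axis, e1)
  rbind(e1, e2)
}

# Rotation matrix taking unit vector a onto unit vector b (Rodrigues).
rotationAlign <- function(a, b) {
  a <- assertUnitAxis(a); b <- assertUnitAxis(b)
  v <- cross3(a, b)
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {
    # antiparallel: rotate pi about any axis perpendicular to a
    p <- lateralBasis(a)[1L, ]
    return(2 * tcrossprod(p) - diag(3))
  }
  vx <- matrix(c(0, v[3L], -v[2L],
                 -v[3L], 0, v[1L],
                 v[2L], -v[1L], 0), 3L, 3L)
  diag(3) + vx + vx %*% vx / (1 + cth)
}
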