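# Small internal geometry helpers shared across modules.

vnorm <- function(x) sqrt(sum(x^2))

unitize <- function(x, tol = 1e-12) {
  n <- vnorm(x)
  if (n < tol) stop("cannot normalize a (near-)zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Deterministic in-plane frame for a plane normal
#'
#' Given a unit normal, returns orthonormal in-plane axes `u`, `v` with
#' `u x v = normal` (right-handed). `u` is the world x-axis projected
#' orthogonally to the normal; when the normal is (anti)parallel to x the
#' world y-axis is used instead. The rule is deterministic so that repeated
#' runs build identical planes.
#'
#' @param normal unit 3-vector.
#' @return list with unit 3-vectors `u` and `v`.
#' @keywords internal
orthonormal_frame <- function(normal) {
  n <- unitize(normal)
  ref <- c(1, 0, 0)
  u <- ref - sum(ref * n) * n
  if (vnorm(u) < 1e-6) {
    ref <- c(0, 1, 0)
    u <- ref - sum(ref * n) * n
  }
  u <- unitize(u)
  v <- cross3(n, u)
  list(u = u, v = v)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Trapezoidal integral of flow rates (mL/s) sampled at times in ms -> mL.
trapz_ml <- function(times_ms, rates_ml_s) {
  pracma::trapz(times_ms / 1000, rates_ml_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
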