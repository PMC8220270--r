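## Small dense-linear-algebra helpers shared by every analysis module.
## Vectors handled here are loading vectors over p limb elements (p = 6 or 7
## under the default configs), so everything is written for small p and
## moderate n; no sparse or blocked paths are needed.

#' Rescale a vector to unit Euclidean norm
#' @param v numeric vector, not all zero
#' @return `v / ||v||`
#' @keywords internal
#' @noRd
.unitize <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("cannot normalize a zero or non-finite vector")
  v / nrm
}

#' Orient a loading vector so its coefficient sum is positive
#'
#' All bones elongate through ontogeny, so the biologically meaningful major
#' axis has positive loadings; fixing the sign this way makes angles between
#' axes well defined without absolute values. Ties (sum exactly zero) fall
#' back to the sign of the first nonzero coefficient.
#' @keywords internal
#' @noRd
.orientPositive <- function(v) {
  s <- sum(v)
  if (s < 0) return(-v)
  if (s == 0) {
    nz <- v[v != 0]
    if (length(nz) && nz[1] < 0) return(-v)
  }
  v
}

#' Angle between two unit vectors, in degrees
#' @keywords internal
#' @noRd
.angleDeg <- function(v1, v2) {
  if (length(v1) != length(v2))
    stop("vectors differ in length (", length(v1), " vs ", length(v2), ")")
  d <- sum(.unitize(v1) * .unitize(v2))
  acos(min(1, max(-1, d))) * 180 / pi
}

#' First principal axis of a data matrix
#'
#' Column-centers `X` (rows = observations) and returns the leading right
#' singular vector, oriented to positive coefficient sum, together with the
#' fraction of total variance it carries.
#' @return list(vector, variance_fraction, center, d = singular values)
#' @keywords internal
#' @noRd
.pc1 <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("matrix contains missing values; impute first")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  sv <- svd(Xc, nu = 0L)
  tot <- sum(sv$d^2)
  if (tot <= 0) stop("zero total variance; no principal axis is defined")
  list(vector = .orientPositive(sv$v[, 1L]),
       variance_fraction = sv$d[1L]^2 / tot,
       center = ctr,
       d = sv$d)
}

#' Minimal rotation carrying one unit vector onto another
#'
#' Returns the orthogonal matrix that rotates `from` onto `to` within the
#' plane the two vectors span and acts as the identity on the orthogonal
#' complement. Degenerate cases: identical vectors give the identity;
#' antipodal vectors have no unique minimal rotation and raise an error.
#'
#' @param from,to unit vectors of equal length.
#' @return a p x p orthogonal matrix `R` with `R %*% from == to`.
#' @export
#' @examples
#' R <- rotationAligning(c(1, 0, 0), c(0, 1, 0))
#' R %*% c(1, 0, 0)
rotationAligning <- function(from, to) {
  from <- .unitize(from); to <- .unitize(to)
  if (length(from) != length(to)) stop("vectors differ in length")
  p <- length(from)
  cth <- sum(from * to)
  if (cth > 1 - 1e-14) return(diag(p))
  if (cth < -1 + 1e-12)
    stop("vectors are antipodal; the minimal rotation is not unique")
  w <- .unitize(to - cth * from)     # in-plane direction orthogonal to `from`
  sth <- sum((to - cth * from) * w)  # = sin(theta) >= 0
  diag(p) +
    (cth - 1) * (tcrossprod(from) + tcrossprod(w)) +
    sth * (tcrossprod(w, from) - tcrossprod(from, w))
}

#' Rotate a unit vector by a fixed angle within a random plane
#'
#' Draws a uniformly random direction orthogonal to `v` (using the current
#' RNG state) and tilts `v` towards it by `theta_deg` degrees. Used to give
#' each simulated species an axis at a controlled angle from the common one.
#' @keywords internal
#' @noRd
.tiltVector <- function(v, theta_deg) {
  v <- .unitize(v)
  if (theta_deg == 0) return(v)
  p <- length(v)
  repeat {
    z <- stats::rnorm(p)
    z <- z - sum(z * v) * v
    if (sqrt(sum(z^2)) > 1e-8) break
  }
  b <- .unitize(z)
  th <- theta_deg * pi / 180
  .unitize(cos(th) * v + sin(th) * b)
}

## Polynomial rolling hash (mod 2^31 - 1) of a character scalar; used to
## stamp result tables with a config fingerprint without a hashing
## dependency. Not cryptographic; collision resistance is irrelevant here.
.configHash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
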