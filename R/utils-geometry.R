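# Small 3-vector helpers used throughout the geometry code.  All take and
# return plain numeric vectors of length 3 (or matrices with xyz columns);
# angles are in degrees.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## angle at vertex b of the triangle a-b-c, degrees in [0, 180]
vangle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

## rotation matrix for a right-handed rotation of `deg` degrees about `axis`
rotmat <- function(axis, deg) {
  a <- vunit(axis)
  th <- deg * pi / 180
  ct <- cos(th); st <- sin(th)
  x <- a[1]; y <- a[2]; z <- a[3]
  matrix(c(
    ct + x * x * (1 - ct),     x * y * (1 - ct) - z * st, x * z * (1 - ct) + y * st,
    y * x * (1 - ct) + z * st, ct + y * y * (1 - ct),     y * z * (1 - ct) - x * st,
    z * x * (1 - ct) - y * st, z * y * (1 - ct) + x * st, ct + z * z * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

## rotate point(s) p (vector or n x 3 matrix) about an axis through `origin`
rotate_about <- function(p, origin, axis, deg) {
  R <- rotmat(axis, deg)
  if (is.matrix(p)) {
    sweep(sweep(p, 2, origin) %*% t(R), 2, origin, "+")
  } else {
    as.numeric(R %*% (p - origin)) + origin
  }
}

## any unit vector perpendicular to v (deterministic choice)
vperp <- function(v) {
  u <- vunit(v)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  vunit(vcross(u, ref))
}

## place atom D at distance `len` from `b`, with angle(a, b, D) = ang,
## and dihedral(ref, a, b, D) = dih (degrees).  Standard internal-coordinate
## (NeRF-style) placement.
place_internal <- function(ref, a, b, len, ang, dih) {
  bc <- vunit(b - a)
  n <- vunit(vcross(a - ref, bc))
  m <- vcross(n, bc)
  ang_r <- ang * pi / 180
  dih_r <- dih * pi / 180
  d2 <- c(-len * cos(ang_r),
          len * sin(ang_r) * cos(dih_r),
          len * sin(ang_r) * sin(dih_r))
  b + d2[1] * bc + d2[2] * m + d2[3] * n
}
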