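# Small 3-vector helpers shared across modules.  All angles in degrees
# unless a function name says otherwise.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle A-B-C in degrees
vangle <- function(a, b, c) {
  u <- vunit(a - b); v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# signed dihedral A-B-C-D in degrees, IUPAC convention
vdihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# NeRF atom placement: position X bonded to c with |X-c| = bond,
# angle(X, c, b) = ang and dihedral(X, c, b, a) = dih.
place_atom <- function(a, b, c, bond, ang, dih) {
  ang <- ang * pi / 180; dih <- dih * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# rotation matrix about unit axis by angle (degrees)
rot_axis <- function(axis, theta) {
  u <- vunit(axis); th <- theta * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
           uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
           uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)),
         nrow = 3, byrow = TRUE)
}

# apply rotation R (3x3) and translation t to an n x 3 coordinate matrix
xform <- function(xyz, R = diag(3), t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, -t)
}

# rows of pairwise distances between two n x 3 matrices (equal nrow)
row_dist <- function(a, b) sqrt(rowSums((a - b)^2))
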