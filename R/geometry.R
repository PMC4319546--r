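## Internal-coordinate geometry helpers.

## Place atom D given positions A, B, C, the C-D bond length, the B-C-D
## angle and the A-B-C-D dihedral (degrees): the natural-extension
## reference-frame construction.
nerf_place <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- pracma_cross(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-8) {                     # colinear reference: pick any normal
    ref <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- pracma_cross(ref, bc)
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- pracma_cross(n, bc)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  C + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("zero-length vector")
  v / nv
}
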