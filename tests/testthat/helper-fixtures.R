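# Fixtures built in code: canonical tetrahedron, icospheres, and small
# synthetic stacks shared across test files.

# unit tetrahedron (4 vertices, 4 faces)
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangle_mesh(v, f)
}

# icosphere by midpoint subdivision of an icosahedron
icosphere <- function(radius = 1, subdiv = 2) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  norm_rows <- function(m) m / sqrt(rowSums(m^2))
  v <- norm_rows(v)
  for (s in seq_len(subdiv)) {
    nf <- nrow(f)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    edges <- unique(rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
                          cbind(f[, 1], f[, 3])))
    ek <- key(edges[, 1], edges[, 2])
    mid <- norm_rows((v[edges[, 1], , drop = FALSE] +
                      v[edges[, 2], , drop = FALSE]) / 2)
    midx <- nrow(v) + seq_len(nrow(mid))
    v <- rbind(v, mid)
    lookup <- stats::setNames(midx, ek)
    m12 <- lookup[key(f[, 1], f[, 2])]
    m23 <- lookup[key(f[, 2], f[, 3])]
    m13 <- lookup[key(f[, 1], f[, 3])]
    f <- rbind(cbind(f[, 1], m12, m13), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m13, m23), cbind(m12, m23, m13))
  }
  triangle_mesh(v * radius, f)
}

# rotation about an arbitrary axis (Rodrigues)
rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# a flat square plane mesh in the x-y plane at z = z0
plane_mesh <- function(half = 50, step = 5, z0 = 0) {
  xs <- seq(-half, half, by = step)
  g <- expand.grid(x = xs, y = xs)
  n <- length(xs)
  i <- rep(seq_len(n - 1), n - 1)
  j <- rep(seq_len(n - 1), each = n - 1)
  v00 <- (j - 1) * n + i
  f <- rbind(cbind(v00, v00 + 1, v00 + n + 1), cbind(v00, v00 + n + 1, v00 + n))
  triangle_mesh(cbind(g$x, g$y, z0), f)
}

# constant-valued frame stack
const_stack <- function(value, h = 16, w = 16, n = 40, fps = 250) {
  frame_stack(array(value, c(h, w, n)), fps)
}

# sorted vertex matrix for order-insensitive mesh comparison
sorted_vertices <- function(mesh) {
  v <- mesh$vertices
  v[do.call(order, as.data.frame(v)), , drop = FALSE]
}
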