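# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (dense network assembly by explicit loops,
# closed-form loop fields) rather than calling the package's own kernels.

# Closed-form on-axis flux density of a circular loop of radius a (m) at
# axial distance z (m), current I (A).
loop_b_axis <- function(I, a, z) {
  mu0 <- 4e-7 * pi
  mu0 * I * a^2 / (2 * (a^2 + z^2)^1.5)
}

# Dense node-potential solve of the voxel impedance network, assembled with
# explicit nested loops straight from Kirchhoff's current law. Returns node
# potentials (grounded at node 1) and the per-edge total field arrays.
# grid: a tissue_grid; einc: an edge_field; sigma_mode "owner" only.
dense_network_solve <- function(grid, einc) {
  g <- grid$grid
  nx <- g$nx; ny <- g$ny; nz <- g$nz
  nx1 <- nx + 1L; ny1 <- ny + 1L; nz1 <- nz + 1L
  dx <- g$dx_mm / 1000; dy <- g$dy_mm / 1000; dz <- g$dz_mm / 1000
  sig <- sigma_arrays(grid)
  id <- function(i, j, k) (i - 1L) * ny1 * nz1 + (k - 1L) * ny1 + j
  n <- nx1 * ny1 * nz1
  A <- matrix(0, n, n)
  b <- complex(n)
  own <- function(v, lim) max(min(v, lim), 1L)
  add_edge <- function(p, q, gcond, emf) {
    A[p, p] <<- A[p, p] + gcond; A[q, q] <<- A[q, q] + gcond
    A[p, q] <<- A[p, q] - gcond; A[q, p] <<- A[q, p] - gcond
    b[p] <<- b[p] - gcond * emf
    b[q] <<- b[q] + gcond * emf
  }
  for (i in 1:nx) for (j in 1:ny1) for (k in 1:nz1) {
    s <- sig$sx[own(j - 1L, ny), own(k - 1L, nz)]
    if (s > 0)
      add_edge(id(i, j, k), id(i + 1L, j, k), s * dy * dz / dx,
               einc$ex[i, j, k] * dx)
  }
  for (i in 1:nx1) for (j in 1:ny) for (k in 1:nz1) {
    s <- sig$sy[j, own(k - 1L, nz)]
    if (s > 0)
      add_edge(id(i, j, k), id(i, j + 1L, k), s * dx * dz / dy,
               einc$ey[i, j, k] * dy)
  }
  for (i in 1:nx1) for (j in 1:ny1) for (k in 1:nz) {
    s <- sig$sz[own(j - 1L, ny), k]
    if (s > 0)
      add_edge(id(i, j, k), id(i, j, k + 1L), s * dx * dy / dz,
               einc$ez[i, j, k] * dz)
  }
  act <- which(diag(A) > 0)
  gnd <- act[1]
  keep <- setdiff(act, gnd)
  V <- complex(n)
  V[keep] <- solve(A[keep, keep], b[keep])
  Varr <- array(V, dim = c(ny1, nz1, nx1))
  ex <- einc$ex; ey <- einc$ey; ez <- einc$ez
  for (i in 1:nx) for (j in 1:ny1) for (k in 1:nz1)
    ex[i, j, k] <- ex[i, j, k] - (Varr[j, k, i + 1L] - Varr[j, k, i]) / dx
  for (i in 1:nx1) for (j in 1:ny) for (k in 1:nz1)
    ey[i, j, k] <- ey[i, j, k] - (Varr[j + 1L, k, i] - Varr[j, k, i]) / dy
  for (i in 1:nx1) for (j in 1:ny1) for (k in 1:nz)
    ez[i, j, k] <- ez[i, j, k] - (Varr[j, k + 1L, i] - Varr[j, k, i]) / dz
  list(V = V, ex = ex, ey = ey, ez = ez)
}

# Uniform synthetic incident edge field (complex), for solver tests that do
# not need a physical coil.
uniform_edge_field <- function(grid, ex = 0, ey = 0, ez = 0, f_Hz = 2000) {
  ep <- edge_points(grid)
  mk <- function(val, fam) array(as.complex(val),
                                 dim = attr(ep[[fam]], "edge_dims"))
  structure(list(ex = mk(ex, "x"), ey = mk(ey, "y"), ez = mk(ez, "z"),
                 f_Hz = f_Hz), class = "edge_field")
}

# Incident edge field with an arbitrary position-dependent generator
# f(x, y, z) -> list(ex, ey, ez); coordinates in mm.
functional_edge_field <- function(grid, fun, f_Hz = 2000) {
  ep <- edge_points(grid)
  comp <- function(fam, which) {
    p <- ep[[fam]]
    vals <- fun(p[, 1], p[, 2], p[, 3])[[which]]
    array(as.complex(vals), dim = attr(p, "edge_dims"))
  }
  structure(list(ex = comp("x", "ex"), ey = comp("y", "ey"),
                 ez = comp("z", "ez"), f_Hz = f_Hz),
            class = "edge_field")
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
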