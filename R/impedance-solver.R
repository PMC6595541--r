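## Impedance-method solver. The voxel grid becomes a resistor network: every
## voxel edge carries an impedance Z = Lv / ((sigma + j 2 pi f er e0) Av)
## built from the directional conductivity of its owning voxel. The incident
## field -j w A drives an EMF on each edge; Kirchhoff's laws give the induced
## correction. We solve the equivalent node-potential form
##   div( G (E_inc - grad V) ) = 0
## which satisfies KCL/KVL on the same network, with insulating (open-circuit)
## domain boundaries. The system is symmetric positive semi-definite; it is
## solved by deflated preconditioned CG whose preconditioner factors each
## cross-sectional node plane exactly (the geometry is extruded, so interior
## planes share one Cholesky factor).

#' Solver configuration
#'
#' @param tol relative residual tolerance of the conjugate-gradient solve.
#' @param maxit iteration cap.
#' @param allow_unconverged if `TRUE`, a solve hitting `maxit` returns with a
#'   warning and the residual history instead of erroring.
#' @return list of class `solve_config`.
#' @export
solve_config <- function(tol = 1e-8, maxit = 400, allow_unconverged = FALSE) {
  if (tol <= 0) stop_cfg("tolerance must be positive")
  structure(list(tol = tol, maxit = as.integer(maxit),
                 allow_unconverged = isTRUE(allow_unconverged)),
            class = "solve_config")
}

## SI spacings of a built grid
grid_spacing_m <- function(grid)
  list(dx = grid$grid$dx_mm / 1000, dy = grid$grid$dy_mm / 1000,
       dz = grid$grid$dz_mm / 1000)

#' Assemble the voxel impedance network
#'
#' Each edge of the voxel lattice gets the admittance
#' `(sigma + j 2 pi f er e0) Av / Lv` where `Lv` is the voxel size along the
#' edge and `Av` the transverse cross-section, using the directional
#' conductivity component along the edge. With `resistive_only = TRUE` (the
#' default; at 2 kHz the reactive part is about five orders of magnitude
#' below the conductive part for these tissues) the permittivity term is
#' dropped and the network is purely resistive. `sigma_mode` selects how an
#' edge shared by several voxels gets its conductivity: the voxel on the
#' edge's negative side (`"owner"`, default) or the arithmetic mean of the
#' adjacent voxels (`"average"`, the parallel combination of their quarter
#' cross-sections). Zero-conductivity edges become open branches.
#'
#' @param grid a [build_grid()] result.
#' @param f_Hz operating frequency in Hz.
#' @param eps_r relative permittivity (used only when
#'   `resistive_only = FALSE`).
#' @param resistive_only drop the `j w eps` term.
#' @param sigma_mode `"owner"` or `"average"`.
#' @return object of class `impedance_network`.
#' @export
edge_impedances <- function(grid, f_Hz, eps_r = 1, resistive_only = TRUE,
                            sigma_mode = c("owner", "average")) {
  if (f_Hz <= 0) stop_cfg("frequency must be positive")
  sigma_mode <- match.arg(sigma_mode)
  sig <- sigma_arrays(grid)
  g <- grid$grid
  sp <- grid_spacing_m(grid)
  ny1 <- g$ny + 1L; nz1 <- g$nz + 1L

  pick <- function(s, expand_rows, expand_cols) {
    # expand a voxel-centred (ny x nz) array onto edge index ranges using
    # either the negative-side owner or the mean of adjacent voxels
    ro <- if (expand_rows) c(1L, seq_len(nrow(s))) else seq_len(nrow(s))
    co <- if (expand_cols) c(1L, seq_len(ncol(s))) else seq_len(ncol(s))
    if (sigma_mode == "owner") return(s[ro, co, drop = FALSE])
    rp <- if (expand_rows) c(seq_len(nrow(s)), nrow(s)) else seq_len(nrow(s))
    cp <- if (expand_cols) c(seq_len(ncol(s)), ncol(s)) else seq_len(ncol(s))
    (s[ro, co, drop = FALSE] + s[rp, co, drop = FALSE] +
       s[ro, cp, drop = FALSE] + s[rp, cp, drop = FALSE]) / 4
  }
  jwe <- if (resistive_only) 0 else 2i * pi * f_Hz * eps_r * EPS0
  gx2d <- (pick(sig$sx, TRUE, TRUE) + jwe) * (sp$dy * sp$dz) / sp$dx
  gy2d <- (pick(sig$sy, FALSE, TRUE) + jwe) * (sp$dx * sp$dz) / sp$dy
  gz2d <- (pick(sig$sz, TRUE, FALSE) + jwe) * (sp$dx * sp$dy) / sp$dz
  if (resistive_only) {
    gx2d <- Re(gx2d); gy2d <- Re(gy2d); gz2d <- Re(gz2d)
  }
  if (all(gx2d == 0) && all(gy2d == 0) && all(gz2d == 0))
    stop_cfg("fully insulating grid: network is singular")
  structure(list(grid = grid, f_Hz = f_Hz, eps_r = eps_r,
                 resistive_only = resistive_only, sigma_mode = sigma_mode,
                 g = list(x = gx2d, y = gy2d, z = gz2d),
                 spacing_m = sp,
                 dims = list(nx = g$nx, ny = g$ny, nz = g$nz,
                             ny1 = ny1, nz1 = nz1, npl = ny1 * nz1,
                             nnode = (g$nx + 1L) * ny1 * nz1),
                 cache = new.env(parent = emptyenv())),
            class = "impedance_network")
}

#' Edge impedances of one axis family
#'
#' Returns the per-edge impedance `Z = 1/admittance` (ohm) as the
#' cross-sectional matrix shared by every axial station (the geometry is
#' extruded). Open branches have `Z = Inf`.
#'
#' @param network an [edge_impedances()] result.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return numeric or complex matrix of impedances.
#' @export
edge_impedance <- function(network, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  1 / network$g[[axis]]
}

## ---- node indexing -------------------------------------------------------
## node id = (i-1)*npl + (k-1)*ny1 + j   (j fastest, then k, then plane i)

node_id <- function(d, i, j, k) (i - 1L) * d$npl + (k - 1L) * d$ny1 + j

## Edge index grids per family, as flat vectors aligned with the edge arrays
## (arrays are indexed [i, j, k] with i fastest after aperm conventions below)
edge_index <- function(d, family) {
  switch(family,
    x = {
      i <- rep(seq_len(d$nx), times = d$npl)
      j <- rep(rep(seq_len(d$ny1), each = d$nx), times = d$nz1)
      k <- rep(seq_len(d$nz1), each = d$nx * d$ny1)
      list(p = node_id(d, i, j, k), q = node_id(d, i + 1L, j, k),
           g2 = cbind(j, k))
    },
    y = {
      nx1 <- d$nx + 1L
      i <- rep(seq_len(nx1), times = d$ny * d$nz1)
      j <- rep(rep(seq_len(d$ny), each = nx1), times = d$nz1)
      k <- rep(seq_len(d$nz1), each = nx1 * d$ny)
      list(p = node_id(d, i, j, k), q = node_id(d, i, j + 1L, k),
           g2 = cbind(j, k))
    },
    z = {
      nx1 <- d$nx + 1L
      i <- rep(seq_len(nx1), times = d$ny1 * d$nz)
      j <- rep(rep(seq_len(d$ny1), each = nx1), times = d$nz)
      k <- rep(seq_len(d$nz), each = nx1 * d$ny1)
      list(p = node_id(d, i, j, k), q = node_id(d, i, j, k + 1L),
           g2 = cbind(j, k))
    })
}

## dims of the three edge arrays [i, j, k]
edge_dims <- function(d)
  list(x = c(d$nx, d$ny1, d$nz1),
       y = c(d$nx + 1L, d$ny, d$nz1),
       z = c(d$nx + 1L, d$ny1, d$nz))

#' Midpoints of all voxel edges
#'
#' Evaluation points for sampling the incident field on the network: the
#' midpoint of every x-, y- and z-directed voxel edge.
#'
#' @param grid a [build_grid()] result.
#' @return list of three N x 3 matrices (mm) named `x`, `y`, `z`, each with
#'   an `edge_dims` attribute.
#' @export
edge_points <- function(grid) {
  g <- grid$grid
  ctr <- grid_axes(g); nod <- node_axes(g)
  d <- list(nx = g$nx, ny = g$ny, nz = g$nz,
            ny1 = g$ny + 1L, nz1 = g$nz + 1L)
  dims <- edge_dims(d)
  mk <- function(xs, ys, zs, dm) {
    pts <- cbind(rep(xs, times = dm[2] * dm[3]),
                 rep(rep(ys, each = dm[1]), times = dm[3]),
                 rep(zs, each = dm[1] * dm[2]))
    attr(pts, "edge_dims") <- dm
    pts
  }
  list(x = mk(ctr$x, nod$y, nod$z, dims$x),
       y = mk(nod$x, ctr$y, nod$z, dims$y),
       z = mk(nod$x, nod$y, ctr$z, dims$z))
}

#' Incident electric field sampled on the network edges
#'
#' Evaluates the vector potential of one or more windings at every edge
#' midpoint (only the component along the edge is needed) and applies
#' `E = -j 2 pi f A`. Multiple windings are superposed with the given
#' per-winding currents.
#'
#' @param windings a `winding` or list of windings (global mm coordinates).
#' @param currents per-winding peak currents in amperes (signed).
#' @param f_Hz frequency in Hz.
#' @param grid a [build_grid()] result.
#' @param singular singularity handling for points near a winding; grids
#'   interleave the coils, so the default clamps the kernel at the wire
#'   radius.
#' @return object of class `edge_field`: complex arrays `ex`, `ey`, `ez`
#'   indexed `[i, j, k]` over the respective edge family, plus `f_Hz`.
#' @export
incident_edge_field <- function(windings, currents, f_Hz, grid,
                                singular = "clamp") {
  if (inherits(windings, "winding")) windings <- list(windings)
  stopifnot(length(windings) == length(currents))
  ep <- edge_points(grid)
  acc <- lapply(ep, function(p) numeric(nrow(p)))
  for (w in seq_along(windings)) {
    if (currents[[w]] == 0) next
    for (fam in 1:3)
      acc[[fam]] <- acc[[fam]] + vector_potential(
        windings[[w]], currents[[w]], ep[[fam]],
        singular = singular, comp = fam)[, 1]
  }
  out <- lapply(1:3, function(fam)
    array(incident_efield(acc[[fam]], f_Hz),
          dim = attr(ep[[fam]], "edge_dims")))
  structure(list(ex = out[[1]], ey = out[[2]], ez = out[[3]], f_Hz = f_Hz),
            class = "edge_field")
}

## ---- system assembly and PCG --------------------------------------------

build_system <- function(network) {
  cache <- network$cache
  if (!is.null(cache$A)) return(invisible(cache))
  d <- network$dims
  nx1 <- d$nx + 1L
  ti <- list(); tj <- list(); tx <- list()
  for (fam in c("x", "y", "z")) {
    e <- edge_index(d, fam)
    gv <- as.numeric(network$g[[fam]])[
      (e$g2[, 2] - 1L) * nrow(network$g[[fam]]) + e$g2[, 1]]
    keep <- gv != 0
    p <- e$p[keep]; q <- e$q[keep]; gv <- gv[keep]
    ti[[fam]] <- c(p, q, p, q)
    tj[[fam]] <- c(q, p, p, q)
    tx[[fam]] <- c(-gv, -gv, gv, gv)
  }
  A <- Matrix::sparseMatrix(i = unlist(ti, use.names = FALSE),
                            j = unlist(tj, use.names = FALSE),
                            x = unlist(tx, use.names = FALSE),
                            dims = c(d$nnode, d$nnode))
  cache$A <- A
  dg <- Matrix::diag(A)
  cache$active <- dg > 0
  shift <- 1e-12 * mean(dg[cache$active])
  blk <- function(i) {
    rng <- ((i - 1L) * d$npl + 1L):(i * d$npl)
    B <- A[rng, rng]
    Matrix::Cholesky(Matrix::forceSymmetric(
      B + Matrix::Diagonal(d$npl, shift)), LDL = FALSE, super = TRUE)
  }
  cache$F_end <- blk(1L)
  cache$F_int <- if (nx1 > 2L) blk(2L) else NULL
  cache$nx1 <- nx1; cache$npl <- d$npl
  invisible(cache)
}

precond_apply <- function(cache, r) {
  R <- matrix(r, cache$npl, cache$nx1)
  Z <- R
  ends <- c(1L, cache$nx1)
  Z[, ends] <- as.matrix(Matrix::solve(cache$F_end, R[, ends, drop = FALSE]))
  if (cache$nx1 > 2L) {
    mid <- 2L:(cache$nx1 - 1L)
    Z[, mid] <- as.matrix(Matrix::solve(cache$F_int, R[, mid, drop = FALSE]))
  }
  as.numeric(Z)
}

pcg_solve <- function(cache, b, tol, maxit) {
  act <- cache$active
  b[!act] <- 0
  b[act] <- b[act] - mean(b[act])
  nb <- sqrt(sum(b^2))
  hist <- numeric(0)
  if (nb == 0)
    return(list(x = numeric(length(b)), relres = 0, iter = 0L,
                converged = TRUE, history = hist))
  A <- cache$A
  x <- numeric(length(b))
  r <- b
  z <- precond_apply(cache, r); z[!act] <- 0
  p <- z
  rz <- sum(r * z)
  it <- 0L; relres <- 1
  while (it < maxit) {
    it <- it + 1L
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    relres <- sqrt(sum(r^2)) / nb
    hist <- c(hist, relres)
    if (relres < tol) break
    z <- precond_apply(cache, r); z[!act] <- 0
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  x[act] <- x[act] - mean(x[act])
  list(x = x, relres = relres, iter = it, converged = relres < tol,
       history = hist)
}

## dense complex solve for the permittivity-retaining option
dense_solve_complex <- function(network, b) {
  d <- network$dims
  n <- d$nnode
  if (n > 20000L)
    stop_cfg("complex (resistive_only = FALSE) solves are limited to small ",
             "grids (", n, " nodes requested); use resistive_only = TRUE")
  A <- matrix(0 + 0i, n, n)
  dg <- complex(n)
  for (fam in c("x", "y", "z")) {
    e <- edge_index(d, fam)
    gv <- as.vector(network$g[[fam]])[
      (e$g2[, 2] - 1L) * nrow(network$g[[fam]]) + e$g2[, 1]]
    keep <- gv != 0
    p <- e$p[keep]; q <- e$q[keep]; gv <- gv[keep]
    A[cbind(p, q)] <- A[cbind(p, q)] - gv
    A[cbind(q, p)] <- A[cbind(q, p)] - gv
    accr <- rowsum(c(Re(gv), Re(gv)), c(p, q))
    acci <- rowsum(c(Im(gv), Im(gv)), c(p, q))
    ii <- as.integer(rownames(accr))
    dg[ii] <- dg[ii] + complex(real = accr[, 1], imaginary = acci[, 1])
  }
  diag(A) <- dg
  act <- Mod(dg) > 0
  # ground the first active node
  gnd <- which(act)[1]
  idx <- setdiff(which(act), gnd)
  x <- complex(n)
  x[idx] <- solve(A[idx, idx], b[idx])
  x
}

#' Solve the induced field on the impedance network
#'
#' Computes the total field `E_total = E_inc - grad V`, where the scalar
#' correction enforces Kirchhoff's current law at every node under
#' insulating domain boundaries. In a homogeneous medium the correction
#' vanishes in the interior and `E_total` approaches the incident field.
#'
#' @param network an [edge_impedances()] result.
#' @param einc an [incident_edge_field()] (same grid).
#' @param cfg a [solve_config()].
#' @return object of class `network_solution`: node potentials, per-edge and
#'   voxel-centred total fields (complex), residual history and iteration
#'   counts.
#' @export
solve_fields <- function(network, einc, cfg = solve_config()) {
  d <- network$dims
  dims <- edge_dims(d)
  if (!identical(dim(einc$ex), dims$x) || !identical(dim(einc$ey), dims$y) ||
      !identical(dim(einc$ez), dims$z))
    stop_cfg("incident field arrays do not match the network grid")
  sp <- network$spacing_m
  ## b = -D' G emf
  b <- complex(d$nnode)
  lens <- c(x = sp$dx, y = sp$dy, z = sp$dz)
  for (fam in c("x", "y", "z")) {
    e <- edge_index(d, fam)
    gv <- as.vector(network$g[[fam]])[
      (e$g2[, 2] - 1L) * nrow(network$g[[fam]]) + e$g2[, 1]]
    emf <- as.vector(einc[[paste0("e", fam)]]) * lens[[fam]]
    w <- gv * emf
    nz <- w != 0
    if (!any(nz)) next
    idx <- c(e$p[nz], e$q[nz])
    accr <- rowsum(c(-Re(w[nz]), Re(w[nz])), idx)
    acci <- rowsum(c(-Im(w[nz]), Im(w[nz])), idx)
    ii <- as.integer(rownames(accr))
    b[ii] <- b[ii] + complex(real = accr[, 1], imaginary = acci[, 1])
  }

  if (network$resistive_only) {
    cache <- build_system(network)
    V <- complex(d$nnode)
    info <- list()
    for (part in c("re", "im")) {
      bb <- if (part == "re") Re(b) else Im(b)
      if (all(bb == 0)) {
        info[[part]] <- list(relres = 0, iter = 0L, converged = TRUE,
                             history = numeric(0))
        next
      }
      sol <- pcg_solve(cache, bb, cfg$tol, cfg$maxit)
      info[[part]] <- sol[c("relres", "iter", "converged", "history")]
      V <- V + (if (part == "re") sol$x else 1i * sol$x)
    }
    converged <- all(vapply(info, `[[`, TRUE, "converged"))
    if (!converged && !cfg$allow_unconverged)
      stop_solver(paste0("impedance solve did not converge in ", cfg$maxit,
                         " iterations (relres ",
                         signif(max(vapply(info, `[[`, 1, "relres")), 3), ")"),
                  residuals = lapply(info, `[[`, "history"))
    if (!converged)
      warning("impedance solve did not converge; residuals recorded")
    residual <- max(vapply(info, `[[`, 1, "relres"))
    iterations <- sum(vapply(info, `[[`, 1L, "iter"))
    history <- lapply(info, `[[`, "history")
  } else {
    V <- dense_solve_complex(network, b)
    residual <- NA_real_; iterations <- NA_integer_; history <- list()
    converged <- TRUE
  }

  Varr <- array(V, dim = c(d$ny1, d$nz1, d$nx + 1L))
  nx1 <- d$nx + 1L
  ex <- einc$ex - aperm(Varr[, , -1L, drop = FALSE] -
                          Varr[, , -nx1, drop = FALSE], c(3, 1, 2)) / sp$dx
  ey <- einc$ey - aperm(Varr[-1L, , , drop = FALSE] -
                          Varr[-d$ny1, , , drop = FALSE], c(3, 1, 2)) / sp$dy
  ez <- einc$ez - aperm(Varr[, -1L, , drop = FALSE] -
                          Varr[, -d$nz1, , drop = FALSE], c(3, 1, 2)) / sp$dz
  avg4 <- function(a, jn, kn) {
    (a[, -(jn + 1L), -(kn + 1L), drop = FALSE] +
       a[, -1L, -(kn + 1L), drop = FALSE] +
       a[, -(jn + 1L), -1L, drop = FALSE] +
       a[, -1L, -1L, drop = FALSE]) / 4
  }
  e_voxel <- list(
    ex = avg4(ex, d$ny, d$nz),
    ey = (ey[-nx1, , , drop = FALSE] + ey[-1L, , , drop = FALSE]) / 2,
    ez = (ez[-nx1, , , drop = FALSE] + ez[-1L, , , drop = FALSE]) / 2)
  # y/z edge arrays have node-resolution in one transverse axis; average the
  # remaining transverse node axis onto voxel centres
  e_voxel$ey <- (e_voxel$ey[, , -(d$nz1), drop = FALSE] +
                   e_voxel$ey[, , -1L, drop = FALSE]) / 2
  e_voxel$ez <- (e_voxel$ez[, -(d$ny1), , drop = FALSE] +
                   e_voxel$ez[, -1L, , drop = FALSE]) / 2
  structure(list(network = network, V = V, einc = einc,
                 e_edge = list(ex = ex, ey = ey, ez = ez),
                 e_voxel = e_voxel,
                 residual = residual, iterations = iterations,
                 history = history, converged = converged, cfg = cfg),
            class = "network_solution")
}

#' Branch currents of a solved network
#'
#' @param solution a [solve_fields()] result.
#' @return list of complex arrays `x`, `y`, `z`: the current (A) through
#'   each edge, positive along the positive axis direction.
#' @export
branch_currents <- function(solution) {
  net <- solution$network
  sp <- net$spacing_m
  lens <- c(x = sp$dx, y = sp$dy, z = sp$dz)
  out <- list()
  for (fam in c("x", "y", "z")) {
    g2 <- net$g[[fam]]
    E <- solution$e_edge[[paste0("e", fam)]]
    garr <- array(rep(as.vector(g2), each = dim(E)[1]), dim = dim(E))
    out[[fam]] <- garr * E * lens[[fam]]
  }
  out
}

#' Current density from the solved field
#'
#' Componentwise `J = sigma E` on voxel centres with the directional
#' conductivity of each voxel; insulating voxels carry exactly zero current.
#'
#' @param solution a [solve_fields()] result.
#' @param grid optional grid override (defaults to the network's grid).
#' @return list of complex arrays `jx`, `jy`, `jz` (A/m^2), dims
#'   `nx x ny x nz`.
#' @export
current_density <- function(solution, grid = NULL) {
  grid <- grid %||% solution$network$grid
  sig <- sigma_arrays(grid)
  nx <- grid$grid$nx
  mul <- function(E, s) E * array(rep(as.vector(s), each = nx), dim = dim(E))
  list(jx = mul(solution$e_voxel$ex, sig$sx),
       jy = mul(solution$e_voxel$ey, sig$sy),
       jz = mul(solution$e_voxel$ez, sig$sz))
}

#' Discrete charge-conservation residual
#'
#' Net branch current into every interior node, normalised by the mean
#' branch-current magnitude; the maximum over interior nodes is the headline
#' value.
#'
#' @param solution a [solve_fields()] result.
#' @return list with `max_interior`, `per_node` (array over interior nodes)
#'   and `mean_branch_current`.
#' @export
conservation_residual <- function(solution) {
  net <- solution$network
  d <- net$dims
  I <- branch_currents(solution)
  net_in <- complex(d$nnode)
  for (fam in c("x", "y", "z")) {
    e <- edge_index(d, fam)
    iv <- as.vector(I[[fam]])
    acc <- rowsum(c(Re(iv), -Re(iv)), c(e$p, e$q))
    acci <- rowsum(c(Im(iv), -Im(iv)), c(e$p, e$q))
    ii <- as.integer(rownames(acc))
    net_in[ii] <- net_in[ii] + complex(real = acc[, 1],
                                       imaginary = acci[, 1])
  }
  scale <- mean(c(Mod(as.vector(I$x)), Mod(as.vector(I$y)),
                  Mod(as.vector(I$z))))
  arr <- array(Mod(net_in), dim = c(d$ny1, d$nz1, d$nx + 1L))
  rng <- function(n1) if (n1 >= 3L) 2L:(n1 - 1L) else seq_len(n1)
  interior <- arr[rng(d$ny1), rng(d$nz1), rng(d$nx + 1L), drop = FALSE]
  list(max_interior = if (scale > 0) max(interior) / scale else 0,
       per_node = interior / max(scale, .Machine$double.xmin),
       mean_branch_current = scale)
}
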