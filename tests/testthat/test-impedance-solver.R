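# Small heterogeneous phantoms solved against a dense first-principles
# network assembly (helper-oracles.R).

two_tissue_grid <- function(n = 4L, dyz = 0.5) {
  make_phantom("two_layer_slab",
               params = list(domain_mm = c(n, n * dyz, n * dyz),
                             dx_mm = 1, dyz_mm = dyz))
}

test_that("edge impedance reproduces the defining relation", {
  # 10 um transverse edge in surrounding tissue: Lv = 1e-5 m,
  # Av = 1 mm x 10 um = 1e-8 m2, sigma = 0.5 -> Z = 2000 ohm
  spec <- nerve_spec(domain_mm = c(2, 0.1, 0.1), nerve_diameter_mm = 0,
                     membrane_um = 0, perineurium_um = 0,
                     fascicles = list(), regions = list())
  grid <- build_grid(spec, grid_spec(1, 0.01))
  net <- edge_impedances(grid, 2000)
  expect_equal(unique(as.vector(edge_impedance(net, "y"))), 2000)
  expect_equal(unique(as.vector(edge_impedance(net, "z"))), 2000)
  # axial edge: Lv = 1 mm, Av = 10 um x 10 um = 1e-10 m2
  expect_equal(unique(as.vector(edge_impedance(net, "x"))),
               1e-3 / (0.5 * 1e-10))
})

test_that("reactive part is ~5 orders below the resistive part at 2 kHz", {
  grid <- make_phantom("homogeneous",
                       params = list(domain_mm = c(2, 1, 1), dyz_mm = 0.5))
  grid$labels[] <- TISSUE_KINDS[["perineurium"]]   # sigma = 0.01, worst case
  net <- edge_impedances(grid, 2000, eps_r = 1, resistive_only = FALSE)
  Z <- edge_impedance(net, "y")
  ratio <- abs(Im(Z[1])) / abs(Re(Z[1]))
  expect_equal(ratio, 2 * pi * 2000 * 8.8541878128e-12 / 0.01,
               tolerance = 1e-6)
  expect_lt(ratio, 1e-4)
  expect_gt(ratio, 1e-6)
})

test_that("admittance is purely real in the DC limit with the eps term retained", {
  grid <- make_phantom("homogeneous",
                       params = list(domain_mm = c(2, 1, 1), dyz_mm = 0.5))
  net <- edge_impedances(grid, 1e-9, resistive_only = FALSE)
  expect_lt(max(abs(Im(edge_impedance(net, "y")))), 1e-15)
})

test_that("sparse solve matches the dense brute-force network oracle", {
  grid <- two_tissue_grid(4L)
  set.seed(7)
  einc <- functional_edge_field(grid, function(x, y, z) {
    list(ex = complex(imaginary = sin(x) + 0.3 * y),
         ey = complex(imaginary = cos(z) * 0.5),
         ez = complex(imaginary = 0.2 * x * y))
  })
  net <- edge_impedances(grid, 2000)
  sol <- solve_fields(net, einc, solve_config(tol = 1e-13, maxit = 2000))
  ref <- dense_network_solve(grid, einc)
  scale <- max(Mod(ref$ex))
  expect_lt(max(Mod(sol$e_edge$ex - ref$ex)) / scale, 1e-10)
  expect_lt(max(Mod(sol$e_edge$ey - ref$ey)) / scale, 1e-10)
  expect_lt(max(Mod(sol$e_edge$ez - ref$ez)) / scale, 1e-10)
})

test_that("oracle agreement holds on 6x6x6 grids with all five tissues", {
  spec <- nerve_spec(domain_mm = c(6, 3, 3), nerve_diameter_mm = 2.4,
                     membrane_um = 250, perineurium_um = 150,
                     fascicles = list(
                       tibial = list(center = c(0, 0.5), semi = c(0.4, 0.35),
                                     rotation = 0.3),
                       peroneal = list(center = c(0, -0.55),
                                       semi = c(0.3, 0.25), rotation = 0)),
                     regions = list())
  grid <- build_grid(spec, grid_spec(1, 0.5))
  einc <- functional_edge_field(grid, function(x, y, z) {
    list(ex = complex(imaginary = 1 + 0.5 * sin(y + z) * cos(x / 2)),
         ey = complex(imaginary = 0.4 * cos(x)),
         ez = complex(imaginary = 0.1 * (x + y)))
  })
  net <- edge_impedances(grid, 2000)
  sol <- solve_fields(net, einc, solve_config(tol = 1e-13, maxit = 4000))
  ref <- dense_network_solve(grid, einc)
  scale <- max(Mod(ref$ex))
  for (comp in c("ex", "ey", "ez"))
    expect_lt(max(Mod(sol$e_edge[[comp]] - ref[[comp]])) / scale, 1e-10)
  # conservation residual of the dense oracle itself is at rounding level
  sol_dense <- sol
  sol_dense$e_edge <- ref[c("ex", "ey", "ez")]
  names(sol_dense$e_edge) <- c("ex", "ey", "ez")
  expect_lt(conservation_residual(sol_dense)$max_interior, 1e-10)
})

test_that("solution is linear in the drive", {
  grid <- two_tissue_grid(4L)
  einc <- uniform_edge_field(grid, ex = -2i)
  net <- edge_impedances(grid, 2000)
  s1 <- solve_fields(net, einc, solve_config(tol = 1e-12))
  einc2 <- einc
  einc2$ex <- einc$ex * 2; einc2$ey <- einc$ey * 2; einc2$ez <- einc$ez * 2
  s2 <- solve_fields(net, einc2, solve_config(tol = 1e-12))
  expect_lt(max(Mod(s2$e_edge$ex - 2 * s1$e_edge$ex)) /
              max(Mod(s1$e_edge$ex)), 1e-9)
})

test_that("scaling all conductivities leaves E and scales J", {
  spec <- nerve_spec(domain_mm = c(4, 2, 2), nerve_diameter_mm = 1.2,
                     fascicles = list(tibial = list(center = c(0, 0),
                                                    semi = c(0.3, 0.2),
                                                    rotation = 0)),
                     regions = list())
  grid <- build_grid(spec, grid_spec(1, 0.25))
  einc <- functional_edge_field(grid, function(x, y, z)
    list(ex = complex(imaginary = sin(x + y)), ey = 0 + 0i, ez = 0 + 0i))
  net1 <- edge_impedances(grid, 2000)
  grid2 <- grid
  grid2$conductivity <- conductivity_table(grid$conductivity * 3)
  net2 <- edge_impedances(grid2, 2000)
  cfg <- solve_config(tol = 1e-12, maxit = 1000)
  s1 <- solve_fields(net1, einc, cfg)
  s2 <- solve_fields(net2, einc, cfg)
  expect_lt(max(Mod(s1$e_edge$ex - s2$e_edge$ex)) /
              max(Mod(s1$e_edge$ex)), 1e-8)
  j1 <- current_density(s1); j2 <- current_density(s2)
  expect_lt(max(Mod(j2$jx - 3 * j1$jx)) / max(Mod(j1$jx)), 1e-8)
})

test_that("current density follows J = sigma E with anisotropy and zero in insulators", {
  grid <- two_tissue_grid(4L)
  # custom table with an insulating tissue and the anisotropic fascicle
  tb <- conductivity_table()
  tb["membrane", ] <- 0
  grid$labels[1, ] <- TISSUE_KINDS[["membrane"]]
  grid$labels[2, ] <- TISSUE_KINDS[["fascicle"]]
  grid$conductivity <- conductivity_table(tb)
  net <- edge_impedances(grid, 2000)
  einc <- uniform_edge_field(grid, ex = 0 - 1i, ey = 0 - 1i, ez = 0 - 1i)
  sol <- solve_fields(net, einc, solve_config(tol = 1e-11, maxit = 1000))
  J <- current_density(sol)
  ins <- grid$labels == TISSUE_KINDS[["membrane"]]
  for (i in seq_len(grid$grid$nx)) {
    expect_true(all(J$jx[i, , ][ins] == 0))
    expect_true(all(J$jy[i, , ][ins] == 0))
  }
  fas <- grid$labels == TISSUE_KINDS[["fascicle"]]
  i0 <- 2L
  expect_equal(J$jx[i0, , ][fas], 0.33 * sol$e_voxel$ex[i0, , ][fas])
  expect_equal(J$jy[i0, , ][fas], 0.08 * sol$e_voxel$ey[i0, , ][fas])
  # doubling E doubles J
  sol2 <- sol
  sol2$e_voxel <- lapply(sol$e_voxel, `*`, 2)
  J2 <- current_density(sol2, grid)
  expect_equal(J2$jx, 2 * J$jx)
})

test_that("converged solves conserve charge; unconverged ones report without error", {
  grid <- two_tissue_grid(5L)
  einc <- functional_edge_field(grid, function(x, y, z)
    list(ex = complex(imaginary = cos(y) + x / 4), ey = 0 + 0i,
         ez = complex(imaginary = 0.3 * y)))
  net <- edge_impedances(grid, 2000)
  sol <- solve_fields(net, einc, solve_config(tol = 1e-10, maxit = 1000))
  expect_lt(conservation_residual(sol)$max_interior, 1e-8)
  expect_error(solve_fields(net, einc, solve_config(tol = 1e-10, maxit = 1)),
               class = "coilsteer_solver_error")
  expect_warning(
    sol1 <- solve_fields(net, einc,
                         solve_config(tol = 1e-10, maxit = 1,
                                      allow_unconverged = TRUE)),
    "did not converge")
  r <- conservation_residual(sol1)
  expect_true(is.finite(r$max_interior))
  expect_gt(r$max_interior, 1e-8)
})

test_that("a fully insulating grid is a configuration error", {
  grid <- make_phantom("homogeneous",
                       params = list(domain_mm = c(2, 1, 1), dyz_mm = 0.5))
  tb <- conductivity_table(); tb[, ] <- 0
  grid$conductivity <- conductivity_table(tb)
  expect_error(edge_impedances(grid, 2000),
               class = "coilsteer_config_error")
})

test_that("complex (permittivity-retaining) solve agrees with the resistive path at 2 kHz", {
  grid <- two_tissue_grid(4L)
  # curl-carrying drive (a conservative one is fully cancelled by grad V)
  einc <- functional_edge_field(grid, function(x, y, z)
    list(ex = complex(imaginary = sin(z) + 0.5 * y),
         ey = 0 + 0i, ez = complex(imaginary = 0.2 * cos(x))))
  net_r <- edge_impedances(grid, 2000, resistive_only = TRUE)
  net_c <- edge_impedances(grid, 2000, eps_r = 1, resistive_only = FALSE)
  s_r <- solve_fields(net_r, einc, solve_config(tol = 1e-13, maxit = 1000))
  s_c <- solve_fields(net_c, einc)
  # the reactive term perturbs admittances by ~1e-5 relative
  expect_lt(max(Mod(s_c$e_edge$ex - s_r$e_edge$ex)) /
              max(Mod(s_r$e_edge$ex)), 1e-4)
  expect_gt(max(Mod(s_r$e_edge$ex)), 0)
})

test_that("field jumps concentrate at tissue boundaries", {
  # perineurium | surrounding half-spaces split along z (50x contrast); a
  # shear drive (Ex growing with z) carries curl, driving eddy loops in the
  # x-z plane whose return currents cross the interface, where the normal
  # field component must jump by the conductivity ratio
  grid <- make_phantom("two_layer_slab",
                       params = list(domain_mm = c(6, 1.5, 1.5), dx_mm = 1,
                                     dyz_mm = 0.1))
  bnd <- floor(grid$grid$nz / 2)
  grid$labels[, seq_len(bnd)] <- TISSUE_KINDS[["perineurium"]]
  grid$labels[, (bnd + 1L):grid$grid$nz] <- TISSUE_KINDS[["surrounding"]]
  einc <- functional_edge_field(grid, function(x, y, z)
    list(ex = complex(imaginary = z), ey = 0 + 0i, ez = 0 + 0i))
  net <- edge_impedances(grid, 2000)
  sol <- solve_fields(net, einc, solve_config(tol = 1e-11, maxit = 3000))
  ez <- -Im(sol$e_voxel$ez)
  nzc <- dim(ez)[3]
  jump_per_col <- vapply(seq_len(nzc - 1L), function(c0)
    max(abs(ez[, , c0 + 1L] - ez[, , c0])), numeric(1))
  expect_gt(jump_per_col[bnd], 5 * max(jump_per_col[-bnd]))
})
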