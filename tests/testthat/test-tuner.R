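# Synthetic per-coil activation stacks on a small symmetric phantom: each
# coil's map decays with distance from the coil centre, so the geometry of
# the heuristic (zero farthest, unity closest, sweep, refine) is exercised
# without field solves.

tuner_fixture <- function() {
  grid <- make_phantom("symmetric_two_fascicle",
                       params = list(domain_mm = c(5, 2, 2), dx_mm = 1,
                                     dyz_mm = 0.1))
  coils <- place_array(coil_spec(), nerve_center = c(2.5, 0, 0),
                       nerve_radius_mm = 0.5, clearance_mm = 0.5)
  ax <- coilsteer:::grid_axes(grid$grid)
  Y <- matrix(ax$y, grid$grid$ny, grid$grid$nz)
  Z <- matrix(ax$z, grid$grid$ny, grid$grid$nz, byrow = TRUE)
  maps <- lapply(coils, function(pc) {
    d2 <- (Y - pc$center[2])^2 + (Z - pc$center[3])^2
    stack <- array(0, dim = c(3, grid$grid$ny, grid$grid$nz))
    for (s in 1:3) stack[s, , ] <- 6000 * exp(-d2 / 4)
    coilsteer:::new_activation_map(stack, grid)
  })
  masks <- list(tibial = region_mask(grid, "tibial"),
                peroneal = region_mask(grid, "peroneal"))
  list(grid = grid, coils = coils, maps = maps, masks = masks)
}

test_that("weight vectors map to per-coil currents by Eq of the drive", {
  expect_equal(weights_to_currents(c(1.1, 0.4, 0, 0), 600),
               c(660, 240, 0, 0))
  expect_equal(weights_to_currents(c(0, 0, 0.8, 0.6), 600),
               c(0, 0, 480, 360))
  expect_equal(weights_to_currents(rep(0, 4), 600), rep(0, 4))
  expect_error(weights_to_currents(c(1, 0, 0, 0), -5),
               class = "coilsteer_config_error")
})

test_that("drive energy is k sum w^2", {
  expect_equal(energy(c(1, 1, 1, -1), 1), 4)
  expect_equal(energy(rep(0, 4)), 0)
  expect_equal(energy(c(0, 0, 0.8, 0.6), 1), 1)
  expect_equal(energy(c(1, 2, 0, 0), 2.5), 12.5)
})

test_that("superposition is a weighted signed sum with identity one-hots", {
  fx <- tuner_fixture()
  m <- superpose(fx$maps, c(0, 1, 0, 0), grid = fx$grid)
  expect_equal(m$stack, fx$maps[[2]]$stack)
  m2 <- superpose(fx$maps, c(1, 1, 1, -1), grid = fx$grid)
  expect_equal(m2$stack,
               fx$maps[[1]]$stack + fx$maps[[2]]$stack +
                 fx$maps[[3]]$stack - fx$maps[[4]]$stack)
  arrs <- lapply(fx$maps, `[[`, "stack")
  expect_equal(superpose(arrs, c(2, 0, 0, -1)),
               2 * arrs[[1]] - arrs[[4]])
  bad <- fx$maps
  bad[[2]]$stack <- bad[[2]]$stack[, 1:5, , drop = FALSE]
  expect_error(superpose(bad, rep(1, 4), grid = fx$grid),
               class = "coilsteer_config_error")
})

test_that("the heuristic zeroes the two farthest coils and fixes unity on the closest", {
  fx <- tuner_fixture()
  tr <- tune_weights(fx$maps, "tibial", fx$masks, fx$coils, fx$grid,
                     tune_config(threshold = 3000))
  ord <- order(coilsteer:::coil_distances(
    fx$coils, coilsteer:::mask_centroid(fx$grid, fx$masks$tibial)))
  expect_identical(sort(tr$zeroed), sort(ord[3:4]))
  expect_identical(tr$closest, ord[1])
  expect_true(all(tr$w[tr$zeroed] == 0))
  sweep_rows <- tr$audit[tr$audit$stage == "sweep", ]
  wm <- as.matrix(sweep_rows[, c("w1", "w2", "w3", "w4")])
  expect_true(all(wm[, tr$closest] == 1))
  expect_true(all(wm[, tr$zeroed] == 0))
  # the swept weight covers the examined range
  expect_equal(sort(unique(wm[, tr$swept])), seq(-1.5, 1.5, by = 0.1),
               tolerance = 1e-9)
})

test_that("tuning matches an exhaustive sweep oracle and refinement never loses", {
  fx <- tuner_fixture()
  cfg <- tune_config(threshold = 3000)
  tr <- tune_weights(fx$maps, "tibial", fx$masks, fx$coils, fx$grid, cfg)
  # oracle: brute-force the sweep stage ourselves
  ord <- order(coilsteer:::coil_distances(
    fx$coils, coilsteer:::mask_centroid(fx$grid, fx$masks$tibial)))
  best_oracle <- -Inf
  for (v in seq(-1.5, 1.5, by = 0.1)) {
    w <- numeric(4); w[ord[1]] <- 1; w[ord[2]] <- v
    m <- superpose(fx$maps, w, grid = fx$grid)
    a <- vapply(fx$masks, function(msk) recruit(m, msk, cfg$threshold)$alpha,
                numeric(1))
    best_oracle <- max(best_oracle, selectivity(a, "tibial")$sel)
  }
  expect_gte(tr$sel, best_oracle)
  sweep_best <- max(tr$audit$sel[tr$audit$stage == "sweep"])
  expect_gte(tr$sel, sweep_best)   # hill climbing is monotone
  expect_equal(max(tr$audit$sel), tr$sel)
})

test_that("selectivity ties are broken by the lower drive energy", {
  fx <- tuner_fixture()
  tr <- tune_weights(fx$maps, "tibial", fx$masks, fx$coils, fx$grid,
                     tune_config(threshold = 3000))
  ties <- tr$audit[abs(tr$audit$sel - tr$sel) <= 1e-12, ]
  expect_equal(tr$energy, min(ties$energy))
})

test_that("tuning is deterministic given identical inputs", {
  fx <- tuner_fixture()
  t1 <- tune_weights(fx$maps, "peroneal", fx$masks, fx$coils, fx$grid)
  t2 <- tune_weights(fx$maps, "peroneal", fx$masks, fx$coils, fx$grid)
  expect_identical(t1$w, t2$w)
  expect_identical(t1$sel, t2$sel)
  expect_identical(t1$audit, t2$audit)
})

test_that("weights stay clamped to the examined range during refinement", {
  fx <- tuner_fixture()
  tr <- tune_weights(fx$maps, "tibial", fx$masks, fx$coils, fx$grid,
                     tune_config(threshold = 500))
  wm <- as.matrix(tr$audit[, c("w1", "w2", "w3", "w4")])
  expect_true(all(wm >= -1.5 - 1e-12 & wm <= 1.5 + 1e-12))
})

test_that("superposed per-coil solves equal the direct multi-coil solve", {
  grid <- make_phantom("symmetric_two_fascicle",
                       params = list(domain_mm = c(5, 2.5, 2.5), dx_mm = 1,
                                     dyz_mm = 0.25))
  coils <- place_array(coil_spec(segments_per_turn = 16),
                       nerve_center = c(2.5, 0, 0),
                       nerve_radius_mm = 0.5, clearance_mm = 0.5)
  drive <- current_drive(600, 2000)
  net <- edge_impedances(grid, drive$f_Hz)
  cfg <- solve_config(tol = 1e-12, maxit = 2000)
  w <- c(1, 1, 1, -1)  # pattern: coils 1-3 in phase, coil 4 inverted
  I_eff <- drive$I0_A * drive$slew_factor
  sols <- lapply(seq_along(coils), function(i)
    solve_fields(net, incident_edge_field(coil_winding(coils[[i]]), I_eff,
                                          drive$f_Hz, grid), cfg))
  einc_all <- incident_edge_field(lapply(coils, coil_winding), w * I_eff,
                                  drive$f_Hz, grid)
  direct <- solve_fields(net, einc_all, cfg)
  combo <- superpose(lapply(sols, function(s) s$e_voxel$ex), w)
  scale <- max(Mod(direct$e_voxel$ex))
  expect_lt(max(Mod(combo - direct$e_voxel$ex)) / scale, 1e-6)
})
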