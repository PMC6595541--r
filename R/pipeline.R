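## Scenario-driven pipeline: build model -> per-coil solves -> activation
## maps -> weight tuning -> report. Plus deterministic test phantoms.

#' Simulation scenario
#'
#' Bundles every parameter of an end-to-end run. The default scenario is the
#' two-fascicle rat sciatic nerve in an 11 x 10 x 10 mm domain, four-coil
#' array at 0.5 mm clearance, 600 A peak at 2 kHz, 4 mV/mm^2 activation
#' threshold, at the desk-scale 40 um cross-sectional resolution.
#'
#' @param geometry a [nerve_spec()].
#' @param grid a [grid_spec()].
#' @param coil a [coil_spec()].
#' @param clearance_mm coil-to-nerve clearance.
#' @param drive a [current_drive()].
#' @param tune a [tune_config()].
#' @param targets regions to tune (subset of the geometry's regions).
#' @param tune_against regions whose recruitment competes in the selectivity
#'   of the tuned targets.
#' @param solver a [solve_config()].
#' @param seed integer seed (used only by randomised phantom perturbations;
#'   the core pipeline is deterministic).
#' @return list of class `scenario`.
#' @export
scenario <- function(geometry = nerve_spec(), grid = grid_spec(1, 0.04),
                     coil = coil_spec(), clearance_mm = 0.5,
                     drive = current_drive(600, 2000),
                     tune = tune_config(),
                     targets = c("MG", "PL", "TA"),
                     tune_against = c("MG", "PL", "TA"),
                     solver = solve_config(), seed = 1L) {
  sc <- structure(list(geometry = geometry, grid = grid, coil = coil,
                       clearance_mm = clearance_mm, drive = drive,
                       tune = tune, targets = targets,
                       tune_against = tune_against, solver = solver,
                       seed = as.integer(seed)),
                  class = "scenario")
  validate_scenario(sc)
  sc
}

#' Validate a scenario
#'
#' Checks the presence, classes and invariants of every component before any
#' compute. Mirrors the shipped JSON schema
#' (`system.file("schema/scenario-schema.json", package = "coilsteer")`).
#'
#' @param sc a [scenario()] or equivalent list.
#' @return the scenario, invisibly; errors on the first violation.
#' @export
validate_scenario <- function(sc) {
  need <- c("geometry", "grid", "coil", "clearance_mm", "drive", "tune",
            "targets", "tune_against", "solver")
  missing <- setdiff(need, names(sc))
  if (length(missing))
    stop_cfg("scenario is missing: ", paste(missing, collapse = ", "))
  if (!inherits(sc$geometry, "nerve_spec")) stop_cfg("invalid geometry spec")
  if (!inherits(sc$coil, "coil_spec")) stop_cfg("invalid coil spec")
  if (!inherits(sc$drive, "current_drive")) stop_cfg("invalid drive")
  validate_nerve_spec(sc$geometry)
  bad <- setdiff(sc$targets, c(names(sc$geometry$regions),
                               names(sc$geometry$fascicles)))
  if (length(bad)) stop_cfg("unknown targets: ", paste(bad, collapse = ", "))
  invisible(sc)
}

#' Per-coil unit-current solutions
#'
#' Builds the impedance network once, computes each coil's incident field at
#' unit current `I0`, solves the network per coil (one shared factorised
#' preconditioner; only the right-hand side changes) and derives per-coil
#' activation stacks.
#'
#' @param grid a [build_grid()] result.
#' @param coils a [place_array()] layout.
#' @param drive a [current_drive()].
#' @param solver a [solve_config()].
#' @param verbose print stage timings.
#' @return list with `network`, `einc` (per-coil incident edge fields),
#'   `solutions` (per-coil `network_solution`s) and `maps` (per-coil
#'   `activation_map`s at unit current).
#' @export
per_coil_solutions <- function(grid, coils, drive, solver = solve_config(),
                               verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  network <- edge_impedances(grid, drive$f_Hz)
  einc <- list(); solutions <- list(); maps <- list()
  I_eff <- drive$I0_A * (drive$slew_factor %||% 1)
  for (i in seq_along(coils)) {
    w <- coil_winding(coils[[i]])
    einc[[i]] <- incident_edge_field(w, I_eff, drive$f_Hz, grid)
    say("coil %d incident field done (%.1f s)", i, proc.time()[3] - t0)
    solutions[[i]] <- solve_fields(network, einc[[i]], solver)
    maps[[i]] <- activation_function(solutions[[i]], grid)
    say("coil %d solve done: %d CG iterations, relres %.2g (%.1f s)",
        i, solutions[[i]]$iterations, solutions[[i]]$residual,
        proc.time()[3] - t0)
  }
  list(network = network, einc = einc, solutions = solutions, maps = maps)
}

#' Run a full scenario
#'
#' Builds the model, solves the four per-coil fields, tunes the weight vector
#' for every target region and assembles recruitment curves. Deterministic:
#' rerunning the same scenario reproduces the report exactly.
#'
#' @param sc a [scenario()].
#' @param verbose print stage progress.
#' @return list of class `run_report`: `tissue` summary, per-target
#'   [tune_weights()] results, fascicle-level selectivity under the tuned
#'   weights, recruitment curves, solver diagnostics and version info.
#' @export
run_scenario <- function(sc, verbose = FALSE) {
  validate_scenario(sc)
  grid <- build_grid(sc$geometry, sc$grid)
  coils <- place_array(sc$coil,
                       nerve_center = c(grid$grid$Lx_mm / 2, 0, 0),
                       nerve_radius_mm = sc$geometry$nerve_diameter_mm / 2,
                       clearance_mm = sc$clearance_mm)
  pc <- per_coil_solutions(grid, coils, sc$drive, sc$solver,
                           verbose = verbose)
  masks_all <- lapply(setNames(nm = sc$tune_against), region_mask,
                      grid = grid)
  tunes <- list()
  curves <- list()
  for (tg in sc$targets) {
    # fascicle-level targets compete against the other fascicle; muscle
    # regions compete against the configured region set
    masks <- if (tg %in% names(masks_all)) masks_all else
      lapply(setNames(nm = names(grid$geometry$fascicles)), region_mask,
             grid = grid)
    tunes[[tg]] <- tune_weights(pc$maps, tg, masks, coils, grid, sc$tune)
    m <- superpose(pc$maps, tunes[[tg]]$w, grid = grid)
    curves[[tg]] <- cbind(target = tg,
                          recruitment_curve(m, masks))
  }
  diag_df <- data.frame(
    coil = seq_along(coils),
    iterations = vapply(pc$solutions, function(s) s$iterations, numeric(1)),
    relres = vapply(pc$solutions, function(s) s$residual, numeric(1)))
  structure(list(
    scenario = sc,
    grid_summary = list(dims = c(grid$grid$nx, grid$grid$ny, grid$grid$nz),
                        spacing_mm = c(grid$grid$dx_mm, grid$grid$dy_mm,
                                       grid$grid$dz_mm)),
    tuning = tunes,
    curves = do.call(rbind, curves),
    solver = diag_df,
    versions = list(coilsteer = as.character(utils::packageVersion("coilsteer")),
                    R = paste(R.version$major, R.version$minor, sep = "."))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (tg in names(x$tuning)) print(x$tuning[[tg]])
  invisible(x)
}

#' Serialize a run report
#'
#' Writes `report.json` (winning weights, selectivity, energies, solver
#' diagnostics) and `curves.csv` (recruitment curves) under `dir`.
#'
#' @param report a [run_scenario()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pay <- list(
    grid = report$grid_summary,
    targets = lapply(report$tuning, function(t) list(
      target = t$target, w = t$w, sel = t$sel,
      alpha = as.list(t$alpha), energy = t$energy, plane = t$plane)),
    solver = report$solver,
    versions = report$versions)
  jsonlite::write_json(pay, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(report$curves, file.path(dir, "curves.csv"), row.names = FALSE)
  for (tg in names(report$tuning))
    write.csv(report$tuning[[tg]]$audit,
              file.path(dir, paste0("audit_", tg, ".csv")),
              row.names = FALSE)
  invisible(dir)
}

#' Deterministic test phantoms
#'
#' Small parametric tissue grids for verification:
#' `homogeneous` (one tissue everywhere), `two_layer_slab` (two half-spaces
#' split along z), `single_fascicle` (one centred elliptical fascicle),
#' `symmetric_two_fascicle` (two mirror-image fascicles), and `default`
#' (the shipped nerve geometry). `seed` drives optional jitter of fascicle
#' centres (`params$jitter_mm`); with no jitter the phantom is seed-free.
#'
#' @param kind phantom kind.
#' @param params list: `domain_mm`, `dx_mm`, `dyz_mm`, `tissue`,
#'   `jitter_mm` as applicable.
#' @param seed integer seed for the jitter.
#' @return a `tissue_grid`.
#' @export
make_phantom <- function(kind = c("homogeneous", "two_layer_slab",
                                  "single_fascicle",
                                  "symmetric_two_fascicle", "default"),
                         params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- modifyList(list(domain_mm = c(4, 2, 2), dx_mm = 1, dyz_mm = 0.1,
                       tissue = "surrounding", jitter_mm = 0), params)
  g <- grid_spec(p$dx_mm, p$dyz_mm)
  jit <- function(x) {
    if (p$jitter_mm == 0) return(x)
    x + runif(length(x), -p$jitter_mm, p$jitter_mm)
  }
  set.seed(seed)
  if (kind == "default") {
    spec <- nerve_spec()
    if (!is.null(params$dyz_mm) || !is.null(params$dx_mm))
      g <- grid_spec(p$dx_mm %||% 1, p$dyz_mm %||% 0.04)
    else g <- grid_spec(1, 0.04)
    return(build_grid(spec, g))
  }
  if (kind == "homogeneous") {
    spec <- nerve_spec(domain_mm = p$domain_mm, nerve_diameter_mm = 0,
                       membrane_um = 0, perineurium_um = 0,
                       fascicles = list(), regions = list())
    grid <- build_grid(spec, g)
    grid$labels[] <- TISSUE_KINDS[[p$tissue]]
    return(grid)
  }
  if (kind == "two_layer_slab") {
    spec <- nerve_spec(domain_mm = p$domain_mm, nerve_diameter_mm = 0,
                       membrane_um = 0, perineurium_um = 0,
                       fascicles = list(), regions = list())
    grid <- build_grid(spec, g)
    nz <- grid$grid$nz
    grid$labels[, seq_len(floor(nz / 2))] <- TISSUE_KINDS[["epineurium"]]
    grid$labels[, (floor(nz / 2) + 1L):nz] <- TISSUE_KINDS[["surrounding"]]
    return(grid)
  }
  nerve_d <- min(p$domain_mm[2:3]) / 2
  if (kind == "single_fascicle") {
    f <- list(center = jit(c(0, 0)),
              semi = c(0.3, 0.15) * nerve_d, rotation = 0)
    spec <- nerve_spec(domain_mm = p$domain_mm,
                       nerve_diameter_mm = nerve_d,
                       membrane_um = 30, perineurium_um = 30,
                       fascicles = list(tibial = f), regions = list())
    return(build_grid(spec, g))
  }
  # symmetric_two_fascicle: mirror-image fascicles at +/- z
  semi <- c(0.22, 0.25) * nerve_d / 2
  off <- 0.45 * nerve_d / 2
  spec <- nerve_spec(domain_mm = p$domain_mm, nerve_diameter_mm = nerve_d,
                     membrane_um = 30, perineurium_um = 30,
                     fascicles = list(
                       tibial = list(center = jit(c(0, off)), semi = semi,
                                     rotation = 0),
                       peroneal = list(center = jit(c(0, -off)), semi = semi,
                                       rotation = 0)),
                     regions = list())
  build_grid(spec, g)
}
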