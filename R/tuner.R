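## Weight-vector tuning of the 4-coil array. Per-coil solutions at unit
## current are superposed under signed weights (negative = 180 degree phase);
## candidate weights are scored by the selectivity index of the target region
## at the reference activation threshold, ties broken by the drive energy
## k * sum(w^2).

#' Tuning configuration
#'
#' @param w_max symmetric weight bound of the examined range.
#' @param w_step sweep step of the coarse grid.
#' @param refine_step step of the local refinement moves.
#' @param threshold activation threshold in V/m^2.
#' @param k energy constant of `energy = k sum(w_i^2)`.
#' @param max_refine iteration cap of the refinement loop.
#' @return list of class `tune_config`.
#' @export
tune_config <- function(w_max = 1.5, w_step = 0.1, refine_step = 0.1,
                        threshold = 4000, k = 1, max_refine = 100L) {
  if (w_step <= 0 || refine_step <= 0) stop_cfg("steps must be positive")
  if (w_max <= 0) stop_cfg("weight bound must be positive")
  structure(list(w_max = w_max, w_step = w_step, refine_step = refine_step,
                 threshold = threshold, k = k,
                 max_refine = as.integer(max_refine)),
            class = "tune_config")
}

#' Map a weight vector to per-coil currents
#'
#' `I_i = w_i I0`; a negative weight is a 180 degree phase inversion.
#'
#' @param w numeric weight vector.
#' @param I0_A unit peak current in amperes (> 0).
#' @return per-coil peak currents in amperes (signed).
#' @export
weights_to_currents <- function(w, I0_A = 600) {
  if (I0_A <= 0) stop_cfg("unit current must be positive")
  w * I0_A
}

#' Drive energy of a weight vector
#'
#' @param w weight vector.
#' @param k energy constant.
#' @return `k * sum(w^2)`.
#' @export
energy <- function(w, k = 1) {
  if (k <= 0) stop_cfg("energy constant must be positive")
  k * sum(w^2)
}

#' Superpose per-coil solutions under a weight vector
#'
#' The network is linear in the drive currents, so the field (or activation
#' map) of all coils driven simultaneously equals the weighted sum of the
#' per-coil unit-current solutions. Accepts a list of `activation_map`s,
#' `edge_field`s, or plain arrays of identical shape.
#'
#' @param fields list (one element per coil).
#' @param w numeric weights, same length as `fields`.
#' @param grid required when superposing activation maps (plane reselection).
#' @param ... passed on (e.g. `plane` for activation maps).
#' @return object of the same type as the inputs.
#' @export
superpose <- function(fields, w, grid = NULL, ...) {
  stopifnot(length(fields) == length(w))
  f1 <- fields[[1]]
  if (inherits(f1, "activation_map")) {
    dims <- lapply(fields, function(f) dim(f$stack))
    if (!all(vapply(dims, identical, TRUE, dims[[1]])))
      stop_cfg("activation stacks have mismatched shapes")
    stack <- Reduce(`+`, Map(function(f, wi) f$stack * wi, fields, w))
    if (is.null(grid)) stop_cfg("grid is required to superpose maps")
    return(new_activation_map(stack, grid, ...))
  }
  if (inherits(f1, "edge_field")) {
    for (f in fields)
      if (!identical(dim(f$ex), dim(f1$ex))) stop_cfg("mismatched grids")
    out <- f1
    for (comp in c("ex", "ey", "ez"))
      out[[comp]] <- Reduce(`+`, Map(function(f, wi) f[[comp]] * wi,
                                     fields, w))
    return(out)
  }
  for (f in fields)
    if (!identical(dim(f), dim(f1))) stop_cfg("mismatched arrays")
  Reduce(`+`, Map(`*`, fields, w))
}

## squared distance from a cross-sectional point (y, z) to each coil centre
coil_distances <- function(coils, yz) {
  vapply(coils, function(pc)
    sqrt((pc$center[2] - yz[1])^2 + (pc$center[3] - yz[2])^2), numeric(1))
}

mask_centroid <- function(grid, mask) {
  ax <- grid_axes(grid$grid)
  idx <- which(mask, arr.ind = TRUE)
  c(mean(ax$y[idx[, 1]]), mean(ax$z[idx[, 2]]))
}

#' Tune the coil weight vector for a target region
#'
#' The search heuristic: (1) the two coils farthest from the target-region
#' centroid get zero weight; (2) the closest coil gets unity weight; (3) the
#' remaining coil's weight sweeps the coarse grid (from `+w_max` down in
#' `w_step` steps) and the candidate with the best selectivity of the target
#' at the reference threshold wins, ties going to lower drive energy;
#' (4) both non-zero weights are refined by coordinate-wise `refine_step`
#' moves until the selectivity stops improving (equal selectivity at lower
#' energy also accepted), clamped to the examined range.
#'
#' @param maps list of four per-coil `activation_map`s at unit current `I0`.
#' @param target name of the target region (must be in `masks`).
#' @param masks named list of region masks; selectivity is computed over all
#'   of them with `target` as the target.
#' @param coils the [place_array()] layout (for the distance ranking).
#' @param grid the `tissue_grid`.
#' @param cfg a [tune_config()].
#' @return list of class `tune_result`: `w`, `sel`, `alpha`, `energy`,
#'   `plane`, and an `audit` data.frame of every evaluated candidate.
#' @export
tune_weights <- function(maps, target, masks, coils, grid,
                         cfg = tune_config()) {
  stopifnot(length(maps) == 4L, length(coils) == 4L)
  if (!target %in% names(masks)) stop_cfg("target must be one of the masks")
  centroid <- mask_centroid(grid, masks[[target]])
  dist <- coil_distances(coils, centroid)
  ord <- order(dist)              # ties broken by coil index
  closest <- ord[1]; sweep_coil <- ord[2]; zeroed <- ord[3:4]

  audit <- list()
  evaluate <- function(w, stage) {
    m <- superpose(maps, w, grid = grid)
    a <- vapply(masks, function(msk) recruit(m, msk, cfg$threshold)$alpha,
                numeric(1))
    sel <- selectivity(a, target)$sel
    en <- energy(w, cfg$k)
    audit[[length(audit) + 1L]] <<- data.frame(
      stage = stage, w1 = w[1], w2 = w[2], w3 = w[3], w4 = w[4],
      sel = sel, energy = en, stringsAsFactors = FALSE)
    list(w = w, sel = sel, alpha = a, energy = en, plane = m$plane)
  }
  better <- function(cand, best) {
    cand$sel > best$sel + 1e-12 ||
      (abs(cand$sel - best$sel) <= 1e-12 && cand$energy < best$energy - 1e-12)
  }

  sweep_vals <- seq(cfg$w_max, -cfg$w_max, by = -cfg$w_step)
  best <- NULL
  for (v in sweep_vals) {
    w <- numeric(4L)
    w[closest] <- 1
    w[sweep_coil] <- v
    cand <- evaluate(w, "sweep")
    if (is.null(best) || better(cand, best)) best <- cand
  }
  if (all(vapply(audit, function(a) a$sel, numeric(1)) == 0) &&
      best$alpha[[target]] == 0)
    warning("no candidate activates any region at this threshold")

  free <- c(closest, sweep_coil)
  it <- 0L
  repeat {
    it <- it + 1L
    improved <- FALSE
    for (ci in free) for (dir in c(1, -1)) {
      w <- best$w
      w[ci] <- min(cfg$w_max, max(-cfg$w_max, w[ci] + dir * cfg$refine_step))
      if (identical(w, best$w)) next
      cand <- evaluate(w, "refine")
      if (better(cand, best)) {
        best <- cand
        improved <- TRUE
      }
    }
    if (!improved || it >= cfg$max_refine) break
  }
  structure(list(target = target, w = best$w, sel = best$sel,
                 alpha = best$alpha, energy = best$energy,
                 plane = best$plane, closest = closest,
                 swept = sweep_coil, zeroed = sort(zeroed),
                 audit = do.call(rbind, audit), cfg = cfg),
            class = "tune_result")
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("<tune_result> target %s: w = [%s], Sel = %.3f, energy = %.2f\n",
              x$target, paste(sprintf("%.1f", x$w), collapse = ", "),
              x$sel, x$energy))
  cat("  alpha:", paste(sprintf("%s=%.3f", names(x$alpha), x$alpha),
                        collapse = ", "), "\n")
  invisible(x)
}
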