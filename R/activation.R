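## Activation function dEx/dx, recruitment and selectivity indices.
##
## Fibre excitation is driven by the axial gradient of the axial electric
## field. The gradient is computed by centred numerical differentiation of
## the voxel-centred Ex between axial slices; the map used for recruitment is
## the cross-sectional plane where the signed gradient inside the nerve is
## maximal. (The model is extruded and the coils are centred axially, so Ex
## is even about the exact mid-plane and the centred difference vanishes
## there by symmetry; the maximal-gradient station is the one adjacent to the
## mid-plane, matching where peak gradients are observed.)
##
## Phase convention: coil currents are cosine references, so the induced
## field phasor is in quadrature (-j w A); the signed peak amplitude of a
## phasor P is -Im(P), which is linear in the (signed) coil weights.

signed_peak <- function(P) -Im(P)

#' Activation function map
#'
#' Computes `dEx/dx` (V/m^2) on every interior axial station by centred
#' differences and selects the evaluation plane.
#'
#' @param E a `network_solution`, or a complex/numeric `nx x ny x nz` array
#'   of voxel-centred Ex.
#' @param grid the `tissue_grid` (needed when `E` is a bare array, and for
#'   the in-nerve plane selection).
#' @param plane `"auto"` (station of maximal signed gradient within the
#'   nerve; ties broken toward larger x), `"mid"` (literal mid station), or
#'   an interior station index (2..nx-1).
#' @return object of class `activation_map`: `values` (ny x nz matrix,
#'   V/m^2) at the selected plane, the full `stack` of interior stations,
#'   `plane` (station index) and `dx_mm`.
#' @export
activation_function <- function(E, grid = NULL, plane = "auto") {
  if (inherits(E, "network_solution")) {
    grid <- grid %||% E$network$grid
    E <- E$e_voxel$ex
  }
  if (is.null(grid)) stop_cfg("grid is required")
  nx <- dim(E)[1]
  if (is.null(nx) || nx < 3L)
    stop_cfg("activation function needs Ex on at least 3 axial slices")
  dx_m <- grid$grid$dx_mm / 1000
  P <- (E[3:nx, , , drop = FALSE] - E[1:(nx - 2L), , , drop = FALSE]) /
    (2 * dx_m)
  stack <- if (is.complex(P)) signed_peak(P) else P
  new_activation_map(stack, grid, plane)
}

new_activation_map <- function(stack, grid, plane = "auto") {
  nerve <- grid$labels != TISSUE_KINDS[["surrounding"]]
  fasc <- grid$fascicle_id > 0L
  sel_mask <- if (any(fasc)) fasc else if (any(nerve)) nerve else
    matrix(TRUE, nrow(grid$labels), ncol(grid$labels))
  nst <- dim(stack)[1]
  if (identical(plane, "auto")) {
    best <- vapply(seq_len(nst), function(s) {
      m <- stack[s, , ]
      max(m[sel_mask])
    }, numeric(1))
    st <- max(which(best >= max(best) - 0))
  } else if (identical(plane, "mid")) {
    st <- as.integer(ceiling(nst / 2))
  } else {
    st <- as.integer(plane) - 1L  # station s differences slices s-1 .. s+1
    if (st < 1L || st > nst) stop_cfg("plane index outside interior stations")
  }
  structure(list(values = stack[st, , ], stack = stack, plane = st + 1L,
                 dx_mm = grid$grid$dx_mm, dims = dim(stack)[2:3]),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf(
    "<activation_map> %d x %d at axial slice %d; range [%.3g, %.3g] V/m^2\n",
    x$dims[1], x$dims[2], x$plane, min(x$values), max(x$values)))
  invisible(x)
}

#' Plot an activation map
#'
#' @param x an `activation_map`.
#' @param mask optional logical matrix; values outside are zeroed.
#' @param ... passed to [graphics::image()].
#' @export
plot.activation_map <- function(x, mask = NULL, ...) {
  v <- x$values
  if (!is.null(mask)) v[!mask] <- 0
  graphics::image(v, useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

#' Recruitment index of a region
#'
#' Fraction of the region's cross-sectional voxels whose activation function
#' meets or exceeds the threshold: `alpha = A_i / A_T`.
#'
#' @param map an [activation_function()] result (or a bare numeric matrix).
#' @param mask logical region mask (ny x nz).
#' @param threshold activation threshold in V/m^2 (4 mV/mm^2 = 4000 V/m^2).
#' @return list of class `recruitment`: `A_i`, `A_T`, `alpha`, `threshold`.
#' @export
recruit <- function(map, mask, threshold) {
  v <- if (inherits(map, "activation_map")) map$values else map
  if (!any(mask)) stop_geom("empty region mask")
  if (threshold <= 0) stop_cfg("threshold must be positive")
  A_T <- sum(mask)
  A_i <- sum(v[mask] >= threshold)
  structure(list(A_i = A_i, A_T = A_T, alpha = A_i / A_T,
                 threshold = threshold),
            class = "recruitment")
}

#' Selectivity index
#'
#' `Sel_i = alpha_i - mean(alpha_j, j != i)`: 1 means the target is fully
#' recruited and nothing else; -1 the reverse.
#'
#' @param alpha numeric vector of recruitment indices (length >= 2), values
#'   in `[0, 1]`; may be named.
#' @param target index or name of the target region.
#' @return list of class `selectivity_result`: `target`, `sel`, `alpha`,
#'   `n`.
#' @export
selectivity <- function(alpha, target) {
  if (length(alpha) < 2L)
    stop_cfg("selectivity needs at least two regions")
  if (any(alpha < 0 | alpha > 1))
    stop_cfg("recruitment indices must lie in [0, 1]")
  if (is.character(target)) target <- match(target, names(alpha))
  if (is.na(target) || target < 1 || target > length(alpha))
    stop_cfg("target region not among the recruitment indices")
  sel <- alpha[[target]] - mean(alpha[-target])
  structure(list(target = target, sel = unname(sel), alpha = alpha,
                 n = length(alpha)),
            class = "selectivity_result")
}

#' Recruitment as a function of activation threshold
#'
#' @param map an [activation_function()] result.
#' @param masks named list of logical region masks.
#' @param thresholds strictly increasing vector of thresholds (V/m^2).
#' @return data.frame with columns `region`, `threshold_V_per_m2`,
#'   `threshold_mV_per_mm2`, `alpha`, `selectivity` (the per-row region as
#'   target against the other regions at that threshold).
#' @export
recruitment_curve <- function(map, masks,
                              thresholds = seq(500, 12000, by = 250)) {
  if (any(diff(thresholds) <= 0))
    stop_cfg("thresholds must be strictly increasing")
  rows <- list()
  for (t in thresholds) {
    a <- vapply(masks, function(m) recruit(map, m, t)$alpha, numeric(1))
    for (r in seq_along(masks)) {
      sel <- if (length(masks) >= 2) selectivity(a, r)$sel else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        region = names(masks)[r], threshold_V_per_m2 = t,
        threshold_mV_per_mm2 = t / 1000, alpha = a[[r]], selectivity = sel,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
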