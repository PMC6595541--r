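## Parametric nerve model: tissue kinds, conductivities, geometry spec,
## voxelisation. The nerve is extruded along x, so tissue labels are stored
## as a single cross-sectional (ny x nz) plane shared by every axial slice.

#' Tissue kinds of the nerve model
#'
#' Integer label codes used in the voxel grid, innermost structures last.
#' Fascicle voxels additionally carry a fascicle id (tibial or peroneal).
#'
#' @format Named integer vector.
#' @export
TISSUE_KINDS <- c(surrounding = 1L, membrane = 2L, epineurium = 3L,
                  perineurium = 4L, fascicle = 5L)

FASCICLE_IDS <- c(tibial = 1L, peroneal = 2L)
REGION_NAMES <- c("tibial", "peroneal", "MG", "PL", "TA")

#' Tissue conductivity table
#'
#' Per-tissue anisotropic conductivity (sigma_x, sigma_y, sigma_z) in S/m.
#' Defaults are the values used throughout: surrounding tissue 0.5 isotropic,
#' nerve membrane 0.02, epineurium 0.1, perineurium 0.01, and fascicle
#' (0.33, 0.08, 0.08) -- anisotropic because axons run along x.
#'
#' @param values optional data.frame overriding the defaults; must have
#'   row names equal to the tissue kinds and columns
#'   `sigma_x`, `sigma_y`, `sigma_z`.
#' @return data.frame of class `conductivity_table`.
#' @export
conductivity_table <- function(values = NULL) {
  if (is.null(values)) {
    values <- data.frame(
      sigma_x = c(0.5, 0.02, 0.1, 0.01, 0.33),
      sigma_y = c(0.5, 0.02, 0.1, 0.01, 0.08),
      sigma_z = c(0.5, 0.02, 0.1, 0.01, 0.08),
      row.names = names(TISSUE_KINDS))
  }
  if (!all(names(TISSUE_KINDS) %in% rownames(values)))
    stop_cfg("conductivity table must cover every tissue kind")
  if (!all(c("sigma_x", "sigma_y", "sigma_z") %in% colnames(values)))
    stop_cfg("conductivity table needs sigma_x, sigma_y, sigma_z columns")
  if (any(as.matrix(values[, c("sigma_x", "sigma_y", "sigma_z")]) < 0))
    stop_cfg("conductivities must be non-negative")
  values <- values[names(TISSUE_KINDS), c("sigma_x", "sigma_y", "sigma_z")]
  class(values) <- c("conductivity_table", "data.frame")
  values
}

#' Look up the conductivity triple of a tissue kind
#'
#' @param table a [conductivity_table()].
#' @param kind tissue kind name (one of `names(TISSUE_KINDS)`).
#' @return numeric `(sigma_x, sigma_y, sigma_z)` in S/m.
#' @export
conductivity_of <- function(table, kind) {
  if (length(kind) != 1L || !kind %in% rownames(table))
    stop_cfg("unknown tissue kind: ", paste(kind, collapse = ", "))
  unlist(table[kind, c("sigma_x", "sigma_y", "sigma_z")])
}

#' Parametric nerve geometry specification
#'
#' Describes the extruded two-fascicle nerve: a circular nerve of the given
#' diameter centred on the x axis, an outer membrane layer, epineurium filling
#' the interior, and per-fascicle ellipses each wrapped in a perineurium
#' shell. Intraneural target regions (MG, PL, TA) are convex polygons in
#' fascicle-local unit coordinates (y/semi_y, z/semi_z).
#'
#' All lengths in mm unless the name says `_um`.
#'
#' @param domain_mm domain extents `c(Lx, Ly, Lz)`.
#' @param nerve_diameter_mm nerve diameter.
#' @param membrane_um thickness of the nerve membrane (outer layer).
#' @param perineurium_um thickness of the perineurium shell around fascicles.
#' @param fascicles named list; each element has `center` (y, z in mm),
#'   `semi` (semi-axes y, z in mm) and optional `rotation` (radians).
#' @param regions named list; each element has `fascicle` (parent id) and
#'   `poly` (n x 2 matrix of local unit coordinates).
#' @param conductivity a [conductivity_table()].
#' @return list of class `nerve_spec`.
#' @export
nerve_spec <- function(domain_mm = c(11, 10, 10),
                       nerve_diameter_mm = 1,
                       membrane_um = 30,
                       perineurium_um = 30,
                       fascicles = default_fascicles(),
                       regions = default_regions(),
                       conductivity = conductivity_table()) {
  spec <- list(domain_mm = as.numeric(domain_mm),
               nerve_diameter_mm = nerve_diameter_mm,
               membrane_um = membrane_um,
               perineurium_um = perineurium_um,
               fascicles = fascicles,
               regions = regions,
               conductivity = conductivity)
  class(spec) <- "nerve_spec"
  validate_nerve_spec(spec)
  spec
}

#' @rdname nerve_spec
#' @export
default_fascicles <- function() {
  list(
    tibial   = list(center = c(0, 0.17),  semi = c(0.23, 0.25), rotation = 0),
    peroneal = list(center = c(0, -0.29), semi = c(0.13, 0.14), rotation = 0))
}

#' @rdname nerve_spec
#' @export
default_regions <- function() {
  # MG and PL sit side by side (split along y) in the tibial fascicle; TA is
  # the central block of the peroneal fascicle. Unit coordinates relative to
  # the fascicle semi-axes.
  list(
    MG = list(fascicle = "tibial",
              poly = rbind(c(-0.85, -0.35), c(-0.10, -0.75),
                           c(-0.10, 0.75), c(-0.85, 0.35))),
    PL = list(fascicle = "tibial",
              poly = rbind(c(0.10, -0.75), c(0.85, -0.35),
                           c(0.85, 0.35), c(0.10, 0.75))),
    TA = list(fascicle = "peroneal",
              poly = rbind(c(-0.80, -0.70), c(0.80, -0.70),
                           c(0.80, 0.70), c(-0.80, 0.70))))
}

validate_nerve_spec <- function(spec) {
  if (length(spec$domain_mm) != 3L || any(spec$domain_mm <= 0))
    stop_cfg("domain extents must be three positive lengths")
  rn <- spec$nerve_diameter_mm / 2
  shell <- spec$perineurium_um / 1000
  for (nm in names(spec$fascicles)) {
    f <- spec$fascicles[[nm]]
    if (any(f$semi <= 0)) stop_geom("fascicle ", nm, " has non-positive axes")
    # outermost point of the perineurium shell must stay inside the nerve
    reach <- sqrt(sum(f$center^2)) + max(f$semi) + shell
    if (rn > 0 && reach >= rn)
      stop_geom("fascicle ", nm, " (with perineurium) leaves the nerve circle")
  }
  if (length(spec$fascicles) == 2L) {
    fs <- spec$fascicles
    if (ellipses_overlap(fs[[1]], fs[[2]], pad = shell))
      stop_geom("fascicle perineurium shells overlap")
  }
  for (nm in names(spec$regions)) {
    r <- spec$regions[[nm]]
    if (!r$fascicle %in% names(spec$fascicles))
      stop_geom("region ", nm, " references unknown fascicle ", r$fascicle)
    if (max(abs(r$poly)) > 1)
      stop_geom("region ", nm, " polygon leaves its fascicle (unit coords)")
  }
  invisible(spec)
}

# conservative overlap test on a dense angular sampling of both inflated
# ellipse boundaries
ellipses_overlap <- function(f1, f2, pad = 0, n = 720) {
  th <- seq(0, 2 * pi, length.out = n)
  bd <- function(f) cbind(f$center[1] + (f$semi[1] + pad) * cos(th),
                          f$center[2] + (f$semi[2] + pad) * sin(th))
  inside <- function(f, p) {
    rot <- f$rotation %||% 0
    u <- (p[, 1] - f$center[1]) * cos(rot) + (p[, 2] - f$center[2]) * sin(rot)
    v <- -(p[, 1] - f$center[1]) * sin(rot) + (p[, 2] - f$center[2]) * cos(rot)
    (u / (f$semi[1] + pad))^2 + (v / (f$semi[2] + pad))^2 < 1
  }
  any(inside(f1, bd(f2))) || any(inside(f2, bd(f1)))
}

#' Voxel grid specification
#'
#' Uniform axial spacing `dx` (mm, on the order of the internodal distance of
#' myelinated axons) and uniform square cross-sectional spacing
#' `dy = dz` (mm). Spacings must divide the domain extents exactly.
#'
#' @param dx_mm axial voxel size in mm.
#' @param dyz_mm cross-sectional voxel size in mm (applies to y and z).
#' @return list of class `grid_spec` (filled in by [build_grid()]).
#' @export
grid_spec <- function(dx_mm = 1, dyz_mm = 0.04) {
  if (dx_mm <= 0 || dyz_mm <= 0) stop_cfg("grid spacings must be positive")
  structure(list(dx_mm = dx_mm, dy_mm = dyz_mm, dz_mm = dyz_mm),
            class = "grid_spec")
}

divides_exactly <- function(extent, spacing) {
  n <- extent / spacing
  abs(n - round(n)) < 1e-9
}

## voxel-centre coordinates; domain centred on the nerve axis in y, z and
## starting at x = 0
grid_axes <- function(grid) {
  list(x = (seq_len(grid$nx) - 0.5) * grid$dx_mm,
       y = (seq_len(grid$ny) - 0.5) * grid$dy_mm - grid$Ly_mm / 2,
       z = (seq_len(grid$nz) - 0.5) * grid$dz_mm - grid$Lz_mm / 2)
}

## node coordinates (voxel corners)
node_axes <- function(grid) {
  list(x = (seq_len(grid$nx + 1L) - 1) * grid$dx_mm,
       y = (seq_len(grid$ny + 1L) - 1) * grid$dy_mm - grid$Ly_mm / 2,
       z = (seq_len(grid$nz + 1L) - 1) * grid$dz_mm - grid$Lz_mm / 2)
}

#' Rasterize the nerve geometry onto a voxel grid
#'
#' Labels every voxel by the innermost structure containing its centre
#' (fascicle > perineurium > epineurium > membrane > surrounding). The
#' geometry is extruded along x, so the label plane is shared by all axial
#' slices. Perineurium and membrane shells are closed morphologically: a
#' voxel adjacent (4-connectivity) to a fascicle voxel can never be
#' epineurium, and the outer membrane ring is at least one voxel thick, so
#' the anatomical topology survives coarse resolutions.
#'
#' @param spec a [nerve_spec()].
#' @param grid a [grid_spec()].
#' @return object of class `tissue_grid`: grid dimensions and spacings, the
#'   cross-sectional label matrix, fascicle ids, region masks and the
#'   conductivity table.
#' @export
build_grid <- function(spec, grid) {
  for (ax in 1:3) {
    sp <- c(grid$dx_mm, grid$dy_mm, grid$dz_mm)[ax]
    if (!divides_exactly(spec$domain_mm[ax], sp))
      stop_cfg("grid spacing does not divide domain extent on axis ", ax)
  }
  g <- grid
  g$Lx_mm <- spec$domain_mm[1]; g$Ly_mm <- spec$domain_mm[2]
  g$Lz_mm <- spec$domain_mm[3]
  g$nx <- as.integer(round(g$Lx_mm / g$dx_mm))
  g$ny <- as.integer(round(g$Ly_mm / g$dy_mm))
  g$nz <- as.integer(round(g$Lz_mm / g$dz_mm))

  ax <- grid_axes(g)
  Y <- matrix(ax$y, g$ny, g$nz)
  Z <- matrix(ax$z, g$ny, g$nz, byrow = TRUE)

  labels <- matrix(TISSUE_KINDS[["surrounding"]], g$ny, g$nz)
  fid <- matrix(0L, g$ny, g$nz)
  rn <- spec$nerve_diameter_mm / 2
  if (rn > 0) {
    r2 <- Y^2 + Z^2
    t_mem <- spec$membrane_um / 1000
    labels[r2 <= rn^2] <- TISSUE_KINDS[["membrane"]]
    labels[r2 <= (rn - t_mem)^2] <- TISSUE_KINDS[["epineurium"]]
  }
  shell <- spec$perineurium_um / 1000
  for (nm in names(spec$fascicles)) {
    f <- spec$fascicles[[nm]]
    per <- ellipse_mask(Y, Z, f, pad = shell)
    fas <- ellipse_mask(Y, Z, f, pad = 0)
    labels[per] <- TISSUE_KINDS[["perineurium"]]
    labels[fas] <- TISSUE_KINDS[["fascicle"]]
    fid[fas] <- FASCICLE_IDS[[nm]]
  }
  # close shells: a fascicle voxel may only touch fascicle or perineurium,
  # whatever the resolution
  if (length(spec$fascicles)) {
    fmask <- labels == TISSUE_KINDS[["fascicle"]]
    touch <- neighbour_any(fmask) & !fmask &
      labels != TISSUE_KINDS[["perineurium"]]
    labels[touch] <- TISSUE_KINDS[["perineurium"]]
  }
  if (rn > 0 && spec$membrane_um > 0) {
    inner <- labels != TISSUE_KINDS[["surrounding"]] &
      labels != TISSUE_KINDS[["membrane"]]
    touch <- neighbour_any(inner) & labels == TISSUE_KINDS[["surrounding"]]
    labels[touch] <- TISSUE_KINDS[["membrane"]]
  }

  regions <- list(
    tibial = fid == FASCICLE_IDS[["tibial"]],
    peroneal = fid == FASCICLE_IDS[["peroneal"]])
  for (nm in names(spec$regions)) {
    r <- spec$regions[[nm]]
    f <- spec$fascicles[[r$fascicle]]
    rot <- f$rotation %||% 0
    u <- ((Y - f$center[1]) * cos(rot) + (Z - f$center[2]) * sin(rot)) /
      f$semi[1]
    v <- (-(Y - f$center[1]) * sin(rot) + (Z - f$center[2]) * cos(rot)) /
      f$semi[2]
    inside <- matrix(mgcv::in.out(close_poly(r$poly), cbind(c(u), c(v))),
                     g$ny, g$nz)
    regions[[nm]] <- inside & regions[[r$fascicle]]
  }

  out <- list(grid = g, labels = labels, fascicle_id = fid,
              regions = regions, conductivity = spec$conductivity,
              geometry = spec, format_version = 1L)
  class(out) <- "tissue_grid"
  out
}

ellipse_mask <- function(Y, Z, f, pad = 0) {
  rot <- f$rotation %||% 0
  u <- (Y - f$center[1]) * cos(rot) + (Z - f$center[2]) * sin(rot)
  v <- -(Y - f$center[1]) * sin(rot) + (Z - f$center[2]) * cos(rot)
  (u / (f$semi[1] + pad))^2 + (v / (f$semi[2] + pad))^2 <= 1
}

close_poly <- function(poly) {
  if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  poly
}

## TRUE where any 4-neighbour of `m` is TRUE
neighbour_any <- function(m) {
  n <- matrix(FALSE, nrow(m), ncol(m))
  n[-1, ] <- n[-1, ] | m[-nrow(m), ]
  n[-nrow(m), ] <- n[-nrow(m), ] | m[-1, ]
  n[, -1] <- n[, -1] | m[, -ncol(m)]
  n[, -ncol(m)] <- n[, -ncol(m)] | m[, -1]
  n
}

#' @export
print.tissue_grid <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<tissue_grid> %d x %d x %d voxels (dx %.3g mm, dy=dz %.3g mm)\n",
              g$nx, g$ny, g$nz, g$dx_mm, g$dy_mm))
  tab <- table(factor(names(TISSUE_KINDS)[x$labels],
                      levels = names(TISSUE_KINDS)))
  cat("  cross-section voxels:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Cross-sectional mask of a named region
#'
#' Returns the logical mask of the region on the mid-axial plane (labels are
#' extruded, so every plane is identical).
#'
#' @param grid a [build_grid()] result.
#' @param region one of `"tibial"`, `"peroneal"`, `"MG"`, `"PL"`, `"TA"`.
#' @return logical `ny x nz` matrix.
#' @export
region_mask <- function(grid, region) {
  if (!region %in% names(grid$regions))
    stop_cfg("unknown region: ", region)
  m <- grid$regions[[region]]
  if (!any(m)) stop_geom("region ", region, " is empty after rasterization")
  m
}

#' Per-voxel directional conductivities of the cross-section
#'
#' @param grid a `tissue_grid`.
#' @return list of three `ny x nz` matrices `sx`, `sy`, `sz` in S/m.
#' @export
sigma_arrays <- function(grid) {
  tb <- grid$conductivity
  look <- function(col) matrix(tb[[col]][grid$labels],
                               grid$grid$ny, grid$grid$nz)
  list(sx = look("sigma_x"), sy = look("sigma_y"), sz = look("sigma_z"))
}

#' Materialize the full 3D label array
#'
#' @param grid a `tissue_grid`.
#' @return integer `nx x ny x nz` array of tissue codes.
#' @export
labels_array <- function(grid) {
  g <- grid$grid
  array(rep(grid$labels, each = g$nx), dim = c(g$nx, g$ny, g$nz))
}

#' Save / load a tissue grid
#'
#' Writes a directory containing `meta.json` (spacings, dimensions, axis
#' order, conductivities, format version) plus raw little-endian arrays for
#' labels, fascicle ids and region masks. The round trip is exact.
#'
#' @param grid a `tissue_grid`.
#' @param path directory to create (save) or read (load).
#' @return `load_grid` returns the `tissue_grid`; `save_grid` the path,
#'   invisibly.
#' @export
save_grid <- function(grid, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- grid$grid
  meta <- list(format_version = grid$format_version,
               package = "coilsteer",
               dims = c(g$nx, g$ny, g$nz),
               spacing_mm = c(g$dx_mm, g$dy_mm, g$dz_mm),
               extent_mm = c(g$Lx_mm, g$Ly_mm, g$Lz_mm),
               axis_order = c("x", "y", "z"),
               index_base = 0L,
               sample_points = "voxel-centre",
               regions = names(grid$regions),
               conductivity = as.list(grid$conductivity),
               geometry = geometry_to_list(grid$geometry))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeBin(as.integer(grid$labels), file.path(path, "labels.bin"), size = 4L,
           endian = "little")
  writeBin(as.integer(grid$fascicle_id), file.path(path, "fascicle_id.bin"),
           size = 4L, endian = "little")
  for (nm in names(grid$regions))
    writeBin(as.integer(grid$regions[[nm]]),
             file.path(path, paste0("region_", nm, ".bin")),
             size = 4L, endian = "little")
  invisible(path)
}

#' @rdname save_grid
#' @export
load_grid <- function(path) {
  metafile <- file.path(path, "meta.json")
  if (!file.exists(metafile)) stop_fmt("no meta.json under ", path)
  meta <- jsonlite::read_json(metafile, simplifyVector = TRUE)
  if (is.null(meta$format_version) || meta$format_version != 1L)
    stop_fmt("unsupported grid container version")
  dims <- as.integer(meta$dims)
  nyz <- dims[2] * dims[3]
  read_arr <- function(file) {
    f <- file.path(path, file)
    if (!file.exists(f)) stop_fmt("missing array file ", file)
    v <- readBin(f, "integer", n = nyz + 1L, size = 4L, endian = "little")
    if (length(v) != nyz) stop_fmt("corrupted array file ", file,
                                   " (expected ", nyz, " values)")
    matrix(v, dims[2], dims[3])
  }
  cond <- conductivity_table(as.data.frame(meta$conductivity,
                                           row.names = names(TISSUE_KINDS)))
  spec <- geometry_from_list(meta$geometry, cond)
  g <- grid_spec(as.numeric(meta$spacing_mm[1]),
                 as.numeric(meta$spacing_mm[2]))
  ext <- as.numeric(meta$extent_mm)
  g$Lx_mm <- ext[1]; g$Ly_mm <- ext[2]; g$Lz_mm <- ext[3]
  g$nx <- dims[1]; g$ny <- dims[2]; g$nz <- dims[3]
  regions <- lapply(setNames(meta$regions, meta$regions), function(nm)
    read_arr(paste0("region_", nm, ".bin")) == 1L)
  out <- list(grid = g, labels = read_arr("labels.bin"),
              fascicle_id = read_arr("fascicle_id.bin"),
              regions = regions, conductivity = cond, geometry = spec,
              format_version = 1L)
  class(out) <- "tissue_grid"
  out
}

geometry_to_list <- function(spec) {
  list(domain_mm = spec$domain_mm,
       nerve_diameter_mm = spec$nerve_diameter_mm,
       membrane_um = spec$membrane_um,
       perineurium_um = spec$perineurium_um,
       fascicles = lapply(spec$fascicles, function(f)
         list(center = f$center, semi = f$semi, rotation = f$rotation %||% 0)),
       regions = lapply(spec$regions, function(r)
         list(fascicle = r$fascicle, poly = unclass(r$poly))))
}

geometry_from_list <- function(lst, cond) {
  nerve_spec(domain_mm = lst$domain_mm,
             nerve_diameter_mm = lst$nerve_diameter_mm,
             membrane_um = lst$membrane_um,
             perineurium_um = lst$perineurium_um,
             fascicles = lapply(lst$fascicles, function(f)
               list(center = as.numeric(f$center), semi = as.numeric(f$semi),
                    rotation = f$rotation %||% 0)),
             regions = lapply(lst$regions, function(r)
               list(fascicle = r$fascicle,
                    poly = matrix(as.numeric(as.matrix(r$poly)), ncol = 2))),
             conductivity = cond)
}
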