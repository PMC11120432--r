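#' Tissue parameter table entry
#'
#' Constructs one row of a tissue parameter table: the relaxation and spin
#' density properties that drive the steady-state signal model. Signal in a
#' voxel is split into a water and a fat compartment by `fat_fraction`; the
#' relaxation times given here describe the water compartment (the fat
#' compartment uses the adipose constants, see [fat_compartment_params()]).
#'
#' @param name Tissue label (character scalar).
#' @param proton_density Relative spin density, dimensionless, `> 0`
#'   (`0` only for background).
#' @param t1_ms Longitudinal relaxation time in ms, `> 0`.
#' @param t2_ms Transverse relaxation time in ms, `> 0`.
#' @param t1rho_ms Rotating-frame (spin-lock) relaxation time in ms, `> 0`.
#' @param fat_fraction Fraction of the signal arising from the fat
#'   compartment, in `[0, 1]`.
#'
#' @return A one-row tibble with the validated fields.
#' @export
tissue_params <- function(name, proton_density, t1_ms, t2_ms, t1rho_ms,
                          fat_fraction = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (proton_density < 0) stop("proton_density must be >= 0", call. = FALSE)
  if (proton_density > 0 && any(c(t1_ms, t2_ms, t1rho_ms) <= 0)) {
    stop("all relaxation times must be positive", call. = FALSE)
  }
  if (fat_fraction < 0 || fat_fraction > 1) {
    stop("fat_fraction must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    name = name, proton_density = proton_density, t1_ms = t1_ms,
    t2_ms = t2_ms, t1rho_ms = t1rho_ms, fat_fraction = fat_fraction
  )
}

#' Relaxation constants of the fat signal compartment
#'
#' The fat compartment of every tissue relaxes with these adipose-tissue
#' constants; only its amplitude (via `fat_fraction` and any fat-saturation
#' residual) differs between tissues.
#'
#' @return Named list with `t1_ms`, `t2_ms`, `t1rho_ms`.
#' @export
fat_compartment_params <- function() {
  list(t1_ms = 380, t2_ms = 130, t1rho_ms = 130)
}

#' Default tissue parameter table for the knee phantom
#'
#' Plausible 3 T values. Cartilage `t2_ms`/`t1rho_ms` give the mid-depth
#' value; the phantom applies the depth-dependent zonal profile around the
#' configured surface/deep endpoints (see [cartilage_zonal_profile()]).
#'
#' @return A tibble with one row per tissue, including an integer `id`
#'   column (background is id 0 with zero proton density).
#' @export
default_tissue_table <- function() {
  dplyr::bind_rows(
    dplyr::mutate(tissue_params("background", 0, 1, 1, 1, 0), id = 0L),
    dplyr::mutate(tissue_params("femoral_cartilage", 0.80, 1200, 40, 45, 0), id = 1L),
    dplyr::mutate(tissue_params("tibial_cartilage", 0.80, 1200, 40, 45, 0), id = 2L),
    dplyr::mutate(tissue_params("synovial_fluid", 1.00, 3600, 800, 800, 0), id = 3L),
    dplyr::mutate(tissue_params("fat_pad", 0.90, 380, 130, 130, 0.9), id = 4L),
    dplyr::mutate(tissue_params("bone_marrow", 0.90, 380, 130, 130, 0.9), id = 5L),
    dplyr::mutate(tissue_params("meniscus", 0.60, 1000, 12, 15, 0), id = 6L),
    dplyr::mutate(tissue_params("muscle", 0.70, 1400, 32, 40, 0), id = 7L)
  )[, c("id", "name", "proton_density", "t1_ms", "t2_ms", "t1rho_ms",
        "fat_fraction")]
}

#' Phantom configuration
#'
#' @param grid_dim Integer 3-vector `(nx, ny, nslices)`; minimum 32 x 32 x 3.
#' @param spacing_mm Numeric 3-vector of voxel size in mm
#'   (in-plane x, in-plane y, slice thickness).
#' @param tissue_table Tissue parameter tibble as from
#'   [default_tissue_table()]; must contain all eight default tissue names.
#' @param cartilage_t2_ms Length-2 numeric `(surface, deep)` T2 endpoints of
#'   the cartilage zonal profile in ms; surface value must exceed deep value.
#' @param cartilage_t1rho_ms Length-2 numeric `(surface, deep)` T1rho
#'   endpoints in ms.
#'
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_dim = c(160L, 160L, 7L),
                           spacing_mm = c(0.875, 0.875, 3),
                           tissue_table = default_tissue_table(),
                           cartilage_t2_ms = c(55, 25),
                           cartilage_t1rho_ms = c(60, 30)) {
  grid_dim <- as.integer(grid_dim)
  stopifnot(length(grid_dim) == 3L, length(spacing_mm) == 3L,
            all(spacing_mm > 0))
  if (any(grid_dim[1:2] < 32L) || grid_dim[3] < 3L) {
    stop("grid too small: need at least 32 x 32 x 3 voxels", call. = FALSE)
  }
  required <- c("background", "femoral_cartilage", "tibial_cartilage",
                "synovial_fluid", "fat_pad", "bone_marrow", "meniscus",
                "muscle")
  missing <- setdiff(required, tissue_table$name)
  if (length(missing)) {
    stop("unknown/missing tissue name(s) in config: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (endpoints in list(cartilage_t2_ms, cartilage_t1rho_ms)) {
    if (!(endpoints[1] > endpoints[2] && endpoints[2] > 0)) {
      stop("cartilage zonal endpoints must satisfy surface > deep > 0",
           call. = FALSE)
    }
  }
  structure(
    list(grid_dim = grid_dim, spacing_mm = as.numeric(spacing_mm),
         tissue_table = tissue_table,
         cartilage_t2_ms = as.numeric(cartilage_t2_ms),
         cartilage_t1rho_ms = as.numeric(cartilage_t1rho_ms)),
    class = "phantom_config"
  )
}

#' Depth-dependent cartilage relaxation profile
#'
#' Linear interpolation between the articular-surface and deep (bone
#' interface) relaxation values, reproducing the zonal stratification of
#' cartilage: superficial values exceed deep values, decreasing
#' monotonically with tissue depth.
#'
#' @param depth_fraction Normalized depth in `[0, 1]`; 0 at the articular
#'   surface, 1 at the bone interface. Vectorized.
#' @param surface_value_ms Relaxation time at the surface (ms).
#' @param deep_value_ms Relaxation time at the bone interface (ms); must be
#'   positive and smaller than `surface_value_ms`.
#'
#' @return Relaxation time(s) in ms.
#' @export
#' @examples
#' cartilage_zonal_profile(c(0, 0.5, 1), 55, 25)
cartilage_zonal_profile <- function(depth_fraction, surface_value_ms,
                                    deep_value_ms) {
  if (!(surface_value_ms > deep_value_ms && deep_value_ms > 0)) {
    stop("require surface_value_ms > deep_value_ms > 0", call. = FALSE)
  }
  if (any(depth_fraction < 0 | depth_fraction > 1, na.rm = TRUE)) {
    stop("depth_fraction must lie in [0, 1]", call. = FALSE)
  }
  surface_value_ms + depth_fraction * (deep_value_ms - surface_value_ms)
}

#' Build a synthetic knee phantom
#'
#' Constructs a sagittal knee-like slab from simple parametric shapes: a
#' curved femoral condyle with an articular cartilage band, a flat tibial
#' plateau with its cartilage band, a synovial fluid pool, wedge-shaped
#' menisci, an anterior infrapatellar fat pad, bone marrow, and posterior
#' muscle. Cartilage ground-truth T2 and T1rho vary with normalized depth
#' from the articular surface via [cartilage_zonal_profile()]; all other
#' tissues carry their tabulated values. Generation is fully deterministic
#' for a given configuration and seed.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed recorded in the phantom provenance (the
#'   geometry itself is deterministic).
#'
#' @return A `tissue_phantom` object: list with `labels` (3D integer
#'   array), `spacing_mm`, `tissue_table`, `truth_t2_ms` and
#'   `truth_t1rho_ms` (3D arrays, NA outside tissue), `config`, `seed`.
#' @export
build_knee_phantom <- function(config = phantom_config(), seed = 1L) {
  if (!inherits(config, "phantom_config")) {
    config <- do.call(phantom_config, config)
  }
  nx <- config$grid_dim[1]; ny <- config$grid_dim[2]; nz <- config$grid_dim[3]
  tt <- config$tissue_table
  id_of <- function(nm) tt$id[match(nm, tt$name)]

  # normalized in-plane coordinates (voxel centers); v grows inferiorly
  u <- (seq_len(nx) - 0.5) / nx
  v <- (seq_len(ny) - 0.5) / ny
  U <- matrix(u, nx, ny)
  V <- matrix(v, nx, ny, byrow = TRUE)

  # femoral condyle: circle centered (0.5, 0.30)
  r <- sqrt((U - 0.5)^2 + (V - 0.30)^2)
  fem_cart <- r >= 0.19 & r <= 0.24 & V > 0.30
  fem_marrow <- r < 0.19

  # tibial plateau: horizontal slabs
  tib_cart <- V >= 0.56 & V < 0.62 & U >= 0.26 & U <= 0.74
  tib_marrow <- V >= 0.62 & U >= 0.22 & U <= 0.78

  # menisci: wedges tapering toward the joint center
  men_l <- U >= 0.22 & U <= 0.32 & V < 0.56 & V >= 0.56 - 0.8 * (0.32 - U)
  men_r <- U >= 0.68 & U <= 0.78 & V < 0.56 & V >= 0.56 - 0.8 * (U - 0.68)
  meniscus <- men_l | men_r

  fluid <- U >= 0.24 & U <= 0.76 & V >= 0.30 & V < 0.56 & r > 0.24 &
    !meniscus & !fem_cart
  fat_pad <- U >= 0.04 & U <= 0.18 & V >= 0.30 & V <= 0.72
  muscle <- U >= 0.82 & U <= 0.96 & V >= 0.15 & V <= 0.85

  slice_labels <- matrix(0L, nx, ny)
  # painting order fixes precedence at shared boundaries
  slice_labels[muscle] <- id_of("muscle")
  slice_labels[fat_pad] <- id_of("fat_pad")
  slice_labels[fluid] <- id_of("synovial_fluid")
  slice_labels[meniscus] <- id_of("meniscus")
  slice_labels[fem_marrow] <- id_of("bone_marrow")
  slice_labels[tib_marrow] <- id_of("bone_marrow")
  slice_labels[fem_cart] <- id_of("femoral_cartilage")
  slice_labels[tib_cart] <- id_of("tibial_cartilage")

  labels <- array(rep(slice_labels, nz), dim = c(nx, ny, nz))

  depth_slice <- matrix(NA_real_, nx, ny)
  depth_slice[fem_cart] <- pmin(1, pmax(0, (0.24 - r[fem_cart]) / 0.05))
  depth_slice[tib_cart] <- pmin(1, pmax(0, (V[tib_cart] - 0.56) / 0.06))
  depth <- array(rep(depth_slice, nz), dim = c(nx, ny, nz))

  truth_t2 <- array(NA_real_, dim = dim(labels))
  truth_t1rho <- array(NA_real_, dim = dim(labels))
  for (k in seq_len(nrow(tt))) {
    if (tt$id[k] == 0L) next
    sel <- labels == tt$id[k]
    truth_t2[sel] <- tt$t2_ms[k]
    truth_t1rho[sel] <- tt$t1rho_ms[k]
  }
  cart <- labels %in% c(id_of("femoral_cartilage"), id_of("tibial_cartilage"))
  truth_t2[cart] <- cartilage_zonal_profile(
    depth[cart], config$cartilage_t2_ms[1], config$cartilage_t2_ms[2])
  truth_t1rho[cart] <- cartilage_zonal_profile(
    depth[cart], config$cartilage_t1rho_ms[1], config$cartilage_t1rho_ms[2])

  counts <- table(factor(labels, levels = tt$id))
  thin <- tt$name[tt$id != 0L][counts[as.character(tt$id[tt$id != 0L])] < 20]
  if (length(thin)) {
    stop("grid too small to place tissue region(s): ",
         paste(thin, collapse = ", "), call. = FALSE)
  }

  structure(
    list(labels = labels, spacing_mm = config$spacing_mm, tissue_table = tt,
         truth_t2_ms = truth_t2, truth_t1rho_ms = truth_t1rho,
         cartilage_depth = depth, config = config, seed = as.integer(seed)),
    class = "tissue_phantom"
  )
}

#' @export
print.tissue_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<tissue_phantom> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing_mm, 4), collapse = " x ")))
  counts <- table(factor(x$labels, levels = x$tissue_table$id))
  info <- x$tissue_table
  info$n_voxels <- as.integer(counts[as.character(info$id)])
  print(tibble::as_tibble(info), ...)
  invisible(x)
}

resolve_tissue_id <- function(phantom, tissue) {
  tt <- phantom$tissue_table
  if (is.character(tissue)) {
    id <- tt$id[match(tissue, tt$name)]
    if (is.na(id)) stop("unknown tissue name: ", tissue, call. = FALSE)
    return(id)
  }
  if (!tissue %in% tt$id) stop("unknown tissue id: ", tissue, call. = FALSE)
  as.integer(tissue)
}

#' Place a circular ROI inside a labeled tissue
#'
#' Converts a nominal in-plane ROI area in mm^2 into a voxel count
#' (round-to-nearest of area / in-plane voxel area, minimum 1) and selects
#' that many tissue voxels on the given slice, nearest to the tissue's
#' in-slice centroid, yielding a connected, approximately disc-shaped
#' region entirely within the tissue. If the centroid falls outside the
#' tissue (e.g., for a curved band), the tissue voxel closest to the
#' centroid is used as center.
#'
#' @param phantom A `tissue_phantom`.
#' @param tissue Tissue name or integer id.
#' @param area_mm2 Nominal ROI area in mm^2 (the study's standard pair-ROI
#'   area is 2.11 mm^2; the homogeneity ROI is 3.76 mm^2).
#' @param slice_index 1-based slice index; defaults to the central slice.
#'
#' @return A `roi_spec`: list with `center_voxel` (x, y, slice),
#'   `voxel_indices` (n x 3 integer matrix), `area_mm2`, `tissue_id`,
#'   `n_voxels`.
#' @export
roi_from_label <- function(phantom, tissue, area_mm2,
                           slice_index = ceiling(dim(phantom$labels)[3] / 2)) {
  stopifnot(inherits(phantom, "tissue_phantom"), area_mm2 > 0)
  tissue_id <- resolve_tissue_id(phantom, tissue)
  d <- dim(phantom$labels)
  if (slice_index < 1 || slice_index > d[3]) {
    stop("slice_index outside the grid", call. = FALSE)
  }
  voxel_area <- phantom$spacing_mm[1] * phantom$spacing_mm[2]
  n_target <- max(1L, as.integer(round(area_mm2 / voxel_area)))

  slab <- phantom$labels[, , slice_index]
  idx <- which(slab == tissue_id, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("tissue absent from slice ", slice_index, call. = FALSE)
  }
  if (nrow(idx) < n_target) {
    stop(sprintf("requested area (%d voxels) exceeds tissue extent (%d voxels) on slice",
                 n_target, nrow(idx)), call. = FALSE)
  }
  centroid <- colMeans(idx)
  d2 <- (idx[, 1] - centroid[1])^2 + (idx[, 2] - centroid[2])^2
  center <- idx[which.min(d2), ]
  d2c <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2
  keep <- order(d2c, idx[, 1], idx[, 2])[seq_len(n_target)]
  vox <- cbind(idx[keep, , drop = FALSE], slice = slice_index)
  colnames(vox) <- c("x", "y", "slice")
  structure(
    list(center_voxel = c(center, slice = slice_index),
         voxel_indices = vox, area_mm2 = area_mm2,
         tissue_id = tissue_id, n_voxels = n_target),
    class = "roi_spec"
  )
}
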