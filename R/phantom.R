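#' SUV volume container
#'
#' A 3D grid of standardized uptake values (SUV, dimensionless,
#' body-weight normalized) with physical voxel spacing in millimetres.
#'
#' @param values 3D numeric array of SUV, all values >= 0.
#' @param spacing_mm numeric length-3, per-axis voxel spacing in mm, all > 0.
#' @return An object of class `suv_volume`: a list with `values` and
#'   `spacing_mm`.
#' @export
suv_volume <- function(values, spacing_mm) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(values < 0))
    stop("SUV values must be non-negative")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive spacings")
  structure(list(values = values, spacing_mm = spacing_mm),
            class = "suv_volume")
}

#' Voxel volume of an SUV grid, in cubic millimetres
#' @param volume an `suv_volume`.
#' @return voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(volume) prod(volume$spacing_mm)

#' Labeled lesion masks over an SUV volume
#'
#' Integer label array aligned with an [suv_volume()], plus a role map
#' distinguishing the primary tumor, individual regional nodes and the
#' mediastinal-background reference region. Exactly one label must carry
#' the role `"primary"` and exactly one the role `"background"`.
#'
#' @param labels integer 3D array, 0 = unlabeled tissue.
#' @param role_map named character vector: names are label values (as
#'   character), values are roles among `"primary"`, `"node"`, `"background"`.
#' @return An object of class `lesion_set`.
#' @export
lesion_set <- function(labels, role_map) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  roles <- unname(role_map)
  if (sum(roles == "primary") != 1L)
    stop("exactly one label must have role 'primary'")
  if (sum(roles == "background") != 1L)
    stop("exactly one label must have role 'background'")
  if (!all(roles %in% c("primary", "node", "background")))
    stop("roles must be 'primary', 'node' or 'background'")
  structure(list(labels = labels, role_map = role_map), class = "lesion_set")
}

#' Logical mask for a role (or a specific label) of a lesion set
#'
#' @param lesions a `lesion_set`.
#' @param role one of `"primary"`, `"background"`, or `"node"`; for
#'   `"node"` all node labels are returned unless `label` narrows it.
#' @param label optional specific integer label.
#' @return logical array of the same shape as the labels.
#' @export
role_mask <- function(lesions, role, label = NULL) {
  if (!is.null(label)) return(lesions$labels == as.integer(label))
  labs <- as.integer(names(lesions$role_map)[lesions$role_map == role])
  if (length(labs) == 0L) stop("no label with role '", role, "'")
  array(lesions$labels %in% labs, dim = dim(lesions$labels))
}

#' Integer labels carrying the node role
#' @param lesions a `lesion_set`.
#' @return integer vector (possibly empty).
#' @export
node_labels <- function(lesions)
  as.integer(names(lesions$role_map)[lesions$role_map == "node"])

supported_profiles <- c("uniform", "radial_linear", "radial_power",
                        "multifocal", "necrotic_core")

#' Specification of a synthetic PET phantom
#'
#' Describes a spherical tumor with a chosen radial uptake profile embedded
#' in normally distributed background tissue, optional spherical nodal
#' lesions, and a mediastinal-style background reference region. The
#' phantom stands in for a patient scan: its uptake heterogeneity profile
#' drives the heterogeneity factor downstream.
#'
#' Profiles (S = SUV before noise, r = distance from tumor center,
#' R = tumor radius, Smax = `suv_max_target`):
#' \describe{
#'   \item{uniform}{S(r) = Smax for r <= R.}
#'   \item{radial_linear}{S(r) = Smax (1 - r/R).}
#'   \item{radial_power}{S(r) = Smax (1 - (r/R)^gamma), `profile_params$gamma` > 0.}
#'   \item{necrotic_core}{uptake peaks on a rim at radius f R
#'     (`profile_params$core_fraction` = f in (0,1)) and falls off linearly
#'     toward both the necrotic center and the tumor edge, clamped at 0.}
#'   \item{multifocal}{max over k linear-profile seeds
#'     (`profile_params$k_seeds`), the first seed at the tumor center so the
#'     center attains Smax; remaining seeds placed at random inside r < R/2.}
#' }
#'
#' @param grid_shape integer length-3, voxel counts per axis.
#' @param voxel_spacing_mm numeric length-3, physical spacing, mm.
#' @param tumor_radius_mm tumor sphere radius, mm.
#' @param tumor_center_mm physical center of the tumor sphere (mm); default
#'   is the grid center.
#' @param profile uptake profile name, see Details.
#' @param profile_params named list of profile parameters.
#' @param suv_max_target peak tumor SUV before noise; must exceed
#'   `background_mean + 2 * background_sd` (otherwise the MTV isocontour
#'   threshold could not separate tumor from background).
#' @param background_mean,background_sd normal-tissue SUV distribution
#'   (Gaussian, clamped at 0).
#' @param node_specs list of nodal lesions, each a list with
#'   `center_mm`, `radius_mm`, `suv_max` (uniform uptake).
#' @param noise_sd additive Gaussian SUV noise applied to every voxel.
#' @param background_roi_radius_mm radius of the spherical background
#'   reference region.
#' @param seed RNG seed; the phantom is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_spacing_mm = c(1, 1, 1),
                         tumor_radius_mm = 20,
                         tumor_center_mm = NULL,
                         profile = "radial_linear",
                         profile_params = list(),
                         suv_max_target = 10,
                         background_mean = 1.5,
                         background_sd = 0.25,
                         node_specs = list(),
                         noise_sd = 0,
                         background_roi_radius_mm = 6,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  voxel_spacing_mm <- as.numeric(voxel_spacing_mm)
  profile <- match.arg(profile, supported_profiles)
  if (any(voxel_spacing_mm <= 0)) stop("voxel spacings must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (tumor_radius_mm <= 0) stop("tumor radius must be positive")
  extent <- grid_shape * voxel_spacing_mm
  if (is.null(tumor_center_mm)) {
    # snap the default center to the nearest voxel center so the peak of
    # the radial profile is actually sampled (SUV at the tumor center must
    # equal suv_max_target before noise)
    idx <- pmax(1, round(extent / 2 / voxel_spacing_mm + 0.5))
    tumor_center_mm <- (idx - 0.5) * voxel_spacing_mm
  }
  if (any(tumor_center_mm - tumor_radius_mm < 0) ||
      any(tumor_center_mm + tumor_radius_mm > extent))
    stop("tumor sphere does not fit inside the grid")
  if (suv_max_target <= background_mean + 2 * background_sd)
    stop("suv_max_target must exceed background_mean + 2*background_sd")
  for (ns in node_specs) {
    if (any(ns$center_mm - ns$radius_mm < 0) ||
        any(ns$center_mm + ns$radius_mm > extent))
      stop("node sphere does not fit inside the grid")
  }
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = voxel_spacing_mm,
                 tumor_radius_mm = tumor_radius_mm,
                 tumor_center_mm = as.numeric(tumor_center_mm),
                 profile = profile, profile_params = profile_params,
                 suv_max_target = suv_max_target,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 node_specs = node_specs, noise_sd = noise_sd,
                 background_roi_radius_mm = background_roi_radius_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# squared distance (mm^2) of every voxel center from a physical point;
# voxel i has center (i - 0.5) * spacing (center-of-voxel rule)
.dist2_grid <- function(grid_shape, spacing, center) {
  ax <- lapply(1:3, function(a) {
    ((seq_len(grid_shape[a]) - 0.5) * spacing[a] - center[a])^2
  })
  d2 <- array(0, dim = grid_shape)
  d2 <- d2 + ax[[1]]                                   # recycles along dim 1
  d2 <- d2 + rep(ax[[2]], each = grid_shape[1])
  d2 <- d2 + rep(ax[[3]], each = grid_shape[1] * grid_shape[2])
  d2
}

.profile_suv <- function(r, R, smax, profile, params) {
  frac <- r / R
  s <- switch(profile,
    uniform       = rep(smax, length(r)),
    radial_linear = smax * (1 - frac),
    radial_power  = {
      gamma <- params$gamma %||% 2
      if (gamma <= 0) stop("radial_power needs gamma > 0")
      smax * (1 - frac^gamma)
    },
    necrotic_core = {
      f <- params$core_fraction %||% 0.4
      if (f <= 0 || f >= 1) stop("core_fraction must be in (0,1)")
      smax * pmax(0, 1 - abs(frac - f) / (1 - f))
    },
    stop("no direct radial profile for '", profile, "'"))
  pmax(s, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic PET phantom
#'
#' Realizes a [phantom_spec()] into an SUV volume and a matching lesion
#' label set. Background tissue is drawn first (Gaussian, clamped at 0),
#' tumor and node voxels are then overwritten with their noise-free uptake
#' profile, and additive Gaussian noise (if any) is applied to every voxel
#' last, with a final clamp at 0. Deterministic given `spec$seed`.
#'
#' @param spec a `phantom_spec`.
#' @return list with elements `volume` ([suv_volume()]) and
#'   `lesions` ([lesion_set()]); labels are 1 = primary tumor,
#'   2..(1+k) = nodes, then one background-region label.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  gs <- spec$grid_shape; sp <- spec$voxel_spacing_mm
  nvox <- prod(gs)
  values <- array(pmax(stats::rnorm(nvox, spec$background_mean,
                                    spec$background_sd), 0), dim = gs)
  labels <- array(0L, dim = gs)

  d2 <- .dist2_grid(gs, sp, spec$tumor_center_mm)
  R <- spec$tumor_radius_mm
  in_tumor <- d2 <= R^2
  r <- sqrt(d2[in_tumor])
  if (spec$profile == "multifocal") {
    k <- spec$profile_params$k_seeds %||% 3
    seeds <- matrix(spec$tumor_center_mm, nrow = 1)
    if (k > 1) {
      # remaining seeds uniform in the half-radius ball around the center
      extra <- matrix(stats::runif(3 * (k - 1), -R / 2, R / 2),
                      ncol = 3, byrow = TRUE)
      keep <- sqrt(rowSums(extra^2)) < R / 2
      seeds <- rbind(seeds, sweep(extra[keep, , drop = FALSE], 2,
                                  spec$tumor_center_mm, `+`))
    }
    s <- rep(0, sum(in_tumor))
    for (i in seq_len(nrow(seeds))) {
      ri <- sqrt(.dist2_grid(gs, sp, seeds[i, ])[in_tumor])
      s <- pmax(s, spec$suv_max_target * pmax(1 - ri / R, 0))
    }
  } else {
    s <- .profile_suv(r, R, spec$suv_max_target, spec$profile,
                      spec$profile_params)
  }
  values[in_tumor] <- s
  labels[in_tumor] <- 1L

  role_map <- c("1" = "primary")
  lab <- 1L
  for (ns in spec$node_specs) {
    lab <- lab + 1L
    d2n <- .dist2_grid(gs, sp, ns$center_mm)
    in_node <- d2n <= ns$radius_mm^2 & labels == 0L
    values[in_node] <- ns$suv_max
    labels[in_node] <- lab
    role_map[as.character(lab)] <- "node"
  }

  bg <- .place_background_roi(spec, labels)
  lab <- lab + 1L
  labels[bg] <- lab
  role_map[as.character(lab)] <- "background"

  if (spec$noise_sd > 0)
    values <- pmax(values + stats::rnorm(nvox, 0, spec$noise_sd), 0)

  list(volume = suv_volume(values, sp),
       lesions = lesion_set(labels, role_map))
}

# spherical reference region placed at the first corner-ward candidate
# that stays clear of every lesion; the radius shrinks (down to one
# voxel) if the grid is too tight for the requested one
.place_background_roi <- function(spec, labels) {
  gs <- spec$grid_shape; sp <- spec$voxel_spacing_mm
  extent <- gs * sp
  fracs <- rbind(c(.12, .12, .12), c(.88, .12, .12), c(.12, .88, .12),
                 c(.12, .12, .88), c(.88, .88, .88), c(.5, .12, .12),
                 c(.88, .88, .12), c(.12, .88, .88))
  rr <- spec$background_roi_radius_mm
  while (rr >= min(sp)) {
    for (i in seq_len(nrow(fracs))) {
      cen <- pmin(pmax(fracs[i, ] * extent, rr), extent - rr)
      clear_tumor <- sqrt(sum((cen - spec$tumor_center_mm)^2)) >
        spec$tumor_radius_mm + rr
      clear_nodes <- all(vapply(spec$node_specs, function(ns)
        sqrt(sum((cen - ns$center_mm)^2)) > ns$radius_mm + rr, TRUE))
      if (clear_tumor && clear_nodes) {
        m <- .dist2_grid(gs, sp, cen) <= rr^2
        if (any(m)) return(m)
      }
    }
    rr <- rr / 2
  }
  stop("could not place a background reference region clear of all lesions")
}

#' Analytic volume-threshold oracle for radially symmetric profiles
#'
#' Closed-form continuum volume of the isocontour region
#' \{S >= t Smax\} for profiles with a known form, used as an independent
#' oracle for the voxelized volume-threshold curve. For the linear radial
#' profile, V(t) = (4/3) pi R^3 (1 - t)^3; a uniform sphere keeps its full
#' volume at every threshold t <= 1.
#'
#' @param profile one of `"uniform"`, `"radial_linear"`, `"radial_power"`,
#'   `"necrotic_core"` (no closed form exists for `"multifocal"`).
#' @param R_mm tumor radius in mm.
#' @param thresholds_pct thresholds as percentages of SUVmax, in (0, 100].
#' @param profile_params as in [phantom_spec()].
#' @return data.frame with `threshold_pct` and `volume_cm3`.
#' @export
analytic_volume_threshold <- function(profile, R_mm,
                                      thresholds_pct = c(40, 50, 60, 70, 80),
                                      profile_params = list()) {
  profile <- match.arg(profile, supported_profiles)
  if (any(thresholds_pct <= 0 | thresholds_pct > 100))
    stop("thresholds must be in (0, 100]")
  t <- thresholds_pct / 100
  full <- 4 / 3 * pi * R_mm^3 / 1000        # cm^3
  vol <- switch(profile,
    uniform       = rep(full, length(t)),
    radial_linear = full * (1 - t)^3,
    radial_power  = {
      gamma <- profile_params$gamma %||% 2
      full * (1 - t)^(3 / gamma)
    },
    necrotic_core = {
      f <- profile_params$core_fraction %||% 0.4
      # S >= t Smax  <=>  |r/R - f| <= (1 - t)(1 - f): a spherical shell
      half <- (1 - t) * (1 - f)
      r1 <- pmax(f - half, 0) * R_mm
      r2 <- pmin(f + half, 1) * R_mm
      4 / 3 * pi * (r2^3 - r1^3) / 1000
    },
    stop("no closed-form volume-threshold function for '", profile, "'"))
  data.frame(threshold_pct = thresholds_pct, volume_cm3 = vol)
}

#' Write a phantom to NIfTI files
#'
#' Writes the SUV volume and the label mask as a pair of NIfTI images on
#' the same grid (spacing carried in the header).
#'
#' @param phantom list with `volume` and `lesions` (from
#'   [generate_phantom()]).
#' @param volume_path,labels_path output file paths (`.nii` or `.nii.gz`).
#' @return invisibly, the two paths.
#' @export
write_phantom_nifti <- function(phantom, volume_path, labels_path) {
  sp <- phantom$volume$spacing_mm
  img <- RNifti::asNifti(phantom$volume$values, pixdim = sp)
  RNifti::writeNifti(img, volume_path)
  lab <- RNifti::asNifti(phantom$lesions$labels + 0, pixdim = sp)
  RNifti::writeNifti(lab, labels_path)
  invisible(c(volume_path, labels_path))
}

#' Read an SUV volume and label mask from NIfTI files
#'
#' @param volume_path path to the SUV image.
#' @param labels_path path to the integer label image.
#' @param role_map role map for the labels; by default label 1 is the
#'   primary, the largest label the background region, and everything in
#'   between a node.
#' @return list with `volume` and `lesions`.
#' @export
read_phantom_nifti <- function(volume_path, labels_path, role_map = NULL) {
  img <- RNifti::readNifti(volume_path)
  lab <- RNifti::readNifti(labels_path)
  sp <- RNifti::pixdim(img)[1:3]
  values <- array(as.numeric(img), dim = dim(img))
  labels <- array(as.integer(round(as.numeric(lab))), dim = dim(lab))
  if (is.null(role_map)) {
    labs <- sort(setdiff(unique(as.vector(labels)), 0L))
    if (length(labs) < 2L)
      stop("label image must contain at least a primary and a background region")
    role_map <- stats::setNames(
      c("primary", rep("node", length(labs) - 2L), "background"),
      as.character(labs))
  }
  list(volume = suv_volume(values, sp),
       lesions = lesion_set(labels, role_map))
}

#' Write a phantom or cohort spec as YAML
#' @param spec a `phantom_spec` or `cohort_spec`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_spec_yaml <- function(spec, path) {
  yaml::write_yaml(c(list(.class = class(spec)[1]), unclass(spec)), path)
  invisible(path)
}
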