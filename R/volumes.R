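# Core data model: scalar volumes on anisotropic lattices, binary structure
# masks, named structure sets and plan configuration, plus NIfTI readers and
# writers and grid-to-grid resampling.

#' Construct a volume grid
#'
#' A `volume_grid` is a 3D scalar lattice with anisotropic physical spacing
#' and an origin, using the voxel-center convention: voxel `(i, j, k)`
#' (0-based) sits at physical position `origin + c(i, j, k) * spacing`
#' (millimetres). Axis order is `(x, y, z)`.
#'
#' @param values 3D numeric array (image intensity in arbitrary units, or
#'   dose in cGy).
#' @param spacing numeric length-3, voxel spacing in mm; strictly positive.
#' @param origin numeric length-3, physical position of voxel `(0,0,0)` in mm.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

grid_dim <- function(grid) dim(grid$values)

#' Construct a binary structure mask
#'
#' A `binary_mask` shares the geometry (shape, spacing, origin) of the grid it
#' was delineated on. Voxels are `TRUE` inside the structure.
#'
#' @param voxels 3D logical array.
#' @param spacing,origin grid geometry in mm (see [volume_grid()]). A
#'   `volume_grid` can be passed as `spacing` to copy its geometry.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (inherits(spacing, "volume_grid")) {
    origin <- spacing$origin
    ref_dim <- dim(spacing$values)
    spacing <- spacing$spacing
    if (!identical(dim(voxels), ref_dim))
      stop("mask shape does not match its reference grid", call. = FALSE)
  }
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L || !is.logical(voxels))
    stop("`voxels` must be a 3D logical array", call. = FALSE)
  if (anyNA(voxels)) stop("mask voxels must not contain NA", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (mm)", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d inside (%.2f cc)\n",
              paste(dim(x$voxels), collapse = "x"),
              sum(x$voxels), mask_volume_cc(x)))
  invisible(x)
}

#' Structure volume in cubic centimetres
#'
#' @param mask a [binary_mask()].
#' @return Volume in cc (`count * dx*dy*dz / 1000`).
#' @export
mask_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

same_geometry <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "binary_mask")) dim(a$voxels) else dim(a$values)
  db <- if (inherits(b, "binary_mask")) dim(b$voxels) else dim(b$values)
  identical(da, db) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

check_same_geometry <- function(a, b) {
  if (!same_geometry(a, b))
    stop("grids/masks do not share geometry (shape, spacing, origin)",
         call. = FALSE)
  invisible(TRUE)
}

#' The nine evaluated planning-structure names
#'
#' Clinical target volume plus the eight organs at risk evaluated for pelvic
#' external-beam radiotherapy plans. Small intestine is not evaluated.
#'
#' @return Character vector of structure names.
#' @export
rt_structure_names <- function() {
  c("CTV", "Spinal Cord", "Kidney L", "Kidney R", "Bladder",
    "Femoral Head L", "Femoral Head R", "Pelvic Bone", "Rectum")
}

#' Construct a structure set
#'
#' A named collection of binary masks sharing one grid geometry, labelled by
#' provenance (`"manual"` reference contours or `"auto"` contours).
#'
#' @param structures named list of [binary_mask()] objects; names unique.
#' @param provenance `"manual"` or `"auto"`.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(structures, provenance = c("manual", "auto")) {
  provenance <- match.arg(provenance)
  if (!is.list(structures) || length(structures) == 0L)
    stop("`structures` must be a non-empty named list of masks", call. = FALSE)
  nms <- names(structures)
  if (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms)))
    stop("structure names must be unique and non-empty", call. = FALSE)
  for (m in structures) {
    if (!inherits(m, "binary_mask"))
      stop("all structures must be binary_mask objects", call. = FALSE)
    check_same_geometry(structures[[1L]], m)
  }
  structure(list(structures = structures, provenance = provenance),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> provenance=%s, %d structures: %s\n",
              x$provenance, length(x$structures),
              paste(names(x$structures), collapse = ", ")))
  invisible(x)
}

#' Plan configuration: prescription and dose constraints
#'
#' Holds the prescription dose, fractionation, and the per-structure planning
#' constraints used for pass/fail checks. The default constraint table is the
#' standard pelvic EBRT set: CTV D99% above prescription and Dmax below 110%
#' of prescription; spinal cord Dmax < 4000 cGy; kidney Dmean < 1200 cGy;
#' bladder and rectum D50% < 100% and D0.03cc < 110% of prescription; femoral
#' head D15% < 3000 cGy and Dmean < 2000 cGy; pelvic bone Dmean < 3000 cGy.
#'
#' @param prescription_cGy prescription dose in cGy (e.g. 4500-5040 at
#'   180 cGy/fraction).
#' @param fractions number of fractions.
#' @param constraints data.frame with columns `structure`, `metric`, `limit`,
#'   `limit_unit` (`"cGy"` or `"pct_rx"`, percent of prescription) and
#'   `direction` (`"lt"` or `"gt"`). Defaults to [default_constraints()].
#' @return An object of class `plan_config`.
#' @export
plan_config <- function(prescription_cGy = 4500, fractions = 25,
                        constraints = default_constraints()) {
  if (!is.numeric(prescription_cGy) || prescription_cGy <= 0)
    stop("prescription must be a positive dose in cGy", call. = FALSE)
  if (!is.numeric(fractions) || fractions < 1)
    stop("fractions must be a positive integer", call. = FALSE)
  needed <- c("structure", "metric", "limit", "limit_unit", "direction")
  if (!all(needed %in% names(constraints)))
    stop("constraints must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(constraints$metric, names(dvi_metric_registry()))
  if (length(bad))
    stop("unknown constraint metric(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(prescription_cGy = as.numeric(prescription_cGy),
                 fractions = as.integer(fractions),
                 constraints = constraints),
            class = "plan_config")
}

#' Default pelvic EBRT constraint table
#'
#' @return data.frame of constraints (see [plan_config()]).
#' @export
default_constraints <- function() {
  df <- rbind(
    data.frame(structure = "CTV", metric = "D99%", limit = 100,
               limit_unit = "pct_rx", direction = "gt"),
    data.frame(structure = "CTV", metric = "D_max", limit = 110,
               limit_unit = "pct_rx", direction = "lt"),
    data.frame(structure = "Spinal Cord", metric = "D_max", limit = 4000,
               limit_unit = "cGy", direction = "lt"),
    data.frame(structure = "Kidney L", metric = "D_mean", limit = 1200,
               limit_unit = "cGy", direction = "lt"),
    data.frame(structure = "Kidney R", metric = "D_mean", limit = 1200,
               limit_unit = "cGy", direction = "lt"),
    data.frame(structure = "Bladder", metric = "D50%", limit = 100,
               limit_unit = "pct_rx", direction = "lt"),
    data.frame(structure = "Bladder", metric = "D0.03cc", limit = 110,
               limit_unit = "pct_rx", direction = "lt"),
    data.frame(structure = "Femoral Head L", metric = "D15%", limit = 3000,
               limit_unit = "cGy", direction = "lt"),
    data.frame(structure = "Femoral Head L", metric = "D_mean", limit = 2000,
               limit_unit = "cGy", direction = "lt"),
    data.frame(structure = "Femoral Head R", metric = "D15%", limit = 3000,
               limit_unit = "cGy", direction = "lt"),
    data.frame(structure = "Femoral Head R", metric = "D_mean", limit = 2000,
               limit_unit = "cGy", direction = "lt"),
    data.frame(structure = "Pelvic Bone", metric = "D_mean", limit = 3000,
               limit_unit = "cGy", direction = "lt"),
    data.frame(structure = "Rectum", metric = "D50%", limit = 100,
               limit_unit = "pct_rx", direction = "lt"),
    data.frame(structure = "Rectum", metric = "D0.03cc", limit = 110,
               limit_unit = "pct_rx", direction = "lt")
  )
  rownames(df) <- NULL
  df
}

#' Dose-volume metric of record per structure
#'
#' The scalar dosimetric endpoint reported per structure when manual and auto
#' contours are compared: Dmean and V100 for the CTV, Dmax for the spinal
#' cord (serial organ), Dmean for the parallel organs at risk.
#'
#' @return data.frame with columns `structure`, `metric`.
#' @export
metrics_of_record <- function() {
  df <- rbind(
    data.frame(structure = "CTV", metric = c("D_mean", "V100")),
    data.frame(structure = "Spinal Cord", metric = "D_max"),
    data.frame(structure = c("Kidney L", "Kidney R", "Bladder",
                             "Femoral Head L", "Femoral Head R",
                             "Pelvic Bone", "Rectum"),
               metric = "D_mean")
  )
  rownames(df) <- NULL
  df
}

## ---- NIfTI I/O -------------------------------------------------------------

grid_to_nifti <- function(values, spacing, origin) {
  img <- RNifti::asNifti(values)
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  RNifti::`qform<-`(img, structure(m, code = 2L))
}

#' Write a volume or labelmap to NIfTI
#'
#' @param x a [volume_grid()] or a [structure_set()] (written as an integer
#'   labelmap, label k = k-th structure; structures must be disjoint).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param dose_unit unit of dose values on disk; grids are stored as given.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, dose_unit = c("cGy", "Gy")) {
  dose_unit <- match.arg(dose_unit)
  if (inherits(x, "structure_set")) {
    first <- x$structures[[1L]]
    lab <- array(0, dim = dim(first$voxels))
    k <- 0L
    for (nm in names(x$structures)) {
      k <- k + 1L
      vox <- x$structures[[nm]]$voxels
      if (any(lab[vox] != 0))
        stop("structures overlap; cannot encode as a single labelmap",
             call. = FALSE)
      lab[vox] <- k
    }
    img <- grid_to_nifti(lab, first$spacing, first$origin)
    img <- RNifti::`pixdim<-`(img, first$spacing)
    RNifti::writeNifti(img, path, datatype = "int16")
  } else if (inherits(x, "volume_grid")) {
    img <- grid_to_nifti(x$values, x$spacing, x$origin)
    img <- RNifti::`pixdim<-`(img, x$spacing)
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    stop("write_volume() handles volume_grid and structure_set objects",
         call. = FALSE)
  }
  invisible(path)
}

#' Read a volume or labelmap from NIfTI
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param kind `"image"` or `"dose"` return a [volume_grid()]; `"labelmap"`
#'   returns a [structure_set()] in which integer label k > 0 maps to
#'   `structure_names[k]`.
#' @param structure_names names for labelmap labels (required for
#'   `kind = "labelmap"`).
#' @param provenance provenance label for a labelmap.
#' @param dose_unit unit of dose stored in the file; `"Gy"` is converted to
#'   cGy on read.
#' @return A [volume_grid()] or [structure_set()].
#' @export
read_volume <- function(path, kind = c("image", "dose", "labelmap"),
                        structure_names = NULL,
                        provenance = c("manual", "auto"),
                        dose_unit = c("cGy", "Gy")) {
  kind <- match.arg(kind)
  dose_unit <- match.arg(dose_unit)
  provenance <- match.arg(provenance)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("unsupported volumetric format (expected .nii or .nii.gz): ", path,
         call. = FALSE)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  vals <- array(as.numeric(vals), dim = dim(vals))  # drop header attributes
  if (length(dim(vals)) != 3L)
    stop("expected a 3D volume, got ", length(dim(vals)), "D", call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  if (kind == "labelmap") {
    if (any(vals < 0) || max(abs(vals - round(vals))) > 1e-6)
      stop("labelmap must contain small non-negative integers", call. = FALSE)
    vals <- round(vals)
    labs <- sort(unique(vals[vals > 0]))
    if (is.null(structure_names))
      stop("structure_names required for kind = 'labelmap'", call. = FALSE)
    if (length(labs) && max(labs) > length(structure_names))
      stop("labelmap contains label ", max(labs), " but only ",
           length(structure_names), " structure names configured",
           call. = FALSE)
    masks <- list()
    for (k in seq_along(structure_names)) {
      masks[[structure_names[k]]] <-
        binary_mask(vals == k, spacing = spacing, origin = origin)
    }
    structure_set(masks, provenance = provenance)
  } else {
    if (kind == "dose" && dose_unit == "Gy") vals <- vals * 100
    volume_grid(vals, spacing = spacing, origin = origin)
  }
}

## ---- Resampling ------------------------------------------------------------

#' Resample a volume onto a reference grid
#'
#' Maps the reference grid's voxel centers into the source grid's continuous
#' index space and interpolates. Trilinear interpolation is intended for dose
#' and image volumes, nearest-neighbor for masks/labelmaps. Voxels whose
#' physical position falls outside the source extent are filled with 0 (with
#' a warning).
#'
#' @param src source [volume_grid()].
#' @param ref reference [volume_grid()] (or [binary_mask()]) supplying the
#'   output geometry.
#' @param mode `"trilinear"` or `"nearest"`.
#' @return A [volume_grid()] with the reference geometry.
#' @export
resample_to <- function(src, ref, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(src, "volume_grid"))
  ref_dim <- if (inherits(ref, "binary_mask")) dim(ref$voxels)
             else dim(ref$values)
  if (same_geometry(src, ref))
    return(volume_grid(src$values, src$spacing, src$origin))

  sdim <- dim(src$values)
  # physical extent overlap check (voxel-center bounding boxes)
  lo_s <- src$origin; hi_s <- src$origin + (sdim - 1) * src$spacing
  lo_r <- ref$origin; hi_r <- ref$origin + (ref_dim - 1) * ref$spacing
  if (any(hi_s < lo_r) || any(hi_r < lo_s))
    stop("source and reference grids have no physical overlap", call. = FALSE)

  # continuous (0-based) source indices of reference voxel centers, per axis
  ax <- lapply(1:3, function(a) {
    (ref$origin[a] + (seq_len(ref_dim[a]) - 1) * ref$spacing[a] -
       src$origin[a]) / src$spacing[a]
  })
  nref <- prod(ref_dim)
  ix <- rep(ax[[1]], times = ref_dim[2] * ref_dim[3])
  iy <- rep(rep(ax[[2]], each = ref_dim[1]), times = ref_dim[3])
  iz <- rep(ax[[3]], each = ref_dim[1] * ref_dim[2])

  out <- numeric(nref)
  if (mode == "nearest") {
    jx <- round(ix); jy <- round(iy); jz <- round(iz)
    ok <- jx >= 0 & jx <= sdim[1] - 1 & jy >= 0 & jy <= sdim[2] - 1 &
      jz >= 0 & jz <= sdim[3] - 1
    lin <- jx[ok] + sdim[1] * (jy[ok] + sdim[2] * jz[ok]) + 1
    out[ok] <- as.numeric(src$values)[lin]
    n_out <- sum(!ok)
  } else {
    x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
    fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
    vals <- as.numeric(src$values)
    corner <- function(dx, dy, dz) {
      cx <- x0 + dx; cy <- y0 + dy; cz <- z0 + dz
      ok <- cx >= 0 & cx <= sdim[1] - 1 & cy >= 0 & cy <= sdim[2] - 1 &
        cz >= 0 & cz <= sdim[3] - 1
      v <- numeric(nref)
      v[ok] <- vals[cx[ok] + sdim[1] * (cy[ok] + sdim[2] * cz[ok]) + 1]
      v
    }
    out <- corner(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
      corner(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
      corner(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
      corner(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
      corner(1, 1, 0) * fx * fy * (1 - fz) +
      corner(1, 0, 1) * fx * (1 - fy) * fz +
      corner(0, 1, 1) * (1 - fx) * fy * fz +
      corner(1, 1, 1) * fx * fy * fz
    n_out <- sum(ix < 0 | ix > sdim[1] - 1 | iy < 0 | iy > sdim[2] - 1 |
                   iz < 0 | iz > sdim[3] - 1)
  }
  if (n_out > 0)
    warning(n_out, " reference voxels fall outside the source extent; ",
            "filled with 0", call. = FALSE)
  volume_grid(array(out, dim = ref_dim), spacing = ref$spacing,
              origin = ref$origin)
}

## ---- distance transform wrapper -------------------------------------------

#' Euclidean distance transform in physical millimetres
#'
#' Distance from every voxel center to the nearest `TRUE` voxel center,
#' honouring anisotropic spacing. Voxels inside the feature set have
#' distance 0; if the mask is empty all distances are `Inf`.
#'
#' @param voxels 3D logical array.
#' @param spacing voxel spacing in mm.
#' @return 3D numeric array of distances (mm).
#' @export
distance_transform_mm <- function(voxels, spacing = c(1, 1, 1)) {
  stopifnot(is.logical(voxels), length(dim(voxels)) == 3L)
  d <- .edt3d_cpp(as.logical(voxels), as.integer(dim(voxels)),
                  as.numeric(spacing))
  array(d, dim = dim(voxels))
}

# signed distance: negative inside the mask, positive outside (mm)
signed_distance_mm <- function(voxels, spacing) {
  outside <- distance_transform_mm(voxels, spacing)   # 0 inside
  inside <- distance_transform_mm(!voxels, spacing)   # 0 outside
  outside - inside
}

# run code with a locally-seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
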