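# Geometric contour-agreement metrics: Dice similarity coefficient, Jaccard
# coefficient, and the (percentile) Hausdorff surface distance computed on
# physical-coordinate surface point sets.

#' Extract the surface point set of a mask
#'
#' A voxel is a surface voxel iff it is inside the structure and at least one
#' of its 6-neighbors is outside (the volume border counts as outside).
#' Points are the physical (mm) coordinates of surface voxel centers.
#'
#' @param mask a non-empty [binary_mask()].
#' @param name structure name carried along for reporting.
#' @return List with `points` (n x 3 matrix, mm), `voxels` (logical array of
#'   surface voxels) and `structure`.
#' @export
extract_surface <- function(mask, name = NA_character_) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$voxels))
    stop("empty structure: no surface can be extracted", call. = FALSE)
  surf <- surface_voxels(mask$voxels)
  idx <- which(surf, arr.ind = TRUE)  # 1-based
  pts <- sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
  colnames(pts) <- c("x", "y", "z")
  list(points = pts, voxels = surf, structure = name)
}

# logical array of 6-connectivity boundary voxels (border counts as outside)
surface_voxels <- function(v) {
  d <- dim(v)
  interior <- array(TRUE, dim = d)
  shift_all_true <- function(axis, by) {
    out <- array(FALSE, dim = d)
    n <- d[axis]
    src <- seq_len(n) + by
    ok <- src >= 1 & src <= n
    if (axis == 1) out[ok, , ] <- v[src[ok], , ]
    if (axis == 2) out[, ok, ] <- v[, src[ok], ]
    if (axis == 3) out[, , ok] <- v[, , src[ok]]
    out
  }
  for (axis in 1:3) {
    interior <- interior & shift_all_true(axis, 1) & shift_all_true(axis, -1)
  }
  v & !interior
}

#' Dice similarity coefficient
#'
#' `DSC = 2|A intersect B| / (|A| + |B|)`: relative overlap of two
#' segmentations in `[0, 1]`, 1 for complete overlap.
#'
#' @param a,b [binary_mask()] objects sharing one grid geometry; not both
#'   empty.
#' @return Unitless DSC in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_same_geometry(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0L)
    stop("DSC undefined: both masks are empty", call. = FALSE)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Jaccard coefficient
#'
#' `JC = |A intersect B| / |A union B|`, in `[0, 1]`.
#'
#' @inheritParams dice
#' @return Unitless JC in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  check_same_geometry(a, b)
  u <- sum(a$voxels | b$voxels)
  if (u == 0L)
    stop("JC undefined: both masks are empty", call. = FALSE)
  sum(a$voxels & b$voxels) / u
}

#' (Percentile) Hausdorff surface distance in mm
#'
#' The directed distance `h(A,B)` is, for every surface point of `B`, the
#' minimum Euclidean distance (mm) to the surface of `A`; classic HD takes
#' the maximum over those, `HD = max(h(A,B), h(B,A))`. A percentile
#' `p < 100` replaces each directed maximum with the p-th percentile of the
#' directed distance distribution (linear interpolation between order
#' statistics); `percentile = 95` gives the 95% Hausdorff distance that
#' discounts the worst 5% of surface separations.
#'
#' @inheritParams dice
#' @param percentile percentile in `(0, 100]`; 100 reproduces classic HD.
#' @return Distance in mm.
#' @export
hausdorff <- function(a, b, percentile = 100) {
  check_same_geometry(a, b)
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile > 100)
    stop("percentile must be in (0, 100]", call. = FALSE)
  if (!any(a$voxels) || !any(b$voxels))
    stop("Hausdorff distance undefined for an empty structure", call. = FALSE)
  sa <- surface_voxels(a$voxels)
  sb <- surface_voxels(b$voxels)
  # exact nearest surface-voxel-center distances via the distance transform
  dta <- distance_transform_mm(sa, a$spacing)  # distance to surface of A
  dtb <- distance_transform_mm(sb, b$spacing)
  h_ab <- dta[sb]  # directed: from each surface point of B to surface of A
  h_ba <- dtb[sa]
  if (percentile == 100) {
    max(max(h_ab), max(h_ba))
  } else {
    max(stats::quantile(h_ab, percentile / 100, names = FALSE, type = 7),
        stats::quantile(h_ba, percentile / 100, names = FALSE, type = 7))
  }
}

#' Geometric metrics for one structure pair
#'
#' @inheritParams dice
#' @param name structure name.
#' @param hd_percentile percentile for the reduced Hausdorff distance
#'   (default 95).
#' @return One-row data.frame: `structure`, `dsc`, `jc`, `hd_mm`, `hd95_mm`.
#' @export
geometric_metrics <- function(a, b, name = NA_character_,
                              hd_percentile = 95) {
  data.frame(structure = name,
             dsc = dice(a, b),
             jc = jaccard(a, b),
             hd_mm = hausdorff(a, b, 100),
             hd95_mm = hausdorff(a, b, hd_percentile))
}

#' Evaluate geometric agreement of two structure sets
#'
#' One row per structure in the union of names. Structures present in only
#' one set, or empty in either set, are reported with `NA` metrics and a
#' non-`"ok"` status rather than silently dropped. Masks are never cropped
#' before comparison.
#'
#' @param ref reference (manual) [structure_set()].
#' @param test test (auto) [structure_set()].
#' @param hd_percentile percentile for the reduced Hausdorff distance.
#' @return data.frame: `structure`, `dsc`, `jc`, `hd_mm`, `hd95_mm`,
#'   `status`.
#' @export
evaluate_geometry <- function(ref, test, hd_percentile = 95) {
  stopifnot(inherits(ref, "structure_set"), inherits(test, "structure_set"))
  common <- intersect(names(ref$structures), names(test$structures))
  if (length(common) == 0L)
    stop("no common structure names between the two sets", call. = FALSE)
  all_names <- union(names(ref$structures), names(test$structures))
  rows <- lapply(all_names, function(nm) {
    in_ref <- nm %in% names(ref$structures)
    in_test <- nm %in% names(test$structures)
    na_row <- function(status)
      data.frame(structure = nm, dsc = NA_real_, jc = NA_real_,
                 hd_mm = NA_real_, hd95_mm = NA_real_, status = status)
    if (!in_test) return(na_row("missing_in_test"))
    if (!in_ref) return(na_row("missing_in_ref"))
    a <- ref$structures[[nm]]
    b <- test$structures[[nm]]
    if (!any(a$voxels) || !any(b$voxels)) return(na_row("empty"))
    out <- geometric_metrics(a, b, nm, hd_percentile)
    out$status <- "ok"
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
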