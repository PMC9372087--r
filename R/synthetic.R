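# Synthetic pelvic phantom cohorts: CT-like images with nine parametric
# planning structures, perturbation-controlled "auto" contours emulating
# auto-segmentation error, and a CTV-conformal dose surrogate.

coord_arrays <- function(shape, spacing, origin = c(0, 0, 0)) {
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 1) * spacing[a])
  list(
    x = array(rep(ax[[1]], times = shape[2] * shape[3]), dim = shape),
    y = array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), dim = shape),
    z = array(rep(ax[[3]], each = shape[1] * shape[2]), dim = shape)
  )
}

ellipsoid <- function(co, center, radii) {
  ((co$x - center[1]) / radii[1])^2 +
    ((co$y - center[2]) / radii[2])^2 +
    ((co$z - center[3]) / radii[3])^2 <= 1
}

xy_ellipse <- function(co, center, radii) {
  ((co$x - center[1]) / radii[1])^2 + ((co$y - center[2]) / radii[2])^2 <= 1
}

tube <- function(co, center_xy, radius_xy, z_range) {
  xy_ellipse(co, center_xy, c(radius_xy, radius_xy)) &
    co$z >= z_range[1] & co$z <= z_range[2]
}

# separable Gaussian smoothing with edge clamping, sigma in mm per axis
gaussian_smooth_mm <- function(arr, spacing, sigma_mm) {
  d <- dim(arr)
  for (a in 1:3) {
    sv <- sigma_mm / spacing[a]
    if (sv < 0.25) next
    r <- ceiling(3 * sv)
    w <- stats::dnorm(seq(-r, r), sd = sv)
    w <- w / sum(w)
    out <- array(0, dim = d)
    n <- d[a]
    for (k in seq(-r, r)) {
      idx <- pmin(pmax(seq_len(n) + k, 1L), n)
      shifted <- switch(a, arr[idx, , , drop = FALSE],
                        arr[, idx, , drop = FALSE],
                        arr[, , idx, drop = FALSE])
      out <- out + w[k + r + 1] * shifted
    }
    arr <- out
  }
  arr
}

# trilinear sample of a scalar field at every voxel center displaced by
# -delta (i.e. the field shifted *by* +delta), out-of-extent filled with
# `fill`
shift_field_mm <- function(arr, spacing, delta, fill) {
  d <- dim(arr)
  off <- delta / spacing  # continuous index offset, f(x - delta)
  ix <- rep(seq_len(d[1]) - 1 - off[1], times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]) - 1 - off[2], each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]) - 1 - off[3], each = d[1] * d[2])
  x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  vals <- as.numeric(arr)
  n <- length(vals)
  corner <- function(dx, dy, dz) {
    cx <- x0 + dx; cy <- y0 + dy; cz <- z0 + dz
    ok <- cx >= 0 & cx <= d[1] - 1 & cy >= 0 & cy <= d[2] - 1 &
      cz >= 0 & cz <= d[3] - 1
    v <- rep(fill, n)
    v[ok] <- vals[cx[ok] + d[1] * (cy[ok] + d[2] * cz[ok]) + 1]
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
  array(out, dim = d)
}

phantom_intensities <- function() {
  c("CTV" = 250, "Spinal Cord" = 210, "Kidney L" = 170, "Kidney R" = 150,
    "Bladder" = 50, "Femoral Head L" = 360, "Femoral Head R" = 330,
    "Pelvic Bone" = 400, "Rectum" = 70)
}

#' Generate one pelvic phantom (image + manual structure set)
#'
#' Places the nine planning structures as parametric solids with
#' anatomically plausible relative positions on a desk-scale anisotropic
#' grid: ellipsoidal kidneys and bladder, tubular rectum and spinal cord,
#' spherical femoral heads, a ring-like pelvic bone and an irregular
#' union-of-ellipsoids CTV. Position and size receive small per-case random
#' jitter. The CT-like image assigns each structure a distinct mean
#' intensity on a soft-tissue background plus Gaussian noise, making the
#' phantom an intensity-coded "easy" segmentation task by design.
#' Structures are carved to be mutually disjoint. Deterministic given
#' `seed`.
#'
#' @param seed integer RNG seed.
#' @param shape grid shape, at least `c(32, 32, 16)`.
#' @param spacing voxel spacing in mm (default `c(2, 2, 5)`: anisotropic,
#'   coarse slices).
#' @param noise_sd image noise standard deviation (intensity units).
#' @return List: `image` ([volume_grid()]), `manual` ([structure_set()]).
#' @export
generate_phantom <- function(seed, shape = c(64, 64, 24),
                             spacing = c(2, 2, 5), noise_sd = 5) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < c(32, 32, 16)))
    stop("shape must be at least (32, 32, 16) to fit the structures",
         call. = FALSE)
  fov <- shape * spacing
  co <- coord_arrays(shape, spacing)
  with_seed(seed, {
    jit <- function(sd_mm = 2) stats::rnorm(3, 0, sd_mm) * c(1, 1, 0.8)
    rj <- function() stats::runif(1, 0.92, 1.08)
    sc <- fov / c(128, 128, 120)  # scale anatomy to the field of view

    ctr <- function(fx, fy, fz) c(fx * fov[1], fy * fov[2], fz * fov[3])

    masks <- list()
    masks[["Spinal Cord"]] <- {
      c0 <- ctr(0.5, 0.78, 0) + jit(1)
      tube(co, c0[1:2], 4 * sc[1] * rj(), c(0.46, 0.98) * fov[3])
    }
    masks[["Kidney L"]] <- {
      c0 <- ctr(0.266, 0.45, 0.85) + jit()
      ellipsoid(co, c0, c(10, 8, 12) * rj() * sc[c(1, 2, 3)])
    }
    masks[["Kidney R"]] <- {
      c0 <- ctr(0.734, 0.45, 0.85) + jit()
      ellipsoid(co, c0, c(10, 8, 12) * rj() * sc[c(1, 2, 3)])
    }
    masks[["Femoral Head L"]] <- {
      c0 <- ctr(0.16, 0.41, 0.21) + jit()
      ellipsoid(co, c0, rep(11 * rj(), 3) * sc[1])
    }
    masks[["Femoral Head R"]] <- {
      c0 <- ctr(0.84, 0.41, 0.21) + jit()
      ellipsoid(co, c0, rep(11 * rj(), 3) * sc[1])
    }
    masks[["Bladder"]] <- {
      c0 <- ctr(0.5, 0.29, 0.43) + jit()
      ellipsoid(co, c0, c(14, 12, 14) * rj() * sc)
    }
    masks[["Rectum"]] <- {
      c0 <- ctr(0.5, 0.71, 0) + jit(1)
      tube(co, c0[1:2], 7 * sc[1] * rj(), c(0.17, 0.58) * fov[3])
    }
    masks[["Pelvic Bone"]] <- {
      c0 <- ctr(0.5, 0.52, 0) + jit(1)
      zr <- c(0.125, 0.5) * fov[3]
      router <- c(46, 38) * sc[1:2] * rj()
      rinner <- router - c(10, 10) * sc[1:2]
      xy_ellipse(co, c0[1:2], router) & !xy_ellipse(co, c0[1:2], rinner) &
        co$z >= zr[1] & co$z <= zr[2]
    }
    masks[["CTV"]] <- {
      c0 <- ctr(0.5, 0.5, 0.42) + jit()
      r1 <- rj()
      ellipsoid(co, c0, c(16, 12, 16) * r1 * sc) |
        ellipsoid(co, c0 + c(0, 4, -14) * sc, c(8, 7, 12) * r1 * sc) |
        ellipsoid(co, c0 + c(0, -6, 16) * sc, c(12, 10, 10) * r1 * sc)
    }

    # carve to mutual disjointness; earlier structures keep their voxels
    order_keep <- c("Spinal Cord", "Kidney L", "Kidney R", "Femoral Head L",
                    "Femoral Head R", "Bladder", "Rectum", "Pelvic Bone",
                    "CTV")
    taken <- array(FALSE, dim = shape)
    for (nm in order_keep) {
      masks[[nm]] <- masks[[nm]] & !taken
      taken <- taken | masks[[nm]]
      if (!any(masks[[nm]]))
        stop("phantom geometry error: structure '", nm,
             "' is empty after carving", call. = FALSE)
    }

    body <- xy_ellipse(co, c(0.5, 0.5) * fov[1:2],
                       c(0.47, 0.42) * fov[1:2])
    img <- array(0, dim = shape)
    img[body] <- 100
    ints <- phantom_intensities()
    for (nm in names(ints)) img[masks[[nm]]] <- ints[[nm]]
    img <- img + stats::rnorm(length(img), 0, noise_sd)

    grid <- volume_grid(img, spacing = spacing, origin = c(0, 0, 0))
    manual <- structure_set(
      lapply(masks[rt_structure_names()], binary_mask,
             spacing = spacing, origin = c(0, 0, 0)),
      provenance = "manual")
    list(image = grid, manual = manual)
  })
}

#' Default auto-segmentation error profile
#'
#' Per-structure perturbation magnitudes (standard deviations, mm) for
#' rigid shift, signed dilation/erosion (morph), correlated boundary noise,
#' and the probability of deleting a superior/inferior border slice. The
#' profile was calibrated once so that a default cohort reproduces the
#' typical fidelity ordering of pelvic auto-segmentation: kidneys, bladder
#' and femoral heads near DSC 0.88-0.93, CTV near 0.77, spinal cord and
#' rectum near 0.71-0.74, pelvic bone near 0.65.
#'
#' @return Named list (one entry per structure) of lists with fields
#'   `shift_mm`, `morph_mm`, `boundary_noise_mm`, `slice_dropout_prob`.
#' @export
default_perturbation <- function() {
  p <- function(shift, morph, noise, drop)
    list(shift_mm = shift, morph_mm = morph, boundary_noise_mm = noise,
         slice_dropout_prob = drop)
  list(
    "CTV" = p(2.2, 1.8, 2.4, 0.15),
    "Spinal Cord" = p(1.0, 0.7, 1.0, 0.30),
    "Kidney L" = p(0.55, 0.3, 0.5, 0.03),
    "Kidney R" = p(0.55, 0.3, 0.5, 0.03),
    "Bladder" = p(0.9, 0.6, 0.9, 0.05),
    "Femoral Head L" = p(1.0, 0.6, 1.0, 0.08),
    "Femoral Head R" = p(1.0, 0.6, 1.0, 0.08),
    "Pelvic Bone" = p(1.6, 3.0, 3.8, 0.20),
    "Rectum" = p(1.6, 1.4, 2.4, 0.30)
  )
}

#' Zero (identity) perturbation profile
#'
#' @return A perturbation profile whose application returns masks unchanged.
#' @export
zero_perturbation <- function() {
  lapply(default_perturbation(), function(p)
    list(shift_mm = 0, morph_mm = 0, boundary_noise_mm = 0,
         slice_dropout_prob = 0))
}

perturb_one <- function(mask, pars, noise_corr_mm = 8) {
  vox <- mask$voxels
  spacing <- mask$spacing
  scale <- 1
  for (attempt in 1:6) {
    delta <- stats::rnorm(3, 0, pars$shift_mm * scale)
    morph <- stats::rnorm(1, 0, pars$morph_mm * scale)
    noise <- 0
    if (pars$boundary_noise_mm > 0) {
      w <- array(stats::rnorm(length(vox)), dim = dim(vox))
      w <- gaussian_smooth_mm(w, spacing, noise_corr_mm)
      w <- w / stats::sd(w)
      noise <- w * pars$boundary_noise_mm * scale
    }
    drop_sup <- stats::runif(1) < pars$slice_dropout_prob
    drop_inf <- stats::runif(1) < pars$slice_dropout_prob

    sdist <- signed_distance_mm(vox, spacing)
    if (any(delta != 0)) sdist <- shift_field_mm(sdist, spacing, delta,
                                                 fill = 1e6)
    new_vox <- (sdist + noise) <= morph
    if (any(new_vox)) {
      zs <- which(apply(new_vox, 3, any))
      if (drop_sup && length(zs) > 1) new_vox[, , max(zs)] <- FALSE
      if (drop_inf && length(zs) > 1) new_vox[, , min(zs)] <- FALSE
    }
    if (any(new_vox))
      return(binary_mask(new_vox, spacing = spacing, origin = mask$origin))
    scale <- scale / 2
    warning("perturbation annihilated a structure; retrying with halved ",
            "magnitude", call. = FALSE)
  }
  mask
}

#' Perturb manual structures into an "auto" structure set
#'
#' Applies, independently per structure, a random rigid shift, a signed
#' morphological dilation/erosion and a spatially correlated boundary
#' displacement (all realized through the structure's signed distance
#' field, in mm), plus optional deletion of the superior/inferior border
#' slice. A zero profile returns the masks unchanged. If a perturbation
#' empties a structure it is retried with halved magnitude.
#'
#' @param manual [structure_set()] of reference contours.
#' @param spec perturbation profile (see [default_perturbation()]); entries
#'   are matched by structure name, unmatched structures get zero
#'   perturbation.
#' @param seed integer RNG seed.
#' @return [structure_set()] with provenance `"auto"`.
#' @export
perturb_structures <- function(manual, spec = default_perturbation(), seed = 1) {
  stopifnot(inherits(manual, "structure_set"))
  with_seed(seed, {
    out <- list()
    for (nm in names(manual$structures)) {
      pars <- spec[[nm]]
      if (is.null(pars))
        pars <- list(shift_mm = 0, morph_mm = 0, boundary_noise_mm = 0,
                     slice_dropout_prob = 0)
      mask <- manual$structures[[nm]]
      if (pars$shift_mm == 0 && pars$morph_mm == 0 &&
          pars$boundary_noise_mm == 0 && pars$slice_dropout_prob == 0) {
        out[[nm]] <- mask
      } else {
        out[[nm]] <- perturb_one(mask, pars)
      }
    }
    structure_set(out, provenance = "auto")
  })
}

#' Synthesize a CTV-conformal dose distribution
#'
#' Geometric dose surrogate for a plan optimized on the manual contours:
#' the prescription (times a small plateau factor) is delivered uniformly
#' inside the CTV expanded by `margin_mm`, with a Gaussian falloff of scale
#' `falloff_sigma_mm` outside the expanded envelope, modulated by a smooth
#' multiplicative noise field. Constructed so that the manual contours
#' satisfy the default constraint set, with manual CTV V100 = 100% by
#' construction. This is a surrogate, not a physics calculation: only the
#' pipeline's comparative behavior is claimed.
#'
#' @param manual [structure_set()] containing a non-empty CTV.
#' @param plan [plan_config()].
#' @param seed integer RNG seed (noise field).
#' @param margin_mm plateau margin around the CTV (mm).
#' @param falloff_sigma_mm Gaussian falloff scale (mm).
#' @param plateau_factor plateau level as a multiple of prescription.
#' @param noise_sd relative SD of the multiplicative noise field.
#' @return Dose [volume_grid()] in cGy.
#' @export
synth_dose <- function(manual, plan = plan_config(), seed = 1,
                       margin_mm = 5, falloff_sigma_mm = 13,
                       plateau_factor = 1.04, noise_sd = 0.005) {
  stopifnot(inherits(manual, "structure_set"), inherits(plan, "plan_config"))
  ctv <- manual$structures[["CTV"]]
  if (is.null(ctv) || !any(ctv$voxels))
    stop("synth_dose requires a non-empty CTV", call. = FALSE)
  spacing <- ctv$spacing
  d <- distance_transform_mm(ctv$voxels, spacing)
  base <- ifelse(d <= margin_mm, 1,
                 exp(-(d - margin_mm)^2 / (2 * falloff_sigma_mm^2)))
  base <- base * plan$prescription_cGy * plateau_factor
  dose <- with_seed(seed, {
    w <- array(stats::rnorm(length(base)), dim = dim(base))
    w <- gaussian_smooth_mm(w, spacing, 10)
    w <- w / stats::sd(w) * noise_sd
    pmax(base * (1 + w), 0)
  })
  volume_grid(array(dose, dim = dim(ctv$voxels)), spacing = spacing,
              origin = ctv$origin)
}

#' Generate a reproducible phantom cohort
#'
#' Case-level seeds are derived deterministically from the master seed, so
#' every artifact is a pure function of `(seed, parameters)`.
#'
#' @param n number of cases (`>= 1`).
#' @param seed master integer seed.
#' @param spec perturbation profile for the auto arm.
#' @param plan [plan_config()] shared by the cohort.
#' @param shape,spacing phantom grid geometry.
#' @return List of `phantom_case` objects: `case_id`, `image`, `manual`,
#'   `auto`, `dose`, `plan`.
#' @export
generate_cohort <- function(n, seed = 1, spec = default_perturbation(),
                            plan = plan_config(), shape = c(64, 64, 24),
                            spacing = c(2, 2, 5)) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    cs <- (as.numeric(seed) * 100003 + i * 127) %% 2147483629
    ph <- generate_phantom(cs, shape = shape, spacing = spacing)
    auto <- perturb_structures(ph$manual, spec, seed = cs + 1)
    dose <- synth_dose(ph$manual, plan, seed = cs + 2)
    structure(list(case_id = sprintf("case_%03d", i), image = ph$image,
                   manual = ph$manual, auto = auto, dose = dose, plan = plan),
              class = "phantom_case")
  })
}
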