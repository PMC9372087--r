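# Dose-volume histogram engine and dose-volume indices (DVIs): Dmean, Dmax,
# V100, Dx%, D0.03cc, with constraint checking and paired manual/auto
# evaluation on one fixed dose distribution.

#' Cumulative dose-volume histogram
#'
#' `cum_volume_pct(d)` is the percentage of the structure's volume receiving
#' at least dose `d`. Edges span `[0, max in-structure dose + one bin]` so
#' the curve always starts at 100% and ends at 0%.
#'
#' @param dose [volume_grid()] of dose in cGy, on the mask's geometry.
#' @param mask non-empty [binary_mask()].
#' @param bin_width_cGy dose bin width (default 1 cGy).
#' @return Object of class `dvh_curve`: `dose_edges` (cGy),
#'   `cum_volume_pct`, `volume_cc`.
#' @export
cumulative_dvh <- function(dose, mask, bin_width_cGy = 1) {
  stopifnot(inherits(dose, "volume_grid"), inherits(mask, "binary_mask"))
  check_same_geometry(dose, mask)
  if (!any(mask$voxels)) stop("empty structure: DVH undefined", call. = FALSE)
  if (!is.numeric(bin_width_cGy) || bin_width_cGy <= 0)
    stop("bin width must be positive", call. = FALSE)
  d <- dose$values[mask$voxels]
  n_edges <- floor(max(d) / bin_width_cGy) + 2
  edges <- (seq_len(n_edges) - 1) * bin_width_cGy
  ds <- sort(d)
  # voxels with dose >= edge = n - (number strictly below edge)
  n_ge <- length(ds) - findInterval(edges, ds, left.open = TRUE)
  structure(list(dose_edges = edges,
                 cum_volume_pct = 100 * n_ge / length(ds),
                 volume_cc = mask_volume_cc(mask)),
            class = "dvh_curve")
}

#' Dose received by the hottest part of a structure (D_x% / D_x cc)
#'
#' The minimum dose received by the hottest `volume_pct` percent (or
#' `volume_cc` cc) of the structure: the largest dose `d` such that the
#' volume receiving at least `d` is at least the requested volume, with
#' linear interpolation on the cumulative curve. Covers D99%, D50%, D30%,
#' D15% and D0.03cc.
#'
#' @param curve a [cumulative_dvh()] result.
#' @param volume_pct requested volume as percent of structure volume in
#'   `(0, 100]`; give exactly one of `volume_pct`, `volume_cc`.
#' @param volume_cc requested absolute volume in cc (must not exceed the
#'   structure volume).
#' @return Dose in cGy.
#' @export
dose_at_volume <- function(curve, volume_pct = NULL, volume_cc = NULL) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (is.null(volume_pct) == is.null(volume_cc))
    stop("give exactly one of volume_pct or volume_cc", call. = FALSE)
  if (!is.null(volume_cc)) {
    if (volume_cc <= 0 || volume_cc > curve$volume_cc)
      stop("requested volume exceeds structure volume (",
           format(curve$volume_cc), " cc)", call. = FALSE)
    volume_pct <- 100 * volume_cc / curve$volume_cc
  }
  if (volume_pct <= 0 || volume_pct > 100)
    stop("volume_pct must be in (0, 100]", call. = FALSE)
  cum <- curve$cum_volume_pct
  edges <- curve$dose_edges
  i <- max(which(cum >= volume_pct))  # cum starts at 100 so i exists
  if (i == length(edges) || cum[i] == volume_pct) return(edges[i])
  # interpolate where the curve crosses volume_pct between edge i and i+1
  edges[i] + (cum[i] - volume_pct) / (cum[i] - cum[i + 1]) *
    (edges[i + 1] - edges[i])
}

#' Volume receiving at least a dose (V_x)
#'
#' Percent of the structure volume receiving at least the given dose.
#' `V100` is this with `pct_rx = 100`.
#'
#' @param curve a [cumulative_dvh()] result.
#' @param dose_cGy absolute dose threshold in cGy; give exactly one of
#'   `dose_cGy`, `pct_rx`.
#' @param pct_rx threshold as percent of the plan prescription.
#' @param plan [plan_config()], required when `pct_rx` is used.
#' @return Volume percent in `[0, 100]`.
#' @export
volume_at_dose <- function(curve, dose_cGy = NULL, pct_rx = NULL,
                           plan = NULL) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (is.null(dose_cGy) == is.null(pct_rx))
    stop("give exactly one of dose_cGy or pct_rx", call. = FALSE)
  if (!is.null(pct_rx)) {
    if (is.null(plan))
      stop("a plan_config is required for a percent-of-prescription spec",
         call. = FALSE)
    dose_cGy <- pct_rx / 100 * plan$prescription_cGy
  }
  if (dose_cGy < 0) stop("dose threshold must be >= 0", call. = FALSE)
  edges <- curve$dose_edges
  if (dose_cGy >= edges[length(edges)]) return(0)
  stats::approx(edges, curve$cum_volume_pct, xout = dose_cGy,
                rule = 2)$y
}

#' Mean and maximum in-structure dose
#'
#' Computed on the raw voxel doses, not on the binned curve.
#'
#' @param dose [volume_grid()] of dose in cGy on the mask geometry.
#' @param mask non-empty [binary_mask()].
#' @return Named numeric: `d_mean_cGy`, `d_max_cGy`.
#' @export
mean_max_dose <- function(dose, mask) {
  stopifnot(inherits(dose, "volume_grid"), inherits(mask, "binary_mask"))
  check_same_geometry(dose, mask)
  if (!any(mask$voxels))
    stop("empty structure: dose statistics undefined", call. = FALSE)
  d <- dose$values[mask$voxels]
  c(d_mean_cGy = mean(d), d_max_cGy = max(d))
}

# registry mapping metric names to evaluator functions
dvi_metric_registry <- function() {
  list(
    "D_mean" = function(dose, mask, curve, plan) mean_max_dose(dose, mask)[["d_mean_cGy"]],
    "D_max" = function(dose, mask, curve, plan) mean_max_dose(dose, mask)[["d_max_cGy"]],
    "V100" = function(dose, mask, curve, plan)
      volume_at_dose(curve, pct_rx = 100, plan = plan),
    "D99%" = function(dose, mask, curve, plan) dose_at_volume(curve, volume_pct = 99),
    "D50%" = function(dose, mask, curve, plan) dose_at_volume(curve, volume_pct = 50),
    "D30%" = function(dose, mask, curve, plan) dose_at_volume(curve, volume_pct = 30),
    "D15%" = function(dose, mask, curve, plan) dose_at_volume(curve, volume_pct = 15),
    "D0.03cc" = function(dose, mask, curve, plan) {
      vcc <- min(0.03, curve$volume_cc)
      dose_at_volume(curve, volume_cc = vcc)
    }
  )
}

#' Full dose-volume index set for one structure
#'
#' @param dose dose [volume_grid()] (cGy) on the mask geometry.
#' @param mask non-empty [binary_mask()].
#' @param plan [plan_config()].
#' @param name structure name.
#' @param bin_width_cGy DVH bin width.
#' @return One-row data.frame with `D_mean`, `D_max`, `V100`, `D99%`,
#'   `D50%`, `D30%`, `D15%`, `D0.03cc` (cGy except V100 in percent).
#' @export
dose_volume_index <- function(dose, mask, plan, name = NA_character_,
                              bin_width_cGy = 1) {
  curve <- cumulative_dvh(dose, mask, bin_width_cGy)
  reg <- dvi_metric_registry()
  vals <- vapply(reg, function(f) f(dose, mask, curve, plan), numeric(1))
  out <- as.data.frame(as.list(vals), check.names = FALSE)
  cbind(data.frame(structure = name), out)
}

constraint_limit_cGy <- function(limit, unit, plan) {
  if (unit == "pct_rx") limit / 100 * plan$prescription_cGy else limit
}

check_constraints <- function(dvi_row, plan) {
  cons <- plan$constraints[plan$constraints$structure == dvi_row$structure, ,
                           drop = FALSE]
  if (nrow(cons) == 0L) return(NULL)
  out <- lapply(seq_len(nrow(cons)), function(i) {
    metric <- cons$metric[i]
    value <- dvi_row[[metric]]
    # V100-style limits are in percent of volume, not dose
    lim <- if (metric == "V100") cons$limit[i]
           else constraint_limit_cGy(cons$limit[i], cons$limit_unit[i], plan)
    pass <- if (cons$direction[i] == "lt") value < lim else value > lim
    data.frame(structure = dvi_row$structure, metric = metric,
               value = value, limit = lim,
               direction = cons$direction[i], pass = pass)
  })
  do.call(rbind, out)
}

#' Paired manual/auto dosimetric evaluation on a fixed dose distribution
#'
#' Implements the transmit-into-original-plan protocol: the dose distribution
#' (computed/optimized for the manual contours) is held fixed, and every
#' dose-volume index is computed twice, once per contour provenance, on that
#' same dose grid. If the dose grid geometry differs from the mask geometry
#' the dose is resampled to the masks by trilinear interpolation. Structures
#' missing or empty in either set are flagged, not fatal.
#'
#' @param dose dose [volume_grid()] in cGy.
#' @param manual,auto [structure_set()] objects sharing one geometry.
#' @param plan [plan_config()].
#' @param bin_width_cGy DVH bin width.
#' @param structures structure names to evaluate (default: metrics-of-record
#'   table intersected with the sets).
#' @return List: `dvi` (long table: structure, provenance, metric, value),
#'   `constraints` (per structure and provenance pass/fail),
#'   `pairs` (structure, metric, manual, auto for the metric of record),
#'   `missing` (character vector of flagged structures).
#' @export
evaluate_dosimetry <- function(dose, manual, auto, plan, bin_width_cGy = 1,
                               structures = NULL) {
  stopifnot(inherits(dose, "volume_grid"),
            inherits(manual, "structure_set"),
            inherits(auto, "structure_set"),
            inherits(plan, "plan_config"))
  mor <- metrics_of_record()
  if (is.null(structures)) structures <- unique(mor$structure)
  ref_mask <- c(manual$structures, auto$structures)[[1L]]
  if (!same_geometry(dose, ref_mask))
    dose <- resample_to(dose, ref_mask, mode = "trilinear")

  dvi_rows <- list(); cons_rows <- list(); pair_rows <- list()
  missing <- character(0)
  for (nm in structures) {
    have_m <- nm %in% names(manual$structures) &&
      any(manual$structures[[nm]]$voxels)
    have_a <- nm %in% names(auto$structures) &&
      any(auto$structures[[nm]]$voxels)
    if (!have_m || !have_a) {
      missing <- c(missing, nm)
    }
    per_prov <- list()
    if (have_m) per_prov$manual <- manual$structures[[nm]]
    if (have_a) per_prov$auto <- auto$structures[[nm]]
    dvis <- list()
    for (prov in names(per_prov)) {
      row <- dose_volume_index(dose, per_prov[[prov]], plan, nm,
                               bin_width_cGy)
      dvis[[prov]] <- row
      long <- data.frame(structure = nm, provenance = prov,
                         metric = setdiff(names(row), "structure"),
                         value = as.numeric(row[setdiff(names(row),
                                                        "structure")]))
      dvi_rows[[paste(nm, prov)]] <- long
      cc <- check_constraints(row, plan)
      if (!is.null(cc)) {
        cc$provenance <- prov
        cons_rows[[paste(nm, prov)]] <- cc
      }
    }
    rec <- mor$metric[mor$structure == nm]
    for (met in rec) {
      pair_rows[[paste(nm, met)]] <- data.frame(
        structure = nm, metric = met,
        manual = if (have_m) dvis$manual[[met]] else NA_real_,
        auto = if (have_a) dvis$auto[[met]] else NA_real_)
    }
  }
  list(dvi = do.call(rbind, c(dvi_rows, list(make.row.names = FALSE))),
       constraints = do.call(rbind, c(cons_rows, list(make.row.names = FALSE))),
       pairs = do.call(rbind, c(pair_rows, list(make.row.names = FALSE))),
       missing = unique(missing))
}
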