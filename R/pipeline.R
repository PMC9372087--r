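# Orchestration: run the three-section evaluation (geometry, dosimetry on a
# fixed dose distribution, correlation statistics) over a cohort and emit
# the report bundle (per-case tables, paired-test summary, Bland-Altman
# data, correlation heatmap, CSV outputs).

#' Run configuration for a cohort evaluation
#'
#' Exactly one cohort source (generate, or load from a directory written by
#' [write_cohort()]) and one auto-contour source (the perturbation model, or
#' a trained segmenter checkpoint/model).
#'
#' @param n cohort size when generating.
#' @param seed master seed when generating.
#' @param perturbation perturbation profile for the auto arm.
#' @param plan [plan_config()].
#' @param cohort_dir directory to load a cohort from (overrides generation).
#' @param segmenter optional trained `rtseval_cnn` (or checkpoint path);
#'   when given, auto contours come from [segment_volume()] on each case
#'   image instead of the perturbation model.
#' @param out_dir optional output directory for CSVs and the summary.
#' @param hd_percentile reduced Hausdorff percentile.
#' @param bin_width_cGy DVH bin width.
#' @return Object of class `run_config`.
#' @export
run_config <- function(n = 30, seed = 1, perturbation = default_perturbation(),
                       plan = plan_config(), cohort_dir = NULL,
                       segmenter = NULL, out_dir = NULL, hd_percentile = 95,
                       bin_width_cGy = 1) {
  structure(list(n = n, seed = seed, perturbation = perturbation, plan = plan,
                 cohort_dir = cohort_dir, segmenter = segmenter,
                 out_dir = out_dir, hd_percentile = hd_percentile,
                 bin_width_cGy = bin_width_cGy),
            class = "run_config")
}

#' Evaluate a cohort end-to-end
#'
#' Section 1: geometric metrics per case and structure. Section 2: paired
#' dose-volume indices on the fixed per-case dose distribution (computed
#' once from the manual contours and never re-optimized for the auto
#' contours) with constraint checks, summarized per structure by the
#' Wilcoxon signed-rank test and Bland-Altman agreement on the metric of
#' record. Section 3: Spearman correlation between geometric metrics and
#' per-case dosimetric differences. Idempotent given the seeds in the
#' configuration.
#'
#' @param config a [run_config()].
#' @return Object of class `comparison_report`: `geometry`, `dvi_pairs`,
#'   `constraints`, `paired_tests`, `bland_altman`, `correlations`
#'   (+`heatmap`), `summary`, `metadata`.
#' @export
run_evaluation <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (!is.null(config$cohort_dir)) {
    load_cohort(config$cohort_dir)
  } else {
    generate_cohort(config$n, config$seed, config$perturbation, config$plan)
  }
  segmenter <- config$segmenter
  if (is.character(segmenter)) segmenter <- load_model(segmenter)

  geom_rows <- list(); pair_rows <- list(); cons_rows <- list()
  for (case in cohort) {
    auto <- if (!is.null(segmenter)) segment_volume(segmenter, case$image)
            else case$auto
    g <- evaluate_geometry(case$manual, auto, config$hd_percentile)
    g <- cbind(data.frame(case_id = case$case_id), g)
    geom_rows[[case$case_id]] <- g
    dz <- evaluate_dosimetry(case$dose, case$manual, auto, case$plan,
                             config$bin_width_cGy)
    pr <- cbind(data.frame(case_id = case$case_id), dz$pairs)
    pair_rows[[case$case_id]] <- pr
    if (!is.null(dz$constraints)) {
      cs <- cbind(data.frame(case_id = case$case_id), dz$constraints)
      cons_rows[[case$case_id]] <- cs
    }
  }
  geometry <- do.call(rbind, c(geom_rows, list(make.row.names = FALSE)))
  dvi_pairs <- do.call(rbind, c(pair_rows, list(make.row.names = FALSE)))
  constraints <- do.call(rbind, c(cons_rows, list(make.row.names = FALSE)))

  # per-structure paired statistics on the metric of record
  keys <- unique(dvi_pairs[c("structure", "metric")])
  tests <- list(); ba <- list()
  for (i in seq_len(nrow(keys))) {
    nm <- keys$structure[i]; met <- keys$metric[i]
    sub <- dvi_pairs[dvi_pairs$structure == nm & dvi_pairs$metric == met, ]
    ok <- !(is.na(sub$manual) | is.na(sub$auto))
    w <- tryCatch(wilcoxon_signed_rank(sub$manual[ok], sub$auto[ok]),
                  error = function(e) NULL)
    b <- tryCatch(bland_altman(sub$manual[ok], sub$auto[ok]),
                  error = function(e) NULL)
    tests[[paste(nm, met)]] <- data.frame(
      structure = nm, metric = met, n = sum(ok),
      manual_mean = mean(sub$manual[ok]), manual_sd = stats::sd(sub$manual[ok]),
      auto_mean = mean(sub$auto[ok]), auto_sd = stats::sd(sub$auto[ok]),
      z = if (is.null(w)) NA_real_ else w$z_statistic,
      p = if (is.null(w)) NA_real_ else w$p_value,
      no_difference = if (is.null(w)) NA else w$no_difference,
      significant = if (is.null(w)) NA else (!w$no_difference &&
                                               w$p_value < 0.05))
    if (!is.null(b)) ba[[paste(nm, met)]] <- b
  }
  paired_tests <- do.call(rbind, c(tests, list(make.row.names = FALSE)))

  deltas <- delta_dose(dvi_pairs)
  corr <- correlation_table(geometry[geometry$status == "ok", , drop = FALSE],
                            deltas)

  summary_df <- stats::aggregate(
    cbind(dsc, jc, hd_mm, hd95_mm) ~ structure,
    data = geometry[geometry$status == "ok", , drop = FALSE], FUN = mean)
  names(summary_df)[-1] <- paste0("mean_", names(summary_df)[-1])

  report <- structure(list(
    geometry = geometry, dvi_pairs = dvi_pairs, deltas = deltas,
    constraints = constraints, paired_tests = paired_tests,
    bland_altman = ba, correlations = corr$table, heatmap = corr$heatmap,
    summary = summary_df,
    metadata = list(n_cases = length(cohort), seed = config$seed,
                    prescription_cGy = config$plan$prescription_cGy,
                    hd_percentile = config$hd_percentile,
                    bin_width_cGy = config$bin_width_cGy,
                    auto_source = if (!is.null(segmenter)) "segmenter"
                                  else "perturbation",
                    multiple_testing_correction = "none",
                    package_version = as.character(utils::packageVersion("rtseval")),
                    timestamp = NA)),
    class = "comparison_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d cases, %d structures\n",
              x$metadata$n_cases, length(unique(x$geometry$structure))))
  cat("\nMean geometric metrics per structure:\n")
  print(x$summary, row.names = FALSE, digits = 3)
  cat("\nPaired dosimetric comparison (metric of record):\n")
  print(x$paired_tests[c("structure", "metric", "manual_mean", "auto_mean",
                         "z", "p")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write the report bundle as CSV + Markdown summary
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file) utils::write.csv(df, file.path(dir, file),
                                            row.names = FALSE)
  wr(report$geometry, "geometry_per_case.csv")
  wr(report$dvi_pairs, "dvi_pairs_per_case.csv")
  if (!is.null(report$constraints)) wr(report$constraints, "constraints.csv")
  wr(report$paired_tests, "paired_tests.csv")
  wr(report$correlations, "correlations.csv")
  hm <- as.data.frame(report$heatmap)
  hm <- cbind(data.frame(structure_metric = rownames(report$heatmap)), hm)
  wr(hm, "correlation_heatmap.csv")
  ba_rows <- lapply(names(report$bland_altman), function(k) {
    b <- report$bland_altman[[k]]
    data.frame(structure_metric = k, case_mean = b$means,
               case_difference = b$differences, bias = b$bias,
               loa_low = b$loa_low, loa_high = b$loa_high,
               p_bias = b$p_bias, applicable = b$applicable)
  })
  wr(do.call(rbind, c(ba_rows, list(make.row.names = FALSE))),
     "bland_altman.csv")
  jsonlite::write_json(report$metadata, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  md <- c("# Cohort evaluation summary", "",
          sprintf("- Cases: %d", report$metadata$n_cases),
          sprintf("- Prescription: %s cGy",
                  format(report$metadata$prescription_cGy)),
          sprintf("- Auto-contour source: %s", report$metadata$auto_source),
          "", "## Mean geometric metrics (mean over cases)", "",
          knit_table(report$summary),
          "", "## Paired dosimetric tests (metric of record)", "",
          knit_table(report$paired_tests[c("structure", "metric",
                                           "manual_mean", "auto_mean", "z",
                                           "p")]))
  writeLines(md, file.path(dir, "summary.md"))
  invisible(dir)
}

# minimal markdown table writer
knit_table <- function(df) {
  fmt <- function(v) if (is.numeric(v)) formatC(v, digits = 4, format = "g")
                     else as.character(v)
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                             " |"))
  c(header, sep, rows)
}

## ---- cohort persistence ----------------------------------------------------

# independently perturbed or predicted contours may overlap, so the auto
# set is stored as a 4D stack of binary channels rather than a labelmap
write_mask_stack <- function(set, path) {
  first <- set$structures[[1L]]
  d <- dim(first$voxels)
  arr <- array(0L, dim = c(d, length(set$structures)))
  for (k in seq_along(set$structures))
    arr[, , , k] <- set$structures[[k]]$voxels
  img <- RNifti::asNifti(arr)
  m <- diag(c(first$spacing, 1)); m[1:3, 4] <- first$origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  img <- RNifti::`pixdim<-`(img, c(first$spacing, 1))
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

read_mask_stack <- function(path, structure_names, provenance) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  stopifnot(length(dim(arr)) == 4L, dim(arr)[4] == length(structure_names))
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- as.numeric(RNifti::xform(img)[1:3, 4])
  masks <- list()
  for (k in seq_along(structure_names)) {
    v <- arr[, , , k] != 0
    masks[[structure_names[k]]] <- binary_mask(
      array(v, dim = dim(arr)[1:3]), spacing = spacing, origin = origin)
  }
  structure_set(masks, provenance = provenance)
}

#' Write a phantom cohort to disk as NIfTI + JSON
#'
#' Each case gets `image.nii.gz`, `dose.nii.gz`, `manual.nii.gz` (integer
#' labelmap; manual structures are disjoint), `auto.nii.gz` (4D stack of
#' binary masks, since auto contours may overlap) and `plan.json` under
#' `<dir>/<case_id>/`, plus a cohort `manifest.csv`.
#'
#' @param cohort list of `phantom_case` objects.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (case in cohort) {
    cdir <- file.path(dir, case$case_id)
    dir.create(cdir, showWarnings = FALSE)
    write_volume(case$image, file.path(cdir, "image.nii.gz"))
    write_volume(case$dose, file.path(cdir, "dose.nii.gz"))
    write_volume(case$manual, file.path(cdir, "manual.nii.gz"))
    write_mask_stack(case$auto, file.path(cdir, "auto.nii.gz"))
    jsonlite::write_json(
      list(prescription_cGy = case$plan$prescription_cGy,
           fractions = case$plan$fractions,
           structures = names(case$manual$structures)),
      file.path(cdir, "plan.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  manifest <- data.frame(case_id = vapply(cohort, `[[`, "", "case_id"))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load a phantom cohort written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.csv`.
#' @return List of `phantom_case` objects.
#' @export
load_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(manifest$case_id, function(cid) {
    cdir <- file.path(dir, cid)
    pj <- jsonlite::read_json(file.path(cdir, "plan.json"),
                              simplifyVector = TRUE)
    plan <- plan_config(pj$prescription_cGy, pj$fractions)
    structure(list(
      case_id = cid,
      image = read_volume(file.path(cdir, "image.nii.gz"), "image"),
      manual = read_volume(file.path(cdir, "manual.nii.gz"), "labelmap",
                           structure_names = pj$structures,
                           provenance = "manual"),
      auto = read_mask_stack(file.path(cdir, "auto.nii.gz"),
                             structure_names = pj$structures,
                             provenance = "auto"),
      dose = read_volume(file.path(cdir, "dose.nii.gz"), "dose"),
      plan = plan), class = "phantom_case")
  })
}
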