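test_that("phantom generation is deterministic and complete", {
  a <- generate_phantom(42)
  b <- generate_phantom(42)
  expect_identical(a$image$values, b$image$values)
  expect_identical(lapply(a$manual$structures, `[[`, "voxels"),
                   lapply(b$manual$structures, `[[`, "voxels"))
  expect_setequal(names(a$manual$structures), rt_structure_names())
  expect_true(all(vapply(a$manual$structures,
                         function(m) sum(m$voxels) > 0, logical(1))))
  c2 <- generate_phantom(43)
  expect_false(identical(a$image$values, c2$image$values))
})

test_that("phantom structures are mutually disjoint", {
  ph <- generate_phantom(44)
  nms <- names(ph$manual$structures)
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (i < j) {
        ov <- sum(ph$manual$structures[[i]]$voxels &
                    ph$manual$structures[[j]]$voxels)
        expect_equal(ov, 0)
      }
    }
  }
})

test_that("phantom rejects a grid too small for the anatomy", {
  expect_error(generate_phantom(1, shape = c(16, 16, 8)), "at least")
})

test_that("zero perturbation returns identical masks (DSC = 1)", {
  ph <- generate_phantom(45)
  auto <- perturb_structures(ph$manual, zero_perturbation(), seed = 46)
  expect_identical(auto$provenance, "auto")
  g <- evaluate_geometry(ph$manual, auto)
  expect_true(all(g$dsc == 1))
  expect_true(all(g$hd95_mm == 0))
})

test_that("perturbation is deterministic in the seed and varies across seeds", {
  ph <- generate_phantom(47)
  a1 <- perturb_structures(ph$manual, seed = 48)
  a2 <- perturb_structures(ph$manual, seed = 48)
  a3 <- perturb_structures(ph$manual, seed = 49)
  expect_identical(lapply(a1$structures, `[[`, "voxels"),
                   lapply(a2$structures, `[[`, "voxels"))
  expect_false(identical(lapply(a1$structures, `[[`, "voxels"),
                         lapply(a3$structures, `[[`, "voxels")))
})

test_that("pure erosion matches the nested-mask DSC closed form", {
  # 20x20x4 cube at (2,2,5) mm; erosion depth 2.5 mm removes exactly the
  # one-voxel in-plane shell (center-to-center depth 2 mm < 2.5) and no z
  # layer (5 mm > 2.5), so the eroded volume is known in closed form
  v <- array(FALSE, c(30, 30, 8)); v[6:25, 6:25, 3:6] <- TRUE
  m <- binary_mask(v, spacing = c(2, 2, 5))
  eroded <- rtseval:::signed_distance_mm(v, c(2, 2, 5)) <= -2.5
  vol_a <- sum(v); vol_b <- sum(eroded)
  expect_equal(vol_b, 18 * 18 * 4)
  got <- dice(m, binary_mask(eroded, spacing = c(2, 2, 5)))
  expect_equal(got, 2 * vol_b / (vol_a + vol_b), tolerance = 1e-12)
})

test_that("pure shift DSC matches the analytic sphere-overlap oracle", {
  # sphere of radius R shifted by s: overlap volume is the lens
  # V = 2 * pi/3 * (R - s/2)^2 * (2R + s/2) -> DSC ~ V / V_sphere
  sp <- c(1, 1, 1)
  shape <- c(48, 48, 48)
  co <- rtseval:::coord_arrays(shape, sp)
  R <- 10; ctr <- c(24, 24, 24)
  sph <- function(center) {
    ((co$x - center[1])^2 + (co$y - center[2])^2 +
       (co$z - center[3])^2) <= R^2
  }
  s <- 3
  a <- binary_mask(sph(ctr), spacing = sp)
  b <- binary_mask(sph(ctr + c(s, 0, 0)), spacing = sp)
  lens <- 2 * pi / 3 * (R - s / 2)^2 * (2 * R + s / 2)
  vsph <- 4 * pi / 3 * R^3
  expect_equal(dice(a, b), lens / vsph, tolerance = 0.02)
})

test_that("increasing morph magnitude degrades DSC and inflates 95%HD", {
  ph <- generate_phantom(50)
  base <- ph$manual$structures$Bladder
  mean_dsc <- function(morph_sd) {
    vals <- vapply(1:20, function(i) {
      spec <- list(Bladder = list(shift_mm = 0, morph_mm = morph_sd,
                                  boundary_noise_mm = 0,
                                  slice_dropout_prob = 0))
      auto <- perturb_structures(ph$manual, spec, seed = 1000 + i)
      dice(base, auto$structures$Bladder)
    }, numeric(1))
    mean(vals)
  }
  mean_hd <- function(morph_sd) {
    vals <- vapply(1:20, function(i) {
      spec <- list(Bladder = list(shift_mm = 0, morph_mm = morph_sd,
                                  boundary_noise_mm = 0,
                                  slice_dropout_prob = 0))
      auto <- perturb_structures(ph$manual, spec, seed = 1000 + i)
      hausdorff(base, auto$structures$Bladder, 95)
    }, numeric(1))
    mean(vals)
  }
  d <- vapply(c(0.5, 2, 5), mean_dsc, numeric(1))
  expect_true(all(diff(d) < 0))
  h <- vapply(c(0.5, 2, 5), mean_hd, numeric(1))
  expect_true(all(diff(h) > 0))
})

test_that("synthetic dose is target-conformal and constraint-compliant", {
  ph <- generate_phantom(51)
  plan <- plan_config(4500)
  dose <- synth_dose(ph$manual, plan, seed = 52)
  expect_true(all(dose$values >= 0))
  ctv <- ph$manual$structures$CTV
  # dose at the CTV centroid reaches prescription
  idx <- which(ctv$voxels, arr.ind = TRUE)
  cen <- round(colMeans(idx))
  expect_gte(dose$values[cen[1], cen[2], cen[3]], 4500)
  # manual CTV V100 = 100% by construction
  cv <- cumulative_dvh(dose, ctv, 1)
  expect_equal(volume_at_dose(cv, pct_rx = 100, plan = plan), 100)
  # kidney mean dose under the default geometry stays below 1200 cGy
  for (k in c("Kidney L", "Kidney R"))
    expect_lt(mean_max_dose(dose, ph$manual$structures[[k]])[["d_mean_cGy"]],
              1200)
  expect_error(synth_dose(structure_set(list(
    Bladder = ph$manual$structures$Bladder), "manual"), plan), "CTV")
})

test_that("manual contours satisfy every planning constraint across cases", {
  coh <- generate_cohort(4, seed = 53)
  for (cs in coh) {
    res <- evaluate_dosimetry(cs$dose, cs$manual, cs$auto, cs$plan)
    man <- res$constraints[res$constraints$provenance == "manual", ]
    expect_true(all(man$pass))
  }
})

test_that("cohorts are reproducible and seed-sensitive", {
  c1 <- generate_cohort(3, seed = 54)
  c2 <- generate_cohort(3, seed = 54)
  c3 <- generate_cohort(3, seed = 55)
  expect_identical(c1[[2]]$image$values, c2[[2]]$image$values)
  expect_identical(c1[[2]]$auto$structures$CTV$voxels,
                   c2[[2]]$auto$structures$CTV$voxels)
  expect_false(identical(c1[[1]]$manual$structures$CTV$voxels,
                         c3[[1]]$manual$structures$CTV$voxels))
  expect_identical(vapply(c1, `[[`, "", "case_id"),
                   c("case_001", "case_002", "case_003"))
})
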