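test_that("surface extraction follows the 6-neighborhood convention", {
  # isolated voxel: its center is the single surface point
  v <- array(FALSE, c(5, 5, 5)); v[3, 3, 3] <- TRUE
  s <- extract_surface(mask_of(v, c(2, 2, 5)))
  expect_equal(nrow(s$points), 1)
  expect_equal(as.numeric(s$points), c(2 * 2, 2 * 2, 2 * 5))

  # solid 3x3x3 cube: only the center voxel is interior
  v <- array(FALSE, c(5, 5, 5)); v[2:4, 2:4, 2:4] <- TRUE
  expect_equal(nrow(extract_surface(mask_of(v))$points), 26)

  # 1-voxel-thick slab: no interior exists
  v <- array(FALSE, c(6, 6, 3)); v[2:5, 2:5, 2] <- TRUE
  expect_equal(nrow(extract_surface(mask_of(v))$points), 16)

  # volume border counts as outside: full array is all surface at the faces
  v <- array(TRUE, c(3, 3, 3))
  expect_equal(nrow(extract_surface(mask_of(v))$points), 26)

  expect_error(extract_surface(mask_of(array(FALSE, c(3, 3, 3)))), "empty")
})

test_that("dice and jaccard match hand counts and are symmetric", {
  v1 <- array(FALSE, c(4, 4, 2)); v1[2, 2, 1] <- TRUE
  v2 <- array(FALSE, c(4, 4, 2)); v2[2, 2, 1] <- TRUE; v2[3, 2, 1] <- TRUE
  a <- mask_of(v1); b <- mask_of(v2)
  expect_equal(dice(a, b), 2 / 3)     # 2*1/(1+2)
  expect_equal(jaccard(a, b), 1 / 2)  # 1/2
  expect_identical(dice(a, b), dice(b, a))
  expect_identical(jaccard(a, b), jaccard(b, a))

  expect_equal(dice(a, a), 1)
  expect_equal(jaccard(a, a), 1)

  v3 <- array(FALSE, c(4, 4, 2)); v3[4, 4, 2] <- TRUE
  expect_equal(dice(a, mask_of(v3)), 0)
  expect_equal(jaccard(a, mask_of(v3)), 0)

  e <- mask_of(array(FALSE, c(4, 4, 2)))
  expect_error(dice(e, e), "empty")
  expect_error(jaccard(e, e), "empty")
})

test_that("hausdorff handles identical masks, single pairs and anisotropy", {
  v <- array(FALSE, c(5, 5, 5)); v[2:3, 2:3, 2:3] <- TRUE
  m <- mask_of(v, c(2, 2, 5))
  expect_equal(hausdorff(m, m, 100), 0)
  expect_equal(hausdorff(m, m, 95), 0)
  expect_equal(hausdorff(m, m, 37.5), 0)

  # two single voxels 3 apart along x with 1 mm spacing -> 3 mm
  a <- array(FALSE, c(8, 3, 3)); a[2, 2, 2] <- TRUE
  b <- array(FALSE, c(8, 3, 3)); b[5, 2, 2] <- TRUE
  expect_equal(hausdorff(mask_of(a), mask_of(b)), 3)

  # adjacent along z with dz = 5 mm -> 5 mm, not 1
  a <- array(FALSE, c(3, 3, 4)); a[2, 2, 2] <- TRUE
  b <- array(FALSE, c(3, 3, 4)); b[2, 2, 3] <- TRUE
  expect_equal(hausdorff(mask_of(a, c(1, 1, 5)), mask_of(b, c(1, 1, 5))), 5)

  expect_error(hausdorff(mask_of(a), mask_of(b), percentile = 0), "percentile")
  expect_error(hausdorff(mask_of(a), mask_of(b), percentile = 101),
               "percentile")
})

test_that("hausdorff equals the exhaustive all-pairs oracle at any percentile", {
  set.seed(101)
  for (rep in 1:8) {
    sp <- list(c(1, 1, 1), c(2, 2, 5), c(1.5, 2.5, 3))[[1 + rep %% 3]]
    a <- random_mask(c(7, 7, 5), sp, p = 0.25)
    b <- random_mask(c(7, 7, 5), sp, p = 0.25)
    for (pct in c(100, 95, 80, 50)) {
      expect_equal(hausdorff(a, b, pct), oracle_hausdorff(a, b, pct),
                   tolerance = 1e-12)
    }
  }
})

test_that("hausdorff with an outlier point: 95th percentile discounts it", {
  # cluster of points within 1 mm plus a 10 mm outlier in B
  a <- array(FALSE, c(30, 5, 3)); a[2:6, 2:3, 2] <- TRUE
  b <- a; b[16, 2, 2] <- TRUE  # outlier 10 mm beyond A's surface extent
  ma <- mask_of(a); mb <- mask_of(b)
  expect_equal(hausdorff(ma, mb, 100), oracle_hausdorff(ma, mb, 100))
  expect_equal(hausdorff(ma, mb, 95), oracle_hausdorff(ma, mb, 95))
  expect_lt(hausdorff(ma, mb, 95), hausdorff(ma, mb, 100))
})

test_that("hausdorff is symmetric and monotone in percentile", {
  set.seed(202)
  a <- random_mask(c(8, 8, 5), c(2, 2, 5), p = 0.3)
  b <- random_mask(c(8, 8, 5), c(2, 2, 5), p = 0.3)
  expect_identical(hausdorff(a, b, 95), hausdorff(b, a, 95))
  pcts <- c(10, 30, 50, 70, 90, 95, 100)
  hh <- vapply(pcts, function(p) hausdorff(a, b, p), numeric(1))
  expect_true(all(diff(hh) >= 0))
})

test_that("dsc-jc identity and translation invariance hold on random pairs", {
  set.seed(303)
  for (rep in 1:20) {
    a <- random_mask(c(9, 9, 6), c(2, 2, 5), p = 0.3)
    b <- random_mask(c(9, 9, 6), c(2, 2, 5), p = 0.3)
    d <- dice(a, b); j <- jaccard(a, b)
    expect_equal(2 * j / (1 + j), d, tolerance = 1e-12)
    expect_true(j <= d)

    # translate both masks by one voxel in each axis (wrap-free region)
    shift1 <- function(m) {
      v <- m$voxels
      w <- array(FALSE, dim = dim(v) + 1)
      w[-1, -1, -1] <- v
      binary_mask(w, spacing = m$spacing, origin = m$origin)
    }
    a2 <- shift1(a); b2 <- shift1(b)
    expect_equal(dice(a2, b2), d)
    expect_equal(jaccard(a2, b2), j)
    expect_equal(hausdorff(a2, b2, 95), hausdorff(a, b, 95))
    expect_equal(hausdorff(a2, b2, 100), hausdorff(a, b, 100))
  }
})

test_that("evaluate_geometry reports all structures and flags missing ones", {
  ph <- generate_phantom(21)
  same <- evaluate_geometry(ph$manual, ph$manual)
  expect_equal(nrow(same), 9)
  expect_true(all(same$status == "ok"))
  expect_true(all(same$dsc == 1 & same$jc == 1 & same$hd95_mm == 0))

  sub <- structure_set(ph$manual$structures[1:5], "auto")
  res <- evaluate_geometry(ph$manual, sub)
  expect_equal(sum(res$status == "missing_in_test"), 4)
  expect_true(all(is.na(res$dsc[res$status == "missing_in_test"])))

  only_a <- structure_set(list(X = ph$manual$structures[[1]]), "auto")
  expect_error(evaluate_geometry(ph$manual, only_a), "common")
})

test_that("per-structure cohort means match independent per-case recomputation", {
  coh <- generate_cohort(3, seed = 99)
  g <- do.call(rbind, lapply(coh, function(cs)
    evaluate_geometry(cs$manual, cs$auto)))
  # independent recomputation of dsc from raw voxel counts
  manual_dsc <- vapply(coh, function(cs) {
    a <- cs$manual$structures[["Bladder"]]$voxels
    b <- cs$auto$structures[["Bladder"]]$voxels
    2 * sum(a & b) / (sum(a) + sum(b))
  }, numeric(1))
  expect_equal(mean(g$dsc[g$structure == "Bladder"]), mean(manual_dsc),
               tolerance = 1e-12)
})
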