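# shared fixture builders: small masks and brute-force oracles

mask_of <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  binary_mask(array(as.logical(arr), dim = dim(arr)), spacing = spacing,
              origin = origin)
}

# random blob-ish mask: a few random boxes/ellipsoids on a small grid
random_mask <- function(shape = c(8, 8, 6), spacing = c(1, 1, 1),
                        p = 0.2, ensure_nonempty = TRUE) {
  v <- array(stats::runif(prod(shape)) < p, dim = shape)
  if (ensure_nonempty && !any(v)) v[ceiling(shape[1] / 2),
                                    ceiling(shape[2] / 2),
                                    ceiling(shape[3] / 2)] <- TRUE
  mask_of(v, spacing)
}

# all-pairs brute-force directed surface distances (oracle for hausdorff)
oracle_hausdorff <- function(a, b, percentile = 100) {
  pa <- extract_surface(a)$points
  pb <- extract_surface(b)$points
  D <- matrix(0, nrow(pa), nrow(pb))
  for (i in seq_len(nrow(pa)))
    D[i, ] <- sqrt(colSums((t(pb) - pa[i, ])^2))
  h_ab <- apply(D, 2, min)  # from each point of B to surface of A
  h_ba <- apply(D, 1, min)
  if (percentile == 100) {
    max(max(h_ab), max(h_ba))
  } else {
    max(stats::quantile(h_ab, percentile / 100, names = FALSE, type = 7),
        stats::quantile(h_ba, percentile / 100, names = FALSE, type = 7))
  }
}

# exhaustive sign-enumeration oracle for the signed-rank two-sided P
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

tiny_uniform_dose <- function(mask, value) {
  volume_grid(array(value, dim = dim(mask$voxels)), spacing = mask$spacing,
              origin = mask$origin)
}
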