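# Compact 2D encoder-decoder segmentation network: three encoders and three
# decoders, 3x3 stride-1 convolutions each followed by batch normalization
# and ReLU, 2x2 max-pool downsampling, 2x2 stride-2 transposed-convolution
# upsampling, level-wise skip concatenation, an input projection and a
# pixel-classification output head, trained with softmax cross-entropy and
# cut/flip augmentation. Implemented in base R matrix algebra; it exists to
# exercise the segment-then-evaluate workflow on phantoms, with no claim of
# clinical-scale performance.

#' Network specification
#'
#' @param n_classes number of pixel classes (background + structures),
#'   `>= 2`.
#' @param in_channels input image channels.
#' @param channels feature widths of the three levels.
#' @param use_skips concatenate encoder features into the matching decoder
#'   level (default TRUE).
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(n_classes, in_channels = 1,
                         channels = c(16, 32, 64), use_skips = TRUE) {
  stopifnot(n_classes >= 2, in_channels >= 1, length(channels) == 3)
  structure(list(n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels),
                 channels = as.integer(channels),
                 levels = 3L, use_skips = isTRUE(use_skips)),
            class = "network_spec")
}

# layer table: conv weights are (9*Cin x Cout); transposed conv (Cin,Cout,4)
segmenter_layers <- function(spec) {
  c1 <- spec$channels[1]; c2 <- spec$channels[2]; c3 <- spec$channels[3]
  s <- if (spec$use_skips) 2L else 1L
  list(
    inproj = c(cin = spec$in_channels, cout = c1),
    enc1 = c(cin = c1, cout = c2),
    enc2 = c(cin = c2, cout = c3),
    enc3 = c(cin = c3, cout = c3),
    up1 = c(cin = c3, cout = c3),
    dec1 = c(cin = s * c3, cout = c3),
    up2 = c(cin = c3, cout = c2),
    dec2 = c(cin = s * c2, cout = c2),
    up3 = c(cin = c2, cout = c1),
    dec3 = c(cin = s * c1, cout = c1),
    outproj = c(cin = c1, cout = spec$n_classes)
  )
}

#' Trainable parameter count of the network
#'
#' Closed-form layer arithmetic: each 3x3 convolution has
#' `9 * cin * cout + cout` weights plus `2 * cout` batch-norm parameters
#' (the output head has no batch norm); each 2x2 transposed convolution has
#' `4 * cin * cout + cout`.
#'
#' @param spec a [network_spec()].
#' @return Integer parameter count.
#' @export
count_params <- function(spec) {
  lay <- segmenter_layers(spec)
  total <- 0
  for (nm in names(lay)) {
    cin <- lay[[nm]][["cin"]]; cout <- lay[[nm]][["cout"]]
    if (startsWith(nm, "up")) {
      total <- total + 4 * cin * cout + cout
    } else {
      total <- total + 9 * cin * cout + cout
      if (nm != "outproj") total <- total + 2 * cout  # batch norm
    }
  }
  as.integer(total)
}

#' Build an untrained segmentation network
#'
#' @param spec a [network_spec()].
#' @param seed RNG seed for weight initialization (He-scaled Gaussian).
#' @param class_names optional class names, length `n_classes` (first is
#'   background); used by [segment_volume()] to name structures.
#' @return Object of class `rtseval_cnn`.
#' @export
build_network <- function(spec, seed = 1, class_names = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.null(class_names)) stopifnot(length(class_names) == spec$n_classes)
  lay <- segmenter_layers(spec)
  with_seed(seed, {
    params <- list()
    bn <- list()
    for (nm in names(lay)) {
      cin <- lay[[nm]][["cin"]]; cout <- lay[[nm]][["cout"]]
      if (startsWith(nm, "up")) {
        params[[paste0(nm, "_W")]] <-
          array(stats::rnorm(4 * cin * cout, 0, sqrt(2 / (4 * cin))),
                dim = c(cin, cout, 4))
        params[[paste0(nm, "_b")]] <- numeric(cout)
      } else {
        params[[paste0(nm, "_W")]] <-
          matrix(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                 nrow = 9 * cin, ncol = cout)
        params[[paste0(nm, "_b")]] <- numeric(cout)
        if (nm != "outproj") {
          params[[paste0(nm, "_gamma")]] <- rep(1, cout)
          params[[paste0(nm, "_beta")]] <- rep(0, cout)
          bn[[paste0(nm, "_mean")]] <- rep(0, cout)
          bn[[paste0(nm, "_var")]] <- rep(1, cout)
        }
      }
    }
    structure(list(spec = spec, params = params, bn = bn,
                   class_names = class_names, trained = FALSE,
                   norm = c(mean = 0, sd = 1), loss_trace = numeric(0)),
              class = "rtseval_cnn")
  })
}

#' @export
print.rtseval_cnn <- function(x, ...) {
  cat(sprintf(
    "<rtseval_cnn> 3-level encoder-decoder, channels (%s), %d classes, %s (%d params)\n",
    paste(x$spec$channels, collapse = ", "), x$spec$n_classes,
    if (x$trained) "trained" else "untrained", count_params(x$spec)))
  invisible(x)
}

# conv + BN + ReLU block; returns output and caches
cbr_forward <- function(model, nm, x, training) {
  p <- model$params
  cv <- conv3_forward(x, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]])
  bn <- bn_forward(cv$y, p[[paste0(nm, "_gamma")]], p[[paste0(nm, "_beta")]],
                   model$bn[[paste0(nm, "_mean")]],
                   model$bn[[paste0(nm, "_var")]], training)
  rl <- relu_forward(bn$y)
  list(y = rl$y, cv = cv, bn = bn, rl = rl)
}

cbr_backward <- function(model, nm, dy, cache, grads) {
  rb <- relu_backward(dy, cache$rl)
  bb <- bn_backward(rb, cache$bn)
  cb <- conv3_backward(bb$dx, cache$cv, model$params[[paste0(nm, "_W")]])
  grads[[paste0(nm, "_gamma")]] <- bb$dgamma
  grads[[paste0(nm, "_beta")]] <- bb$dbeta
  grads[[paste0(nm, "_W")]] <- cb$dW
  grads[[paste0(nm, "_b")]] <- cb$db
  list(dx = cb$dx, grads = grads)
}

segmenter_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0)
    stop("input spatial dims must be divisible by 8 (three 2x2 poolings); ",
         "pad to (", 8 * ceiling(d[1] / 8), ", ", 8 * ceiling(d[2] / 8), ")",
         call. = FALSE)
  use_skips <- model$spec$use_skips
  cc <- list()
  cc$e0 <- cbr_forward(model, "inproj", x, training)
  cc$p1 <- maxpool2_forward(cc$e0$y)
  cc$e1 <- cbr_forward(model, "enc1", cc$p1$y, training)
  cc$p2 <- maxpool2_forward(cc$e1$y)
  cc$e2 <- cbr_forward(model, "enc2", cc$p2$y, training)
  cc$p3 <- maxpool2_forward(cc$e2$y)
  cc$e3 <- cbr_forward(model, "enc3", cc$p3$y, training)

  cc$u1 <- convt2_forward(cc$e3$y, model$params$up1_W, model$params$up1_b)
  in1 <- if (use_skips) concat_channels(cc$u1$y, cc$e2$y) else cc$u1$y
  cc$d1 <- cbr_forward(model, "dec1", in1, training)
  cc$u2 <- convt2_forward(cc$d1$y, model$params$up2_W, model$params$up2_b)
  in2 <- if (use_skips) concat_channels(cc$u2$y, cc$e1$y) else cc$u2$y
  cc$d2 <- cbr_forward(model, "dec2", in2, training)
  cc$u3 <- convt2_forward(cc$d2$y, model$params$up3_W, model$params$up3_b)
  in3 <- if (use_skips) concat_channels(cc$u3$y, cc$e0$y) else cc$u3$y
  cc$d3 <- cbr_forward(model, "dec3", in3, training)
  cc$out <- conv3_forward(cc$d3$y, model$params$outproj_W,
                          model$params$outproj_b)
  list(logits = cc$out$y, caches = cc)
}

segmenter_backward <- function(model, dlogits, cc) {
  grads <- list()
  use_skips <- model$spec$use_skips
  nch <- model$spec$channels

  ob <- conv3_backward(dlogits, cc$out, model$params$outproj_W)
  grads$outproj_W <- ob$dW; grads$outproj_b <- ob$db

  split_skip <- function(dx, c_up) {
    if (use_skips) {
      list(dup = dx[, , , seq_len(c_up), drop = FALSE],
           dskip = dx[, , , c_up + seq_len(dim(dx)[4] - c_up), drop = FALSE])
    } else {
      list(dup = dx, dskip = 0)
    }
  }

  r <- cbr_backward(model, "dec3", ob$dx, cc$d3, grads); grads <- r$grads
  s3 <- split_skip(r$dx, nch[1])
  u3 <- convt2_backward(s3$dup, cc$u3, model$params$up3_W)
  grads$up3_W <- u3$dW; grads$up3_b <- u3$db

  r <- cbr_backward(model, "dec2", u3$dx, cc$d2, grads); grads <- r$grads
  s2 <- split_skip(r$dx, nch[2])
  u2 <- convt2_backward(s2$dup, cc$u2, model$params$up2_W)
  grads$up2_W <- u2$dW; grads$up2_b <- u2$db

  r <- cbr_backward(model, "dec1", u2$dx, cc$d1, grads); grads <- r$grads
  s1 <- split_skip(r$dx, nch[3])
  u1 <- convt2_backward(s1$dup, cc$u1, model$params$up1_W)
  grads$up1_W <- u1$dW; grads$up1_b <- u1$db

  r <- cbr_backward(model, "enc3", u1$dx, cc$e3, grads); grads <- r$grads
  dp3 <- maxpool2_backward(r$dx, cc$p3)
  de2 <- dp3 + (if (use_skips) s1$dskip else 0)
  r <- cbr_backward(model, "enc2", de2, cc$e2, grads); grads <- r$grads
  dp2 <- maxpool2_backward(r$dx, cc$p2)
  de1 <- dp2 + (if (use_skips) s2$dskip else 0)
  r <- cbr_backward(model, "enc1", de1, cc$e1, grads); grads <- r$grads
  dp1 <- maxpool2_backward(r$dx, cc$p1)
  de0 <- dp1 + (if (use_skips) s3$dskip else 0)
  r <- cbr_backward(model, "inproj", de0, cc$e0, grads); grads <- r$grads
  grads
}

# update model running batch-norm statistics from forward caches
update_bn_state <- function(model, cc) {
  for (nm in c("inproj", "enc1", "enc2", "enc3", "dec1", "dec2", "dec3")) {
    key <- switch(nm, inproj = "e0", enc1 = "e1", enc2 = "e2", enc3 = "e3",
                  dec1 = "d1", dec2 = "d2", dec3 = "d3")
    model$bn[[paste0(nm, "_mean")]] <- cc[[key]]$bn$run_mean
    model$bn[[paste0(nm, "_var")]] <- cc[[key]]$bn$run_var
  }
  model
}

#' Training configuration
#'
#' @param epochs number of passes over the slice set.
#' @param lr Adam learning rate.
#' @param batch_size slices per gradient step (0 = full batch).
#' @param seed seed fixing all stochastic choices (shuffling, augmentation).
#' @param augment apply random cut (shift with zero padding) and horizontal
#'   flip augmentation.
#' @param max_shift_px maximum cut shift in pixels.
#' @param class_weighting `"balanced"` weights each class by the inverse
#'   square root of its pixel frequency in the training labels (structures
#'   occupy a tiny pixel fraction next to the background, and unweighted
#'   cross-entropy learns them very slowly); `"none"` uses plain
#'   cross-entropy.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 40, lr = 2e-3, batch_size = 10, seed = 1,
                         augment = TRUE, max_shift_px = 4,
                         class_weighting = c("balanced", "none")) {
  stopifnot(epochs >= 1, lr > 0)
  class_weighting <- match.arg(class_weighting)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 augment = isTRUE(augment),
                 max_shift_px = as.integer(max_shift_px),
                 class_weighting = class_weighting),
            class = "train_config")
}

shift2d <- function(m, sx, sy, fill = 0) {
  d <- dim(m)
  out <- matrix(fill, d[1], d[2])
  xs <- seq_len(d[1]) - sx; ys <- seq_len(d[2]) - sy
  okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

# left-right flips mirror lateralized anatomy, so paired "X L"/"X R"
# classes must swap labels under a flip; flip_perm maps old label -> new
flip_permutation <- function(class_names) {
  perm <- seq_along(class_names)
  for (i in seq_along(class_names)) {
    nm <- class_names[i]
    if (grepl(" L$", nm)) {
      j <- match(sub(" L$", " R", nm), class_names)
      if (!is.na(j)) { perm[i] <- j; perm[j] <- i }
    }
  }
  perm
}

augment_slice <- function(img, lab, max_shift, flip_perm) {
  if (stats::runif(1) < 0.5) {
    img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    lab <- lab[rev(seq_len(nrow(lab))), , drop = FALSE]
    lab <- array(flip_perm[lab + 1L] - 1L, dim = dim(lab))
  }
  s <- sample(seq(-max_shift, max_shift), 2, replace = TRUE)
  if (any(s != 0)) {
    img <- shift2d(img, s[1], s[2])
    lab <- shift2d(lab, s[1], s[2], fill = 0)
  }
  list(img = img, lab = lab)
}

#' Train the segmentation network
#'
#' Full supervised training with softmax cross-entropy over pixel classes
#' and Adam. Deterministic given `config$seed`. Images are standardized by
#' the training-set mean and SD (stored in the model for inference).
#'
#' @param model an [build_network()] model.
#' @param slices list of training slices, each `list(image = HxW matrix,
#'   labels = HxW integer matrix in [0, n_classes))`; at least 10.
#' @param config a [train_config()].
#' @return The trained model, with `loss_trace` (mean epoch loss).
#' @export
train_segmenter <- function(model, slices, config = train_config()) {
  stopifnot(inherits(model, "rtseval_cnn"), inherits(config, "train_config"))
  if (length(slices) < 10)
    stop("at least 10 labeled slices are required", call. = FALSE)
  K <- model$spec$n_classes
  for (s in slices) {
    labs <- s$labels
    if (any(labs < 0) || any(labs >= K) || any(labs != round(labs)))
      stop("labels must be integers in [0, n_classes)", call. = FALSE)
  }
  imgs <- lapply(slices, `[[`, "image")
  mu <- mean(unlist(imgs))
  sdv <- stats::sd(unlist(imgs))
  model$norm <- c(mean = mu, sd = sdv)

  cw <- NULL
  if (identical(config$class_weighting, "balanced")) {
    counts <- rep(0, K)
    for (s in slices) {
      tab <- tabulate(as.integer(s$labels) + 1L, nbins = K)
      counts <- counts + tab
    }
    freq <- counts / sum(counts)
    cw <- 1 / sqrt(pmax(freq, 1e-6))
    cw <- cw / mean(cw)
  }

  n <- length(slices)
  bs <- if (config$batch_size <= 0) n else min(config$batch_size, n)
  flip_perm <- if (is.null(model$class_names)) seq_len(K)
               else flip_permutation(model$class_names)
  with_seed(config$seed, {
    trace <- numeric(config$epochs)
    adam <- adam_init(model$params)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = bs)) {
        take <- ord[start:min(start + bs - 1, n)]
        H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
        xb <- array(0, dim = c(H, W, length(take), 1))
        lb <- array(0L, dim = c(H, W, length(take)))
        for (j in seq_along(take)) {
          sl <- slices[[take[j]]]
          if (config$augment) {
            a <- augment_slice(sl$image, sl$labels, config$max_shift_px,
                               flip_perm)
            xb[, , j, 1] <- a$img; lb[, , j] <- a$lab
          } else {
            xb[, , j, 1] <- sl$image; lb[, , j] <- sl$labels
          }
        }
        xb <- (xb - mu) / sdv
        fw <- segmenter_forward(model, xb, training = TRUE)
        ce <- softmax_ce(fw$logits, lb, class_weights = cw)
        if (!is.finite(ce$loss))
          stop("training diverged (loss not finite); config: epochs=",
               config$epochs, " lr=", config$lr, " batch=", bs, call. = FALSE)
        model <- update_bn_state(model, fw$caches)
        grads <- segmenter_backward(model, ce$dlogits, fw$caches)
        upd <- adam_step(model$params, grads, adam, config$lr)
        model$params <- upd$params
        adam <- upd$state
        ep_loss <- ep_loss + ce$loss; nb <- nb + 1
      }
      trace[ep] <- ep_loss / nb
    }
    model$loss_trace <- trace
    model$trained <- TRUE
    model$train_config <- config
    model
  })
}

#' Segment a volume slice-by-slice
#'
#' Per-slice forward pass, argmax over class scores, reassembled into a 3D
#' labelmap and converted to a [structure_set()] with provenance `"auto"`.
#'
#' @param model a trained [train_segmenter()] model with `class_names`.
#' @param image a [volume_grid()].
#' @return A [structure_set()]; label k maps to `class_names[k + 1]`
#'   (class 0 is background).
#' @export
segment_volume <- function(model, image) {
  stopifnot(inherits(model, "rtseval_cnn"), inherits(image, "volume_grid"))
  if (!model$trained) stop("model has not been trained", call. = FALSE)
  if (is.null(model$class_names))
    stop("model has no class names; rebuild with class_names", call. = FALSE)
  d <- dim(image$values)
  xb <- array(image$values, dim = c(d[1], d[2], d[3], 1))
  xb <- (xb - model$norm[["mean"]]) / model$norm[["sd"]]
  fw <- segmenter_forward(model, xb, training = FALSE)
  K <- model$spec$n_classes
  lg <- fw$logits
  dim(lg) <- c(prod(d), K)
  lab <- max.col(lg, ties.method = "first") - 1L
  lab <- array(lab, dim = d)
  masks <- list()
  for (k in seq_len(K - 1)) {
    masks[[model$class_names[k + 1]]] <-
      binary_mask(lab == k, spacing = image$spacing, origin = image$origin)
  }
  structure_set(masks, provenance = "auto")
}

#' Convert a phantom case to labeled training slices
#'
#' Labels are 0 for background and k for the k-th name in
#' [rt_structure_names()].
#'
#' @param image [volume_grid()] CT-like image.
#' @param manual [structure_set()] of reference contours on the same grid.
#' @param z_indices which slices to extract (default all).
#' @return List of `list(image, labels)` slices.
#' @export
phantom_to_slices <- function(image, manual, z_indices = NULL) {
  d <- dim(image$values)
  if (is.null(z_indices)) z_indices <- seq_len(d[3])
  names_k <- rt_structure_names()
  lab3 <- array(0L, dim = d)
  for (k in seq_along(names_k)) {
    m <- manual$structures[[names_k[k]]]
    if (!is.null(m)) lab3[m$voxels] <- k
  }
  lapply(z_indices, function(z)
    list(image = image$values[, , z], labels = lab3[, , z]))
}

#' Save / load a model checkpoint
#'
#' Binary checkpoint plus a JSON sidecar describing the architecture and
#' training configuration.
#'
#' @param model a `rtseval_cnn`.
#' @param path checkpoint path (`.rds`); the sidecar is `<path>.json`.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(spec = unclass(model$spec), trained = model$trained,
               class_names = model$class_names,
               train_config = if (!is.null(model$train_config))
                 unclass(model$train_config) else NULL,
               n_params = count_params(model$spec))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
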