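test_that("network shape contract: output matches input size and classes", {
  spec <- network_spec(n_classes = 10)
  model <- build_network(spec, seed = 1)
  x <- array(rnorm(64 * 64 * 2), dim = c(64, 64, 2, 1))
  fw <- rtseval:::segmenter_forward(model, x)
  expect_identical(dim(fw$logits), c(64L, 64L, 2L, 10L))
  # bottleneck spatial size is input/8 after three halvings
  expect_identical(dim(fw$caches$e3$y)[1:2], c(8L, 8L))
  # non-multiple-of-8 input raises a shape error with a padding hint
  bad <- array(0, dim = c(60, 64, 1, 1))
  expect_error(rtseval:::segmenter_forward(model, bad), "divisible by 8")
})

test_that("parameter count matches closed-form layer arithmetic", {
  c1 <- 8; c2 <- 16; c3 <- 32; K <- 5
  spec <- network_spec(K, channels = c(c1, c2, c3))
  conv <- function(ci, co, bn = TRUE) 9 * ci * co + co + if (bn) 2 * co else 0
  upc <- function(ci, co) 4 * ci * co + co
  expected <- conv(1, c1) + conv(c1, c2) + conv(c2, c3) + conv(c3, c3) +
    upc(c3, c3) + conv(2 * c3, c3) + upc(c3, c2) + conv(2 * c2, c2) +
    upc(c2, c1) + conv(2 * c1, c1) + conv(c1, K, bn = FALSE)
  expect_equal(count_params(spec), expected)
  # removing skips halves the decoder conv input channels
  spec_ns <- network_spec(K, channels = c(c1, c2, c3), use_skips = FALSE)
  expected_ns <- conv(1, c1) + conv(c1, c2) + conv(c2, c3) + conv(c3, c3) +
    upc(c3, c3) + conv(c3, c3) + upc(c3, c2) + conv(c2, c2) +
    upc(c2, c1) + conv(c1, c1) + conv(c1, K, bn = FALSE)
  expect_equal(count_params(spec_ns), expected_ns)
  expect_lt(count_params(spec_ns), count_params(spec))
})

test_that("layer gradients match finite differences on a tiny problem", {
  set.seed(60)
  spec <- network_spec(n_classes = 3, channels = c(2, 3, 4))
  model <- build_network(spec, seed = 61)
  x <- array(rnorm(16 * 16 * 1), dim = c(16, 16, 1, 1))
  lab <- array(sample(0:2, 16 * 16, replace = TRUE), dim = c(16, 16, 1))
  loss_of <- function(m) {
    fw <- rtseval:::segmenter_forward(m, x, training = TRUE)
    rtseval:::softmax_ce(fw$logits, lab)$loss
  }
  fw <- rtseval:::segmenter_forward(model, x, training = TRUE)
  ce <- rtseval:::softmax_ce(fw$logits, lab)
  grads <- rtseval:::segmenter_backward(model, ce$dlogits, fw$caches)
  eps <- 1e-5
  for (nm in c("inproj_W", "enc2_W", "up2_W", "dec3_W", "outproj_b",
               "enc1_gamma", "dec1_beta")) {
    p <- model$params[[nm]]
    for (i in sample(length(p), 3)) {
      m2 <- model
      m2$params[[nm]][i] <- p[i] + eps
      up <- loss_of(m2)
      m2$params[[nm]][i] <- p[i] - eps
      dn <- loss_of(m2)
      expect_equal(grads[[nm]][i], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("training decreases the loss and is seed-deterministic", {
  ph <- generate_phantom(62)
  sl <- phantom_to_slices(ph$image, ph$manual, 5:16)
  spec <- network_spec(n_classes = 10, channels = c(4, 8, 8))
  cfg <- train_config(epochs = 4, lr = 3e-3, batch_size = 12, seed = 63)
  m1 <- build_network(spec, seed = 63,
                      class_names = c("Background", rt_structure_names()))
  m1 <- train_segmenter(m1, sl, cfg)
  expect_length(m1$loss_trace, 4)
  expect_lt(m1$loss_trace[4], m1$loss_trace[1])
  m2 <- build_network(spec, seed = 63,
                      class_names = c("Background", rt_structure_names()))
  m2 <- train_segmenter(m2, sl, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  # augmentation off also converges and is recorded in the config
  cfg_na <- train_config(epochs = 4, lr = 3e-3, batch_size = 12, seed = 63,
                         augment = FALSE)
  m3 <- build_network(spec, seed = 63,
                      class_names = c("Background", rt_structure_names()))
  m3 <- train_segmenter(m3, sl, cfg_na)
  expect_lt(m3$loss_trace[4], m3$loss_trace[1])
  expect_false(m3$train_config$augment)
})

test_that("training validates inputs", {
  ph <- generate_phantom(64)
  sl <- phantom_to_slices(ph$image, ph$manual, 5:8)
  spec <- network_spec(n_classes = 10, channels = c(4, 4, 4))
  model <- build_network(spec, seed = 65)
  expect_error(train_segmenter(model, sl), "at least 10")
  sl12 <- phantom_to_slices(ph$image, ph$manual, 5:16)
  sl12[[1]]$labels[1, 1] <- 99
  expect_error(train_segmenter(model, sl12, train_config(epochs = 1)),
               "labels")
})

test_that("segmentation output is a consumable structure set", {
  ph <- generate_phantom(66)
  sl <- phantom_to_slices(ph$image, ph$manual, 5:16)
  spec <- network_spec(n_classes = 10, channels = c(4, 8, 8))
  model <- build_network(spec, seed = 67,
                         class_names = c("Background", rt_structure_names()))
  expect_error(segment_volume(model, ph$image), "trained")
  model <- train_segmenter(model, sl,
                           train_config(epochs = 2, lr = 3e-3, seed = 67))
  auto <- segment_volume(model, ph$image)
  expect_s3_class(auto, "structure_set")
  expect_identical(auto$provenance, "auto")
  expect_setequal(names(auto$structures), rt_structure_names())
  # outputs plug into the evaluators without adapters (missing structures
  # from an undertrained model are flagged, not fatal)
  g <- evaluate_geometry(ph$manual, auto)
  expect_equal(nrow(g), 9)
  dz <- evaluate_dosimetry(synth_dose(ph$manual, plan_config(), 68),
                           ph$manual, auto, plan_config())
  expect_equal(sort(unique(dz$pairs$structure)), sort(rt_structure_names()))
})

test_that("model checkpoints round-trip with a JSON sidecar", {
  spec <- network_spec(n_classes = 4, channels = c(2, 2, 2))
  model <- build_network(spec, seed = 69,
                         class_names = c("Background", "A", "B", "C"))
  f <- file.path(tempdir(), "ckpt.rds")
  save_model(model, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- load_model(f)
  expect_identical(back$params, model$params)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$n_params, count_params(spec))
})
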