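test_that("forward pass produces bounded, well-shaped, deterministic outputs", {
  model <- init_model(model_config(depth = 2, base_features = 8), seed = 4)
  x <- matrix(runif(16 * 16), 16, 16)
  out1 <- evtrack:::unet_forward(model, x)
  out2 <- evtrack:::unet_forward(model, x)
  expect_identical(out1$reg, out2$reg)
  expect_equal(dim(out1$reg), c(16, 16))
  expect_equal(dim(out1$cls), c(16, 16, 3))
  expect_true(all(out1$reg > 0 & out1$reg < 1))
  sums <- apply(out1$cls, c(1, 2), sum)
  expect_equal(sums, matrix(1, 16, 16), tolerance = 1e-10)
})

test_that("network gradients match finite differences", {
  set.seed(1)
  model <- init_model(model_config(depth = 2, base_features = 8), seed = 3)
  x <- matrix(runif(64), 8, 8)
  dmap <- matrix(runif(64), 8, 8)
  cmap <- matrix(sample(0:2, 64, TRUE), 8, 8)
  loss_at <- function(m) {
    out <- evtrack:::unet_forward(m, x)
    evtrack:::sample_loss(m, out, dmap, cmap)$total
  }
  out <- evtrack:::unet_forward(model, x, keep_cache = TRUE)
  ls <- evtrack:::sample_loss(model, out, dmap, cmap)
  gr <- evtrack:::unet_backward(model, out$cache, ls$g_reg, ls$g_cls)
  eps <- 1e-6
  spots <- list(
    list(c("enc", 1L, "W1"), gr$enc[[1]]$W1),
    list(c("enc", 2L, "W2"), gr$enc[[2]]$W2),
    list(c("dec", 1L, "W1"), gr$dec[[1]]$W1),
    list(c("head_cls", "W"), gr$head_cls$W)
  )
  for (sp in spots) {
    path <- sp[[1]]; ganal <- as.numeric(sp[[2]])
    get_set <- function(m, delta, idx) {
      if (length(path) == 3L) {
        m$params[[path[1]]][[as.integer(path[2])]][[path[3]]][idx] <-
          m$params[[path[1]]][[as.integer(path[2])]][[path[3]]][idx] + delta
      } else {
        m$params[[path[1]]][[path[2]]][idx] <-
          m$params[[path[1]]][[path[2]]][idx] + delta
      }
      m
    }
    for (idx in sample(length(ganal), 3)) {
      num <- (loss_at(get_set(model, eps, idx)) -
                loss_at(get_set(model, -eps, idx))) / (2 * eps)
      expect_equal(ganal[idx], num, tolerance = 1e-4)
    }
  }
})

test_that("training for zero epochs returns an initialized model and empty history", {
  sc <- generate_scene(scene_params(image_size = c(64, 64), n_cells = 1,
                                    cell_radius = c(11, 1), seed = 2))
  run <- train_model(list(list(frame = sc$frame, truth = sc$truth)),
                     model_config(depth = 2, base_features = 8),
                     epochs = 0, seed = 1)
  expect_s3_class(run, "training_run")
  expect_equal(nrow(run$history), 0)
})

test_that("a short training run reduces the loss and is seed-reproducible", {
  ds <- lapply(1:4, function(s) {
    sc <- generate_scene(scene_params(image_size = c(64, 64), n_cells = 2,
                                      cell_radius = c(11, 1.5),
                                      n_evs_internal = 4, n_evs_external = 3,
                                      seed = s))
    list(frame = sc$frame, truth = sc$truth)
  })
  cfg <- model_config(depth = 2, base_features = 8)
  run1 <- train_model(ds, cfg, aug_cfg = NULL, epochs = 5, seed = 7)
  expect_equal(nrow(run1$history), 5)
  expect_true(all(is.finite(run1$history$total)))
  expect_lt(run1$history$total[5], run1$history$total[1])
  run2 <- train_model(ds, cfg, aug_cfg = NULL, epochs = 5, seed = 7)
  expect_identical(run1$history, run2$history)
})

test_that("checkpoints round-trip through disk", {
  sc <- generate_scene(scene_params(image_size = c(64, 64), n_cells = 1,
                                    cell_radius = c(11, 1), seed = 3))
  run <- train_model(list(list(frame = sc$frame, truth = sc$truth)),
                     model_config(depth = 2, base_features = 8),
                     aug_cfg = NULL, epochs = 1, seed = 5)
  path <- file.path(tempdir(), "ckpt.rds")
  save_checkpoint(run, path)
  back <- load_checkpoint(path)
  expect_equal(back$model$params, run$model$params, tolerance = 1e-15)
  expect_equal(back$model$cfg$depth, run$model$cfg$depth)
  x <- matrix(runif(64), 8, 8)
  expect_equal(evtrack:::unet_forward(back$model, x)$reg,
               evtrack:::unet_forward(run$model, x)$reg, tolerance = 1e-12)
})
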