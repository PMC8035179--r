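# Small synthetic segmentation task shared by the network tests: a bright
# ellipsoid (class 1) and a dim one (class 3) in a noisy background.
unet_toy <- function(dim3 = c(16L, 16L, 16L), seed = 1) {
  with(list(d = dim3), {
    set.seed(seed)
    co <- lapply(d, function(n) seq_len(n))
    lab <- array(0L, dim = d)
    m1 <- outer(outer((co[[1]] - 5)^2, (co[[2]] - 8)^2, "+"),
                (co[[3]] - 8)^2, "+") <= 9
    m3 <- outer(outer((co[[1]] - 12)^2, (co[[2]] - 8)^2, "+"),
                (co[[3]] - 8)^2, "+") <= 6
    lab[m1] <- 1L; lab[m3] <- 3L
    ct <- array(40, dim = d) + rnorm(prod(d), 0, 10)
    ct[m1] <- 15; ct[m3] <- 55
    ctn <- (pmin(pmax(ct, -160), 240) + 160) / 400
    list(x = network_input(ctn), y = lab)
  })
}

test_that("configuration contracts are enforced", {
  expect_error(unet_config(input_shape = c(10L, 16L, 16L), levels = 3L),
               "divisible")
  expect_error(unet_config(patch_size = c(10L, 16L, 16L), levels = 3L,
                           input_shape = c(16L, 16L, 16L)), "divisible")
  expect_error(unet_config(lr = -1), "lr")
  cfg <- unet_config(input_shape = c(16L, 16L, 16L), levels = 3L)
  expect_equal(cfg$levels, 3L)
})

test_that("analytic gradients match finite differences", {
  for (setting in list(c("none", "dice"), c("instance", "dice_ce"))) {
    cfg <- unet_config(input_shape = c(8L, 8L, 8L), levels = 2L,
                       base_channels = 2L, norm = setting[1],
                       loss = setting[2], seed = 3)
    set.seed(42)
    x <- array(runif(9 * 512), dim = c(9, 8, 8, 8))
    y <- array(sample(0:4, 512, TRUE), dim = c(8, 8, 8))
    params <- sialoquant:::unet_init_params(cfg)
    fw <- sialoquant:::unet_forward(params, x, cfg)
    lg <- sialoquant:::dice_loss_grad(fw$logits, y, cfg)
    gr <- sialoquant:::unet_backward(params, fw$cache, lg$dlogits, cfg)
    lossfn <- function(p) {
      f <- sialoquant:::unet_forward(p, x, cfg, keep_cache = FALSE,
                                     training = TRUE)
      sialoquant:::dice_loss_grad(f$logits, y, cfg)$loss
    }
    eps <- 1e-5
    for (nm in c("enc1a", "enc2b", "dec1a", "out", "lin")) {
      pw <- params[[nm]]$w
      for (ii in sample(length(pw), 3)) {
        p2 <- params; p2[[nm]]$w[ii] <- p2[[nm]]$w[ii] + eps
        p3 <- params; p3[[nm]]$w[ii] <- p3[[nm]]$w[ii] - eps
        num <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
        ana <- gr[[nm]]$w[ii]
        err <- min(abs(num - ana),
                   abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
        expect_lt(err, 1e-5)
      }
    }
  }
})

test_that("predicted probabilities are a valid softmax field", {
  cfg <- unet_config(input_shape = c(16L, 16L, 16L), levels = 2L,
                     base_channels = 2L, epochs = 1L, seed = 4)
  toy <- unet_toy()
  m <- suppressWarnings(unet_train(list(toy), cfg))
  p <- predict(m, toy$x)
  sums <- apply(p, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(p >= 0))
  p2 <- predict(m, toy$x)
  expect_identical(p, p2)                    # deterministic inference
})

test_that("a reloaded model reproduces identical inference outputs", {
  cfg <- unet_config(input_shape = c(16L, 16L, 16L), levels = 2L,
                     base_channels = 2L, epochs = 1L, seed = 5)
  toy <- unet_toy()
  m <- suppressWarnings(unet_train(list(toy), cfg))
  path <- tempfile(fileext = ".rds")
  save_unet(m, path)
  m2 <- load_unet(path)
  expect_identical(predict(m, toy$x), predict(m2, toy$x))
})

test_that("training is reproducible from the seed", {
  cfg <- unet_config(input_shape = c(16L, 16L, 16L), levels = 2L,
                     base_channels = 2L, epochs = 2L, seed = 6)
  toy <- unet_toy()
  m1 <- suppressWarnings(unet_train(list(toy), cfg))
  m2 <- suppressWarnings(unet_train(list(toy), cfg))
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$params$out$w, m2$params$out$w)
})

test_that("training input contracts are enforced", {
  cfg <- unet_config(input_shape = c(16L, 16L, 16L), levels = 2L,
                     base_channels = 2L, epochs = 1L)
  toy <- unet_toy()
  bad <- list(x = toy$x[, 1:8, , , drop = FALSE], y = toy$y)
  expect_error(unet_train(list(bad), cfg), "shape")
  empty <- list(x = toy$x, y = array(0L, dim = dim(toy$y)))
  expect_error(unet_train(list(empty), cfg), "foreground")
})

test_that("training loss decreases when overfitting a single noiseless sample", {
  toy <- unet_toy(seed = 2)
  cfg <- unet_config(input_shape = c(16L, 16L, 16L), levels = 2L,
                     base_channels = 4L, norm = "instance", loss = "dice_ce",
                     lr = 3e-2, epochs = 30L, seed = 7, warm_start = FALSE)
  m <- suppressWarnings(unet_train(list(toy), cfg))
  l <- m$history$loss
  expect_lt(l[length(l)], 0.5 * l[1])
  # allow only small transient upticks around the decreasing trend
  expect_lt(sum(diff(l) > 0.05 * l[1]), 3)
})

test_that("postprocessing keeps the largest component and never adds voxels", {
  d <- c(12L, 12L, 6L)
  probs <- array(0, dim = c(d, 5L))
  probs[, , , 1] <- 0.9
  # class 1: one 100-voxel blob and one 3-voxel fragment
  probs[2:6, 2:6, 2:5, 2] <- 0.95
  probs[10:11, 11, 1, 2] <- 0.95
  probs[10, 10, 1, 2] <- 0.95
  lab <- postprocess_labels(probs, spacing = c(2, 2, 2),
                            min_component_voxels = 10L)
  expect_equal(sum(lab$labels == 1L), 5 * 5 * 4)
  expect_equal(lab$labels[10, 10, 1], 0L)
  # argmax counts can only shrink during cleanup
  arg <- apply(probs, 1:3, which.max) - 1L
  expect_lte(sum(lab$labels == 1L), sum(arg == 1L))
  # a single compact blob passes through unchanged
  probs2 <- array(0, dim = c(d, 5L))
  probs2[, , , 1] <- 0.9
  probs2[3:8, 3:8, 2:5, 3] <- 0.95
  lab2 <- postprocess_labels(probs2, spacing = c(2, 2, 2))
  expect_equal(sum(lab2$labels == 2L), 6 * 6 * 4)
  # a lone component below the minimum size is removed entirely
  probs3 <- array(0, dim = c(d, 5L))
  probs3[, , , 1] <- 0.9
  probs3[1:2, 1:2, 1, 4] <- 0.95
  lab3 <- postprocess_labels(probs3, spacing = c(2, 2, 2),
                             min_component_voxels = 10L)
  expect_equal(sum(lab3$labels == 3L), 0L)
})

test_that("cross-validation folds are balanced and seed-stable", {
  co <- suppressWarnings(generate_cohort(tiny_spec(seed = 40), 6))
  cfg <- unet_config(input_shape = c(48L, 32L, 16L), levels = 2L,
                     base_channels = 2L, norm = "instance", loss = "dice_ce",
                     patch_size = c(16L, 16L, 8L), patches_per_volume = 2L,
                     epochs = 2L, seed = 8)
  tab <- crossvalidate_unet(co, folds = 3L, config = cfg, seed = 9)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$n_test == 2L))
  expect_true(all(c("dsc", "mean_pid_manual", "mean_pid_auto", "r2",
                    "mape") %in% names(tab)))
  expect_error(crossvalidate_unet(co, folds = 7L, config = cfg), "smaller")
})
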