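test_that("activation functions follow their closed forms", {
  expect_identical(relu(-3), 0)
  expect_identical(relu(2.5), 2.5)
  expect_equal(sigmoid(0), 0.5)
  grid <- seq(-6, 6, by = 0.5)
  expect_equal(sigmoid(-grid), 1 - sigmoid(grid), tolerance = 1e-12)
})

test_that("binary cross-entropy matches closed forms and a summation oracle", {
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(1, 0), c(0.99, 0.01)), -log(0.99), tolerance = 1e-12)
  set.seed(2)
  a <- rbinom(100, 1, 0.5)
  b <- runif(100, 0.01, 0.99)
  oracle <- 0
  for (i in 1:100)
    oracle <- oracle - (a[[i]] * log(b[[i]]) + (1 - a[[i]]) * log(1 - b[[i]]))
  expect_equal(bce_loss(a, b), oracle / 100, tolerance = 1e-10)
  # clipping keeps the loss finite at the boundary
  expect_true(is.finite(bce_loss(c(1, 0), c(0, 1))))
})

test_that("default configuration reproduces the published architecture", {
  cfg <- model_config()
  expect_identical(cfg$window, 19L)
  expect_identical(cfg$branches, c("pssm", "dssp", "hmm"))
  expect_identical(cfg$kernels, c(5L, 3L, 3L))
  expect_identical(cfg$filters, c(64L, 32L, 16L))
  expect_identical(cfg$dropout, c(pssm = 0.1, dssp = 0.3, hmm = 0.2))
  expect_identical(cfg$dense, c(256L, 128L, 64L, 1L))
  expect_identical(cfg$feature_dims, c(pssm = 20L, dssp = 14L, hmm = 20L))
  # valid-convolution arithmetic: 19 -> 15 -> 13 -> 11, 11 x 16 x 3 = 528
  expect_identical(conv_extents(cfg), c(15L, 13L, 11L))
  expect_identical(concat_width(cfg), 528L)
  expect_error(model_config(window = 7L), "too small")
  expect_error(model_config(window = 18L), "odd")
})

test_that("built model has the declared parameter shapes", {
  m <- build_model(model_config(), seed = 1)
  p <- m$params
  expect_identical(dim(p$pssm.conv1.W), c(100L, 64L))  # k5 x 20 channels
  expect_identical(dim(p$dssp.conv1.W), c(70L, 64L))   # k5 x 14 channels
  expect_identical(dim(p$hmm.conv2.W), c(192L, 32L))   # k3 x 64
  expect_identical(dim(p$pssm.conv3.W), c(96L, 16L))   # k3 x 32
  expect_length(p$dssp.ln.gamma, 11L * 16L)
  expect_identical(dim(p$dense1.W), c(528L, 256L))
  expect_identical(dim(p$dense4.W), c(64L, 1L))
  # two builds with one seed are identical; different seeds differ
  m2 <- build_model(model_config(), seed = 1)
  expect_identical(m$params, m2$params)
  expect_identical(n_params(m), n_params(build_model(model_config(), seed = 9)))
  expect_false(identical(m$params, build_model(model_config(), seed = 9)$params))
})

test_that("forward pass is deterministic at inference and bounded in (0,1)", {
  m <- build_model(model_config(), seed = 4)
  batch <- random_window_batch(32, seed = 6)
  s1 <- model_forward(m, batch)$scores
  s2 <- model_forward(m, batch)$scores
  expect_identical(s1, s2)  # dropout inert at inference
  expect_true(all(s1 > 0 & s1 < 1))
  expect_length(s1, 32L)
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(window = 9L, filters = c(3L, 3L, 2L), dense = c(5L, 1L),
                      dropout = c(pssm = 0, dssp = 0, hmm = 0))
  m <- build_model(cfg, seed = 2)
  batch <- random_window_batch(5, n = 9L, seed = 3)
  fwd <- model_forward(m, batch)
  grads <- ppisite:::model_backward(m, batch, fwd, batch$labels)
  eps <- 1e-6
  set.seed(11)
  for (nm in names(m$params)) {
    for (j in sample(seq_along(m$params[[nm]]),
                     min(4, length(m$params[[nm]])))) {
      m2 <- m
      m2$params[[nm]][j] <- m$params[[nm]][j] + eps
      up <- bce_loss(batch$labels, model_forward(m2, batch)$scores)
      m2$params[[nm]][j] <- m$params[[nm]][j] - eps
      dn <- bce_loss(batch$labels, model_forward(m2, batch)$scores)
      numeric_grad <- (up - dn) / (2 * eps)
      expect_equal(grads[[nm]][j], numeric_grad, tolerance = 1e-3,
                   label = paste("grad", nm))
    }
  }
})

test_that("training is seeded-deterministic and reduces loss on separable data", {
  # linearly separable planted batch: positives have high channel values
  set.seed(7)
  B <- 300
  labels <- rbinom(B, 1, 0.4)
  mk <- function(m) {
    arr <- array(runif(B * 9 * m, 0, 0.4), c(B, 9, m))
    arr[labels == 1, , 1] <- arr[labels == 1, , 1] + 0.6
    arr
  }
  batch <- structure(list(pssm = mk(20), hmm = mk(20), dssp = mk(14),
                          labels = labels, protein_id = rep("S", B),
                          positions = seq_len(B), a = 4L, n = 9L,
                          center = 5L), class = "window_batch")
  cfg <- model_config(window = 9L, epochs = 8L, batch_size = 64L)
  tr1 <- train_model(build_model(cfg, seed = 3), batch, seed = 3)
  tr2 <- train_model(build_model(cfg, seed = 3), batch, seed = 3)
  expect_identical(tr1$model$params, tr2$model$params)
  expect_identical(predict_model(tr1$model, batch),
                   predict_model(tr2$model, batch))
  expect_lt(tr1$history$loss[[8]], tr1$history$loss[[1]])
  expect_gt(compute_metrics(labels, predict_model(tr1$model, batch))$auroc, 0.95)
  expect_error(train_model(build_model(cfg, seed = 1),
                           random_window_batch(10, 9L, labelled = FALSE)),
               "labelled")
})

test_that("reduced-branch models have the matching concatenation width", {
  cfg2 <- model_config(branches = c("pssm", "hmm"))
  expect_identical(concat_width(cfg2), 2L * 176L)
  cfg1 <- model_config(branches = "dssp")
  expect_identical(concat_width(cfg1), 176L)
  m <- build_model(cfg1, seed = 1)
  expect_false(any(grepl("^pssm", names(m$params))))
  batch <- random_window_batch(8, seed = 2)
  expect_length(model_forward(m, batch)$scores, 8L)
})

test_that("checkpoints round-trip through disk", {
  m <- build_model(model_config(), seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$params, m$params)
  expect_true(file.exists(paste0(path, ".json")))
  batch <- random_window_batch(4, seed = 1)
  expect_identical(predict_model(back, batch), predict_model(m, batch))
})
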