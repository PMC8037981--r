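# 1-D CNN regression model

test_that("the shape report matches the fixed architecture", {
  rep <- shape_report(architecture_spec())
  expect_equal(rep$stage,
               c("input", "conv1", "pool1", "conv2", "pool2", "conv3",
                 "gap", "dense"))
  expect_equal(rep$out_len, c(1000L, 1000L, 500L, 500L, 250L, 250L, NA, NA))
  expect_equal(rep$out_channels, c(2L, 100L, 100L, 200L, 200L, 300L, 300L, 1L))
})

test_that("trainable parameter count matches the closed-form sum", {
  m <- build_model(architecture_spec())
  # conv: k*c_in*c_out + c_out; BN: 2*c_out; dense: c_in + 1
  hand <- (21 * 2 * 100 + 100) + (5 * 100 * 200 + 200) +
    (5 * 200 * 300 + 300) + 2 * (100 + 200 + 300) + (300 + 1)
  expect_equal(m$n_params, hand)
  expect_equal(sum(vapply(m$params, length, numeric(1))), hand)
})

test_that("pool-incompatible input lengths are rejected", {
  expect_error(architecture_spec(input_len = 1002), "divisible")
})

test_that("compiled layer kernels agree with the plain-R reference", {
  set.seed(30)
  spec <- small_arch()
  p <- bcgbp:::init_params(spec, 7)
  X <- array(rnorm(6 * 16 * 2), c(6, 16, 2))
  a <- bcgbp:::conv1d_fwd(X, p[["conv1.W"]], p[["conv1.b"]])
  b <- bcgbp:::conv1d_fwd_ref(X, p[["conv1.W"]], p[["conv1.b"]])
  expect_equal(a$out, b$out, tolerance = 1e-12)
  dY <- array(rnorm(length(a$out)), dim(a$out))
  ga <- bcgbp:::conv1d_bwd(dY, a, p[["conv1.W"]])
  gb <- bcgbp:::conv1d_bwd_ref(dY, b, p[["conv1.W"]])
  expect_equal(ga$dX, gb$dX, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ga$dW, gb$dW, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ga$db, gb$db, tolerance = 1e-12)

  g <- runif(4, 0.5, 1.5); be <- rnorm(4)
  bna <- bcgbp:::bn_fwd(a$out, g, be, numeric(4), rep(1, 4), TRUE)
  bnb <- bcgbp:::bn_fwd_ref(b$out, g, be, numeric(4), rep(1, 4), TRUE)
  expect_equal(bna$out, bnb$out, tolerance = 1e-12)
  expect_equal(bna$run_var, bnb$run_var, tolerance = 1e-12)
  ba <- bcgbp:::bn_bwd(dY, bna, g)
  bb <- bcgbp:::bn_bwd_ref(dY, bnb, g)
  expect_equal(ba$dX, bb$dX, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ba$dgamma, bb$dgamma, tolerance = 1e-12)
})

test_that("backpropagated gradients match central differences", {
  set.seed(31)
  spec <- architecture_spec(input_len = 8, in_channels = 2,
                            conv_filters = c(3, 4, 5),
                            conv_kernels = c(3, 3, 3))
  params <- bcgbp:::init_params(spec, 42)
  state <- bcgbp:::init_bn_state(spec)
  X <- array(rnorm(4 * 8 * 2), c(4, 8, 2))
  y <- rnorm(4)
  lossfn <- function(p) {
    fw <- bcgbp:::model_forward(p, state, spec, X, TRUE)
    mean((fw$pred - y)^2)
  }
  fw <- bcgbp:::model_forward(params, state, spec, X, TRUE)
  grads <- bcgbp:::model_backward(2 * (fw$pred - y) / 4, fw, params, spec)
  eps <- 1e-6
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (i in idx) {
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
      g_num <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
      expect_lt(abs(g_num - grads[[nm]][i]), 1e-6)
    }
  }
})

test_that("the fused training step matches the modular double-precision path", {
  set.seed(32)
  spec <- architecture_spec()
  params <- bcgbp:::init_params(spec, 3)
  state <- bcgbp:::init_bn_state(spec)
  X <- array(rnorm(8 * 1000 * 2), c(8, 1000, 2))
  y <- rnorm(8)
  fw <- bcgbp:::model_forward(params, state, spec, X, TRUE)
  g_ref <- bcgbp:::model_backward(2 * (fw$pred - y) / 8, fw, params, spec)
  step <- bcgbp:::cnn_train_step_cpp(params, state, X, y, spec$conv_kernels,
                                     spec$pool_after, spec$in_channels)
  expect_equal(step$pred, fw$pred, tolerance = 1e-4)
  for (nm in names(g_ref)) {
    scale <- max(abs(g_ref[[nm]]), 1e-6)
    expect_lt(max(abs(as.numeric(g_ref[[nm]]) -
                        as.numeric(step$grads[[nm]]))) / scale, 2e-2)
  }
  for (nm in names(state)) {
    expect_equal(step$state[[nm]], fw$state[[nm]], tolerance = 1e-5)
  }
})

test_that("training is deterministic and records one validation MSE per fold", {
  eps <- make_linear_phase_epochs(24, seed = 2)
  plan <- make_cv_folds(split_train_test(eps, seed = 1), k = 3)
  st <- train_settings(max_epochs = 2, early_stop_patience = 2, seed = 11,
                       target = "sbp")
  m1 <- train_model(eps, plan, architecture_spec(), st)
  m2 <- train_model(eps, plan, architecture_spec(), st)
  expect_identical(m1$fold_history, m2$fold_history)
  expect_length(m1$fold_history, 3)
  expect_equal(m1$selected_fold, which.min(m1$fold_history))
  expect_identical(m1$params, m2$params)
})

test_that("training refuses mixed sessions and plans without folds", {
  eps <- make_linear_phase_epochs(24)
  plan <- split_train_test(eps, seed = 1)
  expect_error(train_model(eps, plan), "folds")
  mixed <- eps
  mixed$session[1:12] <- "recovery"
  plan2 <- make_cv_folds(plan, k = 3)
  expect_error(train_model(mixed, plan2), "session")
})

test_that("a linear phase-shift to pressure mapping is learnable", {
  # SBP is an exact linear function of the seat-channel phase delay; the
  # network should overfit the training data nearly perfectly and
  # generalize to held-out epochs
  eps <- make_linear_phase_epochs(50, seed = 3)
  plan <- make_cv_folds(split_train_test(eps, seed = 2), k = 5)
  st <- train_settings(max_epochs = 40, early_stop_patience = 40, seed = 5,
                       target = "sbp", batch_size = 16)
  model <- train_model(eps, plan, architecture_spec(), st)
  train_pred <- predict_bp(model, eps[plan$train])
  expect_lt(mean((train_pred - eps$sbp[plan$train])^2), 1)
  test_pred <- predict_bp(model, eps[plan$test])
  expect_gt(stats::cor(test_pred, eps$sbp[plan$test]), 0.9)
})

test_that("prediction is batch-invariant and rejects wrong geometry", {
  eps <- make_linear_phase_epochs(12, seed = 4)
  plan <- make_cv_folds(split_train_test(eps, seed = 1), k = 2)
  st <- train_settings(max_epochs = 1, seed = 7, target = "sbp")
  model <- train_model(eps, plan, architecture_spec(), st)
  batch <- predict_bp(model, eps)
  single <- vapply(seq_along(eps), function(i) predict_bp(model, eps[i]),
                   numeric(1))
  expect_lt(max(abs(batch - single)), 1e-4)
  # duplicated epoch -> identical prediction
  dup <- eps[c(1, 1)]
  pd <- predict_bp(model, dup)
  expect_identical(pd[1], pd[2])
  short <- make_linear_phase_epochs(2, len = 500)
  expect_error(predict_bp(model, short), "length")
})

test_that("a trained model round-trips through its model directory", {
  eps <- make_linear_phase_epochs(12, seed = 6)
  plan <- make_cv_folds(split_train_test(eps, seed = 1), k = 2)
  st <- train_settings(max_epochs = 1, seed = 8, target = "sbp")
  model <- train_model(eps, plan, architecture_spec(), st)
  dir <- tempfile()
  save_model(model, dir)
  model2 <- load_model(dir)
  expect_equal(predict_bp(model2, eps), predict_bp(model, eps),
               tolerance = 1e-7)
  expect_equal(model2$fold_history, model$fold_history, tolerance = 1e-12)
  expect_equal(model2$target, model$target)
})
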