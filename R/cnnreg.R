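# 1-D CNN regression of blood pressure from two-channel phase epochs.
#
# Architecture (fixed): conv(100 filters, kernel 21, stride 1) -> BN -> ReLU
# -> maxpool/2 -> conv(200, 5) -> BN -> ReLU -> maxpool/2 -> conv(300, 5) ->
# BN -> ReLU -> global average pool -> dense(1, identity). Filter counts are
# 1x, 2x, 3x the 100 Hz sampling rate. Convolutions use length-preserving
# padding so the only length reductions are the two pooling halvings
# (1000 -> 500 -> 250). One model is trained per target (SBP or DBP) and per
# session (rest or recovery).

#' CNN architecture specification
#'
#' @param input_len Epoch length in samples (1000 = 10 s at 100 Hz).
#' @param in_channels Input channels (2: back and seat phase).
#' @param conv_filters Filters per convolution layer.
#' @param conv_kernels Kernel sizes (odd, for symmetric same-padding).
#' @param conv_stride Convolution stride (1).
#' @param pool_after Whether a factor-2 max-pool follows each conv block.
#' @param pool_factor Pooling factor.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(input_len = 1000, in_channels = 2,
                              conv_filters = c(100, 200, 300),
                              conv_kernels = c(21, 5, 5),
                              conv_stride = 1,
                              pool_after = c(TRUE, TRUE, FALSE),
                              pool_factor = 2) {
  n_pool <- sum(pool_after)
  if (input_len %% pool_factor^n_pool != 0) {
    stop("input_len (", input_len, ") is not divisible by pool_factor^",
         n_pool, call. = FALSE)
  }
  stopifnot(length(conv_filters) == length(conv_kernels),
            length(pool_after) == length(conv_filters),
            all(conv_kernels %% 2 == 1), conv_stride == 1)
  structure(list(input_len = as.integer(input_len),
                 in_channels = as.integer(in_channels),
                 conv_filters = as.integer(conv_filters),
                 conv_kernels = as.integer(conv_kernels),
                 conv_stride = as.integer(conv_stride),
                 pool_after = pool_after,
                 pool_factor = as.integer(pool_factor)),
            class = "architecture_spec")
}

#' Training settings
#'
#' @param learning_rate Adam learning rate (0.001).
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum passes over the training fold.
#' @param early_stop_patience Stop a fold after this many epochs without
#'   validation improvement.
#' @param seed Integer seed; training is deterministic given it.
#' @param target `"sbp"` or `"dbp"`.
#' @return An object of class `train_settings`. Loss is mean squared error;
#'   the optimizer is Adam.
#' @export
train_settings <- function(learning_rate = 0.001, batch_size = 32,
                           max_epochs = 200, early_stop_patience = 20,
                           seed = 1L, target = c("sbp", "dbp")) {
  target <- match.arg(target)
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  structure(list(loss = "mse", optimizer = "adam",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed), target = target),
            class = "train_settings")
}

# seeded He initialization; conv weights stored as arrays [k, c_in, c_out]
init_params <- function(spec, seed) {
  with_seed(seed, {
    p <- list()
    cin <- spec$in_channels
    for (i in seq_along(spec$conv_filters)) {
      k <- spec$conv_kernels[i]
      cout <- spec$conv_filters[i]
      p[[paste0("conv", i, ".W")]] <-
        array(stats::rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))),
              c(k, cin, cout))
      p[[paste0("conv", i, ".b")]] <- numeric(cout)
      p[[paste0("bn", i, ".gamma")]] <- rep(1, cout)
      p[[paste0("bn", i, ".beta")]] <- numeric(cout)
      cin <- cout
    }
    p[["dense.W"]] <- matrix(stats::rnorm(cin, 0, sqrt(1 / cin)), cin, 1)
    p[["dense.b"]] <- 0
    p
  })
}

init_bn_state <- function(spec) {
  st <- list()
  for (i in seq_along(spec$conv_filters)) {
    st[[paste0("bn", i, ".mean")]] <- numeric(spec$conv_filters[i])
    st[[paste0("bn", i, ".var")]] <- rep(1, spec$conv_filters[i])
  }
  st
}

#' Build a model realization with its layer-shape report
#'
#' @param spec An [architecture_spec()].
#' @param seed Seed for weight initialization.
#' @return List with `spec`, initial `params` and `state`, the
#'   `shape_report` data frame (per-stage sequence length and channel count),
#'   and `n_params`, the trainable parameter count.
#' @export
build_model <- function(spec = architecture_spec(), seed = 1L) {
  params <- init_params(spec, seed)
  list(spec = spec, params = params, state = init_bn_state(spec),
       shape_report = shape_report(spec),
       n_params = sum(vapply(params, length, numeric(1))))
}

#' Per-layer output-shape report
#'
#' @param spec An [architecture_spec()].
#' @return Data frame with columns `stage`, `out_len`, `out_channels`.
#' @export
shape_report <- function(spec) {
  stage <- "input"; len <- spec$input_len; ch <- spec$in_channels
  for (i in seq_along(spec$conv_filters)) {
    stage <- c(stage, paste0("conv", i))
    len <- c(len, len[length(len)])
    ch <- c(ch, spec$conv_filters[i])
    if (spec$pool_after[i]) {
      stage <- c(stage, paste0("pool", i))
      len <- c(len, len[length(len)] / spec$pool_factor)
      ch <- c(ch, spec$conv_filters[i])
    }
  }
  stage <- c(stage, "gap", "dense")
  len <- c(len, NA, NA)
  ch <- c(ch, spec$conv_filters[length(spec$conv_filters)], 1L)
  data.frame(stage = stage, out_len = as.integer(len),
             out_channels = as.integer(ch))
}

# full forward pass; returns prediction plus caches for backprop
model_forward <- function(params, state, spec, X, training) {
  caches <- vector("list", length(spec$conv_filters))
  A <- X
  for (i in seq_along(spec$conv_filters)) {
    cv <- conv1d_fwd(A, params[[paste0("conv", i, ".W")]],
                     params[[paste0("conv", i, ".b")]])
    bn <- bn_fwd(cv$out, params[[paste0("bn", i, ".gamma")]],
                 params[[paste0("bn", i, ".beta")]],
                 state[[paste0("bn", i, ".mean")]],
                 state[[paste0("bn", i, ".var")]], training)
    if (training) {
      state[[paste0("bn", i, ".mean")]] <- bn$run_mean
      state[[paste0("bn", i, ".var")]] <- bn$run_var
    }
    rl <- relu_fwd(bn$out)
    A <- rl$out
    pl <- NULL
    if (spec$pool_after[i]) {
      pl <- pool2_fwd(A)
      A <- pl$out
    }
    caches[[i]] <- list(cv = cv, bn = bn, rl = rl, pl = pl)
  }
  gp <- gap_fwd(A)
  dn <- dense_fwd(gp$out, params[["dense.W"]], params[["dense.b"]])
  list(pred = dn$out[, 1], caches = caches, gp = gp, dn = dn, state = state)
}

model_backward <- function(dpred, fw, params, spec) {
  grads <- list()
  db <- dense_bwd(matrix(dpred, ncol = 1), fw$dn, params[["dense.W"]])
  grads[["dense.W"]] <- db$dW
  grads[["dense.b"]] <- db$db
  dA <- gap_bwd(db$dX, fw$gp)
  for (i in rev(seq_along(spec$conv_filters))) {
    cc <- fw$caches[[i]]
    if (!is.null(cc$pl)) dA <- pool2_bwd(dA, cc$pl)
    dA <- relu_bwd(dA, cc$rl)
    bb <- bn_bwd(dA, cc$bn, params[[paste0("bn", i, ".gamma")]])
    grads[[paste0("bn", i, ".gamma")]] <- bb$dgamma
    grads[[paste0("bn", i, ".beta")]] <- bb$dbeta
    cb <- conv1d_bwd(bb$dX, cc$cv, params[[paste0("conv", i, ".W")]])
    grads[[paste0("conv", i, ".W")]] <- cb$dW
    grads[[paste0("conv", i, ".b")]] <- cb$db
    dA <- cb$dX
  }
  grads
}

# inference-mode prediction in memory-bounded batches (standardized units)
predict_raw <- function(params, state, spec, X, chunk = 64L) {
  n <- dim(X)[1]
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(n, i0 + chunk - 1L)
    out[idx] <- cnn_predict_cpp(params, state, X[idx, , , drop = FALSE],
                                spec$conv_kernels, spec$pool_after,
                                spec$in_channels)
  }
  out
}

# epoch_set -> input array (n, input_len, 2)
epochs_to_array <- function(epochs, input_len) {
  if (ncol(epochs$phase_back) != input_len) {
    stop("epoch length ", ncol(epochs$phase_back),
         " does not match the model input length ", input_len, call. = FALSE)
  }
  n <- length(epochs)
  X <- array(0, c(n, input_len, 2L))
  X[, , 1] <- epochs$phase_back
  X[, , 2] <- epochs$phase_seat
  X
}

# exact BN inference statistics over (up to 512 samples of) the train fold;
# momentum-averaged mini-batch statistics are too noisy on small folds and
# destabilize inference-mode predictions
recalibrate_bn <- function(params, X, spec) {
  n <- dim(X)[1]
  idx <- seq_len(min(n, 512L))
  cnn_bn_recalibrate_cpp(params, X[idx, , , drop = FALSE],
                         spec$conv_kernels, spec$pool_after,
                         spec$in_channels)
}

# train on (X, y) with optional validation early stopping; targets are
# standardized internally so the identity-output head starts near the
# target scale
train_one <- function(X, y, Xval, yval, spec, settings, seed) {
  mu <- mean(y)
  sdv <- stats::sd(y)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  yz <- (y - mu) / sdv
  params <- init_params(spec, seed)
  state <- init_bn_state(spec)
  opt <- adam_init(params)
  best <- list(mse = Inf, params = params, state = state, epoch = 0L)
  wait <- 0L
  n <- length(yz)
  with_seed(derive_seed(seed, 999L), {
    for (ep in seq_len(settings$max_epochs)) {
      ord <- sample(n)
      for (b0 in seq(1L, n, by = settings$batch_size)) {
        idx <- ord[b0:min(n, b0 + settings$batch_size - 1L)]
        step <- cnn_train_step_cpp(params, state, X[idx, , , drop = FALSE],
                                   yz[idx], spec$conv_kernels,
                                   spec$pool_after, spec$in_channels)
        state <- step$state
        if (!is.finite(step$loss)) {
          stop("training aborted: non-finite loss at epoch ", ep, call. = FALSE)
        }
        st <- adam_step(params, step$grads, opt, settings$learning_rate)
        params <- st$params
        opt <- st$state
      }
      state_eval <- recalibrate_bn(params, X, spec)
      if (!is.null(Xval)) {
        pv <- predict_raw(params, state_eval, spec, Xval) * sdv + mu
        vmse <- mean((pv - yval)^2)
        if (vmse < best$mse - 1e-10) {
          best <- list(mse = vmse, params = params, state = state_eval,
                       epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= settings$early_stop_patience) break
        }
      } else {
        best <- list(mse = NA_real_, params = params, state = state_eval,
                     epoch = ep)
      }
    }
  })
  c(best, list(target_mean = mu, target_sd = sdv))
}

#' Train the CNN regressor with k-fold cross-validated model selection
#'
#' For each cross-validation fold the model is trained on the remaining
#' folds and validated on the held-out fold; the fold-model with the lowest
#' validation MSE is returned as the selected ("optimal") model. Training is
#' deterministic given the settings seed (per-fold initialization and
#' data-order streams are derived from it).
#'
#' @param epochs An `epoch_set` (one session only).
#' @param plan A [split_train_test()] plan with folds from [make_cv_folds()].
#' @param spec An [architecture_spec()].
#' @param settings A [train_settings()]; `target` picks SBP or DBP.
#' @param refit_full_train After selection, retrain the chosen configuration
#'   on the whole train set for the selected fold's best epoch count.
#' @return An object of class `trained_regressor`.
#' @export
train_model <- function(epochs, plan, spec = architecture_spec(),
                        settings = train_settings(),
                        refit_full_train = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(plan, "split_plan"))
  if (is.null(plan$folds)) {
    stop("plan has no cross-validation folds; call make_cv_folds() first",
         call. = FALSE)
  }
  sess <- unique(epochs$session)
  if (length(sess) > 1) {
    stop("epochs mix sessions; train one model per session", call. = FALSE)
  }
  y <- if (settings$target == "sbp") epochs$sbp else epochs$dbp
  X <- epochs_to_array(epochs, spec$input_len)

  k <- length(plan$folds)
  fold_history <- numeric(k)
  fold_models <- vector("list", k)
  for (j in seq_len(k)) {
    val_idx <- plan$folds[[j]]
    tr_idx <- setdiff(plan$train, val_idx)
    fit <- train_one(X[tr_idx, , , drop = FALSE], y[tr_idx],
                     X[val_idx, , , drop = FALSE], y[val_idx],
                     spec, settings, derive_seed(settings$seed, j))
    fold_history[j] <- fit$mse
    fold_models[[j]] <- fit
  }
  sel <- which.min(fold_history)
  fit <- fold_models[[sel]]
  if (refit_full_train) {
    n_ep <- max(1L, fit$epoch)
    refit_settings <- settings
    refit_settings$max_epochs <- n_ep
    fit2 <- train_one(X[plan$train, , , drop = FALSE], y[plan$train],
                      NULL, NULL, spec, refit_settings,
                      derive_seed(settings$seed, sel))
    fit$params <- fit2$params
    fit$state <- fit2$state
    fit$target_mean <- fit2$target_mean
    fit$target_sd <- fit2$target_sd
  }
  structure(list(architecture = spec, params = fit$params, state = fit$state,
                 target = settings$target, session = sess,
                 fold_history = fold_history, selected_fold = sel,
                 target_mean = fit$target_mean, target_sd = fit$target_sd,
                 settings = settings),
            class = "trained_regressor")
}

#' @export
print.trained_regressor <- function(x, ...) {
  cat(sprintf("<trained_regressor> target %s, session %s; %d folds, selected %d (val MSE %.2f mmHg^2)\n",
              toupper(x$target), x$session, length(x$fold_history),
              x$selected_fold, x$fold_history[x$selected_fold]))
  invisible(x)
}

#' Predict blood pressure for phase epochs
#'
#' Runs the network in inference mode (batch normalization uses running
#' statistics), so a prediction does not depend on which other epochs share
#' its batch.
#'
#' @param model A [train_model()] result.
#' @param epochs An `epoch_set` matching the model's input geometry and
#'   session.
#' @return Numeric vector of per-epoch estimates, mmHg.
#' @export
predict_bp <- function(model, epochs) {
  stopifnot(inherits(model, "trained_regressor"), inherits(epochs, "epoch_set"))
  sess <- unique(epochs$session)
  if (!identical(sess, model$session)) {
    stop("epoch session (", paste(sess, collapse = ","),
         ") does not match the model session (", model$session, ")",
         call. = FALSE)
  }
  X <- epochs_to_array(epochs, model$architecture$input_len)
  predict_raw(model$params, model$state, model$architecture, X) *
    model$target_sd + model$target_mean
}

#' Save / load a trained regressor as a plain-text model directory
#'
#' Writes `architecture.json`, `meta.json`, `weights.csv` (flat name/value
#' pairs), `bn_state.csv`, and `training_log.csv` (per-fold validation MSE).
#'
#' @param model A `trained_regressor`.
#' @param dir Output directory (created if missing).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(model$architecture),
                       file.path(dir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(target = model$target, session = model$session,
         selected_fold = model$selected_fold,
         target_mean = model$target_mean, target_sd = model$target_sd,
         settings = unclass(model$settings)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  flat <- function(p) data.frame(
    name = rep(names(p), vapply(p, length, numeric(1))),
    value = unlist(lapply(p, as.numeric), use.names = FALSE))
  utils::write.csv(flat(model$params), file.path(dir, "weights.csv"),
                   row.names = FALSE)
  utils::write.csv(flat(model$state), file.path(dir, "bn_state.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(fold = seq_along(model$fold_history),
                              val_mse = model$fold_history),
                   file.path(dir, "training_log.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  arch <- jsonlite::read_json(file.path(dir, "architecture.json"),
                              simplifyVector = TRUE)
  spec <- architecture_spec(arch$input_len, arch$in_channels,
                            arch$conv_filters, arch$conv_kernels,
                            arch$conv_stride, arch$pool_after,
                            arch$pool_factor)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  unflat <- function(df, template) {
    out <- template
    for (nm in names(template)) {
      v <- df$value[df$name == nm]
      stopifnot(length(v) == length(template[[nm]]))
      dm <- dim(template[[nm]])
      out[[nm]] <- if (is.null(dm)) v else array(v, dm)
    }
    out
  }
  wdf <- utils::read.csv(file.path(dir, "weights.csv"))
  sdf <- utils::read.csv(file.path(dir, "bn_state.csv"))
  log <- utils::read.csv(file.path(dir, "training_log.csv"))
  st <- meta$settings
  structure(list(
    architecture = spec,
    params = unflat(wdf, init_params(spec, 1L)),
    state = unflat(sdf, init_bn_state(spec)),
    target = meta$target, session = meta$session,
    fold_history = log$val_mse, selected_fold = meta$selected_fold,
    target_mean = meta$target_mean, target_sd = meta$target_sd,
    settings = train_settings(st$learning_rate, st$batch_size, st$max_epochs,
                              st$early_stop_patience, st$seed, st$target)),
    class = "trained_regressor")
}
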