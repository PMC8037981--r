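# Epoch construction and train/test/fold planning.
#
# The regression model consumes 10-s, two-channel wrapped-phase epochs
# (2 x 1000 samples at 100 Hz), each paired with one cuff reference SBP/DBP.
# Splits are 8:2 train:test with 10-fold cross-validation inside the train
# set; sessions (rest vs recovery) are never pooled in one plan because the
# models are trained per session.

#' Construct a set of phase epochs
#'
#' @param phase_back,phase_seat Numeric matrices, one row per epoch.
#' @param sbp,dbp Reference pressures, mmHg, one per epoch.
#' @param session Session label(s), `"rest"` or `"recovery"`.
#' @param subject_id Subject label(s).
#' @param fs Sampling rate, Hz.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(phase_back, phase_seat, sbp, dbp,
                      session = "rest", subject_id = "s1", fs = 100) {
  phase_back <- as.matrix(phase_back)
  phase_seat <- as.matrix(phase_seat)
  n <- nrow(phase_back)
  stopifnot(identical(dim(phase_back), dim(phase_seat)),
            length(sbp) == n, length(dbp) == n, all(sbp > dbp))
  structure(list(phase_back = phase_back, phase_seat = phase_seat,
                 sbp = as.numeric(sbp), dbp = as.numeric(dbp),
                 session = rep_len(as.character(session), n),
                 subject_id = rep_len(as.character(subject_id), n),
                 fs = fs),
            class = "epoch_set")
}

#' @export
length.epoch_set <- function(x) nrow(x$phase_back)

#' @export
`[.epoch_set` <- function(x, i) {
  epoch_set(x$phase_back[i, , drop = FALSE], x$phase_seat[i, , drop = FALSE],
            x$sbp[i], x$dbp[i], x$session[i], x$subject_id[i], x$fs)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d samples/channel at %g Hz; sessions: %s\n",
              length(x), ncol(x$phase_back), x$fs,
              paste(unique(x$session), collapse = ", ")))
  invisible(x)
}

#' Combine epoch sets (e.g. across subjects)
#'
#' @param ... `epoch_set` objects with matching epoch length and rate.
#' @return A single `epoch_set`.
#' @export
bind_epoch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "epoch_set")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1)
  ncols <- vapply(sets, function(s) ncol(s$phase_back), numeric(1))
  stopifnot(length(unique(ncols)) == 1)
  epoch_set(do.call(rbind, lapply(sets, `[[`, "phase_back")),
            do.call(rbind, lapply(sets, `[[`, "phase_seat")),
            unlist(lapply(sets, `[[`, "sbp")),
            unlist(lapply(sets, `[[`, "dbp")),
            unlist(lapply(sets, `[[`, "session")),
            unlist(lapply(sets, `[[`, "subject_id")),
            sets[[1]]$fs)
}

#' Cut two phase channels into reference-aligned epochs
#'
#' One epoch per blood-pressure reference, starting at the reference's start
#' time and spanning `epoch_s` seconds (1000 samples per channel at 100 Hz).
#'
#' @param phase_back,phase_seat `phase_series` objects of equal length/rate.
#' @param refs Data frame with columns `epoch_start_s`, `sbp`, `dbp`.
#' @param epoch_s Epoch length, seconds.
#' @param session,subject_id Labels attached to every produced epoch.
#' @return An `epoch_set` with one row per reference.
#' @export
segment_epochs <- function(phase_back, phase_seat, refs, epoch_s = 10,
                           session = "rest", subject_id = "s1") {
  stopifnot(inherits(phase_back, "phase_series"),
            inherits(phase_seat, "phase_series"))
  if (length(phase_back$phase) != length(phase_seat$phase) ||
      abs(phase_back$fs - phase_seat$fs) > 1e-9) {
    stop("phase channels differ in length or sampling rate", call. = FALSE)
  }
  fs <- phase_back$fs
  n <- length(phase_back$phase)
  len <- round(epoch_s * fs)
  starts <- round(refs$epoch_start_s * fs) + 1L
  bad <- which(starts < 1L | starts + len - 1L > n)
  if (length(bad) > 0) {
    stop("reference window(s) ", paste(bad, collapse = ", "),
         " (start ", paste(refs$epoch_start_s[bad], collapse = ", "),
         " s) fall outside the recording", call. = FALSE)
  }
  idx <- vapply(starts, function(s) s:(s + len - 1L), integer(len))
  epoch_set(t(matrix(phase_back$phase[idx], nrow = len)),
            t(matrix(phase_seat$phase[idx], nrow = len)),
            refs$sbp, refs$dbp, session, subject_id, fs)
}

#' 8:2 train/test split plan
#'
#' Splits an epoch set into train and test indices, either per epoch (the
#' default) or per subject (no subject contributes to both sides; use this
#' mode to support claims about generalisation to new subjects). Refuses
#' mixed-session input: models are trained separately per session.
#'
#' @param epochs An `epoch_set`.
#' @param ratio Train fraction (default 0.8).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @param mode `"epoch"` or `"subject"`.
#' @return An object of class `split_plan`: list with integer vectors
#'   `train`, `test`, optional `folds`, plus `seed` and `mode`.
#' @export
split_train_test <- function(epochs, ratio = 0.8, seed = 1L,
                             mode = c("epoch", "subject")) {
  mode <- match.arg(mode)
  n <- length(epochs)
  if (n < 10) stop("need at least 10 epochs to split", call. = FALSE)
  if (length(unique(epochs$session)) > 1) {
    stop("epochs mix sessions; build one plan per session", call. = FALSE)
  }
  if (mode == "epoch") {
    n_train <- round(ratio * n)
    train <- with_seed(seed, sort(sample.int(n, n_train)))
  } else {
    subj <- unique(epochs$subject_id)
    if (length(subj) < 5) {
      stop("subject mode needs at least 5 subjects", call. = FALSE)
    }
    n_test_subj <- max(1L, round((1 - ratio) * length(subj)))
    test_subj <- with_seed(seed, sample(subj, n_test_subj))
    train <- which(!(epochs$subject_id %in% test_subj))
  }
  structure(list(train = train, test = setdiff(seq_len(n), train),
                 folds = NULL, seed = as.integer(seed), mode = mode),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test (%s mode, seed %d)%s\n",
              length(x$train), length(x$test), x$mode, x$seed,
              if (is.null(x$folds)) "" else
                sprintf(", %d CV folds", length(x$folds))))
  invisible(x)
}

#' Add k cross-validation folds to a split plan
#'
#' Partitions the train set into `k` disjoint folds of equal size (within
#' one epoch), for k-fold cross-validated model selection.
#'
#' @param plan A [split_train_test()] plan.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return The plan with a `folds` element (list of k index vectors).
#' @export
make_cv_folds <- function(plan, k = 10, seed = plan$seed) {
  stopifnot(inherits(plan, "split_plan"))
  n_train <- length(plan$train)
  if (k > n_train) {
    stop("k (", k, ") exceeds the train set size (", n_train, ")",
         call. = FALSE)
  }
  perm <- with_seed(seed, sample(plan$train))
  sizes <- rep(n_train %/% k, k) + (seq_len(k) <= n_train %% k)
  plan$folds <- split(perm, rep(seq_len(k), times = sizes))
  names(plan$folds) <- NULL
  plan
}

#' Write / read an epoch bundle as CSV
#'
#' One row per epoch: `subject_id, session, sbp, dbp`, then the back-channel
#' phases and the seat-channel phases.
#' @param epochs An `epoch_set`.
#' @param path File path.
#' @export
write_epoch_bundle <- function(epochs, path) {
  df <- data.frame(subject_id = epochs$subject_id, session = epochs$session,
                   sbp = epochs$sbp, dbp = epochs$dbp)
  df <- cbind(df, as.data.frame(epochs$phase_back),
              as.data.frame(epochs$phase_seat))
  L <- ncol(epochs$phase_back)
  names(df)[-(1:4)] <- c(paste0("pb", seq_len(L)), paste0("ps", seq_len(L)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epoch_bundle
#' @param fs Sampling rate to attach on read.
#' @export
read_epoch_bundle <- function(path, fs = 100) {
  df <- utils::read.csv(path)
  pb <- as.matrix(df[, grepl("^pb", names(df))])
  ps <- as.matrix(df[, grepl("^ps", names(df))])
  epoch_set(pb, ps, df$sbp, df$dbp, df$session, df$subject_id, fs)
}

#' Write / read a split plan as JSON
#'
#' @param plan A `split_plan`.
#' @param path File path.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train = as.integer(x$train), test = as.integer(x$test),
                 folds = if (is.null(x$folds)) NULL else
                   lapply(x$folds, as.integer),
                 seed = as.integer(x$seed), mode = x$mode),
            class = "split_plan")
}
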