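# Epoch segmentation, splits, and cross-validation folds

make_phase_pair <- function(dur_s, fs = 100) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  list(pb = hilbert_phase(cos(2 * pi * 2 * t), fs),
       ps = hilbert_phase(cos(2 * pi * 2 * (t - 0.03)), fs))
}

make_epochs <- function(n, n_subj = n, session = "rest", len = 1000) {
  set.seed(100 + n)
  epoch_set(matrix(stats::runif(n * len, -pi, pi), n),
            matrix(stats::runif(n * len, -pi, pi), n),
            sbp = stats::rnorm(n, 115, 10), dbp = stats::rnorm(n, 75, 5),
            session = session,
            subject_id = rep_len(sprintf("s%02d", seq_len(n_subj)), n))
}

test_that("a rest recording yields five 1000-sample epochs", {
  pp <- make_phase_pair(50)
  refs <- data.frame(epoch_start_s = seq(0, 40, by = 10),
                     sbp = rep(115, 5), dbp = rep(75, 5))
  eps <- segment_epochs(pp$pb, pp$ps, refs)
  expect_length(eps, 5)
  expect_equal(ncol(eps$phase_back), 1000)
  expect_true(all(eps$phase_back > -pi & eps$phase_back <= pi))
})

test_that("a recovery recording yields ten epochs", {
  pp <- make_phase_pair(100)
  refs <- data.frame(epoch_start_s = seq(0, 90, by = 10),
                     sbp = 155 - (0:9), dbp = rep(85, 10))
  eps <- segment_epochs(pp$pb, pp$ps, refs, session = "recovery")
  expect_length(eps, 10)
  expect_equal(eps$sbp, refs$sbp)
})

test_that("an out-of-range reference window is rejected by index", {
  pp <- make_phase_pair(50)
  refs <- data.frame(epoch_start_s = c(0, 45), sbp = c(115, 115),
                     dbp = c(75, 75))
  expect_error(segment_epochs(pp$pb, pp$ps, refs), "2")
  pp2 <- make_phase_pair(50)
  pp2$ps$phase <- pp2$ps$phase[-1]
  expect_error(segment_epochs(pp$pb, pp2$ps, refs[1, ]), "length")
})

test_that("the 8:2 split has the right sizes and is seed-deterministic", {
  eps <- make_epochs(150)
  plan <- split_train_test(eps, seed = 3)
  expect_length(plan$train, 120)
  expect_length(plan$test, 30)
  expect_length(intersect(plan$train, plan$test), 0)
  plan2 <- split_train_test(eps, seed = 3)
  expect_identical(plan, plan2)
  expect_false(identical(plan, split_train_test(eps, seed = 4)))
})

test_that("subject-mode splits keep every subject on one side", {
  eps <- make_epochs(150, n_subj = 30)
  plan <- split_train_test(eps, seed = 5, mode = "subject")
  train_subj <- unique(eps$subject_id[plan$train])
  test_subj <- unique(eps$subject_id[plan$test])
  expect_length(intersect(train_subj, test_subj), 0)
  # exhaustive membership audit
  for (i in plan$test) expect_false(eps$subject_id[i] %in% train_subj)
})

test_that("split preconditions are enforced", {
  expect_error(split_train_test(make_epochs(8)), "at least 10")
  expect_error(split_train_test(make_epochs(20, n_subj = 3),
                                mode = "subject"), "5 subjects")
  mixed <- make_epochs(20)
  mixed$session[1:10] <- "recovery"
  expect_error(split_train_test(mixed), "mix")
})

test_that("cross-validation folds partition the train set evenly", {
  eps <- make_epochs(150)
  plan <- make_cv_folds(split_train_test(eps, seed = 6), k = 10)
  expect_length(plan$folds, 10)
  expect_true(all(lengths(plan$folds) == 12))
  # 125 train epochs -> five folds of 13 and five of 12
  eps2 <- make_epochs(156)
  plan2 <- make_cv_folds(split_train_test(eps2, seed = 6), k = 10)
  expect_length(plan2$train, 125)
  expect_equal(sort(lengths(plan2$folds), decreasing = TRUE),
               c(rep(13, 5), rep(12, 5)))
  # union-and-pairwise-intersection audit
  expect_setequal(unlist(plan$folds), plan$train)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_length(intersect(plan$folds[[i]], plan$folds[[j]]), 0)
  }
  expect_error(make_cv_folds(split_train_test(make_epochs(12)), k = 11), "exceeds")
})

test_that("epoch bundles and split plans round-trip through files", {
  eps <- make_epochs(12, len = 40)
  f <- tempfile(fileext = ".csv")
  write_epoch_bundle(eps, f)
  eps2 <- read_epoch_bundle(f)
  expect_equal(eps2$phase_back, eps$phase_back, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(eps2$sbp, eps$sbp, tolerance = 1e-9)
  expect_identical(eps2$subject_id, eps$subject_id)

  plan <- make_cv_folds(split_train_test(eps, seed = 9), k = 3)
  fp <- tempfile(fileext = ".json")
  write_split_plan(plan, fp)
  expect_identical(read_split_plan(fp), plan)
})
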