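# End-to-end study replica: simulate cohort -> filter -> decompose -> phase
# -> epochs -> split -> train -> evaluate, reproducible from one seed.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort of subjects
#'
#' Draws per-subject resting physiology (age, heart rate, resting pressures)
#' from population-style distributions, then simulates one session per
#' subject with [simulate_session()]. A single cohort seed fans out
#' deterministically into per-subject simulation seeds.
#'
#' @param n_subjects Number of subjects.
#' @param session `"rest"` or `"recovery"`.
#' @param seed Cohort seed.
#' @param pop_ref_sbp Population reference pressure (mmHg): the pressure at
#'   which a subject's baseline transit delay equals `transit_base_ms`.
#'   Subjects whose resting SBP sits above it get proportionally shorter
#'   baseline delays (stiffer arterial path), so absolute pressure — not
#'   only within-session change — is encoded in the inter-channel timing.
#' @param ... Overrides passed on to every subject's [sim_config()] (e.g.
#'   `noise_sd`, `duration_s`).
#' @return List of per-subject lists: `subject_id`, `config`, `recording`,
#'   `refs`.
#' @export
simulate_cohort <- function(n_subjects, session = "rest", seed = 1L,
                            pop_ref_sbp = 115, ...) {
  draws <- with_seed(derive_seed(seed, 1L), {
    age <- pmin(pmax(round(stats::rnorm(n_subjects, 35, 12)), 20), 59)
    sbp <- pmin(pmax(stats::rnorm(n_subjects, 115, 10), 95), 140)
    dbp <- pmin(pmax(sbp - stats::rnorm(n_subjects, 40, 5), 55), sbp - 20)
    hr <- pmin(pmax(stats::rnorm(n_subjects, 65, 7), 50), 90)
    list(age = age, sbp = sbp, dbp = dbp, hr = hr)
  })
  dots <- list(...)
  base0 <- dots$transit_base_ms %||% 30
  slope <- dots$transit_slope_ms_per_mmhg %||% -0.5
  lapply(seq_len(n_subjects), function(i) {
    args <- dots
    # per-subject baseline delay anchored to the population reference, so
    # the subject's absolute resting pressure shows in the transit timing
    args$transit_base_ms <- base0 + slope * (draws$sbp[i] - pop_ref_sbp)
    cfg <- do.call(sim_config, c(list(
      subject_age = draws$age[i],
      resting_hr = draws$hr[i],
      resting_sbp = draws$sbp[i],
      resting_dbp = draws$dbp[i],
      session = session,
      seed = derive_seed(seed, 100L + i)), args))
    sim <- simulate_session(cfg)
    list(subject_id = sprintf("s%02d", i), config = cfg,
         recording = sim$recording, refs = sim$refs)
  })
}

#' Run phase extraction on one subject's recording
#'
#' Band-pass filter, EMD, and Hilbert phase of IMF(1) for both channels,
#' then segmentation into reference-aligned epochs.
#'
#' @param subject One element of a [simulate_cohort()] result (or a list
#'   with `recording`, `refs`, `subject_id`).
#' @param fspec A [filter_spec()].
#' @param sift A [sift_settings()].
#' @param epoch_s Epoch length, seconds.
#' @return An `epoch_set` for the subject.
#' @export
subject_epochs <- function(subject, fspec = NULL, sift = sift_settings(),
                           epoch_s = 10) {
  rec <- subject$recording
  if (is.null(fspec)) fspec <- filter_spec(fs = rec$fs)
  filt <- bandpass_filter(rec, fspec)
  ph <- recording_phase(filt, sift)
  segment_epochs(ph$phase_back, ph$phase_seat, subject$refs,
                 epoch_s = epoch_s, session = rec$session,
                 subject_id = subject$subject_id)
}

#' Default study configuration
#'
#' @param n_subjects Cohort size (30, matching a typical protocol of this
#'   kind).
#' @param sessions Sessions to run (`"rest"`, `"recovery"` or both).
#' @param targets Pressure targets to train (`"sbp"`, `"dbp"`).
#' @param seed Top-level seed; all stage seeds derive from it.
#' @param split_mode `"epoch"` or `"subject"`.
#' @param cv_k Cross-validation folds.
#' @param max_epochs,early_stop_patience,batch_size Training budget.
#' @param sim Named list of [sim_config()] overrides for every subject.
#' @return A named list accepted by [run_study()].
#' @export
study_config <- function(n_subjects = 30, sessions = "rest",
                         targets = c("sbp", "dbp"), seed = 1L,
                         split_mode = "epoch", cv_k = 10,
                         max_epochs = 200, early_stop_patience = 20,
                         batch_size = 32, sim = list()) {
  list(n_subjects = n_subjects, sessions = sessions, targets = targets,
       seed = as.integer(seed), split_mode = split_mode, cv_k = cv_k,
       max_epochs = max_epochs, early_stop_patience = early_stop_patience,
       batch_size = batch_size, sim = sim)
}

#' Run the full study replica
#'
#' Simulates the cohort, extracts two-channel phase epochs, builds the 8:2
#' split with k-fold cross-validation, trains one CNN per target and
#' session, predicts the held-out test epochs, and writes per-model error
#' summaries plus a run manifest (configuration snapshot, stage seeds, and
#' checksums of every written file).
#'
#' @param config A [study_config()] list, or the path of a YAML file with
#'   the same fields.
#' @param out_dir Output directory; created if missing. `NULL` keeps
#'   everything in memory.
#' @param quiet Suppress progress messages.
#' @return List with `summaries` (per session/target `error_summary`
#'   objects), `models`, `epoch_sets`, `plans`, and `manifest`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- study_config()
  config <- utils::modifyList(defaults, config)
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  written <- character(0)
  summaries <- list()
  models <- list()
  epoch_sets <- list()
  plans <- list()
  stage_seeds <- list()

  for (sess in config$sessions) {
    sim_seed <- derive_seed(config$seed, match(sess, c("rest", "recovery")))
    stage_seeds[[paste0("simulate_", sess)]] <- sim_seed
    say("[%s] simulating %d subjects", sess, config$n_subjects)
    cohort <- do.call(simulate_cohort,
                      c(list(n_subjects = config$n_subjects, session = sess,
                             seed = sim_seed), config$sim))
    say("[%s] filtering, decomposing, extracting phase", sess)
    eps <- bind_epoch_sets(lapply(cohort, subject_epochs))
    epoch_sets[[sess]] <- eps

    split_seed <- derive_seed(config$seed, 10L + match(sess, c("rest", "recovery")))
    stage_seeds[[paste0("split_", sess)]] <- split_seed
    plan <- split_train_test(eps, ratio = 0.8, seed = split_seed,
                             mode = config$split_mode)
    plan <- make_cv_folds(plan, k = config$cv_k)
    plans[[sess]] <- plan

    for (target in config$targets) {
      train_seed <- derive_seed(config$seed,
                                100L + match(sess, c("rest", "recovery")) * 10L +
                                  match(target, c("sbp", "dbp")))
      stage_seeds[[paste0("train_", sess, "_", target)]] <- train_seed
      say("[%s] training %s model (%d-fold CV)", sess, toupper(target),
          config$cv_k)
      settings <- train_settings(batch_size = config$batch_size,
                                 max_epochs = config$max_epochs,
                                 early_stop_patience = config$early_stop_patience,
                                 seed = train_seed, target = target)
      model <- train_model(eps, plan, architecture_spec(), settings)
      models[[paste0(sess, "_", target)]] <- model

      test_eps <- eps[plan$test]
      pred <- predict_bp(model, test_eps)
      ref <- if (target == "sbp") test_eps$sbp else test_eps$dbp
      es <- error_summary(pred, ref, target = target, session = sess)
      summaries[[paste0(sess, "_", target)]] <- es
      say("[%s] %s: ME = %.2f, SD = %.2f mmHg (AAMI %s)", sess,
          toupper(target), es$me, es$sd, if (es$aami_pass) "pass" else "FAIL")

      if (!is.null(out_dir)) {
        f <- file.path(out_dir, sprintf("summary_%s_%s.csv", sess, target))
        write_error_summary(es, f)
        written <- c(written, f)
        ba <- bland_altman_table(pred, ref)
        f2 <- file.path(out_dir, sprintf("bland_altman_%s_%s.csv", sess, target))
        utils::write.csv(ba$rows, f2, row.names = FALSE)
        written <- c(written, f2)
      }
    }
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, sprintf("split_plan_%s.json", sess))
      write_split_plan(plan, f)
      written <- c(written, f)
    }
  }

  manifest <- list(
    tool = paste0("bcgbp ", as.character(utils::packageVersion("bcgbp"))),
    config = config[setdiff(names(config), "sim")],
    sim_overrides = config$sim,
    stage_seeds = stage_seeds,
    checksums = if (length(written)) as.list(tools::md5sum(written)) else list()
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(summaries = summaries, models = models, epoch_sets = epoch_sets,
       plans = plans, manifest = manifest)
}
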