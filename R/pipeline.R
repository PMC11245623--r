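#' Configuration for an end-to-end charring experiment
#'
#' Bundles everything [run_experiment()] needs: the variety panel, the
#' training charring condition, the test conditions for the probe variety,
#' pool sizes, tournament settings, the calibration-curve source and the
#' sorting threshold. One top-level seed is fanned out to per-stage child
#' seeds by a fixed derivation, so e.g. changing `n_sessions` does not
#' perturb cloud generation.
#'
#' @param varieties named list of [variety_shape()]s (>= 2).
#' @param n_seeds_per_group pips per variety in the training library
#'   (>= 2).
#' @param n_points surface points per cloud.
#' @param train_condition [charring_condition()] of the training library.
#' @param test_conditions list of [charring_condition()]s for the probe
#'   variety.
#' @param test_variety name of the probe variety (must be in `varieties`).
#' @param n_sessions tournament sessions (>= 1).
#' @param train_fraction per-class subsample fraction per session.
#' @param gamma LDA regularization.
#' @param curve_source `"reference"` (fit to the packaged condition means)
#'   or `"simulated"` (fit to means measured on freshly generated charred
#'   batches).
#' @param threshold_C sorting acceptance threshold in degrees C.
#' @param n_unknown number of unknown-history seeds to generate and sort
#'   (0 disables the sorting stage).
#' @param unknown_mild_fraction fraction of the unknowns charred at mild
#'   (<= 250 degrees C) conditions.
#' @param rng_seed integer top-level seed.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(varieties = default_varieties(),
                              n_seeds_per_group = 10, n_points = 300,
                              train_condition = charring_condition(200, 2),
                              test_conditions = list(
                                charring_condition(200, 2),
                                charring_condition(250, 2),
                                charring_condition(300, 2)),
                              test_variety = names(varieties)[1],
                              n_sessions = 25, train_fraction = 0.8,
                              gamma = 1e-3, curve_source = "reference",
                              threshold_C = 275, n_unknown = 0,
                              unknown_mild_fraction = 0.54, rng_seed = 1) {
  if (length(varieties) < 2L)
    stop_carposort("need >= 2 varieties", class = "carposort_parameter_error")
  if (n_seeds_per_group < 2L)
    stop_carposort("n_seeds_per_group must be >= 2",
                   class = "carposort_parameter_error")
  if (n_sessions < 1L)
    stop_carposort("n_sessions must be >= 1",
                   class = "carposort_parameter_error")
  if (!test_variety %in% names(varieties))
    stop_carposort("test_variety '%s' not in the variety panel",
                   test_variety, class = "carposort_parameter_error")
  curve_source <- match.arg(curve_source, c("reference", "simulated"))
  structure(list(varieties = varieties,
                 n_seeds_per_group = n_seeds_per_group,
                 n_points = n_points, train_condition = train_condition,
                 test_conditions = test_conditions,
                 test_variety = test_variety, n_sessions = n_sessions,
                 train_fraction = train_fraction, gamma = gamma,
                 curve_source = curve_source, threshold_C = threshold_C,
                 n_unknown = n_unknown,
                 unknown_mild_fraction = unknown_mild_fraction,
                 rng_seed = rng_seed),
            class = "experiment_config")
}

#' Generate a pool of seeds with unknown (mixed) charring history
#'
#' Emulates an assemblage of archaeological pips: a `mild_fraction` share
#' charred at conditions up to 250 degrees C and the rest at 300-350
#' degrees C, varieties and exact conditions cycling over the calibrated
#' grid, with per-seed variability at the calibrated CVs.
#'
#' @param n number of seeds.
#' @param model deformation model.
#' @param varieties list of shapes to draw from (default the two
#'   calibrated cultivars).
#' @param mild_fraction fraction charred at mild conditions.
#' @param n_points points per cloud.
#' @param rng_seed integer seed.
#' @return list with `clouds`, and per-seed `variety`, `true_condition`
#'   labels.
#' @export
generate_unknown_pool <- function(n, model,
                                  varieties = list(cabernet_shape(),
                                                   tzuriman_shape()),
                                  mild_fraction = 0.54, n_points = 400,
                                  rng_seed = 1) {
  n_mild <- round(n * mild_fraction)
  mild <- list(charring_condition(200, 2), charring_condition(200, 8),
               charring_condition(250, 2), charring_condition(250, 8))
  harsh <- list(charring_condition(300, 2), charring_condition(300, 8),
                charring_condition(350, 2), charring_condition(350, 8))
  conds <- c(rep_len(mild, n_mild), rep_len(harsh, n - n_mild))
  clouds <- vector("list", n)
  vlab <- character(n)
  clab <- character(n)
  for (i in seq_len(n)) {
    sh <- varieties[[(i - 1L) %% length(varieties) + 1L]]
    batch <- generate_seed_batch(sh, 1L, conds[[i]], model,
                                 n_points = n_points,
                                 rng_seed = derive_seed(rng_seed, i))
    clouds[[i]] <- batch[[1]]
    vlab[i] <- sh$name
    clab[i] <- format(conds[[i]])
  }
  list(clouds = clouds, variety = vlab, true_condition = clab)
}

#' Run the end-to-end charring experiment
#'
#' Generates the training library (all varieties charred at the training
#' condition) and per-condition probe sets, preprocesses every cloud
#' (canonical pose, equal length), computes the all-pairs ICP-MSE cache,
#' runs the classification tournament for each test condition, fits the
#' ratio-versus-temperature curve, and — when `n_unknown > 0` — generates
#' and sorts an unknown-history pool. The report is identical for
#' identical config and seed.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory: stage artifacts (morphometrics CSV,
#'   curve JSON, tournament JSON, sorting CSV) are written there.
#' @param verbose print per-stage progress (default FALSE).
#' @return an object of class `experiment_report`: list with
#'   `tournaments` (one [tournament()] result per test condition, named by
#'   condition), `accuracy_by_condition`, `curve`, `sorting` (or NULL),
#'   `config`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t_stage <- function(expr, what) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", what, conditionMessage(e)),
           call. = FALSE))
    say("stage %-12s %.1fs", what, as.numeric(Sys.time() - t0, "secs"))
    out
  }
  model <- t_stage(calibrate_deformation(), "calibrate")
  seed <- config$rng_seed

  train <- t_stage({
    pools <- lapply(seq_along(config$varieties), function(k) {
      generate_seed_batch(config$varieties[[k]], config$n_seeds_per_group,
                          config$train_condition, model,
                          n_points = config$n_points,
                          rng_seed = derive_seed(seed, 100L + k))
    })
    list(clouds = do.call(c, lapply(pools, unclass)),
         labels = rep(names(config$varieties),
                      each = config$n_seeds_per_group))
  }, "train-pool")

  tests <- t_stage({
    lapply(seq_along(config$test_conditions), function(k) {
      generate_seed_batch(config$varieties[[config$test_variety]],
                          config$n_seeds_per_group,
                          config$test_conditions[[k]], model,
                          n_points = config$n_points,
                          rng_seed = derive_seed(seed, 200L + k))
    })
  }, "test-pools")

  prep <- t_stage({
    all_clouds <- c(train$clouds, do.call(c, lapply(tests, unclass)))
    preprocess_clouds(all_clouds)
  }, "preprocess")

  n_tr <- length(train$clouds)
  n_te <- config$n_seeds_per_group
  train_prepped <- prep[seq_len(n_tr)]

  mse_tt <- t_stage(build_train_matrix(train_prepped), "icp-train")

  tournaments <- t_stage({
    res <- lapply(seq_along(config$test_conditions), function(k) {
      te <- prep[n_tr + (k - 1L) * n_te + seq_len(n_te)]
      te_block <- build_test_matrix(te, train_prepped)
      cache <- matrix(0, n_tr + n_te, n_tr + n_te)
      cache[seq_len(n_tr), seq_len(n_tr)] <- mse_tt
      cache[n_tr + seq_len(n_te), seq_len(n_tr)] <- te_block
      tournament(train_prepped, train$labels, te,
                 rep(config$test_variety, n_te),
                 n_sessions = config$n_sessions,
                 rng_seed = derive_seed(seed, 300L),
                 train_fraction = config$train_fraction,
                 gamma = config$gamma, mse_cache = cache)
    })
    names(res) <- vapply(config$test_conditions, format, character(1))
    res
  }, "tournament")

  curve <- t_stage({
    if (config$curve_source == "reference") {
      fit_curve(reference_curve_observations())
    } else {
      obs <- do.call(rbind, lapply(
        reference_curve_observations()$temperature_C |> unique(),
        function(Tc) {
          do.call(rbind, lapply(c(2, 8), function(dur) {
            ratios <- vapply(
              list(cabernet_shape(), tzuriman_shape()), function(sh) {
                b <- generate_seed_batch(
                  sh, 5L, charring_condition(Tc, dur), model,
                  n_points = config$n_points,
                  rng_seed = derive_seed(seed, 400L + Tc + dur))
                mean(morphometrics_table(preprocess_clouds(b))$lw_ratio)
              }, numeric(1))
            data.frame(temperature_C = Tc, duration_h = dur,
                       mean_lw_ratio = ratios)
          }))
        }))
      fit_curve(obs)
    }
  }, "curve-fit")

  sorting <- NULL
  if (config$n_unknown > 0) {
    sorting <- t_stage({
      pool <- generate_unknown_pool(
        config$n_unknown, model,
        mild_fraction = config$unknown_mild_fraction,
        n_points = config$n_points,
        rng_seed = derive_seed(seed, 500L))
      morph <- morphometrics_table(preprocess_clouds(pool$clouds))
      morph$group <- pool$variety
      sort_seeds(morph, curve, threshold_C = config$threshold_C)
    }, "sorting")
  }

  report <- structure(list(
    tournaments = tournaments,
    accuracy_by_condition = vapply(tournaments,
                                   function(t) t$accumulative_accuracy,
                                   numeric(1)),
    curve = curve, sorting = sorting, config = config),
    class = "experiment_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_curve_json(curve, file.path(out_dir, "curve.json"))
    jsonlite::write_json(
      lapply(tournaments, function(t)
        list(per_session_accuracy = t$per_session_accuracy,
             accumulative_accuracy = t$accumulative_accuracy,
             confusion = as.data.frame.table(t$confusion_counts))),
      file.path(out_dir, "tournament.json"), auto_unbox = TRUE,
      digits = NA)
    if (!is.null(sorting))
      utils::write.csv(sorting$decisions,
                       file.path(out_dir, "sorting.csv"),
                       row.names = FALSE)
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat(sprintf("  train: %d varieties x %d pips at %s\n",
              length(x$config$varieties), x$config$n_seeds_per_group,
              format(x$config$train_condition)))
  cat("  accumulative accuracy by test condition:\n")
  for (nm in names(x$accuracy_by_condition))
    cat(sprintf("    %-10s %.1f%%\n", nm,
                100 * x$accuracy_by_condition[[nm]]))
  cat(sprintf("  curve: r = %.3f x^2 + %.3f\n", x$curve$a, x$curve$b))
  if (!is.null(x$sorting))
    cat(sprintf("  sorting: %d/%d accepted at %g degC\n",
                sum(x$sorting$decisions$accepted),
                nrow(x$sorting$decisions), x$sorting$threshold_C))
  invisible(x)
}
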