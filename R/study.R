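# Monte Carlo study harness: orchestrates population generation, truth
# computation, replicate sampling, estimation, and bias/SE summaries.

#' Simulation-study configuration
#'
#' Defaults reproduce the reference design: four structural setups, 100
#' replicate datasets of 3000 units drawn from a one-million-unit
#' population, 4 time periods, and the full estimator roster (MSM
#' coefficients; TVT outcome and change-score ATT estimators with both
#' control types; group-time DiD estimators crossed over control type,
#' covariate adjustment, and TVT-ATE sampling weighting).
#'
#' @param setups Subset of `1:4`.
#' @param m_grid Confounding-strength multipliers, subset of `1:3` typically.
#' @param n_replicates Replicate datasets per cell (default 100).
#' @param sample_n Units per replicate dataset (default 3000).
#' @param population_n Population size used both for sampling and for the
#'   truth oracle (default 1e6).
#' @param T Number of time periods (default 4).
#' @param master_seed Single integer governing everything: per-cell
#'   population seeds and per-replicate sampling seeds are split from it
#'   deterministically (see Details).
#' @param estimators Character subset of
#'   `c("msm", "tvt-outcome", "tvt-cs", "gt-did")`.
#' @param control_types Subset of `c("never", "notyet")`.
#' @param include_g1 Estimate `ATT(1, t)` with the TVT outcome estimator
#'   (the one estimator for which the first adopters are identifiable)?
#' @param covariate_lags Optional integer vector overriding
#'   [default_covariate_lags()] for every setup.
#' @param coefficients Named list of structural-coefficient overrides passed
#'   to [structural_config()].
#'
#' @details Seed splitting: `set.seed(master_seed)` followed by one
#'   `sample.int(2^31 - 1)` draw per (setup, m) population and per
#'   replicate, in cell-major order. Each replicate is therefore
#'   individually reproducible and all derived seeds stay below 2^31.
#'
#' @return An object of class `tvt_study_config`.
#' @export
study_config <- function(setups = 1:4, m_grid = 1, n_replicates = 100L,
                         sample_n = 3000L, population_n = 1e6, T = 4L,
                         master_seed = 1L,
                         estimators = c("msm", "tvt-outcome", "tvt-cs", "gt-did"),
                         control_types = c("never", "notyet"),
                         include_g1 = TRUE, covariate_lags = NULL,
                         coefficients = list()) {
  if (!length(setups) || !all(setups %in% 1:4)) {
    tvt_error("`setups` must be a subset of 1:4", "tvt_config_error")
  }
  if (!length(m_grid) || !is.numeric(m_grid)) {
    tvt_error("`m_grid` must be numeric", "tvt_config_error")
  }
  estimators <- match.arg(estimators, several.ok = TRUE)
  control_types <- match.arg(control_types,
                             c("never", "notyet"), several.ok = TRUE)
  structure(
    list(setups = as.integer(setups), m_grid = as.numeric(m_grid),
         n_replicates = .assert_count(n_replicates, "n_replicates"),
         sample_n = .assert_count(sample_n, "sample_n"),
         population_n = .assert_count(population_n, "population_n"),
         T = .assert_count(T, "T", min = 2L),
         master_seed = .assert_count(master_seed, "master_seed", min = 0L),
         estimators = estimators, control_types = control_types,
         include_g1 = isTRUE(include_g1), covariate_lags = covariate_lags,
         coefficients = coefficients),
    class = "tvt_study_config"
  )
}

#' Read a study configuration from a JSON file
#'
#' JSON with any subset of the [study_config()] arguments, e.g.
#' `{"setups": [1, 3], "m_grid": [1], "n_replicates": 100}`. A shipped
#' example reproducing the default design is at
#' `system.file("extdata", "study_config.json", package = "tvtpanel")`.
#'
#' @param path JSON file path.
#' @return A `tvt_study_config`.
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    tvt_error(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
              "tvt_config_error")
  }
  do.call(study_config, raw)
}

# Run the full estimator roster on one replicate panel. Returns a list of
# estimate rows and failure records; individual estimator failures (e.g.
# degenerate cells in a small sample) are recorded, not fatal.
.estimate_replicate <- function(panel, config, setup) {
  panel <- .panel_wide(panel)  # pivot/validate once, reuse everywhere
  lags <- config$covariate_lags %||% default_covariate_lags(setup)
  Tn <- config$T
  rows <- list()
  failures <- list()
  note_failure <- function(key, e) {
    failures[[length(failures) + 1L]] <<- data.table::data.table(
      estimator = key, message = conditionMessage(e))
  }
  models <- tryCatch(fit_propensity_models(panel, lags),
                     tvt_error = function(e) {
                       note_failure("propensity-models", e)
                       NULL
                     })
  if (is.null(models)) {
    return(list(estimates = data.table::data.table(),
                failures = data.table::rbindlist(failures)))
  }
  ate_w <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    # assign via [<- so a NULL (failed) slot does not shrink the list
    ate_w[t] <- list(tryCatch(compute_ate_weights(panel, models, t),
                              tvt_error = function(e) {
                                note_failure(sprintf("ate-weights t=%d", t), e)
                                NULL
                              }))
  }
  if ("msm" %in% config$estimators) {
    for (t in seq_len(Tn)) {
      if (is.null(ate_w[[t]])) next
      res <- tryCatch(fit_msm(panel, ate_w[[t]], t),
                      tvt_error = function(e) {
                        note_failure(sprintf("msm t=%d", t), e)
                        NULL
                      })
      if (!is.null(res)) {
        for (d in seq_len(t)) {
          rows[[length(rows) + 1L]] <- .att_row(
            "msm", d, t, NA_character_, NA, NA,
            unname(res$coefficients[d + 1L]), NA_integer_, NA_integer_)
        }
      }
    }
  }
  want_att <- any(c("tvt-outcome", "tvt-cs") %in% config$estimators)
  g_min <- if (config$include_g1 && "tvt-outcome" %in% config$estimators) 1L else 2L
  for (g in g_min:Tn) {
    for (t in g:Tn) {
      for (ct in config$control_types) {
        if (want_att) {
          aw <- tryCatch(
            normalize_att_weights(compute_att_weights(panel, models, g, t, ct)),
            tvt_error = function(e) {
              note_failure(sprintf("att-weights g=%d t=%d %s", g, t, ct), e)
              NULL
            })
          if (!is.null(aw)) {
            if ("tvt-outcome" %in% config$estimators) {
              r <- tryCatch(estimate_att_tvt_outcome(panel, aw, g, t),
                            tvt_error = function(e) {
                              note_failure(sprintf("tvt-outcome g=%d t=%d %s", g, t, ct), e)
                              NULL
                            })
              if (!is.null(r)) rows[[length(rows) + 1L]] <- r
            }
            if ("tvt-cs" %in% config$estimators && g >= 2L) {
              r <- tryCatch(estimate_att_tvt_changescore(panel, aw, g, t),
                            tvt_error = function(e) {
                              note_failure(sprintf("tvt-cs g=%d t=%d %s", g, t, ct), e)
                              NULL
                            })
              if (!is.null(r)) rows[[length(rows) + 1L]] <- r
            }
          }
        }
        if ("gt-did" %in% config$estimators && g >= 2L) {
          for (adj in c(FALSE, TRUE)) {
            for (wtd in c(FALSE, TRUE)) {
              # horizon-T stabilized weights: one weight set for every
              # estimand, and the full product is what de-confounds the
              # never-treated control group (selected through T)
              sw <- if (wtd) ate_w[[Tn]] else NULL
              if (wtd && is.null(sw)) next
              r <- tryCatch(
                estimate_att_gt_did(panel, g, t, ct, adjusted = adj,
                                    sampling_weights = sw),
                tvt_error = function(e) {
                  note_failure(sprintf("gt-did g=%d t=%d %s adj=%s wtd=%s",
                                       g, t, ct, adj, wtd), e)
                  NULL
                })
              if (!is.null(r)) rows[[length(rows) + 1L]] <- r
            }
          }
        }
      }
    }
  }
  list(estimates = data.table::rbindlist(rows),
       failures = data.table::rbindlist(failures))
}

#' Run the Monte Carlo simulation study
#'
#' For each (setup, m) cell: simulates the population, computes the truth
#' table by intervention simulation, draws `n_replicates` samples, runs the
#' full estimator roster on each, and summarizes bias and Monte-Carlo
#' standard error per estimator and estimand. Deterministic given
#' `master_seed`. Estimator failures within a replicate are recorded in the
#' `failures` table and the affected estimate is skipped, not fatal.
#'
#' @param config A [study_config()].
#' @param verbose Print one progress line per cell.
#' @return An object of class `tvt_study`: list with `estimates` (one row
#'   per estimator x estimand x replicate), `truths`, `results` (the
#'   bias/SE summary, see [summarize_study()]), `failures`, and `config`.
#' @export
run_study <- function(config, verbose = interactive()) {
  stopifnot(inherits(config, "tvt_study_config"))
  cells <- expand.grid(m = config$m_grid, setup = config$setups)[, 2:1]
  set.seed(config$master_seed)
  n_cells <- nrow(cells)
  seed_mat <- matrix(sample.int(2147483647L, n_cells * (config$n_replicates + 1L)),
                     nrow = n_cells)
  all_est <- list()
  all_truth <- list()
  all_fail <- list()
  for (ci in seq_len(n_cells)) {
    setup <- cells$setup[ci]
    m <- cells$m[ci]
    if (verbose) {
      message(sprintf("cell %d/%d: setup %d, m = %g", ci, n_cells, setup, m))
    }
    scfg <- structural_config(setup, m = m, T = config$T,
                              coefficients = config$coefficients)
    pop <- simulate_population(scfg, config$population_n,
                               seed = seed_mat[ci, 1L])
    truths <- compute_truth(pop)
    truths[, c("setup", "m") := list(setup, m)]
    all_truth[[ci]] <- truths
    for (r in seq_len(config$n_replicates)) {
      samp <- draw_sample(pop, config$sample_n, seed = seed_mat[ci, r + 1L])
      out <- .estimate_replicate(samp, config, setup)
      if (nrow(out$estimates)) {
        out$estimates[, c("setup", "m", "replicate") := list(setup, m, r)]
        all_est[[length(all_est) + 1L]] <- out$estimates
      }
      if (nrow(out$failures)) {
        out$failures[, c("setup", "m", "replicate") := list(setup, m, r)]
        all_fail[[length(all_fail) + 1L]] <- out$failures
      }
    }
  }
  estimates <- data.table::rbindlist(all_est)
  truths <- data.table::rbindlist(all_truth)
  results <- summarize_study(estimates, truths,
                             n_replicates = config$n_replicates)
  structure(list(estimates = estimates, truths = truths, results = results,
                 failures = data.table::rbindlist(all_fail), config = config),
            class = "tvt_study")
}

#' @export
print.tvt_study <- function(x, ...) {
  cat(sprintf("<tvt_study> %d estimate rows, %d summary rows, %d failures\n",
              nrow(x$estimates), nrow(x$results), nrow(x$failures)))
  invisible(x)
}

#' Summarize replicate estimates against the truth
#'
#' Joins estimates to truths by (setup, m, estimand, g, t) and reports, per
#' estimator variant and estimand: the truth, the Monte-Carlo mean, the bias
#' (MC mean minus truth -- so `truth + bias` equals the MC mean exactly),
#' the Monte-Carlo standard error (SD of the point estimates, denominator
#' `n - 1`), the number of contributing replicates and the number of failed
#' (missing) ones.
#'
#' @param estimates Estimates table as produced by [run_study()] (columns
#'   `estimator`, `setup`, `m`, `replicate`, `g`, `t`, `control_type`,
#'   `adjusted`, `weighted`, `estimate`).
#' @param truths Truth table with columns `setup`, `m`, `estimand`, `g`,
#'   `t`, `true_value` (MSM rows use `estimand = "msm"` with `g` the
#'   coefficient index).
#' @param n_replicates Planned replicates per cell, used to report failures;
#'   default is the maximum replicate index observed.
#' @return A `data.table` with one row per estimator variant x estimand x
#'   setup x m.
#' @export
summarize_study <- function(estimates, truths,
                            n_replicates = max(estimates$replicate)) {
  est <- data.table::copy(data.table::as.data.table(estimates))
  tru <- data.table::as.data.table(truths)
  est[, "estimand" := ifelse(est$estimator == "msm", "msm", "att")]
  keys <- c("setup", "m", "estimand", "g", "t")
  merged <- merge(est, tru[, c(keys, "true_value"), with = FALSE],
                  by = keys, all.x = TRUE)
  if (anyNA(merged$true_value)) {
    bad <- merged[is.na(merged$true_value)][1L]
    tvt_error(sprintf("no truth for estimand %s(g=%s, t=%s) in setup %s, m=%s",
                      bad$estimand, bad$g, bad$t, bad$setup, bad$m),
              "tvt_key_error")
  }
  out <- merged[, list(
    truth = true_value[1L],
    mc_mean = mean(estimate),
    bias = mean(estimate) - true_value[1L],
    se = stats::sd(estimate),
    n_replicates = .N,
    n_failed = n_replicates - .N
  ), by = c("setup", "m", "estimator", "g", "t",
            "control_type", "adjusted", "weighted")]
  data.table::setorderv(out, c("setup", "m", "estimator", "g", "t"))
  out[]
}
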