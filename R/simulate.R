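# Structural-equation simulator: population generation, counterfactual
# intervention simulation with common exogenous draws, truth computation.

# Draw every exogenous noise term up front, in a fixed documented order
# (eps_U, eps_W, eps_X, eps_Y, unif_D) so a single seed pins the population.
.draw_noise <- function(config, n) {
  s <- config$setup
  Tn <- config$T
  noise <- list()
  noise$eps_U <- if (s == 2L) {
    matrix(stats::rnorm(n), n, 1L)
  } else if (s >= 3L) matrix(stats::rnorm(n * Tn), n, Tn)
  noise$eps_W <- if (s == 4L) matrix(stats::rnorm(n * Tn), n, Tn)
  noise$eps_X <- if (s <= 2L) {
    matrix(stats::rnorm(n), n, 1L)
  } else matrix(stats::rnorm(n * Tn), n, Tn)
  noise$eps_Y <- matrix(stats::rnorm(n * Tn), n, Tn)
  noise$unif_D <- matrix(stats::runif(n * Tn), n, Tn)
  noise
}

# One forward pass through the structural equations. With d_fixed = NULL the
# treatment is drawn from its logistic equation (absorbing rule applied);
# with d_fixed an integer n x T matrix the treatment equation is ignored and
# D is set to d_fixed. The factual and counterfactual worlds share this code
# path so that identical (noise, D) yields bit-identical X, U, W, Y.
.sem_forward <- function(config, noise, d_fixed = NULL) {
  s <- config$setup
  Tn <- config$T
  m <- config$m
  cf <- config$coefficients
  n <- nrow(noise$eps_Y)
  factual <- is.null(d_fixed)
  D <- matrix(0L, n, Tn)
  Y <- matrix(NA_real_, n, Tn)

  if (s <= 2L) {
    X1 <- noise$eps_X[, 1L]
    U1 <- if (s == 2L) noise$eps_U[, 1L]
    for (t in seq_len(Tn)) {
      if (factual) {
        lo <- cf$d_intercept + cf$d_x * m * X1
        if (s == 2L) lo <- lo + cf$d_u * m * U1
        init <- noise$unif_D[, t] < stats::plogis(lo)
        D[, t] <- if (t == 1L) as.integer(init) else
          as.integer(D[, t - 1L] == 1L | init)
      } else {
        D[, t] <- d_fixed[, t]
      }
      y <- cf$y_x * m * X1 + cf$y_d * D[, t] + cf$y_dmod * X1 * D[, t] +
        noise$eps_Y[, t]
      if (s == 2L) y <- y + cf$y_u * m * U1
      Y[, t] <- y
    }
    X <- matrix(X1, n, Tn)
    U <- if (s == 2L) matrix(U1, n, Tn)
    W <- NULL
  } else {
    U <- matrix(NA_real_, n, Tn)
    X <- matrix(NA_real_, n, Tn)
    W <- if (s == 4L) matrix(NA_real_, n, Tn)
    for (t in seq_len(Tn)) {
      U[, t] <- if (t == 1L) noise$eps_U[, t] else
        cf$u_ar * U[, t - 1L] + noise$eps_U[, t]
      if (s == 4L) {
        W[, t] <- if (t == 1L) noise$eps_W[, t] else
          cf$w_ar * W[, t - 1L] + noise$eps_W[, t]
      }
      x <- cf$x_u * U[, t] + noise$eps_X[, t]
      if (t > 1L) x <- x + cf$x_dlag * D[, t - 1L]
      X[, t] <- x
      if (factual) {
        lo <- cf$d_intercept + cf$d_x * m * X[, t]
        if (t > 1L) {
          lo <- lo + cf$d_xlag * m * X[, t - 1L] + cf$d_dlag * D[, t - 1L]
        }
        if (s == 4L) lo <- lo + cf$d_w * m * W[, t]
        init <- noise$unif_D[, t] < stats::plogis(lo)
        D[, t] <- if (t == 1L) as.integer(init) else
          as.integer(D[, t - 1L] == 1L | init)
      } else {
        D[, t] <- d_fixed[, t]
      }
      y <- cf$y_u * m * U[, t] + cf$y_d * D[, t] +
        cf$y_dmod * U[, t] * D[, t] + noise$eps_Y[, t]
      if (t > 1L) y <- y + cf$y_ylag * Y[, t - 1L]
      if (s == 4L) y <- y + cf$y_w * m * W[, t]
      Y[, t] <- y
    }
  }
  list(D = D, X = X, U = U, W = W, Y = Y)
}

#' Simulate a population from a structural-equation setup
#'
#' Generates `n_units` units over `config$T` time periods. Treatment is drawn
#' from its logistic structural equation and is absorbing: once a unit is
#' treated the treatment equation is ignored and the unit stays treated. All
#' exogenous noise draws are retained inside the returned object so that
#' potential outcomes under arbitrary strategies can later be recomputed with
#' common random numbers ([simulate_counterfactual()], [compute_truth()]).
#'
#' @param config A [structural_config()] object.
#' @param n_units Number of units (>= 1).
#' @param seed Optional integer seed; the whole population is a deterministic
#'   function of `(config, n_units, seed)`.
#' @return An object of class `tvt_population` with elements `config`, `n`,
#'   matrices `D`, `X`, `Y` (and `U`, `W` when the setup has them), the
#'   first-treatment time `G` (`Inf` = never treated), and the retained
#'   `noise` list.
#' @seealso [as_panel()], [draw_sample()], [simulate_counterfactual()]
#' @export
#' @examples
#' pop <- simulate_population(structural_config(1), 500, seed = 1)
#' table(pop$G)
simulate_population <- function(config, n_units, seed = NULL) {
  if (!inherits(config, "tvt_config")) {
    tvt_error("`config` must be a tvt_config object", "tvt_config_error")
  }
  n_units <- .assert_count(n_units, "n_units")
  if (!is.null(seed)) set.seed(seed)
  noise <- .draw_noise(config, n_units)
  sys <- .sem_forward(config, noise)
  structure(
    list(config = config, n = n_units, noise = noise,
         D = sys$D, X = sys$X, U = sys$U, W = sys$W, Y = sys$Y,
         G = .first_treatment(sys$D), seed = seed),
    class = "tvt_population"
  )
}

#' @export
print.tvt_population <- function(x, ...) {
  cat(sprintf("<tvt_population> setup %d, m = %g, T = %d, %d units\n",
              x$config$setup, x$config$m, x$config$T, x$n))
  gtab <- table(factor(ifelse(is.infinite(x$G), "never", x$G),
                       levels = c(seq_len(x$config$T), "never")))
  cat("  first-treatment groups:",
      paste(sprintf("%s:%d", names(gtab), gtab), collapse = " "), "\n")
  invisible(x)
}

#' Convert a simulated population to a long-format panel
#'
#' @param population A `tvt_population`.
#' @param include_latent Keep the latent confounder columns `U`/`W`? These
#'   are oracle-only: estimators must never see them.
#' @param units Integer indices of the units to keep (default all).
#' @return A `data.table` with one row per unit-time: columns `unit_id`,
#'   `time`, `D`, `X`, `Y`, `G` (`Inf` = never treated), plus `U`/`W` when
#'   requested and present.
#' @export
as_panel <- function(population, include_latent = TRUE,
                     units = seq_len(population$n)) {
  stopifnot(inherits(population, "tvt_population"))
  Tn <- population$config$T
  k <- length(units)
  long <- function(M) as.numeric(t(M[units, , drop = FALSE]))
  dt <- data.table::data.table(
    unit_id = rep(units, each = Tn),
    time = rep(seq_len(Tn), k),
    D = as.integer(long(population$D)),
    X = long(population$X),
    Y = long(population$Y),
    G = rep(population$G[units], each = Tn)
  )
  if (include_latent && !is.null(population$U)) dt[, "U" := long(population$U)]
  if (include_latent && !is.null(population$W)) dt[, "W" := long(population$W)]
  dt[]
}

#' Static treatment strategy initiating at time g
#'
#' Under absorbing treatment every static strategy of interest is indexed by
#' its initiation time: zeros before `g`, ones from `g` on. `g = Inf` (or
#' `"never"`) gives the never-treat strategy.
#'
#' @param g Initiation time in `1..T`, or `Inf`/`"never"`.
#' @param T Number of periods.
#' @return Integer 0/1 vector of length `T`.
#' @export
#' @examples
#' initiation_strategy(2, 4)  # c(0, 1, 1, 1)
initiation_strategy <- function(g, T) {
  T <- .assert_count(T, "T")
  if (identical(g, "never") || is.infinite(g)) return(integer(T))
  g <- .assert_count(g, "g")
  if (g > T) tvt_error("`g` must be in 1..T or Inf/'never'", "tvt_argument_error")
  as.integer(seq_len(T) >= g)
}

.strategy_matrix <- function(strategy, population) {
  Tn <- population$config$T
  n <- population$n
  if (is.matrix(strategy)) {
    if (!all(dim(strategy) == c(n, Tn))) {
      tvt_error("per-unit strategy matrix must be n x T", "tvt_argument_error")
    }
    d <- strategy
  } else {
    if (length(strategy) != Tn) {
      tvt_error(sprintf("strategy must have length T = %d", Tn),
                "tvt_argument_error")
    }
    d <- matrix(strategy, n, Tn, byrow = TRUE)
  }
  if (!all(d %in% c(0, 1))) {
    tvt_error("strategy entries must be 0/1", "tvt_argument_error")
  }
  storage.mode(d) <- "integer"
  d
}

# Counterfactual outcome matrix (n x T) under a fixed strategy, reusing the
# population's exogenous draws. Internal fast path shared by the exported
# wrapper and the truth oracle.
.cf_outcomes <- function(population, strategy) {
  if (is.null(population$noise)) {
    tvt_error(paste("population has no retained noise draws; regenerate it",
                    "with simulate_population() before computing counterfactuals"),
              "tvt_state_error")
  }
  d <- .strategy_matrix(strategy, population)
  .sem_forward(population$config, population$noise, d_fixed = d)$Y
}

#' Simulate potential outcomes under a fixed treatment strategy
#'
#' Recomputes every endogenous variable forward in time with treatment fixed
#' at `strategy` (the treatment equation is ignored), reusing the exogenous
#' noise draws stored in the population: common random numbers. By
#' construction, evaluating each unit at its own factual treatment path
#' reproduces the factual outcomes exactly.
#'
#' @param population A `tvt_population` with retained noise.
#' @param strategy Length-`T` 0/1 vector (see [initiation_strategy()]) or an
#'   `n x T` matrix of per-unit strategies.
#' @return A `data.table` with columns `unit_id`, `time`, `Y_pot`, carrying
#'   the strategy as attribute `"strategy"`.
#' @export
#' @examples
#' pop <- simulate_population(structural_config(1), 200, seed = 1)
#' cf <- simulate_counterfactual(pop, initiation_strategy("never", 4))
simulate_counterfactual <- function(population, strategy) {
  stopifnot(inherits(population, "tvt_population"))
  Ycf <- .cf_outcomes(population, strategy)
  Tn <- population$config$T
  out <- data.table::data.table(
    unit_id = rep(seq_len(population$n), each = Tn),
    time = rep(seq_len(Tn), population$n),
    Y_pot = as.numeric(t(Ycf))
  )
  data.table::setattr(out, "strategy", strategy)
  out[]
}

#' True average treatment effect of one strategy versus another
#'
#' Population mean of `Y_t(d1) - Y_t(d0)` by intervention simulation with
#' common exogenous draws.
#'
#' @param population A `tvt_population` with retained noise.
#' @param d1,d0 Strategies: length-`T` 0/1 vectors, or initiation times
#'   (`1..T`, `Inf`, `"never"`).
#' @param t Outcome time.
#' @return Scalar effect in outcome units.
#' @export
true_ate <- function(population, d1, d0, t) {
  Tn <- population$config$T
  as_strat <- function(d) if (length(d) == 1L) initiation_strategy(d, Tn) else d
  t <- .assert_count(t, "t")
  if (t > Tn) tvt_error("`t` exceeds T", "tvt_argument_error")
  Y1 <- .cf_outcomes(population, as_strat(d1))
  Y0 <- .cf_outcomes(population, as_strat(d0))
  mean(Y1[, t]) - mean(Y0[, t])
}

#' True group-time average treatment effect on the treated
#'
#' `ATT(g, t)`: among units whose natural (factual) first-treatment time is
#' `g`, the mean of `Y_t(initiate at g) - Y_t(never treat)`, computed by
#' intervention simulation.
#'
#' @param population A `tvt_population` with retained noise.
#' @param g Treatment group (initiation time).
#' @param t Outcome time (`t >= g`).
#' @return Scalar effect in outcome units.
#' @export
true_att <- function(population, g, t) {
  Tn <- population$config$T
  g <- .assert_count(g, "g")
  t <- .assert_count(t, "t")
  if (g > Tn || t > Tn || t < g) {
    tvt_error("need 1 <= g <= t <= T", "tvt_argument_error")
  }
  sel <- population$G == g
  if (!any(sel)) {
    tvt_error(sprintf("no units with natural first treatment at g = %d: ATT(%d,%d) undefined",
                      g, g, t), "tvt_estimand_error")
  }
  Yg <- .cf_outcomes(population, initiation_strategy(g, Tn))
  Y0 <- .cf_outcomes(population, integer(Tn))
  mean(Yg[sel, t]) - mean(Y0[sel, t])
}

#' True marginal-structural-model contrast
#'
#' The slope on `D_d` in the saturated absorbing-treatment MSM for `Y_t`
#' equals the average effect of initiating at `d` versus initiating at
#' `d + 1` (never, when `d = T`), evaluated at time `t`.
#'
#' @param population A `tvt_population` with retained noise.
#' @param t Outcome time.
#' @param d Coefficient index `1..t`.
#' @return Scalar contrast in outcome units.
#' @export
true_msm_contrast <- function(population, t, d) {
  Tn <- population$config$T
  t <- .assert_count(t, "t")
  d <- .assert_count(d, "d")
  if (t > Tn || d > t) tvt_error("need 1 <= d <= t <= T", "tvt_argument_error")
  nxt <- if (d + 1L > Tn) Inf else d + 1L
  true_ate(population, d, nxt, t)
}

#' Truth table for all default estimands of a population
#'
#' Computes, by intervention simulation on the full population, the true
#' group-time ATTs for every `(g, t)` with `t >= g` and the true MSM
#' contrasts for every `(t, d)` with `d <= t`. Each initiation strategy's
#' counterfactual outcomes are simulated once and reused. A group with no
#' units in the natural population yields an undefined (flagged, `NA`) ATT
#' rather than a silent zero.
#'
#' @param population A `tvt_population` with retained noise.
#' @return A `data.table` with columns `estimand` (`"att"`/`"msm"`), `g`
#'   (treatment group, or coefficient index for MSM rows), `t`,
#'   `true_value`, `defined`.
#' @export
compute_truth <- function(population) {
  stopifnot(inherits(population, "tvt_population"))
  Tn <- population$config$T
  # one counterfactual world per initiation strategy, g = 1..T plus never
  Ycf <- lapply(seq_len(Tn + 1L), function(g) {
    s <- if (g > Tn) integer(Tn) else initiation_strategy(g, Tn)
    .cf_outcomes(population, s)
  })
  never <- Tn + 1L
  rows <- list()
  for (g in seq_len(Tn)) {
    sel <- population$G == g
    for (t in g:Tn) {
      defined <- any(sel)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        estimand = "att", g = g, t = t,
        true_value = if (defined) mean(Ycf[[g]][sel, t]) - mean(Ycf[[never]][sel, t]) else NA_real_,
        defined = defined
      )
    }
  }
  for (t in seq_len(Tn)) {
    for (d in seq_len(t)) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        estimand = "msm", g = d, t = t,
        true_value = mean(Ycf[[d]][, t]) - mean(Ycf[[d + 1L]][, t]),
        defined = TRUE
      )
    }
  }
  data.table::rbindlist(rows)
}

#' Draw an observed sample from a simulated population
#'
#' Samples `n` units without replacement and returns their long-format
#' observed panel. Latent (oracle-only) columns are stripped: a sample looks
#' like data an analyst could actually have.
#'
#' @param population A `tvt_population`.
#' @param n Number of units to sample (`<=` population size).
#' @param seed Optional integer seed; same seed, same sample.
#' @return A long-format `data.table` (`unit_id`, `time`, `D`, `X`, `Y`, `G`).
#' @export
draw_sample <- function(population, n, seed = NULL) {
  stopifnot(inherits(population, "tvt_population"))
  n <- .assert_count(n, "n")
  if (n > population$n) {
    tvt_error(sprintf("cannot sample %d units from a population of %d",
                      n, population$n), "tvt_argument_error")
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample.int(population$n, n))
  as_panel(population, include_latent = FALSE, units = idx)
}
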