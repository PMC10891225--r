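# Inverse-probability weights for time-varying (absorbing) treatments:
# per-time treatment-initiation models, stabilized ATE weights, odds-type
# group-time ATT weights with never-/not-yet-treated control logic.

#' Fit per-time treatment-initiation models
#'
#' For each time `t` fits, on the at-risk set (units still untreated through
#' `t - 1`), a maximum-likelihood logistic regression of treatment initiation
#' on the requested covariate terms (the denominator model) and an
#' intercept-only model (the stabilization numerator, whose fitted value is
#' the at-risk initiation proportion). Under absorbing treatment the models
#' are only meaningful on the at-risk set: treatment continuation is
#' deterministic, so previously treated units contribute probability-1
#' factors to every weight product.
#'
#' A time whose at-risk set is empty or shows no variation in initiation is
#' flagged degenerate; building weights that need that time raises a
#' positivity error rather than silently clipping.
#'
#' @param panel Long-format panel (see [validate_panel()]).
#' @param covariate_lags Integer vector of lag orders of `X` to include in
#'   the denominator model: `0` = concurrent `X_t`, `1` = `X_{t-1}`, ...
#'   Lags that do not exist at an early time are dropped for that time.
#'   `integer(0)` gives an intercept-only denominator (no adjustment).
#'   Defaults per setup via [default_covariate_lags()].
#' @return An object of class `tvt_propensity_models`: per-time fitted
#'   initiation probabilities for at-risk units (`p_hat`, `n x T`, `NA` off
#'   the at-risk set), numerator proportions `p_num`, coefficient vectors,
#'   degenerate flags, and at-risk counts.
#' @seealso [compute_ate_weights()], [compute_att_weights()]
#' @export
#' @examples
#' pop <- simulate_population(structural_config(1), 2000, seed = 1)
#' pm <- fit_propensity_models(draw_sample(pop, 1000, seed = 2))
#' pm$coefficients[[1]]
fit_propensity_models <- function(panel, covariate_lags = 0L) {
  w <- .panel_wide(panel)
  Tn <- w$T
  n <- w$n
  covariate_lags <- as.integer(covariate_lags)
  p_hat <- matrix(NA_real_, n, Tn)
  p_num <- rep(NA_real_, Tn)
  coefs <- vector("list", Tn)
  degenerate <- logical(Tn)
  n_at_risk <- integer(Tn)
  for (t in seq_len(Tn)) {
    at_risk <- w$G >= t
    init <- as.integer(w$G[at_risk] == t)
    n_at_risk[t] <- sum(at_risk)
    if (n_at_risk[t] == 0L || length(unique(init)) < 2L) {
      degenerate[t] <- TRUE
      next
    }
    p_num[t] <- mean(init)
    lags <- covariate_lags[t - covariate_lags >= 1L]
    mm <- cbind(1, w$X[at_risk, t - lags, drop = FALSE])
    colnames(mm) <- c("(Intercept)",
                      if (length(lags)) paste0("X_lag", lags))
    fit <- stats::glm.fit(mm, init, family = stats::binomial())
    if (!fit$converged) {
      tvt_error(sprintf("treatment model did not converge at time %d", t),
                "tvt_convergence_error")
    }
    p_hat[at_risk, t] <- fit$fitted.values
    coefs[[t]] <- fit$coefficients
  }
  structure(
    list(T = Tn, unit_ids = w$unit_ids, p_num = p_num, p_hat = p_hat,
         coefficients = coefs, degenerate = degenerate,
         n_at_risk = n_at_risk, covariate_lags = covariate_lags),
    class = "tvt_propensity_models"
  )
}

#' @export
print.tvt_propensity_models <- function(x, ...) {
  cat(sprintf("<tvt_propensity_models> T = %d\n", x$T))
  for (t in seq_len(x$T)) {
    if (x$degenerate[t]) {
      cat(sprintf("  t=%d: degenerate (at risk: %d)\n", t, x$n_at_risk[t]))
    } else {
      cat(sprintf("  t=%d: at risk %d, initiation %.3f, coef [%s]\n",
                  t, x$n_at_risk[t], x$p_num[t],
                  paste(sprintf("%.3f", x$coefficients[[t]]), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Assemble a treatment-model set from known probabilities
#'
#' Constructor used for fixtures and oracle tests: supply the per-time
#' numerator probabilities and the matrix of per-unit initiation
#' probabilities directly instead of fitting them.
#'
#' @param p_num Numeric vector of length `T`: marginal (numerator)
#'   initiation probabilities per time.
#' @param p_hat `n x T` matrix of conditional initiation probabilities
#'   (`NA` where a unit is no longer at risk).
#' @param unit_ids Unit identifiers matching the rows of `p_hat`.
#' @return A `tvt_propensity_models` object.
#' @export
propensity_model_set <- function(p_num, p_hat, unit_ids = seq_len(nrow(p_hat))) {
  stopifnot(is.matrix(p_hat), length(p_num) == ncol(p_hat),
            length(unit_ids) == nrow(p_hat))
  structure(
    list(T = ncol(p_hat), unit_ids = unit_ids, p_num = as.numeric(p_num),
         p_hat = p_hat, coefficients = vector("list", ncol(p_hat)),
         degenerate = is.na(as.numeric(p_num)),
         n_at_risk = colSums(!is.na(p_hat)), covariate_lags = NA_integer_),
    class = "tvt_propensity_models"
  )
}

# Align a model set to a panel's wide view; errors if units don't match.
.align_models <- function(w, models) {
  idx <- match(w$unit_ids, models$unit_ids)
  if (anyNA(idx)) {
    tvt_error("propensity models were fit on a different set of units",
              "tvt_argument_error")
  }
  list(p_hat = models$p_hat[idx, , drop = FALSE], p_num = models$p_num)
}

.check_positivity <- function(p, unit_ids, t) {
  bad <- which(!is.na(p) & (p <= 0 | p >= 1))
  if (length(bad)) {
    tvt_error(sprintf("positivity violation: fitted probability %g for unit %s at time %d",
                      p[bad[1]], unit_ids[bad[1]], t),
              "tvt_positivity_error")
  }
}

#' Stabilized ATE weights for an outcome horizon
#'
#' Builds the stabilized inverse-probability weight of each unit's own
#' realized treatment strategy through time `horizon`: the product over
#' `k = 1..horizon` of the marginal over the conditional probability of the
#' unit's own treatment value at `k`. Under absorbing treatment every factor
#' after a unit's initiation time is exactly 1, so the product effectively
#' stops at `min(G, horizon)`. Weighting by these creates a pseudopopulation
#' in which treatment at each time is independent of the modeled covariates,
#' so strategy means can be compared directly (e.g. via [fit_msm()]).
#'
#' @param panel Long-format panel the models were fit on.
#' @param models A `tvt_propensity_models` object.
#' @param horizon Outcome time `t`: the weight product runs to `t`, not to
#'   `T` (treatment decisions after the outcome cannot confound it).
#' @return A `tvt_weights` `data.table` (`unit_id`, `weight`) with
#'   attributes `estimand = "ate"` and `t = horizon`.
#' @export
compute_ate_weights <- function(panel, models, horizon) {
  w <- .panel_wide(panel)
  horizon <- .assert_count(horizon, "horizon")
  if (horizon > models$T) tvt_error("`horizon` exceeds T", "tvt_argument_error")
  al <- .align_models(w, models)
  weight <- rep(1, w$n)
  for (k in seq_len(horizon)) {
    active <- w$G >= k  # factor is 1 once the unit has initiated before k
    if (!any(active)) next
    if (models$degenerate[k]) {
      tvt_error(sprintf("treatment model at time %d is degenerate; cannot build ATE weights",
                        k), "tvt_positivity_error")
    }
    ph <- al$p_hat[, k]
    .check_positivity(ph[active], w$unit_ids, k)
    initiating <- active & w$G == k
    num <- ifelse(initiating, al$p_num[k], 1 - al$p_num[k])
    den <- ifelse(initiating, ph, 1 - ph)
    weight[active] <- weight[active] * num[active] / den[active]
  }
  out <- data.table::data.table(unit_id = w$unit_ids, weight = weight)
  data.table::setattr(out, "estimand", "ate")
  data.table::setattr(out, "t", horizon)
  data.table::setattr(out, "class", c("tvt_weights", class(out)))
  out[]
}

#' Group-time ATT weights
#'
#' Weights targeting `ATT(g, t)` for the group initiating treatment at `g`,
#' generalizing single-period odds weighting (`p/(1-p)` for controls):
#' \itemize{
#'   \item units with `G = g` get weight exactly 1;
#'   \item valid controls get the product over `k = 1..t` of the probability
#'     of the *target* strategy's treatment value at `k` (given the target
#'     history and the control's own covariates) over the probability of the
#'     control's own value; post-initiation factors of the target strategy
#'     are 1, so with `t = g = 1` this reduces to `p(X)/(1-p(X))`;
#'   \item all other units get weight exactly 0.
#' }
#' Valid controls are the never-treated units (`control_type = "never"`) or
#' additionally the units that have not initiated by time `t`
#' (`control_type = "notyet"`).
#'
#' The horizon of the weight product matches the selection that defines the
#' control group, so that the reweighted control covariate density equals
#' the group-`g` density: for never-treated controls (selected on remaining
#' untreated through `T`) the denominator product runs to `T`; for
#' not-yet-treated controls (selected on remaining untreated through `t`)
#' it runs to `t`. Numerator factors after the target initiation `g` are 1
#' either way (absorbing treatment).
#'
#' @param panel Long-format panel the models were fit on.
#' @param models A `tvt_propensity_models` object.
#' @param g Target treatment group (initiation time), `g <= t`.
#' @param t Outcome time.
#' @param control_type `"never"` or `"notyet"`.
#' @return A `tvt_weights` `data.table` (`unit_id`, `weight`, `role` in
#'   treated/control/excluded) with attributes `g`, `t`, `control_type`,
#'   `normalized = FALSE`.
#' @seealso [normalize_att_weights()]
#' @export
compute_att_weights <- function(panel, models, g, t,
                                control_type = c("never", "notyet")) {
  control_type <- match.arg(control_type)
  w <- .panel_wide(panel)
  g <- .assert_count(g, "g")
  t <- .assert_count(t, "t")
  if (g > t || t > models$T) {
    tvt_error("need 1 <= g <= t <= T", "tvt_argument_error")
  }
  al <- .align_models(w, models)
  treated <- w$G == g
  valid <- if (control_type == "never") is.infinite(w$G) else w$G > t
  if (!any(treated)) {
    tvt_error(sprintf("no units with G = %d: ATT(%d,%d) undefined", g, g, t),
              "tvt_estimand_error")
  }
  if (!any(valid)) {
    tvt_error(sprintf("no valid %s-treated controls for ATT(%d,%d)",
                      if (control_type == "never") "never" else "not-yet",
                      g, t), "tvt_estimand_error")
  }
  num <- rep(1, w$n)
  den <- rep(1, w$n)
  kmax <- if (control_type == "never") models$T else t
  for (k in seq_len(kmax)) {
    if (models$degenerate[k]) {
      tvt_error(sprintf("treatment model at time %d is degenerate; cannot build ATT weights",
                        k), "tvt_positivity_error")
    }
    ph <- al$p_hat[, k]
    .check_positivity(ph[valid], w$unit_ids, k)
    # numerator: target strategy (0 before g, initiate at g, then factor 1),
    # evaluated at the control's covariates
    if (k < g) num[valid] <- num[valid] * (1 - ph[valid])
    if (k == g) num[valid] <- num[valid] * ph[valid]
    # denominator: the control's own (untreated through t) strategy
    den[valid] <- den[valid] * (1 - ph[valid])
  }
  weight <- numeric(w$n)
  weight[treated] <- 1
  weight[valid] <- num[valid] / den[valid]
  role <- rep("excluded", w$n)
  role[treated] <- "treated"
  role[valid] <- "control"
  out <- data.table::data.table(unit_id = w$unit_ids, weight = weight,
                                role = role)
  for (a in c("g", "t", "control_type")) {
    data.table::setattr(out, a, get(a))
  }
  data.table::setattr(out, "estimand", "att")
  data.table::setattr(out, "normalized", FALSE)
  data.table::setattr(out, "class", c("tvt_weights", class(out)))
  out[]
}

#' Normalize ATT control weights
#'
#' Rescales control weights to sum to the number of treated (`G = g`) units;
#' treated weights stay 1. Idempotent.
#'
#' @param weights A `tvt_weights` object from [compute_att_weights()].
#' @return The weight set with normalized control weights and attribute
#'   `normalized = TRUE`.
#' @export
normalize_att_weights <- function(weights) {
  if (!inherits(weights, "tvt_weights") ||
      !identical(attr(weights, "estimand"), "att")) {
    tvt_error("`weights` must be an ATT weight set", "tvt_argument_error")
  }
  out <- data.table::copy(weights)
  ctrl <- out$role == "control"
  mass <- sum(out$weight[ctrl])
  if (!is.finite(mass) || mass <= 0) {
    tvt_error("control weights have zero total mass; cannot normalize",
              "tvt_normalization_error")
  }
  n_treated <- sum(out$role == "treated")
  out[ctrl, "weight" := out$weight[ctrl] * n_treated / mass]
  data.table::setattr(out, "normalized", TRUE)
  out[]
}

#' Export a weight set to CSV
#'
#' Writes `unit_id, estimand, g, t, control_type, weight`.
#'
#' @param weights A `tvt_weights` object.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_weights <- function(weights, path) {
  out <- data.table::data.table(
    unit_id = weights$unit_id,
    estimand = attr(weights, "estimand"),
    g = attr(weights, "g") %||% NA_integer_,
    t = attr(weights, "t"),
    control_type = attr(weights, "control_type") %||% NA_character_,
    weight = weights$weight
  )
  data.table::fwrite(out, path)
  invisible(path)
}
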