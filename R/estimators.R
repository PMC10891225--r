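# Causal-contrast estimators: weighted-least-squares marginal structural
# models, TVT-weighted outcome and change-score ATT estimators, and
# group-time difference-in-differences estimators.

# Merge a weight set onto a wide panel view by unit id.
.align_weights <- function(w, weights) {
  idx <- match(w$unit_ids, weights$unit_id)
  if (anyNA(idx)) {
    tvt_error("weight set does not cover every unit in the panel",
              "tvt_argument_error")
  }
  list(weight = weights$weight[idx],
       role = if ("role" %in% names(weights)) weights$role[idx])
}

.att_row <- function(estimator, g, t, control_type, adjusted, weighted,
                     estimate, n_treated, n_controls) {
  data.table::data.table(
    estimator = estimator, g = g, t = t,
    control_type = control_type %||% NA_character_,
    adjusted = adjusted, weighted = weighted,
    estimate = estimate, n_treated = n_treated, n_controls = n_controls
  )
}

# Weighted slope of y on a 0/1 indicator: difference of weighted group means.
.wslope <- function(y, ind, w) {
  .wmean(y[ind == 1L], w[ind == 1L]) - .wmean(y[ind == 0L], w[ind == 0L])
}

#' Fit a marginal structural model by weighted least squares
#'
#' Regresses `Y_t` on the treatment history `(D_1, ..., D_t)` with an
#' intercept, weighting by stabilized ATE weights built at horizon `t`.
#' Under absorbing treatment the design is saturated: at time `t` there are
#' exactly `t + 1` realizable treatment patterns (initiation at `1..t`, or
#' untreated through `t`) and `t + 1` coefficients, so each coefficient
#' `beta_td` is the weighted-mean contrast of initiating at `d` versus
#' initiating one period later. Every pattern must be occupied; a missing
#' pattern raises a rank-deficiency error naming it.
#'
#' @param panel Long-format panel.
#' @param ate_weights A `tvt_weights` ATE set built at horizon `t`
#'   ([compute_ate_weights()]), or `NULL` for unit weights.
#' @param t Outcome time.
#' @return An object of class `tvt_msm` with `coefficients` named
#'   `beta_<t><0..t>`, the outcome time, and the sample size.
#' @export
fit_msm <- function(panel, ate_weights, t) {
  w <- .panel_wide(panel)
  t <- .assert_count(t, "t")
  if (t > w$T) tvt_error("`t` exceeds panel length", "tvt_argument_error")
  wt <- if (is.null(ate_weights)) rep(1, w$n) else .align_weights(w, ate_weights)$weight
  patt <- pmin(w$G, t + 1L)  # initiation time truncated at "not by t"
  missing_patt <- setdiff(seq_len(t + 1L), unique(patt))
  if (length(missing_patt)) {
    lab <- ifelse(missing_patt > t, sprintf("untreated through %d", t),
                  sprintf("initiation at %d", missing_patt))
    tvt_error(paste0("treatment pattern empty at time ", t, ": ",
                     paste(lab, collapse = "; "), " -- design is rank deficient"),
              "tvt_rank_error")
  }
  mm <- cbind(1, w$D[, seq_len(t), drop = FALSE])
  fit <- stats::lm.wfit(mm, w$Y[, t], wt)
  coefs <- fit$coefficients
  names(coefs) <- paste0("beta_", t, "_", 0:t)
  structure(list(t = t, coefficients = coefs, n = w$n,
                 weighted = !is.null(ate_weights)),
            class = "tvt_msm")
}

#' @export
print.tvt_msm <- function(x, ...) {
  cat(sprintf("<tvt_msm> outcome time %d, n = %d%s\n", x$t, x$n,
              if (x$weighted) ", ATE-weighted" else ", unweighted"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' TVT-weighted outcome estimator of a group-time ATT
#'
#' `ATT(g, t)` estimated as the mean outcome at `t` among the `G = g` group
#' minus the ATT-weighted mean outcome among valid controls; algebraically
#' identical to the slope of an ATT-weighted regression of `Y_t` on the
#' group indicator (both routes are computed and cross-checked). Defined for
#' `g = 1` as well: outcome weighting does not need a pre-treatment period.
#'
#' @param panel Long-format panel.
#' @param att_weights ATT weight set for `(g, t)` from
#'   [compute_att_weights()] (normalized or not; the estimator is invariant).
#' @param g,t Target group and outcome time (must match the weight set).
#' @return One-row `data.table` (`estimator`, `g`, `t`, `control_type`,
#'   `adjusted`, `weighted`, `estimate`, `n_treated`, `n_controls`).
#' @export
estimate_att_tvt_outcome <- function(panel, att_weights, g, t) {
  w <- .panel_wide(panel)
  .check_att_args(att_weights, g, t)
  al <- .align_weights(w, att_weights)
  use <- al$role != "excluded"
  if (!any(al$role == "treated") || !any(al$role == "control")) {
    tvt_error("empty treated or control set", "tvt_estimand_error")
  }
  y <- w$Y[use, t]
  ind <- as.integer(al$role[use] == "treated")
  wt <- al$weight[use]
  est <- .wslope(y, ind, wt)
  # independent algebraic route: difference of (weighted) group means
  est2 <- mean(w$Y[al$role == "treated", t]) -
    .wmean(w$Y[al$role == "control", t], al$weight[al$role == "control"])
  stopifnot(abs(est - est2) < 1e-8)
  .att_row("tvt-outcome", g, t, attr(att_weights, "control_type"),
           NA, NA, est, sum(ind), sum(ind == 0L))
}

#' TVT-weighted change-score (hybrid) estimator of a group-time ATT
#'
#' Forms the change score `Delta_{g,t} = Y_t - Y_{g-1}` (outcome change from
#' the last pre-initiation period of group `g`) and estimates `ATT(g, t)` as
#' the slope of an ATT-weighted regression of `Delta` on the group
#' indicator. Differencing removes confounders that shift only the level of
#' the outcome (including unmeasured time-invariant ones); the weights
#' handle measured, possibly time-varying, confounding of the trend.
#' Undefined for `g = 1` (no pre-period).
#'
#' @inheritParams estimate_att_tvt_outcome
#' @return One-row `data.table` as in [estimate_att_tvt_outcome()].
#' @export
estimate_att_tvt_changescore <- function(panel, att_weights, g, t) {
  if (g == 1L) {
    tvt_error("change-score estimator undefined for g = 1 (no pre-period)",
              "tvt_estimand_error")
  }
  w <- .panel_wide(panel)
  .check_att_args(att_weights, g, t)
  al <- .align_weights(w, att_weights)
  use <- al$role != "excluded"
  if (!any(al$role == "treated") || !any(al$role == "control")) {
    tvt_error("empty treated or control set", "tvt_estimand_error")
  }
  delta <- w$Y[use, t] - w$Y[use, g - 1L]
  ind <- as.integer(al$role[use] == "treated")
  est <- .wslope(delta, ind, al$weight[use])
  .att_row("tvt-cs", g, t, attr(att_weights, "control_type"),
           NA, NA, est, sum(ind), sum(ind == 0L))
}

.check_att_args <- function(att_weights, g, t) {
  if (!inherits(att_weights, "tvt_weights") ||
      !identical(attr(att_weights, "estimand"), "att")) {
    tvt_error("`att_weights` must come from compute_att_weights()",
              "tvt_argument_error")
  }
  if (!identical(as.integer(attr(att_weights, "g")), as.integer(g)) ||
      !identical(as.integer(attr(att_weights, "t")), as.integer(t))) {
    tvt_error("weight set was built for a different (g, t)",
              "tvt_argument_error")
  }
}

#' Group-time difference-in-differences estimator
#'
#' Change-score (DiD) estimator of `ATT(g, t)` in the staggered-adoption
#' framework. Units treated in the first period are dropped from the
#' analysis set (they have no pre-period under parallel trends). The
#' unadjusted flavor is the difference in (sampling-weighted) mean change
#' scores `Delta_{g,t} = Y_t - Y_{g-1}` between group `g` and the controls.
#' The adjusted flavor is an outcome-regression variant using the covariate
#' measured at the first time point: a (sampling-weighted) linear model of
#' `Delta` on `X_1` is fit among controls, its prediction subtracted from
#' each group-`g` unit's change score, and the (sampling-weighted) mean
#' residual reported. Optional sampling weights (e.g. stabilized TVT-ATE
#' weights at horizon `t`) turn these into hybrid estimators robust to
#' measured time-varying confounding.
#'
#' @param panel Long-format panel.
#' @param g Target group, `g >= 2`.
#' @param t Outcome time, `t >= g`.
#' @param control_type `"never"` or `"notyet"`.
#' @param adjusted Adjust for the first-period covariate `X_1`?
#' @param sampling_weights Optional `tvt_weights` (or data.frame with
#'   `unit_id`, `weight`) used as sampling weights; `NULL` = unweighted.
#' @return One-row `data.table` as in [estimate_att_tvt_outcome()].
#' @export
estimate_att_gt_did <- function(panel, g, t,
                                control_type = c("never", "notyet"),
                                adjusted = FALSE, sampling_weights = NULL) {
  control_type <- match.arg(control_type)
  g <- .assert_count(g, "g")
  t <- .assert_count(t, "t")
  if (g < 2L) {
    tvt_error("group-time DiD undefined for g = 1 (no pre-period)",
              "tvt_estimand_error")
  }
  if (t < g) tvt_error("need t >= g", "tvt_argument_error")
  w <- .panel_wide(panel)
  if (t > w$T) tvt_error("`t` exceeds panel length", "tvt_argument_error")
  sw <- if (is.null(sampling_weights)) rep(1, w$n) else {
    idx <- match(w$unit_ids, sampling_weights$unit_id)
    if (anyNA(idx)) {
      tvt_error("sampling weights do not cover every unit", "tvt_argument_error")
    }
    sampling_weights$weight[idx]
  }
  keep <- w$G != 1L  # first-period adopters are dropped
  treated <- keep & w$G == g
  ctrl <- keep & (if (control_type == "never") is.infinite(w$G) else w$G > t)
  if (!any(treated) || !any(ctrl)) {
    tvt_error(sprintf("empty %s cell for gt-did ATT(%d,%d)",
                      if (!any(treated)) "treated" else "control", g, t),
              "tvt_estimand_error")
  }
  delta <- w$Y[, t] - w$Y[, g - 1L]
  if (!adjusted) {
    est <- .wmean(delta[treated], sw[treated]) - .wmean(delta[ctrl], sw[ctrl])
  } else {
    x1 <- w$X[, 1L]
    if (anyNA(x1)) {
      tvt_error("first-period covariate required for the adjusted estimator",
                "tvt_argument_error")
    }
    fit <- stats::lm.wfit(cbind(1, x1[ctrl]), delta[ctrl], sw[ctrl])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0  # collinear (e.g. constant) covariate: intercept-only fit
    pred <- cbind(1, x1[treated]) %*% cf
    est <- .wmean(delta[treated] - as.numeric(pred), sw[treated])
  }
  .att_row("gt-did", g, t, control_type, adjusted,
           !is.null(sampling_weights), est, sum(treated), sum(ctrl))
}
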