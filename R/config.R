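#' Default structural coefficients
#'
#' Returns the default coefficient values of the four structural-equation
#' setups. Confounder loadings (on `X`, `U`, `W` in both the treatment
#' log-odds and the outcome equation) are scaled by the confounding-strength
#' multiplier `m` at simulation time; the remaining coefficients are fixed.
#'
#' @details Coefficient names and roles:
#' \describe{
#'   \item{`d_intercept`}{Intercept of the treatment log-odds (-1).}
#'   \item{`d_x`, `d_xlag`}{Loadings of concurrent and lagged `X` in the
#'     treatment log-odds (-0.5, scaled by `m`; the lag exists only in the
#'     time-varying setups 3-4).}
#'   \item{`d_u`, `d_w`}{Loadings of the unmeasured confounders in the
#'     treatment log-odds (-0.5, scaled by `m`; setups 2 and 4).}
#'   \item{`d_dlag`}{Coefficient on lagged treatment in the treatment
#'     log-odds (0.5; setups 3-4). Vacuous in practice: once a unit is
#'     treated the absorbing rule overrides the treatment equation, so this
#'     term never enters a realized treatment draw. It is retained literally
#'     in the linear predictor.}
#'   \item{`y_x`, `y_u`, `y_w`}{Confounder loadings in the outcome equation
#'     (0.5, scaled by `m`).}
#'   \item{`y_d`}{Concurrent treatment effect on the outcome (0.5).}
#'   \item{`y_dmod`}{Treatment-effect heterogeneity: interaction of treatment
#'     with the effect modifier (0.1) -- `X` in setups 1-2, `U_t` in 3-4.}
#'   \item{`y_ylag`}{Outcome autoregression (0.5; setups 3-4).}
#'   \item{`u_ar`, `w_ar`}{AR(1) coefficients of the latent confounders
#'     (0.5; setups 3-4).}
#'   \item{`x_u`, `x_dlag`}{Loadings of `U_t` and lagged treatment in the
#'     time-varying proxy `X_t` (0.5; setups 3-4).}
#' }
#'
#' @return Named list of numeric coefficients.
#' @export
#' @examples
#' default_coefficients()$y_d  # concurrent treatment effect
default_coefficients <- function() {
  list(
    d_intercept = -1, d_x = -0.5, d_xlag = -0.5, d_u = -0.5, d_w = -0.5,
    d_dlag = 0.5,
    y_x = 0.5, y_u = 0.5, y_w = 0.5, y_d = 0.5, y_dmod = 0.1, y_ylag = 0.5,
    u_ar = 0.5, w_ar = 0.5, x_u = 0.5, x_dlag = 0.5
  )
}

#' Structural-equation configuration
#'
#' Defines one of four panel data-generating setups with a confounding
#' strength multiplier. All noise terms are independent standard normal and
#' treatment is binary, absorbing (once on, stays on), drawn from a logistic
#' model at each time point.
#'
#' \describe{
#'   \item{Setup 1}{Time-invariant measured confounding: `X = eps_X`;
#'     treatment log-odds `-1 - 0.5 m X`; outcome
#'     `Y_t = 0.5 m X + 0.5 D_t + 0.1 X D_t + eps_Yt`.}
#'   \item{Setup 2}{Adds a time-invariant unmeasured confounder `U = eps_U`
#'     to both the treatment log-odds (`- 0.5 m U`) and the outcome
#'     (`+ 0.5 m U`).}
#'   \item{Setup 3}{Time-varying measured confounding with
#'     treatment-confounder feedback: `U_t = 0.5 U_{t-1} + eps_Ut`;
#'     `X_t = 0.5 U_t + 0.5 D_{t-1} + eps_Xt`; treatment log-odds
#'     `-1 - 0.5 m X_t - 0.5 m X_{t-1} + 0.5 D_{t-1}`; outcome
#'     `Y_t = 0.5 m U_t + 0.5 D_t + 0.5 Y_{t-1} + 0.1 U_t D_t + eps_Yt`.}
#'   \item{Setup 4}{Adds a time-varying unmeasured confounder
#'     `W_t = 0.5 W_{t-1} + eps_Wt` entering the treatment log-odds
#'     (`- 0.5 m W_t`) and the outcome (`+ 0.5 m W_t`).}
#' }
#'
#' At `t = 1` every lagged term is dropped from the structural equations
#' (deleted, not zero-imputed -- numerically equivalent here).
#'
#' @param setup Integer 1-4, the data-generating setup.
#' @param m Confounding-strength multiplier (typical grid `1:3`).
#' @param T Number of time periods (default 4).
#' @param coefficients Named list of overrides of [default_coefficients()].
#' @return An object of class `tvt_config`.
#' @export
#' @examples
#' cfg <- structural_config(3, m = 2)
#' cfg$coefficients$y_d
structural_config <- function(setup, m = 1, T = 4L, coefficients = list()) {
  if (!is.numeric(setup) || length(setup) != 1L || !(setup %in% 1:4)) {
    tvt_error("`setup` must be 1, 2, 3 or 4", "tvt_config_error")
  }
  if (!is.numeric(m) || length(m) != 1L || is.na(m)) {
    tvt_error("`m` must be a single number", "tvt_config_error")
  }
  T <- .assert_count(T, "T", min = 2L)
  cf <- default_coefficients()
  if (length(coefficients)) {
    unknown <- setdiff(names(coefficients), names(cf))
    if (length(unknown)) {
      tvt_error(paste0("unknown coefficient(s): ", paste(unknown, collapse = ", ")),
                "tvt_config_error")
    }
    cf[names(coefficients)] <- coefficients
  }
  structure(
    list(setup = as.integer(setup), m = as.numeric(m), T = T,
         coefficients = cf),
    class = "tvt_config"
  )
}

#' @export
print.tvt_config <- function(x, ...) {
  cat(sprintf("<tvt_config> setup %d, m = %g, T = %d\n", x$setup, x$m, x$T))
  invisible(x)
}

#' Default propensity-model covariate lags for a setup
#'
#' The per-time treatment models condition on the covariates that the
#' generating treatment equation actually uses: concurrent `X` in the
#' time-invariant setups (1-2) and concurrent plus one-period-lagged `X` in
#' the time-varying setups (3-4). Lags that do not exist at early times are
#' dropped automatically when fitting.
#'
#' @param setup Integer 1-4.
#' @return Integer vector of lag orders (0 = concurrent).
#' @export
default_covariate_lags <- function(setup) {
  if (setup %in% 1:2) 0L else if (setup %in% 3:4) c(0L, 1L) else
    tvt_error("`setup` must be 1, 2, 3 or 4", "tvt_config_error")
}
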