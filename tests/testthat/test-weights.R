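# Treatment-initiation models, stabilized ATE weights, group-time ATT
# weights: structural properties, hand-computed values, and agreement with
# the literal per-term product oracles.

test_that("numerator model equals the at-risk initiation proportion", {
  pop <- simulate_population(structural_config(1), 4000, seed = 1)
  panel <- as_panel(pop, include_latent = FALSE)
  pm <- fit_propensity_models(panel)
  for (t in 1:4) {
    at_risk <- pop$G >= t
    expect_equal(pm$p_num[t], mean(pop$G[at_risk] == t))
    expect_equal(pm$n_at_risk[t], sum(at_risk))
  }
})

test_that("propensity fits recover the generating treatment coefficients", {
  pop <- simulate_population(structural_config(1), 30000, seed = 2)
  pm <- fit_propensity_models(as_panel(pop, include_latent = FALSE))
  for (t in 1:2) {
    expect_lt(abs(pm$coefficients[[t]][1] - (-1)), 0.1)
    expect_lt(abs(pm$coefficients[[t]][2] - (-0.5)), 0.1)
  }
  # time-varying setups include the lag from t=2 on, dropped at t=1
  pop3 <- simulate_population(structural_config(3), 5000, seed = 3)
  pm3 <- fit_propensity_models(as_panel(pop3, include_latent = FALSE),
                               covariate_lags = c(0L, 1L))
  expect_length(pm3$coefficients[[1]], 2)
  expect_length(pm3$coefficients[[2]], 3)
})

test_that("times with no initiation are flagged degenerate and poison weights", {
  # 6 units, T = 3: initiation at t=1 only; nobody initiates at t=2 or t=3
  D <- rbind(c(1, 1, 1), c(1, 1, 1), matrix(0L, 4, 3))
  # overlapping X so the t=1 logistic fit cannot separate
  panel <- mk_panel(D, X = c(0, 1, -1, 0.5, -0.5, 0.2), Y = 1:6 / 2)
  pm <- fit_propensity_models(panel)
  expect_false(pm$degenerate[1])
  expect_true(pm$degenerate[2])
  expect_error(compute_ate_weights(panel, pm, 2),
               class = "tvt_positivity_error")
  expect_error(compute_att_weights(panel, pm, 1, 2, "notyet"),
               class = "tvt_positivity_error")
  # horizon 1 never needs the degenerate times
  expect_silent(compute_ate_weights(panel, pm, 1))
})

test_that("ATE weight matches the worked two-period example", {
  # never-treated unit: numerator no-initiation probs 0.8, 0.9; denominator
  # no-initiation probs 0.6, 0.75 -> (0.8/0.6)*(0.9/0.75) = 1.6
  D <- rbind(c(0, 0), c(1, 1))
  panel <- mk_panel(D, X = c(0.3, -0.2), Y = c(1, 2))
  pm <- propensity_model_set(p_num = c(0.2, 0.1),
                             p_hat = rbind(c(0.4, 0.25), c(0.4, NA)))
  w <- compute_ate_weights(panel, pm, 2)
  expect_equal(w$weight[1], 1.6, tolerance = 1e-12)
  # treated-at-1 unit: single factor p_num/p_hat = 0.2/0.4
  expect_equal(w$weight[2], 0.5, tolerance = 1e-12)
})

test_that("without covariates the ATE weights are identically 1", {
  cfg <- structural_config(1, coefficients = list(d_x = 0))
  pop <- simulate_population(cfg, 3000, seed = 4)
  panel <- as_panel(pop)
  pm <- fit_propensity_models(panel, covariate_lags = integer(0))
  for (t in c(1, 4)) {
    w <- compute_ate_weights(panel, pm, t)
    expect_equal(w$weight, rep(1, 3000), tolerance = 1e-6)
  }
  # and ATT control weights collapse to the marginal strategy-probability ratio
  aw <- compute_att_weights(panel, pm, 2, 2, "never")
  ctrl <- aw$weight[aw$role == "control"]
  expected <- prod(1 - pm$p_num[1]) * pm$p_num[2] / prod(1 - pm$p_num[1:4])
  expect_equal(ctrl, rep(expected, length(ctrl)), tolerance = 1e-6)
})

test_that("stabilized ATE weights have mean 1 on n=3000 samples, all setups", {
  for (s in 1:4) {
    pop <- simulate_population(structural_config(s), 20000, seed = 200 + s)
    for (r in 1:5) {
      panel <- draw_sample(pop, 3000, seed = 300 + 10 * s + r)
      pm <- fit_propensity_models(panel, default_covariate_lags(s))
      w <- compute_ate_weights(panel, pm, 4)
      expect_lt(abs(mean(w$weight) - 1), 0.05)
    }
  }
})

test_that("ATT weights are exactly 1 for the group and 0 for invalid units", {
  for (s in 1:4) {
    pop <- simulate_population(structural_config(s), 10000, seed = 400 + s)
    panel <- draw_sample(pop, 3000, seed = 500 + s)
    pm <- fit_propensity_models(panel, default_covariate_lags(s))
    first <- panel[!duplicated(panel$unit_id), ]
    for (g in 2:4) {
      for (t in g:4) {
        for (ct in c("never", "notyet")) {
          w <- compute_att_weights(panel, pm, g, t, ct)
          expect_identical(w$weight[first$G == g], rep(1, sum(first$G == g)))
          valid <- if (ct == "never") is.infinite(first$G) else first$G > t
          invalid <- !valid & first$G != g
          expect_identical(w$weight[invalid], rep(0, sum(invalid)))
          expect_true(all(w$weight[valid] > 0))
        }
      }
    }
  }
})

test_that("single-period ATT weight is the conditional odds p/(1-p)", {
  D <- matrix(c(1, 1, 0, 0, 0), ncol = 1)
  panel <- mk_panel(D, X = c(1, 2, -1, 0, 1), Y = 1:5)
  p <- c(0.6, 0.7, 0.2, 0.5, 0.8)
  pm <- propensity_model_set(p_num = 0.4, p_hat = matrix(p, ncol = 1))
  w <- compute_att_weights(panel, pm, 1, 1, "never")
  expect_equal(w$weight[3:5], p[3:5] / (1 - p[3:5]), tolerance = 1e-12)
  expect_identical(w$weight[1:2], c(1, 1))
})

test_that("not-yet-treated validity is judged at the outcome time", {
  fx <- weight_fixture()  # groups 1,1,2,2,3,never x 3 periods
  w <- compute_att_weights(fx$panel, fx$models, 2, 2, "notyet")
  expect_true(all(w$weight[fx$G == 3] > 0))   # not yet treated by t=2
  expect_identical(unique(w$role[fx$G == 3]), "control")
  w3 <- compute_att_weights(fx$panel, fx$models, 2, 3, "notyet")
  expect_identical(w3$weight[fx$G == 3], 0)   # treated by t=3 -> invalid
  expect_identical(w3$role[fx$G == 3], "excluded")
})

test_that("vectorized weights match the literal product-loop oracles", {
  fx <- weight_fixture()
  for (h in 1:3) {
    w <- compute_ate_weights(fx$panel, fx$models, h)
    oracle <- vapply(1:8, function(i)
      oracle_ate_weight(fx$G[i], fx$p_hat[i, ], fx$p_num, h), numeric(1))
    expect_equal(w$weight, oracle, tolerance = 1e-10)
  }
  for (g in 2:3) {
    for (t in g:3) {
      for (ct in c("never", "notyet")) {
        w <- compute_att_weights(fx$panel, fx$models, g, t, ct)
        oracle <- vapply(1:8, function(i)
          oracle_att_weight(fx$G[i], fx$p_hat[i, ], g, t, 3, ct), numeric(1))
        expect_equal(w$weight, oracle, tolerance = 1e-10)
      }
    }
  }
})

test_that("normalization rescales controls to the treated count, idempotently", {
  w <- mk_att_weights(1:4, c(1, 1, 1, 3), c("treated", "treated", "control", "control"),
                      g = 2, t = 2)
  nw <- normalize_att_weights(w)
  expect_equal(nw$weight, c(1, 1, 0.5, 1.5))
  expect_equal(sum(nw$weight[nw$role == "control"]), 2)
  expect_equal(normalize_att_weights(nw)$weight, nw$weight)
  zero <- mk_att_weights(1:2, c(1, 0), c("treated", "control"), g = 2, t = 2)
  expect_error(normalize_att_weights(zero), class = "tvt_normalization_error")
  expect_error(normalize_att_weights(data.frame(weight = 1)),
               class = "tvt_argument_error")
})

test_that("exact 0/1 fitted probabilities raise positivity errors", {
  D <- rbind(c(0, 0), c(0, 1), c(1, 1))
  panel <- mk_panel(D, X = c(0, 1, 2), Y = 1:3)
  pm <- propensity_model_set(p_num = c(1 / 3, 0.5),
                             p_hat = rbind(c(0.2, 1), c(0.3, 0.5), c(0.4, NA)))
  expect_error(compute_ate_weights(panel, pm, 2),
               class = "tvt_positivity_error")
  expect_error(compute_att_weights(panel, pm, 2, 2, "never"),
               class = "tvt_positivity_error")
})

test_that("weight construction demands the panel the models were fit on", {
  pop <- simulate_population(structural_config(1), 500, seed = 6)
  panel <- draw_sample(pop, 200, seed = 1)
  other <- draw_sample(pop, 200, seed = 99)
  pm <- fit_propensity_models(panel)
  expect_error(compute_ate_weights(other, pm, 2), class = "tvt_argument_error")
})
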