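# Structural-equation simulator: configuration, factual generation,
# counterfactual consistency, truth oracle, sampling.

test_that("structural_config validates inputs and applies overrides", {
  expect_error(structural_config(5), class = "tvt_config_error")
  expect_error(structural_config(1, T = 1), class = "tvt_argument_error")
  expect_error(structural_config(1, coefficients = list(nope = 1)),
               class = "tvt_config_error")
  cfg <- structural_config(3, m = 2, coefficients = list(y_d = 0.7))
  expect_equal(cfg$coefficients$y_d, 0.7)
  expect_equal(cfg$coefficients$u_ar, 0.5)  # untouched default
  expect_error(simulate_population(list(), 10), class = "tvt_config_error")
})

test_that("setup 1 observed marginals match the generating equations", {
  n <- 40000
  pop <- simulate_population(structural_config(1), n, seed = 11)
  x <- pop$X[, 1]
  expect_lt(abs(mean(x)), 3 / sqrt(n))
  expect_lt(abs(var(x) - 1), 3 * sqrt(2 / n))
  # fraction initiating at t=1 vs the logistic-normal integral, computed
  # independently by 1-D quadrature (frozen; integrate() and 40-node
  # Gauss-Hermite agree to 1e-10)
  p1 <- 0.2794191848
  expect_lt(abs(mean(pop$D[, 1]) - p1), 3 * sqrt(p1 * (1 - p1) / n))
})

test_that("treatment is absorbing and G is consistent in every setup", {
  for (s in 1:4) {
    pop <- simulate_population(structural_config(s), 2000, seed = 20 + s)
    expect_true(all(pop$D[, -1] >= pop$D[, -pop$config$T]))
    # validate_panel re-derives G from D and errors on mismatch
    expect_silent(validate_panel(as_panel(pop, include_latent = FALSE)))
    expect_true(all(is.infinite(pop$G) | (pop$G >= 1 & pop$G <= 4)))
  }
})

test_that("counterfactual at the factual strategy reproduces Y bit-for-bit", {
  for (s in 1:4) {
    pop <- simulate_population(structural_config(s), 1500, seed = 30 + s)
    cf <- simulate_counterfactual(pop, pop$D)
    expect_identical(cf$Y_pot, as_panel(pop)$Y)
  }
})

test_that("counterfactual simulation errors without retained noise", {
  pop <- simulate_population(structural_config(1), 100, seed = 1)
  pop$noise <- NULL
  expect_error(simulate_counterfactual(pop, initiation_strategy(1, 4)),
               class = "tvt_state_error")
  pop2 <- simulate_population(structural_config(1), 100, seed = 1)
  expect_error(simulate_counterfactual(pop2, c(0, 1)),
               class = "tvt_argument_error")
  expect_error(simulate_counterfactual(pop2, c(0, 2, 1, 1)),
               class = "tvt_argument_error")
})

test_that("never-treat potential outcomes are mean-zero in setup 1", {
  n <- 20000
  pop <- simulate_population(structural_config(1), n, seed = 40)
  cf <- simulate_counterfactual(pop, initiation_strategy("never", 4))
  for (t in 1:4) {
    y <- cf$Y_pot[cf$time == t]
    expect_lt(abs(mean(y)), 3 * sd(y) / sqrt(n))
  }
})

test_that("analytically forced contrasts hold (setup 1 ATE, setup 3 lag)", {
  n <- 50000
  pop1 <- simulate_population(structural_config(1), n, seed = 41)
  # per-unit effect of initiating at 2 on Y_2 is 0.5 + 0.1 X exactly
  d1 <- simulate_counterfactual(pop1, initiation_strategy(2, 4))
  d0 <- simulate_counterfactual(pop1, initiation_strategy("never", 4))
  diff2 <- d1$Y_pot[d1$time == 2] - d0$Y_pot[d0$time == 2]
  expect_lt(abs(mean(diff2) - 0.5), 3 * sd(diff2) / sqrt(n))
  expect_equal(true_ate(pop1, 2, "never", 2), mean(diff2))

  # setup 3: effect of treating at 3 on Y_4, relative to treating only at 4,
  # flows through the outcome autoregression: 0.5 * (0.5 + 0.1 U_3) => 0.25
  pop3 <- simulate_population(structural_config(3), n, seed = 42)
  a <- simulate_counterfactual(pop3, c(0, 0, 1, 1))
  b <- simulate_counterfactual(pop3, c(0, 0, 0, 1))
  diff4 <- a$Y_pot[a$time == 4] - b$Y_pot[b$time == 4]
  expect_lt(abs(mean(diff4) - 0.25), 3 * sd(diff4) / sqrt(n))
})

test_that("treated groups have negative selection: ATT(2,2) < ATE at t=2", {
  pop <- simulate_population(structural_config(1), 50000, seed = 43)
  ate <- true_ate(pop, 2, "never", 2)
  att <- true_att(pop, 2, 2)
  expect_lt(att, ate)
})

test_that("zero interaction makes ATT equal ATE; zero effect makes both 0", {
  for (s in c(1, 3)) {
    cfg <- structural_config(s, coefficients = list(y_dmod = 0))
    pop <- simulate_population(cfg, 20000, seed = 50 + s)
    # per-unit effect is the constant 0.5: ATT and ATE coincide exactly
    expect_equal(true_att(pop, 2, 2), true_ate(pop, 2, "never", 2),
                 tolerance = 1e-12)
    expect_equal(true_att(pop, 2, 2), 0.5, tolerance = 1e-12)
  }
  cfg0 <- structural_config(3, coefficients = list(y_d = 0, y_dmod = 0))
  pop0 <- simulate_population(cfg0, 20000, seed = 55)
  expect_equal(true_ate(pop0, 1, "never", 4), 0)
  expect_equal(true_att(pop0, 2, 3), 0)
})

test_that("zeroing the extra confounder nests setup 2 in 1 and 4 in 3", {
  n <- 50000
  se2 <- function(a, b) 3 * sqrt(var(a) / length(a) + var(b) / length(b))
  nest <- function(sa, sb, coefs) {
    pa <- simulate_population(structural_config(sa, coefficients = coefs),
                              n, seed = 60 + sa)
    pb <- simulate_population(structural_config(sb), n, seed = 70 + sb)
    for (t in 1:4) {
      expect_lt(abs(mean(pa$Y[, t]) - mean(pb$Y[, t])), se2(pa$Y[, t], pb$Y[, t]))
      expect_lt(abs(mean(pa$D[, t]) - mean(pb$D[, t])), se2(pa$D[, t], pb$D[, t]))
      expect_lt(abs(var(pa$Y[, t]) - var(pb$Y[, t])),
                3 * sqrt(2 * var(pa$Y[, t])^2 / n + 2 * var(pb$Y[, t])^2 / n))
    }
  }
  nest(2, 1, list(d_u = 0, y_u = 0))
  nest(4, 3, list(d_w = 0, y_w = 0))
})

test_that("lagged terms are absent (not zero-imputed) at time 1", {
  # coefficients that only multiply lagged quantities must not affect t=1
  a <- simulate_population(structural_config(3), 2000, seed = 80)
  b <- simulate_population(
    structural_config(3, coefficients = list(x_dlag = 9, d_dlag = 9,
                                             y_ylag = 9, d_xlag = 9)),
    2000, seed = 80)
  expect_identical(a$U[, 1], b$U[, 1])
  expect_identical(a$X[, 1], b$X[, 1])
  expect_identical(a$D[, 1], b$D[, 1])
  expect_identical(a$Y[, 1], b$Y[, 1])
})

test_that("compute_truth tabulates ATT and MSM estimands coherently", {
  pop <- simulate_population(structural_config(1), 30000, seed = 90)
  tt <- compute_truth(pop)
  expect_setequal(unique(tt$estimand), c("att", "msm"))
  expect_equal(nrow(tt[tt$estimand == "att", ]), 10)  # (g,t), t >= g, T=4
  expect_equal(nrow(tt[tt$estimand == "msm", ]), 10)  # (t,d), d <= t
  expect_true(all(tt$defined))
  r <- tt[tt$estimand == "att" & tt$g == 2 & tt$t == 2, ]
  expect_equal(r$true_value, true_att(pop, 2, 2))
  m <- tt[tt$estimand == "msm" & tt$g == 2 & tt$t == 2, ]
  expect_equal(m$true_value, true_msm_contrast(pop, 2, 2))
  # beta_22 truth is the 0.5 concurrent effect (E[X] = 0 kills the interaction)
  expect_lt(abs(m$true_value - 0.5), 0.02)
})

test_that("true_att flags empty groups instead of returning zero", {
  # forcing initiation never to happen at t=4 is awkward; instead subset a
  # tiny population where some group is empty by chance
  pop <- simulate_population(structural_config(1), 8, seed = 3)
  empty_g <- setdiff(1:4, unique(pop$G[is.finite(pop$G)]))
  if (length(empty_g)) {
    expect_error(true_att(pop, empty_g[1], 4), class = "tvt_estimand_error")
  }
  expect_error(true_att(pop, 3, 2), class = "tvt_argument_error")  # t < g
})

test_that("draw_sample returns an analyst-facing panel, reproducibly", {
  pop <- simulate_population(structural_config(4), 5000, seed = 100)
  s1 <- draw_sample(pop, 300, seed = 7)
  expect_equal(length(unique(s1$unit_id)), 300)
  expect_equal(nrow(s1), 300 * 4)
  expect_false(any(c("U", "W") %in% names(s1)))
  expect_identical(s1, draw_sample(pop, 300, seed = 7))
  expect_false(identical(s1, draw_sample(pop, 300, seed = 8)))
  all_units <- draw_sample(pop, 5000, seed = 9)
  expect_equal(sort(unique(all_units$unit_id)), 1:5000)
  expect_error(draw_sample(pop, 5001, seed = 1), class = "tvt_argument_error")
})
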