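# Fixtures and independent oracles shared across test files.
# Everything here is built in code; no stored data.

# Long panel from per-unit vectors: D is an n x T 0/1 matrix.
mk_panel <- function(D, X = NULL, Y = NULL, unit_id = seq_len(nrow(D))) {
  n <- nrow(D)
  Tn <- ncol(D)
  G <- rep(Inf, n)
  for (t in rev(seq_len(Tn))) G[D[, t] == 1] <- t
  if (is.null(X)) X <- matrix(0, n, Tn)
  if (is.null(Y)) Y <- matrix(0, n, Tn)
  if (!is.matrix(X)) X <- matrix(X, n, Tn)
  data.table::data.table(
    unit_id = rep(unit_id, each = Tn),
    time = rep(seq_len(Tn), n),
    D = as.integer(t(D)),
    X = as.numeric(t(X)),
    Y = as.numeric(t(Y)),
    G = rep(G, each = Tn)
  )
}

# ATT weight set with caller-chosen weights/roles (for closed-form tests).
mk_att_weights <- function(unit_id, weight, role, g, t,
                           control_type = "never", normalized = FALSE) {
  out <- data.table::data.table(unit_id = unit_id, weight = weight, role = role)
  data.table::setattr(out, "estimand", "att")
  data.table::setattr(out, "g", as.integer(g))
  data.table::setattr(out, "t", as.integer(t))
  data.table::setattr(out, "control_type", control_type)
  data.table::setattr(out, "normalized", normalized)
  data.table::setattr(out, "class", c("tvt_weights", class(out)))
  out
}

# Unit ATT weights derived from a panel's G column: treated group 1,
# valid controls 1, everything else 0/excluded.
unit_att_weights <- function(panel, g, t, control_type = "never") {
  dt <- data.table::as.data.table(panel)
  first <- dt[!duplicated(dt$unit_id), ]
  G <- first$G
  role <- rep("excluded", nrow(first))
  role[G == g] <- "treated"
  valid <- if (control_type == "never") is.infinite(G) else G > t
  role[valid] <- "control"
  mk_att_weights(first$unit_id, as.numeric(role != "excluded"), role, g, t,
                 control_type)
}

# --- Independent weight oracles: literal per-unit, per-term product loops ---

# Stabilized ATE weight of one unit (initiation time G_i, fitted conditional
# probabilities p_hat_i[k], marginal probabilities p_num[k]).
oracle_ate_weight <- function(G_i, p_hat_i, p_num, horizon) {
  w <- 1
  for (k in seq_len(horizon)) {
    if (G_i < k) next             # post-initiation factor is exactly 1
    if (G_i == k) {
      w <- w * p_num[k] / p_hat_i[k]
    } else {
      w <- w * (1 - p_num[k]) / (1 - p_hat_i[k])
    }
  }
  w
}

# ATT weight of one unit for target group g at outcome time t.
oracle_att_weight <- function(G_i, p_hat_i, g, t, Tn, control_type) {
  if (G_i == g) return(1)
  valid <- if (control_type == "never") is.infinite(G_i) else G_i > t
  if (!valid) return(0)
  kmax <- if (control_type == "never") Tn else t
  num <- 1
  den <- 1
  for (k in seq_len(kmax)) {
    if (k < g) num <- num * (1 - p_hat_i[k])
    if (k == g) num <- num * p_hat_i[k]
    den <- den * (1 - p_hat_i[k])
  }
  num / den
}

# 8-unit x 3-period fixture with hand-chosen initiation probabilities:
# groups 1,1,2,2,3,never,never,never. p_hat rows are each unit's conditional
# initiation probabilities while at risk (NA afterwards).
weight_fixture <- function() {
  G <- c(1, 1, 2, 2, 3, Inf, Inf, Inf)
  D <- t(vapply(G, function(g) as.integer(1:3 >= g), integer(3)))
  p_hat <- matrix(NA_real_, 8, 3)
  p_hat[, 1] <- c(0.30, 0.45, 0.20, 0.15, 0.25, 0.10, 0.40, 0.35)
  p_hat[G > 1, 2] <- c(0.25, 0.30, 0.15, 0.20, 0.35, 0.10)
  p_hat[G > 2, 3] <- c(0.20, 0.15, 0.30, 0.25)
  p_num <- c(0.25, 1 / 3, 0.25)
  list(panel = mk_panel(D, X = seq(-1, 0.75, by = 0.25), Y = 1:8 / 4),
       models = propensity_model_set(p_num, p_hat),
       G = G, p_hat = p_hat, p_num = p_num)
}
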