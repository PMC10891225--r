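# Internal helpers shared across modules.

#' @importFrom data.table := .N data.table as.data.table setattr setorderv
#' @importFrom data.table rbindlist fwrite fread copy uniqueN
#' @importFrom stats glm.fit lm.wfit plogis rnorm runif sd binomial
#' @importFrom utils head
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

# All package errors carry class "tvt_error" plus a specific subclass so
# callers (and the study harness) can distinguish positivity failures,
# undefined estimands, validation problems, etc.
tvt_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tvt_error")))
}

# First treatment time per unit from an n x T 0/1 matrix; Inf = never treated.
.first_treatment <- function(D) {
  G <- rep(Inf, nrow(D))
  for (t in rev(seq_len(ncol(D)))) G[D[, t] == 1L] <- t
  G
}

.assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != trunc(x)) {
    tvt_error(sprintf("`%s` must be a single integer >= %d", name, min),
              "tvt_argument_error")
  }
  as.integer(x)
}

.wmean <- function(x, w) sum(w * x) / sum(w)
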