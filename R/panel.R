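# Long-format panel validation and CSV round-tripping.

.obs_cols <- c("unit_id", "time", "D", "X", "Y", "G")

#' Validate a long-format panel
#'
#' Checks the structural contract of an observed panel: required columns,
#' exactly one row per unit-time with every unit observed at times `1..T`,
#' no missing values in observed columns, binary treatment that is monotone
#' nondecreasing within unit (absorbing), and a `G` column consistent with
#' `D` (`G = min{t : D_t = 1}`, `Inf` if never treated). Violations raise a
#' `tvt_validation_error` naming the offending units/times.
#'
#' @param panel A data.frame/data.table in long format.
#' @param strict Check the absorbing-treatment and `G`-consistency rules
#'   (default `TRUE`).
#' @return The panel, invisibly, as a `data.table`.
#' @export
validate_panel <- function(panel, strict = TRUE) {
  dt <- data.table::as.data.table(panel)
  missing_cols <- setdiff(.obs_cols, names(dt))
  if (length(missing_cols)) {
    tvt_error(paste0("panel is missing column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "tvt_validation_error")
  }
  for (cc in setdiff(.obs_cols, "G")) {
    if (anyNA(dt[[cc]])) {
      bad <- dt[is.na(dt[[cc]]), ]
      tvt_error(sprintf("missing %s for unit %s at time %s", cc,
                        bad$unit_id[1], bad$time[1]),
                "tvt_validation_error")
    }
  }
  if (!all(dt$D %in% c(0L, 1L))) {
    tvt_error("treatment D must be 0/1", "tvt_validation_error")
  }
  data.table::setorderv(dt, c("unit_id", "time"))
  Tn <- max(dt$time)
  if (nrow(dt) %% Tn != 0L ||
      !identical(as.integer(dt$time), rep(seq_len(Tn), nrow(dt) %/% Tn))) {
    cnt <- dt[, list(n = .N, ntimes = data.table::uniqueN(time)), by = "unit_id"]
    bad <- cnt[cnt$n != Tn | cnt$ntimes != Tn, ]
    tvt_error(paste0("unit(s) without exactly one row per time 1..T: ",
                     paste(utils::head(bad$unit_id, 5L), collapse = ", ")),
              "tvt_validation_error")
  }
  n <- nrow(dt) %/% Tn
  first_row <- seq(1L, nrow(dt), by = Tn)
  if (any(dt$unit_id != rep(dt$unit_id[first_row], each = Tn))) {
    tvt_error("duplicate unit-time rows detected", "tvt_validation_error")
  }
  if (strict) {
    # columns = units after sorting, so all checks are vectorized
    Dm <- matrix(dt$D, nrow = Tn)
    if (Tn > 1L) {
      nonmono <- colSums(Dm[-1L, , drop = FALSE] < Dm[-Tn, , drop = FALSE]) > 0L
      if (any(nonmono)) {
        tvt_error(paste0("non-absorbing treatment path (D switches off) for unit(s): ",
                         paste(utils::head(dt$unit_id[first_row][nonmono], 5L),
                               collapse = ", ")),
                  "tvt_validation_error")
      }
    }
    g0 <- rep(Inf, n)
    for (t in rev(seq_len(Tn))) g0[Dm[t, ] == 1L] <- t
    bad_g <- colSums(matrix(dt$G, nrow = Tn) != rep(g0, each = Tn)) > 0L
    if (any(bad_g)) {
      tvt_error(paste0("G inconsistent with D for unit(s): ",
                       paste(utils::head(dt$unit_id[first_row][bad_g], 5L),
                             collapse = ", ")),
                "tvt_validation_error")
    }
  }
  invisible(dt)
}

#' Write / read a panel CSV
#'
#' Long-format CSV with header `unit_id,time,D,X,Y,G` (plus `U`/`W` when
#' `include_latent = TRUE` and present). Never-treated units carry
#' `G = "never"` on disk and `G = Inf` in memory. Write-then-read is an
#' identity on the observed columns.
#'
#' @param panel Long-format panel (validated before writing).
#' @param path File path.
#' @param include_latent Keep latent `U`/`W` columns if present.
#' @return `write_panel()`: the path, invisibly. `read_panel()`: a validated
#'   `data.table`.
#' @export
write_panel <- function(panel, path, include_latent = FALSE) {
  dt <- data.table::as.data.table(panel)
  validate_panel(dt)
  keep <- c(.obs_cols, if (include_latent) intersect(c("U", "W"), names(dt)))
  out <- dt[, keep, with = FALSE]
  out$G <- ifelse(is.infinite(out$G), "never", as.character(out$G))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_panel
#' @param validate Validate after reading (default `TRUE`).
#' @export
read_panel <- function(path, validate = TRUE) {
  dt <- data.table::fread(path, colClasses = list(character = "G"))
  if ("G" %in% names(dt)) {
    g <- suppressWarnings(as.numeric(dt$G))
    g[dt$G %in% c("never", "Inf")] <- Inf
    dt$G <- g
  }
  if (validate) validate_panel(dt) else dt
}

#' Write a results or estimates table to CSV
#'
#' Plain CSV writer for the tidy tables produced by the study harness
#' (estimates, truths, bias/SE summaries) and the weight exporter.
#'
#' @param x A data.frame/data.table.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_results <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path)
  invisible(path)
}

# Wide-format view used internally by all estimation code: per-unit vectors
# and n x T matrices, units in unit_id order. Estimation entry points accept
# either a long panel or an already-built view (so the study harness can
# pivot once per replicate and reuse it across dozens of estimator calls).
.panel_wide <- function(panel) {
  if (inherits(panel, "tvt_panel_wide")) return(panel)
  dt <- validate_panel(panel, strict = TRUE)
  Tn <- max(dt$time)
  n <- nrow(dt) / Tn
  mat <- function(col) matrix(dt[[col]], n, Tn, byrow = TRUE)
  structure(
    list(
      unit_ids = dt$unit_id[seq(1L, nrow(dt), by = Tn)],
      G = dt$G[seq(1L, nrow(dt), by = Tn)],
      T = Tn, n = n,
      D = mat("D"), X = mat("X"), Y = mat("Y")
    ),
    class = "tvt_panel_wide"
  )
}
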