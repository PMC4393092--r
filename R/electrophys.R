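# Conductance from current-voltage recordings. The slope of I (pA)
# versus V (mV) is numerically the conductance in nS. The fit is
# ordinary least squares with a free intercept: bilayer recordings can
# carry an offset current, which must load the intercept, never the
# slope.

#' Membrane conductance from an I/V series
#'
#' OLS fit of current against voltage over the points inside `v_range`
#' (default -20 to +20 mV, the window used for bilayer conductance
#' readings).
#'
#' @param iv an `iv_series` (see [read_iv()] / [iv_series()]).
#' @param v_range length-2 voltage window in mV.
#' @return object of class `conductance_result`: list with `g_nS`
#'   (slope), `intercept_pA`, `v_range_mV`, `r_squared`, `n_points`.
#' @export
conductance <- function(iv, v_range = c(-20, 20)) {
  keep <- iv$voltage_mV >= min(v_range) & iv$voltage_mV <= max(v_range)
  v <- iv$voltage_mV[keep]
  i <- iv$current_pA[keep]
  if (length(unique(v)) < 2) {
    stop("need at least 2 distinct voltages inside [",
         min(v_range), ", ", max(v_range), "] mV; have ", length(unique(v)))
  }
  fit <- stats::lm(i ~ v)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((i - mean(i))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(g_nS = unname(stats::coef(fit)[2]),
                 intercept_pA = unname(stats::coef(fit)[1]),
                 v_range_mV = c(min(v_range), max(v_range)),
                 r_squared = r2,
                 n_points = length(v)),
            class = "conductance_result")
}

#' @export
print.conductance_result <- function(x, ...) {
  cat(sprintf("conductance g = %.4f nS (intercept %.3f pA, R^2 %.4f, %d points in [%g, %g] mV)\n",
              x$g_nS, x$intercept_pA, x$r_squared, x$n_points,
              x$v_range_mV[1], x$v_range_mV[2]))
  invisible(x)
}

#' Normalized conductance
#'
#' Conductance in a test condition divided by the reference condition
#' (e.g. after metabolite addition over the plain-salt value); 0.90 means
#' a 10 percent decrease.
#'
#' @param g_test,g_reference conductances (numbers or
#'   `conductance_result`s).
#' @return ratio `g_test / g_reference`.
#' @export
normalized_conductance <- function(g_test, g_reference) {
  gt <- if (inherits(g_test, "conductance_result")) g_test$g_nS else g_test
  gr <- if (inherits(g_reference, "conductance_result")) g_reference$g_nS else g_reference
  if (gr == 0) stop("reference conductance is zero")
  gt / gr
}
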