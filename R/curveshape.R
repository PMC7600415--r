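## Peak and persistency curve-shape parameters of fitted lactation curves.

#' Curve shape of a fitted Ali-Schaeffer curve
#'
#' For the Ali-Schaeffer model the peak parameter is `b0` (the curve level)
#' and persistency is described by the pair `(b1, b2)` (the polynomial
#' decline terms). `b3` and `b4` do not enter the shape summary.
#'
#' @param b fitted 5-parameter vector.
#' @return list of class `"curve_shape"` with `model_id`, `peak`,
#'   `persistency_b1`, `persistency_b2`.
#' @export
shape_ali_schaeffer <- function(b) {
  stopifnot(length(b) == 5L)
  structure(list(model_id = "ali_schaeffer", peak = b[1],
                 persistency_b1 = b[2], persistency_b2 = b[3]),
            class = "curve_shape")
}

#' Curve shape of a fitted parabolic yield-density curve
#'
#' Peak parameter \eqn{-b_1/(2 b_2)} (the stationary point of the
#' denominator quadratic, i.e. the extremum location of the curve) and
#' persistency \eqn{2 b_0 \cdot days + b_1} with `days` defaulting to the
#' 210-day standardized horizon.
#'
#' @param b fitted 3-parameter vector; `b[3]` must be non-zero.
#' @param days lactation horizon used in the persistency expression.
#' @return list of class `"curve_shape"` with `model_id`, `peak`,
#'   `persistency`.
#' @export
shape_pyd <- function(b, days = 210) {
  stopifnot(length(b) == 3L)
  if (b[3] == 0)
    stop_caprihap("peak undefined: quadratic coefficient b2 is zero",
                  "caprihap_domain_error")
  structure(list(model_id = "parabolic_yield_density",
                 peak = -b[2] / (2 * b[3]),
                 persistency = 2 * b[1] * days + b[2]),
            class = "curve_shape")
}

#' Curve shape of a lactation fit
#'
#' Dispatches on the fitted model family.
#'
#' @param fit a `"lactation_fit"`.
#' @param days horizon for the parabolic yield-density persistency.
#' @return a `"curve_shape"` list.
#' @export
curve_shape <- function(fit, days = 210) {
  stopifnot(inherits(fit, "lactation_fit"))
  switch(fit$model_id,
         ali_schaeffer = shape_ali_schaeffer(fit$b),
         parabolic_yield_density = shape_pyd(fit$b, days = days),
         stop_caprihap(sprintf("no shape definition for model '%s'", fit$model_id),
                       "caprihap_registry_error"))
}

#' @export
print.curve_shape <- function(x, ...) {
  cat(sprintf("<curve_shape %s: peak = %.4g%s>\n", x$model_id, x$peak,
              if (!is.null(x$persistency))
                sprintf(", persistency = %.4g", x$persistency)
              else sprintf(", persistency b1 = %.4g, b2 = %.4g",
                           x$persistency_b1, x$persistency_b2)))
  invisible(x)
}
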