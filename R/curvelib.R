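## Lactation-curve model registry and per-lactation least-squares fitting.
##
## Models map days in milk (DIM, t >= 1) and a parameter vector b to a
## predicted trait value. Fitting is multi-start damped least squares
## (Levenberg-Marquardt) with convergence declared when the relative change
## in the residual sum of squares falls below `tol`.

#' Ali-Schaeffer lactation curve
#'
#' Five-parameter curve, linear in its parameters:
#' \deqn{y(t) = b_0 + b_1 x + b_2 x^2 + b_3 \ln(1/x) + b_4 \ln^2(1/x),
#'       \quad x = t/T,}
#' the classic test-day model for milk yield and composition. The scaling
#' horizon \eqn{T} defaults to 340 days, the value used in the original
#' formulation of the model; all curve-shape quantities extracted from a fit
#' are invariant to the choice of \eqn{T}.
#'
#' @param t days in milk, numeric vector, all `>= 1`.
#' @param b numeric parameter vector `(b0, b1, b2, b3, b4)`.
#' @param horizon scaling horizon \eqn{T} in days.
#' @return predicted trait values, same length as `t`.
#' @seealso [parabolic_yield_density()], [fit_lactation()]
#' @export
#' @examples
#' ali_schaeffer(1:210, c(3.5, 0.2, -0.1, 0.05, 0.01))
ali_schaeffer <- function(t, b, horizon = 340) {
  if (any(t <= 0)) stop_caprihap("days in milk must be positive", "caprihap_domain_error")
  stopifnot(length(b) == 5L, all(is.finite(b)))
  x <- t / horizon
  lx <- log(1 / x)
  b[1] + b[2] * x + b[3] * x^2 + b[4] * lx + b[5] * lx^2
}

#' Parabolic yield-density curve
#'
#' Reciprocal-quadratic curve \eqn{y(t) = 1/(b_0 + b_1 t + b_2 t^2)}, used
#' here for somatic cell count. The denominator must stay positive over the
#' requested days.
#'
#' @param t days in milk, numeric vector.
#' @param b numeric parameter vector `(b0, b1, b2)`.
#' @return predicted trait values.
#' @export
parabolic_yield_density <- function(t, b) {
  stopifnot(length(b) == 3L, all(is.finite(b)))
  den <- b[1] + b[2] * t + b[3] * t^2
  if (any(den <= 0))
    stop_caprihap("parabolic yield-density denominator <= 0 on the requested days",
                  "caprihap_domain_error")
  1 / den
}

#' Define a lactation-curve model
#'
#' @param model_id unique model name.
#' @param k number of parameters.
#' @param fn function `(t, b) -> fitted values`.
#' @param init function `(t, y) -> list of starting parameter vectors`
#'   (the multi-start grid; moment-based heuristics for the built-ins).
#' @param linear_in_params logical; `TRUE` when `fn` is linear in `b`, in
#'   which case the fit agrees with ordinary least squares on the design
#'   columns.
#' @param design for linear models only: function `(t) -> design matrix`.
#' @return an object of class `"lactation_model"`.
#' @export
lactation_model <- function(model_id, k, fn, init, linear_in_params = FALSE,
                            design = NULL) {
  stopifnot(is.character(model_id), length(model_id) == 1L, nzchar(model_id),
            is.function(fn), is.function(init))
  structure(list(model_id = model_id, k = as.integer(k), fn = fn, init = init,
                 linear_in_params = isTRUE(linear_in_params), design = design),
            class = "lactation_model")
}

#' @export
print.lactation_model <- function(x, ...) {
  cat(sprintf("<lactation_model '%s': k = %d%s>\n", x$model_id, x$k,
              if (x$linear_in_params) ", linear in parameters" else ""))
  invisible(x)
}

## ---- registry ------------------------------------------------------------

.registry <- new.env(parent = emptyenv())

#' Register a lactation-curve model
#'
#' Adds a user-defined model to the session registry. Built-in model ids
#' cannot be overwritten.
#'
#' @param model a [lactation_model()].
#' @return the model, invisibly.
#' @export
register_model <- function(model) {
  stopifnot(inherits(model, "lactation_model"))
  if (model$model_id %in% names(lactation_models()))
    stop_caprihap(sprintf("model id '%s' is already registered", model$model_id),
                  "caprihap_registry_error")
  assign(model$model_id, model, envir = .registry)
  invisible(model)
}

#' Remove a user-registered model
#' @param model_id id previously passed to [register_model()].
#' @export
unregister_model <- function(model_id) {
  if (exists(model_id, envir = .registry)) rm(list = model_id, envir = .registry)
  invisible(NULL)
}

#' The lactation-curve model registry
#'
#' Returns the built-in models (Ali-Schaeffer; parabolic yield-density; Wood;
#' Wilmink with the customary fixed decay 0.05/day; quadratic polynomial;
#' inverse quadratic polynomial; mixed log) plus any user-registered models.
#'
#' @return named list of [lactation_model()] objects.
#' @export
lactation_models <- function() {
  out <- builtin_models()
  for (nm in ls(.registry)) out[[nm]] <- get(nm, envir = .registry)
  out
}

## ---- fitting -------------------------------------------------------------

#' Fit a lactation-curve model to one lactation
#'
#' Damped least squares (Levenberg-Marquardt) started from every vector in
#' the model's initial grid; the start reaching the lowest residual sum of
#' squares wins. A start converges when the relative RSS change between
#' successive accepted steps drops below `tol` within `max_iter` iterations.
#'
#' @param t days in milk, strictly increasing.
#' @param y observed trait values.
#' @param model a [lactation_model()] or a model id from [lactation_models()].
#' @param tol relative RSS convergence tolerance.
#' @param max_iter maximum iterations per start.
#' @param starts optional list of starting vectors overriding the model grid.
#' @return object of class `"lactation_fit"`: list with `model_id`, `b`,
#'   `converged`, `iterations`, `rss`, `residuals`, `fitted`, `n`, `t`, `y`.
#' @export
fit_lactation <- function(t, y, model, tol = 1e-8, max_iter = 2000L,
                          starts = NULL) {
  if (is.character(model)) {
    model <- lactation_models()[[model]]
    if (is.null(model)) stop_caprihap("unknown model id", "caprihap_registry_error")
  }
  stopifnot(inherits(model, "lactation_model"))
  n <- length(t)
  if (length(y) != n) stop_caprihap("t and y lengths differ", "caprihap_data_error")
  if (n < model$k)
    stop_caprihap(sprintf("insufficient data: n = %d observations for k = %d parameters",
                          n, model$k), "caprihap_insufficient_data")
  if (any(diff(t) <= 0)) stop_caprihap("t must be strictly increasing", "caprihap_data_error")

  if (is.null(starts)) starts <- model$init(t, y)
  stopifnot(length(starts) >= 1L)

  ## analytic Jacobian for linear-in-parameter models (their design matrix);
  ## forward differences otherwise
  jac <- if (model$linear_in_params && !is.null(model$design)) {
    J_lin <- model$design(t)
    function(b, f0) J_lin
  } else NULL

  best <- NULL
  for (b0 in starts) {
    res <- lm_least_squares(t, y, model$fn, as.numeric(b0), tol, max_iter, jac)
    if (is.null(best) || (is.finite(res$rss) && res$rss < best$rss)) best <- res
  }
  fitted <- tryCatch(model$fn(t, best$b), error = function(e) rep(NA_real_, n))
  structure(list(model_id = model$model_id, b = best$b, converged = best$converged,
                 iterations = best$iterations, rss = best$rss,
                 residuals = y - fitted, fitted = fitted, n = n, k = model$k,
                 t = t, y = y),
            class = "lactation_fit")
}

#' @export
print.lactation_fit <- function(x, ...) {
  cat(sprintf("<lactation_fit '%s': n = %d, rss = %.6g, %s in %d iter>\n",
              x$model_id, x$n, x$rss,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat("  b =", signif(x$b, 6), "\n")
  invisible(x)
}

## Damped Gauss-Newton / Levenberg-Marquardt with forward-difference
## Jacobian. For models linear in b the Jacobian is exact, so the first
## accepted step with small damping lands on the OLS solution.
lm_least_squares <- function(t, y, fn, b, tol, max_iter, jac = NULL) {
  safe_rss <- function(bb) {
    f <- tryCatch(fn(t, bb), error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f))) return(Inf)
    sum((y - f)^2)
  }
  k <- length(b)
  lambda <- 1e-3
  rss <- safe_rss(b)
  if (!is.finite(rss)) return(list(b = b, rss = Inf, converged = FALSE, iterations = 0L))
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    f0 <- fn(t, b)
    r <- y - f0
    if (!is.null(jac)) J <- jac(b, f0)
    else {
      J <- matrix(0, length(t), k)
      for (j in seq_len(k)) {
        h <- 1e-7 * max(abs(b[j]), 1)
        bj <- b; bj[j] <- bj[j] + h
        fj <- tryCatch(fn(t, bj), error = function(e) rep(NA_real_, length(t)))
        J[, j] <- (fj - f0) / h
      }
    }
    if (any(!is.finite(J))) break
    A <- crossprod(J)
    g <- crossprod(J, r)
    step_ok <- FALSE
    for (try in 1:30) {
      delta <- tryCatch(solve(A + lambda * diag(diag(A) + 1e-12, k), g),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        b_new <- b + as.numeric(delta)
        rss_new <- safe_rss(b_new)
        if (is.finite(rss_new) && rss_new <= rss) {
          rel <- (rss - rss_new) / max(rss, .Machine$double.eps)
          b <- b_new
          rss <- rss_new
          lambda <- max(lambda / 10, 1e-12)
          step_ok <- TRUE
          if (rel < tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!step_ok) { converged <- TRUE; break }  # no descent direction: stationary
    if (converged) break
  }
  ## undamped Gauss-Newton polish: exact for linear-in-parameter models
  if (converged && is.finite(rss)) {
    f0 <- tryCatch(fn(t, b), error = function(e) NULL)
    if (!is.null(f0) && all(is.finite(f0))) {
      J <- if (!is.null(jac)) jac(b, f0) else NULL
      if (!is.null(J) && all(is.finite(J))) {
        delta <- tryCatch(qr.solve(J, y - f0), error = function(e) NULL)
        if (!is.null(delta)) {
          b_new <- b + as.numeric(delta)
          rss_new <- safe_rss(b_new)
          if (is.finite(rss_new) && rss_new <= rss * (1 + 1e-9)) {
            b <- b_new; rss <- rss_new
          }
        }
      }
    }
  }
  list(b = b, rss = rss, converged = converged, iterations = it)
}

## ---- built-in models -----------------------------------------------------

## moment-based starting grids: level from the mean of y, slope/shape
## perturbed around zero.
grid_linear <- function(k) {
  function(t, y) {
    m <- mean(y)
    base <- c(m, rep(0, k - 1))
    out <- list(base)
    for (j in 2:k) {
      up <- base; up[j] <- 0.1 * max(abs(m), 1); out[[length(out) + 1L]] <- up
      dn <- base; dn[j] <- -0.1 * max(abs(m), 1); out[[length(out) + 1L]] <- dn
    }
    out
  }
}

builtin_models <- function() {
  horizon <- 340

  as_design <- function(t) {
    x <- t / horizon; lx <- log(1 / x)
    cbind(1, x, x^2, lx, lx^2)
  }
  wil_design <- function(t) cbind(1, t, exp(-0.05 * t))
  quad_design <- function(t) cbind(1, t, t^2)
  mlog_design <- function(t) cbind(1, sqrt(t), log(t))

  models <- list(
    ali_schaeffer = lactation_model(
      "ali_schaeffer", 5,
      fn = function(t, b) ali_schaeffer(t, b, horizon = horizon),
      init = grid_linear(5),
      linear_in_params = TRUE, design = as_design),

    parabolic_yield_density = lactation_model(
      "parabolic_yield_density", 3,
      fn = function(t, b) parabolic_yield_density(t, b),
      init = function(t, y) {
        ## moments of 1/y give a linear start for the denominator
        ypos <- pmax(y, .Machine$double.eps)
        z <- 1 / ypos
        cf <- tryCatch(stats::lm.fit(cbind(1, t, t^2), z)$coefficients,
                       error = function(e) c(1 / mean(ypos), 0, 0))
        cf[!is.finite(cf)] <- 0
        list(as.numeric(cf), c(1 / mean(ypos), 0, 0),
             c(1 / mean(ypos), 1e-5, 0), c(1 / mean(ypos), -1e-5, 1e-7))
      }),

    wood = lactation_model(
      "wood", 3,
      fn = function(t, b) b[1] * t^b[2] * exp(-b[3] * t),
      init = function(t, y) {
        ## log-linearization start where y > 0
        ok <- y > 0
        if (sum(ok) >= 3) {
          cf <- tryCatch(stats::lm.fit(cbind(1, log(t[ok]), t[ok]), log(y[ok]))$coefficients,
                         error = function(e) c(log(max(mean(y), 0.1)), 0.1, 0.002))
          cf[!is.finite(cf)] <- 0
          list(c(exp(cf[1]), cf[2], -cf[3]),
               c(max(mean(y), 0.1), 0.2, 0.002), c(max(mean(y), 0.1), 0.05, 0.001))
        } else list(c(max(mean(y), 0.1), 0.2, 0.002))
      }),

    wilmink = lactation_model(
      "wilmink", 3,
      fn = function(t, b) b[1] + b[2] * t + b[3] * exp(-0.05 * t),
      init = grid_linear(3),
      linear_in_params = TRUE, design = wil_design),

    quadratic = lactation_model(
      "quadratic", 3,
      fn = function(t, b) b[1] + b[2] * t + b[3] * t^2,
      init = grid_linear(3),
      linear_in_params = TRUE, design = quad_design),

    inverse_quadratic = lactation_model(
      "inverse_quadratic", 3,
      fn = function(t, b) {
        den <- b[1] + b[2] * t + b[3] * t^2
        if (any(den == 0)) stop("zero denominator")
        t / den
      },
      init = function(t, y) {
        ypos <- pmax(y, .Machine$double.eps)
        z <- t / ypos
        cf <- tryCatch(stats::lm.fit(cbind(1, t, t^2), z)$coefficients,
                       error = function(e) c(1, 1 / mean(ypos), 0))
        cf[!is.finite(cf)] <- 0
        list(as.numeric(cf), c(1, 1 / mean(ypos), 0))
      }),

    mixed_log = lactation_model(
      "mixed_log", 3,
      fn = function(t, b) b[1] + b[2] * sqrt(t) + b[3] * log(t),
      init = grid_linear(3),
      linear_in_params = TRUE, design = mlog_design)
  )
  models
}
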