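#' Yeoh hyperelastic parameters
#'
#' Coefficients of the three-term Yeoh strain-energy model for the
#' tissue-mimicking gel. Shipped defaults are the gel's fitted values:
#' c1 = 7.3 kPa, c2 = 9.4 kPa, c3 = 0.
#'
#' @param c1,c2,c3 material coefficients, Pa (`c1 > 0`; `c2, c3 >= 0`).
#' @return an object of class `yeoh_params`.
#' @export
yeoh_params <- function(c1 = 7300, c2 = 9400, c3 = 0) {
  if (c1 <= 0) stop("`c1` must be > 0", call. = FALSE)
  if (c2 < 0 || c3 < 0) stop("`c2` and `c3` must be >= 0", call. = FALSE)
  structure(list(c1 = c1, c2 = c2, c3 = c3), class = "yeoh_params")
}

#' @export
print.yeoh_params <- function(x, ...) {
  cat(sprintf("Yeoh parameters: c1 = %g Pa, c2 = %g Pa, c3 = %g Pa\n",
              x$c1, x$c2, x$c3))
  invisible(x)
}

#' Uniaxial first Piola-Kirchhoff stress of the Yeoh model
#'
#' For an isotropic, incompressible Yeoh solid under uniaxial stretch
#' `lam`, with isochoric first invariant `I1 = lam^2 + 2/lam`:
#' \deqn{T = 2 (\lambda - \lambda^{-2}) [c_1 + 2 c_2 (I_1 - 3) +
#'   3 c_3 (I_1 - 3)^2]}
#' The stress-free reference (`T = 0` at `lam = 1`) and the neo-Hookean
#' reduction (`c2 = c3 = 0`) follow directly.
#'
#' @param params a [yeoh_params()].
#' @param lam principal stretch (> 0); vectorised.
#' @return engineering (first Piola-Kirchhoff) stress, Pa.
#' @examples
#' yeoh_uniaxial_stress(yeoh_params(), lam = 1.2)
#' @export
yeoh_uniaxial_stress <- function(params, lam) {
  stopifnot(inherits(params, "yeoh_params"))
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop("`lam` must be positive", call. = FALSE)
  i1 <- lam^2 + 2 / lam
  e <- i1 - 3
  2 * (lam - lam^-2) * (params$c1 + 2 * params$c2 * e + 3 * params$c3 * e^2)
}

#' Fit Yeoh parameters to uniaxial stretch-stress data
#'
#' The uniaxial Yeoh stress is linear in `(c1, c2, c3)` once the kinematic
#' factor `2 (lam - lam^-2)` is factored out, so the fit is an exact linear
#' least-squares solve — no starting values, no convergence question.
#' Columns of the design matrix are `f`, `2 f (I1 - 3)`, `3 f (I1 - 3)^2`
#' with `f = 2 (lam - lam^-2)`.
#'
#' @param stretch principal stretches (> 0); at least 3 distinct values
#'   (2 if `fix_c3_zero`).
#' @param stress measured engineering stresses, Pa.
#' @param fix_c3_zero fit the two-term model with `c3 = 0`.
#' @return an object of class `yeoh_fit` with components `coefficients`
#'   (named c1, c2, c3), `fitted.values`, `residuals`, `sigma` (residual
#'   SE), `vcov`, `df.residual` and the data; supports [coef()],
#'   [predict()], [residuals()], `summary()` and `print()`.
#' @examples
#' lam <- seq(0.85, 1.3, length.out = 12)
#' fit <- fit_yeoh(lam, yeoh_uniaxial_stress(yeoh_params(), lam))
#' coef(fit)
#' @export
fit_yeoh <- function(stretch, stress, fix_c3_zero = FALSE) {
  if (length(stretch) != length(stress))
    stop("`stretch` and `stress` must have equal length", call. = FALSE)
  if (any(stretch <= 0)) stop("`stretch` must be positive", call. = FALSE)
  need <- if (fix_c3_zero) 2L else 3L
  if (length(unique(stretch)) < need)
    stop(sprintf("need >= %d distinct stretches", need), call. = FALSE)
  f <- 2 * (stretch - stretch^-2)
  e <- stretch^2 + 2 / stretch - 3
  X <- cbind(c1 = f, c2 = 2 * f * e, c3 = 3 * f * e^2)
  if (fix_c3_zero) X <- X[, 1:2, drop = FALSE]
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("rank-deficient design: stretches do not identify the parameters",
         call. = FALSE)
  beta <- qr.coef(qrx, stress)
  fitted <- as.vector(X %*% beta)
  res <- stress - fitted
  dfres <- length(stress) - ncol(X)
  sigma2 <- if (dfres > 0) sum(res^2) / dfres else NA_real_
  xtxinv <- chol2inv(qr.R(qrx))
  cf <- c(beta, c3 = 0)[c("c1", "c2", "c3")]
  vc <- matrix(0, 3, 3, dimnames = list(names(cf), names(cf)))
  vc[seq_len(ncol(X)), seq_len(ncol(X))] <- sigma2 * xtxinv
  structure(list(coefficients = cf, fitted.values = fitted,
                 residuals = res, sigma = sqrt(sigma2), vcov = vc,
                 df.residual = dfres, fix_c3_zero = fix_c3_zero,
                 data = data.frame(stretch = stretch, stress = stress)),
            class = "yeoh_fit")
}

#' @export
print.yeoh_fit <- function(x, ...) {
  cat("Yeoh uniaxial fit",
      if (x$fix_c3_zero) "(c3 fixed at 0)" else "", "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("residual SE: %.4g Pa on %d df\n", x$sigma, x$df.residual))
  invisible(x)
}

#' @export
coef.yeoh_fit <- function(object, ...) object$coefficients

#' @export
residuals.yeoh_fit <- function(object, ...) object$residuals

#' @export
vcov.yeoh_fit <- function(object, ...) object$vcov

#' @export
predict.yeoh_fit <- function(object, newdata = NULL, ...) {
  lam <- if (is.null(newdata)) object$data$stretch
         else if (is.list(newdata)) newdata$stretch else newdata
  cf <- object$coefficients
  f <- 2 * (lam - lam^-2)
  e <- lam^2 + 2 / lam - 3
  unname(f * (cf["c1"] + 2 * cf["c2"] * e + 3 * cf["c3"] * e^2))
}

#' @export
summary.yeoh_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se)
  if (object$fix_c3_zero) tab <- tab[1:2, , drop = FALSE]
  structure(list(coefficients = tab, sigma = object$sigma,
                 df.residual = object$df.residual,
                 fix_c3_zero = object$fix_c3_zero),
            class = "summary.yeoh_fit")
}

#' @export
print.summary.yeoh_fit <- function(x, ...) {
  cat("Yeoh uniaxial fit",
      if (x$fix_c3_zero) "(c3 fixed at 0)" else "", "\n")
  print(x$coefficients)
  cat(sprintf("residual SE: %.4g Pa on %d df\n", x$sigma, x$df.residual))
  invisible(x)
}

#' Kelvin-Voigt viscoelastic parameters
#'
#' Linear viscoelastic solid `sigma = E eps + eta deps/dt`, the simplified
#' model of the gel's dynamics. The retardation time is `tau = eta / E`;
#' the gel's value is approximately 0.01 s. Supply any two of the three
#' quantities: defaults give `E = 10 kPa`, `tau = 0.01 s`,
#' `eta = 100 Pa.s`.
#'
#' @param e_mod elastic modulus E, Pa (> 0).
#' @param eta viscosity, Pa.s (> 0); defaults to `e_mod * tau`.
#' @param tau retardation time, s; used only when `eta` is missing.
#' @return an object of class `kelvin_voigt` with `e_mod`, `eta`, `tau`.
#' @export
kelvin_voigt <- function(e_mod = 1e4, eta = NULL, tau = 0.01) {
  if (e_mod <= 0) stop("`e_mod` must be > 0", call. = FALSE)
  if (is.null(eta)) eta <- e_mod * tau
  if (eta <= 0) stop("`eta` must be > 0", call. = FALSE)
  structure(list(e_mod = e_mod, eta = eta, tau = eta / e_mod),
            class = "kelvin_voigt")
}

#' @export
print.kelvin_voigt <- function(x, ...) {
  cat(sprintf("Kelvin-Voigt: E = %g Pa, eta = %g Pa.s, tau = %g s\n",
              x$e_mod, x$eta, x$tau))
  invisible(x)
}

#' Retardation time of a Kelvin-Voigt solid
#'
#' `tau = eta / E`, the time scale on which strain approaches its static
#' value under constant stress.
#'
#' @param e_mod elastic modulus, Pa (> 0).
#' @param eta viscosity, Pa.s.
#' @return tau, s.
#' @export
retardation_time <- function(e_mod, eta) {
  if (any(e_mod <= 0)) stop("`e_mod` must be > 0", call. = FALSE)
  eta / e_mod
}

#' Strain history container
#'
#' Time series of strain with its rate; the rate defaults to the same
#' central/one-sided finite-difference scheme used for velocity fields so
#' constitutive evaluation and field processing share one discretisation.
#'
#' @param time strictly increasing times, s.
#' @param strain strain values (dimensionless).
#' @param strain_rate optional strain rate, 1/s; computed by finite
#'   differences when omitted.
#' @return an object of class `strain_history`.
#' @export
strain_history <- function(time, strain, strain_rate = NULL) {
  if (length(time) != length(strain))
    stop("`time` and `strain` must have equal length", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("`time` must be strictly increasing", call. = FALSE)
  if (is.null(strain_rate)) {
    n <- length(time)
    strain_rate <- numeric(n)
    strain_rate[1] <- (strain[2] - strain[1]) / (time[2] - time[1])
    strain_rate[n] <- (strain[n] - strain[n - 1]) / (time[n] - time[n - 1])
    if (n > 2)
      strain_rate[2:(n - 1)] <- (strain[3:n] - strain[1:(n - 2)]) /
        (time[3:n] - time[1:(n - 2)])
  } else if (length(strain_rate) != length(time)) {
    stop("`strain_rate` must match `time` in length", call. = FALSE)
  }
  structure(list(time = time, strain = strain, strain_rate = strain_rate),
            class = "strain_history")
}

#' Kelvin-Voigt stress response to a strain history
#'
#' Pointwise `sigma(t) = E eps(t) + eta deps/dt`.
#'
#' @param params a [kelvin_voigt()].
#' @param history a [strain_history()].
#' @return stress series, Pa.
#' @export
kelvin_voigt_stress <- function(params, history) {
  stopifnot(inherits(params, "kelvin_voigt"),
            inherits(history, "strain_history"))
  params$e_mod * history$strain + params$eta * history$strain_rate
}

#' Simulate creep of a Kelvin-Voigt solid under constant stress
#'
#' Inverts the constitutive law as the ODE
#' `deps/dt = (sigma0 - E eps) / eta` and integrates it numerically from
#' zero strain. The closed-form solution is
#' `eps(t) = (sigma0 / E) (1 - exp(-t / tau))`, which the numerical result
#' should match to integration tolerance.
#'
#' @param params a [kelvin_voigt()].
#' @param sigma0 applied stress, Pa.
#' @param times output times, s (starting at 0).
#' @return a [strain_history()] carrying the simulated strain.
#' @export
kelvin_voigt_creep <- function(params, sigma0, times) {
  stopifnot(inherits(params, "kelvin_voigt"))
  sol <- deSolve::ode(y = c(eps = 0), times = times,
                      func = function(t, y, p)
                        list((sigma0 - params$e_mod * y[1]) / params$eta),
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  strain_history(times, as.vector(sol[, "eps"]))
}
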