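#' Fit exponential growth from cell-count time courses
#'
#' Fits \eqn{X(t) = X_0 e^{\mu t}} by minimizing the robust soft-L1
#' objective \eqn{\sum_i \rho(r_i / f_{scale})} with
#' \eqn{\rho(z) = 2(\sqrt{1+z^2} - 1)} on standardized residuals
#' (residuals divided by the series' median absolute count, so that the
#' dimensionless `f_scale` marks the outlier transition regardless of
#' the counting units).  With `robust = FALSE` the ordinary
#' least-squares objective is used.  Standard errors come from the
#' (weighted) Gauss-Newton Jacobian at the optimum.
#'
#' @param times sampling times, h.
#' @param counts cell counts (> 0), same length as `times`.
#' @param robust use the soft-L1 loss (default) or plain least squares.
#' @param f_scale soft-L1 scale on standardized residuals.
#' @return object of class `"growth_fit"`: `X0`, `mu`, `se_X0`, `se_mu`,
#'   `loss`, `converged`, `n`.
#' @export
fit_growth <- function(times, counts, robust = TRUE, f_scale = 0.3) {
  if (length(times) != length(counts)) stop("times and counts differ in length")
  if (length(unique(times)) < 3) stop("need at least 3 distinct time points")
  if (any(counts <= 0)) stop("counts must be positive")

  s <- stats::median(abs(counts))
  start <- stats::coef(stats::lm(log(counts) ~ times))
  par0 <- c(lx0 = unname(start[1]), mu = unname(start[2]))

  resid_fn <- function(par) (exp(par[1] + par[2] * times) - counts) / s
  obj <- function(par) {
    z <- resid_fn(par) / f_scale
    if (robust) sum(2 * (sqrt(1 + z^2) - 1)) else sum(z^2)
  }
  grad <- function(par) {
    f <- exp(par[1] + par[2] * times)
    z <- ((f - counts) / s) / f_scale
    psi <- if (robust) 2 * z / sqrt(1 + z^2) else 2 * z
    w <- psi / (s * f_scale)
    c(sum(w * f), sum(w * f * times))
  }
  opt <- stats::optim(par0, obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  gn <- sqrt(sum(grad(opt$par)^2))
  if (opt$convergence != 0 && gn > 1e-4) {
    stop("growth fit did not converge (final gradient norm ",
         format(gn, digits = 3), ")")
  }
  X0 <- exp(opt$par[1])
  mu <- opt$par[2]

  f <- X0 * exp(mu * times)
  e <- f - counts
  z <- (e / s) / f_scale
  w <- if (robust) 1 / sqrt(1 + z^2) else rep(1, length(e))
  J <- cbind(X0 = exp(mu * times), mu = X0 * times * exp(mu * times))
  n <- length(times)
  sigma2 <- sum(w * e^2) / max(n - 2, 1)
  # invert with the columns rescaled to unit diagonal (X0 and mu live on
  # wildly different scales)
  A <- crossprod(J, w * J)
  d <- sqrt(diag(A))
  cv <- tryCatch(sigma2 * solve(A / (d %o% d)) / (d %o% d),
                 error = function(e) matrix(NA_real_, 2, 2))
  structure(list(X0 = unname(X0), mu = unname(mu),
                 se_X0 = sqrt(abs(cv[1, 1])), se_mu = sqrt(abs(cv[2, 2])),
                 loss = opt$value, converged = TRUE, robust = robust, n = n),
            class = "growth_fit")
}

#' Biomass calibration from dry mass per cell
#' @param m_dw dry mass per cell, g.
#' @param se_m_dw its standard error, g.
#' @return object of class `"biomass_calibration"`.
#' @export
biomass_calibration <- function(m_dw, se_m_dw = 0) {
  stopifnot(m_dw > 0, se_m_dw >= 0)
  structure(list(m_dw = m_dw, se_m_dw = se_m_dw),
            class = "biomass_calibration")
}

.exprel <- function(x) ifelse(abs(x) < 1e-8, 1 + x / 2, expm1(x) / x)

#' Fit a specific exchange rate from medium concentration time courses
#'
#' With growth rate and initial biomass fixed from [fit_growth()] and a
#' [biomass_calibration()], the medium amount follows
#' \deqn{C(t) = C_0 + q \frac{B_0}{\mu}(e^{\mu t} - 1),}
#' linear in \eqn{(C_0, q)}, which is fitted by least squares.  If a
#' cell-free control series is supplied, a first-order decay constant k
#' is fitted to it (log-linear) and the model becomes the closed
#' solution of \eqn{dC/dt = q B(t) - k C}:
#' \deqn{C(t) = C_0 e^{-kt} + q \frac{B_0}{\mu + k}
#'   \left(e^{\mu t} - e^{-kt}\right),}
#' with k fixed from the control — still linear in \eqn{(C_0, q)} after
#' multiplying through by \eqn{e^{kt}}.  Positive q is secretion,
#' negative is uptake.  For \eqn{\mu \le 0} the biomass integral
#' degenerates continuously to \eqn{B_0 t} (linear-in-biomass-integral
#' form, logged).
#'
#' The reported standard error follows the measurement-repeatability
#' convention: the residual scatter is treated as the technical error of
#' a single measurement and propagated through a one-observation-per-
#' time-point design (no replicate-averaging gain), then combined in
#' quadrature with the relative errors of \eqn{\mu} and \eqn{B_0}.
#'
#' @param times sampling times, h (must include 0).
#' @param conc data.frame with columns `time_h` and `concentration`
#'   (one row per replicate measurement), or a numeric vector parallel
#'   to `times`.
#' @param growth a [fit_growth()] result for the same condition.
#' @param calib a [biomass_calibration()].
#' @param abiotic optional cell-free control data.frame (`time_h`,
#'   `concentration`) used to fix the decay constant.
#' @param fix_c0 fix \eqn{C_0} at the mean measured t=0 value instead of
#'   fitting it jointly with q.
#' @param metabolite label stored on the result.
#' @return object of class `"exchange_rate"`: `metabolite`, `q`, `se_q`,
#'   `lower`, `upper`, `C0`, `k`, `sigma`.
#' @export
fit_exchange <- function(times, conc, growth, calib, abiotic = NULL,
                         fix_c0 = FALSE, metabolite = NA_character_) {
  if (is.numeric(conc)) {
    conc <- data.frame(time_h = times, concentration = conc)
  }
  if (!0 %in% conc$time_h) stop("times must include 0")
  mu <- growth$mu
  B0 <- growth$X0 * calib$m_dw
  if (mu <= 0) {
    message("non-positive growth rate; using the linear-in-biomass-integral ",
            "limit for the exchange fit")
  }

  k <- 0
  if (!is.null(abiotic)) {
    if (any(abiotic$concentration <= 0)) {
      stop("cell-free control series must be positive for the decay fit")
    }
    k <- -unname(stats::coef(stats::lm(log(concentration) ~ time_h,
                                       data = abiotic))[2])
  }

  t <- conc$time_h
  y <- conc$concentration * exp(k * t)
  # integral of B(t) e^{kt}: the decay-corrected biomass exposure
  A <- B0 * t * .exprel((mu + k) * t)
  if (fix_c0) {
    C0 <- mean(y[t == 0])
    fit <- stats::lm(I(y - C0) ~ A - 1)
    q <- unname(stats::coef(fit)[1])
  } else {
    fit <- stats::lm(y ~ A)
    C0 <- unname(stats::coef(fit)[1])
    q <- unname(stats::coef(fit)[2])
  }
  dfree <- max(stats::df.residual(fit), 1)
  sigma <- sqrt(sum(stats::residuals(fit)^2) / dfree)
  if (!is.finite(sigma)) sigma <- 0

  # per-measurement propagation on the unique-time design
  tu <- sort(unique(t))
  Au <- B0 * tu * .exprel((mu + k) * tu)
  Xu <- if (fix_c0) cbind(Au) else cbind(1, Au)
  xtx <- tryCatch(solve(crossprod(Xu)), error = function(e) NULL)
  se_meas <- if (is.null(xtx)) NA_real_ else sigma * sqrt(xtx[ncol(Xu), ncol(Xu)])
  rel_mu <- abs(growth$se_mu / mu)
  rel_B0 <- sqrt((growth$se_X0 / growth$X0)^2 + (calib$se_m_dw / calib$m_dw)^2)
  se_q <- sqrt(se_meas^2 + q^2 * (rel_mu^2 + rel_B0^2))
  bounds <- propagate_bounds(q, se_q, mode = "propagated")
  structure(list(metabolite = metabolite, q = q, se_q = se_q,
                 lower = bounds[1], upper = bounds[2], C0 = C0, k = k,
                 sigma = sigma),
            class = "exchange_rate")
}

#' Turn an estimate and its error into flux bounds
#'
#' @param estimate point estimate (signed).
#' @param se in `"propagated"` mode the absolute standard error; in
#'   `"relative"` mode the relative standard error.
#' @param mode `"propagated"`: bounds `estimate -/+ se`; `"relative"`:
#'   `estimate * (1 -/+ se)` with the ordering enforced after sign
#'   handling.
#' @return numeric `c(lower, upper)`.
#' @export
propagate_bounds <- function(estimate, se, mode = c("propagated", "relative")) {
  mode <- match.arg(mode)
  stopifnot(se >= 0)
  b <- if (mode == "propagated") c(estimate - se, estimate + se)
       else estimate * c(1 - se, 1 + se)
  sort(b)
}

#' Combine independent relative standard errors in quadrature
#' @param ... relative standard errors.
#' @return `sqrt(sum(se^2))`.
#' @export
combine_rel_se <- function(...) sqrt(sum(c(...)^2))

#' Growth (biomass-flux) bounds from fitted rate and dry-mass calibration
#'
#' Half-width is the quadrature combination of the relative errors of
#' the fitted growth rate and the dry mass per cell, applied to \eqn{\mu}.
#'
#' @param growth a [fit_growth()] result.
#' @param calib a [biomass_calibration()].
#' @return numeric `c(lower, upper)` for the biomass reaction.
#' @export
growth_bounds <- function(growth, calib) {
  rel <- combine_rel_se(growth$se_mu / growth$mu, calib$se_m_dw / calib$m_dw)
  propagate_bounds(growth$mu, rel, mode = "relative")
}
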