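## Closed-form equilibrium binding isotherms and their least-squares fits.
## All three are exact solutions of the underlying quadratic mass-action
## equilibrium (no ligand-excess approximation), as appropriate when
## K_D < [target].

#' Stoichiometric titration curve
#'
#' Fraction of labeled RNA bound as a function of the molar ratio
#' r = \[RISC\]/\[RNA\]:
#' `f(r) = f_max * ((r + K_D + n) - sqrt((r + K_D + n)^2 - 4 r n)) / (2 n)`
#' where `n` is the stoichiometric equivalence point. Used to measure the
#' concentration of active, binding-competent RISC.
#'
#' @param r Molar ratio \[RISC\]/\[RNA\] (vectorized).
#' @param K_D Apparent dissociation constant (in ratio units), >= 0.
#' @param n Stoichiometric equivalence point, > 0.
#' @param f_max Maximum fraction bound, in (0, 1].
#' @export
titration_fraction <- function(r, K_D, n, f_max = 1) {
  stopifnot(K_D >= 0, n > 0, f_max > 0, f_max <= 1, all(r >= 0))
  b <- r + K_D + n
  disc <- b^2 - 4 * r * n
  if (any(disc < -1e-9 * b^2)) stop("negative discriminant")
  ## algebraically identical small-root form, (b - sqrt(disc))/(2n) =
  ## 2r/(b + sqrt(disc)): no cancellation when K_D dominates b
  f_max * 2 * r / (b + sqrt(pmax(disc, 0)))
}

#' Direct-binding isotherm (double filter binding)
#'
#' `f = ((E_T + S_T + K_D) - sqrt((E_T + S_T + K_D)^2 - 4 E_T S_T)) / (2 S_T)`
#'
#' @param E_T Total RISC concentration (nM).
#' @param S_T Total labeled target concentration (nM), > 0.
#' @param K_D Apparent dissociation constant (nM), >= 0.
#' @export
binding_fraction <- function(E_T, S_T, K_D) {
  stopifnot(S_T > 0, K_D >= 0, all(E_T >= 0))
  b <- E_T + S_T + K_D
  disc <- b^2 - 4 * E_T * S_T
  ## stable small-root form of the printed quadratic solution
  2 * E_T / (b + sqrt(pmax(disc, 0)))
}

#' Competition-binding isotherm
#'
#' Fraction of labeled target bound in the presence of an unlabeled
#' competitor with apparent dissociation constant `K_C`: the direct-binding
#' quadratic with the effective constant `K_D * (1 + C_T / K_C)`.
#'
#' @param E_T,S_T Total RISC and labeled-target concentrations (nM).
#' @param C_T Total competitor concentration (nM), >= 0 (vectorized).
#' @param K_D Labeled-target dissociation constant (nM).
#' @param K_C Competitor dissociation constant (nM), > 0.
#' @export
competition_fraction <- function(E_T, S_T, C_T, K_D, K_C) {
  if (any(K_C <= 0)) stop("K_C must be > 0")
  stopifnot(all(C_T >= 0))
  binding_fraction(E_T, S_T, K_D * (1 + C_T / K_C))
}

#' Fit a binding isotherm by nonlinear least squares
#'
#' Free parameters follow the assays' usage: titration fits
#' `(K_D, n, f_max)`; direct binding fits `K_D` (plus `f_max` when
#' `float_fmax = TRUE`, exposed because the original fits do not state it);
#' competition fits `K_C` with `(E_T, S_T, K_D)` fixed from the direct
#' experiment. Fractions are assumed background-subtracted and normalized
#' upstream. Unweighted least squares; CIs are +/- 1.96 SE from the fit
#' covariance.
#'
#' @param model `"titration"`, `"direct"` or `"competition"`.
#' @param data data.frame with columns `x` (r, E_T or C_T respectively) and
#'   `fraction_bound`.
#' @param fixed Named list of fixed parameters (`E_T`, `S_T`, `K_D` for
#'   competition; `S_T` for direct).
#' @param float_fmax Float `f_max` (direct model only; default `FALSE`,
#'   fixing `f_max = 1`).
#' @param start Optional named list of start values (heuristics otherwise).
#' @return A list: `model`, `estimate` (named), `se`, `ci` (2-column
#'   matrix), `fitted`, `residuals`, `fit` (the `nls` object).
#' @export
fit_isotherm <- function(model = c("titration", "direct", "competition"),
                         data, fixed = list(), float_fmax = FALSE,
                         start = NULL) {
  model <- match.arg(model)
  stopifnot(all(c("x", "fraction_bound") %in% names(data)))
  x <- data$x; y <- data$fraction_bound
  ctrl <- stats::nls.control(maxiter = 200, scaleOffset = 1, warnOnly = FALSE)

  if (model == "titration") {
    if (is.null(start)) {
      fm <- max(y)
      half <- x[which.min(abs(y - fm / 2))]
      start <- list(K_D = max(half / 10, 1e-4), n = max(2 * half, 1e-3),
                    f_max = min(fm, 0.999))
    }
    fit <- stats::nls(y ~ titration_fraction(x, K_D, n, f_max),
                      start = start, control = ctrl,
                      algorithm = "port",
                      lower = c(K_D = 0, n = 1e-6, f_max = 1e-3),
                      upper = c(K_D = Inf, n = Inf, f_max = 1))
  } else if (model == "direct") {
    S_T <- fixed$S_T %||% stop("direct model requires fixed S_T")
    if (float_fmax) {
      if (is.null(start)) {
        start <- list(K_D = max(x[which.min(abs(y - max(y) / 2))], 1e-6),
                      f_max = min(max(y), 0.999))
      }
      fit <- stats::nls(y ~ f_max * binding_fraction(x, S_T, K_D),
                        start = start, control = ctrl, algorithm = "port",
                        lower = c(K_D = 0, f_max = 1e-3),
                        upper = c(K_D = Inf, f_max = 1))
    } else {
      if (is.null(start)) {
        start <- list(K_D = max(x[which.min(abs(y - 0.5))], 1e-6))
      }
      fit <- stats::nls(y ~ binding_fraction(x, S_T, K_D),
                        start = start, control = ctrl, algorithm = "port",
                        lower = c(K_D = 0), upper = c(K_D = Inf))
    }
  } else {
    for (p in c("E_T", "S_T", "K_D")) {
      if (is.null(fixed[[p]])) stop("competition model requires fixed ", p)
    }
    E_T <- fixed$E_T; S_T <- fixed$S_T; K_D <- fixed$K_D
    if (is.null(start)) {
      ## C_T at half-drop ~ E_T * K_C / K_D when K_D << E_T
      mid <- x[which.min(abs(y - max(y) / 2))]
      start <- list(K_C = max(mid * K_D / max(E_T, 1e-12), 1e-6))
    }
    fit <- stats::nls(y ~ competition_fraction(E_T, S_T, x, K_D, K_C),
                      start = start, control = ctrl, algorithm = "port",
                      lower = c(K_C = 1e-12), upper = c(K_C = Inf))
  }

  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  ci <- cbind(low = est - 1.96 * se, high = est + 1.96 * se)
  list(model = model, estimate = est, se = se, ci = ci,
       fitted = stats::fitted(fit), residuals = stats::resid(fit), fit = fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
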