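#' Concentration / volume-fraction conversion
#'
#' Linear map c[g/L] = 1430 * phi calibrated on the crowded protein
#' systems; the coefficient is close to typical protein mass densities.
#' A warning is emitted for phi outside the physically meaningful range.
#'
#' @param c Mass concentration in g/L (>= 0).
#' @return Volume fraction phi.
#' @export
phi_from_c <- function(c) {
  if (any(c < 0)) stop("concentration must be non-negative", call. = FALSE)
  phi <- c / 1430
  if (any(phi >= 0.45)) {
    warning("volume fraction >= 0.45: outside the supported physical range",
            call. = FALSE)
  }
  phi
}

#' @rdname phi_from_c
#' @param phi Volume fraction (>= 0).
#' @export
c_from_phi <- function(phi) {
  if (any(phi < 0)) stop("volume fraction must be non-negative", call. = FALSE)
  1430 * phi
}

#' Relative-viscosity models
#'
#' Einstein hard-sphere law eta_r = 1 + 2.5 phi; quadratic extension
#' eta_r = 1 + 2.5 phi + b phi^2 whose coefficient b captures attractive
#' interactions; and Mooney's semiempirical form
#' eta_r = exp(S phi / (1 - K phi)) with intrinsic viscosity S (2.5 for
#' rigid spheres) and self-crowding factor K. All three equal 1 at
#' phi = 0 and share the first-order slope when S = 2.5.
#'
#' @param phi Volume fraction in [0, 1).
#' @param b Quadratic interaction coefficient.
#' @param S Intrinsic viscosity.
#' @param K Self-crowding factor; requires K * phi < 1.
#' @return Relative viscosity eta_r.
#' @export
eta_einstein <- function(phi) {
  check_phi(phi)
  1 + 2.5 * phi
}

#' @rdname eta_einstein
#' @export
eta_quadratic <- function(phi, b) {
  check_phi(phi)
  1 + 2.5 * phi + b * phi^2
}

#' @rdname eta_einstein
#' @export
eta_mooney <- function(phi, S, K) {
  check_phi(phi)
  if (any(K * phi >= 1)) {
    stop("K * phi >= 1: at or beyond the Mooney packing pole", call. = FALSE)
  }
  exp(S * phi / (1 - K * phi))
}

check_phi <- function(phi) {
  if (any(phi < 0) || any(phi >= 1)) {
    stop("`phi` must lie in [0, 1)", call. = FALSE)
  }
  invisible(phi)
}

#' Fit a relative-viscosity model to concentration data
#'
#' Weighted least squares with the unity intercept constrained exactly
#' (all models pass through eta_r(0) = 1) and, for the quadratic model,
#' the Einstein term fixed at 2.5. Weights default to 1/se^2 when
#' standard errors are supplied.
#'
#' @param phi Volume fractions (or supply `c_gL`).
#' @param eta_r Relative viscosities.
#' @param se Optional standard errors of `eta_r`.
#' @param model "quadratic" or "mooney".
#' @param c_gL Optional concentrations in g/L (converted via
#'   [phi_from_c]).
#' @param max_c_gL Optional concentration cutoff (points above are
#'   dropped; the quadratic expansion is conventionally fit up to
#'   ~250 g/L).
#' @return A `viscosity_fit`: list with `model`, `parameters`, and
#'   `residual`.
#' @export
fit_eta <- function(phi = NULL, eta_r, se = NULL,
                    model = c("quadratic", "mooney"),
                    c_gL = NULL, max_c_gL = NULL) {
  model <- match.arg(model)
  if (is.null(phi)) phi <- phi_from_c(c_gL)
  if (!is.null(max_c_gL)) {
    keep <- c_from_phi(phi) <= max_c_gL
    phi <- phi[keep]; eta_r <- eta_r[keep]
    if (!is.null(se)) se <- se[keep]
  }
  n_min <- if (model == "quadratic") 3 else 4
  if (length(phi) < n_min) {
    stop(sprintf("need at least %d points for the %s model", n_min, model),
         call. = FALSE)
  }
  if (any(eta_r < 1)) {
    warning("relative viscosities below 1 present", call. = FALSE)
  }
  w <- if (!is.null(se) && all(se > 0)) 1 / se^2 else rep(1, length(phi))
  if (model == "quadratic") {
    # linear in b: closed-form weighted LS of (eta_r - 1 - 2.5 phi) on phi^2
    y <- eta_r - 1 - 2.5 * phi
    b <- sum(w * y * phi^2) / sum(w * phi^4)
    res <- sum(w * (y - b * phi^2)^2)
    out <- list(model = "quadratic", parameters = c(b = b), residual = res)
  } else {
    best <- NULL
    for (K0 in c(0.5, 2, 5, 10)) {
      f <- tryCatch(minpack.lm::nls.lm(
        par = c(2.5, K0),
        fn = function(p) sqrt(w) * (eta_r - eta_mooney(phi, p[1], min(p[2], 0.999 / max(phi)))),
        lower = c(0, 0), upper = c(50, 0.999 / max(phi)),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (!is.null(f) && f$info >= 1 && f$info <= 4 &&
          (is.null(best) || sum(f$fvec^2) < sum(best$fvec^2))) best <- f
    }
    if (is.null(best)) stop("Mooney fit failed to converge", call. = FALSE)
    out <- list(model = "mooney",
                parameters = c(S = best$par[1], K = best$par[2]),
                residual = sum(best$fvec^2))
  }
  class(out) <- "viscosity_fit"
  out
}

#' @export
print.viscosity_fit <- function(x, ...) {
  cat(sprintf("<viscosity_fit> %s: %s (residual %.3g)\n", x$model,
              paste(names(x$parameters), round(x$parameters, 4),
                    sep = " = ", collapse = ", "), x$residual))
  invisible(x)
}

#' Predict eta_r from a viscosity fit
#' @param object A `viscosity_fit`.
#' @param phi Volume fractions.
#' @param ... Unused.
#' @return Relative viscosities.
#' @export
predict.viscosity_fit <- function(object, phi, ...) {
  p <- unname(object$parameters)
  switch(object$model,
         quadratic = eta_quadratic(phi, p[1]),
         mooney = eta_mooney(phi, p[1], p[2]))
}

#' Effective-cluster-size diffusion model
#'
#' Fits D(phi) = D0 * eta_r(phi)^(-1) * (1 + zeta phi)^(-p) where
#' 1 + zeta phi is an effective cluster size (zeta = 0 means no
#' clustering). The default exponents follow Stokes-Einstein scaling of a
#' compact cluster of (1 + zeta phi) molecules, R_h ~ size^(1/3):
#' p = 1/3 for translational and p = 1 for rotational diffusion. zeta is
#' bounded below at 0; hitting the bound is reported.
#'
#' @param phi Volume fractions.
#' @param D Diffusion coefficients.
#' @param se Optional standard errors (weights 1/se^2).
#' @param eta_r_fun Function phi -> relative viscosity (e.g. a closure
#'   over a [fit_eta] result).
#' @param kind "translational" (p = 1/3) or "rotational" (p = 1).
#' @param exponent Optional explicit exponent overriding `kind`.
#' @return A `diffusion_fit`: D0, zeta, exponent, at_bound flag, and a
#'   `cluster_size` function phi -> 1 + zeta phi.
#' @export
fit_cluster_model <- function(phi, D, se = NULL, eta_r_fun,
                              kind = c("translational", "rotational"),
                              exponent = NULL) {
  kind <- match.arg(kind)
  if (is.null(exponent)) exponent <- if (kind == "translational") 1 / 3 else 1
  if (is.null(eta_r_fun)) stop("an eta_r model is required", call. = FALSE)
  w <- if (!is.null(se) && all(se > 0)) 1 / se^2 else rep(1, length(phi))
  eta_r <- eta_r_fun(phi)
  best <- NULL
  for (z0 in c(0.5, 5, 50)) {
    f <- tryCatch(minpack.lm::nls.lm(
      par = c(max(D / (eta_r^-1 * 1)), z0),
      fn = function(p) {
        pred <- p[1] / eta_r * (1 + p[2] * phi)^(-exponent)
        sqrt(w) * (D - pred)
      },
      lower = c(1e-12, 0), upper = c(Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(f) && f$info >= 1 && f$info <= 4 &&
        (is.null(best) || sum(f$fvec^2) < sum(best$fvec^2))) best <- f
  }
  if (is.null(best)) stop("cluster-model fit failed", call. = FALSE)
  zeta <- best$par[2]
  structure(list(D0 = best$par[1], zeta = zeta, exponent = exponent,
                 kind = kind, at_bound = zeta < 1e-8,
                 residual = sum(best$fvec^2),
                 cluster_size = function(phi) 1 + zeta * phi),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "<diffusion_fit> %s (p = %.3g): D0 = %.4g, zeta = %.4g%s\n",
    x$kind, x$exponent, x$D0, x$zeta,
    if (x$at_bound) " (at the zeta = 0 bound: no clustering detected)" else ""))
  invisible(x)
}

#' Generalized Stokes-Einstein ratio
#'
#' (D / D0) / (eta0 / eta): equals 1 when diffusion slows exactly in
#' proportion to the viscosity increase; values below 1 indicate excess
#' slow-down, the signature of transient cluster formation.
#'
#' @param D,D0 Diffusion coefficient and its dilute reference.
#' @param eta,eta0 Viscosity and its dilute reference (cP).
#' @return Dimensionless ratio.
#' @export
generalized_se_ratio <- function(D, D0, eta, eta0) {
  if (any(c(D, D0, eta, eta0) <= 0)) {
    stop("all inputs must be positive", call. = FALSE)
  }
  (D / D0) / (eta0 / eta)
}
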