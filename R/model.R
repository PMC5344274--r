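#' Model variants
#'
#' Three nested forms of the two-compartment model are supported:
#' \describe{
#'   \item{`"linear"`}{linear epithelial feedback: the senescence-like loss
#'     of E grows linearly with population size (`k*E`); no EMT; `m` unused.}
#'   \item{`"saturated"`}{saturated feedback `k*E/(1 + m*E)` capping the
#'     per-capita loss; no EMT (`beta4` unused).}
#'   \item{`"saturated_emt"`}{saturated feedback plus the EMT flux
#'     `beta4*E` converting epithelial cells back into mesenchymal cells.}
#' }
#' @return Character vector of recognized variant names.
#' @export
model_variants <- function() c("linear", "saturated", "saturated_emt")

match_variant <- function(variant) {
  if (length(variant) != 1L || !variant %in% model_variants())
    stop("unknown model variant: ", paste(variant, collapse = ", "),
         "; must be one of ", paste(model_variants(), collapse = ", "),
         call. = FALSE)
  variant
}

#' Right-hand side of the population ODEs
#'
#' Time derivatives of the mesenchymal (M) and epithelial (E) compartments.
#' In the EMT variant:
#' \deqn{dM/dt = (\alpha_1 - \alpha_2 - \alpha_3) M + \beta_4 E}
#' \deqn{dE/dt = \alpha_2 M + (\beta_1 - \beta_2 - \beta_3 - \beta_4 -
#'   kE/(1+mE)) E}
#' The non-EMT variants drop the `beta4` terms; the linear variant replaces
#' the saturated feedback by `k*E`.
#'
#' @param state Numeric vector `c(M = , E = )`, both non-negative.
#' @param p An `emt_params` object (or coercible).
#' @param variant One of [model_variants()].
#' @return Named numeric vector `c(dM = , dE = )`.
#' @examples
#' model_rhs(c(M = 0, E = 0), emt_params())        # origin is a fixed point
#' model_rhs(c(M = 1, E = 10), emt_params(), "linear")
#' @export
model_rhs <- function(state, p, variant = "saturated_emt") {
  p <- as_emt_params(p)
  variant <- match_variant(variant)
  M <- state[["M"]]; E <- state[["E"]]
  if (M < 0 || E < 0) stop("abundances must be non-negative", call. = FALSE)
  feedback <- switch(variant,
    linear = p[["k"]] * E,
    p[["k"]] * E / (1 + p[["m"]] * E))
  b4 <- if (variant == "saturated_emt") p[["beta4"]] else 0
  dM <- (p[["alpha1"]] - p[["alpha2"]] - p[["alpha3"]]) * M + b4 * E
  dE <- p[["alpha2"]] * M +
    (p[["beta1"]] - p[["beta2"]] - p[["beta3"]] - b4 - feedback) * E
  c(dM = dM, dE = dE)
}

#' Closed-form mesenchymal trajectory without EMT
#'
#' With no EMT feeding the stem compartment, M decouples and follows
#' \eqn{M(t) = M_0 e^{\alpha t}} with \eqn{\alpha = \alpha_1 - \alpha_2 -
#' \alpha_3}: exponential growth for positive net rate, decay for negative,
#' and homeostasis (a single pioneer stem cell persisting unchanged) when
#' divisions are purely asymmetric and death-free (`alpha1 == alpha2`,
#' `alpha3 == 0`).
#'
#' @param t Non-negative time(s), in divisions.
#' @param M0 Initial mesenchymal abundance.
#' @param p An `emt_params` object (or coercible).
#' @return M(t), vectorized over `t`.
#' @export
closed_form_M <- function(t, M0, p) {
  p <- as_emt_params(p)
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  alpha <- p[["alpha1"]] - p[["alpha2"]] - p[["alpha3"]]
  M0 * exp(alpha * t)
}

#' Analytic Jacobian of the EMT model
#'
#' Partial derivatives of the saturated-feedback EMT system, including the
#' derivative of the saturated term: writing
#' \eqn{f_E = \alpha_2 M + cE - kE^2/(1+mE)} with
#' \eqn{c = \beta_1-\beta_2-\beta_3-\beta_4},
#' \eqn{\partial f_E/\partial E = c - k(2E + mE^2)/(1+mE)^2}.
#'
#' @param state Numeric vector `c(M = , E = )`.
#' @param p An `emt_params` object (or coercible).
#' @param variant One of [model_variants()].
#' @return A 2x2 matrix with rows/cols (M, E).
#' @export
model_jacobian <- function(state, p, variant = "saturated_emt") {
  p <- as_emt_params(p)
  variant <- match_variant(variant)
  E <- state[["E"]]
  b4 <- if (variant == "saturated_emt") p[["beta4"]] else 0
  cc <- p[["beta1"]] - p[["beta2"]] - p[["beta3"]] - b4
  dfeedback <- switch(variant,
    linear = 2 * p[["k"]] * E,
    p[["k"]] * (2 * E + p[["m"]] * E^2) / (1 + p[["m"]] * E)^2)
  matrix(c(p[["alpha1"]] - p[["alpha2"]] - p[["alpha3"]], b4,
           p[["alpha2"]], cc - dfeedback),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("M", "E"), c("M", "E")))
}
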