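#' Analytic steady states of the EMT model
#'
#' The saturated-feedback EMT system has two equilibrium branches. The
#' tumor branch is
#' \deqn{E^* = \frac{\beta_2\alpha_3+\beta_3\alpha_3+\beta_4\alpha_3-
#'   \alpha_2\beta_4-\beta_1\alpha_3}{\alpha_2\beta_4 m+\beta_1 m\alpha_3-
#'   \beta_2 m\alpha_3-\beta_3 m\alpha_3-\beta_4 m\alpha_3-k\alpha_3}}
#' with \eqn{M^* = (\beta_4/\alpha_3) E^*} — the M:E ratio at equilibrium is
#' forced algebraically to `beta4/alpha3`. The other branch is the
#' tumor-free state (0, 0). A tumor branch with any non-positive component
#' is biologically inadmissible (the dynamics then converge on the
#' tumor-free state instead) and is flagged as such, not dropped.
#'
#' @param p An `emt_params` object (or coercible). `alpha3 > 0` is required
#'   for the tumor branch; with `alpha3 == 0` it is reported as undefined.
#' @return A list of two `steady_state` records, each with elements `kind`
#'   ("tumor" or "tumor_free"), `M_star`, `E_star`, `admissible`, `stable`
#'   and `eigenvalues` (stability from the analytic Jacobian).
#' @examples
#' ss <- steady_states(emt_params())
#' ss[[1]]$E_star  # about 153.9 cells
#' @export
steady_states <- function(p) {
  p <- as_emt_params(p)
  a2 <- p[["alpha2"]]; a3 <- p[["alpha3"]]
  b1 <- p[["beta1"]]; b2 <- p[["beta2"]]; b3 <- p[["beta3"]]
  b4 <- p[["beta4"]]; k <- p[["k"]]; m <- p[["m"]]
  if (a3 > 0) {
    num <- b2 * a3 + b3 * a3 + b4 * a3 - a2 * b4 - b1 * a3
    den <- a2 * b4 * m + b1 * m * a3 - b2 * m * a3 - b3 * m * a3 -
      b4 * m * a3 - k * a3
    if (den == 0)
      stop("degenerate parameters: tumor-branch denominator is zero",
           call. = FALSE)
    E_star <- num / den
    M_star <- b4 / a3 * E_star
    tumor <- steady_state_record("tumor", M_star, E_star, p)
  } else {
    tumor <- list(kind = "tumor", M_star = NA_real_, E_star = NA_real_,
                  admissible = FALSE, stable = NA, eigenvalues = NULL)
    class(tumor) <- "steady_state"
  }
  free <- steady_state_record("tumor_free", 0, 0, p)
  list(tumor = tumor, tumor_free = free)
}

steady_state_record <- function(kind, M_star, E_star, p) {
  admissible <- if (kind == "tumor_free") TRUE else (M_star > 0 && E_star > 0)
  # stability is meaningful only where the branch is a genuine fixed point
  # (non-negative components; with beta4 = 0 the tumor branch can sit on the
  # M = 0 boundary and still be a real equilibrium)
  if (M_star >= 0 && E_star >= 0) {
    stab <- classify_stability(c(M = M_star, E = E_star), p)
    stable <- stab$stable
    eig <- stab$eigenvalues
  } else {
    stable <- NA
    eig <- NULL
  }
  out <- list(kind = kind, M_star = M_star, E_star = E_star,
              admissible = admissible, stable = stable, eigenvalues = eig)
  class(out) <- "steady_state"
  out
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("%s state: M* = %.6g, E* = %.6g (%s%s)\n", x$kind,
              x$M_star, x$E_star,
              if (isTRUE(x$admissible)) "admissible" else "inadmissible",
              if (is.na(x$stable)) "" else
                if (x$stable) ", stable" else ", unstable"))
  invisible(x)
}

#' Eigenvalue-based stability of a fixed point
#'
#' Evaluates the analytic Jacobian of the selected variant at a point and
#' classifies it as stable iff all eigenvalue real parts are negative. If
#' the point is not a fixed point (residual derivative norm above `tol`
#' relative to the state magnitude), the classification is still returned
#' but flagged with `at_fixed_point = FALSE` and a warning.
#'
#' @param state Numeric vector `c(M = , E = )`.
#' @param p An `emt_params` object (or coercible).
#' @param variant One of [model_variants()].
#' @param tol Relative residual tolerance for the fixed-point check.
#' @return A list with `jacobian`, `eigenvalues`, `determinant`, `stable`,
#'   and `at_fixed_point`.
#' @examples
#' classify_stability(c(M = 0, E = 0), emt_params())$stable  # FALSE: tumor
#' # grows back from nothing whenever beta3 is below the threshold
#' @export
classify_stability <- function(state, p, variant = "saturated_emt",
                               tol = 1e-6) {
  p <- as_emt_params(p)
  J <- model_jacobian(state, p, variant)
  rhs <- model_rhs(state, p, variant)
  resid <- sqrt(sum(rhs^2))
  at_fp <- resid < tol * (1 + sqrt(sum(unlist(state)^2)))
  if (!at_fp)
    warning("state is not a fixed point (|rhs| = ", format(resid),
            "); classification refers to the linearization there",
            call. = FALSE)
  ev <- eigen(J, only.values = TRUE)$values
  list(jacobian = J, eigenvalues = ev, determinant = det(J),
       stable = all(Re(ev) < 0), at_fixed_point = at_fp)
}

#' Epithelial death-rate threshold for tumor eradication
#'
#' The tumor and tumor-free equilibria exchange stability in a
#' transcritical bifurcation at
#' \deqn{\beta^* = \frac{\beta_4\alpha_2}{\alpha_3} +
#'   (\beta_1 - \beta_2 - \beta_4).}
#' The first term is the mesenchymal contribution to epithelial production
#' (amplified by EMT); the second is the net intrinsic growth of E. A
#' chemotherapy that raises epithelial death `beta3` above this threshold
#' drives the system to the tumor-free state from any initial population;
#' below it, a stable tumor persists and regrows after treatment.
#'
#' @param p An `emt_params` object (or coercible); requires `alpha3 > 0`.
#' @return The threshold death rate (1/div).
#' @examples
#' beta_star(emt_params())  # 0.6575 at baseline
#' @export
beta_star <- function(p) {
  p <- as_emt_params(p)
  if (p[["alpha3"]] <= 0)
    stop("beta_star requires alpha3 > 0", call. = FALSE)
  p[["beta4"]] * p[["alpha2"]] / p[["alpha3"]] +
    (p[["beta1"]] - p[["beta2"]] - p[["beta4"]])
}

#' Scan the epithelial death rate through the bifurcation
#'
#' Traces both equilibrium branches over a grid of `beta3` values,
#' classifying stability at each point, and locates the exchange of
#' stability, which occurs exactly at [beta_star()]. Optionally verifies by
#' integration that trajectories from initial conditions on both sides of
#' the threshold converge to the stable branch.
#'
#' @param p An `emt_params` object (baseline; its `beta3` is replaced).
#' @param beta3_range Length-2 numeric, scan limits.
#' @param n Number of grid points.
#' @param verify_dynamics If TRUE, integrate from small and large initial
#'   populations at the range endpoints and record the attractor reached.
#' @param t_end Integration horizon for the verification runs.
#' @return A list of class `bifurcation_result`: `branches` (data.frame with
#'   `beta3`, `E_tumor`, `M_tumor`, `tumor_admissible`, `tumor_stable`,
#'   `free_stable`), `beta_star`, `crossed` (whether the range spans the
#'   threshold) and optionally `verification`.
#' @export
bifurcation_scan <- function(p, beta3_range = c(0.3, 0.8), n = 101,
                             verify_dynamics = FALSE, t_end = 2000) {
  p <- as_emt_params(p)
  bs <- beta_star(p)
  grid <- seq(beta3_range[1], beta3_range[2], length.out = n)
  rows <- lapply(grid, function(b3) {
    pi <- apply_overrides(p, list(beta3 = b3))
    ss <- steady_states(pi)
    data.frame(beta3 = b3,
               M_tumor = ss$tumor$M_star, E_tumor = ss$tumor$E_star,
               tumor_admissible = ss$tumor$admissible,
               tumor_stable = isTRUE(ss$tumor$stable),
               free_stable = isTRUE(ss$tumor_free$stable))
  })
  branches <- do.call(rbind, rows)
  crossed <- min(grid) < bs && max(grid) > bs
  if (!crossed)
    warning("beta3 range does not span the bifurcation at beta* = ",
            format(bs), call. = FALSE)
  out <- list(branches = branches, beta_star = bs, crossed = crossed)
  if (verify_dynamics) {
    initials <- list(small = c(M = 1, E = 1), large = c(M = 50, E = 400))
    verification <- list()
    for (b3 in beta3_range) {
      pi <- apply_overrides(p, list(beta3 = b3))
      for (nm in names(initials)) {
        tr <- simulate_ode(pi, initials[[nm]], t_end = t_end, dt = 5)
        fin <- tr[nrow(tr), ]
        verification[[paste0("beta3_", format(b3), "_", nm)]] <-
          list(beta3 = b3, initial = initials[[nm]],
               final = c(M = fin$M, E = fin$E),
               attractor = if (fin$M + fin$E < 1e-3) "tumor_free" else "tumor")
      }
    }
    out$verification <- verification
  }
  class(out) <- "bifurcation_result"
  out
}

#' Local sensitivity of the steady-state mesenchymal population
#'
#' Perturbs each kinetic rate constant independently by a fixed fraction
#' (default 5%) and measures the change in M at `t_eval` (default 500,
#' after the system has reached steady state from a single pioneer stem
#' cell), giving the finite-difference sensitivity coefficient
#' \eqn{\partial M/\partial p \approx (M(p + \Delta p) - M(p))/\Delta p}
#' with \eqn{\Delta p = \mathrm{fraction} \times p}. A central-difference
#' scheme is available. The EMT rate `beta4` dominates by a wide margin,
#' with the stem proliferation rate `alpha1` second — small changes in the
#' probability of EMT perturb the dormant steady state far more than
#' comparable changes in proliferation, senescence or death rates.
#'
#' @param p An `emt_params` object (or coercible).
#' @param fraction Relative perturbation (> 0), default 0.05.
#' @param t_eval Evaluation time, default 500.
#' @param initial Initial state for the baseline and perturbed runs.
#' @param scheme `"forward"` (default) or `"central"`.
#' @param params Which parameters to perturb (default the seven rates).
#' @return A data.frame of class `sensitivity_report` with columns
#'   `parameter`, `base_value`, `coefficient`, `abs_coefficient`, `rank`
#'   (1 = largest magnitude), plus attributes `t_eval`, `fraction`,
#'   `scheme`, `M_base` and `converged` (steady-state flag at `t_eval`).
#' @export
sensitivity_scan <- function(p, fraction = 0.05, t_eval = 500,
                             initial = c(M = 1, E = 0),
                             scheme = c("forward", "central"),
                             params = rate_param_names()) {
  p <- as_emt_params(p)
  scheme <- match.arg(scheme)
  if (fraction <= 0) stop("fraction must be positive", call. = FALSE)
  if (t_eval <= 0) stop("t_eval must be positive", call. = FALSE)
  M_at <- function(pp) {
    tr <- simulate_ode(pp, initial, t_end = t_eval, dt = min(t_eval, 5))
    tr$M[nrow(tr)]
  }
  M_base <- M_at(p)
  fin <- simulate_ode(p, initial, t_end = t_eval, dt = min(t_eval, 5))
  fin <- fin[nrow(fin), ]
  rhs_end <- model_rhs(c(M = fin$M, E = fin$E), p)
  converged <- sqrt(sum(rhs_end^2)) <
    1e-6 * (1 + sqrt(fin$M^2 + fin$E^2))
  coefs <- vapply(params, function(nm) {
    base <- p[[nm]]
    if (base == 0) return(NA_real_)  # relative perturbation undefined
    dp <- fraction * base
    up <- M_at(apply_overrides(p, stats::setNames(list(base + dp), nm)))
    if (scheme == "forward") (up - M_base) / dp
    else {
      dn <- M_at(apply_overrides(p, stats::setNames(list(base - dp), nm)))
      (up - dn) / (2 * dp)
    }
  }, numeric(1))
  out <- data.frame(parameter = params,
                    base_value = unclass(p)[params],
                    coefficient = coefs,
                    abs_coefficient = abs(coefs),
                    row.names = NULL)
  out$rank <- rank(-out$abs_coefficient, na.last = "keep")
  structure(out, class = c("sensitivity_report", "data.frame"),
            t_eval = t_eval, fraction = fraction, scheme = scheme,
            M_base = M_base, converged = converged)
}

#' Joint sweep of mesenchymal and epithelial death rates
#'
#' Evaluates the steady-state epithelial population over a grid of
#' (`alpha3`, `beta3`) combinations — the two death rates a cytotoxic
#' therapy could target — and the shift from the baseline steady state.
#' Cells where the tumor branch is inadmissible or `beta3` exceeds the
#' per-cell threshold [beta_star()] map to the tumor-free value 0.
#' Per absolute unit of rate, raising mesenchymal death `alpha3` shifts the
#' steady state far more than raising epithelial death `beta3`.
#'
#' @param p Baseline `emt_params`.
#' @param alpha3_grid,beta3_grid Numeric vectors of death-rate values.
#' @return A list of class `sweep_result`: `alpha3`, `beta3`, matrices
#'   `E_star` and `delta_E` (rows = alpha3, cols = beta3), and
#'   `E_baseline`.
#' @export
sweep_death_rates <- function(p, alpha3_grid, beta3_grid) {
  p <- as_emt_params(p)
  if (!length(alpha3_grid) || !length(beta3_grid))
    return(structure(list(alpha3 = numeric(0), beta3 = numeric(0),
                          E_star = matrix(numeric(0), 0, 0),
                          delta_E = matrix(numeric(0), 0, 0),
                          E_baseline = NA_real_),
                     class = "sweep_result"))
  E_base <- steady_states(p)$tumor$E_star
  E <- matrix(NA_real_, length(alpha3_grid), length(beta3_grid),
              dimnames = list(format(alpha3_grid), format(beta3_grid)))
  for (i in seq_along(alpha3_grid)) {
    for (j in seq_along(beta3_grid)) {
      pij <- apply_overrides(p, list(alpha3 = alpha3_grid[i],
                                     beta3 = beta3_grid[j]))
      ss <- steady_states(pij)$tumor
      above <- pij[["alpha3"]] > 0 && beta3_grid[j] > beta_star(pij)
      E[i, j] <- if (!isTRUE(ss$admissible) || above) 0 else ss$E_star
    }
  }
  structure(list(alpha3 = alpha3_grid, beta3 = beta3_grid,
                 E_star = E, delta_E = E - E_base, E_baseline = E_base),
            class = "sweep_result")
}
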