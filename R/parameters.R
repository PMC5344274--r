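#' Rate parameters of the dormant-tumor population model
#'
#' Constructs the full parameter set of the two-compartment
#' mesenchymal/epithelial model. All rates are per cell division (1/div);
#' `k` is 1/(N div) and `m` is 1/N where N counts epithelial cells.
#' Defaults are the baseline values used throughout the model analysis:
#' they place the tumor branch at a small, stable micrometastatic
#' equilibrium.
#'
#' @param alpha1 Proliferative capacity of mesenchymal (stem-like) cells M.
#' @param alpha2 Differentiation rate M -> E (asymmetric division output).
#' @param alpha3 Death rate of M.
#' @param beta1 Proliferative capacity of epithelial cells E.
#' @param beta2 Senescence rate of E.
#' @param beta3 Death rate of E (the chemotherapy target).
#' @param beta4 EMT rate E -> M.
#' @param k Carrying-capacity constant of the epithelial feedback term.
#' @param m Maximum per-capita growth-rate constant of the saturated
#'   feedback term \code{k*E/(1 + m*E)}.
#'
#' @return An object of class `emt_params`: a named numeric vector with the
#'   nine rate constants.
#' @examples
#' p <- emt_params()
#' p["beta4"]
#' emt_params(beta3 = 0.7)  # epithelial death above the eradication threshold
#' @export
emt_params <- function(alpha1 = 0.32, alpha2 = 0.32, alpha3 = 0.02,
                       beta1 = 0.87, beta2 = 0.25, beta3 = 0.4,
                       beta4 = 0.0025, k = 0.0026, m = 0.0036) {
  p <- c(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
         beta1 = beta1, beta2 = beta2, beta3 = beta3, beta4 = beta4,
         k = k, m = m)
  validate_emt_params(p)
  structure(p, class = "emt_params")
}

param_names <- function() {
  c("alpha1", "alpha2", "alpha3", "beta1", "beta2", "beta3", "beta4", "k", "m")
}

#' @rdname emt_params
#' @description `rate_param_names()` returns the seven kinetic rate constants
#'   (the alphas and betas), the parameters subject to sensitivity analysis.
#' @export
rate_param_names <- function() {
  c("alpha1", "alpha2", "alpha3", "beta1", "beta2", "beta3", "beta4")
}

validate_emt_params <- function(p) {
  if (!is.numeric(p) || length(p) != 9L || !identical(names(p), param_names()))
    stop("parameter set must be the nine named rate constants: ",
         paste(param_names(), collapse = ", "), call. = FALSE)
  if (anyNA(p) || any(!is.finite(p)))
    stop("parameters must be finite and non-missing", call. = FALSE)
  if (any(p < 0))
    stop("all rate constants must be non-negative; got negative: ",
         paste(names(p)[p < 0], collapse = ", "), call. = FALSE)
  invisible(p)
}

#' @export
print.emt_params <- function(x, ...) {
  cat("Dormant-tumor model parameters [1/div]:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Coerce to an `emt_params` object
#'
#' Accepts a named numeric vector or list with any subset of the nine
#' parameter names; missing entries take the baseline defaults.
#'
#' @param x Named numeric vector or list of parameter values.
#' @return An `emt_params` object.
#' @export
as_emt_params <- function(x) {
  if (inherits(x, "emt_params")) return(x)
  x <- unlist(x)
  unknown <- setdiff(names(x), param_names())
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(emt_params, as.list(x))
}

#' Read model parameters from a flat JSON file
#'
#' The file holds a single JSON object with any subset of the keys
#' `alpha1 ... beta4, k, m`; absent keys fall back to the baseline values.
#'
#' @param path Path to a JSON file.
#' @return An `emt_params` object.
#' @seealso [write_params_json()]
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_emt_params(x)
}

#' @rdname read_params_json
#' @param p An `emt_params` object.
#' @export
write_params_json <- function(p, path) {
  p <- as_emt_params(p)
  jsonlite::write_json(as.list(unclass(p)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert cell doubling times to division rates
#'
#' Proliferation-rate bounds for the model are anchored to measured cell
#' doubling times in cancer cell lines: a doubling time of d days
#' corresponds to 1/d cell divisions per day. The reported doubling-time
#' range 0.725--3.31 days therefore bounds proliferation rates to
#' 0.302--1.38 divisions per day, which is why the baseline takes
#' `alpha1 = 0.32` (slow-cycling stem-like cells, lower end) and
#' `beta1 = 0.87` (faster epithelial turnover).
#'
#' @param doubling_days Numeric vector of doubling times in days (> 0).
#' @return Division rates in divisions per day (element-wise reciprocal).
#' @examples
#' division_rate_from_doubling_time(c(0.725, 3.31))
#' @export
division_rate_from_doubling_time <- function(doubling_days) {
  if (any(doubling_days <= 0))
    stop("doubling times must be positive", call. = FALSE)
  1 / doubling_days
}
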