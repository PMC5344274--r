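#' Piecewise parameter overrides modeling therapy
#'
#' A treatment schedule is an ordered set of non-overlapping time intervals,
#' each carrying a map of parameter overrides (e.g. raised epithelial death
#' `beta3` during a chemotherapy course, or `beta4 = 0` under an EMT
#' inhibitor), plus an optional override map applied after the final
#' interval — used to model acquired resistance, where a parameter does not
#' revert to its pre-treatment value.
#'
#' @param intervals A list of lists, each with elements `t_start`, `t_end`
#'   and `overrides` (named list of parameter values). Intervals must be
#'   non-overlapping with `t_start < t_end`.
#' @param post Optional named list of overrides active after the last
#'   interval ends (default none: parameters revert to baseline).
#' @return An object of class `treatment_schedule`.
#' @examples
#' treatment_schedule(list(
#'   list(t_start = 500, t_end = 750, overrides = list(beta3 = 0.532))
#' ))
#' @export
treatment_schedule <- function(intervals = list(), post = NULL) {
  for (iv in intervals) {
    if (!all(c("t_start", "t_end", "overrides") %in% names(iv)))
      stop("each interval needs t_start, t_end, overrides", call. = FALSE)
    if (iv$t_start >= iv$t_end)
      stop("interval must have t_start < t_end", call. = FALSE)
    check_override_names(iv$overrides)
  }
  if (length(intervals) > 1) {
    o <- order(vapply(intervals, `[[`, numeric(1), "t_start"))
    intervals <- intervals[o]
    starts <- vapply(intervals, `[[`, numeric(1), "t_start")
    ends <- vapply(intervals, `[[`, numeric(1), "t_end")
    if (any(starts[-1] < ends[-length(ends)]))
      stop("treatment intervals must not overlap", call. = FALSE)
  }
  if (!is.null(post)) check_override_names(post)
  structure(list(intervals = intervals, post = post),
            class = "treatment_schedule")
}

check_override_names <- function(ov) {
  bad <- setdiff(names(ov), param_names())
  if (length(bad))
    stop("override keys must be parameter names; unknown: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(ov)
}

apply_overrides <- function(p, overrides) {
  p <- unclass(as_emt_params(p))
  if (length(overrides)) p[names(overrides)] <- unlist(overrides)
  as_emt_params(p)
}

# Split [0, t_end] into segments of constant parameters under a schedule.
schedule_segments <- function(schedule, p, t_end) {
  if (is.null(schedule) ||
      (length(schedule$intervals) == 0 && is.null(schedule$post)))
    return(list(list(t0 = 0, t1 = t_end, p = as_emt_params(p))))
  cuts <- 0
  for (iv in schedule$intervals) cuts <- c(cuts, iv$t_start, iv$t_end)
  cuts <- sort(unique(pmin(pmax(cuts, 0), t_end)))
  if (cuts[length(cuts)] < t_end) cuts <- c(cuts, t_end)
  last_end <- if (length(schedule$intervals))
    max(vapply(schedule$intervals, `[[`, numeric(1), "t_end")) else 0
  segs <- list()
  for (i in seq_len(length(cuts) - 1)) {
    t0 <- cuts[i]; t1 <- cuts[i + 1]
    if (t1 <= t0) next
    mid <- (t0 + t1) / 2
    ov <- NULL
    for (iv in schedule$intervals)
      if (mid >= iv$t_start && mid < iv$t_end) ov <- iv$overrides
    if (is.null(ov) && !is.null(schedule$post) && mid >= last_end)
      ov <- schedule$post
    segs[[length(segs) + 1]] <- list(t0 = t0, t1 = t1,
                                     p = apply_overrides(p, ov))
  }
  segs
}

#' Integrate the population dynamics
#'
#' Numerically integrates the selected model variant with a stiff-capable
#' adaptive solver (deSolve's `lsoda`, relative tolerance 1e-8, absolute
#' 1e-10). Abundances are clipped at zero to absorb solver undershoot. A
#' [treatment_schedule()] makes the parameters piecewise-constant in time;
#' integration restarts at every interval boundary so discontinuities are
#' handled exactly.
#'
#' @param p An `emt_params` object (or coercible).
#' @param initial Numeric vector `c(M = , E = )` at t = 0.
#' @param t_end Final time (> 0), in divisions.
#' @param variant One of [model_variants()].
#' @param schedule Optional [treatment_schedule()].
#' @param dt Output time step (default 1).
#' @param rtol,atol Solver tolerances.
#' @return A data.frame of class `emt_trajectory` with columns `t`, `M`, `E`,
#'   strictly increasing in `t`.
#' @examples
#' tr <- simulate_ode(emt_params(), c(M = 1, E = 0), t_end = 500)
#' tail(tr, 1)  # close to the tumor steady state (19.24, 153.9)
#' @export
simulate_ode <- function(p, initial = c(M = 1, E = 0), t_end,
                         variant = "saturated_emt", schedule = NULL,
                         dt = 1, rtol = 1e-8, atol = 1e-10) {
  p <- as_emt_params(p)
  variant <- match_variant(variant)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  if (any(initial < 0)) stop("initial abundances must be non-negative",
                             call. = FALSE)
  y <- c(M = unname(initial[["M"]]), E = unname(initial[["E"]]))
  segs <- schedule_segments(schedule, p, t_end)
  derivs <- function(t, y, parms) {
    y <- pmax(y, 0)
    list(unname(model_rhs(c(M = y[[1]], E = y[[2]]), parms, variant)))
  }
  out <- NULL
  for (seg in segs) {
    times <- unique(c(seq(seg$t0, seg$t1, by = dt), seg$t1))
    sol <- deSolve::ode(y = y, times = times, func = derivs, parms = seg$p,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integration failed on [", seg$t0, ", ", seg$t1, "]",
           call. = FALSE)
    sol <- as.data.frame(sol)
    names(sol) <- c("t", "M", "E")
    sol$M <- pmax(sol$M, 0)
    sol$E <- pmax(sol$E, 0)
    y <- c(M = sol$M[nrow(sol)], E = sol$E[nrow(sol)])
    out <- if (is.null(out)) sol else rbind(out, sol[-1, ])
  }
  rownames(out) <- NULL
  class(out) <- c("emt_trajectory", "data.frame")
  out
}

#' Write a trajectory to CSV
#'
#' Full-precision CSV with header `t,M,E`.
#' @param trajectory An `emt_trajectory` data.frame.
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- as.data.frame(trajectory)[, c("t", "M", "E")]
  df[] <- lapply(df, function(x) format(x, digits = 17, trim = TRUE,
                                        scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
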