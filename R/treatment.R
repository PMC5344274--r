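#' Canonical chemotherapy scenarios
#'
#' Builds the [treatment_schedule()] for one of four scenarios of therapy
#' applied to a dormant tumor sitting at its steady state:
#' \describe{
#'   \item{`e_death_only`}{a cytotoxic agent raising epithelial death
#'     `beta3` by 33% during the treatment window, reverting afterwards.
#'     Mesenchymal cells are assumed drug-resistant (`alpha3` untouched).}
#'   \item{`resistance`}{the same agent, but the surviving epithelial
#'     population acquires resistance: after treatment `beta3` settles
#'     below its pre-treatment value (default 90% of baseline), moving the
#'     tumor to a new, larger steady state.}
#'   \item{`emt_block`}{an agent preventing EMT (`beta4 = 0`) during the
#'     window. The stem compartment decays at rate `alpha3` but the
#'     epithelial population barely moves; full recovery afterwards.}
#'   \item{`combined`}{EMT blockade plus the raised `beta3`
#'     simultaneously: the mesenchymal population is driven to extinction
#'     and only a small epithelial remnant survives — yet that remnant
#'     regrows the whole tumor once treatment stops and EMT resumes.}
#' }
#'
#' @param scenario One of `"e_death_only"`, `"resistance"`, `"emt_block"`,
#'   `"combined"`.
#' @param p Baseline `emt_params`.
#' @param t_treat_start,t_treat_end Treatment window (defaults 500--750:
#'   long enough for each phase to approach its steady state).
#' @param beta3_factor Multiplier on `beta3` during treatment (default 1.33).
#' @param resistance_factor Post-treatment `beta3` multiplier for the
#'   resistance scenario (default 0.9, i.e. below baseline).
#' @return A [treatment_schedule()].
#' @export
scenario_schedule <- function(scenario, p = emt_params(),
                              t_treat_start = 500, t_treat_end = 750,
                              beta3_factor = 1.33,
                              resistance_factor = 0.9) {
  p <- as_emt_params(p)
  b3 <- p[["beta3"]]
  during <- switch(scenario,
    e_death_only = list(beta3 = b3 * beta3_factor),
    resistance   = list(beta3 = b3 * beta3_factor),
    emt_block    = list(beta4 = 0),
    combined     = list(beta3 = b3 * beta3_factor, beta4 = 0),
    stop("unknown scenario: ", scenario, "; must be one of ",
         "e_death_only, resistance, emt_block, combined", call. = FALSE))
  post <- if (scenario == "resistance")
    list(beta3 = b3 * resistance_factor) else NULL
  treatment_schedule(
    list(list(t_start = t_treat_start, t_end = t_treat_end,
              overrides = during)),
    post = post)
}

#' Simulate a chemotherapy scenario on a dormant tumor
#'
#' Runs the EMT model from a single pioneer stem cell through a
#' pre-treatment phase, a treatment window and a post-treatment phase
#' under one of the [scenario_schedule()] regimes, and annotates each phase
#' with the steady state its parameters define and whether the trajectory
#' approached it.
#'
#' @inheritParams scenario_schedule
#' @param initial Initial state (default a single stem cell).
#' @param t_end End of the simulation (default 1250).
#' @param ... Passed to [scenario_schedule()].
#' @return A list of class `treatment_result`: `trajectory`
#'   (an `emt_trajectory`), `schedule`, `scenario` and `phases` — a
#'   data.frame with one row per phase (`phase`, `t_start`, `t_end`,
#'   `M_end`, `E_end`, `M_target`, `E_target`), where the target columns
#'   hold the stable steady state under that phase's parameters.
#' @examples
#' \donttest{
#' res <- simulate_treatment_scenario("combined")
#' res$phases
#' }
#' @export
simulate_treatment_scenario <- function(scenario, p = emt_params(),
                                        initial = c(M = 1, E = 0),
                                        t_treat_start = 500,
                                        t_treat_end = 750, t_end = 1250,
                                        ...) {
  p <- as_emt_params(p)
  schedule <- scenario_schedule(scenario, p, t_treat_start, t_treat_end, ...)
  traj <- simulate_ode(p, initial, t_end = t_end, schedule = schedule)
  bounds <- data.frame(
    phase = c("pre", "treat", "post"),
    t_start = c(0, t_treat_start, t_treat_end),
    t_end = c(t_treat_start, t_treat_end, t_end))
  phases <- do.call(rbind, lapply(seq_len(nrow(bounds)), function(i) {
    b <- bounds[i, ]
    seg <- schedule_segments(schedule, p, t_end)
    pp <- NULL
    for (s in seg)
      if (b$t_start >= s$t0 - 1e-9 && b$t_end <= s$t1 + 1e-9) pp <- s$p
    if (is.null(pp)) pp <- p
    ss <- steady_states(pp)
    tum <- ss$tumor
    # stable tumor (or, under EMT blockade, epithelial-only boundary) state
    target <- if (isTRUE(tum$stable) && !is.na(tum$M_star) &&
                  tum$M_star >= 0 && tum$E_star > 0)
      c(tum$M_star, tum$E_star) else c(0, 0)
    at_end <- traj[which.min(abs(traj$t - b$t_end)), ]
    data.frame(phase = b$phase, t_start = b$t_start, t_end = b$t_end,
               M_end = at_end$M, E_end = at_end$E,
               M_target = target[1], E_target = target[2])
  }))
  structure(list(trajectory = traj, schedule = schedule,
                 scenario = scenario, phases = phases),
            class = "treatment_result")
}

#' @export
print.treatment_result <- function(x, ...) {
  cat("Treatment scenario:", x$scenario, "\n")
  print(x$phases, digits = 4)
  invisible(x)
}
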