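#' Configuration of a stochastic branching experiment
#'
#' The stochastic model is generation-synchronous: at each step every
#' mesenchymal stem cell divides asymmetrically (persisting and emitting
#' one fresh epithelial cell), and every live epithelial cell either
#' undergoes EMT — with probability `delta`, converting to a stem cell in
#' place of its division — or divides into two daughters one division
#' closer to senescence. Epithelial lineages senesce after `g` divisions
#' (the generational capacity); senescent cells are inert and leave the
#' live population.
#'
#' @param g Generational capacity, divisions per epithelial lineage (>= 1).
#' @param delta Per-division EMT probability, in [0, 1].
#' @param generations Number of synchronous generation steps (>= 1).
#' @param init_M Initial stem-cell count.
#' @param init_E Initial epithelial count (fresh cells at full capacity).
#' @param trials Batch size for [run_batch()].
#' @param seed Master RNG seed; each trial runs on its own substream.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(g = 18, delta = 1e-8, generations = 120)
#' @export
sim_config <- function(g, delta, generations, init_M = 1, init_E = 0,
                       trials = 1000, seed = 1) {
  stopifnot(g >= 1, delta >= 0, delta <= 1, generations >= 1,
            init_M >= 0, init_E >= 0, init_M + init_E >= 1, trials >= 1)
  structure(list(g = as.integer(g), delta = delta,
                 generations = as.integer(generations),
                 init_M = as.double(init_M), init_E = as.double(init_E),
                 trials = as.integer(trials), seed = as.integer(seed)),
            class = "sim_config")
}

#' Initial cohort state for a configuration
#'
#' The population is tracked as cohort counts: the number of stem cells,
#' a vector of live epithelial counts indexed by divisions completed
#' (d = 0 .. g-1), the cumulative senescent count and the cumulative
#' number of EMT events.
#'
#' @param config A [sim_config()].
#' @return A `cohort_state` list with elements `M_count`, `E_counts`
#'   (length `g`), `senescent_count`, `N_E` and `generation`.
#' @export
new_cohort_state <- function(config) {
  E <- numeric(config$g)
  E[1] <- config$init_E
  structure(list(M_count = config$init_M, E_counts = E,
                 senescent_count = 0, N_E = 0, generation = 0L),
            class = "cohort_state")
}

live_total <- function(state) state$M_count + sum(state$E_counts)

#' Advance the cohort population by one synchronous generation
#'
#' One step: (i) every stem cell emits one fresh epithelial cell (d = 0)
#' and persists; (ii) in each epithelial cohort the number of EMT
#' conversions is drawn from a binomial with per-cell probability `delta`
#' — converted cells become stem cells active from the next generation and
#' increment the cumulative EMT count; (iii) every remaining epithelial
#' cell divides into two cells with one more division completed, daughters
#' reaching the generational capacity becoming senescent; (iv) the
#' generation counter increments. Cohort-level binomial sampling is
#' distributionally identical to per-cell Bernoulli draws but costs O(g)
#' per step, so large designs run in seconds.
#'
#' @param state A `cohort_state`.
#' @param config A [sim_config()].
#' @return The updated `cohort_state`. Uses the current R RNG stream.
#' @export
step_generation <- function(state, config) {
  g <- config$g
  E <- state$E_counts
  conv <- if (config$delta > 0) stats::rbinom(g, E, config$delta)
          else numeric(g)
  divided <- E - conv
  newE <- numeric(g)
  newE[1] <- state$M_count                     # fresh E from asymmetric division
  if (g > 1) newE[2:g] <- 2 * divided[1:(g - 1)]
  state$senescent_count <- state$senescent_count + 2 * divided[g]
  state$M_count <- state$M_count + sum(conv)   # EMT products are full stems
  state$N_E <- state$N_E + sum(conv)
  state$E_counts <- newE
  state$generation <- state$generation + 1L
  state
}

#' Run a single stochastic trial
#'
#' Applies [step_generation()] for `generations` steps, stopping early if
#' the live population is extinct (possible only when the run starts
#' without stem cells and no EMT event rescues it).
#'
#' @param config A [sim_config()].
#' @return A `trial_record` list: `live_by_generation` (live totals after
#'   each step, padded with the final value if the run ended early),
#'   `n_emt` (final cumulative EMT count), `first_emt_generation` (NA if
#'   no event), `final_live`, and `final_state`. Uses the current RNG
#'   stream; see [run_batch()] for seeded substreams.
#' @export
run_trial <- function(config) {
  state <- new_cohort_state(config)
  live <- numeric(config$generations)
  first_emt <- NA_integer_
  for (s in seq_len(config$generations)) {
    state <- step_generation(state, config)
    live[s] <- live_total(state)
    if (is.na(first_emt) && state$N_E > 0) first_emt <- s
    if (live[s] == 0) {                       # extinct: all E senesced, no stems
      if (s < config$generations) live[(s + 1):config$generations] <- 0
      break
    }
  }
  structure(list(live_by_generation = live, n_emt = state$N_E,
                 first_emt_generation = first_emt,
                 final_live = live_total(state), final_state = state),
            class = "trial_record")
}

# Deterministic per-trial substream seed from the master seed.
trial_seed <- function(seed, trial) {
  as.integer((as.double(seed %% 2147483647L) * 48271 +
                as.double(trial) * 69621) %% 2147483647)
}

#' Run a batch of independent stochastic trials
#'
#' Each trial runs on a deterministic substream derived from the master
#' seed, so batches are reproducible and trial results do not depend on
#' execution order.
#'
#' @param config A [sim_config()].
#' @param keep_trials If TRUE, attach the per-trial records.
#' @return A `batch_summary` list: `fraction_with_emt` (share of trials
#'   with >= 1 EMT event), `n_with_emt`, `emt_count_histogram` (named
#'   table over EMT counts), `cumulative_fraction_by_generation` (running
#'   share of trials whose first EMT occurred by each generation),
#'   `trials` (a data.frame `trial, first_emt_generation, n_emt,
#'   final_live`), `config`, and optionally `records`.
#' @examples
#' \donttest{
#' b <- run_batch(sim_config(g = 18, delta = 1e-8, generations = 120,
#'                           trials = 1000, seed = 7))
#' b$fraction_with_emt  # about 0.24
#' }
#' @export
run_batch <- function(config, keep_trials = FALSE) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  records <- vector("list", config$trials)
  for (i in seq_len(config$trials)) {
    set.seed(trial_seed(config$seed, i))
    records[[i]] <- run_trial(config)
  }
  summarize_batch(records, config, keep_trials)
}

summarize_batch <- function(records, config, keep_trials = FALSE) {
  n_emt <- vapply(records, `[[`, numeric(1), "n_emt")
  first <- vapply(records, function(r)
    as.double(r$first_emt_generation), numeric(1))
  final <- vapply(records, `[[`, numeric(1), "final_live")
  cum <- vapply(seq_len(config$generations), function(s)
    mean(!is.na(first) & first <= s), numeric(1))
  out <- list(
    fraction_with_emt = mean(n_emt >= 1),
    n_with_emt = sum(n_emt >= 1),
    emt_count_histogram = table(factor(n_emt, levels = 0:max(n_emt))),
    cumulative_fraction_by_generation = cum,
    trials = data.frame(trial = seq_along(records),
                        first_emt_generation = first,
                        n_emt = n_emt, final_live = final),
    config = config)
  if (keep_trials) out$records <- records
  structure(out, class = "batch_summary")
}

#' @export
print.batch_summary <- function(x, ...) {
  cat(sprintf(
    "Batch of %d trials (g = %d, delta = %g, %d generations):\n",
    x$config$trials, x$config$g, x$config$delta, x$config$generations))
  ci <- binomial_ci(x$n_with_emt, x$config$trials)
  cat(sprintf("  trials with >= 1 EMT event: %d (%.1f%%, 95%% CI %.1f-%.1f%%)\n",
              x$n_with_emt, 100 * x$fraction_with_emt,
              100 * ci[1], 100 * ci[2]))
  invisible(x)
}

binomial_ci <- function(x, n, level = 0.95) {
  fit <- stats::binom.test(x, n, conf.level = level)
  unname(fit$conf.int)
}

#' Tumor-recurrence experiment from residual epithelial cells
#'
#' Models recovery of a dormant tumor after a chemotherapy that eliminated
#' every mesenchymal stem cell, leaving a small population of fresh
#' epithelial cells. The tumor recurs if an EMT event occurs before the
#' whole epithelial population is lost to senescence — which, absent EMT,
#' takes exactly `g` generations. The fraction of trials with at least one
#' EMT event estimates the recurrence probability.
#'
#' @param g Generational capacity.
#' @param delta Per-division EMT probability.
#' @param init_E Number of residual epithelial cells (full capacity).
#' @param trials Number of independent trials.
#' @param seed Master RNG seed.
#' @return A `batch_summary` (see [run_batch()]).
#' @examples
#' \donttest{
#' r <- recurrence_experiment(g = 18, delta = 1e-7, init_E = 10,
#'                            trials = 1000, seed = 7)
#' r$n_with_emt  # about 230 of 1000
#' }
#' @export
recurrence_experiment <- function(g, delta, init_E = 10, trials = 1000,
                                  seed = 1) {
  if (init_E < 1) {
    cfg <- sim_config(g, delta, generations = g, init_M = 0, init_E = 1,
                      trials = trials, seed = seed)
    cfg$init_E <- 0  # degenerate empty start: nothing can happen
  } else {
    cfg <- sim_config(g, delta, generations = g, init_M = 0,
                      init_E = init_E, trials = trials, seed = seed)
  }
  run_batch(cfg)
}

#' Count epithelial division events in the EMT-free trajectory
#'
#' Deterministic count of the epithelial division events — the EMT
#' opportunities — occurring over a design when `delta = 0`. Until the
#' first EMT event every stochastic trajectory coincides with this
#' deterministic one, so this count feeds the exact occurrence oracle
#' [expected_emt_fraction()]. For a single fresh epithelial lineage run to
#' exhaustion the count is `2^g - 1` (the internal nodes of a full binary
#' tree of depth g).
#'
#' @param g Generational capacity.
#' @param generations Number of generation steps (for pure-epithelial
#'   starts, `g` steps exhaust the population).
#' @param init_M,init_E Initial counts.
#' @return The exact number of division events (numeric; exact up to 2^53).
#' @examples
#' division_event_count(g = 3, generations = 3, init_M = 0, init_E = 1) # 7
#' division_event_count(g = 2, generations = 5, init_M = 1)             # 10
#' @export
division_event_count <- function(g, generations, init_M = 1, init_E = 0) {
  E <- numeric(g)
  E[1] <- init_E
  M <- init_M
  events <- 0
  for (s in seq_len(generations)) {
    events <- events + sum(E)
    newE <- numeric(g)
    newE[1] <- M
    if (g > 1) newE[2:g] <- 2 * E[1:(g - 1)]
    E <- newE
  }
  events
}

#' Exact probability that a trial shows at least one EMT event
#'
#' Before its first EMT event a trajectory is identical to the EMT-free
#' one, so the number of independent Bernoulli(delta) opportunities is the
#' deterministic division-event count D and
#' \deqn{P(\ge 1\ \mathrm{EMT}) = 1 - (1-\delta)^D} exactly. Computed via
#' `expm1`/`log1p` so tiny `delta` keeps full precision.
#'
#' @param delta Per-division EMT probability.
#' @param D Division-event count (see [division_event_count()]).
#' @return The occurrence probability.
#' @examples
#' expected_emt_fraction(1e-7, 10 * (2^18 - 1))  # about 0.231
#' @export
expected_emt_fraction <- function(delta, D) {
  stopifnot(delta >= 0, delta <= 1, D >= 0)
  if (delta == 0 || D == 0) return(0)
  if (delta == 1) return(1)
  -expm1(D * log1p(-delta))
}

#' Closed-form steady-state tumor size
#'
#' Without cell death the live tumor population founded by stem cells
#' reaches a constant plateau: each stem cell sustains a full epithelial
#' pedigree of \eqn{2^g} live cells (itself included), and each EMT event
#' founds one more, giving total size \eqn{T = 2^g (1 + N_E)}. For
#' g = 20 a single pioneer cell yields about one million cells — a tumor
#' small enough to remain clinically undetectable.
#'
#' @param g Generational capacity (>= 1).
#' @param N_E Number of EMT events (>= 0).
#' @return Total live tumor size in cells.
#' @examples
#' tumor_size_closed_form(20, 0)  # 1048576
#' @export
tumor_size_closed_form <- function(g, N_E = 0) {
  stopifnot(g >= 1, N_E >= 0)
  2^g * (1 + N_E)
}

#' Per-cell reference implementation of a trial
#'
#' A naive simulator holding every epithelial cell individually and
#' drawing one Bernoulli per cell per generation. Distributionally
#' identical to the cohort-binomial engine; exponentially slower, intended
#' as a cross-check at small generational capacity.
#'
#' @param config A [sim_config()] (keep `g` small).
#' @return A `trial_record`, as [run_trial()].
#' @export
run_trial_percell <- function(config) {
  g <- config$g
  M <- config$init_M
  cells <- rep.int(0L, config$init_E)   # divisions completed, one entry per cell
  senescent <- 0; N_E <- 0
  live <- numeric(config$generations)
  first_emt <- NA_integer_
  for (s in seq_len(config$generations)) {
    conv <- if (length(cells) && config$delta > 0)
      stats::runif(length(cells)) < config$delta else logical(length(cells))
    n_conv <- sum(conv)
    N_E <- N_E + n_conv
    if (is.na(first_emt) && N_E > 0) first_emt <- s
    dividing <- cells[!conv]
    daughters <- rep(dividing + 1L, each = 2L)
    senescent <- senescent + sum(daughters >= g)
    cells <- c(rep.int(0L, M), daughters[daughters < g])
    M <- M + n_conv
    live[s] <- M + length(cells)
    if (live[s] == 0) {
      if (s < config$generations) live[(s + 1):config$generations] <- 0
      break
    }
  }
  structure(list(live_by_generation = live, n_emt = N_E,
                 first_emt_generation = first_emt,
                 final_live = M + length(cells), final_state = NULL),
            class = "trial_record")
}
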