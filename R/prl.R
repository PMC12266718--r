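# Probabilistic reversal learning (PRL) task logic. Trials are organised in
# two alternating blocks; each block assigns every stimulation type a reward
# probability ("reward block contingencies"), and block lengths are drawn
# uniformly from a configured range. A trial generator decides the next
# trial's stimulation and reward availability and tracks correct licks per
# port; a trial controller plays one trial through its timed phases (odour,
# pre-response delay, response window, reward window) against a rig event
# stream and reports the outcome. The generator and controller form the
# 2-cycle at the heart of the task graph: each trial's history feeds the
# definition of the next.

#' PRL task configuration
#'
#' The reference configuration has 4 stimulation types and 2 blocks whose
#' reward contingencies are mirror images (0.8/0.8/0.2/0.2 versus
#' 0.2/0.2/0.8/0.8), so a reversal swaps which stimuli are worth responding
#' to. Block lengths are drawn uniformly (inclusive) from
#' `block_length_range`.
#'
#' @param contingencies numeric matrix, blocks x stimulation types, of
#'   reward probabilities in `[0, 1]`.
#' @param block_length_range integer `c(lo, hi)`, `1 <= lo <= hi`.
#' @return a `rigflow_prl_config`.
#' @export
prl_config <- function(contingencies = rbind(c(0.8, 0.8, 0.2, 0.2),
                                             c(0.2, 0.2, 0.8, 0.8)),
                       block_length_range = c(20L, 40L)) {
  contingencies <- as.matrix(contingencies)
  if (any(contingencies < 0) || any(contingencies > 1)) {
    stop("reward contingencies must be probabilities in [0, 1]", call. = FALSE)
  }
  lo <- block_length_range[[1]]
  hi <- block_length_range[[2]]
  if (lo < 1 || lo > hi) {
    stop("block_length_range must satisfy 1 <= lo <= hi", call. = FALSE)
  }
  structure(list(contingencies = contingencies,
                 n_blocks = nrow(contingencies),
                 n_stim_types = ncol(contingencies),
                 block_length_range = c(as.integer(lo), as.integer(hi))),
            class = "rigflow_prl_config")
}

#' Fresh trial-generator state
#'
#' Blocks alternate in a strict cycle starting at block 0; the first step
#' draws the first block's length. Correct-lick tallies per port are
#' tracked from the trial history but do not, by default, influence block
#' transitions (lengths are drawn, not performance-gated); an optional
#' performance rule can be enabled via `performance_rule`.
#'
#' @param cfg a [prl_config()].
#' @param performance_rule optional list `list(m, w)`: advance the block
#'   early once the last `w` trials contain at least `m` correct licks.
#'   `NULL` (default) disables the rule.
#' @return a `rigflow_prl_state`.
#' @export
prl_generator_state <- function(cfg = prl_config(), performance_rule = NULL) {
  structure(list(
    block_index = 0L,
    remaining = NA_integer_,       # first step draws the first block length
    trial_number = 0L,
    port_correct_tally = integer(n_ports(cfg)),
    recent_correct = logical(),
    block_lengths = integer(),
    performance_rule = performance_rule
  ), class = "rigflow_prl_state")
}

# Stimulation types map onto lick ports in consecutive pairs
# (stims {0,1} -> port 0, {2,3} -> port 1, ...).
n_ports <- function(cfg) max(1L, cfg$n_stim_types %/% 2L)

#' Port a stimulation type is assigned to
#'
#' @param stim_type 0-based stimulation type (vectorised).
#' @return 0-based port index, `stim_type %/% 2`.
#' @export
stim_port <- function(stim_type) as.integer(stim_type) %/% 2L

#' Generate the next trial
#'
#' Updates the running tallies from the previous trial's result, advances
#' the block when the current one is exhausted (drawing a fresh length
#' uniformly from the configured range), draws the stimulation type
#' uniformly over the configured types, and draws reward availability with
#' the contingency probability of the (block, stimulation) cell. Randomness
#' comes from R's global RNG; seed the session with `set.seed()` for
#' reproducible schedules.
#'
#' @param state a `rigflow_prl_state`.
#' @param prev the previous trial's result (a list with `correct_port_licked`
#'   and `stim_type`), or `NULL` for the start signal.
#' @param cfg a [prl_config()].
#' @return list with elements `state` (updated) and `trial` (a
#'   `rigflow_trial_definition`: `stim_type`, `reward_available`,
#'   `block_index`, `trial_number`).
#' @export
trial_generator_step <- function(state, prev = NULL, cfg = prl_config()) {
  stopifnot(inherits(state, "rigflow_prl_state"), inherits(cfg, "rigflow_prl_config"))
  if (!is.null(prev) && isTRUE(as.logical(prev$correct_port_licked)[[1]])) {
    port <- stim_port(prev$stim_type[[1]]) + 1L
    state$port_correct_tally[[port]] <- state$port_correct_tally[[port]] + 1L
  }
  if (!is.null(prev)) {
    state$recent_correct <- c(state$recent_correct,
                              isTRUE(as.logical(prev$correct_port_licked)[[1]]))
  }
  advance <- FALSE
  if (is.na(state$remaining)) {
    state$remaining <- draw_block_length(cfg)     # first block, index stays 0
    state$block_lengths <- state$remaining
  } else if (state$remaining == 0L) {
    advance <- TRUE
  } else if (!is.null(state$performance_rule)) {
    rule <- state$performance_rule
    recent <- tail(state$recent_correct, rule$w)
    if (length(recent) == rule$w && sum(recent) >= rule$m) advance <- TRUE
  }
  if (advance) {
    state$block_index <- (state$block_index + 1L) %% cfg$n_blocks
    state$remaining <- draw_block_length(cfg)
    state$block_lengths <- c(state$block_lengths, state$remaining)
    state$port_correct_tally <- integer(n_ports(cfg))
    state$recent_correct <- logical()
  }
  stim <- sample.int(cfg$n_stim_types, 1L) - 1L
  p <- cfg$contingencies[state$block_index + 1L, stim + 1L]
  reward_available <- runif(1L) < p
  trial <- structure(list(
    stim_type = stim,
    reward_available = reward_available,
    block_index = state$block_index,
    trial_number = state$trial_number
  ), class = "rigflow_trial_definition")
  state$remaining <- state$remaining - 1L
  state$trial_number <- state$trial_number + 1L
  list(state = state, trial = trial)
}

draw_block_length <- function(cfg) {
  r <- cfg$block_length_range
  r[[1]] + sample.int(r[[2]] - r[[1]] + 1L, 1L) - 1L
}

#' Controller timing parameters
#'
#' Durations are in seconds and converted to integer nanoseconds
#' internally. `reward_only_after_lick` gates the reward on a correct-port
#' lick inside the response window; when `FALSE` an available reward is
#' delivered regardless of behaviour. Serial-port fields (`com_port`,
#' `baud_rate`) are accepted for graph-file compatibility but ignored: the
#' rig here is a simulated event stream.
#'
#' @param odour_window,pre_response_delay,response_window,reward_window
#'   phase durations in seconds, all `>= 0`.
#' @param reward_only_after_lick logical.
#' @param com_port,baud_rate accepted and ignored (no serial hardware).
#' @return a `rigflow_controller_params`.
#' @export
controller_params <- function(odour_window = 0.5, pre_response_delay = 0.25,
                              response_window = 1.5, reward_window = 1.0,
                              reward_only_after_lick = TRUE,
                              com_port = NULL, baud_rate = NULL) {
  durations <- c(odour_window, pre_response_delay, response_window, reward_window)
  if (any(durations < 0)) stop("phase durations must be >= 0", call. = FALSE)
  if (!is.null(com_port) || !is.null(baud_rate)) {
    warning("com_port/baud_rate are ignored: the rig is simulated", call. = FALSE)
  }
  structure(list(
    odour_window_ns = odour_window * 1e9,
    pre_response_delay_ns = pre_response_delay * 1e9,
    response_window_ns = response_window * 1e9,
    reward_window_ns = reward_window * 1e9,
    reward_only_after_lick = isTRUE(reward_only_after_lick)
  ), class = "rigflow_controller_params")
}

#' Run one trial through its phases
#'
#' Phases execute in order odour -> pre-response delay -> response window ->
#' reward window, timed against the supplied clock. Licks are read from the
#' rig event stream; a lick on the correct port inside the response window
#' registers as a correct response, and reward is delivered when it was
#' available and the `reward_only_after_lick` gate is satisfied.
#'
#' @param trial a trial definition from [trial_generator_step()].
#' @param params a [controller_params()].
#' @param rig a [scripted_session()] (or its data.frame of events).
#' @param clock a clock from [clock_real()] or [clock_simulated()].
#' @return a `rigflow_trial_result`: `stim_type`, `licked`,
#'   `correct_port_licked`, `rewarded`, `block_index`, `trial_number`, and
#'   phase timestamps `t_odour_on`, `t_pre_response`, `t_response_open`,
#'   `t_reward_open`, `t_trial_end` (ns, non-decreasing).
#' @export
trial_controller_run_trial <- function(trial, params = controller_params(),
                                       rig = scripted_session(), clock = clock_simulated()) {
  stopifnot(inherits(params, "rigflow_controller_params"))
  events <- if (inherits(rig, "rigflow_session")) rig$events else rig
  t_odour_on <- clock$now()
  clock$sleep(params$odour_window_ns)
  t_pre_response <- clock$now()
  clock$sleep(params$pre_response_delay_ns)
  t_response_open <- clock$now()
  clock$sleep(params$response_window_ns)
  t_reward_open <- clock$now()
  licks <- events[events$kind == "lick" &
                    events$time_ns >= t_response_open &
                    events$time_ns < t_reward_open, , drop = FALSE]
  licked <- nrow(licks) > 0L
  correct <- any(licks$port == stim_port(trial$stim_type))
  rewarded <- isTRUE(trial$reward_available) &&
    (!params$reward_only_after_lick || correct)
  clock$sleep(params$reward_window_ns)
  t_trial_end <- clock$now()
  structure(list(
    stim_type = trial$stim_type,
    licked = licked,
    correct_port_licked = correct,
    rewarded = rewarded,
    block_index = trial$block_index,
    trial_number = trial$trial_number,
    t_odour_on = t_odour_on,
    t_pre_response = t_pre_response,
    t_response_open = t_response_open,
    t_reward_open = t_reward_open,
    t_trial_end = t_trial_end
  ), class = "rigflow_trial_result")
}

#' Simulate a whole PRL session
#'
#' Drives the generator/controller loop for `n_trials` with a scripted
#' subject that licks the correct port with probability `p_correct_lick`
#' (and a random port otherwise) in every response window. Useful for
#' statistical checks of the task logic without the process engine.
#'
#' @param n_trials number of trials.
#' @param cfg a [prl_config()].
#' @param params a [controller_params()].
#' @param p_correct_lick probability the simulated subject licks the correct
#'   port on a trial.
#' @param seed RNG seed for the whole session.
#' @return list with `trials` (data.frame, one row per trial) and
#'   `block_lengths` (integer vector of drawn lengths, last one possibly
#'   unfinished).
#' @export
simulate_prl_session <- function(n_trials, cfg = prl_config(),
                                 params = controller_params(),
                                 p_correct_lick = 0.8, seed = 1L) {
  set.seed(seed)
  state <- prl_generator_state(cfg)
  prev <- NULL
  rows <- vector("list", n_trials)
  clock <- clock_simulated()
  for (i in seq_len(n_trials)) {
    step <- trial_generator_step(state, prev, cfg)
    state <- step$state
    trial <- step$trial
    # scripted subject: lick mid response window
    lick_correct <- runif(1L) < p_correct_lick
    port <- if (lick_correct) stim_port(trial$stim_type) else
      sample.int(n_ports(cfg), 1L) - 1L
    t_lick <- clock$now() + params$odour_window_ns + params$pre_response_delay_ns +
      params$response_window_ns / 2
    rig <- scripted_session(data.frame(time_ns = t_lick, kind = "lick", port = port))
    res <- trial_controller_run_trial(trial, params, rig, clock)
    prev <- res
    rows[[i]] <- data.frame(
      trial_number = trial$trial_number,
      block_index = trial$block_index,
      stim_type = trial$stim_type,
      reward_available = trial$reward_available,
      licked = res$licked,
      correct_port_licked = res$correct_port_licked,
      rewarded = res$rewarded
    )
  }
  list(trials = do.call(rbind, rows), block_lengths = state$block_lengths)
}
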