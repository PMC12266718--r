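test_that("degenerate contingencies force reward availability", {
  cfg_all <- prl_config(contingencies = rbind(rep(1, 4), rep(1, 4)),
                        block_length_range = c(5L, 10L))
  cfg_none <- prl_config(contingencies = rbind(rep(0, 4), rep(0, 4)),
                         block_length_range = c(5L, 10L))
  set.seed(1)
  s <- prl_generator_state(cfg_all)
  for (i in 1:50) {
    step <- trial_generator_step(s, NULL, cfg_all)
    s <- step$state
    expect_true(step$trial$reward_available)
  }
  set.seed(1)
  s <- prl_generator_state(cfg_none)
  for (i in 1:50) {
    step <- trial_generator_step(s, NULL, cfg_none)
    s <- step$state
    expect_false(step$trial$reward_available)
  }
  expect_error(prl_config(contingencies = rbind(c(0.5, 1.2, 0, 0), rep(0, 4))),
               "probabilities")
  expect_error(prl_config(block_length_range = c(0L, 5L)), "lo")
})

test_that("a 10^4-trial session recovers the contingency matrix within 99% CIs", {
  cfg <- prl_config()
  s <- simulate_prl_session(10000L, cfg, seed = 42L)
  trials <- s$trials
  expect_identical(sort(unique(trials$stim_type)), 0:3)
  # block lengths stay within the configured range
  lengths_complete <- head(s$block_lengths, -1)
  expect_true(all(lengths_complete >= cfg$block_length_range[[1]]))
  expect_true(all(lengths_complete <= cfg$block_length_range[[2]]))
  # per-cell empirical reward frequency within the binomial 99% CI
  for (b in 0:1) for (st in 0:3) {
    cell <- trials[trials$block_index == b & trials$stim_type == st, ]
    p <- cfg$contingencies[b + 1, st + 1]
    n <- nrow(cell)
    expect_gt(n, 500)
    half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(cell$reward_available) - p), half + 1e-12,
              label = sprintf("cell block %d stim %d", b, st))
  }
})

test_that("drawn block lengths are uniform on the configured range", {
  cfg <- prl_config(block_length_range = c(5L, 10L))
  set.seed(7)
  lengths <- integer(1000)
  for (i in seq_along(lengths)) lengths[[i]] <- rigflow:::draw_block_length(cfg)
  expect_true(all(lengths >= 5L & lengths <= 10L))
  p <- stats::chisq.test(table(factor(lengths, levels = 5:10)))$p.value
  expect_gt(p, 0.01)
})

test_that("controller phases run in order and gate reward on the lick", {
  params <- controller_params(odour_window = 0.5, pre_response_delay = 0.25,
                              response_window = 1.5, reward_window = 1,
                              reward_only_after_lick = TRUE)
  trial <- structure(list(stim_type = 1L, reward_available = TRUE,
                          block_index = 0L, trial_number = 0L),
                     class = "rigflow_trial_definition")
  # lick at mid response window on the correct port -> rewarded
  rig <- scripted_session(data.frame(time_ns = 0.5e9 + 0.25e9 + 0.75e9,
                                     kind = "lick", port = stim_port(1L)))
  res <- trial_controller_run_trial(trial, params, rig, clock_simulated())
  expect_true(res$licked)
  expect_true(res$correct_port_licked)
  expect_true(res$rewarded)
  expect_true(res$t_odour_on <= res$t_pre_response)
  expect_true(res$t_pre_response <= res$t_response_open)
  expect_true(res$t_response_open <= res$t_reward_open)
  expect_true(res$t_reward_open <= res$t_trial_end)
  expect_equal(res$t_trial_end, 3.25e9)

  # no lick -> no reward under the gate
  res2 <- trial_controller_run_trial(trial, params, scripted_session(), clock_simulated())
  expect_false(res2$licked)
  expect_false(res2$rewarded)

  # wrong-port lick -> no reward under the gate
  rig3 <- scripted_session(data.frame(time_ns = 1.5e9, kind = "lick",
                                      port = 1L - stim_port(1L)))
  res3 <- trial_controller_run_trial(trial, params, rig3, clock_simulated())
  expect_true(res3$licked)
  expect_false(res3$correct_port_licked)
  expect_false(res3$rewarded)

  # reward not gated on licking: available reward is delivered regardless
  free <- controller_params(reward_only_after_lick = FALSE)
  res4 <- trial_controller_run_trial(trial, free, scripted_session(), clock_simulated())
  expect_true(res4$rewarded)
})

test_that("all-zero windows produce an unrewarded zero-duration trial", {
  params <- controller_params(0, 0, 0, 0)
  trial <- structure(list(stim_type = 0L, reward_available = FALSE,
                          block_index = 0L, trial_number = 0L),
                     class = "rigflow_trial_definition")
  res <- trial_controller_run_trial(trial, params, scripted_session(), clock_simulated())
  expect_false(res$rewarded)
  expect_equal(res$t_trial_end - res$t_odour_on, 0)
  expect_error(controller_params(odour_window = -1), ">= 0")
})

test_that("the rewarded flag never violates its invariants across a session", {
  s <- simulate_prl_session(2000L, seed = 9L, p_correct_lick = 0.5)
  t <- s$trials
  expect_true(all(!t$rewarded | t$reward_available))      # rewarded => available
  expect_true(all(!t$rewarded | t$correct_port_licked))   # gate was on
  expect_true(all(!t$correct_port_licked | t$licked))
})

test_that("replaying a scripted session gives identical results", {
  a <- simulate_prl_session(500L, seed = 123L)
  b <- simulate_prl_session(500L, seed = 123L)
  expect_identical(a$trials, b$trials)
  expect_identical(a$block_lengths, b$block_lengths)
  expect_error(scripted_session(data.frame(time_ns = c(2, 1), kind = "lick",
                                           port = 0L)),
               "non-decreasing")
})

test_that("the optional performance rule advances blocks early", {
  cfg <- prl_config(block_length_range = c(50L, 50L))
  set.seed(4)
  s <- prl_generator_state(cfg, performance_rule = list(m = 5L, w = 5L))
  prev <- NULL
  blocks <- integer(30)
  for (i in 1:30) {
    step <- trial_generator_step(s, prev, cfg)
    s <- step$state
    blocks[[i]] <- step$trial$block_index
    prev <- list(stim_type = step$trial$stim_type, correct_port_licked = TRUE)
  }
  expect_true(any(blocks == 1L))   # switched well before the drawn length of 50
})
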