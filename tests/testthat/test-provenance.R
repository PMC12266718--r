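test_that("drop counting follows the at-most-once arithmetic", {
  expect_identical(count_drops(216300, 216244), 56)
  expect_identical(count_drops(10, 10), 0)
  expect_error(count_drops(5, 7), "at-most-once")
})

test_that("compose_chain matches the exhaustive relational join", {
  # hand example: terminal 4 maps back to origin 7, five packets lost
  origin <- data.frame(packet_index = 0:9)
  log <- data.frame(upstream_node = "A",
                    upstream_packet_id = c(0L, 1L, 3L, 4L, 7L),
                    local_packet_id = 0:4,
                    timestamp_ns = 0:4)
  cc <- compose_chain(origin, list(log))
  expect_equal(cc$table, brute_force_compose(0:9, list(log)))
  expect_identical(cc$table$origin_index[cc$table$terminal_index == 4], 7L)
  expect_identical(cc$summary$dropped, 5L)

  # identity logs over three stages compose to the identity mapping
  id_log <- function(n) data.frame(upstream_node = "X",
                                   upstream_packet_id = 0:(n - 1),
                                   local_packet_id = 0:(n - 1),
                                   timestamp_ns = 0:(n - 1))
  cc3 <- compose_chain(data.frame(packet_index = 0:49),
                       list(id_log(50), id_log(50), id_log(50)))
  expect_identical(cc3$table$terminal_index, cc3$table$origin_index)
  expect_identical(cc3$summary$dropped, 0L)
})

test_that("seeded random chains reconcile exactly to the simulator's hidden truth", {
  for (seed in c(11L, 12L)) {
    sim <- rigflow:::simulate_capture_chain(10000L, c(0.01, 0.02, 0.005), seed)
    cc <- compose_chain(sim$substate, sim$logs)
    truth <- sim$truth[sim$truth$survived, ]
    # the simulator's origin is the trigger train; the chain's origin is the
    # capture node's packets, so map back through the substate
    expect_identical(cc$table$terminal_index, truth$terminal_index)
    expect_identical(sim$substate$pulse_index[cc$table$origin_index + 1L],
                     truth$trigger_index)
    # brute-force oracle on the same instance
    expect_equal(cc$table, brute_force_compose(sim$substate$packet_index, sim$logs))
    # monotone in both coordinates, end-anchored
    expect_true(all(diff(cc$table$terminal_index) > 0))
    expect_true(all(diff(cc$table$origin_index) > 0))
    expect_identical(tail(cc$table$terminal_index, 1),
                     tail(sim$logs[[length(sim$logs)]]$local_packet_id, 1))
  }
})

test_that("malformed logs are rejected with the offending row named", {
  origin <- data.frame(packet_index = 0:9)
  non_monotone <- data.frame(upstream_node = "A", upstream_packet_id = c(0L, 2L, 1L),
                             local_packet_id = 0:2, timestamp_ns = 0:2)
  expect_error(compose_chain(origin, list(non_monotone)), "row 3")
  gappy_local <- data.frame(upstream_node = "A", upstream_packet_id = 0:2,
                            local_packet_id = c(0L, 1L, 3L), timestamp_ns = 0:2)
  expect_error(compose_chain(origin, list(gappy_local)), "gapless")
  broken_subset <- data.frame(upstream_node = "A", upstream_packet_id = c(0L, 12L),
                              local_packet_id = 0:1, timestamp_ns = 0:1)
  expect_error(compose_chain(origin, list(broken_subset)), "not an id")
})

test_that("divided pulses are attributed to the first base pulse of their group", {
  expect_identical(divided_pulse_origin(0, 4), 0L)
  expect_identical(divided_pulse_origin(3, 4), 12L)
  expect_identical(divided_pulse_origin(0:3, 4, onset = FALSE), c(3L, 7L, 11L, 15L))
  # a 120 Hz train divided by 4 runs at 30 Hz
  n_base <- 120L * 10L
  n_div <- n_base %/% 4L
  expect_identical(n_div %/% 10L, 30L)
})

test_that("pulse records enforce the division-factor count within one pulse", {
  expect_s3_class(pulse_record(1:16, 1:4, 120, 4), "rigflow_pulse_record")
  expect_s3_class(pulse_record(1:18, 1:4, 120, 4), "rigflow_pulse_record")  # floor +- 1
  expect_error(pulse_record(1:16, 1:2, 120, 4), "inconsistent")
})

test_that("lossless two-chain alignment maps B frame j to A frame 4j", {
  sub_a <- data.frame(packet_index = 0:15, pulse_index = 0:15)
  sub_b <- data.frame(packet_index = 0:3, pulse_index = 0:3)
  id_corr <- function(n) {
    structure(list(table = data.frame(terminal_index = 0:(n - 1),
                                      origin_index = 0:(n - 1)),
                   summary = list(origin_total = n, terminal_total = n, dropped = 0L)),
              class = "rigflow_correspondence")
  }
  pulses <- pulse_record(0:15, (0:3) * 4, 120, 4)
  map <- align_two_chains(id_corr(16), id_corr(4), sub_a, sub_b, pulses)
  expect_identical(map$a_terminal, c(0L, 4L, 8L, 12L))
  expect_true(all(map$matched))
})

test_that("a dropped A frame flags its B partner instead of deleting it", {
  sub_a <- data.frame(packet_index = 0:15, pulse_index = 0:15)
  sub_b <- data.frame(packet_index = 0:3, pulse_index = 0:3)
  # A terminal chain lost origin frame 4
  a_tbl <- data.frame(terminal_index = 0:14, origin_index = setdiff(0:15, 4L))
  chain_a <- structure(list(table = a_tbl,
                            summary = list(origin_total = 16L, terminal_total = 15L,
                                           dropped = 1L)),
                       class = "rigflow_correspondence")
  chain_b <- structure(list(table = data.frame(terminal_index = 0:3, origin_index = 0:3),
                            summary = list(origin_total = 4L, terminal_total = 4L,
                                           dropped = 0L)),
                       class = "rigflow_correspondence")
  pulses <- pulse_record(0:15, (0:3) * 4, 120, 4)
  map <- align_two_chains(chain_a, chain_b, sub_a, sub_b, pulses)
  expect_identical(nrow(map), 4L)          # nothing silently removed
  expect_false(map$matched[map$b_terminal == 1])
  expect_true(all(map$matched[map$b_terminal != 1]))
})

test_that("full-rig alignment equals the simulator's ground truth", {
  rig <- simulate_rig(rig_sim_config(base_rate = 120, division_factor = 4L,
                                     duration = 60,
                                     drop_probs_a = c(0.005, 0.01),
                                     drop_probs_b = c(0.01, 0.005),
                                     seed = 77L))
  chain_a <- compose_chain(rig$chain_a$substate, rig$chain_a$logs)
  chain_b <- compose_chain(rig$chain_b$substate, rig$chain_b$logs)
  map <- align_two_chains(chain_a, chain_b, rig$chain_a$substate,
                          rig$chain_b$substate, rig$pulses)
  truth <- rig$truth[!is.na(rig$truth$b_terminal), ]
  expected_a <- truth$a_terminal[match(map$base_pulse, truth$base_pulse)]
  expect_identical(map$a_terminal, expected_a)
  expect_identical(map$b_terminal, truth$b_terminal)
  # every surviving B frame appears exactly once; unmatched are flagged
  expect_identical(sum(map$matched), sum(!is.na(expected_a)))
})
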