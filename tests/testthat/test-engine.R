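# Live engine tests: each start_graph spawns real OS processes (director,
# three forwarders, com + worker per node), so runs are kept short and each
# run is mined for several assertions.

test_that("a running graph is 2N+4 processes and stops without orphans", {
  for (n in c(1L, 3L)) {
    g <- chain_graph(n, values = as.numeric(1:5), interval_ns = 1e7)
    h <- start_graph(g, test_run_config(seed = 1L))
    expect_identical(process_census(h), 2L * n + 4L)
    rep <- stop_graph(h)
    expect_identical(rep$orphan_count, 0L)
    expect_length(rep$forced, 0)
    for (nd in rep$nodes) {
      expect_identical(nd$exit, "graceful")
      expect_true(nd$end_of_life)
    }
    # each healthy worker ran its end-of-life hook exactly once
    worker_logs <- list.files(file.path(rep$run_dir, "logs"),
                              pattern = "^worker_.*\\.log$", full.names = TRUE)
    expect_length(worker_logs, n)
    for (wl in worker_logs) {
      expect_identical(sum(grepl(" eol ", readLines(wl))), 1L, label = wl)
    }
    expect_error(process_census(h), "stopped")
  }
})

test_that("busy callbacks drop packets without buffering; counters conserve", {
  g <- chain_graph(2L, values = as.numeric(1:30), interval_ns = 1e7,
                   sink_sleep_ns = 1.5e8)
  h <- start_graph(g, test_run_config(seed = 2L))
  Sys.sleep(1.5)
  rep <- stop_graph(h)
  l <- rep$links[[1]]
  expect_identical(l$emitted, 30L)
  expect_identical(l$emitted, l$delivered + l$dropped)       # conservation
  expect_gt(l$dropped, 0L)                                   # busy windows lost packets
  expect_lt(l$delivered, l$emitted)                          # at most once
  log <- read_com_log(file.path(rep$run_dir, "logs", "Sink_0_com_log.csv"))
  expect_identical(nrow(log), l$delivered)
  expect_identical(log$local_packet_id, seq_len(nrow(log)) - 1L)  # gapless local ids
  expect_true(all(diff(log$upstream_packet_id) > 0))         # no reordering/duplication
  expect_identical(log$upstream_packet_id[[1]], 0L)          # first arrival delivered
  # the saved counters file agrees with the report
  counters <- read_link_counters(rep$run_dir)
  expect_identical(counters$emitted, l$emitted)
  expect_identical(counters$delivered + counters$dropped, l$emitted)
})

test_that("the PRL loop runs live, honours parameter rules, and is reproducible", {
  run_session <- function(seed) {
    g <- prl_example_graph()
    # bound the session so the saved table has a well-defined length
    g$nodes[[2]]$parameters[[length(g$nodes[[2]]$parameters) + 1L]] <-
      parameter_spec("max_trials", 30L, updatable = FALSE)
    h <- start_graph(g, test_run_config(seed = seed))
    list(h = h, g = g)
  }
  s <- run_session(99L)
  h <- s$h
  expect_identical(process_census(h), 12L)    # 2*4+4
  # unknown parameter: error ack, run unaffected
  bad <- update_parameter(h, "Trial Controller##0", "no_such_param", 1)
  expect_false(bad$ok)
  expect_match(bad$message, "unknown parameter")
  expect_false(update_parameter(h, "NoNode##0", "x", 1)$ok)
  # non-updatable parameter: refused, worker value unchanged
  fixed <- update_parameter(h, "Trial Generator##0", "block_length_min", 1L)
  expect_false(fixed$ok)
  expect_match(fixed$message, "not updatable")
  Sys.sleep(3)                                # session runs to its 30 trials
  # updatable parameter: travels to the worker and is acknowledged
  expect_true(update_parameter(h, "Trial Controller##0", "p_correct_lick", 1.0)$ok)
  rep1 <- stop_graph(h)
  expect_identical(rep1$orphan_count, 0L)
  tab1 <- read.csv(file.path(rep1$run_dir, "logs", "Save_Table_0_table.csv"))
  expect_identical(nrow(tab1), 30L)
  expect_true(all(tab1$trial_number == 0:29))
  expect_true(all(tab1$stim_type %in% 0:3))

  # same seed, fresh topology: identical saved trial table
  s2 <- run_session(99L)
  Sys.sleep(3)
  rep2 <- stop_graph(s2$h)
  tab2 <- read.csv(file.path(rep2$run_dir, "logs", "Save_Table_0_table.csv"))
  expect_identical(tab2, tab1)
})

test_that("an initialise failure aborts the start and reaps every process", {
  bad_ref <- tempfile(fileext = ".R")
  writeLines(c("make_worker <- function() {",
               "  rigflow::worker_definition('source',",
               "    initialise = function(ctx) stop('device absent'),",
               "    work = function(ctx) list(1))",
               "}"), bad_ref)
  g <- graph(
    nodes = list(
      node_spec("Good", "source", outputs = "Out",
                parameters = list(parameter_spec("values", 1)),
                worker_ref = "rigflow::worker_scripted_source"),
      node_spec("Bad", "source", outputs = "Out", worker_ref = bad_ref)))
  wait_actor_quiescence()
  expect_error(start_graph(g, test_run_config()), "device absent")
  expect_true(wait_actor_quiescence())
})

test_that("an unresolvable worker_ref fails before any spawn", {
  g <- graph(nodes = list(node_spec("X", "source", outputs = "Out",
                                    worker_ref = "rigflow::no_such_factory")))
  wait_actor_quiescence()
  expect_error(start_graph(g, test_run_config()), "unresolvable")
  expect_length(actor_pids(), 0)
})

test_that("non-local placement is parsed but refused at start", {
  g <- graph(nodes = list(node_spec("X", "source", outputs = "Out",
                                    worker_ref = "rigflow::worker_scripted_source",
                                    placement = "lab-pc-2")))
  expect_identical(validate_graph(g), character(0))
  expect_error(start_graph(g, test_run_config()), "remote execution not implemented")
})

test_that("a worker stuck in its callback is force-killed, still no orphans", {
  g <- chain_graph(2L, values = as.numeric(1:3), interval_ns = 1e7,
                   sink_sleep_ns = 120e9)     # callback effectively never returns
  h <- start_graph(g, test_run_config(seed = 3L, stop_grace = 2))
  Sys.sleep(1)
  rep <- stop_graph(h)
  expect_identical(rep$orphan_count, 0L)
  expect_true("worker_Sink##0" %in% rep$forced)
  expect_false(rep$nodes[["Sink##0"]]$end_of_life)
  expect_identical(rep$nodes[["Sink##0"]]$exit, "forced")
  expect_identical(rep$nodes[["Src##0"]]$exit, "graceful")
})
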