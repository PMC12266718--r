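test_that("worker definitions enforce the hook shapes", {
  expect_error(worker_definition("source", work = function(ctx, ev) NULL),
               "one argument")
  expect_error(worker_definition("sink", work = function(ctx) NULL),
               "two arguments")
  def <- worker_definition("transform", work = function(ctx, ev) list(ev$item))
  expect_s3_class(def, "rigflow_worker")
})

test_that("a scripted source emits ids 0..4 then idles", {
  node <- node_spec("S", "source", outputs = "Out",
                    parameters = list(parameter_spec("values", as.numeric(0:4))))
  ctx <- node_context(node, clock = clock_simulated())
  packets <- run_source_loop(worker_scripted_source(), ctx, passes = 20)
  expect_length(packets, 5)
  expect_identical(vapply(packets, `[[`, numeric(1), "packet_id"), as.numeric(0:4))
  expect_identical(vapply(packets, function(p) p$payload[[1]], numeric(1)),
                   as.numeric(0:4))
})

test_that("payload arity violations are contract faults", {
  two_out <- worker_definition("source", work = function(ctx) list(1))  # 1 item
  expect_error(run_source_loop(two_out, node_context(clock = clock_simulated()),
                               passes = 1, n_outputs = 2),
               "contract violation")
  chatty_sink <- worker_definition("sink", work = function(ctx, ev) list(1))
  expect_error(run_callback_worker(chatty_sink, node_context(clock = clock_simulated()),
                                   input_event("In", 1, "up", 0L)),
               "sink callback must return NULL")
})

test_that("a paced source on a simulated clock emits rate x duration packets", {
  # 120 passes/s for 10 simulated seconds -> 1200 packets, no wall-clock wait
  node <- node_spec("Cam", "source", outputs = "Out",
                    parameters = list(parameter_spec("values", as.numeric(1:1200)),
                                      parameter_spec("interval_ns", 1e9 / 120)))
  ctx <- node_context(node, clock = clock_simulated())
  packets <- run_source_loop(worker_scripted_source(), ctx, passes = 1200)
  expect_length(packets, 1200)
  expect_equal(ctx$clock$now(), 10e9)
})

test_that("two-output transforms map list elements to outputs first-output-first", {
  def <- worker_definition("transform",
                           work = function(ctx, ev) list("result", "history"))
  res <- run_callback_worker(def, node_context(clock = clock_simulated()),
                             input_event("In", 1, "up", 0L), n_outputs = 2)
  expect_identical(res[[1]], "result")
  expect_identical(res[[2]], "history")
})

test_that("substate recording is once per pass with reserved names protected", {
  ctx <- node_context(clock = clock_simulated())
  ctx$packet_index <- 7L
  record_substate(ctx, list(device_frame_id = 7L))
  expect_error(record_substate(ctx, list(device_frame_id = 8L)), "already called")
  ctx$pass_recorded <- FALSE
  expect_error(record_substate(ctx, list(packet_index = 1L)), "reserved")
  expect_error(record_substate(ctx, list(1, 2)), "named")
  tbl <- substate_table(ctx)
  expect_identical(names(tbl), c("packet_index", "timestamp_ns", "device_frame_id"))
  expect_identical(tbl$packet_index, 7L)
  expect_identical(tbl$device_frame_id, 7L)
})

test_that("every-pass recording yields one substate row per pass", {
  node <- node_spec("Cam", "source", outputs = "Out")
  def <- worker_definition("source", work = function(ctx) {
    record_substate(ctx, list(device_frame_id = ctx$packet_index))
    list(ctx$packet_index)
  })
  ctx <- node_context(node, clock = clock_simulated())
  run_source_loop(def, ctx, passes = 500)
  tbl <- substate_table(ctx)
  expect_identical(nrow(tbl), 500L)
  expect_identical(tbl$device_frame_id, 0:499)
  expect_true(all(diff(tbl$packet_index) >= 0))
})

test_that("worker references resolve from namespaces and files, or fail loudly", {
  fac <- resolve_worker_ref("rigflow::worker_identity")
  expect_s3_class(fac(), "rigflow_worker")
  path <- tempfile(fileext = ".R")
  writeLines(c("make_worker <- function() {",
               "  rigflow::worker_definition('transform',",
               "    work = function(ctx, event) list(event$item * 10))",
               "}"), path)
  fac2 <- resolve_worker_ref(path)
  res <- run_callback_worker(fac2(), node_context(clock = clock_simulated()),
                             input_event("In", 4, "up", 0L))
  expect_identical(res[[1]], 40)
  expect_error(resolve_worker_ref("rigflow::no_such_worker"), "unresolvable")
  expect_error(resolve_worker_ref("/no/such/file.R"), "unresolvable")
})

test_that("the pulse divider emits every k-th delivery with a running count", {
  drive_divider <- function(k, n_in) {
    node <- node_spec("Div", "transform", inputs = "In", outputs = "Out",
                      parameters = list(parameter_spec("division_factor", k)))
    ctx <- node_context(node, clock = clock_simulated())
    def <- worker_pulse_divider()
    def$initialise(ctx)
    out <- c()
    for (i in seq_len(n_in)) {
      res <- run_callback_worker(def, ctx, input_event("In", i, "up", i - 1L))
      if (!is.null(res)) out <- c(out, res[[1]])
    }
    out
  }
  expect_identical(drive_divider(4L, 16L), 1:4)       # divide-by-four
  expect_identical(drive_divider(1L, 5L), 1:5)        # pass-through counter
  expect_identical(drive_divider(4L, 15L), 1:3)       # partial group not emitted
})

test_that("udf nodes apply the wrapped function per delivered packet", {
  doubler <- udf_node(function(x) x * 2)()
  ctx <- node_context(clock = clock_simulated())
  script <- list(1:3, matrix(1:4, 2), 10)
  outs <- lapply(seq_along(script), function(i) {
    run_callback_worker(doubler, ctx, input_event("In", script[[i]], "up", i - 1L))[[1]]
  })
  expect_identical(outs, lapply(script, function(x) x * 2))
})

test_that("the table sink appends records and rejects tensors", {
  node <- node_spec("T", "sink", inputs = "In",
                    parameters = list(parameter_spec("path", tempfile(fileext = ".csv"))))
  ctx <- node_context(node, clock = clock_simulated())
  def <- worker_table_sink()
  def$initialise(ctx)
  for (i in 1:3) {
    run_callback_worker(def, ctx, input_event("In", list(trial = i, ok = TRUE), "up", i - 1L))
  }
  expect_error(run_callback_worker(def, ctx, input_event("In", 1:5, "up", 3L)),
               "record payloads")
  def$end_of_life(ctx)
  tbl <- read.csv(ctx$param("path"))
  expect_identical(nrow(tbl), 3L)
  expect_identical(tbl$trial, 1:3)
})
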