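# Ready-made node workers. Each exported `worker_*` function is a factory
# (zero arguments, returns a worker_definition) so graph files can name it
# directly, e.g. "worker_ref": "rigflow::worker_scripted_source". Worker
# state lives in ctx$state; parameters are read through ctx$param() at each
# pass, so live updates take effect between passes, never within one.

#' Scripted source: emits a fixed schedule of values, then idles
#'
#' Parameters: `values` (numeric vector; one packet per element),
#' `interval_ns` (pacing between passes, default 0).
#'
#' @return a source [worker_definition()].
#' @export
worker_scripted_source <- function() {
  worker_definition("source",
    initialise = function(ctx) {
      ctx$state$i <- 0L
      TRUE
    },
    work = function(ctx) {
      values <- ctx$param("values", numeric())
      interval <- ctx$param("interval_ns", 0)
      if (ctx$state$i >= length(values)) return(NULL)   # schedule done: idle
      ctx$state$i <- ctx$state$i + 1L
      if (interval > 0) ctx$clock$sleep(interval)
      list(as.numeric(values[[ctx$state$i]]))
    })
}

#' Key-press source: emits one start record, then idles
#'
#' Stands in for the experimenter's start button: the first pass emits a
#' record `{key: <key>}` (parameter `key`, default `"space"`), after which
#' the source idles.
#'
#' @return a source [worker_definition()].
#' @export
worker_keypress <- function() {
  worker_definition("source",
    initialise = function(ctx) { ctx$state$fired <- FALSE; TRUE },
    work = function(ctx) {
      if (ctx$state$fired) return(NULL)
      ctx$state$fired <- TRUE
      list(list(key = ctx$param("key", "space")))
    })
}

#' Identity transform
#'
#' @return a transform [worker_definition()] forwarding each delivered item
#'   unchanged.
#' @export
worker_identity <- function() {
  worker_definition("transform", work = function(ctx, event) list(event$item))
}

#' Wrap a plain one-input/one-output function as a transform worker
#'
#' The function is applied to each delivered payload item; its return value
#' becomes the node's single output. This is the quickest way to run an
#' arbitrary function as a node, or to probe a node under development with
#' scripted inputs, without writing against the full worker API.
#'
#' @param fn a function of one payload item.
#' @return a factory producing a transform [worker_definition()].
#' @export
udf_node <- function(fn) {
  stopifnot(is.function(fn))
  force(fn)
  function() worker_definition("transform", work = function(ctx, event) list(fn(event$item)))
}

#' Pulse divider transform
#'
#' Emits one output packet per `division_factor` delivered inputs (the
#' divide-by-k TTL logic of the synchronisation rig: with k = 4, a 120 Hz
#' train becomes a 30 Hz train). The emitted payload is the count of
#' emissions so far (1, 2, 3, ...).
#'
#' Parameters: `division_factor` (integer >= 1, default 4).
#'
#' @return a transform [worker_definition()].
#' @export
worker_pulse_divider <- function() {
  worker_definition("transform",
    initialise = function(ctx) {
      k <- ctx$param("division_factor", 4L)
      if (k < 1) stop("division_factor must be >= 1")
      ctx$state$seen <- 0L
      ctx$state$emitted <- 0L
      TRUE
    },
    work = function(ctx, event) {
      k <- as.integer(ctx$param("division_factor", 4L))
      ctx$state$seen <- ctx$state$seen + 1L
      if (ctx$state$seen %% k != 0L) return(NULL)
      ctx$state$emitted <- ctx$state$emitted + 1L
      list(ctx$state$emitted)
    })
}

#' Counting sink: consume anything, record one substate row per delivery
#'
#' Accepts any payload and records `{value_sum}` substate rows; parameter
#' `sleep_ns` (default 0) makes the callback busy for that long per pass,
#' which is how the drop-semantics tests induce controlled busy windows.
#'
#' @return a sink [worker_definition()].
#' @export
worker_counter_sink <- function() {
  worker_definition("sink",
    initialise = function(ctx) { ctx$state$seen <- 0L; TRUE },
    work = function(ctx, event) {
      ctx$state$seen <- ctx$state$seen + 1L
      sleep_ns <- ctx$param("sleep_ns", 0)
      if (sleep_ns > 0) ctx$clock$sleep(sleep_ns)
      v <- if (is.numeric(event$item)) sum(event$item) else NA_real_
      record_substate(ctx, list(upstream_id = event$upstream_packet_id, value_sum = v))
      NULL
    })
}

#' Table sink: append one row per delivered record, save CSV on stop
#'
#' Parameters: `path` (output CSV; default `<node>_table.csv` in the run's
#' log directory). Non-record payloads are a contract fault.
#'
#' @return a sink [worker_definition()].
#' @export
worker_table_sink <- function() {
  worker_definition("sink",
    initialise = function(ctx) { ctx$state$rows <- list(); TRUE },
    work = function(ctx, event) {
      item <- event$item
      if (!is.list(item) || is.null(names(item))) {
        stop("table sink requires record payloads (named fields)")
      }
      ctx$state$rows[[length(ctx$state$rows) + 1L]] <-
        lapply(item, function(v) if (length(v) == 1L) v else paste(v, collapse = ";"))
      NULL
    },
    end_of_life = function(ctx) {
      path <- ctx$param("path", file.path(ctx$param(".log_dir", "."),
                                          paste0(gsub("[^A-Za-z0-9]+", "_", ctx$name),
                                                 "_table.csv")))
      rows <- ctx$state$rows
      if (length(rows) > 0L) {
        df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
        write.csv(df, path, row.names = FALSE, quote = FALSE)
      } else {
        writeLines("", path)
      }
      invisible(NULL)
    })
}

#' PRL trial-generator transform
#'
#' Input `"Start/Previous Trial Result"` (the start record or the
#' controller's trial history), output `"Trial Definition"`. Parameters:
#' `contingencies_block0`, `contingencies_block1` (numeric vectors of
#' per-stimulation reward probabilities), `block_length_min`,
#' `block_length_max`, and `max_trials` (stop emitting definitions once this
#' many trials have been generated, ending the session; default unlimited).
#'
#' @return a transform [worker_definition()].
#' @export
worker_trial_generator <- function() {
  worker_definition("transform",
    initialise = function(ctx) {
      cfg <- prl_config(
        contingencies = rbind(ctx$param("contingencies_block0", c(0.8, 0.8, 0.2, 0.2)),
                              ctx$param("contingencies_block1", c(0.2, 0.2, 0.8, 0.8))),
        block_length_range = c(ctx$param("block_length_min", 20L),
                               ctx$param("block_length_max", 40L)))
      ctx$state$cfg <- cfg
      ctx$state$gen <- prl_generator_state(cfg)
      TRUE
    },
    work = function(ctx, event) {
      prev <- if (!is.null(event$item$stim_type)) event$item else NULL
      if (ctx$state$gen$trial_number >= ctx$param("max_trials", Inf)) {
        return(NULL)                       # session complete: break the loop
      }
      step <- trial_generator_step(ctx$state$gen, prev, ctx$state$cfg)
      ctx$state$gen <- step$state
      t <- step$trial
      record_substate(ctx, list(trial_number = t$trial_number, block = t$block_index))
      list(list(stim_type = t$stim_type,
                reward_available = t$reward_available,
                block_index = t$block_index,
                trial_number = t$trial_number))
    })
}

#' PRL trial-controller transform
#'
#' Input `"Trial Definition"`, outputs `"Trial Result"` then
#' `"Trial History"` (two payload items, first output first). Each trial is
#' played on a simulated clock against a simulated subject that licks the
#' correct port with probability `p_correct_lick`. Parameters:
#' `odour_window`, `pre_response_delay`, `response_window`, `reward_window`
#' (seconds), `reward_only_after_lick`, `p_correct_lick`.
#'
#' @return a transform [worker_definition()].
#' @export
worker_trial_controller <- function() {
  worker_definition("transform",
    initialise = function(ctx) {
      ctx$state$clock <- clock_simulated()
      TRUE
    },
    work = function(ctx, event) {
      d <- event$item
      params <- controller_params(
        odour_window = ctx$param("odour_window", 0.5),
        pre_response_delay = ctx$param("pre_response_delay", 0.25),
        response_window = ctx$param("response_window", 1.5),
        reward_window = ctx$param("reward_window", 1.0),
        reward_only_after_lick = ctx$param("reward_only_after_lick", TRUE))
      clock <- ctx$state$clock
      correct_port <- stim_port(d$stim_type)
      lick_correct <- runif(1L) < ctx$param("p_correct_lick", 0.8)
      port <- if (lick_correct) correct_port else
        max(0L, 1L - correct_port)
      t_lick <- clock$now() + params$odour_window_ns + params$pre_response_delay_ns +
        params$response_window_ns / 2
      rig <- scripted_session(data.frame(time_ns = t_lick, kind = "lick", port = port))
      res <- trial_controller_run_trial(d, params, rig, clock)
      record_substate(ctx, list(trial_number = res$trial_number,
                                rewarded = res$rewarded))
      result <- list(stim_type = res$stim_type, licked = res$licked,
                     correct_port_licked = res$correct_port_licked,
                     rewarded = res$rewarded, block_index = res$block_index,
                     trial_number = res$trial_number,
                     t_odour_on = res$t_odour_on, t_trial_end = res$t_trial_end)
      history <- list(stim_type = res$stim_type,
                      correct_port_licked = res$correct_port_licked,
                      rewarded = res$rewarded)
      list(result, history)
    })
}

#' External-process sink: manage a child executable over a line protocol
#'
#' The initialise hook launches the executable and completes a handshake:
#' the child connects back to `127.0.0.1:<port>` (port passed in the
#' environment variable `RIGFLOW_HANDSHAKE_PORT`), sends the line `READY`,
#' receives one line of JSON holding the node's parameters, and replies
#' `ACK`. Each delivered string payload is then forwarded to the child as
#' one line on the same connection; end_of_life sends `QUIT`, waits briefly
#' and terminates the child if it lingers. The child's lifetime is strictly
#' contained in the worker's.
#'
#' Parameters: `command` (executable path), `args` (character vector),
#' `handshake_timeout` (seconds, default 10).
#'
#' @return a sink [worker_definition()].
#' @export
worker_external_process <- function() {
  worker_definition("sink",
    initialise = function(ctx) {
      command <- ctx$param("command")
      if (is.null(command) || !file.exists(command)) {
        stop("external process command not found: ", command)
      }
      bound <- rf_bind_any()
      Sys.setenv(RIGFLOW_HANDSHAKE_PORT = bound$port)
      pidfile <- tempfile("extpid")
      system2(command, c(as.character(ctx$param("args", character())), pidfile),
              wait = FALSE, stdout = FALSE, stderr = FALSE)
      timeout <- ctx$param("handshake_timeout", 10)
      if (!socketSelect(list(bound$srv), timeout = timeout)) {
        close(bound$srv)
        stop("external process handshake timeout")
      }
      con <- socketAccept(bound$srv, blocking = TRUE, open = "a+b")
      close(bound$srv)
      ready <- readLines(con, n = 1L)
      if (!identical(ready, "READY")) { close(con); stop("bad handshake: ", ready) }
      params <- as.list(ctx$params)
      params <- params[!grepl("^\\.", names(params))]
      writeLines(as.character(jsonlite::toJSON(params, auto_unbox = TRUE)), con)
      flush(con)
      ack <- readLines(con, n = 1L)
      if (!identical(ack, "ACK")) { close(con); stop("bad handshake ack: ", ack) }
      ctx$state$con <- con
      ctx$state$child_pid <- if (file.exists(pidfile)) {
        as.integer(readLines(pidfile, n = 1L))
      } else NA_integer_
      TRUE
    },
    work = function(ctx, event) {
      writeLines(as.character(event$item), ctx$state$con)
      flush(ctx$state$con)
      NULL
    },
    end_of_life = function(ctx) {
      con <- ctx$state$con
      if (!is.null(con)) {
        try(writeLines("QUIT", con), silent = TRUE)
        try(flush(con), silent = TRUE)
        try(close(con), silent = TRUE)
      }
      pid <- ctx$state$child_pid
      if (!is.na(pid)) {
        for (i in 1:50) {
          if (!rf_pid_alive(pid)) break
          Sys.sleep(0.05)
        }
        if (rf_pid_alive(pid)) tools::pskill(pid)
      }
      invisible(NULL)
    })
}
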