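# Actor process entry points. A running graph is 2N + 4 OS processes: one
# director, three forwarder brokers (proof-of-life, parameters, data), and
# a com + worker pair per node. Every process is an actor: private state,
# influenced only by messages. These mains are executed in child Rscript
# processes via inst/actors/actor.R; they never run inside the caller's
# session.
#
# Topics:
#   pol broker:   "director" (hellos, acks, reports -> director),
#                 "worker/<node>/ctrl", "com/<node>/ctrl" (director -> actor),
#                 "heartbeat" (director -> workers)
#   param broker: "param/<node>" (director -> worker)
#   data broker:  "link/<node>/<output>" (com -> com, one topic per output),
#                 "w2c/<node>" (worker -> its com), "c2w/<node>" (com -> worker)

link_topic <- function(node, output) paste0("link/", node, "/", output)

#' Actor process entry point (internal)
#'
#' Dispatches to the director, forwarder, com or worker main based on the
#' `role=` argument. Called by the package's actor script in a child
#' process, never directly.
#'
#' @param args character vector of `key=value` arguments.
#' @keywords internal
actor_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  kv <- rf_parse_kv_args(args)
  switch(kv$role,
    director = director_main(kv),
    forwarder = forwarder_main(kv),
    com = com_main(kv),
    worker = worker_main(kv),
    stop("unknown actor role: ", kv$role)
  )
}

# ---- forwarder --------------------------------------------------------------

forwarder_main <- function(kv) {
  bound <- rf_bind_any()
  director <- rf_connect(as.integer(kv$director_port))
  rf_send_frame(director, list(kind = "hello", role = "forwarder", name = kv$name,
                               pid = Sys.getpid(), port = bound$port))
  clients <- list(list(con = director, subs = character()))
  repeat {
    ready <- rf_poll(c(list(bound$srv), lapply(clients, `[[`, "con")), timeout = 0.25)
    for (i in ready) {
      if (i == 1L) {
        con <- socketAccept(bound$srv, blocking = TRUE, open = "a+b", options = "no-delay")
        clients[[length(clients) + 1L]] <- list(con = con, subs = character())
        next
      }
      ci <- i - 1L
      f <- rf_recv_frame(clients[[ci]]$con)
      if (is.null(f)) {                      # peer gone
        try(close(clients[[ci]]$con), silent = TRUE)
        clients[[ci]]$dead <- TRUE
        if (ci == 1L) return(invisible(NULL))  # director vanished: shut down
        next
      }
      if (identical(f$kind, "sub")) {
        clients[[ci]]$subs <- union(clients[[ci]]$subs, f$topics)
      } else if (identical(f$kind, "pub")) {
        for (j in seq_along(clients)) {
          if (isTRUE(clients[[j]]$dead)) next
          if (f$topic %in% clients[[j]]$subs) {
            ok <- tryCatch(rf_send_frame(clients[[j]]$con, f), error = function(e) FALSE)
            if (!isTRUE(ok)) clients[[j]]$dead <- TRUE
          }
        }
      } else if (identical(f$kind, "shutdown")) {
        for (cl in clients) try(close(cl$con), silent = TRUE)
        close(bound$srv)
        return(invisible(NULL))
      }
    }
    keep <- !vapply(clients, function(cl) isTRUE(cl$dead), logical(1))
    keep[1L] <- TRUE                          # director slot is positional
    clients <- clients[keep]
  }
}

# ---- worker -----------------------------------------------------------------

worker_main <- function(kv) {
  run <- readRDS(file.path(kv$run_dir, "run.rds"))
  name <- kv$node
  node <- graph_node(run$graph, name)
  node_index <- match(name, graph_node_names(run$graph))
  log <- rf_logger(file.path(kv$run_dir, "logs",
                             paste0("worker_", gsub("[^A-Za-z0-9]+", "_", name), ".log")))
  pol <- rf_broker_connect(as.integer(kv$pol_port),
                           c("heartbeat", paste0("worker/", name, "/ctrl")))
  par <- rf_broker_connect(as.integer(kv$param_port), paste0("param/", name))
  dat <- rf_broker_connect(as.integer(kv$data_port), paste0("c2w/", name))

  if (!is.null(node$cpu_pin)) {
    ok <- suppressWarnings(system2("taskset", c("-pc", node$cpu_pin, Sys.getpid()),
                                   stdout = FALSE, stderr = FALSE))
    if (!identical(ok, 0L)) log("cpu_pin_unsupported", node$cpu_pin)
  }

  seed <- (run$config$seed + 7919L * node_index) %% .Machine$integer.max
  ctx <- node_context(node, clock = clock_real(), seed = seed)
  ctx$log <- log
  assign(".log_dir", file.path(kv$run_dir, "logs"), envir = ctx$params)

  def <- tryCatch(resolve_worker_ref(node$worker_ref)(), error = function(e) e)
  init <- if (inherits(def, "error")) def else {
    tryCatch({ def$initialise(ctx); TRUE }, error = function(e) e)
  }
  if (inherits(init, "error") || inherits(def, "error")) {
    msg <- conditionMessage(if (inherits(def, "error")) def else init)
    log("init_fail", msg)
    rf_publish(pol, "director", list(kind = "init_fail", node = name,
                                     pid = Sys.getpid(), message = msg))
    Sys.sleep(0.2)
    return(invisible(NULL))
  }
  if (!identical(def$node_type, node$node_type)) {
    rf_publish(pol, "director", list(kind = "init_fail", node = name, pid = Sys.getpid(),
      message = sprintf("worker is a %s but the node is a %s", def$node_type, node$node_type)))
    return(invisible(NULL))
  }
  rf_publish(pol, "director", list(kind = "hello", role = "worker", node = name,
                                   pid = Sys.getpid()))
  log("proof_of_life", Sys.getpid())

  is_source <- node$node_type == "source"
  n_out <- length(node$outputs)
  go <- FALSE; stopped <- FALSE; eol_reason <- "stop"
  emitted <- 0L
  hb_period <- run$config$heartbeat_period %||% 1
  hb_misses <- run$config$heartbeat_misses %||% 5
  last_hb <- Sys.time()
  pending_params <- list()

  apply_params <- function() {
    repeat {
      ready <- rf_poll(list(par), timeout = 0)
      if (length(ready) == 0L) break
      f <- rf_recv_frame(par)
      if (is.null(f)) break
      m <- f$msg
      if (identical(m$kind, "param_set")) {
        assign(m$param, m$value, envir = ctx$params)
        log("param_update", m$param)
        if (isTRUE(m$ack)) {
          rf_publish(pol, "director", list(kind = "param_ack", node = name,
                                           param = m$param, ok = TRUE))
        }
      }
    }
  }

  emit_payload <- function(kind, payload) {
    if (length(payload) != n_out) {
      log("contract_fault", sprintf("payload length %d != %d outputs",
                                    length(payload), n_out))
      rf_publish(pol, "director", list(kind = "node_fault", node = name,
        message = sprintf("payload list length %d does not match %d declared outputs",
                          length(payload), n_out)))
      return(FALSE)
    }
    rf_publish(dat, paste0("w2c/", name),
               list(kind = kind, packet_id = emitted,
                    timestamp_ns = ctx$clock$now(),
                    payload = wire_encode_payload(payload)))
    emitted <<- emitted + 1L
    TRUE
  }

  while (!stopped) {
    apply_params()
    ready <- rf_poll(list(pol), timeout = 0)
    while (length(ready) > 0L) {
      f <- rf_recv_frame(pol)
      if (is.null(f)) { stopped <- TRUE; eol_reason <- "broker_lost"; break }
      m <- f$msg
      if (identical(m$kind, "hb")) last_hb <- Sys.time()
      else if (identical(m$kind, "go")) go <- TRUE
      else if (identical(m$kind, "stop")) { stopped <- TRUE; break }
      else if (identical(m$kind, "kill")) return(invisible(NULL))
      ready <- rf_poll(list(pol), timeout = 0)
    }
    if (stopped) break
    if (as.numeric(Sys.time() - last_hb) > hb_misses * hb_period) {
      log("heartbeat_lost", "")
      stopped <- TRUE; eol_reason <- "heartbeat_lost"
      break
    }
    if (!go) { Sys.sleep(0.005); next }

    if (is_source) {
      ctx$packet_index <- emitted
      ctx$pass_recorded <- FALSE
      res <- tryCatch(def$work(ctx), error = function(e) e)
      if (inherits(res, "error")) {
        log("work_fault", conditionMessage(res))
        rf_publish(pol, "director", list(kind = "node_fault", node = name,
                                         message = conditionMessage(res)))
        Sys.sleep(0.01)
      } else if (is.null(res)) {
        Sys.sleep(0.002)                      # idle pass
      } else {
        emit_payload("emit", res)
      }
    } else {
      ready <- rf_poll(list(dat), timeout = 0.01)
      if (length(ready) > 0L) {
        f <- rf_recv_frame(dat)
        if (is.null(f)) { stopped <- TRUE; eol_reason <- "broker_lost"; break }
        m <- f$msg
        if (identical(m$kind, "deliver")) {
          ctx$packet_index <- m$local_id
          ctx$pass_recorded <- FALSE
          ev <- input_event(m$port, wire_decode(m$item), m$upstream_node,
                            m$upstream_id, m$local_id, m$timestamp_ns)
          res <- tryCatch(def$work(ctx, ev), error = function(e) e)
          if (inherits(res, "error")) {
            log("work_fault", conditionMessage(res))
            rf_publish(pol, "director", list(kind = "node_fault", node = name,
                                             message = conditionMessage(res)))
            rf_publish(dat, paste0("w2c/", name), list(kind = "done"))
          } else if (is.null(res)) {
            rf_publish(dat, paste0("w2c/", name), list(kind = "done"))
          } else if (node$node_type == "sink") {
            log("contract_fault", "sink callback returned a payload")
            rf_publish(pol, "director", list(kind = "node_fault", node = name,
              message = "sink callback must return NULL"))
            rf_publish(dat, paste0("w2c/", name), list(kind = "done"))
          } else {
            if (!emit_payload("result", res)) {
              rf_publish(dat, paste0("w2c/", name), list(kind = "done"))
            }
          }
        }
      }
    }
  }

  rf_publish(dat, paste0("w2c/", name), list(kind = "eos"))
  eol_ok <- tryCatch({ def$end_of_life(ctx); TRUE }, error = function(e) {
    log("eol_fault", conditionMessage(e)); FALSE
  })
  log("eol", eol_reason)
  sub <- substate_table(ctx)
  write_substate(sub, file.path(kv$run_dir, "logs",
                                paste0(gsub("[^A-Za-z0-9]+", "_", name), "_substate.csv")))
  rf_publish(pol, "director", list(kind = "worker_report", node = name,
                                   pid = Sys.getpid(), eol_ok = eol_ok,
                                   emitted = emitted, reason = eol_reason))
  Sys.sleep(0.2)                              # let the frames drain
  for (con in list(pol, par, dat)) try(close(con), silent = TRUE)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- com --------------------------------------------------------------------

com_main <- function(kv) {
  run <- readRDS(file.path(kv$run_dir, "run.rds"))
  name <- kv$node
  node <- graph_node(run$graph, name)
  log <- rf_logger(file.path(kv$run_dir, "logs",
                             paste0("com_", gsub("[^A-Za-z0-9]+", "_", name), ".log")))
  edges_in <- Filter(function(e) e$to_node == name, run$graph$edges)
  edges_out <- Filter(function(e) e$from_node == name, run$graph$edges)
  in_topics <- unique(vapply(edges_in, function(e) link_topic(e$from_node, e$from_output),
                             character(1)))
  out_ports <- port_names(node$outputs)

  pol <- rf_broker_connect(as.integer(kv$pol_port), paste0("com/", name, "/ctrl"))
  dat <- rf_broker_connect(as.integer(kv$data_port),
                           c(paste0("w2c/", name), in_topics))
  rf_publish(pol, "director", list(kind = "hello", role = "com", node = name,
                                   pid = Sys.getpid()))

  clock <- clock_real()
  st <- new.env()
  st$busy <- FALSE
  st$worker_eos <- FALSE
  st$local_id <- 0L
  st$log_rows <- list()
  st$eos_seen <- character()
  st$finish <- FALSE
  st$deadline <- Inf
  counters <- new.env()
  for (e in c(edges_in, edges_out)) {
    counters[[edge_id(e)]] <- list(emitted = 0L, delivered = 0L, dropped = 0L)
  }
  bump <- function(id, field) {
    c0 <- counters[[id]]
    c0[[field]] <- c0[[field]] + 1L
    counters[[id]] <- c0
  }

  publish_outputs <- function(packet_id, payload_raws, ts) {
    done_topics <- character()
    for (oi in seq_along(out_ports)) {
      port <- out_ports[[oi]]
      port_edges <- Filter(function(e) e$from_output == port, edges_out)
      if (length(port_edges) == 0L) next
      topic <- link_topic(name, port)
      if (!topic %in% done_topics) {
        rf_publish(dat, topic, list(kind = "packet", from_node = name,
                                    from_output = port, packet_id = packet_id,
                                    timestamp_ns = ts, item = payload_raws[[oi]]))
        done_topics <- c(done_topics, topic)
      }
      for (e in port_edges) bump(edge_id(e), "emitted")
    }
  }

  publish_eos <- function() {
    for (topic in unique(vapply(edges_out, function(e) link_topic(e$from_node, e$from_output),
                                character(1)))) {
      rf_publish(dat, topic, list(kind = "eos", from_node = name))
    }
  }

  finalize <- function() {
    rows <- st$log_rows
    log_df <- if (length(rows) > 0L) {
      do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
    } else {
      data.frame(upstream_node = character(), upstream_packet_id = integer(),
                 local_packet_id = integer(), timestamp_ns = numeric())
    }
    path <- node$com_log_path %||%
      file.path(kv$run_dir, "logs", paste0(gsub("[^A-Za-z0-9]+", "_", name), "_com_log.csv"))
    write_com_log(log_df, path)
    rf_publish(pol, "director", list(
      kind = "com_report", node = name, pid = Sys.getpid(),
      counters = as.list(counters), delivered_total = st$local_id))
    Sys.sleep(0.2)
    try(close(pol), silent = TRUE)
    try(close(dat), silent = TRUE)
  }

  can_finalize <- function() {
    (st$worker_eos && all(in_topics %in% st$eos_seen)) ||
      (st$finish && Sys.time() > st$deadline)
  }

  repeat {
    ready <- rf_poll(list(dat, pol), timeout = 0.05)
    for (i in ready) {
      con <- list(dat, pol)[[i]]
      f <- rf_recv_frame(con)
      if (is.null(f)) { finalize(); return(invisible(NULL)) }
      m <- f$msg
      if (i == 2L) {                           # pol control
        if (identical(m$kind, "finish")) {
          st$finish <- TRUE
          st$deadline <- Sys.time() + (run$config$stop_grace %||% 10)
        } else if (identical(m$kind, "kill")) return(invisible(NULL))
        next
      }
      topic <- f$topic
      if (topic == paste0("w2c/", name)) {
        if (identical(m$kind, "emit")) {
          publish_outputs(m$packet_id, m$payload, m$timestamp_ns)
        } else if (identical(m$kind, "result")) {
          st$busy <- FALSE
          publish_outputs(m$packet_id, m$payload, m$timestamp_ns)
        } else if (identical(m$kind, "done")) {
          st$busy <- FALSE
        } else if (identical(m$kind, "eos")) {
          st$worker_eos <- TRUE
          publish_eos()
        }
      } else {                                 # inbound link topic
        matching <- Filter(function(e) link_topic(e$from_node, e$from_output) == topic,
                           edges_in)
        if (identical(m$kind, "packet")) {
          for (e in matching) {
            if (st$busy || st$worker_eos) {
              bump(edge_id(e), "dropped")
              log("drop", edge_id(e), m$packet_id)
            } else {
              ts <- clock$now()
              st$log_rows[[length(st$log_rows) + 1L]] <- list(
                upstream_node = m$from_node, upstream_packet_id = m$packet_id,
                local_packet_id = st$local_id, timestamp_ns = ts)
              rf_publish(dat, paste0("c2w/", name), list(
                kind = "deliver", port = e$to_input, item = m$item,
                upstream_node = m$from_node, upstream_id = m$packet_id,
                local_id = st$local_id, timestamp_ns = ts))
              bump(edge_id(e), "delivered")
              st$local_id <- st$local_id + 1L
              st$busy <- TRUE
            }
          }
        } else if (identical(m$kind, "eos")) {
          st$eos_seen <- union(st$eos_seen, topic)
        }
      }
    }
    if (can_finalize()) { finalize(); return(invisible(NULL)) }
  }
}

# ---- director ---------------------------------------------------------------

director_main <- function(kv) {
  run_dir <- kv$run_dir
  run <- readRDS(file.path(run_dir, "run.rds"))
  g <- run$graph
  config <- run$config
  dir.create(file.path(run_dir, "logs"), recursive = TRUE, showWarnings = FALSE)
  log <- rf_logger(file.path(run_dir, "logs", "director.log"))
  caller <- rf_connect(as.integer(kv$caller_port))
  rf_send_frame(caller, list(kind = "ready", pid = Sys.getpid()))

  bound <- rf_bind_any()
  pids <- list(director = Sys.getpid())
  fw <- list()
  for (nm in c("pol", "param", "data")) {
    rf_spawn_actor(c("role=forwarder", paste0("name=", nm),
                     paste0("director_port=", bound$port)),
                   log_file = file.path(run_dir, "logs", paste0("forwarder_", nm, ".out")))
  }
  deadline <- Sys.time() + (config$start_timeout %||% 30)
  while (length(fw) < 3L) {
    if (Sys.time() > deadline) {
      rf_send_frame(caller, list(kind = "error", message = "forwarders failed to start"))
      return(invisible(NULL))
    }
    if (length(rf_poll(list(bound$srv), 0.2)) > 0L) {
      con <- socketAccept(bound$srv, blocking = TRUE, open = "a+b", options = "no-delay")
      h <- rf_recv_frame(con)
      fw[[h$name]] <- list(con = con, port = h$port, pid = h$pid)
      pids[[paste0("forwarder_", h$name)]] <- h$pid
      log("spawn", "forwarder", h$name, h$pid)
    }
  }
  # the director is itself a client of the pol and param brokers
  rf_send_frame(fw$pol$con, list(kind = "sub", topics = "director"))

  order <- start_order(g)
  abort <- function(message) {
    log("abort", message)
    for (n in order) {
      rf_publish(fw$pol$con, paste0("worker/", n, "/ctrl"), list(kind = "kill"))
      rf_publish(fw$pol$con, paste0("com/", n, "/ctrl"), list(kind = "kill"))
    }
    Sys.sleep(0.3)
    for (p in unlist(pids)) if (p != Sys.getpid() && rf_pid_alive(p)) tools::pskill(p)
    rf_send_frame(caller, list(kind = "error", message = message, pids = pids))
    for (f in fw) try(close(f$con), silent = TRUE)
    invisible(NULL)
  }

  ports_args <- c(paste0("pol_port=", fw$pol$port),
                  paste0("param_port=", fw$param$port),
                  paste0("data_port=", fw$data$port),
                  paste0("run_dir=", run_dir))
  for (n in order) {
    for (role in c("com", "worker")) {
      rf_spawn_actor(c(paste0("role=", role), paste0("node=", n), ports_args),
                     log_file = file.path(run_dir, "logs",
                                          paste0(role, "_", gsub("[^A-Za-z0-9]+", "_", n), ".out")))
      log("spawn", role, n)
    }
  }

  expected <- 2L * length(order)
  got <- 0L
  deadline <- Sys.time() + (config$start_timeout %||% 30)
  while (got < expected) {
    if (Sys.time() > deadline) return(abort("timeout waiting for node proofs of life"))
    if (length(rf_poll(list(fw$pol$con), 0.2)) == 0L) next
    f <- rf_recv_frame(fw$pol$con)
    if (is.null(f)) return(abort("proof-of-life broker lost"))
    m <- f$msg
    if (identical(m$kind, "hello")) {
      pids[[paste0(m$role, "_", m$node)]] <- m$pid
      got <- got + 1L
      log("proof_of_life", m$role, m$node, m$pid)
    } else if (identical(m$kind, "init_fail")) {
      pids[[paste0("worker_", m$node)]] <- m$pid
      return(abort(sprintf("node %s failed to initialise: %s", m$node, m$message)))
    }
  }

  # push initial parameter values, then open the data flow
  for (n in order) {
    node <- graph_node(g, n)
    for (p in node$parameters) {
      rf_publish(fw$param$con, paste0("param/", n),
                 list(kind = "param_set", param = p$name, value = p$value, ack = FALSE))
    }
  }
  for (n in order) {
    rf_publish(fw$pol$con, paste0("worker/", n, "/ctrl"), list(kind = "go"))
  }
  rf_send_frame(caller, list(kind = "started", pids = pids))
  log("started", length(unlist(pids)))

  stop_sequence <- function() {
    for (n in order) {
      rf_publish(fw$pol$con, paste0("worker/", n, "/ctrl"), list(kind = "stop"))
    }
    for (n in order) {
      rf_publish(fw$pol$con, paste0("com/", n, "/ctrl"), list(kind = "finish"))
    }
    worker_reports <- list()
    com_reports <- list()
    grace <- config$stop_grace %||% 10
    deadline <- Sys.time() + grace + 5
    while (length(worker_reports) + length(com_reports) < 2L * length(order)) {
      if (Sys.time() > deadline) break
      if (length(rf_poll(list(fw$pol$con), 0.2)) == 0L) next
      f <- rf_recv_frame(fw$pol$con)
      if (is.null(f)) break
      m <- f$msg
      if (identical(m$kind, "worker_report")) worker_reports[[m$node]] <- m
      else if (identical(m$kind, "com_report")) com_reports[[m$node]] <- m
    }
    forced <- character()
    for (n in order) {
      for (role in c("worker", "com")) {
        pid <- pids[[paste0(role, "_", n)]]
        if (!is.null(pid) && rf_pid_alive(pid)) {
          deadline2 <- Sys.time() + 2
          while (rf_pid_alive(pid) && Sys.time() < deadline2) Sys.sleep(0.05)
          if (rf_pid_alive(pid)) {
            tools::pskill(pid)
            forced <- c(forced, paste0(role, "_", n))
            log("forced_kill", role, n, pid)
          }
        }
      }
    }
    # merge per-link counters: emitted from the emitting com, delivered and
    # dropped from the receiving com
    links <- list()
    for (e in g$edges) {
      id <- edge_id(e)
      from_c <- com_reports[[e$from_node]]$counters[[id]]
      to_c <- com_reports[[e$to_node]]$counters[[id]]
      links[[id]] <- list(link_id = id,
                          emitted = from_c$emitted %||% NA_integer_,
                          delivered = to_c$delivered %||% NA_integer_,
                          dropped = to_c$dropped %||% NA_integer_)
    }
    nodes <- lapply(order, function(n) {
      wr <- worker_reports[[n]]
      list(node = n,
           exit = if (paste0("worker_", n) %in% forced) "forced" else
             if (is.null(wr)) "missing" else "graceful",
           end_of_life = if (is.null(wr)) FALSE else isTRUE(wr$eol_ok),
           emitted = if (is.null(wr)) NA_integer_ else wr$emitted)
    })
    names(nodes) <- order
    list(nodes = nodes, links = links, forced = forced)
  }

  hb_period <- config$heartbeat_period %||% 1
  last_hb <- Sys.time() - hb_period
  report <- NULL
  running <- TRUE
  while (running) {
    if (as.numeric(Sys.time() - last_hb) >= hb_period) {
      rf_publish(fw$pol$con, "heartbeat", list(kind = "hb", t = as.numeric(Sys.time())))
      last_hb <- Sys.time()
    }
    ready <- rf_poll(list(caller, fw$pol$con), timeout = 0.1)
    for (i in ready) {
      con <- list(caller, fw$pol$con)[[i]]
      f <- rf_recv_frame(con)
      if (is.null(f)) {
        if (i == 1L) { report <- stop_sequence(); running <- FALSE }  # caller gone
        break
      }
      if (i == 2L) { log("event", f$msg$kind %||% "?", f$msg$node %||% ""); next }
      m <- f
      if (identical(m$kind, "cmd")) {
        if (identical(m$cmd, "stop")) {
          report <- stop_sequence()
          rf_send_frame(caller, list(kind = "report", report = report))
          running <- FALSE
        } else if (identical(m$cmd, "census")) {
          alive <- sum(vapply(unlist(pids), rf_pid_alive, logical(1)))
          rf_send_frame(caller, list(kind = "census", count = alive, pids = pids))
        } else if (identical(m$cmd, "param")) {
          ack <- validate_param_update(g, m$node, m$param)
          if (!is.null(ack)) {
            rf_send_frame(caller, list(kind = "param_ack", ok = FALSE, message = ack))
          } else {
            rf_publish(fw$param$con, paste0("param/", m$node),
                       list(kind = "param_set", param = m$param, value = m$value,
                            ack = TRUE))
            log("param_update", m$node, m$param)
            ok <- FALSE
            deadline <- Sys.time() + 5
            while (Sys.time() < deadline && !ok) {
              if (length(rf_poll(list(fw$pol$con), 0.1)) == 0L) next
              f2 <- rf_recv_frame(fw$pol$con)
              if (is.null(f2)) break
              m2 <- f2$msg
              if (identical(m2$kind, "param_ack") && identical(m2$node, m$node) &&
                  identical(m2$param, m$param)) ok <- TRUE
            }
            rf_send_frame(caller, list(
              kind = "param_ack", ok = ok,
              message = if (ok) "" else "no acknowledgement from worker"))
          }
        }
      }
    }
  }

  # write the report artifacts, shut down the forwarders, leave nothing behind
  if (!is.null(report)) {
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE, null = "null"),
               file.path(run_dir, "report.json"))
    link_df <- do.call(rbind, lapply(report$links, function(l) {
      data.frame(link_id = l$link_id, emitted = l$emitted,
                 delivered = l$delivered, dropped = l$dropped)
    }))
    if (!is.null(link_df)) {
      write.csv(link_df, file.path(run_dir, "link_counters.csv"), row.names = FALSE)
    }
  }
  for (f in fw) try(rf_send_frame(f$con, list(kind = "shutdown")), silent = TRUE)
  Sys.sleep(0.2)
  for (nm in names(fw)) {
    pid <- fw[[nm]]$pid
    if (rf_pid_alive(pid)) {
      deadline <- Sys.time() + 2
      while (rf_pid_alive(pid) && Sys.time() < deadline) Sys.sleep(0.05)
      if (rf_pid_alive(pid)) tools::pskill(pid)
    }
    try(close(fw[[nm]]$con), silent = TRUE)
  }
  close(bound$srv)
  log("shutdown", "")
  invisible(NULL)
}

validate_param_update <- function(g, node_name, param_name) {
  node <- graph_node(g, node_name)
  if (is.null(node)) return(sprintf("unknown node %s", sQuote(node_name)))
  for (p in node$parameters) {
    if (p$name == param_name) {
      if (!p$updatable) {
        return(sprintf("parameter %s of %s is not updatable", sQuote(param_name),
                       sQuote(node_name)))
      }
      return(NULL)
    }
  }
  sprintf("unknown parameter %s on node %s", sQuote(param_name), sQuote(node_name))
}
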