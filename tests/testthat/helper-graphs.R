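# Shared graph builders and oracles for the suite. All fixtures are built
# in code; engine runs use short schedules so a full run lasts a few
# seconds.

# A linear chain of n nodes: scripted source -> (n-2) identity transforms ->
# counting sink. n = 1 gives a lone source with an unconnected output.
chain_graph <- function(n, values = as.numeric(1:10), interval_ns = 1e7,
                        sink_sleep_ns = 0) {
  stopifnot(n >= 1)
  nodes <- list(node_spec("Src", "source", outputs = "Out",
                          parameters = list(parameter_spec("values", values),
                                            parameter_spec("interval_ns", interval_ns)),
                          worker_ref = "rigflow::worker_scripted_source"))
  if (n >= 2) {
    for (i in seq_len(n - 2)) {
      nodes[[length(nodes) + 1L]] <-
        node_spec("Pass", "transform", inputs = "In", outputs = "Out",
                  worker_ref = "rigflow::worker_identity")
    }
    nodes[[length(nodes) + 1L]] <-
      node_spec("Sink", "sink", inputs = "In",
                parameters = list(parameter_spec("sleep_ns", sink_sleep_ns)),
                worker_ref = "rigflow::worker_counter_sink")
  }
  g <- graph(nodes = nodes)
  names_ <- vapply(g$nodes, display_name, character(1))
  edges <- list()
  for (i in seq_len(length(names_) - 1L)) {
    from_port <- "Out"
    to_port <- "In"
    edges[[i]] <- edge(names_[[i]], from_port, names_[[i + 1L]], to_port)
  }
  graph(nodes = g$nodes, edges = edges)
}

prl_example_graph <- function() {
  parse_graph(system.file("extdata", "prl_graph.json", package = "rigflow"))
}

# Quiet engine run with conservative timeouts for a loaded single-CPU box.
test_run_config <- function(seed = 1L, ...) {
  run_config(seed = seed, start_timeout = 120, ...)
}

# Pids of engine actor processes currently alive (any run). The bracketed
# character class keeps the pattern from matching this test process itself.
actor_pids <- function() {
  suppressWarnings(system2("pgrep", c("-f", shQuote("acto[r]s/actor\\.R")),
                           stdout = TRUE, stderr = FALSE))
}

# Wait until no engine actors are left over from earlier tests.
wait_actor_quiescence <- function(timeout = 15) {
  deadline <- Sys.time() + timeout
  while (length(actor_pids()) > 0 && Sys.time() < deadline) Sys.sleep(0.2)
  length(actor_pids()) == 0
}

# Brute-force relational-join oracle for compose_chain: walk every origin id
# through each log by explicit lookup, stage by stage.
brute_force_compose <- function(origin_ids, logs) {
  out_origin <- integer()
  out_terminal <- integer()
  for (oid in origin_ids) {
    id <- oid
    alive <- TRUE
    for (log in logs) {
      hit <- which(log$upstream_packet_id == id)
      if (length(hit) == 0L) { alive <- FALSE; break }
      id <- log$local_packet_id[[hit]]
    }
    if (alive) {
      out_origin <- c(out_origin, oid)
      out_terminal <- c(out_terminal, id)
    }
  }
  data.frame(terminal_index = out_terminal, origin_index = out_origin)
}

# A random valid graph (correct port rules) with arbitrary, possibly cyclic
# wiring; used by the validation property tests.
random_valid_graph <- function(n_nodes) {
  types <- sample(c("source", "transform", "sink"), n_nodes, replace = TRUE)
  nodes <- lapply(seq_len(n_nodes), function(i) {
    type <- types[[i]]
    n_in <- if (type == "source") 0L else sample(1:3, 1L)
    n_out <- if (type == "sink") 0L else sample(1:3, 1L)
    node_spec(paste0("N", i), type,
              inputs = if (n_in > 0) paste0("in", seq_len(n_in)) else character(),
              outputs = if (n_out > 0) paste0("out", seq_len(n_out)) else character(),
              worker_ref = "rigflow::worker_identity")
  })
  g <- graph(nodes = nodes)
  names_ <- vapply(g$nodes, display_name, character(1))
  # random edges between compatible ports, no duplicates
  candidates <- list()
  for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    for (o in port_names_of(g$nodes[[i]], "outputs")) {
      for (p in port_names_of(g$nodes[[j]], "inputs")) {
        candidates[[length(candidates) + 1L]] <- c(names_[[i]], o, names_[[j]], p)
      }
    }
  }
  k <- if (length(candidates) > 0) sample(0:min(6, length(candidates)), 1L) else 0L
  picked <- if (k > 0) sample(candidates, k) else list()
  edges <- lapply(picked, function(e) edge(e[[1]], e[[2]], e[[3]], e[[4]]))
  graph(nodes = g$nodes, edges = edges)
}

port_names_of <- function(node, which) {
  vapply(node[[which]], `[[`, character(1), "name")
}
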