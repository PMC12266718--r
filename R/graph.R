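# The pipeline description ("knowledge graph"): an ordered list of node
# specifications plus directed port-to-port links. Authoring order matters:
# it is the order in which node processes are started, and cycles are a
# normal, supported topology (a trial generator and controller feeding each
# other form a 2-cycle).

GRAPH_SCHEMA_VERSION <- "1"
NODE_TYPES <- c("source", "transform", "sink")

#' Construct a port specification
#'
#' @param name non-empty port label, unique within its node and direction.
#' @param direction `"input"` or `"output"`.
#' @return a `rigflow_port` object.
#' @export
port_spec <- function(name, direction) {
  stopifnot(is.character(name), length(name) == 1L)
  direction <- match.arg(direction, c("input", "output"))
  structure(list(name = name, direction = direction), class = "rigflow_port")
}

#' Construct a parameter specification
#'
#' @param name parameter name, unique within its node.
#' @param value scalar, string or list default value.
#' @param updatable can the value be changed while the graph runs?
#' @return a `rigflow_parameter` object.
#' @export
parameter_spec <- function(name, value, updatable = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, is.logical(updatable))
  structure(list(name = name, value = value, updatable = isTRUE(updatable)),
            class = "rigflow_parameter")
}

#' Construct a node specification
#'
#' A node's display name is `base_name` and `instance_index` joined with
#' `"##"` (e.g. `"Visualiser##1"`), and must be unique within a graph.
#' Sources have outputs only, sinks inputs only, transforms both.
#'
#' @param base_name human-readable node name.
#' @param node_type one of `"source"`, `"transform"`, `"sink"`.
#' @param inputs,outputs character vectors of port names (or lists of
#'   [port_spec()]).
#' @param parameters list of [parameter_spec()].
#' @param worker_ref locator of the worker definition: either
#'   `"package::function"` naming a worker factory, or a path to an R file
#'   defining `make_worker()`.
#' @param instance_index non-negative integer; auto-assigned at parse when
#'   absent.
#' @param placement host descriptor; only `"local"` can be executed.
#' @param cpu_pin optional core index for best-effort CPU pinning.
#' @param com_log_path optional path for the node's relay log.
#' @return a `rigflow_node` object.
#' @export
node_spec <- function(base_name, node_type, inputs = character(), outputs = character(),
                      parameters = list(), worker_ref = NULL, instance_index = NA_integer_,
                      placement = "local", cpu_pin = NULL, com_log_path = NULL) {
  node_type <- match.arg(node_type, NODE_TYPES)
  as_ports <- function(x, direction) {
    if (is.character(x)) x <- lapply(x, port_spec, direction = direction)
    x
  }
  structure(list(
    base_name = base_name,
    instance_index = as.integer(instance_index),
    node_type = node_type,
    inputs = as_ports(inputs, "input"),
    outputs = as_ports(outputs, "output"),
    parameters = parameters,
    worker_ref = worker_ref,
    placement = placement,
    cpu_pin = cpu_pin,
    com_log_path = com_log_path
  ), class = "rigflow_node")
}

#' Display name of a node
#'
#' @param node a [node_spec()].
#' @return `"base_name##index"`.
#' @export
display_name <- function(node) {
  paste0(node$base_name, "##", node$instance_index)
}

#' Construct an edge between two ports
#'
#' @param from_node,from_output emitting node display name and output port.
#' @param to_node,to_input receiving node display name and input port.
#' @return a `rigflow_edge` object.
#' @export
edge <- function(from_node, from_output, to_node, to_input) {
  structure(list(from_node = from_node, from_output = from_output,
                 to_node = to_node, to_input = to_input),
            class = "rigflow_edge")
}

edge_id <- function(e) {
  paste0(e$from_node, "/", e$from_output, "->", e$to_node, "/", e$to_input)
}

#' Construct a pipeline graph
#'
#' Node order is the authoring order and is preserved through
#' parse/serialize round trips; it defines the start order of the runtime
#' processes. Cycles are allowed.
#'
#' @param nodes ordered list of [node_spec()].
#' @param edges list of [edge()].
#' @param schema_version graph file schema version.
#' @return a `rigflow_graph` object.
#' @export
graph <- function(nodes = list(), edges = list(), schema_version = GRAPH_SCHEMA_VERSION) {
  nodes <- assign_instance_indices(nodes)
  structure(list(nodes = nodes, edges = edges, schema_version = schema_version),
            class = "rigflow_graph")
}

# Auto-assign missing instance indices: per base name, the smallest
# non-negative integers not already taken, in authoring order.
assign_instance_indices <- function(nodes) {
  taken <- list()
  for (n in nodes) {
    if (!is.na(n$instance_index)) {
      taken[[n$base_name]] <- c(taken[[n$base_name]], n$instance_index)
    }
  }
  for (i in seq_along(nodes)) {
    n <- nodes[[i]]
    if (is.na(n$instance_index)) {
      used <- taken[[n$base_name]]
      idx <- 0L
      while (idx %in% used) idx <- idx + 1L
      nodes[[i]]$instance_index <- idx
      taken[[n$base_name]] <- c(used, idx)
    }
  }
  nodes
}

#' @export
print.rigflow_graph <- function(x, ...) {
  cat(sprintf("<rigflow graph: %d nodes, %d edges, schema %s>\n",
              length(x$nodes), length(x$edges), x$schema_version))
  for (n in x$nodes) {
    cat(sprintf("  %-28s %-9s in:[%s] out:[%s]\n", display_name(n), n$node_type,
                paste(port_names(n$inputs), collapse = ","),
                paste(port_names(n$outputs), collapse = ",")))
  }
  for (e in x$edges) cat("  ", edge_id(e), "\n", sep = "")
  invisible(x)
}

port_names <- function(ports) vapply(ports, `[[`, character(1), "name")

graph_node <- function(g, name) {
  for (n in g$nodes) if (display_name(n) == name) return(n)
  NULL
}

graph_node_names <- function(g) vapply(g$nodes, display_name, character(1))

# ---- parsing ----------------------------------------------------------------

ALLOWED_KEYS <- list(
  top = c("schema_version", "nodes", "edges"),
  node = c("base_name", "instance_index", "node_type", "inputs", "outputs",
           "parameters", "worker_ref", "placement", "cpu_pin", "com_log_path"),
  parameter = c("name", "value", "updatable"),
  edge = c("from_node", "from_output", "to_node", "to_input")
)

check_keys <- function(x, allowed, path) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0L) {
    stop(sprintf("graph parse error at %s: unknown key(s) %s", path,
                 paste(sQuote(extra), collapse = ", ")), call. = FALSE)
  }
}

need_key <- function(x, key, path) {
  if (is.null(x[[key]])) {
    stop(sprintf("graph parse error at %s: missing required key %s", path, sQuote(key)),
         call. = FALSE)
  }
  x[[key]]
}

#' Parse a graph definition file
#'
#' Graph files are JSON with an explicit `schema_version`. Parsing is strict:
#' unknown keys are rejected with an error naming the offending path, so a
#' run definition either loads exactly as written or fails loudly. Defaults
#' applied: `placement = "local"`, `updatable = TRUE`, auto-assigned
#' `instance_index`.
#'
#' @param text graph-file content as a single string, or a file path.
#' @return a `rigflow_graph`.
#' @seealso [serialize_graph()], [validate_graph()]
#' @export
parse_graph <- function(text) {
  if (length(text) == 1L && !grepl("[{\n]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  raw <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) stop("graph parse error: invalid JSON: ", conditionMessage(e),
                             call. = FALSE)
  )
  check_keys(raw, ALLOWED_KEYS$top, "$")
  version <- need_key(raw, "schema_version", "$")
  if (!identical(as.character(version), GRAPH_SCHEMA_VERSION)) {
    stop("graph parse error at $.schema_version: unsupported version ",
         sQuote(version), call. = FALSE)
  }
  nodes <- lapply(seq_along(raw$nodes), function(i) {
    path <- sprintf("$.nodes[%d]", i)
    nd <- raw$nodes[[i]]
    check_keys(nd, ALLOWED_KEYS$node, path)
    params <- lapply(seq_along(nd$parameters), function(j) {
      p <- nd$parameters[[j]]
      ppath <- sprintf("%s.parameters[%d]", path, j)
      check_keys(p, ALLOWED_KEYS$parameter, ppath)
      value <- need_key(p, "value", ppath)
      if (is.list(value)) value <- unlist(value, use.names = FALSE)
      parameter_spec(need_key(p, "name", ppath), value,
                     updatable = if (is.null(p$updatable)) TRUE else isTRUE(p$updatable))
    })
    node_type <- need_key(nd, "node_type", path)
    if (!node_type %in% NODE_TYPES) {
      stop(sprintf("graph parse error at %s.node_type: %s is not one of %s", path,
                   sQuote(node_type), paste(NODE_TYPES, collapse = "/")), call. = FALSE)
    }
    node_spec(
      base_name = need_key(nd, "base_name", path),
      node_type = node_type,
      inputs = as.character(unlist(nd$inputs)),
      outputs = as.character(unlist(nd$outputs)),
      parameters = params,
      worker_ref = nd$worker_ref,
      instance_index = if (is.null(nd$instance_index)) NA_integer_ else nd$instance_index,
      placement = if (is.null(nd$placement)) "local" else nd$placement,
      cpu_pin = nd$cpu_pin,
      com_log_path = nd$com_log_path
    )
  })
  edges <- lapply(seq_along(raw$edges), function(i) {
    path <- sprintf("$.edges[%d]", i)
    ed <- raw$edges[[i]]
    check_keys(ed, ALLOWED_KEYS$edge, path)
    edge(need_key(ed, "from_node", path), need_key(ed, "from_output", path),
         need_key(ed, "to_node", path), need_key(ed, "to_input", path))
  })
  g <- graph(nodes = nodes, edges = edges, schema_version = as.character(version))
  check_edge_references(g)
  g
}

# Dangling edge endpoints are a parse-time error (the file is malformed);
# everything else is reported as data by validate_graph().
check_edge_references <- function(g) {
  names <- graph_node_names(g)
  for (i in seq_along(g$edges)) {
    e <- g$edges[[i]]
    path <- sprintf("$.edges[%d]", i)
    for (end in list(c(e$from_node, e$from_output, "outputs"),
                     c(e$to_node, e$to_input, "inputs"))) {
      if (!end[[1]] %in% names) {
        stop(sprintf("graph parse error at %s: unknown node %s", path, sQuote(end[[1]])),
             call. = FALSE)
      }
      node <- graph_node(g, end[[1]])
      if (!end[[2]] %in% port_names(node[[end[[3]]]])) {
        stop(sprintf("graph parse error at %s: node %s has no %s port %s", path,
                     sQuote(end[[1]]), sub("s$", "", end[[3]]), sQuote(end[[2]])),
             call. = FALSE)
      }
    }
  }
  invisible(g)
}

#' Serialize a graph back to its JSON file form
#'
#' `parse_graph(serialize_graph(g))` reproduces `g` field by field,
#' preserving node order.
#'
#' @param g a `rigflow_graph`.
#' @return a JSON string.
#' @export
serialize_graph <- function(g) {
  nodes <- lapply(g$nodes, function(n) {
    out <- list(
      base_name = jsonlite::unbox(n$base_name),
      instance_index = jsonlite::unbox(n$instance_index),
      node_type = jsonlite::unbox(n$node_type),
      inputs = as.list(port_names(n$inputs)),
      outputs = as.list(port_names(n$outputs)),
      parameters = lapply(n$parameters, function(p) {
        list(name = jsonlite::unbox(p$name),
             value = if (length(p$value) == 1L) jsonlite::unbox(p$value) else p$value,
             updatable = jsonlite::unbox(p$updatable))
      }),
      placement = jsonlite::unbox(n$placement)
    )
    if (!is.null(n$worker_ref)) out$worker_ref <- jsonlite::unbox(n$worker_ref)
    if (!is.null(n$cpu_pin)) out$cpu_pin <- jsonlite::unbox(n$cpu_pin)
    if (!is.null(n$com_log_path)) out$com_log_path <- jsonlite::unbox(n$com_log_path)
    out
  })
  edges <- lapply(g$edges, function(e) lapply(e, jsonlite::unbox))
  jsonlite::toJSON(list(schema_version = jsonlite::unbox(g$schema_version),
                        nodes = nodes, edges = edges),
                   auto_unbox = FALSE, pretty = TRUE, null = "null")
}

# ---- validation -------------------------------------------------------------

#' Validate a graph's structural invariants
#'
#' Violations are returned as data (a character vector, empty when valid),
#' never thrown. Checked: node-type port rules (sources emit only, sinks
#' receive only, transforms both), display-name uniqueness, port-name
#' uniqueness within node and direction, parameter-name uniqueness, edge
#' endpoint existence and direction, duplicate edges. Cycles are legal and
#' never reported.
#'
#' @param g a `rigflow_graph`.
#' @return character vector of violation messages; `character(0)` if valid.
#' @export
validate_graph <- function(g) {
  v <- character()
  names <- graph_node_names(g)
  dup <- unique(names[duplicated(names)])
  for (d in dup) v <- c(v, sprintf("duplicate display name %s", sQuote(d)))
  for (n in g$nodes) {
    nm <- display_name(n)
    n_in <- length(n$inputs)
    n_out <- length(n$outputs)
    if (n$node_type == "source" && (n_in > 0L || n_out < 1L)) {
      v <- c(v, sprintf("node %s: a source must have no inputs and at least one output (has %d in, %d out)",
                        sQuote(nm), n_in, n_out))
    }
    if (n$node_type == "sink" && (n_out > 0L || n_in < 1L)) {
      v <- c(v, sprintf("node %s: a sink must have no outputs and at least one input (has %d in, %d out)",
                        sQuote(nm), n_in, n_out))
    }
    if (n$node_type == "transform" && (n_in < 1L || n_out < 1L)) {
      v <- c(v, sprintf("node %s: a transform must have at least one input and one output (has %d in, %d out)",
                        sQuote(nm), n_in, n_out))
    }
    for (ports in list(n$inputs, n$outputs)) {
      pn <- port_names(ports)
      if (any(!nzchar(pn))) v <- c(v, sprintf("node %s: empty port name", sQuote(nm)))
      for (d in unique(pn[duplicated(pn)])) {
        v <- c(v, sprintf("node %s: duplicate port name %s", sQuote(nm), sQuote(d)))
      }
    }
    prm <- vapply(n$parameters, `[[`, character(1), "name")
    for (d in unique(prm[duplicated(prm)])) {
      v <- c(v, sprintf("node %s: duplicate parameter name %s", sQuote(nm), sQuote(d)))
    }
    if (!is.na(n$instance_index) && n$instance_index < 0L) {
      v <- c(v, sprintf("node %s: negative instance index", sQuote(nm)))
    }
  }
  seen <- character()
  for (e in g$edges) {
    id <- edge_id(e)
    if (id %in% seen) v <- c(v, sprintf("duplicate edge %s", id))
    seen <- c(seen, id)
    from <- graph_node(g, e$from_node)
    to <- graph_node(g, e$to_node)
    if (is.null(from)) {
      v <- c(v, sprintf("edge %s: unknown node %s", id, sQuote(e$from_node)))
    } else if (!e$from_output %in% port_names(from$outputs)) {
      v <- c(v, sprintf("edge %s: node %s has no output port %s", id,
                        sQuote(e$from_node), sQuote(e$from_output)))
    }
    if (is.null(to)) {
      v <- c(v, sprintf("edge %s: unknown node %s", id, sQuote(e$to_node)))
    } else if (!e$to_input %in% port_names(to$inputs)) {
      v <- c(v, sprintf("edge %s: node %s has no input port %s", id,
                        sQuote(e$to_node), sQuote(e$to_input)))
    }
  }
  v
}

#' Node start order
#'
#' Nodes start in authoring order (the order they appear in the graph file),
#' regardless of topology. There is no topological sort — cycles are legal
#' and the order is purely positional.
#'
#' @param g a valid `rigflow_graph`.
#' @return character vector of display names in start order.
#' @export
start_order <- function(g) {
  v <- validate_graph(g)
  if (length(v) > 0L) {
    stop("cannot order an invalid graph:\n", paste(" -", v, collapse = "\n"), call. = FALSE)
  }
  graph_node_names(g)
}
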