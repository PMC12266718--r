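# The node API: the contract every worker implements. A worker definition
# registers three hooks — initialise, work, end_of_life — plus a node type.
# Sources implement `work(ctx)` as one pass of an infinite loop returning a
# payload list (or NULL for an idle pass); transforms and sinks implement
# `work(ctx, event)` as a callback invoked once per delivered packet, with
# transforms returning a payload list (one item per output, first output
# first) and sinks returning NULL. Workers see their parameters through the
# context and can record at most one substate row per work pass.

#' Define a node worker
#'
#' @param node_type `"source"`, `"transform"` or `"sink"` — must match the
#'   node the worker is attached to.
#' @param initialise `function(ctx)`; run once before any data flows. An
#'   error here fails the node's proof of life and aborts the graph start.
#' @param work for sources `function(ctx)` returning a payload list (one
#'   item per declared output) or `NULL` for an idle pass; for transforms
#'   and sinks `function(ctx, event)` — transforms return a payload list
#'   (or `NULL` to emit nothing this pass), sinks return `NULL`.
#' @param end_of_life `function(ctx)`; run exactly once at graceful stop.
#' @return a `rigflow_worker` definition.
#' @export
worker_definition <- function(node_type, work, initialise = function(ctx) TRUE,
                              end_of_life = function(ctx) invisible(NULL)) {
  node_type <- match.arg(node_type, NODE_TYPES)
  stopifnot(is.function(work), is.function(initialise), is.function(end_of_life))
  n_work_args <- length(formals(work))
  if (node_type == "source" && n_work_args != 1L) {
    stop("a source work hook takes one argument (ctx)", call. = FALSE)
  }
  if (node_type != "source" && n_work_args != 2L) {
    stop("a ", node_type, " work hook takes two arguments (ctx, event)", call. = FALSE)
  }
  structure(list(node_type = node_type, initialise = initialise, work = work,
                 end_of_life = end_of_life),
            class = "rigflow_worker")
}

#' An input event delivered to a callback worker
#'
#' @param input_port the receiving port name.
#' @param item the payload item.
#' @param upstream_node display name of the emitting node.
#' @param upstream_packet_id the packet id assigned by the emitter.
#' @param local_packet_id the id assigned by this node's relay.
#' @param timestamp_ns relay timestamp.
#' @return a `rigflow_input_event`.
#' @export
input_event <- function(input_port, item, upstream_node, upstream_packet_id,
                        local_packet_id = NA_integer_, timestamp_ns = NA_real_) {
  structure(list(input_port = input_port, item = item, upstream_node = upstream_node,
                 upstream_packet_id = upstream_packet_id,
                 local_packet_id = local_packet_id, timestamp_ns = timestamp_ns),
            class = "rigflow_input_event")
}

#' Build a node context
#'
#' The context is the worker's window on the engine: parameter values
#' (`ctx$param(name)`), the clock, the current packet index, and substate
#' recording. Used directly by the engine's worker processes; exported so
#' node logic can be exercised in-process in tests and simulations.
#'
#' @param node a [node_spec()] (or `NULL` for a bare context).
#' @param clock a clock object.
#' @param seed optional seed applied to the session RNG.
#' @return an environment of class `rigflow_context`.
#' @export
node_context <- function(node = NULL, clock = clock_real(), seed = NULL) {
  ctx <- new.env(parent = emptyenv())
  ctx$node <- node
  ctx$name <- if (!is.null(node)) display_name(node) else "<detached>"
  ctx$clock <- clock
  ctx$params <- new.env(parent = emptyenv())
  if (!is.null(node)) {
    for (p in node$parameters) assign(p$name, p$value, envir = ctx$params)
  }
  ctx$param <- function(name, default = NULL) {
    if (exists(name, envir = ctx$params, inherits = FALSE)) {
      get(name, envir = ctx$params, inherits = FALSE)
    } else default
  }
  ctx$packet_index <- 0L
  ctx$pass_recorded <- FALSE
  ctx$substate_rows <- list()
  ctx$state <- new.env(parent = emptyenv())   # scratch space for worker state
  ctx$log <- function(...) invisible(NULL)    # engine installs a real logger
  if (!is.null(seed)) set.seed(seed)
  class(ctx) <- c("rigflow_context", "environment")
  ctx
}

RESERVED_SUBSTATE_FIELDS <- c("packet_index", "timestamp_ns")

#' Record a substate row for the current work pass
#'
#' One optional provenance row per pass: the engine stamps the current
#' packet index and timestamp, and the worker contributes user fields (for
#' example a hardware frame id read from the device). Calling it twice in
#' one pass is an error; the reserved field names `packet_index` and
#' `timestamp_ns` are rejected. The table is flushed to CSV when the graph
#' stops.
#'
#' @param ctx the node context.
#' @param fields named list/vector of scalar user fields.
#' @return invisibly, the row as a list.
#' @export
record_substate <- function(ctx, fields) {
  fields <- as.list(fields)
  if (is.null(names(fields)) || any(!nzchar(names(fields)))) {
    stop("substate fields must be named", call. = FALSE)
  }
  bad <- intersect(names(fields), RESERVED_SUBSTATE_FIELDS)
  if (length(bad) > 0L) {
    stop("substate field name(s) reserved by the engine: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (isTRUE(ctx$pass_recorded)) {
    stop("record_substate() already called in this work pass", call. = FALSE)
  }
  row <- c(list(packet_index = ctx$packet_index, timestamp_ns = ctx$clock$now()), fields)
  ctx$substate_rows[[length(ctx$substate_rows) + 1L]] <- row
  ctx$pass_recorded <- TRUE
  invisible(row)
}

#' Materialise a context's substate table
#'
#' @param ctx the node context.
#' @return data.frame with `packet_index`, `timestamp_ns`, then user fields
#'   in first-recorded order.
#' @export
substate_table <- function(ctx) {
  rows <- ctx$substate_rows
  if (length(rows) == 0L) {
    return(data.frame(packet_index = integer(), timestamp_ns = numeric()))
  }
  all_fields <- unique(unlist(lapply(rows, names)))
  cols <- lapply(all_fields, function(f) {
    vals <- lapply(rows, function(r) if (is.null(r[[f]])) NA else r[[f]])
    unlist(vals)
  })
  names(cols) <- all_fields
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Write a substate table as CSV
#'
#' @param table data.frame from [substate_table()].
#' @param path file path.
#' @export
write_substate <- function(table, path) {
  write_fixture_csv(table, path)
  invisible(path)
}

#' Drive a source worker's loop in-process
#'
#' Runs the source loop body for up to `passes` passes against the given
#' context, collecting the emitted packets. This is the in-process
#' embodiment of the engine's source loop (the engine runs the same
#' contract in a dedicated worker process): each pass returning a payload
#' list emits one packet with the next id (starting at 0); `NULL` passes
#' are idle. The end-of-life hook runs before returning.
#'
#' @param def a source [worker_definition()].
#' @param ctx a [node_context()]; `def$initialise(ctx)` is called first.
#' @param passes number of loop passes to run.
#' @param n_outputs declared output count (payload arity is enforced).
#' @return list of packets, each `list(packet_id, timestamp_ns, payload)`.
#' @export
run_source_loop <- function(def, ctx = node_context(), passes, n_outputs = 1L) {
  stopifnot(inherits(def, "rigflow_worker"), def$node_type == "source")
  def$initialise(ctx)
  packets <- list()
  for (i in seq_len(passes)) {
    ctx$packet_index <- length(packets)
    ctx$pass_recorded <- FALSE
    res <- def$work(ctx)
    if (is.null(res)) next
    if (length(res) != n_outputs) {
      stop("contract violation: payload list length ", length(res),
           " does not match ", n_outputs, " declared outputs", call. = FALSE)
    }
    packets[[length(packets) + 1L]] <- list(packet_id = length(packets),
                                            timestamp_ns = ctx$clock$now(),
                                            payload = res)
  }
  def$end_of_life(ctx)
  packets
}

#' Invoke a callback worker for one delivered event
#'
#' The in-process embodiment of the engine's callback dispatch: transforms
#' must return a payload list of `n_outputs` items (or `NULL` to emit
#' nothing); sinks must return `NULL`.
#'
#' @param def a transform or sink [worker_definition()].
#' @param ctx a [node_context()].
#' @param event an [input_event()].
#' @param n_outputs declared output count for transforms.
#' @return the payload list, or `NULL`.
#' @export
run_callback_worker <- function(def, ctx, event, n_outputs = 1L) {
  stopifnot(inherits(def, "rigflow_worker"), def$node_type != "source")
  ctx$pass_recorded <- FALSE
  res <- def$work(ctx, event)
  if (def$node_type == "sink" && !is.null(res)) {
    stop("contract violation: sink callback must return NULL", call. = FALSE)
  }
  if (def$node_type == "transform" && !is.null(res) && length(res) != n_outputs) {
    stop("contract violation: payload list length ", length(res),
         " does not match ", n_outputs, " declared outputs", call. = FALSE)
  }
  res
}

#' Resolve a worker reference to a worker factory
#'
#' A `worker_ref` is either `"package::function"` naming an exported
#' factory (a zero-argument function returning a [worker_definition()]), or
#' a path to an R file that defines `make_worker()`.
#'
#' @param ref the worker reference string.
#' @return the factory function.
#' @export
resolve_worker_ref <- function(ref) {
  if (is.null(ref) || !nzchar(ref)) stop("empty worker_ref", call. = FALSE)
  if (grepl("::", ref, fixed = TRUE)) {
    parts <- strsplit(ref, "::", fixed = TRUE)[[1]]
    fac <- tryCatch(getExportedValue(parts[[1]], parts[[2]]), error = function(e) NULL)
    if (is.null(fac)) {
      stop("unresolvable worker_ref ", sQuote(ref), call. = FALSE)
    }
    return(fac)
  }
  if (!file.exists(ref)) stop("unresolvable worker_ref ", sQuote(ref),
                              ": file not found", call. = FALSE)
  env <- new.env(parent = globalenv())
  sys.source(ref, envir = env)
  if (!exists("make_worker", envir = env, inherits = FALSE)) {
    stop("worker file ", sQuote(ref), " does not define make_worker()", call. = FALSE)
  }
  get("make_worker", envir = env, inherits = FALSE)
}
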