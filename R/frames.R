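# Internal socket plumbing. All inter-actor traffic is length-prefixed
# frames (4-byte big-endian length, then a serialized R list) on local TCP
# connections. Brokers implement topic-based publish-subscribe: a client's
# first frames declare its subscriptions, after which `pub` frames are
# forwarded to every subscriber of the topic. Push-pull style handshakes
# (proof of life, parameter acks) are pub frames on a single-subscriber
# topic.

rf_send_frame <- function(con, obj) {
  b <- serialize(obj, NULL)
  header <- writeBin(length(b), raw(), size = 4L, endian = "big")
  writeBin(c(header, b), con)   # single write per frame
  flush(con)
  invisible(TRUE)
}

# NULL on EOF / closed peer.
rf_recv_frame <- function(con) {
  n <- tryCatch(readBin(con, integer(), n = 1L, size = 4L, endian = "big"),
                error = function(e) integer())
  if (length(n) == 0L) return(NULL)
  b <- readBin(con, raw(), n = n)
  if (length(b) < n) return(NULL)
  unserialize(b)
}

# Bind a listening socket on a free local port (random high port, retried).
rf_bind_any <- function(tries = 100L) {
  for (i in seq_len(tries)) {
    port <- sample(20000:60000, 1L)
    srv <- tryCatch(serverSocket(port), error = function(e) NULL)
    if (!is.null(srv)) return(list(srv = srv, port = port))
  }
  stop("could not bind a local port", call. = FALSE)
}

rf_connect <- function(port, timeout = 10) {
  deadline <- Sys.time() + timeout
  repeat {
    con <- tryCatch(
      socketConnection("127.0.0.1", port, blocking = TRUE, open = "a+b", timeout = 3600,
                       options = "no-delay"),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(con)) return(con)
    if (Sys.time() > deadline) stop("could not connect to port ", port, call. = FALSE)
    Sys.sleep(0.05)
  }
}

# Connect to a broker and declare subscriptions.
rf_broker_connect <- function(port, subs = character(), timeout = 10) {
  con <- rf_connect(port, timeout)
  rf_send_frame(con, list(kind = "sub", topics = subs))
  con
}

rf_publish <- function(con, topic, msg) {
  rf_send_frame(con, list(kind = "pub", topic = topic, msg = msg))
}

# Readable members of a list of connections (indices), or integer(0).
rf_poll <- function(cons, timeout = 0.05) {
  if (length(cons) == 0L) { Sys.sleep(timeout); return(integer()) }
  ready <- socketSelect(cons, write = FALSE, timeout = timeout)
  which(ready)
}

# A process that has exited but not yet been reaped by its parent (zombie)
# counts as dead: it holds no resources and can never run again.
rf_pid_alive <- function(pid) {
  if (is.na(pid)) return(FALSE)
  stat_path <- file.path("/proc", pid, "stat")
  if (!file.exists(stat_path)) return(FALSE)
  s <- tryCatch(readLines(stat_path, n = 1L, warn = FALSE), error = function(e) character())
  if (length(s) == 0L) return(FALSE)
  state <- sub(".*\\) +(\\S).*", "\\1", s)
  !identical(state, "Z")
}

# Spawn a detached actor process running this package's actor entry script.
# The child inherits the caller's library paths through R_LIBS so it can
# library() the installed package.
rf_spawn_actor <- function(args, log_file = NULL) {
  script <- system.file("actors", "actor.R", package = "rigflow")
  if (!nzchar(script)) stop("actor entry script not found; is rigflow installed?",
                            call. = FALSE)
  Sys.setenv(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))
  out <- if (is.null(log_file)) FALSE else log_file
  system2(file.path(R.home("bin"), "Rscript"),
          c("--vanilla", shQuote(script), vapply(args, shQuote, character(1))),
          wait = FALSE, stdout = out, stderr = out)
  invisible(TRUE)
}

rf_parse_kv_args <- function(args) {
  kv <- strsplit(args, "=", fixed = TRUE)
  setNames(lapply(kv, function(x) paste(x[-1L], collapse = "=")),
           vapply(kv, `[[`, character(1), 1L))
}

# One line per event, timestamped with the wall clock; used by every actor.
rf_logger <- function(path) {
  function(event, ...) {
    details <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                            character(1)), collapse = " ")
    cat(sprintf("%.6f %s %s\n", as.numeric(Sys.time()), event, details),
        file = path, append = TRUE)
  }
}
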