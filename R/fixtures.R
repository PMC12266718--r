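# Seeded synthetic fixtures. Everything the tests and examples consume is
# generated here: TTL pulse trains with an integer-divided secondary train,
# lossy frame-capture chains with their com logs and substate tables, and
# scripted rig sessions for the trial controller. Every generator carries
# its hidden ground truth alongside the "observable" files so reconciliation
# results can be checked against what actually happened. Event times are
# integer nanoseconds computed with integer arithmetic only, so a fixed seed
# reproduces byte-identical files on any platform.

#' Scripted rig event stream
#'
#' A replayable, clock-driven stream of rig events (licks, pokes, ...) for
#' [trial_controller_run_trial()].
#'
#' @param events data.frame with columns `time_ns` (non-decreasing), `kind`
#'   (character) and `port` (integer); or omitted for an empty stream.
#' @return a `rigflow_session`.
#' @export
scripted_session <- function(events = NULL) {
  if (is.null(events)) {
    events <- data.frame(time_ns = numeric(), kind = character(), port = integer())
  }
  stopifnot(all(c("time_ns", "kind", "port") %in% names(events)))
  if (nrow(events) > 1L && any(diff(events$time_ns) < 0)) {
    stop("scripted session times must be non-decreasing", call. = FALSE)
  }
  structure(list(events = events), class = "rigflow_session")
}

#' Rig simulation configuration
#'
#' Describes the reference synchronisation rig: a base TTL pulse train (the
#' projector photodiode at 120 Hz in the reference setup) triggering camera
#' A, an integer pulse divider producing the secondary train (divide by 4,
#' giving 30 Hz) triggering camera B, and per-stage drop probabilities for
#' each camera's capture-and-save chain.
#'
#' @param base_rate base train rate in Hz.
#' @param division_factor integer `k` of the pulse divider.
#' @param duration recording duration in seconds.
#' @param drop_probs_a,drop_probs_b per-stage drop probabilities in `[0, 1)`
#'   for the two chains; the first stage is the capture node itself, later
#'   stages are downstream relays.
#' @param seed integer RNG seed.
#' @return a `rigflow_rig_config`.
#' @export
rig_sim_config <- function(base_rate = 120, division_factor = 4L, duration = 60,
                           drop_probs_a = c(0.0002, 0.0001),
                           drop_probs_b = c(0.0002, 0.0001),
                           seed = 1L) {
  stopifnot(base_rate > 0, division_factor >= 1, duration > 0)
  for (p in c(drop_probs_a, drop_probs_b)) {
    if (p < 0 || p >= 1) stop("drop probabilities must be in [0, 1)", call. = FALSE)
  }
  structure(list(base_rate = base_rate, division_factor = as.integer(division_factor),
                 duration = duration, drop_probs_a = drop_probs_a,
                 drop_probs_b = drop_probs_b, seed = as.integer(seed)),
            class = "rigflow_rig_config")
}

# Integer-ns pulse times: pulse i of a train at `rate` Hz fires at
# floor(i * 1e9 / rate). Exact for any index below 2^53 / 1e9 seconds.
pulse_times_ns <- function(n, rate) {
  (seq_len(n) - 1) * 1e9 %/% rate
}

# Simulate one capture/relay chain over `n_origin` trigger events.
# Stage 1 is the capture node (its survivors become origin packets with a
# substate row linking packet_index to the trigger/pulse index); stages 2..S
# are downstream relays, each producing a com log. Returns the observable
# tables plus the hidden truth (trigger -> terminal index or NA).
simulate_capture_chain <- function(n_origin, drop_probs, seed,
                                   node_names = paste0("stage", seq_along(drop_probs))) {
  stopifnot(length(drop_probs) >= 1L)
  survived <- matrix(FALSE, nrow = n_origin, ncol = length(drop_probs))
  alive <- rep(TRUE, n_origin)
  for (s in seq_along(drop_probs)) {
    set.seed(seed + 1000L * s)              # stage-local substream
    u <- runif(n_origin)
    alive <- alive & (u >= drop_probs[[s]])
    survived[, s] <- alive
  }
  pulse_index <- which(survived[, 1L]) - 1L  # triggers the capture node caught
  n_frames <- length(pulse_index)
  substate <- data.frame(
    packet_index = seq_len(n_frames) - 1L,
    timestamp_ns = pulse_times_ns(n_origin, 1)[pulse_index + 1L],  # placeholder spacing
    pulse_index = pulse_index
  )
  logs <- list()
  prev_local <- substate$packet_index       # ids at the previous stage
  prev_alive <- survived[, 1L]
  for (s in seq_along(drop_probs)[-1L]) {
    keep <- survived[prev_alive, s]         # which of the previous survivors live on
    upstream <- prev_local[keep]
    local <- seq_along(upstream) - 1L
    logs[[length(logs) + 1L]] <- data.frame(
      upstream_node = node_names[[s - 1L]],
      upstream_packet_id = upstream,
      local_packet_id = local,
      timestamp_ns = local
    )
    prev_local <- local
    prev_alive <- survived[, s]
  }
  terminal <- rep(NA_integer_, n_origin)
  terminal[survived[, length(drop_probs)]] <- seq_len(sum(survived[, length(drop_probs)])) - 1L
  list(substate = substate, logs = logs,
       truth = data.frame(trigger_index = seq_len(n_origin) - 1L,
                          survived = survived[, length(drop_probs)],
                          terminal_index = terminal))
}

#' Simulate the full two-camera synchronisation rig
#'
#' Generates the base and divided pulse trains, runs both capture chains
#' with seeded stochastic drops, and emits exactly the tables the
#' provenance machinery consumes ([compose_chain()], [align_two_chains()]),
#' together with a ground-truth event table kept separate from the
#' observable files. The same seed produces identical output.
#'
#' @param cfg a [rig_sim_config()].
#' @param dir optional directory; when given, all observable tables, the
#'   ground truth and a manifest are written as CSV/JSON files.
#' @return list with `pulses` (a [pulse_record()]), `chain_a`, `chain_b`
#'   (each `list(substate, logs)`), `truth` (full event table: one row per
#'   base pulse with both chains' frame indices and survival flags), `cfg`,
#'   and `files` (named paths when `dir` was given).
#' @export
simulate_rig <- function(cfg = rig_sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "rigflow_rig_config"))
  k <- cfg$division_factor
  n_base <- floor(cfg$base_rate * cfg$duration)
  n_div <- n_base %/% k
  base_times <- pulse_times_ns(n_base, cfg$base_rate)
  div_times <- base_times[divided_pulse_origin(seq_len(n_div) - 1L, k) + 1L]
  pulses <- pulse_record(base_times, div_times, cfg$base_rate, k)

  a <- simulate_capture_chain(n_base, cfg$drop_probs_a, cfg$seed,
                              node_names = c("CameraA##0", "SaveA##0"))
  b <- simulate_capture_chain(n_div, cfg$drop_probs_b, cfg$seed + 500000L,
                              node_names = c("CameraB##0", "SaveB##0"))
  a$substate$timestamp_ns <- base_times[a$substate$pulse_index + 1L]
  b$substate$timestamp_ns <- div_times[b$substate$pulse_index + 1L]

  a_frame <- match(seq_len(n_base) - 1L, a$substate$pulse_index) - 1L
  truth <- data.frame(
    base_pulse = seq_len(n_base) - 1L,
    a_frame = a_frame,
    a_terminal = a$truth$terminal_index,
    divided_pulse = NA_integer_,
    b_frame = NA_integer_,
    b_terminal = NA_integer_
  )
  div_rows <- divided_pulse_origin(seq_len(n_div) - 1L, k) + 1L
  truth$divided_pulse[div_rows] <- seq_len(n_div) - 1L
  truth$b_frame[div_rows] <- match(seq_len(n_div) - 1L, b$substate$pulse_index) - 1L
  truth$b_terminal[div_rows] <- b$truth$terminal_index

  out <- list(pulses = pulses, chain_a = a[c("substate", "logs")],
              chain_b = b[c("substate", "logs")], truth = truth, cfg = cfg)
  if (!is.null(dir)) out$files <- write_rig_fixture(out, dir)
  out
}

# Deterministic CSV writer: integer-valued doubles are printed as plain
# integers so identical seeds give byte-identical files.
write_fixture_csv <- function(df, path) {
  fmt <- function(col) {
    if (is.numeric(col)) {
      out <- sprintf("%.0f", col)
      out[is.na(col)] <- ""
      out
    } else as.character(col)
  }
  out <- as.data.frame(lapply(df, fmt), stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}

write_rig_fixture <- function(rig, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  files <- c(
    substate_a = write_fixture_csv(rig$chain_a$substate, p("substate_camera_a.csv")),
    substate_b = write_fixture_csv(rig$chain_b$substate, p("substate_camera_b.csv")),
    pulse_record = write_fixture_csv(
      data.frame(train = c(rep("base", length(rig$pulses$base_times)),
                           rep("divided", length(rig$pulses$divided_times))),
                 pulse_index = c(seq_along(rig$pulses$base_times) - 1L,
                                 seq_along(rig$pulses$divided_times) - 1L),
                 time_ns = c(rig$pulses$base_times, rig$pulses$divided_times)),
      p("pulse_record.csv")),
    ground_truth = write_fixture_csv(rig$truth, p("ground_truth.csv"))
  )
  for (chain in c("a", "b")) {
    logs <- rig[[paste0("chain_", chain)]]$logs
    for (i in seq_along(logs)) {
      nm <- sprintf("com_log_%s_%d", chain, i)
      files[[nm]] <- write_fixture_csv(logs[[i]], p(nm, ".csv"))
    }
  }
  manifest <- list(seed = rig$cfg$seed, base_rate = rig$cfg$base_rate,
                   division_factor = rig$cfg$division_factor,
                   duration = rig$cfg$duration,
                   files = as.list(basename(files)))
  manifest_path <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE), manifest_path)
  c(files, manifest = manifest_path)
}

#' Read a pulse-record CSV back into a [pulse_record()]
#'
#' @param path CSV written by [simulate_rig()] (columns `train`,
#'   `pulse_index`, `time_ns`).
#' @param base_rate,division_factor train metadata (from the manifest).
#' @return a `rigflow_pulse_record`.
#' @export
read_pulse_record <- function(path, base_rate, division_factor) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  pulse_record(df$time_ns[df$train == "base"], df$time_ns[df$train == "divided"],
               base_rate, division_factor)
}

#' Reference two-stage capture-chain fixture
#'
#' The worked drop-accounting example: a camera device generates `n_origin`
#' hardware frames, relayed through a two-node chain (the capture node, then
#' the video-save node) that together lose `n_drops` frames. The origin
#' substate enumerates the device frames; each node contributes one com log.
#' Which frames are lost is drawn with the seed; the totals are exact by
#' construction.
#'
#' @param n_origin frames generated at the origin device.
#' @param n_drops total frames lost across the two nodes (split evenly).
#' @param seed RNG seed selecting which frames drop.
#' @return list with `substate` (one row per device frame), `logs` (com
#'   logs of the capture node and the save node, in chain order), and
#'   `truth` (`origin_total`, `terminal_total`, `dropped`).
#' @export
reference_capture_chain <- function(n_origin = 216300L, n_drops = 56L, seed = 1L) {
  stopifnot(n_drops <= n_origin)
  set.seed(seed)
  substate <- data.frame(packet_index = seq_len(n_origin) - 1L,
                         timestamp_ns = seq_len(n_origin) - 1L)
  n1 <- n_drops %/% 2L
  n2 <- n_drops - n1
  make_log <- function(prev_ids, n_lost, upstream_node) {
    keep <- setdiff(prev_ids, sort(sample(prev_ids, n_lost)))
    data.frame(upstream_node = upstream_node,
               upstream_packet_id = keep,
               local_packet_id = seq_along(keep) - 1L,
               timestamp_ns = keep)
  }
  capture_log <- make_log(substate$packet_index, n1, "CameraDevice")
  save_log <- make_log(capture_log$local_packet_id, n2, "CameraA##0")
  list(substate = substate, logs = list(capture_log, save_log),
       truth = list(origin_total = n_origin,
                    terminal_total = nrow(save_log),
                    dropped = n_drops))
}
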