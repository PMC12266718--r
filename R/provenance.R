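# Packet provenance reconciliation. The engine never buffers: packets that
# arrive while a node's callback is busy are dropped. Every relay keeps a
# com log pairing the upstream packet id with the locally assigned id, and
# workers can record substate rows pairing their packet index with a device
# id (e.g. a hardware frame counter). Composing these relations recovers an
# exact terminal-frame -> origin-frame correspondence despite drops, and a
# TTL pulse divider recorded on a common device extends it across machines.

#' Count dropped packets from origin and terminal totals
#'
#' Under at-most-once delivery, every packet lost along a relay chain shows
#' up as the difference between the number generated at the origin device
#' and the number surviving at the terminal (saved) end.
#'
#' @param origin_total packets generated at the origin.
#' @param terminal_total packets surviving at the terminal stage.
#' @return the number dropped, `origin_total - terminal_total`.
#' @export
#' @examples
#' count_drops(216300, 216244) # the 0.02% two-node capture chain loss
count_drops <- function(origin_total, terminal_total) {
  stopifnot(length(origin_total) == 1L, length(terminal_total) == 1L,
            origin_total >= 0, terminal_total >= 0)
  if (terminal_total > origin_total) {
    stop("terminal_total (", terminal_total, ") exceeds origin_total (", origin_total,
         "): impossible under at-most-once delivery", call. = FALSE)
  }
  origin_total - terminal_total
}

#' Read / write a com log CSV
#'
#' Columns: `upstream_node`, `upstream_packet_id`, `local_packet_id`,
#' `timestamp_ns`.
#'
#' @param path file path.
#' @return `read_com_log()` returns a data.frame.
#' @export
read_com_log <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("upstream_node", "upstream_packet_id", "local_packet_id", "timestamp_ns")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("com log ", path, " lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @param log com-log data.frame.
#' @rdname read_com_log
#' @export
write_com_log <- function(log, path) {
  write.csv(log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_com_log <- function(log, label = "com log") {
  up <- log$upstream_packet_id
  loc <- log$local_packet_id
  if (nrow(log) > 1L) {
    bad <- which(diff(up) <= 0)
    if (length(bad) > 0L) {
      stop(label, ": upstream ids not strictly increasing at row ", bad[[1]] + 1L,
           call. = FALSE)
    }
    bad <- which(diff(loc) <= 0)
    if (length(bad) > 0L) {
      stop(label, ": local ids not strictly increasing at row ", bad[[1]] + 1L,
           call. = FALSE)
    }
  }
  if (nrow(log) > 0L && !identical(as.integer(loc), seq.int(0L, nrow(log) - 1L))) {
    stop(label, ": local ids must be gapless starting at 0", call. = FALSE)
  }
  invisible(log)
}

#' Compose a relay chain into a terminal/origin correspondence
#'
#' Given the origin node's substate table (one row per generated packet) and
#' the ordered com logs of each downstream relay stage, composes the id
#' relations stage by stage. A packet appears in the result only if it
#' survived every stage; the summary drop count is the sum of per-stage
#' losses and equals `origin_total - terminal_total`.
#'
#' @param origin_substate data.frame with a `packet_index` column listing
#'   the ids assigned at the origin (0-based, strictly increasing).
#' @param logs list of com-log data.frames, ordered from the stage nearest
#'   the origin to the terminal stage.
#' @return a `rigflow_correspondence`: list with `table` (data.frame
#'   `terminal_index`, `origin_index`) and `summary` (`origin_total`,
#'   `terminal_total`, `dropped`).
#' @export
compose_chain <- function(origin_substate, logs) {
  if (!"packet_index" %in% names(origin_substate)) {
    stop("origin substate lacks a packet_index column", call. = FALSE)
  }
  origin_ids <- as.integer(origin_substate$packet_index)
  if (length(origin_ids) > 1L && any(diff(origin_ids) <= 0)) {
    stop("origin substate: packet_index not strictly increasing", call. = FALSE)
  }
  current <- origin_ids          # ids as assigned by the previous stage
  origin <- origin_ids           # the origin id each survivor maps back to
  for (s in seq_along(logs)) {
    log <- logs[[s]]
    check_com_log(log, label = sprintf("com log [stage %d]", s))
    up <- as.integer(log$upstream_packet_id)
    extra <- setdiff(up, current)
    if (length(extra) > 0L) {
      stop(sprintf("com log [stage %d]: upstream id %d is not an id of the previous stage",
                   s, extra[[1]]), call. = FALSE)
    }
    keep <- match(up, current)
    origin <- origin[keep]
    current <- as.integer(log$local_packet_id)
  }
  table <- data.frame(terminal_index = current, origin_index = origin)
  structure(list(
    table = table,
    summary = list(origin_total = length(origin_ids),
                   terminal_total = nrow(table),
                   dropped = length(origin_ids) - nrow(table))
  ), class = "rigflow_correspondence")
}

#' @export
print.rigflow_correspondence <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<correspondence: %d origin -> %d terminal, %d dropped (%.2f%%)>\n",
              s$origin_total, s$terminal_total, s$dropped,
              if (s$origin_total > 0) 100 * s$dropped / s$origin_total else 0))
  invisible(x)
}

#' Write a correspondence table to CSV
#'
#' Columns `terminal_index`, `origin_index`; unmatched rows (if any) have an
#' empty origin.
#'
#' @param corr a `rigflow_correspondence` or its `$table`.
#' @param path file path.
#' @export
write_correspondence <- function(corr, path) {
  tbl <- if (inherits(corr, "rigflow_correspondence")) corr$table else corr
  write.csv(tbl, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Origin of a divided TTL pulse
#'
#' A pulse divider emits one output pulse per `k` input pulses (`k = 4` in
#' the reference rig relates a 120 Hz camera trigger train to a 30 Hz one).
#' Divided pulse `j` is attributed to the first base pulse of its group,
#' i.e. base index `k * j`. Group-onset attribution is the package
#' convention; pass `onset = FALSE` to attribute to the last pulse of the
#' group (`k * j + k - 1`).
#'
#' @param j 0-based divided-train pulse index (vectorised).
#' @param k positive integer division factor.
#' @param onset attribute to the first (`TRUE`, default) or last pulse of
#'   the group of `k`.
#' @return 0-based base-train pulse index.
#' @export
#' @examples
#' divided_pulse_origin(3, 4) # 12
divided_pulse_origin <- function(j, k, onset = TRUE) {
  stopifnot(all(j >= 0), length(k) == 1L, k >= 1)
  j <- as.integer(j)
  k <- as.integer(k)
  if (onset) k * j else k * j + (k - 1L)
}

#' Describe a recorded pulse-train pair
#'
#' @param base_times ordered pulse times of the base train on the common
#'   recorder (integer ns).
#' @param divided_times ordered pulse times of the divided train.
#' @param base_rate base train rate in Hz.
#' @param division_factor integer `k` of the divider.
#' @return a `rigflow_pulse_record`.
#' @export
pulse_record <- function(base_times, divided_times, base_rate, division_factor) {
  stopifnot(base_rate > 0, division_factor >= 1)
  expected <- length(base_times) %/% division_factor
  if (abs(length(divided_times) - expected) > 1L) {
    stop(sprintf(
      "pulse trains inconsistent with division factor %d: %d base pulses imply %d divided pulses (+/-1), got %d",
      division_factor, length(base_times), expected, length(divided_times)), call. = FALSE)
  }
  structure(list(base_times = base_times, divided_times = divided_times,
                 base_rate = base_rate, division_factor = as.integer(division_factor)),
            class = "rigflow_pulse_record")
}

#' Align two capture chains through a shared pulse train
#'
#' Chain A's frames are triggered by the base TTL train and chain B's by the
#' divided train. Both chains have been reconciled to their origin devices
#' with [compose_chain()], and each origin's substate links its frames to
#' pulse indices. Terminal frame `j` of B maps to the terminal A frame whose
#' origin pulse index is `divided_pulse_origin(pulse(j), k)`, when that A
#' frame survived its chain; B frames whose partner was dropped are kept in
#' the output with an `NA` partner (flagged, never silently removed).
#'
#' @param chain_a,chain_b `rigflow_correspondence` objects for the two
#'   chains.
#' @param substate_a data.frame linking A origin frames to base-pulse
#'   indices: columns `packet_index`, `pulse_index`.
#' @param substate_b data.frame linking B origin frames to divided-pulse
#'   indices: columns `packet_index`, `pulse_index`.
#' @param pulses a [pulse_record()] pairing the two trains.
#' @param onset group-onset convention, see [divided_pulse_origin()].
#' @return data.frame with columns `b_terminal`, `b_origin`, `divided_pulse`,
#'   `base_pulse`, `a_origin`, `a_terminal` (`NA` when unmatched) and
#'   `matched` (logical).
#' @export
align_two_chains <- function(chain_a, chain_b, substate_a, substate_b, pulses,
                             onset = TRUE) {
  stopifnot(inherits(chain_a, "rigflow_correspondence"),
            inherits(chain_b, "rigflow_correspondence"),
            inherits(pulses, "rigflow_pulse_record"))
  k <- pulses$division_factor
  b <- chain_b$table
  # B terminal frame -> B origin frame -> divided pulse index
  divided <- substate_b$pulse_index[match(b$origin_index, substate_b$packet_index)]
  base <- divided_pulse_origin(divided, k, onset = onset)
  # base pulse -> A origin frame -> A terminal frame (NA where dropped)
  a_origin <- substate_a$packet_index[match(base, substate_a$pulse_index)]
  a_terminal <- chain_a$table$terminal_index[match(a_origin, chain_a$table$origin_index)]
  out <- data.frame(
    b_terminal = b$terminal_index,
    b_origin = b$origin_index,
    divided_pulse = divided,
    base_pulse = base,
    a_origin = a_origin,
    a_terminal = a_terminal
  )
  out$matched <- !is.na(out$a_terminal)
  out
}
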