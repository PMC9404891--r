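#' Joining-order index
#'
#' The index `1 - (I - 1)/(N - 1)` of an individual joining a collective
#' movement at 1-based position `I` among `N` participants: 1 for the first
#' joiner (the initiator), 0 for the last. Vectorized over `I`.
#'
#' @param I 1-based join position(s), `1 <= I <= N`.
#' @param N number of participants in the movement; must be at least 2.
#' @return Numeric vector of indices in \[0, 1\].
#' @export
order_index <- function(I, N) {
  if (any(N < 2)) stop("order index undefined for N < 2")
  if (any(I < 1 | I > N)) stop("join position I must satisfy 1 <= I <= N")
  1 - (I - 1) / (N - 1)
}

#' Initiator test for a displacement observation
#'
#' An individual qualifies as the initiator of a movement if it is the first
#' to walk over 10 m (strict) within 30 s (inclusive).
#'
#' @param displacement distance moved, m.
#' @param elapsed time over which the displacement happened, s.
#' @param any_earlier did some other individual already qualify in this event?
#' @return Logical.
#' @export
is_initiator <- function(displacement, elapsed, any_earlier = FALSE) {
  displacement > 10 & elapsed <= 30 & !any_earlier
}

#' Follower test for a displacement observation
#'
#' A follower moves over 5 m (strict) within 45 degrees (inclusive, circular
#' difference) of the initiator's direction.
#'
#' @param displacement distance moved, m.
#' @param bearing movement bearing, degrees in \[0, 360).
#' @param reference_bearing the initiator's bearing, degrees.
#' @return Logical.
#' @export
is_follower <- function(displacement, bearing, reference_bearing) {
  diff <- abs((bearing - reference_bearing + 180) %% 360 - 180)
  displacement > 5 & diff <= 45
}

#' Segment a join stream into collective-movement events
#'
#' Joins are grouped into events by the five-minute rule: an event closes once
#' 300 s pass (strictly more) after the last join with no new joiner. Within
#' an event each individual is counted once (repeat joins are merged into the
#' first, their calls summed). An event is successful if it has at least 3
#' participants, initiator included. The initiator is the first joiner; ties
#' in join time keep record order.
#'
#' @param join_stream data.frame with columns `individual_id`, `join_time_s`
#'   and optionally `n_calls`, sorted by `join_time_s`.
#' @return List of `movement_event` objects: each a list with `event_id`,
#'   `joins` (data.frame `individual_id`, `join_time_s`, `position`),
#'   `initiator_id`, `calls` (named per-individual counts), `successful`.
#' @export
segment_events <- function(join_stream) {
  st <- as.data.frame(join_stream)
  if (nrow(st) == 0) return(list())
  if (is.unsorted(st$join_time_s)) stop("join stream must be sorted by time")
  if (is.null(st$n_calls)) st$n_calls <- 0L
  gap <- c(0, diff(st$join_time_s))
  event_no <- cumsum(gap > 300)
  lapply(split(seq_len(nrow(st)), event_no), function(rows) {
    block <- st[rows, , drop = FALSE]
    first <- !duplicated(block$individual_id)
    calls <- tapply(block$n_calls, factor(block$individual_id,
                                          levels = unique(block$individual_id)), sum)
    joins <- data.frame(individual_id = block$individual_id[first],
                        join_time_s = block$join_time_s[first],
                        position = seq_len(sum(first)),
                        stringsAsFactors = FALSE)
    structure(list(
      event_id = event_no[rows[1]] + 1L,
      joins = joins,
      initiator_id = joins$individual_id[1],
      calls = calls,
      successful = nrow(joins) >= 3
    ), class = "movement_event")
  })
}

#' @export
print.movement_event <- function(x, ...) {
  cat(sprintf("<movement_event %s: N=%d, initiator=%s, %s, %d calls>\n",
              x$event_id, nrow(x$joins), x$initiator_id,
              if (x$successful) "successful" else "unsuccessful",
              sum(x$calls)))
  invisible(x)
}

event_is_vocal <- function(ev) sum(ev$calls) > 0

#' Per-event joining-order index table
#'
#' @param events list of `movement_event`s (see [segment_events()]); only
#'   successful events contribute (the index needs at least 2 participants
#'   and the study unit is the successful movement).
#' @return data.frame with columns `event_id`, `individual_id`, `position`,
#'   `n_participants`, `order_index`.
#' @export
order_index_table <- function(events) {
  rows <- lapply(events, function(ev) {
    if (!ev$successful) return(NULL)
    n <- nrow(ev$joins)
    data.frame(event_id = ev$event_id,
               individual_id = ev$joins$individual_id,
               position = ev$joins$position,
               n_participants = n,
               order_index = order_index(ev$joins$position, n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Vocal-communication tallies and per-individual call rates
#'
#' Summarises a set of collective movements: how many were vocal (any
#' participant emitted at least one call), how often the initiator was among
#' the callers, and each individual's vocal frequency (total calls divided by
#' the number of events the individual participated in). Percentages are
#' reported to one decimal with largest-remainder reconciliation, so each
#' complementary pair sums to exactly 100.0.
#'
#' @param events list of `movement_event`s.
#' @param successful_only restrict to successful events (default).
#' @return List with `n_events`, `n_vocal`, `n_nonvocal`, `pct_vocal`,
#'   `pct_nonvocal`, `n_initiator_vocal`, `pct_initiator_vocal_of_vocal`,
#'   `pct_initiator_nonvocal_of_vocal`, and `rates`: a data.frame
#'   (`individual_id`, `total_calls`, `n_events_participated`,
#'   `vocal_frequency`).
#' @export
vocal_summary <- function(events, successful_only = TRUE) {
  if (successful_only) events <- Filter(function(e) e$successful, events)
  n <- length(events)
  if (n == 0) {
    return(list(n_events = 0L, n_vocal = 0L, n_nonvocal = 0L,
                pct_vocal = NA_real_, pct_nonvocal = NA_real_,
                n_initiator_vocal = 0L,
                pct_initiator_vocal_of_vocal = NA_real_,
                pct_initiator_nonvocal_of_vocal = NA_real_,
                rates = data.frame(individual_id = character(),
                                   total_calls = numeric(),
                                   n_events_participated = integer(),
                                   vocal_frequency = numeric())))
  }
  vocal <- vapply(events, event_is_vocal, logical(1))
  init_vocal <- vapply(events, function(e) {
    e$calls[[e$initiator_id]] > 0
  }, logical(1))
  pv <- percent_pair(sum(vocal), sum(!vocal))
  piv <- if (sum(vocal) > 0) {
    percent_pair(sum(init_vocal & vocal), sum(vocal & !init_vocal))
  } else c(NA_real_, NA_real_)
  ids <- sort(unique(unlist(lapply(events, function(e) e$joins$individual_id))))
  total_calls <- sapply(ids, function(id) {
    sum(vapply(events, function(e) {
      if (id %in% names(e$calls)) e$calls[[id]] else 0
    }, numeric(1)))
  })
  n_part <- sapply(ids, function(id) {
    sum(vapply(events, function(e) id %in% e$joins$individual_id, logical(1)))
  })
  list(
    n_events = n,
    n_vocal = sum(vocal),
    n_nonvocal = sum(!vocal),
    pct_vocal = pv[1], pct_nonvocal = pv[2],
    n_initiator_vocal = sum(init_vocal & vocal),
    pct_initiator_vocal_of_vocal = piv[1],
    pct_initiator_nonvocal_of_vocal = piv[2],
    rates = data.frame(individual_id = ids,
                       total_calls = as.numeric(total_calls),
                       n_events_participated = as.integer(n_part),
                       vocal_frequency = as.numeric(total_calls) / n_part,
                       stringsAsFactors = FALSE, row.names = NULL)
  )
}

#' Per-event participant counts split by vocal status
#'
#' @param events list of `movement_event`s.
#' @param successful_only restrict to successful events.
#' @return data.frame with `event_id`, `n_participants`, `vocal`.
#' @export
participant_counts <- function(events, successful_only = TRUE) {
  if (successful_only) events <- Filter(function(e) e$successful, events)
  data.frame(
    event_id = vapply(events, function(e) e$event_id, numeric(1)),
    n_participants = vapply(events, function(e) nrow(e$joins), numeric(1)),
    vocal = vapply(events, event_is_vocal, logical(1))
  )
}
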