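# Write a data.frame as CSV only if the serialized bytes differ from what is
# already on disk, so re-running an unchanged stage is a no-op.
write_if_changed <- function(df, path) {
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE, na = "")
  if (file.exists(path) &&
      identical(unname(tools::md5sum(tmp)), unname(tools::md5sum(path)))) {
    unlink(tmp)
    return(invisible(FALSE))
  }
  file.copy(tmp, path, overwrite = TRUE)
  unlink(tmp)
  invisible(TRUE)
}

#' Flatten movement events to a join log
#'
#' @param events list of `movement_event`s.
#' @return data.frame with columns `event_id`, `individual_id`,
#'   `join_time_s`, `n_calls`.
#' @export
events_to_log <- function(events) {
  rows <- lapply(events, function(e) {
    data.frame(event_id = e$event_id,
               individual_id = e$joins$individual_id,
               join_time_s = e$joins$join_time_s,
               n_calls = as.numeric(e$calls[e$joins$individual_id]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read a movement log into events
#'
#' If the log carries an `event_id` column, rows are grouped by it;
#' otherwise events are segmented from the join times by the five-minute
#' rule via [segment_events()].
#'
#' @param log data.frame (or CSV path) with columns `individual_id`,
#'   `join_time_s`, optionally `n_calls` and `event_id`.
#' @return List of `movement_event`s.
#' @export
read_movement_log <- function(log) {
  if (is.character(log)) log <- utils::read.csv(log, stringsAsFactors = FALSE)
  if (is.null(log$n_calls)) log$n_calls <- 0
  if (is.null(log$event_id)) return(segment_events(log))
  lapply(split(log, log$event_id), function(block) {
    block <- block[order(block$join_time_s), , drop = FALSE]
    first <- !duplicated(block$individual_id)
    calls <- tapply(block$n_calls,
                    factor(block$individual_id, levels = unique(block$individual_id)),
                    sum)
    joins <- data.frame(individual_id = block$individual_id[first],
                        join_time_s = block$join_time_s[first],
                        position = seq_len(sum(first)),
                        stringsAsFactors = FALSE)
    structure(list(event_id = block$event_id[1], joins = joins,
                   initiator_id = joins$individual_id[1], calls = calls,
                   successful = nrow(joins) >= 3),
              class = "movement_event")
  })
}
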