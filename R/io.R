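#' Write and read editor event logs
#'
#' Event logs are tab-delimited text with a header row and one row per
#' event; times are integer milliseconds. Columns: `participant`,
#' `language`, `t_ms`, `action` (`insert`, `backspace`, `delete_range`,
#' `cursor_move`, `mouse_move`, `shift`), `payload` (inserted character,
#' `start:end` range, or target position), `cursor_before`, `cursor_after`.
#' `write_event_log()` and [read_event_log()] round-trip exactly.
#'
#' @param events event data.frame (see [generate_session()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  cols <- c("participant", "language", "t_ms", "action", "payload",
            "cursor_before", "cursor_after")
  miss <- setdiff(cols, names(events))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  utils::write.table(events[cols], path, sep = "\t", quote = 5,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  .check_delim_file(path, 7L)
  ev <- utils::read.delim(path, sep = "\t", quote = "\"",
                          stringsAsFactors = FALSE,
                          colClasses = c(participant = NA,
                                         language = "character",
                                         t_ms = "integer",
                                         action = "character",
                                         payload = "character",
                                         cursor_before = "integer",
                                         cursor_after = "integer"))
  ev$payload[is.na(ev$payload)] <- ""
  bad_act <- !ev$action %in% c("insert", "backspace", "delete_range",
                               "cursor_move", "mouse_move", "shift")
  if (any(bad_act)) {
    stop("parse error at line ", which(bad_act)[1] + 1L,
         ": unknown action '", ev$action[which(bad_act)[1]], "'")
  }
  for (grp in split(seq_len(nrow(ev)),
                    interaction(ev$participant, ev$language, drop = TRUE))) {
    if (any(diff(ev$t_ms[grp]) < 0)) {
      bad <- grp[which(diff(ev$t_ms[grp]) < 0)[1] + 1L]
      stop("parse error at line ", bad + 1L, ": timestamps out of order")
    }
  }
  ev
}

#' Write and read fixation logs
#'
#' Fixation streams are tab-delimited text with columns `participant`,
#' `language`, `t_start_ms`, `duration_ms`, `x_px`, `y_px`, `on_prompt`.
#'
#' @param fixations fixation data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fixation_log <- function(fixations, path) {
  cols <- c("participant", "language", "t_start_ms", "duration_ms",
            "x_px", "y_px", "on_prompt")
  miss <- setdiff(cols, names(fixations))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  utils::write.table(fixations[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_fixation_log
#' @export
read_fixation_log <- function(path) {
  .check_delim_file(path, 7L)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(participant = NA,
                                   language = "character",
                                   t_start_ms = "integer",
                                   duration_ms = "integer",
                                   x_px = "numeric", y_px = "numeric",
                                   on_prompt = "logical"))
}

.check_delim_file <- function(path, n_fields) {
  if (!file.exists(path)) stop("no such file: ", path)
  cf <- utils::count.fields(path, sep = "\t", quote = "\"", blank.lines.skip = FALSE)
  bad <- which(!is.na(cf) & cf != n_fields)
  if (length(bad) > 0) {
    stop("parse error at line ", bad[1], ": expected ", n_fields,
         " fields, found ", cf[bad[1]])
  }
}
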