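#' Edit-session events
#'
#' A `click_event` is one interactive edit; an `edit_session` is an ordered
#' list of events plus the base [affinity_config()] that events inherit
#' from. Replaying a session is strictly order-dependent and deterministic,
#' which makes an edit history reproducible without a graphical interface.
#'
#' Event kinds: `smart_add` ([smart_click()]), `smart_remove`
#' ([anti_smart_click()]), `paint_add` and `paint_remove` ([paint()]).
#' Any [affinity_config()] field supplied to the event overrides the session
#' default for that event only; `brush_radius` applies to paint kinds.
#'
#' @param kind One of `"smart_add"`, `"smart_remove"`, `"paint_add"`,
#'   `"paint_remove"`.
#' @param coordinate Clicked voxel, 1-based `(slice, row, col)`.
#' @param brush_radius Brush radius in voxels (paint kinds only).
#' @param ... Per-event [affinity_config()] overrides (e.g. `sensitivity_a`,
#'   `scope`, `closing_radius`).
#' @return A `click_event` list.
#' @export
click_event <- function(kind, coordinate, brush_radius = NULL, ...) {
  kinds <- c("smart_add", "smart_remove", "paint_add", "paint_remove")
  if (!is.character(kind) || length(kind) != 1 || !kind %in% kinds)
    iris_abort(sprintf("kind must be one of: %s", paste(kinds, collapse = ", ")),
               "irisseg_usage_error")
  coordinate <- as.integer(coordinate)
  if (length(coordinate) != 3 || any(is.na(coordinate)))
    iris_abort("coordinate must be 3 integers (slice, row, col)",
               "irisseg_usage_error")
  overrides <- list(...)
  allowed <- c("sensitivity_a", "threshold", "connectivity", "scope",
               "comparison_mode", "closing_radius")
  bad <- setdiff(names(overrides), allowed)
  if (length(bad))
    iris_abort(sprintf("unknown event field(s): %s", paste(bad, collapse = ", ")),
               "irisseg_usage_error")
  structure(list(kind = kind, coordinate = coordinate,
                 brush_radius = brush_radius, overrides = overrides),
            class = "click_event")
}

#' @param events List of [click_event()]s.
#' @param config Base [affinity_config()] inherited by all events.
#' @rdname click_event
#' @export
edit_session <- function(events = list(), config = affinity_config()) {
  if (inherits(events, "click_event")) events <- list(events)
  if (!all(vapply(events, inherits, logical(1), "click_event")))
    iris_abort("events must be a list of click_event objects",
               "irisseg_usage_error")
  if (!inherits(config, "affinity_config"))
    iris_abort("config must be an affinity_config", "irisseg_usage_error")
  structure(list(events = events, config = config), class = "edit_session")
}

#' @export
print.edit_session <- function(x, ...) {
  cat(sprintf("<edit_session> %d event(s)\n", length(x$events)))
  for (i in seq_along(x$events)) {
    e <- x$events[[i]]
    cat(sprintf("  %2d. %-12s at (%s)%s\n", i, e$kind,
                paste(e$coordinate, collapse = ", "),
                if (length(e$overrides))
                  paste0(" [", paste(names(e$overrides), unlist(e$overrides),
                                     sep = "=", collapse = ", "), "]")
                else ""))
  }
  invisible(x)
}

# Merge per-event overrides into the base config.
event_config <- function(base, event) {
  if (!length(event$overrides)) return(base)
  args <- unclass(base)
  args[names(event$overrides)] <- event$overrides
  do.call(affinity_config, args)
}

#' Read or write a session script (JSON)
#'
#' The on-disk format is a JSON object with a `config` object (the base
#' [affinity_config()]) and an `events` array. Each event object has
#' `"kind"` and `"coordinate"` (1-based `[slice, row, col]`), optionally
#' `"brush_radius"` and any affinity-config field as a per-event override;
#' missing fields inherit the session defaults. A bare JSON array of event
#' objects is also accepted on read (defaults then apply throughout).
#'
#' @param path Path to a JSON session script.
#' @param session An [edit_session()].
#' @return `read_session()` returns an [edit_session()];
#'   `write_session()` returns `path` invisibly.
#' @export
read_session <- function(path) {
  if (!file.exists(path))
    iris_abort(sprintf("session file not found: %s", path), "irisseg_io_error")
  js <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) iris_abort(
                   sprintf("invalid JSON in %s: %s", path, conditionMessage(e)),
                   "irisseg_io_error"))
  if (is.list(js) && !is.null(js$events)) {
    cfg_fields <- js$config
    raw_events <- js$events
  } else {
    cfg_fields <- NULL
    raw_events <- js
  }
  config <- if (is.null(cfg_fields)) affinity_config()
            else do.call(affinity_config, cfg_fields)
  events <- lapply(seq_along(raw_events), function(i) {
    ev <- raw_events[[i]]
    if (is.null(ev$kind) || is.null(ev$coordinate))
      iris_abort(sprintf("event %d: 'kind' and 'coordinate' are required", i),
                 "irisseg_usage_error")
    extras <- ev[setdiff(names(ev), c("kind", "coordinate", "brush_radius"))]
    do.call(click_event, c(list(kind = ev$kind,
                                coordinate = unlist(ev$coordinate),
                                brush_radius = ev$brush_radius),
                           extras))
  })
  edit_session(events, config)
}

#' @rdname read_session
#' @export
write_session <- function(session, path) {
  if (!inherits(session, "edit_session"))
    iris_abort("session must be an edit_session", "irisseg_usage_error")
  events <- lapply(session$events, function(e) {
    c(list(kind = e$kind, coordinate = e$coordinate),
      if (!is.null(e$brush_radius)) list(brush_radius = e$brush_radius),
      e$overrides)
  })
  obj <- list(config = unclass(session$config), events = events)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deterministically replay an edit session
#'
#' Applies the session's events strictly in order, each event's output mask
#' feeding the next. The per-event audit trail (voxel counts before/after
#' and the delta) is attached as attribute `log` (a data frame). The first
#' invalid event aborts the replay with its index in the error message.
#'
#' @param volume A normalized [image_volume()].
#' @param initial_mask The starting [binary_mask()] (e.g. the automated
#'   level-set output).
#' @param session An [edit_session()].
#' @return The final [binary_mask()] with attribute `log`.
#' @export
replay_session <- function(volume, initial_mask, session) {
  if (!inherits(session, "edit_session"))
    iris_abort("session must be an edit_session", "irisseg_usage_error")
  if (!inherits(volume, "iris_volume") || !inherits(initial_mask, "iris_mask"))
    iris_abort("expected an iris_volume and an iris_mask",
               "irisseg_usage_error")
  check_congruent(volume, initial_mask, "volume and initial_mask")
  mask <- initial_mask
  n <- length(session$events)
  log <- data.frame(event = integer(n), kind = character(n),
                    voxels_before = integer(n), voxels_after = integer(n),
                    delta = integer(n))
  for (i in seq_len(n)) {
    e <- session$events[[i]]
    before <- sum(mask$data)
    mask <- tryCatch(
      apply_event(volume, mask, e, session$config),
      irisseg_error = function(err) iris_abort(
        sprintf("event %d (%s): %s", i, e$kind, conditionMessage(err)),
        "irisseg_usage_error"))
    after <- sum(mask$data)
    log[i, ] <- list(i, e$kind, before, after, after - before)
  }
  attr(mask, "log") <- log
  mask
}

apply_event <- function(volume, mask, e, base_config) {
  switch(e$kind,
    smart_add = smart_click(volume, mask, e$coordinate,
                            event_config(base_config, e)),
    smart_remove = anti_smart_click(volume, mask, e$coordinate,
                                    event_config(base_config, e)),
    paint_add = paint(mask, e$coordinate,
                      if (is.null(e$brush_radius)) 0 else e$brush_radius,
                      "add"),
    paint_remove = paint(mask, e$coordinate,
                         if (is.null(e$brush_radius)) 0 else e$brush_radius,
                         "remove"))
}
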