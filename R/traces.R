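# Product traces: all events of one tag-activation episode, in time order,
# with a derived disposition.

new_product_trace <- function(product_id, tag_id, events, terminal, disposition) {
  structure(
    list(
      product_id = product_id,
      tag_id = tag_id,
      activation_time = events$timestamp[events$event_type == "activation"][1],
      activation_location = events$location_id[events$event_type == "activation"][1],
      events = events,
      readings = events[events$event_type == "reading", , drop = FALSE],
      terminal = terminal,
      disposition = disposition
    ),
    class = "product_trace"
  )
}

#' Build per-product traces from a tag event stream
#'
#' Groups events by tag, splits each tag's history at `activation` events into
#' episodes (a reused tag yields one trace per activation), and derives a
#' disposition for every episode:
#'
#' * `never_left` - no event was observed outside the blood transfusion
#'   laboratory (BTL);
#' * `transfused` - the episode ends with a `stopbox_drop`;
#' * `returned` - the episode ends with a `deactivation` at the BTL, or (when
#'   the deactivation was never registered) its last observed event is back at
#'   the BTL after having left it;
#' * `lost` - the tag fell silent away from the BTL with no terminal event.
#'
#' @param events An event tibble (see [read_events()]); events must be
#'   time-sorted within each tag, every tag's history must start with an
#'   activation, and an episode may contain at most one terminal event.
#' @param facility A [facility_map()].
#' @return A list of `product_trace` objects.
#' @export
build_traces <- function(events, facility) {
  validate_events(events, facility)
  if (nrow(events) == 0) return(list())
  events <- dplyr::arrange(events, .data$tag_id, .data$timestamp)
  btl <- btl_id(facility)
  traces <- list()
  for (tag_events in split(events, events$tag_id)) {
    act_idx <- which(tag_events$event_type == "activation")
    if (length(act_idx) == 0 || act_idx[1] != 1) {
      stop("tag ", tag_events$tag_id[1],
           ": events observed before any activation", call. = FALSE)
    }
    episode_id <- findInterval(seq_len(nrow(tag_events)), act_idx)
    for (ep in split(tag_events, episode_id)) {
      traces[[length(traces) + 1]] <- build_one_trace(ep, btl)
    }
  }
  names(traces) <- vapply(traces, function(tr) tr$product_id, character(1))
  traces
}

build_one_trace <- function(ep, btl) {
  term_idx <- which(ep$event_type %in% c("deactivation", "stopbox_drop"))
  if (length(term_idx) > 1) {
    stop("tag ", ep$tag_id[1], ": more than one terminal event in an episode",
         call. = FALSE)
  }
  terminal <- NULL
  if (length(term_idx) == 1) {
    if (term_idx != nrow(ep)) {
      stop("tag ", ep$tag_id[1], ": events observed after the terminal event",
           call. = FALSE)
    }
    terminal <- list(
      type = ep$event_type[term_idx],
      time = ep$timestamp[term_idx],
      location_id = ep$location_id[term_idx]
    )
  }
  outside <- any(ep$location_id != btl)
  last_loc <- ep$location_id[nrow(ep)]
  disposition <-
    if (!outside) {
      "never_left"
    } else if (!is.null(terminal) && terminal$type == "stopbox_drop") {
      "transfused"
    } else if (!is.null(terminal) && terminal$location_id == btl) {
      "returned"
    } else if (is.null(terminal) && last_loc == btl) {
      "returned" # back at the BTL but the deactivation was never registered
    } else {
      "lost"
    }
  product_id <- ep$product_id[ep$product_id != ""][1]
  if (is.na(product_id)) product_id <- paste0(ep$tag_id[1], "-ep1")
  new_product_trace(product_id, ep$tag_id[1], ep, terminal, disposition)
}

#' @export
print.product_trace <- function(x, ...) {
  cat(sprintf("<product_trace %s> tag %s, %d events (%d readings), disposition %s\n",
              x$product_id, x$tag_id, nrow(x$events), nrow(x$readings),
              x$disposition))
  invisible(x)
}

#' @export
format.product_trace <- function(x, ...) {
  sprintf("<product_trace %s: %s>", x$product_id, x$disposition)
}
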