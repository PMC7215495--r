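# Daily tailoring loop: one unsent message per user per day, ratings fed
# back into cold-start user-factor inference, hard caps of 30 messages
# within a 65-day window.

#' Create a per-user schedule state
#'
#' Tracks which messages were sent, the current study day, and the
#' activity window: at most `max_messages` sends within `max_days` days;
#' the state deactivates as soon as either limit is reached.
#'
#' @param user_id user identifier.
#' @param max_messages message cap (default 30).
#' @param max_days day horizon (default 65).
#' @return object of class `schedule_state`.
#' @export
schedule_state <- function(user_id, max_messages = 30, max_days = 65) {
  structure(list(user_id = user_id, sent = character(0),
                 day_index = 1L, messages_sent = 0L,
                 max_messages = as.integer(max_messages),
                 max_days = as.integer(max_days), active = TRUE),
            class = "schedule_state")
}

#' Select and record the next message for a user
#'
#' Ranks the unsent messages in the bank with [rank_messages()] (ties
#' broken by ascending message id) and records the top one as sent.
#'
#' @param state a [schedule_state()].
#' @param model fitted recommender.
#' @param view the user's current `user_view`.
#' @param bank a [message_bank()].
#' @return list with updated `state` and `message_id` (`NA` with the state
#'   deactivated when the user is done or the bank exhausted).
#' @export
next_message <- function(state, model, view, bank) {
  stopifnot(inherits(state, "schedule_state"))
  if (!state$active) return(list(state = state, message_id = NA_character_))
  candidates <- setdiff(bank$message_id, state$sent)
  if (!length(candidates)) {
    state$active <- FALSE
    return(list(state = state, message_id = NA_character_))
  }
  top <- rank_messages(model, view, candidates)$message_id[1]
  state$sent <- c(state$sent, top)
  state$messages_sent <- state$messages_sent + 1L
  if (state$messages_sent >= state$max_messages) state$active <- FALSE
  list(state = state, message_id = top)
}

#' Ingest a reply rating and refresh the user's factors
#'
#' A present rating (1..5) grows the user's rating set and re-runs
#' [infer_user_factors()] against the frozen model; a missing rating (the
#' message was sent but never rated) changes nothing. Rating a message
#' that was never sent is an error.
#'
#' @param state the user's [schedule_state()] (read-only here).
#' @param model fitted recommender.
#' @param view the user's current `user_view`.
#' @param message_id the rated message.
#' @param value rating 1..5, or `NA` for no reply.
#' @param seed RNG seed for the factor re-inference.
#' @return updated `user_view` (identical to `view` when `value` is `NA`).
#' @export
ingest_rating <- function(state, model, view, message_id, value, seed = 1) {
  if (!message_id %in% state$sent) {
    stop_invalid("cannot ingest a rating for unsent message: %s", message_id)
  }
  if (is.na(value)) return(view)
  if (value < 1 || value > 5) stop_invalid("rating value outside 1..5")
  ratings <- view$ratings
  ratings[message_id] <- value
  infer_user_factors(model, ratings, seed = seed)
}

#' Advance the schedule by one day
#'
#' Deactivates the state when the day horizon is reached (or the message
#' cap was already hit). Advancing an inactive state is a warning no-op.
#'
#' @param state a [schedule_state()].
#' @return updated state.
#' @export
advance_day <- function(state) {
  if (!state$active) {
    warning("advance_day on an inactive schedule: no-op")
    return(state)
  }
  if (state$day_index >= state$max_days) {
    state$active <- FALSE
  } else {
    state$day_index <- state$day_index + 1L
  }
  state
}

#' Simulate a full scheduling run for one user
#'
#' Drives the daily loop against a rating policy: on each send day the
#' top-ranked unsent message goes out and, with probability `rate_prob`,
#' the user replies with `true_rating(message_id)` (rounded and clipped to
#' 1..5), which immediately updates the user's factors. `send_days`
#' selects which study days carry a send (default: every day), so gapped
#' cadences still terminate within the window.
#'
#' @param model fitted recommender.
#' @param bank a [message_bank()].
#' @param true_rating function `message_id -> numeric` giving the user's
#'   true preference.
#' @param rate_prob probability a sent message gets rated (default 1).
#' @param reply_noise SD of the noise added to the true preference before
#'   rounding the reply to the Likert grid (default 0: deterministic
#'   replies).
#' @param send_days integer days on which sends happen (default `1:65`).
#' @param max_messages,max_days window caps (defaults 30 / 65).
#' @param seed RNG seed.
#' @return data frame of sends: `day_index`, `message_id`, `predicted`,
#'   `rated`, `value`; attribute `state` carries the final state.
#' @export
simulate_user_schedule <- function(model, bank, true_rating, rate_prob = 1,
                                   reply_noise = 0, send_days = 1:65,
                                   max_messages = 30, max_days = 65,
                                   seed = 1) {
  set.seed(seed)
  state <- schedule_state("sim", max_messages, max_days)
  view <- suppressWarnings(infer_user_factors(model, stats::setNames(numeric(0), character(0))))
  log <- list()
  repeat {
    if (state$active && state$day_index %in% send_days) {
      nx <- next_message(state, model, view, bank)
      state <- nx$state
      if (!is.na(nx$message_id)) {
        pred <- predict_for_user(model, view, nx$message_id)
        rated <- stats::runif(1) < rate_prob
        value <- NA_real_
        if (rated) {
          value <- clip_rating(round(true_rating(nx$message_id) +
                                       stats::rnorm(1, 0, reply_noise)))
          view <- ingest_rating(state, model, view, nx$message_id, value,
                                seed = seed + state$messages_sent)
        }
        log[[length(log) + 1]] <- data.frame(
          day_index = state$day_index, message_id = nx$message_id,
          predicted = unname(pred), rated = rated, value = value,
          stringsAsFactors = FALSE)
      }
    }
    if (!state$active) break
    state <- advance_day(state)
    if (!state$active) break
  }
  out <- if (length(log)) do.call(rbind, log) else
    data.frame(day_index = integer(0), message_id = character(0),
               predicted = numeric(0), rated = logical(0),
               value = numeric(0))
  attr(out, "state") <- state
  out
}
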