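# Domain types and on-disk formats: message banks (JSON), user profiles,
# rating events and trial records (CSV). All readers validate invariants and
# all writers round-trip exactly.

MESSAGE_SOURCES <- c("expert", "peer")

#' Stages-of-change readiness levels
#'
#' The five ordered readiness-to-quit stages collected at registration, from
#' precontemplation through having already quit.
#' @export
READINESS_STAGES <- c(
  "not_thinking_of_quitting",
  "thinking_of_quitting",
  "set_a_quit_date",
  "quit_today",
  "already_quit"
)

AGE_BANDS <- c("19-34", "35-44", "45+")

PROFILE_COLUMNS <- c(
  "user_id", "group", "gender", "age_band", "education", "ethnicity",
  "allow_smoking_home", "visited_cessation_site", "past_year_quit_attempt",
  "smoking_status", "readiness"
)

TRIAL_COLUMNS <- c(
  "user_id", "group", "website_visits",
  paste0("impact_", 1:7), "quit_30day"
)

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Construct a validated message bank
#'
#' A message bank is a data frame with one row per persuasive message:
#' an opaque unique `message_id`, the message `text`, its provenance
#' `source` (`"expert"` or `"peer"`), and a list-column `tags` of content
#' labels (e.g. reasons-to-quit, tips-strategies, nrt).
#'
#' @param df data frame with columns `message_id`, `text`, `source` and
#'   optionally `tags` (character vector per row, or a single
#'   semicolon-separated string).
#' @return data frame of class `message_bank`.
#' @export
message_bank <- function(df) {
  required <- c("message_id", "text", "source")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_invalid("message bank is missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  df$message_id <- as.character(df$message_id)
  df$text <- as.character(df$text)
  df$source <- as.character(df$source)
  if (is.null(df[["tags"]])) {
    df$tags <- replicate(nrow(df), character(0), simplify = FALSE)
  } else if (!is.list(df$tags)) {
    df$tags <- lapply(strsplit(as.character(df$tags), ";", fixed = TRUE),
                      function(x) x[nzchar(x)])
  }
  dup <- unique(df$message_id[duplicated(df$message_id)])
  if (length(dup)) {
    stop_invalid("duplicate message_id(s): %s", paste(dup, collapse = ", "))
  }
  empty <- df$message_id[!nzchar(trimws(df$text))]
  if (length(empty)) {
    stop_invalid("empty text for message(s): %s", paste(empty, collapse = ", "))
  }
  bad_src <- df$message_id[!df$source %in% MESSAGE_SOURCES]
  if (length(bad_src)) {
    stop_invalid("source must be one of {expert, peer}; offending message(s): %s",
                 paste(bad_src, collapse = ", "))
  }
  structure(df[, c("message_id", "text", "source", "tags")],
            class = c("message_bank", "data.frame"))
}

#' Read a message bank from disk
#'
#' Accepts a JSON array of `{message_id, text, source, tags}` objects or a
#' CSV with the same columns (`tags` semicolon-separated). An empty file
#' yields an empty bank.
#'
#' @param path file path (`.json` or `.csv`).
#' @return a [message_bank()].
#' @export
load_message_bank <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(raw) == 0) {
      raw <- data.frame(message_id = character(0), text = character(0),
                        source = character(0))
    }
  } else {
    raw <- utils::read.csv(path, colClasses = "character")
  }
  message_bank(as.data.frame(raw))
}

#' Write a message bank to JSON
#'
#' Round-trips exactly through [load_message_bank()].
#' @param bank a [message_bank()].
#' @param path output path.
#' @export
write_message_bank <- function(bank, path) {
  out <- data.frame(message_id = bank$message_id, text = bank$text,
                    source = bank$source, stringsAsFactors = FALSE)
  out$tags <- unname(bank$tags)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Construct validated user profiles
#'
#' One row per participant with the baseline fields: comparison `group`
#' (open vocabulary; trial contrasts require exactly two), gender, ordered
#' age band (`19-34`, `35-44`, `45+`), education (`other` vs
#' `advanced_degree`), ethnicity, whether smoking is allowed at home,
#' whether a cessation website was ever visited, a past-year quit attempt,
#' current smoking status, and the five-stage readiness-to-quit measure.
#'
#' @param df data frame carrying all profile columns.
#' @return data frame of class `user_profiles`.
#' @export
user_profiles <- function(df) {
  missing_cols <- setdiff(PROFILE_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop_invalid("profiles missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  df$user_id <- as.character(df$user_id)
  dup <- unique(df$user_id[duplicated(df$user_id)])
  if (length(dup)) stop_invalid("duplicate user_id(s): %s", paste(dup, collapse = ", "))
  for (col in c("allow_smoking_home", "visited_cessation_site",
                "past_year_quit_attempt")) {
    df[[col]] <- as.logical(df[[col]])
  }
  bad <- df$user_id[!df$readiness %in% READINESS_STAGES]
  if (length(bad)) {
    stop_invalid("readiness must be one of the five stages; offending user(s): %s",
                 paste(bad, collapse = ", "))
  }
  bad_age <- df$user_id[!df$age_band %in% AGE_BANDS]
  if (length(bad_age)) {
    stop_invalid("unknown age_band for user(s): %s", paste(bad_age, collapse = ", "))
  }
  structure(df[, PROFILE_COLUMNS],
            class = c("user_profiles", "data.frame"))
}

#' @rdname user_profiles
#' @param path CSV path.
#' @export
load_profiles <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  user_profiles(utils::read.csv(path, colClasses = "character"))
}

#' @rdname user_profiles
#' @param profiles a `user_profiles` frame to serialize.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(as.data.frame(profiles), path, row.names = FALSE)
  invisible(path)
}

validate_events <- function(events, bank = NULL, roster = NULL) {
  required <- c("user_id", "message_id", "day_index", "value")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols)) {
    stop_invalid("rating events missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  events$user_id <- as.character(events$user_id)
  events$message_id <- as.character(events$message_id)
  events$day_index <- as.integer(events$day_index)
  events$value <- suppressWarnings(as.numeric(events$value))

  if (nrow(events)) {
    bad_day <- which(is.na(events$day_index) | events$day_index < 1L)
    if (length(bad_day)) {
      stop_invalid("day_index must be an integer >= 1 (row %s)", bad_day[1])
    }
    obs <- !is.na(events$value)
    bad_val <- which(obs & (events$value < 1 | events$value > 5 |
                              events$value != round(events$value)))
    if (length(bad_val)) {
      stop_invalid("rating value outside 1..5 at row %s (value=%s)",
                   bad_val[1], events$value[bad_val[1]])
    }
    key_um <- paste(events$user_id, events$message_id)
    if (anyDuplicated(key_um)) {
      stop_invalid("duplicate (user, message) rating: %s",
                   key_um[which(duplicated(key_um))[1]])
    }
    key_ud <- paste(events$user_id, events$day_index)
    if (anyDuplicated(key_ud)) {
      stop_invalid("more than one message for (user, day): %s",
                   key_ud[which(duplicated(key_ud))[1]])
    }
    if (!is.null(bank)) {
      unknown <- setdiff(events$message_id, bank$message_id)
      if (length(unknown)) {
        stop_invalid("rating references unknown message_id(s): %s",
                     paste(unknown, collapse = ", "))
      }
    }
    if (!is.null(roster)) {
      roster_ids <- if (is.data.frame(roster)) roster$user_id else roster
      unknown <- setdiff(events$user_id, roster_ids)
      if (length(unknown)) {
        stop_invalid("rating references unknown user_id(s): %s",
                     paste(unknown, collapse = ", "))
      }
    }
  }
  events[, required]
}

#' Build a sparse rating matrix from rating events
#'
#' Users-by-messages Likert matrix; cells never rated are `NA` (never
#' zero-filled — 0 is outside the 1..5 scale and would corrupt means).
#' Events with a missing `value` record a message that was sent but not
#' rated; they contribute no observed cell.
#'
#' @param events data frame of rating events
#'   (`user_id`, `message_id`, `day_index`, `value`).
#' @param users,items optional orderings / supersets of ids; defaults to the
#'   sorted ids present in `events`.
#' @return object of class `rating_matrix`: list with `users`, `items`, and
#'   numeric matrix `R` (`NA` = unobserved).
#' @export
rating_matrix <- function(events, users = NULL, items = NULL) {
  events <- validate_events(events)
  if (is.null(users)) users <- sort(unique(events$user_id))
  if (is.null(items)) items <- sort(unique(events$message_id))
  users <- as.character(users); items <- as.character(items)
  R <- matrix(NA_real_, length(users), length(items),
              dimnames = list(users, items))
  obs <- events[!is.na(events$value), , drop = FALSE]
  if (nrow(obs)) {
    R[cbind(match(obs$user_id, users), match(obs$message_id, items))] <- obs$value
  }
  structure(list(users = users, items = items, R = R),
            class = "rating_matrix")
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf("rating_matrix: %d users x %d items, %d observed (density %.3f)\n",
              length(x$users), length(x$items), sum(!is.na(x$R)),
              rating_density(x)))
  invisible(x)
}

#' Fraction of observed cells in a rating matrix
#' @param matrix a [rating_matrix()].
#' @export
rating_density <- function(matrix) {
  sum(!is.na(matrix$R)) / (length(matrix$users) * length(matrix$items))
}

#' Read rating events and assemble the rating matrix
#'
#' CSV columns `user_id,message_id,day_index,value`; an empty `value` field
#' encodes a sent-but-unrated message. Ids are checked against `bank` and
#' `roster` when supplied.
#'
#' @param path CSV path.
#' @param bank optional [message_bank()] for id validation.
#' @param roster optional `user_profiles` (or character vector of user ids).
#' @return list with `events` (data frame) and `matrix` ([rating_matrix()]).
#' @export
load_ratings <- function(path, bank = NULL, roster = NULL) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  raw <- utils::read.csv(path, colClasses = c(user_id = "character",
                                              message_id = "character"))
  events <- validate_events(raw, bank = bank, roster = roster)
  users <- if (!is.null(roster)) {
    if (is.data.frame(roster)) roster$user_id else roster
  } else NULL
  items <- if (!is.null(bank)) bank$message_id else NULL
  list(events = events, matrix = rating_matrix(events, users, items))
}

#' Write rating events to CSV
#'
#' Missing ratings are written as an empty field, never 0, and restored as
#' `NA` on load; `load_ratings(write_ratings(x))` reproduces `x` exactly.
#'
#' @param events rating-event data frame.
#' @param path output path.
#' @export
write_ratings <- function(events, path) {
  events <- validate_events(events)
  utils::write.csv(events, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Trial outcome records
#'
#' One row per participant: group, website visit count, the seven
#' intervention-impact Likert items (in collection order: talk to a doctor,
#' get support, list reasons to quit, behavioral strategies, use NRT, set a
#' quit date, quit smoking) and the 30-day cessation flag ("stopped smoking
#' for one day or longer"). Impact items and the cessation flag may be
#' missing (lost to follow-up); visits are a nonnegative count.
#'
#' @param df data frame with columns `user_id`, `group`, `website_visits`,
#'   `impact_1`..`impact_7`, `quit_30day`.
#' @return data frame of class `trial_records`.
#' @export
trial_records <- function(df) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop_invalid("trial records missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  df$user_id <- as.character(df$user_id)
  df$group <- as.character(df$group)
  df$website_visits <- as.integer(df$website_visits)
  if (any(is.na(df$website_visits)) || any(df$website_visits < 0)) {
    stop_invalid("website_visits must be nonnegative integers")
  }
  for (j in 1:7) {
    col <- paste0("impact_", j)
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(v) & (v < 1 | v > 5 | v != round(v)))
    if (length(bad)) {
      stop_invalid("%s outside 1..5 for user %s", col, df$user_id[bad[1]])
    }
    df[[col]] <- v
  }
  df$quit_30day <- as.logical(df$quit_30day)
  structure(df[, TRIAL_COLUMNS], class = c("trial_records", "data.frame"))
}

#' @rdname trial_records
#' @param path CSV path.
#' @export
load_trial <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  trial_records(utils::read.csv(path, colClasses = c(user_id = "character",
                                                     group = "character")))
}

#' @rdname trial_records
#' @param records a `trial_records` frame to serialize.
#' @export
write_trial <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}
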