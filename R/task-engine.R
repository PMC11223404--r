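# WCST administration and scoring: rule sequence, feedback, category
# criterion, termination, and the four outcome metrics (perseveration
# errors, non-perseveration errors, categories obtained, correct sorts).

#' Administration configuration
#'
#' Heaton-style administration: the required sorting dimension starts at
#' colour and cycles colour -> shape -> number; after `criterion_correct`
#' consecutive correct sorts a category is complete and the rule advances
#' covertly; the session ends when `max_categories` categories are complete
#' or the deck is exhausted.
#'
#' @param deck A deck from [build_deck()], or `NULL` to build the standard
#'   128-card deck inside [administer()] using the session seed.
#' @param rule_sequence Character vector of dimensions cycled over as rules.
#' @param criterion_correct Consecutive correct sorts completing a category.
#' @param max_categories Categories after which the session terminates.
#' @return A list of class `wcst_admin_config`.
#' @export
administration_config <- function(deck = NULL,
                                  rule_sequence = c("color", "shape", "number"),
                                  criterion_correct = 10L,
                                  max_categories = 6L) {
  if (length(rule_sequence) < 1 ||
      !all(rule_sequence %in% wcst_dimensions())) {
    rlang::abort("`rule_sequence` must be a nonempty vector of dimensions.",
                 class = "wcstsim_config_error")
  }
  if (criterion_correct < 1 || max_categories < 1) {
    rlang::abort("`criterion_correct` and `max_categories` must be >= 1.",
                 class = "wcstsim_config_error")
  }
  structure(
    list(
      deck = deck,
      rule_sequence = match(rule_sequence, wcst_dimensions()),
      criterion_correct = as.integer(criterion_correct),
      max_categories = as.integer(max_categories)
    ),
    class = "wcst_admin_config"
  )
}

#' Score a single sort
#'
#' A sort is correct when the chosen dimension equals the current rule. An
#' incorrect sort is a perseveration error (PE) when the chosen dimension is
#' the immediately preceding rule — the previously correct strategy
#' maintained although feedback now marks it incorrect — and otherwise a
#' non-perseveration error (NPE). Before the first rule change no previous
#' rule exists, so no error can be perseverative.
#'
#' @param chosen_dimension,rule_at_trial Dimension names (or indices).
#' @param previous_rule Dimension name/index, or `NA`/`NULL` before the
#'   first rule change.
#' @return `"correct"`, `"PE"` or `"NPE"`.
#' @examples
#' score_trial("color", "shape", "color")  # PE
#' score_trial("number", "shape", "color") # NPE
#' score_trial("shape", "shape", "color")  # correct
#' @export
score_trial <- function(chosen_dimension, rule_at_trial, previous_rule = NA) {
  to_idx <- function(x) {
    if (is.null(x) || (length(x) == 1 && is.na(x))) return(NA_integer_)
    if (is.character(x)) match(x, wcst_dimensions()) else as.integer(x)
  }
  chosen <- to_idx(chosen_dimension)
  rule <- to_idx(rule_at_trial)
  prev <- to_idx(previous_rule)
  if (chosen == rule) return("correct")
  if (!is.na(prev) && chosen == prev) return("PE")
  "NPE"
}

#' Administer the WCST to an agent
#'
#' Runs a complete session: each trial the agent deliberates and sorts the
#' next card, receives feedback, and updates its working memory; the engine
#' tracks the consecutive-correct run, advances the rule after each
#' completed category, and stops after `max_categories` categories or when
#' the deck is exhausted. All randomness (deck order when the config carries
#' no deck, activation noise, tie-breaking) is drawn from a stream seeded by
#' `rng_seed`, so a session is exactly reproducible.
#'
#' @param agent A `wcst_agent` from [make_agent()] (or one of the reference
#'   agents, [oracle_agent()] and friends).
#' @param config An [administration_config()].
#' @param rng_seed Integer session seed.
#' @param keep_log Keep the per-trial log (default `TRUE`); grid runs drop
#'   it to save memory.
#' @return A list of class `wcst_session` with elements `pe`, `npe`,
#'   `categories`, `correct_sorts`, `trials_administered`, `seed`, and
#'   `trial_log` (a tibble, or `NULL` when `keep_log = FALSE`).
#' @examples
#' s <- administer(oracle_agent(), administration_config(), rng_seed = 1)
#' s$correct_sorts; s$categories
#' @export
administer <- function(agent, config = administration_config(),
                       rng_seed = 1L, keep_log = TRUE) {
  if (!inherits(agent, "wcst_agent")) {
    rlang::abort("`agent` must be a `wcst_agent`.",
                 class = "wcstsim_protocol_error")
  }
  withr::local_seed(as.integer(rng_seed))

  deck <- config$deck
  if (is.null(deck)) {
    deck <- build_deck(set_count = 2L,
                       order_seed = sample.int(.Machine$integer.max, 1L))
  }
  n_cards <- nrow(deck)
  rule_seq <- config$rule_sequence
  crit <- config$criterion_correct
  max_cat <- config$max_categories

  state <- agent$state
  type <- agent$type
  rule_pos <- 1L
  rule <- rule_seq[1L]
  prev_rule <- NA_integer_
  run <- 0L
  pe <- 0L; npe <- 0L; correct <- 0L; categories <- 0L
  chosen_v <- integer(n_cards); rule_v <- integer(n_cards)
  prev_v <- integer(n_cards); score_v <- character(n_cards)
  t <- 0L

  while (t < n_cards) {
    t <- t + 1L
    chosen <- switch(type,
      oracle = rule,
      perseverator = agent$dimension,
      scripted = {
        if (t > length(agent$script)) {
          rlang::abort("Scripted agent ran out of choices.",
                       class = "wcstsim_protocol_error")
        }
        agent$script[t]
      },
      ef = {
        d <- deliberate(state, agent$profile, agent$cycle_budget,
                        agent$constants)
        state$activation <- d$activation
        d$choice
      }
    )
    if (is.null(chosen) || is.na(chosen)) {
      rlang::abort("Agent failed to return a dimension.",
                   class = "wcstsim_protocol_error")
    }
    if (chosen == rule) {
      sc <- "correct"
      correct <- correct + 1L
      run <- run + 1L
    } else {
      sc <- if (!is.na(prev_rule) && chosen == prev_rule) "PE" else "NPE"
      if (sc == "PE") pe <- pe + 1L else npe <- npe + 1L
      run <- 0L
    }
    if (type == "ef") {
      state <- process_feedback(state, chosen,
                                if (sc == "correct") "correct" else "incorrect",
                                agent$profile, agent$constants)
    }
    chosen_v[t] <- chosen; rule_v[t] <- rule
    prev_v[t] <- prev_rule; score_v[t] <- sc
    if (run == crit) {
      categories <- categories + 1L
      prev_rule <- rule
      rule_pos <- rule_pos %% length(rule_seq) + 1L
      rule <- rule_seq[rule_pos]
      run <- 0L
      if (categories == max_cat) break
    }
  }

  log <- NULL
  if (keep_log) {
    dims <- wcst_dimensions()
    log <- tibble::tibble(
      trial = seq_len(t),
      color = deck$color[seq_len(t)],
      shape = deck$shape[seq_len(t)],
      number = deck$number[seq_len(t)],
      chosen_dimension = dims[chosen_v[seq_len(t)]],
      rule = dims[rule_v[seq_len(t)]],
      previous_rule = dims[prev_v[seq_len(t)]],
      feedback = ifelse(score_v[seq_len(t)] == "correct",
                        "correct", "incorrect"),
      score = score_v[seq_len(t)]
    )
  }
  structure(
    list(pe = pe, npe = npe, categories = categories,
         correct_sorts = correct, trials_administered = t,
         seed = as.integer(rng_seed), trial_log = log),
    class = "wcst_session"
  )
}

#' @export
print.wcst_session <- function(x, ...) {
  cat(sprintf(
    "<wcst_session> trials=%d  PE=%d  NPE=%d  categories=%d  correct=%d  (seed %d)\n",
    x$trials_administered, x$pe, x$npe, x$categories, x$correct_sorts, x$seed
  ))
  invisible(x)
}

#' Tidy a session's trial log
#'
#' @param x A `wcst_session`.
#' @param ... Unused.
#' @return The per-trial log as a tibble (`tidy()`), or a one-row summary of
#'   the session outcomes (`glance()`).
#' @export
tidy.wcst_session <- function(x, ...) {
  if (is.null(x$trial_log)) {
    rlang::abort("Session was run with `keep_log = FALSE`.")
  }
  x$trial_log
}

#' @rdname tidy.wcst_session
#' @export
glance.wcst_session <- function(x, ...) {
  tibble::tibble(
    pe = x$pe, npe = x$npe, categories = x$categories,
    correct_sorts = x$correct_sorts,
    trials = x$trials_administered, seed = x$seed
  )
}

#' Write a session to disk
#'
#' The trial log goes to CSV and the outcome summary to a single-object
#' JSON file.
#'
#' @param session A `wcst_session`.
#' @param log_path,summary_path Output file paths (`NULL` skips that file).
#' @return `session`, invisibly.
#' @export
write_session <- function(session, log_path = NULL, summary_path = NULL) {
  if (!is.null(log_path)) {
    readr::write_csv(tidy.wcst_session(session), log_path)
  }
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      as.list(glance.wcst_session(session)),
      summary_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(session)
}
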