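# Cycle-limited cognitive agent: interactive-activation deliberation over the
# three candidate sorting dimensions, with monitoring/updating, strategy
# evaluation/shifting, and inhibition parameterised at discrete ability levels.

#' Executive-function ability levels
#'
#' Tabulated parameter values for each ability level of the three executive
#' functions. Updating and inhibition are gain/strength values at four
#' levels; shifting ranks candidate strategies with whole numbers and so has
#' three levels, expressed as a (toward, away) bias pair.
#'
#' @return A named list with elements `updating`, `shifting`, `inhibition`.
#'   `updating` and `inhibition` are named numeric vectors; `shifting` is a
#'   named list of length-2 numeric vectors `c(toward, away)`.
#' @export
ef_levels <- function() {
  list(
    updating = c(very_poor = 0.07, poor = 0.12, medium = 0.24, high = 0.37),
    shifting = list(
      poor = c(0, 0),
      medium = c(1, -1),
      high = c(2, -2)
    ),
    inhibition = c(very_poor = 0.10, poor = 0.22, medium = 0.44, high = 0.65)
  )
}

#' Construct an executive-function profile
#'
#' One of the 48 level combinations (4 updating x 3 shifting x 4 inhibition),
#' or an arbitrary combination of the tabulated levels.
#'
#' @param updating One of `"very_poor"`, `"poor"`, `"medium"`, `"high"`.
#' @param shifting One of `"poor"`, `"medium"`, `"high"`.
#' @param inhibition One of `"very_poor"`, `"poor"`, `"medium"`, `"high"`.
#' @return A list of class `ef_profile` with the level names and their
#'   numeric values (`updating`, `shift_toward`, `shift_away`, `inhibition`).
#' @examples
#' ef_profile("high", "high", "high")
#' @export
ef_profile <- function(updating, shifting, inhibition) {
  lv <- ef_levels()
  updating <- rlang::arg_match(updating, names(lv$updating))
  shifting <- rlang::arg_match(shifting, names(lv$shifting))
  inhibition <- rlang::arg_match(inhibition, names(lv$inhibition))
  structure(
    list(
      updating_level = updating,
      shifting_level = shifting,
      inhibition_level = inhibition,
      updating = unname(lv$updating[updating]),
      shift_toward = lv$shifting[[shifting]][1],
      shift_away = lv$shifting[[shifting]][2],
      inhibition = unname(lv$inhibition[inhibition])
    ),
    class = "ef_profile"
  )
}

#' The expert profile
#'
#' The unimpaired base agent: the `"high"` level of each component reflects
#' 99% of expert functioning, so the expert values are the `"high"` values
#' divided by 0.99.
#'
#' @return An `ef_profile` with expert-grade numeric values (levels labelled
#'   `"expert"`).
#' @export
ef_profile_expert <- function() {
  p <- ef_profile("high", "high", "high")
  p$updating <- p$updating / 0.99
  p$shift_toward <- p$shift_toward / 0.99
  p$shift_away <- p$shift_away / 0.99
  p$inhibition <- p$inhibition / 0.99
  p$updating_level <- p$shifting_level <- p$inhibition_level <- "expert"
  p
}

#' @export
print.ef_profile <- function(x, ...) {
  cat(sprintf(
    "<ef_profile> updating=%s (%.4f), shifting=%s (%+g,%+g), inhibition=%s (%.4f)\n",
    x$updating_level, x$updating, x$shifting_level, x$shift_toward,
    x$shift_away, x$inhibition_level, x$inhibition
  ))
  invisible(x)
}

#' Agent constants
#'
#' Fixed scaling constants of the agent dynamics, shared by every profile.
#' These are configuration, calibrated once so that the aggregate behaviour
#' of the default grid holds (cycle-budget monotonicity of perseveration,
#' the inhibition-by-cycles interaction, near-universal session completion),
#' then frozen; see the methods vignette for the rationale behind each value.
#'
#' @param noise_sd Standard deviation of the zero-mean Gaussian activation
#'   noise added each processing cycle (default 0.015; 0 disables noise).
#' @param decay Multiplicative between-trial activation decay in \[0, 1\]
#'   (default 0.98).
#' @param kappa_shift Scaling of the per-cycle strategy-evaluation biases
#'   (default 0.01); the toward/away shifting values multiply this.
#' @param kappa_inhib Scaling of the per-cycle inhibitory decrement applied
#'   to a disconfirmed prepotent strategy (default 0.045); the inhibition
#'   value multiplies this.
#' @param kappa_prepotent Per-cycle automatic activation bonus of the
#'   prepotent (last positively reinforced, not disconfirmed) strategy
#'   (default 0.05).
#' @param anticipation Strength of the anticipatory evidence demotion applied
#'   when an agent with active shifting expects the covert rule change
#'   (default 0.5); multiplied by the magnitude of the away-shift value and
#'   capped at 1.
#' @param expected_run_length Task-structure knowledge: the criterion run
#'   length after which a rule change is anticipated (default 10).
#' @return A named list of constants.
#' @export
agent_constants <- function(noise_sd = 0.015, decay = 0.98,
                            kappa_shift = 0.01, kappa_inhib = 0.045,
                            kappa_prepotent = 0.05, anticipation = 0.5,
                            expected_run_length = 10L) {
  stopifnot(noise_sd >= 0, decay >= 0, decay <= 1, kappa_shift >= 0,
            kappa_inhib >= 0, kappa_prepotent >= 0, anticipation >= 0,
            expected_run_length >= 1)
  list(
    noise_sd = noise_sd, decay = decay, kappa_shift = kappa_shift,
    kappa_inhib = kappa_inhib, kappa_prepotent = kappa_prepotent,
    anticipation = anticipation,
    expected_run_length = as.integer(expected_run_length)
  )
}

#' Initial agent state
#'
#' Uniform evidence (1/3 per dimension), zero activations, no prepotent
#' strategy, no disconfirmed flags, empty reinforcement streak.
#'
#' @return A list with elements `activation`, `evidence` (numeric length 3,
#'   ordered color/shape/number), `prepotent` (integer index or `NA`),
#'   `disconfirmed` (logical length 3), `streak` (integer).
#' @export
agent_state_init <- function() {
  list(
    activation = c(0, 0, 0),
    evidence = rep(1 / 3, 3),
    prepotent = NA_integer_,
    disconfirmed = c(FALSE, FALSE, FALSE),
    streak = 0L
  )
}

#' Create a simulated WCST participant
#'
#' Bundles an executive-function profile, a deliberation cycle budget, the
#' shared dynamic constants and a private seed into an agent object that the
#' task engine can administer. The grid of the default experiment uses cycle
#' budgets 20, 40 and 60; other positive budgets are allowed for
#' exploration.
#'
#' @param profile An [ef_profile()] (or [ef_profile_expert()]).
#' @param cycle_budget Positive integer number of processing cycles permitted
#'   before each sort.
#' @param seed Integer seed of the agent's private random stream (used by
#'   [administer()]).
#' @param constants Dynamic constants from [agent_constants()].
#' @return A list of class `wcst_agent`.
#' @examples
#' make_agent(ef_profile("high", "high", "high"), cycle_budget = 60, seed = 1)
#' @export
make_agent <- function(profile, cycle_budget, seed = 1L,
                       constants = agent_constants()) {
  if (!inherits(profile, "ef_profile")) {
    rlang::abort("`profile` must be an `ef_profile`.",
                 class = "wcstsim_config_error")
  }
  if (!is.numeric(cycle_budget) || length(cycle_budget) != 1 ||
      is.na(cycle_budget) || cycle_budget < 1) {
    rlang::abort("`cycle_budget` must be a positive integer.",
                 class = "wcstsim_config_error")
  }
  structure(
    list(
      type = "ef",
      profile = profile,
      cycle_budget = as.integer(cycle_budget),
      seed = as.integer(seed),
      constants = constants,
      state = agent_state_init()
    ),
    class = "wcst_agent"
  )
}

#' Scripted reference agents
#'
#' Degenerate agents used as oracles and stress cases for the task engine:
#' the omniscient oracle always sorts by the current rule; the perseverator
#' always sorts by one fixed dimension; a scripted agent replays a fixed
#' choice sequence.
#'
#' @param dimension For `perseverator_agent()`, the dimension always chosen.
#' @param choices For `scripted_agent()`, a character vector of dimensions
#'   replayed trial by trial.
#' @return A `wcst_agent` object.
#' @export
oracle_agent <- function() {
  structure(list(type = "oracle", cycle_budget = NA_integer_,
                 state = agent_state_init()),
            class = "wcst_agent")
}

#' @rdname oracle_agent
#' @export
perseverator_agent <- function(dimension = "color") {
  dimension <- rlang::arg_match(dimension, wcst_dimensions())
  structure(list(type = "perseverator",
                 dimension = match(dimension, wcst_dimensions()),
                 cycle_budget = NA_integer_, state = agent_state_init()),
            class = "wcst_agent")
}

#' @rdname oracle_agent
#' @export
scripted_agent <- function(choices) {
  idx <- match(choices, wcst_dimensions())
  if (anyNA(idx)) {
    rlang::abort("`choices` must all be WCST dimensions.",
                 class = "wcstsim_config_error")
  }
  structure(list(type = "scripted", script = idx,
                 cycle_budget = NA_integer_, state = agent_state_init()),
            class = "wcst_agent")
}

#' One deliberation episode
#'
#' Runs exactly `cycle_budget` processing cycles over the agent's activation
#' field and returns the chosen sorting dimension. Each cycle applies, in
#' order:
#' \enumerate{
#'   \item monitoring — the activation of every candidate (non-disconfirmed)
#'     dimension moves toward its working-memory evidence with gain equal to
#'     the updating value; a disconfirmed dimension receives no working-memory
#'     support;
#'   \item strategy evaluation — the highest-evidence candidate dimension
#'     receives `kappa_shift * shift_toward`, every other dimension
#'     `kappa_shift * shift_away`;
#'   \item inhibition — a disconfirmed dimension is decremented by
#'     `inhibition * kappa_inhib`;
#'   \item automatic activation — the prepotent dimension, while not
#'     disconfirmed, receives `kappa_prepotent`;
#'   \item additive zero-mean Gaussian noise with sd `noise_sd`, then
#'     clipping to \[0, 1\].
#' }
#' The chosen dimension is the activation argmax after the final cycle, ties
#' broken uniformly at random from the current RNG stream.
#'
#' @param state Agent state (see [agent_state_init()]).
#' @param profile An [ef_profile()].
#' @param cycle_budget Number of cycles to run.
#' @param constants Constants from [agent_constants()].
#' @return A list with `choice` (integer dimension index) and `activation`
#'   (the final activation vector).
#' @export
deliberate <- function(state, profile, cycle_budget,
                       constants = agent_constants()) {
  a <- state$activation
  e <- state$evidence
  disc <- state$disconfirmed
  prep <- state$prepotent
  u <- profile$updating
  s_pos <- profile$shift_toward * constants$kappa_shift
  s_neg <- profile$shift_away * constants$kappa_shift
  inh <- profile$inhibition * constants$kappa_inhib
  bonus <- constants$kappa_prepotent
  sd_n <- constants$noise_sd

  # candidate with the highest evidence (ties resolved in canonical
  # color/shape/number order); disconfirmed dimensions are not candidates
  # (all-flagged states cannot arise from feedback, but guard anyway)
  cand <- which(!disc)
  if (length(cand) == 0L) cand <- 1:3
  target <- cand[which.max(e[cand])]
  shifting_on <- (s_pos != 0) || (s_neg != 0)

  if (sd_n > 0) {
    noise <- matrix(stats::rnorm(3L * cycle_budget, 0, sd_n), nrow = 3L)
  }
  for (cyc in seq_len(cycle_budget)) {
    a[cand] <- a[cand] + u * (e[cand] - a[cand])
    if (any(disc)) a[disc] <- a[disc] - inh
    if (shifting_on) {
      a[target] <- a[target] + s_pos
      a[-target] <- a[-target] + s_neg
    }
    if (!is.na(prep) && !disc[prep]) a[prep] <- a[prep] + bonus
    if (sd_n > 0) a <- a + noise[, cyc]
    a[a < 0] <- 0
    a[a > 1] <- 1
  }
  top <- which(a == max(a))
  choice <- if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
  list(choice = choice, activation = a)
}

#' Consume trial feedback
#'
#' Updates the agent's working memory after a sort. On positive feedback the
#' evidence for the chosen dimension moves toward 1 with gain equal to the
#' updating value, the chosen dimension becomes prepotent, and disconfirmed
#' flags are cleared. On negative feedback the evidence for the chosen
#' dimension moves toward 0 with the same gain and the chosen dimension is
#' flagged disconfirmed — in particular a disconfirmed prepotent strategy
#' loses its automatic-activation support and becomes the object of
#' inhibition. An agent with active
#' shifting additionally anticipates the covert rule change once its run of
#' consecutive positive feedback reaches the criterion length: the current
#' strategy's evidence is demoted by `anticipation * |shift_away|` (capped at
#' a full reset) and the strategy is flagged disconfirmed. Between trials all
#' activations decay multiplicatively.
#'
#' @param state Agent state.
#' @param chosen Integer index (or dimension name) of the sorted dimension.
#' @param feedback `"correct"` or `"incorrect"`.
#' @param profile An [ef_profile()].
#' @param constants Constants from [agent_constants()].
#' @return The updated state.
#' @export
process_feedback <- function(state, chosen, feedback, profile,
                             constants = agent_constants()) {
  if (is.character(chosen)) chosen <- match(chosen, wcst_dimensions())
  u <- profile$updating
  if (identical(feedback, "correct")) {
    state$evidence[chosen] <- state$evidence[chosen] +
      u * (1 - state$evidence[chosen])
    state$prepotent <- chosen
    state$disconfirmed[] <- FALSE
    state$streak <- state$streak + 1L
    if (state$streak >= constants$expected_run_length &&
        profile$shift_away < 0) {
      drop <- min(1, constants$anticipation * abs(profile$shift_away))
      state$evidence[chosen] <- state$evidence[chosen] * (1 - drop)
      state$disconfirmed[chosen] <- TRUE
      state$streak <- 0L
    }
  } else {
    state$evidence[chosen] <- state$evidence[chosen] * (1 - u)
    # the sorted strategy has just been contradicted by feedback: it is no
    # longer a candidate until something is positively reinforced again
    state$disconfirmed[chosen] <- TRUE
    state$streak <- 0L
  }
  state$activation <- state$activation * constants$decay
  state
}
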