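# Factorial experiment: 48 executive-function variants x cycle budgets x
# virtual participants, emitting the tidy results table the analyses run on.

#' Enumerate the 48 executive-function variants
#'
#' The full factorial of 4 updating x 3 shifting x 4 inhibition levels in a
#' documented canonical order: updating varies slowest (very poor to high),
#' then shifting (poor to high), then inhibition (very poor to high). This
#' ordering is the package's own; the printed comparison table of model
#' means ships with its own model numbering (see [load_table6()]).
#'
#' @return A 48-row tibble with `variant_id` and the three level columns.
#' @examples
#' enumerate_variants()
#' @export
enumerate_variants <- function() {
  lv <- ef_levels()
  grid <- tidyr::expand_grid(
    updating = names(lv$updating),
    shifting = names(lv$shifting),
    inhibition = names(lv$inhibition)
  )
  dplyr::mutate(grid, variant_id = dplyr::row_number(), .before = 1)
}

#' Grid configuration
#'
#' Defaults mirror the study design: 48 variants x 3 cycle budgets (20, 40,
#' 60) x 20 virtual participants = 2,880 sessions of the 128-card WCST.
#'
#' @param n_participants Virtual participants per model (default 20).
#' @param cycle_budgets Cycle budgets crossed with the variants.
#' @param master_seed Master seed; per-participant child seeds are derived
#'   deterministically from it and recorded in the results table.
#' @param constants Agent constants ([agent_constants()]).
#' @param admin An [administration_config()] (deck built per session from
#'   the child seed when it carries none).
#' @return A list of class `wcst_grid_config`.
#' @export
grid_config <- function(n_participants = 20L,
                        cycle_budgets = c(20L, 40L, 60L),
                        master_seed = 1L,
                        constants = agent_constants(),
                        admin = administration_config()) {
  if (n_participants < 1) {
    rlang::abort("`n_participants` must be >= 1.",
                 class = "wcstsim_config_error")
  }
  if (length(cycle_budgets) < 1 || any(cycle_budgets < 1)) {
    rlang::abort("`cycle_budgets` must be positive.",
                 class = "wcstsim_config_error")
  }
  structure(
    list(n_participants = as.integer(n_participants),
         cycle_budgets = as.integer(cycle_budgets),
         master_seed = as.integer(master_seed),
         constants = constants, admin = admin),
    class = "wcst_grid_config"
  )
}

# Deterministic child seed for (model row, participant); distinct for every
# (model_row, participant) pair under a fixed master seed, and kept below
# 2^31 (doubles are exact here).
child_seed <- function(master_seed, model_row, participant) {
  base <- (abs(as.numeric(master_seed)) %% 48611) * 43651
  as.integer((base + (model_row - 1) * 1009 + participant * 7) %%
               .Machine$integer.max)
}

#' Run the factorial grid
#'
#' Runs one independent WCST session per (variant, cycle budget,
#' participant) triple — no state carries over between sessions — and
#' returns the tidy results table. Deterministic given `master_seed`.
#'
#' @param config A [grid_config()].
#' @param progress Print one line per model (default `FALSE`).
#' @return A tibble with one row per session: `model_id`, `variant_id`,
#'   `updating`, `shifting`, `inhibition`, `cycles`, `participant`, `seed`,
#'   `pe`, `npe`, `categories`, `correct_sorts`, `trials`.
#' @examples
#' \donttest{
#' res <- run_grid(grid_config(n_participants = 1, master_seed = 7))
#' nrow(res)  # 144
#' }
#' @export
run_grid <- function(config = grid_config(), progress = FALSE) {
  variants <- enumerate_variants()
  models <- tidyr::expand_grid(
    variant_id = variants$variant_id,
    cycles = config$cycle_budgets
  )
  models <- dplyr::left_join(models, variants, by = "variant_id")
  models <- dplyr::mutate(models, model_id = dplyr::row_number(), .before = 1)

  out <- purrr::pmap(models, function(model_id, variant_id, cycles,
                                      updating, shifting, inhibition) {
    if (progress) {
      message(sprintf("model %3d: %s/%s/%s @ %d cycles",
                      model_id, updating, shifting, inhibition, cycles))
    }
    profile <- ef_profile(updating, shifting, inhibition)
    purrr::map(seq_len(config$n_participants), function(p) {
      seed <- child_seed(config$master_seed, model_id, p)
      agent <- make_agent(profile, cycles, seed = seed,
                          constants = config$constants)
      s <- administer(agent, config$admin, rng_seed = seed, keep_log = FALSE)
      list(model_id = model_id, variant_id = variant_id,
           updating = updating, shifting = shifting,
           inhibition = inhibition, cycles = cycles, participant = p,
           seed = seed, pe = s$pe, npe = s$npe, categories = s$categories,
           correct_sorts = s$correct_sorts, trials = s$trials_administered)
    })
  })
  dplyr::bind_rows(purrr::flatten(out))
}

#' Per-model and per-cycle-group summaries
#'
#' `summarize_models()` gives one row per (variant, cycle budget) model with
#' the mean and sample SD (n - 1 denominator) of PE; `cycle_descriptives()`
#' gives the descriptive table per cycle group plus a `total` row (n, mean,
#' SD, SE, normal-approximation 95% CI, min, max).
#'
#' @param results A results table from [run_grid()] (or any table with the
#'   same columns).
#' @return A tibble.
#' @export
summarize_models <- function(results) {
  if (nrow(results) == 0) {
    rlang::abort("Empty results table.", class = "wcstsim_no_data")
  }
  results |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("model_id", "variant_id", "updating", "shifting", "inhibition",
        "cycles")
    ))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_pe = mean(.data$pe),
      sd_pe = ifelse(dplyr::n() > 1, stats::sd(.data$pe), 0),
      .groups = "drop"
    )
}

#' @rdname summarize_models
#' @export
cycle_descriptives <- function(results) {
  if (nrow(results) == 0) {
    rlang::abort("Empty results table.", class = "wcstsim_no_data")
  }
  per_group <- results |>
    dplyr::mutate(group = paste0(.data$cycles, "-cycles")) |>
    dplyr::group_by(.data$group)
  total <- dplyr::mutate(results, group = "total") |>
    dplyr::group_by(.data$group)
  dplyr::bind_rows(
    pe_descriptives(per_group),
    pe_descriptives(total)
  )
}
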