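# Reading and writing run configuration as YAML/JSON.

#' Serialise and restore grid configurations
#'
#' A [grid_config()] round-trips through a plain YAML (or JSON) mapping:
#' participant count, cycle budgets, master seed, the agent constants, and
#' the administration settings (criterion, categories, rule sequence).
#' Decks are rebuilt from seeds rather than serialised.
#'
#' @param config A [grid_config()].
#' @param path File path; format chosen by extension (`.yml`/`.yaml` or
#'   `.json`).
#' @return `write_grid_config()` returns `config` invisibly;
#'   `read_grid_config()` returns a `wcst_grid_config`.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' write_grid_config(grid_config(n_participants = 5, master_seed = 3), f)
#' read_grid_config(f)$n_participants
#' @export
write_grid_config <- function(config, path) {
  x <- list(
    n_participants = config$n_participants,
    cycle_budgets = config$cycle_budgets,
    master_seed = config$master_seed,
    constants = config$constants,
    admin = list(
      rule_sequence = wcst_dimensions()[config$admin$rule_sequence],
      criterion_correct = config$admin$criterion_correct,
      max_categories = config$admin$max_categories
    )
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(config)
}

#' @rdname write_grid_config
#' @export
read_grid_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  grid_config(
    n_participants = x$n_participants,
    cycle_budgets = unlist(x$cycle_budgets),
    master_seed = x$master_seed,
    constants = do.call(agent_constants, x$constants),
    admin = administration_config(
      rule_sequence = unlist(x$admin$rule_sequence),
      criterion_correct = x$admin$criterion_correct,
      max_categories = x$admin$max_categories
    )
  )
}
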