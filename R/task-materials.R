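# WCST stimulus materials: cards, key cards, and deck construction.

#' Dimension and attribute vocabularies
#'
#' The WCST stimulus space is the full cross of four colours, four shapes and
#' the numbers 1 to 4 (64 distinct cards). Cards are sorted along one of three
#' dimensions: colour, shape or number.
#'
#' @return `wcst_dimensions()` returns the three sorting dimensions in their
#'   canonical order; `wcst_colors()` and `wcst_shapes()` return the four
#'   attribute values of their dimension, ordered so that position `k`
#'   belongs to key card `k`.
#' @export
wcst_dimensions <- function() c("color", "shape", "number")

#' @rdname wcst_dimensions
#' @export
wcst_colors <- function() c("red", "green", "yellow", "blue")

#' @rdname wcst_dimensions
#' @export
wcst_shapes <- function() c("triangle", "star", "cross", "circle")

#' The four key cards
#'
#' The fixed reference cards of the standard (Heaton) materials: one red
#' triangle, two green stars, three yellow crosses, four blue circles. Across
#' the four keys every value of every dimension appears exactly once, so any
#' card matches exactly one key on any given dimension.
#'
#' @return A four-row tibble with columns `key`, `number`, `color`, `shape`.
#' @examples
#' wcst_key_cards()
#' @export
wcst_key_cards <- function() {
  tibble::tibble(
    key = 1:4,
    number = 1:4,
    color = wcst_colors(),
    shape = wcst_shapes()
  )
}

#' Enumerate the 64-card stimulus set
#'
#' @return A 64-row tibble with columns `color`, `shape`, `number`, one row
#'   per distinct (color, shape, number) combination.
#' @export
wcst_card_space <- function() {
  tidyr::expand_grid(
    color = wcst_colors(),
    shape = wcst_shapes(),
    number = 1:4
  )
}

#' Build an ordered WCST deck
#'
#' Concatenates `set_count` copies of the complete 64-card stimulus set, each
#' copy independently shuffled under a seeded uniform permutation. The
#' standard 128-card administration uses two sets. The published fixed card
#' order is copyrighted, so ordering is randomised but fully reproducible
#' from `order_seed`.
#'
#' @param set_count Number of 64-card sets (>= 1); 2 gives the 128-card deck.
#' @param order_seed Integer seed controlling the within-set shuffles.
#' @return A tibble with columns `position`, `color`, `shape`, `number` and
#'   `64 * set_count` rows; each consecutive block of 64 rows contains every
#'   combination exactly once.
#' @examples
#' deck <- build_deck(set_count = 2, order_seed = 1)
#' nrow(deck)
#' @export
build_deck <- function(set_count = 2, order_seed = 1) {
  if (!is.numeric(set_count) || length(set_count) != 1 ||
      is.na(set_count) || set_count < 1 || set_count != floor(set_count)) {
    rlang::abort("`set_count` must be a positive integer.",
                 class = "wcstsim_config_error")
  }
  space <- wcst_card_space()
  withr::with_seed(order_seed, {
    sets <- purrr::map(seq_len(set_count), function(i) {
      space[sample.int(64L), ]
    })
  })
  deck <- dplyr::bind_rows(sets)
  deck <- dplyr::mutate(deck, position = dplyr::row_number(), .before = 1)
  deck
}

#' Find the key card matching a card on a dimension
#'
#' For any card and any sorting dimension there is exactly one key card that
#' agrees with it on that dimension (the key set covers each attribute value
#' once). Vectorised over cards.
#'
#' @param color,shape,number Card attributes (recycled to a common length).
#' @param dimension One of `"color"`, `"shape"`, `"number"`.
#' @return Integer vector of key indices in 1..4.
#' @examples
#' matching_key("red", "star", 2, "color")   # key 1 (red)
#' matching_key("red", "star", 2, "shape")   # key 2 (stars)
#' @export
matching_key <- function(color, shape, number, dimension) {
  dimension <- rlang::arg_match(dimension, wcst_dimensions())
  key <- switch(dimension,
    color = match(color, wcst_colors()),
    shape = match(shape, wcst_shapes()),
    number = as.integer(number)
  )
  if (anyNA(key) || any(key < 1L | key > 4L)) {
    rlang::abort("Card attributes outside the WCST stimulus space.",
                 class = "wcstsim_config_error")
  }
  as.integer(key)
}

#' Read and write decks as CSV
#'
#' Decks serialise to plain CSV with columns `position`, `color`, `shape`,
#' `number`; the round trip is exact.
#'
#' @param deck A deck tibble from [build_deck()].
#' @param path File path.
#' @return `write_deck_csv()` returns `deck` invisibly; `read_deck_csv()`
#'   returns the deck tibble.
#' @export
write_deck_csv <- function(deck, path) {
  readr::write_csv(deck[, c("position", "color", "shape", "number")], path)
  invisible(deck)
}

#' @rdname write_deck_csv
#' @export
read_deck_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      position = readr::col_integer(),
      color = readr::col_character(),
      shape = readr::col_character(),
      number = readr::col_integer()
    )
  )
}
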