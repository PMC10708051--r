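#' Analytical Eco-Scale penalty ledger
#'
#' A ledger is a tibble of itemized penalty points (PPs) with columns
#' `category`, `description`, `pp`. Categories come from the closed set
#' reagent_amount, reagent_hazard, instrument_energy, occupational,
#' waste_production, waste_treatment. Items may be rule-derived (see
#' [hazard_pp()], [amount_pp()]) or directly asserted, since published scores
#' often state per-reagent PPs as outcomes.
#'
#' @param category Character vector of categories.
#' @param description What the item penalizes.
#' @param pp Non-negative integer penalty points.
#' @param method Optional method label attached as the `method` attribute.
#' @return A validated `penalty_ledger` tibble.
#' @export
#' @examples
#' penalty_ledger(
#'   category = c("reagent_amount", "reagent_hazard"),
#'   description = c("methanol, <1 mL per sample", "methanol"),
#'   pp = c(1, 3)
#' )
penalty_ledger <- function(category, description, pp, method = NULL) {
  ledger <- tibble::tibble(
    category = category, description = description, pp = pp
  )
  validate_ledger(ledger)
  attr(ledger, "method") <- method
  class(ledger) <- c("penalty_ledger", class(ledger))
  ledger
}

AES_CATEGORIES <- c("reagent_amount", "reagent_hazard", "instrument_energy",
                    "occupational", "waste_production", "waste_treatment")

validate_ledger <- function(ledger) {
  need <- c("category", "description", "pp")
  if (!all(need %in% names(ledger))) {
    abort(sprintf("ledger needs columns %s", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(ledger$category), AES_CATEGORIES)
  if (length(bad) > 0) {
    abort(sprintf("unknown penalty category '%s' (must be one of %s)",
                  bad[1], paste(AES_CATEGORIES, collapse = ", ")))
  }
  if (any(ledger$pp < 0)) abort("penalty points must be non-negative")
  if (any(ledger$pp != round(ledger$pp))) abort("penalty points must be integers")
  invisible(ledger)
}

#' Analytical Eco-Scale score
#'
#' score = max(100 - total penalty points, 0); classification "excellent" for
#' score > 75, "acceptable" for score > 50, otherwise "inadequate". The score
#' is additive in the ledger: merging two ledgers sums their penalty points.
#'
#' @param ledger A [penalty_ledger()] (or plain data frame with the same
#'   columns).
#' @return An `aes_result` list with `total_pp`, `score`, `classification`,
#'   `by_category` (subtotal tibble) and the `ledger` itself.
#' @export
#' @examples
#' aes_score(penalty_ledger("waste_treatment", "no treatment", 3))
aes_score <- function(ledger) {
  ledger <- tibble::as_tibble(ledger)
  validate_ledger(ledger)
  total <- sum(ledger$pp)
  score <- max(100 - total, 0)
  classification <- if (score > 75) "excellent" else if (score > 50) "acceptable" else "inadequate"
  by_cat <- ledger |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(pp = sum(.data$pp), .groups = "drop")
  structure(
    list(total_pp = total, score = score, classification = classification,
         by_category = by_cat, ledger = ledger),
    class = "aes_result"
  )
}

#' @export
print.aes_result <- function(x, ...) {
  cat("Analytical Eco-Scale\n")
  for (i in seq_len(nrow(x$ledger))) {
    cat(sprintf("  %-18s %-45s %3d\n", x$ledger$category[i],
                x$ledger$description[i], x$ledger$pp[i]))
  }
  cat(sprintf("  %-64s %3d\n", "Total penalty points", x$total_pp))
  cat(sprintf("  %-64s %3d  (%s)\n", "Eco-Scale score", x$score, x$classification))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.aes_result <- function(x, ...) {
  tibble::tibble(total_pp = x$total_pp, score = x$score,
                 classification = x$classification)
}

#' Hazard penalty points for a reagent
#'
#' pp = number of GHS pictograms x signal-word multiplier (none 0, warning 1,
#' danger 2).
#'
#' @param pictogram_count Number of GHS pictograms (>= 0).
#' @param signal_word One of "none", "warning", "danger".
#' @return Penalty points.
#' @export
#' @examples
#' hazard_pp(3, "warning")  # 3
hazard_pp <- function(pictogram_count, signal_word = c("none", "warning", "danger")) {
  signal_word <- match.arg(signal_word)
  if (pictogram_count < 0) abort("pictogram count must be non-negative")
  mult <- c(none = 0, warning = 1, danger = 2)[[signal_word]]
  pictogram_count * mult
}

#' Amount penalty points for a solvent or reagent
#'
#' Banded by the volume consumed per sample: below 1 mL scores 1 pp, 1-10 mL
#' scores 2, above 10 mL scores 3. A volume of exactly zero (reagent not used)
#' scores 0.
#'
#' @param volume_ml_per_sample Volume per sample, mL (>= 0).
#' @return Penalty points.
#' @export
#' @examples
#' amount_pp(0.1)  # 1
amount_pp <- function(volume_ml_per_sample) {
  if (volume_ml_per_sample < 0) abort("volume must be non-negative")
  if (volume_ml_per_sample == 0) return(0)
  if (volume_ml_per_sample < 1) 1 else if (volume_ml_per_sample <= 10) 2 else 3
}

#' Read a penalty ledger from YAML or JSON
#'
#' Expected structure: optional `method` label and an `items` list, each item
#' with `category`, `description`, `pp`. May also carry `gapi` / `agree`
#' fields, which are passed through into reports untouched (those tools'
#' scores are published outputs, not computed here).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `penalty_ledger` with any `gapi`/`agree` passthrough stored in
#'   attributes.
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) abort(sprintf("ledger file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    abort(sprintf("unsupported ledger format '.%s' (use YAML or JSON)", ext))
  )
  if (is.null(raw$items) || length(raw$items) == 0) {
    abort(sprintf("%s: ledger has no items", path))
  }
  items <- purrr::map_dfr(raw$items, function(it) {
    tibble::tibble(
      category = it$category %||% NA_character_,
      description = it$description %||% "",
      pp = as.numeric(it$pp %||% NA_real_)
    )
  })
  if (any(is.na(items$category)) || any(is.na(items$pp))) {
    abort(sprintf("%s: every item needs `category` and `pp`", path))
  }
  ledger <- penalty_ledger(items$category, items$description, items$pp,
                           method = raw$method)
  attr(ledger, "gapi") <- raw$gapi
  attr(ledger, "agree") <- raw$agree
  ledger
}

`%||%` <- function(a, b) if (is.null(a)) b else a
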