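#' @title Event timing tables
#'
#' @description An event timing table is a long-format tibble with one row per
#'   empirically known neurodevelopmental event occurrence:
#'   \describe{
#'     \item{species}{character, species identifier (case-sensitive, trimmed)}
#'     \item{event}{character, event identifier}
#'     \item{pc_day}{positive double, post-conceptional day of the event}
#'     \item{is_primate}{logical, species group flag}
#'     \item{event_class}{factor-like character in `cortical`, `limbic`, `other`}
#'   }
#'   `(species, event)` pairs are unique, and the species flag / event class are
#'   constant within a species / event respectively.
#' @name event_table
NULL

event_classes <- c("cortical", "limbic", "other")

#' Validate an event timing table
#'
#' Checks the schema and invariants described in [event_table]: required
#' columns, positive `pc_day`, unique `(species, event)` pairs, and exactly one
#' primate flag per species and one class per event.
#'
#' @param df A data frame in the event-table schema.
#' @return The validated table as a tibble (identifiers trimmed), invisibly
#'   usable in a pipe.
#' @export
validate_event_table <- function(df) {
  required <- c("species", "event", "pc_day", "is_primate", "event_class")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("event table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "devtiming_schema_error")
  }
  df <- tibble::as_tibble(df)
  df$species <- trimws(as.character(df$species))
  df$event <- trimws(as.character(df$event))
  df$is_primate <- parse_flag(df$is_primate)
  df$event_class <- trimws(as.character(df$event_class))

  pc <- suppressWarnings(as.numeric(df$pc_day))
  bad <- which(is.na(pc) | pc <= 0)
  if (length(bad) > 0) {
    abort(sprintf("pc_day must be a positive number; offending row(s): %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "devtiming_value_error")
  }
  df$pc_day <- pc

  dup <- duplicated(df[c("species", "event")])
  if (any(dup)) {
    abort(sprintf("duplicate (species, event) pair(s), e.g. row %d: (%s, %s)",
                  which(dup)[1], df$species[which(dup)[1]], df$event[which(dup)[1]]),
          class = "devtiming_value_error")
  }
  if (!all(df$event_class %in% event_classes)) {
    bad_cls <- setdiff(unique(df$event_class), event_classes)
    abort(sprintf("event_class must be one of %s; found: %s",
                  paste(event_classes, collapse = "/"),
                  paste(bad_cls, collapse = ", ")),
          class = "devtiming_value_error")
  }
  chk <- df |>
    dplyr::distinct(.data$species, .data$is_primate) |>
    dplyr::count(.data$species) |>
    dplyr::filter(.data$n > 1)
  if (nrow(chk) > 0) {
    abort(sprintf("species with conflicting is_primate flags: %s",
                  paste(chk$species, collapse = ", ")),
          class = "devtiming_value_error")
  }
  chk <- df |>
    dplyr::distinct(.data$event, .data$event_class) |>
    dplyr::count(.data$event) |>
    dplyr::filter(.data$n > 1)
  if (nrow(chk) > 0) {
    abort(sprintf("events with conflicting event_class labels: %s",
                  paste(chk$event, collapse = ", ")),
          class = "devtiming_value_error")
  }
  df
}

# Model-fitting entry points sort observations canonically so fitted values,
# and hence leave-one-out predictions, are exactly invariant to input row
# order (floating-point reductions are order-sensitive).
canonical_order <- function(df) {
  dplyr::arrange(df, .data$species, .data$event)
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes")] <- TRUE
  out[x %in% c("0", "false", "f", "no")] <- FALSE
  if (anyNA(out)) {
    abort("is_primate must be one of 0/1/true/false",
          class = "devtiming_value_error")
  }
  out
}

#' Read an event timing table from TSV or CSV
#'
#' @param path Path to a delimited file with header
#'   `species,event,pc_day,is_primate,event_class`.
#' @param format `"auto"` (by file extension, default TSV), `"tsv"` or `"csv"`.
#' @return A validated event-table tibble (see [event_table]).
#' @examples
#' path <- system.file("extdata", "example_events.tsv", package = "devtiming")
#' read_event_table(path)
#' @export
read_event_table <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "devtiming_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  reader <- if (format == "csv") readr::read_csv else readr::read_tsv
  df <- reader(path, comment = "#", show_col_types = FALSE,
               col_types = readr::cols(.default = readr::col_character()))
  validate_event_table(df)
}

#' Filter an event table to a minimum species/event coverage
#'
#' Keeps only events documented in at least `min_species_per_event` species and
#' species with at least `min_events_per_species` events. Because removing an
#' event can push a species below threshold (and vice versa), the two rules are
#' applied alternately until a fixed point, so the returned table satisfies
#' both simultaneously; the operation is idempotent.
#'
#' @param df An event-table tibble.
#' @param min_species_per_event Minimum species per retained event (default 2).
#' @param min_events_per_species Minimum events per retained species (default 2).
#' @return The filtered tibble.
#' @export
filter_min_coverage <- function(df, min_species_per_event = 2,
                                min_events_per_species = 2) {
  df <- validate_event_table(df)
  repeat {
    n_before <- nrow(df)
    keep_events <- df |>
      dplyr::count(.data$event) |>
      dplyr::filter(.data$n >= min_species_per_event) |>
      dplyr::pull(.data$event)
    df <- dplyr::filter(df, .data$event %in% keep_events)
    keep_species <- df |>
      dplyr::count(.data$species) |>
      dplyr::filter(.data$n >= min_events_per_species) |>
      dplyr::pull(.data$species)
    df <- dplyr::filter(df, .data$species %in% keep_species)
    if (nrow(df) == n_before) break
  }
  if (nrow(df) == 0) {
    abort("no events survive coverage filter", class = "devtiming_value_error")
  }
  df
}

#' Natural-log transform of timing values
#'
#' Applied solely to reduce the dynamic range of post-conceptional days before
#' model fitting; no normality claim is attached.
#'
#' @param values Numeric vector of positive days.
#' @return `log(values)` element-wise.
#' @export
log_transform <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)) || any(values <= 0)) {
    abort("log_transform requires finite, strictly positive values",
          class = "devtiming_value_error")
  }
  log(values)
}

#' Distribution summary of timing values
#'
#' Fisher-Pearson (moment-based) sample skewness and excess kurtosis, with
#' range and count. Raw post-conceptional days are typically strongly
#' right-skewed; the log transform reduces both skewness and kurtosis.
#'
#' @param values Numeric vector, length >= 3.
#' @return A one-row tibble with columns `n`, `skewness`, `kurtosis`
#'   (excess), `min`, `max`.
#' @export
distribution_summary <- function(values) {
  if (!is.numeric(values) || length(values) < 3) {
    abort("distribution_summary requires at least 3 numeric values",
          class = "devtiming_value_error")
  }
  n <- length(values)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  tibble::tibble(
    n = n,
    skewness = m3 / m2^1.5,
    kurtosis = m4 / m2^2 - 3,
    min = min(values),
    max = max(values)
  )
}
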