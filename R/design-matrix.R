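#' Build the binary dummy-variable design matrix
#'
#' Encodes each known observation as binary species and event indicators, in
#' one of two configurations shared by the two models:
#' \itemize{
#'   \item Regression (offset-log) configuration: `drop_base = TRUE`,
#'     `interactions = TRUE`, `intercept = TRUE`. One species and one event are
#'     designated as base levels and their indicator columns dropped to avoid
#'     singularity, and two binary interaction columns (primate x cortical,
#'     primate x limbic) are appended, then an intercept. Column count is
#'     `(s-1) + (e-1) + 2 + 1 = s + e + 1`.
#'   \item Network configuration: `drop_base = FALSE`, `interactions = FALSE`,
#'     `intercept = FALSE`. All `s + e` indicator columns are kept (every row
#'     sums to exactly 2); the network supplies its own biases and weight decay
#'     handles the redundancy.
#' }
#'
#' @param df An event-table tibble (see [event_table]).
#' @param drop_base Drop the base species/event indicator columns?
#' @param base_species,base_event Base level identifiers, or `NULL` to pick the
#'   lexicographically first level (deterministic; in-sample predictions are
#'   invariant to the choice on identifiable tables).
#' @param interactions Append primate x cortical and primate x limbic columns?
#' @param intercept Append a column of ones?
#' @return A `design_matrix` object: the 0/1 matrix plus column labels, base
#'   identities, level orderings and species/event metadata needed to encode
#'   prediction queries.
#' @export
build_design <- function(df, drop_base = TRUE, base_species = NULL,
                         base_event = NULL, interactions = TRUE,
                         intercept = TRUE) {
  df <- validate_event_table(df)
  if (nrow(df) == 0) abort("empty event table", class = "devtiming_value_error")
  species_levels <- sort(unique(df$species))
  event_levels <- sort(unique(df$event))
  primate_map <- df |>
    dplyr::distinct(.data$species, .data$is_primate) |>
    (\(d) setNames(d$is_primate, d$species))()
  class_map <- df |>
    dplyr::distinct(.data$event, .data$event_class) |>
    (\(d) setNames(d$event_class, d$event))()

  if (drop_base) {
    if (is.null(base_species)) base_species <- species_levels[1]
    if (is.null(base_event)) base_event <- event_levels[1]
    if (!base_species %in% species_levels) {
      abort(sprintf("unknown base species: %s", base_species),
            class = "devtiming_value_error")
    }
    if (!base_event %in% event_levels) {
      abort(sprintf("unknown base event: %s", base_event),
            class = "devtiming_value_error")
    }
  } else {
    base_species <- NULL
    base_event <- NULL
  }

  design <- structure(
    list(
      species_levels = species_levels,
      event_levels = event_levels,
      base_species = base_species,
      base_event = base_event,
      primate_map = primate_map,
      class_map = class_map,
      config = list(drop_base = drop_base, interactions = interactions,
                    intercept = intercept)
    ),
    class = "design_matrix"
  )
  design$column_labels <- design_column_labels(design)
  design$matrix <- encode_rows(design, df$species, df$event)
  rownames(design$matrix) <- NULL
  design$n_rows <- nrow(df)
  design
}

design_column_labels <- function(design) {
  sp <- design$species_levels
  ev <- design$event_levels
  if (design$config$drop_base) {
    sp <- setdiff(sp, design$base_species)
    ev <- setdiff(ev, design$base_event)
  }
  c(paste0("species:", sp), paste0("event:", ev),
    if (design$config$interactions) c("primate_x_cortical", "primate_x_limbic"),
    if (design$config$intercept) "(Intercept)")
}

# Encode (species, event) pairs as rows of the design; the workhorse behind
# both build_design and encode_query.
encode_rows <- function(design, species, event) {
  unknown_sp <- setdiff(unique(species), design$species_levels)
  unknown_ev <- setdiff(unique(event), design$event_levels)
  if (length(unknown_sp) > 0 || length(unknown_ev) > 0) {
    abort(sprintf(
      "untrainable query: no coefficient exists for unseen %s",
      paste(c(
        if (length(unknown_sp)) sprintf("species (%s)", paste(unknown_sp, collapse = ", ")),
        if (length(unknown_ev)) sprintf("event (%s)", paste(unknown_ev, collapse = ", "))
      ), collapse = " and ")
    ), class = "devtiming_query_error")
  }
  sp_cols <- design$species_levels
  ev_cols <- design$event_levels
  if (design$config$drop_base) {
    sp_cols <- setdiff(sp_cols, design$base_species)
    ev_cols <- setdiff(ev_cols, design$base_event)
  }
  n <- length(species)
  X_sp <- matrix(0, n, length(sp_cols))
  idx <- match(species, sp_cols)
  ok <- !is.na(idx)
  X_sp[cbind(which(ok), idx[ok])] <- 1
  X_ev <- matrix(0, n, length(ev_cols))
  idx <- match(event, ev_cols)
  ok <- !is.na(idx)
  X_ev[cbind(which(ok), idx[ok])] <- 1
  X <- cbind(X_sp, X_ev)
  if (design$config$interactions) {
    if (anyNA(design$primate_map) || anyNA(design$class_map)) {
      abort("interaction columns need primate flags and event classes",
            class = "devtiming_value_error")
    }
    prim <- as.numeric(design$primate_map[species])
    cls <- design$class_map[event]
    X <- cbind(X, prim * (cls == "cortical"), prim * (cls == "limbic"))
  }
  if (design$config$intercept) X <- cbind(X, 1)
  colnames(X) <- design$column_labels
  X
}

#' Encode prediction queries against an existing design
#'
#' @param design A `design_matrix` from [build_design()].
#' @param species,event Character vectors (recycled to common length) naming
#'   species/events that were present when the design was built; anything
#'   unseen has no coefficient and raises an untrainable-query error.
#' @return A binary matrix with one row per query, columns matching
#'   `design$column_labels`.
#' @export
encode_query <- function(design, species, event) {
  stopifnot(inherits(design, "design_matrix"))
  n <- max(length(species), length(event))
  encode_rows(design, rep_len(trimws(species), n), rep_len(trimws(event), n))
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf(
    "<design_matrix> %d rows x %d columns (%d species, %d events)\n",
    nrow(x$matrix), ncol(x$matrix),
    length(x$species_levels), length(x$event_levels)
  ))
  cfg <- x$config
  cat(sprintf("  drop_base=%s interactions=%s intercept=%s\n",
              cfg$drop_base, cfg$interactions, cfg$intercept))
  if (cfg$drop_base) {
    cat(sprintf("  base species: %s; base event: %s\n",
                x$base_species, x$base_event))
  }
  invisible(x)
}
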