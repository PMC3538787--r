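#' Serialize a fitted model to JSON
#'
#' Writes everything needed to reproduce predictions in a later session: the
#' model type, design configuration (levels, base identities, metadata maps)
#' and all coefficients/weights. Round-trips through [read_model_json()].
#'
#' @param fit An `fd_fit` or `ffnn_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  design <- fit$design
  design_json <- list(
    species_levels = design$species_levels,
    event_levels = design$event_levels,
    base_species = design$base_species,
    base_event = design$base_event,
    is_primate = as.list(setNames(as.logical(design$primate_map),
                                  names(design$primate_map))),
    event_class = as.list(design$class_map),
    config = design$config,
    column_labels = design$column_labels
  )
  obj <- if (inherits(fit, "fd_fit")) {
    list(
      model = "fd",
      version = as.character(utils::packageVersion("devtiming")),
      k = fit$k,
      k_estimated = fit$k_estimated,
      beta = as.list(fit$beta),
      design = design_json
    )
  } else if (inherits(fit, "ffnn_fit")) {
    p <- fit$params
    list(
      model = "ffnn",
      version = as.character(utils::packageVersion("devtiming")),
      arch = list(hidden = p$arch$hidden, skip = p$arch$skip,
                  decay = p$arch$decay),
      seed = fit$seed,
      theta = p$theta,
      design = design_json
    )
  } else {
    abort("write_model_json supports fd_fit and ffnn_fit objects",
          class = "devtiming_value_error")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a fitted model from JSON
#'
#' @param path Path written by [write_model_json()].
#' @return An object of class `fd_fit` or `ffnn_fit` capable of `predict()`
#'   and [complete_table()] (training data and diagnostics are not stored;
#'   fields depending on them are `NULL`).
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$design
  design <- structure(
    list(
      species_levels = d$species_levels,
      event_levels = d$event_levels,
      base_species = d$base_species,
      base_event = d$base_event,
      primate_map = unlist(d$is_primate),
      class_map = unlist(d$event_class),
      config = d$config,
      column_labels = d$column_labels
    ),
    class = "design_matrix"
  )
  if (obj$model == "fd") {
    structure(
      list(k = obj$k, k_estimated = obj$k_estimated,
           beta = setNames(unlist(obj$beta), design$column_labels),
           design = design, fitted_log = NULL, residuals_log = NULL,
           data = NULL, correlation_profile = NULL),
      class = "fd_fit"
    )
  } else if (obj$model == "ffnn") {
    arch <- ffnn_arch(obj$arch$hidden, obj$arch$skip, obj$arch$decay)
    params <- make_params(obj$theta, arch, length(design$column_labels),
                          design$column_labels)
    structure(
      list(params = params, restart_losses = NULL, arch = arch,
           design = design, data = NULL, seed = obj$seed),
      class = "ffnn_fit"
    )
  } else {
    abort(sprintf("unknown model type in %s: %s", path, obj$model),
          class = "devtiming_value_error")
  }
}
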