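# Serialization: expert statistics (JSON, with a CSV mirror), training traces
# (CSV), run manifests (JSON), prior specs (JSON). Plain-text formats only.

#' Save expert statistics to JSON
#'
#' One record per statistic: id, target, technique, quantile probabilities
#' where applicable, and the values.
#'
#' @param expert an `"expert_statistics"` object.
#' @param path output file.
#' @export
save_expert_statistics <- function(expert, path) {
  obj <- list(
    statistics = lapply(expert$records, function(r) {
      r[!vapply(r, is.null, TRUE)]
    }),
    provenance = list(lambda_star = as.list(attr(expert, "lambda_star")),
                      S_expert = attr(expert, "S_expert"),
                      seed = attr(expert, "seed"),
                      study = attr(expert, "study")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load and validate expert statistics from JSON
#'
#' Schema violations (missing fields, unknown techniques, non-monotone
#' quantiles, non-finite values, empty statistic list) are collected and
#' reported together.
#'
#' @param path JSON file written by [save_expert_statistics()] (or following
#'   the same schema).
#' @return an `"expert_statistics"` object.
#' @export
load_expert_statistics <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  stats <- obj$statistics
  errs <- character()
  if (length(stats) < 1) errs <- c(errs, "empty statistic list")
  records <- lapply(seq_along(stats), function(i) {
    r <- stats[[i]]
    lab <- r$id %||% paste0("record ", i)
    for (f in c("id", "target", "technique", "values"))
      if (is.null(r[[f]]))
        errs <<- c(errs, paste0(lab, ": missing field '", f, "'"))
    vals <- as.numeric(unlist(r$values))
    if (length(vals) && any(!is.finite(vals)))
      errs <<- c(errs, paste0(lab, ": non-finite values"))
    tech <- r$technique %||% ""
    if (!tech %in% c("quantiles", "moments", "histogram"))
      errs <<- c(errs, paste0(lab, ": unknown technique '", tech, "'"))
    if (identical(tech, "quantiles") && is.unsorted(vals))
      errs <<- c(errs, paste0(lab, ": non-monotone quantiles"))
    if (identical(tech, "moments") &&
        (length(vals) != 2 || vals[2] < 0))
      errs <<- c(errs, paste0(lab, ": moments must be (mean, sd >= 0)"))
    list(id = r$id, target = r$target, technique = tech,
         p = if (!is.null(r$p)) as.numeric(unlist(r$p)), values = vals)
  })
  if (length(errs))
    stop("invalid expert statistics file:\n  ", paste(errs, collapse = "\n  "))
  prov <- obj$provenance
  structure(list(records = records), class = "expert_statistics",
            lambda_star = unlist(prov$lambda_star), S_expert = prov$S_expert,
            seed = prov$seed, study = prov$study)
}

#' Export expert statistics as CSV
#'
#' Long format: one row per value (id, target, technique, index, p, value).
#' @inheritParams save_expert_statistics
#' @export
export_expert_statistics_csv <- function(expert, path) {
  rows <- do.call(rbind, lapply(expert$records, function(r) {
    k <- seq_along(r$values)
    data.frame(id = r$id, target = r$target, technique = r$technique,
               index = k,
               p = if (!is.null(r$p)) r$p[k] else NA_real_,
               value = r$values)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Export a training trace as CSV
#'
#' One row per epoch x loss component, plus the total, learning rate and
#' natural-scale hyperparameters (wide columns prefixed `lambda.`).
#'
#' @param trace a `"training_trace"`.
#' @param path output file.
#' @export
export_trace_csv <- function(trace, path) {
  E <- trace$epochs
  M <- ncol(trace$loss)
  lam <- trace$lambda_nat
  colnames(lam) <- paste0("lambda.", trace$names)
  long <- data.frame(
    epoch = rep(seq_len(E), each = M),
    component = rep(colnames(trace$loss), E),
    loss = as.numeric(t(trace$loss)),
    weight = as.numeric(t(trace$weights)),
    total = rep(trace$total, each = M),
    lr = rep(trace$lr, each = M))
  long <- cbind(long, lam[rep(seq_len(E), each = M), , drop = FALSE])
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Enough to reproduce the run bit-identically with the same build: the
#' configuration, seeds, final hyperparameters, diagnostics flags, and the
#' paths of the artifacts written alongside.
#'
#' @param trace a `"training_trace"`.
#' @param path output JSON file.
#' @param extra named list merged into the manifest (e.g. file paths, study).
#' @export
write_manifest <- function(trace, path, extra = list()) {
  cfg <- trace$config
  cfg$init <- NULL
  rep <- convergence_report(trace, window = min(cfg$window, trace$epochs))
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("priormatch")),
    config = unclass(cfg),
    final_lambda = as.list(to_natural(final_estimate(
      trace, window = min(cfg$window, trace$epochs)))),
    diagnostics = list(converged = rep$converged,
                       total_slope = rep$total_slope,
                       max_abs_grad = rep$max_abs_grad,
                       divergence_events = rep$divergence_events),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize a prior specification to JSON
#' @param spec a [prior_spec()].
#' @param path output file.
#' @export
save_prior_spec <- function(spec, path) {
  jsonlite::write_json(list(components = spec$components), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a prior specification from JSON
#' @param path JSON file.
#' @return a [prior_spec()].
#' @export
load_prior_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  prior_spec(obj$components)
}

#' Export a design matrix as CSV (header row, one column per predictor)
#' @param design a [design_matrix()].
#' @param path output file.
#' @export
export_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design$X), path, row.names = FALSE)
  invisible(path)
}

#' Import a design matrix from CSV
#' @param path CSV with a header row.
#' @param meta optional metadata list.
#' @return a [design_matrix()].
#' @export
import_design_csv <- function(path, meta = list()) {
  design_matrix(as.matrix(utils::read.csv(path, check.names = FALSE)), meta)
}
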