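# Versioned text (JSON) model files — adapted forests stay diffable and
# portable — and the TSV prediction report.

MODEL_FORMAT <- "selforest-model"
MODEL_VERSION <- 1L

#' Save a forest to a versioned JSON model file
#'
#' The schema is plain JSON: a `format`/`version` envelope, the forest
#' kind, classes, feature names, optional standardization parameters,
#' the training configuration, and one object per tree holding the
#' variant tag and the flat node table (full-precision numbers, so
#' `load_model(save_model(f))` reproduces identical trees and
#' predictions).
#'
#' @param forest A `selforest_forest`.
#' @param path Output path.
#' @export
save_model <- function(forest, path) {
  stopifnot(inherits(forest, "selforest_forest"))
  obj <- list(
    format = MODEL_FORMAT,
    version = MODEL_VERSION,
    kind = forest$kind,
    classes = forest$classes,
    feature_names = forest$feature_names,
    standardization = if (!is.null(forest$standardization)) {
      list(center = unname(forest$standardization$center),
           scale = unname(forest$standardization$scale))
    },
    config = unclass(forest$config),
    trees = lapply(forest$trees, function(tr) {
      list(variant = tr$variant,
           nodes = lapply(as.list(tr$nodes), unname))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = FALSE)
  invisible(path)
}

#' Load a forest from a JSON model file
#'
#' @param path Path written by [save_model()]. A wrong `format` or
#'   `version` field raises an incompatibility error.
#' @return A `selforest_forest`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, MODEL_FORMAT) ||
      !identical(as.integer(obj$version), MODEL_VERSION)) {
    stop(sprintf(
      "incompatible model file (format '%s' version %s; expected '%s' version %d)",
      obj$format %||% "?", obj$version %||% "?", MODEL_FORMAT,
      MODEL_VERSION), call. = FALSE)
  }
  classes <- obj$classes
  std <- NULL
  if (!is.null(obj$standardization)) {
    std <- structure(list(
      center = stats::setNames(obj$standardization$center,
                               obj$feature_names),
      scale = stats::setNames(obj$standardization$scale,
                              obj$feature_names)),
      class = "standardization")
  }
  trees <- lapply(seq_len(nrow(obj$trees)), function(i) {
    nodes <- as.data.frame(lapply(obj$trees$nodes[i, ], unlist),
                           stringsAsFactors = FALSE)
    structure(list(nodes = nodes, variant = obj$trees$variant[i],
                   classes = classes),
              class = "selforest_tree")
  })
  cfg <- obj$config
  config <- if (!is.null(cfg)) do.call(forest_config, as.list(cfg))
  structure(list(trees = trees, kind = obj$kind, classes = classes,
                 config = config, standardization = std,
                 feature_names = obj$feature_names),
            class = "selforest_forest")
}

#' Write a prediction report
#'
#' Tab-separated report in Symbol / log(omega) / log(phi) / Class /
#' Prob. order. Because the model was adapted to an unlabeled target
#' domain its accuracy cannot be measured directly, so the first line of
#' the file is always a comment containing the warning
#' `accuracy unknown`.
#'
#' @param records Data frame with columns `gene`, `log_omega`,
#'   `log_phi`, `class_label`, `probability` (see
#'   [prediction_records()]).
#' @param path Output path.
#' @export
write_predictions <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(
    "# accuracy unknown: predictions come from a model adapted to an",
    "unlabeled target domain; interpret with caution"), con)
  header <- c("Symbol", "log(omega)", "log(phi)", "Class", "Prob.")
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(records)) {
    lines <- paste(records$gene,
                   format(records$log_omega, trim = TRUE),
                   format(records$log_phi, trim = TRUE),
                   records$class_label,
                   format(records$probability, trim = TRUE),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Merge classifications with selection estimates into report records
#'
#' @param classified Output of [classify()].
#' @param features Data frame holding `gene`, `log_omega`, `log_phi`
#'   (e.g. from [build_feature_matrix()]).
#' @return Data frame ready for [write_predictions()].
#' @export
prediction_records <- function(classified, features) {
  i <- match(classified$gene, features$gene)
  if (anyNA(i)) {
    stop("classified genes missing from the feature table", call. = FALSE)
  }
  data.frame(gene = classified$gene,
             log_omega = features$log_omega[i],
             log_phi = features$log_phi[i],
             class_label = classified$class_label,
             probability = classified$probability,
             stringsAsFactors = FALSE)
}
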