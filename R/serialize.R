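## Versioned JSON serialization of the Stage-2 models (coefficients,
## centroids, percentile grids, tree node lists); models reload
## bit-identically (digits = NA keeps full double precision).

model_kind <- function(model) {
  if (inherits(model, "cluster_model")) "cluster"
  else if (inherits(model, "fuzzy_model")) "fuzzy"
  else if (inherits(model, "lda_model")) "lda"
  else if (inherits(model, "beat_tree")) "tree"
  else stop("not a serializable model: ", paste(class(model), collapse = "/"))
}

#' Serialize a Stage-2 model to JSON
#'
#' @param model a `cluster_model`, `fuzzy_model`, `lda_model` or `beat_tree`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
model_to_json <- function(model, path = NULL) {
  doc <- list(format = "hbclass/model", version = 1L,
              kind = model_kind(model), payload = unclass(model))
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Restore a Stage-2 model from JSON
#'
#' @param json a JSON string or file path produced by [model_to_json()].
#' @return The model with its original class.
#' @export
model_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE,
                            simplifyMatrix = TRUE)
  if (!identical(doc$format, "hbclass/model")) stop("not a model document")
  p <- doc$payload
  switch(doc$kind,
    cluster = structure(list(
      k = as.integer(p$k),
      centroids = matrix(unlist(p$centroids), nrow = p$k),
      labels = as.character(p$labels),
      replicate_score = p$replicate_score,
      feature_names = p$feature_names), class = "cluster_model"),
    fuzzy = structure(list(
      # per-class lists of equal-length vectors come back as a matrix
      # (rows = features); re-split them
      dist = lapply(p$dist, function(cl) {
        if (is.matrix(cl)) lapply(asplit(cl, 1), as.numeric)
        else lapply(cl, as.numeric)
      }),
      p = as.integer(p$p),
      feature_names = p$feature_names), class = "fuzzy_model"),
    lda = structure(list(
      mu1 = as.numeric(p$mu1), mu2 = as.numeric(p$mu2),
      sigma_pooled = matrix(unlist(p$sigma_pooled), length(p$mu1)),
      a_hat = as.numeric(p$a_hat), priors = as.numeric(p$priors),
      threshold = p$threshold, std_coeffs = as.numeric(p$std_coeffs),
      feature_names = p$feature_names, aper = p$aper), class = "lda_model"),
    tree = {
      nodes <- as.data.frame(p$nodes)
      structure(list(nodes = nodes, criterion = p$criterion,
                     priors = as.numeric(p$priors),
                     min_impure = p$min_impure, n = p$n,
                     feature_names = p$feature_names,
                     prune_sequence = if (is.null(p$prune_sequence)) NULL
                                      else as.data.frame(p$prune_sequence)),
                class = "beat_tree")
    },
    stop("unknown model kind: ", doc$kind))
}
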