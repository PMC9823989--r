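# plain-list (YAML-safe) representations of fitted models

bc_to_list <- function(bc) {
  out <- unclass(bc)
  out$sv <- list(
    nrow = nrow(bc$sv), ncol = ncol(bc$sv),
    data = as.numeric(t(bc$sv)) # row-major
  )
  out$platt <- as.list(bc$platt)
  out
}

bc_from_list <- function(x) {
  x$sv <- matrix(as.numeric(x$sv$data), nrow = x$sv$nrow, byrow = TRUE)
  x$sv_coefs <- as.numeric(x$sv_coefs)
  x$platt <- setNames(as.numeric(x$platt[c("A", "B")]), c("A", "B"))
  x$features <- as.character(x$features)
  structure(x, class = "binary_classifier")
}

serialize_model <- function(model) {
  if (inherits(model, "stager")) {
    list(
      type = "stager",
      recognizers = purrr::map(model$recognizers, unclass),
      fusion = purrr::map(unclass(model$fusion), bc_to_list),
      control = model$control
    )
  } else if (inherits(model, "quality_model")) {
    list(
      type = "quality_model",
      classifier = bc_to_list(model$classifier),
      cv = model$cv,
      feature_names = model$feature_names
    )
  } else {
    abort("cannot serialize this model type.")
  }
}

deserialize_model <- function(x) {
  if (identical(x$type, "stager")) {
    recognizers <- purrr::map(x$recognizers, function(r) {
      r$features <- as.character(r$features)
      r$flip <- as.character(r$flip)
      r$k <- as.numeric(r$k)
      structure(r, class = "recognizer")
    })
    fusion <- structure(purrr::map(x$fusion, bc_from_list), class = "fusion_model")
    structure(
      list(recognizers = recognizers, fusion = fusion, control = x$control),
      class = "stager"
    )
  } else if (identical(x$type, "quality_model")) {
    structure(
      list(
        classifier = bc_from_list(x$classifier),
        cv = x$cv,
        feature_names = as.character(x$feature_names)
      ),
      class = "quality_model"
    )
  } else {
    abort("unknown model bundle type.")
  }
}
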