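#' Construct a feature stack
#'
#' A named collection of co-registered `rows x cols` feature layers
#' (spectral indices, moment-distance rasters, texture measures) with a
#' per-layer provenance record of the operation and parameters that
#' produced it.
#'
#' @param layers Named list of numeric matrices sharing one shape.
#' @param provenance Optional named list (same names) of character
#'   strings describing how each layer was computed.
#' @return An object of class `feature_stack`.
#' @export
feature_stack <- function(layers = list(), provenance = list()) {
  if (length(layers)) {
    nm <- names(layers)
    if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
      stop("layers must have unique non-empty names")
    }
    d <- dim(layers[[1L]])
    ok <- vapply(layers, function(l) is.matrix(l) && identical(dim(l), d),
                 logical(1))
    if (!all(ok)) stop("all layers must be matrices of one shared shape")
  }
  structure(list(layers = layers, provenance = provenance),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- if (length(x$layers)) dim(x$layers[[1L]]) else c(0L, 0L)
  cat("<feature_stack> ", length(x$layers), " layers of ", d[1L], " x ",
      d[2L], ": ", paste(names(x$layers), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
names.feature_stack <- function(x) names(x$layers)

#' Add or replace a layer
#' @param stack A [feature_stack()].
#' @param name Layer name.
#' @param values `rows x cols` matrix.
#' @param provenance Description of the producing operation.
#' @return The updated stack.
#' @export
fs_add <- function(stack, name, values, provenance = NA_character_) {
  if (length(stack$layers) &&
      !identical(dim(values), dim(stack$layers[[1L]]))) {
    stop("layer '", name, "' shape does not match the stack")
  }
  stack$layers[[name]] <- values
  stack$provenance[[name]] <- provenance
  stack
}

#' Combine feature stacks
#' @param ... [feature_stack()] objects with disjoint layer names.
#' @return A single combined stack.
#' @export
fs_bind <- function(...) {
  stacks <- list(...)
  out <- feature_stack()
  for (s in stacks) {
    for (nm in names(s$layers)) {
      if (nm %in% names(out$layers)) stop("duplicate layer name '", nm, "'")
      out <- fs_add(out, nm, s$layers[[nm]],
                    if (!is.null(s$provenance[[nm]])) s$provenance[[nm]]
                    else NA_character_)
    }
  }
  out
}

#' Flatten a stack to a pixels-by-features matrix
#' @param x A [feature_stack()].
#' @param ... Unused.
#' @return Matrix with one column per layer, pixels in column-major order.
#' @export
as.matrix.feature_stack <- function(x, ...) {
  if (!length(x$layers)) return(matrix(numeric(0), 0, 0))
  do.call(cbind, lapply(x$layers, as.vector))
}
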