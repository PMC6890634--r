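#' Min-max scaling of the medium factors
#'
#' The Gaussian kernel works on Euclidean distances, so the four factors
#' (whose raw ranges differ by two orders of magnitude) are mapped to
#' \[0, 1\] before any distance is taken. `fit_scaler()` learns the per-column
#' minimum and range; `scale_factors()` applies the map and
#' `unscale_factors()` inverts it exactly. A constant column maps to 0.
#'
#' @param data A data frame or matrix containing `cols`.
#' @param cols Columns to scale (default [medium_factors()]).
#' @return `fit_scaler()` returns a `factor_scaler` object; `scale_factors()`
#'   and `unscale_factors()` return a numeric matrix with one column per
#'   scaled factor.
#' @export
#' @examples
#' sc <- fit_scaler(chrysanthemum_treatments())
#' head(scale_factors(sc, chrysanthemum_treatments()))
fit_scaler <- function(data, cols = medium_factors()) {
  x <- as_factor_matrix(data, cols)
  if (nrow(x) == 0) abort("cannot fit a scaler on empty data")
  mins <- apply(x, 2, min)
  ranges <- apply(x, 2, max) - mins
  structure(
    list(cols = cols, min = mins, range = ranges),
    class = "factor_scaler"
  )
}

#' @rdname fit_scaler
#' @param scaler A `factor_scaler` from `fit_scaler()`.
#' @export
scale_factors <- function(scaler, data) {
  stopifnot(inherits(scaler, "factor_scaler"))
  x <- as_factor_matrix(data, scaler$cols)
  rng <- ifelse(scaler$range == 0, 1, scaler$range)
  sweep(sweep(x, 2, scaler$min, "-"), 2, rng, "/")
}

#' @rdname fit_scaler
#' @export
unscale_factors <- function(scaler, data) {
  stopifnot(inherits(scaler, "factor_scaler"))
  x <- as_factor_matrix(data, scaler$cols)
  rng <- ifelse(scaler$range == 0, 1, scaler$range)
  sweep(sweep(x, 2, rng, "*"), 2, scaler$min, "+")
}

#' @export
print.factor_scaler <- function(x, ...) {
  cat("<factor_scaler>\n")
  print(tibble::tibble(
    factor = x$cols, min = unname(x$min),
    range = unname(x$range)
  ))
  invisible(x)
}

# Accept a data frame with named columns, or a bare matrix/vector assumed to
# already be in column order.
as_factor_matrix <- function(data, cols) {
  if (is.data.frame(data)) {
    missing <- setdiff(cols, names(data))
    if (length(missing)) {
      abort(paste0("missing columns: ", paste(missing, collapse = ", ")))
    }
    x <- as.matrix(data[cols])
  } else if (is.matrix(data)) {
    if (ncol(data) != length(cols)) {
      abort("matrix input must have one column per factor")
    }
    x <- data
  } else {
    if (length(data) != length(cols)) {
      abort("vector input must have one value per factor")
    }
    x <- matrix(as.numeric(data), nrow = 1)
  }
  colnames(x) <- cols
  storage.mode(x) <- "double"
  x
}
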