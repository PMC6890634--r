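#' Variable sensitivity error (VSE)
#'
#' Model error when one input is "not available": the indicated factor
#' column is replaced, for every record, by its mean over the full dataset
#' (hold-at-mean substitution; the fitted model is untouched) and the
#' prediction error against the observed response is recomputed. A variable
#' the model ignores leaves the error unchanged; an influential variable
#' inflates it.
#'
#' @param model A fitted `rbf_model`.
#' @param records Replicate records with factor and response columns
#'   (typically the full dataset, training plus testing).
#' @param variable Factor to knock out: a name from [medium_factors()] or an
#'   index 1-4.
#' @param metric `"rmse"` (default) or `"mse"`.
#' @param refit Optional refit function implementing the alternative
#'   "retrain without the variable" mechanism: called as
#'   `refit(records, variable)` and expected to return predictions for
#'   `records`. Default `NULL` uses hold-at-mean substitution.
#' @return The error (response units for RMSE).
#' @export
vse <- function(model, records, variable, metric = c("rmse", "mse"),
                refit = NULL) {
  metric <- match.arg(metric)
  fac <- medium_factors()
  if (is.numeric(variable)) {
    if (variable < 1 || variable > length(fac)) abort("invalid variable index")
    variable <- fac[variable]
  }
  if (!variable %in% fac) abort(sprintf("unknown factor '%s'", variable))
  if (nrow(records) == 0) abort("records is empty")
  y <- records[[model$response]]
  pred <- if (is.null(refit)) {
    sub <- records
    sub[[variable]] <- mean(records[[variable]])
    predict(model, sub)
  } else {
    refit(records, variable)
  }
  if (metric == "rmse") sqrt(mean((y - pred)^2)) else mean((y - pred)^2)
}

#' VSE/VSR sensitivity report for all responses and factors
#'
#' For every fitted surrogate, computes the variable sensitivity error of
#' each factor and the variable sensitivity ratio
#' `VSR = VSE / full-model error` on the same records. A VSR near 1 means
#' the factor hardly matters; larger VSR means the model leans on it more.
#' Factors are ranked 1-4 per response by descending VSR, with ties broken
#' by factor order.
#'
#' @param models Named list of `rbf_model`s (`pr`, `sn`, `sl`, `bcw` or any
#'   subset).
#' @param records Records to evaluate on (conventionally the entire dataset,
#'   training and testing together).
#' @param metric Error metric passed to [vse()].
#' @return A tibble with columns `response`, `factor`, `vse`, `error_full`,
#'   `vsr`, `rank`.
#' @export
#' @examples
#' \donttest{
#' reps <- simulate_replicates(chrysanthemum_treatments(), seed = 1)
#' ctl <- rbf_control(spread_grid = 0.2, max_centers = 40)
#' m <- list(pr = rbf_fit(reps, "pr", control = ctl))
#' sensitivity_vsr(m, reps)
#' }
sensitivity_vsr <- function(models, records, metric = c("rmse", "mse")) {
  metric <- match.arg(metric)
  fac <- medium_factors()
  rows <- lapply(names(models), function(resp) {
    model <- models[[resp]]
    y <- records[[model$response]]
    pred <- predict(model, records)
    full <- if (metric == "rmse") {
      sqrt(mean((y - pred)^2))
    } else {
      mean((y - pred)^2)
    }
    if (full == 0) {
      abort(paste0(
        "full-model error is zero for '", resp,
        "': the model interpolates these records and VSR is undefined"
      ))
    }
    errs <- vapply(fac, function(v) vse(model, records, v, metric), numeric(1))
    out <- tibble::tibble(
      response = resp, factor = fac,
      vse = unname(errs), error_full = full, vsr = unname(errs) / full
    )
    # descending VSR; ties keep factor order (BAP, IBA, PG, sucrose)
    out$rank <- rank(-out$vsr, ties.method = "first")
    out
  })
  dplyr::bind_rows(rows)
}

#' Bar chart of variable sensitivity ratios
#'
#' @param report Tibble from [sensitivity_vsr()].
#' @return A ggplot object, one panel per response.
#' @export
plot_sensitivity <- function(report) {
  ggplot2::ggplot(
    report,
    ggplot2::aes(.data$factor, .data$vsr, fill = .data$factor)
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~response, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "variable sensitivity ratio (VSE / full error)"
    )
}
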