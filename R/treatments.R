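#' Chrysanthemum shoot-proliferation factorial experiment
#'
#' Treatment-level results of a 3^4 full factorial tissue-culture experiment
#' on chrysanthemum 'Hornbill Dark' single-node explants: three levels each of
#' BAP (0, 2.22, 4.44 uM), IBA (0, 0.25, 0.49 uM), phloroglucinol
#' (0, 0.2, 0.4 mM) and sucrose (43.82, 87.64, 131.46 mM), with the mean and
#' standard error of four growth responses per treatment (proliferation rate,
#' shoot number, shoot length, basal callus weight). Each printed mean
#' summarizes nine repetitions; media without cytokinin (BAP = 0) produced no
#' regeneration, so those treatments are exact zeros with zero SE.
#'
#' @return A tibble with 81 rows and 12 columns: the four factor columns
#'   (`bap_uM`, `iba_uM`, `pg_mM`, `sucrose_mM`) followed by
#'   `<response>_mean` and `<response>_se` for `pr`, `sn`, `sl`, `bcw`.
#'   Rows are ordered with IBA varying fastest, then BAP, PG and sucrose.
#' @seealso [simulate_replicates()] to expand the table to replicate-level
#'   records, [read_treatments()] to load a user table of the same schema.
#' @export
#' @examples
#' trt <- chrysanthemum_treatments()
#' dplyr::filter(trt, bap_uM == 2.22, iba_uM == 0.25, pg_mM == 0.2)
chrysanthemum_treatments <- function() {
  path <- system.file("extdata", "table1_treatments.csv",
    package = "mediumopt", mustWork = TRUE
  )
  read_treatments(path)
}

treatment_schema <- function() {
  c(
    medium_factors(),
    as.vector(t(outer(growth_responses(), c("_mean", "_se"), paste0)))
  )
}

#' Read or write a treatment-level table
#'
#' CSV schema: the four factor columns (`bap_uM`, `iba_uM`, `pg_mM`,
#' `sucrose_mM`) followed by `{pr,sn,sl,bcw}_{mean,se}`; header required,
#' decimal point, UTF-8.
#'
#' @param path File path.
#' @param x For `write_treatments()`, a treatment tibble of the above schema.
#' @return `read_treatments()` returns a validated tibble;
#'   `write_treatments()` returns `path` invisibly.
#' @export
read_treatments <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_treatments(x)
}

#' @rdname read_treatments
#' @export
write_treatments <- function(x, path) {
  validate_treatments(x)
  readr::write_csv(x, path)
  invisible(path)
}

validate_treatments <- function(x) {
  missing <- setdiff(treatment_schema(), names(x))
  if (length(missing)) {
    abort(paste0(
      "treatment table is missing columns: ",
      paste(missing, collapse = ", ")
    ))
  }
  x <- tibble::as_tibble(x)[treatment_schema()]
  se_cols <- paste0(growth_responses(), "_se")
  if (any(as.matrix(x[se_cols]) < 0)) {
    abort("standard errors must be non-negative")
  }
  if (any(x$pr_mean < 0 | x$pr_mean > 100)) {
    abort("pr_mean must lie in [0, 100]")
  }
  mean_cols <- paste0(growth_responses(), "_mean")
  if (any(as.matrix(x[mean_cols]) < 0)) {
    abort("response means must be non-negative")
  }
  x
}

#' Observed bounds of each medium factor
#'
#' The closed range of every factor in a treatment (or replicate) table.
#' These ranges are used as box constraints during optimization: the RBF
#' surrogates interpolate well but extrapolate poorly, so recipes are never
#' sought outside the experimental region.
#'
#' @param data A data frame containing the [medium_factors()] columns.
#' @return A tibble with columns `factor`, `lower`, `upper`.
#' @export
#' @examples
#' factor_bounds(chrysanthemum_treatments())
factor_bounds <- function(data) {
  fac <- medium_factors()
  missing <- setdiff(fac, names(data))
  if (length(missing)) {
    abort(paste0("missing factor columns: ", paste(missing, collapse = ", ")))
  }
  tibble::tibble(
    factor = fac,
    lower = unname(vapply(data[fac], min, numeric(1))),
    upper = unname(vapply(data[fac], max, numeric(1)))
  )
}

#' Best observed value of each response (the ideal point)
#'
#' The ideal point gathers, over the observed data, the maximum proliferation
#' rate, shoot number and shoot length together with the minimum basal callus
#' weight. It is the reference against which Pareto-front members are scored
#' by scaled Euclidean distance (see [select_ideal()]).
#'
#' Accepts either a replicate-level table (columns `pr`, `sn`, `sl`, `bcw`)
#' or a treatment-level table (columns `pr_mean`, ..., `bcw_mean`).
#'
#' @param data A data frame of observed responses.
#' @return A one-row tibble with columns `pr`, `sn`, `sl`, `bcw`.
#' @export
#' @examples
#' ideal_point(chrysanthemum_treatments())
ideal_point <- function(data) {
  resp <- growth_responses()
  cols <- if (all(resp %in% names(data))) {
    resp
  } else if (all(paste0(resp, "_mean") %in% names(data))) {
    paste0(resp, "_mean")
  } else {
    abort("data must contain pr/sn/sl/bcw columns (raw or *_mean)")
  }
  if (nrow(data) == 0) abort("data is empty")
  tibble::tibble(
    pr = max(data[[cols[1]]]),
    sn = max(data[[cols[2]]]),
    sl = max(data[[cols[3]]]),
    bcw = min(data[[cols[4]]])
  )
}
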