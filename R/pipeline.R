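# per-response observed min/max, accepting replicate or treatment schema
observed_response_ranges <- function(records) {
  resp <- growth_responses()
  cols <- if (all(resp %in% names(records))) {
    resp
  } else if (all(paste0(resp, "_mean") %in% names(records))) {
    paste0(resp, "_mean")
  } else {
    abort("records must contain pr/sn/sl/bcw columns (raw or *_mean)")
  }
  out <- lapply(seq_along(resp), function(j) range(records[[cols[j]]]))
  names(out) <- resp
  tibble::as_tibble(out)
}

#' Bundle four fitted surrogates into a 4-objective function
#'
#' Maps a decision matrix (medium compositions in original units) to the
#' internal minimization objectives `(-PR, -SN, -SL, +BCW)`, so minimizing
#' all four simultaneously maximizes proliferation rate, shoot number and
#' shoot length while minimizing basal callus weight. Raw surrogate outputs
#' are used (no clipping) to keep the objective landscape smooth; clipping to
#' physical bounds happens only when predictions are reported.
#'
#' @param models Named list of `rbf_model` objects with entries `pr`, `sn`,
#'   `sl`, `bcw`.
#' @return A function taking a numeric matrix (rows = decision vectors in
#'   [medium_factors()] order) and returning a 4-column objective matrix.
#' @export
build_objectives <- function(models) {
  resp <- growth_responses()
  missing <- setdiff(resp, names(models))
  if (length(missing)) {
    abort(paste0("missing models for: ", paste(missing, collapse = ", ")))
  }
  sign <- c(pr = -1, sn = -1, sl = -1, bcw = 1)
  function(X) {
    X <- as_factor_matrix(X, medium_factors())
    out <- vapply(
      resp,
      function(r) sign[[r]] * predict(models[[r]], X),
      numeric(nrow(X))
    )
    if (!is.matrix(out)) out <- matrix(out, nrow = 1)
    colnames(out) <- resp
    out
  }
}

#' Select the compromise solution closest to the ideal point
#'
#' Every objective is min-max scaled to \[0, 1\]; each front member is then
#' scored by the Euclidean distance
#' `sqrt((PR - m)^2 + (SN - n)^2 + (SL - o)^2 + (BCW - p)^2)` on the scaled
#' values, where `(m, n, o, p)` is the scaled ideal. The member with minimal
#' distance is selected; ties are broken by smaller predicted BCW, then by
#' lexicographic decision vector.
#'
#' The scaling set is controlled by `scale_bounds`. When the observed-data
#' extremes are supplied (the default used by [optimize_medium()]), every
#' objective lives on the fixed scale of the experiment and the scaled ideal
#' sits at `(1, 1, 1, 0)`; surrogate predictions that overshoot an observed
#' extreme may scale slightly outside \[0, 1\], which leaves the distance
#' well-defined. When `scale_bounds` is `NULL`, each objective is scaled
#' over the union of the front predictions and the ideal value, which
#' guarantees a distance of zero exactly when the ideal is attained but
#' makes the scale depend on the front composition. An objective with zero
#' range contributes nothing either way.
#'
#' @param front A tibble with the four factor columns and the four predicted
#'   response columns `pr`, `sn`, `sl`, `bcw` (model scale, unclipped).
#' @param ideal One-row tibble from [ideal_point()].
#' @param scale_bounds Optional two-row data frame (rows = min, max) with
#'   columns `pr`, `sn`, `sl`, `bcw` giving the scaling range per objective;
#'   `NULL` scales over the front-plus-ideal pool.
#' @return A list with `index` (selected row), `distance` (scaled distance of
#'   every member, numeric vector) and `selected` (the winning row of
#'   `front`).
#' @export
select_ideal <- function(front, ideal, scale_bounds = NULL) {
  if (nrow(front) == 0) abort("front is empty")
  resp <- growth_responses()
  pred <- as.matrix(front[resp])
  ideal_v <- as.numeric(ideal[1, resp])

  scaled <- matrix(0, nrow(pred), 4, dimnames = list(NULL, resp))
  ideal_s <- numeric(4)
  for (j in seq_along(resp)) {
    pool <- if (is.null(scale_bounds)) {
      c(pred[, j], ideal_v[j])
    } else {
      scale_bounds[[resp[j]]]
    }
    lo <- min(pool)
    rng <- max(pool) - lo
    if (rng > 0) {
      scaled[, j] <- (pred[, j] - lo) / rng
      ideal_s[j] <- (ideal_v[j] - lo) / rng
    }
  }
  d <- sqrt(rowSums(sweep(scaled, 2, ideal_s, "-")^2))

  ord <- order(
    d, pred[, "bcw"],
    front[[medium_factors()[1]]], front[[medium_factors()[2]]],
    front[[medium_factors()[3]]], front[[medium_factors()[4]]]
  )
  idx <- ord[1]
  list(index = idx, distance = d, selected = front[idx, ])
}

#' Optimize the medium composition over fitted surrogates
#'
#' The full surrogate-optimization step: the four RBF models become a
#' 4-objective function (maximize PR, SN, SL; minimize BCW), NSGA-II searches
#' the box spanned by the observed factor ranges, and the recommended recipe
#' is the Pareto-front member with minimal scaled distance to the ideal point
#' of the observed data.
#'
#' @param models Named list of `rbf_model`s (`pr`, `sn`, `sl`, `bcw`).
#' @param records Observed replicate (or treatment) records; they provide
#'   the optimization bounds (observed factor ranges), the ideal point and
#'   the default objective scaling ranges.
#' @param control An [nsga_control()] object.
#' @param scale_from `"observed"` (default) scales the ideal-point distance
#'   by the observed response ranges of `records`; `"front"` scales over the
#'   front-plus-ideal pool (see [select_ideal()]).
#' @return An object of class `medium_opt`: a list with `recipe` (one-row
#'   tibble of factor settings), `predicted` (one-row tibble of surrogate
#'   predictions at the recipe, clipped to physical bounds), `distance`
#'   (scaled ideal distance of the recipe), `front` (tibble of all
#'   non-dominated solutions with predictions on the biological scale and
#'   their distances), `ideal`, `bounds` and `control`.
#' @export
#' @examples
#' \donttest{
#' trt <- chrysanthemum_treatments()
#' reps <- simulate_replicates(trt, seed = 1)
#' ctl <- rbf_control(spread_grid = 0.2, max_centers = 40)
#' models <- purrr::map(
#'   setNames(growth_responses(), growth_responses()),
#'   ~ rbf_fit(reps, .x, control = ctl)
#' )
#' opt <- optimize_medium(models, reps,
#'   control = nsga_control(pop_size = 40, generations = 50, seed = 1)
#' )
#' glance(opt)
#' }
optimize_medium <- function(models, records, control = nsga_control(),
                            scale_from = c("observed", "front")) {
  scale_from <- match.arg(scale_from)
  bounds <- factor_bounds(records)
  ideal <- ideal_point(records)
  scale_bounds <- if (scale_from == "observed") {
    observed_response_ranges(records)
  } else {
    NULL
  }
  fn <- build_objectives(models)

  res <- nsga2(
    fn,
    lower = bounds$lower, upper = bounds$upper, control = control,
    decision_names = medium_factors(),
    objective_names = paste0("obj_", growth_responses())
  )

  front <- res$front[medium_factors()]
  # back to the biological scale: PR/SN/SL were negated for minimization
  front$pr <- -res$front$obj_pr
  front$sn <- -res$front$obj_sn
  front$sl <- -res$front$obj_sl
  front$bcw <- res$front$obj_bcw

  sel <- select_ideal(front, ideal, scale_bounds = scale_bounds)
  front$distance <- sel$distance

  recipe <- sel$selected[medium_factors()]
  predicted <- sel$selected[growth_responses()]
  for (r in growth_responses()) {
    b <- response_bounds(r)
    predicted[[r]] <- pmin(pmax(predicted[[r]], b[1]), b[2])
  }

  structure(
    list(
      recipe = recipe, predicted = predicted,
      distance = sel$distance[sel$index], front = front, ideal = ideal,
      bounds = bounds, control = control, pareto = res
    ),
    class = "medium_opt"
  )
}

#' @export
print.medium_opt <- function(x, ...) {
  cat("<medium_opt> recommended medium composition\n")
  print(x$recipe)
  cat("predicted responses (clipped to physical bounds):\n")
  print(x$predicted)
  cat(sprintf(
    "scaled ideal-point distance: %.4f (front of %d solutions)\n",
    x$distance, nrow(x$front)
  ))
  invisible(x)
}

#' @describeIn optimize_medium The full front: factor settings, predictions
#'   on the biological scale and scaled ideal distances.
#' @param x A `medium_opt`.
#' @method tidy medium_opt
#' @export
tidy.medium_opt <- function(x, ...) x$front

#' @describeIn optimize_medium One-row summary: recipe, clipped predictions
#'   and ideal distance.
#' @method glance medium_opt
#' @export
glance.medium_opt <- function(x, ...) {
  out <- dplyr::bind_cols(x$recipe, x$predicted)
  out$distance <- x$distance
  out$front_size <- nrow(x$front)
  out
}

#' @describeIn optimize_medium PR-SN view of the front coloured by BCW, with
#'   the selected recipe highlighted.
#' @param object A `medium_opt`.
#' @method autoplot medium_opt
#' @export
autoplot.medium_opt <- function(object, ...) {
  sel <- dplyr::bind_cols(object$recipe, object$predicted)
  ggplot2::ggplot(object$front, ggplot2::aes(.data$pr, .data$sn)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$bcw)) +
    ggplot2::geom_point(
      data = sel, shape = 4, size = 4, stroke = 1.5, colour = "red"
    ) +
    ggplot2::labs(
      title = "Pareto front of predicted responses",
      subtitle = "cross: recipe closest to the ideal point",
      x = "predicted PR (%)", y = "predicted SN"
    )
}
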