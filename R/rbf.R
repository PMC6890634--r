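#' Gaussian radial basis kernel
#'
#' Activation of a hidden unit centred at `xb` for an input `xr`:
#' `exp(-(||xr - xb|| * 0.8326 / h)^2)`. The constant 0.8326 (approximately
#' `sqrt(log(2))`) makes the activation exactly 0.5 when the input sits at
#' distance `h` (the spread) from the centre, which is the conventional
#' parameterization for RBF regression networks.
#'
#' @param xr,xb Numeric vectors of equal length (typically scaled factor
#'   coordinates).
#' @param h Spread, a positive scalar in the same (scaled) units as the
#'   coordinates.
#' @return A scalar in (0, 1\]; equals 1 iff `xr == xb`.
#' @export
#' @examples
#' rbf_kernel(c(0, 0), c(0, 0), h = 0.3) # 1
#' rbf_kernel(c(0.3, 0), c(0, 0), h = 0.3) # 0.5
rbf_kernel <- function(xr, xb, h) {
  if (!is.numeric(h) || length(h) != 1 || h <= 0) {
    abort("spread h must be a positive scalar")
  }
  if (length(xr) != length(xb)) abort("xr and xb must have equal length")
  d2 <- sum((xr - xb)^2)
  exp(-d2 * (0.8326 / h)^2)
}

# Kernel (design) matrix between scaled inputs X (n x d) and centers C
# (m x d). Squared distances via the usual Gram expansion; no sqrt needed
# because the kernel only uses the squared distance.
kernel_matrix <- function(X, C, h) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  d2[d2 < 0] <- 0
  exp(-d2 * (0.8326 / h)^2)
}

#' Control parameters for RBF fitting
#'
#' @param spread_grid Candidate spreads (scaled-input units) searched by
#'   K-fold cross-validation. The default grid spans widths from far
#'   narrower than the factorial level spacing (1/2 of a level step on the
#'   unit cube) to wider than the whole design region.
#' @param max_centers Maximum number of hidden units. The default 80 is just
#'   under the 81 distinct factorial locations of the built-in design, so a
#'   fit can allocate a centre to essentially every treatment cell.
#' @param goal_mse Training MSE at which centre addition stops early
#'   (default 0: grow until `max_centers` or candidate exhaustion).
#' @param k_folds Folds for cross-validated spread selection (default 5).
#' @param ridge Ridge term added to the normal equations of the weight solve
#'   (never applied to the bias). Guards near-singular activation matrices;
#'   at the default 1e-8 it is numerically invisible for well-posed fits.
#' @param cv_rule How the spread is picked from the cross-validation profile.
#'   `"stable_1se"` (default): among spreads whose mean CV MSE lies within
#'   one fold-standard-error of the minimum, take the widest kernel whose
#'   weight solve stays well-conditioned (see `kappa_max`). This follows the
#'   classic stability/accuracy trade-off of RBF interpolation - flatter
#'   kernels interpolate more smoothly between design points but their
#'   linear systems degrade - and matters here because a replicated
#'   factorial design leaves CV nearly flat in the spread (held-out points
#'   sit at the same design locations as the training points), so the bare
#'   minimum is an unstable coin flip that can land on an ill-conditioned
#'   fit whose predictions oscillate wildly between design cells.
#'   `"min"`: plain minimum mean CV MSE.
#' @param kappa_max Condition-number cap for `cv_rule = "stable_1se"`,
#'   applied to the normal-equations matrix actually solved (so the design
#'   matrix condition enters squared). Default `1/sqrt(.Machine$double.eps)`,
#'   the usual "half the significant digits survive" threshold.
#' @param seed Optional integer seed controlling the CV fold assignment.
#' @return A list of class `rbf_control`.
#' @export
rbf_control <- function(spread_grid = c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6),
                        max_centers = 80, goal_mse = 0, k_folds = 5,
                        ridge = 1e-8, cv_rule = c("stable_1se", "min"),
                        kappa_max = 1 / sqrt(.Machine$double.eps),
                        seed = NULL) {
  if (length(spread_grid) == 0 || any(spread_grid <= 0)) {
    abort("spread_grid must be non-empty and positive")
  }
  if (max_centers < 1) abort("max_centers must be >= 1")
  if (k_folds < 2) abort("k_folds must be >= 2")
  if (ridge < 0) abort("ridge must be >= 0")
  structure(
    list(
      spread_grid = spread_grid, max_centers = max_centers,
      goal_mse = goal_mse, k_folds = k_folds, ridge = ridge,
      cv_rule = match.arg(cv_rule), kappa_max = kappa_max, seed = seed
    ),
    class = "rbf_control"
  )
}

# Core trainer on pre-scaled inputs. Centres are chosen greedily: starting
# from a bias-only model, repeatedly promote the training input with the
# largest absolute residual (skipping locations already used) and re-solve
# the ridge least-squares problem for all weights plus bias.
rbf_train <- function(Xs, y, h, max_centers, goal_mse, ridge) {
  n <- nrow(Xs)
  max_centers <- min(max_centers, n)
  bias <- mean(y)
  resid <- y - bias
  centers <- matrix(numeric(0), 0, ncol(Xs))
  weights <- numeric(0)
  Phi <- matrix(numeric(0), n, 0)
  used <- rep(FALSE, n)
  mse <- mean(resid^2)

  # rows numerically identical to an existing centre are never re-added
  key <- apply(round(Xs, 12), 1, paste, collapse = "\r")
  used_keys <- character(0)

  while (ncol(Phi) < max_centers && mse > goal_mse) {
    ord <- order(abs(resid), decreasing = TRUE)
    cand <- ord[!used[ord] & !(key[ord] %in% used_keys)][1]
    if (is.na(cand)) break
    used[cand] <- TRUE
    used_keys <- c(used_keys, key[cand])
    centers <- rbind(centers, Xs[cand, , drop = FALSE])
    Phi <- cbind(Phi, kernel_matrix(Xs, Xs[cand, , drop = FALSE], h))
    m <- ncol(Phi)
    A <- cbind(1, Phi)
    G <- crossprod(A) + diag(c(0, rep(ridge, m)))
    b <- crossprod(A, y)
    coef <- tryCatch(
      solve(G, b),
      error = function(e) solve(G + diag(1e-10, m + 1), b)
    )
    bias <- coef[1]
    weights <- coef[-1]
    resid <- y - as.vector(A %*% coef)
    mse <- mean(resid^2)
  }
  list(
    centers = centers, weights = as.vector(weights), bias = bias,
    spread = h, train_mse = mse
  )
}

#' Fit a Gaussian RBF regression surrogate
#'
#' Trains a single-output radial-basis-function network on replicate-level
#' records. Inputs are min-max scaled to the unit cube; hidden centres are
#' added greedily at the training input with the largest absolute residual
#' under the current network; output weights and bias are re-estimated at
#' each step by ridge-stabilized linear least squares. The spread is chosen
#' from `control$spread_grid` by minimum mean K-fold cross-validation MSE
#' (one network per response, per the one-model-per-output design).
#'
#' @param data Replicate tibble containing the [medium_factors()] columns and
#'   the `response` column.
#' @param response Which response to model: one of [growth_responses()].
#' @param control An [rbf_control()] object.
#' @param scaler Optional pre-fitted [fit_scaler()] object; by default the
#'   scaler is fitted on `data`.
#' @return An object of class `rbf_model` with elements `centers`, `spread`,
#'   `weights`, `bias`, `scaler`, `response`, `cv` (spread-selection table)
#'   and `train_metrics`.
#' @seealso [predict.rbf_model()], [rbf_cv_mse()], [regression_metrics()]
#' @export
#' @examples
#' reps <- simulate_replicates(chrysanthemum_treatments(), seed = 1)
#' fit <- rbf_fit(reps, "sl",
#'   control = rbf_control(spread_grid = 0.2, max_centers = 40)
#' )
#' glance(fit)
rbf_fit <- function(data, response, control = rbf_control(), scaler = NULL) {
  stopifnot(inherits(control, "rbf_control"))
  if (!response %in% names(data)) {
    abort(sprintf("response column '%s' not found", response))
  }
  if (nrow(data) == 0) abort("cannot fit on empty data")
  scaler <- scaler %||% fit_scaler(data)
  Xs <- scale_factors(scaler, data)
  y <- as.numeric(data[[response]])

  cv <- NULL
  if (length(control$spread_grid) > 1) {
    folds <- lapply(
      control$spread_grid,
      function(h) cv_fold_mse(Xs, y, h, control)
    )
    cv <- tibble::tibble(
      spread = control$spread_grid,
      cv_mse = vapply(folds, mean, numeric(1)),
      cv_se = vapply(
        folds, function(f) sd(f) / sqrt(length(f)), numeric(1)
      )
    )
    h <- select_spread(cv, Xs, y, control)
  } else {
    h <- control$spread_grid
  }

  net <- rbf_train(
    Xs, y, h, control$max_centers, control$goal_mse,
    control$ridge
  )
  fitted <- rbf_eval(net, Xs)
  structure(
    list(
      centers = net$centers, spread = net$spread, weights = net$weights,
      bias = net$bias, scaler = scaler, response = response, cv = cv,
      control = control,
      train_metrics = if (var(y) > 0) regression_metrics(y, fitted) else NULL,
      fitted = fitted, y = y
    ),
    class = "rbf_model"
  )
}

rbf_eval <- function(net, Xs) {
  if (nrow(net$centers) == 0) {
    return(rep(net$bias, nrow(Xs)))
  }
  as.vector(kernel_matrix(Xs, net$centers, net$spread) %*% net$weights) +
    net$bias
}

#' Predict from a fitted RBF surrogate
#'
#' Evaluates the network sum `Y = sum_b w_b * f(x, center_b) + w_0` at new
#' medium compositions.
#'
#' @param object An `rbf_model`.
#' @param newdata A data frame with the factor columns, or a numeric matrix /
#'   vector in [medium_factors()] order (original units).
#' @param ... Unused.
#' @return Numeric vector of predictions in the response's units (raw network
#'   output; not clipped to physical bounds).
#' @export
predict.rbf_model <- function(object, newdata, ...) {
  Xs <- scale_factors(object$scaler, newdata)
  rbf_eval(object, Xs)
}

#' Cross-validated MSE for one candidate spread
#'
#' Partitions the records into `control$k_folds` seeded folds of sizes
#' differing by at most one, trains the greedy RBF on each complement and
#' scores mean squared error on the held-out fold.
#'
#' @inheritParams rbf_fit
#' @param spread Candidate spread (scaled-input units).
#' @return Mean held-out MSE across folds.
#' @export
rbf_cv_mse <- function(data, response, spread, control = rbf_control(),
                       scaler = NULL) {
  scaler <- scaler %||% fit_scaler(data)
  Xs <- scale_factors(scaler, data)
  y <- as.numeric(data[[response]])
  mean(cv_fold_mse(Xs, y, spread, control))
}

cv_fold_mse <- function(Xs, y, spread, control) {
  n <- nrow(Xs)
  k <- control$k_folds
  if (k > n) abort("k_folds exceeds the number of records")
  fold <- local({
    if (!is.null(control$seed)) withr::local_seed(control$seed)
    sample(rep(seq_len(k), length.out = n))
  })
  vapply(seq_len(k), function(i) {
    hold <- fold == i
    net <- rbf_train(
      Xs[!hold, , drop = FALSE], y[!hold], spread,
      control$max_centers, control$goal_mse, control$ridge
    )
    mean((y[hold] - rbf_eval(net, Xs[hold, , drop = FALSE]))^2)
  }, numeric(1))
}

# Spread selection from the CV profile. "min" is the bare argmin. The
# default "stable_1se" treats numerical stability as a hard constraint:
# spreads whose normal-equations solve exceeds the condition cap are
# discarded first, then - among the stable spreads within one fold-SE of
# the stable minimum - the widest (smoothest interpolant) is returned. If
# no spread is stable, the narrowest grid spread is used (narrow kernels
# give near-diagonal designs).
select_spread <- function(cv, Xs, y, control) {
  if (control$cv_rule == "min") {
    return(cv$spread[which.min(cv$cv_mse)])
  }
  stable <- vapply(cv$spread, function(h) {
    net <- rbf_train(
      Xs, y, h, control$max_centers, control$goal_mse,
      control$ridge
    )
    A <- cbind(1, kernel_matrix(Xs, net$centers, h))
    kappa(A, exact = FALSE)^2 <= control$kappa_max
  }, logical(1))
  if (!any(stable)) {
    return(min(cv$spread))
  }
  cv_s <- cv[stable, ]
  i_min <- which.min(cv_s$cv_mse)
  cap <- cv_s$cv_mse[i_min] + cv_s$cv_se[i_min]
  max(cv_s$spread[cv_s$cv_mse <= cap])
}

#' Goodness-of-fit metrics for observed vs. predicted values
#'
#' Computes the coefficient of determination
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, the root mean square
#' error, the mean absolute error (reported as `mbe`, matching the printed
#' mean-bias-error formula built on absolute differences) and the signed mean
#' bias `mean(y - yhat)` (the signed reading of the same statistic; both are
#' reported because either convention appears in practice).
#'
#' @param y_obs,y_pred Equal-length numeric vectors. When `y_obs` has zero
#'   variance R2 is undefined: it is reported as `NA` with a warning while
#'   the error metrics are still computed.
#' @return A one-row tibble with columns `r2`, `rmse`, `mbe`, `signed_bias`,
#'   `n`.
#' @export
#' @examples
#' regression_metrics(c(0, 1), c(3, 4)) # rmse sqrt(9), mbe 3
regression_metrics <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred)) {
    abort("y_obs and y_pred must have equal length")
  }
  if (length(y_obs) == 0) abort("empty input")
  err <- y_obs - y_pred
  r2 <- if (length(y_obs) > 1 && var(y_obs) > 0) {
    1 - sum(err^2) / sum((y_obs - mean(y_obs))^2)
  } else {
    warn("R2 is undefined when y_obs has zero variance; reporting NA")
    NA_real_
  }
  tibble::tibble(
    r2 = r2,
    rmse = sqrt(mean(err^2)),
    mbe = mean(abs(err)),
    signed_bias = mean(err),
    n = length(y_obs)
  )
}

#' @export
print.rbf_model <- function(x, ...) {
  cat(sprintf(
    "<rbf_model> response: %s | %d centers, spread %.4g\n",
    x$response, nrow(x$centers), x$spread
  ))
  if (!is.null(x$train_metrics)) {
    cat(sprintf(
      "  train R2 %.3f, RMSE %.4g\n",
      x$train_metrics$r2, x$train_metrics$rmse
    ))
  }
  invisible(x)
}

#' @describeIn rbf_fit One row per hidden unit: centre coordinates (original
#'   units) and output weight.
#' @param x An `rbf_model`.
#' @method tidy rbf_model
#' @export
tidy.rbf_model <- function(x, ...) {
  if (nrow(x$centers) == 0) {
    return(tibble::tibble())
  }
  orig <- unscale_factors(x$scaler, x$centers)
  out <- tibble::as_tibble(orig)
  out$weight <- x$weights
  out
}

#' @describeIn rbf_fit One-row model summary (response, size, spread, bias,
#'   training metrics, selected CV MSE).
#' @method glance rbf_model
#' @export
glance.rbf_model <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    n_centers = nrow(x$centers),
    spread = x$spread,
    bias = x$bias,
    r2 = x$train_metrics$r2 %||% NA_real_,
    rmse = x$train_metrics$rmse %||% NA_real_,
    cv_mse = if (is.null(x$cv)) NA_real_ else min(x$cv$cv_mse)
  )
}

#' @describeIn rbf_fit Observed-vs-fitted scatter of the training records.
#' @param object An `rbf_model`.
#' @method autoplot rbf_model
#' @export
autoplot.rbf_model <- function(object, ...) {
  df <- tibble::tibble(observed = object$y, predicted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      title = sprintf("RBF surrogate for %s", toupper(object$response)),
      x = "observed", y = "predicted"
    )
}

#' Serialize a fitted RBF surrogate to JSON
#'
#' Round-trips all quantities needed for prediction: centres (scaled),
#' spread, weights, bias, scaler parameters and the response name.
#'
#' @param model An `rbf_model`.
#' @param path Destination (for `write_rbf()`) or source (for `read_rbf()`)
#'   file path.
#' @return `write_rbf()` returns `path` invisibly; `read_rbf()` returns an
#'   `rbf_model` whose predictions equal the original's.
#' @export
write_rbf <- function(model, path) {
  stopifnot(inherits(model, "rbf_model"))
  doc <- list(
    response = model$response,
    spread = model$spread,
    bias = model$bias,
    weights = model$weights,
    centers = model$centers,
    scaler = list(
      cols = model$scaler$cols,
      min = unname(model$scaler$min),
      range = unname(model$scaler$range)
    )
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rbf
#' @export
read_rbf <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaler <- structure(
    list(
      cols = doc$scaler$cols,
      min = setNames(doc$scaler$min, doc$scaler$cols),
      range = setNames(doc$scaler$range, doc$scaler$cols)
    ),
    class = "factor_scaler"
  )
  centers <- matrix(doc$centers, ncol = length(doc$scaler$cols))
  colnames(centers) <- doc$scaler$cols
  structure(
    list(
      centers = centers, spread = doc$spread,
      weights = as.numeric(doc$weights), bias = doc$bias, scaler = scaler,
      response = doc$response, cv = NULL, control = NULL,
      train_metrics = NULL, fitted = NULL, y = NULL
    ),
    class = "rbf_model"
  )
}
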