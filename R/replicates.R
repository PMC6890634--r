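#' Simulate replicate-level records from a treatment table
#'
#' Expands each factorial treatment into `n_rep` simulated data lines. Each
#' response is drawn from a normal distribution centred on the treatment mean
#' with standard deviation `3 * SE` and then truncated to its physical range
#' (PR to \[0, 100\], the others to non-negative values). The factor 3 = sqrt(9)
#' converts the printed standard error of a nine-repetition mean back to the
#' per-repetition spread, so the simulator reproduces the dispersion of the
#' underlying experiment regardless of how many lines are requested.
#' Treatments with zero mean and zero SE (media without cytokinin) yield
#' exact zeros.
#'
#' @param treatments Treatment tibble as returned by
#'   [chrysanthemum_treatments()] or [read_treatments()].
#' @param n_rep Number of simulated lines per treatment (default 9, which for
#'   the built-in 81-treatment table gives the canonical 729 data lines).
#' @param seed Optional integer seed; the draw is fully reproducible given
#'   the same treatments, `n_rep` and seed.
#' @return A tibble with `n_rep * nrow(treatments)` rows and columns
#'   `treatment_id`, `replicate`, the four factor columns and the four
#'   response columns `pr`, `sn`, `sl`, `bcw`.
#' @export
#' @examples
#' reps <- simulate_replicates(chrysanthemum_treatments(), n_rep = 9, seed = 1)
#' nrow(reps) # 729
simulate_replicates <- function(treatments, n_rep = 9, seed = NULL) {
  treatments <- validate_treatments(treatments)
  if (!is.numeric(n_rep) || length(n_rep) != 1 || n_rep < 1 ||
    n_rep != round(n_rep)) {
    abort("n_rep must be a positive integer")
  }
  n_rep <- as.integer(n_rep)
  if (!is.null(seed)) withr::local_seed(seed)

  n_trt <- nrow(treatments)
  out <- treatments[rep(seq_len(n_trt), each = n_rep), medium_factors()]
  out <- tibble::add_column(out,
    treatment_id = rep(seq_len(n_trt), each = n_rep),
    replicate = rep(seq_len(n_rep), times = n_trt),
    .before = 1
  )
  for (resp in growth_responses()) {
    mu <- rep(treatments[[paste0(resp, "_mean")]], each = n_rep)
    sigma <- 3 * rep(treatments[[paste0(resp, "_se")]], each = n_rep)
    draw <- rnorm(length(mu), mean = mu, sd = sigma)
    b <- response_bounds(resp)
    out[[resp]] <- pmin(pmax(draw, b[1]), b[2])
  }
  out
}

#' Split replicate records into training and testing partitions
#'
#' Uniform random partition without replacement; the training set holds
#' `ceiling(train_frac * n)` records. After drawing, the split is checked for
#' range overlap: every factor's training range must cover its testing range
#' (the surrogates are interpolators, so the test set must not probe outside
#' the trained region). If the check fails the split is redrawn with an
#' incremented seed, up to `max_attempts` times.
#'
#' @param records Replicate tibble from [simulate_replicates()] or
#'   [read_replicates()].
#' @param train_frac Fraction of records assigned to training, in (0, 1\].
#' @param seed Optional integer seed.
#' @param max_attempts Maximum redraws for the range-overlap check.
#' @return An object of class `medium_split`: a list with tibbles `train` and
#'   `test`, plus the `seed` actually used.
#' @export
#' @examples
#' reps <- simulate_replicates(chrysanthemum_treatments(), seed = 1)
#' sp <- split_replicates(reps, seed = 1)
#' c(nrow(sp$train), nrow(sp$test)) # 547, 182
split_replicates <- function(records, train_frac = 0.75, seed = NULL,
                             max_attempts = 100) {
  if (nrow(records) == 0) abort("records is empty")
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac > 1) {
    abort("train_frac must lie in (0, 1]")
  }
  n <- nrow(records)
  n_train <- ceiling(train_frac * n)
  fac <- intersect(medium_factors(), names(records))

  draw <- function(s) {
    if (!is.null(s)) withr::local_seed(s)
    idx <- sample.int(n, n_train)
    list(
      train = records[sort(idx), ],
      test = records[setdiff(seq_len(n), idx), ]
    )
  }
  covers <- function(sp) {
    if (nrow(sp$test) == 0 || length(fac) == 0) {
      return(TRUE)
    }
    all(vapply(fac, function(f) {
      rtr <- range(sp$train[[f]])
      rte <- range(sp$test[[f]])
      rtr[1] <= rte[1] && rtr[2] >= rte[2]
    }, logical(1)))
  }

  s <- seed
  for (attempt in seq_len(max_attempts)) {
    sp <- draw(s)
    if (covers(sp)) {
      return(structure(
        list(train = sp$train, test = sp$test, seed = s),
        class = "medium_split"
      ))
    }
    s <- if (is.null(s)) NULL else s + 1L
  }
  abort("could not draw a split whose training ranges cover the test ranges")
}

#' @export
print.medium_split <- function(x, ...) {
  cat(sprintf(
    "<medium_split> train: %d records, test: %d records (seed %s)\n",
    nrow(x$train), nrow(x$test),
    if (is.null(x$seed)) "unset" else x$seed
  ))
  invisible(x)
}

#' Read or write a replicate-level table
#'
#' CSV schema: the four factor columns followed by `pr`, `sn`, `sl`, `bcw`;
#' any extra columns (e.g. `treatment_id`, `replicate`) are preserved.
#'
#' @param path File path.
#' @param x For `write_replicates()`, a replicate tibble.
#' @return `read_replicates()` returns a tibble; `write_replicates()` returns
#'   `path` invisibly.
#' @export
read_replicates <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c(medium_factors(), growth_responses())
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    abort(paste0(
      "replicate table is missing columns: ",
      paste(missing, collapse = ", ")
    ))
  }
  x
}

#' @rdname read_replicates
#' @export
write_replicates <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
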