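#' Pareto dominance (minimization convention)
#'
#' `a` dominates `b` when it is no worse in every objective and strictly
#' better in at least one.
#'
#' @param a,b Numeric objective vectors of equal length.
#' @return Logical scalar.
#' @export
#' @examples
#' pareto_dominates(c(1, 1), c(2, 2)) # TRUE
#' pareto_dominates(c(1, 3), c(2, 2)) # FALSE (incomparable)
pareto_dominates <- function(a, b) {
  if (length(a) != length(b)) abort("objective vectors differ in length")
  all(a <= b) && any(a < b)
}

#' Fast non-dominated sorting
#'
#' Partitions a population into successive Pareto fronts: front 1 is the
#' non-dominated set, front i+1 the non-dominated set once fronts <= i are
#' removed. Dominance is evaluated for all pairs with vectorized matrix
#' comparisons, then fronts are peeled by dominator counting.
#'
#' @param objectives Numeric matrix, one row per individual, one column per
#'   objective (minimized).
#' @return A list with `rank` (integer vector, 1 = best) and `fronts`
#'   (list of row-index vectors, one per front).
#' @export
#' @examples
#' nondominated_sort(rbind(c(1, 1), c(2, 2), c(0, 3)))$rank
nondominated_sort <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0) abort("empty population")
  le <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (j in seq_len(ncol(objectives))) {
    o <- objectives[, j]
    cmp <- outer(o, o, "-") # cmp[i, k] = o_i - o_k
    le <- le & (cmp <= 0)
    lt <- lt | (cmp < 0)
  }
  dom <- le & lt # dom[i, k]: i dominates k
  n_dominators <- colSums(dom)
  rank <- integer(n)
  fronts <- list()
  remaining <- rep(TRUE, n)
  r <- 0L
  while (any(remaining)) {
    r <- r + 1L
    front <- which(remaining & n_dominators == 0)
    rank[front] <- r
    fronts[[r]] <- front
    remaining[front] <- FALSE
    if (length(front)) {
      dropped <- if (length(front) == 1) {
        dom[front, ]
      } else {
        colSums(dom[front, , drop = FALSE])
      }
      n_dominators <- n_dominators - dropped
    }
  }
  list(rank = rank, fronts = fronts)
}

#' Crowding distance within one front
#'
#' The standard cuboid density estimator: per objective the front is sorted,
#' the two boundary members receive infinite distance, and interior members
#' accumulate the normalized gap between their neighbours. An objective with
#' zero range contributes nothing. Fronts of one or two members are entirely
#' boundary and get `Inf`.
#'
#' @param objectives Numeric matrix of the front members' objectives.
#' @return Numeric vector of crowding distances (may contain `Inf`).
#' @export
#' @examples
#' crowding_distance(rbind(c(0, 2), c(1, 1), c(2, 0))) # Inf, 2, Inf
crowding_distance <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0) abort("empty front")
  d <- numeric(n)
  for (j in seq_len(ncol(objectives))) {
    o <- objectives[, j]
    ord <- order(o)
    rng <- o[ord[n]] - o[ord[1]]
    d[ord[c(1, n)]] <- Inf
    if (n > 2 && rng > 0) {
      gaps <- (o[ord[3:n]] - o[ord[1:(n - 2)]]) / rng
      d[ord[2:(n - 1)]] <- d[ord[2:(n - 1)]] + gaps
    }
  }
  d
}

#' Crowded binary tournament selection
#'
#' Draws two members uniformly at random; the lower rank wins, ties go to the
#' larger crowding distance, and remaining ties are broken by a fair coin.
#'
#' @param rank Integer vector of front ranks for the population.
#' @param crowding Numeric vector of crowding distances.
#' @param n Number of winners to draw.
#' @return Integer vector of `n` winning indices.
#' @export
tournament_select <- function(rank, crowding, n = 1) {
  m <- length(rank)
  i1 <- sample.int(m, n, replace = TRUE)
  i2 <- sample.int(m, n, replace = TRUE)
  win <- i1
  take2 <- rank[i2] < rank[i1] |
    (rank[i2] == rank[i1] & crowding[i2] > crowding[i1])
  tie <- rank[i2] == rank[i1] & crowding[i2] == crowding[i1]
  flip <- tie & (runif(n) < 0.5)
  win[take2 | flip] <- i2[take2 | flip]
  win
}

#' Two-point crossover on real-coded vectors
#'
#' With probability `rate` two cut points `1 <= i < j <= length - 1` are
#' drawn uniformly and the middle segment (genes `i+1 .. j`) is exchanged
#' between the parents; otherwise the children are copies of the parents.
#' Values are exchanged, never blended, so children always stay within any
#' box bounds the parents satisfy.
#'
#' @param p1,p2 Equal-length numeric parent vectors.
#' @param rate Crossover probability in \[0, 1\].
#' @return A list with children `c1` and `c2`.
#' @export
#' @examples
#' withr::with_seed(1, crossover_two_point(1:4, 5:8, rate = 1))
crossover_two_point <- function(p1, p2, rate = 0.7) {
  if (length(p1) != length(p2)) abort("parents differ in length")
  len <- length(p1)
  if (len < 2 || runif(1) >= rate) {
    return(list(c1 = p1, c2 = p2))
  }
  cuts <- sort(sample.int(len - 1, 2, replace = FALSE))
  seg <- (cuts[1] + 1):cuts[2]
  c1 <- p1
  c2 <- p2
  c1[seg] <- p2[seg]
  c2[seg] <- p1[seg]
  list(c1 = c1, c2 = c2)
}

#' Uniform mutation within box bounds
#'
#' Each gene is independently replaced, with probability `rate`, by a fresh
#' uniform draw from its bound interval (the conventional per-gene reading of
#' the mutation probability; set `scope = "individual"` to instead mutate
#' every gene of a `rate`-fraction of individuals).
#'
#' @param x Numeric decision vector (or matrix with one row per individual).
#' @param rate Mutation probability in \[0, 1\].
#' @param lower,upper Numeric bound vectors, one entry per gene.
#' @param scope `"gene"` (default) or `"individual"`.
#' @return Mutated object of the same shape, always within bounds.
#' @export
mutate_uniform <- function(x, rate, lower, upper, scope = c("gene", "individual")) {
  scope <- match.arg(scope)
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, nrow = 1) else x
  n <- nrow(X)
  d <- ncol(X)
  if (length(lower) != d || length(upper) != d) {
    abort("bounds must have one entry per gene")
  }
  mask <- if (scope == "gene") {
    matrix(runif(n * d) < rate, n, d)
  } else {
    matrix(runif(n) < rate, n, d)
  }
  if (any(mask)) {
    draws <- matrix(
      runif(n * d, rep(lower, each = n), rep(upper, each = n)), n, d
    )
    X[mask] <- draws[mask]
  }
  if (vec) as.vector(X) else X
}

#' Control parameters for NSGA-II
#'
#' Defaults follow the settings used for the medium-optimization study:
#' population 200, 1000 generations, crossover rate 0.7, per-gene uniform
#' mutation rate 0.05, two-point crossover and crowded binary tournament
#' selection.
#'
#' @param pop_size Even population size >= 4.
#' @param generations Fixed generation budget (no early stopping).
#' @param crossover_rate,mutation_rate Variation probabilities in \[0, 1\].
#' @param mutation_scope `"gene"` or `"individual"` (see [mutate_uniform()]).
#' @param seed Optional integer seed; the whole run is reproducible given it.
#' @return A list of class `nsga_control`.
#' @export
nsga_control <- function(pop_size = 200, generations = 1000,
                         crossover_rate = 0.7, mutation_rate = 0.05,
                         mutation_scope = "gene", seed = NULL) {
  if (pop_size < 4 || pop_size %% 2 != 0) {
    abort("pop_size must be even and >= 4")
  }
  if (generations < 1) abort("generations must be >= 1")
  stopifnot(
    crossover_rate >= 0, crossover_rate <= 1,
    mutation_rate >= 0, mutation_rate <= 1
  )
  structure(
    list(
      pop_size = pop_size, generations = generations,
      crossover_rate = crossover_rate, mutation_rate = mutation_rate,
      mutation_scope = match.arg(mutation_scope, c("gene", "individual")),
      seed = seed
    ),
    class = "nsga_control"
  )
}

# crowding distances computed front-by-front for a whole population
pop_crowding <- function(objectives, fronts) {
  d <- numeric(nrow(objectives))
  for (f in fronts) {
    d[f] <- crowding_distance(objectives[f, , drop = FALSE])
  }
  d
}

#' Elitist NSGA-II over a box-constrained decision space
#'
#' Real-coded (mu + lambda) NSGA-II: the parent and offspring populations are
#' pooled each generation, refilled front by front, and the last partial
#' front is truncated by descending crowding distance. Offspring are produced
#' by crowded binary tournament, two-point crossover and uniform mutation;
#' all variation respects the box bounds by construction. Runs exactly
#' `control$generations` iterations and returns the final rank-1 set with
#' duplicate decision vectors collapsed.
#'
#' @param objective_fn Objective function, minimized componentwise. Called
#'   with a numeric matrix (one row per decision vector, columns in
#'   `lower`/`upper` order) and expected to return a matrix with one row per
#'   input and one column per objective; a function of a single vector
#'   returning a vector is also accepted and wrapped row-wise.
#' @param lower,upper Numeric vectors of per-variable closed bounds.
#' @param control An [nsga_control()] object.
#' @param decision_names,objective_names Optional column names for the
#'   returned front.
#' @return An object of class `pareto_front`: a list with `front` (tibble of
#'   decision columns, objective columns and `crowding`), the final
#'   `population`, and the `control` used.
#' @export
#' @examples
#' sch <- function(X) cbind(X[, 1]^2, (X[, 1] - 2)^2)
#' res <- nsga2(sch, -5, 10, nsga_control(pop_size = 40, generations = 50, seed = 1))
#' range(res$front$x1) # within [0, 2]
nsga2 <- function(objective_fn, lower, upper, control = nsga_control(),
                  decision_names = NULL, objective_names = NULL) {
  stopifnot(inherits(control, "nsga_control"))
  if (length(lower) != length(upper) || any(upper < lower)) {
    abort("invalid bounds")
  }
  d <- length(lower)
  n <- control$pop_size
  if (!is.null(control$seed)) withr::local_seed(control$seed)

  fn <- as_matrix_objective(objective_fn, lower, upper)

  P <- matrix(runif(n * d, rep(lower, each = n), rep(upper, each = n)), n, d)
  obj <- fn(P)
  k <- ncol(obj)

  for (gen in seq_len(control$generations)) {
    srt <- nondominated_sort(obj)
    crowd <- pop_crowding(obj, srt$fronts)

    parents <- tournament_select(srt$rank, crowd, n)
    Q <- P[parents, , drop = FALSE]
    for (i in seq(1, n - 1, by = 2)) {
      ch <- crossover_two_point(Q[i, ], Q[i + 1, ], control$crossover_rate)
      Q[i, ] <- ch$c1
      Q[i + 1, ] <- ch$c2
    }
    Q <- mutate_uniform(
      Q, control$mutation_rate, lower, upper,
      scope = control$mutation_scope
    )
    obj_Q <- fn(Q)

    R <- rbind(P, Q)
    obj_R <- rbind(obj, obj_Q)
    srt_R <- nondominated_sort(obj_R)
    crowd_R <- pop_crowding(obj_R, srt_R$fronts)
    keep <- integer(0)
    for (f in srt_R$fronts) {
      if (length(keep) + length(f) <= n) {
        keep <- c(keep, f)
      } else {
        slots <- n - length(keep)
        keep <- c(keep, f[order(crowd_R[f], decreasing = TRUE)][seq_len(slots)])
        break
      }
    }
    P <- R[keep, , drop = FALSE]
    obj <- obj_R[keep, , drop = FALSE]
  }

  srt <- nondominated_sort(obj)
  front_idx <- srt$fronts[[1]]
  Pf <- P[front_idx, , drop = FALSE]
  Of <- obj[front_idx, , drop = FALSE]
  dup <- duplicated(round(Pf, 9))
  Pf <- Pf[!dup, , drop = FALSE]
  Of <- Of[!dup, , drop = FALSE]
  crowd_f <- crowding_distance(Of)

  decision_names <- decision_names %||% paste0("x", seq_len(d))
  objective_names <- objective_names %||% paste0("f", seq_len(k))
  front <- tibble::as_tibble(as.data.frame(Pf, col.names = decision_names))
  names(front) <- decision_names
  for (j in seq_len(k)) front[[objective_names[j]]] <- Of[, j]
  front$crowding <- crowd_f

  structure(
    list(
      front = front, decision_names = decision_names,
      objective_names = objective_names,
      population = P, population_objectives = obj, control = control,
      lower = lower, upper = upper
    ),
    class = "pareto_front"
  )
}

as_matrix_objective <- function(objective_fn, lower, upper) {
  d <- length(lower)
  probe <- matrix(rep((lower + upper) / 2, each = 2), 2, d)
  ok <- tryCatch(
    {
      out <- objective_fn(probe)
      is.matrix(out) && nrow(out) == 2
    },
    error = function(e) FALSE
  )
  if (ok) {
    return(objective_fn)
  }
  function(X) {
    out <- apply(X, 1, objective_fn)
    if (is.matrix(out)) t(out) else matrix(out, ncol = 1)
  }
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf(
    "<pareto_front> %d non-dominated solutions in %d objectives\n",
    nrow(x$front), length(x$objective_names)
  ))
  print(head(x$front, 10))
  if (nrow(x$front) > 10) cat("...\n")
  invisible(x)
}

#' @method tidy pareto_front
#' @export
tidy.pareto_front <- function(x, ...) x$front

#' @method glance pareto_front
#' @export
glance.pareto_front <- function(x, ...) {
  tibble::tibble(
    n_solutions = nrow(x$front),
    n_objectives = length(x$objective_names),
    pop_size = x$control$pop_size,
    generations = x$control$generations
  )
}

#' @method autoplot pareto_front
#' @export
autoplot.pareto_front <- function(object, ...) {
  on <- object$objective_names
  df <- object$front
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(.data[[on[1]]], .data[[on[2]]])
  )
  if (length(on) >= 3) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[on[3]]]))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(title = "Pareto front (minimization scale)")
}
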