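test_that("Pareto dominance follows the componentwise definition", {
  expect_true(pareto_dominates(c(1, 1), c(2, 2)))
  expect_false(pareto_dominates(c(1, 1), c(1, 1)))
  expect_false(pareto_dominates(c(1, 3), c(2, 2)))
  expect_false(pareto_dominates(c(2, 2), c(1, 3)))
  expect_true(pareto_dominates(c(1, 2), c(1, 3)))
  expect_error(pareto_dominates(c(1, 2), c(1, 2, 3)), "length")
})

test_that("non-dominated sorting matches the exhaustive pairwise oracle", {
  # degenerate shapes first
  nd <- nondominated_sort(rbind(c(0, 2), c(1, 1), c(2, 0)))
  expect_equal(nd$rank, c(1, 1, 1))
  chain <- nondominated_sort(cbind(1:5, 1:5))
  expect_equal(chain$rank, 1:5)
  expect_equal(lengths(chain$fronts), rep(1L, 5))

  # random instances against the brute-force double loop
  withr::local_seed(19)
  for (i in 1:50) {
    n <- sample(c(20, 60, 150, 300), 1)
    k <- sample(2:4, 1)
    # mix continuous and low-resolution objectives so exact ties occur
    obj <- matrix(round(runif(n * k), sample(c(1, 2, 6), 1)), n, k)
    fast <- nondominated_sort(obj)$rank
    expect_equal(fast, brute_force_sort(obj))
  }
})

test_that("crowding distance implements the cuboid estimator", {
  # hand-evaluated interior value: ranges 2 and 2, gaps 2/2 + 2/2
  d <- crowding_distance(rbind(c(0, 2), c(1, 1), c(2, 0)))
  expect_equal(d, c(Inf, 2, Inf))

  expect_equal(crowding_distance(matrix(c(1, 2), 1)), Inf)
  expect_equal(crowding_distance(rbind(c(0, 1), c(1, 0))), c(Inf, Inf))

  # per-objective extremes always get infinity
  withr::local_seed(4)
  obj <- matrix(runif(40), 20, 2)
  d <- crowding_distance(obj)
  for (j in 1:2) {
    expect_equal(d[which.min(obj[, j])], Inf)
    expect_equal(d[which.max(obj[, j])], Inf)
  }

  # a zero-range objective contributes nothing
  obj0 <- cbind(seq(0, 1, length.out = 5), rep(3, 5))
  d0 <- crowding_distance(obj0)
  expect_equal(d0[2:4], c(0.5, 0.5, 0.5))
})

test_that("binary tournaments prefer rank, then crowding, then a fair coin", {
  withr::local_seed(8)
  # rank always dominates
  rk <- c(1, 2)
  cw <- c(0, 10)
  wins <- tournament_select(rk, cw, 2000)
  expect_true(all(rk[wins] <= 2))
  expect_gt(mean(rk[wins] == 1), 0.7) # rank-1 wins every mixed pairing

  # equal rank: larger crowding wins every mixed pairing
  rk <- c(1, 1)
  cw <- c(Inf, 0.5)
  wins <- tournament_select(rk, cw, 2000)
  expect_gt(mean(wins == 1), 0.7)

  # full tie: each side wins about half the time
  rk <- c(1, 1)
  cw <- c(1, 1)
  wins <- tournament_select(rk, cw, 10000)
  expect_lt(abs(mean(wins == 1) - 0.5), 0.02)
})

test_that("two-point crossover exchanges a middle segment", {
  p1 <- c(1, 2, 3, 4)
  p2 <- c(5, 6, 7, 8)

  ch <- withr::with_seed(1, crossover_two_point(p1, p2, rate = 0))
  expect_equal(ch$c1, p1)
  expect_equal(ch$c2, p2)

  ch <- withr::with_seed(2, crossover_two_point(p1, p1, rate = 1))
  expect_equal(ch$c1, p1)
  expect_equal(ch$c2, p1)

  # the three legal cut pairs (1,2), (1,3), (2,3) exchange genes {2},
  # {2,3}, {3}; children must always be one of these patterns, all of
  # which occur, and gene sets are conserved positionwise
  pattern <- function(ch) paste(which(ch$c1 != p1), collapse = ",")
  seen <- character(0)
  withr::local_seed(3)
  for (i in 1:200) {
    ch <- crossover_two_point(p1, p2, rate = 1)
    expect_true(all(ch$c1 %in% c(p1, p2)) && all(ch$c2 %in% c(p1, p2)))
    swapped <- which(ch$c1 != p1)
    expect_equal(which(ch$c2 != p2), swapped)
    expect_equal(ch$c1[swapped], p2[swapped])
    seen <- union(seen, pattern(ch))
  }
  expect_setequal(seen, c("2", "2,3", "3"))

  expect_error(crossover_two_point(1:3, 1:4), "length")
})

test_that("uniform mutation stays in bounds with per-gene uniform draws", {
  lower <- c(0, 0, 0, 43.82)
  upper <- c(4.44, 0.49, 0.4, 131.46)
  x <- c(1, 0.2, 0.1, 60)

  expect_equal(
    withr::with_seed(1, mutate_uniform(x, 0, lower, upper)), x
  )

  withr::local_seed(6)
  draws <- t(replicate(10000, mutate_uniform(x, 1, lower, upper)))
  expect_true(all(sweep(draws, 2, lower, ">=")))
  expect_true(all(sweep(draws, 2, upper, "<=")))
  # uniformity per gene (KS) and mean at the interval midpoint +- 3 SE
  for (j in 1:4) {
    ks <- stats::ks.test(draws[, j], "punif", lower[j], upper[j])
    expect_gt(ks$p.value, 1e-4)
    width <- upper[j] - lower[j]
    se <- width / sqrt(12) / sqrt(10000)
    expect_lt(abs(mean(draws[, j]) - (lower[j] + upper[j]) / 2), 3 * se)
  }

  # per-individual scope flips all-or-none genes
  withr::local_seed(7)
  M <- matrix(rep(x, each = 50), 50, 4)
  out <- mutate_uniform(M, 0.5, lower, upper, scope = "individual")
  changed <- rowSums(out != M)
  expect_true(all(changed %in% c(0L, 4L)))
})

test_that("the evolutionary loop solves known benchmark problems", {
  # Schaffer bi-objective: Pareto set x in [0, 2], front f2 = (sqrt(f1)-2)^2
  sch <- function(X) cbind(X[, 1]^2, (X[, 1] - 2)^2)
  res <- nsga2(
    sch, -5, 10,
    nsga_control(pop_size = 100, generations = 100, seed = 41)
  )
  expect_true(all(res$front$x1 >= -0.05 & res$front$x1 <= 2.05))
  expect_lt(
    max(abs(res$front$f2 - (sqrt(pmax(res$front$f1, 0)) - 2)^2)), 0.05
  )

  # degenerate single objective collapses to the minimum
  res1 <- nsga2(
    function(X) matrix(X[, 1]^2, ncol = 1), -3, 3,
    nsga_control(pop_size = 40, generations = 60, seed = 5)
  )
  expect_lt(max(abs(res1$front$x1)), 0.01)

  # decisions respect the box for a 4-variable problem
  lw <- c(0, 0, 0, 43.82)
  up <- c(4.44, 0.49, 0.4, 131.46)
  fn <- function(X) cbind(-rowSums(X), X[, 1] * X[, 4])
  res4 <- nsga2(fn, lw, up, nsga_control(pop_size = 24, generations = 30, seed = 2))
  dec <- as.matrix(res4$front[res4$decision_names])
  expect_true(all(sweep(dec, 2, lw, ">=") & sweep(dec, 2, up, "<=")))

  # returned front is mutually non-dominated and deduplicated
  objs <- as.matrix(res4$front[res4$objective_names])
  expect_equal(nondominated_sort(objs)$rank, rep(1L, nrow(objs)))
  expect_equal(anyDuplicated(round(dec, 9)), 0L)

  # determinism: identical config and seed give identical fronts
  res4b <- nsga2(fn, lw, up, nsga_control(pop_size = 24, generations = 30, seed = 2))
  expect_equal(res4$front, res4b$front)

  # a vector objective function is wrapped row-wise
  resv <- nsga2(
    function(x) c(x[1]^2, (x[1] - 2)^2), -5, 10,
    nsga_control(pop_size = 20, generations = 20, seed = 3)
  )
  expect_true(all(resv$front$x1 > -0.5 & resv$front$x1 < 2.5))
})

test_that("longer runs never lose the per-objective best (elitism)", {
  sch <- function(X) cbind(X[, 1]^2, (X[, 1] - 2)^2)
  best_f1 <- Inf
  for (g in c(5, 20, 80)) {
    res <- nsga2(sch, -5, 10, nsga_control(
      pop_size = 30, generations = g, seed = 11
    ))
    f1 <- min(res$front$f1)
    expect_lte(f1, best_f1 + 1e-12)
    best_f1 <- f1
  }
})
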