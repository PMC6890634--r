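# Shared builders used across the suite. Everything is generated in code;
# no stored fixtures beyond the package's own treatment table.

resp_names <- function() growth_responses()

# A hand-specified RBF model (class rbf_model) over the four medium factors,
# bypassing fitting entirely. Centers are given in ORIGINAL units and scaled
# through `scaler`.
manual_rbf <- function(centers, weights, bias, spread, scaler,
                       response = "pr") {
  centers <- if (is.null(centers)) {
    matrix(numeric(0), 0, 4)
  } else {
    scale_factors(scaler, centers)
  }
  structure(
    list(
      centers = centers, spread = spread, weights = weights, bias = bias,
      scaler = scaler, response = response, cv = NULL, control = NULL,
      train_metrics = NULL, fitted = NULL, y = NULL
    ),
    class = "rbf_model"
  )
}

# Scaler for a synthetic unit box in original units equal to the factorial
# treatment ranges.
treatment_scaler <- function() {
  fit_scaler(chrysanthemum_treatments())
}

# Exhaustive O(n^2 k) non-dominated sorting oracle built directly on the
# pairwise dominance definition; independent of the peeled matrix algorithm.
brute_force_sort <- function(objectives) {
  n <- nrow(objectives)
  remaining <- seq_len(n)
  rank <- integer(n)
  r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(
        setdiff(remaining, i),
        function(j) pareto_dominates(objectives[j, ], objectives[i, ]),
        logical(1)
      ))
    }, logical(1))]
    rank[nd] <- r
    remaining <- setdiff(remaining, nd)
  }
  rank
}

# Small replicate set used by fast unit tests (3 lines per treatment).
small_replicates <- function(seed = 42, n_rep = 3) {
  simulate_replicates(chrysanthemum_treatments(), n_rep = n_rep, seed = seed)
}
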