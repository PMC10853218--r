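test_that("initial design has the seed point and honors the box", {
  cfg <- opt_config(seed = 4)
  X <- initial_design(cfg)
  expect_equal(dim(X), c(73, 36))          # 72 random + the zero seed
  expect_equal(X[1, ], rep(0, 36))
  expect_true(all(abs(X) <= 25))
  expect_identical(X, initial_design(opt_config(seed = 4)))
  expect_false(identical(X, initial_design(opt_config(seed = 5))))
})

test_that("the RBF surrogate interpolates and reproduces linear functions", {
  set.seed(11)
  d <- 6
  X <- matrix(runif(40 * d, -1, 1), 40, d)
  y <- sin(X[, 1]) + X[, 2]^2
  s <- fit_surrogate(X, y)
  expect_lt(max(abs(s$predict(X) - y)), 1e-6 * max(1, max(abs(y))))

  # linear target: exact off-sample reproduction through the polynomial tail
  beta <- seq_len(d)
  ylin <- as.vector(X %*% beta) + 2
  slin <- fit_surrogate(X, ylin)
  Z <- matrix(runif(20 * d, -1, 1), 20, d)
  expect_lt(max(abs(slin$predict(Z) - (as.vector(Z %*% beta) + 2))), 1e-6)

  # duplicated points are deduplicated before fitting
  sdup <- fit_surrogate(rbind(X, X[1:5, ]), c(y, y[1:5] + 100))
  expect_equal(nrow(sdup$points), 40)
  expect_error(fit_surrogate(X[1:3, ], y[1:3]), "dim")
})

test_that("candidate proposal stays in bounds and avoids duplicates", {
  set.seed(3)
  cfg <- opt_config(dim = 8L, n_initial = 10L, bound = 25, seed = 3)
  X <- matrix(runif(12 * 8, -25, 25), 12, 8)
  y <- rowSums(X^2)
  s <- fit_surrogate(X, y)
  for (it in 1:8) {
    cand <- propose_candidate(s, X[which.min(y), ], X, cfg, scale = 0.2,
                              iteration = it)
    expect_true(all(abs(cand) <= 25))
    expect_gt(min(sqrt(rowSums((X - matrix(cand, 12, 8, byrow = TRUE))^2))),
              1e-6)
  }
})

test_that("surrogate search beats random search on a quadratic bowl", {
  # shortened budget: 40 initial + 60 adaptive evaluations, 3 seeds
  sphere <- function(x) list(of = sum(x^2), feasible = TRUE, max_pressure = 0)
  for (s in 1:3) {
    cfg <- opt_config(dim = 36L, n_initial = 40L, max_iter_phase1 = 60L,
                      max_iter_extended = 60L, seed = s)
    st <- optimize_brace(sphere, cfg)
    set.seed(s + 500)
    rand_best <- min(rowSums(matrix(runif(nrow(st$points) * 36, -25, 25),
                                    ncol = 36)^2))
    expect_lt(st$best_feasible$of, rand_best)
    # best-so-far trace never increases
    bsf <- st$history$best_so_far
    expect_true(all(diff(bsf[!is.na(bsf)]) <= 0))
    expect_true(all(abs(st$points) <= 25))
    expect_equal(anyDuplicated(round(st$points, 9)), 0)
  }
})

test_that("the convergence rule fires on a stalled objective", {
  cst <- function(x) list(of = 5, feasible = TRUE, max_pressure = 0)
  cfg <- opt_config(dim = 4L, n_initial = 8L, max_iter_phase1 = 60L,
                    max_iter_extended = 400L, conv_window = 50L, seed = 2)
  st <- optimize_brace(cst, cfg)
  # 0 % improvement < 5 %: stops exactly when the rule is first checked
  expect_equal(st$converged_at, 60L)
  expect_equal(st$iterations, 60L)
})

test_that("infeasible-everywhere runs return a flagged fallback", {
  bad <- function(x) list(of = sum(x^2), feasible = FALSE, max_pressure = 999)
  cfg <- opt_config(dim = 4L, n_initial = 6L, max_iter_phase1 = 10L,
                    max_iter_extended = 10L, seed = 1)
  st <- optimize_brace(bad, cfg)
  expect_true(st$best_feasible$fallback)
  expect_true(all(!st$feasible))
  expect_true(all(is.na(st$history$best_so_far)))
})

test_that("feasibility gates the incumbent", {
  # feasible only away from the origin: the best feasible point must respect
  # the constraint even though infeasible points score better
  ev <- function(x) list(of = sum(x^2), feasible = sum(x^2) > 100,
                         max_pressure = if (sum(x^2) > 100) 100 else 500)
  cfg <- opt_config(dim = 4L, n_initial = 20L, max_iter_phase1 = 30L,
                    max_iter_extended = 30L, seed = 6)
  st <- optimize_brace(ev, cfg)
  expect_false(st$best_feasible$fallback)
  expect_gt(sum(st$best_feasible$x^2), 100)
})
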