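# Constrained surrogate optimization over the 36-dimensional rho-offset
# space: random initial design seeded with the initial brace topography,
# cubic radial-basis-function surrogate with linear tail, merit-function
# candidate sampling cycling exploitation/exploration weights, additive
# penalty for pressure-infeasible designs, and the published stopping rule
# (< 5 % best-score improvement over more than 50 iterations, checked from
# iteration 500, hard stop at 1000).

#' Optimizer configuration
#'
#' @param dim Number of design variables (36 for the 6 x 6 patch grid).
#' @param n_initial Random points of the initial design (the zero vector --
#'   the initial brace -- is always added as seed).
#' @param max_iter_phase1 Iteration count at which the convergence rule is
#'   first checked.
#' @param max_iter_extended Hard iteration cap.
#' @param conv_window,conv_rel_improvement Convergence rule: stop when the
#'   relative best-score improvement over the last `conv_window` iterations
#'   falls below `conv_rel_improvement`.
#' @param bound Box half-width per variable, mm.
#' @param n_candidates Merit-function samples per iteration.
#' @param merit_weights Exploitation weights cycled across iterations.
#' @param perturb_prob Probability of perturbing each coordinate of the
#'   incumbent when sampling candidates (dimension-adaptive by default).
#' @param scale_init Initial sampling scale, fraction of the box width.
#' @param scale_fail_max Consecutive non-improving iterations before the
#'   scale is halved (counter resets on success).
#' @param infeasibility_penalty Additive penalty entered into the surrogate
#'   for pressure-infeasible designs; `NULL` = 10 x initial-design spread.
#' @param seed Integer seed.
#' @return An `opt_config` list.
#' @export
opt_config <- function(dim = 36L, n_initial = 72L, max_iter_phase1 = 500L,
                       max_iter_extended = 1000L, conv_window = 50L,
                       conv_rel_improvement = 0.05, bound = 25,
                       n_candidates = 500L,
                       merit_weights = c(0.3, 0.5, 0.8, 0.95),
                       perturb_prob = min(1, 20 / dim),
                       scale_init = 0.2, scale_fail_max = 3L * dim,
                       infeasibility_penalty = NULL, seed = 1L) {
  stopifnot(n_initial >= dim + 1, max_iter_phase1 <= max_iter_extended,
            bound > 0, conv_window >= 1)
  structure(as.list(environment()), class = "opt_config")
}

#' Initial design of the surrogate
#'
#' `n_initial` uniform random points in the box plus the zero vector (the
#' unmodified initial brace topography) as seed point.
#'
#' @param config An `opt_config`.
#' @return Matrix `(n_initial + 1) x dim`; first row is the zero seed.
#' @export
initial_design <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(config$seed))
  X <- matrix(stats::runif(config$n_initial * config$dim,
                           -config$bound, config$bound),
              config$n_initial, config$dim)
  rbind(rep(0, config$dim), X)
}

#' Fit a cubic radial-basis-function interpolant
#'
#' Cubic kernel `phi(r) = r^3` augmented with a linear polynomial tail; the
#' augmented symmetric system enforces interpolation at the (deduplicated)
#' sample points and exact reproduction of linear functions.
#'
#' @param points Matrix `n x d` of sample locations.
#' @param values Length-`n` responses (finite; penalized values for
#'   infeasible points).
#' @return An `rbf_surrogate` with a `predict(newpoints)` closure.
#' @export
fit_surrogate <- function(points, values) {
  X <- as.matrix(points)
  y <- as.numeric(values)
  stopifnot(nrow(X) == length(y), all(is.finite(y)))
  # deduplicate (keep first occurrence)
  dup <- duplicated(round(X, 9))
  X <- X[!dup, , drop = FALSE]
  y <- y[!dup]
  n <- nrow(X); d <- ncol(X)
  if (n < d + 1) stop("need at least dim + 1 distinct points")
  D <- as.matrix(stats::dist(X))
  Phi <- D^3
  P <- cbind(1, X)
  A <- rbind(cbind(Phi, P), cbind(t(P), matrix(0, d + 1, d + 1)))
  rhs <- c(y, rep(0, d + 1))
  sol <- tryCatch(solve(A, rhs),
                  error = function(e) qr.solve(A, rhs, tol = 1e-12))
  lambda <- sol[seq_len(n)]
  cf <- sol[n + seq_len(d + 1)]
  predict_fun <- function(newpoints) {
    Z <- as.matrix(newpoints)
    if (ncol(Z) != d) Z <- matrix(Z, ncol = d)
    cross <- outer(rowSums(Z^2), rowSums(X^2), "+") - 2 * Z %*% t(X)
    cross[cross < 0] <- 0
    as.vector(sqrt(cross)^3 %*% lambda + cbind(1, Z) %*% cf)
  }
  structure(list(points = X, values = y, lambda = lambda, coef = cf,
                 predict = predict_fun), class = "rbf_surrogate")
}

#' Propose the next evaluation point
#'
#' Samples `n_candidates` Gaussian perturbations of the incumbent best point
#' (each coordinate perturbed with probability `perturb_prob`, standard
#' deviation `scale * box width`), clips to the box, discards near-duplicates
#' of evaluated points, and scores a merit function `w * (scaled surrogate
#' value) + (1 - w) * (1 - scaled distance to the evaluated set)` with the
#' exploitation weight `w` cycled across iterations.
#'
#' @param surrogate An `rbf_surrogate`.
#' @param incumbent Current best point (length `dim`).
#' @param evaluated Matrix of evaluated points.
#' @param config An `opt_config`.
#' @param scale Current sampling scale (fraction of box width).
#' @param iteration Iteration counter (selects the merit weight).
#' @return A length-`dim` candidate within bounds.
#' @export
propose_candidate <- function(surrogate, incumbent, evaluated, config, scale,
                              iteration = 1L) {
  d <- config$dim
  bw <- 2 * config$bound
  nc <- config$n_candidates
  pert <- matrix(stats::rnorm(nc * d, 0, scale * bw), nc, d)
  mask <- matrix(stats::runif(nc * d) < config$perturb_prob, nc, d)
  z <- which(rowSums(mask) == 0)
  if (length(z)) mask[cbind(z, sample.int(d, length(z), replace = TRUE))] <- TRUE
  C <- matrix(incumbent, nc, d, byrow = TRUE) + pert * mask
  C <- pmin(pmax(C, -config$bound), config$bound)

  sv <- surrogate$predict(C)
  # distance to evaluated set
  E <- as.matrix(evaluated)
  cross <- outer(rowSums(C^2), rowSums(E^2), "+") - 2 * C %*% t(E)
  cross[cross < 0] <- 0
  dmin <- sqrt(apply(cross, 1, min))
  keep <- dmin > 1e-6 * bw
  if (!any(keep)) return(stats::runif(d, -config$bound, config$bound))
  C <- C[keep, , drop = FALSE]; sv <- sv[keep]; dmin <- dmin[keep]

  rng <- function(v) if (diff(range(v)) < 1e-12) rep(0.5, length(v)) else
    (v - min(v)) / (max(v) - min(v))
  w <- config$merit_weights[1 + (iteration - 1) %% length(config$merit_weights)]
  merit <- w * rng(sv) + (1 - w) * (1 - rng(dmin))
  C[which.min(merit), ]
}

#' Run the constrained surrogate optimization
#'
#' Evaluates the initial design (zero seed + random points), then iterates:
#' fit surrogate on all evaluations (infeasible designs entered at their
#' score plus the infeasibility penalty), propose a candidate, evaluate it,
#' update the incumbent.  The best feasible point never regresses; the search
#' scale halves after `scale_fail_max` consecutive failures to improve and the
#' failure counter resets on success.  Stops when the convergence rule fires
#' (checked from `max_iter_phase1`) or at `max_iter_extended` iterations.
#'
#' @param evaluator Function `rho -> list(of =, feasible =, max_pressure =
#'   )` (any extra elements are stored in the history).
#' @param config An `opt_config`.
#' @param progress Optional function `(iteration, best_of)` called per
#'   iteration.
#' @return An `opt_state`: evaluated `points`, `of`, `feasible`,
#'   `max_pressure`, `best_feasible` (`x`, `of`, `index`; `NULL` when nothing
#'   feasible was found, with `fallback` flagged), `history` data frame, and
#'   `converged_at`.
#' @export
optimize_brace <- function(evaluator, config = opt_config(), progress = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(config$seed) + 1L)

  X <- initial_design(config)
  d <- config$dim
  evals <- lapply(seq_len(nrow(X)), function(i) evaluator(X[i, ]))
  of <- vapply(evals, function(e) e$of, numeric(1))
  feas <- vapply(evals, function(e) isTRUE(e$feasible), logical(1))
  mp <- vapply(evals, function(e) e$max_pressure %||% NA_real_, numeric(1))

  pen <- config$infeasibility_penalty
  if (is.null(pen)) {
    spread <- diff(range(of[is.finite(of)]))
    pen <- 10 * max(spread, 1)
  }
  surr_val <- function(of_, feas_) ifelse(feas_, of_, of_ + pen)

  best_idx <- if (any(feas)) which(feas)[which.min(of[feas])] else NA_integer_
  best_of_trace <- numeric(0)
  scale <- config$scale_init
  fails <- 0L
  converged_at <- NA_integer_

  iter <- 0L
  while (iter < config$max_iter_extended) {
    iter <- iter + 1L
    sur <- fit_surrogate(X, surr_val(of, feas))
    inc <- if (!is.na(best_idx)) X[best_idx, ] else X[which.min(surr_val(of, feas)), ]
    cand <- propose_candidate(sur, inc, X, config, scale, iter)
    ev <- evaluator(cand)
    X <- rbind(X, cand)
    of <- c(of, ev$of)
    feas <- c(feas, isTRUE(ev$feasible))
    mp <- c(mp, ev$max_pressure %||% NA_real_)
    i_new <- nrow(X)
    improved <- FALSE
    if (feas[i_new] && (is.na(best_idx) || of[i_new] < of[best_idx])) {
      best_idx <- i_new
      improved <- TRUE
    }
    if (improved) fails <- 0L else fails <- fails + 1L
    if (fails >= config$scale_fail_max) {
      scale <- scale / 2
      fails <- 0L
    }
    best_of_trace <- c(best_of_trace,
                       if (is.na(best_idx)) NA_real_ else of[best_idx])
    if (!is.null(progress)) progress(iter, utils::tail(best_of_trace, 1))

    if (iter >= config$max_iter_phase1 && iter > config$conv_window) {
      now <- best_of_trace[iter]
      then <- best_of_trace[iter - config$conv_window]
      if (!is.na(now) && !is.na(then)) {
        rel <- (then - now) / max(abs(then), 1e-12)
        if (rel < config$conv_rel_improvement) {
          converged_at <- iter
          break
        }
      } else if (is.na(now) && is.na(then)) {
        converged_at <- iter
        break
      }
    }
  }

  n_init <- config$n_initial + 1L
  hist <- data.frame(
    evaluation = seq_len(nrow(X)),
    phase = rep(c("initial", "adaptive"), c(n_init, nrow(X) - n_init)),
    of = of, feasible = feas, max_pressure = mp,
    best_so_far = cummax_best(of, feas))
  best <- if (!is.na(best_idx))
    list(x = X[best_idx, ], of = of[best_idx], index = best_idx,
         max_pressure = mp[best_idx], fallback = FALSE)
  else {
    pi_ <- which.min(surr_val(of, feas))
    list(x = X[pi_, ], of = of[pi_], index = pi_, max_pressure = mp[pi_],
         fallback = TRUE)
  }
  structure(list(points = X, of = of, feasible = feas, max_pressure = mp,
                 best_feasible = best, history = hist,
                 iterations = iter, converged_at = converged_at,
                 penalty = pen, config = config),
            class = "opt_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# running best feasible objective (NA until the first feasible evaluation)
cummax_best <- function(of, feas) {
  out <- numeric(length(of))
  cur <- NA_real_
  for (i in seq_along(of)) {
    if (feas[i] && (is.na(cur) || of[i] < cur)) cur <- of[i]
    out[i] <- cur
  }
  out
}
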