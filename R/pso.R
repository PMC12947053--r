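# Global-best particle swarm optimization for the fusion weights.
#
# Each particle is a candidate (w2d, w3d) vector (optionally with the bias
# as a third dimension). Standard update:
#   v <- inertia*v + cognitive*r1*(pbest - x) + social*r2*(gbest - x)
# with positions clamped to the feasible box (non-negativity of the
# weights) and velocities clamped to a fraction of the box width.

#' Swarm configuration
#'
#' @param population particle count (>= 2, default 20).
#' @param iterations update sweeps (>= 1, default 50).
#' @param inertia,cognitive,social coefficients; defaults 0.72 / 1.49 / 1.49,
#'   standard constriction-like values.
#' @param lower,upper per-dimension bounds; weight dimensions must have
#'   `lower >= 0`. Defaults `[0, 5]` per weight.
#' @param velocity_clamp maximum |velocity| as a fraction of the box width.
#' @param seed RNG seed; the whole search is reproducible given it.
#' @return An object of class `swarm_config`.
#' @export
swarm_config <- function(population = 20L, iterations = 50L, inertia = 0.72,
                         cognitive = 1.49, social = 1.49,
                         lower = c(0, 0), upper = c(5, 5),
                         velocity_clamp = 0.5, seed = 1L) {
  stopifnot(population >= 2L, iterations >= 1L, length(lower) == length(upper),
            all(upper > lower), velocity_clamp > 0)
  structure(list(population = as.integer(population),
                 iterations = as.integer(iterations), inertia = inertia,
                 cognitive = cognitive, social = social,
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 velocity_clamp = velocity_clamp, seed = as.integer(seed)),
            class = "swarm_config")
}

#' Maximize a scalar objective by particle swarm
#'
#' @param objective function from a position vector to a finite scalar;
#'   `NaN`/`NA` evaluations are treated as `-Inf` with a warning.
#' @param config a [swarm_config()].
#' @return list with `par` (best position), `value` (best objective) and
#'   `trace` (global best value after each iteration, non-decreasing).
#' @export
pso_maximize <- function(objective, config = swarm_config()) {
  stopifnot(inherits(config, "swarm_config"))
  set.seed(config$seed)
  ndim <- length(config$lower)
  lo <- config$lower; hi <- config$upper
  width <- hi - lo
  vmax <- config$velocity_clamp * width
  warned <- FALSE
  eval_obj <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) {
      if (!warned) {
        warning("pso_maximize: non-finite objective value(s) treated as -Inf")
        warned <<- TRUE
      }
      v <- -Inf
    }
    v
  }
  X <- matrix(stats::runif(config$population * ndim, rep(lo, each = config$population),
                           rep(hi, each = config$population)),
              config$population, ndim)
  V <- matrix(stats::runif(config$population * ndim, rep(-vmax, each = config$population),
                           rep(vmax, each = config$population)),
              config$population, ndim)
  fit <- apply(X, 1, eval_obj)
  Pb <- X; pb_val <- fit
  g <- which.max(pb_val)
  gbest <- Pb[g, ]; gbest_val <- pb_val[g]
  trace <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    r1 <- matrix(stats::runif(config$population * ndim), config$population, ndim)
    r2 <- matrix(stats::runif(config$population * ndim), config$population, ndim)
    V <- config$inertia * V +
      config$cognitive * r1 * (Pb - X) +
      config$social * r2 * sweep(X, 2, gbest, function(x, g2) g2 - x)
    V <- pmin(pmax(V, matrix(-vmax, config$population, ndim, byrow = TRUE)),
              matrix(vmax, config$population, ndim, byrow = TRUE))
    X <- X + V
    X <- pmin(pmax(X, matrix(lo, config$population, ndim, byrow = TRUE)),
              matrix(hi, config$population, ndim, byrow = TRUE))
    fit <- apply(X, 1, eval_obj)
    improved <- fit > pb_val
    Pb[improved, ] <- X[improved, ]
    pb_val[improved] <- fit[improved]
    g <- which.max(pb_val)
    if (pb_val[g] > gbest_val) {
      gbest <- Pb[g, ]; gbest_val <- pb_val[g]
    }
    trace[it] <- gbest_val
  }
  list(par = gbest, value = gbest_val, trace = trace)
}

#' Mean-Dice objective over frozen training cases
#'
#' Builds a pure function of the fusion weights: for each case, fuse the
#' frozen global 2D probability with the frozen composite 3D map, binarize
#' (strictly > 0.5), score Dice against the reference, and average over
#' cases. The expensive volumes are captured once, so each particle
#' evaluation costs only the fusion and the Dice count.
#'
#' @param cases nonempty list; each element a list with `p2d` (array or
#'   [probability_volume()]), `composite` (from [build_composite()]) and
#'   `ref` ([label_volume()] or 0/1 array).
#' @param b_policy `"centered"` (bias `-(w2d+w3d)/2`), a fixed numeric bias,
#'   or `"optimize"` (bias is the third position dimension).
#' @return function mapping a weight vector to mean Dice.
#' @export
dsc_objective <- function(cases, b_policy = "centered") {
  if (length(cases) == 0L) stop("dsc_objective: empty case list")
  cases <- lapply(cases, function(cs) {
    p2d <- if (inherits(cs$p2d, "probability_volume")) cs$p2d$data else cs$p2d
    ref <- if (inherits(cs$ref, "label_volume")) cs$ref$data else cs$ref
    if (sum(ref) == 0) stop("dsc_objective: empty reference mask")
    list(p2d = p2d, composite = cs$composite, ref = ref)
  })
  function(w) {
    b <- if (identical(b_policy, "optimize")) w[3]
      else if (identical(b_policy, "centered")) -(w[1] + w[2]) / 2
      else b_policy
    wt <- fusion_weights(w[1], w[2], b)
    mean(vapply(cases, function(cs) {
      pred <- binarize(fuse(cs$p2d, cs$composite, wt))
      dice(pred, cs$ref)
    }, numeric(1)))
  }
}

#' Optimize fusion weights by PSO on training cases
#'
#' @param cases as in [dsc_objective()].
#' @param config a [swarm_config()]; 2 dimensions for `b_policy`
#'   `"centered"`/fixed, 3 when the bias is optimized.
#' @param b_policy see [dsc_objective()].
#' @return list with `weights` ([fusion_weights()]), `objective` (mean Dice
#'   at the optimum) and `trace`.
#' @export
optimize_fusion_weights <- function(cases, config = swarm_config(),
                                    b_policy = "centered") {
  if (identical(b_policy, "optimize") && length(config$lower) == 2L)
    config <- swarm_config(config$population, config$iterations,
                           config$inertia, config$cognitive, config$social,
                           lower = c(config$lower, -5),
                           upper = c(config$upper, 5),
                           velocity_clamp = config$velocity_clamp,
                           seed = config$seed)
  res <- pso_maximize(dsc_objective(cases, b_policy), config)
  b <- if (identical(b_policy, "optimize")) res$par[3]
    else if (identical(b_policy, "centered")) "centered" else b_policy
  list(weights = fusion_weights(res$par[1], res$par[2], b),
       objective = res$value, trace = res$trace)
}
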