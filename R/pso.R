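#' Global-best particle swarm optimization
#'
#' Minimizes `fn` over a box. Velocities follow the standard constriction
#' update: inertia `w` plus attraction to each particle's personal best
#' (weight `c1`) and the swarm's global best (weight `c2`), with uniform
#' random factors. Positions leaving the box are handled per
#' `bounds_handling`: clipped to the boundary or reflected. Deterministic
#' under a fixed seed.
#'
#' @param fn Objective function taking a numeric vector, returning a scalar;
#'   non-finite values are treated as a large penalty.
#' @param lower,upper Numeric bound vectors (equal length, `lower < upper`).
#' @param swarm Number of particles (>= 2).
#' @param iters Number of iterations (>= 1).
#' @param w,c1,c2 Inertia, cognitive and social weights; defaults are the
#'   standard constriction values 0.729 / 1.494 / 1.494.
#' @param seed Integer seed for the swarm's private RNG stream.
#' @param bounds_handling `"clip"` or `"reflect"`.
#' @param trace If `TRUE`, prints the best value every 10 iterations.
#' @return List with `par` (best position), `value` (best objective),
#'   `history` (best value per iteration), `evals` (objective evaluations).
#' @examples
#' sphere <- function(x) sum(x^2)
#' pso_optimize(sphere, c(-5, -5), c(5, 5), swarm = 20, iters = 50,
#'              seed = 1)$value
#' @export
pso_optimize <- function(fn, lower, upper, swarm = 30, iters = 200,
                         w = 0.729, c1 = 1.494, c2 = 1.494, seed = 1L,
                         bounds_handling = c("clip", "reflect"),
                         trace = FALSE) {
  bounds_handling <- match.arg(bounds_handling)
  d <- length(lower)
  stopifnot(length(upper) == d, all(lower < upper), swarm >= 2, iters >= 1)
  safe_fn <- function(x) {
    v <- tryCatch(fn(x), error = function(e) Inf)
    if (!is.finite(v)) 1e12 else v
  }
  .with_seed(seed, {
    span <- upper - lower
    pos <- matrix(stats::runif(swarm * d), swarm, d) %*% diag(span, d) +
      matrix(lower, swarm, d, byrow = TRUE)
    vel <- (matrix(stats::runif(swarm * d), swarm, d) - 0.5) %*% diag(span, d)
    pbest <- pos
    pval <- apply(pos, 1, safe_fn)
    evals <- swarm
    if (all(!is.finite(pval)) || all(pval >= 1e12))
      stop("all particles infeasible at initialization")
    gi <- which.min(pval)
    gbest <- pos[gi, ]; gval <- pval[gi]
    history <- numeric(iters)
    for (it in seq_len(iters)) {
      r1 <- matrix(stats::runif(swarm * d), swarm, d)
      r2 <- matrix(stats::runif(swarm * d), swarm, d)
      vel <- w * vel + c1 * r1 * (pbest - pos) +
        c2 * r2 * (matrix(gbest, swarm, d, byrow = TRUE) - pos)
      pos <- pos + vel
      for (j in seq_len(d)) {
        lo <- pos[, j] < lower[j]; hi <- pos[, j] > upper[j]
        if (bounds_handling == "clip") {
          pos[lo, j] <- lower[j]; pos[hi, j] <- upper[j]
        } else {
          pos[lo, j] <- pmin(upper[j],
                             2 * lower[j] - pos[lo, j])
          pos[hi, j] <- pmax(lower[j],
                             2 * upper[j] - pos[hi, j])
        }
        vel[lo | hi, j] <- -0.5 * vel[lo | hi, j]
      }
      val <- apply(pos, 1, safe_fn)
      evals <- evals + swarm
      better <- val < pval
      pbest[better, ] <- pos[better, , drop = FALSE]
      pval[better] <- val[better]
      gi <- which.min(pval)
      if (pval[gi] < gval) {
        gval <- pval[gi]; gbest <- pbest[gi, ]
      }
      history[it] <- gval
      if (trace && it %% 10 == 0)
        cat(sprintf("iter %4d best %.6g\n", it, gval))
    }
    list(par = gbest, value = gval, history = history, evals = evals)
  })
}
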