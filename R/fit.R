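#' Mean squared error between observed and simulated series
#'
#' @param observed,simulated Equal-length numeric vectors, simulated values
#'   taken at the observation days.
#' @return `mean((observed - simulated)^2)`.
#' @examples
#' mse(c(0, 0), c(3, 3))  # 9
#' @export
mse <- function(observed, simulated) {
  if (length(observed) != length(simulated)) stop("length mismatch")
  if (length(observed) == 0) stop("empty series")
  mean((observed - simulated)^2)
}

#' Describe a calibration objective
#'
#' Bundles everything needed to evaluate the goodness of fit of a model
#' variant against observation series: which parameters are free (with box
#' bounds), the fixed parameter values, the event settings per condition,
#' and the integration tolerance used during optimization.
#'
#' @param observations Observation data frame (`species`, `condition`,
#'   `day`, `value`), e.g. from [qpcr_to_observations()].
#' @param variant Model variant to fit.
#' @param free Character vector of parameter names to estimate.
#' @param lower,upper Named (or unnamed, matched to `free`) bound vectors;
#'   default is a ten-fold box around the starting values.
#' @param params Full starting/fixed parameter vector.
#' @param initial Initial amounts.
#' @param eps Knockdown fraction for inhibition conditions.
#' @param t_off Event release time; variant default when `NULL`.
#' @param rtol Integration relative tolerance during optimization.
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(observations, variant = c("enhanced", "initial"),
                           free, lower = NULL, upper = NULL,
                           params = default_params(variant),
                           initial = default_initials(variant),
                           eps = 0.925, t_off = NULL, rtol = 1e-6) {
  variant <- match.arg(variant)
  .check_observations(observations)
  sp <- if (variant == "enhanced") .species_enhanced() else .species_initial()
  bad <- setdiff(unique(observations$species), sp$name)
  if (length(bad)) stop("observation series for unknown species: ",
                        paste(bad, collapse = ", "))
  miss <- setdiff(free, names(params))
  if (length(miss)) stop("free parameter(s) not in params: ",
                         paste(miss, collapse = ", "))
  if (is.null(lower)) lower <- params[free] / 10
  if (is.null(upper)) upper <- params[free] * 10
  lower <- rep_len(unname(lower), length(free))
  upper <- rep_len(unname(upper), length(free))
  if (any(lower <= 0) || any(lower >= upper))
    stop("bounds must satisfy 0 < lower < upper")
  structure(list(observations = observations, variant = variant,
                 free = free, lower = lower, upper = upper, params = params,
                 initial = initial, eps = eps, t_off = t_off, rtol = rtol),
            class = "objective_spec")
}

# simulate every condition once and return the per-(species, condition) MSEs
.per_object_mse <- function(par, spec, rtol = spec$rtol) {
  params <- spec$params
  params[spec$free] <- par
  obs <- spec$observations
  out <- numeric(0)
  for (cond in unique(obs$condition)) {
    sub <- obs[obs$condition == cond, , drop = FALSE]
    days <- sort(unique(sub$day))
    times <- sort(unique(c(0, days)))
    base <- build_model(spec$variant, params = params,
                        initial = spec$initial)
    t_off <- if (is.null(spec$t_off)) {
      if (spec$variant == "enhanced") 4.5 else 7
    } else spec$t_off
    m <- if (cond == "control") base
         else .condition_model(base, cond, eps = spec$eps, t_off = t_off)
    tr <- simulate_model(m, times = times, condition = cond, rtol = rtol)
    for (s in unique(sub$species)) {
      ser <- sub[sub$species == s, , drop = FALSE]
      sim <- tr$states[match(ser$day, times), s]
      out[paste(s, cond, sep = " | ")] <- mse(ser$value, sim)
    }
  }
  out
}

#' Evaluate a calibration objective
#'
#' Simulates every condition once at the candidate parameters and returns
#' the sum of per-object (species x condition series) mean squared errors.
#' Simulation failures return a large finite penalty with a message, so
#' optimizers can continue.
#'
#' @param par Numeric vector of values for the free parameters (in
#'   `spec$free` order).
#' @param spec An [objective_spec()].
#' @return Non-negative scalar.
#' @export
objective_value <- function(par, spec) {
  stopifnot(inherits(spec, "objective_spec"))
  tryCatch(sum(.per_object_mse(par, spec)),
           error = function(e) {
             message("simulation failed (", conditionMessage(e),
                     "); returning penalty")
             1e12
           })
}

#' Fit kinetic model parameters to observation series by particle swarm
#'
#' The package's central estimator: calibrates the chosen free parameters of
#' the initial or enhanced chondrogenesis model against model-unit
#' observation series (control and inhibition conditions) by minimizing the
#' summed per-object mean squared error with global-best particle swarm
#' optimization.
#'
#' @inheritParams objective_spec
#' @param swarm,iters,w,c1,c2 PSO settings (see [pso_optimize()]).
#' @param seed Integer seed; the fit is deterministic given it.
#' @param threshold MSE threshold for the fit assessment (default 3).
#' @param trace Print PSO progress.
#' @return An object of class `kinetic_fit` with components `par` (named
#'   fitted parameters), `objective` (best summed MSE), `assessment`
#'   (a `fit_assessment`, computed at reporting tolerance 1e-8),
#'   `spec`, `pso` (history and evaluation count) and `call`. Methods:
#'   `print`, `summary`, `coef`, `predict`, `residuals`, `fitted`,
#'   `simulate`, `plot`.
#' @examples
#' \donttest{
#' study <- generate_synthetic_study(noise_sd = 0, seed = 2)
#' obs <- qpcr_to_observations(study$qpcr, study$calibration)
#' fit <- fit_kinetics(obs, free = c("rep_miR199a5p_FZD6", "act_ACANmRNA_GAG"),
#'                     swarm = 10, iters = 20, seed = 1)
#' coef(fit)
#' }
#' @export
fit_kinetics <- function(observations, variant = c("enhanced", "initial"),
                         free, lower = NULL, upper = NULL,
                         params = default_params(variant),
                         initial = default_initials(variant),
                         eps = 0.925, t_off = NULL, rtol = 1e-6,
                         swarm = 30, iters = 200, w = 0.729, c1 = 1.494,
                         c2 = 1.494, seed = 1L, threshold = 3,
                         trace = FALSE) {
  variant <- match.arg(variant)
  spec <- objective_spec(observations, variant, free, lower, upper, params,
                         initial, eps, t_off, rtol)
  opt <- pso_optimize(function(p) objective_value(p, spec),
                      lower = spec$lower, upper = spec$upper,
                      swarm = swarm, iters = iters, w = w, c1 = c1, c2 = c2,
                      seed = seed, trace = trace)
  par <- stats::setNames(opt$par, spec$free)
  fit <- structure(
    list(par = par, objective = opt$value, spec = spec,
         pso = list(history = opt$history, evals = opt$evals,
                    swarm = swarm, iters = iters, seed = seed),
         call = match.call()),
    class = "kinetic_fit")
  fit$assessment <- assess(fit, threshold = threshold)
  fit
}

#' Assess a fitted model by per-object mean squared error
#'
#' Computes the MSE of every (species, condition) observation series at the
#' fitted parameters, the number of objects with MSE strictly below the
#' threshold, and the arithmetic mean MSE across all objects with data.
#'
#' @param fit A `kinetic_fit` (or a named numeric vector of per-object MSEs).
#' @param threshold Strict MSE threshold (default 3: "lower than 3").
#' @param ... Unused.
#' @return A `fit_assessment`: list with `per_object` (named numeric),
#'   `n_below_threshold`, `threshold`, `average_mse`, `n_objects`.
#' @export
assess <- function(fit, threshold = 3, ...) UseMethod("assess")

#' @export
assess.kinetic_fit <- function(fit, threshold = 3, ...) {
  per <- .per_object_mse(unname(fit$par), fit$spec, rtol = 1e-8)
  assess(per, threshold = threshold)
}

#' @export
assess.numeric <- function(fit, threshold = 3, ...) {
  if (length(fit) == 0) stop("no objects with data")
  if (any(fit < 0)) stop("negative MSE")
  structure(list(per_object = fit,
                 n_below_threshold = sum(fit < threshold),
                 threshold = threshold,
                 average_mse = mean(fit),
                 n_objects = length(fit)),
            class = "fit_assessment")
}

#' @export
print.fit_assessment <- function(x, ...) {
  cat(sprintf("Fit assessment: %d/%d objects with MSE < %g; average MSE %.4g\n",
              x$n_below_threshold, x$n_objects, x$threshold, x$average_mse))
  invisible(x)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Particle-swarm calibrated kinetic model (", x$spec$variant,
      " variant)\n", sep = "")
  cat("  free parameters:", paste(x$spec$free, collapse = ", "), "\n")
  cat("  objective (sum of per-object MSE):", format(x$objective), "\n")
  print(x$assessment)
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  a <- object$assessment
  res <- list(variant = object$spec$variant,
              coefficients = object$par,
              bounds = cbind(lower = object$spec$lower,
                             upper = object$spec$upper),
              per_object_mse = a$per_object,
              assessment = a,
              objective = object$objective,
              pso = object$pso)
  class(res) <- "summary.kinetic_fit"
  res
}

#' @export
print.summary.kinetic_fit <- function(x, ...) {
  cat("Kinetic model calibration (", x$variant, " variant)\n\n", sep = "")
  cat("Fitted parameters:\n")
  print(x$coefficients)
  cat("\nPer-object MSE:\n")
  print(round(x$per_object_mse, 4))
  cat("\n")
  print(x$assessment)
  cat(sprintf("PSO: swarm %d x %d iterations (%d evaluations), seed %d\n",
              x$pso$swarm, x$pso$iters, x$pso$evals, x$pso$seed))
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) object$par

# full parameter vector with fitted values substituted
.fitted_params <- function(object) {
  p <- object$spec$params
  p[object$spec$free] <- object$par
  p
}

# fitted model for a condition label
.fit_model <- function(object, condition) {
  base <- build_model(object$spec$variant, params = .fitted_params(object),
                      initial = object$spec$initial)
  if (condition == "control") return(base)
  if (is.null(object$spec$t_off))
    .condition_model(base, condition, eps = object$spec$eps)
  else
    .condition_model(base, condition, eps = object$spec$eps,
                     t_off = object$spec$t_off)
}

#' Predict species values from a fitted kinetic model
#'
#' @param object A `kinetic_fit`.
#' @param newdata Data frame with columns `species`, `condition`, `day`;
#'   defaults to the observation points used for fitting.
#' @param rtol Integration tolerance.
#' @param ... Unused.
#' @return `newdata` with a `value` column of simulated amounts.
#' @export
predict.kinetic_fit <- function(object, newdata = NULL, rtol = 1e-8, ...) {
  if (is.null(newdata))
    newdata <- object$spec$observations[c("species", "condition", "day")]
  out <- newdata
  out$value <- NA_real_
  for (cond in unique(newdata$condition)) {
    sel <- newdata$condition == cond
    times <- sort(unique(c(0, newdata$day[sel])))
    tr <- simulate_model(.fit_model(object, cond), times = times,
                         condition = cond, rtol = rtol)
    out$value[sel] <- tr$states[cbind(match(newdata$day[sel], times),
                                      match(newdata$species[sel],
                                            colnames(tr$states)))]
  }
  out
}

#' @export
fitted.kinetic_fit <- function(object, ...) predict(object)$value

#' @export
residuals.kinetic_fit <- function(object, ...) {
  object$spec$observations$value - fitted(object)
}

#' Simulate noisy replicate observations from a fitted model
#'
#' Draws `nsim` replicate observation sets at the fitted parameters by
#' applying multiplicative lognormal noise to the deterministic simulated
#' values at the original observation points.
#'
#' @param object A `kinetic_fit`.
#' @param nsim Number of replicate data sets.
#' @param seed Integer seed.
#' @param noise_sd Lognormal sdlog of the measurement noise.
#' @param ... Unused.
#' @return A list of `nsim` observation data frames.
#' @export
simulate.kinetic_fit <- function(object, nsim = 1, seed = 1L,
                                 noise_sd = 0.1, ...) {
  det <- predict(object)
  .with_seed(seed, lapply(seq_len(nsim), function(i) {
    out <- det
    out$value <- det$value * stats::rlnorm(nrow(det), 0, noise_sd)
    out
  }))
}

#' Plot a fitted kinetic model against its observations
#'
#' One panel per (species, condition) series: simulated trajectory as a
#' line, observations as points, per-object MSE in the panel title.
#'
#' @param x A `kinetic_fit`.
#' @param rtol Integration tolerance for the plotted trajectories.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.kinetic_fit <- function(x, rtol = 1e-8, ...) {
  obs <- x$spec$observations
  keys <- unique(obs[c("species", "condition")])
  nk <- nrow(keys)
  oldpar <- graphics::par(mfrow = c(ceiling(nk / 3), min(3, nk)),
                          mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  per <- x$assessment$per_object
  for (i in seq_len(nk)) {
    s <- keys$species[i]; cond <- keys$condition[i]
    ser <- obs[obs$species == s & obs$condition == cond, , drop = FALSE]
    tgrid <- seq(0, max(ser$day), length.out = 100)
    tr <- simulate_model(.fit_model(x, cond), times = tgrid,
                         condition = cond, rtol = rtol)
    ylim <- range(c(tr$states[, s], ser$value))
    graphics::plot(tgrid, tr$states[, s], type = "l", col = "blue",
                   xlab = "day", ylab = "amount (model units)",
                   ylim = ylim,
                   main = sprintf("%s | %s (MSE %.3g)", s, cond,
                                  per[paste(s, cond, sep = " | ")]), ...)
    graphics::points(ser$day, ser$value, col = "red", pch = 4)
  }
  invisible(x)
}
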