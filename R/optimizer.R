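# Adaptive stochastic gradient descent (ASGD). Steps follow
#   x_{k+1} = x_k - gamma(t_k) g_k,   gamma(t) = a / (A + t)^alpha,
# where the artificial time t grows by a sigmoid of the inner product of
# successive gradients: anticorrelated gradients (oscillation) advance time
# and shrink the step, correlated gradients rewind it and keep steps large.
# This makes the schedule robust to the noise of a randomly sampled metric.

#' Minimize an objective with adaptive stochastic gradient descent
#'
#' @param objective function of the parameter vector returning
#'   `list(value =, gradient =)`; gradients may be stochastic (e.g. finite
#'   differences on a sampled metric).
#' @param x0 start parameters.
#' @param config a [reg_config()]; uses `iterations`, `asgd_a`, `asgd_A`,
#'   `asgd_alpha`, `step_target` and `tol`.
#' @param seed optional RNG seed wrapped around the whole run (the objective
#'   may itself draw random samples).
#' @return `list(par, value, iterations, converged, trace)`; `trace` holds
#'   the objective value per iteration.
#' @export
asgd_minimize <- function(objective, x0, config = reg_config(), seed = NULL) {
  with_seed(seed, {
    x <- as.numeric(x0)
    a <- config$asgd_a
    A <- config$asgd_A
    alpha <- config$asgd_alpha
    tcur <- 0
    gprev <- NULL
    ip_scale <- NULL
    trace <- numeric(0)
    converged <- FALSE
    k <- 0
    while (k < config$iterations) {
      k <- k + 1
      o <- objective(x)
      if (!is.finite(o$value) || any(!is.finite(o$gradient))) {
        warning("non-finite objective; aborting optimization")
        return(list(par = x, value = NA_real_, iterations = k,
                    converged = FALSE, trace = trace))
      }
      trace[k] <- o$value
      g <- o$gradient
      if (is.null(a)) {
        gmax <- max(abs(g))
        if (gmax < 1e-12) {
          converged <- TRUE
          break
        }
        a <- config$step_target * (A + 1)^alpha / gmax
      }
      gamma <- a / (A + tcur)^alpha
      step <- gamma * g
      # trust region: scaled parameters are calibrated so one unit is about
      # one pixel of induced motion, so cap the step at max_step pixels
      snorm <- sqrt(sum(step^2))
      if (snorm > config$max_step) step <- step * (config$max_step / snorm)
      x <- x - step
      if (!is.null(gprev)) {
        ip <- sum(g * gprev)
        ip_scale <- if (is.null(ip_scale)) abs(ip) else
          0.9 * ip_scale + 0.1 * abs(ip)
        omega <- max(ip_scale, 1e-12)
        # sigmoid in [-0.5, 1]: oscillation -> slow down, progress -> keep pace
        sig <- -0.5 + 1.5 / (1 + exp(ip / omega))
        tcur <- max(0, tcur + sig)
      } else {
        tcur <- tcur + 1
      }
      gprev <- g
      if (sqrt(sum(step^2)) < config$tol) {
        converged <- TRUE
        break
      }
    }
    list(par = x, value = if (k > 0) trace[k] else NA_real_, iterations = k,
         converged = converged, trace = trace)
  })
}
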