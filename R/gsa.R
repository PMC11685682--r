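#' Generalized simulated annealing
#'
#' Bounded global minimization by generalized simulated annealing (GSA),
#' the scheme that interpolates between classical and fast simulated
#' annealing: candidate steps are drawn from the Tsallis (Cauchy-Lorentz
#' family) visiting distribution with shape `qv`, worse moves are accepted
#' under the generalized Metropolis rule with shape `qa`, and the visiting
#' temperature follows t(i) = t0 (2^(qv-1) - 1) / ((1+i)^(qv-1) - 1).
#' Candidates outside the box are folded back in. Optionally the incumbent
#' best point is polished with bounded L-BFGS-B whenever it improves, and
#' once more at the end.
#'
#' The routine consumes the R random number stream: seed it with
#' `set.seed()` for reproducible runs.
#'
#' @param fn Objective: numeric vector -> finite scalar.
#' @param lower,upper Box bounds (finite, lower < upper elementwise).
#' @param x0 Start point inside the box; default the box center.
#' @param maxiter Outer annealing iterations (each visits all coordinates
#'   jointly and then one by one).
#' @param qv Visiting distribution shape, in (1, 3); 2.62 is the standard
#'   GSA default.
#' @param qa Acceptance shape; negative values give harder rejection of
#'   uphill moves as temperature falls.
#' @param t0 Initial visiting temperature.
#' @param local_polish Run bounded L-BFGS-B from new incumbent bests?
#' @return List with `par`, `value`, `trace` (data.frame iteration /
#'   best_objective), and `n_eval`.
#' @export
gsa_minimize <- function(fn, lower, upper, x0 = NULL, maxiter = 200,
                         qv = 2.62, qa = -5.0, t0 = 5230,
                         local_polish = TRUE) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  n <- length(lower)
  if (length(upper) != n) stop("bound lengths differ")
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper))
    stop("bounds must be finite with lower < upper")
  if (is.null(x0)) x0 <- (lower + upper) / 2
  if (length(x0) != n || any(x0 < lower - 1e-12) || any(x0 > upper + 1e-12))
    stop("start point must lie inside the bounds")
  if (qv <= 1 || qv >= 3) stop("qv must lie in (1, 3)")

  n_eval <- 0L
  eval_fn <- function(x) {
    v <- fn(x)
    n_eval <<- n_eval + 1L
    if (!is.finite(v))
      stop(sprintf("non-finite objective at parameters: %s",
                   paste(signif(x, 6), collapse = ", ")))
    v
  }
  fold <- function(x) {
    r <- upper - lower
    lower + (x - lower) %% r
  }
  polish <- function(par, value) {
    o <- tryCatch(
      stats::optim(par, eval_fn, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 100)),
      error = function(e) NULL)
    if (!is.null(o) && is.finite(o$value) && o$value < value)
      list(par = o$par, value = o$value)
    else list(par = par, value = value)
  }

  x <- x0
  fx <- eval_fn(x)
  best <- x; fbest <- fx
  fraw <- fx                       # best raw (unpolished) chain value
  if (local_polish) {
    p <- polish(best, fbest); best <- p$par; fbest <- p$value
  }
  trace <- data.frame(iteration = integer(maxiter),
                      best_objective = numeric(maxiter))
  tfac <- 2^(qv - 1) - 1

  for (i in seq_len(maxiter)) {
    temp <- t0 * tfac / ((1 + i)^(qv - 1) - 1)
    t_accept <- temp / i
    for (j in seq_len(2L * n)) {
      if (j <= n) {
        step <- gsa_visit(temp, n, qv)
        cand <- fold(x + step)
      } else {
        k <- j - n
        cand <- x
        r <- upper[k] - lower[k]
        cand[k] <- lower[k] + (x[k] + gsa_visit(temp, 1L, qv) - lower[k]) %% r
      }
      fc <- eval_fn(cand)
      de <- fc - fx
      accept <- if (de < 0) TRUE else {
        pqa <- 1 - (1 - qa) * de / t_accept
        pqa > 0 && stats::runif(1) < pqa^(1 / (1 - qa))
      }
      if (accept) {
        x <- cand; fx <- fc
        if (fx < fbest) { best <- x; fbest <- fx }
        # polish every materially new raw basin the chain discovers, so
        # distinct local minima each get a chance at the global optimum
        if (fx < fraw - max(0.2 * abs(fraw), 1e-9)) {
          fraw <- fx
          if (local_polish) {
            p <- polish(x, fx)
            if (p$value < fbest) { best <- p$par; fbest <- p$value }
          }
        }
      }
    }
    # periodically polish the current chain point too: at moderate
    # temperature the chain wanders between basins, and this samples them
    if (local_polish && i %% 5L == 0L) {
      p <- polish(x, fx)
      if (p$value < fbest) { best <- p$par; fbest <- p$value }
    }
    trace$iteration[i] <- i
    trace$best_objective[i] <- fbest
  }
  if (local_polish) {
    p <- polish(best, fbest); best <- p$par; fbest <- p$value
  }
  list(par = best, value = fbest, trace = trace, n_eval = n_eval)
}

# One draw (per dimension) from the Tsallis visiting distribution at the
# given temperature: a Gaussian scaled by a temperature-dependent sigma,
# divided by a power of a second Gaussian's magnitude (heavy tails).
gsa_visit <- function(temperature, n, qv) {
  f1 <- exp(log(temperature) / (qv - 1))
  f2 <- exp((4 - qv) * log(qv - 1))
  f3 <- exp((2 - qv) * log(2) / (qv - 1))
  f4 <- sqrt(pi) * f1 * f2 / (f3 * (3 - qv))
  f5 <- 1 / (qv - 1) - 0.5
  f6 <- pi * (1 - f5) / sin(pi * (1 - f5)) / gamma(2 - f5)
  sigmax <- exp(-(qv - 1) * log(f6 / f4) / (3 - qv))
  gx <- sigmax * stats::rnorm(n)
  gy <- stats::rnorm(n)
  den <- exp((qv - 1) * log(abs(gy)) / (3 - qv))
  v <- gx / den
  pmin(pmax(v, -1e8), 1e8)
}
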