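#' Exponential feed rate
#'
#' Open-loop exponential feeding profile
#' F(t) = yxs * mu0 * x0 * V0 * exp(mu0 t) / (cf - cs),
#' with cs the design-time vessel substrate concentration (a constant, taken
#' from the plan; the profile is not adapted to measured accumulation).
#'
#' @param plan a \code{\link{FedBatchPlan}}.
#' @param t time since feed start, h (vectorized).
#' @return Feed rate in L/h.
#' @examples
#' p <- fedBatchPlan(yxs = 3, mu0 = 0.05, cf = 220, cs0 = 0, x0 = 10.9,
#'                   v0 = 0.5)
#' feedRate(p, 0) * 1000   # mL/h at feed start, ~3.72
#' @export
feedRate <- function(plan, t) {
  stopifnot(is(plan, "FedBatchPlan"), all(t >= 0))
  if (plan@cf <= plan@cs0)
    stop("feed concentration must exceed the vessel concentration")
  plan@yxs * plan@mu0 * plan@x0 * plan@v0 * exp(plan@mu0 * t) /
    (plan@cf - plan@cs0)
}

#' Simulate a fed-batch cultivation under the exponential feed
#'
#' Integrates the vessel mass balances with a fixed-step 4th-order
#' Runge-Kutta scheme:
#' dV/dt = F, d(xV)/dt = mu_eff xV, d(csV)/dt = F cf - yxs mu_eff xV,
#' where F follows \code{\link{feedRate}} and mu_eff is either the design
#' rate (\code{"ideal"}) or a piecewise schedule (\code{phases}), emulating
#' the multi-phase growth seen in practice. When consumption drives the
#' vessel substrate to zero, growth becomes substrate-limited: consumption is
#' capped at the feed supply and the trajectory is flagged.
#'
#' @param plan a \code{\link{FedBatchPlan}}.
#' @param growthModel \code{"ideal"} or \code{"phased"}.
#' @param phases for \code{"phased"}: data.frame with columns
#'   \code{duration} (h) and \code{mu} (1/h); beyond the schedule the last
#'   phase's rate applies.
#' @param dt integration step, h (default 0.01).
#' @return A \code{\link{FedBatchTrajectory}}.
#' @examples
#' p <- fedBatchPlan(yxs = 2.3, mu0 = 0.05, cf = 190, cs0 = 0, x0 = 14.6,
#'                   v0 = 0.5, duration = 24)
#' tr <- simulateFedBatch(p)
#' tail(tr@trajectory, 1)
#' @export
simulateFedBatch <- function(plan, growthModel = c("ideal", "phased"),
                             phases = NULL, dt = 0.01) {
  stopifnot(is(plan, "FedBatchPlan"), dt > 0)
  growthModel <- match.arg(growthModel)
  if (growthModel == "phased") {
    if (is.null(phases) || !all(c("duration", "mu") %in% names(phases)))
      stop("phased mode needs a phases data.frame with duration and mu")
    bounds <- cumsum(phases$duration)
    muAt <- function(t) {
      i <- findInterval(t, c(0, bounds), rightmost.closed = FALSE)
      phases$mu[min(i, nrow(phases))]
    }
  } else {
    muAt <- function(t) plan@mu0
  }

  nstep <- max(0L, ceiling(plan@duration / dt - 1e-9))
  times <- seq(0, by = dt, length.out = nstep + 1)
  if (nstep > 0) times[nstep + 1] <- min(times[nstep + 1], plan@duration)
  out <- matrix(NA_real_, nstep + 1, 5,
                dimnames = list(NULL, c("t", "V", "x", "cs", "F")))
  limited <- FALSE

  # state y = (V, X = xV, Ms = cs*V)
  deriv <- function(t, y) {
    f <- feedRate(plan, t)
    mu <- muAt(t)
    cons <- plan@yxs * mu * y[2]
    c(f, mu * y[2], f * plan@cf - cons)
  }
  y <- c(plan@v0, plan@x0 * plan@v0, plan@cs0 * plan@v0)
  out[1, ] <- c(0, y[1], y[2] / y[1], y[3] / y[1], feedRate(plan, 0))
  for (i in seq_len(nstep)) {
    t0 <- times[i]
    h <- times[i + 1] - t0
    if (h <= 0) { out[i + 1, ] <- out[i, ]; out[i + 1, 1] <- times[i + 1]; next }
    k1 <- deriv(t0, y)
    k2 <- deriv(t0 + h / 2, y + h / 2 * k1)
    k3 <- deriv(t0 + h / 2, y + h / 2 * k2)
    k4 <- deriv(t0 + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (y[3] < 0) {  # substrate exhausted within the step
      limited <- TRUE
      y[3] <- 0
    }
    out[i + 1, ] <- c(times[i + 1], y[1], y[2] / y[1], y[3] / y[1],
                      feedRate(plan, times[i + 1]))
  }
  new("FedBatchTrajectory", trajectory = as.data.frame(out),
      substrateLimited = limited)
}

#' Write a fed-batch trajectory (and pump profile) as TSV
#'
#' @param trajectory a \code{\link{FedBatchTrajectory}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(trajectory, path) {
  utils::write.table(trajectory@trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
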