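#' Integrate a network to rest
#'
#' Solves the influence-network ODEs from a starting state until the system
#' is at rest (max |dX/dt| below \code{rate_tol}) or \code{max_time} model
#' time units have elapsed, whichever comes first. Integration uses the
#' livermore solver with root-triggered termination, so the trajectory stops
#' at the moment the rest criterion is met.
#'
#' @param net an \code{\link{influence_network}}.
#' @param x0 starting state; values are expected in [0, 1] and are clipped
#'   (with a warning) when slightly outside.
#' @param signals named numeric vector of signal levels.
#' @param max_time maximum model time (1 time unit = 1.5 days).
#' @param rate_tol rest criterion on max |dX/dt|.
#' @param record_dt spacing of recorded trajectory points.
#' @return A data frame of class \code{"network_trajectory"} with a
#'   \code{time} column and one column per node; attributes \code{final}
#'   (ending state), \code{converged} (logical: rest criterion met),
#'   \code{reason} (\code{"rest"} or \code{"max_time"}) and \code{residual}
#'   (max |dX/dt| at the ending state).
#' @export
integrate_network <- function(net, x0, signals = NULL,
                              max_time = 1000, rate_tol = 1e-9,
                              record_dt = NULL) {
  x0 <- check_state(net, x0)
  if (any(x0 < 0) || any(x0 > 1)) {
    if (any(x0 < -1e-8) || any(x0 > 1 + 1e-8))
      warning("starting state outside [0,1]; clipping to the unit box")
    x0 <- pmin(pmax(x0, 0), 1)
  }
  s <- full_signals(net, signals)
  if (is.null(record_dt)) record_dt <- max(max_time / 400, 0.25)
  times <- unique(c(seq(0, max_time, by = record_dt), max_time))

  derivs <- function(t, y, parms) list(as.numeric(network_rhs(net, y, s)))
  rootfn <- function(t, y, parms) max(abs(network_rhs(net, y, s))) - rate_tol
  jacfn  <- function(t, y, parms) network_jacobian(net, y, s)

  sol <- deSolve::lsodar(y = stats::setNames(x0, net$nodes), times = times,
                         func = derivs, rootfunc = rootfn, jacfunc = jacfn,
                         jactype = "fullusr", rtol = 1e-10, atol = 1e-12)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0)
    stop("integration failed (solver istate = ", attr(sol, "istate")[1],
         "); try a smaller rate_tol or check the model parameters", call. = FALSE)
  out <- as.data.frame(unclass(sol)[seq_len(nrow(sol)), , drop = FALSE])
  names(out) <- c("time", net$nodes)
  final <- stats::setNames(as.numeric(out[nrow(out), -1L]), net$nodes)
  residual <- max(abs(network_rhs(net, final, s)))
  converged <- residual <= rate_tol * (1 + 1e-6)
  structure(out,
            class = c("network_trajectory", "data.frame"),
            final = final, converged = converged,
            reason = if (converged) "rest" else "max_time",
            residual = residual, signals = s)
}

#' Ending state of a trajectory
#' @param traj a \code{"network_trajectory"}.
#' @return named numeric state vector at the end of the trajectory.
#' @export
final_state <- function(traj) attr(traj, "final")

# Classical fixed-step RK4 integration of one state; independent of the
# adaptive solver and of the batch population integrator's convergence
# logic. Used as a step-halving reference.
rk4_integrate <- function(net, x0, signals = NULL, t_end = 10, dt = 0.01) {
  s <- full_signals(net, signals)
  x <- check_state(net, x0)
  nstep <- ceiling(t_end / dt)
  dt <- t_end / nstep
  for (k in seq_len(nstep)) {
    k1 <- as.numeric(network_rhs(net, x, s))
    k2 <- as.numeric(network_rhs(net, x + dt / 2 * k1, s))
    k3 <- as.numeric(network_rhs(net, x + dt / 2 * k2, s))
    k4 <- as.numeric(network_rhs(net, x + dt * k3, s))
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  stats::setNames(x, net$nodes)
}
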