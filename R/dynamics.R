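#' Numerically stable logistic sigmoid
#'
#' The soft-threshold response function \eqn{F(u) = 1/(1 + e^{-u})} through
#' which every effective drive acts. Stable for arguments of very large
#' magnitude (no overflow up to and beyond |u| ~ 700).
#'
#' @param u numeric vector of drives; must be finite.
#' @return values in (0, 1), same length as \code{u}.
#' @examples
#' sigmoid(0)        # 0.5
#' sigmoid(log(3))   # 0.75
#' @export
sigmoid <- function(u) {
  if (!is.numeric(u) || any(!is.finite(u)))
    stop("`u` must be finite numeric", call. = FALSE)
  out <- u
  pos <- u >= 0
  out[pos] <- 1 / (1 + exp(-u[pos]))
  eu <- exp(u[!pos])
  out[!pos] <- eu / (1 + eu)
  out
}

# apply the optional per-signal saturation transform s -> smax * s / (K + s)
saturate_signals <- function(net, s) {
  if (is.null(net$saturation)) return(s)
  for (nm in names(net$saturation)) {
    el <- net$saturation[[nm]]
    s[nm] <- el$smax * s[nm] / (el$K + s[nm])
  }
  s
}

check_state <- function(net, x) {
  x <- as.numeric(x)
  if (length(x) != n_nodes(net))
    stop("state must have length ", n_nodes(net), call. = FALSE)
  if (any(!is.finite(x))) stop("state must be finite", call. = FALSE)
  x
}

#' Effective drive of every node
#'
#' Computes \eqn{W_i = \omega_{i0} + \sum_j \omega_{j\to i} X_j +
#' \sum_s \omega_{s\to i} S_s} for each node, with signals optionally passed
#' through their saturation transform first.
#'
#' @param net an \code{\link{influence_network}}.
#' @param x numeric state vector (one activity per node).
#' @param signals named numeric vector of signal levels (missing signals
#'   default to 0; unknown names are an error).
#' @return named numeric vector of drives, one per node.
#' @export
effective_drive <- function(net, x, signals = NULL) {
  x <- check_state(net, x)
  s <- saturate_signals(net, full_signals(net, signals))
  w <- net$omega0 + as.vector(crossprod(net$omega, x))
  if (length(s)) w <- w + as.vector(crossprod(net$signal_omega, s))
  stats::setNames(w, net$nodes)
}

#' Right-hand side of the influence-network ODEs
#'
#' The equations of motion are
#' \deqn{dX_i/dt = \gamma_i \left( F(\sigma_i W_i) - X_i \right)}
#' with \eqn{F} the logistic sigmoid and \eqn{W_i} the effective drive.
#'
#' @inheritParams effective_drive
#' @return named numeric vector of rates \eqn{dX_i/dt}.
#' @export
network_rhs <- function(net, x, signals = NULL) {
  w <- effective_drive(net, x, signals)
  stats::setNames(net$gamma * (sigmoid(net$sigma * w) - as.numeric(x)), net$nodes)
}

#' Jacobian of the influence-network ODEs
#'
#' Analytic Jacobian
#' \eqn{J_{ij} = \gamma_i \sigma_i F'(\sigma_i W_i)\, \omega_{j\to i} -
#' \gamma_i \delta_{ij}} with \eqn{F' = F (1 - F)}, used for stability
#' classification and for the continuation test functions.
#'
#' @inheritParams effective_drive
#' @return square numeric matrix, rows and columns named by node.
#' @export
network_jacobian <- function(net, x, signals = NULL) {
  x <- check_state(net, x)
  w <- effective_drive(net, x, signals)
  f <- sigmoid(net$sigma * w)
  g <- net$gamma * net$sigma * f * (1 - f)
  J <- g * t(net$omega)
  diag(J) <- diag(J) - net$gamma
  dimnames(J) <- list(net$nodes, net$nodes)
  J
}

# derivative of the rhs with respect to one signal level (used by continuation)
rhs_dparam <- function(net, x, signals, param) {
  w <- effective_drive(net, x, signals)
  f <- sigmoid(net$sigma * w)
  dsdp <- 1
  if (!is.null(net$saturation) && param %in% names(net$saturation)) {
    el <- net$saturation[[param]]
    s0 <- full_signals(net, signals)[param]
    dsdp <- el$smax * el$K / (el$K + s0)^2
  }
  net$gamma * net$sigma * f * (1 - f) * net$signal_omega[param, ] * dsdp
}
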