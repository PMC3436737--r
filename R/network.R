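#' Construct an influence network
#'
#' An influence network is the phenomenological model of a gene-regulatory
#' motif used throughout this package: each node (typically a master
#' regulator such as T-bet or GATA3) carries an activity \eqn{X_i \in [0,1]}
#' that relaxes, at rate \eqn{\gamma_i}, towards a sigmoidal function of its
#' effective drive
#' \deqn{W_i = \omega_{i0} + \sum_j \omega_{j\to i} X_j + \sum_s \omega_{s\to i} S_s,}
#' where the \eqn{S_s} are exogenous signal levels. See
#' \code{\link{network_rhs}} for the equations of motion.
#'
#' @param nodes character vector of node (state variable) names.
#' @param signals character vector of exogenous signal names (may be empty).
#' @param omega square numeric matrix of interaction weights; entry
#'   \code{omega[j, i]} is the weight of the influence of node \code{j} on
#'   node \code{i} (negative for inhibition). Defaults to all zeros.
#' @param omega0 per-node basal weight \eqn{\omega_{i0}} (recycled).
#' @param sigma per-node sigmoid steepness \eqn{\sigma_i > 0} (recycled).
#' @param gamma per-node relaxation rate \eqn{\gamma_i > 0} (recycled), in
#'   inverse model-time units (one model-time unit corresponds to 1.5 days).
#' @param signal_omega numeric matrix of signal weights with one row per
#'   signal and one column per node; entry \code{signal_omega[s, i]} is the
#'   weight of signal \code{s} on node \code{i}. Defaults to all zeros.
#' @param regulators character vector naming the two designated master
#'   regulators used for phenotype calling; defaults to the first two nodes
#'   when the network has at least two nodes.
#' @param polarizing optional character vector naming the two polarizing
#'   signals that are exchanged under the X/Y mirror symmetry; defaults to
#'   the second and third signal when three or more signals are present.
#' @param saturation optional named list switching on signal saturation for
#'   individual signals; each element is a list with components \code{smax}
#'   and \code{K}, and the named signal level \code{s} is transformed to
#'   \code{smax * s / (K + s)} before entering the drive. Off by default.
#'
#' @return An object of class \code{"influence_network"}.
#' @examples
#' net <- influence_network(
#'   nodes = c("X", "Y"), signals = c("S1", "S2", "S3"),
#'   omega = matrix(c(0, -4, -4, 0), 2, 2, dimnames = list(c("X", "Y"), c("X", "Y"))),
#'   omega0 = -2.2, sigma = 2, gamma = 5,
#'   signal_omega = rbind(S1 = c(2.7, 2.7), S2 = c(3, 0), S3 = c(0, 3))
#' )
#' is_symmetric_network(net)
#' @export
influence_network <- function(nodes, signals = character(),
                              omega = NULL, omega0 = 0,
                              sigma = 1, gamma = 1,
                              signal_omega = NULL,
                              regulators = NULL,
                              polarizing = NULL,
                              saturation = NULL) {
  if (!is.character(nodes) || length(nodes) < 1L || anyDuplicated(nodes))
    stop("`nodes` must be a character vector of distinct names", call. = FALSE)
  if (!is.character(signals) || anyDuplicated(signals))
    stop("`signals` must be a character vector of distinct names", call. = FALSE)
  n <- length(nodes); s <- length(signals)

  if (is.null(omega)) omega <- matrix(0, n, n)
  omega <- as.matrix(omega)
  if (!is.numeric(omega) || nrow(omega) != n || ncol(omega) != n)
    stop("`omega` must be a ", n, "x", n, " numeric matrix (one row/column per node)",
         call. = FALSE)
  dimnames(omega) <- list(nodes, nodes)

  omega0 <- rep_len(as.numeric(omega0), n)
  sigma  <- rep_len(as.numeric(sigma), n)
  gamma  <- rep_len(as.numeric(gamma), n)
  if (any(!is.finite(c(omega, omega0, sigma, gamma))))
    stop("network parameters must all be finite", call. = FALSE)
  if (any(sigma <= 0)) stop("`sigma` must be > 0 for every node", call. = FALSE)
  if (any(gamma <= 0)) stop("`gamma` must be > 0 for every node", call. = FALSE)

  if (is.null(signal_omega)) signal_omega <- matrix(0, s, n)
  signal_omega <- matrix(as.numeric(signal_omega), s, n)
  if (s > 0 && (!is.numeric(signal_omega) || any(!is.finite(signal_omega))))
    stop("`signal_omega` must be a finite numeric ", s, "x", n, " matrix", call. = FALSE)
  dimnames(signal_omega) <- list(signals, nodes)

  if (is.null(regulators) && n >= 2L) regulators <- nodes[1:2]
  if (!is.null(regulators)) {
    if (length(regulators) != 2L || !all(regulators %in% nodes))
      stop("`regulators` must name exactly two nodes of the network", call. = FALSE)
  }
  if (is.null(polarizing) && s >= 3L) polarizing <- signals[2:3]
  if (!is.null(polarizing) &&
      (length(polarizing) != 2L || !all(polarizing %in% signals)))
    stop("`polarizing` must name exactly two signals of the network", call. = FALSE)

  if (!is.null(saturation)) {
    if (!is.list(saturation) || is.null(names(saturation)) ||
        !all(names(saturation) %in% signals))
      stop("`saturation` must be a named list keyed by signal names", call. = FALSE)
    for (nm in names(saturation)) {
      el <- saturation[[nm]]
      if (!is.list(el) || !all(c("smax", "K") %in% names(el)) ||
          el$K <= 0 || el$smax <= 0)
        stop("saturation entry for signal '", nm,
             "' must be list(smax = , K = ) with positive values", call. = FALSE)
    }
  }

  structure(
    list(nodes = nodes, signals = signals,
         omega = omega, omega0 = stats::setNames(omega0, nodes),
         sigma = stats::setNames(sigma, nodes),
         gamma = stats::setNames(gamma, nodes),
         signal_omega = signal_omega,
         regulators = regulators, polarizing = polarizing,
         saturation = saturation),
    class = "influence_network")
}

#' @export
print.influence_network <- function(x, ...) {
  cat("<influence_network> ", length(x$nodes), " node(s): ",
      paste(x$nodes, collapse = ", "), "\n", sep = "")
  if (length(x$signals))
    cat("  signals: ", paste(x$signals, collapse = ", "), "\n", sep = "")
  if (!is.null(x$regulators))
    cat("  regulators: ", paste(x$regulators, collapse = " / "), "\n", sep = "")
  cat("  omega:\n")
  print(x$omega)
  cat("  omega0: "); print(x$omega0)
  cat("  sigma:  "); print(x$sigma)
  cat("  gamma:  "); print(x$gamma)
  if (length(x$signals)) { cat("  signal_omega:\n"); print(x$signal_omega) }
  if (!is.null(x$saturation))
    cat("  saturation on: ", paste(names(x$saturation), collapse = ", "), "\n", sep = "")
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)

#' Fill and validate a set of signal levels
#'
#' Returns a full named vector of signal levels for the network, defaulting
#' unmentioned signals to 0 and rejecting unknown signal names.
#'
#' @param net an \code{\link{influence_network}}.
#' @param signals named numeric vector (or list) of signal levels.
#' @return Named numeric vector with one nonnegative entry per network signal.
#' @export
full_signals <- function(net, signals = NULL) {
  out <- stats::setNames(numeric(length(net$signals)), net$signals)
  if (is.null(signals) || length(signals) == 0L) return(out)
  signals <- unlist(signals)
  if (is.null(names(signals)) || any(names(signals) == ""))
    stop("signal levels must be named", call. = FALSE)
  unknown <- setdiff(names(signals), net$signals)
  if (length(unknown))
    stop("unknown signal name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (any(!is.finite(signals)))
    stop("signal levels must be finite", call. = FALSE)
  out[names(signals)] <- as.numeric(signals)
  out
}

# node permutation that swaps the two designated regulators
swap_perm <- function(net) {
  p <- seq_along(net$nodes)
  i <- match(net$regulators, net$nodes)
  p[i] <- rev(i)
  p
}

#' Test the X/Y mirror symmetry of a network
#'
#' A network is symmetric when simultaneously swapping its two master
#' regulators and its two polarizing signals leaves every parameter
#' (interaction weights, basal weights, steepness, relaxation rates and
#' signal weights) unchanged. Symmetric networks undergo pitchfork rather
#' than fold bifurcations on the symmetric branch.
#'
#' @param net an \code{\link{influence_network}} with two designated
#'   regulators.
#' @param tol numeric comparison tolerance.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
is_symmetric_network <- function(net, tol = 1e-12) {
  if (is.null(net$regulators)) return(FALSE)
  p <- swap_perm(net)
  q <- seq_along(net$signals)
  if (!is.null(net$polarizing)) {
    i <- match(net$polarizing, net$signals)
    q[i] <- rev(i)
  }
  ok <- max(abs(net$omega[p, p] - net$omega)) < tol &&
    max(abs(net$omega0[p] - net$omega0)) < tol &&
    max(abs(net$sigma[p] - net$sigma)) < tol &&
    max(abs(net$gamma[p] - net$gamma)) < tol
  if (length(net$signals))
    ok <- ok && max(abs(net$signal_omega[q, p, drop = FALSE] - net$signal_omega)) < tol
  ok
}

# reflect a state (or matrix of states, rows = states) through the X<->Y mirror
mirror_state <- function(net, x) {
  p <- swap_perm(net)
  if (is.matrix(x)) x[, p, drop = FALSE] else x[p]
}
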