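# Vectorised multistart Newton solver for fixed points of the map
# x -> F(sigma * W(x)).  `X` holds one start per row; `drive` holds, per row,
# the state-independent part of the drive (basal + signal terms), so a single
# call can serve many signal combinations at once (used by the stability-map
# module).  Returns the refined states plus a convergence flag per row.
newton_batch <- function(net, X, drive, tol = 1e-12, max_iter = 60L) {
  n <- n_nodes(net)
  m <- nrow(X)
  om <- net$omega
  sg <- net$sigma
  done <- rep(FALSE, m)
  for (iter in seq_len(max_iter)) {
    act <- which(!done)
    if (!length(act)) break
    Xa <- X[act, , drop = FALSE]
    U <- sweep(drive[act, , drop = FALSE] + Xa %*% om, 2L, sg, "*")
    Fv <- sigmoid(U)
    f <- Fv - Xa
    ok <- rowSums(abs(f) < tol) == n
    done[act[ok]] <- TRUE
    act2 <- act[!ok]
    if (!length(act2)) break
    Xa <- X[act2, , drop = FALSE]
    Fv <- Fv[!ok, , drop = FALSE]
    f <- f[!ok, , drop = FALSE]
    G <- sweep(Fv * (1 - Fv), 2L, sg, "*")   # sigma_i F'_i per row
    if (n == 1L) {
      a11 <- G[, 1] * om[1, 1] - 1
      X[act2, 1] <- Xa[, 1] - f[, 1] / a11
    } else if (n == 2L) {
      a11 <- G[, 1] * om[1, 1] - 1; a12 <- G[, 1] * om[2, 1]
      a21 <- G[, 2] * om[1, 2];     a22 <- G[, 2] * om[2, 2] - 1
      dt <- a11 * a22 - a12 * a21
      dx1 <- (f[, 1] * a22 - f[, 2] * a12) / dt
      dx2 <- (a11 * f[, 2] - a21 * f[, 1]) / dt
      X[act2, ] <- Xa - cbind(dx1, dx2)
    } else {
      for (r in seq_along(act2)) {
        A <- G[r, ] * t(om)
        diag(A) <- diag(A) - 1
        st <- tryCatch(Xa[r, ] - solve(A, f[r, ]), error = function(e) rep(NA_real_, n))
        X[act2[r], ] <- st
      }
    }
    bad <- rowSums(!is.finite(X[act2, , drop = FALSE])) > 0 |
      apply(abs(X[act2, , drop = FALSE]), 1L, max) > 10
    if (any(bad)) X[act2[bad], ] <- NA_real_
    done[act2[bad]] <- TRUE                  # diverged; flagged by NA
  }
  list(X = X, converged = done & stats::complete.cases(X))
}

# real parts of the eigenvalues of the scaled Jacobian at states (rows of X)
# for a single drive row; returns list(re = m x n matrix, im = m x n)
jac_eigen_batch <- function(net, X, drive) {
  n <- n_nodes(net)
  U <- sweep(drive + X %*% net$omega, 2L, net$sigma, "*")
  Fv <- sigmoid(U)
  G <- sweep(Fv * (1 - Fv), 2L, net$sigma * net$gamma, "*")
  if (n == 2L) {
    j11 <- G[, 1] * net$omega[1, 1] - net$gamma[1]
    j12 <- G[, 1] * net$omega[2, 1]
    j21 <- G[, 2] * net$omega[1, 2]
    j22 <- G[, 2] * net$omega[2, 2] - net$gamma[2]
    tr <- j11 + j22; dd <- j11 * j22 - j12 * j21
    disc <- tr^2 - 4 * dd
    sq <- sqrt(pmax(disc, 0))
    re1 <- ifelse(disc >= 0, (tr + sq) / 2, tr / 2)
    re2 <- ifelse(disc >= 0, (tr - sq) / 2, tr / 2)
    im1 <- ifelse(disc >= 0, 0, sqrt(-pmin(disc, 0)) / 2)
    list(re = cbind(re1, re2), im = cbind(im1, -im1))
  } else {
    re <- im <- matrix(NA_real_, nrow(X), n)
    for (r in seq_len(nrow(X))) {
      J <- G[r, ] * t(net$omega)
      diag(J) <- diag(J) - net$gamma
      ev <- eigen(J, only.values = TRUE)$values
      re[r, ] <- Re(ev); im[r, ] <- Im(ev)
    }
    list(re = re, im = im)
  }
}

classify_stability <- function(re, marginal_tol = 1e-9) {
  if (any(abs(re) < marginal_tol)) {
    warning("steady state with near-zero eigenvalue; labelled 'unstable'",
            call. = FALSE)
    return("unstable")
  }
  if (all(re < 0)) "stable" else if (all(re > 0)) "unstable" else "saddle"
}

#' Locate all steady states of a network
#'
#' Runs Newton's method from a regular grid of starting points covering the
#' unit box, deduplicates the converged fixed points, and classifies the
#' stability of each from the eigenvalues of the analytic Jacobian. The
#' returned list is ordered lexicographically by state vector so results are
#' reproducible run to run.
#'
#' @param net an \code{\link{influence_network}}.
#' @param signals named numeric vector of signal levels.
#' @param grid_n number of multistart grid points per state dimension.
#' @param dedupe_tol states closer than this (max-norm) are merged.
#' @param marginal_tol eigenvalues with |Re| below this are treated as
#'   marginal; the state is then labelled \code{"unstable"} with a warning.
#' @return A data frame of class \code{"steady_states"}: one column per
#'   node, plus \code{stability} (\code{"stable"}, \code{"saddle"} or
#'   \code{"unstable"}), \code{residual} (max |dX/dt|), and (for two-
#'   regulator networks) \code{phenotype}. Attribute \code{eigenvalues} is a
#'   list of Jacobian spectra; attribute \code{n_failed} counts Newton
#'   starts that did not converge.
#' @examples
#' net <- get_model("generic1")$network
#' find_steady_states(net, c(S1 = 1.5))
#' @export
find_steady_states <- function(net, signals = NULL, grid_n = 7L,
                               dedupe_tol = 1e-5, marginal_tol = 1e-9) {
  n <- n_nodes(net)
  s <- saturate_signals(net, full_signals(net, signals))
  base <- net$omega0
  if (length(s)) base <- base + as.vector(crossprod(net$signal_omega, s))
  starts <- as.matrix(expand.grid(rep(list(seq(0, 1, length.out = grid_n)), n)))
  colnames(starts) <- net$nodes
  drive <- matrix(base, nrow(starts), n, byrow = TRUE)
  res <- newton_batch(net, starts, drive)
  ok <- res$converged
  n_failed <- sum(!ok)
  X <- res$X[ok, , drop = FALSE]
  if (!nrow(X))
    stop("no steady state found from any start point", call. = FALSE)
  # deduplicate (max-norm) on the rounded grid
  keyX <- round(X / dedupe_tol)
  keep <- !duplicated(apply(keyX, 1L, paste, collapse = "|"))
  X <- X[keep, , drop = FALSE]
  # a second pass for states straddling a rounding boundary
  if (nrow(X) > 1L) {
    drop <- logical(nrow(X))
    for (i in seq_len(nrow(X) - 1L)) {
      if (drop[i]) next
      d <- apply(abs(sweep(X[(i + 1):nrow(X), , drop = FALSE], 2L, X[i, ])), 1L, max)
      drop[(i + 1):nrow(X)][d < dedupe_tol] <- TRUE
    }
    X <- X[!drop, , drop = FALSE]
  }
  ord <- do.call(order, as.data.frame(X))
  X <- X[ord, , drop = FALSE]
  drive1 <- matrix(base, nrow(X), n, byrow = TRUE)
  ev <- jac_eigen_batch(net, X, drive1)
  U <- sweep(drive1 + X %*% net$omega, 2L, net$sigma, "*")
  resid <- apply(abs(sweep(sigmoid(U) - X, 2L, net$gamma, "*")), 1L, max)
  stab <- vapply(seq_len(nrow(X)),
                 function(r) classify_stability(ev$re[r, ], marginal_tol),
                 character(1))
  out <- as.data.frame(X)
  names(out) <- net$nodes
  out$stability <- stab
  out$residual <- resid
  if (!is.null(net$regulators) && n >= 2L)
    out$phenotype <- as.character(classify_phenotype(X, net))
  structure(out, class = c("steady_states", "data.frame"),
            eigenvalues = lapply(seq_len(nrow(X)), function(r)
              complex(real = ev$re[r, ], imaginary = ev$im[r, ])),
            n_failed = n_failed, signals = s)
}

#' Phenotype of a state
#'
#' Calls the phenotype of a state (or of each row of a matrix of states)
#' from the activities of the two designated master regulators X and Y:
#' \code{naive} when neither exceeds the expression threshold, \code{XSP} /
#' \code{YSP} when exactly one does, and \code{DP} when both do. The
#' comparison is strict: a regulator exactly at the threshold is not
#' expressed.
#'
#' @param x state vector, or matrix with one state per row.
#' @param net an \code{\link{influence_network}} with two designated
#'   regulators.
#' @param threshold expression cutoff, in (0, 1); default 0.5 units.
#' @return factor with levels \code{naive}, \code{XSP}, \code{YSP},
#'   \code{DP}.
#' @export
classify_phenotype <- function(x, net, threshold = 0.5) {
  if (is.null(net$regulators) || length(net$regulators) != 2L)
    stop("phenotype calling needs a network with exactly two designated regulators",
         call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  if (!is.matrix(x)) x <- matrix(x, 1L, dimnames = list(NULL, net$nodes))
  ix <- match(net$regulators, net$nodes)
  ex <- x[, ix[1]] > threshold
  ey <- x[, ix[2]] > threshold
  lab <- ifelse(ex & ey, "DP", ifelse(ex, "XSP", ifelse(ey, "YSP", "naive")))
  factor(lab, levels = c("naive", "XSP", "YSP", "DP"))
}

#' @export
print.steady_states <- function(x, ...) {
  cat("<steady_states> ", nrow(x), " state(s); ",
      sum(x$stability == "stable"), " stable\n", sep = "")
  print(as.data.frame(x), digits = 6)
  invisible(x)
}
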