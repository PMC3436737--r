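# --- branch continuation and bifurcation detection -------------------------
#
# The fixed-point curves of the influence-network ODEs are traced with
# pseudo-arclength continuation: the augmented state z = (x, p) moves along
# the curve G(z) = rhs(x; p) = 0 with a tangent predictor and a Newton
# corrector orthogonal to the tangent.  Folds are flagged by a sign change
# of the tangent's parameter component (equivalently of det J) and refined
# on the augmented fold system [G = 0, det J = 0]; on symmetry-invariant
# branches of mirror-symmetric networks, pitchforks are flagged by a zero
# crossing of the swap-antisymmetric eigenvalue and refined on the
# symmetric-subspace system.

branch_G <- function(net, x, signals, param, p) {
  signals[param] <- p
  as.numeric(network_rhs(net, x, signals))
}

branch_J <- function(net, x, signals, param, p) {
  signals[param] <- p
  network_jacobian(net, x, signals)
}

branch_Gp <- function(net, x, signals, param, p) {
  signals[param] <- p
  as.numeric(rhs_dparam(net, x, signals, param))
}

# unit tangent of the fixed-point curve at z = (x, p)
branch_tangent <- function(net, x, signals, param, p, prev = NULL) {
  n <- length(x)
  M <- cbind(branch_J(net, x, signals, param, p),
             branch_Gp(net, x, signals, param, p))
  tt <- qr.Q(qr(t(M)), complete = TRUE)[, n + 1L]
  tt <- tt / sqrt(sum(tt^2))
  if (!is.null(prev) && sum(tt * prev) < 0) tt <- -tt
  tt
}

# Newton corrector for the pseudo-arclength system
branch_correct <- function(net, z, signals, param, tt, z_pred,
                           tol = 1e-11, max_iter = 12L) {
  n <- length(z) - 1L
  for (k in seq_len(max_iter)) {
    x <- z[1:n]; p <- z[n + 1L]
    G <- branch_G(net, x, signals, param, p)
    cons <- sum(tt * (z - z_pred))
    if (max(abs(G)) < tol && abs(cons) < tol)
      return(list(z = z, ok = TRUE, iters = k))
    A <- rbind(cbind(branch_J(net, x, signals, param, p),
                     branch_Gp(net, x, signals, param, p)),
               tt)
    dz <- tryCatch(solve(A, c(G, cons)), error = function(e) NULL)
    if (is.null(dz) || any(!is.finite(dz))) return(list(z = z, ok = FALSE))
    z <- z - dz
  }
  list(z = z, ok = FALSE)
}

# swap-antisymmetric eigenvalue of the Jacobian on a symmetric branch
antisym_eigenvalue <- function(net, x, signals, param, p) {
  J <- branch_J(net, x, signals, param, p)
  v <- numeric(length(x))
  i <- match(net$regulators, net$nodes)
  v[i] <- c(1, -1) / sqrt(2)
  sum(v * (J %*% v))
}

on_symmetric_branch <- function(net, x, tol = 1e-7) {
  !is.null(net$regulators) && max(abs(x - mirror_state(net, x))) < tol
}

# refine a pitchfork on the symmetric branch: solve the 2-unknown system
# (first-regulator residual, antisymmetric eigenvalue) = 0 in (s, p)
refine_pitchfork <- function(net, signals, param, s0, p0, tol = 1e-12) {
  i <- match(net$regulators, net$nodes)
  make_x <- function(s) { x <- rep(s, n_nodes(net)); x }
  fn <- function(v) {
    x <- make_x(v[1])
    c(branch_G(net, x, signals, param, v[2])[i[1]],
      antisym_eigenvalue(net, x, signals, param, v[2]))
  }
  v <- c(s0, p0)
  for (k in 1:40) {
    f0 <- fn(v)
    if (max(abs(f0)) < tol) break
    h <- 1e-7 * pmax(abs(v), 1)
    Jn <- matrix(0, 2, 2)
    for (j in 1:2) {
      vp <- v; vp[j] <- vp[j] + h[j]
      vm <- v; vm[j] <- vm[j] - h[j]
      Jn[, j] <- (fn(vp) - fn(vm)) / (2 * h[j])
    }
    dv <- tryCatch(solve(Jn, f0), error = function(e) NULL)
    if (is.null(dv)) return(NULL)
    v <- v - dv
    if (max(abs(dv)) < 1e-14) break
  }
  if (max(abs(fn(v))) > 1e-8) return(NULL)
  list(s = v[1], p = v[2], x = make_x(v[1]))
}

# refine a fold: Newton on the augmented system [G(x, p) = 0, det J(x, p) = 0]
refine_fold <- function(net, signals, param, x0, p0, tol = 1e-11) {
  n <- length(x0)
  fn <- function(z) {
    x <- z[1:n]; p <- z[n + 1L]
    c(branch_G(net, x, signals, param, p),
      det(branch_J(net, x, signals, param, p)))
  }
  z <- c(x0, p0)
  for (k in 1:40) {
    f0 <- fn(z)
    if (max(abs(f0)) < tol) break
    h <- 1e-6 * pmax(abs(z), 1)
    Jn <- matrix(0, n + 1L, n + 1L)
    for (j in seq_len(n + 1L)) {
      zp <- z; zp[j] <- zp[j] + h[j]
      zm <- z; zm[j] <- zm[j] - h[j]
      Jn[, j] <- (fn(zp) - fn(zm)) / (2 * h[j])
    }
    dz <- tryCatch(solve(Jn, f0), error = function(e) NULL)
    if (is.null(dz) || any(!is.finite(dz))) return(NULL)
    z <- z - dz
    if (max(abs(dz)) < 1e-14) break
  }
  if (max(abs(fn(z))) > 1e-7) return(NULL)
  list(x = z[1:n], p = z[n + 1L])
}

#' Trace a branch of steady states
#'
#' Pseudo-arclength continuation of a fixed-point branch as one signal level
#' varies over a range, with detection of special points: folds
#' (saddle-nodes) anywhere, and pitchforks on symmetry-invariant branches of
#' mirror-symmetric networks (detected through a zero crossing of the
#' swap-antisymmetric eigenvalue of the Jacobian). Detected special points
#' are refined by Newton iteration on their defining augmented systems, so
#' their parameter values are sharp to well below 1e-6.
#'
#' @param net an \code{\link{influence_network}}.
#' @param signals named numeric vector of signal levels held fixed.
#' @param param name of the signal used as the free parameter.
#' @param range numeric length-2 parameter range; tracing starts at
#'   \code{range[1]}.
#' @param start steady state at \code{range[1]} to continue from; when
#'   \code{NULL}, the lexicographically first stable steady state there is
#'   used.
#' @param ds0,ds_min,ds_max initial, minimum and maximum arclength step.
#' @param max_steps cap on continuation steps (truncates with a warning).
#' @return Object of class \code{"branch"}: list with \code{samples} (data
#'   frame: arclength, parameter, state columns, stability) and
#'   \code{special_points} (data frame: kind, parameter value, state
#'   columns, criticality — criticality is filled in by
#'   \code{\link{classify_pitchfork}}).
#' @examples
#' gm1 <- get_model("generic1")$network
#' br <- trace_branch(gm1, c(S2 = 0, S3 = 0), "S1", c(0, 3))
#' br$special_points
#' @export
trace_branch <- function(net, signals = NULL, param, range, start = NULL,
                         ds0 = 1e-2, ds_min = 1e-6, ds_max = NULL,
                         max_steps = 5000L) {
  s <- full_signals(net, signals)
  if (!param %in% net$signals)
    stop("`param` must name one of the network's signals", call. = FALSE)
  if (length(range) != 2L || range[2] <= range[1])
    stop("`range` must be increasing and of length 2", call. = FALSE)
  if (is.null(ds_max)) ds_max <- diff(range) / 25
  n <- n_nodes(net)

  if (is.null(start)) {
    ss <- find_steady_states(net, replace(s, param, range[1]))
    stbl <- ss[ss$stability == "stable", , drop = FALSE]
    if (!nrow(stbl))
      stop("no stable steady state at the start of the range; supply `start`",
           call. = FALSE)
    x <- as.numeric(stbl[1L, net$nodes])
  } else {
    x <- check_state(net, start)
    G0 <- branch_G(net, x, s, param, range[1])
    if (max(abs(G0)) > 1e-6)
      stop("`start` is not a steady state at range[1] (max |dX/dt| = ",
           format(max(abs(G0)), digits = 3), ")", call. = FALSE)
  }

  p <- range[1]
  tt <- branch_tangent(net, x, s, param, p)
  if (tt[n + 1L] < 0) tt <- -tt                 # march towards range[2]

  rec_state <- function(x, p, arc) {
    J <- branch_J(net, x, s, param, p)
    ev <- eigen(J, only.values = TRUE)$values
    symb <- on_symmetric_branch(net, x) && is_symmetric_network(net) &&
      (is.null(net$polarizing) ||
         abs(diff(unname(s[net$polarizing]))) < 1e-12)
    la <- if (symb) antisym_eigenvalue(net, x, s, param, p) else NA_real_
    list(arc = arc, p = p, x = x,
         stability = classify_stability(Re(ev)),
         detJ = det(J), la = la, tp = tt[n + 1L])
  }

  samples <- list(rec_state(x, p, 0))
  specials <- list()
  ds <- ds0
  arc <- 0
  z <- c(x, p)
  step <- 0L
  truncated <- FALSE

  while (step < max_steps) {
    step <- step + 1L
    z_pred <- z + ds * tt
    res <- branch_correct(net, z_pred, s, param, tt, z_pred)
    if (!res$ok) {
      ds <- ds / 2
      if (ds < ds_min) { truncated <- TRUE; break }
      next
    }
    z_new <- res$z
    x_new <- z_new[1:n]; p_new <- z_new[n + 1L]
    # reject steps where the corrector wandered far from the predictor
    # (symptom of jumping onto a coexisting branch near a fold)
    if (sqrt(sum((z_new - z_pred)^2)) > 2 * ds && ds > 2 * ds_min) {
      ds <- ds / 2
      next
    }
    tt_new <- branch_tangent(net, x_new, s, param, p_new, prev = tt)
    # reject steps that bend the tangent sharply
    if (sum(tt_new * tt) < 0.5 && ds > 2 * ds_min) {
      ds <- ds / 2
      next
    }
    arc_new <- arc + sqrt(sum((z_new - z)^2))

    prev <- samples[[length(samples)]]
    tt_save <- tt
    tt <- tt_new
    cur <- rec_state(x_new, p_new, arc_new)

    # --- special-point tests between prev and cur ---
    if (!is.na(prev$la) && !is.na(cur$la) && prev$la * cur$la < 0) {
      pf <- refine_pitchfork(net, s, param, (prev$x[1] + cur$x[1]) / 2,
                             (prev$p + cur$p) / 2)
      if (!is.null(pf) && pf$p >= range[1] - 1e-9 && pf$p <= range[2] + 1e-9)
        specials[[length(specials) + 1L]] <-
          list(kind = "pitchfork", p = pf$p, x = pf$x)
    } else if (prev$detJ * cur$detJ < 0 || tt_save[n + 1L] * tt_new[n + 1L] < 0) {
      fd <- refine_fold(net, s, param, (prev$x + cur$x) / 2, (prev$p + cur$p) / 2)
      if (!is.null(fd) && fd$p >= range[1] - 1e-9 && fd$p <= range[2] + 1e-9 &&
          abs(fd$p - (prev$p + cur$p) / 2) < 10 * abs(cur$p - prev$p) + 1e-3)
        specials[[length(specials) + 1L]] <-
          list(kind = "fold", p = fd$p, x = fd$x)
    }

    samples[[length(samples) + 1L]] <- cur
    z <- z_new; arc <- arc_new

    if (res$iters <= 3L) ds <- min(ds * 1.4, ds_max)

    if (p_new > range[2] + 1e-12 || p_new < range[1] - 1e-12) break
  }
  if (step >= max_steps || truncated)
    warning("continuation truncated (",
            if (truncated) "step-size underflow" else "max_steps reached", ")",
            call. = FALSE)

  sm <- data.frame(
    arclength = vapply(samples, `[[`, 0, "arc"),
    param = vapply(samples, `[[`, 0, "p"))
  X <- matrix(unlist(lapply(samples, `[[`, "x")), ncol = n, byrow = TRUE)
  colnames(X) <- net$nodes
  sm <- cbind(sm, X)
  sm$stability <- vapply(samples, `[[`, "", "stability")
  names(sm)[2] <- param

  if (length(specials)) {
    sp <- data.frame(kind = vapply(specials, `[[`, "", "kind"),
                     param = vapply(specials, `[[`, 0, "p"))
    SX <- matrix(unlist(lapply(specials, `[[`, "x")), ncol = n, byrow = TRUE)
    colnames(SX) <- net$nodes
    sp <- cbind(sp, SX)
    sp$criticality <- NA_character_
    names(sp)[2] <- param
    sp <- sp[order(sp[[2]]), , drop = FALSE]
    # collapse near-duplicate detections
    if (nrow(sp) > 1L) {
      d <- c(Inf, diff(sp[[2]]))
      sp <- sp[d > 1e-6 | c(FALSE, sp$kind[-nrow(sp)] != sp$kind[-1]), , drop = FALSE]
    }
    rownames(sp) <- NULL
  } else {
    sp <- data.frame(kind = character(), param = numeric(),
                     criticality = character())
  }

  structure(list(param = param, samples = sm, special_points = sp,
                 net = net, signals = s, range = range),
            class = "branch")
}

#' @export
print.branch <- function(x, ...) {
  cat("<branch> free parameter ", x$param, " in [",
      x$range[1], ", ", x$range[2], "], ",
      nrow(x$samples), " samples\n", sep = "")
  if (nrow(x$special_points)) {
    cat("special points:\n")
    print(x$special_points, digits = 6)
  } else cat("no special points detected\n")
  invisible(x)
}

# reduced antisymmetric residual r(d) at fixed parameter value: the
# symmetric mode s is slaved (solved from the mean equation), then
# r(d) = antisymmetric component of the fixed-point residual.  Its cubic
# coefficient at a pitchfork decides criticality.
reduced_residual <- function(net, signals, param, p, d, s_guess) {
  i <- match(net$regulators, net$nodes)
  sig <- replace(signals, param, p)
  s <- s_guess
  for (k in 1:60) {
    x <- numeric(n_nodes(net)); x[i] <- c(s + d, s - d)
    w <- effective_drive(net, x, sig)
    Fv <- sigmoid(net$sigma * w)
    m <- (Fv[i[1]] + Fv[i[2]]) / 2 - s
    if (abs(m) < 1e-14) break
    h <- 1e-7
    x2 <- x; x2[i] <- x2[i] + h
    Fv2 <- sigmoid(net$sigma * effective_drive(net, x2, sig))
    mp <- ((Fv2[i[1]] + Fv2[i[2]]) / 2 - (s + h) - m) / h
    s <- s - m / mp
  }
  x <- numeric(n_nodes(net)); x[i] <- c(s + d, s - d)
  Fv <- sigmoid(net$sigma * effective_drive(net, x, sig))
  list(r = (Fv[i[1]] - Fv[i[2]]) / 2 - d, s = s)
}

#' Classify a pitchfork as supercritical or subcritical
#'
#' Determines the criticality of a pitchfork detected by
#' \code{\link{trace_branch}} from the emergent asymmetric branches. The
#' symmetric mode is slaved to the antisymmetric amplitude \eqn{d}, giving a
#' reduced scalar residual \eqn{r(d) = \lambda d + C d^3 + O(d^5)} at the
#' bifurcation; the sign of the cubic coefficient \eqn{C} (estimated by
#' Richardson-extrapolated finite differences) decides the case:
#' \eqn{C < 0} means the bifurcating branches are stable and exist only on
#' the destabilised side (supercritical), \eqn{C > 0} means unstable
#' branches fold back, flanked by saddle-nodes (subcritical). A vanishing
#' cubic term yields \code{"indeterminate"}. With \code{method = "count"}
#' the classification instead counts fixed points on either side of the
#' bifurcation (5 fixed points on the doubly-stable side just outside the
#' pitchfork indicate folded-back subcritical branches); this slower route
#' is useful as a cross-check.
#'
#' @param branch a \code{"branch"} from \code{\link{trace_branch}} on a
#'   symmetric network.
#' @param point index into \code{branch$special_points} (must be a
#'   pitchfork).
#' @param method \code{"cubic"} (default) or \code{"count"}.
#' @param h base finite-difference amplitude for the cubic estimate.
#' @param delta parameter offset used by \code{method = "count"}.
#' @return \code{"supercritical"}, \code{"subcritical"} or
#'   \code{"indeterminate"}.
#' @export
classify_pitchfork <- function(branch, point = 1L, method = c("cubic", "count"),
                               h = 0.02, delta = 0.02) {
  method <- match.arg(method)
  sp <- branch$special_points
  if (point > nrow(sp) || sp$kind[point] != "pitchfork")
    stop("`point` must index a detected pitchfork", call. = FALSE)
  net <- branch$net
  p0 <- sp[[branch$param]][point]
  s0 <- as.numeric(sp[point, net$nodes[1]])
  if (method == "cubic") {
    rr <- function(d, hh) reduced_residual(net, branch$signals, branch$param,
                                           p0, d, s0)$r
    C_at <- function(hh) {
      r <- vapply(c(2, 1, -1, -2) * hh, rr, 0, hh = hh)
      (r[1] - 2 * r[2] + 2 * r[3] - r[4]) / (2 * hh^3) / 6
    }
    C1 <- C_at(h); C2 <- C_at(h / 2)
    C <- (4 * C2 - C1) / 3
    if (!is.finite(C) || abs(C) < 1e-5) return("indeterminate")
    if (C > 0) "subcritical" else "supercritical"
  } else {
    # which side of the pitchfork is symmetric-stable? look at the
    # antisymmetric eigenvalue slightly below/above
    la_at <- function(p) {
      rs <- reduced_residual(net, branch$signals, branch$param, p, 0, s0)
      x <- numeric(n_nodes(net))
      x[match(net$regulators, net$nodes)] <- rs$s
      antisym_eigenvalue(net, x, branch$signals, branch$param, p)
    }
    side <- if (la_at(p0 - delta) < 0) -1 else 1   # stable side
    nfix <- function(p) {
      ss <- find_steady_states(net, replace(branch$signals, branch$param, p),
                               grid_n = 15L)
      nrow(ss)
    }
    if (nfix(p0 + side * delta) >= 5L) "subcritical" else "supercritical"
  }
}

# --- two-parameter fold loci and cusp estimation ---------------------------

#' Continue a fold locus in a second parameter
#'
#' Natural-parameter continuation of a saddle-node (fold) point in the
#' \code{(par1, par2)} plane: at each value of \code{par2} the augmented
#' system (steady state + singular Jacobian) is re-solved by Newton
#' iteration in (state, \code{par1}), predictor-extrapolated from the
#' previous solutions, with adaptive step halving. Continuation stops at
#' the range boundary or when the defining singularity can no longer be
#' tracked (e.g. on approach to a cusp), reporting which.
#'
#' @param net an \code{\link{influence_network}}.
#' @param signals fixed signal levels.
#' @param par1 name of the signal in which the fold occurs.
#' @param par2 name of the continuation signal.
#' @param start list with elements \code{x} (state at the fold) and
#'   \code{p1} (the fold's \code{par1} value) at \code{par2 = p2_from}.
#' @param p2_from,p2_to continuation range for \code{par2}.
#' @param step0,min_step,max_step continuation step sizes for \code{par2}.
#' @return data frame of class \code{"fold_locus"} with columns \code{par2},
#'   \code{par1} and the state columns; attribute \code{terminal} is
#'   \code{"range_end"} or \code{"singularity_lost"}.
#' @export
continue_fold_locus <- function(net, signals = NULL, par1, par2, start,
                                p2_from = 0, p2_to = 1,
                                step0 = 0.02, min_step = 1e-6,
                                max_step = 0.05) {
  s <- full_signals(net, signals)
  n <- n_nodes(net)
  dir <- sign(p2_to - p2_from); if (dir == 0) stop("empty par2 range")
  p2 <- p2_from
  sol <- list(x = check_state(net, start$x), p1 = start$p1)
  rows <- list(c(p2, sol$p1, sol$x))
  prev2 <- NULL
  dp <- step0 * dir
  terminal <- "range_end"
  while ((p2 - p2_to) * dir < -1e-12) {
    p2_new <- if ((p2 + dp - p2_to) * dir > 0) p2_to else p2 + dp
    # secant predictor
    guess <- if (!is.null(prev2)) {
      w <- (p2_new - p2) / (p2 - prev2$p2)
      list(x = sol$x + w * (sol$x - prev2$x),
           p1 = sol$p1 + w * (sol$p1 - prev2$p1))
    } else sol
    s2 <- replace(s, par2, p2_new)
    fd <- refine_fold(net, s2, par1, guess$x, guess$p1)
    if (is.null(fd)) {
      dp <- dp / 2
      if (abs(dp) < min_step) { terminal <- "singularity_lost"; break }
      next
    }
    prev2 <- c(sol, list(p2 = p2))
    sol <- list(x = fd$x, p1 = fd$p)
    p2 <- p2_new
    rows[[length(rows) + 1L]] <- c(p2, sol$p1, sol$x)
    dp <- dir * min(abs(dp) * 1.4, max_step)
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c(par2, par1, net$nodes)
  structure(out, class = c("fold_locus", "data.frame"), terminal = terminal)
}

# locate the fold that a symmetric-branch pitchfork unfolds into when the
# symmetry-breaking signal par2 takes a small positive value
seed_fold_from_pitchfork <- function(net, signals, par1, par2, pf, p2_seed) {
  s2 <- replace(signals, par2, p2_seed)
  i <- match(net$regulators, net$nodes)
  for (amp in c(0.05, -0.05, 0.12, -0.12, 0.02, -0.02)) {
    x0 <- pf$x
    x0[i] <- x0[i] + c(amp, -amp)
    fd <- refine_fold(net, s2, par1, x0, pf$p)
    if (!is.null(fd) && abs(fd$p - pf$p) < 0.5) return(fd)
  }
  NULL
}

#' Continue a pitchfork pair to its coalescence (cusp)
#'
#' Starting from the two pitchfork points of a symmetric network's
#' symmetric branch, traces the pair of special-point loci in the
#' \code{(par1, par2)} plane. For \code{par2 > 0} the mirror symmetry is
#' broken and each pitchfork unfolds into a saddle-node; the two fold loci
#' are advanced in lockstep (same \code{par2} steps, adaptively halved as
#' the loci approach each other) until their \code{par1} separation falls
#' below \code{sep_tol} or the steps underflow. The coalescence ordinate is
#' then obtained by Richardson extrapolation of the separation, using the
#' two-thirds-power law of a cusp (separation ~ (p2c - p2)^(3/2)).
#'
#' @param net a mirror-symmetric \code{\link{influence_network}}.
#' @param signals fixed signal levels (the polarizing pair at 0).
#' @param par1 primary signal name (branch parameter).
#' @param par2 symmetry-breaking signal to continue in.
#' @param branch optional precomputed symmetric branch holding the two
#'   pitchforks; computed over \code{par1_range} when missing.
#' @param par1_range range used to find the pitchforks when \code{branch}
#'   is \code{NULL}.
#' @param p2_max upper bound for the continuation in \code{par2}.
#' @param p2_seed small positive \code{par2} used to unfold the pitchforks.
#' @param sep_tol loci separation below which coalescence is declared.
#' @return list with elements \code{loci} (two data frames: \code{par2},
#'   \code{par1}, states), \code{cusp} (list: \code{par2}, \code{par1}) and
#'   \code{terminal}.
#' @examples
#' \donttest{
#' gm1 <- get_model("generic1")$network
#' cc <- continue_pitchfork_pair(gm1, par1 = "S1", par2 = "S2")
#' cc$cusp$par2   # coalescence ordinate
#' }
#' @export
continue_pitchfork_pair <- function(net, signals = NULL, par1 = "S1",
                                    par2 = "S2", branch = NULL,
                                    par1_range = c(0, 3), p2_max = 1,
                                    p2_seed = 5e-3, sep_tol = 1e-4) {
  s <- full_signals(net, signals)
  if (is.null(branch))
    branch <- trace_branch(net, s, par1, par1_range)
  sp <- branch$special_points
  sp <- sp[sp$kind == "pitchfork", , drop = FALSE]
  if (nrow(sp) != 2L)
    stop("expected exactly two pitchforks on the symmetric branch; found ",
         nrow(sp), call. = FALSE)
  pfs <- lapply(1:2, function(k)
    list(p = sp[[par1]][k], x = as.numeric(sp[k, net$nodes])))
  folds <- lapply(pfs, function(pf)
    seed_fold_from_pitchfork(net, s, par1, par2, pf, p2_seed))
  if (any(vapply(folds, is.null, TRUE)))
    stop("could not seed the unfolded saddle-nodes at par2 = ", p2_seed,
         call. = FALSE)

  p2 <- p2_seed
  path <- list(c(p2, folds[[1]]$p, folds[[2]]$p))
  states <- list(folds)
  dp <- 0.02
  terminal <- "coalesced"
  while (p2 < p2_max - 1e-12) {
    p2_new <- min(p2 + dp, p2_max)
    s2 <- replace(s, par2, p2_new)
    f1 <- refine_fold(net, s2, par1, folds[[1]]$x, folds[[1]]$p)
    f2 <- refine_fold(net, s2, par1, folds[[2]]$x, folds[[2]]$p)
    ok <- !is.null(f1) && !is.null(f2) && f1$p < f2$p
    if (!ok) {
      dp <- dp / 2
      if (dp < 1e-7) { terminal <- "steps_underflowed"; break }
      next
    }
    folds <- list(f1, f2)
    p2 <- p2_new
    path[[length(path) + 1L]] <- c(p2, f1$p, f2$p)
    sep <- f2$p - f1$p
    if (sep < sep_tol) break
    # keep several points inside the final approach for the extrapolation
    dp <- min(dp * 1.3, 0.03, max(sep / 6, 1e-6))
    if (p2 >= p2_max - 1e-12) { terminal <- "range_end"; break }
  }
  P <- do.call(rbind, path)
  sep <- P[, 3] - P[, 2]
  cusp <- list(par2 = NA_real_, par1 = NA_real_)
  if (terminal %in% c("coalesced", "steps_underflowed") && nrow(P) >= 4) {
    # cusp law: sep ~ (p2c - p2)^{3/2}  =>  sep^{2/3} linear in p2
    k <- max(1L, nrow(P) - 5L):nrow(P)
    fit <- stats::lm.fit(cbind(1, P[k, 1]), sep[k]^(2 / 3))
    cusp$par2 <- -fit$coefficients[[1]] / fit$coefficients[[2]]
    cusp$par1 <- stats::approx(P[, 1], (P[, 2] + P[, 3]) / 2,
                               xout = min(cusp$par2, P[nrow(P), 1]),
                               rule = 2)$y
  }
  loci <- list(
    data.frame(p2 = P[, 1], p1 = P[, 2]),
    data.frame(p2 = P[, 1], p1 = P[, 3]))
  for (k in 1:2) names(loci[[k]]) <- c(par2, par1)
  list(loci = loci, cusp = cusp, terminal = terminal)
}
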