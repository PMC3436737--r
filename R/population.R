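# --- cell populations with parametric variability --------------------------

#' Configuration of a simulated cell population
#'
#' @param n_cells number of cells (default 200).
#' @param cv coefficient of variation of the parameter perturbations
#'   (default 0.05): each perturbed parameter of each cell is drawn from a
#'   normal distribution with the basal value as mean and sd = cv * |basal|.
#' @param seed RNG seed (integer).
#' @param perturb which parameter groups vary from cell to cell; by default
#'   all model parameters (interaction weights, basal weights, signal
#'   weights, steepness, relaxation rates).
#' @return list of class \code{"population_config"}.
#' @export
population_config <- function(n_cells = 200L, cv = 0.05, seed = 1L,
                              perturb = c("omega", "omega0", "signal_omega",
                                          "sigma", "gamma")) {
  if (n_cells < 1L) stop("`n_cells` must be >= 1", call. = FALSE)
  if (cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  perturb <- match.arg(perturb, several.ok = TRUE)
  structure(list(n_cells = as.integer(n_cells), cv = cv,
                 seed = as.integer(seed), perturb = perturb),
            class = "population_config")
}

# draw n values around each element of `basal` (any numeric array):
# zero entries encode absent influences and are never perturbed;
# sign-constrained entries (positive = TRUE) are redrawn while nonpositive
draw_params <- function(basal, n, cv, positive = FALSE) {
  dims <- c(n, dim(basal) %||% length(basal))
  out <- array(rep(as.numeric(basal), each = n), dims)
  if (cv == 0) return(out)
  nz <- which(basal != 0)
  for (k in nz) {
    v <- stats::rnorm(n, mean = basal[k], sd = cv * abs(basal[k]))
    if (positive) {
      bad <- which(v <= 0)
      tries <- 0L
      while (length(bad)) {
        tries <- tries + 1L
        if (tries > 100L)
          stop("could not draw a positive parameter after 100 redraws",
               call. = FALSE)
        v[bad] <- stats::rnorm(length(bad), mean = basal[k],
                               sd = cv * abs(basal[k]))
        bad <- bad[v[bad] <= 0]
      }
    }
    # column-major: cells vary fastest, so element k of `basal` occupies
    # the flat slots (k-1)*n + 1 ... k*n
    out[(k - 1L) * n + seq_len(n)] <- v
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample a cell population around a basal network
#'
#' Each cell receives its own copy of the network's parameters, every
#' perturbed parameter drawn independently from Normal(basal, cv * |basal|).
#' Parameters whose basal value is 0 encode absent influences and stay 0;
#' steepness and relaxation rates are redrawn while nonpositive. The
#' imaginary cell carrying exactly the basal values is the "average" cell;
#' with \code{cv = 0} every sampled cell equals it.
#'
#' @param net the basal \code{\link{influence_network}}.
#' @param config a \code{\link{population_config}}.
#' @return Object of class \code{"cell_population"}: per-cell parameter
#'   arrays, current state matrix (\code{NA} until equilibrated), the basal
#'   network and the seed used.
#' @export
sample_population <- function(net, config = population_config()) {
  n <- config$n_cells
  N <- n_nodes(net)
  S <- length(net$signals)
  set.seed(config$seed)
  cv <- function(group) if (group %in% config$perturb) config$cv else 0
  params <- list(
    omega = draw_params(net$omega, n, cv("omega")),
    omega0 = draw_params(as.numeric(net$omega0), n, cv("omega0")),
    signal_omega = draw_params(net$signal_omega, n, cv("signal_omega")),
    sigma = draw_params(as.numeric(net$sigma), n, cv("sigma"), positive = TRUE),
    gamma = draw_params(as.numeric(net$gamma), n, cv("gamma"), positive = TRUE))
  structure(list(basal = net, n_cells = n, cv = config$cv,
                 seed = config$seed, config = config, params = params,
                 states = matrix(NA_real_, n, N,
                                 dimnames = list(NULL, net$nodes)),
                 equilibrated = FALSE),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat("<cell_population> ", x$n_cells, " cells, cv = ", x$cv,
      ", seed = ", x$seed,
      if (x$equilibrated) ", equilibrated" else "", "\n", sep = "")
  if (!anyNA(x$states)) {
    cat("current composition:\n")
    print(composition(x))
  }
  invisible(x)
}

# batch right-hand side over all cells: X is n_cells x N, D the
# state-independent drive (n_cells x N); returns rates (n_cells x N)
pop_rhs <- function(params, X, D) {
  N <- ncol(X)
  W <- D
  for (j in seq_len(N)) W <- W + params$omega[, j, ] * X[, j]
  params$gamma * (sigmoid(params$sigma * W) - X)
}

pop_drive <- function(pop, signals) {
  s <- saturate_signals(pop$basal, full_signals(pop$basal, signals))
  D <- pop$params$omega0
  for (k in seq_along(s))
    if (s[k] != 0) D <- D + pop$params$signal_omega[, k, ] * s[k]
  D
}

# fixed-step RK4 relaxation of the whole population towards rest.
# Small steps keep the scheme well inside its stability region for the
# shipped models; convergence is checked in blocks of `check_every` time
# units on max |dX/dt| per cell.
pop_relax <- function(pop, signals = NULL, dt = 0.02, rate_tol = 1e-9,
                      max_time = 1000) {
  D <- pop_drive(pop, signals)
  X <- pop$states
  params <- pop$params
  check_every <- 0.5
  nblock <- max(1L, round(check_every / dt))
  t <- 0
  repeat {
    for (k in seq_len(nblock)) {
      k1 <- pop_rhs(params, X, D)
      k2 <- pop_rhs(params, X + dt / 2 * k1, D)
      k3 <- pop_rhs(params, X + dt / 2 * k2, D)
      k4 <- pop_rhs(params, X + dt * k3, D)
      X <- X + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    t <- t + nblock * dt
    resid <- apply(abs(pop_rhs(params, X, D)), 1L, max)
    if (all(resid < rate_tol) || t >= max_time) break
  }
  pop$states <- X
  attr(pop$states, "residual") <- resid
  attr(pop$states, "converged") <- resid < rate_tol
  attr(pop$states, "time") <- t
  pop
}

#' Equilibrate a population to its naive states
#'
#' Integrates every cell from small initial activities (default 0.01 for
#' every node) to rest in the absence of exogenous signals. Every cell of a
#' well-formed model ends in its own stable double-negative (naive) steady
#' state; a cell that does not is reported as a model error together with
#' its index.
#'
#' @param pop a \code{\link{cell_population}}.
#' @param x0 small initial activity given to every node.
#' @param dt integration step; \code{rate_tol}, \code{max_time} as in
#'   \code{\link{integrate_network}}.
#' @param rate_tol rest criterion on max |dX/dt| per cell.
#' @param max_time cap on the equilibration time.
#' @return the population with its states at the naive steady states.
#' @export
equilibrate_naive <- function(pop, x0 = 0.01, dt = 0.02, rate_tol = 1e-9,
                              max_time = 1000) {
  pop$states[] <- x0
  pop <- pop_relax(pop, NULL, dt = dt, rate_tol = rate_tol,
                   max_time = max_time)
  ph <- classify_phenotype(pop$states, pop$basal)
  if (any(ph != "naive")) {
    bad <- which(ph != "naive")[1]
    stop("no naive state: cell ", bad, " equilibrated to phenotype '",
         ph[bad], "' (state ",
         paste(format(pop$states[bad, ], digits = 4), collapse = ", "),
         ") in the absence of signals", call. = FALSE)
  }
  pop$equilibrated <- TRUE
  pop
}

#' Staged stimulus protocol
#'
#' A protocol is an ordered list of stages; each stage holds the full set
#' of exogenous signal levels applied during that stage (signals not named
#' are 0) and runs until the population is at rest (or \code{max_time}).
#' States carry over from stage to stage, which is what produces hysteresis
#' under sequential stimulation.
#'
#' @param ... one named numeric vector of signal levels per stage.
#' @param max_time,rate_tol stage stopping rule (applied to every stage).
#' @return object of class \code{"signal_protocol"}.
#' @examples
#' signal_protocol(c(S1 = 1.5), c(S1 = 1.5, S2 = 0.2))
#' @export
signal_protocol <- function(..., max_time = 1000, rate_tol = 1e-9) {
  stages <- list(...)
  if (!length(stages)) stop("a protocol needs at least one stage", call. = FALSE)
  structure(list(stages = stages, max_time = max_time, rate_tol = rate_tol),
            class = "signal_protocol")
}

#' Run a stimulus protocol on a population
#'
#' Applies the protocol's stages in order, integrating every cell to rest
#' at each stage with states carried over; by the end each cell sits at its
#' induced phenotype.
#'
#' @param pop an equilibrated \code{\link{cell_population}} (supply
#'   \code{waive_equilibration = TRUE} to run from the current states).
#' @param protocol a \code{\link{signal_protocol}}.
#' @param dt integration step.
#' @param waive_equilibration skip the equilibration check.
#' @return the population with final states; attribute \code{stage_log}
#'   records per-stage convergence.
#' @export
run_protocol <- function(pop, protocol, dt = 0.02,
                         waive_equilibration = FALSE) {
  if (!pop$equilibrated && !waive_equilibration)
    stop("population not equilibrated; call equilibrate_naive() first ",
         "or set waive_equilibration = TRUE", call. = FALSE)
  if (!inherits(protocol, "signal_protocol"))
    stop("`protocol` must be a signal_protocol", call. = FALSE)
  log <- vector("list", length(protocol$stages))
  for (k in seq_along(protocol$stages)) {
    pop <- pop_relax(pop, protocol$stages[[k]], dt = dt,
                     rate_tol = protocol$rate_tol,
                     max_time = protocol$max_time)
    log[[k]] <- list(signals = full_signals(pop$basal, protocol$stages[[k]]),
                     converged = all(attr(pop$states, "converged")),
                     time = attr(pop$states, "time"))
    if (!log[[k]]$converged)
      warning(sum(!attr(pop$states, "converged")),
              " cell(s) not at rest after stage ", k, call. = FALSE)
  }
  attr(pop, "stage_log") <- log
  pop
}

#' Phenotype compositions over a signal grid
#'
#' Repeats the full induced-differentiation simulation (sample a population,
#' equilibrate it to naive states, apply the stimulus protocol) at every
#' point of a two-signal grid and records the phenotype composition. By
#' default a fresh population is drawn at each grid point from seeds
#' spawned deterministically from the master seed; set
#' \code{resample = FALSE} to reuse one population (it is equilibrated
#' once and restarted from its naive states at each point).
#'
#' @param net basal \code{\link{influence_network}}.
#' @param axis1,axis2 one-element named lists: signal name -> grid values.
#' @param config a \code{\link{population_config}} (its seed is the master
#'   seed).
#' @param protocol function \code{(v1, v2)} returning the
#'   \code{\link{signal_protocol}} for a grid point; the default applies
#'   both signals simultaneously in a single stage.
#' @param fixed named levels of the remaining signals, applied in every
#'   stage of the default protocol.
#' @param threshold expression threshold for phenotype calling.
#' @param resample draw a fresh population per grid point (default) or
#'   reuse one.
#' @param dt integration step.
#' @return Object of class \code{"composition_grid"}: axes, a
#'   \code{counts} array (axis1 x axis2 x phenotype) and metadata.
#' @export
composition_grid <- function(net, axis1, axis2,
                             config = population_config(),
                             protocol = NULL, fixed = NULL,
                             threshold = 0.5, resample = TRUE, dt = 0.02) {
  nm1 <- names(axis1); v1 <- as.numeric(axis1[[1]])
  nm2 <- names(axis2); v2 <- as.numeric(axis2[[1]])
  if (is.null(protocol))
    protocol <- function(a, b) {
      sig <- c(stats::setNames(c(a, b), c(nm1, nm2)), fixed)
      do.call(signal_protocol, list(sig))
    }
  npts <- length(v1) * length(v2)
  set.seed(config$seed)
  point_seeds <- sample.int(.Machine$integer.max - 1L, npts)
  counts <- array(0L, c(length(v1), length(v2), 4L),
                  dimnames = list(NULL, NULL, c("naive", "XSP", "YSP", "DP")))
  base_pop <- NULL
  if (!resample) {
    base_pop <- sample_population(net, config)
    base_pop <- equilibrate_naive(base_pop, dt = dt)
  }
  failed <- matrix(FALSE, length(v1), length(v2))
  k <- 0L
  for (j in seq_along(v2)) for (i in seq_along(v1)) {
    k <- k + 1L
    pop <- if (resample) {
      cfg <- config; cfg$seed <- point_seeds[k]
      p <- sample_population(net, cfg)
      equilibrate_naive(p, dt = dt)
    } else base_pop
    res <- tryCatch(run_protocol(pop, protocol(v1[i], v2[j]), dt = dt),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed[i, j] <- TRUE
      next
    }
    cmp <- composition(res$states, net, threshold)
    counts[i, j, ] <- as.integer(cmp)
  }
  if (any(failed))
    warning(sum(failed), " grid point(s) failed and were marked missing",
            call. = FALSE)
  structure(list(axis1 = list(name = nm1, values = v1),
                 axis2 = list(name = nm2, values = v2),
                 counts = counts, n_cells = config$n_cells,
                 cv = config$cv, seed = config$seed,
                 resample = resample, failed = failed,
                 threshold = threshold),
            class = "composition_grid")
}

#' @export
print.composition_grid <- function(x, ...) {
  cat("<composition_grid> ", x$axis1$name, " x ", x$axis2$name, ": ",
      length(x$axis1$values), " x ", length(x$axis2$values),
      " points, ", x$n_cells, " cells each (cv = ", x$cv, ")\n", sep = "")
  tot <- apply(x$counts, 3L, sum)
  print(round(tot / sum(tot), 3))
  invisible(x)
}

#' Heterogeneity scores over a composition grid
#'
#' @param grid a \code{\link{composition_grid}}.
#' @param phenotypes phenotypes of interest (see
#'   \code{\link{phenotype_presets}}).
#' @return matrix of scores (axis1 indexing rows).
#' @export
score_grid <- function(grid, phenotypes = c("XSP", "YSP")) {
  d <- dim(grid$counts)
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (grid$failed[i, j]) next
    cmp <- composition(stats::setNames(grid$counts[i, j, ],
                                       dimnames(grid$counts)[[3]]))
    out[i, j] <- heterogeneity_score(cmp, phenotypes)$score
  }
  out
}
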