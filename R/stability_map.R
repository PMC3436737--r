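# --- two-parameter stability maps and bidirectional diagrams ---------------

#' Map stable-state counts and types over a signal plane
#'
#' At every point of a two-signal grid, all steady states are located (by
#' the same multistart Newton solver as \code{\link{find_steady_states}},
#' batched across the whole grid) and the stable ones are phenotype-
#' labelled. The map is continuation-free, so it can serve as an
#' independent cross-check of bifurcation loci found by continuation.
#'
#' @param net an \code{\link{influence_network}}.
#' @param axis1,axis2 one-element named lists giving the signal name and its
#'   grid, e.g. \code{list(S1 = seq(0, 3, length.out = 101))}.
#' @param fixed named numeric vector of the remaining signal levels.
#' @param grid_n multistart grid points per state dimension at each map
#'   point.
#' @param threshold expression threshold for phenotype labelling.
#' @return Object of class \code{"stability_map"}: list with the axes,
#'   \code{n_stable} (matrix, axis1 indexing rows) and \code{signature}
#'   (matrix of sorted stable-phenotype labels joined by \code{"+"}).
#' @export
count_attractors_map <- function(net, axis1, axis2, fixed = NULL,
                                 grid_n = 7L, threshold = 0.5) {
  stopifnot(is.list(axis1), length(axis1) == 1L, !is.null(names(axis1)),
            is.list(axis2), length(axis2) == 1L, !is.null(names(axis2)))
  nm1 <- names(axis1); v1 <- as.numeric(axis1[[1]])
  nm2 <- names(axis2); v2 <- as.numeric(axis2[[1]])
  if (!all(c(nm1, nm2) %in% net$signals))
    stop("axis names must be signals of the network", call. = FALSE)
  n <- n_nodes(net)
  fx <- full_signals(net, fixed)
  fx[c(nm1, nm2)] <- 0
  fxs <- saturate_signals(net, fx)
  base <- net$omega0 + as.vector(crossprod(net$signal_omega, fxs))

  # per-signal saturation of the axis values
  sat <- function(nm, v) {
    if (!is.null(net$saturation) && nm %in% names(net$saturation)) {
      el <- net$saturation[[nm]]
      el$smax * v / (el$K + v)
    } else v
  }
  e1 <- sat(nm1, v1); e2 <- sat(nm2, v2)

  pts <- expand.grid(i = seq_along(v1), j = seq_along(v2))
  npts <- nrow(pts)
  drive_pts <- matrix(base, npts, n, byrow = TRUE) +
    outer(e1[pts$i], net$signal_omega[nm1, ]) +
    outer(e2[pts$j], net$signal_omega[nm2, ])

  starts <- as.matrix(expand.grid(rep(list(seq(0, 1, length.out = grid_n)), n)))
  ns <- nrow(starts)
  X0 <- starts[rep(seq_len(ns), npts), , drop = FALSE]
  pid <- rep(seq_len(npts), each = ns)
  D <- drive_pts[pid, , drop = FALSE]
  res <- newton_batch(net, X0, D)
  ok <- res$converged
  X <- res$X[ok, , drop = FALSE]
  pid <- pid[ok]
  D <- D[ok, , drop = FALSE]
  # deduplicate within each map point
  key <- paste(pid, apply(round(X * 1e5), 1L, paste, collapse = "|"))
  keep <- !duplicated(key)
  X <- X[keep, , drop = FALSE]; pid <- pid[keep]; D <- D[keep, , drop = FALSE]
  ev <- jac_eigen_batch(net, X, D)
  stable <- rowSums(ev$re < 0) == n & rowSums(abs(ev$re) < 1e-9) == 0
  ph <- as.character(classify_phenotype(X, net, threshold))

  n_stable <- matrix(0L, length(v1), length(v2))
  signature <- matrix(NA_character_, length(v1), length(v2))
  sp <- split(ph[stable], pid[stable])
  cnt <- vapply(sp, length, 0L)
  lev <- c("naive", "XSP", "YSP", "DP")   # canonical, locale-independent
  sig <- vapply(sp, function(z) paste(lev[lev %in% z], collapse = "+"), "")
  idx <- as.integer(names(sp))
  n_stable[cbind(pts$i[idx], pts$j[idx])] <- cnt
  signature[cbind(pts$i[idx], pts$j[idx])] <- sig
  if (any(n_stable == 0L))
    warning(sum(n_stable == 0L),
            " map point(s) with no stable state found", call. = FALSE)

  structure(list(axis1 = list(name = nm1, values = v1),
                 axis2 = list(name = nm2, values = v2),
                 fixed = fx[setdiff(net$signals, c(nm1, nm2))],
                 n_stable = n_stable, signature = signature,
                 threshold = threshold),
            class = "stability_map")
}

#' @export
print.stability_map <- function(x, ...) {
  cat("<stability_map> ", x$axis1$name, " x ", x$axis2$name, ": ",
      length(x$axis1$values), " x ", length(x$axis2$values), " grid\n", sep = "")
  cat("stable-state counts:\n")
  print(table(x$n_stable))
  cat("signatures:\n")
  print(sort(table(x$signature), decreasing = TRUE))
  invisible(x)
}

#' Assemble a bidirectional two-parameter diagram
#'
#' Stacks two stability maps that share their primary-signal axis into the
#' bidirectional representation: the first polarizing signal increases
#' upward, the second downward from the shared horizontal axis. For a
#' mirror-symmetric network the lower half is the mirror image of the upper
#' half with the XSP and YSP labels exchanged.
#'
#' @param upper \code{\link{count_attractors_map}} over (primary, polarizing
#'   1).
#' @param lower \code{\link{count_attractors_map}} over (primary, polarizing
#'   2).
#' @param loci optional list of special-point loci to carry along.
#' @return Object of class \code{"bidirectional_diagram"}.
#' @export
assemble_bidirectional <- function(upper, lower, loci = NULL) {
  if (upper$axis1$name != lower$axis1$name ||
      length(upper$axis1$values) != length(lower$axis1$values) ||
      max(abs(upper$axis1$values - lower$axis1$values)) > 1e-12)
    stop("the two maps must share an identical primary-signal axis",
         call. = FALSE)
  share0 <- upper$axis2$values[1] == 0 && lower$axis2$values[1] == 0
  if (share0 && any(upper$signature[, 1] != lower$signature[, 1],
                    na.rm = TRUE))
    warning("upper and lower maps disagree on the shared axis row",
            call. = FALSE)
  structure(list(upper = upper, lower = lower, loci = loci,
                 shared_axis = share0),
            class = "bidirectional_diagram")
}

# combined signature matrix: rows = vertical coordinate from +max(axis2 of
# upper) down to -max(axis2 of lower); columns = shared primary axis
combined_signatures <- function(diag) {
  up <- t(diag$upper$signature)     # rows now axis2
  lo <- t(diag$lower$signature)
  up <- up[rev(seq_len(nrow(up))), , drop = FALSE]
  if (diag$shared_axis) lo <- lo[-1L, , drop = FALSE]
  rbind(up, lo)
}

#' Contiguous stability regions of a bidirectional diagram
#'
#' Partitions the diagram's plane into maximal 4-connected regions of
#' constant stable-phenotype signature, reproducing the annotated regions
#' of a two-parameter bifurcation diagram as data.
#'
#' @param diag a \code{\link{assemble_bidirectional}} diagram.
#' @return data frame with one row per region: \code{region}, \code{signature},
#'   \code{n_cells}.
#' @export
region_table <- function(diag) {
  M <- combined_signatures(diag)
  nr <- nrow(M); nc <- ncol(M)
  comp <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(comp == 0L & !is.na(M))) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      r <- (cell - 1L) %% nr + 1L
      cl <- (cell - 1L) %/% nr + 1L
      for (nb in list(c(r - 1L, cl), c(r + 1L, cl), c(r, cl - 1L), c(r, cl + 1L))) {
        if (nb[1] < 1L || nb[1] > nr || nb[2] < 1L || nb[2] > nc) next
        id <- (nb[2] - 1L) * nr + nb[1]
        if (comp[id] == 0L && !is.na(M[id]) && M[id] == M[cell]) {
          comp[id] <- cur
          queue[[length(queue) + 1L]] <- id
        }
      }
    }
  }
  sig <- vapply(seq_len(cur), function(k) M[match(k, comp)], "")
  data.frame(region = seq_len(cur), signature = sig,
             n_cells = as.integer(table(factor(comp[comp > 0], seq_len(cur)))))
}

#' Number of distinct stability regions
#' @param diag a \code{\link{assemble_bidirectional}} diagram.
#' @return integer count of 4-connected constant-signature regions.
#' @export
n_regions <- function(diag) nrow(region_table(diag))
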