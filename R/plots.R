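# --- minimal base-graphics views ------------------------------------------

#' @export
plot.branch <- function(x, node = NULL, ...) {
  if (is.null(node)) node <- x$net$regulators[1] %||% x$net$nodes[1]
  sm <- x$samples
  stable <- sm$stability == "stable"
  plot(sm[[2]], sm[[node]], type = "n",
       xlab = x$param, ylab = paste0(node, "*"), ...)
  # draw stable and unstable segments separately (solid vs dashed)
  runs <- rle(stable)
  idx <- cumsum(c(0, runs$lengths))
  for (k in seq_along(runs$values)) {
    seg <- seq(max(idx[k], 1L), idx[k + 1])
    graphics::lines(sm[[2]][seg], sm[[node]][seg],
                    lty = if (runs$values[k]) 1 else 2)
  }
  sp <- x$special_points
  if (nrow(sp))
    graphics::points(sp[[2]], sp[[node]], pch = 19, col = 2)
  invisible(x)
}

#' @export
plot.stability_map <- function(x, what = c("n_stable", "signature"), ...) {
  what <- match.arg(what)
  z <- if (what == "n_stable") x$n_stable
  else matrix(as.integer(factor(x$signature)), nrow(x$signature))
  graphics::image(x$axis1$values, x$axis2$values, z,
                  xlab = x$axis1$name, ylab = x$axis2$name,
                  main = what, ...)
  invisible(x)
}

#' Phase-plane portrait with nullclines
#'
#' Draws the two regulators' nullclines (solved pointwise) and the steady
#' states for a two-node network at the given signal levels.
#'
#' @param net a two-node \code{\link{influence_network}}.
#' @param signals named signal levels.
#' @param n grid resolution for the nullclines.
#' @param ... passed to \code{plot}.
#' @export
plot_phase_plane <- function(net, signals = NULL, n = 201L, ...) {
  if (n_nodes(net) != 2L) stop("phase plane needs a two-node network")
  s <- full_signals(net, signals)
  g <- seq(0, 1, length.out = n)
  # X-nullcline: for each y solve F(sigma_1 W_1(x, y)) = x in x (monotone
  # contraction unless auto-activation is strong; bisection on the residual)
  null_of <- function(i) {
    j <- 3L - i
    sapply(g, function(v) {
      f <- function(u) {
        x <- numeric(2); x[i] <- u; x[j] <- v
        sigmoid(net$sigma[i] * effective_drive(net, x, s)[i]) - u
      }
      r <- try(stats::uniroot(f, c(1e-12, 1 - 1e-12))$root, silent = TRUE)
      if (inherits(r, "try-error")) NA_real_ else r
    })
  }
  nx <- null_of(1L); ny <- null_of(2L)
  plot(NA, xlim = c(0, 1), ylim = c(0, 1),
       xlab = net$nodes[1], ylab = net$nodes[2], ...)
  graphics::lines(nx, g, col = "darkgreen")
  graphics::lines(g, ny, col = "red")
  ss <- find_steady_states(net, s)
  graphics::points(ss[[1]], ss[[2]],
                   pch = ifelse(ss$stability == "stable", 19, 21), cex = 1.3)
  invisible(ss)
}
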