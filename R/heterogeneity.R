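#' Phenotype composition of a set of states
#'
#' Counts the cells of each phenotype (naive, XSP, YSP, DP) in a matrix of
#' final states, or wraps an explicit vector of counts.
#'
#' @param x matrix of states (one cell per row), a
#'   \code{\link{cell_population}}, or a named numeric vector of counts over
#'   the four phenotype labels.
#' @param net the \code{\link{influence_network}} used for phenotype calling
#'   (ignored when \code{x} is already a vector of counts).
#' @param threshold expression threshold passed to
#'   \code{\link{classify_phenotype}}.
#' @return Object of class \code{"phenotype_composition"}: a named integer
#'   vector of counts over \code{naive}, \code{XSP}, \code{YSP}, \code{DP}
#'   with attribute \code{total}.
#' @export
composition <- function(x, net = NULL, threshold = 0.5) {
  labels <- c("naive", "XSP", "YSP", "DP")
  if (inherits(x, "cell_population")) {
    net <- x$basal
    x <- x$states
  }
  if (is.numeric(x) && !is.matrix(x) && !is.null(names(x))) {
    if (!all(names(x) %in% labels))
      stop("count names must be among: ", paste(labels, collapse = ", "), call. = FALSE)
    if (any(x < 0) || any(x != round(x)))
      stop("counts must be nonnegative integers", call. = FALSE)
    counts <- stats::setNames(integer(4), labels)
    counts[names(x)] <- as.integer(x)
  } else {
    ph <- classify_phenotype(x, net, threshold)
    counts <- stats::setNames(as.integer(table(ph)), labels)
  }
  structure(counts, total = sum(counts), class = "phenotype_composition")
}

#' @export
print.phenotype_composition <- function(x, ...) {
  cat("<phenotype_composition> N =", attr(x, "total"), "\n")
  print(stats::setNames(as.integer(x), names(unclass(x))))
  invisible(x)
}

#' Named phenotype subsets matching the usual score panels
#'
#' Presets for the phenotype subsets the heterogeneity score is most often
#' evaluated over: the two single-positive phenotypes, each single-positive
#' with the double-positive, and all three functional phenotypes.
#' @export
phenotype_presets <- list(
  XSP_YSP     = c("XSP", "YSP"),
  XSP_DP      = c("XSP", "DP"),
  YSP_DP      = c("YSP", "DP"),
  XSP_YSP_DP  = c("XSP", "YSP", "DP")
)

#' Heterogeneity score of a phenotype composition
#'
#' For phenotypes of interest \eqn{P_1, \ldots, P_n} with cell counts
#' \eqn{C_{P_i}} in a population of \eqn{N} cells, the score is the
#' normalised sum of pairwise balance terms
#' \deqn{S_H = \sum_{i<j} \frac{C_{P_i} + C_{P_j} - 2\,|C_{P_i} - C_{P_j}|}{(n-1)\,N}.}
#' \eqn{S_H \approx 1} when the phenotypes of interest are present in
#' comparable numbers, \eqn{S_H \approx -1} when one of them dominates the
#' population, and \eqn{S_H \approx 0} when few cells carry any phenotype of
#' interest. The score always lies in \eqn{[-1, 1]}.
#'
#' @param comp a \code{\link{composition}} (or named counts coercible to
#'   one).
#' @param phenotypes character vector of 2 to 4 distinct phenotype labels.
#' @return Object of class \code{"heterogeneity_result"} with elements
#'   \code{score}, \code{phenotypes} and \code{composition}.
#' @examples
#' heterogeneity_score(composition(c(XSP = 100, YSP = 100)), c("XSP", "YSP"))
#' @export
heterogeneity_score <- function(comp, phenotypes = c("XSP", "YSP")) {
  if (!inherits(comp, "phenotype_composition")) comp <- composition(comp)
  labels <- names(unclass(comp))
  if (anyDuplicated(phenotypes))
    stop("`phenotypes` must be distinct", call. = FALSE)
  if (!all(phenotypes %in% labels))
    stop("unknown phenotype label(s): ",
         paste(setdiff(phenotypes, labels), collapse = ", "), call. = FALSE)
  n <- length(phenotypes)
  if (n < 2L || n > 4L)
    stop("between 2 and 4 phenotypes of interest are required", call. = FALSE)
  N <- attr(comp, "total")
  if (!isTRUE(N > 0)) stop("composition has no cells (N = 0)", call. = FALSE)
  cc <- as.numeric(unclass(comp)[phenotypes])
  s <- 0
  for (i in seq_len(n - 1L))
    for (j in seq(i + 1L, n))
      s <- s + (cc[i] + cc[j] - 2 * abs(cc[i] - cc[j]))
  structure(list(score = s / ((n - 1) * N),
                 phenotypes = phenotypes, composition = comp),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat("S_H(", paste(x$phenotypes, collapse = ", "), ") = ",
      format(x$score, digits = 6), "  [N = ",
      attr(x$composition, "total"), "]\n", sep = "")
  invisible(x)
}
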