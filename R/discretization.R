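#' Discretization: the ordinal side of every computation
#'
#' A k-point discrete law: strictly increasing support values with
#' probabilities. With \code{values = 1:k} this is the consecutive-integer
#' scoring (CIS) of an ordinal variable.
#'
#' @param values strictly increasing numeric vector of length k >= 2.
#' @param probs nonnegative probabilities of the same length, summing to 1
#'   (within 1e-12; renormalized exactly).
#' @return An object of class \code{"ppc_disc"}: list with \code{values},
#'   \code{probs}, \code{cumprobs}, \code{k}.
#' @examples
#' discretization(1:4, rep(0.25, 4))
#' equal_prob_discretization(5)   # CIS, p_i = 1/5
#' @export
discretization <- function(values, probs) {
  stopifnot(is.numeric(values), is.numeric(probs),
            length(values) == length(probs), length(values) >= 2L)
  if (any(!is.finite(values))) stop("support values must be finite")
  if (any(diff(values) <= 0)) stop("support values must be strictly increasing")
  if (any(probs < -1e-12)) stop("probabilities must be nonnegative")
  probs <- pmax(probs, 0)
  if (abs(sum(probs) - 1) > 1e-12)
    stop("probabilities must sum to 1 (off by ", sum(probs) - 1, ")")
  probs <- probs / sum(probs)
  if (sum(probs > 0) < 2L)
    stop("at least two categories need positive mass (zero variance otherwise)")
  structure(list(values = values, probs = probs,
                 cumprobs = cumsum(probs), k = length(values)),
            class = "ppc_disc")
}

#' @rdname discretization
#' @param k number of categories.
#' @export
equal_prob_discretization <- function(k) {
  stopifnot(k >= 2)
  discretization(seq_len(k), rep(1 / k, k))
}

#' @export
print.ppc_disc <- function(x, ...) {
  cat("<ppc_disc> k =", x$k, "\n")
  print(data.frame(value = x$values, prob = x$probs, cumprob = x$cumprobs),
        row.names = FALSE)
  invisible(x)
}

#' Moments of a discretization
#'
#' @param disc a \code{ppc_disc}.
#' @return scalar mean \eqn{\sum x_i p_i} or variance
#'   \eqn{\sum x_i^2 p_i - (\sum x_i p_i)^2}.
#' @export
disc_mean <- function(disc) {
  stopifnot(inherits(disc, "ppc_disc"))
  sum(disc$values * disc$probs)
}

#' @rdname disc_mean
#' @export
disc_var <- function(disc) {
  stopifnot(inherits(disc, "ppc_disc"))
  sum(disc$values^2 * disc$probs) - disc_mean(disc)^2
}
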