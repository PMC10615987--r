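#' Likelihood of a response vector under one attribute profile
#'
#' Conditional likelihood under local independence: the product over items of
#' `P^x (1-P)^(1-x)`. Computed in the log domain with success probabilities
#' clamped to `[1e-10, 1 - 1e-10]`, so boundary parameter estimates cannot
#' produce NaNs; a response pattern that is impossible under the (clamped)
#' profile probabilities returns a likelihood of (numerically) zero rather
#' than an error.
#'
#' @param x Binary response vector of length J.
#' @param alpha Binary attribute profile.
#' @param params Item parameters (`dinaParams` or `gdinaParams`).
#' @param Q The Q-matrix.
#' @return The likelihood value.
#' @export
responseLikelihood <- function(x, alpha, params, Q) {
  P <- itemSuccessProbs(params, Q)[, patternIndex(alpha)]
  P <- pmin(pmax(P, 1e-10), 1 - 1e-10)
  exp(sum(x * log(P) + (1 - x) * log(1 - P)))
}

# N x L matrix of log lik(x_i | alpha_l) for all persons and profiles
logLikMatrix <- function(X, params, Q) {
  P <- itemSuccessProbs(params, Q)                 # J x L
  P <- pmin(pmax(P, 1e-10), 1 - 1e-10)
  X %*% log(P) + (1 - X) %*% log(1 - P)            # N x L
}

#' Posterior distribution over attribute profiles
#'
#' Bayes rule per person: class l gets mass proportional to
#' `lik(x_i | alpha_l) * pi_l`, normalized over the `2^K` profiles. The latent
#' class distribution `pi` plays the role of an empirical-Bayes prior. If a
#' row's products are all numerically zero (possible only with degenerate
#' priors), the row falls back to the prior and a warning names the persons
#' affected.
#'
#' @param X N x J binary response matrix.
#' @param params Item parameters.
#' @param pi Latent class distribution (length `2^K`, sums to 1).
#' @param Q The Q-matrix.
#' @return N x `2^K` matrix with rows summing to 1.
#' @export
posteriorProfiles <- function(X, params, pi, Q) {
  X <- responseMatrix(X, nrow(Q))
  if (abs(sum(pi) - 1) > 1e-8)
    stop("'pi' must sum to 1", call. = FALSE)
  ll <- logLikMatrix(X, params, Q)
  lp <- sweep(ll, 2, ifelse(pi > 0, log(pi), -Inf), "+")
  m <- apply(lp, 1, max)
  bad <- !is.finite(m)
  m[bad] <- 0
  post <- exp(lp - m)
  rs <- rowSums(post)
  zero <- bad | rs == 0
  if (any(zero)) {
    warning("posterior underflow for person(s) ",
            paste(utils::head(which(zero), 5), collapse = ", "),
            if (sum(zero) > 5) " ..." else "",
            "; falling back to the prior for those rows", call. = FALSE)
    post[zero, ] <- matrix(pi, sum(zero), length(pi), byrow = TRUE)
    rs[zero] <- 1
  }
  post / rs
}

#' Marginal posterior mastery probabilities
#'
#' Collapses a profile posterior to per-attribute mastery probabilities:
#' entry (i, k) is the posterior mass of all profiles with attribute k
#' mastered.
#'
#' @param post N x `2^K` posterior matrix (rows normalized).
#' @param K Number of attributes.
#' @return N x K matrix of mastery probabilities.
#' @export
marginalMastery <- function(post, K) {
  pat <- attributePatterns(K)
  if (ncol(post) != nrow(pat))
    stop("posterior has ", ncol(post), " columns; expected ", nrow(pat), call. = FALSE)
  m <- post %*% pat
  m[m < 0] <- 0   # guard against floating-point spill from the row sums
  m[m > 1] <- 1
  m
}

#' EAP attribute classification
#'
#' Thresholds each attribute's marginal posterior mastery probability.
#' A probability exactly at the threshold classifies as mastery.
#'
#' @param mastery N x K matrix of marginal mastery probabilities.
#' @param threshold Classification threshold, default 0.5.
#' @return List with `alpha` (N x K binary matrix of classifications) and
#'   `mastery` (the input probabilities).
#' @export
eapClassify <- function(mastery, threshold = 0.5) {
  mastery <- as.matrix(mastery)
  if (any(mastery < 0 | mastery > 1))
    stop("mastery probabilities must lie in [0, 1]", call. = FALSE)
  alpha <- matrix(as.integer(mastery >= threshold), nrow(mastery), ncol(mastery))
  list(alpha = alpha, mastery = mastery)
}

# validate / coerce a binary response matrix against an expected item count
responseMatrix <- function(X, J = NULL) {
  X <- as.matrix(X)
  if (!all(X %in% c(0, 1)))
    stop("response matrix entries must all be 0 or 1", call. = FALSE)
  storage.mode(X) <- "double"
  if (!is.null(J) && ncol(X) != J)
    stop("response matrix has ", ncol(X), " items; Q-matrix has ", J, call. = FALSE)
  X
}
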