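#' DINA item parameters
#'
#' Container for guessing and slip parameters. Under the DINA model an item
#' is answered correctly with probability `1 - slip` by respondents mastering
#' all required attributes and with probability `guess` otherwise.
#'
#' @param guess,slip Numeric J-vectors of probabilities.
#' @return An object of class `dinaParams`.
#' @export
dinaParams <- function(guess, slip) {
  if (length(guess) != length(slip))
    stop("'guess' and 'slip' must have the same length", call. = FALSE)
  if (any(guess < 0 | guess > 1 | slip < 0 | slip > 1))
    stop("guessing and slip parameters must lie in [0, 1]", call. = FALSE)
  structure(list(guess = as.numeric(guess), slip = as.numeric(slip)),
            class = c("dinaParams", "itemParams"))
}

#' G-DINA item parameters
#'
#' Saturated (identity-link) parameterization: one success probability per
#' reduced attribute profile of each item, stored in the canonical
#' binary-counting order of the reduced space. The delta (intercept, main and
#' interaction effect) coefficients of the saturated model are a linear
#' transform of these probabilities; the per-class probabilities are the
#' internal representation because the EM M-step is closed-form in them.
#'
#' @param probs List of length J; element j is a numeric vector of length
#'   `2^{K*_j}` with the success probabilities of item j's reduced profiles.
#' @return An object of class `gdinaParams`.
#' @export
gdinaParams <- function(probs) {
  if (!is.list(probs)) stop("'probs' must be a list of numeric vectors", call. = FALSE)
  for (j in seq_along(probs)) {
    p <- probs[[j]]
    if (any(p < 0 | p > 1))
      stop("item ", j, ": probabilities must lie in [0, 1]", call. = FALSE)
    if (bitwAnd(length(p), length(p) - 1L) != 0L)
      stop("item ", j, ": needs one probability per reduced profile (a power of 2)",
           call. = FALSE)
  }
  structure(list(probs = lapply(probs, as.numeric)),
            class = c("gdinaParams", "itemParams"))
}

#' DINA item response function
#'
#' Success probability of one item for one attribute profile: `1 - s` if all
#' attributes required by the item are mastered, `g` otherwise.
#'
#' @param g,s Guessing and slip probabilities.
#' @param alpha Binary attribute profile.
#' @param qrow Binary Q-matrix row of the item.
#' @return Success probability.
#' @export
pDINA <- function(g, s, alpha, qrow) {
  if (any(c(g, s) < 0 | c(g, s) > 1))
    stop("'g' and 's' must lie in [0, 1]", call. = FALSE)
  if (all(alpha[qrow == 1] == 1)) 1 - s else g
}

#' G-DINA item response function
#'
#' Success probability of one item for one attribute profile under the
#' saturated model: the stored probability of the matching reduced profile.
#'
#' @param pj Numeric vector of length `2^{K*_j}`: the item's reduced-class
#'   success probabilities in canonical order.
#' @param alpha Binary attribute profile.
#' @param qrow Binary Q-matrix row of the item.
#' @return Success probability.
#' @export
pGDINA <- function(pj, alpha, qrow) {
  idx <- reducedPatternIndex(alpha, qrow)
  if (idx > length(pj))
    stop("item parameter vector does not cover reduced profile ", idx,
         " (has ", length(pj), " entries)", call. = FALSE)
  pj[idx]
}

#' Convert DINA parameters to the saturated reduced-class representation
#'
#' DINA is nested in G-DINA: filling an item's reduced-class table with `g`
#' everywhere except `1 - s` for the all-mastered reduced profile reproduces
#' the DINA item response function exactly.
#'
#' @param params A `dinaParams` object.
#' @param Q The Q-matrix.
#' @return A `gdinaParams` object.
#' @export
dinaToGdina <- function(params, Q) {
  stopifnot(inherits(params, "dinaParams"))
  J <- nrow(Q)
  probs <- vector("list", J)
  for (j in seq_len(J)) {
    Ks <- sum(Q[j, ])
    p <- rep(params$guess[j], 2^Ks)
    p[2^Ks] <- 1 - params$slip[j]
    probs[[j]] <- p
  }
  gdinaParams(probs)
}

#' Success probabilities of every item for every attribute profile
#'
#' Expands item parameters into the `J x 2^K` table `P[j, l] = P(X_j = 1 |
#' alpha_l)` used by the likelihood, posterior and EM routines.
#'
#' @param params A `dinaParams` or `gdinaParams` object.
#' @param Q The Q-matrix.
#' @return A `J x 2^K` numeric matrix.
#' @export
itemSuccessProbs <- function(params, Q) {
  UseMethod("itemSuccessProbs")
}

#' @export
itemSuccessProbs.dinaParams <- function(params, Q) {
  grp <- itemGroupIndex(Q, "DINA")
  J <- nrow(Q)
  P <- matrix(NA_real_, J, ncol(grp$index))
  for (j in seq_len(J))
    P[j, ] <- c(params$guess[j], 1 - params$slip[j])[grp$index[j, ]]
  P
}

#' @export
itemSuccessProbs.gdinaParams <- function(params, Q) {
  grp <- itemGroupIndex(Q, "GDINA")
  J <- nrow(Q)
  if (length(params$probs) != J)
    stop("parameter list length does not match the Q-matrix", call. = FALSE)
  P <- matrix(NA_real_, J, ncol(grp$index))
  for (j in seq_len(J)) {
    if (length(params$probs[[j]]) != grp$ngroup[j])
      stop("item ", j, ": expected ", grp$ngroup[j], " reduced-class probabilities",
           call. = FALSE)
    P[j, ] <- params$probs[[j]][grp$index[j, ]]
  }
  P
}
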