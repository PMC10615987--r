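#' Marginal log-likelihood of a cognitive diagnosis model
#'
#' `sum_i log sum_l lik(x_i | alpha_l) * pi_l`, evaluated stably through a
#' log-sum-exp over the `2^K` latent classes.
#'
#' @param X N x J binary response matrix.
#' @param params Item parameters (`dinaParams` or `gdinaParams`).
#' @param pi Latent class distribution.
#' @param Q The Q-matrix.
#' @return Scalar log-likelihood.
#' @export
marginalLogLik <- function(X, params, pi, Q) {
  X <- responseMatrix(X, nrow(Q))
  lp <- sweep(logLikMatrix(X, params, Q), 2, ifelse(pi > 0, log(pi), -Inf), "+")
  m <- apply(lp, 1, max)
  sum(m + log(rowSums(exp(lp - m))))
}

#' E-step expected counts
#'
#' Computes the profile posteriors under the current parameter values and the
#' posterior-weighted tallies that the closed-form M-step needs: the expected
#' number of persons and the expected number of correct responses in each of
#' an item's latent response groups.
#'
#' @inheritParams marginalLogLik
#' @return List with `posterior` (N x `2^K`), `classCounts` (expected persons
#'   per latent class, sums to N), and `groupCounts` (per item: a matrix with
#'   rows `n` = expected persons and `r` = expected correct responses per
#'   latent group).
#' @export
eStep <- function(X, params, pi, Q) {
  X <- responseMatrix(X, nrow(Q))
  model <- if (inherits(params, "dinaParams")) "DINA" else "GDINA"
  post <- posteriorProfiles(X, params, pi, Q)
  nl <- colSums(post)
  Rjl <- crossprod(X, post)                        # J x L expected correct
  grp <- itemGroupIndex(Q, model)
  groupCounts <- lapply(seq_len(nrow(Q)), function(j) {
    g <- grp$index[j, ]
    n <- as.numeric(tapply(nl, g, sum))
    r <- as.numeric(tapply(Rjl[j, ], g, sum))
    full <- matrix(0, 2, grp$ngroup[j], dimnames = list(c("n", "r"), NULL))
    full[1, sort(unique(g))] <- n
    full[2, sort(unique(g))] <- r
    full
  })
  list(posterior = post, classCounts = nl, groupCounts = groupCounts)
}

#' Closed-form M-step
#'
#' Each latent group's success probability is the expected proportion correct
#' among the persons expected in that group. Groups with (numerically) no
#' expected mass retain the previous iterate's value; estimates are clamped
#' to `bounds`.
#'
#' @param counts Output of [eStep()].
#' @param previous Item parameters from the previous iterate (same class as
#'   the model being fitted).
#' @param bounds Length-2 numeric: clamp interval for success probabilities.
#' @return Updated item parameters of the same class as `previous`.
#' @export
mStep <- function(counts, previous, bounds = c(1e-4, 1 - 1e-4)) {
  upd <- lapply(seq_along(counts$groupCounts), function(j) {
    gc <- counts$groupCounts[[j]]
    prev <- if (inherits(previous, "dinaParams"))
      c(previous$guess[j], 1 - previous$slip[j])
    else previous$probs[[j]]
    p <- prev
    ok <- gc["n", ] >= 1e-8
    p[ok] <- pmin(pmax(gc["r", ok] / gc["n", ok], bounds[1]), bounds[2])
    p
  })
  if (inherits(previous, "dinaParams"))
    dinaParams(guess = vapply(upd, `[`, 0, 1),
               slip = 1 - vapply(upd, `[`, 0, 2))
  else gdinaParams(upd)
}

# deterministic starting values: DINA g = s = 0.2; G-DINA reduced-class
# probabilities linearly spaced 0.2 -> 0.8 in canonical reduced order
emStartValues <- function(Q, model) {
  grp <- itemGroupIndex(Q, model)
  lapply(grp$ngroup, function(ng) {
    if (model == "DINA") c(0.2, 0.8) else seq(0.2, 0.8, length.out = ng)
  })
}

#' Fit a DINA or G-DINA model by marginal maximum likelihood (EM)
#'
#' Alternates the E-step (profile posteriors and expected counts under the
#' current parameters, with the latent class distribution updated to the mean
#' posterior as an empirical-Bayes prior) with the closed-form M-step, until
#' the largest absolute change in any item success probability and any latent
#' class probability falls below `tolParam`, or the marginal log-likelihood
#' changes by less than `tolLoglik`. Starting values are deterministic (see
#' [mStep()] and the package vignette), so a fit is fully reproducible.
#'
#' @param X N x J binary response matrix (persons as rows).
#' @param Q J x K binary Q-matrix.
#' @param model `"DINA"` or `"GDINA"` (the saturated model).
#' @param maxit Maximum EM iterations.
#' @param tolParam Convergence tolerance on parameter changes.
#' @param tolLoglik Convergence tolerance on the log-likelihood change.
#' @param bounds Clamp interval for estimated success probabilities.
#' @return An object of class `cdmFit`: item parameters (`params`), latent
#'   distribution (`pi`), the posterior matrix, marginal mastery
#'   probabilities and EAP classifications at convergence, the final marginal
#'   log-likelihood with its per-iteration trajectory, and convergence
#'   metadata.
#' @examples
#' Q <- simQmatrix(15)
#' set.seed(1)
#' alpha <- simAttributesUniform(300, 5)
#' pars <- simItemParams("DINA", Q, IQ = 0.6)
#' X <- simResponses(alpha, pars, Q)
#' fit <- fitCDM(X, Q, "DINA")
#' fit
#' @export
fitCDM <- function(X, Q, model = c("GDINA", "DINA"), maxit = 1000,
                   tolParam = 1e-4, tolLoglik = 1e-7,
                   bounds = c(1e-4, 1 - 1e-4)) {
  model <- match.arg(model)
  Q <- qMatrix(Q)
  X <- responseMatrix(X, nrow(Q))
  K <- ncol(Q)
  grp <- itemGroupIndex(Q, model)
  init <- emStartValues(Q, model)
  pi0 <- rep(1 / 2^K, 2^K)
  res <- .em_fit_cpp(X, grp$index, init, pi0, as.integer(maxit),
                     tolParam, tolLoglik, bounds[1], bounds[2])
  params <- if (model == "DINA")
    dinaParams(guess = vapply(res$p, `[`, 0, 1),
               slip = 1 - vapply(res$p, `[`, 0, 2))
  else gdinaParams(res$p)
  mastery <- marginalMastery(res$posterior, K)
  cls <- eapClassify(mastery)
  structure(list(
    model = model, Q = Q, params = params,
    pi = as.numeric(res$pi), posterior = res$posterior,
    mastery = mastery, alpha = cls$alpha,
    loglik = res$loglik, trajectory = as.numeric(res$trajectory),
    niter = res$niter, converged = res$converged,
    N = nrow(X), J = nrow(Q), K = K), class = "cdmFit")
}

#' @export
logLik.cdmFit <- function(object, ...) {
  npar <- if (object$model == "DINA") 2L * object$J
  else sum(2L^rowSums(object$Q))
  structure(object$loglik, df = npar + 2L^object$K - 1L,
            nobs = object$N, class = "logLik")
}

#' @export
print.cdmFit <- function(x, ...) {
  cat(sprintf("%s fit: %d persons, %d items, %d attributes (%d latent classes)\n",
              x$model, x$N, x$J, x$K, 2^x$K))
  cat(sprintf("logLik %.3f after %d EM iterations (%s)\n", x$loglik, x$niter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.cdmFit <- function(object, ...) {
  if (object$model == "DINA")
    cbind(guess = object$params$guess, slip = object$params$slip)
  else object$params$probs
}
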