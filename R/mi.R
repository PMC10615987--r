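#' Nonparametric bootstrap resample of a response matrix
#'
#' Samples N persons with replacement. Uses the current RNG state unless a
#' `seed` is supplied.
#'
#' @param X N x J binary response matrix.
#' @param seed Optional integer seed for reproducibility.
#' @return N x J resampled matrix.
#' @export
bootstrapResample <- function(X, seed = NULL) {
  X <- as.matrix(X)
  if (!is.null(seed)) set.seed(seed)
  X[sample.int(nrow(X), nrow(X), replace = TRUE), , drop = FALSE]
}

#' Bootstrap ensemble of refitted model parameters
#'
#' Approximates the joint sampling distribution of the item parameters and
#' the latent class distribution by nonparametric bootstrap: persons are
#' resampled with replacement and the same model/Q-matrix is refitted to each
#' resample with the deterministic EM starting values (no warm start, so the
#' sampling variability is not artificially shrunk). Each stored draw is a
#' (delta_r, pi_r) pair taken jointly from one converged refit; nonconverged
#' refits are discarded and redrawn, up to `5 * R` total attempts.
#'
#' @param X N x J binary response matrix (the original sample).
#' @param Q The Q-matrix.
#' @param model `"DINA"` or `"GDINA"`.
#' @param R Number of bootstrap draws to keep (default 500; `R = 100` is a
#'   documented fast mode with little precision loss).
#' @param seed Optional integer seed.
#' @param ... Further arguments passed to [fitCDM()] (tolerances, `maxit`).
#' @return An object of class `cdmEnsemble`: lists `params` and `pi` of
#'   length `R`, the attempt/discard counts, and the seed used (if any).
#' @export
buildEnsemble <- function(X, Q, model = c("GDINA", "DINA"), R = 500,
                          seed = NULL, ...) {
  model <- match.arg(model)
  Q <- qMatrix(Q)
  X <- responseMatrix(X, nrow(Q))
  if (R < 1) stop("'R' must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  params <- vector("list", R)
  pis <- vector("list", R)
  kept <- 0L; attempts <- 0L; discarded <- 0L
  while (kept < R) {
    if (attempts >= 5L * R)
      stop("bootstrap refits failed to converge in ", attempts, " attempts (",
           discarded, " discarded); the model may be unstable for these data",
           call. = FALSE)
    attempts <- attempts + 1L
    xb <- X[sample.int(nrow(X), nrow(X), replace = TRUE), , drop = FALSE]
    fit <- fitCDM(xb, Q, model, ...)
    if (!fit$converged) { discarded <- discarded + 1L; next }
    kept <- kept + 1L
    params[[kept]] <- fit$params
    pis[[kept]] <- fit$pi
  }
  structure(list(params = params, pi = pis, R = R, model = model,
                 attempts = attempts, discarded = discarded, seed = seed),
            class = "cdmEnsemble")
}

#' @export
print.cdmEnsemble <- function(x, ...) {
  cat(sprintf("Bootstrap ensemble: %d %s draws (%d attempts, %d nonconverged discarded)\n",
              x$R, x$model, x$attempts, x$discarded))
  invisible(x)
}

#' Multiple-imputation posterior distribution
#'
#' Integrates the model parameters out of the profile posteriors by averaging
#' the posterior computed under each bootstrap draw:
#' `P(alpha_l | x_i) = (1/R) sum_r P(alpha_l | x_i, delta_r, pi_r)`.
#' Rows remain normalized because each inner posterior is.
#'
#' @param X N x J binary response matrix.
#' @param ensemble A `cdmEnsemble` object.
#' @param Q The Q-matrix.
#' @return N x `2^K` MI posterior matrix.
#' @export
miPosterior <- function(X, ensemble, Q) {
  stopifnot(inherits(ensemble, "cdmEnsemble"))
  Q <- qMatrix(Q)
  X <- responseMatrix(X, nrow(Q))
  acc <- 0
  for (r in seq_len(ensemble$R))
    acc <- acc + posteriorProfiles(X, ensemble$params[[r]], ensemble$pi[[r]], Q)
  acc / ensemble$R
}

#' MI-corrected classification accuracy
#'
#' The parameter-uncertainty-corrected counterpart of [reliabilityEM()]:
#' tau and tau_k are recomputed with the multiple-imputation posterior while
#' the EAP classifications are held fixed at the original full-sample
#' estimates — the correction changes the certainty attached to the
#' classifications, not the classifications themselves.
#'
#' @param fit The original `cdmFit` on the full sample.
#' @param X The response matrix the model was fitted to.
#' @param ensemble A `cdmEnsemble`; if `NULL`, one is built with `R` draws.
#' @param R Bootstrap draws used when `ensemble` is `NULL`.
#' @param seed Optional seed passed to [buildEnsemble()].
#' @param ... Passed to [buildEnsemble()].
#' @return A `cdmReliability` object with `method = "MI"` plus the MI
#'   posterior (`posterior`) and the ensemble used.
#' @export
reliabilityMI <- function(fit, X, ensemble = NULL, R = 500, seed = NULL, ...) {
  stopifnot(inherits(fit, "cdmFit"))
  X <- responseMatrix(X, fit$J)
  if (is.null(ensemble))
    ensemble <- buildEnsemble(X, fit$Q, fit$model, R = R, seed = seed, ...)
  post <- miPosterior(X, ensemble, fit$Q)
  mastery <- marginalMastery(post, fit$K)
  structure(list(tau = tauIndex(post, fit$alpha),
                 tauK = tauK(fit$alpha, mastery),
                 method = "MI", posterior = post, ensemble = ensemble),
            class = "cdmReliability")
}
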