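#' Posterior probability of each person's estimated attribute profile
#'
#' Looks up, for every person, the posterior mass of the profile assembled
#' from the attribute-wise EAP decisions (which need not be the modal
#' profile).
#'
#' @param post N x `2^K` posterior matrix.
#' @param alpha N x K binary matrix of estimated attribute profiles.
#' @return Numeric N-vector.
#' @export
posteriorAtEstimate <- function(post, alpha) {
  alpha <- as.matrix(alpha)
  idx <- apply(alpha, 1, patternIndex)
  post[cbind(seq_len(nrow(post)), idx)]
}

#' Profile-level classification accuracy index tau
#'
#' The average over persons of the posterior probability of the estimated
#' attribute profile — an estimator of the proportion of correctly
#' classified attribute vectors (PCV).
#'
#' @param post N x `2^K` posterior matrix (point-estimate or MI-corrected).
#' @param alpha N x K matrix of EAP attribute classifications.
#' @return Scalar in [0, 1].
#' @export
tauIndex <- function(post, alpha) {
  if (nrow(post) == 0) stop("empty posterior matrix", call. = FALSE)
  mean(posteriorAtEstimate(post, alpha))
}

#' Attribute-level classification accuracy indices tau_k
#'
#' For each attribute, the average posterior probability of the estimated
#' category: `mean(alpha_hat * P + (1 - alpha_hat) * (1 - P))` with `P` the
#' marginal posterior mastery probability — an estimator of the proportion
#' of correct attribute classifications (PCA).
#'
#' @param alpha N x K binary matrix of EAP classifications.
#' @param mastery N x K matrix of marginal posterior mastery probabilities.
#' @return Numeric K-vector.
#' @export
tauK <- function(alpha, mastery) {
  alpha <- as.matrix(alpha); mastery <- as.matrix(mastery)
  stopifnot(all(dim(alpha) == dim(mastery)))
  colMeans(alpha * mastery + (1 - alpha) * (1 - mastery))
}

#' Classification accuracy report from a fitted model
#'
#' Computes tau and tau_k from a [fitCDM()] fit using its point-estimate
#' posteriors (the traditional, EM-based estimator).
#'
#' @param fit A `cdmFit` object.
#' @return An object of class `cdmReliability` with elements `tau`, `tauK`
#'   and `method = "EM"`.
#' @export
reliabilityEM <- function(fit) {
  stopifnot(inherits(fit, "cdmFit"))
  structure(list(tau = tauIndex(fit$posterior, fit$alpha),
                 tauK = tauK(fit$alpha, fit$mastery),
                 method = "EM"),
            class = "cdmReliability")
}

#' @export
print.cdmReliability <- function(x, ...) {
  cat(sprintf("Classification accuracy (%s posteriors)\n", x$method))
  cat(sprintf("  tau   = %.4f\n", x$tau))
  cat("  tau_k =", paste(sprintf("%.4f", x$tauK), collapse = " "), "\n")
  invisible(x)
}

#' True classification accuracy against known generating profiles
#'
#' Benchmark for simulation studies: the proportion of exactly recovered
#' attribute profiles (PCV) and the per-attribute proportions of correct
#' classification (PCA).
#'
#' @param alphaTrue,alphaHat N x K binary matrices of true and estimated
#'   attribute profiles.
#' @return List with `pcv` (scalar) and `pca` (K-vector).
#' @export
trueAccuracy <- function(alphaTrue, alphaHat) {
  alphaTrue <- as.matrix(alphaTrue); alphaHat <- as.matrix(alphaHat)
  stopifnot(all(dim(alphaTrue) == dim(alphaHat)))
  agree <- alphaTrue == alphaHat
  list(pcv = mean(rowSums(agree) == ncol(agree)), pca = colMeans(agree))
}

#' Root-mean-square error of replicate estimates against a benchmark
#'
#' @param estimates Numeric vector of per-replication estimates.
#' @param benchmark Scalar benchmark (e.g. the condition's mean PCV).
#' @return Scalar RMSE.
#' @export
rmse <- function(estimates, benchmark) {
  if (length(estimates) < 1) stop("need at least one estimate", call. = FALSE)
  sqrt(mean((estimates - benchmark)^2))
}
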