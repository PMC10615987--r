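#' Generate attribute profiles under the uniform structure
#'
#' Each of the K attributes is an independent Bernoulli(0.5), so all `2^K`
#' profiles are equiprobable.
#'
#' @param N Number of persons.
#' @param K Number of attributes.
#' @return N x K binary matrix.
#' @export
simAttributesUniform <- function(N, K) {
  matrix(stats::rbinom(N * K, 1L, 0.5), N, K)
}

#' Generate attribute profiles under a higher-order structure
#'
#' A common continuous trait `theta_i ~ N(0, 1)` drives all attributes
#' through a two-parameter logistic link:
#' `P(alpha_ik = 1) = 1 / (1 + exp(-a_k (theta_i - b_k)))`.
#' The defaults (`a = 1.5`, `b = 0`) give each attribute an expected
#' prevalence of 0.5 and pairwise attribute correlations of about 0.3.
#'
#' @param N Number of persons.
#' @param K Number of attributes.
#' @param a,b Discrimination and difficulty, recycled to length K.
#' @return N x K binary matrix.
#' @export
simAttributesHigherOrder <- function(N, K, a = 1.5, b = 0) {
  a <- rep_len(a, K); b <- rep_len(b, K)
  theta <- stats::rnorm(N)
  p <- stats::plogis(outer(theta, b, "-") * rep(a, each = N))
  matrix(stats::rbinom(N * K, 1L, p), N, K)
}

#' Generate item parameters at a given item quality
#'
#' Item quality is defined as `IQ = 1 - P(0) - P(1)`, with the success
#' probability for persons mastering no required attribute, `P(0)`, equal to
#' the failure probability for persons mastering all of them, `P(1)`; both
#' endpoints equal `(1 - IQ) / 2`. For DINA this fixes guess and slip. For
#' the saturated G-DINA model the endpoint probabilities are fixed at
#' `P(0)` and `1 - P(1)` and the remaining reduced-class probabilities are
#' drawn uniformly on `(P(0), 1 - P(1))`, accepted only when strictly
#' increasing along the componentwise dominance order of the reduced
#' profiles (e.g. `P(1,1) > P(1,0) > P(0,0)`), by rejection sampling —
#' which leaves the draws exactly uniform on the monotone region.
#'
#' @param model `"DINA"` or `"GDINA"`.
#' @param Q The Q-matrix.
#' @param IQ Item quality in (0, 1); the study conditions use 0.4, 0.6, 0.8.
#' @return `dinaParams` or `gdinaParams`.
#' @export
simItemParams <- function(model = c("GDINA", "DINA"), Q, IQ) {
  model <- match.arg(model)
  Q <- qMatrix(Q)
  if (IQ <= 0 || IQ >= 1) stop("'IQ' must lie in (0, 1)", call. = FALSE)
  p0 <- (1 - IQ) / 2
  J <- nrow(Q)
  if (model == "DINA")
    return(dinaParams(guess = rep(p0, J), slip = rep(p0, J)))
  probs <- lapply(seq_len(J), function(j) {
    Ks <- sum(Q[j, ])
    ng <- 2^Ks
    pat <- attributePatterns(Ks)
    # componentwise dominance pairs (a strictly below b)
    dom <- which(outer(seq_len(ng), seq_len(ng), Vectorize(function(a, b) {
      a != b && all(pat[a, ] <= pat[b, ])
    })), arr.ind = TRUE)
    repeat {
      p <- c(p0, if (ng > 2) stats::runif(ng - 2, p0, 1 - p0), 1 - p0)
      if (all(p[dom[, 1]] < p[dom[, 2]])) return(p)
    }
  })
  gdinaParams(probs)
}

#' Generate item responses from true profiles and parameters
#'
#' Bernoulli sampling from the item response functions: person i answers
#' item j correctly with probability `P(X_j = 1 | alpha_i)`.
#'
#' @param alpha N x K binary matrix of true attribute profiles.
#' @param params Item parameters.
#' @param Q The Q-matrix.
#' @return N x J binary response matrix.
#' @export
simResponses <- function(alpha, params, Q) {
  alpha <- as.matrix(alpha)
  P <- itemSuccessProbs(params, Q)                 # J x L
  li <- apply(alpha, 1, patternIndex)
  pr <- t(P[, li, drop = FALSE])                   # N x J
  matrix(stats::rbinom(length(pr), 1L, pr), nrow(pr), ncol(pr))
}

#' Run one simulation condition
#'
#' Replicates the full study pipeline under one design cell: generate true
#' attribute profiles (uniform or higher-order) and item parameters at the
#' requested item quality, simulate responses, fit the model by EM, classify
#' by EAP, compute the point-estimate accuracy indices (tau, tau_k), the
#' MI-corrected indices when `Rboot > 0`, and the true-accuracy benchmarks
#' (PCV, PCA) against the generating profiles. Summaries report per-condition
#' means plus the RMSE and mean absolute error of each estimator against the
#' condition's mean PCV (and mean PCA, averaged over attributes).
#'
#' @param structure `"uniform"` or `"higher-order"` attribute structure.
#' @param model `"DINA"` or `"GDINA"` (used to generate and to fit).
#' @param J Test length (15 or 30, selecting the built-in Q-matrix) or a
#'   custom Q-matrix via `Q`.
#' @param N Sample size per replication.
#' @param IQ Item quality.
#' @param reps Number of replications.
#' @param Rboot Bootstrap draws for the MI correction; 0 skips MI.
#' @param seed Optional master seed; per-replication child seeds are drawn
#'   from it so replications are individually reproducible.
#' @param Q Optional explicit Q-matrix overriding `J`.
#' @param ... Passed to [fitCDM()].
#' @return An object of class `cdmCondition`: `records` (one row per
#'   successful replication), `summary` (named list of condition means and
#'   errors) and `failures` (count of replications that raised estimation
#'   errors).
#' @export
runCondition <- function(structure = c("uniform", "higher-order"),
                         model = c("GDINA", "DINA"), J = 15, N = 100,
                         IQ = 0.4, reps = 100, Rboot = 0, seed = NULL,
                         Q = NULL, ...) {
  structure <- match.arg(structure)
  model <- match.arg(model)
  if (is.null(Q)) Q <- simQmatrix(J)
  Q <- qMatrix(Q)
  K <- ncol(Q)
  if (!is.null(seed)) set.seed(seed)
  childSeeds <- sample.int(.Machine$integer.max - 1L, reps)
  rows <- vector("list", reps)
  failures <- 0L
  for (r in seq_len(reps)) {
    set.seed(childSeeds[r])
    rec <- tryCatch({
      alpha <- if (structure == "uniform") simAttributesUniform(N, K)
               else simAttributesHigherOrder(N, K)
      pars <- simItemParams(model, Q, IQ)
      X <- simResponses(alpha, pars, Q)
      fit <- fitCDM(X, Q, model, ...)
      relEM <- reliabilityEM(fit)
      acc <- trueAccuracy(alpha, fit$alpha)
      tauMIv <- NA_real_; tauKMIv <- rep(NA_real_, K)
      if (Rboot > 0) {
        relMI <- reliabilityMI(fit, X, R = Rboot, ...)
        tauMIv <- relMI$tau; tauKMIv <- relMI$tauK
      }
      c(rep = r, tauEM = relEM$tau, tauMI = tauMIv, pcv = acc$pcv,
        tauKEM = relEM$tauK, tauKMI = tauKMIv, pca = acc$pca,
        converged = as.integer(fit$converged), niter = fit$niter)
    }, error = function(e) {
      message("replication ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(rec)) failures <- failures + 1L else rows[[r]] <- rec
  }
  records <- as.data.frame(do.call(rbind, rows[!vapply(rows, is.null, TRUE)]))
  if (nrow(records) == 0) stop("all replications failed", call. = FALSE)
  kEM <- grep("^tauKEM", names(records)); kMI <- grep("^tauKMI", names(records))
  kPCA <- grep("^pca", names(records))
  meanPCV <- mean(records$pcv)
  meanPCA <- colMeans(records[kPCA])
  tauKEMmat <- as.matrix(records[kEM])
  summary <- list(
    structure = structure, model = model, J = nrow(Q), N = N, IQ = IQ,
    reps = nrow(records),
    meanPCV = meanPCV, meanPCA = meanPCA,
    meanTauEM = mean(records$tauEM),
    meanTauKEM = colMeans(tauKEMmat),
    rmseTauEM = rmse(records$tauEM, meanPCV),
    maeTauEM = mean(abs(records$tauEM - meanPCV)),
    rmseTauKEM = mean(vapply(seq_along(kEM), function(k)
      rmse(tauKEMmat[, k], meanPCA[k]), 0)))
  if (Rboot > 0) {
    tauKMImat <- as.matrix(records[kMI])
    summary <- c(summary, list(
      meanTauMI = mean(records$tauMI),
      meanTauKMI = colMeans(tauKMImat),
      rmseTauMI = rmse(records$tauMI, meanPCV),
      maeTauMI = mean(abs(records$tauMI - meanPCV)),
      rmseTauKMI = mean(vapply(seq_along(kMI), function(k)
        rmse(tauKMImat[, k], meanPCA[k]), 0))))
  }
  structure(list(records = records, summary = summary, failures = failures,
                 seed = seed),
            class = "cdmCondition")
}

#' @export
print.cdmCondition <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s / %s structure, J=%d, N=%d, IQ=%.1f (%d replications, %d failed)\n",
              s$model, s$structure, s$J, s$N, s$IQ, s$reps, x$failures))
  cat(sprintf("  mean PCV     %.3f\n  mean tau^EM  %.3f (RMSE %.3f)\n",
              s$meanPCV, s$meanTauEM, s$rmseTauEM))
  if (!is.null(s$meanTauMI))
    cat(sprintf("  mean tau^MI  %.3f (RMSE %.3f)\n", s$meanTauMI, s$rmseTauMI))
  invisible(x)
}

#' Bootstrap-count stability of the MI accuracy estimate
#'
#' Repeats the MI tau estimation many times on one fixed dataset with fresh
#' bootstrap seeds, for each candidate number of resamples, and reports the
#' spread — how stable tau^MI is as a function of R.
#'
#' @param X Fixed response matrix.
#' @param Q The Q-matrix.
#' @param model `"DINA"` or `"GDINA"`.
#' @param Rgrid Integer vector of bootstrap sizes to probe.
#' @param nrepeat Repeated MI estimations per R (>= 2).
#' @param seed Optional master seed.
#' @param ... Passed to [fitCDM()].
#' @return List with `table` (data frame: R, mean and SD of tau^MI) and
#'   `values` (matrix of the individual estimates, repeats x R values).
#' @export
stabilityStudy <- function(X, Q, model = c("GDINA", "DINA"), Rgrid = 100,
                           nrepeat = 50, seed = NULL, ...) {
  model <- match.arg(model)
  if (nrepeat < 2) stop("'nrepeat' must be at least 2", call. = FALSE)
  Q <- qMatrix(Q)
  X <- responseMatrix(X, nrow(Q))
  if (!is.null(seed)) set.seed(seed)
  fit <- fitCDM(X, Q, model, ...)
  values <- matrix(NA_real_, nrepeat, length(Rgrid),
                   dimnames = list(NULL, paste0("R", Rgrid)))
  for (g in seq_along(Rgrid))
    for (m in seq_len(nrepeat))
      values[m, g] <- reliabilityMI(fit, X, R = Rgrid[g], ...)$tau
  list(table = data.frame(R = Rgrid, mean = colMeans(values),
                          sd = apply(values, 2, stats::sd)),
       values = values, fit = fit)
}

#' Subsampling study on a complete dataset
#'
#' Emulates small-sample calibration from a large real dataset: for each
#' requested size, response vectors are repeatedly drawn without replacement
#' from the full sample, the model is refitted, the profiles re-estimated by
#' EAP, and tau computed with both the point-estimate (EM) and MI posteriors.
#' The benchmark for each replicate is tau evaluated with posteriors under
#' the full-sample parameter estimates (assumed nearly exact) at the
#' replicate's estimated profiles.
#'
#' @param Xfull Complete N x J response matrix.
#' @param Q The Q-matrix.
#' @param model `"DINA"` or `"GDINA"`.
#' @param sizes Subsample sizes (each <= nrow(Xfull)).
#' @param reps Replicates per size.
#' @param Rboot Bootstrap draws for MI; 0 skips MI.
#' @param seed Optional master seed.
#' @param ... Passed to [fitCDM()].
#' @return List with `records` (size, rep, tauEM, tauMI, benchmark) and
#'   `fullFit` (the complete-sample fit).
#' @export
subsampleStudy <- function(Xfull, Q, model = c("GDINA", "DINA"), sizes,
                           reps = 100, Rboot = 0, seed = NULL, ...) {
  model <- match.arg(model)
  Q <- qMatrix(Q)
  Xfull <- responseMatrix(Xfull, nrow(Q))
  if (max(sizes) > nrow(Xfull))
    stop("subsample size exceeds the available sample", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fullFit <- fitCDM(Xfull, Q, model, ...)
  rows <- list()
  for (n in sizes) {
    for (r in seq_len(reps)) {
      idx <- sample.int(nrow(Xfull), n, replace = FALSE)
      Xs <- Xfull[idx, , drop = FALSE]
      fit <- fitCDM(Xs, Q, model, ...)
      bench <- tauIndex(
        posteriorProfiles(Xs, fullFit$params, fullFit$pi, Q), fit$alpha)
      tauMIv <- NA_real_
      if (Rboot > 0) tauMIv <- reliabilityMI(fit, Xs, R = Rboot, ...)$tau
      rows[[length(rows) + 1L]] <- data.frame(
        size = n, rep = r, tauEM = reliabilityEM(fit)$tau, tauMI = tauMIv,
        benchmark = bench)
    }
  }
  list(records = do.call(rbind, rows), fullFit = fullFit)
}
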