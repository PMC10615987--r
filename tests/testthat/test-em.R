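test_that("marginal log-likelihood sums the latent-class mixture", {
  Q <- qMatrix(matrix(1, 1, 1))
  pars <- dinaParams(0.2, 0.2)
  expect_equal(marginalLogLik(matrix(1, 1, 1), pars, c(0.5, 0.5), Q),
               log(0.5), tolerance = 1e-12)
  # duplicating every person doubles the log-likelihood exactly
  set.seed(404)
  d <- tiny_dataset(N = 40)
  pi <- rep(1 / 32, 32)
  ll1 <- marginalLogLik(d$X, d$pars, pi, d$Q)
  ll2 <- marginalLogLik(rbind(d$X, d$X), d$pars, pi, d$Q)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
  # brute-force enumeration oracle on a small random instance
  Qs <- qMatrix(rbind(c(1, 0), c(0, 1), c(1, 1)))
  pars2 <- random_gdina_params(Qs)
  X2 <- matrix(rbinom(12, 1, 0.5), 4, 3)
  pi2 <- c(0.1, 0.2, 0.3, 0.4)
  llOracle <- sum(log(sapply(seq_len(4), function(i) {
    pats <- attributePatterns(2)
    sum(sapply(1:4, function(l)
      oracle_likelihood(X2[i, ], pats[l, ], pars2, Qs) * pi2[l]))
  })))
  expect_equal(marginalLogLik(X2, pars2, pi2, Qs), llOracle, tolerance = 1e-10)
})

test_that("E-step expected counts are posterior-weighted tallies", {
  set.seed(405)
  d <- tiny_dataset(N = 60)
  pi <- rep(1 / 32, 32)
  es <- eStep(d$X, d$pars, pi, d$Q)
  expect_equal(sum(es$classCounts), 60, tolerance = 1e-8)
  for (j in c(1, 8, 15)) {
    expect_equal(sum(es$groupCounts[[j]]["n", ]), 60, tolerance = 1e-8)
    expect_true(all(es$groupCounts[[j]]["r", ] <= es$groupCounts[[j]]["n", ] + 1e-10))
  }
  # point-mass prior concentrates all expected mass in one class
  piDeg <- c(1, rep(0, 31))
  esDeg <- eStep(d$X, d$pars, piDeg, d$Q)
  expect_equal(esDeg$classCounts[1], 60, tolerance = 1e-8)
  expect_equal(sum(esDeg$classCounts[-1]), 0)
})

test_that("M-step is the expected proportion correct, with empty-group guard", {
  prev <- dinaParams(0.25, 0.25)
  counts <- list(groupCounts = list(rbind(n = c(10, 20), r = c(5, 18))))
  upd <- mStep(counts, prev)
  expect_equal(upd$guess, 0.5)
  expect_equal(upd$slip, 1 - 0.9)
  # zero expected mass in the non-master group: parameter retained
  counts0 <- list(groupCounts = list(rbind(n = c(0, 20), r = c(0, 18))))
  upd0 <- mStep(counts0, prev)
  expect_equal(upd0$guess, 0.25)
  expect_equal(upd0$slip, 1 - 0.9)
})

test_that("EM recovers DINA generating parameters at large N", {
  set.seed(406)
  Q <- simQmatrix(15)
  alpha <- simAttributesUniform(5000, 5)
  pars <- simItemParams("DINA", Q, 0.8)   # g = s = 0.1
  X <- simResponses(alpha, pars, Q)
  fit <- fitCDM(X, Q, "DINA")
  err <- c(abs(fit$params$guess - 0.1), abs(fit$params$slip - 0.1))
  expect_true(fit$converged)
  expect_lt(max(err), 0.03)
  expect_lt(mean(err), 0.02)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-8)
  expect_true(all(fit$pi >= 0))
})

test_that("converged EM solution is a fixed point of the R-level E/M step", {
  set.seed(407)
  d <- tiny_dataset(N = 2000, IQ = 0.6)
  for (model in c("DINA", "GDINA")) {
    fit <- fitCDM(d$X, d$Q, model)
    es <- eStep(d$X, fit$params, fit$pi, d$Q)
    upd <- mStep(es, fit$params)
    drift <- if (model == "DINA")
      max(abs(upd$guess - fit$params$guess), abs(upd$slip - fit$params$slip))
    else max(abs(unlist(upd$probs) - unlist(fit$params$probs)))
    expect_lt(drift, 5e-4)
    expect_lt(max(abs(colSums(es$posterior) / 2000 - fit$pi)), 1e-3)
  }
})

test_that("one EM step from the truth barely moves at very large N", {
  set.seed(408)
  Q <- simQmatrix(15)
  alpha <- simAttributesUniform(20000, 5)
  pars <- simItemParams("DINA", Q, 0.6)
  X <- simResponses(alpha, pars, Q)
  es <- eStep(X, pars, rep(1 / 32, 32), Q)
  upd <- mStep(es, pars)
  expect_lt(max(abs(upd$guess - pars$guess)), 0.01)
  expect_lt(max(abs(upd$slip - pars$slip)), 0.01)
})

test_that("log-likelihood trajectory is nondecreasing on every fit", {
  set.seed(409)
  for (model in c("DINA", "GDINA")) {
    for (IQ in c(0.4, 0.8)) {
      d <- tiny_dataset(N = 100, IQ = IQ, model = model)
      fit <- fitCDM(d$X, d$Q, model)
      expect_true(all(diff(fit$trajectory) > -1e-8),
                  label = paste(model, IQ, "monotone trajectory"))
    }
  }
})

test_that("degenerate constant items clamp at the bounds and fit completes", {
  set.seed(410)
  d <- tiny_dataset(N = 80)
  d$X[, 3] <- 1  # item answered correctly by everyone
  fit <- fitCDM(d$X, d$Q, "DINA")
  expect_true(is.finite(fit$loglik))
  expect_gte(1 - fit$params$slip[3], 1 - 1e-4)  # clamped at the upper bound
  expect_gt(fit$params$guess[3], 0.9)
})

test_that("G-DINA on DINA data recovers the two-valued pattern at large N", {
  set.seed(411)
  Q <- simQmatrix(15)
  # average the fitted tables over independent datasets first: the nesting
  # property concerns systematic structure, and single-draw group estimates
  # carry ~0.01 binomial noise each
  fits <- replicate(3, {
    alpha <- simAttributesUniform(20000, 5)
    pars <- simItemParams("DINA", Q, 0.6)   # g = s = 0.2
    X <- simResponses(alpha, pars, Q)
    fitCDM(X, Q, "GDINA")$params$probs
  }, simplify = FALSE)
  # within each multi-attribute item, the non-full-mastery classes share g
  spread <- vapply(which(rowSums(Q) > 1), function(j) {
    p <- (fits[[1]][[j]] + fits[[2]][[j]] + fits[[3]][[j]]) / 3
    diff(range(p[-length(p)]))
  }, 0)
  expect_lt(max(spread), 0.05)
  # and the full-mastery class recovers 1 - s = 0.8
  top <- vapply(seq_len(15), function(j) {
    mean(vapply(fits, function(f) f[[j]][length(f[[j]])], 0))
  }, 0)
  expect_lt(max(abs(top - 0.8)), 0.05)
})

test_that("parameter recovery improves with sample size", {
  set.seed(412)
  Q <- simQmatrix(15)
  maeAt <- function(N) {
    alpha <- simAttributesUniform(N, 5)
    pars <- simItemParams("DINA", Q, 0.6)
    fit <- fitCDM(simResponses(alpha, pars, Q), Q, "DINA")
    mean(c(abs(fit$params$guess - 0.2), abs(fit$params$slip - 0.2)))
  }
  errSmall <- mean(replicate(10, maeAt(200)))
  errLarge <- mean(replicate(10, maeAt(5000)))
  expect_lt(errLarge, errSmall)
})
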