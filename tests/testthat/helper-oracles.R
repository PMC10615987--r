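# Brute-force oracles, written from the model definitions with plain loops.
# They deliberately share no code with the package's vectorized/C++ paths.

# success probability of item j for profile alpha, straight from the
# conjunctive rule / saturated lookup
oracle_prob <- function(params, j, alpha, Q) {
  req <- which(Q[j, ] == 1)
  if (inherits(params, "dinaParams")) {
    if (all(alpha[req] == 1)) 1 - params$slip[j] else params$guess[j]
  } else {
    bits <- alpha[req]
    idx <- 1
    for (b in bits) idx <- 2 * (idx - 1) + b + 1
    params$probs[[j]][idx]
  }
}

# conditional likelihood as a literal product over items
oracle_likelihood <- function(x, alpha, params, Q) {
  out <- 1
  for (j in seq_along(x)) {
    p <- oracle_prob(params, j, alpha, Q)
    out <- out * (if (x[j] == 1) p else 1 - p)
  }
  out
}

# Bayes rule by explicit enumeration of all 2^K classes
oracle_posterior <- function(X, params, pi, Q) {
  K <- ncol(Q)
  pats <- as.matrix(expand.grid(rep(list(0:1), K)))[, K:1, drop = FALSE]
  # reorder rows to binary counting with attribute 1 most significant
  ord <- order(apply(pats, 1, function(a) sum(a * 2^(K - seq_len(K)))))
  pats <- pats[ord, , drop = FALSE]
  post <- matrix(0, nrow(X), nrow(pats))
  for (i in seq_len(nrow(X))) {
    w <- numeric(nrow(pats))
    for (l in seq_len(nrow(pats)))
      w[l] <- oracle_likelihood(X[i, ], pats[l, ], params, Q) * pi[l]
    post[i, ] <- w / sum(w)
  }
  post
}

# marginal mastery by summing posterior mass over the matching class subset
oracle_mastery <- function(post, K) {
  pats <- attributePatterns(K)
  out <- matrix(0, nrow(post), K)
  for (i in seq_len(nrow(post)))
    for (k in seq_len(K))
      out[i, k] <- sum(post[i, pats[, k] == 1])
  out
}

# random G-DINA parameter list with probabilities bounded away from 0/1
random_gdina_params <- function(Q) {
  gdinaParams(lapply(seq_len(nrow(Q)), function(j)
    stats::runif(2^sum(Q[j, ]), 0.05, 0.95)))
}

# small simulated dataset for tests
tiny_dataset <- function(N = 50, J = 15, model = "DINA", IQ = 0.6, K = 5,
                         Q = simQmatrix(J)) {
  alpha <- simAttributesUniform(N, ncol(Q))
  pars <- simItemParams(model, Q, IQ)
  list(X = simResponses(alpha, pars, Q), Q = Q, alpha = alpha, pars = pars)
}
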