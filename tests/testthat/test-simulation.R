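test_that("uniform attribute structure: independent Bernoulli(0.5)", {
  expect_equal(nrow(simAttributesUniform(0, 5)), 0)
  set.seed(701)
  a <- simAttributesUniform(10000, 5)
  se <- sqrt(0.25 / 10000)
  expect_true(all(abs(colMeans(a) - 0.5) < 3 * se))
  cors <- cor(a)[upper.tri(diag(5))]
  expect_true(all(abs(cors) < 3 / sqrt(10000)))
})

test_that("higher-order structure: prevalence 0.5, intercorrelation ~0.3", {
  set.seed(702)
  a <- simAttributesHigherOrder(20000, 5)
  expect_true(all(abs(colMeans(a) - 0.5) < 3 * sqrt(0.25 / 20000)))
  cors <- cor(a)[upper.tri(diag(5))]
  expect_lt(abs(mean(cors) - 0.3), 0.04)
  # theta = 0 at default a, b gives mastery probability one half:
  expect_equal(stats::plogis(1.5 * (0 - 0)), 0.5)
})

test_that("item quality fixes the endpoint probabilities", {
  Q <- simQmatrix(15)
  pd <- simItemParams("DINA", Q, 0.8)
  expect_equal(pd$guess, rep(0.1, 15))
  expect_equal(pd$slip, rep(0.1, 15))
  expect_length(pd$guess, 15)
  set.seed(703)
  pg <- simItemParams("GDINA", Q, 0.4)
  for (j in 1:15) {
    pj <- pg$probs[[j]]
    expect_equal(pj[1], 0.3)
    expect_equal(pj[length(pj)], 0.7)
  }
  expect_error(simItemParams("DINA", Q, 1.2), "\\(0, 1\\)")
})

test_that("generated G-DINA parameters respect the dominance order", {
  set.seed(704)
  Q <- simQmatrix(30)
  for (rep in 1:5) {
    pg <- simItemParams("GDINA", Q, 0.4)
    for (j in seq_len(30)) {
      Ks <- sum(Q[j, ])
      pat <- attributePatterns(Ks)
      pj <- pg$probs[[j]]
      for (a in seq_len(2^Ks)) for (b in seq_len(2^Ks)) {
        if (a != b && all(pat[a, ] <= pat[b, ]))
          expect_lt(pj[a], pj[b])
      }
    }
  }
})

test_that("responses are Bernoulli draws from the item response functions", {
  Q <- qMatrix(rbind(c(1, 0), c(0, 1), c(1, 1)))
  sure <- gdinaParams(list(c(1, 1), c(1, 1), c(1, 1, 1, 1)))
  never <- gdinaParams(list(c(0, 0), c(0, 0), c(0, 0, 0, 0)))
  alpha <- rbind(c(0, 1), c(1, 1))
  expect_true(all(simResponses(alpha, sure, Q) == 1))
  expect_true(all(simResponses(alpha, never, Q) == 0))
  set.seed(705)
  pars <- gdinaParams(list(c(0.2, 0.7), c(0.3, 0.9), c(0.1, 0.4, 0.5, 0.8)))
  a1 <- matrix(rep(c(1, 0), 10000), ncol = 2, byrow = TRUE)
  X <- simResponses(a1, pars, Q)
  truth <- c(0.7, 0.3, 0.5)   # profile (1,0): reduced classes (1), (0), (1,0)
  se <- sqrt(truth * (1 - truth) / 10000)
  expect_true(all(abs(colMeans(X) - truth) < 3 * se))
})

test_that("condition runs are reproducible under a fixed seed", {
  c1 <- runCondition("uniform", "DINA", J = 15, N = 60, IQ = 0.8, reps = 2,
                     Rboot = 5, seed = 99)
  c2 <- runCondition("uniform", "DINA", J = 15, N = 60, IQ = 0.8, reps = 2,
                     Rboot = 5, seed = 99)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$summary, c2$summary)
  expect_true(all(c(c1$summary$meanPCV, c1$summary$meanTauEM,
                    c1$summary$meanTauMI) >= 0))
  expect_true(all(c1$records$tauEM <= 1 & c1$records$tauEM >= 0))
})

test_that("subsampling at the full size with one replicate is the identity", {
  set.seed(706)
  d <- tiny_dataset(N = 150, IQ = 0.8)
  full <- fitCDM(d$X, d$Q, "DINA")
  res <- subsampleStudy(d$X, d$Q, "DINA", sizes = nrow(d$X), reps = 1)
  expect_equal(res$records$tauEM, reliabilityEM(full)$tau, tolerance = 1e-10)
  expect_equal(res$records$benchmark, res$records$tauEM, tolerance = 1e-10)
  expect_error(subsampleStudy(d$X, d$Q, "DINA", sizes = 151, reps = 1),
               "exceeds")
})

test_that("stability study reports the spread of repeated MI estimates", {
  set.seed(707)
  d <- tiny_dataset(N = 60, IQ = 0.8)
  st <- stabilityStudy(d$X, d$Q, "DINA", Rgrid = c(5, 20), nrepeat = 4, seed = 3)
  expect_equal(dim(st$values), c(4L, 2L))
  expect_true(all(st$table$sd >= 0))
  expect_true(all(st$values >= 0 & st$values <= 1))
  expect_error(stabilityStudy(d$X, d$Q, "DINA", nrepeat = 1), "at least 2")
})
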