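test_that("initialisation is seeded and has 5h + 1 parameters", {
  a <- initNetwork(4, seed = 1)
  b <- initNetwork(4, seed = 1)
  expect_identical(thermaheal:::.packParams(a),
                   thermaheal:::.packParams(b))
  expect_length(thermaheal:::.packParams(a), 21)   # 5 * 4 + 1
  expect_length(thermaheal:::.packParams(initNetwork(1)), 6)
  expect_error(initNetwork(0), "h must be")
})

test_that("forward pass matches an explicit-loop oracle", {
  m <- initNetwork(3, seed = 5)
  zero <- m
  zero@w1[] <- 0; zero@b1[] <- 0; zero@w2[] <- 0; zero@b2 <- 0
  expect_equal(bnnForward(zero, c(1, -2, 3)), 0.5)
  big <- zero; big@b2 <- 50
  expect_gt(bnnForward(big, c(0, 0, 0)), 1 - 1e-12)
  set.seed(71)
  for (rep in 1:10) {
    x <- rnorm(3)
    y <- bnnForward(m, x)
    acc <- m@b2
    for (k in 1:m@h) {
      s <- m@b1[k]
      for (j in 1:3) s <- s + m@w1[k, j] * x[j]
      acc <- acc + m@w2[k] * tanh(s)
    }
    expect_equal(y, 1 / (1 + exp(-acc)), tolerance = 1e-12)
  }
})

test_that("cost decomposes into cross-entropy and weight decay", {
  m <- initNetwork(2, seed = 3)
  m@w1[] <- 0; m@b1[] <- 0; m@w2[] <- 0; m@b2 <- 0
  x <- matrix(rnorm(12), 4, 3)
  cost <- bnnCost(m, x, c(0, 1, 0, 1), alpha = 0.3)
  expect_equal(cost$G, 4 * log(2))
  expect_equal(cost$EW, 0)
  expect_equal(cost$M, cost$G)
  # perfectly confident predictions drive G towards 0
  sep <- initNetwork(1, seed = 4)
  sep@w1[] <- c(100, 0, 0); sep@b1 <- 0; sep@w2 <- 100; sep@b2 <- 0
  xs <- matrix(c(1, 1, -1, -1, rep(0, 8)), 4, 3)
  expect_lt(bnnCost(sep, xs, c(1, 1, 0, 0), alpha = 0)$G, 1e-10)
})

test_that("analytic gradients match central finite differences", {
  set.seed(72)
  worst <- 0
  for (k in 1:20) {
    h <- sample(1:5, 1)
    m <- initNetwork(h, seed = k)
    w <- thermaheal:::.packParams(m)
    x <- matrix(rnorm(30), 10, 3)
    t <- rbinom(10, 1, 0.5)
    al <- runif(1, 0.01, 1)
    g <- thermaheal:::.gradFn(w, h, x, t, al)
    eps <- 1e-6
    gn <- vapply(seq_along(w), function(i) {
      wp <- w; wp[i] <- w[i] + eps
      wm <- w; wm[i] <- w[i] - eps
      (thermaheal:::.costFn(wp, h, x, t, al) -
         thermaheal:::.costFn(wm, h, x, t, al)) / (2 * eps)
    }, 0)
    worst <- max(worst, max(abs(g - gn) / pmax(abs(gn), 1e-8)))
  }
  expect_lt(worst, 1e-5)
})

test_that("training is deterministic, fits separable data, and shrinks under a huge prior", {
  set.seed(73)
  x <- rbind(matrix(rnorm(60, 2), 20, 3), matrix(rnorm(60, -2), 20, 3))
  t <- rep(c(1, 0), each = 20)
  m1 <- trainBNN(initNetwork(2, seed = 1), x, t)
  m2 <- trainBNN(initNetwork(2, seed = 1), x, t)
  expect_identical(thermaheal:::.packParams(m1),
                   thermaheal:::.packParams(m2))
  expect_gte(mean((bnnForward(m1, x) >= 0.5) == t), 0.95)
  # fixed alpha = 1e6 without re-estimation: prior dominates
  mBig <- trainBNN(initNetwork(2, seed = 1), x, t, alpha0 = 1e6,
                   reestimate = FALSE)
  expect_lt(sum(thermaheal:::.packParams(mBig)^2), 1e-4)
  expect_true(all(abs(bnnForward(mBig, x) - 0.5) < 0.01))
})

test_that("final weight norm is non-increasing in a fixed alpha", {
  set.seed(74)
  x <- matrix(rnorm(90), 30, 3)
  t <- rbinom(30, 1, plogis(x[, 1]))
  ew <- sapply(10^seq(-2, 2), function(al) {
    m <- trainBNN(initNetwork(3, seed = 2), x, t, alpha0 = al,
                  reestimate = FALSE)
    bnnCost(m, x, t)$EW
  })
  expect_true(all(diff(ew) <= 1e-8))
})

test_that("log evidence is finite with gamma in [0, W]", {
  set.seed(75)
  for (k in 1:10) {
    h <- sample(1:4, 1)
    n <- 20
    x <- matrix(rnorm(3 * n), n, 3)
    t <- rbinom(n, 1, 0.5)
    m <- trainBNN(initNetwork(h, seed = k), x, t)
    ev <- logEvidence(m, x, t)
    expect_true(is.finite(ev$logEvidence))
    expect_gte(ev$gamma, 0)
    expect_lte(ev$gamma, 5 * h + 1)
  }
  # alpha >> all eigenvalues: nothing is well determined
  m0 <- initNetwork(1, seed = 1)
  m0@w1[] <- 0; m0@b1 <- 0; m0@w2 <- 0; m0@b2 <- 0
  m0@trained <- TRUE
  x0 <- matrix(0, 8, 3)
  ev0 <- logEvidence(m0, x0, rep(c(0, 1), 4), alpha = 1e8)
  expect_true(is.finite(ev0$logEvidence))
  expect_lt(ev0$gamma, 0.01)
})

test_that("architecture selection picks a trainable width and reports evidence per h", {
  set.seed(76)
  x <- rbind(matrix(rnorm(45, 1.5), 15, 3),
             matrix(rnorm(45, -1.5), 15, 3))
  t <- rep(c(1, 0), each = 15)
  sel <- selectArchitecture(x, t, hRange = 1:4, restarts = 2, seed = 5)
  expect_true(sel$h %in% 1:4)
  expect_equal(sel$evidence$h, 1:4)
  expect_true(all(is.finite(sel$evidence$logEvidence)))
  expect_true(sel$model@trained)
  expect_gte(mean((bnnForward(sel$model, x) >= 0.5) == t), 0.95)
  # ties break to the smaller width (first maximum wins)
  expect_equal(sel$evidence$h[which.max(c(-50, -45, -45, -46))], 2)
})

test_that("prediction thresholds and probabilities behave", {
  set.seed(77)
  x <- matrix(rnorm(30), 10, 3)
  m <- trainBNN(initNetwork(2, seed = 3), x, rbinom(10, 1, 0.5))
  pr <- predictBNN(m, x)
  expect_equal(pr$probability, as.vector(bnnForward(m, x)))
  expect_true(all(predictBNN(m, x, threshold = 0)$label == "unhealed"))
  hi <- predictBNN(m, x, threshold = 1 + 1e-9)
  expect_true(all(hi$label == "healed"))
  expect_error(predictBNN(initNetwork(2), x), "untrained")
})

test_that("network models survive a JSON round trip", {
  set.seed(78)
  x <- matrix(rnorm(30), 10, 3)
  m <- trainBNN(initNetwork(3, seed = 9), x, rbinom(10, 1, 0.5))
  f <- withr::local_tempfile(fileext = ".json")
  writeBNNModel(m, f, extra = list(seed = 9))
  back <- readBNNModel(f)
  expect_equal(bnnForward(back, x), bnnForward(m, x))
  expect_equal(back@alpha, m@alpha)
})
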