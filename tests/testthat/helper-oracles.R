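# Independent reference implementations and shared fixtures.
# The oracles deliberately use naive explicit loops so they share no
# code path with the package implementations they check.

# --- naive double-loop GLCM feature oracle -------------------------

naiveGLCMFeatures <- function(p) {
  Ng <- nrow(p)
  px <- numeric(Ng); py <- numeric(Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:Ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sigx <- 0; sigy <- 0
  for (i in 1:Ng) {
    sigx <- sigx + (i - mux)^2 * px[i]
    sigy <- sigy + (i - muy)^2 * py[i]
  }
  sigx <- sqrt(sigx); sigy <- sqrt(sigy)
  psum <- numeric(2 * Ng)                # index k = 2..2Ng
  pdiff <- numeric(Ng)                   # index k+1 = |i-j|+1
  for (i in 1:Ng) for (j in 1:Ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }
  xlx <- function(v) if (v > 0) v * log(v) else 0
  eng <- cont <- acorr <- entr <- hom <- dsim <- 0
  clsha <- clpro <- idhom <- idnorm <- idmnorm <- hxy1 <- sumsq <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    v <- p[i, j]
    eng <- eng + v^2
    cont <- cont + (i - j)^2 * v
    acorr <- acorr + i * j * v
    entr <- entr - xlx(v)
    hom <- hom + v / (1 + (i - j)^2)
    dsim <- dsim + abs(i - j) * v
    clsha <- clsha + (i + j - mux - muy)^3 * v
    clpro <- clpro + (i + j - mux - muy)^4 * v
    idhom <- idhom + v / (1 + abs(i - j))
    idnorm <- idnorm + v / (1 + abs(i - j) / Ng)
    idmnorm <- idmnorm + v / (1 + (i - j)^2 / Ng^2)
    sumsq <- sumsq + (i - mux)^2 * v
    if (v > 0) hxy1 <- hxy1 - v * log(px[i] * py[j])
  }
  corr <- if (sigx == 0 || sigy == 0) 0 else
    (acorr - mux * muy) / (sigx * sigy)
  sumav <- 0
  for (k in 2:(2 * Ng)) sumav <- sumav + k * psum[k]
  sumvar <- 0
  for (k in 2:(2 * Ng)) sumvar <- sumvar + (k - sumav)^2 * psum[k]
  sument <- 0
  for (k in 2:(2 * Ng)) sument <- sument - xlx(psum[k])
  diffent <- 0
  for (k in 1:Ng) diffent <- diffent - xlx(pdiff[k])
  hx <- 0; hy <- 0
  for (i in 1:Ng) { hx <- hx - xlx(px[i]); hy <- hy - xlx(py[i]) }
  imcorr <- if (max(hx, hy) == 0) 0 else (entr - hxy1) / max(hx, hy)
  c(Eng = eng, Cont = cont, Corr = corr, sumSq = sumsq,
    sumAv = sumav, sumVar = sumvar, Entr = entr, sumEnt = sument,
    diffEnt = diffent, imCorr = imcorr, Hom = hom, aCorr = acorr,
    dSim = dsim, clSha = clsha, clPro = clpro,
    maxProb = max(p), idHom = idhom, idNorm = idnorm,
    idmNorm = idmnorm)
}

randomGLCM <- function(Ng, symmetric = TRUE) {
  m <- matrix(runif(Ng * Ng), Ng, Ng)
  if (symmetric) m <- m + t(m)
  m / sum(m)
}

# --- pairwise concordance oracle for the AUC -----------------------

concordanceAUC <- function(prob, truth) {
  pos <- prob[truth == "unhealed"]; neg <- prob[truth == "healed"]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# --- teacher-network data for the evidence Occam simulation --------

teacherData <- function(seed, n = 45, hTrue = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n * 3), n, 3)
  teacher <- initNetwork(hTrue, seed = seed + 7777)
  teacher@w1 <- teacher@w1 * 3
  teacher@w2 <- teacher@w2 * 3
  list(x = x, t = rbinom(n, 1, bnnForward(teacher, x)))
}

# --- shared cohorts (computed once per test run) -------------------

smallParams <- function(...) {
  syntheticParams(width = 80L, height = 60L, woundAxes = c(10, 16),
                  logoRect = c(4L, 4L, 20L, 6L), ...)
}

tinyParams <- function(...) {
  syntheticParams(width = 64L, height = 48L, woundAxes = c(8, 13),
                  logoRect = c(4L, 4L, 16L, 5L), ...)
}

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureEnv))
    assign(name, expr, envir = .fixtureEnv)
  get(name, envir = .fixtureEnv)
}

smallCohortTable <- function() fixture("smallCohortTable", {
  extractFeatureTable(
    generateCohort(20, 20, smallParams(), seed = 11),
    preprocessConfig(logoRect = c(4L, 4L, 20L, 6L)))
})

defaultCohortTable <- function() fixture("defaultCohortTable", {
  extractFeatureTable(generateCohort(47, 17, syntheticParams(),
                                     seed = 42))
})
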