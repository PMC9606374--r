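# parameter vector layout: c(as.vector(w1), b1, w2, b2); length 5h + 1
.packParams <- function(model)
  c(as.vector(model@w1), model@b1, model@w2, model@b2)

.unpackParams <- function(w, h) {
  list(w1 = matrix(w[seq_len(3L * h)], h, 3L),
       b1 = w[3L * h + seq_len(h)],
       w2 = w[4L * h + seq_len(h)],
       b2 = w[5L * h + 1L])
}

.setParams <- function(model, w) {
  p <- .unpackParams(w, model@h)
  model@w1 <- p$w1; model@b1 <- p$b1; model@w2 <- p$w2; model@b2 <- p$b2
  model
}

# pre-sigmoid output and hidden activations for an n x 3 score matrix
.forwardRaw <- function(w, h, x) {
  p <- .unpackParams(w, h)
  z <- tanh(x %*% t(p$w1) + matrix(p$b1, nrow(x), h, byrow = TRUE))
  list(a = as.vector(z %*% p$w2 + p$b2), z = z, p = p)
}

# Jacobian of the pre-sigmoid output wrt the parameter vector (n x W)
.outputJacobian <- function(w, h, x) {
  fw <- .forwardRaw(w, h, x)
  dz <- 1 - fw$z^2                      # n x h
  Jw1 <- do.call(cbind, lapply(1:3, function(j)
    dz * matrix(fw$p$w2, nrow(x), h, byrow = TRUE) * x[, j]))
  Jb1 <- dz * matrix(fw$p$w2, nrow(x), h, byrow = TRUE)
  cbind(Jw1, Jb1, fw$z, rep(1, nrow(x)))
}

#' Initialise a 3-h-1 network
#'
#' Weights and biases are drawn i.i.d. Gaussian with SD 1/sqrt(fan-in)
#' (fan-in 3 for the hidden layer, h for the output), deterministically
#' per seed.
#'
#' @param h hidden-node count (>= 1).
#' @param seed integer seed.
#' @param alpha initial weight-decay hyperparameter.
#' @return an untrained \code{\linkS4class{BNNModel}} with 5h + 1
#'   parameters.
#' @export
initNetwork <- function(h, seed = 1L, alpha = 0.1) {
  h <- as.integer(h)
  if (h < 1L) stop("h must be >= 1")
  .withSeed(seed, {
    new("BNNModel",
        w1 = matrix(rnorm(3L * h, sd = 1 / sqrt(3)), h, 3L),
        b1 = rnorm(h, sd = 1 / sqrt(3)),
        w2 = rnorm(h, sd = 1 / sqrt(h)),
        b2 = rnorm(1L, sd = 1 / sqrt(h)),
        h = h, alpha = alpha, trained = FALSE)
  })
}

#' Forward pass: probability that a wound is unhealed
#'
#' y = sigmoid(w2' tanh(W1 x + b1) + b2), the predicted probability of
#' the positive class (unhealed).
#'
#' @param model a \code{\linkS4class{BNNModel}}.
#' @param x numeric score vector of length 3, or an m x 3 matrix.
#' @return probability vector in (0, 1).
#' @export
bnnForward <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, ncol = 3L)
  if (ncol(x) != 3L) stop("scores must have 3 columns")
  a <- .forwardRaw(.packParams(model), model@h, x)$a
  1 / (1 + exp(-a))
}

#' Training cost: cross-entropy plus weight decay
#'
#' G is the cross-entropy of the clipped output probabilities
#' (clipping at 1e-12 keeps it finite), E_W = 0.5 sum(w^2) over all
#' weights and biases, and M = G + alpha E_W.
#'
#' @param model a \code{\linkS4class{BNNModel}}.
#' @param x m x 3 score matrix.
#' @param t binary labels (1 = unhealed).
#' @param alpha weight decay (default the model's).
#' @return list with \code{M}, \code{G} and \code{EW}.
#' @export
bnnCost <- function(model, x, t, alpha = model@alpha) {
  stopifnot(all(t %in% c(0, 1)))
  y <- pmin(pmax(bnnForward(model, x), 1e-12), 1 - 1e-12)
  G <- -sum(t * log(y) + (1 - t) * log(1 - y))
  w <- .packParams(model)
  EW <- 0.5 * sum(w^2)
  list(M = G + alpha * EW, G = G, EW = EW)
}

# cost and analytic gradient on a bare parameter vector
.costFn <- function(w, h, x, t, alpha) {
  a <- .forwardRaw(w, h, x)$a
  # stable cross-entropy of sigmoid(a): log(1 + exp(-|a|)) form
  G <- sum((1 - t) * a + log1p(exp(-abs(a))) + pmax(-a, 0))
  G + alpha * 0.5 * sum(w^2)
}

.gradFn <- function(w, h, x, t, alpha) {
  a <- .forwardRaw(w, h, x)$a
  y <- 1 / (1 + exp(-a))
  J <- .outputJacobian(w, h, x)
  as.vector(crossprod(J, y - t)) + alpha * w
}

# Gauss-Newton (outer-product) approximation of the data-term Hessian
.dataHessian <- function(w, h, x, t) {
  a <- .forwardRaw(w, h, x)$a
  y <- 1 / (1 + exp(-a))
  J <- .outputJacobian(w, h, x)
  crossprod(J * sqrt(y * (1 - y)))
}

#' Train a network with evidence-based weight decay
#'
#' Alternates (a) minimisation of M(w) = G + alpha E_W by BFGS with the
#' analytic gradient, and (b) evidence re-estimation
#' alpha <- gamma / (2 E_W), where gamma = sum(lambda / (lambda +
#' alpha)) over the eigenvalues of the Gauss-Newton data-term Hessian
#' at the minimum, until alpha changes by less than 1% or
#' \code{maxOuter} rounds are used. Deterministic for a fixed starting
#' model and data.
#'
#' @param model an initialised \code{\linkS4class{BNNModel}}.
#' @param x m x 3 training score matrix.
#' @param t binary training labels (1 = unhealed).
#' @param alpha0 starting weight decay.
#' @param maxOuter maximum re-estimation rounds.
#' @param maxit BFGS iteration cap per round.
#' @param reestimate set \code{FALSE} to keep alpha fixed at
#'   \code{alpha0}.
#' @return the trained model (slot \code{alpha} holds the final value).
#' @export
trainBNN <- function(model, x, t, alpha0 = 0.1, maxOuter = 20L,
                     maxit = 500L, reestimate = TRUE) {
  stopifnot(is(model, "BNNModel"), nrow(x) == length(t))
  h <- model@h
  w <- .packParams(model)
  alpha <- alpha0
  for (outer in seq_len(maxOuter)) {
    opt <- optim(w, .costFn, .gradFn, h = h, x = x, t = t,
                 alpha = alpha, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-12))
    if (!is.finite(opt$value))
      stop("non-finite cost during optimisation")
    w <- opt$par
    if (!reestimate) break
    EW <- 0.5 * sum(w^2)
    lam <- pmax(eigen(.dataHessian(w, h, x, t),
                      symmetric = TRUE, only.values = TRUE)$values, 0)
    gamma <- sum(lam / (lam + alpha))
    alphaNew <- if (EW > 1e-10) gamma / (2 * EW) else alpha
    if (!is.finite(alphaNew) || alphaNew <= 0) alphaNew <- alpha
    converged <- abs(alphaNew - alpha) < 0.01 * alpha
    alpha <- alphaNew
    if (converged) break
  }
  model <- .setParams(model, w)
  model@alpha <- alpha
  model@trained <- TRUE
  model
}

#' Log evidence of a trained network (Laplace approximation)
#'
#' ln Ev = -G - alpha E_W - 0.5 ln det A + (W/2) ln alpha, where
#' A = H_G + alpha I with H_G the Gauss-Newton data-term Hessian at the
#' minimum (its positive semi-definiteness stabilises the determinant
#' for tiny datasets) and W = 5h + 1. Eigenvalues of A are floored at
#' 1e-10 before the log determinant. Also returns the effective number
#' of well-determined parameters
#' gamma = sum(lambda / (lambda + alpha)) in [0, W].
#'
#' With \code{symmetryFactor = TRUE} the classical hidden-unit
#' mode-count ln(h!) + h ln 2 is added. It is off by default: weight
#' decay prunes surplus hidden units towards zero, and a pruned unit's
#' permutation "modes" coincide rather than being distinct posterior
#' modes, so the factor overcounts and makes the evidence grow
#' monotonically with width instead of trading fit against complexity.
#'
#' @param model a trained \code{\linkS4class{BNNModel}} at a local
#'   minimum of M.
#' @param x m x 3 training score matrix.
#' @param t binary training labels.
#' @param alpha weight decay (default the model's final value).
#' @param symmetryFactor add the ln(h!) + h ln 2 mode-count term.
#' @return list with \code{h}, \code{logEvidence}, \code{gamma},
#'   \code{alpha}, \code{G}, \code{EW}.
#' @export
logEvidence <- function(model, x, t, alpha = model@alpha,
                        symmetryFactor = FALSE) {
  stopifnot(is(model, "BNNModel"), alpha > 0)
  h <- model@h
  w <- .packParams(model)
  npar <- 5L * h + 1L
  cost <- bnnCost(model, x, t, alpha)
  lam <- pmax(eigen(.dataHessian(w, h, x, t),
                    symmetric = TRUE, only.values = TRUE)$values, 0)
  aEig <- pmax(lam + alpha, 1e-10)
  if (any(!is.finite(aEig)) || any(aEig <= 0))
    stop("regularised Hessian not positive definite after flooring")
  logEv <- -cost$G - alpha * cost$EW - 0.5 * sum(log(aEig)) +
    (npar / 2) * log(alpha)
  if (symmetryFactor) logEv <- logEv + lfactorial(h) + h * log(2)
  list(h = h, logEvidence = logEv,
       gamma = sum(lam / (lam + alpha)), alpha = alpha,
       G = cost$G, EW = cost$EW)
}

#' Select the hidden-layer width by maximum evidence
#'
#' For each candidate width, trains \code{restarts} networks from
#' distinct derived seeds, keeps the restart with the highest log
#' evidence, and returns the width with the global maximum (ties go to
#' the smaller width). A width whose restarts all fail is skipped with
#' a warning.
#'
#' @param x m x 3 training score matrix.
#' @param t binary training labels (1 = unhealed).
#' @param hRange candidate widths (default 1..9).
#' @param restarts random restarts per width (default 5).
#' @param seed master seed for the restart initialisations.
#' @param alpha0 starting weight decay.
#' @param maxOuter,maxit passed to \code{\link{trainBNN}}.
#' @param symmetryFactor passed to \code{\link{logEvidence}}.
#' @return list with \code{h} (selected width), \code{model} (its best
#'   trained network), and \code{evidence}, a data.frame over widths
#'   with columns \code{h}, \code{logEvidence}, \code{gamma},
#'   \code{alpha}, \code{G}, \code{EW}, \code{restartsUsed}.
#' @export
selectArchitecture <- function(x, t, hRange = 1:9, restarts = 5L,
                               seed = 1L, alpha0 = 0.1,
                               maxOuter = 20L, maxit = 500L,
                               symmetryFactor = FALSE) {
  rows <- list(); models <- list()
  for (h in hRange) {
    bestEv <- NULL; bestModel <- NULL; used <- 0L
    for (r in seq_len(restarts)) {
      fit <- tryCatch({
        m0 <- initNetwork(h, seed = deriveSeed(seed, h * 100L + r),
                          alpha = alpha0)
        m1 <- trainBNN(m0, x, t, alpha0 = alpha0,
                       maxOuter = maxOuter, maxit = maxit)
        list(model = m1,
             ev = logEvidence(m1, x, t, symmetryFactor = symmetryFactor))
      }, error = function(e) NULL)
      if (is.null(fit)) next
      used <- used + 1L
      if (is.null(bestEv) || fit$ev$logEvidence > bestEv$logEvidence) {
        bestEv <- fit$ev; bestModel <- fit$model
      }
    }
    if (is.null(bestEv)) {
      warning("all restarts failed for h = ", h, "; width skipped")
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(h = h, logEvidence = bestEv$logEvidence,
                 gamma = bestEv$gamma, alpha = bestEv$alpha,
                 G = bestEv$G, EW = bestEv$EW, restartsUsed = used)
    models[[as.character(h)]] <- bestModel
  }
  if (!length(rows)) stop("no architecture could be trained")
  evidence <- do.call(rbind, rows)
  best <- evidence$h[which.max(evidence$logEvidence)]  # first max: smaller h
  list(h = best, model = models[[as.character(best)]],
       evidence = evidence)
}

#' Predict healing labels from score vectors
#'
#' @param model a trained \code{\linkS4class{BNNModel}}.
#' @param scores m x 3 score matrix.
#' @param threshold decision threshold; a wound is labelled unhealed
#'   when its probability is at or above it (default 0.5).
#' @return data.frame with \code{probability} (of being unhealed) and
#'   \code{label}.
#' @export
predictBNN <- function(model, scores, threshold = 0.5) {
  if (!model@trained) stop("model is untrained")
  p <- bnnForward(model, scores)
  data.frame(probability = p,
             label = ifelse(p >= threshold, "unhealed", "healed"))
}

#' Serialise a network to JSON
#'
#' @param model a \code{\linkS4class{BNNModel}}.
#' @param path output file.
#' @param extra optional named list stored alongside the weights
#'   (e.g. evidence, seed, config) for provenance.
#' @return \code{path}, invisibly.
#' @export
writeBNNModel <- function(model, path, extra = list()) {
  obj <- c(list(w1 = model@w1, b1 = model@b1, w2 = model@w2,
                b2 = model@b2, h = model@h, alpha = model@alpha,
                trained = model@trained), extra)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a network from JSON
#'
#' @param path file written by \code{\link{writeBNNModel}}.
#' @return a \code{\linkS4class{BNNModel}}.
#' @export
readBNNModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("BNNModel", w1 = matrix(as.numeric(obj$w1), obj$h, 3L),
      b1 = as.numeric(obj$b1), w2 = as.numeric(obj$w2),
      b2 = as.numeric(obj$b2), h = as.integer(obj$h),
      alpha = obj$alpha, trained = isTRUE(obj$trained))
}
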