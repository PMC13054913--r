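# Gaussian process regression internals (squared-exponential ARD kernel +
# white noise), fitted by marginal-likelihood maximization with analytic
# gradients. Targets are standardized per region before fitting; all
# hyperparameters live on the log scale.

# squared-difference matrices per predictor, computed once per design
.sqDiffList <- function(X1, X2 = X1) {
  lapply(seq_len(ncol(X1)), function(d) outer(X1[, d], X2[, d], "-")^2)
}

.seKernel <- function(Dlist, theta) {
  sf2 <- exp(theta[1])
  d <- length(Dlist)
  E <- 0
  for (j in seq_len(d)) E <- E + Dlist[[j]] / exp(2 * theta[1 + j])
  sf2 * exp(-0.5 * E)
}

# negative log marginal likelihood and its gradient w.r.t. log-params
.gpNllGrad <- function(theta, Dlist, y) {
  n <- length(y)
  d <- length(Dlist)
  Kse <- .seKernel(Dlist, theta)
  sn2 <- exp(theta[d + 2])
  K <- Kse + diag(sn2, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(list(value = 1e10, grad = rep(0, d + 2)))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(L)
  # dnll/dtheta_j = -0.5 * tr((alpha alpha' - Kinv) dK/dtheta_j)
  A <- tcrossprod(alpha) - Kinv
  grad <- numeric(d + 2)
  grad[1] <- -0.5 * sum(A * Kse)
  for (j in seq_len(d))
    grad[1 + j] <- -0.5 * sum(A * (Kse * Dlist[[j]] /
                                     exp(2 * theta[1 + j])))
  grad[d + 2] <- -0.5 * sum(diag(A)) * sn2
  list(value = nll, grad = grad)
}

# fit one region; y raw, X standardized covariates
.gpFitRegion <- function(Dlist, y, nRestarts = 3L, seed = 1L) {
  yMean <- mean(y); ySd <- sd(y)
  if (ySd == 0) {
    return(list(constant = TRUE, yMean = yMean, ySd = 1,
                theta = c(log_sf2 = log(1e-12),
                          setNames(rep(0, length(Dlist)),
                                   paste0("log_l", seq_along(Dlist))),
                          log_sn2 = log(1e-12)),
                logLik = NA_real_))
  }
  ys <- (y - yMean) / ySd
  d <- length(Dlist)
  set.seed(seed)
  starts <- vector("list", nRestarts)
  starts[[1]] <- c(log(0.5), rep(0, d), log(0.5))
  if (nRestarts > 1)
    for (r in 2:nRestarts)
      starts[[r]] <- starts[[1]] + rnorm(d + 2, 0, 0.7)

  cache <- new.env()
  evalAt <- function(theta) {
    key <- paste(signif(theta, 12), collapse = ",")
    if (!identical(cache$key, key)) {
      cache$res <- .gpNllGrad(theta, Dlist, ys)
      cache$key <- key
    }
    cache$res
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, fn = function(th) evalAt(th)$value,
            gr = function(th) evalAt(th)$grad,
            method = "L-BFGS-B", lower = rep(-8, d + 2),
            upper = rep(8, d + 2), control = list(maxit = 100)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("GP hyperparameter optimization failed")
  theta <- setNames(best$par,
                    c("log_sf2", paste0("log_l", seq_len(d)), "log_sn2"))
  Kse <- .seKernel(Dlist, theta)
  K <- Kse + diag(exp(theta[["log_sn2"]]), length(ys))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  list(constant = FALSE, yMean = yMean, ySd = ySd, theta = theta,
       alpha = alpha, L = L, logLik = -best$value)
}

# predictive mean and latent variance (original units) at new covariates
.gpPredictRegion <- function(model, DcrossList, nNew) {
  if (isTRUE(model$constant)) {
    return(list(mean = rep(model$yMean, nNew),
                var = rep(0, nNew),
                noiseVar = 1e-6))
  }
  Ks <- .seKernel(DcrossList, model$theta)   # n_train x n_new
  mu <- drop(crossprod(Ks, model$alpha))
  v <- forwardsolve(t(model$L), Ks)
  latentVar <- pmax(exp(model$theta[["log_sf2"]]) - colSums(v^2), 0)
  list(mean = model$yMean + model$ySd * mu,
       var = model$ySd^2 * latentVar,
       noiseVar = model$ySd^2 * exp(model$theta[["log_sn2"]]))
}
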