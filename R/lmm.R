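# Random-intercept linear model by one-dimensional variance profiling.
#
# Model: y = X beta + b[subject] + e, b ~ N(0, sigma_b^2), e ~ N(0, sigma^2).
# With theta = sigma_b^2 / sigma^2 the covariance is sigma^2 (I + theta Z Z'),
# block-diagonal over subjects, and (I + theta J_k)^{-1} has the closed form
# I - theta/(1 + theta n_k) J_k. The profiled (ML) log-likelihood is then a
# function of theta alone and is maximised by a bounded 1-D search.
fit_random_intercept <- function(y, X, subject) {
  subject <- as.factor(subject)
  groups <- split(seq_along(y), subject)
  n <- length(y)
  p <- ncol(X)

  gls_pieces <- function(theta) {
    XtVX <- matrix(0, p, p)
    XtVy <- numeric(p)
    ytVy <- 0
    logdet <- 0
    for (idx in groups) {
      nk <- length(idx)
      ck <- theta / (1 + theta * nk)
      Xk <- X[idx, , drop = FALSE]
      yk <- y[idx]
      sx <- colSums(Xk)
      sy <- sum(yk)
      XtVX <- XtVX + crossprod(Xk) - ck * tcrossprod(sx)
      XtVy <- XtVy + crossprod(Xk, yk)[, 1] - ck * sx * sy
      ytVy <- ytVy + sum(yk^2) - ck * sy^2
      logdet <- logdet + log1p(theta * nk)
    }
    list(XtVX = XtVX, XtVy = XtVy, ytVy = ytVy, logdet = logdet)
  }

  floor_ll <- -sqrt(.Machine$double.xmax)   # finite, keeps optimize quiet
  prof_loglik <- function(u) {
    theta <- exp(u)
    gp <- gls_pieces(theta)
    beta <- tryCatch(solve(gp$XtVX, gp$XtVy), error = function(e) NULL)
    if (is.null(beta)) return(floor_ll)
    rss <- gp$ytVy - 2 * sum(beta * gp$XtVy) + sum(beta * (gp$XtVX %*% beta))
    if (rss <= 0) return(floor_ll)
    sigma2 <- rss / n
    -n / 2 * (log(2 * pi * sigma2) + 1) - gp$logdet / 2
  }

  opt <- tryCatch(stats::optimize(prof_loglik, interval = c(-15, 10),
                                  maximum = TRUE),
                  error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective) ||
      opt$objective <= floor_ll) {
    return(list(converged = FALSE))
  }
  theta <- exp(opt$maximum)
  gp <- gls_pieces(theta)
  beta <- solve(gp$XtVX, gp$XtVy)
  rss <- gp$ytVy - 2 * sum(beta * gp$XtVy) + sum(beta * (gp$XtVX %*% beta))
  sigma2 <- rss / n
  vcov_beta <- sigma2 * solve(gp$XtVX)
  list(converged = TRUE,
       beta = beta, vcov = vcov_beta,
       sigma = sqrt(sigma2), sigma_b = sqrt(theta * sigma2),
       theta = theta, loglik = opt$objective,
       n = n, n_groups = length(groups))
}

# subject-demeaned OLS fallback: removes intercepts exactly, loses the
# intercept and any between-subject information
fit_demeaned_ols <- function(y, X, subject) {
  subject <- as.factor(subject)
  dm <- function(v) v - stats::ave(v, subject)
  yd <- dm(y)
  keep <- which(colnames(X) != "(Intercept)")
  Xd <- apply(X[, keep, drop = FALSE], 2, dm)
  fit <- stats::lm.fit(Xd, yd)
  p <- length(keep)
  dfres <- length(y) - p - nlevels(subject)
  sigma2 <- sum(fit$residuals^2) / dfres
  XtX_inv <- chol2inv(chol(crossprod(Xd)))
  beta <- rep(NA_real_, ncol(X))
  names(beta) <- colnames(X)
  beta[keep] <- fit$coefficients
  vcov <- matrix(NA_real_, ncol(X), ncol(X),
                 dimnames = list(colnames(X), colnames(X)))
  vcov[keep, keep] <- sigma2 * XtX_inv
  list(converged = TRUE, beta = beta, vcov = vcov,
       sigma = sqrt(sigma2), sigma_b = NA_real_,
       n = length(y), n_groups = nlevels(subject))
}
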