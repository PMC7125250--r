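# Independent reference implementations used as oracles. These deliberately
# avoid the package's own likelihood code paths.

# naive conditional log-likelihood (observation density + random-effect prior)
naive_cll <- function(times, y, th, eta, w2, sg) {
  f <- th[1] * exp(eta[1]) *
    (exp(th[2] * exp(eta[2]) * times) + exp(-th[3] * exp(eta[3]) * times) - 1)
  ll <- sum(-0.5 * log(2 * pi * sg^2) - (y - f)^2 / (2 * sg^2))
  for (k in 1:3) {
    if (w2[k] > 1e-10)
      ll <- ll - 0.5 * log(2 * pi * w2[k]) - eta[k]^2 / (2 * w2[k])
  }
  ll
}

# adaptive Gauss-Hermite marginal log-likelihood for one lesion: tensor-grid
# quadrature centred at the conditional mode and scaled by the curvature
agq_logmarg <- function(times, y, th, w2, sg, n_nodes = 64) {
  free <- which(w2 > 1e-10)
  d <- length(free)
  negll <- function(ef) {
    e <- numeric(3); e[free] <- ef
    -naive_cll(times, y, th, e, w2, sg)
  }
  if (d == 0) return(-negll(numeric(0)))
  opt <- stats::optim(rep(0, d), negll, method = "BFGS")
  H <- stats::optimHess(opt$par, negll)
  L <- t(chol(solve(H)))
  gh <- pracma::gaussHermite(n_nodes)
  Z <- as.matrix(expand.grid(rep(list(gh$x), d)))
  lw <- rowSums(as.matrix(expand.grid(rep(list(log(gh$w)), d))))
  E <- matrix(0, nrow(Z), 3)
  E[, free] <- matrix(opt$par, nrow(Z), d, byrow = TRUE) +
    sqrt(2) * Z %*% t(L)
  a <- th[1] * exp(E[, 1]); b <- th[2] * exp(E[, 2]); cc <- th[3] * exp(E[, 3])
  ll <- rep(0, nrow(Z))
  for (j in seq_along(times)) {
    f <- a * (exp(b * times[j]) + exp(-cc * times[j]) - 1)
    ll <- ll - 0.5 * log(2 * pi * sg^2) - (y[j] - f)^2 / (2 * sg^2)
  }
  for (k in seq_along(free))
    ll <- ll - 0.5 * log(2 * pi * w2[free[k]]) - E[, free[k]]^2 / (2 * w2[free[k]])
  lse <- lw + ll + rowSums(Z^2)
  m <- max(lse)
  (d / 2) * log(2) + sum(log(diag(L))) + m + log(sum(exp(lse - m)))
}

agq_ofv <- function(data, population, operator = "LOCAL", n_nodes = 64) {
  d <- tgiagree:::extract_operator(data, operator)
  th <- c(population$theta$ts0, population$theta$kg, population$theta$kd)
  -2 * sum(vapply(seq_along(d$ids), function(i)
    agq_logmarg(d$times[[i]], d$y[[i]], th, as.numeric(population$omega2),
                population$sigma_add, n_nodes), 0))
}
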