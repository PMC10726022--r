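# Independent oracles, deliberately implemented with different algorithms
# than the package code paths they check.

# Monte-Carlo gene-dropping estimate of the additive relationship matrix:
# drop unique founder alleles through the pedigree many times; A_ij is the
# average allele-sharing count over ordered allele pairs divided by 2.
# Returns the estimate and its per-entry Monte-Carlo standard error.
gene_drop_oracle <- function(ped, nrep = 3000, seed = 99) {
  set.seed(seed)
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  acc <- matrix(0, n, n)
  acc2 <- matrix(0, n, n)
  for (r in seq_len(nrep)) {
    al <- matrix(0L, n, 2)
    nal <- 0L
    for (i in seq_len(n)) {
      al[i, 1] <- if (is.na(si[i])) (nal <- nal + 1L) else
        al[si[i], sample.int(2, 1)]
      al[i, 2] <- if (is.na(di[i])) (nal <- nal + 1L) else
        al[di[i], sample.int(2, 1)]
    }
    E <- (outer(al[, 1], al[, 1], "==") + outer(al[, 1], al[, 2], "==") +
          outer(al[, 2], al[, 1], "==") + outer(al[, 2], al[, 2], "==")) / 2
    acc <- acc + E
    acc2 <- acc2 + E^2
  }
  est <- acc / nrep
  se <- sqrt(pmax(acc2 / nrep - est^2, 0) / nrep)
  dimnames(est) <- dimnames(se) <- list(ped$animal, ped$animal)
  list(A = est, se = se)
}

# Dense-matrix restricted log-likelihood by direct V inversion.
# sigma2 = c(a, m, e); Km = NULL for the no-maternal model.
dense_reml_loglik <- function(sigma2, y, X, Ka, Km = NULL) {
  n <- length(y)
  V <- sigma2[1] * Ka + sigma2[3] * diag(n)
  if (!is.null(Km)) V <- V + sigma2[2] * Km
  Vi <- solve(V)
  p <- ncol(X)
  if (p > 0) {
    XVX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XVX, crossprod(X, Vi))
    ldx <- as.numeric(determinant(XVX, logarithm = TRUE)$modulus)
  } else {
    P <- Vi
    ldx <- 0
  }
  -0.5 * (as.numeric(determinant(V, logarithm = TRUE)$modulus) + ldx +
          sum(y * (P %*% y)) + (n - p) * log(2 * pi))
}

# Numeric search for the REML optimum over log-variances: multi-start
# Nelder-Mead (REML surfaces at tiny n often have boundary optima, where a
# single start can stall)
dense_reml_oracle <- function(y, X, Ka, Km = NULL) {
  v <- var(y)
  f <- function(lt) {
    s <- exp(lt)
    sig <- if (is.null(Km)) c(s[1], 0, s[2]) else s
    -dense_reml_loglik(sig, y, X, Ka, Km)
  }
  starts <- list(c(1, 1, 1) / 3, c(0.6, 0.1, 0.3), c(0.1, 0.6, 0.3),
                 c(0.05, 0.05, 0.9))
  best <- NULL
  for (st in starts) {
    par0 <- log(v * (if (is.null(Km)) st[c(1, 3)] else st))
    o <- stats::optim(par0, f, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  s <- exp(best$par)
  list(sigma2 = if (is.null(Km)) c(a = s[1], m = NA, e = s[2]) else
         c(a = s[1], m = s[2], e = s[3]),
       loglik = -best$value)
}

# GLS fixed effects and BLUP through direct V inversion:
# beta = (X'Vi X)^-1 X'Vi y;  u = s2u A Zu' Vi (y - X beta)
gls_blup_oracle <- function(y, X, A, ia, idam, sigma2) {
  n <- length(y)
  q <- nrow(A)
  Za <- matrix(0, n, q); Za[cbind(seq_len(n), ia)] <- 1
  V <- sigma2[["a"]] * A[ia, ia] + sigma2[["e"]] * diag(n)
  Zm <- NULL
  if (!is.null(idam)) {
    Zm <- matrix(0, n, q); Zm[cbind(seq_len(n), idam)] <- 1
    V <- V + sigma2[["m"]] * A[idam, idam]
  }
  Vi <- solve(V)
  beta <- if (ncol(X) > 0)
    solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y)) else
    matrix(0, 0, 1)
  r <- y - if (ncol(X) > 0) X %*% beta else 0
  a <- sigma2[["a"]] * A %*% t(Za) %*% Vi %*% r
  m <- if (!is.null(idam)) sigma2[["m"]] * A %*% t(Zm) %*% Vi %*% r
  list(beta = as.vector(beta), a = as.vector(a),
       m = if (!is.null(m)) as.vector(m))
}

# least-square means by brute force: average the model prediction over the
# full factorial grid of the other factors
lsmeans_oracle <- function(fit, fac) {
  d <- fit$data
  grid <- expand.grid(lapply(fit$factors, function(f) levels(d[[f]])),
                      stringsAsFactors = FALSE)
  names(grid) <- fit$factors
  sapply(levels(d[[fac]]), function(lv) {
    g <- grid
    g[[fac]] <- lv
    mean(predict(fit$lm, newdata = g))
  })
}
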