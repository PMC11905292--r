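# Vectorised bounded Levenberg-Marquardt across voxels.
#
# Minimises, independently for every voxel v (rows),
#   sum_t w[v,t] (obs[v,t] - model(par)[v,t])^2
#     + sum_p prior_prec[v,p] (par[v,p] - prior_mean[v,p])^2
# subject to box bounds. All voxels are iterated simultaneously with
# per-voxel damping; the Jacobian is taken by forward differences and the
# damped normal equations are solved by a Cholesky factorisation vectorised
# across voxels (with Jacobi scaling, since likelihood weights and prior
# precisions can differ by many orders of magnitude). This is the workhorse
# behind the saturation-recovery, kinetic and PVEc fits, where 10^3-10^4
# small independent problems make per-voxel nls calls impractical.

# Cholesky factor of the Jacobi-scaled, damped normal matrix.
# A: (V,P,P); lambda: length-V damping. Returns L (V,P,P) and scale s (V,P).
vchol_factor <- function(A, lambda) {
  V <- dim(A)[1]; P <- dim(A)[2]
  s <- matrix(0, V, P)
  for (p in seq_len(P)) s[, p] <- sqrt(pmax(A[, p, p], 1e-300))
  M <- A
  for (p in seq_len(P)) for (q in seq_len(P))
    M[, p, q] <- A[, p, q] / (s[, p] * s[, q])
  for (p in seq_len(P)) M[, p, p] <- M[, p, p] * (1 + lambda) + 1e-10
  L <- array(0, c(V, P, P))
  for (p in seq_len(P)) {
    acc <- M[, p, p]
    if (p > 1) for (k in seq_len(p - 1)) acc <- acc - L[, p, k]^2
    L[, p, p] <- sqrt(pmax(acc, 1e-30))
    if (p < P) for (q in (p + 1):P) {
      acc <- M[, q, p]
      if (p > 1) for (k in seq_len(p - 1)) acc <- acc - L[, q, k] * L[, p, k]
      L[, q, p] <- acc / L[, p, p]
    }
  }
  list(L = L, s = s)
}

# Solve the factored system for right-hand sides b (V,P); returns (V,P).
vchol_solve <- function(fac, b) {
  L <- fac$L; s <- fac$s
  V <- dim(L)[1]; P <- dim(L)[2]
  bs <- b / s
  y <- matrix(0, V, P)
  for (p in seq_len(P)) {
    acc <- bs[, p]
    if (p > 1) for (k in seq_len(p - 1)) acc <- acc - L[, p, k] * y[, k]
    y[, p] <- acc / L[, p, p]
  }
  x <- matrix(0, V, P)
  for (p in rev(seq_len(P))) {
    acc <- y[, p]
    if (p < P) for (k in (p + 1):P) acc <- acc - L[, k, p] * x[, k]
    x[, p] <- acc / L[, p, p]
  }
  x / s
}

vlm_fit <- function(model, x0, lower, upper, obs, w,
                    prior_mean = NULL, prior_prec = NULL,
                    tol = 1e-8, maxit = 50L, want_cov = FALSE) {
  x0 <- as.matrix(x0)
  V <- nrow(x0); P <- ncol(x0)
  lo <- matrix(lower, V, P, byrow = TRUE)
  hi <- matrix(upper, V, P, byrow = TRUE)
  if (is.null(prior_mean)) prior_mean <- matrix(0, V, P)
  if (is.null(prior_prec)) prior_prec <- matrix(0, V, P)
  par <- pmin(pmax(x0, lo), hi)

  objective <- function(p) {
    r <- obs - model(p)
    rowSums(w * r * r) + rowSums(prior_prec * (p - prior_mean)^2)
  }
  normal_eq <- function(par, pred, res) {
    J <- vector("list", P)
    for (p in seq_len(P)) {
      h <- 1e-6 * (abs(par[, p]) + 1e-3)
      pp <- par; pp[, p] <- pp[, p] + h
      J[[p]] <- (model(pp) - pred) / h
    }
    A <- array(0, c(V, P, P))
    b <- matrix(0, V, P)
    for (p in seq_len(P)) {
      b[, p] <- rowSums(w * J[[p]] * res) -
        prior_prec[, p] * (par[, p] - prior_mean[, p])
      for (q in p:P) {
        apq <- rowSums(w * J[[p]] * J[[q]])
        A[, p, q] <- apq
        A[, q, p] <- apq
      }
      A[, p, p] <- A[, p, p] + prior_prec[, p]
    }
    list(A = A, b = b)
  }

  obj <- objective(par)
  lambda <- rep(1e-3, V)
  converged <- rep(FALSE, V)
  iter <- 0L
  A_last <- NULL

  for (iter in seq_len(maxit)) {
    if (all(converged)) break
    pred <- model(par)
    ne <- normal_eq(par, pred, obs - pred)
    A_last <- ne$A
    step <- vchol_solve(vchol_factor(ne$A, lambda), ne$b)
    step[!is.finite(step)] <- 0
    cand <- pmin(pmax(par + step, lo), hi)
    obj_new <- objective(cand)
    better <- !is.na(obj_new) & (obj_new <= obj + 1e-14)
    improve <- better & !converged
    rel <- abs(cand - par) / (abs(par) + 1e-3)
    relmax <- rel[, 1]
    for (p in seq_len(P)[-1]) relmax <- pmax(relmax, rel[, p])
    small <- relmax < tol
    par[improve, ] <- cand[improve, , drop = FALSE]
    obj[improve] <- obj_new[improve]
    lambda[improve] <- pmax(lambda[improve] * 0.3, 1e-12)
    reject <- !better & !converged
    lambda[reject] <- pmin(lambda[reject] * 10, 1e12)
    converged <- converged | (improve & small) | (reject & lambda >= 1e9)
  }

  out <- list(par = par, objective = obj, converged = converged, niter = iter)
  if (want_cov) {
    # Gaussian posterior covariance diagonal at the solution
    pred <- model(par)
    ne <- normal_eq(par, pred, obs - pred)
    fac <- vchol_factor(ne$A, rep(0, V))
    covd <- matrix(NA_real_, V, P)
    for (p in seq_len(P)) {
      e <- matrix(0, V, P); e[, p] <- 1
      covd[, p] <- vchol_solve(fac, e)[, p]
    }
    out$cov_diag <- covd
  }
  out
}
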