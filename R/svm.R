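# Weighted C-SVC with RBF kernel, solved by SMO (maximal-violating-pair
# working-set selection on the standard dual:
#   min 1/2 a' Q a - e' a,  s.t. y' a = 0, 0 <= a_i <= C_i,
# Q_ij = y_i y_j K_ij). Per-sample box constraints C_i carry the class
# weights. Small-n solver; no shrinking or caching needed at this scale.

#' @noRd
rbf_kernel <- function(x, z, gamma) {
  x <- as.matrix(x); z <- as.matrix(z)
  d2 <- outer(rowSums(x^2), rowSums(z^2), "+") - 2 * tcrossprod(x, z)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# y in {-1, +1}; Cvec per-sample upper bounds
#' @noRd
smo_solve <- function(K, y, Cvec, tol = 1e-3, max_iter = 100000L) {
  n <- length(y)
  Q <- K * tcrossprod(y)
  alpha <- numeric(n)
  grad <- rep(-1, n)          # grad = Q a - e
  for (iter in seq_len(max_iter)) {
    vals <- -y * grad
    up <- (y > 0 & alpha < Cvec - 1e-12) | (y < 0 & alpha > 1e-12)
    low <- (y < 0 & alpha < Cvec - 1e-12) | (y > 0 & alpha > 1e-12)
    if (!any(up) || !any(low)) break
    i <- which(up)[which.max(vals[up])]
    j <- which(low)[which.min(vals[low])]
    if (vals[i] - vals[j] < tol) break
    # two-variable subproblem on (i, j) with box clipping
    s <- y[i] * y[j]
    f <- y * (grad + 1)        # decision values without bias
    Ei <- f[i] - y[i]; Ej <- f[j] - y[j]
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta <= 1e-12) eta <- 1e-12
    aj_new <- alpha[j] + y[j] * (Ei - Ej) / eta
    if (s < 0) {
      L <- max(0, alpha[j] - alpha[i])
      H <- min(Cvec[j], Cvec[i] + alpha[j] - alpha[i])
    } else {
      L <- max(0, alpha[i] + alpha[j] - Cvec[i])
      H <- min(Cvec[j], alpha[i] + alpha[j])
    }
    aj_new <- min(max(aj_new, L), H)
    ai_new <- alpha[i] + s * (alpha[j] - aj_new)
    dai <- ai_new - alpha[i]; daj <- aj_new - alpha[j]
    if (abs(dai) < 1e-14 && abs(daj) < 1e-14) break
    grad <- grad + Q[, i] * dai + Q[, j] * daj
    alpha[i] <- ai_new; alpha[j] <- aj_new
  }
  # bias from free support vectors, else from the bound midpoint
  f <- y * (grad + 1)
  free <- alpha > 1e-8 & alpha < Cvec - 1e-8
  b <- if (any(free)) {
    mean(y[free] - f[free])
  } else {
    vals <- -y * grad
    up <- (y > 0 & alpha < Cvec - 1e-12) | (y < 0 & alpha > 1e-12)
    low <- (y < 0 & alpha < Cvec - 1e-12) | (y > 0 & alpha > 1e-12)
    ub <- if (any(up)) max(vals[up]) else 0
    lb <- if (any(low)) min(vals[low]) else 0
    (ub + lb) / 2
  }
  list(alpha = alpha, b = b)
}

# fit a weighted RBF C-SVC on an already-preprocessed matrix
#' @noRd
svm_core_fit <- function(X, y01, C, gamma, weights) {
  y <- ifelse(y01 == 1, 1, -1)
  Cvec <- C * weights[as.character(y01)]
  K <- rbf_kernel(X, X, gamma)
  sol <- smo_solve(K, y, Cvec)
  sv <- sol$alpha > 1e-8
  list(sv_x = X[sv, , drop = FALSE], sv_coef = (sol$alpha * y)[sv],
       b = sol$b, gamma = gamma)
}

#' @noRd
svm_core_decision <- function(core, X) {
  K <- rbf_kernel(X, core$sv_x, core$gamma)
  as.numeric(K %*% core$sv_coef + core$b)
}
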