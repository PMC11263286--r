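# Random-intercept logistic mixed model: maximum likelihood with a Laplace
# approximation to the integrated likelihood (optionally refined by adaptive
# Gauss-Hermite quadrature), Wald inference.

# Gauss-Hermite nodes/weights for integrals against exp(-z^2), via the
# Golub-Welsch eigendecomposition of the Jacobi matrix.
gauss_hermite <- function(k) {
  if (k == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(k - 1) / 2)
  J <- diag(0, k)
  J[cbind(1:(k - 1), 2:k)] <- off
  J[cbind(2:k, 1:(k - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Per-group posterior modes of the random intercepts by Newton iteration,
# simultaneously over all groups.
glmm_modes <- function(eta0, y, gi, J, s2, tol = 1e-10, maxit = 50) {
  b <- rep(0, J)
  for (i in seq_len(maxit)) {
    p <- stats::plogis(eta0 + b[gi])
    grad <- rowsum(y - p, gi)[, 1] - b / s2
    W <- rowsum(p * (1 - p), gi)[, 1] + 1 / s2
    step <- grad / W
    # halve overly large steps to stay in the concave basin
    step <- sign(step) * pmin(abs(step), 5)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  p <- stats::plogis(eta0 + b[gi])
  list(b = b, H = rowsum(p * (1 - p), gi)[, 1] + 1 / s2)
}

# Marginal log-likelihood at (beta, log sigma); agq = 1 is Laplace.
glmm_loglik <- function(par, X, y, gi, J, agq = 1) {
  beta <- par[-length(par)]
  s2 <- exp(2 * par[length(par)])
  eta0 <- as.numeric(X %*% beta)
  m <- glmm_modes(eta0, y, gi, J, s2)
  h <- function(b) { # per-group joint log-density (data + prior), vector J
    eta <- eta0 + b[gi]
    log1pe <- pmax(eta, 0) + log1p(exp(-abs(eta)))  # stable log(1 + e^eta)
    rowsum(y * eta - log1pe, gi)[, 1] -
      b^2 / (2 * s2) - 0.5 * log(2 * pi * s2)
  }
  if (agq <= 1) {
    sum(h(m$b)) + J * 0.5 * log(2 * pi) - 0.5 * sum(log(m$H))
  } else {
    gh <- gauss_hermite(agq)
    sd_j <- sqrt(2 / m$H)
    h0 <- h(m$b)
    acc <- matrix(NA_real_, J, agq)
    for (q in seq_len(agq)) {
      bq <- m$b + sd_j * gh$nodes[q]
      acc[, q] <- h(bq) - h0 + gh$nodes[q]^2 + log(gh$weights[q])
    }
    mx <- apply(acc, 1, max)
    sum(h0 + log(sd_j) - 0.5 * log(pi) + mx +
          log(rowSums(exp(acc - mx))) + 0.5 * log(pi))
  }
}

#' Fit a random-intercept logistic mixed model
#'
#' Maximum-likelihood estimation of a binary-response model
#' `y ~ fixed + (1 | group)` with logit link. The random intercept is
#' integrated out with a Laplace approximation (the per-group posterior
#' modes are found by Newton iteration); setting `agq > 1` refines the
#' integral by adaptive Gauss-Hermite quadrature centred on those modes.
#' Fixed-effect columns are standardized internally for a well-conditioned
#' optimization and transformed back. Inference is Wald (z) on the observed
#' information.
#'
#' @param formula e.g. `success ~ D * W + (1 | subject)`.
#' @param data data.frame; the response may be logical or 0/1.
#' @param agq number of adaptive Gauss-Hermite nodes (1 = Laplace).
#' @return a `mixed_fit` (family `"binomial"`) with Wald coefficient table,
#'   `sigma2_subject`, log-likelihood and convergence information.
#' @export
fit_glmm_logistic <- function(formula, data, agq = 1) {
  pf <- parse_mixed_formula(formula)
  vars <- c(all.vars(pf$fixed), pf$group)
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), ,
               drop = FALSE]
  mf <- stats::model.frame(pf$fixed, data)
  X <- stats::model.matrix(pf$fixed, mf)
  y <- as.numeric(stats::model.response(mf))
  if (!all(y %in% c(0, 1)))
    stop_domain("fit_glmm_logistic: response must be binary")
  g <- factor(data[[pf$group]])
  gi <- as.integer(g); J <- nlevels(g)
  if (J < 2) stop_domain("fit_glmm_logistic: need >= 2 groups")
  p <- ncol(X)
  # standardize non-intercept columns
  has_int <- colnames(X)[1] == "(Intercept)"
  ctr <- rep(0, p); scl <- rep(1, p)
  if (p > 1) {
    idx <- if (has_int) 2:p else 1:p
    ctr[idx] <- colMeans(X[, idx, drop = FALSE])
    scl[idx] <- pmax(apply(X[, idx, drop = FALSE], 2, stats::sd), 1e-12)
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  start <- tryCatch(
    stats::glm.fit(Xs, y, family = stats::binomial())$coefficients,
    error = function(e) rep(0, p))
  start[!is.finite(start)] <- 0
  par0 <- c(start, 0)   # log sigma starts at 0 (sigma = 1)
  negll <- function(par) -glmm_loglik(par, Xs, y, gi, J, agq)
  opt <- stats::optim(par0, negll, method = "L-BFGS-B",
                      lower = c(rep(-Inf, p), log(1e-4)),
                      upper = c(rep(Inf, p), log(100)),
                      control = list(maxit = 300, factr = 1e4))
  if (opt$convergence != 0)
    stop_domain("fit_glmm_logistic did not converge (code %d): %s",
                opt$convergence, opt$message)
  if (any(abs(opt$par[1:p]) > 30))
    stop_domain("fit_glmm_logistic: diverging coefficients suggest complete separation")
  sigma <- exp(opt$par[p + 1])
  hs <- pmax(1e-3 * abs(opt$par), 1e-4)
  H <- num_hessian(negll, opt$par, hs)
  vcov_all <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, p + 1, p + 1))
  # back-transform: beta = M beta_s
  M <- diag(1 / scl)
  if (has_int) { M[1, 1] <- 1; M[1, -1] <- -ctr[-1] / scl[-1] }
  beta <- as.numeric(M %*% opt$par[1:p])
  vcov_beta <- M %*% vcov_all[1:p, 1:p] %*% t(M)
  se <- sqrt(pmax(diag(vcov_beta), 0))
  se[se == 0] <- NA_real_
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  coef_tab <- data.frame(term = colnames(X), estimate = beta, se = se,
                         df = NA_real_, statistic = z, p = pval,
                         row.names = NULL, stringsAsFactors = FALSE)
  structure(list(formula = formula, family = "binomial",
                 method = if (agq <= 1) "Laplace" else sprintf("AGQ%d", agq),
                 coefficients = coef_tab,
                 beta = stats::setNames(beta, colnames(X)),
                 vcov_beta = vcov_beta,
                 sigma2_subject = sigma^2, sigma2_resid = pi^2 / 3,
                 logLik = -opt$value,
                 fitted_fixed = as.numeric(X %*% beta),
                 singular = sigma < 1e-3, converged = TRUE,
                 n = length(y), n_groups = J,
                 terms = stats::terms(pf$fixed), model_frame = mf,
                 group = pf$group),
            class = "mixed_fit")
}
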