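# Random-intercept linear mixed model: profiled REML over the
# subject-to-residual variance ratio, GLS fixed effects, Satterthwaite
# degrees of freedom. Written against the closed-form inverse of
# V_j = sigma_e^2 I + sigma_b^2 J available for a single grouping factor.

# Split `y ~ fixed + (1 | group)` into the fixed formula and the group name.
parse_mixed_formula <- function(formula) {
  if (length(formula) != 3)
    stop_domain("model formula must have a response")
  terms_list <- list()
  collect <- function(e) {
    if (is.call(e) && identical(e[[1]], as.name("+"))) {
      collect(e[[2]]); collect(e[[3]])
    } else terms_list[[length(terms_list) + 1]] <<- e
  }
  collect(formula[[3]])
  is_ran <- vapply(terms_list, function(e)
    is.call(e) && identical(e[[1]], as.name("(")) &&
      is.call(e[[2]]) && identical(e[[2]][[1]], as.name("|")), logical(1))
  if (sum(is_ran) != 1)
    stop_domain("exactly one random term (1 | group) is required")
  bar <- terms_list[is_ran][[1]][[2]]
  if (deparse(bar[[2]]) != "1")
    stop_domain("only random intercepts (1 | group) are supported")
  fixed_terms <- vapply(terms_list[!is_ran], deparse, character(1))
  if (length(fixed_terms) == 0) fixed_terms <- "1"
  fixed <- stats::reformulate(fixed_terms, response = formula[[2]])
  environment(fixed) <- environment(formula)
  list(fixed = fixed, group = deparse(bar[[3]]))
}

# REML log-likelihood of the random-intercept model at variance components
# sigma = (sb2, se2), using per-group sufficient statistics.
lmm_reml_loglik <- function(sb2, se2, ss) {
  sb2 <- max(sb2, 0); se2 <- max(se2, 1e-300)
  k <- sb2 / (se2 + ss$n_j * sb2)
  XtViX <- (ss$XtX - crossprod(ss$Sx * sqrt(k))) / se2
  XtViy <- (ss$Xty - colSums(ss$Sx * (k * ss$Sy))) / se2
  yViy <- (ss$yty - sum(k * ss$Sy^2)) / se2
  beta <- solve(XtViX, XtViy)
  rVr <- yViy - sum(beta * XtViy)
  logdetV <- (ss$n - length(ss$n_j)) * log(se2) +
    sum(log(se2 + ss$n_j * sb2))
  -0.5 * (logdetV + determinant(XtViX)$modulus[1] + rVr +
            (ss$n - ss$p) * log(2 * pi))
}

#' Fit a random-intercept linear mixed model
#'
#' Estimates `y ~ fixed + (1 | group)` by restricted maximum likelihood. The
#' REML criterion is profiled down to a bounded scalar search over the log
#' variance ratio `theta = sigma_b^2 / sigma_e^2` (tolerance 1e-10); fixed
#' effects are the generalized-least-squares solution at the optimum.
#' Inference uses Satterthwaite degrees of freedom computed from the numeric
#' Hessian of the REML log-likelihood in the two variance components. A fit
#' driven to `sigma_b^2 = 0` is reported as singular, not an error, and
#' reduces to ordinary least squares.
#'
#' @param formula model formula, e.g. `MT ~ ID + (1 | subject)`.
#' @param data data.frame; rows with missing values in the used variables
#'   are dropped.
#' @return object of class `mixed_fit` with coefficient table (estimate, SE,
#'   Satterthwaite df, t, p), variance components, conditional-R2 inputs and
#'   convergence information.
#' @export
fit_lmm <- function(formula, data) {
  pf <- parse_mixed_formula(formula)
  vars <- c(all.vars(pf$fixed), pf$group)
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), ,
               drop = FALSE]
  mf <- stats::model.frame(pf$fixed, data)
  X <- stats::model.matrix(pf$fixed, mf)
  y <- stats::model.response(mf)
  g <- factor(data[[pf$group]])
  n <- length(y); p <- ncol(X)
  if (nlevels(g) < 2) stop_domain("fit_lmm: need >= 2 groups")
  ss <- list(XtX = crossprod(X), Xty = crossprod(X, y)[, 1],
             yty = sum(y^2), Sx = rowsum(X, g), Sy = rowsum(y, g)[, 1],
             n_j = as.numeric(table(g)), n = n, p = p)
  # profiled REML criterion in log(theta)
  crit <- function(lt) {
    th <- exp(lt)
    k <- th / (1 + ss$n_j * th)
    XtViX <- ss$XtX - crossprod(ss$Sx * sqrt(k))
    XtViy <- ss$Xty - colSums(ss$Sx * (k * ss$Sy))
    yViy <- ss$yty - sum(k * ss$Sy^2)
    beta <- solve(XtViX, XtViy)
    rVr <- yViy - sum(beta * XtViy)
    sum(log(1 + ss$n_j * th)) + determinant(XtViX)$modulus[1] +
      (n - p) * log(rVr)
  }
  opt <- stats::optimize(crit, c(log(1e-8), log(1e8)), tol = 1e-10)
  theta <- exp(opt$minimum)
  if (crit(log(1e-8)) < opt$objective) theta <- 1e-8  # boundary beats interior
  k <- theta / (1 + ss$n_j * theta)
  XtViX <- ss$XtX - crossprod(ss$Sx * sqrt(k))
  XtViy <- ss$Xty - colSums(ss$Sx * (k * ss$Sy))
  yViy <- ss$yty - sum(k * ss$Sy^2)
  beta <- solve(XtViX, XtViy)
  rVr <- yViy - sum(beta * XtViy)
  se2 <- as.numeric(rVr) / (n - p)
  sb2 <- theta * se2
  vcov_beta <- solve(XtViX) * se2
  singular <- theta <= 1e-6
  # Satterthwaite: df_k = 2 f^2 / (g' A g), f = Var(beta_k) as a function of
  # the variance components, A = asymptotic covariance of their REML
  # estimates (inverse observed information).
  fvar <- function(s) {
    s <- pmax(s, c(0, 1e-300))
    kk <- s[1] / (s[2] + ss$n_j * s[1])
    diag(solve((ss$XtX - crossprod(ss$Sx * sqrt(kk))) / s[2]))
  }
  sig <- c(sb2, se2)
  hstep <- pmax(1e-4 * sig, 1e-9)
  A <- tryCatch({
    H <- num_hessian(function(s) -lmm_reml_loglik(s[1], s[2], ss), sig,
                     hstep)
    solve(H)
  }, error = function(e) NULL)
  df <- rep(n - p, p)
  if (!is.null(A) && all(is.finite(A))) {
    gmat <- num_jacobian(fvar, sig, hstep)  # p x 2
    f0 <- fvar(sig)
    for (j in seq_len(p)) {
      denom <- drop(gmat[j, ] %*% A %*% gmat[j, ])
      if (is.finite(denom) && denom > 0)
        df[j] <- min(2 * f0[j]^2 / denom, n - p)
    }
  }
  se <- sqrt(diag(vcov_beta))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  coef_tab <- data.frame(term = colnames(X), estimate = as.numeric(beta),
                         se = se, df = df, statistic = tval, p = pval,
                         row.names = NULL, stringsAsFactors = FALSE)
  structure(list(formula = formula, family = "gaussian", method = "REML",
                 coefficients = coef_tab,
                 beta = stats::setNames(as.numeric(beta), colnames(X)),
                 vcov_beta = vcov_beta,
                 sigma2_subject = sb2, sigma2_resid = se2, theta = theta,
                 logLik = lmm_reml_loglik(sb2, se2, ss),
                 fitted_fixed = as.numeric(X %*% beta),
                 singular = singular, converged = TRUE,
                 n = n, n_groups = nlevels(g),
                 terms = stats::terms(pf$fixed), model_frame = mf,
                 group = pf$group),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("%s random-intercept model (%s): %s\n", x$family, x$method,
              deparse(x$formula)))
  cat(sprintf("  n = %d, groups = %d; sigma2_subject = %.4g, %s = %.4g%s\n",
              x$n, x$n_groups, x$sigma2_subject,
              if (x$family == "gaussian") "sigma2_resid" else "logit resid",
              if (x$family == "gaussian") x$sigma2_resid else pi^2 / 3,
              if (isTRUE(x$singular)) " (singular)" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}
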