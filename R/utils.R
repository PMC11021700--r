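#' @keywords internal
"_PACKAGE"

#' @importFrom stats glm glm.fit binomial quasibinomial qnorm pnorm rnorm runif
#'   rpois rbinom rexp uniroot quantile sd median model.matrix setNames
#'   coef predict as.formula aggregate terms plogis qlogis
#' @importFrom utils write.csv read.csv head
#' @importFrom rlang .data
NULL

expit <- function(x) plogis(x)
logit <- function(p) qlogis(p)

# Truncated-normal draws by inverse-CDF: exact, vectorised, no rejection.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Binary indicator with exact marginal prevalence p whose log-odds rise with
# the latent score u (loading rho): threshold construction on a standard
# normal score.
rbinary_latent <- function(u, p, rho) {
  score <- rho * u + sqrt(1 - rho^2) * rnorm(length(u))
  as.integer(score > qnorm(1 - p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Weighted logistic fit on a prebuilt model matrix: damped Newton-Raphson
# (identical to IRLS for the logistic likelihood) built on crossprod/solve so
# the pipeline's weight models support frequency weights (bootstrap
# multiplicities) and warm starts cheaply.  Agreement with stats::glm is
# covered by a unit test.  `family` is accepted for signature compatibility:
# the solver maximizes the binomial/quasibinomial likelihood either way and
# reports the binomial AIC only when the response is 0/1.
fit_logit <- function(x, y, weights = NULL, start = NULL, family = NULL,
                      maxit = 50, tol = 1e-9) {
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  p <- ncol(x)
  beta <- if (!is.null(start) && length(start) == p && !anyNA(start))
    start else qr.coef(qr(sqrt(w) * x), sqrt(w) * (4 * y - 2))
  beta[is.na(beta)] <- 0
  mu_of <- function(eta) expit(pmin(pmax(eta, -30), 30))
  dev_of <- function(mu) -2 * sum(w * (y * log(mu) + (1 - y) * log1p(-mu)))
  eta <- drop(x %*% beta)
  mu <- mu_of(eta)
  dev <- dev_of(mu)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    score <- crossprod(x, w * (y - mu))
    H <- crossprod(x * sqrt(w * mu * (1 - mu)))
    delta <- tryCatch(solve(H, score),
                      error = function(e)
                        solve(H + diag(1e-8 * (1 + diag(H))), score))
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      eta_new <- drop(x %*% beta_new)
      mu_new <- mu_of(eta_new)
      dev_new <- dev_of(mu_new)
      if (is.finite(dev_new) && dev_new <= dev + 1e-8) break
      step <- step / 2
      if (step < 1e-8) {
        beta_new <- beta; eta_new <- eta; mu_new <- mu; dev_new <- dev; break
      }
    }
    done <- abs(dev - dev_new) / (abs(dev_new) + 0.1) < tol
    beta <- drop(beta_new); eta <- eta_new; mu <- mu_new; dev <- dev_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged)
    stopf("logistic model did not converge after %d iterations", maxit)
  beta <- setNames(as.numeric(beta), colnames(x))
  is_binary <- all(y %in% c(0, 1))
  list(coefficients = beta, fitted = expit(eta), eta = eta,
       aic = if (is_binary) dev + 2 * p else NA_real_, deviance = dev)
}

# Weighted logistic fit on a person-month expansion whose design is
# [xper[person, ], k]: every covariate except the month index k is constant
# within person.  Mathematically identical to
# fit_logit(cbind(xper[person, ], k), y, weights) but the score and Hessian
# are accumulated with person-level crossprods plus rowsum() over the
# expansion, so the cost scales with persons rather than person-months.
# Agreement with fit_logit on the expanded matrix is covered by a unit test.
fit_logit_pm <- function(xper, k, person, y, weights = NULL, start = NULL,
                         maxit = 50, tol = 1e-9) {
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  p <- ncol(xper) + 1L
  beta <- if (!is.null(start) && length(start) == p && !anyNA(start))
    start else c(logit(max(min(sum(w * y) / sum(w), 1 - 1e-6), 1e-6)),
                 numeric(p - 1L))
  beta[is.na(beta)] <- 0
  eta_of <- function(beta)
    drop(xper %*% beta[-p])[person] + beta[p] * k
  mu_of <- function(eta) expit(pmin(pmax(eta, -30), 30))
  dev_of <- function(mu) -2 * sum(w * (y * log(mu) + (1 - y) * log1p(-mu)))
  eta <- eta_of(beta)
  mu <- mu_of(eta)
  dev <- dev_of(mu)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    r <- w * (y - mu)
    wt <- w * mu * (1 - mu)
    acc <- rowsum(cbind(r, wt, wt * k, wt * k * k), person)
    score <- c(crossprod(xper, acc[, 1]), sum(r * k))
    H <- matrix(0, p, p)
    H[-p, -p] <- crossprod(xper, xper * acc[, 2])
    H[-p, p] <- H[p, -p] <- crossprod(xper, acc[, 3])
    H[p, p] <- sum(acc[, 4])
    delta <- tryCatch(solve(H, score),
                      error = function(e)
                        solve(H + diag(1e-8 * (1 + diag(H))), score))
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      eta_new <- eta_of(beta_new)
      mu_new <- mu_of(eta_new)
      dev_new <- dev_of(mu_new)
      if (is.finite(dev_new) && dev_new <= dev + 1e-8) break
      step <- step / 2
      if (step < 1e-8) {
        beta_new <- beta; eta_new <- eta; mu_new <- mu; dev_new <- dev; break
      }
    }
    done <- abs(dev - dev_new) / (abs(dev_new) + 0.1) < tol
    beta <- drop(beta_new); eta <- eta_new; mu <- mu_new; dev <- dev_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged)
    stopf("logistic model did not converge after %d iterations", maxit)
  beta <- setNames(as.numeric(beta), c(colnames(xper), "k"))
  list(coefficients = beta, fitted = expit(eta), eta = eta,
       aic = dev + 2 * p, deviance = dev)
}

# Linear-interpolation (type 7) quantiles, the convention used throughout
# reporting because quartile values are user-visible.
quartiles <- function(x) {
  q <- quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(lq = q[1], median = q[2], uq = q[3])
}
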