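# Gaussian generalized estimating equations with identity link,
# exchangeable (or independence) working correlation and cluster-robust
# sandwich covariance. Clusters here are participants; observations are
# eyes. Written from the standard moment-based GEE recipe: iterate
# between a GLS update of beta given the working correlation and a
# Pearson-residual moment update of the exchangeable parameter alpha.

#' Fit a Gaussian GEE
#'
#' Identity-link GEE for a continuous outcome with clustered
#' observations. The working correlation is exchangeable by default
#' (fellow eyes are exchangeable units); an independence structure is
#' available as a sensitivity option, under which the point estimates
#' equal ordinary least squares. Standard errors are always
#' cluster-robust (sandwich) and inference is Wald with normal
#' quantiles.
#'
#' @param y numeric outcome vector.
#' @param X design matrix (including intercept column).
#' @param id cluster identifier vector, same length as `y`.
#' @param corstr `"exchangeable"` or `"independence"`.
#' @param tol,max_iter convergence control on the coefficient update.
#' @return List with `coefficients`, `robust_se`, `vcov` (sandwich),
#'   `alpha` (working correlation), `n_obs`, `n_clusters`, `converged`.
#' @export
gee_gaussian <- function(y, X, id, corstr = c("exchangeable", "independence"),
                         tol = 1e-10, max_iter = 50L) {
  corstr <- match.arg(corstr)
  stopifnot(length(y) == nrow(X), length(id) == length(y))
  keep <- complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; id <- id[keep]
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank deficient (zero-variance predictor?)")
  p <- ncol(X)
  cl <- split(seq_along(y), id)
  n_clusters <- length(cl)
  beta <- qr.coef(qrX, y)
  alpha <- 0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    r <- y - X %*% beta
    phi <- sum(r^2) / (length(y) - p)
    if (corstr == "exchangeable") {
      num <- 0; npairs <- 0
      for (ix in cl) {
        m <- length(ix)
        if (m > 1) {
          ri <- r[ix]
          num <- num + (sum(ri)^2 - sum(ri^2)) / 2
          npairs <- npairs + m * (m - 1) / 2
        }
      }
      alpha <- if (npairs > p) num / (phi * (npairs - p)) else 0
      alpha <- max(min(alpha, 0.99), -0.99)
    } else alpha <- 0
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (ix in cl) {
      m <- length(ix)
      Xi <- X[ix, , drop = FALSE]
      yi <- y[ix]
      Ri <- matrix(alpha, m, m); diag(Ri) <- 1
      Vinv <- solve(Ri) / phi
      A <- A + crossprod(Xi, Vinv %*% Xi)
      b <- b + crossprod(Xi, Vinv %*% yi)
    }
    beta_new <- solve(A, b)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  r <- as.numeric(y - X %*% beta)
  A <- matrix(0, p, p)
  B <- matrix(0, p, p)
  phi <- sum(r^2) / (length(y) - p)
  for (ix in cl) {
    m <- length(ix)
    Xi <- X[ix, , drop = FALSE]
    ri <- r[ix]
    Ri <- matrix(alpha, m, m); diag(Ri) <- 1
    Vinv <- solve(Ri) / phi
    XtV <- crossprod(Xi, Vinv)
    A <- A + XtV %*% Xi
    u <- XtV %*% ri
    B <- B + tcrossprod(u)
  }
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
       robust_se = stats::setNames(sqrt(diag(V)), colnames(X)),
       vcov = V, alpha = alpha, phi = phi,
       n_obs = length(y), n_clusters = n_clusters,
       converged = converged)
}

# z-score a numeric vector on the analysis sample; binary 0/1 columns and
# factors are left alone by the callers.
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("zero-variance variable cannot be standardized")
  (x - mean(x)) / s
}

is_binary01 <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}

# Build a standardized design: outcome and continuous predictors
# z-scored, binary covariates kept 0/1, factors expanded to dummies.
standardized_design <- function(data, outcome, predictors) {
  y <- zscore(data[[outcome]])
  cols <- list(`(Intercept)` = rep(1, nrow(data)))
  for (v in predictors) {
    x <- data[[v]]
    if (is.factor(x) || is.character(x)) {
      f <- factor(x)
      for (lv in levels(f)[-1])
        cols[[paste0(v, lv)]] <- as.numeric(f == lv)
    } else if (is_binary01(x)) {
      cols[[v]] <- x
    } else {
      cols[[v]] <- zscore(x)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(y = y, X = X)
}
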