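## Logistic generalized estimating equations for clustered binary outcomes:
## logit link, exchangeable working correlation with a moment estimate of
## the intra-cluster correlation, and robust (sandwich) covariance. Written
## directly from the standard estimating-equation scheme; per-coefficient
## Wald chi-square statistics (1 df) test each effect.

#' Logistic GEE with exchangeable working correlation
#'
#' Fits the marginal logistic model \eqn{logit P(y=1) = X\beta} for binary
#' outcomes correlated within clusters. Iterates between Fisher-scoring
#' updates of \eqn{\beta} under the exchangeable working correlation
#' \eqn{R(\alpha)} and moment updates of \eqn{\alpha} (and the dispersion
#' \eqn{\phi}) from Pearson residuals. Standard errors come from the
#' robust sandwich covariance; \code{wald} is \eqn{(\hat\beta/SE)^2}
#' referred to a chi-square with 1 df.
#'
#' With \code{alpha_fixed = 0} the estimating equation is the independence
#' score, so the coefficients coincide with ordinary logistic regression.
#' Non-convergence or separation is reported explicitly via the
#' \code{converged} and \code{status} slots, never silently.
#'
#' @param formula model formula for the binary outcome, e.g.
#'   \code{error ~ phase}.
#' @param data data.frame holding outcome and covariates.
#' @param id cluster identifier: a vector of length \code{nrow(data)} or the
#'   name of a column of \code{data}. At least 2 clusters required.
#' @param alpha_fixed if non-NULL, hold the working correlation at this
#'   value instead of estimating it.
#' @param maxit,tol iteration cap and convergence tolerance on
#'   \eqn{\max|\Delta\beta|}.
#' @return A \code{\linkS4class{GEEFit}}.
#' @examples
#' fx <- buildFixtureLog(table4Margins(), layout = "by_group")
#' df <- fx$log
#' df$error <- vapply(seq_len(nrow(df)), function(i)
#'   isError(as.list(df[i, ]),
#'           Filter(function(g) g$case_id == df$case_id[i], fx$gold)[[1]]),
#'   NA)
#' geeLogistic(error ~ phase, df, id = "tester_id")
#' @export
geeLogistic <- function(formula, data, id, alpha_fixed = NULL, maxit = 50L,
                        tol = 1e-8) {
  if (is.character(id) && length(id) == 1L) {
    if (!id %in% names(data)) stop(sprintf("no column '%s' in data", id))
    id <- data[[id]]
  }
  mf <- stats::model.frame(formula, data)
  y <- as.numeric(stats::model.response(mf))
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1)")
  X <- stats::model.matrix(formula, mf)
  n <- length(y); p <- ncol(X)
  id <- as.character(id)
  cl <- split(seq_len(n), id)
  K <- length(cl)
  if (K < 2L) stop("at least 2 clusters required")
  sizes <- lengths(cl)
  n_pairs <- sum(sizes * (sizes - 1) / 2)

  beta <- stats::coef(stats::glm.fit(X, y, family = stats::binomial()))
  alpha <- if (is.null(alpha_fixed)) 0 else alpha_fixed
  phi <- 1
  converged <- FALSE
  status <- "ok"
  iter <- 0L

  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    v <- mu * (1 - mu)
    if (any(v < 1e-12)) {
      status <- "separation: fitted probabilities numerically 0 or 1"
      break
    }
    s <- sqrt(v)
    z <- (y - mu) / s    # Pearson residuals

    phi <- sum(z^2) / (n - p)
    if (is.null(alpha_fixed) && n_pairs > p) {
      cross <- vapply(cl, function(ix) {
        zi <- z[ix]
        (sum(zi)^2 - sum(zi^2)) / 2
      }, 0)
      alpha <- sum(cross) / ((n_pairs - p) * phi)
      lower <- -1 / (max(sizes) - 1) + 1e-6
      alpha <- min(max(alpha, lower), 0.999)
    }

    ## exchangeable R(alpha)^{-1} applied in closed form per cluster
    M <- matrix(0, p, p)
    g <- numeric(p)
    Blist <- vector("list", K)
    for (k in seq_len(K)) {
      ix <- cl[[k]]
      ni <- length(ix)
      P <- X[ix, , drop = FALSE] * s[ix]
      zi <- z[ix]
      denom <- 1 + (ni - 1) * alpha
      c1 <- 1 / (1 - alpha)
      c2 <- alpha / ((1 - alpha) * denom)
      csum <- colSums(P)
      Rinv_z <- c1 * zi - c2 * sum(zi)
      M <- M + c1 * crossprod(P) - c2 * tcrossprod(csum)
      gk <- drop(t(P) %*% Rinv_z)
      g <- g + gk
      Blist[[k]] <- gk
    }
    delta <- tryCatch(solve(M, g), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) {
      status <- "singular working information matrix"
      break
    }
    beta <- beta + delta
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && status == "ok")
    status <- sprintf("did not converge in %d iterations", maxit)

  ## sandwich covariance at the final beta
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  v <- pmax(mu * (1 - mu), 1e-12)
  s <- sqrt(v)
  z <- (y - mu) / s
  M <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (k in seq_len(K)) {
    ix <- cl[[k]]
    ni <- length(ix)
    P <- X[ix, , drop = FALSE] * s[ix]
    zi <- z[ix]
    denom <- 1 + (ni - 1) * alpha
    c1 <- 1 / (1 - alpha)
    c2 <- alpha / ((1 - alpha) * denom)
    csum <- colSums(P)
    M <- M + c1 * crossprod(P) - c2 * tcrossprod(csum)
    gk <- drop(t(P) %*% (c1 * zi - c2 * sum(zi)))
    B <- B + tcrossprod(gk)
  }
  Minv <- tryCatch(solve(M), error = function(e) matrix(NA_real_, p, p))
  vcov_robust <- Minv %*% B %*% Minv
  robust_se <- sqrt(pmax(diag(vcov_robust), 0))
  naive_se <- sqrt(pmax(diag(phi * Minv), 0))
  wald <- (beta / robust_se)^2
  pval <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
  nm <- colnames(X)
  names(beta) <- names(robust_se) <- names(naive_se) <- nm
  names(wald) <- names(pval) <- nm

  new("GEEFit", coefficients = beta, robust_se = robust_se,
      naive_se = naive_se, wald = wald, p_value = pval, alpha = alpha,
      phi = phi, converged = converged, n_iter = iter,
      n_clusters = as.integer(K), n_obs = as.integer(n), status = status)
}
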