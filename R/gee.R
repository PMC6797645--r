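#' @name gee
#' @title Generalized estimating equations with exchangeable correlation
#'
#' @description
#' Marginal regression for clustered trial-level outcomes. Trials are
#' clustered within subjects; the working correlation is exchangeable (any
#' two trials of a subject share a common correlation alpha, estimated by
#' the moment method of Liang and Zeger), and inference uses the robust
#' sandwich covariance, which stays valid even when the working structure is
#' wrong. Continuous outcomes use the identity link with Gaussian variance;
#' counts use the log link with Poisson variance (no overdispersion
#' parameter is needed — sandwich inference absorbs it).
NULL

# inverse of the exchangeable correlation matrix, closed form:
# R^{-1} = (I - a/(1+(n-1)a) J) / (1-a)
exch_solve <- function(alpha, m) {
  n <- nrow(m)
  if (n == 1L) return(m)
  (m - alpha / (1 + (n - 1) * alpha) * matrix(colSums(m), n, ncol(m),
                                              byrow = TRUE)) / (1 - alpha)
}

#' Fit a GEE model
#'
#' Fisher-scoring GEE with an exchangeable working correlation and robust
#' (sandwich) standard errors. Rows with missing values in the outcome,
#' covariates, or cluster id are dropped listwise (count reported on the
#' fit). Covariate columns that are inestimable in the data (aliased or
#' constant, e.g. an interaction with a flag no subject carries) are dropped
#' with a warning.
#'
#' @param formula Model formula (outcome ~ covariates).
#' @param data Data frame of trial-level rows.
#' @param id Name of the cluster (subject) column in `data`.
#' @param family `"gaussian"` (identity link) or `"poisson"` (log link).
#' @param maxit,tol Scoring iteration controls.
#' @return An object of class `mt_gee` with fields `coefficients`,
#'   `robust_se`, `p_values`, `vcov` (robust), `alpha` (working
#'   correlation), `phi` (dispersion), `n_clusters`, `n_obs`,
#'   `n_dropped_rows`, `dropped_terms`, `converged`, `iterations`.
#' @examples
#' tab <- simulate_measures(n_subjects = 30, effects = c(xdev = 0.5), seed = 1)
#' fit <- gee_fit(xdev ~ ambiguous, tab, id = "subject_id")
#' coef(fit)["ambiguous"]
#' @export
gee_fit <- function(formula, data, id, family = c("gaussian", "poisson"),
                    maxit = 100, tol = 1e-10) {
  family <- match.arg(family)
  stopifnot(is.character(id), id %in% names(data))

  vars <- all.vars(formula)
  stopifnot(all(vars %in% names(data)))
  complete <- stats::complete.cases(data[, c(vars, id)])
  n_dropped <- sum(!complete)
  d <- data[complete, , drop = FALSE]
  if (!nrow(d)) stop("no complete rows to fit", call. = FALSE)

  X <- stats::model.matrix(formula, d)
  y <- stats::model.response(stats::model.frame(formula, d))
  cl <- factor(d[[id]])
  if (nlevels(cl) < 2L) {
    stop("GEE needs at least 2 clusters; got ", nlevels(cl), call. = FALSE)
  }

  # drop aliased / inestimable columns
  dropped_terms <- character(0)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped_terms <- colnames(X)[-keep]
    warning("dropping inestimable terms: ",
            paste(dropped_terms, collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)
  n <- nrow(X)

  linkinv <- if (family == "poisson") exp else identity
  varfun  <- if (family == "poisson") identity else function(mu) rep(1, length(mu))
  mu_eta  <- if (family == "poisson") exp else function(eta) rep(1, length(eta))

  beta <- tryCatch(
    stats::glm.fit(X, y,
                   family = if (family == "poisson") stats::poisson()
                            else stats::gaussian())$coefficients,
    error = function(e) rep(0, p))
  beta[is.na(beta)] <- 0

  idx <- split(seq_len(n), cl)
  n_i <- lengths(idx)
  pair_count <- sum(n_i * (n_i - 1)) / 2

  alpha <- 0; phi <- 1
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- linkinv(eta)
    A <- varfun(mu)
    resid <- y - mu
    e <- resid / sqrt(A)

    phi <- sum(e^2) / (n - p)
    if (pair_count > p) {
      num <- sum(vapply(idx, function(ii) {
        s <- sum(e[ii]); (s^2 - sum(e[ii]^2)) / 2
      }, numeric(1)))
      alpha <- num / ((pair_count - p) * phi)
    } else {
      alpha <- 0
    }
    # keep the working matrix positive definite
    max_ni <- max(n_i)
    alpha <- min(max(alpha, -1 / (max_ni - 1) + 1e-6), 0.999)

    H <- matrix(0, p, p)
    U <- numeric(p)
    dmu <- mu_eta(eta)
    for (ii in idx) {
      Di <- X[ii, , drop = FALSE] * dmu[ii]
      sa <- sqrt(A[ii])
      # W = D' V^{-1} with V = phi A^{1/2} R A^{1/2}
      W <- t(exch_solve(alpha, (Di / sa))) / phi
      W <- sweep(W, 2L, sa, "/")
      H <- H + W %*% Di
      U <- U + drop(W %*% resid[ii])
    }
    delta <- solve(H, U)
    beta <- beta + delta
    if (max(abs(delta)) < tol * (1 + max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }

  # sandwich covariance at the converged estimate
  eta <- drop(X %*% beta)
  mu <- linkinv(eta)
  A <- varfun(mu)
  resid <- y - mu
  dmu <- mu_eta(eta)
  H <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ii in idx) {
    Di <- X[ii, , drop = FALSE] * dmu[ii]
    sa <- sqrt(A[ii])
    W <- t(exch_solve(alpha, (Di / sa))) / phi
    W <- sweep(W, 2L, sa, "/")
    H <- H + W %*% Di
    g <- drop(W %*% resid[ii])
    M <- M + tcrossprod(g)
  }
  Hinv <- solve(H)
  V <- Hinv %*% M %*% t(Hinv)
  se <- sqrt(diag(V))
  z <- beta / se
  pvals <- 2 * stats::pnorm(-abs(z))
  names(beta) <- names(se) <- names(pvals) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))

  structure(
    list(coefficients = beta, robust_se = se, p_values = pvals, vcov = V,
         alpha = alpha, phi = phi, n_clusters = length(idx), n_obs = n,
         n_dropped_rows = n_dropped, dropped_terms = dropped_terms,
         converged = converged, iterations = iter,
         family = family, formula = formula, id = id),
    class = "mt_gee"
  )
}

#' @export
coef.mt_gee <- function(object, ...) object$coefficients

#' @export
vcov.mt_gee <- function(object, ...) object$vcov

#' @export
print.mt_gee <- function(x, ...) {
  cat("<mt_gee> ", x$family,
      if (x$family == "poisson") " (log link)" else " (identity link)",
      ", exchangeable working correlation\n", sep = "")
  cat("  ", x$n_obs, " trials in ", x$n_clusters, " clusters; alpha = ",
      signif(x$alpha, 3), ", phi = ", signif(x$phi, 3),
      if (!x$converged) "; NOT CONVERGED", "\n", sep = "")
  print(tidy_gee(x), digits = 4)
  invisible(x)
}

#' Tidy a GEE fit into a term-level data frame
#'
#' @param fit An `mt_gee`.
#' @return Data frame with columns `term`, `estimate`, `robust_se`,
#'   `p_value` (plus `outcome` and `link` when the fit carries them).
#' @export
tidy_gee <- function(fit) {
  stopifnot(inherits(fit, "mt_gee"))
  out <- data.frame(term = names(fit$coefficients),
                    estimate = unname(fit$coefficients),
                    robust_se = unname(fit$robust_se),
                    p_value = unname(fit$p_values),
                    stringsAsFactors = FALSE)
  if (!is.null(fit$outcome)) {
    out$outcome <- fit$outcome
    out$link <- if (fit$family == "poisson") "log" else "identity"
  }
  out
}
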