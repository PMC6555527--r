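whiten_term <- function(Z, K = NULL, tol = 1e-10) {
  Z <- as.matrix(Z)
  if (is.null(K)) {
    return(list(Zt = Z, Tmat = NULL, labels = colnames(Z)))
  }
  K <- unclass(as.matrix(K))
  if (ncol(Z) != nrow(K)) {
    stop("incidence/covariance dimension mismatch for a random term",
         call. = FALSE)
  }
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE)
  keep <- ev$values > tol * max(ev$values, 0)
  if (!any(keep)) stop("covariance matrix has no positive eigenvalues",
                       call. = FALSE)
  Tmat <- ev$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(ev$values[keep]), sum(keep))
  list(Zt = Z %*% Tmat, Tmat = Tmat, labels = colnames(Z))
}

#' Specify a Gaussian mixed model
#'
#' Assembles the response, fixed-effect design and random terms (each with an
#' optional known covariance structure) consumed by [fit_reml()] and
#' [gibbs_vc()]. Each random term `u_k ~ N(0, sigma2_k K_k)` is internally
#' reparameterized through the eigendecomposition of `K_k` into independent
#' coefficients (rank-deficient covariances, e.g. record-level G-by-E
#' kernels, are handled by retaining the positive eigenvalues only).
#'
#' @param y numeric response vector (NAs allowed: [gibbs_vc()] treats them
#'   as unobserved records to predict; [fit_reml()] refuses them).
#' @param fixed design matrix for the fixed effects (include the intercept
#'   column). An `assign` attribute plus `term_labels` attribute, as
#'   produced by [model.matrix()], enables per-term Wald tests.
#' @param random named list of random terms: each element is either an
#'   incidence matrix `Z` (iid effects) or a `list(Z = , K = )` with a
#'   symmetric covariance `K`.
#' @param size_guard maximum number of records; record-level interaction
#'   kernels are materialized densely, so very large data sets are refused.
#' @return a list of class `mm_spec`.
#' @export
mixed_model_spec <- function(y, fixed, random = list(),
                             size_guard = 20000) {
  y <- as.numeric(y)
  n <- length(y)
  if (n > size_guard) {
    stop(sprintf("n = %d records exceeds the dense-model size guard (%d)",
                 n, size_guard), call. = FALSE)
  }
  X <- as.matrix(fixed)
  if (nrow(X) != n) stop("fixed design row count differs from y", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  terms <- lapply(random, function(r) {
    if (is.matrix(r) || inherits(r, "Matrix")) whiten_term(r)
    else whiten_term(r$Z, r$K)
  })
  for (tm in terms) {
    if (nrow(tm$Zt) != n) stop("random incidence row count differs from y",
                               call. = FALSE)
  }
  structure(list(y = y, X = X, terms = terms, n = n,
                 assign = attr(fixed, "assign"),
                 term_labels = attr(fixed, "term_labels")),
            class = "mm_spec")
}

reduce_rank_X <- function(X) {
  qrX <- qr(X)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  keep <- sort(keep)
  list(X = X[, keep, drop = FALSE], keep = keep, rank = qrX$rank)
}

# direct dense-V restricted log-likelihood (used by the unconstrained
# refinement; intentionally independent of the MME recursion)
reml_loglik_direct <- function(y, X, Zt_list, vc) {
  n <- length(y)
  V <- diag(vc[length(vc)], n)
  for (k in seq_along(Zt_list)) {
    V <- V + vc[k] * tcrossprod(Zt_list[[k]])
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  ch2 <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch2)) return(-Inf)
  beta <- backsolve(ch2, forwardsolve(t(ch2), crossprod(X, Vi_y)))
  yPy <- sum(y * Vi_y) - sum(crossprod(X, Vi_y) * beta)
  -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(ch2))) + yPy +
            (n - ncol(X)) * log(2 * pi))
}

#' Fit a Gaussian mixed model by EM-REML
#'
#' Estimates variance components by the EM algorithm on the mixed-model
#' equations of the eigen-whitened random terms. EM updates are sums of
#' quadratic forms, so components are nonnegative by construction and the
#' restricted log-likelihood is non-decreasing across iterations (the trace
#' is returned). Components that collapse to (numerical) zero are flagged as
#' boundary estimates. With `constrain = FALSE`, the EM solution is refined
#' by a direct Nelder-Mead maximization of the restricted likelihood that
#' permits negative components (as some REML software reports), subject only
#' to the total covariance staying positive definite.
#'
#' @param spec a [mixed_model_spec()].
#' @param tol convergence tolerance on the relative change of every
#'   component.
#' @param max_iter maximum EM iterations.
#' @param constrain keep all components nonnegative (default TRUE).
#' @return object of class `reml_fit`: `beta` (fixed estimates),
#'   `beta_cov`, `blups` (list of effect vectors in the original
#'   parameterization), `vc` (named vector, `residual` last),
#'   `loglik_reml`, `loglik_trace`, `converged`, `n_iter`, `boundary`
#'   (logical per component), `n`, `p`.
#' @export
fit_reml <- function(spec, tol = 1e-8, max_iter = 500, constrain = TRUE) {
  stopifnot(inherits(spec, "mm_spec"))
  if (anyNA(spec$y)) stop("fit_reml requires a complete response", call. = FALSE)
  y <- spec$y
  n <- spec$n
  rx <- reduce_rank_X(spec$X)
  X <- rx$X
  p <- rx$rank
  K <- length(spec$terms)
  if (n - p <= 0) stop("no residual degrees of freedom", call. = FALSE)

  if (K == 0) {
    XtX <- crossprod(X)
    beta <- solve(XtX, crossprod(X, y))
    resid <- y - X %*% beta
    s2e <- sum(resid^2) / (n - p)
    ll <- reml_loglik_direct(y, X, list(), s2e)
    return(structure(list(
      beta = setNames(as.vector(beta), colnames(X)),
      beta_cov = solve(XtX) * s2e, blups = list(),
      vc = c(residual = s2e), loglik_reml = ll, loglik_trace = ll,
      converged = TRUE, n_iter = 0L,
      boundary = logical(0), n = n, p = p,
      keep_cols = rx$keep, assign = spec$assign,
      term_labels = spec$term_labels, spec = spec
    ), class = "reml_fit"))
  }

  Zt_list <- lapply(spec$terms, `[[`, "Zt")
  r_k <- vapply(Zt_list, ncol, integer(1))
  W <- cbind(X, do.call(cbind, Zt_list))
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  yty <- sum(y^2)
  blocks <- split(p + seq_len(sum(r_k)), rep(seq_len(K), r_k))
  vary <- var(y)
  lb <- 1e-10 * vary

  s2 <- rep(vary / (K + 1), K)
  s2e <- vary / 2
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lambda <- s2e / s2
    M <- WtW
    for (k in seq_len(K)) {
      idx <- blocks[[k]]
      M[cbind(idx, idx)] <- M[cbind(idx, idx)] + lambda[k]
    }
    ch <- chol(M)
    Minv <- chol2inv(ch)
    b <- Minv %*% Wty
    quad <- (yty - sum(b * Wty)) / s2e
    ll <- -0.5 * ((n - p - sum(r_k)) * log(s2e) + sum(r_k * log(s2)) +
                    2 * sum(log(diag(ch))) + quad + (n - p) * log(2 * pi))
    trace <- c(trace, ll)

    s2_new <- vapply(seq_len(K), function(k) {
      idx <- blocks[[k]]
      (sum(b[idx]^2) + s2e * sum(diag(Minv)[idx])) / r_k[k]
    }, numeric(1))
    s2e_new <- (yty - sum(b * Wty)) / (n - p)
    s2_new <- pmax(s2_new, lb)
    s2e_new <- max(s2e_new, lb)

    delta <- max(abs(c(s2_new - s2, s2e_new - s2e)) /
                   (abs(c(s2, s2e)) + lb))
    s2 <- s2_new
    s2e <- s2e_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  term_names <- names(spec$terms)
  vc <- setNames(c(s2, s2e), c(term_names, "residual"))
  boundary <- setNames(s2 <= lb * 1.01, term_names)

  if (!constrain) {
    opt <- optim(
      par = c(s2, s2e),
      fn = function(th) {
        if (th[K + 1] <= 0) return(Inf)
        -reml_loglik_direct(y, X, Zt_list, th)
      },
      method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-12)
    )
    vc <- setNames(c(opt$par), c(term_names, "residual"))
    s2 <- opt$par[seq_len(K)]
    s2e <- opt$par[K + 1]
    boundary <- setNames(rep(FALSE, K), term_names)
  }

  # final solve at the returned components
  lambda <- s2e / s2
  M <- WtW
  for (k in seq_len(K)) {
    idx <- blocks[[k]]
    M[cbind(idx, idx)] <- M[cbind(idx, idx)] + lambda[k]
  }
  ch <- chol(M)
  Minv <- chol2inv(ch)
  b <- Minv %*% Wty
  quad <- (yty - sum(b * Wty)) / s2e
  ll <- -0.5 * ((n - p - sum(r_k)) * log(abs(s2e)) +
                  sum(r_k * log(abs(s2))) +
                  2 * sum(log(diag(ch))) + quad + (n - p) * log(2 * pi))
  beta <- setNames(as.vector(b[seq_len(p)]), colnames(X))
  beta_cov <- Minv[seq_len(p), seq_len(p), drop = FALSE] * s2e
  dimnames(beta_cov) <- list(colnames(X), colnames(X))
  blups <- lapply(seq_len(K), function(k) {
    alpha <- as.vector(b[blocks[[k]]])
    tm <- spec$terms[[k]]
    u <- if (is.null(tm$Tmat)) alpha else as.vector(tm$Tmat %*% alpha)
    setNames(u, tm$labels)
  })
  names(blups) <- term_names

  structure(list(
    beta = beta, beta_cov = beta_cov, blups = blups, vc = vc,
    loglik_reml = ll, loglik_trace = trace, converged = converged,
    n_iter = iter, boundary = boundary, n = n, p = p,
    keep_cols = rx$keep, assign = spec$assign,
    term_labels = spec$term_labels, spec = spec
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("<reml_fit> n = %d, REML loglik = %.3f, %sconverged (%d it.)\n",
              x$n, x$loglik_reml, if (x$converged) "" else "NOT ", x$n_iter))
  print(round(x$vc, 5))
  invisible(x)
}

#' Wald chi-square test for a fixed-effect term
#'
#' Tests the joint nullity of all estimable coefficients belonging to one
#' fixed-effect term, using the REML-based covariance of the fixed-effect
#' estimates. The statistic is `b' Cov(b)^-1 b` on the term's coefficients
#' with as many degrees of freedom as coefficients.
#'
#' @param fit a [fit_reml()] result whose fixed design carried `assign` and
#'   `term_labels` attributes.
#' @param term character, the term label to test.
#' @return tibble with `term`, `statistic`, `df`, `p_value`.
#' @export
wald_fixed <- function(fit, term) {
  stopifnot(inherits(fit, "reml_fit"))
  if (is.null(fit$assign) || is.null(fit$term_labels)) {
    stop("fit carries no term information for Wald tests", call. = FALSE)
  }
  it <- match(term, fit$term_labels)
  if (is.na(it)) stop("unknown fixed term: ", term, call. = FALSE)
  cols_full <- which(fit$assign == it)
  cols <- match(intersect(cols_full, fit$keep_cols), fit$keep_cols)
  if (length(cols) == 0) {
    stop(sprintf("term '%s' has zero estimable degrees of freedom", term),
         call. = FALSE)
  }
  b <- fit$beta[cols]
  Vb <- fit$beta_cov[cols, cols, drop = FALSE]
  stat <- as.numeric(crossprod(b, solve(Vb, b)))
  df <- length(cols)
  tibble::tibble(term = term, statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Likelihood-ratio test for a variance component on the boundary
#'
#' Compares two nested REML fits differing by one random term. Because the
#' null value sits on the boundary of the parameter space, the statistic
#' `2 * (loglik_full - loglik_reduced)` (floored at zero) is referred to the
#' 50:50 mixture of a point mass at zero and a chi-square with 1 df; the
#' reported p-value is `P(T >= t)` under that mixture, which equals 1 at
#' `t = 0` and `0.5 * P(chisq_1 >= t)` for `t > 0`.
#'
#' @param full,reduced [fit_reml()] results; `reduced` must drop exactly the
#'   tested random terms of `full` (same fixed design and response length).
#' @return tibble with `statistic`, `df`, `p_value`.
#' @export
lrt_random <- function(full, reduced) {
  stopifnot(inherits(full, "reml_fit"), inherits(reduced, "reml_fit"))
  full_terms <- setdiff(names(full$vc), "residual")
  red_terms <- setdiff(names(reduced$vc), "residual")
  if (!all(red_terms %in% full_terms) || full$n != reduced$n) {
    stop("models are not nested", call. = FALSE)
  }
  stat <- max(0, 2 * (full$loglik_reml - reduced$loglik_reml))
  p <- if (stat <= 0) 1 else 0.5 * pchisq(stat, 1, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = 1,
                 dropped = paste(setdiff(full_terms, red_terms),
                                 collapse = ","),
                 p_value = p)
}
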