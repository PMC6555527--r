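#' Gibbs sampler for variance components and effects
#'
#' Bayesian counterpart of [fit_reml()]: a Gibbs sampler with Gaussian
#' conditionals for every (whitened) effect coefficient, flat priors on the
#' fixed effects, and scaled-inverse-chi-square conditionals for the
#' variance components. Missing responses are treated as unobserved records
#' and imputed each iteration, so the posterior mean of the linear predictor
#' at those rows is the model's genomic prediction for them.
#'
#' Priors follow whole-genome-regression defaults: each variance gets a
#' scaled-inverse-chi-square prior with `df0` degrees of freedom and scale
#' chosen so that a fraction `R2` of the phenotypic variance is split
#' equally across the random terms, the remainder assigned to the residual.
#'
#' @param spec a [mixed_model_spec()] (NAs in `y` allowed).
#' @param n_iter total iterations (default 50000).
#' @param burn_in burn-in iterations discarded from summaries (default 5000).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed optional integer seed (calls [set.seed()]).
#' @param df0 prior degrees of freedom for every variance.
#' @param R2 prior fraction of phenotypic variance attributed to the random
#'   terms jointly.
#' @return object of class `gibbs_fit`: `vc_mean`, `vc_sd` (named, residual
#'   last), `beta_mean`, `blups` (posterior-mean effects, original
#'   parameterization), `pred` (posterior mean of the linear predictor per
#'   record, including imputed rows), `missing` (row indices that were NA),
#'   `settings`.
#' @export
gibbs_vc <- function(spec, n_iter = 50000, burn_in = 5000, thin = 1,
                     seed = NULL, df0 = 5, R2 = 0.5) {
  stopifnot(inherits(spec, "mm_spec"))
  if (burn_in >= n_iter) {
    stop("burn_in must be smaller than n_iter", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  K <- length(spec$terms)
  miss <- which(is.na(spec$y)) - 1L
  y <- spec$y
  y[is.na(y)] <- 0
  vy <- var(spec$y, na.rm = TRUE)
  S0 <- if (K > 0) rep(vy * R2 / K * (df0 + 2) / df0, K) else numeric(0)
  S0e <- vy * (1 - R2) * (df0 + 2) / df0

  rx <- reduce_rank_X(spec$X)
  Zlist <- lapply(spec$terms, `[[`, "Zt")
  res <- gibbs_core(y, as.integer(miss), rx$X, Zlist,
                    rep(df0, K), S0, df0, S0e,
                    as.integer(n_iter), as.integer(burn_in),
                    as.integer(thin))

  term_names <- names(spec$terms)
  blups <- lapply(seq_len(K), function(k) {
    a <- as.vector(res$alpha_mean[[k]])
    tm <- spec$terms[[k]]
    u <- if (is.null(tm$Tmat)) a else as.vector(tm$Tmat %*% a)
    setNames(u, tm$labels)
  })
  names(blups) <- term_names

  structure(list(
    vc_mean = setNames(c(as.vector(res$vc_mean), res$s2e_mean),
                       c(term_names, "residual")),
    vc_sd = setNames(c(as.vector(res$vc_sd), res$s2e_sd),
                     c(term_names, "residual")),
    beta_mean = setNames(as.vector(res$beta_mean), colnames(rx$X)),
    blups = blups,
    pred = as.vector(res$pred_mean),
    missing = which(is.na(spec$y)),
    settings = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                    df0 = df0, R2 = R2, n_kept = res$n_kept)
  ), class = "gibbs_fit")
}

#' @export
print.gibbs_fit <- function(x, ...) {
  cat(sprintf("<gibbs_fit> %d kept draws; posterior mean (sd) of variances:\n",
              x$settings$n_kept))
  for (nm in names(x$vc_mean)) {
    cat(sprintf("  %-10s %.5f (%.5f)\n", nm, x$vc_mean[nm], x$vc_sd[nm]))
  }
  invisible(x)
}
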