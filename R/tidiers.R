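#' Tidy a REML fit
#'
#' @param x a [fit_reml()] result.
#' @param ... unused.
#' @return tibble of variance components with boundary flags.
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$vc),
    estimate = unname(x$vc),
    boundary = c(unname(x$boundary), FALSE)[seq_along(x$vc)]
  )
}

#' @rdname tidy.reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(loglik_reml = x$loglik_reml, converged = x$converged,
                 n_iter = x$n_iter, nobs = x$n, p = x$p)
}

#' Tidy a diallel analysis
#'
#' Returns the variance components joined with the likelihood-ratio tests
#' (random effects) when available; `effects = "fixed"` returns the Wald
#' table instead.
#'
#' @param x a `diallel_fit`.
#' @param effects `"random"` (default) or `"fixed"`.
#' @param ... unused.
#' @export
tidy.diallel_fit <- function(x, effects = c("random", "fixed"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    if (is.null(x$wald)) stop("fit was run with do_tests = FALSE", call. = FALSE)
    return(x$wald)
  }
  out <- x$vc
  if (!is.null(x$lrt)) {
    out <- dplyr::left_join(out,
                            dplyr::select(x$lrt, "term", lrt = "statistic",
                                          "p_value"),
                            by = "term")
  }
  out
}

#' @rdname tidy.diallel_fit
#' @export
glance.diallel_fit <- function(x, ...) {
  dplyr::mutate(glance(x$fit), trait = x$trait, analysis = x$analysis,
                .before = 1)
}

#' Tidy a Gibbs fit
#'
#' @param x a [gibbs_vc()] result.
#' @param ... unused.
#' @return tibble of posterior means and sds of the variance components.
#' @export
tidy.gibbs_fit <- function(x, ...) {
  tibble::tibble(term = names(x$vc_mean),
                 posterior_mean = unname(x$vc_mean),
                 posterior_sd = unname(x$vc_sd))
}

#' Tidy cross-validation accuracies
#'
#' @param x an [run_cv()] result.
#' @param ... unused.
#' @return per-repeat accuracies (`tidy`) or the one-row summary
#'   (`glance`).
#' @export
tidy.accuracy_result <- function(x, ...) {
  dplyr::mutate(x$per_repeat, model = x$summary$model,
                scheme = x$summary$scheme)
}

#' @rdname tidy.accuracy_result
#' @export
glance.accuracy_result <- function(x, ...) x$summary

#' Boxplot of cross-validated prediction accuracies
#'
#' @param object an `accuracy_result` or a list of them.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.accuracy_result <- function(object, ...) {
  results <- if (inherits(object, "accuracy_result")) list(object) else object
  df <- purrr::map_dfr(results, tidy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$accuracy,
                                   fill = .data$scheme)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "Pearson prediction accuracy",
                  fill = "CV scheme") +
    ggplot2::theme_minimal()
}

#' Biplot-style view of the SCA principal components
#'
#' @param object an [sca_pca()] result.
#' @param ... unused.
#' @return a ggplot of hybrid scores on PC1/PC2.
#' @export
autoplot.sca_pca <- function(object, ...) {
  df <- tibble::as_tibble(object$scores[, 1:2], rownames = "hybrid_id")
  pct <- 100 * object$eigenvalues / sum(object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                  y = sprintf("PC2 (%.1f%%)", pct[2])) +
    ggplot2::theme_minimal()
}

#' Density plot of heterosis estimates by trait and treatment
#'
#' @param het a [heterosis()] table.
#' @param measure `"MPH_pct"` or `"HPH_pct"`.
#' @return a ggplot.
#' @export
plot_heterosis <- function(het, measure = c("MPH_pct", "HPH_pct")) {
  measure <- match.arg(measure)
  ggplot2::ggplot(het, ggplot2::aes(x = .data[[measure]],
                                    fill = .data$treatment)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::labs(x = sub("_pct", " (%)", measure), fill = NULL) +
    ggplot2::theme_minimal()
}
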