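#' Stage-1 adjustment of phenotypes for design effects
#'
#' First stage of the two-stage prediction approach: within each treatment,
#' trait and environment (year), removes block and countertop effects by
#' fixed-effects least squares and returns one adjusted value per genotype
#' and environment (the genotype's estimated marginal mean).
#'
#' @param phenotypes phenotype tibble.
#' @return tibble of class `adjusted_phenotypes` with columns `hybrid_id`,
#'   `env`, `treatment`, `trait`, `value`.
#' @export
stage1_adjust <- function(phenotypes) {
  need <- c("genotype_id", "year", "block", "countertop", "treatment",
            "trait", "value")
  miss <- setdiff(need, names(phenotypes))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- phenotypes |>
    dplyr::group_by(.data$treatment, .data$trait, env = .data$year) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::mutate(d,
        genotype = factor(.data$genotype_id),
        blk = factor(.data$block),
        ctp = factor(paste(.data$block, .data$countertop, sep = ":")))
      n_per <- table(d$genotype)
      if (any(n_per < 2)) {
        warning(sprintf("%d genotypes unreplicated in an environment; retained",
                        sum(n_per < 2)), call. = FALSE)
      }
      f <- if (nlevels(d$blk) > 1) value ~ blk + ctp + genotype
           else value ~ genotype
      fit <- lm(f, data = d)
      em <- summary(suppressMessages(
        emmeans::emmeans(fit, "genotype", weights = "equal")))
      tibble::tibble(hybrid_id = as.character(em$genotype),
                     value = em$emmean)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("hybrid_id", "env", "treatment", "trait", "value")
  class(out) <- c("adjusted_phenotypes", class(out))
  out
}

gp_variants <- c("GB", "GK", "GB+GxE", "GK+GxE")

gp_build_spec <- function(adjusted, C, design, variant, y_override = NULL) {
  if (!variant %in% gp_variants) {
    stop("unknown model variant: ", variant,
         " (use one of ", paste(gp_variants, collapse = ", "), ")",
         call. = FALSE)
  }
  if (dplyr::n_distinct(adjusted$treatment) != 1 ||
      dplyr::n_distinct(adjusted$trait) != 1) {
    stop("supply a single treatment x trait subset", call. = FALSE)
  }
  cr <- canonical_crosses(design)
  hid <- match(adjusted$hybrid_id, cr$hybrid_id)
  if (anyNA(hid)) {
    stop("hybrids missing from the design: ",
         paste(unique(adjusted$hybrid_id[is.na(hid)]), collapse = ", "),
         call. = FALSE)
  }
  parents <- sort(unique(c(cr$parent1, cr$parent2)))
  C <- unclass(as.matrix(C))[parents, parents]
  H <- build_H(C, cr)

  n <- nrow(adjusted)
  Z_E <- indicator(factor(adjusted$env))
  Z_p1 <- matrix(0, n, length(parents), dimnames = list(NULL, parents))
  Z_p2 <- Z_p1
  Z_p1[cbind(seq_len(n), match(cr$parent1[hid], parents))] <- 1
  Z_p2[cbind(seq_len(n), match(cr$parent2[hid], parents))] <- 1
  Z_G <- Z_p1 + Z_p2
  Z_H <- matrix(0, n, nrow(cr), dimnames = list(NULL, cr$hybrid_id))
  Z_H[cbind(seq_len(n), hid)] <- 1

  X <- model.matrix(~ env, data.frame(env = factor(adjusted$env)))
  attr(X, "term_labels") <- "Environment"

  random <- list(GCA = list(Z = Z_G, K = C), SCA = list(Z = Z_H, K = unclass(H)))
  if (grepl("GxE", variant, fixed = TRUE)) {
    V <- build_VG_VH(C, H, Z_G, Z_H, Z_E)
    I_n <- diag(n)
    random$GCAxE <- list(Z = I_n, K = V$V_G)
    random$SCAxE <- list(Z = I_n, K = V$V_H)
  }
  y <- if (is.null(y_override)) adjusted$value else y_override
  mixed_model_spec(y, X, random)
}

#' Fit a genomic prediction model for hybrid performance
#'
#' Second stage of the two-stage approach: fits the across-environment
#' GCA/SCA model `y = Z_E beta_E + Z_G g + Z_H h + e` with `g ~ N(0,
#' sigma2_G C)` (C the GB or GK parental kernel) and `h ~ N(0, sigma2_H H)`,
#' or its multi-environment extension with record-level interaction effects
#' `u_G ~ N(0, sigma2_GE V_G)`, `u_H ~ N(0, sigma2_HE V_H)` (variants
#' `"GB+GxE"` / `"GK+GxE"`), by Gibbs sampling ([gibbs_vc()]). `Z_G` maps a
#' record to both parents (`Z_G = Z_p1 + Z_p2`). Missing adjusted values
#' are predicted.
#'
#' @param adjusted [stage1_adjust()] output restricted to one treatment and
#'   trait (NAs in `value` mark records to predict).
#' @param C parental kernel ([compute_GB()] or [compute_GK()]); the variant
#'   label records which kernel you supplied.
#' @param design diallel design tibble.
#' @param variant one of `"GB"`, `"GK"`, `"GB+GxE"`, `"GK+GxE"`.
#' @param n_iter,burn_in,thin,seed,df0,R2 passed to [gibbs_vc()].
#' @return object of class `gp_fit`: the [gibbs_vc()] result plus
#'   `predictions` (tibble: `hybrid_id`, `env`, `observed`, `predicted`)
#'   and `variant`.
#' @export
fit_prediction_model <- function(adjusted, C, design, variant = "GB",
                                 n_iter = 50000, burn_in = 5000, thin = 1,
                                 seed = NULL, df0 = 5, R2 = 0.5) {
  spec <- gp_build_spec(adjusted, C, design, variant)
  fit <- gibbs_vc(spec, n_iter = n_iter, burn_in = burn_in, thin = thin,
                  seed = seed, df0 = df0, R2 = R2)
  fit$predictions <- tibble::tibble(
    hybrid_id = adjusted$hybrid_id, env = adjusted$env,
    observed = adjusted$value, predicted = fit$pred
  )
  fit$variant <- variant
  class(fit) <- c("gp_fit", class(fit))
  fit
}

#' Cross-validation plan
#'
#' @param scheme `"CV1"` (hybrids untested in every environment) or `"CV2"`
#'   (hybrids tested in some but not all environments).
#' @param k_folds number of folds (>= 2).
#' @param n_repeats number of randomized repetitions.
#' @param seed integer seed for fold assignment.
#' @return list of class `cv_plan`.
#' @export
cv_plan <- function(scheme = c("CV1", "CV2"), k_folds = 5, n_repeats = 100,
                    seed = 1) {
  scheme <- match.arg(scheme)
  if (k_folds < 2) stop("k_folds must be >= 2", call. = FALSE)
  structure(list(scheme = scheme, k_folds = k_folds, n_repeats = n_repeats,
                 seed = seed), class = "cv_plan")
}

#' Cross-validated prediction accuracy
#'
#' Evaluates a prediction model variant under CV1 or CV2. Hybrids are
#' partitioned into `k_folds` validation groups (fold sizes differ by at
#' most one; a fresh seeded shuffle per repeat). Under CV1 every record of
#' a validation hybrid is masked in all environments; under CV2 each
#' validation hybrid is masked in one randomly chosen environment and
#' observed in the rest (requires >= 2 environments). Kernels are built
#' once from all parents; only phenotypes are masked. Per fold the Pearson
#' correlation of predicted versus held-out adjusted values is computed
#' within each environment and averaged; fold values are averaged into one
#' accuracy per repeat.
#'
#' @inheritParams fit_prediction_model
#' @param plan a [cv_plan()].
#' @param n_iter,burn_in chain profile per training fit; the package's
#'   analysis default is 50000/5000, while interactive checks usually run a
#'   scaled-down profile such as 6000/1000.
#' @return object of class `accuracy_result`: `per_repeat` (tibble:
#'   `repeat_id`, `accuracy`), `summary` (tibble: model, scheme, treatment,
#'   trait, mean accuracy, sd, n_repeats).
#' @export
run_cv <- function(adjusted, C, design, variant = "GB", plan = cv_plan(),
                   n_iter = 6000, burn_in = 1000, thin = 1, df0 = 5,
                   R2 = 0.5) {
  stopifnot(inherits(plan, "cv_plan"))
  envs <- unique(adjusted$env)
  if (plan$scheme == "CV2" && length(envs) < 2) {
    stop("CV2 requires at least 2 environments", call. = FALSE)
  }
  hybrids <- unique(adjusted$hybrid_id)
  nh <- length(hybrids)
  spec_template <- gp_build_spec(adjusted, C, design, variant)

  per_repeat <- purrr::map_dfr(seq_len(plan$n_repeats), function(r) {
    set.seed(plan$seed + 7919L * r)
    fold_of <- setNames(sample(rep(seq_len(plan$k_folds), length.out = nh)),
                        hybrids)
    fold_acc <- vapply(seq_len(plan$k_folds), function(f) {
      val_hyb <- hybrids[fold_of[hybrids] == f]
      mask <- if (plan$scheme == "CV1") {
        adjusted$hybrid_id %in% val_hyb
      } else {
        masked_env <- setNames(sample(envs, length(val_hyb), replace = TRUE),
                               val_hyb)
        adjusted$hybrid_id %in% val_hyb &
          adjusted$env == masked_env[adjusted$hybrid_id]
      }
      if (!any(mask)) return(NA_real_)
      spec <- spec_template
      spec$y[mask] <- NA
      fit <- gibbs_vc(spec, n_iter = n_iter, burn_in = burn_in, thin = thin,
                      df0 = df0, R2 = R2)
      held <- tibble::tibble(env = adjusted$env[mask],
                             obs = adjusted$value[mask],
                             pred = fit$pred[mask])
      accs <- held |>
        dplyr::group_by(.data$env) |>
        dplyr::summarise(r = cor_or_na(.data$obs, .data$pred),
                         .groups = "drop")
      mean(accs$r, na.rm = TRUE)
    }, numeric(1))
    tibble::tibble(repeat_id = r, accuracy = mean(fold_acc, na.rm = TRUE))
  })

  summary <- tibble::tibble(
    model = variant, scheme = plan$scheme,
    treatment = adjusted$treatment[1], trait = adjusted$trait[1],
    accuracy = mean(per_repeat$accuracy),
    sd = sd(per_repeat$accuracy),
    n_repeats = plan$n_repeats
  )
  structure(list(per_repeat = per_repeat, summary = summary),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<accuracy_result> %s / %s: mean r = %.3f (sd %.3f, %d repeats)\n",
              s$model, s$scheme, s$accuracy, s$sd, s$n_repeats))
  invisible(x)
}

#' Combine accuracy results into a comparison table
#'
#' @param results list of [run_cv()] results.
#' @return long tibble, one row per model x scheme x treatment x trait.
#' @export
accuracy_report <- function(results) {
  if (inherits(results, "accuracy_result")) results <- list(results)
  if (length(results) == 0) stop("no results supplied", call. = FALSE)
  out <- purrr::map_dfr(results, "summary")
  key <- paste(out$model, out$scheme, out$treatment, out$trait)
  if (anyDuplicated(key)) {
    stop("duplicated model/scheme/treatment/trait rows", call. = FALSE)
  }
  out
}
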