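diallel_fixed_design <- function(df, with_inoculation = TRUE) {
  yr <- factor(df$year)
  blk <- factor(df$block)
  ctp <- factor(df$countertop)
  trt <- factor(df$treatment)
  multi_year <- nlevels(yr) > 1
  if (!multi_year) {
    warning("single year supplied; year terms dropped", call. = FALSE)
  }
  dat <- data.frame(yr = yr, blk = blk, ctp = ctp, trt = trt)
  if (with_inoculation) {
    f <- if (multi_year) {
      ~ yr + yr:blk + yr:blk:ctp + trt + yr:trt
    } else {
      ~ blk + blk:ctp + trt
    }
  } else {
    f <- if (multi_year) ~ yr + yr:blk + yr:blk:ctp else ~ blk + blk:ctp
  }
  X <- model.matrix(f, dat)
  raw <- attr(stats::terms(f), "term.labels")
  pretty <- c(yr = "Year", trt = "Inoculation", `yr:blk` = "Block(Year)",
              `yr:trt` = "YearxInoculation",
              `yr:blk:ctp` = "Countertop(Block)",
              blk = "Block", `blk:ctp` = "Countertop(Block)")
  labels <- unname(pretty[raw])
  # model.matrix assign: 0 = intercept, i = i-th term label
  attr(X, "term_labels") <- labels
  X
}

diallel_random_terms <- function(inc, G, with_inoculation = TRUE,
                                 multi_year = TRUE) {
  parents <- inc$levels$parents
  G <- unclass(as.matrix(G))[parents, parents]
  nE <- length(inc$levels$year)
  terms <- list(
    GCA = list(Z = inc$Z_G, K = G),
    SCA = list(Z = inc$Z_H, K = NULL)
  )
  if (multi_year) {
    terms$GCAxY <- list(Z = inc$Z_GE, K = kronecker(diag(nE), G))
    terms$SCAxY <- list(Z = inc$Z_HE, K = NULL)
  }
  if (with_inoculation) {
    terms$GCAxI <- list(Z = inc$Z_GI, K = kronecker(diag(2), G))
    terms$SCAxI <- list(Z = inc$Z_HI, K = NULL)
  }
  terms
}

fit_diallel_engine <- function(phenotypes, G, design, with_inoculation,
                               do_tests, constrain, tol, max_iter) {
  df <- phenotypes
  if (dplyr::n_distinct(df$trait) != 1) {
    stop("supply a single trait (filter the phenotype table first)",
         call. = FALSE)
  }
  df <- df[df$genotype_id %in% design$hybrid_id, , drop = FALSE]
  if (nrow(df) == 0) stop("no hybrid records", call. = FALSE)
  multi_year <- dplyr::n_distinct(df$year) > 1
  X <- diallel_fixed_design(df, with_inoculation)
  inc <- build_incidence(df, design)
  random <- diallel_random_terms(inc, G, with_inoculation, multi_year)
  spec <- mixed_model_spec(df$value, X, random)
  fit <- fit_reml(spec, tol = tol, max_iter = max_iter, constrain = constrain)

  wald <- lrt <- NULL
  if (do_tests) {
    wald <- purrr::map_dfr(unique(attr(X, "term_labels")),
                           function(tm) wald_fixed(fit, tm))
    lrt <- purrr::map_dfr(names(random), function(nm) {
      red <- fit_reml(mixed_model_spec(df$value, X, random[names(random) != nm]),
                      tol = tol, max_iter = max_iter, constrain = constrain)
      out <- lrt_random(fit, red)
      out$term <- nm
      out[, c("term", "statistic", "df", "p_value")]
    })
  }
  list(fit = fit, wald = wald, lrt = lrt, n = nrow(df))
}

#' Joint diallel analysis across treatments
#'
#' Fits the joint diallel mixed model for one trait over both treatments:
#' fixed year, block-within-year, countertop-within-block, inoculation and
#' year-by-inoculation effects; random GCA (covariance `sigma2_G * G`), SCA
#' (iid), and their year and inoculation interactions with Kronecker
#' covariances `I (x) G` (GCA) and identity (SCA). Fixed effects are tested
#' by Wald chi-square, random effects by boundary-corrected LRT (each term
#' dropped and the model refitted).
#'
#' @param phenotypes phenotype tibble (single trait; hybrids are selected by
#'   membership in `design$hybrid_id`).
#' @param G parental genomic relationship matrix ([compute_GB()]).
#' @param design diallel design tibble.
#' @param do_tests run the Wald and LRT tables (default TRUE; implies one
#'   refit per random term).
#' @param constrain,tol,max_iter passed to [fit_reml()].
#' @return object of class `diallel_fit`: `fit` (the [fit_reml()] result),
#'   `wald`, `lrt` (tibbles), `vc` (tibble of variance components),
#'   `analysis` (`"joint"`), `trait`.
#' @export
fit_joint_diallel <- function(phenotypes, G, design, do_tests = TRUE,
                              constrain = TRUE, tol = 1e-8, max_iter = 500) {
  trts <- unique(phenotypes$treatment)
  if (length(trts) < 2) {
    stop("joint analysis needs both treatments; use fit_individual_diallel()",
         call. = FALSE)
  }
  res <- fit_diallel_engine(phenotypes, G, design, with_inoculation = TRUE,
                            do_tests, constrain, tol, max_iter)
  new_diallel_fit(res, analysis = "joint", trait = phenotypes$trait[1])
}

#' Individual diallel analysis for one treatment
#'
#' Same model as [fit_joint_diallel()] restricted to one treatment's
#' records, disregarding the inoculation effect and its interactions.
#'
#' @inheritParams fit_joint_diallel
#' @param treatment the treatment label to analyze.
#' @export
fit_individual_diallel <- function(phenotypes, G, design, treatment,
                                   do_tests = TRUE, constrain = TRUE,
                                   tol = 1e-8, max_iter = 500) {
  if (!treatment %in% phenotypes$treatment) {
    stop("treatment not present in the phenotypes: ", treatment,
         call. = FALSE)
  }
  df <- phenotypes[phenotypes$treatment == treatment, , drop = FALSE]
  res <- fit_diallel_engine(df, G, design, with_inoculation = FALSE,
                            do_tests, constrain, tol, max_iter)
  new_diallel_fit(res, analysis = treatment, trait = df$trait[1])
}

new_diallel_fit <- function(res, analysis, trait) {
  vc <- tibble::tibble(
    term = names(res$fit$vc),
    variance = unname(res$fit$vc),
    boundary = c(unname(res$fit$boundary), FALSE)
  )
  structure(list(fit = res$fit, wald = res$wald, lrt = res$lrt, vc = vc,
                 analysis = analysis, trait = trait, n = res$n),
            class = "diallel_fit")
}

#' @export
print.diallel_fit <- function(x, ...) {
  cat(sprintf("<diallel_fit> trait %s, analysis %s, n = %d records\n",
              x$trait, x$analysis, x$n))
  print(as.data.frame(x$vc), digits = 4)
  invisible(x)
}

#' Genetic parameters from diallel variance components
#'
#' Converts GCA/SCA/residual variances into additive and dominance genetic
#' variances (`sigma2_a = 4 sigma2_G`, `sigma2_d = 4 sigma2_H`), narrow- and
#' broad-sense heritability
#' (`h2 = sigma2_a / (sigma2_a + sigma2_d + sigma2_e)`,
#' `H2 = (sigma2_a + sigma2_d) / (sigma2_a + sigma2_d + sigma2_e)`) and
#' Baker's ratio (`BR = 2 sigma2_G / (2 sigma2_G + sigma2_H)`), the share of
#' single-cross progeny variance attributable to GCA. Arithmetic is exact;
#' round only for reporting.
#'
#' @param x either a `diallel_fit`, or a data frame with numeric columns
#'   `sigma_G2`, `sigma_H2`, `sigma_e2` (other columns are carried through),
#'   or a named numeric vector with those elements.
#' @return tibble with `sigma_a2`, `sigma_d2`, `h2`, `H2`, `baker` appended.
#' @export
genetic_params <- function(x) {
  if (inherits(x, "diallel_fit")) {
    v <- x$fit$vc
    x <- tibble::tibble(trait = x$trait, analysis = x$analysis,
                        sigma_G2 = v[["GCA"]], sigma_H2 = v[["SCA"]],
                        sigma_e2 = v[["residual"]])
  } else if (is.numeric(x) && !is.null(names(x))) {
    x <- tibble::as_tibble(as.list(x))
  } else {
    x <- tibble::as_tibble(x)
  }
  need <- c("sigma_G2", "sigma_H2", "sigma_e2")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(x$sigma_e2 <= 0)) stop("sigma_e2 must be positive", call. = FALSE)
  if (any(x$sigma_G2 < 0 | x$sigma_H2 < 0)) {
    stop("sigma_G2 and sigma_H2 must be nonnegative", call. = FALSE)
  }
  if (any(x$sigma_G2 + x$sigma_H2 == 0)) {
    stop("all genetic variances are zero; ratios undefined", call. = FALSE)
  }
  dplyr::mutate(
    x,
    sigma_a2 = 4 * .data$sigma_G2,
    sigma_d2 = 4 * .data$sigma_H2,
    h2 = .data$sigma_a2 / (.data$sigma_a2 + .data$sigma_d2 + .data$sigma_e2),
    H2 = (.data$sigma_a2 + .data$sigma_d2) /
      (.data$sigma_a2 + .data$sigma_d2 + .data$sigma_e2),
    baker = 2 * .data$sigma_G2 / (2 * .data$sigma_G2 + .data$sigma_H2)
  )
}

#' Principal-component summary of SCA values
#'
#' PCA of the hybrid-by-trait matrix of SCA predictions. The per-trait
#' contribution to the variation retained by the first two components is
#' `Cont = (C1 * Eig1 + C2 * Eig2) / (Eig1 + Eig2)`, where `C1`, `C2` are
#' the percent contributions of the trait to PC1 and PC2 (squared loadings,
#' summing to 100 within a component) and `Eig1`, `Eig2` the variances
#' retained by the components. Input columns are centered; set
#' `standardize = TRUE` to also scale to unit variance.
#'
#' @param sca numeric matrix or data frame, hybrids in rows, traits in
#'   columns (at least 3 hybrids and 2 traits).
#' @param standardize scale traits to unit variance before the PCA.
#' @return object of class `sca_pca`: `scores`, `eigenvalues`,
#'   `contributions` (tibble: trait, C1, C2, Cont), `var_explained_12`
#'   (percent of variance retained by PC1+PC2), `pca` (the `prcomp` fit).
#' @export
sca_pca <- function(sca, standardize = FALSE) {
  sca <- as.matrix(sca)
  if (nrow(sca) < 3 || ncol(sca) < 2) {
    stop("need at least 3 hybrids and 2 traits", call. = FALSE)
  }
  const <- apply(sca, 2, sd) == 0
  if (any(const)) {
    warning("dropping constant trait columns: ",
            paste(colnames(sca)[const], collapse = ", "), call. = FALSE)
    sca <- sca[, !const, drop = FALSE]
    if (ncol(sca) < 2) stop("fewer than 2 non-constant traits", call. = FALSE)
  }
  pca <- prcomp(sca, center = TRUE, scale. = standardize)
  eig <- pca$sdev^2
  C1 <- 100 * pca$rotation[, 1]^2
  C2 <- 100 * pca$rotation[, 2]^2
  cont <- (C1 * eig[1] + C2 * eig[2]) / (eig[1] + eig[2])
  structure(list(
    scores = pca$x,
    eigenvalues = eig,
    contributions = tibble::tibble(trait = colnames(sca), C1 = unname(C1),
                                   C2 = unname(C2), Cont = unname(cont)),
    var_explained_12 = 100 * sum(eig[1:2]) / sum(eig),
    pca = pca
  ), class = "sca_pca")
}

#' @export
print.sca_pca <- function(x, ...) {
  cat(sprintf("<sca_pca> PC1+PC2 explain %.1f%% of the SCA variance\n",
              x$var_explained_12))
  print(as.data.frame(x$contributions), digits = 3)
  invisible(x)
}

#' Pairwise trait correlation network
#'
#' Pearson correlations between all trait pairs within each treatment,
#' emitted as an edge list (the tabular content of a correlation network;
#' rendering is out of scope).
#'
#' @param values long tibble with columns `genotype_id`, `treatment`,
#'   `trait`, `value` (one value per genotype x treatment x trait, e.g.
#'   BLUP-based genotypic values or adjusted means).
#' @return tibble with columns `treatment`, `trait1`, `trait2`, `r`,
#'   `degenerate` (TRUE when a trait had zero variance, `r` then NA).
#' @export
trait_correlation_network <- function(values) {
  need <- c("genotype_id", "treatment", "trait", "value")
  miss <- setdiff(need, names(values))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  values |>
    dplyr::group_by(.data$treatment) |>
    dplyr::group_modify(function(d, key) {
      wide <- tidyr::pivot_wider(d, id_cols = "genotype_id",
                                 names_from = "trait",
                                 values_from = "value")
      m <- as.matrix(wide[, -1, drop = FALSE])
      if (nrow(m) < 3) stop("need at least 3 genotypes", call. = FALSE)
      traits <- colnames(m)
      sds <- apply(m, 2, sd, na.rm = TRUE)
      pairs <- utils::combn(traits, 2)
      purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
        t1 <- pairs[1, j]; t2 <- pairs[2, j]
        degen <- sds[t1] == 0 || sds[t2] == 0
        tibble::tibble(
          trait1 = t1, trait2 = t2,
          r = if (degen) NA_real_ else
            cor(m[, t1], m[, t2], use = "complete.obs"),
          degenerate = degen
        )
      })
    }) |>
    dplyr::ungroup()
}
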