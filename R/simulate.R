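#' Configuration for a synthetic diallel study
#'
#' Collects the design sizes, variance components and fixed effects used by
#' [simulate_study()]. Defaults emulate the greenhouse design this package
#' targets: 19 inbred parents crossed in an incomplete half-diallel of 118
#' single crosses, evaluated over 2 years x 3 blocks (pots split over 2
#' countertops) under two treatments (N stress, and N stress plus
#' *Azospirillum brasilense* seed inoculation), one plant per pot. Default
#' variance components are the joint-analysis estimates for root volume
#' (cm^3 scale) of the motivating study; default fixed effects are modest
#' year/block/countertop gradients with a positive inoculation effect.
#'
#' @param n_parents number of inbred parents.
#' @param n_markers number of biallelic SNP markers retained after MAF
#'   filtering.
#' @param maf_range allele-frequency interval in (0, 0.5\] from which
#'   per-marker frequencies are drawn; markers whose *empirical* minor
#'   allele frequency falls below `maf_range[1]` are redrawn, so the
#'   simulated panel is already MAF-filtered.
#' @param n_crosses number of single crosses (at most
#'   `n_parents*(n_parents-1)/2`); sampled uniformly at random from the
#'   possible crosses unless `crosses` is supplied.
#' @param crosses optional explicit data frame (`parent1`, `parent2`) of
#'   crosses, overriding random sampling.
#' @param n_years,n_blocks,n_countertops design dimensions; blocks are
#'   nested in years, countertops split each year-block-treatment cell.
#' @param treatments character vector of the two treatment labels
#'   (control first).
#' @param true_vc named list of true variance components: `G` (GCA), `H`
#'   (SCA), `GE` (GCA x year), `HE` (SCA x year), `GI` (GCA x inoculation),
#'   `HI` (SCA x inoculation), `e` (residual). All must be nonnegative.
#' @param fixed_effects named list: `intercept` (scalar), `year` (length
#'   `n_years`), `block` (length `n_blocks`, reused across years),
#'   `countertop` (length `n_countertops`), `inoculation` (length 2),
#'   `year_inoculation` (scalar slope added to treated records of the last
#'   year; 0 by default).
#' @param n_subpops number of parental subpopulations (1 = unstructured
#'   panel, the default; 2 adds a simple allele-frequency divergence
#'   between two halves of the panel).
#' @param missing_rate completely-at-random missing genotype call rate
#'   (default 0: complete data).
#' @param seed integer seed controlling every random draw.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_parents = 19,
                       n_markers = 5000,
                       maf_range = c(0.05, 0.5),
                       n_crosses = 118,
                       crosses = NULL,
                       n_years = 2,
                       n_blocks = 3,
                       n_countertops = 2,
                       treatments = c("Nstress", "NstressAzo"),
                       true_vc = list(G = 3.92, H = 0.63, GE = 0.27,
                                      HE = 0.03, GI = 0.40, HI = 0,
                                      e = 17.75),
                       fixed_effects = list(
                         intercept = 20,
                         year = seq(0, by = 1.5, length.out = n_years),
                         block = c(0, 0.8, -0.5)[seq_len(n_blocks)],
                         countertop = c(0, 0.4)[seq_len(n_countertops)],
                         inoculation = c(0, 1),
                         year_inoculation = 0
                       ),
                       n_subpops = 1,
                       missing_rate = 0,
                       seed = 1) {
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an interval within (0, 0.5]", call. = FALSE)
  }
  max_crosses <- n_parents * (n_parents - 1) / 2
  if (is.null(crosses) && n_crosses > max_crosses) {
    stop(sprintf("n_crosses exceeds the %d possible crosses", max_crosses),
         call. = FALSE)
  }
  vc_names <- c("G", "H", "GE", "HE", "GI", "HI", "e")
  miss <- setdiff(vc_names, names(true_vc))
  if (length(miss) > 0) {
    stop("true_vc missing components: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(unlist(true_vc[vc_names]) < 0)) {
    stop("variance components must be nonnegative", call. = FALSE)
  }
  if (length(treatments) != 2) stop("exactly two treatments", call. = FALSE)
  structure(list(
    n_parents = n_parents, n_markers = n_markers, maf_range = maf_range,
    n_crosses = n_crosses, crosses = crosses, n_years = n_years,
    n_blocks = n_blocks, n_countertops = n_countertops,
    treatments = treatments, true_vc = true_vc[vc_names],
    fixed_effects = fixed_effects, n_subpops = n_subpops,
    missing_rate = missing_rate, seed = seed
  ), class = "sim_config")
}

#' Simulate fully homozygous parental genotypes
#'
#' Draws per-marker allele frequencies uniformly from `cfg$maf_range` and
#' samples each inbred parent's dosage as 0 or 2 (fully homozygous). Markers
#' whose empirical minor allele frequency falls below the lower bound of
#' `maf_range` (including monomorphic draws) are rejected and redrawn, so
#' the returned panel passes MAF filtering by construction. With
#' `cfg$n_subpops = 2`, the panel is split into two halves whose
#' subpopulation allele frequencies are perturbed in opposite directions,
#' emulating mild population structure.
#'
#' @param cfg a [sim_config()].
#' @return a [marker_matrix()] with `cfg$n_parents` rows and
#'   `cfg$n_markers` columns, values in \{0, 2\} (NAs only if
#'   `cfg$missing_rate > 0`).
#' @export
simulate_parents <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_parents
  ids <- sprintf("P%02d", seq_len(n))
  sub <- if (cfg$n_subpops >= 2) rep(1:2, length.out = n) else rep(1L, n)

  collected <- matrix(NA_real_, n, 0)
  while (ncol(collected) < cfg$n_markers) {
    batch <- max(cfg$n_markers - ncol(collected), 64L)
    p <- runif(batch, cfg$maf_range[1], cfg$maf_range[2])
    if (cfg$n_subpops >= 2) {
      shift <- runif(batch, 0, 0.1)
      p1 <- pmin(pmax(p + shift, 0.01), 0.99)
      p2 <- pmin(pmax(p - shift, 0.01), 0.99)
      d <- 2 * matrix(rbinom(n * batch, 1, rep(ifelse(sub == 1, 1, 0), batch) *
                               rep(p1, each = n) +
                               rep(ifelse(sub == 2, 1, 0), batch) *
                               rep(p2, each = n)),
                      n, batch)
    } else {
      d <- 2 * matrix(rbinom(n * batch, 1, rep(p, each = n)), n, batch)
    }
    emp_maf <- minor_allele_freq(colMeans(d) / 2)
    collected <- cbind(collected, d[, emp_maf >= cfg$maf_range[1], drop = FALSE])
  }
  d <- collected[, seq_len(cfg$n_markers), drop = FALSE]
  if (cfg$missing_rate > 0) {
    d[runif(length(d)) < cfg$missing_rate] <- NA_real_
  }
  dimnames(d) <- list(ids, sprintf("M%05d", seq_len(ncol(d))))
  marker_matrix(d)
}

#' Sample an incomplete half-diallel design
#'
#' Samples `n_crosses` parent pairs uniformly at random (without reciprocals
#' or selfs) from all pairwise combinations of `parent_ids`, or canonicalizes
#' an explicit cross list.
#'
#' @param parent_ids character vector of parent labels.
#' @param n_crosses number of crosses to sample.
#' @param crosses optional explicit data frame (`parent1`, `parent2`).
#' @param seed optional seed (used only when sampling).
#' @return tibble (`parent1`, `parent2`, `hybrid_id`) with lexicographically
#'   ordered parent pairs and `hybrid_id = "P01xP05"`-style labels.
#' @export
make_design <- function(parent_ids, n_crosses = NULL, crosses = NULL,
                        seed = NULL) {
  if (is.null(crosses)) {
    all_pairs <- t(utils::combn(sort(parent_ids), 2))
    if (is.null(n_crosses)) n_crosses <- nrow(all_pairs)
    if (n_crosses > nrow(all_pairs)) {
      stop("n_crosses exceeds the number of possible crosses", call. = FALSE)
    }
    if (!is.null(seed)) set.seed(seed)
    pick <- sort(sample.int(nrow(all_pairs), n_crosses))
    crosses <- tibble::tibble(parent1 = all_pairs[pick, 1],
                              parent2 = all_pairs[pick, 2])
  }
  unknown <- setdiff(unique(c(crosses$parent1, crosses$parent2)), parent_ids)
  if (length(unknown) > 0) {
    stop("unknown parent IDs in crosses: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p1 <- pmin(crosses$parent1, crosses$parent2)
  p2 <- pmax(crosses$parent1, crosses$parent2)
  canonical_crosses(tibble::tibble(parent1 = p1, parent2 = p2,
                                   hybrid_id = paste0(p1, "x", p2)))
}

#' Derive F1 hybrid genotypes from parental genotypes
#'
#' Each hybrid locus is the Mendelian combination of two homozygous parents:
#' dosage `(p1 + p2) / 2` on the 0--2 scale, so a locus is heterozygous
#' (dosage 1) exactly when the parents are opposite homozygotes.
#'
#' @param parents a [marker_matrix()] of parental dosages.
#' @param design design tibble (`parent1`, `parent2`, `hybrid_id`).
#' @return a [marker_matrix()] of hybrids in design row order.
#' @export
make_hybrids <- function(parents, design) {
  stopifnot(inherits(parents, "marker_matrix"))
  cr <- canonical_crosses(design)
  i1 <- match(cr$parent1, parents$ids)
  i2 <- match(cr$parent2, parents$ids)
  if (anyNA(i1) || anyNA(i2)) {
    bad <- unique(c(cr$parent1[is.na(i1)], cr$parent2[is.na(i2)]))
    stop("unknown parent IDs: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- (parents$dosages[i1, , drop = FALSE] +
          parents$dosages[i2, , drop = FALSE]) / 2
  rownames(d) <- cr$hybrid_id
  marker_matrix(d)
}

draw_mvn <- function(q, sigma2, Tmat = NULL) {
  z <- rnorm(q)
  if (is.null(Tmat)) sqrt(sigma2) * z else sqrt(sigma2) * as.vector(Tmat %*% z)
}

kernel_root <- function(K, jitter_tol = 1e-8) {
  ev <- eigen(K, symmetric = TRUE)
  # centering makes a genomic relationship matrix rank-deficient by one;
  # only deficiency beyond that (e.g. too few markers) is flagged
  n_null <- sum(ev$values < jitter_tol * max(ev$values))
  if (n_null > 1) {
    warning("near-singular genomic relationship matrix; adding jitter",
            call. = FALSE)
    ev$values <- ev$values + jitter_tol * max(ev$values)
  }
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(K))
}

#' Simulate phenotypes from the joint diallel model
#'
#' Draws GCA effects with covariance `sigma2_G * G` (G the VanRaden kernel of
#' the simulated parents), SCA effects iid, year and inoculation interaction
#' effects with the Kronecker covariances `I (x) G` / `I (x) I`, and adds the
#' fixed year/block/countertop/inoculation effects and homoscedastic Gaussian
#' residual noise. Each hybrid's GCA contribution is the sum of both parents'
#' effects. Each record is one pot (one plant); the countertop is assigned by
#' splitting the hybrids of each year-block-treatment cell over the
#' countertops at random.
#'
#' @param parents [marker_matrix()] of parents.
#' @param design design tibble from [make_design()].
#' @param cfg a [sim_config()].
#' @param G optional precomputed parental kernel; computed by [compute_GB()]
#'   when NULL.
#' @param trait trait label written in the `trait` column (default `"RV"`).
#' @param include_parents also simulate the inbred-line records (parental
#'   per-se value `intercept + 2*u_G + noise`), appended with
#'   `parent1 == parent2 == genotype_id`.
#' @return list with `phenotypes` (tibble: `genotype_id`, `parent1`,
#'   `parent2`, `year`, `block`, `countertop`, `treatment`, `trait`,
#'   `value`) and `truth` (drawn effects and realized components).
#' @export
simulate_phenotypes <- function(parents, design, cfg, G = NULL,
                                trait = "RV", include_parents = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  cr <- canonical_crosses(design)
  vc <- cfg$true_vc
  fe <- cfg$fixed_effects
  parent_ids <- sort(unique(c(cr$parent1, cr$parent2)))
  np <- length(parent_ids)
  nh <- nrow(cr)

  if (is.null(G)) G <- compute_GB(parents)
  G <- G[parent_ids, parent_ids]
  Tg <- kernel_root(G)

  years <- paste0("Y", seq_len(cfg$n_years))
  blocks <- paste0("B", seq_len(cfg$n_blocks))
  ctops <- paste0("C", seq_len(cfg$n_countertops))

  grid <- tidyr::expand_grid(
    hybrid = seq_len(nh),
    year = years, block = blocks, treatment = cfg$treatments
  )
  # split each year-block-treatment cell over the countertops
  grid <- grid |>
    dplyr::group_by(.data$year, .data$block, .data$treatment) |>
    dplyr::mutate(countertop = ctops[
      1 + (sample.int(dplyr::n()) %% cfg$n_countertops)]) |>
    dplyr::ungroup()

  u_G <- draw_mvn(np, vc$G, Tg)
  u_H <- draw_mvn(nh, vc$H)
  u_GE <- matrix(draw_mvn(np * cfg$n_years, vc$GE,
                          kronecker(diag(cfg$n_years), Tg)),
                 np, cfg$n_years)
  u_HE <- matrix(draw_mvn(nh * cfg$n_years, vc$HE), nh, cfg$n_years)
  u_GI <- matrix(draw_mvn(np * 2, vc$GI, kronecker(diag(2), Tg)), np, 2)
  u_HI <- matrix(draw_mvn(nh * 2, vc$HI), nh, 2)
  names(u_G) <- parent_ids
  rownames(u_GE) <- rownames(u_GI) <- parent_ids
  names(u_H) <- cr$hybrid_id
  rownames(u_HE) <- rownames(u_HI) <- cr$hybrid_id

  iy <- match(grid$year, years)
  ib <- match(grid$block, blocks)
  ic <- match(grid$countertop, ctops)
  it <- match(grid$treatment, cfg$treatments)
  i1 <- match(cr$parent1[grid$hybrid], parent_ids)
  i2 <- match(cr$parent2[grid$hybrid], parent_ids)

  fixed_part <- fe$intercept + fe$year[iy] + fe$block[ib] +
    fe$countertop[ic] + fe$inoculation[it] +
    fe$year_inoculation * (iy == cfg$n_years) * (it == 2)
  genetic_part <- u_G[i1] + u_G[i2] + u_H[grid$hybrid] +
    u_GE[cbind(i1, iy)] + u_GE[cbind(i2, iy)] + u_HE[cbind(grid$hybrid, iy)] +
    u_GI[cbind(i1, it)] + u_GI[cbind(i2, it)] + u_HI[cbind(grid$hybrid, it)]
  eps <- rnorm(nrow(grid), 0, sqrt(vc$e))

  phen <- tibble::tibble(
    genotype_id = cr$hybrid_id[grid$hybrid],
    parent1 = cr$parent1[grid$hybrid],
    parent2 = cr$parent2[grid$hybrid],
    year = grid$year, block = grid$block, countertop = grid$countertop,
    treatment = grid$treatment, trait = trait,
    value = unname(fixed_part + genetic_part + eps)
  )

  if (include_parents) {
    pgrid <- tidyr::expand_grid(parent = parent_ids, year = years,
                                block = blocks, treatment = cfg$treatments)
    pgrid <- pgrid |>
      dplyr::group_by(.data$year, .data$block, .data$treatment) |>
      dplyr::mutate(countertop = ctops[
        1 + (sample.int(dplyr::n()) %% cfg$n_countertops)]) |>
      dplyr::ungroup()
    ip <- match(pgrid$parent, parent_ids)
    jy <- match(pgrid$year, years)
    jb <- match(pgrid$block, blocks)
    jc <- match(pgrid$countertop, ctops)
    jt <- match(pgrid$treatment, cfg$treatments)
    pfix <- fe$intercept + fe$year[jy] + fe$block[jb] + fe$countertop[jc] +
      fe$inoculation[jt] + fe$year_inoculation * (jy == cfg$n_years) * (jt == 2)
    pval <- pfix + 2 * u_G[ip] + 2 * u_GE[cbind(ip, jy)] +
      2 * u_GI[cbind(ip, jt)] + rnorm(nrow(pgrid), 0, sqrt(vc$e))
    phen <- dplyr::bind_rows(phen, tibble::tibble(
      genotype_id = pgrid$parent, parent1 = pgrid$parent,
      parent2 = pgrid$parent, year = pgrid$year, block = pgrid$block,
      countertop = pgrid$countertop, treatment = pgrid$treatment,
      trait = trait, value = unname(pval)
    ))
  }

  list(
    phenotypes = phen,
    truth = list(u_G = u_G, u_H = u_H, u_GE = u_GE, u_HE = u_HE,
                 u_GI = u_GI, u_HI = u_HI, vc = vc, fixed = fe, G = G)
  )
}

#' Simulate a complete synthetic diallel study
#'
#' Runs [simulate_parents()], [make_design()], [make_hybrids()] and
#' [simulate_phenotypes()] under a single seed, returning every piece a
#' downstream analysis needs. Bitwise reproducible for a fixed `cfg`.
#'
#' @inheritParams simulate_phenotypes
#' @param cfg a [sim_config()].
#' @return list of class `simulated_study`: `parents`, `hybrids`, `design`,
#'   `phenotypes`, `truth`, `G`, `cfg`.
#' @export
simulate_study <- function(cfg, trait = "RV", include_parents = FALSE) {
  parents <- simulate_parents(cfg)  # sets the seed
  design <- make_design(parents$ids, cfg$n_crosses, cfg$crosses)
  hybrids <- make_hybrids(parents, design)
  qc <- if (anyNA(parents$dosages)) {
    suppressMessages(qc_markers(parents, maf_min = cfg$maf_range[1]))
  } else parents
  G <- compute_GB(qc)
  sim <- simulate_phenotypes(qc, design, cfg, G = G, trait = trait,
                             include_parents = include_parents)
  structure(list(parents = parents, hybrids = hybrids, design = design,
                 phenotypes = sim$phenotypes, truth = sim$truth,
                 G = G, cfg = cfg),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> %d parents, %d crosses, %d phenotype records\n",
    x$cfg$n_parents, nrow(x$design), nrow(x$phenotypes)
  ))
  invisible(x)
}
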