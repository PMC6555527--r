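#' Adjusted genotype means per treatment
#'
#' Least-squares (estimated marginal) genotype means adjusted for the
#' experimental design: within each treatment and trait the fixed model
#' `value ~ year + block(year) + countertop(block) + genotype +
#' genotype:year` is fitted and genotype means are averaged over the design
#' factors on equal weights. Hybrids and inbred lines are processed as
#' separate sets (they were grown as individual experiments); a record is a
#' line when `parent1 == parent2`.
#'
#' @param phenotypes phenotype tibble ([read_phenotypes()] layout).
#' @param genotype_by_year include the genotype-by-year interaction
#'   (default TRUE; dropped automatically for single-year data).
#' @return tibble with columns `genotype_id`, `set` (`"hybrid"`/`"line"`),
#'   `treatment`, `trait`, `adj_mean`, `se`. Non-estimable means (genotype
#'   absent in a year) are NA with a warning.
#' @export
adjusted_means <- function(phenotypes, genotype_by_year = TRUE) {
  need <- c("genotype_id", "parent1", "parent2", "year", "block",
            "countertop", "treatment", "trait", "value")
  miss <- setdiff(need, names(phenotypes))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- dplyr::mutate(phenotypes,
                      set = ifelse(.data$parent1 == .data$parent2,
                                   "line", "hybrid"))
  df |>
    dplyr::group_by(.data$set, .data$treatment, .data$trait) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::mutate(d,
        genotype = factor(.data$genotype_id),
        yr = factor(.data$year),
        blk = factor(paste(.data$year, .data$block, sep = ":")),
        ctp = factor(paste(.data$year, .data$block, .data$countertop,
                           sep = ":")))
      multi_year <- nlevels(d$yr) > 1
      f <- if (multi_year) {
        if (genotype_by_year) value ~ yr + blk + ctp + genotype + genotype:yr
        else value ~ yr + blk + ctp + genotype
      } else {
        value ~ blk + ctp + genotype
      }
      fit <- lm(f, data = d)
      em <- suppressMessages(
        emmeans::emmeans(fit, "genotype", weights = "equal")
      )
      es <- summary(em)
      if (anyNA(es$emmean)) {
        warning(sprintf(
          "%d genotype means not estimable (genotype absent in a year)",
          sum(is.na(es$emmean))), call. = FALSE)
      }
      tibble::tibble(genotype_id = as.character(es$genotype),
                     adj_mean = es$emmean, se = es$SE)
    }) |>
    dplyr::ungroup()
}

#' Mid-parent and high-parent heterosis percentages
#'
#' `MPH(%) = 100 * (F1 - MP) / MP` and `HPH(%) = 100 * (F1 - BP) / BP`,
#' where `MP = (P1 + P2) / 2` is the mid-parent mean and `BP` the better
#' (larger-mean) parent. Records with a zero denominator are flagged and
#' left NA.
#'
#' @param F1,P1,P2 numeric vectors of hybrid and parental means.
#' @return tibble with `F1`, `MP`, `BP`, `MPH_pct`, `HPH_pct`,
#'   `degenerate`.
#' @export
heterosis_pct <- function(F1, P1, P2) {
  MP <- (P1 + P2) / 2
  BP <- pmax(P1, P2)
  degen <- MP == 0 | BP == 0
  if (any(degen)) {
    warning(sprintf("%d records with zero mid- or better-parent mean flagged",
                    sum(degen)), call. = FALSE)
  }
  tibble::tibble(
    F1 = F1, MP = MP, BP = BP,
    MPH_pct = ifelse(degen, NA_real_, 100 * (F1 - MP) / MP),
    HPH_pct = ifelse(degen, NA_real_, 100 * (F1 - BP) / BP),
    degenerate = degen
  )
}

#' Heterosis table from adjusted means
#'
#' Joins each hybrid's adjusted mean with its parents' line means per
#' treatment and trait and computes [heterosis_pct()]. Supply only the
#' traits for which heterosis is meaningful (typically those with a
#' significant inoculation effect in the joint diallel analysis).
#'
#' @param adj_means output of [adjusted_means()] (both sets).
#' @param design diallel design tibble.
#' @param traits optional character vector restricting the traits.
#' @return tibble with `hybrid_id`, `parent1`, `parent2`, `treatment`,
#'   `trait` and the [heterosis_pct()] columns.
#' @export
heterosis <- function(adj_means, design, traits = NULL) {
  cr <- canonical_crosses(design)
  hy <- dplyr::filter(adj_means, .data$set == "hybrid",
                      .data$genotype_id %in% cr$hybrid_id)
  ln <- dplyr::filter(adj_means, .data$set == "line")
  if (!is.null(traits)) {
    hy <- dplyr::filter(hy, .data$trait %in% traits)
    ln <- dplyr::filter(ln, .data$trait %in% traits)
  }
  lnv <- dplyr::select(ln, "genotype_id", "treatment", "trait",
                       line_mean = "adj_mean")
  hy |>
    dplyr::left_join(cr, by = c(genotype_id = "hybrid_id")) |>
    dplyr::left_join(dplyr::rename(lnv, P1_mean = "line_mean"),
                     by = c(parent1 = "genotype_id", "treatment", "trait")) |>
    dplyr::left_join(dplyr::rename(lnv, P2_mean = "line_mean"),
                     by = c(parent2 = "genotype_id", "treatment", "trait")) |>
    (\(d) dplyr::bind_cols(
      dplyr::select(d, hybrid_id = "genotype_id", "parent1", "parent2",
                    "treatment", "trait"),
      heterosis_pct(d$adj_mean, d$P1_mean, d$P2_mean)
    ))()
}

#' Inoculation response per hybrid
#'
#' `delta = T2 - T1` between the hybrid's adjusted means under the
#' inoculated (`T2`) and control (`T1`) treatments, per trait, plus the 15%
#' bottom and top responder subsets (subset size `round(frac * n)`, ties
#' broken by hybrid ID through a stable sort). Hybrids present under only
#' one treatment are excluded with a message.
#'
#' @param adj_means output of [adjusted_means()] (hybrid set).
#' @param control,inoculated the two treatment labels.
#' @param frac subset fraction (default 0.15).
#' @return tibble with `hybrid_id`, `trait`, `T1`, `T2`, `delta`, `group`
#'   (`"bottom"`, `"mid"`, `"top"`).
#' @export
delta_response <- function(adj_means, control, inoculated, frac = 0.15) {
  hy <- dplyr::filter(adj_means,
                      !("set" %in% names(adj_means)) | .data$set == "hybrid")
  wide <- hy |>
    dplyr::filter(.data$treatment %in% c(control, inoculated)) |>
    tidyr::pivot_wider(id_cols = c("genotype_id", "trait"),
                       names_from = "treatment", values_from = "adj_mean")
  if (!all(c(control, inoculated) %in% names(wide))) {
    stop("both treatment levels must be present", call. = FALSE)
  }
  dropped <- is.na(wide[[control]]) | is.na(wide[[inoculated]])
  if (any(dropped)) {
    message(sprintf("delta_response: excluded %d hybrid x trait cells present under one treatment",
                    sum(dropped)))
    wide <- wide[!dropped, , drop = FALSE]
  }
  out <- tibble::tibble(
    hybrid_id = wide$genotype_id, trait = wide$trait,
    T1 = wide[[control]], T2 = wide[[inoculated]],
    delta = wide[[inoculated]] - wide[[control]]
  )
  out |>
    dplyr::group_by(.data$trait) |>
    dplyr::group_modify(function(d, key) {
      n_sub <- round(frac * nrow(d))
      ord <- order(d$delta, d$hybrid_id)   # stable tie-break by hybrid ID
      grp <- rep("mid", nrow(d))
      if (n_sub > 0) {
        grp[ord[seq_len(n_sub)]] <- "bottom"
        grp[ord[nrow(d) + 1 - seq_len(n_sub)]] <- "top"
      }
      d$group <- grp
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("hybrid_id")
}

cor_or_na <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])
}

#' Correlations of heterozygosity, performance and inoculation response
#'
#' Pearson correlations, per trait, of genomic heterozygosity with the
#' hybrids' adjusted means under each treatment and with the inoculation
#' response delta, and of delta with the control-treatment means (the
#' negative relation indicating that hybrids performing worse under N
#' stress respond more to inoculation). Constant inputs give NA with
#' `degenerate = TRUE`.
#'
#' @param het tibble from [heterozygosity()].
#' @param adj_means hybrid adjusted means ([adjusted_means()]).
#' @param deltas tibble from [delta_response()].
#' @param control,inoculated treatment labels.
#' @return tibble with `trait`, `comparison`, `r`, `n`, `degenerate`.
#' @export
heterozygosity_correlations <- function(het, adj_means, deltas,
                                        control, inoculated) {
  hy <- dplyr::filter(adj_means,
                      !("set" %in% names(adj_means)) | .data$set == "hybrid")
  if (nrow(het) < 3) stop("need at least 3 hybrids", call. = FALSE)
  purrr::map_dfr(unique(deltas$trait), function(tr) {
    d <- dplyr::filter(deltas, .data$trait == tr)
    m1 <- dplyr::filter(hy, .data$trait == tr, .data$treatment == control)
    m2 <- dplyr::filter(hy, .data$trait == tr, .data$treatment == inoculated)
    h <- het$heterozygosity[match(d$hybrid_id, het$hybrid_id)]
    h1 <- het$heterozygosity[match(m1$genotype_id, het$hybrid_id)]
    h2 <- het$heterozygosity[match(m2$genotype_id, het$hybrid_id)]
    res <- tibble::tibble(
      trait = tr,
      comparison = c("het_vs_control_mean", "het_vs_inoculated_mean",
                     "het_vs_delta", "delta_vs_control_mean"),
      r = c(cor_or_na(h1, m1$adj_mean), cor_or_na(h2, m2$adj_mean),
            cor_or_na(h, d$delta), cor_or_na(d$delta, d$T1)),
      n = c(sum(stats::complete.cases(h1, m1$adj_mean)),
            sum(stats::complete.cases(h2, m2$adj_mean)),
            sum(stats::complete.cases(h, d$delta)),
            sum(stats::complete.cases(d$delta, d$T1)))
    )
    res$degenerate <- is.na(res$r)
    res
  })
}
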