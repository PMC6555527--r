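indicator <- function(f, prefix = NULL) {
  f <- factor(f)
  Z <- matrix(0, length(f), nlevels(f))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  colnames(Z) <- if (is.null(prefix)) levels(f) else paste0(prefix, levels(f))
  Z
}

#' Incidence matrices for the diallel mixed model
#'
#' Builds the full set of fixed- and random-effect indicator matrices for
#' the joint diallel model from a phenotype table and the cross design.
#' Nesting is honored: block levels are defined within year, countertop
#' within block-by-year. `Z_G` maps every record to BOTH parents of its
#' hybrid (row sums 2) and equals `Z_p1 + Z_p2`; `Z_H` maps each record to
#' its single cross (row sums 1). Interaction incidences (`Z_GE`, `Z_HE`,
#' `Z_GI`, `Z_HI`) index effects ordered as (environment or treatment level)
#' x (parent or hybrid), matching the Kronecker covariances `I (x) G` used
#' by [fit_joint_diallel()].
#'
#' @param phenotypes phenotype tibble with columns `genotype_id`, `year`,
#'   `block`, `countertop`, `treatment` (single trait; see
#'   [read_phenotypes()]). Factor columns must be complete.
#' @param design diallel design tibble (`parent1`, `parent2`, `hybrid_id`).
#' @return a list of class `incidence_set` with elements `X_E`, `X_B`,
#'   `X_C`, `X_I`, `X_EI`, `Z_E`, `Z_G`, `Z_H`, `Z_GE`, `Z_HE`, `Z_GI`,
#'   `Z_HI`, `Z_p1`, `Z_p2`, plus `levels` (a list of factor levels).
#' @export
build_incidence <- function(phenotypes, design) {
  need <- c("genotype_id", "year", "block", "countertop", "treatment")
  miss <- setdiff(need, names(phenotypes))
  if (length(miss) > 0) {
    stop("phenotypes missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(phenotypes[need])) {
    stop("design factors contain missing values", call. = FALSE)
  }
  cr <- canonical_crosses(design)
  hid <- match(phenotypes$genotype_id, cr$hybrid_id)
  if (anyNA(hid)) {
    stop("hybrids without recorded parents: ",
         paste(unique(phenotypes$genotype_id[is.na(hid)]), collapse = ", "),
         call. = FALSE)
  }

  yr <- factor(phenotypes$year)
  blk <- factor(paste(phenotypes$year, phenotypes$block, sep = ":"))
  ctp <- factor(paste(phenotypes$year, phenotypes$block, phenotypes$countertop,
                      sep = ":"))
  trt <- factor(phenotypes$treatment)
  yrtrt <- factor(paste(phenotypes$year, phenotypes$treatment, sep = ":"))

  parent_ids <- sort(unique(c(cr$parent1, cr$parent2)))
  Z_p1 <- matrix(0, nrow(phenotypes), length(parent_ids),
                 dimnames = list(NULL, parent_ids))
  Z_p2 <- Z_p1
  Z_p1[cbind(seq_len(nrow(phenotypes)), match(cr$parent1[hid], parent_ids))] <- 1
  Z_p2[cbind(seq_len(nrow(phenotypes)), match(cr$parent2[hid], parent_ids))] <- 1
  Z_G <- Z_p1 + Z_p2

  Z_H <- matrix(0, nrow(phenotypes), nrow(cr),
                dimnames = list(NULL, cr$hybrid_id))
  Z_H[cbind(seq_len(nrow(phenotypes)), hid)] <- 1

  # effect index (level, genotype) ordered level-major to match I (x) K
  cross_ind <- function(Zin, f) {
    lev <- levels(f)
    out <- matrix(0, nrow(Zin), length(lev) * ncol(Zin),
                  dimnames = list(NULL, as.vector(outer(
                    colnames(Zin), lev, function(g, l) paste(l, g, sep = ":")
                  ))))
    for (k in seq_along(lev)) {
      rows <- f == lev[k]
      cols <- (k - 1) * ncol(Zin) + seq_len(ncol(Zin))
      out[rows, cols] <- Zin[rows, , drop = FALSE]
    }
    out
  }

  structure(list(
    X_E = indicator(yr), X_B = indicator(blk), X_C = indicator(ctp),
    X_I = indicator(trt), X_EI = indicator(yrtrt),
    Z_E = indicator(yr),
    Z_G = Z_G, Z_H = Z_H,
    Z_GE = cross_ind(Z_G, yr), Z_HE = cross_ind(Z_H, yr),
    Z_GI = cross_ind(Z_G, trt), Z_HI = cross_ind(Z_H, trt),
    Z_p1 = Z_p1, Z_p2 = Z_p2,
    levels = list(year = levels(yr), block = levels(blk),
                  countertop = levels(ctp), treatment = levels(trt),
                  parents = parent_ids, hybrids = cr$hybrid_id)
  ), class = "incidence_set")
}

#' Record-level genotype-by-environment covariances V_G and V_H
#'
#' Builds the multi-environment interaction covariances as Hadamard
#' (entrywise) products: `V_G = (Z_G G Z_G') * (Z_E Z_E')` and
#' `V_H = (Z_H H Z_H') * (Z_E Z_E')`, so that two records covary through
#' the genomic kernels only when they share the environment.
#'
#' @param C parental covariance (GB or GK).
#' @param H hybrid SCA kernel from [build_H()].
#' @param Z_G,Z_H,Z_E incidence matrices at the record level (columns of
#'   `Z_G` must match `rownames(C)`, of `Z_H` `rownames(H)`).
#' @return list with symmetric PSD matrices `V_G` and `V_H`.
#' @export
build_VG_VH <- function(C, H, Z_G, Z_H, Z_E) {
  n <- nrow(Z_G)
  if (nrow(Z_H) != n || nrow(Z_E) != n) {
    stop("incidence row counts differ (Z_G/Z_H/Z_E)", call. = FALSE)
  }
  if (ncol(Z_G) != nrow(C)) stop("Z_G does not match C", call. = FALSE)
  if (ncol(Z_H) != nrow(H)) stop("Z_H does not match H", call. = FALSE)
  E <- tcrossprod(Z_E)
  V_G <- (Z_G %*% C %*% t(Z_G)) * E
  V_H <- (Z_H %*% H %*% t(Z_H)) * E
  list(V_G = (V_G + t(V_G)) / 2, V_H = (V_H + t(V_H)) / 2)
}
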