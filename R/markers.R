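#' Marker matrix objects
#'
#' A `marker_matrix` holds SNP dosages on the 0--2 minor/alternate allele
#' count scale for a set of genotypes (inbred parents or hybrids), together
#' with per-marker allele frequencies. Inbred lines carry only dosages 0 and
#' 2; an F1 hybrid of two opposite homozygotes carries dosage 1.
#'
#' @param dosages numeric matrix, genotypes in rows, markers in columns,
#'   values in \[0, 2\] (NA allowed for missing calls). Row and column names
#'   are used as genotype and marker identifiers; defaults are generated
#'   when absent.
#' @return An object of class `marker_matrix`: a list with elements
#'   `dosages`, `ids`, `allele_freqs` (alternate-allele frequency per
#'   marker, computed over non-missing calls) and `m` (marker count).
#' @export
marker_matrix <- function(dosages) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("G%02d", seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("M%05d", seq_len(ncol(dosages)))
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  structure(
    list(
      dosages = dosages,
      ids = rownames(dosages),
      allele_freqs = colMeans(dosages, na.rm = TRUE) / 2,
      m = ncol(dosages)
    ),
    class = "marker_matrix"
  )
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf(
    "<marker_matrix> %d genotypes x %d markers (%.2f%% missing)\n",
    nrow(x$dosages), x$m, 100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$dosages)

minor_allele_freq <- function(p) pmin(p, 1 - p)

#' Marker quality control
#'
#' Removes markers with low call rate or low minor allele frequency and
#' mean-imputes the remaining missing calls, the standard preparation for
#' genomic relationship matrices. Counts of retained/removed markers are
#' attached as the `"qc_report"` attribute and reported via `message()`.
#'
#' @param M a [marker_matrix()].
#' @param maf_min minimum minor allele frequency; markers below are dropped.
#' @param callrate_min minimum fraction of non-missing calls per marker.
#' @return A filtered, imputed `marker_matrix`, with attribute `qc_report`
#'   (a tibble with columns `n_input`, `n_callrate_removed`,
#'   `n_maf_removed`, `n_retained`, `n_imputed`).
#' @export
qc_markers <- function(M, maf_min = 0.05, callrate_min = 0.95) {
  stopifnot(inherits(M, "marker_matrix"))
  if (nrow(M$dosages) < 2) stop("need at least 2 genotypes", call. = FALSE)
  d <- M$dosages
  callrate <- colMeans(!is.na(d))
  keep_cr <- callrate >= callrate_min
  p <- colMeans(d, na.rm = TRUE) / 2
  keep_maf <- minor_allele_freq(p) >= maf_min & !is.nan(p)
  keep <- keep_cr & keep_maf
  if (!any(keep)) {
    stop(sprintf(
      "all %d markers removed by QC (%d call-rate, %d MAF)",
      ncol(d), sum(!keep_cr), sum(keep_cr & !keep_maf)
    ), call. = FALSE)
  }
  d <- d[, keep, drop = FALSE]
  n_imputed <- sum(is.na(d))
  if (n_imputed > 0) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  out <- marker_matrix(d)
  report <- tibble::tibble(
    n_input = ncol(M$dosages),
    n_callrate_removed = sum(!keep_cr),
    n_maf_removed = sum(keep_cr & !keep_maf),
    n_retained = ncol(d),
    n_imputed = n_imputed
  )
  attr(out, "qc_report") <- report
  message(sprintf(
    "qc_markers: retained %d/%d markers (%d call-rate, %d MAF removals), imputed %d calls",
    report$n_retained, report$n_input, report$n_callrate_removed,
    report$n_maf_removed, report$n_imputed
  ))
  out
}

#' Centered and standardized marker matrix W
#'
#' Centers dosages by twice the allele frequency (2p) and scales each marker,
#' by default by `sqrt(2p(1-p))` (VanRaden scaling, so that `WW'/m` has
#' average diagonal near 1 for unrelated genotypes); `method = "unit"` scales
#' by the empirical standard deviation instead. Zero-variance markers are
#' dropped with a warning.
#'
#' @param M a [marker_matrix()] (complete; run [qc_markers()] first if needed).
#' @param method `"vanraden"` (default) or `"unit"`.
#' @return numeric matrix W with the same genotype rows; attribute
#'   `"dropped"` holds names of excluded zero-variance markers.
#' @export
standardize_markers <- function(M, method = c("vanraden", "unit")) {
  stopifnot(inherits(M, "marker_matrix"))
  method <- match.arg(method)
  d <- M$dosages
  if (anyNA(d)) stop("missing dosages; run qc_markers() first", call. = FALSE)
  p <- colMeans(d) / 2
  sds <- if (method == "vanraden") sqrt(2 * p * (1 - p)) else apply(d, 2, sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance markers", sum(!keep)),
            call. = FALSE)
  }
  W <- sweep(d[, keep, drop = FALSE], 2, 2 * p[keep], "-")
  W <- sweep(W, 2, sds[keep], "/")
  attr(W, "dropped") <- colnames(d)[!keep]
  W
}

new_kernel <- function(C, kind, ...) {
  C <- (C + t(C)) / 2
  attr(C, "kind") <- kind
  extra <- list(...)
  for (nm in names(extra)) attr(C, nm) <- extra[[nm]]
  class(C) <- c("genomic_kernel", class(C))
  C
}

#' @export
print.genomic_kernel <- function(x, ...) {
  cat(sprintf("<genomic_kernel %s> %d x %d\n", attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

#' VanRaden genomic relationship matrix (G-BLUP kernel)
#'
#' Computes the linear genomic kernel `GB = WW'/m` from the centered and
#' standardized marker matrix W, the covariance used for GCA effects in
#' G-BLUP.
#'
#' @inheritParams standardize_markers
#' @return a symmetric PSD `genomic_kernel` matrix (kind `"GB"`) with
#'   genotype dimnames.
#' @export
compute_GB <- function(M, method = c("vanraden", "unit")) {
  stopifnot(inherits(M, "marker_matrix"))
  if (M$m < 1) stop("need at least one marker", call. = FALSE)
  if (nrow(M$dosages) < 2) stop("need at least 2 genotypes", call. = FALSE)
  W <- standardize_markers(M, method)
  C <- tcrossprod(W) / ncol(W)
  new_kernel(C, "GB", m = ncol(W))
}

#' Gaussian kernel (RKHS) relationship matrix
#'
#' Computes `GK = exp(-h * d2)` where `d2` is the squared Euclidean distance
#' between genotype rows of the standardized marker matrix W and `h` is the
#' bandwidth. With `scale = "mean_offdiag"` (default) the distances are first
#' divided by their mean off-diagonal value so that `h = 1` acts at a
#' comparable decay rate regardless of the marker count; `scale = "none"`
#' applies the raw squared distances.
#'
#' @inheritParams standardize_markers
#' @param h nonnegative bandwidth (default 1).
#' @param scale `"mean_offdiag"` or `"none"`.
#' @return a `genomic_kernel` (kind `"GK"`) with unit diagonal; attributes
#'   `h` and `d2` (the scaled squared-distance matrix).
#' @export
compute_GK <- function(M, h = 1, scale = c("mean_offdiag", "none"),
                       method = c("vanraden", "unit")) {
  stopifnot(inherits(M, "marker_matrix"))
  scale <- match.arg(scale)
  if (h < 0) stop("bandwidth h must be nonnegative", call. = FALSE)
  if (nrow(M$dosages) < 2) {
    stop("Gaussian kernel undefined for a single genotype", call. = FALSE)
  }
  W <- standardize_markers(M, method)
  d2 <- as.matrix(stats::dist(W))^2
  if (scale == "mean_offdiag") {
    off <- mean(d2[upper.tri(d2)])
    if (off > 0) d2 <- d2 / off
  }
  C <- exp(-h * d2)
  diag(C) <- 1
  new_kernel(C, "GK", h = h, d2 = d2, scale = scale)
}

canonical_crosses <- function(design) {
  stopifnot(all(c("parent1", "parent2", "hybrid_id") %in% names(design)))
  if (any(design$parent1 == design$parent2)) {
    stop("self crosses are not allowed in a diallel design", call. = FALSE)
  }
  p1 <- pmin(design$parent1, design$parent2)
  p2 <- pmax(design$parent1, design$parent2)
  key <- paste(p1, p2, sep = "\r")
  if (anyDuplicated(key)) {
    stop("reciprocal/duplicate crosses present; collapse them first", call. = FALSE)
  }
  tibble::tibble(parent1 = p1, parent2 = p2, hybrid_id = design$hybrid_id)
}

#' Hybrid SCA relationship matrix H
#'
#' Builds the hybrid-level kernel from a parental covariance matrix C (GB or
#' GK): the entry for hybrids (i,j) and (i',j') is `C[i,i'] * C[j,j']`, the
#' genetic covariance between two single crosses under the dominance/SCA
#' model. Parent pairs are canonically ordered (lexicographic) first;
#' reciprocal crosses are not modeled.
#'
#' @param C parental covariance matrix with parent dimnames (a
#'   `genomic_kernel` or plain matrix).
#' @param design data frame with columns `parent1`, `parent2`, `hybrid_id`.
#' @return a symmetric `genomic_kernel` (kind `"H"`) over the hybrids, in
#'   the design's row order.
#' @export
build_H <- function(C, design) {
  cr <- canonical_crosses(design)
  missing <- setdiff(unique(c(cr$parent1, cr$parent2)), rownames(C))
  if (length(missing) > 0) {
    stop("parents missing from C: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  i1 <- match(cr$parent1, rownames(C))
  i2 <- match(cr$parent2, rownames(C))
  H <- C[i1, i1, drop = FALSE] * C[i2, i2, drop = FALSE]
  dimnames(H) <- list(cr$hybrid_id, cr$hybrid_id)
  new_kernel(unclass(H), "H")
}

#' Genomic heterozygosity per hybrid
#'
#' The fraction of markers at which a hybrid is heterozygous (dosage 1),
#' i.e. loci where its parents are opposite homozygotes.
#'
#' @param hybrids a [marker_matrix()] of hybrid dosages.
#' @return tibble with columns `hybrid_id` and `heterozygosity` in \[0, 1\].
#' @export
heterozygosity <- function(hybrids) {
  stopifnot(inherits(hybrids, "marker_matrix"))
  if (hybrids$m == 0) stop("no markers", call. = FALSE)
  tibble::tibble(
    hybrid_id = hybrids$ids,
    heterozygosity = unname(rowMeans(hybrids$dosages == 1, na.rm = TRUE))
  )
}

#' Check a kernel for symmetric positive semidefiniteness
#'
#' @param C matrix.
#' @param tol relative eigenvalue tolerance.
#' @return TRUE/FALSE.
#' @export
is_psd <- function(C, tol = 1e-8) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev[length(ev)] >= -tol * max(abs(ev[1]), 1)
}
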