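test_that("marker_matrix validates and summarizes dosages", {
  d <- rbind(P01 = c(0, 2, 2, 0), P02 = c(2, 2, 0, 0), P03 = c(0, 0, 2, 2))
  colnames(d) <- paste0("M", 1:4)
  M <- marker_matrix(d)
  expect_s3_class(M, "marker_matrix")
  expect_equal(dim(M), c(3L, 4L))
  expect_equal(unname(M$allele_freqs), c(1/3, 2/3, 2/3, 1/3))
  expect_equal(M$m, 4L)
  expect_error(marker_matrix(d - 1), "must lie in")
  expect_error(marker_matrix(d + 1), "must lie in")
})

test_that("qc_markers filters by call rate and MAF and mean-imputes", {
  # M1 fine, M2 low MAF (1/8), M3 half missing, M4 fine with one NA
  d <- cbind(M1 = c(0, 2, 2, 0), M2 = c(0, 0, 0, 1),
             M3 = c(NA, NA, 2, 0), M4 = c(0, 2, NA, 2))
  rownames(d) <- paste0("P", 1:4)
  M <- marker_matrix(d)
  out <- suppressMessages(qc_markers(M, maf_min = 0.2, callrate_min = 0.75))
  rep <- attr(out, "qc_report")
  expect_equal(colnames(out$dosages), c("M1", "M4"))
  expect_equal(rep$n_input, 4L)
  expect_equal(rep$n_callrate_removed, 1L)
  expect_equal(rep$n_maf_removed, 1L)
  expect_equal(rep$n_retained, 2L)
  expect_equal(rep$n_imputed, 1L)
  # mean imputation: M4 mean over observed = (0+2+2)/3
  expect_equal(out$dosages["P3", "M4"], 4/3)
  expect_false(anyNA(out$dosages))
  expect_error(suppressMessages(qc_markers(M, maf_min = 0.6)),
               "all 4 markers removed")
})

test_that("standardize_markers centers by 2p and scales by sqrt(2p(1-p))", {
  d <- rbind(A = c(0, 2), B = c(2, 2), C = c(2, 0), D = c(0, 0))
  colnames(d) <- c("M1", "M2")
  W <- standardize_markers(marker_matrix(d))
  p <- colMeans(d) / 2
  manual <- sweep(sweep(d, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  expect_equal(unclass(W), manual, ignore_attr = TRUE)
  expect_equal(colMeans(W), c(M1 = 0, M2 = 0))
  # zero-variance marker dropped with a warning
  d2 <- cbind(d, M3 = c(2, 2, 2, 2))
  expect_warning(W2 <- standardize_markers(marker_matrix(d2)),
                 "zero-variance")
  expect_equal(attr(W2, "dropped"), "M3")
  expect_equal(ncol(W2), 2L)
})

test_that("compute_GB matches a naive loop implementation", {
  set.seed(11)
  M <- simulate_parents(sim_config(n_parents = 7, n_markers = 60,
                                   n_crosses = 10, seed = 11))
  GB <- compute_GB(M)
  # independent oracle: explicit loops over genotypes and markers
  d <- M$dosages
  p <- colMeans(d) / 2
  n <- nrow(d); m <- ncol(d)
  W <- matrix(0, n, m)
  for (i in seq_len(n)) for (k in seq_len(m)) {
    W[i, k] <- (d[i, k] - 2 * p[k]) / sqrt(2 * p[k] * (1 - p[k]))
  }
  G0 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    G0[i, j] <- sum(W[i, ] * W[j, ]) / m
  }
  expect_lt(max(abs(unclass(GB) - G0)), 1e-10)
  expect_true(is_psd(GB))
  expect_equal(attr(GB, "kind"), "GB")
})

test_that("compute_GK matches a naive loop implementation and has unit diagonal", {
  set.seed(12)
  M <- simulate_parents(sim_config(n_parents = 6, n_markers = 50,
                                   n_crosses = 10, seed = 12))
  h <- 0.3
  GK <- compute_GK(M, h = h, scale = "none")
  W <- standardize_markers(M)
  n <- nrow(W)
  G0 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    G0[i, j] <- exp(-h * sum((W[i, ] - W[j, ])^2))
  }
  expect_lt(max(abs(unclass(GK) - G0)), 1e-10)
  expect_equal(unname(diag(GK)), rep(1, n))
  # h = 0 gives the all-ones matrix; larger h decays off-diagonals
  GK0 <- compute_GK(M, h = 0, scale = "none")
  expect_equal(unclass(GK0), matrix(1, n, n), ignore_attr = TRUE)
  GK2 <- compute_GK(M, h = 2 * h, scale = "none")
  off <- upper.tri(GK)
  expect_true(all(GK2[off] <= GK[off] + 1e-12))
  # mean_offdiag scaling normalizes the mean off-diagonal squared distance
  GKs <- compute_GK(M, h = 1, scale = "mean_offdiag")
  d2 <- attr(GKs, "d2")
  expect_equal(mean(d2[upper.tri(d2)]), 1)
  expect_error(compute_GK(M, h = -1), "nonnegative")
})

test_that("build_H matches a naive loop and canonicalizes parent order", {
  set.seed(13)
  M <- simulate_parents(sim_config(n_parents = 6, n_markers = 80,
                                   n_crosses = 10, seed = 13))
  C <- compute_GB(M)
  design <- make_design(M$ids, n_crosses = 9, seed = 13)
  H <- build_H(C, design)
  nh <- nrow(design)
  H0 <- matrix(0, nh, nh)
  for (a in seq_len(nh)) for (b in seq_len(nh)) {
    H0[a, b] <- C[design$parent1[a], design$parent1[b]] *
      C[design$parent2[a], design$parent2[b]]
  }
  expect_lt(max(abs(unclass(H) - H0)), 1e-10)
  expect_equal(rownames(H), design$hybrid_id)
  # swapping parent order must not change H
  swapped <- design
  swapped$parent1 <- design$parent2
  swapped$parent2 <- design$parent1
  expect_equal(unclass(build_H(C, swapped)), unclass(H))
  # selfs and duplicated reciprocals rejected
  selfed <- design
  selfed$parent2[1] <- selfed$parent1[1]
  expect_error(build_H(C, selfed), "self crosses")
  dup <- rbind(design, design[1, ])
  expect_error(build_H(C, dup), "reciprocal/duplicate")
})

test_that("build_VG_VH matches a naive loop implementation", {
  set.seed(14)
  M <- simulate_parents(sim_config(n_parents = 5, n_markers = 60,
                                   n_crosses = 8, seed = 14))
  C <- unclass(compute_GB(M))
  design <- make_design(M$ids, n_crosses = 6, seed = 14)
  H <- unclass(build_H(C, design))
  # 6 hybrids x 2 environments
  env <- rep(c("Y1", "Y2"), each = 6)
  hyb <- rep(seq_len(6), times = 2)
  n <- length(env)
  parents <- sort(M$ids)
  Z_G <- matrix(0, n, 5, dimnames = list(NULL, parents))
  Z_H <- matrix(0, n, 6)
  for (r in seq_len(n)) {
    Z_G[r, design$parent1[hyb[r]]] <- Z_G[r, design$parent1[hyb[r]]] + 1
    Z_G[r, design$parent2[hyb[r]]] <- Z_G[r, design$parent2[hyb[r]]] + 1
    Z_H[r, hyb[r]] <- 1
  }
  Z_E <- cbind(as.numeric(env == "Y1"), as.numeric(env == "Y2"))
  V <- build_VG_VH(C, H, Z_G, Z_H, Z_E)
  # oracle: record-level covariance with explicit loops
  VG0 <- matrix(0, n, n); VH0 <- matrix(0, n, n)
  for (r in seq_len(n)) for (s in seq_len(n)) {
    same_env <- as.numeric(env[r] == env[s])
    g <- 0
    for (a in parents) for (b in parents) {
      g <- g + Z_G[r, a] * Z_G[s, b] * C[a, b]
    }
    VG0[r, s] <- g * same_env
    VH0[r, s] <- H[hyb[r], hyb[s]] * same_env
  }
  expect_lt(max(abs(V$V_G - VG0)), 1e-10)
  expect_lt(max(abs(V$V_H - VH0)), 1e-10)
  expect_true(is_psd(V$V_G))
  expect_true(is_psd(V$V_H))
})

test_that("heterozygosity counts dosage-1 loci and agrees with parental differences", {
  d <- rbind(P1 = c(0, 0, 2, 2), P2 = c(2, 0, 2, 0))
  colnames(d) <- paste0("M", 1:4)
  parents <- marker_matrix(d)
  design <- tibble::tibble(parent1 = "P1", parent2 = "P2",
                           hybrid_id = "P1xP2")
  hy <- make_hybrids(parents, design)
  het <- heterozygosity(hy)
  # parents differ at M1 and M4 only
  expect_equal(het$heterozygosity, 0.5)
  expect_equal(het$hybrid_id, "P1xP2")
  # identical to the fraction of loci where the parents differ
  expect_equal(het$heterozygosity, mean(d["P1", ] != d["P2", ]))
})
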