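test_that("heterosis_pct trivial cases hold exactly", {
  # F1 equal to the mid-parent: MPH = 0; equal to the better parent: HPH = 0
  out <- heterosis_pct(F1 = c(10, 12), P1 = c(8, 8), P2 = c(12, 12))
  expect_equal(out$MP, c(10, 10))
  expect_equal(out$BP, c(12, 12))
  expect_equal(out$MPH_pct, c(0, 20))
  expect_equal(out$HPH_pct, c(-100 * 2 / 12, 0))
  expect_false(any(out$degenerate))
  # hand-checked asymmetric case
  h <- heterosis_pct(15, 5, 10)
  expect_equal(h$MPH_pct, 100)   # (15 - 7.5) / 7.5
  expect_equal(h$HPH_pct, 50)    # (15 - 10) / 10
})

test_that("heterosis percentages are scale invariant and ordered", {
  set.seed(51)
  F1 <- runif(50, 5, 20); P1 <- runif(50, 5, 20); P2 <- runif(50, 5, 20)
  a <- heterosis_pct(F1, P1, P2)
  b <- heterosis_pct(7.3 * F1, 7.3 * P1, 7.3 * P2)
  expect_equal(a$MPH_pct, b$MPH_pct)
  expect_equal(a$HPH_pct, b$HPH_pct)
  # for positive values BP >= MP, so HPH <= MPH
  expect_true(all(a$HPH_pct <= a$MPH_pct + 1e-12))
})

test_that("heterosis_pct flags zero denominators", {
  expect_warning(out <- heterosis_pct(5, 0, 0), "zero mid- or better-parent")
  expect_true(out$degenerate)
  expect_true(is.na(out$MPH_pct))
  expect_true(is.na(out$HPH_pct))
})

test_that("adjusted_means recovers genotype values exactly in a balanced noise-free design", {
  # value = genotype effect + block effect; equal-weight marginal means must
  # recover the genotype effects up to a common constant
  gts <- c(A = 1, B = 3, C = 6)
  blocks <- c(B1 = 0, B2 = 10)
  grid <- expand.grid(genotype_id = names(gts), block = names(blocks),
                      countertop = c("C1", "C2"),
                      stringsAsFactors = FALSE)
  ph <- tibble::tibble(
    genotype_id = grid$genotype_id,
    parent1 = grid$genotype_id, parent2 = grid$genotype_id,  # a line set
    year = "Y1", block = grid$block, countertop = grid$countertop,
    treatment = "ctrl", trait = "t",
    value = gts[grid$genotype_id] + blocks[grid$block]
  )
  am <- suppressWarnings(adjusted_means(ph))  # perfect fit warns in lm
  expect_equal(am$set, rep("line", 3))
  est <- setNames(am$adj_mean, am$genotype_id)
  expect_equal(est - est["A"], gts - gts["A"], tolerance = 1e-10,
               ignore_attr = TRUE)
  # the block contrast is removed: each mean equals genotype + mean(block)
  expect_equal(unname(est), unname(gts + mean(blocks)), tolerance = 1e-10)
})

test_that("heterosis() joins hybrids with their parents' line means", {
  design <- tibble::tibble(parent1 = c("P1", "P1"), parent2 = c("P2", "P3"),
                           hybrid_id = c("P1xP2", "P1xP3"))
  am <- tibble::tibble(
    genotype_id = c("P1xP2", "P1xP3", "P1", "P2", "P3"),
    set = c("hybrid", "hybrid", "line", "line", "line"),
    treatment = "ctrl", trait = "t",
    adj_mean = c(12, 9, 8, 12, 4), se = 0.1
  )
  het <- heterosis(am, design)
  expect_equal(nrow(het), 2L)
  r1 <- het[het$hybrid_id == "P1xP2", ]
  expect_equal(r1$MP, 10)
  expect_equal(r1$BP, 12)
  expect_equal(r1$MPH_pct, 20)
  expect_equal(r1$HPH_pct, 0)
  r2 <- het[het$hybrid_id == "P1xP3", ]
  expect_equal(r2$MP, 6)
  expect_equal(r2$MPH_pct, 50)
  expect_equal(r2$HPH_pct, 12.5)
})

test_that("delta_response computes deltas and the 15% responder groups", {
  n <- 118
  ids <- sprintf("H%03d", seq_len(n))
  set.seed(52)
  t1 <- rnorm(n, 10)
  dlt <- rnorm(n)
  am <- dplyr::bind_rows(
    tibble::tibble(genotype_id = ids, set = "hybrid", treatment = "ctrl",
                   trait = "t", adj_mean = t1, se = 0.1),
    tibble::tibble(genotype_id = ids, set = "hybrid", treatment = "azo",
                   trait = "t", adj_mean = t1 + dlt, se = 0.1)
  )
  out <- delta_response(am, control = "ctrl", inoculated = "azo")
  expect_equal(nrow(out), n)
  expect_equal(out$delta, out$T2 - out$T1)
  expect_equal(unname(out$delta[match(ids, out$hybrid_id)]), dlt)
  # subset size round(0.15 * 118) = 18 at each extreme
  expect_equal(sum(out$group == "bottom"), 18L)
  expect_equal(sum(out$group == "top"), 18L)
  expect_equal(sum(out$group == "mid"), n - 36L)
  # groups are the actual extremes of the delta distribution
  expect_lt(max(out$delta[out$group == "bottom"]),
            min(out$delta[out$group == "mid"]))
  expect_gt(min(out$delta[out$group == "top"]),
            max(out$delta[out$group == "mid"]))
})

test_that("delta_response breaks ties stably and handles one-sided hybrids", {
  am <- dplyr::bind_rows(
    tibble::tibble(genotype_id = c("H1", "H2", "H3"), set = "hybrid",
                   treatment = "ctrl", trait = "t", adj_mean = 1, se = 0.1),
    tibble::tibble(genotype_id = c("H1", "H2", "H3"), set = "hybrid",
                   treatment = "azo", trait = "t", adj_mean = 2, se = 0.1)
  )
  # all deltas tie at 1: bottom/top picked by hybrid ID deterministically
  out <- delta_response(am, "ctrl", "azo", frac = 0.34)
  expect_equal(out$group[out$hybrid_id == "H1"], "bottom")
  expect_equal(out$group[out$hybrid_id == "H3"], "top")
  # a hybrid missing one treatment is excluded with a message
  am2 <- am[-(1:1), ]  # drop H1's control record
  expect_message(out2 <- delta_response(am2, "ctrl", "azo"),
                 "excluded 1 hybrid")
  expect_false("H1" %in% out2$hybrid_id)
  expect_error(delta_response(am[am$treatment == "ctrl", ], "ctrl", "azo"),
               "both treatment levels")
})

test_that("heterozygosity_correlations recovers constructed correlations", {
  set.seed(53)
  n <- 40
  ids <- sprintf("H%02d", seq_len(n))
  t1 <- rnorm(n, 10)
  dlt <- -t1 + 10            # exactly r(delta, T1) = -1
  hetv <- runif(n, 0.1, 0.5)
  am <- dplyr::bind_rows(
    tibble::tibble(genotype_id = ids, set = "hybrid", treatment = "ctrl",
                   trait = "t", adj_mean = t1, se = 0.1),
    tibble::tibble(genotype_id = ids, set = "hybrid", treatment = "azo",
                   trait = "t", adj_mean = hetv * 100, se = 0.1)
  )
  deltas <- tibble::tibble(hybrid_id = ids, trait = "t", T1 = t1,
                           T2 = t1 + dlt, delta = dlt, group = "mid")
  het <- tibble::tibble(hybrid_id = ids, heterozygosity = hetv)
  out <- heterozygosity_correlations(het, am, deltas, "ctrl", "azo")
  expect_equal(nrow(out), 4L)
  get <- function(cmp) out$r[out$comparison == cmp]
  expect_equal(get("delta_vs_control_mean"), -1)
  expect_equal(get("het_vs_inoculated_mean"), 1)  # means constructed from het
  expect_equal(unique(out$n), n)
  expect_false(any(out$degenerate))
})

test_that("heterozygosity_correlations flags degenerate inputs", {
  ids <- c("H1", "H2", "H3", "H4")
  am <- dplyr::bind_rows(
    tibble::tibble(genotype_id = ids, set = "hybrid", treatment = "ctrl",
                   trait = "t", adj_mean = 5, se = 0.1),  # constant
    tibble::tibble(genotype_id = ids, set = "hybrid", treatment = "azo",
                   trait = "t", adj_mean = rnorm(4), se = 0.1)
  )
  deltas <- tibble::tibble(hybrid_id = ids, trait = "t", T1 = 5,
                           T2 = rnorm(4), delta = rnorm(4), group = "mid")
  het <- tibble::tibble(hybrid_id = ids, heterozygosity = runif(4))
  out <- heterozygosity_correlations(het, am, deltas, "ctrl", "azo")
  ctrl_row <- out[out$comparison == "het_vs_control_mean", ]
  expect_true(ctrl_row$degenerate)
  expect_true(is.na(ctrl_row$r))
})
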