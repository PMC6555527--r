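# small study shared across tests: 8 parents, 16 crosses, 2 years x 2 blocks
small_cfg <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_parents = 8, n_markers = 400, n_crosses = 16,
         n_years = 2, n_blocks = 2, seed = seed),
    list(...)
  )
  do.call(sim_config, args)
}

small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(small_cfg(), include_parents = TRUE)
    }
    cache
  }
})

# toy marker matrix with hand-set dosages
toy_markers <- function(d) {
  marker_matrix(d)
}

# GCA/SCA simulation without marker data: direct draws from the
# across-treatment diallel covariance structure (independent of the
# package's own generator; used as a parameter-recovery oracle)
sim_gca_sca <- function(n_parents, crosses, n_years, n_blocks, n_trt,
                        s2_G, s2_H, s2_e, G = diag(n_parents), seed = 1) {
  set.seed(seed)
  parents <- sprintf("P%02d", seq_len(n_parents))
  rownames(G) <- colnames(G) <- parents
  design <- make_design(parents, crosses)
  cr <- design
  u_G <- as.vector(t(chol(G + diag(1e-8, n_parents))) %*% rnorm(n_parents)) *
    sqrt(s2_G)
  names(u_G) <- parents
  u_H <- rnorm(nrow(cr), 0, sqrt(s2_H))
  grid <- expand.grid(hybrid = seq_len(nrow(cr)),
                      year = paste0("Y", seq_len(n_years)),
                      block = paste0("B", seq_len(n_blocks)),
                      treatment = paste0("T", seq_len(n_trt)),
                      stringsAsFactors = FALSE)
  y <- 10 + u_G[cr$parent1[grid$hybrid]] + u_G[cr$parent2[grid$hybrid]] +
    u_H[grid$hybrid] + rnorm(nrow(grid), 0, sqrt(s2_e))
  phen <- tibble::tibble(
    genotype_id = cr$hybrid_id[grid$hybrid],
    parent1 = cr$parent1[grid$hybrid], parent2 = cr$parent2[grid$hybrid],
    year = grid$year, block = grid$block, countertop = "C1",
    treatment = grid$treatment, trait = "sim", value = unname(y)
  )
  list(phenotypes = phen, design = design, G = G,
       u_G = u_G, u_H = u_H)
}
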