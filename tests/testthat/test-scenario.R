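coarse_ddg <- function() build_grid("ddg", -2, 13, 1)

test_that("folding-only between-allele doubles are exactly additive", {
  res <- run_scenario("model1", grid = coarse_ddg(),
                      combinations = "between")
  expect_true(all(abs(res$e_add) <= 1e-12))
  # ... but not log-additive for destabilizing pairs
  det <- res$ddG_A > 1 & res$ddG_B > 1 & res$E_log_defined
  expect_true(all(res$E_log[det] < 0))
})

test_that("scenario tables are deterministic and label-symmetric", {
  run <- function() run_scenario("model2", config = system_config(ligand_ratio = 1),
                                 grid = coarse_ddg(),
                                 combinations = c("within", "between",
                                                  "compound_het"))
  r1 <- run(); r2 <- run()
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  for (kind in c("within", "between", "compound_het")) {
    d <- r1[r1$combination == kind, ]
    key_fwd <- paste(d$ddG_A, d$ddG_B)
    key_rev <- paste(d$ddG_B, d$ddG_A)
    expect_equal(d$W_obs[match(key_rev, key_fwd)], d$W_obs,
                 tolerance = 1e-12)
  }
})

test_that("infeasible phenotype targets are dropped and counted", {
  expect_warning(
    res <- run_scenario("model2", grid = build_grid("phenotype_single",
                                                    step = 0.02),
                        combinations = "between"),
    regexp = NA)   # warnings are absorbed into the run summary
  m <- attr(res, "meta")
  expect_gt(m$dropped[["single"]], 0)   # the 1.02 AU ceiling is unattainable
  n_kept <- sqrt(nrow(res))
  expect_equal(n_kept, round(n_kept))   # full ordered-pair square survives
})

test_that("expectations and clamps operate on the transformed scale", {
  lk <- linking_spec("concave", 1.5)
  res <- run_scenario("model2", grid = coarse_ddg(),
                      combinations = "within", linking = lk)
  # recompute one interior row by hand on the transformed scale
  i <- which(res$ddG_A == 2 & res$ddG_B == 3)
  p <- energy_params(); cfg <- system_config()
  wA <- apply_linking(model2_phenotype(genotype(allele(ddG_folding = 2)), p, cfg), lk)
  wB <- apply_linking(model2_phenotype(genotype(allele(ddG_folding = 3)), p, cfg), lk)
  wAB <- apply_linking(model2_phenotype(genotype(allele(ddG_folding = 5)), p, cfg), lk)
  expect_equal(res$W_A[i], wA, tolerance = 1e-12)
  expect_equal(res$W_exp_add[i], max(0.5, wA + wB - 1), tolerance = 1e-12)
  expect_equal(res$e_add[i], wAB - max(0.5, wA + wB - 1), tolerance = 1e-12)
  # deep-detrimental corner: the transformed clamp must have engaged
  corner <- res$ddG_A == 13 & res$ddG_B == 13
  expect_true(all(res$clamp_add[corner]))
  expect_equal(res$W_exp_add[corner], 0.5)
})

test_that("dominance weakens as ligand becomes abundant", {
  max_dom <- vapply(c(1, 2, 10), function(r) {
    res <- run_scenario("model2", config = system_config(ligand_ratio = r),
                        grid = coarse_ddg(), combinations = "compound_het")
    max(abs(res$degree[res$degree_defined]), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(max_dom) < 0))
  expect_gt(max_dom[1], 0.1)    # clear dominance at ratio 1
  expect_lt(max_dom[3], 0.05)   # nearly additive at ratio 10
})

test_that("between-allele interactions decay like 1/ratio towards additivity", {
  # the residual floor is physical: the free-ligand shift between mutant and
  # wild-type cells is O(X_T), so deviations scale as O(X_T / L_T)
  resid_at <- function(ratio) {
    res <- run_scenario("model2", config = system_config(ligand_ratio = ratio),
                        grid = build_grid("ddg", -2, 13, 1),
                        combinations = "between")
    max(abs(res$W_obs - (res$W_A + res$W_B - 1)))
  }
  r <- vapply(c(1e2, 1e3, 1e4, 1e6), resid_at, 0)
  expect_true(all(diff(r) < 0))
  expect_lt(r[2] / r[1], 0.2)      # about one decade per decade of ligand
  expect_lt(r[4], 1e-6)            # full decoupling deep in ligand excess
})

test_that("inconsistent model / mutation-type requests are rejected", {
  expect_error(run_scenario("model1", mutation_type = "binding"),
               "folding-only")
  expect_error(run_scenario("model1", grid = build_grid("phenotype_homozygote"),
                            combinations = "within"))
})
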