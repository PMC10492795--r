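test_that("every solved equilibrium satisfies both conservation laws", {
  set.seed(42)
  p <- energy_params()
  for (ratio in c(0.8, 1, 2, 10)) {
    cfg <- system_config(ligand_ratio = ratio)
    for (k in 1:25) {
      g <- genotype(
        allele(rnorm(1, 2, 3), rnorm(1, 2, 3), runif(1) > 0.1),
        allele(rnorm(1, 2, 3), rnorm(1, 2, 3), runif(1) > 0.1))
      eq <- model2_equilibrium(g, p, cfg)
      expect_true(all(eq$species >= 0))
      expect_lt(abs(eq$free_ligand + sum(eq$species[, "bound"]) - cfg$L_T) /
                  cfg$L_T, 1e-10)
      for (i in 1:2) {
        a <- if (i == 1) g$allele1 else g$allele2
        tot <- sum(eq$species[i, ])
        if (a$expressed) expect_lt(abs(tot - 0.5) / 0.5, 1e-10)
        else expect_identical(tot, 0)
      }
    }
  }
})

test_that("degenerate ligand regimes behave as limits", {
  p <- energy_params()
  # no ligand at all
  eq0 <- model2_equilibrium(genotype(), p, system_config(ligand_ratio = 0))
  expect_identical(eq0$free_ligand, 0)
  expect_identical(unname(eq0$species[, "bound"]), c(0, 0))
  # binding abolished on both alleles: all ligand stays free
  g <- genotype(allele(ddG_binding = 1000), allele(ddG_binding = 1000))
  eq <- model2_equilibrium(g, p, system_config(ligand_ratio = 1))
  expect_equal(eq$free_ligand, 1, tolerance = 1e-9)
})

test_that("free ligand agrees with a dense scan of the conservation function", {
  p <- energy_params()
  cases <- list(
    list(ddg = c(0, 0, 0, 0), ratio = 10),
    list(ddg = c(0, 0, 0, 0), ratio = 0.8),
    list(ddg = c(3, 0, 0, 0), ratio = 1),
    list(ddg = c(2, 1, -1, 2), ratio = 2))
  for (cs in cases) {
    cfg <- system_config(ligand_ratio = cs$ratio)
    g <- genotype(allele(cs$ddg[1], cs$ddg[2]), allele(cs$ddg[3], cs$ddg[4]))
    eq <- model2_equilibrium(g, p, cfg)
    K1 <- oracle_m2_K(cs$ddg[1], cs$ddg[2])
    K2 <- oracle_m2_K(cs$ddg[3], cs$ddg[4])
    L_star <- oracle_free_ligand(K1, K2, 0.5, 0.5, cfg$L_T)
    expect_equal(eq$free_ligand, L_star, tolerance = 1e-9)
  }
  # wild type at ligand excess: essentially all protein is complexed
  eq10 <- model2_equilibrium(genotype(), p, system_config(ligand_ratio = 10))
  expect_gt(sum(eq10$species[, "bound"]), 0.999)
  expect_equal(eq10$free_ligand, 10 - sum(eq10$species[, "bound"]),
               tolerance = 1e-10)
})

test_that("binding-model phenotypes match the printed closed forms", {
  p <- energy_params()
  cfg <- system_config(ligand_ratio = 1)
  Kwt <- oracle_m2_K(0, 0)
  Lwt <- oracle_free_ligand(Kwt, Kwt, 0.5, 0.5, cfg$L_T)
  cases <- expand.grid(ddg_f = c(-1, 0, 1, 2.5, 6),
                       ddg_b = c(0, 1.5, 4))
  for (r in seq_len(nrow(cases))) {
    a <- cases$ddg_f[r]; b <- cases$ddg_b[r]
    KA <- oracle_m2_K(a, b)
    # single heterozygote
    L <- oracle_free_ligand(KA, Kwt, 0.5, 0.5, cfg$L_T)
    expect_equal(
      model2_phenotype(genotype(allele(a, b)), p, cfg),
      oracle_m2_single(KA, L, Lwt, Kwt), tolerance = 1e-8)
    # homozygote
    Lh <- oracle_free_ligand(KA, KA, 0.5, 0.5, cfg$L_T)
    expect_equal(
      model2_phenotype(genotype(allele(a, b), allele(a, b)), p, cfg),
      oracle_m2_homo(KA, Lh, Lwt, Kwt), tolerance = 1e-8)
    # between-allele double against a second mutation
    KB <- oracle_m2_K(b, a)
    Lb <- oracle_free_ligand(KA, KB, 0.5, 0.5, cfg$L_T)
    expect_equal(
      model2_phenotype(genotype(allele(a, b), allele(b, a)), p, cfg),
      oracle_m2_between(KA, KB, Lb, Lwt, Kwt), tolerance = 1e-8)
  }
})

test_that("ligand limitation reproduces the null-heterozygote arithmetic", {
  p <- energy_params()
  g_null_het <- genotype(null_allele(), allele())
  # scarce ligand: half the protein still binds 0.5/0.8 of the reference
  w08 <- model2_phenotype(g_null_het, p, system_config(ligand_ratio = 0.8))
  expect_equal(w08, 0.625, tolerance = 1e-3)
  # ligand excess: alleles decouple and the phenotype halves
  w10 <- model2_phenotype(g_null_het, p, system_config(ligand_ratio = 10))
  expect_equal(w10, 0.5, tolerance = 1e-3)
  expect_identical(model2_phenotype(genotype(), p, system_config()), 1)
})

test_that("phenotype is non-increasing in each energy component", {
  p <- energy_params()
  cfg <- system_config(ligand_ratio = 1)
  ddg <- seq(-4, 14, 0.5)
  w_f <- vapply(ddg, function(a)
    model2_phenotype(genotype(allele(ddG_folding = a)), p, cfg), 0)
  w_b <- vapply(ddg, function(a)
    model2_phenotype(genotype(allele(ddG_binding = a)), p, cfg), 0)
  expect_true(all(diff(w_f) <= 1e-12))
  expect_true(all(diff(w_b) <= 1e-12))
})
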