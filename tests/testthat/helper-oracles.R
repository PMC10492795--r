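# Independent oracles: printed closed forms evaluated term by term, and a
# staged dense scan of the ligand conservation function. These deliberately
# avoid the package's internal computation paths.

RT_DEF <- 1.98e-3 * 310.15

# folding-only model, closed forms (G = wild-type folding energy)
oracle_m1_single <- function(a, G = -2, rt = RT_DEF) {
  (2 + exp(G / rt) + exp((G + a) / rt)) / (2 * (1 + exp((G + a) / rt)))
}
oracle_m1_between <- function(a, b, G = -2, rt = RT_DEF) {
  (1 + exp(G / rt)) * (2 + exp((G + a) / rt) + exp((G + b) / rt)) /
    (2 * (1 + exp((G + a) / rt)) * (1 + exp((G + b) / rt)))
}
oracle_m1_within <- function(a, b, G = -2, rt = RT_DEF) {
  oracle_m1_single(a + b, G, rt)
}
oracle_m1_homo <- function(a, G = -2, rt = RT_DEF) {
  (1 + exp(G / rt)) / (1 + exp((G + a) / rt))
}

# lumped per-allele constant of the binding model, written out explicitly
oracle_m2_K <- function(ddg_f, ddg_b, Gf = -2, Gb = -5, rt = RT_DEF) {
  exp((Gb + ddg_b) / rt) * (1 + exp((Gf + ddg_f) / rt))
}

# free ligand by staged scan of the monotone conservation function
oracle_free_ligand <- function(K1, K2, w1, w2, LT, stages = 4, pts = 2000) {
  if (LT == 0) return(0)
  g <- function(L) L + L * (w1 / (L + K1) + w2 / (L + K2)) - LT
  lo <- 0; hi <- LT
  for (s in seq_len(stages)) {
    grid <- seq(lo, hi, length.out = pts)
    i <- which(g(grid) >= 0)[1]
    hi <- grid[i]
    lo <- grid[max(i - 1L, 1L)]
  }
  0.5 * (lo + hi)
}

# binding-model phenotypes from the printed closed forms, given the free
# ligand in the mutant cell (L) and in the wild-type cell (Lwt)
oracle_m2_between <- function(KA, KB, L, Lwt, Kwt) {
  L * (Lwt + Kwt) * (2 * L + KA + KB) / (2 * Lwt * (L + KA) * (L + KB))
}
oracle_m2_single <- function(KA, L, Lwt, Kwt) {
  oracle_m2_between(KA, Kwt, L, Lwt, Kwt)
}
oracle_m2_homo <- function(KA, L, Lwt, Kwt) {
  L * (Lwt + Kwt) / (Lwt * (L + KA))
}

# three replicate means with mean mu and standard error exactly se
mu_rep <- function(mu, se) mu + c(-1, 0, 1) * se * sqrt(3)

# hand-built mutant summary with prescribed phenotype and SE
summary_fix <- function(gfp, se) {
  structure(list(gfp_obs = gfp, se_obs = se, n_replicates = 3, batch = 1),
            class = "mutant_summary")
}

# small event-table builder for gating tests
make_events <- function(fsc, ssc, gfp = 100, genotype = "g", replicate = 1,
                        batch = 1) {
  data.frame(FSC_A = fsc, SSC_A = ssc, GFP = gfp, genotype = genotype,
             replicate = replicate, batch = batch)
}
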