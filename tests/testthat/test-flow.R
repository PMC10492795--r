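test_that("the scatter gate applies the linear SSC boundary", {
  gate <- gate_spec()
  # upper SSC bound at FSC-A = 5000 is log10(0.93)*5000 + 530 ~ 372.4
  ev <- make_events(fsc = c(5000, 5000, 5000, 899, 9801, 5000),
                    ssc = c(200, 372, 373, 200, 200, 109))
  kept <- gate_events(ev[c(1, 2), ], gate)   # clearly inside
  expect_equal(nrow(kept), 2)
  expect_equal(nrow(gate_events(rbind(ev[1, ], ev[3, ]), gate)), 1)
  expect_equal(nrow(gate_events(rbind(ev[1, ], ev[4, ]), gate)), 1)
  expect_equal(nrow(gate_events(rbind(ev[1, ], ev[5, ]), gate)), 1)
  expect_equal(nrow(gate_events(rbind(ev[1, ], ev[6, ]), gate)), 1)
})

test_that("gating is idempotent and reports retention", {
  set.seed(11)
  ev <- make_events(fsc = rlnorm(500, log(3000), 0.4),
                    ssc = rlnorm(500, log(200), 0.5))
  g1 <- gate_events(ev)
  g2 <- gate_events(g1)
  expect_equal(nrow(g1), nrow(g2))
  expect_identical(g1$FSC_A, g2$FSC_A)
  ret <- attr(g1, "retention")
  expect_equal(ret$n_before, 500L)
  expect_equal(ret$n_after, nrow(g1))
})

test_that("an emptied population raises an error naming it", {
  ev <- rbind(make_events(5000, 200, genotype = "ok"),
              make_events(100, 200, genotype = "lost"))
  expect_error(gate_events(ev), "lost")
  expect_error(gate_events(make_events(5000, 200)[0, ]), "empty")
})

test_that("GFP normalization matches the printed ratio and its SE", {
  # exact anchors
  s0 <- normalize_with_se(c(9, 10, 11), c(109, 110, 111), c(9, 10, 11))
  expect_equal(s0$gfp_obs, 0)
  s1 <- normalize_with_se(c(109, 110, 111), c(109, 110, 111), c(9, 10, 11))
  expect_equal(s1$gfp_obs, 1)
  # worked record: means 60/110/10 with replicate SEs 2/3/1
  mut <- mu_rep(60, 2); wt <- mu_rep(110, 3); ctrl <- mu_rep(10, 1)
  s <- normalize_with_se(mut, wt, ctrl)
  expect_equal(s$gfp_obs, 0.5, tolerance = 1e-12)
  # independent evaluation of the nested-radical SE formula
  se_oracle <- sqrt((sqrt(2^2 + 1^2) / (60 - 10))^2 +
                    (sqrt(3^2 + 1^2) / (110 - 10))^2)
  expect_equal(s$se_obs, se_oracle, tolerance = 1e-12)
  expect_error(normalize_with_se(c(1, 2), c(5, 5), c(10, 10)), "degenerate")
})

test_that("interaction records propagate SEs exactly as printed", {
  A <- summary_fix(0.9, 3); B <- summary_fix(0.8, 4)
  WT <- summary_fix(1, 0); AB <- summary_fix(0.65, 0)
  rec <- interaction_with_se(A, B, WT, AB, "within")
  expect_equal(rec$SE_exp_add, 5)   # sqrt(9 + 16 + 0)
  expect_equal(rec$W_exp_add, 0.7, tolerance = 1e-12)
  expect_equal(rec$e_add, -0.05, tolerance = 1e-12)
  se_log_oracle <- sqrt((3 / 0.9)^2 + (4 / 0.8)^2)
  expect_equal(rec$SE_exp_log, se_log_oracle, tolerance = 1e-12)
  expect_equal(rec$SE_interaction_add, sqrt(0 + 25), tolerance = 1e-12)
  # all-zero input SEs give a zero interaction SE
  z <- interaction_with_se(summary_fix(0.9, 0), summary_fix(0.8, 0),
                           summary_fix(1, 0), summary_fix(0.7, 0), "within")
  expect_equal(z$SE_interaction_add, 0)
  expect_equal(z$SE_interaction_log, 0)
})

test_that("SE propagation is homogeneous of degree one", {
  base <- list(A = c(0.88, 0.9, 0.92), B = c(0.78, 0.8, 0.82),
               WT = c(0.99, 1, 1.01), AB = c(0.64, 0.65, 0.66))
  scale_reps <- function(x, k) mean(x) + k * (x - mean(x))
  rec_at <- function(k) {
    s <- lapply(base, function(x)
      normalize_with_se(scale_reps(x * 100, k), scale_reps(c(99, 100, 101), k),
                        scale_reps(c(4.9, 5, 5.1), k)))
    interaction_with_se(s$A, s$B, s$WT, s$AB, "between")
  }
  r1 <- rec_at(1); r3 <- rec_at(3)
  expect_equal(r3$SE_exp_add / r1$SE_exp_add, 3, tolerance = 1e-6)
  expect_equal(r3$SE_interaction_add / r1$SE_interaction_add, 3,
               tolerance = 1e-6)
})
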