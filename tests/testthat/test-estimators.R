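test_that("rds2_weights match the arithmetic oracle and its invariants", {
  # degrees (1, 2, 4): mean(1/d) = 7/12, so weights are (12/7, 6/7, 3/7)
  expect_equal(rds2_weights(c(1, 2, 4)), c(12, 6, 3) / 7)
  expect_equal(rds2_weights(rep(7, 5)), rep(1, 5))
  set.seed(31)
  d <- sample(1:50, 40, replace = TRUE)
  w <- rds2_weights(d)
  expect_equal(sum(w), 40)                       # mean-one normalization
  expect_equal(rds2_weights(3 * d), w)           # scale invariance
  expect_true(all(w > 0))
  expect_error(rds2_weights(c(2, 0)), ">= 1")
  expect_error(rds2_weights(numeric(0)), ">= 1")
})

test_that("naive prevalence is the sample proportion with a Wald CI", {
  s <- manual_sample(id = 1:4, recruiter = c(NA, 1, 1, 2),
                     wave = c(0, 1, 1, 2), degree = rep(2, 4),
                     group = c(1, 1, 0, 0))
  e <- naive_prevalence(s)
  expect_equal(e$point, 0.5)
  expect_equal(e$se, sqrt(0.25 / 4))
  expect_equal(e$ci, pmin(pmax(0.5 + c(-1, 1) * qnorm(0.975) * e$se, 0), 1))
  # degenerate all-G2 sample
  s0 <- manual_sample(id = 1:3, recruiter = c(NA, 1, 2), wave = 0:2,
                      degree = rep(2, 3), group = c(0, 0, 0))
  e0 <- naive_prevalence(s0)
  expect_equal(e0$point, 0)
  expect_true(all(e0$ci >= 0 & e0$ci <= 1))
})

test_that("rds2 prevalence is the Hajek ratio with inverse-degree weights", {
  s <- manual_sample(id = 1:2, recruiter = c(NA, 1), wave = 0:1,
                     degree = c(1, 4), group = c(1, 0))
  expect_equal(rds2_prevalence(s)$point, 0.8)    # (1/1)/(1/1 + 1/4)
  # equal degrees collapse to the naive estimate
  s2 <- manual_sample(id = 1:6, recruiter = c(NA, 1, 1, 2, 3, 3),
                      wave = c(0, 1, 1, 2, 2, 2), degree = rep(3, 6),
                      group = c(1, 0, 1, 0, 0, 1))
  expect_equal(rds2_prevalence(s2)$point, naive_prevalence(s2)$point)
  # Hajek boundedness
  set.seed(32)
  s3 <- manual_sample(id = 1:30, recruiter = c(NA, 1:29),
                      wave = 0:29, degree = sample(1:40, 30, TRUE),
                      group = rbinom(30, 1, 0.4))
  expect_gte(rds2_prevalence(s3)$point, 0)
  expect_lte(rds2_prevalence(s3)$point, 1)
})

test_that("all estimators return exactly pi on an equal-degree census", {
  pop <- small_population(pi = 0.3, hx = 1.1, N = 500)
  census <- manual_sample(id = seq_len(pop$N),
                          recruiter = c(NA, seq_len(pop$N - 1L)),
                          wave = seq_len(pop$N) - 1L,
                          degree = rep(5, pop$N), group = pop$group)
  expect_equal(naive_prevalence(census)$point, 0.3)
  expect_equal(rds2_prevalence(census)$point, 0.3)
})

test_that("rds1 matches a hand-computed reciprocity oracle", {
  # recruitment tree: 1(G1) -> 2(G2), 3(G1); 2 -> 4(G1); 3 -> 5(G2);
  # 4 -> 6(G2); degrees give harmonic means D1 = 4, D2 = 2.
  # Cross proportions: G1 recruiters made 4 recruitments, 3 to G2
  # (s10 = 3/4); G2 recruiters made 1, 1 to G1 (s01 = 1).
  # P(G1) = s01*D0 / (s10*D1 + s01*D0) = 2 / (3 + 2) = 0.4
  s <- manual_sample(id = 1:6,
                     recruiter = c(NA, 1, 1, 2, 3, 4),
                     wave = c(0, 1, 1, 2, 2, 3),
                     degree = c(4, 2, 4, 4, 2, 2),
                     group = c(1, 0, 1, 1, 0, 0))
  expect_equal(rds1_prevalence(s)$point, 0.4)
  # symmetric toy: equal degrees, equal cross-recruitment -> naive = 0.5
  sym <- manual_sample(id = 1:4, recruiter = c(NA, NA, 1, 2),
                       wave = c(0, 0, 1, 1), degree = rep(3, 4),
                       group = c(1, 0, 0, 1))
  expect_equal(rds1_prevalence(sym)$point, naive_prevalence(sym)$point)
  # direction: weighting favours the lower-degree group
  lowdeg <- manual_sample(id = 1:6,
                          recruiter = c(NA, 1, 1, 2, 3, 4),
                          wave = c(0, 1, 1, 2, 2, 3),
                          degree = c(2, 8, 2, 2, 8, 8),
                          group = c(1, 0, 1, 1, 0, 0))
  expect_gt(rds1_prevalence(lowdeg)$point, naive_prevalence(lowdeg)$point)
  # no cross-group recruitment -> undefined
  homo <- manual_sample(id = 1:4, recruiter = c(NA, 1, 2, 3),
                        wave = 0:3, degree = rep(2, 4),
                        group = rep(1, 4))
  expect_error(rds1_prevalence(homo), "cross-group|undefined")
})

test_that("prevalence_interval supports wald, design_robust and bootstrap", {
  # closed-form Wald: p = 0.5, n = 100 -> 0.5 +/- 1.96 * 0.05
  s <- manual_sample(id = 1:100, recruiter = c(NA, 1:99), wave = 0:99,
                     degree = rep(4, 100), group = rep(c(1, 0), 50))
  e <- prevalence_interval(s, "naive", "wald")
  expect_equal(e$ci, 0.5 + c(-1, 1) * qnorm(0.975) * 0.05, tolerance = 1e-10)
  # design_robust with unit weights matches wald up to the n vs n-1 factor
  er <- prevalence_interval(s, "naive", "design_robust")
  expect_equal(er$se, e$se, tolerance = 1e-6)
  # seed-chain bootstrap: percentile interval contains the point estimate
  pop <- small_population(N = 600)
  set.seed(33)
  smp <- rds_sample(pop, rds_config(n_seeds = 5, target_n = 150))
  eb <- prevalence_interval(smp, "rds2", "salganik_bootstrap", n_boot = 200)
  expect_true(eb$ci[1] <= eb$point && eb$point <= eb$ci[2])
  expect_false(isTRUE(eb$single_chain_warning))
  # single chain flagged
  k5 <- manual_population(utils::combn(5, 2), N = 5)
  set.seed(34)
  one <- rds_sample(k5, rds_config(n_seeds = 1, coupons = 4,
                                   response_prob = 1, target_n = 5),
                    seeds = 1L)
  eb1 <- prevalence_interval(one, "naive", "salganik_bootstrap",
                             n_boot = 50)
  expect_true(eb1$single_chain_warning)
})

test_that("weighted estimators shift toward the low-degree group", {
  # homophilous fixture where G1 members report low degree
  set.seed(35)
  s <- manual_sample(id = 1:40, recruiter = c(NA, 1:39), wave = 0:39,
                     degree = c(rep(2, 10), rep(20, 30)),
                     group = c(rep(1, 10), rep(0, 30)))
  expect_gt(rds2_prevalence(s)$point, naive_prevalence(s)$point)
})
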