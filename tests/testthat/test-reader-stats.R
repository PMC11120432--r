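test_that("paired sample size reproduces the normal-approximation formula", {
  expect_identical(min_sample_size(0.5, 0.4, 0.8, 0.01), 8L)
  # ceil(((qnorm(0.995)+qnorm(0.8)) * 0.4 / 0.8)^2) = ceil(2.92) = 3
  expect_identical(min_sample_size(0.8, 0.4, 0.8, 0.01), 3L)
  expect_error(min_sample_size(0, 0.4, 0.8, 0.01), "delta")
  expect_error(min_sample_size(0.5, -1, 0.8, 0.01), "sd")
  expect_error(min_sample_size(0.5, 0.4, 1.2, 0.01), "power")
})

test_that("sample size is monotone in its arguments", {
  base <- min_sample_size(0.5, 0.4, 0.8, 0.01)
  expect_lte(min_sample_size(0.6, 0.4, 0.8, 0.01), base)   # larger effect
  expect_lte(min_sample_size(0.5, 0.4, 0.8, 0.05), base)   # looser alpha
  expect_gte(min_sample_size(0.5, 0.4, 0.9, 0.01), base)   # more power
  expect_gte(min_sample_size(0.5, 0.6, 0.8, 0.01), base)   # noisier
  # quartic blow-up before ceiling when the effect halves
  expect_gte(min_sample_size(0.25, 0.4, 0.8, 0.01), 4 * (base - 1))
})

test_that("Likert simulation is deterministic, saturates, and matches closed-form probabilities", {
  d1 <- simulate_likert(seed = 42)
  d2 <- simulate_likert(seed = 42)
  expect_identical(d1, d2)
  expect_true(all(d1$score %in% 1:5))
  expect_equal(nrow(d1), 10 * 3 * 22 * 3)

  sat <- simulate_likert(beta = c(50, 50, 50), seed = 1)
  expect_true(all(sat$score == 5L))

  # no random effects: empirical category frequencies vs cumulative logits
  th <- c(-1.5, -0.5, 0.5, 1.5)
  d0 <- simulate_likert(sequences = "only", beta = 0, thresholds = th,
                        n_specimen = 1000, n_reader = 10, n_structure = 10,
                        re_sd = c(structure = 0, reader = 0, specimen = 0),
                        seed = 3)
  expect_equal(nrow(d0), 1e5)
  p_hat <- tabulate(d0$score, 5) / nrow(d0)
  p_true <- diff(c(0, plogis(th), 1))
  expect_true(all(abs(p_hat - p_true) < 4 * sqrt(p_true * (1 - p_true) / 1e5)))

  expect_error(simulate_likert(thresholds = c(1, 0.5, 2, 3)),
               "strictly increasing")
})

test_that("fixed-effects fit equals independent proportional-odds ML (polr)", {
  d <- simulate_likert(n_specimen = 6,
                       re_sd = c(structure = 0, reader = 0, specimen = 0),
                       seed = 2)
  fit <- fit_clmm(d, random_terms = character(0))
  pol <- MASS::polr(factor(score) ~ sequence, data = d, method = "logistic",
                    control = list(reltol = 1e-12))
  expect_equal(fit$loglik, as.numeric(stats::logLik(pol)), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(coef(pol)), tolerance = 1e-4)
  expect_equal(unname(fit$thresholds), unname(pol$zeta), tolerance = 1e-4)
})

test_that("CLMM errors on degenerate inputs", {
  d <- simulate_likert(n_specimen = 2, seed = 1)
  one_cat <- d
  one_cat$score <- 3L
  expect_error(fit_clmm(one_cat), "one category")
  one_seq <- d[d$sequence == "MIXTURE", ]
  expect_error(fit_clmm(one_seq), "sequence levels")
  expect_error(fit_clmm(d, random_terms = "site"), "absent")
})

test_that("CLMM recovers the latent sequence effect on zero-variance data", {
  # 2000 rows, two sequences, no random-effect variance, beta_truth = 1
  d <- simulate_likert(sequences = c("ref", "alt"), beta = c(0, 1),
                       n_specimen = 100, n_reader = 1, n_structure = 10,
                       re_sd = c(structure = 0, reader = 0, specimen = 0),
                       seed = 11)
  expect_equal(nrow(d), 2000)
  fit <- fit_clmm(d)
  expect_true(fit$convergence)
  expect_lt(abs(fit$beta[["alt"]] - 1), 2 * fit$se_beta[["alt"]])
  # estimated random-effect SDs collapse toward zero
  expect_true(all(fit$re_sd < 0.1))
})

test_that("Laplace fit with random effects recovers simulation truth", {
  d <- simulate_likert(seed = 5)   # beta (0, 0.5, 0.25), re_sd (0.5, 0.3, 0.4)
  fit <- fit_clmm(d)
  expect_true(fit$convergence)
  expect_lt(abs(fit$beta[["MIXTURE"]] - 0.5), 3 * fit$se_beta[["MIXTURE"]])
  expect_lt(abs(fit$beta[["3D TSE"]] - 0.25), 3 * fit$se_beta[["3D TSE"]])
  expect_equal(unname(fit$re_sd[["structure"]]), 0.5, tolerance = 0.5)
  expect_true(all(diff(fit$thresholds) > 0))
})

test_that("EMM table has k(k-1)/2 Tukey contrasts that dominate raw p-values", {
  d <- simulate_likert(seed = 6)
  fit <- fit_clmm(d)
  em <- emm_and_tukey(fit)
  expect_equal(nrow(em$emm), 3)
  expect_equal(nrow(em$contrasts), 3)
  expect_true(all(em$contrasts$p_tukey >= em$contrasts$p_raw - 1e-12))
  expect_true(all(em$contrasts$p_tukey >= 0 & em$contrasts$p_tukey <= 1))
  # contrasts of latent EMMs equal fixed-effect differences
  expect_equal(em$emm$emm[2] - em$emm$emm[1], unname(fit$beta["MIXTURE"]))
  # EMMs are centered by the mean threshold
  expect_equal(em$emm$emm[1], -mean(fit$thresholds))
})

test_that("null CLMM contrasts are non-significant at moderate n", {
  d <- simulate_likert(beta = c(0, 0, 0), n_specimen = 8, n_structure = 10,
                       seed = 13)
  fit <- fit_clmm(d)
  em <- emm_and_tukey(fit)
  expect_true(all(em$contrasts$p_tukey > 0.05))
})

test_that("repeated-measures ANOVA matches hand-computed sums of squares", {
  # specimens x sequences table with known decomposition:
  # SS_seq = 54, SS_subject = 2/3, SS_error = 16/3, F = 27 / (4/3) = 20.25
  tab <- matrix(c(1, 2, 3, 5, 4, 6, 8, 9, 7), nrow = 3,
                dimnames = list(NULL, c("A", "B", "C")))
  fit <- rm_anova_tukey(tab)
  expect_equal(fit$ss_sequence, 54)
  expect_equal(fit$ss_subject, 2 / 3)
  expect_equal(fit$ss_error, 16 / 3)
  expect_equal(fit$f, 20.25)
  expect_equal(fit$df1, 2)
  expect_equal(fit$df2, 4)

  # independent oracle: aov with a specimen error stratum
  long <- data.frame(value = as.vector(tab),
                     specimen = factor(rep(1:3, 3)),
                     sequence = factor(rep(c("A", "B", "C"), each = 3)))
  a <- summary(stats::aov(value ~ sequence + Error(specimen), data = long))
  f_aov <- a[["Error: Within"]][[1]]["sequence", "F value"]
  p_aov <- a[["Error: Within"]][[1]]["sequence", "Pr(>F)"]
  expect_equal(fit$f, f_aov)
  expect_equal(fit$p_value, p_aov)

  # Tukey-Kramer against base ptukey arithmetic
  q_bc <- abs(mean(tab[, "C"]) - mean(tab[, "B"])) / sqrt(fit$ms_error / 3)
  expect_equal(fit$pairwise$q[fit$pairwise$contrast == "C - B"], q_bc)
  expect_equal(fit$pairwise$p_tukey[fit$pairwise$contrast == "C - B"],
               ptukey(q_bc, 3, 4, lower.tail = FALSE))
})

test_that("identical sequences give F = 0 and all adjusted p = 1", {
  tab <- matrix(rep(c(1.2, 3.4, 5.6, 2.2), 3), nrow = 4)
  fit <- rm_anova_tukey(tab)
  expect_equal(fit$f, 0)
  expect_equal(fit$p_value, 1)
  expect_true(all(fit$pairwise$p_tukey == 1))
})

test_that("rm-ANOVA accepts long tables and rejects incomplete ones", {
  long <- tidyr::expand_grid(specimen = factor(1:5), sequence = c("a", "b"))
  long$value <- rnorm(nrow(long))
  fit <- rm_anova_tukey(long)
  expect_equal(fit$df2, 4)
  expect_error(rm_anova_tukey(long[-1, ]), "missing cells|incomplete")
  expect_error(rm_anova_tukey(long[long$specimen == 1, ]), ">= 2")
})

test_that("rm-ANOVA holds its nominal type-I error under the null", {
  n_sim <- 2000
  alpha <- 0.01
  set.seed(99)
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    tab <- matrix(rnorm(8 * 3), nrow = 8)
    if (rm_anova_tukey(tab)$p_value <= alpha) rejections <- rejections + 1L
  }
  ci <- stats::binom.test(round(n_sim * alpha), n_sim)$conf.int
  expect_gte(rejections / n_sim, ci[1])
  expect_lte(rejections / n_sim, ci[2])
})

test_that("tidy and glance methods expose fit summaries", {
  d <- simulate_likert(n_specimen = 4, seed = 3)
  fit <- fit_clmm(d)
  td <- tidy(fit)
  expect_true(all(c("term", "type", "estimate", "std.error") %in% names(td)))
  expect_equal(sum(td$type == "threshold"), 4)
  gl <- glance(fit)
  expect_equal(gl$logLik, fit$loglik)

  tab <- matrix(rnorm(9), 3)
  fa <- rm_anova_tukey(tab)
  expect_equal(nrow(tidy(fa)), 3)
  expect_equal(glance(fa)$statistic, fa$f)
})
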