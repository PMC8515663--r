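test_that("dual likelihood factorizes exactly under an independent joint matrix", {
  set.seed(31)
  df <- random_panel_df(n = 8, T = 3, p_miss = 0.3)
  p <- panel_data(df)
  beta1 <- rbind(c(-1, 0.2), c(1, -0.1))
  beta2 <- rbind(c(0, 0.3), c(-2, 0.5))
  m1 <- c(0.4, 0.6); m2 <- c(0.7, 0.3)
  dp <- dual_params(beta1, beta2, outer(m1, m2))
  ll_dual <- dual_loglik(dp, p)
  ll1 <- gbtm_loglik(traj_params(beta1, m1), p, "depression")
  ll2 <- gbtm_loglik(traj_params(beta2, m2), p, "anxiety")
  expect_equal(ll_dual, ll1 + ll2, tolerance = 1e-12)
})

test_that("J=K=1 dual likelihood is the sum of two single-group likelihoods", {
  df <- random_panel_df(n = 5, T = 3)
  p <- panel_data(df)
  dp <- dual_params(matrix(c(0, 0), 1), matrix(c(1, -0.5), 1),
                    matrix(1, 1, 1))
  expect_equal(
    dual_loglik(dp, p),
    gbtm_loglik(traj_params(matrix(c(0, 0), 1), 1), p, "depression") +
      gbtm_loglik(traj_params(matrix(c(1, -0.5), 1), 1), p, "anxiety")
  )
})

test_that("dual likelihood matches brute-force double-sum enumeration", {
  set.seed(32)
  for (rep in 1:4) {
    df <- random_panel_df(n = 5, T = 3, p_miss = 0.3)
    p <- panel_data(df)
    beta1 <- matrix(rnorm(4), 2)
    beta2 <- matrix(rnorm(4), 2)
    Pi <- matrix(c(0.4, 0.1, 0.2, 0.3), 2)
    dp <- dual_params(beta1, beta2, Pi)
    expect_equal(
      dual_loglik(dp, p),
      brute_dual_loglik(outcome_matrix(p, "depression"),
                        outcome_matrix(p, "anxiety"), beta1, beta2, Pi),
      tolerance = 1e-10
    )
  }
})

test_that("conditional probability matrices are correct row-normalizations", {
  Pi <- rbind(c(0.5, 0.1), c(0.1, 0.3))
  c21 <- conditional_probs(Pi, "2|1")
  expect_equal(c21[1, 1], 0.5 / 0.6)
  expect_equal(unname(rowSums(c21)), c(1, 1))
  c12 <- conditional_probs(Pi, "1|2")
  expect_equal(c12[1, 1], 0.5 / 0.6)
  expect_equal(unname(rowSums(c12)), c(1, 1))

  # independence: every conditional row equals the other channel's margin
  ind <- outer(c(0.3, 0.7), c(0.6, 0.4))
  expect_equal(conditional_probs(ind, "2|1"),
               rbind(c(0.6, 0.4), c(0.6, 0.4)))
  # perfect coupling: identity conditionals
  expect_equal(conditional_probs(diag(2) / 2, "2|1"), diag(2))
  expect_equal(conditional_probs(diag(2) / 2, "1|2"), diag(2))
  # zero marginal row reported as missing
  z <- rbind(c(0, 0), c(0.5, 0.5))
  expect_true(all(is.na(conditional_probs(z, "2|1")[1, ])))
})

test_that("marginal_probs returns row/column sums that conserve mass", {
  Pi <- matrix(0.25, 2, 2)
  m <- marginal_probs(Pi)
  expect_equal(m$channel1, c(0.5, 0.5))
  expect_equal(m$channel2, c(0.5, 0.5))
  cfg <- khps_preset()
  m <- marginal_probs(cfg$joint_pi)
  expect_equal(sum(m$channel1), 1, tolerance = 1e-12)
  expect_equal(sum(m$channel2), 1, tolerance = 1e-12)
})

test_that("dual EM recovers an independent joint structure at N=2000", {
  b1 <- rbind(c(-2.5, 0), c(1.5, 0))
  b2 <- rbind(c(-2, 0), c(2, 0))
  m1 <- c(0.6, 0.4); m2 <- c(0.7, 0.3)
  cfg <- synthetic_config(N = 2000, T_waves = 5, beta1 = b1, beta2 = b2,
                          joint_pi = outer(m1, m2),
                          retention = c(1, rep(0.8, 4)), seed = 1)
  sim <- generate_dual_panel(cfg, seed = 33)
  f <- dual_fit(sim$panel, 2, 2, seed = 3, n_starts = 2)
  expect_lt(max(abs(f$params$joint_pi - outer(m1, m2))), 0.03)
})

test_that("dual EM concentrates mass on the diagonal under perfect coupling", {
  b1 <- rbind(c(-2.5, 0), c(1.5, 0))
  b2 <- rbind(c(-2, 0), c(2, 0))
  cfg <- synthetic_config(N = 1000, T_waves = 5, beta1 = b1, beta2 = b2,
                          joint_pi = diag(c(0.55, 0.45)),
                          retention = c(1, rep(0.8, 4)), seed = 1)
  sim <- generate_dual_panel(cfg, seed = 34)
  f <- dual_fit(sim$panel, 2, 2, seed = 4, n_starts = 2)
  expect_gte(sum(diag(f$params$joint_pi)), 0.95)
})

test_that("marginal-fit initialization agrees with a multistart search", {
  cfg <- khps_preset(N = 600)
  sim <- generate_dual_panel(cfg, seed = 35)
  m1 <- gbtm_fit(sim$panel, "depression", 2, seed = 11, n_starts = 4)
  m2 <- gbtm_fit(sim$panel, "anxiety", 2, seed = 12, n_starts = 4)
  f_init <- dual_fit(sim$panel, 2, 2, init = list(m1, m2), seed = 13,
                     n_starts = 1)
  f_multi <- dual_fit(sim$panel, 2, 2, seed = 14, n_starts = 6)
  expect_equal(f_init$loglik, f_multi$loglik, tolerance = 1e-4)
})

test_that("dual EM trace is monotone and all structures stay stochastic", {
  cfg <- khps_preset(N = 300)
  sim <- generate_dual_panel(cfg, seed = 36)
  f <- dual_fit(sim$panel, 2, 2, seed = 5, n_starts = 2)
  expect_true(all(diff(f$loglik_trace) > -1e-6))
  expect_equal(sum(f$params$joint_pi), 1, tolerance = 1e-10)
  expect_equal(unname(rowSums(f$cond_2_given_1)), rep(1, 2), tolerance = 1e-10)
  expect_equal(unname(rowSums(f$cond_1_given_2)), rep(1, 2), tolerance = 1e-10)
  expect_equal(unname(apply(f$joint_posterior, 1, sum)),
               rep(1, n_subjects(sim$panel)), tolerance = 1e-10)
})

test_that("dual log-likelihood at the independence initialization equals the sum of marginal log-likelihoods", {
  cfg <- khps_preset(N = 300)
  sim <- generate_dual_panel(cfg, seed = 37)
  m1 <- gbtm_fit(sim$panel, "depression", 2, seed = 21, n_starts = 3)
  m2 <- gbtm_fit(sim$panel, "anxiety", 2, seed = 22, n_starts = 3)
  dp <- dual_params(m1$params$beta, m2$params$beta,
                    outer(m1$params$pi, m2$params$pi))
  expect_equal(dual_loglik(dp, sim$panel), m1$loglik + m2$loglik,
               tolerance = 1e-8)
  # factorized case: joint posterior marginalized over k equals the
  # channel-1 Bayes-rule posterior under the implied marginal model
  W <- dual_posterior(dp, sim$panel)
  P1 <- apply(W, c(1, 2), sum)
  expect_equal(unname(P1),
               unname(gbtm_posterior(m1$params, sim$panel, "depression")),
               tolerance = 1e-10)
})
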