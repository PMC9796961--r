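test_that("composite log-likelihood matches closed forms", {
  # four entries with p = 1/4 and unit counts: 4 * ln(0.25)
  mass <- array(0, dim = c(3, 3, 3))
  mass[2, 1, 1] <- 1; mass[1, 2, 1] <- 1; mass[1, 1, 2] <- 1
  mass[2, 2, 1] <- 1
  obs <- fusioncoal:::new_joint_sfs(mass, n = c(2, 2, 2), folded = TRUE,
                                    polymorphic_only = TRUE)
  p <- array(0, dim = c(3, 3, 3))
  p[2, 1, 1] <- 0.25; p[1, 2, 1] <- 0.25; p[1, 1, 2] <- 0.25
  p[2, 2, 1] <- 0.25
  probs <- fusioncoal:::new_joint_sfs(p, n = c(2, 2, 2), folded = TRUE,
                                      polymorphic_only = TRUE,
                                      probability = TRUE)
  expect_equal(composite_loglik(obs, probs), 4 * log(0.25))

  # all mass on one entry with probability 1
  m1 <- array(0, dim = c(3, 3, 3)); m1[2, 1, 1] <- 7
  p1 <- array(0, dim = c(3, 3, 3)); p1[2, 1, 1] <- 1
  expect_equal(composite_loglik(
    fusioncoal:::new_joint_sfs(m1, c(2, 2, 2), TRUE, TRUE),
    fusioncoal:::new_joint_sfs(p1, c(2, 2, 2), TRUE, TRUE, TRUE)), 0)

  # observed mass on a zero-probability entry with flooring: finite, equals
  # count * ln(p_floor) plus the rest
  floor_p <- 1e-5
  p2 <- p; p2[2, 2, 1] <- floor_p
  probs2 <- fusioncoal:::new_joint_sfs(p2, c(2, 2, 2), TRUE, TRUE, TRUE)
  expect_equal(composite_loglik(obs, probs2),
               3 * log(0.25) + log(floor_p))

  # shape mismatch
  bad <- fusioncoal:::new_joint_sfs(array(1, dim = c(2, 2, 2)),
                                    c(1, 1, 1), TRUE, FALSE)
  expect_error(composite_loglik(obs, bad), "dimensions")
})

test_that("monomorphic mass never contributes to the likelihood", {
  gen <- generate_study_like(scale = 0.05, seed = 3)
  obs <- joint_sfs(gen$dataset)
  probs <- expected_sfs(study_model(), sample_config(obs$n[1], obs$n[2],
                                                     obs$n[3]),
                        n_sims = 5000, seed = 1)
  ll <- composite_loglik(obs, probs)
  padded <- obs
  padded$mass[1, 1, 1] <- 500  # monomorphic corner
  expect_equal(composite_loglik(padded, probs), ll)
})

test_that("the diversity anchor follows N_e = pi / (4 mu)", {
  expect_equal(ne_from_pi(0.0112, 2.8e-9), 1e6)
  expect_equal(ne_from_pi(0, 1e-8), 0)
  pi0 <- 0.004
  expect_equal(4 * ne_from_pi(pi0, 2.8e-9) * 2.8e-9, pi0)
  expect_error(ne_from_pi(0.01, 0))
})

test_that("fitting is deterministic given the seed and records a monotone trace", {
  m <- toy_fusion_model(gamma = 0.5, N = 1e4, T_hyb = 5e3, T_div1 = 2e4)
  s <- sample_config(6, 6, 4)
  obs <- simulate_sfs(m, s, 400, seed = 77)
  set <- fit_settings(n_sims = 3000, n_sims_final = 3000, cycles = 2,
                      iters_per_cycle = 10, n_replicates = 2, prescan = 3)
  f1 <- fit_model(obs, model_spec("fusion", "none"), anchor = 1e4,
                  settings = set, seed = 5)
  f2 <- fit_model(obs, model_spec("fusion", "none"), anchor = 1e4,
                  settings = set, seed = 5)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$lnL, f2$lnL)
  expect_equal(f1$best_replicate, which.max(f1$trace$lnL))
  for (acc in f1$cycle_trace) {
    expect_true(all(diff(acc) >= 0))
  }
  expect_equal(nrow(f1$trace), 2)
  expect_error(fit_model(obs, model_spec("fusion", "none"), anchor = -1,
                         settings = set, seed = 1))
})

test_that("the likelihood at truth dominates a 2x time perturbation", {
  m <- study_model()
  s <- sample_config(18, 14, 6)
  spec <- model_spec("fusion", "contemporary")
  wins <- 0L
  n_trials <- 6L
  for (i in seq_len(n_trials)) {
    obs <- simulate_sfs(m, s, 2000, seed = 800 + i)
    pert <- m$params[free_param_names(spec)]
    pert["T_div1"] <- pert["T_div1"] * 2
    ll_true <- composite_loglik(
      obs, expected_sfs(m, s, 2e4, seed = 900 + i))
    ll_pert <- composite_loglik(
      obs, expected_sfs(model_from_params(spec, pert, 1e6), s, 2e4,
                        seed = 900 + i))
    if (ll_true >= ll_pert) wins <- wins + 1L
  }
  expect_gte(wins, n_trials - 1L)
})

test_that("fit results serialize to JSON with a trace table", {
  m <- toy_fusion_model()
  obs <- simulate_sfs(m, sample_config(4, 4, 4), 200, seed = 1)
  set <- fit_settings(n_sims = 2000, n_sims_final = 2000, cycles = 1,
                      iters_per_cycle = 5, n_replicates = 2, prescan = 2)
  fit <- fit_model(obs, model_spec("fusion", "none"), anchor = 1e4,
                   settings = set, seed = 2)
  path <- file.path(tempdir(), "fit.json")
  write_fit_result(fit, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$lnL, fit$lnL)
  expect_equal(doc$estimates$gamma_hyb, unname(fit$estimates["gamma_hyb"]))
  trace <- read.table(file.path(tempdir(), "fit.trace.tsv"), header = TRUE,
                      sep = "\t")
  expect_equal(nrow(trace), 2)
  unlink(c(path, file.path(tempdir(), "fit.trace.tsv")))
})
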