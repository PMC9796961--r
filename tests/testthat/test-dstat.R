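test_that("site-pattern weights match the frequency-weighted definition", {
  expect_equal(site_pattern_weights(0, 1, 1, 0), list(abba = 1, baba = 0))
  expect_equal(site_pattern_weights(1, 0, 1, 0), list(abba = 0, baba = 1))
  expect_equal(site_pattern_weights(0.5, 0.5, 0.5, 0),
               list(abba = 0.125, baba = 0.125))
  # outgroup polymorphism downweights through (1 - p4)
  w <- site_pattern_weights(0, 1, 1, 0.25)
  expect_equal(w$abba, 0.75)
  expect_error(site_pattern_weights(-0.1, 0.5, 0.5, 0))
  expect_error(site_pattern_weights(0.5, 0.5, 1.2, 0))
})

make_quartet_dataset <- function(geno_by_group, n_per_group = 2) {
  # geno_by_group: list of p1, p2, p3, out locus x individual blocks
  geno <- do.call(cbind, geno_by_group)
  demes <- rep(c("sau", "alg", "bin", "out"),
               times = vapply(geno_by_group, ncol, integer(1)))
  ids <- paste0(demes, "_", sequence(vapply(geno_by_group, ncol, integer(1))))
  snp_dataset(geno, data.frame(id = ids, deme = demes,
                               outgroup = demes == "out"))
}

test_that("pure pattern datasets give |D| = 1 and P1/P2 swap negates D exactly", {
  n <- 40
  # pure ABBA: P1 ancestral, P2 and P3 fixed derived, outgroup ancestral
  ds <- make_quartet_dataset(list(
    p1 = matrix(0L, n, 2), p2 = matrix(2L, n, 2),
    p3 = matrix(2L, n, 2), out = matrix(0L, n, 2)
  ))
  q <- quartet_assignment("sau", "alg", "bin", "out")
  r <- d_statistic(ds, q, n_boot = 100, seed = 1)
  expect_equal(r$D, 1)
  expect_equal(r$abba, n)
  expect_equal(r$baba, 0)

  # mixed data: swapping P1 and P2 negates D
  set.seed(9)
  ds2 <- make_quartet_dataset(list(
    p1 = matrix(sample(0:2, n * 2, TRUE), n, 2),
    p2 = matrix(sample(0:2, n * 2, TRUE), n, 2),
    p3 = matrix(sample(0:2, n * 2, TRUE), n, 2),
    out = matrix(0L, n, 2)
  ))
  r12 <- d_statistic(ds2, quartet_assignment("sau", "alg", "bin", "out"),
                     n_boot = 50, seed = 2)
  r21 <- d_statistic(ds2, quartet_assignment("alg", "sau", "bin", "out"),
                     n_boot = 50, seed = 2)
  expect_equal(r12$D, -r21$D, tolerance = 1e-12)

  # balanced ABBA and BABA mass gives D = 0
  half <- n / 2
  ds3 <- make_quartet_dataset(list(
    p1 = rbind(matrix(0L, half, 2), matrix(2L, half, 2)),
    p2 = rbind(matrix(2L, half, 2), matrix(0L, half, 2)),
    p3 = matrix(2L, n, 2), out = matrix(0L, n, 2)
  ))
  r0 <- d_statistic(ds3, q, n_boot = 50, seed = 3)
  expect_equal(r0$D, 0)
})

test_that("Z equals D/SD, the bootstrap is seed-reproducible, and errors are raised", {
  gen <- generate_study_like(scale = 0.1, seed = 21)
  q <- quartet_assignment("sau", "alg", "bin", "out")
  r1 <- d_statistic(gen$dataset, q, n_boot = 300, seed = 4)
  r2 <- d_statistic(gen$dataset, q, n_boot = 300, seed = 4)
  expect_identical(r1$D, r2$D)
  expect_identical(r1$SD, r2$SD)
  expect_equal(r1$Z, r1$D / r1$SD)
  expect_true(abs(r1$D) <= 1)
  expect_error(d_statistic(gen$dataset,
                           quartet_assignment("sau", "alg", "bin", "nope")),
               "nope|no individuals")
})

test_that("fusion-simulated data shows the P2-P3 excess and bifurcating data does not", {
  s <- sample_config(8, 8, 6, n_out = 4)
  q <- quartet_assignment("sau", "alg", "bin", "out")
  # strong admixture from bin into alg
  fus <- toy_fusion_model(gamma = 0.4, N = 2e4, T_hyb = 2e4, T_div1 = 1e5)
  ds <- simulate_snp_dataset(fus, s, 1500, seed = 31)
  r <- d_statistic(ds, q, n_boot = 500, seed = 32)
  expect_gt(r$D, 0)
  expect_gt(r$Z, 3)
  # strictly bifurcating control: alg sister to sau, no pulse
  bif <- toy_bifurcating_model(N = 2e4, T_div2 = 2e4, T_div1 = 1e5)
  zs <- vapply(1:3, function(i) {
    dsb <- simulate_snp_dataset(bif, s, 1500, seed = 40 + i)
    d_statistic(dsb, q, n_boot = 500, seed = 50 + i)$Z
  }, numeric(1))
  expect_gte(sum(abs(zs) < 3), 2)
})

test_that("batch mode returns one labelled row per quartet", {
  gen <- generate_study_like(scale = 0.05, seed = 61)
  tab <- d_statistic_batch(
    gen$dataset,
    data.frame(p1 = c("sau", "alg"), p2 = c("alg", "sau"),
               p3 = c("bin", "bin"), outgroup = c("out", "out")),
    n_boot = 100, seed = 6)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$D[1], -tab$D[2], tolerance = 1e-12)
  expect_true(all(c("D", "SD", "Z", "p_value", "significant") %in%
                    names(tab)))
})
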