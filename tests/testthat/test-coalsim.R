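test_that("pairwise coalescence matches the standard neutral expectation", {
  N <- 1e4
  m <- single_deme_model(N)
  tm <- simulate_tmrca(m, sample_config(2, 0, 0), 4000, seed = 1)
  # E[TMRCA] = 2N for n = 2; SE = 2N/sqrt(reps)
  expect_lt(abs(mean(tm) - 2 * N), 4 * 2 * N / sqrt(length(tm)))
  # genealogy structure invariants
  g <- simulate_genealogy(m, sample_config(4, 2, 2), seed = 3)
  expect_equal(sum(is.na(g$parent)), 1)  # single root
  expect_equal(g$n_leaves, 8)
  ok <- !is.na(g$parent)
  expect_true(all(g$time[g$parent[ok]] >= g$time[ok]))
  expect_equal(g$leaf_deme, rep(c("bin", "sau", "alg"), c(4, 2, 2)))
})

test_that("an admixture pulse with gamma = 1 sends every alg lineage to bin", {
  # alg pairs (kept from coalescing early by a huge N_alg) must coalesce
  # shortly after T_hyb when the bin-side parental deme is tiny
  m <- toy_fusion_model(gamma = 1, N = 1e3, N_alg = 1e7, T_hyb = 5e3,
                        T_div1 = 1e7, N_anc_bin = 100, N_anc_sau = 1e7)
  tm <- simulate_tmrca(m, sample_config(0, 0, 2), 500, seed = 2)
  expect_true(all(tm > 5e3))
  expect_lt(mean(tm - 5e3), 5 * 200)  # ~2 * N_anc_bin after the pulse
  # with gamma = 0 the same pairs sit in the huge sau-side ancestor instead
  m0 <- toy_fusion_model(gamma = 0, N = 1e3, N_alg = 1e7, T_hyb = 5e3,
                         T_div1 = 1e7, N_anc_bin = 100, N_anc_sau = 1e7)
  tm0 <- simulate_tmrca(m0, sample_config(0, 0, 2), 500, seed = 2)
  expect_gt(mean(tm0), 50 * mean(tm))
})

test_that("SNP simulation returns the requested number of polymorphic loci, deterministically", {
  m <- toy_fusion_model()
  s <- sample_config(4, 4, 4)
  ds <- simulate_snp_dataset(m, s, 500, seed = 11)
  expect_equal(nrow(ds$geno), 500)
  expect_equal(ncol(ds$geno), 6)
  counts <- rowSums(ds$geno)
  expect_true(all(counts >= 1 & counts <= 11))  # polymorphic in full sample
  ds2 <- simulate_snp_dataset(m, s, 500, seed = 11)
  expect_identical(ds$geno, ds2$geno)
  ds3 <- simulate_snp_dataset(m, s, 500, seed = 12)
  expect_false(identical(ds$geno, ds3$geno))
})

test_that("single-deme site frequencies follow the neutral 1/i law", {
  m <- single_deme_model(5e3)
  n <- 8
  ds <- simulate_snp_dataset(m, sample_config(n, 0, 0), 10000, seed = 21)
  counts <- rowSums(ds$geno)  # derived copies among n=8, unfolded
  tab <- tabulate(counts, nbins = n - 1)
  p <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
  chisq <- sum((tab - 10000 * p)^2 / (10000 * p))
  # 6 degrees of freedom; 99.9% quantile ~ 22.5
  expect_lt(chisq, 22.5)
})

test_that("expected folded SFS matches the closed form for a single deme of 4", {
  m <- single_deme_model(1e4)
  e <- expected_sfs(m, sample_config(4, 0, 0), n_sims = 20000, seed = 31)
  expect_equal(sum(e$mass), 1, tolerance = 1e-12)
  expect_equal(e$mass[2], 8 / 11, tolerance = 0.02)
  expect_equal(e$mass[3], 3 / 11, tolerance = 0.02)
})

test_that("fusion with gamma = 0 equals a bifurcating history with matched sizes", {
  # fusion(gamma = 0): all alg lineages join sau at T_hyb; equivalent to a
  # bifurcating model with T_div2 = T_hyb when the bin branch keeps its
  # contemporary size above the split
  N <- 1e4
  fus <- toy_fusion_model(gamma = 0, N = N, T_hyb = 5e3, T_div1 = 2e4,
                          N_anc_bin = N)
  bif <- toy_bifurcating_model(N = N, T_div2 = 5e3, T_div1 = 2e4)
  s <- sample_config(4, 4, 4)
  e1 <- expected_sfs(fus, s, 40000, seed = 41)
  e2 <- expected_sfs(bif, s, 40000, seed = 42)
  sup <- e1$mass > 2e-3 | e2$mass > 2e-3
  expect_lt(max(abs(e1$mass[sup] - e2$mass[sup]) /
                  sqrt((e1$mass[sup] + e2$mass[sup]) / 2)), 0.1)
})

test_that("relabeling symmetric demes permutes the expected SFS axes", {
  # bin and sau fully exchangeable: same sizes, same migration to alg,
  # symmetric topology up to the deepest split
  m <- toy_fusion_model(gamma = 0.5, N = 1e4, T_hyb = 5e3, T_div1 = 2e4,
                        N_anc_bin = 2e4, N_anc_sau = 2e4)
  s <- sample_config(4, 4, 2)
  e1 <- expected_sfs(m, s, 60000, seed = 51)
  e2 <- expected_sfs(m, s, 60000, seed = 52)
  swapped <- aperm(e2$mass, c(2, 1, 3))
  big <- e1$mass > 5e-3
  expect_lt(max(abs(e1$mass[big] - swapped[big])), 0.012)
})

test_that("expected SFS normalizes and floors unobserved entries", {
  m <- toy_fusion_model()
  e <- expected_sfs(m, sample_config(6, 6, 4), 5000, seed = 61)
  expect_equal(sum(e$mass), 1, tolerance = 1e-12)
  sup <- fusioncoal:::.folded_support(dim(e$mass))
  expect_true(all(e$mass[sup] > 0))
  expect_true(all(e$mass[sup] >= 1 / (10 * 5000) * 0.5))
  expect_error(expected_sfs(m, sample_config(4, 4, 4), 500, seed = 1),
               "n_sims")
})

test_that("the fusion-pulse expected SFS matches an independent coalescent simulator at small n", {
  # scaled-down fusion demography (pulse + parental size changes + root
  # merge, no migration) checked entrywise against msprime's branch AFS
  m <- toy_fusion_model(gamma = 0.3, N = 1e4, T_hyb = 8e3, T_div1 = 4e4,
                        N_alg = 5e3, N_anc_bin = 2e4, N_anc_sau = 3e4,
                        N_anc = 1e4)
  s <- sample_config(2, 2, 2)
  n_batches <- 6
  ours <- lapply(seq_len(n_batches), function(b) {
    expected_sfs(m, s, n_sims = 6000, seed = 8800 + b)$mass
  })
  ours_mean <- Reduce(`+`, ours) / n_batches
  ours_se <- sqrt(Reduce(`+`, lapply(ours, function(x) (x - ours_mean)^2)) /
                    (n_batches - 1) / n_batches)
  out <- system2("python",
                 c(test_path("msprime_fusion_oracle.py"),
                   1e4, 1e4, 5e3, 2e4, 3e4, 1e4, 8e3, 4e4, 0.3,
                   2, 2, 2, 36000, n_batches, 31), stdout = TRUE)
  raw <- do.call(rbind, lapply(strsplit(out, " "), as.numeric))
  msp <- lapply(seq_len(nrow(raw)), function(b) {
    arr <- aperm(array(raw[b, ], dim = c(3, 3, 3)), c(3, 2, 1))
    arr <- fusioncoal:::.zero_monomorphic(fusioncoal:::.fold_mass(arr))
    arr / sum(arr)
  })
  msp_mean <- Reduce(`+`, msp) / length(msp)
  msp_se <- sqrt(Reduce(`+`, lapply(msp, function(x) (x - msp_mean)^2)) /
                   (length(msp) - 1) / length(msp))
  sup <- fusioncoal:::.folded_support(dim(ours_mean))
  diff <- abs(ours_mean - msp_mean)[sup]
  tol <- (3 * sqrt(ours_se^2 + msp_se^2))[sup]
  expect_true(all(diff <= pmax(tol, 1e-4)),
              info = paste0("max excess: ",
                            signif(max(diff - pmax(tol, 1e-4)), 3)))
})

test_that("Monte-Carlo error of the expected SFS shrinks with the simulation count", {
  m <- toy_fusion_model()
  s <- sample_config(4, 4, 2)
  disc <- function(n_sims, seeds) {
    a <- expected_sfs(m, s, n_sims, seed = seeds[1])$mass
    b <- expected_sfs(m, s, n_sims, seed = seeds[2])$mass
    sum(abs(a - b))
  }
  # total discrepancy between independent runs scales ~ n_sims^(-1/2):
  # a 16x larger run should shrink it by ~4; require a clear decrease
  d_small <- disc(4000, c(101, 102))
  d_big <- disc(64000, c(103, 104))
  expect_lt(d_big, d_small / 1.8)
})

test_that("simulator rejects impossible demographies", {
  m <- toy_fusion_model()
  m$params["N_anc_sau"] <- 0  # zero size in an active epoch
  expect_error(simulate_tmrca(m, sample_config(2, 2, 2), 10, seed = 1))
})
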