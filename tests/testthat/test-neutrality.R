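test_that("Tajima's D matches hand-derived toy values and the two-route check", {
  expect_equal(tajima_d(summary_stats(toy_alignment())), 0.1677,
               tolerance = 1e-3)
  expect_equal(tajima_d(summary_stats(toy_star())), -0.7545, tolerance = 1e-3)
  expect_true(is.na(tajima_d(4, S = 0, mean_pairwise = 0)))
  # independent re-derivation via (theta_pi - theta_W)/sd on random data
  for (seed in 1:100) {
    aln <- random_alignment(n_ind = sample(3:6, 1), L = 25, seed = 200 + seed)
    st <- summary_stats(aln)
    if (st$S == 0) next
    k <- sundapop:::tajima_constants(st$n)
    theta_pi <- st$mean_pairwise
    theta_w_abs <- st$S / k$a1
    d2 <- (theta_pi - theta_w_abs) /
      sqrt(k$e1 * st$S + k$e2 * st$S * (st$S - 1))
    expect_equal(tajima_d(st), d2, tolerance = 1e-12)
  }
})

test_that("fixed-S null is deterministic, centred and degenerate at n = 2", {
  a <- neutral_interval(24, 20, reps = 2000, seed = 5)
  b <- neutral_interval(24, 20, reps = 2000, seed = 5)
  expect_identical(a$lo, b$lo)
  expect_identical(a$D, b$D)
  expect_lt(a$lo, 0)
  expect_gt(a$hi, 0)
  # mean of fixed-S D is slightly negative; two seeds agree within MC error
  c2 <- neutral_interval(24, 20, reps = 2000, seed = 99)
  expect_lt(abs(mean(a$D) - mean(c2$D)), 0.05)
  # n = 2: every mutation separates the pair, mean pairwise == S exactly
  s2 <- sim_neutral(2, S = 7, seed = 3)
  expect_identical(ncol(s2$G), 7L)
  expect_true(all(s2$G[1, ] != s2$G[2, ]))
  # p at the simulated median is ~1
  med <- median(a$D)
  pm <- neutral_interval(24, 20, reps = 2000, seed = 5, D_obs = med)$p
  expect_gt(pm, 0.9)
})

test_that("the fixed-S null rejects its own data at ~5%", {
  ni <- neutral_interval(24, 12, reps = 10000, seed = 77)
  rej <- mean(ni$D < ni$lo | ni$D > ni$hi)
  expect_lt(abs(rej - 0.05), 0.01)
})

test_that("multilocus D test averages per-locus nulls", {
  # identical loci: multilocus p ~ single-locus p
  tab1 <- data.frame(locus = "A", n = 24, S = 15, D = -1.2)
  p1 <- neutral_interval(24, 15, reps = 4000, seed = 1, D_obs = -1.2)$p
  tabm <- data.frame(locus = c("A", "B", "C"), n = 24, S = 15, D = -1.2)
  pm <- multilocus_d_test(tabm, reps = 4000, seed = 1)$p
  # averaging shrinks the null spread: same observed average is more extreme
  expect_lte(pm, p1 + 0.05)
  # reproducibility
  expect_identical(multilocus_d_test(tabm, reps = 1000, seed = 3)$p,
                   multilocus_d_test(tabm, reps = 1000, seed = 3)$p)
  # loci with S = 0 are dropped
  tab0 <- rbind(tabm, data.frame(locus = "Z", n = 24, S = 0, D = NA))
  expect_equal(nrow(multilocus_d_test(tab0, reps = 500, seed = 2)$loci), 3)
  # strongly negative average D on a paper-sized configuration is significant
  tabneg <- data.frame(locus = paste0("L", 1:5), n = 154,
                       S = c(30, 40, 35, 25, 38), D = -1.8)
  expect_lt(multilocus_d_test(tabneg, reps = 3000, seed = 4)$p, 0.05)
})

test_that("MK test reproduces the five printed tables exactly", {
  fx <- mk_fixture()
  printed <- data.frame(
    locus = c("GapC", "GBSSI", "PgiC", "SBE2", "SODH"),
    fisher = c(0.12874, 0.00181, 1.00000, 0.52381, 0.21678),
    g = c(0.06825, 0.00078, 0.79974, 0.34063, 0.06971))
  for (i in seq_len(nrow(fx))) {
    m <- mk_test(fx$fixed_syn[i], fx$fixed_rep[i], fx$poly_syn[i],
                 fx$poly_rep[i])
    expect_equal(round(m$fisher_p, 5), printed$fisher[i], tolerance = 1e-9,
                 label = paste("fisher", fx$locus[i]))
    expect_equal(round(m$g_p, 5), printed$g[i], tolerance = 1e-9,
                 label = paste("G", fx$locus[i]))
  }
})

test_that("two-tailed Fisher equals stats::fisher.test over random tables", {
  set.seed(42)
  for (rep in 1:60) {
    repeat {
      x <- as.vector(stats::rmultinom(1, sample(8:80, 1), rep(0.25, 4)))
      if (all(rowSums(matrix(x, 2)) > 0) && all(colSums(matrix(x, 2)) > 0))
        break
    }
    ours <- sundapop:::fisher_two_tailed(x[1], x[2], x[3], x[4])
    ref <- stats::fisher.test(matrix(x, 2, 2))$p.value
    expect_equal(ours, ref, tolerance = 1e-7)
  }
})

test_that("degenerate MK margins give fisher p = 1 with a flag", {
  m <- mk_test(0, 0, 5, 3)
  expect_true(m$degenerate)
  expect_equal(m$fisher_p, 1)
})

test_that("Ka/Ks behaves on constructed codon differences", {
  # identical sequences: zero on both axes
  a <- locus_alignment("kk", c("TTTAAAGGGCCC", "TTTAAAGGGCCC"),
                       c("I1", "I1"),
                       data.frame(start = 0, end = 12, frame = 0))
  r0 <- ka_ks(a, "TTTAAAGGGCCC")
  expect_equal(r0$Ka, 0)
  expect_equal(r0$Ks, 0)
  # one synonymous change (GGG -> GGA): Ks > 0, Ka = 0
  r1 <- ka_ks(a, "TTTAAAGGACCC")
  expect_gt(r1$Ks, 0)
  expect_equal(r1$Ka, 0)
  # one replacement change (AAA -> GAA, Lys -> Glu): Ka > 0, Ks = 0
  r2 <- ka_ks(a, "TTTGAAGGGCCC")
  expect_gt(r2$Ka, 0)
  expect_equal(r2$Ks, 0)
  # outgroup with two identical haplotypes gives the same answer as one
  r3 <- ka_ks(a, c("TTTAAAGGACCC", "TTTAAAGGACCC"))
  expect_equal(r3$Ks, r1$Ks)
})

test_that("HKA matches a straight-line estimating-equation oracle", {
  tab <- data.frame(locus = c("A", "B"), n = c(10, 10), S = c(12, 6),
                    D = c(20, 10))
  res <- hka_test(tab)
  # oracle: solve the same equations independently
  a_n <- sum(1 / (1:9))
  f <- function(T) sum((tab$S + tab$D) * (T + 1) / (a_n + T + 1)) - sum(tab$D)
  T0 <- uniroot(f, c(1e-9, 1e5), tol = 1e-12)$root
  th <- (tab$S + tab$D) / (a_n + T0 + 1)
  expect_equal(res$T, T0, tolerance = 1e-8)
  expect_equal(res$theta, th, tolerance = 1e-8)
  # conservation: observed totals equal expected totals on each side
  expect_equal(sum(res$table$exp_S), sum(tab$S), tolerance = 1e-6)
  expect_equal(sum(res$table$exp_D), sum(tab$D), tolerance = 1e-6)
  # proportional polymorphism/divergence -> chi2 ~ 0
  expect_lt(res$chi2, 1e-10)
  expect_equal(res$df, 1)
  # doubling one locus's polymorphism breaks proportionality
  tab2 <- tab
  tab2$S[1] <- 24
  res2 <- hka_test(tab2)
  expect_gt(res2$chi2, res$chi2)
  # permutation invariance
  expect_equal(hka_test(tab2[2:1, ])$chi2, res2$chi2, tolerance = 1e-9)
  # no divergence anywhere is an error
  expect_error(hka_test(data.frame(locus = 1:2, n = 10, S = c(3, 4),
                                   D = c(0, 0))), "no information")
})
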