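test_that("conversion identities hold exactly and reproduce printed values", {
  est <- im_params(theta_sm = 4.367, theta_b = 11.2873, theta_A = 1.1677,
                   m_sm = 0.755, m_b = 0.045, t = 0.685)
  # the printed per-generation rate bracket V = (1.55e-5, 5.78e-5) divided
  # by the 60-year generation time gives the annual rates
  dt <- convert_parameters(est, u_annual = c(min = 1.55e-5, max = 5.78e-5) / 60,
                           gen_years = 60)
  mx <- dt[dt$bracket == "max", ]
  expect_equal(round(mx$two_Nm_sm, 2), 1.65)
  expect_equal(round(mx$two_Nm_b, 2), 0.25)
  expect_equal(round(mx$Ne_A), 5051)
  # round trip: theta = 4 V Ne and t = T u to machine precision
  for (r in seq_len(nrow(dt))) {
    expect_equal(4 * dt$V[r] * dt$Ne_sm[r], 4.367, tolerance = 1e-12)
    expect_equal(dt$T_years[r] * dt$u_locus_year[r], 0.685, tolerance = 1e-12)
  }
  # locus-table route: geometric mean of per-locus annual rates
  lt <- data.frame(locus = c("a", "b"), silent_sites = c(800, 900),
                   replacement_sites = c(300, 250), ka_ks = c(0.1, 0.2))
  d2 <- convert_parameters(est, u_syn_min = 0.7e-9, u_syn_max = 2.61e-9,
                           gen_years = 60, locus_table = lt)
  r1 <- 0.7e-9 * (800 + 0.1 * 300)
  r2 <- 0.7e-9 * (900 + 0.2 * 250)
  expect_equal(d2$u_locus_year[d2$bracket == "min"], sqrt(r1 * r2),
               tolerance = 1e-12)
  expect_error(convert_parameters(est, u_annual = c(min = 0)), "zero")
})

test_that("mixed chi-square p has the boundary-null shape", {
  expect_equal(mixed_chisq_p(0), 1)
  x <- seq(0.01, 10, length.out = 50)
  p <- mixed_chisq_p(x)
  expect_true(all(diff(p) < 0))
  expect_equal(p, 0.5 * pchisq(x, 1, lower.tail = FALSE))
  expect_equal(mixed_chisq_p(qchisq(1 - 0.1, 1)), 0.05, tolerance = 1e-12)
})

test_that("observed summary vector is invariant to haplotype relabelling", {
  ds <- sim_two_pop_dataset(n_ind_per_pop = 6, n_loci = 4, seed = 3,
                            params = im_params(4, 6, 2, 0.3, 0.3, 1))
  o1 <- obs_im_summaries(ds)
  # permute loci
  ds2 <- multilocus_dataset(ds$loci[c(3, 1, 4, 2)], ds$popmap)
  o2 <- obs_im_summaries(ds2)
  expect_equal(sort(unname(o1$obs)), sort(unname(o2$obs)), tolerance = 1e-12)
  expect_equal(unname(colMeans(rbind(o1$obs))), unname(colMeans(rbind(o2$obs))),
               tolerance = 1e-12)
  # permute individuals within groups (relabel haplotypes)
  perm <- unlist(lapply(seq(1, 24, by = 4), function(i) c(i + 2, i + 3, i, i + 1)))
  loci3 <- lapply(ds$loci, function(a)
    locus_alignment(a$locus_name, a$seqs[perm, ], a$individuals[perm], a$exons))
  ds3 <- multilocus_dataset(loci3, ds$popmap)
  o3 <- obs_im_summaries(ds3)
  expect_equal(o1$obs, o3$obs, tolerance = 1e-12)
})

test_that("synthetic likelihood is deterministic given a seed and sane", {
  p <- c(4, 8, 2, 0.5, 0.1, 0.8)
  obs <- colMeans(sundapop:::cpp_im_summaries(p, 20L, 20L, rep(1, 6), 40L, 5L))
  l1 <- sundapop:::sl_objective(p, obs, 20, 20, rep(1, 6), 24, 9L)
  l2 <- sundapop:::sl_objective(p, obs, 20, 20, rep(1, 6), 24, 9L)
  expect_identical(l1, l2)
  expect_true(is.finite(l1))
  # a grossly wrong parameter point scores much worse
  lw <- sundapop:::sl_objective(c(30, 30, 30, 8, 8, 4), obs, 20, 20,
                                rep(1, 6), 24, 9L)
  expect_lt(lw, l1 - 10)
  expect_identical(sundapop:::sl_objective(c(-1, 8, 2, 0.5, 0.1, 0.8), obs,
                                           20, 20, rep(1, 6), 24, 9L), -Inf)
})

test_that("demographic-null Tajima test is reproducible and floors at 2/reps", {
  ds <- sim_two_pop_dataset(n_ind_per_pop = 5, n_loci = 2, seed = 7,
                            params = im_params(4, 4, 2, 0.2, 0.2, 1))
  pars <- im_params(4, 4, 2, 0.2, 0.2, 1)
  r1 <- demographic_null_tajima(pars, ds, reps = 200, seed = 3)
  r2 <- demographic_null_tajima(pars, ds, reps = 200, seed = 3)
  expect_identical(r1, r2)
  expect_true(all(r1$p >= 0 & r1$p <= 1, na.rm = TRUE))
  expect_equal(nrow(r1), 2 * 3)
})

test_that("nested menu covers the standard constraint set", {
  menu <- sundapop:::im_nested_menu()
  expect_length(menu, 8)
  expect_equal(menu$isolation$zero, c("m_sm", "m_b"))
  expect_equal(menu$theta_all$equal[[1]],
               c("theta_sm", "theta_b", "theta_A"))
})
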