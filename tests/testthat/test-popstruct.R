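# arbitrary even number of haplotypes per population (one individual per
# two consecutive haplotypes)
make_big_two_pop <- function(seqs1, seqs2) {
  m <- do.call(rbind, strsplit(c(seqs1, seqs2), ""))
  n1 <- length(seqs1) / 2; n2 <- length(seqs2) / 2
  inds <- c(rep(sprintf("A%02d", seq_len(n1)), each = 2),
            rep(sprintf("B%02d", seq_len(n2)), each = 2))
  multilocus_dataset(
    list(A = locus_alignment("A", m, inds)),
    data.frame(individual = unique(inds),
               population = rep(c("P1", "P2"), c(n1, n2)),
               group = rep(c("sumatra_malay", "borneo"), c(n1, n2))))
}

make_two_pop_fixed <- function(seqs1, seqs2, L) {
  # two populations of 2 individuals each with given haplotype strings
  m <- do.call(rbind, strsplit(c(seqs1, seqs2), ""))
  ds <- multilocus_dataset(
    list(A = locus_alignment("A", m, rep(c("I1", "I2", "I3", "I4"), each = 2))),
    data.frame(individual = c("I1", "I2", "I3", "I4"),
               population = c("P1", "P1", "P2", "P2"),
               group = c("sumatra_malay", "sumatra_malay", "borneo", "borneo")))
  ds
}

test_that("Hudson Fst matches hand counts and limiting cases", {
  # identical pools: |Fst| small (the estimator's within-pool pairs exclude
  # self-pairs, so it is slightly negative at finite n, never positive)
  h <- rep(c("AAAA", "AATT"), 12)
  ds0 <- make_big_two_pop(h, h)
  f0 <- fst_matrix(ds0)$A["P1", "P2"]
  expect_lte(f0, 0)
  expect_lt(abs(f0), 0.05)
  # two populations fixed for different haplotypes: Fst = 1
  ds1 <- make_two_pop_fixed(rep("AAAA", 4), rep("TTTT", 4))
  expect_equal(fst_matrix(ds1)$A["P1", "P2"], 1)
  # hand count: P1 = {AAAA, AAAT}, P2 = {TTAA, TTAT}: Hw = (1+1)/2 = 1,
  # Hb = (2+3+3+2)/4 = 2.5, Fst = 1 - 1/2.5 = 0.6
  ds2 <- make_big_two_pop(c("AAAA", "AAAT"), c("TTAA", "TTAT"))
  expect_equal(fst_matrix(ds2)$A["P1", "P2"], 0.6, tolerance = 1e-12)
  # brute-force oracle on random data
  ds3 <- sim_two_pop_dataset(n_ind_per_pop = 3, n_loci = 1, seed = 9)
  aln <- ds3$loci[[1]]
  A <- aln$seqs[1:6, ]; B <- aln$seqs[7:12, ]
  hw <- (brute_mean_pairwise(A) + brute_mean_pairwise(B)) / 2
  hb <- sundapop:::mean_pairwise_between(A, B)
  expect_equal(fst_matrix(ds3)[[1]]["P1", "P2"], 1 - hw / hb,
               tolerance = 1e-12)
})

test_that("identical populations give Da = 0 and monomorphic pairs give NA Fst", {
  ds <- make_two_pop_fixed(rep("ACGT", 4), rep("ACGT", 4))
  expect_true(is.na(fst_matrix(ds)$A["P1", "P2"]))
  da <- da_matrix(ds)
  expect_equal(unclass(da)["P1", "P2"], 0)
})

test_that("NJ recovers additive trees exactly", {
  # fixed 4-taxon additive case: ((A,B),(C,D)) internal branch 1
  dm <- matrix(c(0, 2, 4, 4,
                 2, 0, 4, 4,
                 4, 4, 0, 2,
                 4, 4, 2, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(dm)
  expect_true(ape::is.monophyletic(tr$tree, c("A", "B")))
  expect_true(ape::is.monophyletic(tr$tree, c("C", "D")))
  cp <- ape::cophenetic.phylo(tr$tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(unname(cp), unname(dm), tolerance = 1e-9)
  # random additive trees, up to 8 taxa
  set.seed(7)
  for (rep in 1:20) {
    nt <- sample(4:8, 1)
    tree <- ape::rtree(nt, br = function(n) runif(n, 0.5, 2))
    dmat <- ape::cophenetic.phylo(tree)
    rec <- nj_tree(dmat)$tree
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tree), ape::unroot(rec))), 0)
  }
})

test_that("NJ output has no negative branch lengths", {
  set.seed(21)
  m <- matrix(runif(25, 0.5, 2), 5, 5)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(letters[1:5], letters[1:5])
  tr <- nj_tree(m)
  expect_true(all(tr$tree$edge.length >= 0))
  expect_match(tr$newick, "^\\(")
  expect_error(nj_tree(m[1:2, 1:2]), ">= 3")
})

test_that("haplotype grouping is single-linkage with deterministic codes", {
  # chain h1 - h2 - h3, one difference apart: one allele at max_diff = 1
  aln <- locus_alignment("g", c("AAAA", "AAAT", "AATT",
                                "AAAA", "AAAT", "AATT"),
                         c("I1", "I2", "I3", "I1", "I2", "I3"))
  c0 <- group_haplotypes(aln, 0)
  expect_equal(attr(c0, "n_alleles"), 3)
  c1 <- group_haplotypes(aln, 1)
  expect_equal(attr(c1, "n_alleles"), 1)
  # identity grouping maps equal sequences to equal codes
  expect_equal(c0[1:3], c0[4:6])
  # deterministic under row permutation of equal content
  aln2 <- locus_alignment("g", aln$seqs[c(4, 5, 6, 1, 2, 3), ],
                          aln$individuals[c(4, 5, 6, 1, 2, 3)])
  expect_equal(attr(group_haplotypes(aln2, 0), "n_alleles"), 3)
})

test_that("admixture model recovers a clean two-population split", {
  # K = 1: Q is identically 1
  geno <- matrix(1L, 10, 6)
  r1 <- admixture_fit(geno, K = 1, burn_in = 100, reps = 400, seed = 1)
  expect_true(all(r1$Q == 1))
  # two populations fixed for different alleles at 5 loci
  set.seed(3)
  g2 <- cbind(matrix(rep(c(1L, 2L), each = 10), 20, 10))
  g2 <- matrix(c(rep(1L, 100), rep(2L, 100)), 20, 10, byrow = TRUE)
  g2 <- rbind(matrix(1L, 10, 10), matrix(2L, 10, 10))
  hits <- 0
  for (seed in 1:5) {
    r <- admixture_fit(g2, K = 2, burn_in = 300, reps = 1500, seed = seed)
    lab <- apply(r$Q, 1, which.max)
    ok <- (all(lab[1:10] == lab[1]) && all(lab[11:20] == lab[11]) &&
             lab[1] != lab[11])
    hits <- hits + ok
  }
  expect_gte(hits, 5 * 0.95 - 1)
  # same seed, same output
  ra <- admixture_fit(g2, K = 2, burn_in = 100, reps = 500, seed = 11)
  rb <- admixture_fit(g2, K = 2, burn_in = 100, reps = 500, seed = 11)
  expect_identical(ra$Q, rb$Q)
  expect_identical(ra$lnP, rb$lnP)
})

test_that("admixed individuals get intermediate membership", {
  # two source populations fixed for different alleles; planted 50/50
  # admixed individuals carry one allele copy from each side
  g <- rbind(matrix(1L, 10, 10), matrix(2L, 10, 10))
  adm <- matrix(rep(c(1L, 2L), 5), 4, 10, byrow = TRUE)
  gall <- rbind(g, adm)
  hits <- 0
  for (seed in 1:5) {
    r <- admixture_fit(gall, K = 2, burn_in = 500, reps = 2000, seed = seed)
    q <- r$Q[21:24, 1]
    hits <- hits + all(q > 0.2 & q < 0.8)
  }
  expect_gte(hits, 4)
})

test_that("Evanno delta-K picks the knee and validates its inputs", {
  mk_run <- function(K, lnP) structure(list(K = K, lnP = lnP,
                                            settings = list()),
                                       class = "cluster_run")
  # strong knee at K = 2
  runs <- c(lapply(c(-500, -501), function(x) mk_run(1, x)),
            lapply(c(-300, -302), function(x) mk_run(2, x)),
            lapply(c(-295, -299), function(x) mk_run(3, x)),
            lapply(c(-293, -296), function(x) mk_run(4, x)))
  sel <- select_k(runs)
  expect_equal(sel$K_star, 2)
  # delta K is invariant to adding a constant to all lnP
  runs2 <- lapply(runs, function(r) { r$lnP <- r$lnP + 1000; r })
  sel2 <- select_k(runs2)
  expect_equal(sel$table$delta_K, sel2$table$delta_K)
  expect_error(select_k(runs[1:4]), ">= 3")
})
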