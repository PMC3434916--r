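# small in-code fixtures shared across tests

toy_alignment <- function() {
  # 4 haplotypes, 4 all-silent sites: AAAA / AAAT / AATT / ATTT
  locus_alignment("toy4", c("AAAA", "AAAT", "AATT", "ATTT"),
                  c("I1", "I1", "I2", "I2"))
}

toy_star <- function() {
  # 3 identical + 1 triply diverged haplotype
  locus_alignment("star", c("AAA", "AAA", "AAA", "TTT"),
                  c("I1", "I1", "I2", "I2"))
}

random_alignment <- function(n_ind = 4, L = 30, seed = 1, p_var = 0.2) {
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  n <- 2 * n_ind
  m <- matrix(rep(anc, each = n), n, L)
  for (j in seq_len(L)) {
    if (runif(1) < p_var) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), anc[j]), 1)
      carriers <- sample(n, sample(n - 1, 1))
      m[carriers, j] <- alt
    }
  }
  locus_alignment(paste0("rand", seed), m,
                  rep(sprintf("I%02d", seq_len(n_ind)), each = 2))
}

# brute-force pi / mean pairwise oracle
brute_mean_pairwise <- function(seqs, mask = NULL) {
  if (!is.null(mask)) seqs <- seqs[, !mask, drop = FALSE]
  n <- nrow(seqs)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(seqs[i, ] != seqs[j, ])
  tot / (n * (n - 1) / 2)
}

# small two-population dataset built from sim_im output
sim_two_pop_dataset <- function(n_ind_per_pop = 6, n_loci = 3, seed = 1,
                                params = im_params(4, 4, 2, 0, 0, 2),
                                L = 400) {
  loci <- list()
  n1 <- n_ind_per_pop * 2
  n2 <- n_ind_per_pop * 2
  inds <- sprintf("I%02d", seq_len(2 * n_ind_per_pop))
  for (l in seq_len(n_loci)) {
    smp <- sim_im(params, n1, n2, L = L, seed = seed * 100 + l)
    anc <- {
      set.seed(seed * 1000 + l)
      sample(c("A", "C", "G", "T"), L, replace = TRUE)
    }
    m <- matrix(rep(anc, each = n1 + n2), n1 + n2, L)
    for (s in seq_len(ncol(smp$G))) {
      alt <- setdiff(c("A", "C", "G", "T"), anc[smp$columns[s] + 1])[1]
      m[smp$G[, s] == 1, smp$columns[s] + 1] <- alt
    }
    loci[[paste0("L", l)]] <- locus_alignment(paste0("L", l), m,
                                              rep(inds, each = 2))
  }
  popmap <- data.frame(individual = inds,
                       population = rep(c("P1", "P2"), each = n_ind_per_pop),
                       group = rep(c("sumatra_malay", "borneo"),
                                   each = n_ind_per_pop))
  multilocus_dataset(loci, popmap)
}
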