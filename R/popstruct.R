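#' Pairwise population Fst per locus
#'
#' Hudson-style fixation index: Fst = 1 - Hw/Hb, with Hw the mean
#' within-population pairwise difference count (average of the two
#' populations) and Hb the mean between-population pairwise difference
#' count. Undefined (NA) when Hb = 0.
#'
#' @param ds A `multilocus_dataset`.
#' @return List (by locus) of symmetric population x population matrices.
#' @export
fst_matrix <- function(ds) {
  pops <- unique(ds$popmap$population)
  out <- list()
  for (nm in names(ds$loci)) {
    aln <- ds$loci[[nm]]
    seqs <- aln$seqs[, !aln$mask, drop = FALSE]
    popof <- ds$popmap$population[match(aln$individuals, ds$popmap$individual)]
    M <- matrix(NA_real_, length(pops), length(pops),
                dimnames = list(pops, pops))
    diag(M) <- 0
    for (i in seq_along(pops)) for (j in seq_len(i - 1)) {
      A <- seqs[popof == pops[i], , drop = FALSE]
      B <- seqs[popof == pops[j], , drop = FALSE]
      if (nrow(A) < 2 || nrow(B) < 2) next
      hw <- (mean_pairwise_within(A) + mean_pairwise_within(B)) / 2
      hb <- mean_pairwise_between(A, B)
      M[i, j] <- M[j, i] <- if (hb > 0) 1 - hw / hb else NA_real_
    }
    out[[nm]] <- M
  }
  out
}

mean_pairwise_within <- function(A) {
  n <- nrow(A)
  if (n < 2) return(NA_real_)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) tot <- tot + sum(A[i, ] != A[j, ])
  tot / (n * (n - 1) / 2)
}

mean_pairwise_between <- function(A, B) {
  tot <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    tot <- tot + sum(A[i, ] != B[j, ])
  tot / (nrow(A) * nrow(B))
}

#' Net nucleotide divergence (Da) between populations
#'
#' Da = Dxy - (pi_x + pi_y)/2, computed on the concatenated unmasked sites
#' across loci. Small negative entries are legal (net correction) and are
#' preserved.
#'
#' @param ds A `multilocus_dataset`.
#' @return A symmetric labelled matrix (class `dist_matrix`).
#' @export
da_matrix <- function(ds) {
  pops <- unique(ds$popmap$population)
  concat <- do.call(cbind, lapply(ds$loci, function(a)
    a$seqs[order(a$individuals), !a$mask, drop = FALSE]))
  inds <- sort(unique(ds$popmap$individual))
  popof <- rep(ds$popmap$population[match(inds, ds$popmap$individual)], each = 2)
  M <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1)) {
    A <- concat[popof == pops[i], , drop = FALSE]
    B <- concat[popof == pops[j], , drop = FALSE]
    dxy <- mean_pairwise_between(A, B)
    da <- dxy - (mean_pairwise_within(A) + mean_pairwise_within(B)) / 2
    M[i, j] <- M[j, i] <- da
  }
  structure(M, class = c("dist_matrix", "matrix"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape). Negative branch lengths are
#' truncated to zero with the length transferred to the adjacent branch, the
#' common convention for distance trees.
#'
#' @param dm Symmetric labelled distance matrix (e.g. from [da_matrix()]).
#' @return List with the `phylo` tree and its Newick text.
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3) stop("NJ needs >= 3 taxa")
  tr <- ape::nj(stats::as.dist(dm))
  # truncate negative branches, moving length to the adjacent branch
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    child <- tr$edge[e, 2]
    parent <- tr$edge[e, 1]
    adj <- which(tr$edge[, 2] == parent)
    if (length(adj) == 1)
      tr$edge.length[adj] <- tr$edge.length[adj] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  list(tree = tr, newick = ape::write.tree(tr))
}

#' Group related haplotypes into alleles
#'
#' Single-linkage clustering of the distinct haplotypes of one locus at
#' Hamming distance <= `max_diff` (on unmasked columns); each cluster is one
#' allele code. `max_diff = 0` gives identity grouping. Codes are
#' deterministic given the sorted haplotype order.
#'
#' @param aln A `locus_alignment`.
#' @param max_diff Maximum single-link distance within an allele group.
#' @return Integer allele code per haplotype (in `aln` row order), with the
#'   number of allele classes as attribute `n_alleles` and the `max_diff`
#'   used as attribute.
#' @export
group_haplotypes <- function(aln, max_diff = 0) {
  stopifnot(max_diff >= 0)
  seqs <- aln$seqs[, !aln$mask, drop = FALSE]
  hap_str <- apply(seqs, 1, paste, collapse = "")
  uh <- sort(unique(hap_str))
  idx <- match(hap_str, uh)
  k <- length(uh)
  if (k == 1) {
    codes <- rep(1L, nrow(seqs))
  } else {
    um <- do.call(rbind, strsplit(uh, ""))
    d <- matrix(0, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      d[i, j] <- d[j, i] <- sum(um[i, ] != um[j, ])
    if (max_diff == 0) {
      cl <- seq_len(k)
    } else {
      hc <- stats::hclust(stats::as.dist(d), method = "single")
      cl <- stats::cutree(hc, h = max_diff + 0.5)
    }
    # renumber deterministically by first appearance in sorted order
    cl <- as.integer(factor(cl, levels = unique(cl)))
    codes <- cl[idx]
  }
  attr(codes, "n_alleles") <- length(unique(codes))
  attr(codes, "max_diff") <- max_diff
  codes
}

#' Allele-coded genotype matrix for admixture clustering
#'
#' @param ds A `multilocus_dataset`.
#' @param max_diff Haplotype-grouping threshold passed to
#'   [group_haplotypes()].
#' @return List with `geno` (individuals x 2*loci integer matrix, 1-based
#'   codes), `n_alleles` per locus, `individuals`, `loci`, `max_diff`.
#' @export
alleles_from_dataset <- function(ds, max_diff = 0) {
  inds <- sort(unique(ds$popmap$individual))
  L <- length(ds$loci)
  geno <- matrix(NA_integer_, length(inds), 2 * L)
  n_alleles <- integer(L)
  for (l in seq_len(L)) {
    aln <- ds$loci[[l]]
    codes <- group_haplotypes(aln, max_diff)
    n_alleles[l] <- attr(codes, "n_alleles")
    for (i in seq_along(inds)) {
      rows <- which(aln$individuals == inds[i])
      geno[i, 2 * l - 1] <- codes[rows[1]]
      geno[i, 2 * l] <- codes[rows[2]]
    }
  }
  list(geno = geno, n_alleles = n_alleles, individuals = inds,
       loci = names(ds$loci), max_diff = max_diff)
}

#' Fit the admixture clustering model (STRUCTURE-style Gibbs sampler)
#'
#' Admixture model with uncorrelated allele frequencies: a latent cluster of
#' origin for each allele copy, Dirichlet(lambda + counts) frequency
#' updates, Dirichlet(alpha + counts) ancestry updates, and a Metropolis
#' update of the common alpha under a uniform prior on (0, alpha_max]. The
#' data log-probability is estimated as mean(lnL) - var(lnL)/2 over
#' post-burn-in samples. Cluster labels are arbitrary per run.
#'
#' @param alleles Result of [alleles_from_dataset()], or an individuals x
#'   (2 * loci) integer matrix of 1-based allele codes.
#' @param K Number of clusters (>= 1).
#' @param burn_in,reps Burn-in and collection iterations.
#' @param seed Integer seed.
#' @param lambda Dirichlet prior parameter for allele frequencies.
#' @param alpha_max,alpha_prop_sd Prior bound and proposal s.d. for alpha.
#' @return A `cluster_run`: `K`, `Q` (membership fractions), `lnP`,
#'   `alpha` trace, settings and seed.
#' @export
admixture_fit <- function(alleles, K, burn_in = 5000, reps = 20000, seed = 1,
                          lambda = 1, alpha_max = 10, alpha_prop_sd = 0.05) {
  stopifnot(K >= 1, reps > 0, burn_in >= 0)
  if (is.matrix(alleles)) alleles <- list(geno = alleles,
    n_alleles = vapply(seq_len(ncol(alleles) / 2), function(l)
      max(alleles[, c(2 * l - 1, 2 * l)]), 0), individuals = rownames(alleles))
  geno0 <- alleles$geno - 1L
  monomorphic <- all(alleles$n_alleles == 1)
  if (monomorphic && K > 1)
    warning("monomorphic dataset with K > 1: Q is symmetric by construction")
  r <- cpp_structure_gibbs(geno0, as.integer(alleles$n_alleles), as.integer(K),
                           as.integer(burn_in), as.integer(reps), lambda, 1.0,
                           alpha_max, alpha_prop_sd, as.integer(seed))
  rownames(r$Q) <- alleles$individuals
  structure(list(K = K, Q = r$Q, lnP = r$lnP, mean_lnL = r$mean_lnL,
                 var_lnL = r$var_lnL, alpha = r$alpha,
                 settings = list(burn_in = burn_in, reps = reps,
                                 lambda = lambda, alpha_max = alpha_max),
                 seed = seed),
            class = "cluster_run")
}

#' @export
print.cluster_run <- function(x, ...) {
  cat(sprintf("cluster_run: K=%d lnP=%.2f (burn-in %d, reps %d, seed %d)\n",
              x$K, x$lnP, x$settings$burn_in, x$settings$reps, x$seed))
  invisible(x)
}

#' Evanno delta-K model selection
#'
#' delta K(K) = mean over runs of |lnP(K-1) + lnP(K+1) - 2 lnP(K)| divided
#' by the run-to-run standard deviation of lnP(K); the selected K is the
#' argmax over interior K values. A zero standard deviation yields an
#' infinite delta K, reported with a flag.
#'
#' @param runs List of `cluster_run` objects covering >= 3 consecutive K
#'   values with >= 2 runs each.
#' @return A `delta_k_table`: per-K means/sds, |L''|, delta K, selected
#'   `K_star`.
#' @export
select_k <- function(runs) {
  Ks <- vapply(runs, function(r) r$K, 0)
  lnP <- vapply(runs, function(r) r$lnP, 0)
  kvals <- sort(unique(Ks))
  if (length(kvals) < 3) stop("need >= 3 consecutive K values")
  if (any(diff(kvals) != 1)) stop("K values must be consecutive")
  reps_per_k <- table(Ks)
  if (any(reps_per_k < 2)) stop("need >= 2 runs per K")
  R <- min(reps_per_k)
  # pair runs by within-K order for the per-run second difference
  byk <- lapply(kvals, function(k) sort(lnP[Ks == k])[seq_len(R)])
  names(byk) <- kvals
  tab <- data.frame(K = kvals,
                    mean_lnP = vapply(byk, mean, 0),
                    sd_lnP = vapply(byk, sd, 0))
  tab$abs_Lpp <- NA_real_
  tab$delta_K <- NA_real_
  for (i in seq_along(kvals)) {
    if (i == 1 || i == length(kvals)) next
    d2 <- abs(byk[[i - 1]] + byk[[i + 1]] - 2 * byk[[i]])
    tab$abs_Lpp[i] <- mean(d2)
    tab$delta_K[i] <- mean(d2) / tab$sd_lnP[i]
  }
  sd_zero <- any(tab$sd_lnP[-c(1, length(kvals))] == 0)
  K_star <- tab$K[which.max(tab$delta_K)]
  structure(list(table = tab, K_star = K_star, sd_zero = sd_zero,
                 runs_per_k = R),
            class = "delta_k_table")
}

#' @export
print.delta_k_table <- function(x, ...) {
  print(x$table, digits = 4)
  cat("selected K* =", x$K_star,
      if (x$sd_zero) "(warning: zero sd at some K)" else "", "\n")
  invisible(x)
}

#' Run the admixture sampler over a K range and select K
#'
#' @param ds A `multilocus_dataset`.
#' @param k_range Integer vector of K values (>= 3 consecutive values).
#' @param n_runs Independent runs per K.
#' @param burn_in,reps MCMC settings per run.
#' @param seed Integer seed (per-run seeds derived deterministically).
#' @param max_diff Haplotype-grouping threshold.
#' @return List with all `runs`, the [select_k()] table, and the allele
#'   encoding used.
#' @export
structure_scan <- function(ds, k_range = 1:4, n_runs = 5, burn_in = 5000,
                           reps = 20000, seed = 1, max_diff = 0) {
  alleles <- alleles_from_dataset(ds, max_diff)
  runs <- list()
  for (K in k_range) {
    for (r in seq_len(n_runs)) {
      runs[[length(runs) + 1]] <-
        admixture_fit(alleles, K, burn_in, reps,
                      seed = derive_seed(seed, paste0("K", K, "r", r)))
    }
  }
  list(runs = runs, selection = select_k(runs), alleles = alleles)
}
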