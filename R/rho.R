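#' Monte-Carlo two-locus likelihood table for rho estimation
#'
#' For each value of the pairwise recombination rate grid, simulates
#' two-locus coalescent samples (one mutation conditioned onto each marginal
#' tree) and tabulates the probability of each two-site haplotype-count
#' configuration, folded over allele relabelling at either site. The table
#' is cached on disk keyed by (n, grid, mc_reps, seed).
#'
#' @param n Sample size.
#' @param grid Pairwise rho values (4Nr between the two sites).
#' @param mc_reps Simulations per grid value.
#' @param seed Integer seed.
#' @param cache_dir Directory for the cache (default `tempdir()`).
#' @return A `two_locus_table`: list of per-rho named probability vectors.
#' @export
two_locus_table <- function(n, grid = c(0, 0.5, 1, 2, 5, 10, 20, 50, 100),
                            mc_reps = 4000, seed = 1,
                            cache_dir = file.path(tempdir(), "sundapop_rho")) {
  key <- paste0("tl_n", n, "_g", paste(grid, collapse = "-"), "_r", mc_reps,
                "_s", seed, ".rds")
  path <- file.path(cache_dir, gsub("[^A-Za-z0-9._-]", "_", key))
  if (file.exists(path)) return(readRDS(path))
  tabs <- list()
  for (i in seq_along(grid)) {
    cfg <- cpp_two_locus(as.integer(n), grid[i], as.integer(mc_reps),
                         derive_seed(seed, paste0("rho", i)))
    keys <- apply(cfg, 1, canonical_config)
    tb <- table(keys)
    tabs[[as.character(grid[i])]] <- tb / sum(tb)
  }
  out <- structure(list(n = n, grid = grid, mc_reps = mc_reps, seed = seed,
                        tables = tabs),
                   class = "two_locus_table")
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(out, path)
  out
}

# canonical key of (n11, n10, n01, n00) under allele relabelling at either
# site: minimum over the 4 label swaps
canonical_config <- function(x) {
  v <- list(x,
            c(x[3], x[4], x[1], x[2]),  # swap alleles at site A
            c(x[2], x[1], x[4], x[3]),  # swap alleles at site B
            c(x[4], x[3], x[2], x[1]))  # both
  keys <- vapply(v, paste, "", collapse = ",")
  sort(keys)[1]
}

#' Composite-likelihood estimate of the population recombination rate
#'
#' For every pair of bi-allelic segregating sites, the two-locus
#' configuration likelihood is looked up (nearest table grid value to
#' rho_per_site x distance) from a Monte-Carlo two-locus table; the
#' composite log-likelihood sums over pairs and rho-hat is the grid argmax.
#'
#' @param x A `locus_alignment`, `coalescent_sample`, or 0/1 matrix (with
#'   `columns`).
#' @param rho_grid Candidate per-site rho values to profile.
#' @param table Optional precomputed [two_locus_table()] (built on the fly
#'   otherwise).
#' @param columns Site columns for matrix input (0-based).
#' @param mc_reps,seed,cache_dir Passed to [two_locus_table()].
#' @return List with `rho` (per site), the profile data.frame, and the
#'   table key used. `rho` is NA without polymorphism.
#' @export
estimate_rho <- function(x, rho_grid = c(0, 1e-4, 3e-4, 0.001, 0.003, 0.01,
                                         0.03, 0.1),
                         table = NULL, columns = NULL, mc_reps = 4000,
                         seed = 1, cache_dir = file.path(tempdir(), "sundapop_rho")) {
  if (inherits(x, "locus_alignment")) {
    b <- binary_sites(x)
    G <- b$G; columns <- b$columns
  } else if (inherits(x, "coalescent_sample")) {
    G <- x$G; columns <- x$columns %||% as.integer(floor(x$positions * 1e4))
  } else G <- x
  S <- ncol(G)
  if (S < 2) return(list(rho = NA_real_, profile = NULL,
                         note = "fewer than 2 bi-allelic segregating sites"))
  n <- nrow(G)
  if (is.null(table))
    table <- two_locus_table(n, mc_reps = mc_reps, seed = seed,
                             cache_dir = cache_dir)
  pair_keys <- list(); pair_d <- numeric(0)
  idx <- 0
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    a <- G[, i]; b2 <- G[, j]
    n11 <- sum(a == 1 & b2 == 1); n10 <- sum(a == 1 & b2 == 0)
    n01 <- sum(a == 0 & b2 == 1); n00 <- n - n11 - n10 - n01
    idx <- idx + 1
    pair_keys[[idx]] <- canonical_config(c(n11, n10, n01, n00))
    pair_d[idx] <- abs(columns[j] - columns[i])
  }
  gridv <- table$grid
  floorp <- 0.5 / table$mc_reps # unseen configurations
  ll <- vapply(rho_grid, function(rv) {
    tot <- 0
    for (p in seq_len(idx)) {
      R <- rv * pair_d[p]
      gi <- which.min(abs(log1p(gridv) - log1p(R)))
      pr <- table$tables[[gi]][pair_keys[[p]]]
      tot <- tot + log(if (is.na(pr)) floorp else as.numeric(pr))
    }
    tot
  }, 0)
  list(rho = rho_grid[which.max(ll)],
       profile = data.frame(rho = rho_grid, logCL = ll),
       table_key = list(n = n, grid = gridv, mc_reps = table$mc_reps,
                        seed = table$seed))
}
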