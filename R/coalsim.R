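#' Standard neutral coalescent sample
#'
#' Hudson-style coalescent under infinite sites. Either exactly `S`
#' mutations are placed on the genealogy in proportion to branch length
#' (fixed-S conditioning; no recombination), or mutations are Poisson with
#' rate theta/2 per branch-length unit (fixed-theta), optionally on an
#' ancestral recombination graph along the unit interval with total
#' recombination rate `rho`.
#'
#' @param n Sample size (haplotypes).
#' @param S Fixed number of segregating sites (fixed-S mode; requires
#'   `rho = 0`).
#' @param theta Population mutation rate 4Nu per locus (fixed-theta mode).
#' @param rho Total population recombination rate 4Nr across the locus.
#' @param L Optional alignment length: continuous positions are mapped to
#'   distinct integer columns (collisions re-drawn, preserving infinite
#'   sites).
#' @param seed Integer seed.
#' @return A `coalescent_sample`: 0/1 genotype matrix `G` (rows =
#'   haplotypes), `positions` in [0,1), optional integer `columns`, `n`,
#'   `seed`.
#' @export
sim_neutral <- function(n, S = NULL, theta = NULL, rho = 0, L = NULL, seed = 1) {
  stopifnot(n >= 2)
  if (is.null(S) == is.null(theta))
    stop("give exactly one of S (fixed-S) or theta (fixed-theta)")
  if (!is.null(S) && rho != 0)
    stop("fixed-S conditioning is only supported without recombination")
  r <- cpp_sim_neutral(as.integer(n), theta %||% 0, as.integer(S %||% -1L),
                       rho, as.integer(seed))
  out <- structure(list(G = r$G, positions = r$positions, n = n, seed = seed,
                        mode = if (is.null(S)) "fixed_theta" else "fixed_S"),
                   class = "coalescent_sample")
  if (!is.null(L)) out$columns <- positions_to_columns(r$positions, L, seed)
  out
}

#' Two-deme isolation-with-migration coalescent sample
#'
#' Backward-in-time structured coalescent on the IMa parameter scale: deme
#' coalescence rates proportional to 1/theta, migration rates per mutation
#' (m_sm: lineages sampled in the Sumatra-Malay deme trace back to the
#' Borneo deme), merger into a single ancestral deme of size theta_A at
#' divergence time `t` (mutational units), infinite-sites mutations at rate
#' `locus_scale` per lineage per unit time.
#'
#' @param params An [im_params()] object (or named list with theta_sm,
#'   theta_b, theta_A, m_sm, m_b, t).
#' @param n_sm,n_b Haplotype counts sampled from each deme.
#' @param locus_scale Relative mutation weight of the locus.
#' @param L Optional alignment length for integer column mapping.
#' @param seed Integer seed.
#' @return A `coalescent_sample` with a `deme` vector (1 = sm, 2 = b).
#' @export
sim_im <- function(params, n_sm, n_b, locus_scale = 1, L = NULL, seed = 1) {
  p <- as_im_params(params)
  if (p$theta_sm <= 0 || p$theta_b <= 0 || p$theta_A <= 0)
    stop("all theta parameters must be positive")
  stopifnot(n_sm + n_b >= 2)
  r <- cpp_sim_im(as.integer(n_sm), as.integer(n_b), p$theta_sm, p$theta_b,
                  p$theta_A, p$m_sm, p$m_b, p$t, locus_scale,
                  as.integer(seed))
  out <- structure(list(G = r$G, positions = r$positions, deme = r$deme,
                        n = n_sm + n_b, seed = seed, params = p),
                   class = "coalescent_sample")
  if (!is.null(L)) out$columns <- positions_to_columns(r$positions, L, seed)
  out
}

positions_to_columns <- function(pos, L, seed) {
  S <- length(pos)
  if (S > L) stop("requested S exceeds locus length")
  cols <- floor(pos * L)
  # re-draw collisions deterministically (infinite sites on a finite grid)
  set.seed(derive_seed(seed, "columns"))
  while (anyDuplicated(cols)) {
    dup <- duplicated(cols)
    free <- setdiff(0:(L - 1), cols[!dup])
    cols[dup] <- sample(free, sum(dup))
  }
  as.integer(cols)
}

#' @export
print.coalescent_sample <- function(x, ...) {
  cat("coalescent_sample: n =", x$n, ", S =", ncol(x$G), "\n")
  invisible(x)
}

#' Longest four-gamete-clean alignment block
#'
#' Returns the longest contiguous alignment interval (0-based half-open)
#' such that no pair of bi-allelic segregating sites inside exhibits all
#' four gametes (00, 01, 10, 11) -- the four-gamete evidence of
#' recombination. Ties are broken by the leftmost start. With fewer than 2
#' segregating sites the whole alignment is returned.
#'
#' @param x A `locus_alignment`, a `coalescent_sample` (with `columns` or
#'   `positions`), or a 0/1 matrix (then give `columns` and `len`).
#' @param columns Integer site columns (0-based) for matrix input.
#' @param len Alignment length for matrix input.
#' @return Integer vector `c(start, end)`.
#' @export
longest_nonrecombining_block <- function(x, columns = NULL, len = NULL) {
  if (inherits(x, "locus_alignment")) {
    b <- binary_sites(x)
    G <- b$G; columns <- b$columns; len <- x$aligned_length
  } else if (inherits(x, "coalescent_sample")) {
    G <- x$G
    columns <- x$columns %||% as.integer(floor(x$positions * 1e6))
    len <- len %||% (max(columns) + 1L)
  } else {
    G <- x
    stopifnot(!is.null(columns), !is.null(len))
  }
  S <- ncol(G)
  if (S < 2) return(c(0L, as.integer(len)))
  ord <- order(columns)
  G <- G[, ord, drop = FALSE]
  columns <- columns[ord]
  incompat <- function(i, j) {
    a <- G[, i]; b <- G[, j]
    length(unique(paste0(a, b))) == 4
  }
  best <- c(0L, 0L); bestlen <- -1
  lo_idx <- 1
  for (r in seq_len(S)) {
    for (i in lo_idx:r) {
      if (i < r && incompat(i, r)) lo_idx <- max(lo_idx, i + 1)
    }
    start <- if (lo_idx == 1) 0L else columns[lo_idx - 1] + 1L
    end <- if (r == S) as.integer(len) else columns[r + 1]
    if (end - start > bestlen) {
      bestlen <- end - start
      best <- c(as.integer(start), as.integer(end))
    }
  }
  best
}

# bi-allelic segregating sites of an alignment as a 0/1 matrix (minor allele
# coded 1; multi-allelic and masked columns dropped)
binary_sites <- function(aln) {
  ok <- which(!aln$mask)
  G <- NULL; cols <- integer(0)
  for (j in ok) {
    tb <- table(aln$seqs[, j])
    if (length(tb) != 2) next
    minor <- names(sort(tb))[1]
    G <- cbind(G, as.integer(aln$seqs[, j] == minor))
    cols <- c(cols, j - 1L)
  }
  if (is.null(G)) G <- matrix(integer(0), nrow(aln$seqs), 0)
  list(G = G, columns = as.integer(cols))
}
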