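#' Per-sample diversity statistics for one locus
#'
#' Computes the segregating-site count S, mean pairwise differences,
#' nucleotide diversity per site by site category (total, silent,
#' synonymous, replacement), haplotype diversity Hd with the n/(n-1) bias
#' correction, and Watterson's theta per site. Pairwise differences are
#' counted on unmasked columns only; per-category pi divides the category's
#' summed pairwise differences by the category's fractional site count, with
#' each polymorphic coding column assigned in full to the synonymous or
#' replacement class by its variant classification.
#'
#' @param aln A `locus_alignment`.
#' @param individuals Optional subset of individual ids.
#' @param classification Optional result of [classify_sites()] for `aln`
#'   (computed on the full alignment if omitted).
#' @return An object of class `summary_stats`: list with `n`, `S`,
#'   `mean_pairwise`, `pi` (named vector total/silent/synonymous/replacement,
#'   NA where the category has zero sites), `Hd`, `theta_w`, and the category
#'   site counts used.
#' @export
summary_stats <- function(aln, individuals = NULL, classification = NULL) {
  if (is.null(classification)) classification <- classify_sites(aln)
  sub <- subset_alignment(aln, individuals)
  n <- nrow(sub$seqs)
  if (n < 2) stop("summary statistics require at least 2 haplotypes")
  ok <- !aln$mask
  seqs <- sub$seqs[, ok, drop = FALSE]
  sites <- classification$sites[ok, , drop = FALSE]
  counts <- classification$counts

  # per-column derived... allele counts (columns may be multi-allelic in
  # principle; pairwise differences handle that exactly)
  ncolL <- ncol(seqs)
  pairdiff_col <- numeric(ncolL)
  poly <- logical(ncolL)
  for (j in seq_len(ncolL)) {
    tb <- table(seqs[, j])
    if (length(tb) > 1) {
      poly[j] <- TRUE
      pairdiff_col[j] <- (n * (n - 1) / 2) - sum(tb * (tb - 1) / 2)
    }
  }
  S <- sum(poly)
  cn2 <- n * (n - 1) / 2
  mean_pairwise <- sum(pairdiff_col) / cn2

  vc <- sites$variant_class
  w_silent <- poly & !is.na(vc) & vc %in% c("silent", "syn")
  w_syn <- poly & !is.na(vc) & vc == "syn"
  w_rep <- poly & !is.na(vc) & vc == "rep"
  pi_cat <- function(w, denom) {
    if (is.na(denom) || denom <= 0) return(NA_real_)
    sum(pairdiff_col[w]) / cn2 / denom
  }
  pi <- c(total = if (counts$n_total > 0) mean_pairwise / counts$n_total else NA_real_,
          silent = pi_cat(w_silent, counts$n_silent),
          synonymous = pi_cat(w_syn, counts$n_synonymous),
          replacement = pi_cat(w_rep, counts$n_replacement))

  hap_str <- apply(seqs, 1, paste, collapse = "")
  p <- table(hap_str) / n
  Hd <- n / (n - 1) * (1 - sum(p^2))
  a_n <- sum(1 / seq_len(n - 1))
  theta_w <- if (counts$n_total > 0) S / (a_n * counts$n_total) else NA_real_

  structure(list(n = n, S = S, mean_pairwise = mean_pairwise, pi = pi,
                 Hd = Hd, theta_w = theta_w, a_n = a_n,
                 sites = counts,
                 cat_pairdiff = c(silent = sum(pairdiff_col[w_silent]) / cn2,
                                  synonymous = sum(pairdiff_col[w_syn]) / cn2,
                                  replacement = sum(pairdiff_col[w_rep]) / cn2)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats: n=%d S=%d k=%.4f Hd=%.4f theta_w=%.5f\n",
              x$n, x$S, x$mean_pairwise, x$Hd, x$theta_w))
  print(round(x$pi, 5))
  invisible(x)
}

#' Population-by-locus summary table with pooled averages
#'
#' Builds the per-population, per-locus diversity table plus per-population
#' averages over loci and a pooled total-sample row. Averages over loci are
#' unweighted means for Hd (and rho, when requested); pi categories are
#' pooled as total pairwise differences divided by total category sites
#' across loci.
#'
#' @param ds A `multilocus_dataset` (hybrids already removed).
#' @param include_rho Also estimate the per-site population recombination
#'   parameter rho per population (composite likelihood; slow).
#' @param rho_args List of arguments passed to [estimate_rho()].
#' @return List with `per_locus` and `averages` data.frames.
#' @export
population_table <- function(ds, include_rho = FALSE, rho_args = list()) {
  cls <- lapply(ds$loci, classify_sites)
  pops <- unique(ds$popmap$population)
  groups <- c(as.list(setNames(
    lapply(pops, function(p) ds$popmap$individual[ds$popmap$population == p]),
    pops)), list(Total = unique(ds$popmap$individual)))
  per_locus <- list()
  averages <- list()
  for (gname in names(groups)) {
    inds <- groups[[gname]]
    sums <- list()
    for (nm in names(ds$loci)) {
      aln <- ds$loci[[nm]]
      n_avail <- sum(aln$individuals %in% inds)
      if (n_avail < 2) {
        warning("population ", gname, " has < 2 haplotypes at locus ", nm,
                "; cell reported missing")
        next
      }
      st <- summary_stats(aln, inds, cls[[nm]])
      row <- data.frame(population = gname, locus = nm, n = st$n, S = st$S,
                        Hd = st$Hd, pi_total = st$pi["total"],
                        pi_silent = st$pi["silent"],
                        pi_syn = st$pi["synonymous"],
                        pi_rep = st$pi["replacement"],
                        theta_w = st$theta_w, row.names = NULL)
      if (include_rho) {
        row$rho <- tryCatch(
          do.call(estimate_rho, c(list(subset_alignment(aln, inds)), rho_args))$rho,
          error = function(e) NA_real_)
      }
      sums[[nm]] <- st
      per_locus[[length(per_locus) + 1]] <- row
    }
    if (length(sums) == 0) next
    tot_sites <- function(f) sum(vapply(sums, function(s) s$sites[[f]], 0))
    tot_pd <- function(cat) sum(vapply(sums, function(s) s$cat_pairdiff[cat], 0))
    mp_tot <- sum(vapply(sums, function(s) s$mean_pairwise, 0))
    avg <- data.frame(
      population = gname,
      n = max(vapply(sums, function(s) s$n, 0)),
      Hd = mean(vapply(sums, function(s) s$Hd, 0)),
      pi_total = mp_tot / tot_sites("n_total"),
      pi_silent = tot_pd("silent") / tot_sites("n_silent"),
      pi_syn = tot_pd("synonymous") / tot_sites("n_synonymous"),
      pi_rep = tot_pd("replacement") / tot_sites("n_replacement"),
      row.names = NULL)
    if (include_rho) {
      pl <- do.call(rbind, per_locus)
      avg$rho <- mean(pl$rho[pl$population == gname], na.rm = TRUE)
    }
    averages[[length(averages) + 1]] <- avg
  }
  list(per_locus = do.call(rbind, per_locus),
       averages = do.call(rbind, averages),
       pooling = "pi pooled as total differences over total category sites; Hd and rho unweighted means over loci")
}
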