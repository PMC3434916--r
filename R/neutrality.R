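#' Tajima's D
#'
#' Standardized difference between the pairwise and Watterson estimators of
#' theta, with the usual variance constants computed from the sample size.
#' Undefined (NA) when there are no segregating sites.
#'
#' @param x A `summary_stats` object, or the haplotype count `n` when `S` and
#'   `mean_pairwise` are given explicitly.
#' @param S Segregating sites.
#' @param mean_pairwise Average pairwise differences (count).
#' @return The D statistic (NA if S = 0).
#' @export
tajima_d <- function(x, S = NULL, mean_pairwise = NULL) {
  if (inherits(x, "summary_stats")) {
    n <- x$n; S <- x$S; mean_pairwise <- x$mean_pairwise
  } else n <- x
  if (is.null(S) || S <= 0) return(NA_real_)
  k <- tajima_constants(n)
  v <- k$e1 * S + k$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (mean_pairwise - S / k$a1) / sqrt(v)
}

tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Coalescent null interval for Tajima's D with fixed S
#'
#' Simulates standard-neutral genealogies for `n` tips with exactly `S`
#' mutations placed in proportion to branch length (the observed number of
#' polymorphic sites is given to the simulation), and returns the empirical
#' 2.5/97.5 percent interval of D plus a two-sided empirical p-value for an
#' observed D.
#'
#' @param n Haplotype count.
#' @param S Segregating sites to condition on.
#' @param reps Coalescent replicates (>= 1000 recommended for intervals).
#' @param seed Integer seed.
#' @param D_obs Optional observed D for which to report p.
#' @return List with `lo`, `hi`, `p` (NA without `D_obs`), `reps`, `seed`,
#'   and the simulated values `D`.
#' @export
neutral_interval <- function(n, S, reps = 10000, seed = 1, D_obs = NULL) {
  stopifnot(n >= 2, S >= 1, reps >= 1)
  d <- cpp_tajima_null(as.integer(n), as.integer(S), as.integer(reps),
                       as.integer(seed))
  q <- quantile(d, c(0.025, 0.975), names = FALSE)
  p <- NA_real_
  if (!is.null(D_obs) && !is.na(D_obs))
    p <- min(1, 2 * min(mean(d <= D_obs), mean(d >= D_obs)))
  list(lo = q[1], hi = q[2], p = p, reps = reps, seed = seed, D = d)
}

#' Multilocus Tajima's D test
#'
#' Tests the across-loci average D: each replicate simulates every locus
#' independently under the standard neutral model with its own sample size
#' and fixed S, averages D across loci, and the two-sided empirical p
#' compares the observed average against that null. Loci with S = 0 are
#' dropped from observed and simulated averages alike.
#'
#' @param loci data.frame with columns `n`, `S`, `D` (observed), e.g. built
#'   from per-locus [summary_stats()]; or a `multilocus_dataset`.
#' @param individuals Optional individual subset (dataset input only).
#' @param reps Replicates.
#' @param seed Integer seed.
#' @return List with `D_avg`, `p`, per-locus table, `reps`, `seed`.
#' @export
multilocus_d_test <- function(loci, individuals = NULL, reps = 10000, seed = 1) {
  if (inherits(loci, "multilocus_dataset")) {
    tab <- do.call(rbind, lapply(names(loci$loci), function(nm) {
      st <- summary_stats(loci$loci[[nm]], individuals)
      data.frame(locus = nm, n = st$n, S = st$S, D = tajima_d(st))
    }))
  } else tab <- loci
  use <- tab$S >= 1
  if (sum(use) < 2) stop("need >= 2 loci with S >= 1")
  tab2 <- tab[use, , drop = FALSE]
  sims <- vapply(seq_len(nrow(tab2)), function(i) {
    cpp_tajima_null(as.integer(tab2$n[i]), as.integer(tab2$S[i]),
                    as.integer(reps), derive_seed(seed, tab2$locus[i] %||% i))
  }, numeric(reps))
  avg_null <- rowMeans(sims)
  D_avg <- mean(tab2$D)
  p <- min(1, 2 * min(mean(avg_null <= D_avg), mean(avg_null >= D_avg)))
  list(D_avg = D_avg, p = p, loci = tab2, reps = reps, seed = seed,
       null_mean = mean(avg_null))
}

#' Tajima's D table across populations and loci
#'
#' Table of per-population, per-locus D with fixed-S coalescent null
#' intervals and p-values, plus the across-loci average and its multilocus
#' p-value per population. Monomorphic cells are reported missing.
#'
#' @param ds A `multilocus_dataset`.
#' @param by `"population"`, `"group"`, or `"total"` (rows of the table).
#' @param reps Coalescent replicates per cell.
#' @param seed Integer seed.
#' @export
tajima_table <- function(ds, by = c("population", "group", "total"),
                         reps = 10000, seed = 1) {
  by <- match.arg(by)
  sets <- switch(by,
    population = setNames(lapply(unique(ds$popmap$population), function(p)
      ds$popmap$individual[ds$popmap$population == p]),
      unique(ds$popmap$population)),
    group = {
      g <- setdiff(unique(ds$popmap$group), "unassigned")
      setNames(lapply(g, function(x)
        ds$popmap$individual[ds$popmap$group == x]), g)
    },
    total = list(Total = unique(ds$popmap$individual)))
  out <- list()
  for (s in names(sets)) {
    rows <- do.call(rbind, lapply(names(ds$loci), function(nm) {
      st <- summary_stats(ds$loci[[nm]], sets[[s]])
      D <- tajima_d(st)
      if (!is.na(D)) {
        ni <- neutral_interval(st$n, st$S, reps,
                               derive_seed(seed, paste(s, nm)), D)
        data.frame(set = s, locus = nm, n = st$n, S = st$S, D = D,
                   lo = ni$lo, hi = ni$hi, p = ni$p)
      } else {
        data.frame(set = s, locus = nm, n = st$n, S = st$S, D = NA,
                   lo = NA, hi = NA, p = NA)
      }
    }))
    ml <- tryCatch(
      multilocus_d_test(data.frame(locus = rows$locus, n = rows$n, S = rows$S,
                                   D = rows$D),
                        reps = reps, seed = derive_seed(seed, s)),
      error = function(e) NULL)
    rows <- rbind(rows, data.frame(set = s, locus = "Average",
                                   n = max(rows$n), S = NA,
                                   D = if (is.null(ml)) NA else ml$D_avg,
                                   lo = NA, hi = NA,
                                   p = if (is.null(ml)) NA else ml$p))
    out[[s]] <- rows
  }
  do.call(rbind, out)
}

# two-tailed Fisher exact p for a 2x2 table by the point-probability rule:
# sum of probabilities of all tables with the observed margins whose point
# probability does not exceed the observed table's
fisher_two_tailed <- function(a, b, c, d) {
  m <- a + b      # row 1 total
  n2 <- c + d     # row 2 total
  k <- a + c      # column 1 total
  lo <- max(0, k - n2); hi <- min(k, m)
  xs <- lo:hi
  probs <- dhyper(xs, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' McDonald-Kreitman test
#'
#' Contrasts synonymous and replacement (nonsynonymous) counts of fixed
#' interspecific differences versus intraspecific polymorphisms in a 2x2
#' table: two-tailed Fisher exact test (point-probability rule) and the
#' uncorrected G test (chi-square, df = 1). A zero margin yields a
#' degenerate Fisher p of 1 (flagged).
#'
#' @param fixed_syn,fixed_rep,poly_syn,poly_rep Non-negative counts.
#' @return An `mk_table`: the counts, `fisher_p`, `g_stat`, `g_p`,
#'   `degenerate` flag, and the neutrality index.
#' @export
mk_test <- function(fixed_syn, fixed_rep, poly_syn, poly_rep) {
  cnt <- c(fixed_syn, fixed_rep, poly_syn, poly_rep)
  stopifnot(all(cnt >= 0), all(cnt == round(cnt)))
  m <- matrix(c(fixed_syn, poly_syn, fixed_rep, poly_rep), 2, 2, byrow = TRUE,
              dimnames = list(c("syn", "rep"), c("fixed", "poly")))
  degenerate <- any(rowSums(m) == 0) || any(colSums(m) == 0)
  fisher_p <- if (degenerate) 1 else
    fisher_two_tailed(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  gg <- 2 * sum(m * log(m / E), na.rm = TRUE) # 0*log(0) dropped
  g_p <- pchisq(gg, df = 1, lower.tail = FALSE)
  ni <- if (fixed_rep > 0 && poly_syn > 0)
    (poly_rep / poly_syn) / (fixed_rep / fixed_syn) else NA_real_
  structure(list(table = m, fisher_p = fisher_p, g_stat = gg, g_p = g_p,
                 degenerate = degenerate, neutrality_index = ni),
            class = "mk_table")
}

#' @export
print.mk_table <- function(x, ...) {
  print(x$table)
  cat(sprintf("Fisher two-tailed p = %.5f; G = %.4f, p = %.5f%s\n",
              x$fisher_p, x$g_stat, x$g_p,
              if (x$degenerate) " (degenerate margin)" else ""))
  invisible(x)
}

#' Build MK counts for a locus against an outgroup
#'
#' Fixed differences are counted against the consensus of a single outgroup
#' individual; sites polymorphic in the focal sample that also differ from
#' the outgroup count as polymorphic only (standard MK convention; the
#' number of such sites is reported). Synonymous/replacement classification
#' uses the consensus codon context. Columns with an outgroup gap are
#' dropped.
#'
#' @param aln A `locus_alignment` (focal sample).
#' @param outgroup Character matrix (or vector) of outgroup haplotypes
#'   aligned to `aln`.
#' @param classification Optional [classify_sites()] result.
#' @return List with the four counts, the resulting [mk_test()], and the
#'   number of polymorphic-and-divergent sites.
#' @export
mk_counts <- function(aln, outgroup, classification = NULL) {
  if (is.null(classification)) classification <- classify_sites(aln)
  if (is.character(outgroup) && !is.matrix(outgroup))
    outgroup <- do.call(rbind, strsplit(toupper(outgroup), ""))
  stopifnot(ncol(outgroup) == aln$aligned_length)
  og <- apply(outgroup, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return("-")
    names(sort(table(col), decreasing = TRUE))[1]
  })
  ok <- !aln$mask & og != "-"
  cons <- classification$consensus
  sites <- classification$sites
  counts <- c(fixed_syn = 0, fixed_rep = 0, poly_syn = 0, poly_rep = 0)
  both <- 0
  for (j in which(ok)) {
    col <- aln$seqs[, j]
    poly <- length(unique(col)) > 1
    divergent <- !poly && col[1] != og[j]
    if (poly) {
      cl <- sites$variant_class[j]
      if (is.na(cl) || cl == "silent") next # non-coding or unclassifiable
      if (cl == "syn") counts["poly_syn"] <- counts["poly_syn"] + 1
      if (cl == "rep") counts["poly_rep"] <- counts["poly_rep"] + 1
      if (!(og[j] %in% col)) both <- both + 1 # polymorphic and divergent
    } else if (divergent) {
      if (sites$category[j] != "coding") next
      # classify the fixed change in consensus codon context
      cl <- classify_change(cons, j, col[1], og[j], aln)
      if (is.na(cl)) next
      if (cl == "syn") counts["fixed_syn"] <- counts["fixed_syn"] + 1
      else counts["fixed_rep"] <- counts["fixed_rep"] + 1
    }
  }
  mk <- mk_test(counts["fixed_syn"], counts["fixed_rep"],
                counts["poly_syn"], counts["poly_rep"])
  list(counts = counts, mk = mk, poly_and_divergent = both)
}

# synonymous/replacement call for a single-base change at column j (1-based)
classify_change <- function(cons, j, base1, base2, aln) {
  for (e in seq_len(nrow(aln$exons))) {
    st <- aln$exons$start[e] + aln$exons$frame[e]
    en <- aln$exons$end[e]
    if (j - 1 >= st && j - 1 < st + 3 * floor((en - st) / 3)) {
      off <- (j - 1 - st) %% 3
      cols <- (j - off):(j - off + 2)
      if (any(aln$mask[cols])) return(NA_character_)
      c1 <- paste(replace(cons[cols], off + 1, base1), collapse = "")
      c2 <- paste(replace(cons[cols], off + 1, base2), collapse = "")
      return(if (translate_codon(c1) == translate_codon(c2)) "syn" else "rep")
    }
  }
  NA_character_
}

#' Ka/Ks between the focal consensus and an outgroup
#'
#' Nei-Gojobori proportions (equal-pathway counting over minimal mutational
#' paths, site counts averaged over the two sequences) with the Jukes-Cantor
#' multiple-hit correction. The ratio is undefined when Ks = 0.
#'
#' @param aln A `locus_alignment` with coding annotation.
#' @param outgroup Outgroup haplotype (character vector of length 1 sequence,
#'   or matrix; the consensus is used).
#' @param classification Optional [classify_sites()] result.
#' @return List with `Ka`, `Ks`, `ratio`, and the raw proportions and site
#'   counts.
#' @export
ka_ks <- function(aln, outgroup, classification = NULL) {
  if (nrow(aln$exons) == 0) stop("ka_ks requires a coding annotation")
  if (is.null(classification)) classification <- classify_sites(aln)
  if (is.character(outgroup) && !is.matrix(outgroup))
    outgroup <- do.call(rbind, strsplit(toupper(outgroup), ""))
  og <- apply(outgroup, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) "-" else names(sort(table(col), decreasing = TRUE))[1]
  })
  cons <- classification$consensus
  Sd <- Nd <- Ssites <- Nsites <- 0
  for (e in seq_len(nrow(aln$exons))) {
    st <- aln$exons$start[e] + aln$exons$frame[e]
    en <- aln$exons$end[e]
    if (en - st < 3) next
    for (cs in seq(st, en - 3, by = 3)) {
      cols <- (cs + 1):(cs + 3)
      if (any(aln$mask[cols]) || any(og[cols] == "-")) next
      c1 <- paste(cons[cols], collapse = "")
      c2 <- paste(og[cols], collapse = "")
      if (translate_codon(c1) == "*" || translate_codon(c2) == "*") next
      Ssites <- Ssites + mean(c(sum(vapply(1:3, function(p) syn_fraction(c1, p), 0)),
                                sum(vapply(1:3, function(p) syn_fraction(c2, p), 0))))
      Nsites <- Nsites + mean(c(3 - sum(vapply(1:3, function(p) syn_fraction(c1, p), 0)),
                                3 - sum(vapply(1:3, function(p) syn_fraction(c2, p), 0))))
      d <- codon_path_counts(c1, c2)
      Sd <- Sd + d["syn"]
      Nd <- Nd + d["rep"]
    }
  }
  ps <- if (Ssites > 0) Sd / Ssites else NA_real_
  pn <- if (Nsites > 0) Nd / Nsites else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(ps); Ka <- jc(pn)
  ratio <- if (!is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  list(Ka = unname(Ka), Ks = unname(Ks), ratio = unname(ratio),
       ps = unname(ps), pn = unname(pn),
       syn_sites = Ssites, rep_sites = Nsites,
       syn_diff = unname(Sd), rep_diff = unname(Nd))
}

# average synonymous/replacement difference counts over all minimal
# mutational pathways between two codons (pathways through stops excluded
# unless all pass through stops)
codon_path_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(syn = 0, rep = 0))
  perms <- if (length(pos) == 1) list(pos) else {
    if (length(pos) == 2) list(pos, rev(pos)) else {
      idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      lapply(idx, function(i) pos[i])
    }
  }
  res <- list()
  for (pr in perms) {
    cur <- c1
    syn <- 0; rep <- 0; valid <- TRUE
    for (p in pr) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (translate_codon(nxt) == "*") { valid <- FALSE; break }
      if (translate_codon(cur) == translate_codon(nxt)) syn <- syn + 1
      else rep <- rep + 1
      cur <- nxt
    }
    if (valid) res[[length(res) + 1]] <- c(syn = syn, rep = rep)
  }
  if (length(res) == 0) { # all pathways hit a stop: fall back to all
    for (pr in perms) {
      cur <- c1; syn <- 0; rep <- 0
      for (p in pr) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (translate_codon(cur) == translate_codon(nxt)) syn <- syn + 1
        else rep <- rep + 1
        cur <- nxt
      }
      res[[length(res) + 1]] <- c(syn = syn, rep = rep)
    }
  }
  colMeans(do.call(rbind, res))
}

#' Multilocus HKA test
#'
#' Tests the proportionality of within-species polymorphism to divergence
#' from an outgroup across loci. Per-locus theta estimates and one shared
#' divergence-time parameter are solved from the classical estimating
#' equations (expected polymorphism theta_i * a_n; expected divergence
#' theta_i * (T + 1) under equal current and ancestral sizes, as appropriate
#' with a single outgroup sequence); the statistic sums squared deviations
#' over polymorphism and divergence scaled by their variances and is
#' compared to chi-square with df = number of loci - 1.
#'
#' @param ds A `multilocus_dataset` with an outgroup at every locus, or a
#'   data.frame with columns `locus`, `n`, `S` (polymorphic sites) and `D`
#'   (mean divergence, may be fractional).
#' @param individuals Optional focal subset (dataset input only).
#' @return An `hka_result` with per-locus observed/expected values, the
#'   chi-square total, df and p.
#' @export
hka_test <- function(ds, individuals = NULL) {
  if (inherits(ds, "multilocus_dataset")) {
    if (is.null(ds$outgroups)) stop("HKA requires outgroup haplotypes")
    tab <- do.call(rbind, lapply(names(ds$loci), function(nm) {
      aln <- subset_alignment(ds$loci[[nm]], individuals)
      og <- ds$outgroups[[nm]]
      ok <- !ds$loci[[nm]]$mask & apply(og != "-", 2, all)
      seqs <- aln$seqs[, ok, drop = FALSE]
      ogc <- apply(og[, ok, drop = FALSE], 2, function(col)
        names(sort(table(col), decreasing = TRUE))[1])
      S <- sum(apply(seqs, 2, function(col) length(unique(col)) > 1))
      # mean divergence: average differences between each focal haplotype
      # and the outgroup consensus
      D <- mean(apply(seqs, 1, function(h) sum(h != ogc)))
      data.frame(locus = nm, n = nrow(seqs), S = S, D = D)
    }))
  } else tab <- ds
  L <- nrow(tab)
  if (L < 2) stop("HKA needs >= 2 loci")
  if (all(tab$D == 0)) stop("no divergence at any locus: no information")
  a <- vapply(tab$n, function(n) sum(1 / seq_len(n - 1)), 0)
  b <- vapply(tab$n, function(n) sum(1 / seq_len(n - 1)^2), 0)
  f_T <- function(T) sum((tab$S + tab$D) * (T + 1) / (a + T + 1)) - sum(tab$D)
  That <- uniroot(f_T, c(1e-9, 1e6), extendInt = "upX", tol = 1e-12)$root
  theta <- (tab$S + tab$D) / (a + That + 1)
  ES <- theta * a
  ED <- theta * (That + 1)
  VS <- theta * a + theta^2 * b
  VD <- theta * (That + 1) + theta^2
  chi2 <- sum((tab$S - ES)^2 / VS) + sum((tab$D - ED)^2 / VD)
  df <- L - 1
  p <- pchisq(chi2, df, lower.tail = FALSE)
  structure(list(table = cbind(tab, exp_S = ES, exp_D = ED, var_S = VS,
                               var_D = VD),
                 theta = theta, T = That, chi2 = chi2, df = df, p = p),
            class = "hka_result")
}

#' @export
print.hka_result <- function(x, ...) {
  print(x$table, digits = 4)
  cat(sprintf("T = %.4f; chi2 = %.4f, df = %d, p = %.4f\n",
              x$T, x$chi2, x$df, x$p))
  invisible(x)
}
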