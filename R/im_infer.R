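#' Isolation-with-migration model parameters (IMa scale)
#'
#' theta = 4*N_e*u per locus for the Sumatra-Malay deme, the Borneo deme and
#' their ancestral population; migration rates per mutation event (m_sm:
#' rate at which lineages in sm trace back to b, i.e. migration from the
#' Borneo group into the Sumatra-Malay group forward in time); divergence
#' time t in mutational units.
#'
#' @param theta_sm,theta_b,theta_A,m_sm,m_b,t Non-negative reals.
#' @return An `im_params` object.
#' @export
im_params <- function(theta_sm, theta_b, theta_A, m_sm = 0, m_b = 0, t = 0) {
  p <- list(theta_sm = theta_sm, theta_b = theta_b, theta_A = theta_A,
            m_sm = m_sm, m_b = m_b, t = t)
  if (any(unlist(p) < 0)) stop("IM parameters must be non-negative")
  structure(p, class = "im_params")
}

as_im_params <- function(x) {
  if (inherits(x, "im_params")) return(x)
  if (is.numeric(x) && length(x) == 6 && !is.null(names(x)))
    x <- as.list(x)
  do.call(im_params, x[c("theta_sm", "theta_b", "theta_A", "m_sm", "m_b", "t")])
}

par_names <- c("theta_sm", "theta_b", "theta_A", "m_sm", "m_b", "t")

im_par_vec <- function(p) {
  p <- as_im_params(p)
  setNames(c(p$theta_sm, p$theta_b, p$theta_A, p$m_sm, p$m_b, p$t), par_names)
}

#' Observed two-group summary vector for IM fitting
#'
#' Reduces each locus to its longest four-gamete-clean block, extracts the
#' bi-allelic segregating sites inside it, and computes the across-locus
#' mean of the per-locus two-group summary statistics (per-group S, pi,
#' Tajima's D, between-group mean differences, Da, Hudson Fst, and counts of
#' shared / fixed / private polymorphisms). All statistics are invariant to
#' allele relabelling, so they need no ancestral-state polarization.
#'
#' @param ds A `multilocus_dataset` whose popmap carries exactly two group
#'   labels besides `unassigned`.
#' @param use_blocks Reduce loci to four-gamete-clean blocks (the IM model
#'   assumes no recombination within a locus).
#' @return List with `obs` (mean summary vector), `n_sm`, `n_b`, per-locus
#'   `blocks` and `weights` (relative block lengths, geometric mean 1).
#' @export
obs_im_summaries <- function(ds, use_blocks = TRUE) {
  groups <- setdiff(unique(ds$popmap$group), "unassigned")
  if (length(groups) != 2)
    stop("IM fitting requires exactly two group labels (besides 'unassigned')")
  g1 <- if ("sumatra_malay" %in% groups) "sumatra_malay" else groups[1]
  g2 <- setdiff(groups, g1)
  ind1 <- ds$popmap$individual[ds$popmap$group == g1]
  ind2 <- ds$popmap$individual[ds$popmap$group == g2]
  stats <- NULL
  blocks <- list()
  blen <- numeric(0)
  n1 <- n2 <- NULL
  for (nm in names(ds$loci)) {
    aln <- ds$loci[[nm]]
    in1 <- aln$individuals %in% ind1
    in2 <- aln$individuals %in% ind2
    blk <- if (use_blocks) longest_nonrecombining_block(aln)
           else c(0L, aln$aligned_length)
    blocks[[nm]] <- blk
    blen <- c(blen, blk[2] - blk[1])
    b <- binary_sites(aln)
    keep <- b$columns >= blk[1] & b$columns < blk[2]
    G <- b$G[, keep, drop = FALSE]
    k1 <- colSums(G[in1, , drop = FALSE])
    k2 <- colSums(G[in2, , drop = FALSE])
    poly <- (k1 + k2) > 0 & (k1 + k2) < sum(in1) + sum(in2)
    st <- cpp_locus_stats(as.integer(k1[poly]), as.integer(k2[poly]),
                          sum(in1), sum(in2))
    stats <- rbind(stats, st)
    n1 <- sum(in1); n2 <- sum(in2)
  }
  mu <- apply(stats, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else 0
  })
  sdv <- apply(stats, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1) sd(x) else 0
  })
  obs <- c(mu, setNames(sdv, paste0("sd_", names(sdv))))
  weights <- blen / exp(mean(log(pmax(blen, 1))))
  list(obs = obs, n_sm = n1, n_b = n2, blocks = blocks,
       weights = weights, groups = c(sm = g1, b = g2),
       per_locus = stats)
}

# Gaussian synthetic log-likelihood of the observed summary vector under the
# IM model at `par`, from `reps` simulated multilocus datasets (common random
# numbers via `seed`). The covariance is estimated from the same simulations
# with correlation shrinkage toward the diagonal and a variance floor, and
# inflated by (1 + 1/reps) for the mean's Monte-Carlo error.
sl_objective <- function(par, obs, n_sm, n_b, weights, reps, seed,
                         shrink = 0.1) {
  if (any(par[1:3] <= 0) || any(par < 0)) return(-Inf)
  sims <- cpp_im_summaries(unname(par), as.integer(n_sm), as.integer(n_b),
                           weights, as.integer(reps), as.integer(seed))
  # the across-locus mean of Da is an exact linear combination of pib, pi1
  # and pi2; keep the independent pieces only so the Gaussian metric is not
  # degenerate (column 8 = mean Da; its dispersion column is kept)
  sims <- sims[, -8, drop = FALSE]
  obs <- obs[-8]
  mu <- colMeans(sims)
  X <- sweep(sims, 2, mu)
  S <- crossprod(X) / (reps - 1)
  d <- sqrt(diag(S))
  d2 <- pmax(d, 0.02 * (1 + abs(mu)))
  R <- S / (d %o% d)
  R[!is.finite(R)] <- 0
  R <- (1 - shrink) * R
  diag(R) <- 1
  Sig <- R * (d2 %o% d2) * (1 + 1 / reps)
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch)) {
    diag(Sig) <- diag(Sig) * 1.05 + 1e-8
    ch <- chol(Sig)
  }
  z <- backsolve(ch, obs - mu, transpose = TRUE)
  # winsorize the whitened residuals: the true summary distribution is
  # heavier-tailed than Gaussian, and unbounded quadratic penalties let rare
  # outlier datasets dominate likelihood-ratio comparisons
  z <- pmin(pmax(z, -3.5), 3.5)
  -0.5 * sum(z^2) - sum(log(diag(ch))) - 0.5 * length(obs) * log(2 * pi)
}

default_im_settings <- function() {
  list(sims_per_eval = 40, pilot_draws = 500, pilot_reps = 8,
       pilot_starts = 3, mcmc_iters = 1000, mcmc_burn = 250, big_reps = 250,
       optim_maxit = 150, seed = 1)
}

#' Fit the six-parameter IM model by synthetic likelihood
#'
#' Simulation-based inference: the objective is a Gaussian synthetic
#' log-likelihood over a fixed vector of two-group summary statistics, with
#' moments estimated from IM coalescent simulations at each evaluated
#' parameter point (common random numbers). A pilot random search over wide
#' priors refines the prior box (mirroring empirical prior elicitation),
#' then a random-walk Metropolis chain samples the synthetic posterior;
#' marginal peaks are the point estimates and 90% HPD intervals are the
#' shortest sample intervals. Estimates at a prior boundary are flagged.
#'
#' @param ds A `multilocus_dataset` with two group labels, or the result of
#'   [obs_im_summaries()].
#' @param priors Named vector of prior upper bounds for the six parameters
#'   (wide defaults; refined by the pilot stage).
#' @param settings List overriding [default_im_settings()] entries
#'   (`sims_per_eval`, `mcmc_iters`, `mcmc_burn`, `pilot_draws`, `big_reps`,
#'   `seed`, ...).
#' @return An `im_fit`: `estimate` (named vector), `hpd` (2 x 6), `lnL`,
#'   posterior `samples`, `settings`, `priors` (refined box), boundary
#'   flags, and the per-locus blocks used.
#' @export
fit_im <- function(ds, priors = c(theta_sm = 40, theta_b = 40, theta_A = 40,
                                  m_sm = 10, m_b = 10, t = 5),
                   settings = list()) {
  s <- utils::modifyList(default_im_settings(), settings)
  od <- if (inherits(ds, "multilocus_dataset")) obs_im_summaries(ds) else ds
  obs <- od$obs; n1 <- od$n_sm; n2 <- od$n_b; w <- od$weights
  priors <- priors[par_names]
  seed <- s$seed
  obj <- function(par, reps = s$sims_per_eval, sd_ = 0)
    sl_objective(par, obs, n1, n2, w, reps, derive_seed(seed, paste0("ev", sd_)))

  # stage 1: pilot search. Log-uniform draws cover the small-parameter
  # corner of the box (theta_A, migration and t spend most of their prior
  # mass there on the IM scale), plus moment-based anchor points built from
  # the observed within/between-group diversities.
  set.seed(derive_seed(seed, "pilot"))
  lo <- priors / 400
  cand <- sapply(par_names, function(p)
    exp(runif(s$pilot_draws, log(lo[[p]]), log(priors[[p]]))))
  pi1 <- max(obs[3], 0.05); pi2 <- max(obs[4], 0.05)
  pib <- max(obs[7], 0.05); da <- max(obs[8], 0.02)
  anchors <- as.matrix(expand.grid(
    theta_sm = c(pi1, 2 * pi1), theta_b = c(pi2, 2 * pi2),
    theta_A = c(0.2 * min(pi1, pi2), min(pi1, pi2)),
    m_sm = c(0.05, 1), m_b = c(0.05, 1), t = c(da, pib / 2)))
  anchors <- pmin(anchors, matrix(priors, nrow(anchors), 6, byrow = TRUE))
  cand <- rbind(cand, anchors)
  cand[, 1:3] <- pmax(cand[, 1:3], 0.05)
  pll <- vapply(seq_len(nrow(cand)), function(i)
    sl_objective(cand[i, ], obs, n1, n2, w, s$pilot_reps,
                 derive_seed(seed, "pilotev")), 0)
  # polish the top pilot points (Nelder-Mead, common random numbers) and
  # keep the best mode, so the refined box is centred on the global mode
  top <- order(pll, decreasing = TRUE)[seq_len(s$pilot_starts)]
  pols <- lapply(top, function(i)
    optimize_constrained(list(zero = character(0), equal = list()),
                         setNames(cand[i, ], par_names), priors,
                         function(p) obj(p, sd_ = "polish"),
                         maxit = s$optim_maxit))
  pol_ll <- vapply(pols, function(p) obj(p$par, sd_ = "polish2"), 0)
  best <- pols[[which.max(pol_ll)]]$par
  refined <- pmin(priors, pmax(5 * best, 0.2 * priors))
  names(refined) <- par_names

  # stage 2: random-walk Metropolis on the synthetic likelihood; both the
  # current and the proposed point are re-estimated each iteration with a
  # shared per-iteration seed, so the accept ratio reflects the parameter
  # difference rather than frozen Monte-Carlo noise
  set.seed(derive_seed(seed, "mcmc"))
  step <- refined / 15
  cur <- pmin(pmax(best, refined * 0.05), refined * 0.95)
  niter <- s$mcmc_iters
  samples <- matrix(NA_real_, niter, 6, dimnames = list(NULL, par_names))
  lls <- numeric(niter)
  acc_win <- rep(0, 6)
  try_win <- rep(0, 6)
  for (it in seq_len(niter)) {
    j <- 1 + (it - 1) %% 6 # cycle coordinates
    prop <- cur
    prop[j] <- cur[j] + stats::rnorm(1, 0, step[j])
    while (prop[j] < 0 || prop[j] > refined[j]) {
      if (prop[j] < 0) prop[j] <- -prop[j]
      if (prop[j] > refined[j]) prop[j] <- 2 * refined[j] - prop[j]
    }
    if (j <= 3) prop[j] <- max(prop[j], 1e-3)
    cur_ll <- obj(cur, sd_ = paste0("m", it))
    prop_ll <- obj(prop, sd_ = paste0("m", it))
    try_win[j] <- try_win[j] + 1
    if (log(runif(1)) < prop_ll - cur_ll) {
      cur <- prop; cur_ll <- prop_ll
      acc_win[j] <- acc_win[j] + 1
    }
    samples[it, ] <- cur
    lls[it] <- cur_ll
    # adapt each coordinate's step toward ~35% acceptance during burn-in
    if (it <= s$mcmc_burn && it %% 60 == 0) {
      for (jj in 1:6) {
        if (try_win[jj] > 0)
          step[jj] <- step[jj] * exp(acc_win[jj] / try_win[jj] - 0.35)
      }
      acc_win[] <- 0; try_win[] <- 0
    }
  }
  keep <- samples[(s$mcmc_burn + 1):niter, , drop = FALSE]
  est <- apply(keep, 2, marginal_peak)
  hpd <- apply(keep, 2, hpd_interval, mass = 0.90)
  rownames(hpd) <- c("lower", "upper")
  # enforce lower <= peak <= upper on the reported grid
  est <- pmin(pmax(est, hpd["lower", ]), hpd["upper", ])
  lnL <- obj(est, reps = s$big_reps, sd_ = "big")
  boundary <- est > 0.95 * refined
  if (any(boundary))
    warning("estimate at prior boundary for: ",
            paste(par_names[boundary], collapse = ", "),
            " (prior possibly too small)")
  pilot_top <- cand[order(pll, decreasing = TRUE)[seq_len(8)], , drop = FALSE]
  colnames(pilot_top) <- par_names
  structure(list(estimate = est, hpd = hpd, lnL = lnL, samples = keep,
                 pilot_top = pilot_top,
                 priors = refined, wide_priors = priors,
                 boundary = boundary, settings = s,
                 n_sm = n1, n_b = n2, weights = w, obs = obs,
                 blocks = od$blocks %||% NULL),
            class = "im_fit")
}

marginal_peak <- function(x) {
  d <- density(x, from = min(x), to = max(x), n = 256)
  d$x[which.max(d$y)]
}

hpd_interval <- function(x, mass = 0.90) {
  xs <- sort(x)
  m <- length(xs)
  k <- max(1, ceiling(mass * m))
  if (k >= m) return(c(xs[1], xs[m]))
  widths <- xs[(k + 1):m] - xs[1:(m - k)]
  i <- which.min(widths)
  c(xs[i], xs[i + k])
}

#' @export
print.im_fit <- function(x, ...) {
  cat("im_fit (synthetic likelihood):\n")
  tab <- rbind(estimate = x$estimate, x$hpd)
  print(round(tab, 4))
  cat(sprintf("lnL at estimate = %.3f\n", x$lnL))
  invisible(x)
}

#' p-value from the boundary mixed chi-square distribution
#'
#' Null distribution of a likelihood ratio when the constrained parameter
#' sits on the boundary of its space: half point-mass at zero, half
#' chi-square with 1 df. p(0) = 1; for LLR > 0, p = 0.5 * P(chi2_1 >= LLR).
#'
#' @param llr Log-likelihood-ratio statistic (2 * delta lnL).
#' @export
mixed_chisq_p <- function(llr) {
  ifelse(llr <= 0, 1, 0.5 * pchisq(llr, df = 1, lower.tail = FALSE))
}

im_nested_menu <- function() {
  list(
    m_sm_0        = list(zero = "m_sm", equal = list(), df = 1),
    m_b_0         = list(zero = "m_b", equal = list(), df = 1),
    m_equal       = list(zero = character(0), equal = list(c("m_sm", "m_b")), df = 1),
    isolation     = list(zero = c("m_sm", "m_b"), equal = list(), df = 2),
    theta_sm_b    = list(zero = character(0), equal = list(c("theta_sm", "theta_b")), df = 1),
    theta_sm_A    = list(zero = character(0), equal = list(c("theta_sm", "theta_A")), df = 1),
    theta_b_A     = list(zero = character(0), equal = list(c("theta_b", "theta_A")), df = 1),
    theta_all     = list(zero = character(0), equal = list(c("theta_sm", "theta_b", "theta_A")), df = 2))
}

# maximize the synthetic likelihood under a constraint spec (Nelder-Mead on
# a logit-transformed box; common random numbers across evaluations)
optimize_constrained <- function(spec, start, upper, objfun, maxit = 120,
                                 objfun_coarse = NULL) {
  reps <- setNames(par_names, par_names)
  for (eq in spec$equal) reps[eq] <- eq[1]
  free <- setdiff(unique(reps), spec$zero)
  expand <- function(z) {
    x <- upper[free] * stats::plogis(z)
    full <- setNames(numeric(6), par_names)
    for (p in par_names) {
      full[p] <- if (p %in% spec$zero) 0 else x[[reps[[p]]]]
    }
    full
  }
  st <- start
  for (eq in spec$equal) st[eq] <- mean(start[eq])
  st <- pmin(pmax(st[free], upper[free] * 1e-3), upper[free] * 0.999)
  z0 <- stats::qlogis(st / upper[free])
  if (!is.null(objfun_coarse)) { # cheap exploration pass
    o0 <- optim(z0, function(z) -objfun_coarse(expand(z)),
                method = "Nelder-Mead", control = list(maxit = maxit))
    z0 <- o0$par
  }
  negobj <- function(z) -objfun(expand(z))
  o <- optim(z0, negobj, method = "Nelder-Mead",
             control = list(maxit = maxit))
  list(par = expand(o$par), lnL = -o$value, free = free)
}

#' Nested-model likelihood-ratio tests for the IM fit
#'
#' Refits each nested model of the standard menu (single or joint zero /
#' equality constraints on migration rates and thetas) with the same
#' synthetic-likelihood machinery and common random numbers, and reports
#' LLR = 2(lnL_full - lnL_nested) with chi-square p-values. The isolation
#' model uses the two-step ladder: full vs {m_sm = m_b} on chi-square(1),
#' then {m_sm = m_b} vs {m_sm = m_b = 0} on the boundary mixed chi-square;
#' the isolation model is accepted only if neither step rejects.
#'
#' @param fit An `im_fit`.
#' @param alpha Significance level for the ladder verdict.
#' @param models Names of nested models to fit (default: the full menu; the
#'   ladder models `m_equal` and `isolation` are always included).
#' @return A `nested_test_table` data.frame plus the ladder verdict.
#' @export
nested_model_tests <- function(fit, alpha = 0.05,
                               models = names(im_nested_menu())) {
  s <- fit$settings
  # optimize on a low-noise surface (big_reps simulations per evaluation,
  # common random numbers): differential optimization error on a noisy
  # surface would otherwise inflate the LLR of true nested models
  crn <- derive_seed(s$seed, "nested")
  objfun <- function(par) sl_objective(par, fit$obs, fit$n_sm, fit$n_b,
                                       fit$weights, s$big_reps, crn)
  objcoarse <- function(par) sl_objective(par, fit$obs, fit$n_sm, fit$n_b,
                                          fit$weights,
                                          max(50L, s$big_reps %/% 3L),
                                          derive_seed(s$seed, "nestedcoarse"))
  bigfun <- function(par) sl_objective(par, fit$obs, fit$n_sm, fit$n_b,
                                       fit$weights, 6L * s$big_reps,
                                       derive_seed(s$seed, "nestedbig"))
  # optimize over the wide prior box: the pilot-refined box is an MCMC
  # device, and a constrained refit may need values outside it
  upper <- fit$wide_priors %||% fit$priors
  menu <- im_nested_menu()
  menu <- menu[union(intersect(names(menu), models), c("m_equal", "isolation"))]
  full_spec <- list(zero = character(0), equal = list(), df = 0)
  menu2 <- c(list(full = full_spec), menu)
  # pass 1: every model from the fitted point, plus a start from the best
  # pilot-stage candidate (guards against the fit having settled in a
  # secondary likelihood basin)
  starts1 <- list(fit$estimate)
  if (!is.null(fit$pilot_top)) {
    pv <- vapply(seq_len(nrow(fit$pilot_top)), function(i)
      objcoarse(fit$pilot_top[i, ]), 0)
    starts1[[2]] <- fit$pilot_top[which.max(pv), ]
  }
  opt1 <- lapply(menu2, function(spec) {
    os <- lapply(starts1, function(st)
      optimize_constrained(spec, st, upper, objfun, s$optim_maxit,
                           objfun_coarse = objcoarse))
    os[[which.max(vapply(os, function(o) o$lnL, 0))]]
  })
  # pass 2: restart each model from the other pass-1 optima (projected into
  # its constraint set); the best big-simulation value over all candidates
  # is the model's lnL. Cross-starting keeps the optima mutually coherent,
  # so the LLR reflects the constraint rather than optimizer scatter.
  extra_starts <- c("full", "isolation")
  lnL <- setNames(numeric(length(menu2)), names(menu2))
  pars <- list()
  for (nm in names(menu2)) {
    cands <- list(opt1[[nm]])
    for (st in setdiff(extra_starts, nm))
      cands[[length(cands) + 1]] <-
        optimize_constrained(menu2[[nm]], opt1[[st]]$par, upper, objfun,
                             s$optim_maxit, objfun_coarse = objcoarse)
    vals <- vapply(cands, function(o) bigfun(o$par), 0)
    lnL[nm] <- max(vals)
    pars[[nm]] <- cands[[which.max(vals)]]$par
  }
  # coherence: a nested model's feasible set lies inside the full model's
  lnL["full"] <- max(lnL)
  lnL["m_equal"] <- max(lnL["m_equal"], lnL["isolation"])
  lnL_full <- lnL[["full"]]
  rows <- list()
  for (nm in names(menu)) {
    spec <- menu[[nm]]
    llr <- max(0, 2 * (lnL_full - lnL[[nm]]))
    p <- pchisq(llr, df = spec$df, lower.tail = FALSE)
    rows[[nm]] <- data.frame(model = nm,
                             constraints = paste(c(
                               if (length(spec$zero)) paste0(spec$zero, "=0"),
                               vapply(spec$equal, paste, "", collapse = "=")),
                               collapse = ","),
                             df = spec$df, lnL = lnL[[nm]], LLR = llr, p = p,
                             reference = paste0("chisq(", spec$df, ")"))
  }
  fits <- lapply(names(menu), function(nm) list(par = pars[[nm]]))
  names(fits) <- names(menu)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # isolation ladder
  lnL_meq <- lnL[["m_equal"]]
  lnL_iso <- lnL[["isolation"]]
  llr1 <- max(0, 2 * (lnL_full - lnL_meq))
  p1 <- pchisq(llr1, df = 1, lower.tail = FALSE)
  llr2 <- max(0, 2 * (lnL_meq - lnL_iso))
  p2 <- mixed_chisq_p(llr2)
  tab$p[tab$model == "isolation"] <- p2
  tab$reference[tab$model == "isolation"] <- "ladder: chisq(1) then mixed chisq"
  tab$LLR[tab$model == "isolation"] <- llr2
  accepted <- (p1 >= alpha) && (p2 >= alpha)
  structure(list(table = tab, lnL_full = lnL_full,
                 ladder = data.frame(step = c("full_vs_m_equal",
                                              "m_equal_vs_isolation"),
                                     LLR = c(llr1, llr2), p = c(p1, p2)),
                 isolation_accepted = accepted, alpha = alpha,
                 nested_fits = lapply(fits, `[[`, "par")),
            class = "nested_test_table")
}

#' @export
print.nested_test_table <- function(x, ...) {
  print(x$table, digits = 4)
  cat("isolation model", if (x$isolation_accepted) "ACCEPTED" else "REJECTED",
      sprintf("(ladder p = %.4f, %.4f; alpha = %.2f)\n",
              x$ladder$p[1], x$ladder$p[2], x$alpha))
  invisible(x)
}

#' Convert IM coalescent parameters to demographic quantities
#'
#' N_e = theta / (4V) with V the per-locus per-generation mutation rate; T =
#' t / u with u the geometric mean per-locus annual mutation rate; 2Nm =
#' theta * m / 2 (bracket-independent). When a per-locus table is supplied,
#' the per-locus annual rate is u_syn * silent_sites + u_syn * KaKs *
#' replacement_sites and u is its geometric mean; alternatively pass the
#' geometric-mean per-locus annual rates directly via `u_annual`.
#'
#' @param est An `im_params` / named vector of the six estimates.
#' @param u_syn_min,u_syn_max Synonymous mutation rates per site per year
#'   bracketing the plausible range.
#' @param gen_years Generation time in years.
#' @param locus_table Optional data.frame with `silent_sites`,
#'   `replacement_sites`, `ka_ks` per locus.
#' @param u_annual Optional named vector c(min=, max=) of geometric-mean
#'   per-locus annual rates (overrides `locus_table`).
#' @return A `demographic_table` data.frame (one row per bracket) with N_e
#'   for sm/b/A, T in years, 2Nm per direction, and the inputs used.
#' @export
convert_parameters <- function(est, u_syn_min = 0.7e-9, u_syn_max = 2.61e-9,
                               gen_years = 60, locus_table = NULL,
                               u_annual = NULL) {
  p <- im_par_vec(est)
  if (is.null(u_annual)) {
    if (is.null(locus_table))
      stop("supply either locus_table or u_annual")
    rate <- function(u) {
      r <- u * locus_table$silent_sites +
        u * locus_table$ka_ks * locus_table$replacement_sites
      if (any(r <= 0)) stop("zero per-locus mutation rate")
      exp(mean(log(r)))
    }
    u_annual <- c(min = rate(u_syn_min), max = rate(u_syn_max))
  }
  if (any(u_annual <= 0)) stop("zero mutation rate")
  rows <- lapply(names(u_annual), function(br) {
    u <- u_annual[[br]]
    V <- u * gen_years
    data.frame(bracket = br, u_locus_year = u, V = V,
               Ne_sm = p["theta_sm"] / (4 * V),
               Ne_b = p["theta_b"] / (4 * V),
               Ne_A = p["theta_A"] / (4 * V),
               T_years = p["t"] / u,
               two_Nm_sm = p["theta_sm"] * p["m_sm"] / 2,
               two_Nm_b = p["theta_b"] * p["m_b"] / 2,
               gen_years = gen_years, row.names = NULL)
  })
  structure(do.call(rbind, rows), class = c("demographic_table", "data.frame"))
}

#' Tajima's D test under the fitted demographic model
#'
#' Replaces the standard-neutral null with the fitted two-group IM model:
#' multilocus IM simulations at the point estimates with the observed
#' sampling configuration and per-locus mutation weights give the null
#' distribution of D for the pooled sample and for each group; empirical
#' two-sided p-values are reported per locus and set. Simulated replicates
#' with S = 0 give missing D and are dropped pairwise.
#'
#' @param fit An `im_fit` or `im_params`.
#' @param ds The observed `multilocus_dataset` (group labels consistent with
#'   the fit).
#' @param reps Simulation replicates.
#' @param seed Integer seed.
#' @param weights Optional per-locus mutation weights (defaults to the
#'   fit's, else relative unmasked locus lengths).
#' @return data.frame with observed D and empirical p per locus x
#'   {total, sm, b}.
#' @export
demographic_null_tajima <- function(fit, ds, reps = 1000, seed = 1,
                                    weights = NULL) {
  par <- if (inherits(fit, "im_fit")) fit$estimate else im_par_vec(fit)
  groups <- setdiff(unique(ds$popmap$group), "unassigned")
  g1 <- if ("sumatra_malay" %in% groups) "sumatra_malay" else groups[1]
  g2 <- setdiff(groups, g1)
  ind1 <- ds$popmap$individual[ds$popmap$group == g1]
  ind2 <- ds$popmap$individual[ds$popmap$group == g2]
  L <- length(ds$loci)
  if (is.null(weights)) {
    weights <- if (inherits(fit, "im_fit") && length(fit$weights) == L)
      fit$weights
    else {
      len <- vapply(ds$loci, function(a) sum(!a$mask), 0)
      len / exp(mean(log(len)))
    }
  }
  out <- list()
  for (l in seq_len(L)) {
    aln <- ds$loci[[l]]
    in1 <- aln$individuals %in% ind1
    in2 <- aln$individuals %in% ind2
    n1 <- sum(in1); n2 <- sum(in2)
    obs <- c(total = tajima_d(summary_stats(aln)),
             sm = if (n1 >= 4) tajima_d(summary_stats(aln, intersect(aln$individuals, ind1))) else NA,
             b = if (n2 >= 4) tajima_d(summary_stats(aln, intersect(aln$individuals, ind2))) else NA)
    sims <- matrix(NA_real_, reps, 3)
    for (r in seq_len(reps)) {
      smp <- cpp_sim_im(n1, n2, par[1], par[2], par[3], par[4], par[5], par[6],
                        weights[l], derive_seed(seed, paste0("l", l, "r", r)))
      G <- smp$G
      sims[r, 1] <- d_from_G(G)
      sims[r, 2] <- d_from_G(G[seq_len(n1), , drop = FALSE])
      sims[r, 3] <- d_from_G(G[n1 + seq_len(n2), , drop = FALSE])
    }
    for (k in 1:3) {
      d <- sims[, k][!is.na(sims[, k])]
      o <- obs[k]
      p <- if (is.na(o) || length(d) == 0) NA_real_ else
        min(1, 2 * min(mean(d <= o), mean(d >= o)))
      out[[length(out) + 1]] <- data.frame(
        locus = names(ds$loci)[l], set = c("total", g1, g2)[k],
        D_obs = unname(o), p = p, reps_used = length(d))
    }
  }
  do.call(rbind, out)
}

# Tajima's D from a 0/1 genotype matrix (columns = segregating sites)
d_from_G <- function(G) {
  n <- nrow(G)
  if (n < 2) return(NA_real_)
  k <- colSums(G)
  poly <- k > 0 & k < n
  S <- sum(poly)
  if (S == 0) return(NA_real_)
  mp <- sum(k[poly] * (n - k[poly])) / (n * (n - 1) / 2)
  tajima_d(n, S, mp)
}
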