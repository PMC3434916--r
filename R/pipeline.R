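#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates load/generate -> hybrid filtering -> summary statistics ->
#' Tajima tests -> MK / HKA (when an outgroup is present) -> Fst / Da / NJ
#' tree -> admixture clustering with delta-K -> IM fit -> nested-model tests
#' -> parameter conversion -> demographic-null Tajima retest. One global
#' seed deterministically derives every stage seed; optional stages degrade
#' gracefully with logged skips.
#'
#' @param config List (or path to a YAML file) with entries:
#'   \describe{
#'     \item{scenario}{`"paper_like"`, `"two_pop"`, or an `im_scenario`
#'       (alternatively give `fasta_paths`/`popmap`/`annotation` input
#'       paths).}
#'     \item{seed}{Global integer seed (default 1).}
#'     \item{out_dir}{Output directory (default `tempfile()`), receives
#'       TSV tables, the Newick tree and `manifest.json`.}
#'     \item{tajima_reps, k_range, structure_runs, structure_burnin,
#'       structure_reps, im, null_reps, u_syn_min, u_syn_max, gen_years}{
#'       Stage settings (desk-scale defaults).}
#'   }
#' @return List of stage results (invisibly also written to `out_dir`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    scenario = "paper_like", seed = 1, out_dir = tempfile("sundapop_run_"),
    tajima_reps = 2000, k_range = 1:4, structure_runs = 3,
    structure_burnin = 2000, structure_reps = 8000, max_diff = 0,
    im = list(), null_reps = 400,
    u_syn_min = 0.7e-9, u_syn_max = 2.61e-9, gen_years = 60), config)
  seed <- cfg$seed
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  out <- list(config = cfg)

  # stage: input
  if (!is.null(cfg$fasta_paths)) {
    say("stage load: reading dataset from files")
    ds <- load_dataset(cfg$fasta_paths, cfg$popmap, cfg$annotation,
                       cfg$outgroup_paths)
    refs <- NULL
  } else {
    sc <- if (inherits(cfg$scenario, "im_scenario")) cfg$scenario
          else switch(cfg$scenario, paper_like = scenario_paper_like(),
                      two_pop = scenario_two_pop(),
                      stop("unknown scenario: ", cfg$scenario))
    say("stage generate: scenario ", sc$name)
    gen <- generate_dataset(sc, seed = derive_seed(seed, "generate"))
    ds <- gen$dataset
    refs <- gen$refs
    out$truth <- gen$truth
  }

  # stage: hybrid filtering
  if (!is.null(refs)) {
    hy <- flag_hybrids(ds, refs)
    say("stage hybrids: ", length(hy$report$flagged), " individual(s) excluded")
    out$hybrids <- hy$report
    ds <- hy$dataset
  } else say("stage hybrids: skipped (no reference haplotype sets)")
  out$dataset <- ds

  # stage: summary statistics
  say("stage stats: population x locus summary table")
  out$stats <- population_table(ds)
  write.table(out$stats$per_locus, file.path(cfg$out_dir, "stats_per_locus.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(out$stats$averages, file.path(cfg$out_dir, "stats_averages.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  # stage: Tajima tests
  say("stage tajima: fixed-S coalescent nulls (", cfg$tajima_reps, " reps)")
  out$tajima <- rbind(
    tajima_table(ds, "total", reps = cfg$tajima_reps,
                 seed = derive_seed(seed, "tajima_total")),
    tajima_table(ds, "group", reps = cfg$tajima_reps,
                 seed = derive_seed(seed, "tajima_group")))
  write.table(out$tajima, file.path(cfg$out_dir, "tajima.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  # stage: MK / HKA (need outgroup)
  if (!is.null(ds$outgroups)) {
    say("stage mk/hka: outgroup neutrality tests")
    out$mk <- lapply(names(ds$loci), function(nm)
      mk_counts(ds$loci[[nm]], ds$outgroups[[nm]]))
    names(out$mk) <- names(ds$loci)
    mk_tab <- do.call(rbind, lapply(names(out$mk), function(nm)
      data.frame(locus = nm, t(out$mk[[nm]]$counts),
                 fisher_p = out$mk[[nm]]$mk$fisher_p,
                 g_p = out$mk[[nm]]$mk$g_p)))
    write.table(mk_tab, file.path(cfg$out_dir, "mk.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    out$hka <- tryCatch(hka_test(ds), error = function(e) {
      say("stage hka: skipped (", conditionMessage(e), ")")
      NULL
    })
  } else say("stage mk/hka: skipped (no outgroup)")

  # stage: population structure
  say("stage structure: Fst/Da/NJ + admixture clustering")
  out$fst <- fst_matrix(ds)
  out$da <- da_matrix(ds)
  if (nrow(out$da) >= 3) {
    out$nj <- nj_tree(out$da)
    writeLines(out$nj$newick, file.path(cfg$out_dir, "tree.nwk"))
  } else say("stage structure: NJ tree skipped (< 3 populations)")
  scan <- structure_scan(ds, k_range = cfg$k_range, n_runs = cfg$structure_runs,
                         burn_in = cfg$structure_burnin,
                         reps = cfg$structure_reps,
                         seed = derive_seed(seed, "structure"),
                         max_diff = cfg$max_diff)
  out$delta_k <- scan$selection
  say("stage structure: delta-K selects K = ", scan$selection$K_star)
  kstar_runs <- Filter(function(r) r$K == scan$selection$K_star, scan$runs)
  best <- kstar_runs[[which.max(vapply(kstar_runs, function(r) r$lnP, 0))]]
  out$Q <- best$Q
  write.table(out$Q, file.path(cfg$out_dir, "Q_matrix.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  write.table(scan$selection$table, file.path(cfg$out_dir, "delta_k.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  # stage: IM inference
  groups <- setdiff(unique(ds$popmap$group), "unassigned")
  if (length(groups) == 2) {
    say("stage im: synthetic-likelihood fit")
    out$im_fit <- fit_im(ds, settings = utils::modifyList(
      list(seed = derive_seed(seed, "imfit")), cfg$im))
    say("stage im: nested-model LLR tests")
    out$nested <- nested_model_tests(out$im_fit)
    # per-locus conversion inputs from the data (Ka/Ks against the outgroup
    # when available, else neutral replacement weight 1)
    lt <- do.call(rbind, lapply(names(ds$loci), function(nm) {
      cl <- classify_sites(ds$loci[[nm]])
      kk <- if (!is.null(ds$outgroups)) tryCatch(
        ka_ks(ds$loci[[nm]], ds$outgroups[[nm]], cl)$ratio,
        error = function(e) NA_real_) else NA_real_
      if (is.na(kk)) kk <- 1
      data.frame(locus = nm, silent_sites = cl$counts$n_silent,
                 replacement_sites = cl$counts$n_replacement,
                 ka_ks = max(kk, 1e-3))
    }))
    # scale per-locus annual rates: u_syn per site per year over the sites
    out$conversion <- convert_parameters(out$im_fit$estimate,
                                         u_syn_min = cfg$u_syn_min,
                                         u_syn_max = cfg$u_syn_max,
                                         gen_years = cfg$gen_years,
                                         locus_table = lt)
    write.table(out$conversion, file.path(cfg$out_dir, "demographic_table.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(out$nested$table, file.path(cfg$out_dir, "nested_tests.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    say("stage nulltest: Tajima's D under the fitted model")
    out$null_tajima <- demographic_null_tajima(out$im_fit, ds,
                                               reps = cfg$null_reps,
                                               seed = derive_seed(seed, "null"))
    write.table(out$null_tajima, file.path(cfg$out_dir, "null_tajima.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  } else say("stage im: skipped (need exactly two group labels)")

  manifest <- list(seed = seed, stages = log,
                   settings = cfg[setdiff(names(cfg), "scenario")],
                   delta_k = out$delta_k$K_star %||% NA)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  out$log <- log
  invisible(out)
}
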