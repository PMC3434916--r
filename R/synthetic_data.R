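#' Simulation scenario for the synthetic-data generator
#'
#' A scenario fixes the sampling design (populations, sizes, group labels,
#' per-population admixture proportions), the IM parameters of the two
#' diverged groups, the per-locus design (aligned length, exon structure,
#' relative mutation weight), the planted interspecific F1 hybrid, and the
#' outgroup/donor divergences.
#'
#' @param name Scenario name.
#' @param populations data.frame with `name`, `size` (individuals), `group`
#'   (`sumatra_malay` / `borneo`), `q` (probability that a haplotype of an
#'   individual originates from the sumatra_malay side; 1 and 0 give
#'   unadmixed populations).
#' @param loci data.frame with `name`, `length`, `weight`, plus exon
#'   intervals in `exons` (list of data.frames start/end/frame).
#' @param params [im_params()] of the two groups.
#' @param hybrid NULL, or list(individual_index, population, t_donor) for
#'   one planted F1 whose second haplotype comes from a diverged donor
#'   lineage at each locus.
#' @param t_outgroup Outgroup divergence in mutational units.
#' @param rep_skew Fraction of exon-mapped mutations forced onto external
#'   branches (phenomenological low-frequency skew of replacement variants).
#' @export
im_scenario <- function(name, populations, loci, params, hybrid = NULL,
                        t_outgroup = 10, rep_skew = 0) {
  stopifnot(all(populations$size > 0), all(populations$q >= 0 & populations$q <= 1),
            all(loci$length > 0))
  structure(list(name = name, populations = populations, loci = loci,
                 params = as_im_params(params), hybrid = hybrid,
                 t_outgroup = t_outgroup, rep_skew = rep_skew),
            class = "im_scenario")
}

#' The seven-population, five-locus study scenario
#'
#' Emulates the study sampling design: seven populations of 12 individuals
#' (six for ITCI Karya Utama; 78 in total), five loci with aligned lengths
#' 1111/1229/1248/1075/1277 bp (5940 bp total) carrying one or two exons
#' covering roughly 30 percent of sites, two diverged groups with one
#' admixed population on each side (q = 0.5), IM parameters at the fitted
#' point estimates of the study system, and one interspecific F1 hybrid
#' planted in a Sumatran population.
#'
#' @export
scenario_paper_like <- function() {
  pops <- data.frame(
    name = c("Seremban", "Mersing", "NanjakMakmur", "Asialog",
             "SariBumiKusuma", "ITCIKaryaUtama", "Sumalindo"),
    size = c(12, 12, 12, 12, 12, 6, 12),
    group = c("sumatra_malay", "sumatra_malay", "sumatra_malay",
              "sumatra_malay", "borneo", "borneo", "borneo"),
    q = c(1, 1, 1, 0.5, 0, 0.5, 0))
  lens <- c(1111, 1229, 1248, 1075, 1277)
  exons <- list(
    data.frame(start = 120, end = 453, frame = 0),
    data.frame(start = c(80, 700), end = c(263, 886), frame = c(0, 0)),
    data.frame(start = 300, end = 675, frame = 0),
    data.frame(start = 150, end = 474, frame = 0),
    data.frame(start = c(60, 800), end = c(240, 1013), frame = c(0, 0)))
  loci <- data.frame(name = paste0("locus", 1:5), length = lens,
                     weight = lens / exp(mean(log(lens))))
  loci$exons <- I(exons)
  im_scenario("paper_like", pops, loci,
              im_params(theta_sm = 4.367, theta_b = 11.2873, theta_A = 1.1677,
                        m_sm = 0.755, m_b = 0.045, t = 0.685),
              hybrid = list(individual_index = 1, population = "NanjakMakmur",
                            t_donor = 5),
              t_outgroup = 10, rep_skew = 0.6)
}

#' Plain two-group recovery scenario (no admixture, no hybrid)
#'
#' @param n_loci Number of loci.
#' @param n_per_group Individuals per group.
#' @param params IM parameters.
#' @param length Locus length (bp).
#' @export
scenario_two_pop <- function(n_loci = 20, n_per_group = 20,
                             params = im_params(4, 11, 1.2, 0.75, 0.05, 0.7),
                             length = 1200) {
  pops <- data.frame(name = c("popSM", "popB"),
                     size = c(n_per_group, n_per_group),
                     group = c("sumatra_malay", "borneo"), q = c(1, 0))
  loci <- data.frame(name = sprintf("locus%02d", seq_len(n_loci)),
                     length = length, weight = 1)
  loci$exons <- I(rep(list(data.frame(start = integer(0), end = integer(0),
                                      frame = integer(0))), n_loci))
  im_scenario("two_pop_recovery", pops, loci, params)
}

#' Generate a synthetic multilocus dataset from a scenario
#'
#' Haplotypes are drawn from the two-deme IM coalescent with the scenario's
#' parameters; admixed populations assign each haplotype to the
#' sumatra_malay side with probability q. An outgroup individual and (when
#' requested) an F1-hybrid donor lineage are simulated as diverged lineages
#' carrying private fixed differences. The 0/1 site patterns are mapped to
#' nucleotide alignments of the scenario lengths (distinct columns, uniform
#' ancestral base, derived base uniform among the other three). A truth
#' manifest records every latent assignment.
#'
#' @param scenario An `im_scenario`.
#' @param seed Integer seed.
#' @param out_dir Optional directory: writes per-locus FASTA, popmap.tsv,
#'   annotation.tsv, reference FASTAs and manifest.json.
#' @return List with `dataset` (a `multilocus_dataset`), `refs` (per-species
#'   reference haplotypes for [flag_hybrids()]), and `truth` (manifest).
#' @export
generate_dataset <- function(scenario, seed = 1, out_dir = NULL) {
  sc <- scenario
  pops <- sc$populations
  n_ind <- sum(pops$size)
  ind_pop <- rep(pops$name, pops$size)
  ind_ids <- sprintf("IND%03d", seq_len(n_ind))
  hybrid_ind <- NA_character_
  if (!is.null(sc$hybrid)) {
    cand <- which(ind_pop == sc$hybrid$population)
    hybrid_ind <- ind_ids[cand[sc$hybrid$individual_index]]
  }
  # haplotype deme assignment (shared across loci: ancestry is genome-wide)
  set.seed(derive_seed(seed, "demes"))
  qof <- pops$q[match(ind_pop, pops$name)]
  hap_deme <- matrix(0L, n_ind, 2) # 1 = sm, 2 = b
  for (i in seq_len(n_ind)) hap_deme[i, ] <- ifelse(runif(2) < qof[i], 1L, 2L)
  # the hybrid's second haplotype comes from the donor lineage
  donor_slot <- !is.na(hybrid_ind) & ind_ids == hybrid_ind

  loci <- list()
  outgroups <- list()
  refs_focal <- list()
  refs_donor <- list()
  truth_loci <- list()
  # reference individuals for hybrid assignment: 2 from each unadmixed side
  ref_inds <- c(ind_ids[ind_pop == pops$name[1]][1:2],
                ind_ids[ind_pop == pops$name[which(pops$q == 0)[1]]][1:2])

  for (l in seq_len(nrow(sc$loci))) {
    lname <- sc$loci$name[l]
    Lbp <- sc$loci$length[l]
    w <- sc$loci$weight[l]
    lseed <- derive_seed(seed, paste0("locus", l))
    # focal haplotype slots (hybrid's donor slot excluded from the focal tree)
    slot_ind <- rep(seq_len(n_ind), each = 2)
    slot_hap <- rep(1:2, n_ind)
    is_donor_slot <- donor_slot[slot_ind] & slot_hap == 2
    focal_slots <- which(!is_donor_slot)
    deme_of_slot <- hap_deme[cbind(slot_ind, slot_hap)]
    fd <- deme_of_slot[focal_slots]
    ord <- order(fd) # sim_im wants deme-1 rows first
    n1 <- sum(fd == 1); n2 <- sum(fd == 2)
    smp <- sim_im(sc$params, n1, n2, locus_scale = w,
                  seed = derive_seed(lseed, "im"))
    Gf <- smp$G
    # rows of Gf follow order(fd); invert the permutation
    Gfull <- matrix(0L, length(focal_slots), ncol(Gf))
    Gfull[ord, ] <- Gf

    # outgroup + donor: diverged lineages carrying private fixed differences
    set.seed(derive_seed(lseed, "divergence"))
    n_og_mut <- rpois(1, 2 * sc$t_outgroup * w)
    n_dn_mut <- if (!is.null(sc$hybrid)) rpois(1, 2 * sc$hybrid$t_donor * w) else 0
    n_focal_priv <- rpois(1, if (!is.null(sc$hybrid)) sc$hybrid$t_donor * w else 0)

    S_pol <- ncol(Gfull)
    S_all <- S_pol + n_og_mut + n_dn_mut + n_focal_priv
    if (S_all > Lbp) stop("locus ", lname, ": requested sites exceed length")
    cols <- sort(sample.int(Lbp, S_all)) - 1L
    set.seed(derive_seed(lseed, "bases"))
    anc <- sample(c("A", "C", "G", "T"), Lbp, replace = TRUE)
    # avoid stop codons in the ancestral reading frames
    exons0 <- sc$loci$exons[[l]]
    if (nrow(exons0) > 0) {
      for (e in seq_len(nrow(exons0))) {
        st <- exons0$start[e] + exons0$frame[e]
        for (cs in seq(st, exons0$end[e] - 3, by = 3)) {
          while (translate_codon(paste(anc[(cs + 1):(cs + 3)], collapse = "")) == "*")
            anc[cs + 3] <- sample(c("A", "C", "G", "T"), 1)
        }
      }
    }

    # low-frequency skew of exon-mapped focal mutations (purifying-selection
    # signature, phenomenological)
    exons <- sc$loci$exons[[l]]
    in_exon <- function(cc) {
      if (nrow(exons) == 0) return(rep(FALSE, length(cc)))
      out <- rep(FALSE, length(cc))
      for (e in seq_len(nrow(exons)))
        out <- out | (cc >= exons$start[e] & cc < exons$end[e])
      out
    }
    pol_cols <- cols[sample.int(length(cols), S_pol)]
    if (sc$rep_skew > 0 && S_pol > 0) {
      skew <- in_exon(pol_cols) & runif(S_pol) < sc$rep_skew
      for (j in which(skew)) {
        carrier <- sample.int(nrow(Gfull), 1)
        Gfull[, j] <- 0L
        Gfull[carrier, j] <- 1L
      }
    }
    og_cols <- setdiff(cols, pol_cols)
    dn_cols <- if (n_dn_mut > 0) og_cols[sample.int(length(og_cols), n_dn_mut)] else integer(0)
    og_cols2 <- setdiff(og_cols, dn_cols)
    fp_cols <- if (n_focal_priv > 0) og_cols2[sample.int(length(og_cols2), n_focal_priv)] else integer(0)
    og_cols3 <- setdiff(og_cols2, fp_cols)

    derived <- function(a) {
      vapply(a, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    # build sequences
    n_slots <- 2 * n_ind
    seqmat <- matrix(rep(anc, each = n_slots), n_slots, Lbp)
    # focal polymorphism
    der_pol <- derived(anc[pol_cols + 1])
    for (j in seq_len(S_pol)) {
      rows <- focal_slots[Gfull[, j] == 1L]
      seqmat[rows, pol_cols[j] + 1] <- der_pol[j]
    }
    # focal-lineage private fixed differences (focal differs from both
    # outgroup and donor at these columns)
    der_fp <- derived(anc[fp_cols + 1])
    for (j in seq_along(fp_cols))
      seqmat[focal_slots, fp_cols[j] + 1] <- der_fp[j]
    # donor haplotype for the hybrid
    donor_base <- anc
    der_dn <- derived(anc[dn_cols + 1])
    donor_base[dn_cols + 1] <- der_dn
    donor_refs <- matrix(rep(donor_base, each = 4), 4, Lbp)
    # donor within-species variation: a couple of private polymorphisms
    n_dpoly <- rpois(1, 0.5 * w)
    if (n_dpoly > 0) {
      free <- setdiff(seq_len(Lbp) - 1L, cols)
      dp <- free[sample.int(length(free), min(n_dpoly, length(free)))]
      for (cc in dp) {
        rows <- sample.int(4, sample(1:2, 1))
        donor_refs[rows, cc + 1] <- derived(anc[cc + 1])
      }
    }
    if (!is.null(sc$hybrid)) {
      dslot <- which(is_donor_slot)
      seqmat[dslot, ] <- donor_refs[1, ]
    }
    # outgroup individual (2 identical haplotypes at divergence t_outgroup)
    og_seq <- anc
    og_seq[og_cols3 + 1] <- derived(anc[og_cols3 + 1])
    ogm <- matrix(rep(og_seq, each = 2), 2, Lbp)
    rownames(ogm) <- c("OUT_h1", "OUT_h2")

    individuals <- ind_ids[slot_ind]
    loci[[lname]] <- locus_alignment(lname,
                                     seqmat, individuals, exons)
    outgroups[[lname]] <- ogm
    # species reference sets for hybrid flagging
    ref_rows <- which(individuals %in% ref_inds & !is_donor_slot)
    refs_focal[[lname]] <- seqmat[ref_rows, , drop = FALSE]
    refs_donor[[lname]] <- donor_refs[2:4, , drop = FALSE]
    truth_loci[[lname]] <- list(S_polymorphic = S_pol,
                                n_outgroup_fixed = length(og_cols3),
                                n_donor_fixed = length(dn_cols),
                                weight = w)
  }
  popmap <- data.frame(individual = ind_ids, population = ind_pop,
                       group = pops$group[match(ind_pop, pops$name)])
  ds <- multilocus_dataset(loci, popmap, outgroups,
                           meta = list(scenario = sc$name, seed = seed))
  truth <- list(scenario = sc$name, seed = seed,
                params = unclass(sc$params),
                hybrid_individual = hybrid_ind,
                hap_deme = setNames(split(hap_deme, row(hap_deme)), ind_ids),
                populations = pops, loci = truth_loci)
  refs <- list(focal = refs_focal, donor = refs_donor)
  if (!is.null(out_dir)) write_dataset(ds, refs, truth, out_dir)
  list(dataset = ds, refs = refs, truth = truth)
}

write_fasta <- function(mat, ids, path) {
  lines <- character(0)
  for (i in seq_len(nrow(mat)))
    lines <- c(lines, paste0(">", ids[i]), paste(mat[i, ], collapse = ""))
  writeLines(lines, path)
}

write_dataset <- function(ds, refs, truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- list()
  for (nm in names(ds$loci)) {
    aln <- ds$loci[[nm]]
    hap_idx <- stats::ave(seq_along(aln$individuals), aln$individuals,
                          FUN = seq_along)
    ids <- paste0(aln$individuals, "_h", hap_idx)
    write_fasta(aln$seqs, ids, file.path(out_dir, paste0(nm, ".fasta")))
    if (!is.null(ds$outgroups[[nm]]))
      write_fasta(ds$outgroups[[nm]], rownames(ds$outgroups[[nm]]),
                  file.path(out_dir, paste0(nm, "_outgroup.fasta")))
    for (sp in names(refs))
      write_fasta(refs[[sp]][[nm]],
                  paste0(sp, "_", seq_len(nrow(refs[[sp]][[nm]]))),
                  file.path(out_dir, paste0(nm, "_ref_", sp, ".fasta")))
    if (nrow(aln$exons) > 0)
      ann[[nm]] <- cbind(locus = nm, aln$exons)
  }
  write.table(ds$popmap, file.path(out_dir, "popmap.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (length(ann) > 0)
    write.table(do.call(rbind, ann), file.path(out_dir, "annotation.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(truth, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' The five printed McDonald-Kreitman 2x2 tables
#'
#' Packaged fixed/polymorphic synonymous and replacement counts for the five
#' nuclear gene regions GapC, GBSSI, PgiC, SBE2 and SODH.
#'
#' @return data.frame with one row per locus.
#' @export
mk_fixture <- function() {
  data.frame(
    locus = c("GapC", "GBSSI", "PgiC", "SBE2", "SODH"),
    fixed_syn = c(3, 12, 2, 1, 1),
    poly_syn = c(10, 23, 13, 4, 7),
    fixed_rep = c(4, 1, 1, 2, 3),
    poly_rep = c(2, 29, 9, 2, 2))
}
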