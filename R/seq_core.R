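#' Construct a per-locus haplotype alignment
#'
#' A locus alignment holds the phased haplotypes of a set of diploid
#' individuals (two equal-length sequences per individual), an optional exon
#' annotation, and a column mask. Columns containing an alignment gap (`-`)
#' in any haplotype are masked and excluded from every downstream statistic;
#' masking (rather than column deletion) keeps coordinates stable.
#'
#' @param locus_name Character scalar.
#' @param seqs Character vector of aligned sequences (A/C/G/T/-), or a
#'   character matrix with one row per haplotype.
#' @param individuals Individual id for each haplotype (each id must occur
#'   exactly twice).
#' @param exons Optional data.frame with columns `start`, `end`, `frame`
#'   (0-based half-open alignment coordinates; `frame` is the offset of the
#'   first complete codon after `start`). Intervals must not overlap and the
#'   in-frame length must be a multiple of 3.
#' @return An object of class `locus_alignment`.
#' @export
locus_alignment <- function(locus_name, seqs, individuals, exons = NULL) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) {
      bad <- which(lens != lens[1])[1]
      stop("locus ", locus_name, ": sequence for '", individuals[bad],
           "' has length ", lens[bad], ", expected ", lens[1])
    }
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  if (!all(seqs %in% c("A", "C", "G", "T", "-"))) {
    stop("locus ", locus_name,
         ": only A/C/G/T/- are accepted (ambiguity codes are rejected)")
  }
  if (length(individuals) != nrow(seqs))
    stop("one individual id per haplotype is required")
  tab <- table(individuals)
  if (any(tab != 2)) {
    stop("locus ", locus_name, ": individuals without exactly 2 haplotypes: ",
         paste(names(tab)[tab != 2], collapse = ", "))
  }
  L <- ncol(seqs)
  mask <- apply(seqs == "-", 2, any)
  if (!is.null(exons) && nrow(exons) > 0) {
    exons <- exons[order(exons$start), , drop = FALSE]
    if (any(exons$start < 0 | exons$end > L | exons$start >= exons$end))
      stop("locus ", locus_name, ": exon interval out of bounds")
    if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
      stop("locus ", locus_name, ": overlapping exon intervals")
    if (any((exons$end - exons$start - exons$frame) %% 3 != 0))
      stop("locus ", locus_name,
           ": exon length not divisible by 3 after frame offset")
  } else {
    exons <- data.frame(start = integer(0), end = integer(0), frame = integer(0))
  }
  structure(list(locus_name = locus_name, seqs = seqs,
                 individuals = as.character(individuals),
                 aligned_length = L, mask = mask, exons = exons),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("locus_alignment '", x$locus_name, "': ", nrow(x$seqs),
      " haplotypes (", length(unique(x$individuals)), " individuals), ",
      x$aligned_length, " bp (", sum(x$mask), " gap-masked columns), ",
      nrow(x$exons), " exon(s)\n", sep = "")
  invisible(x)
}

parse_hap_ids <- function(ids, hap_sep = "_h") {
  m <- regmatches(ids, regexec(paste0("^(.*)", hap_sep, "([12])$"), ids))
  bad <- vapply(m, length, 1L) != 3
  if (any(bad)) {
    stop("sequence id(s) not of the form <individual>", hap_sep,
         "<1|2>: ", paste(ids[bad], collapse = ", "))
  }
  data.frame(id = ids,
             individual = vapply(m, `[`, "", 2),
             hap = as.integer(vapply(m, `[`, "", 3)))
}

read_fasta_matrix <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- names(x)
  seqs
}

#' Load a multilocus phased haplotype dataset
#'
#' Reads one FASTA file per locus (record ids of the form `IND_h1` /
#' `IND_h2`), a population map, and an exon annotation. Columns containing a
#' gap in any haplotype of a locus are masked from all analyses.
#'
#' @param fasta_paths Named character vector of per-locus FASTA files (names
#'   become locus names; unnamed paths use the file base name).
#' @param popmap_path TSV with columns `individual`, `population`, `group`
#'   (group in `sumatra_malay` / `borneo` / `unassigned`).
#' @param annotation_path Optional TSV with columns `locus`, `start`, `end`,
#'   `frame` (0-based half-open).
#' @param outgroup_paths Optional named character vector of per-locus FASTA
#'   files with outgroup haplotypes (same locus names).
#' @param hap_sep Separator between individual id and haplotype index.
#' @return A `multilocus_dataset`: list of `locus_alignment`s, the population
#'   map, and any outgroup haplotype matrices.
#' @export
load_dataset <- function(fasta_paths, popmap_path, annotation_path = NULL,
                         outgroup_paths = NULL, hap_sep = "_h") {
  if (is.null(names(fasta_paths)) || any(names(fasta_paths) == ""))
    names(fasta_paths) <- tools::file_path_sans_ext(basename(fasta_paths))
  popmap <- read.delim(popmap_path, stringsAsFactors = FALSE)
  stopifnot(all(c("individual", "population", "group") %in% names(popmap)))
  ann <- NULL
  if (!is.null(annotation_path)) {
    ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
    stopifnot(all(c("locus", "start", "end", "frame") %in% names(ann)))
  }
  loci <- list()
  for (nm in names(fasta_paths)) {
    seqs <- read_fasta_matrix(fasta_paths[[nm]])
    info <- parse_hap_ids(names(seqs), hap_sep)
    missing <- setdiff(info$individual, popmap$individual)
    if (length(missing) > 0)
      stop("locus ", nm, ": individual(s) missing from population map: ",
           paste(missing, collapse = ", "))
    ex <- if (!is.null(ann)) ann[ann$locus == nm, c("start", "end", "frame")] else NULL
    loci[[nm]] <- locus_alignment(nm, unname(seqs), info$individual, ex)
  }
  inds <- lapply(loci, function(a) sort(unique(a$individuals)))
  if (length(unique(inds)) != 1)
    stop("all loci must cover the same set of individuals")
  outgroups <- NULL
  if (!is.null(outgroup_paths)) {
    outgroups <- lapply(outgroup_paths, function(p) {
      s <- read_fasta_matrix(p)
      m <- do.call(rbind, strsplit(toupper(unname(s)), ""))
      rownames(m) <- names(s)
      m
    })
    names(outgroups) <- names(outgroup_paths) %||% names(fasta_paths)
  }
  multilocus_dataset(loci, popmap, outgroups)
}

#' Assemble a multilocus dataset from in-memory pieces
#'
#' @param loci Named list of `locus_alignment` objects (same individual set).
#' @param popmap data.frame with `individual`, `population`, `group`.
#' @param outgroups Optional named list (by locus) of outgroup haplotype
#'   character matrices.
#' @param meta Optional provenance list (seed, scenario, ...).
#' @export
multilocus_dataset <- function(loci, popmap, outgroups = NULL, meta = list()) {
  stopifnot(length(loci) >= 1)
  if (is.null(names(loci)))
    names(loci) <- vapply(loci, function(a) a$locus_name, "")
  inds <- lapply(loci, function(a) sort(unique(a$individuals)))
  if (length(unique(inds)) != 1)
    stop("all loci must cover the same set of individuals")
  missing <- setdiff(inds[[1]], popmap$individual)
  if (length(missing) > 0)
    stop("individual(s) missing from population map: ",
         paste(missing, collapse = ", "))
  popmap <- popmap[popmap$individual %in% inds[[1]], , drop = FALSE]
  structure(list(loci = loci, popmap = popmap, outgroups = outgroups,
                 meta = meta),
            class = "multilocus_dataset")
}

#' @export
print.multilocus_dataset <- function(x, ...) {
  cat("multilocus_dataset: ", length(x$loci), " loci, ",
      length(unique(x$popmap$individual)), " individuals, ",
      length(unique(x$popmap$population)), " populations\n", sep = "")
  for (a in x$loci) print(a)
  invisible(x)
}

.code_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  # standard code, indexed by codon string
  if (is.null(.code_env$tab)) {
    bases <- c("T", "C", "A", "G")
    aas <- strsplit(paste0(
      "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
      "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
    codons <- character(64)
    i <- 0
    for (b1 in bases) for (b2 in bases) for (b3 in bases) {
      i <- i + 1
      codons[i] <- paste0(b1, b2, b3)
    }
    .code_env$tab <- setNames(aas, codons)
  }
  .code_env$tab
}

translate_codon <- function(codon) unname(genetic_code()[codon])

# fraction of the 3 possible single-base changes at codon position p (1..3)
# that are synonymous (Nei-Gojobori equal-pathway counting)
syn_fraction <- function(codon, p) {
  code <- genetic_code()
  aa <- code[[codon]]
  alt <- setdiff(c("A", "C", "G", "T"), substr(codon, p, p))
  nsyn <- 0
  for (b in alt) {
    c2 <- codon
    substr(c2, p, p) <- b
    if (code[[c2]] == aa) nsyn <- nsyn + 1
  }
  nsyn / 3
}

consensus_seq <- function(aln) {
  apply(aln$seqs, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return("-")
    tb <- sort(table(col), decreasing = TRUE)
    top <- names(tb)[tb == max(tb)]
    sort(top)[1]
  })
}

#' Classify alignment sites into silent / synonymous / replacement categories
#'
#' Intronic (non-exon) unmasked columns count 1.0 silent site each. Each
#' unmasked exon position in a complete, fully unmasked codon contributes
#' fractional synonymous and replacement site counts by enumerating the three
#' possible single-base changes in the codon context of the majority
#' consensus (Nei-Gojobori counting). Codons containing a masked column are
#' excluded and contribute 0 sites; codons whose consensus is a stop codon
#' raise a warning and are counted as non-coding (intron-like). Polymorphic
#' columns additionally receive a variant classification (the observed
#' change, evaluated in the consensus context).
#'
#' @param aln A `locus_alignment`.
#' @return A list with `counts` (n_total, n_intron, n_synonymous, n_silent,
#'   n_replacement) and `sites`, a per-column data.frame with the category
#'   (`intron` / `coding` / `excluded` / `masked`), the synonymous site
#'   fraction, and the variant class (`syn` / `rep` / `silent`, NA for
#'   monomorphic columns).
#' @export
classify_sites <- function(aln) {
  L <- aln$aligned_length
  cons <- consensus_seq(aln)
  category <- ifelse(aln$mask, "masked", "intron")
  syn_w <- rep(NA_real_, L)
  code_pos <- rep(NA_integer_, L) # position within codon
  codon_of <- rep(NA_integer_, L)
  codon_id <- 0
  if (nrow(aln$exons) > 0) {
    for (e in seq_len(nrow(aln$exons))) {
      st <- aln$exons$start[e] + aln$exons$frame[e]
      en <- aln$exons$end[e]
      if (en <= st) next
      starts <- seq(st, en - 3, by = 3)
      for (cs in starts) {
        codon_id <- codon_id + 1
        cols <- (cs + 1):(cs + 3) # 1-based
        if (any(aln$mask[cols])) {
          category[cols][!aln$mask[cols]] <- "excluded"
          next
        }
        codon <- paste(cons[cols], collapse = "")
        if (translate_codon(codon) == "*") {
          warning("locus ", aln$locus_name, ": stop codon in reference frame at ",
                  cs, "; counted as non-coding")
          next # stays "intron"
        }
        for (p in 1:3) {
          category[cols[p]] <- "coding"
          syn_w[cols[p]] <- syn_fraction(codon, p)
          code_pos[cols[p]] <- p
          codon_of[cols[p]] <- codon_id
        }
      }
    }
  }
  # per-variant classification at polymorphic columns
  variant <- rep(NA_character_, L)
  for (j in which(!aln$mask)) {
    col <- aln$seqs[, j]
    ub <- unique(col)
    if (length(ub) < 2) next
    if (category[j] == "intron") { variant[j] <- "silent"; next }
    if (category[j] != "coding") next
    tb <- sort(table(col), decreasing = TRUE)
    b1 <- names(tb)[1]; b2 <- names(tb)[2]
    # consensus codon context with the two observed bases at this position
    p <- code_pos[j]
    cols <- (j - p + 1):(j - p + 3)
    codon1 <- paste(replace(cons[cols], p, b1), collapse = "")
    codon2 <- paste(replace(cons[cols], p, b2), collapse = "")
    variant[j] <- if (translate_codon(codon1) == translate_codon(codon2))
      "syn" else "rep"
  }
  n_total <- sum(!aln$mask)
  n_intron <- sum(category == "intron")
  n_syn <- sum(syn_w[category == "coding"], na.rm = TRUE)
  n_rep <- sum(1 - syn_w[category == "coding"], na.rm = TRUE)
  counts <- list(n_total = n_total, n_intron = n_intron,
                 n_synonymous = n_syn, n_silent = n_intron + n_syn,
                 n_replacement = n_rep)
  sites <- data.frame(col = seq_len(L) - 1L, category = category,
                      syn_weight = syn_w, variant_class = variant)
  list(counts = counts, sites = sites, consensus = cons)
}

hamming_to_set <- function(hap, refmat, ok) {
  # min Hamming distance from hap to any row of refmat over columns ok
  if (is.null(refmat) || nrow(refmat) == 0) return(Inf)
  min(vapply(seq_len(nrow(refmat)), function(r) {
    sum(hap[ok] != refmat[r, ok])
  }, 0))
}

#' Detect and exclude interspecific F1 hybrids
#'
#' Per locus, each haplotype of each individual is assigned to the species
#' whose reference set contains its nearest neighbor (Hamming distance on
#' unmasked columns). An individual is flagged F1-like when its two
#' haplotypes assign to two different species at `min_loci` or more loci
#' (default: all loci). Loci with a tied nearest-species assignment are
#' uninformative and never count toward `min_loci`. Flagged individuals are
#' removed from the returned dataset.
#'
#' @param ds A `multilocus_dataset`.
#' @param refs Named list of species; each species is a named list (by locus)
#'   of haplotype character matrices. One entry should represent the focal
#'   species.
#' @param min_loci Number of species-discordant loci required for a flag.
#' @return List with `report` (class `hybrid_report`) and `dataset`, the
#'   filtered `multilocus_dataset`.
#' @export
flag_hybrids <- function(ds, refs, min_loci = NULL) {
  stopifnot(length(refs) >= 2)
  if (is.null(min_loci)) min_loci <- length(ds$loci)
  species <- names(refs)
  rows <- list()
  for (nm in names(ds$loci)) {
    aln <- ds$loci[[nm]]
    ok <- !aln$mask
    refmats <- lapply(refs, function(sp) {
      m <- sp[[nm]]
      if (is.character(m) && !is.matrix(m)) m <- do.call(rbind, strsplit(toupper(m), ""))
      m
    })
    for (ind in unique(aln$individuals)) {
      hrows <- which(aln$individuals == ind)
      assign2 <- character(2)
      tie <- FALSE
      for (h in 1:2) {
        d <- vapply(refmats, function(m) hamming_to_set(aln$seqs[hrows[h], ], m, ok), 0)
        mn <- min(d)
        winners <- species[d == mn]
        if (length(winners) > 1) { tie <- TRUE; assign2[h] <- NA } else assign2[h] <- winners
      }
      rows[[length(rows) + 1]] <- data.frame(
        individual = ind, locus = nm, hap1_species = assign2[1],
        hap2_species = assign2[2], informative = !tie,
        discordant = !tie && assign2[1] != assign2[2])
    }
  }
  per_locus <- do.call(rbind, rows)
  agg <- stats::aggregate(discordant ~ individual, per_locus, sum)
  flagged <- agg$individual[agg$discordant >= min_loci]
  report <- structure(list(per_locus = per_locus,
                           n_discordant = setNames(agg$discordant, agg$individual),
                           flagged = flagged, min_loci = min_loci),
                      class = "hybrid_report")
  if (length(flagged) > 0) {
    loci <- lapply(ds$loci, function(aln) {
      keep <- !(aln$individuals %in% flagged)
      locus_alignment(aln$locus_name, aln$seqs[keep, , drop = FALSE],
                      aln$individuals[keep], aln$exons)
    })
    popmap <- ds$popmap[!(ds$popmap$individual %in% flagged), , drop = FALSE]
    ds <- multilocus_dataset(loci, popmap, ds$outgroups, ds$meta)
  }
  list(report = report, dataset = ds)
}

#' @export
print.hybrid_report <- function(x, ...) {
  cat("hybrid_report: ", length(x$flagged), " individual(s) flagged ",
      "(discordant at >= ", x$min_loci, " loci)\n", sep = "")
  if (length(x$flagged) > 0) cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Subset a dataset to the haplotypes of chosen individuals
#'
#' @param aln A `locus_alignment`.
#' @param individuals Individual ids to keep (NULL keeps all).
#' @keywords internal
subset_alignment <- function(aln, individuals = NULL) {
  if (is.null(individuals)) return(aln)
  keep <- aln$individuals %in% individuals
  if (!any(keep)) stop("no haplotypes left after subsetting")
  locus_alignment(aln$locus_name, aln$seqs[keep, , drop = FALSE],
                  aln$individuals[keep], aln$exons)
}
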