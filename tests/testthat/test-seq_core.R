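test_that("loading round-trips FASTA, popmap and annotation with gap masking", {
  dir <- withr::local_tempdir()
  writeLines(c(">I1_h1", "ACGTAC", ">I1_h2", "ACGTAC",
               ">I2_h1", "ACG-AC", ">I2_h2", "ACGTAC"),
             file.path(dir, "locA.fasta"))
  writeLines(c(">I1_h1", "TTTT", ">I1_h2", "TTTT",
               ">I2_h1", "TTCT", ">I2_h2", "TTTT"),
             file.path(dir, "locB.fasta"))
  writeLines(c("individual\tpopulation\tgroup",
               "I1\tP1\tsumatra_malay", "I2\tP1\tsumatra_malay"),
             file.path(dir, "popmap.tsv"))
  writeLines(c("locus\tstart\tend\tframe", "locA\t0\t6\t0"),
             file.path(dir, "annotation.tsv"))
  ds <- load_dataset(c(locA = file.path(dir, "locA.fasta"),
                       locB = file.path(dir, "locB.fasta")),
                     file.path(dir, "popmap.tsv"),
                     file.path(dir, "annotation.tsv"))
  expect_length(ds$loci, 2)
  expect_equal(nrow(ds$loci$locA$seqs), 4)
  # the gap column is masked for all haplotypes of that locus
  expect_equal(which(ds$loci$locA$mask), 4)
  expect_equal(classify_sites(ds$loci$locA)$counts$n_total, 5)
  expect_false(any(ds$loci$locB$mask))
})

test_that("load errors name the offending sequence or individual", {
  dir <- withr::local_tempdir()
  writeLines(c(">I1_h1", "ACGT", ">I1_h2", "ACG",
               ">I2_h1", "ACGT", ">I2_h2", "ACGT"),
             file.path(dir, "locA.fasta"))
  writeLines(c("individual\tpopulation\tgroup", "I1\tP1\tborneo",
               "I2\tP1\tborneo"),
             file.path(dir, "popmap.tsv"))
  expect_error(load_dataset(c(locA = file.path(dir, "locA.fasta")),
                            file.path(dir, "popmap.tsv")), "I1")
  writeLines(c(">I1_h1", "ACGT", ">I1_h2", "ACGT",
               ">I3_h1", "ACGT", ">I3_h2", "ACGT"),
             file.path(dir, "locB.fasta"))
  expect_error(load_dataset(c(locB = file.path(dir, "locB.fasta")),
                            file.path(dir, "popmap.tsv")), "I3")
})

test_that("ambiguity codes are rejected and ids must parse", {
  expect_error(locus_alignment("x", c("ACGN", "ACGT"), c("I1", "I1")),
               "ambiguity")
  expect_error(sundapop:::parse_hap_ids(c("I1_h1", "I1_hX")), "I1_hX")
})

test_that("site classification gives Nei-Gojobori fractional counts", {
  # all-intron locus: every unmasked site is silent
  a <- locus_alignment("intr", c(strrep("A", 50), strrep("A", 50)),
                       c("I1", "I1"))
  cl <- classify_sites(a)
  expect_equal(cl$counts$n_silent, 50)
  expect_equal(cl$counts$n_synonymous, 0)
  # single codon TTT (Phe): 1/3 synonymous site, 8/3 replacement
  b <- locus_alignment("cod", c("TTT", "TTT"), c("I1", "I1"),
                       data.frame(start = 0, end = 3, frame = 0))
  clb <- classify_sites(b)
  expect_equal(clb$counts$n_synonymous, 1 / 3, tolerance = 1e-12)
  expect_equal(clb$counts$n_replacement, 8 / 3, tolerance = 1e-12)
  # codon with a masked column contributes nothing
  cc <- locus_alignment("msk", c("TTTAAA", "TT-AAA"), c("I1", "I1"),
                        data.frame(start = 0, end = 6, frame = 0))
  clc <- classify_sites(cc)
  expect_equal(clc$counts$n_synonymous, sundapop:::syn_fraction("AAA", 1) +
                 sundapop:::syn_fraction("AAA", 2) +
                 sundapop:::syn_fraction("AAA", 3))
  expect_true(all(clc$sites$category[1:2] == "excluded"))
})

test_that("classification totals equal the sum of per-codon and intron parts", {
  for (seed in 1:5) {
    aln <- random_alignment(n_ind = 3, L = 60, seed = seed)
    aln$exons <- data.frame(start = c(6, 30), end = c(21, 54), frame = c(0, 0))
    cl <- suppressWarnings(classify_sites(aln))
    with(cl$counts, {
      expect_equal(n_silent, n_intron + n_synonymous, tolerance = 1e-9)
      expect_lte(n_silent + n_replacement, n_total + 1e-9)
    })
    coding <- cl$sites$category == "coding"
    expect_equal(sum(cl$sites$syn_weight[coding]) +
                   sum(1 - cl$sites$syn_weight[coding]),
                 sum(coding), tolerance = 1e-9)
  }
})

test_that("masking is idempotent and statistics ignore haplotype order", {
  aln <- random_alignment(n_ind = 4, L = 40, seed = 3)
  aln$seqs[2, 5] <- "-"
  aln2 <- locus_alignment(aln$locus_name, aln$seqs, aln$individuals)
  expect_equal(aln2$mask,
               locus_alignment("x", aln2$seqs, aln2$individuals)$mask)
  st1 <- summary_stats(aln2)
  perm <- c(3, 4, 1, 2, 7, 8, 5, 6)
  aln3 <- locus_alignment("x", aln2$seqs[perm, ], aln2$individuals[perm])
  st2 <- summary_stats(aln3)
  expect_equal(st1$pi, st2$pi)
  expect_equal(st1$Hd, st2$Hd)
  expect_equal(st1$S, st2$S)
})

test_that("stop codons in the reference frame downgrade to non-coding", {
  a <- locus_alignment("stp", c("TAAAAA", "TAAAAA"), c("I1", "I1"),
                       data.frame(start = 0, end = 6, frame = 0))
  expect_warning(cl <- classify_sites(a), "stop codon")
  expect_equal(cl$sites$category[1:3], rep("intron", 3))
})

test_that("hybrid flagging finds exactly the planted F1 and filters it", {
  gen <- generate_dataset(scenario_paper_like(), seed = 42)
  hy <- flag_hybrids(gen$dataset, gen$refs)
  expect_equal(hy$report$flagged, gen$truth$hybrid_individual)
  expect_equal(nrow(hy$dataset$loci[[1]]$seqs),
               2 * (length(unique(gen$dataset$popmap$individual)) - 1))
})

test_that("hybrid flagging never flags against the focal species itself", {
  ds <- sim_two_pop_dataset(n_ind_per_pop = 4, n_loci = 2, seed = 5)
  self_refs <- list(
    focal = lapply(ds$loci, function(a) a$seqs),
    other = lapply(ds$loci, function(a)
      matrix("A", 2, a$aligned_length))) # distant constant dummy
  # all haplotypes are closest to the focal set (distance 0)
  hy <- flag_hybrids(ds, self_refs)
  expect_length(hy$report$flagged, 0)
  expect_identical(nrow(hy$dataset$loci[[1]]$seqs), nrow(ds$loci[[1]]$seqs))
})
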