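test_that("the study scenario reproduces the sampling design", {
  sc <- scenario_paper_like()
  expect_equal(sc$populations$size, c(12, 12, 12, 12, 12, 6, 12))
  expect_equal(sum(sc$populations$size), 78)
  expect_equal(sc$loci$length, c(1111, 1229, 1248, 1075, 1277))
  expect_equal(sum(sc$loci$length), 5940)
  gen <- generate_dataset(sc, seed = 3)
  ds <- gen$dataset
  expect_length(ds$loci, 5)
  expect_equal(nrow(ds$loci[[1]]$seqs), 156)
  expect_equal(length(unique(ds$popmap$individual)), 78)
  expect_false(is.na(gen$truth$hybrid_individual))
})

test_that("generated datasets survive a disk round-trip through load_dataset", {
  dir <- withr::local_tempdir()
  gen <- generate_dataset(scenario_paper_like(), seed = 5, out_dir = dir)
  fas <- setNames(file.path(dir, paste0(names(gen$dataset$loci), ".fasta")),
                  names(gen$dataset$loci))
  ds2 <- load_dataset(fas, file.path(dir, "popmap.tsv"),
                      file.path(dir, "annotation.tsv"))
  expect_identical(lapply(ds2$loci, function(a) unname(a$seqs)),
                   lapply(gen$dataset$loci, function(a) unname(a$seqs)))
  expect_identical(sort(ds2$popmap$individual),
                   sort(gen$dataset$popmap$individual))
  # manifest round-trips the planted truth
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$hybrid_individual, gen$truth$hybrid_individual)
  expect_equal(man$params$theta_b, 11.2873)
})

test_that("generation is byte-identical under the same seed", {
  g1 <- generate_dataset(scenario_paper_like(), seed = 11)
  g2 <- generate_dataset(scenario_paper_like(), seed = 11)
  expect_identical(g1$dataset$loci[[3]]$seqs, g2$dataset$loci[[3]]$seqs)
  g3 <- generate_dataset(scenario_paper_like(), seed = 12)
  expect_false(identical(g1$dataset$loci[[3]]$seqs, g3$dataset$loci[[3]]$seqs))
})

test_that("two-pop recovery scenario echoes its inputs in the truth manifest", {
  sc <- scenario_two_pop(n_loci = 4, n_per_group = 5)
  gen <- generate_dataset(sc, seed = 2)
  expect_equal(gen$truth$params$theta_sm, 4)
  expect_true(is.na(gen$truth$hybrid_individual))
  expect_equal(length(gen$dataset$loci), 4)
  expect_equal(nrow(gen$dataset$loci[[1]]$seqs), 20)
})

test_that("mk_fixture returns the five printed tables", {
  fx <- mk_fixture()
  expect_equal(nrow(fx), 5)
  expect_equal(fx$locus, c("GapC", "GBSSI", "PgiC", "SBE2", "SODH"))
  gb <- fx[fx$locus == "GBSSI", ]
  expect_equal(c(gb$fixed_syn, gb$fixed_rep, gb$poly_syn, gb$poly_rep),
               c(12, 1, 23, 29))
  expect_true(all(fx[, -1] >= 0))
  expect_true(all(fx[, -1] == round(fx[, -1])))
})

test_that("admixed populations draw haplotypes from both sides", {
  gen <- generate_dataset(scenario_paper_like(), seed = 8)
  hd <- do.call(rbind, gen$truth$hap_deme)
  pop <- gen$dataset$popmap$population[match(rownames(hd),
                                             gen$dataset$popmap$individual)]
  pure_sm <- hd[pop %in% c("Seremban", "Mersing", "NanjakMakmur"), ]
  expect_true(all(pure_sm == 1))
  pure_b <- hd[pop %in% c("SariBumiKusuma", "Sumalindo"), ]
  expect_true(all(pure_b == 2))
  adm <- hd[pop %in% c("Asialog", "ITCIKaryaUtama"), ]
  expect_true(any(adm == 1) && any(adm == 2))
})
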