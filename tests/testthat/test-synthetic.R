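test_that("generators are pure functions of their seed", {
  a <- make_trna(trna_spec(seed = 77))
  b <- make_trna(trna_spec(seed = 77))
  expect_identical(a$record$sequence, b$record$sequence)
  expect_identical(a$ss, b$ss)
  c <- make_trna(trna_spec(seed = 78))
  expect_false(identical(a$record$sequence, c$record$sequence))

  g1 <- make_genome(genome_spec(n_trnas = 10, n_cds = 20, seed = 5))
  g2 <- make_genome(genome_spec(n_trnas = 10, n_cds = 20, seed = 5))
  expect_identical(g1$ss, g2$ss)
  expect_identical(g1$bundle$cds, g2$bundle$cds)

  o1 <- make_orthogroups(2, seed = 9)
  o2 <- make_orthogroups(2, seed = 9)
  expect_identical(o1[[1]]$proteins, o2[[1]]$proteins)

  r1 <- make_replicates(c(1, 5), sd = 0.5, seed = 3)
  r2 <- make_replicates(c(1, 5), sd = 0.5, seed = 3)
  expect_identical(r1, r2)
})

test_that("invalid tRNA specs are rejected", {
  expect_error(trna_spec(as_pairs = 8), "between 2 and 7")
  expect_error(trna_spec(as_pairs = 5, unpinned = "top"), "as_pairs == 4")
  expect_error(trna_spec(anticodon = "CCAA"), "triplet")
})

test_that("genome mixtures and plans control the tRNA classes drawn", {
  pure <- make_genome(genome_spec(
    n_trnas = 30, class_mixture = c(AS5 = 1), n_cds = 5, seed = 61))
  expect_true(all(pure$bundle$trnas$as_bin == "AS5"))

  planned <- make_genome(genome_spec(
    n_trnas = 5, n_cds = 5,
    trna_plan = data.frame(isotype = "Trp", anticodon = "CCA",
                           as_bin = "AS4_top", n = 3),
    exclude_species = data.frame(isotype = "Trp", anticodon = "CCA"),
    seed = 62))
  trp <- planned$bundle$trnas
  trp <- trp[trp$isotype == "Trp" & trp$anticodon == "CCA", ]
  expect_equal(nrow(trp), 3)
  expect_true(all(trp$as_bin == "AS4_top"))

  expect_error(genome_spec(code_label = "trp_uga", uga_stop_fraction = 0.2),
               "cannot use UGA")
})

test_that("replicate tables honour their group means", {
  exact <- make_replicates(c(2, 4, 8), sd = 0, n_per_group = 3, seed = 1)
  expect_equal(as.numeric(tapply(exact$value, exact$group, mean)),
               c(2, 4, 8))

  # well-separated means at n = 3: Welch detects the difference
  set.seed(63)
  hits <- vapply(1:50, function(k) {
    d <- make_replicates(c(0, 10), sd = 1, n_per_group = 3, seed = k)
    welch_t(d$value[d$group == "g1"], d$value[d$group == "g2"])$p_value
  }, 1)
  expect_gte(mean(hits < 0.05), 0.95)
})

test_that("simulated fixture directories carry their planted truth", {
  dir <- withr::local_tempdir()
  simulate_fixtures(dir, n_genomes = 6, n_trnas = 6, n_cds = 8,
                    n_families = 2, seed = 99)
  expect_true(file.exists(file.path(dir, "genomes.tsv")))
  expect_true(file.exists(file.path(dir, "trnas.ss")))
  truth <- utils::read.table(file.path(dir, "truth", "genomes.tsv"),
                             header = TRUE, sep = "\t")
  expect_equal(nrow(truth), 7)  # 6 standard + 1 reassigned genome
  inputs <- load_genome_inputs(dir)
  expect_length(inputs$bundles, 7)
  # planted Trp(CCA) variant strata are recovered from the parsed records
  for (k in seq_len(nrow(truth))) {
    b <- inputs$bundles[[truth$genome_id[k]]]
    trp <- b$trnas[b$trnas$isotype == "Trp" & b$trnas$anticodon == "CCA", ]
    got <- if (any(trp$as_bin == "AS5") && any(trp$as_bin == "AS4_top"))
      "both"
    else if (any(trp$as_bin == "AS4_top")) "as4_only" else "as5_only"
    expect_equal(got, truth$trp_variant[k], info = truth$genome_id[k])
  }
})
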