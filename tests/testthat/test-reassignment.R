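test_that("conceptual translation follows the declared code", {
  std <- genetic_code("standard")
  trp <- genetic_code("trp_uga")
  expect_equal(std$stops, c("UAA", "UAG", "UGA"))
  expect_equal(trp$stops, c("UAA", "UAG"))
  expect_equal(unname(trp$codons["UGA"]), "W")
  expect_length(std$codons, 64)

  expect_equal(translate_cds("AUGUGGUAA", std), "MW")
  expect_equal(translate_cds("AUGUGAUAA", trp), "MW")
  p <- translate_cds("AUGUGAUAA", std)
  expect_equal(as.character(p), "M")
  expect_equal(attr(p, "premature_stop"), 2)
  expect_equal(translate_cds("", std), "")
  expect_error(translate_cds("AUGA", std), "divisible by 3")
})

test_that("translation under trp_uga is never shorter than under standard", {
  set.seed(31)
  std <- genetic_code("standard"); trp <- genetic_code("trp_uga")
  for (k in 1:100) {
    cds <- paste(sample(names(std$codons), sample(5:30, 1), replace = TRUE),
                 collapse = "")
    expect_gte(nchar(translate_cds(cds, trp)), nchar(translate_cds(cds, std)))
  }
})

test_that("conserved C-terminus filter inspects exactly the last k columns", {
  rows <- c(a = "MKLV-WEPT", b = "MKLVAWEPT")
  expect_true(conserved_cterm_filter(rows, k = 4))
  expect_false(conserved_cterm_filter(rows, k = 5))
  expect_false(conserved_cterm_filter(c(a = "MKLVW-", b = "MKLVWE"), k = 5))
  expect_true(conserved_cterm_filter(rows, k = 0))
  expect_error(conserved_cterm_filter(rows, k = 20), "shorter than k")
})

test_that("C-terminal extension measurement is exact and one-sided", {
  aln <- c(r1 = "MKLVWE----", r2 = "MKLVWE----", target = "MKLVWEAGHW")
  expect_equal(cterm_extension(aln, "target"), 4L)
  co <- c(r1 = "MKLVWE", r2 = "MKLVWE", target = "MKLVWE")
  expect_equal(cterm_extension(co, "target"), 0L)
  trunc <- c(r1 = "MKLVWE", r2 = "MKLVWE", target = "MKLV--")
  expect_equal(cterm_extension(trunc, "target"), 0L)
  expect_error(cterm_extension(co, "absent"), "target row absent")
  # max-over-references end column is the default
  ragged <- c(r1 = "MKLVW-", r2 = "MKLVWE", target = "MKLVWE")
  expect_equal(cterm_extension(ragged, "target"), 0L)
  expect_equal(cterm_extension(ragged, "target", reference_end = "min"), 1L)
})

test_that("center-star alignment reduces to pairwise and keeps rows intact", {
  ident <- center_star_msa(c(a = "MKWE", b = "MKWE", c = "MKWE"))
  expect_true(all(!grepl("-", ident$rows)))

  two <- center_star_msa(c(x = "MKLWE", y = "MKWE"))
  ref <- nw_align("MKLWE", "MKWE")
  expect_equal(unname(two$rows), c(ref$aligned_a, ref$aligned_b))

  set.seed(32)
  prots <- vapply(1:4, function(i)
    paste(sample(LETTERS[1:20], 30, replace = TRUE), collapse = ""), "")
  msa <- center_star_msa(prots)
  expect_length(unique(nchar(msa$rows)), 1)
  for (k in seq_along(prots))
    expect_equal(gsub("-", "", msa$rows[[k]]), prots[k])
})

test_that("planted extensions and planted gaps are recovered from families", {
  lens <- c(1L, 2L, 7L, 20L, 50L)
  og <- make_orthogroups(length(lens), n_members = 5, extension_plan = lens,
                         seed = 33)
  for (k in seq_along(og)) {
    v <- validate_orthogroup(og[[k]]$proteins, og[[k]]$codes)
    expect_true(v$filter_pass)
    expect_equal(v$extension, lens[k])
  }
  clean <- make_orthogroups(3, n_members = 4, extension_plan = 0, seed = 34)
  for (f in clean)
    expect_equal(validate_orthogroup(f$proteins, f$codes)$extension, 0L)
  gapped <- make_orthogroups(2, n_members = 4, cterm_gap_families = 1,
                             seed = 35)
  expect_false(validate_orthogroup(gapped[[1]]$proteins,
                                   gapped[[1]]$codes)$filter_pass)
  expect_true(validate_orthogroup(gapped[[2]]$proteins,
                                  gapped[[2]]$codes)$filter_pass)
})

test_that("suppressor check keys on the UCA anticodon of retained records", {
  with_sup <- fake_classification("g1", "Trp", c("CCA", "UCA"),
                                  c("AS5", "AS5"))
  expect_true(suppressor_check(with_sup))
  expect_false(suppressor_check(fake_classification("g1", "Trp", "CCA",
                                                    "AS4_top")))
  expect_false(suppressor_check(with_sup[0, ]))
})

test_that("evidence summary renders the three verdicts", {
  sup <- summarize_evidence(0, 0, TRUE, rf2_present = FALSE)
  expect_equal(sup$verdict, "supported")

  codetta_only <- summarize_evidence(0, 0, FALSE,
                                     codetta_support_columns = 150,
                                     rf2_present = FALSE)
  expect_equal(codetta_only$verdict, "supported")

  contra <- summarize_evidence(30, 0, TRUE)
  expect_equal(contra$verdict, "contradicted")
  expect_match(contra$reasons[1], "UGA terminates")

  ext <- summarize_evidence(0, 2, TRUE)
  expect_equal(ext$verdict, "contradicted")

  inconclusive <- summarize_evidence(0, 0, FALSE,
                                     codetta_support_columns = 40)
  expect_equal(inconclusive$verdict, "inconclusive")
})

test_that("orthogroup FASTA round-trips member codes and genome tags", {
  og <- make_orthogroups(2, n_members = 4, target_genome = "g9", seed = 36)
  dir <- withr::local_tempdir()
  write_orthogroup_fasta(og, dir)
  back <- read_orthogroup_fasta(sort(list.files(dir, full.names = TRUE)))
  expect_equal(back[[1]]$proteins, og[[1]]$proteins)
  expect_equal(back[[1]]$codes, og[[1]]$codes)
  expect_equal(back[[2]]$genomes, og[[2]]$genomes)
})
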