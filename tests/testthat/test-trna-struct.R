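test_that("pair_map matches hand-checkable nestings and rejects bad input", {
  expect_equal(pair_map(">>..<<"),
               cbind(i = c(1L, 2L), j = c(6L, 5L)))
  expect_equal(nrow(pair_map("......")), 0)
  expect_equal(nrow(pair_map(".......")), 0)  # no-pair tRNA-like case
  expect_error(pair_map(">>.<"), "unmatched '>' at index 1")
  expect_error(pair_map(".<"), "unmatched '<' at index 2")
  expect_error(pair_map(">x<"), "invalid structure character")
})

test_that("pair_map agrees with a brute-force innermost-pair matcher", {
  set.seed(101)
  for (k in 1:300) {
    s <- random_structure(sample(4:40, 1))
    expect_equal(unname(pair_map(s)), unname(brute_pair_map(s)), info = s)
  }
})

test_that("-ss parser handles notes, undetermined types and bad blocks", {
  good <- make_trna(trna_spec(seed = 3))
  undet <- paste0("gX.trna2 (5-80)\tLength: 10 bp\n",
                  "Type: Undet\tAnticodon: NNN at 3-5 (7-9)\tScore: 20.1\n",
                  "Seq: AANNNAAAAA\nStr: ..........\n")
  pseudo <- sub("Seq:", "Possible pseudogene:  HMM Sc=12\nSeq:", good$ss)
  pseudo <- gsub("synth.trna1", "gY.trna3", pseudo)
  broken <- "gZ.trna4 (1-4)\tLength: 4 bp\nType: Trp\tAnticodon: CCA at 1-3 (1-3)\nSeq: CCAA\nStr: >>.\n"
  res <- parse_ss_records(paste(good$ss, undet, pseudo, broken, sep = "\n"))
  expect_length(res$records, 3)
  expect_equal(nrow(res$errors), 1)
  expect_match(res$errors$message, "length")
  expect_true(res$records[[2]]$undetermined)
  expect_true(res$records[[3]]$pseudogene)
  expect_equal(res$records[[2]]$genome_id, "gX")
})

test_that("writer/parser round-trips synthetic records field-for-field", {
  set.seed(7)
  for (k in 1:60) {
    sp <- trna_spec(as_pairs = sample(2:7, 1),
                    plant_A9C = k %% 2 == 0, plant_G24A = k %% 3 == 0,
                    seed = k)
    sim <- make_trna(sp, record_id = sprintf("g%02d.trna%d", k, k))
    back <- parse_ss_records(sim$ss)
    expect_equal(nrow(back$errors), 0)
    r <- back$records[[1]]
    for (f in c("record_id", "genome_id", "isotype", "anticodon",
                "sequence", "structure", "anticodon_start", "pseudogene",
                "undetermined"))
      expect_identical(r[[f]], sim$record[[f]], info = f)
  }
})

test_that("arm annotation recovers the planted cloverleaf", {
  canonical <- make_trna(trna_spec(seed = 11))
  arm <- annotate_arms(canonical$record)
  expect_equal(nrow(arm$acceptor), 7)
  expect_equal(nrow(arm$d_stem), 4)
  expect_equal(nrow(arm$anticodon_stem), 5)
  expect_equal(nrow(arm$t_stem), 5)
  expect_equal(arm$al_length, 7L)
  sp <- as_span(arm)
  expect_equal(c(sp$span5, sp$span3, sp$bin_length), c(5L, 5L, 5L))

  top <- annotate_arms(make_trna(trna_spec(as_pairs = 4, unpinned = "top",
                                           seed = 11))$record)
  expect_equal(nrow(top$anticodon_stem), 4)
  expect_equal(top$al_length, 7L)
  expect_equal(as_span(top)$bin_length, 4L)

  bottom <- annotate_arms(make_trna(trna_spec(as_pairs = 4,
                                              unpinned = "bottom",
                                              seed = 11))$record)
  expect_equal(nrow(bottom$anticodon_stem), 4)
  expect_equal(bottom$al_length, 9L)
})

test_that("a single bulged nucleotide widens the span by one", {
  for (side in c("five_prime", "three_prime")) {
    sim <- make_trna(trna_spec(as_pairs = 4, bulge = side, seed = 5))
    arm <- annotate_arms(sim$record)
    sp <- as_span(arm)
    expect_equal(nrow(arm$anticodon_stem), 4)   # four pairs...
    expect_equal(sp$bin_length, 5L)             # ...bin as 5 bp
    expect_equal(sort(c(sp$span5, sp$span3)), c(4L, 5L))
  }
})

test_that("canonical positions map planted substitutions and degenerate linkers", {
  a9c <- classify(make_trna(trna_spec(plant_A9C = TRUE, seed = 2))$record)
  expect_identical(a9c$pos9, "C")
  expect_true(a9c$flag_A9C)
  g24a <- classify(make_trna(trna_spec(plant_G24A = TRUE, seed = 2))$record)
  expect_identical(g24a$pos24, "A")
  expect_true(g24a$flag_G24A)

  # hand-built record with a 1-nt linker between acceptor and D stem:
  # position 9 cannot be mapped
  strc <- paste0(">>>>", ".", ">>>", ".....", "<<<", "..",
                 ">>>", ".....", "<<<", "..", "<<<<")
  seqc <- paste(rep("A", nchar(strc)), collapse = "")
  rec <- trna_record("h.trna1", seqc, strc, "Trp", "AAA",
                     anticodon_start = 23, validate = FALSE)
  arm <- annotate_arms(rec)
  pos <- canonical_positions(rec, arm)
  expect_true(is.na(pos$pos9))
  expect_equal(pos$pos8, 5L)
})

test_that("classify reproduces the unpinned-pair notation and blasto flag", {
  c27a <- classify(make_trna(trna_spec("Trp", "CCA", as_pairs = 4,
                                       unpinned = "top",
                                       unpinned_bases = c("A", "G"),
                                       seed = 9))$record)
  expect_equal(c27a$as_bin, "AS4_top")
  expect_equal(c27a$unpinned_pair, "A:G")
  expect_true(c27a$blasto_like)

  hirsh <- classify(make_trna(trna_spec("Trp", "CCA", as_pairs = 4,
                                        unpinned = "top", plant_G24A = TRUE,
                                        seed = 9))$record)
  expect_equal(hirsh$as_bin, "AS4_top")
  expect_false(hirsh$blasto_like)

  as5 <- classify(make_trna(trna_spec("Trp", "CCA", seed = 9))$record)
  expect_equal(as5$as_bin, "AS5")
  expect_false(as5$blasto_like)
  expect_true(is.na(as5$unpinned_pair))
})

test_that("filter_records excludes with machine-readable reasons", {
  keepers <- make_trna(trna_spec(seed = 1))$record
  pseudo <- make_trna(trna_spec(seed = 2))$record
  pseudo$pseudogene <- TRUE
  undet <- trna_record("u.trna1", "AANNNAA", ".......", "Undet", "NNN", 3,
                       validate = FALSE)
  shifted <- make_trna(trna_spec(seed = 3))$record
  shifted$anticodon_start <- 30L
  shifted$anticodon <- substr(shifted$sequence, 30, 32)
  out <- filter_records(list(keepers, pseudo, undet, shifted))
  expect_length(out$kept, 1)
  expect_equal(out$excluded$reason,
               c("pseudogene", "undetermined", "anticodon_window"))
  # anticodon starting anywhere in 33-35 is retained
  expect_length(filter_records(list(keepers))$kept, 1)
})

test_that("span bin length is at least the paired count, equal iff no bulge", {
  set.seed(13)
  for (k in 1:40) {
    b <- sample(c("none", "five_prime", "three_prime"), 1)
    p <- sample(2:7, 1)
    arm <- annotate_arms(make_trna(trna_spec(as_pairs = p, bulge = b,
                                             seed = k))$record)
    sp <- as_span(arm)
    expect_gte(sp$bin_length, nrow(arm$anticodon_stem))
    expect_equal(sp$bin_length == nrow(arm$anticodon_stem), b == "none")
  }
})
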