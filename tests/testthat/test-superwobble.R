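test_that("readable codons follow the declared pairing rules", {
  expect_equal(readable_codons("CCA", "AS5", "wobble"), "UGG")
  expect_setequal(readable_codons("CCA", "AS4_top", "extended"),
                  c("UGG", "UGA"))
  # C:A pairing needs the 4-bp stem: a 5-bp stem keeps the strict range
  expect_equal(readable_codons("CCA", "AS5", "extended"), "UGG")
  expect_setequal(readable_codons("UCC", "AS5", "superwobble"),
                  c("GGA", "GGG", "GGC", "GGU"))
  expect_setequal(readable_codons("GAA", "AS5", "wobble"),
                  c("UUC", "UUU"))
  expect_setequal(readable_codons("ICG", "AS5", "wobble"),
                  c("CGU", "CGC", "CGA"))
  expect_error(readable_codons("CNA"), "ambiguous")
  expect_error(readable_codons("CIA"), "wobble position")
})

test_that("every readable set contains the strict Watson-Crick codon", {
  set.seed(41)
  rep <- standard_anticodons()
  for (k in 1:60) {
    ac <- rep$anticodon[sample(nrow(rep), 1)]
    strict <- readable_codons(ac, "AS5", "strict")
    for (m in c("wobble", "superwobble", "extended"))
      for (cls in c("AS5", "AS4_top"))
        expect_true(strict %in% readable_codons(ac, cls, m))
  }
})

test_that("coverage distinguishes wobble from extended for C34 tRNAs", {
  # a lone 4-bp-stem Gly tRNA with C34 (anticodon CCC, codons GGG/GGA)
  tr <- data.frame(record_id = "t1", isotype = "Gly", anticodon = "CCC",
                   as_bin = "AS4_top")
  ext <- coverage(tr, "extended")
  expect_true(all(c("GGG", "GGA") %in% names(ext$decoded)))
  wob <- coverage(tr, "wobble")
  expect_true("GGG" %in% names(wob$decoded))
  expect_true("GGA" %in% wob$uncovered_sense)

  # 4-bp-stem elongator Met tRNA misreads AUA (isoleucine) as methionine
  met <- coverage(data.frame(record_id = "m1", isotype = "Met",
                             anticodon = "CAU", as_bin = "AS4_top"),
                  "extended")
  expect_true("AUA" %in% names(met$misread))

  # 4-bp-stem Trp(CCA) reads through the UGA stop codon
  trp <- coverage(data.frame(record_id = "w1", isotype = "Trp",
                             anticodon = "CCA", as_bin = "AS4_top"),
                  "extended")
  expect_true("UGA" %in% names(trp$stop_readthrough))

  empty <- coverage(data.frame(record_id = character(0),
                               isotype = character(0),
                               anticodon = character(0),
                               as_bin = character(0)), "wobble")
  expect_length(empty$uncovered_sense, 61)
})

test_that("coverage is monotone along strict -> wobble -> extended", {
  set.seed(42)
  for (k in 1:60) {
    tr <- random_trna_set(sample(3:10, 1))
    cs <- names(coverage(tr, "strict")$decoded)
    cw <- names(coverage(tr, "wobble")$decoded)
    ce <- names(coverage(tr, "extended")$decoded)
    expect_true(all(cs %in% cw))
    expect_true(all(cw %in% ce))
  }
})

test_that("minimal anticodon sets are exact and monotone across models", {
  strict <- minimal_anticodon_set("strict")
  expect_equal(strict$size, 61)  # one tRNA per sense codon, forced

  sizes <- vapply(c("strict", "wobble", "superwobble", "extended"),
                  function(m) minimal_anticodon_set(m)$size, 1L)
  expect_true(all(diff(sizes) <= 0))

  # witness sets actually cover all sense codons without misreading
  for (m in c("wobble", "extended")) {
    w <- minimal_anticodon_set(m)$witness
    code <- genetic_code()
    covered <- character(0)
    for (r in seq_len(nrow(w))) {
      reads <- readable_codons(w$anticodon[r], w$as_class[r], m)
      reads <- intersect(reads, sense_codons(code))
      expect_true(all(unname(code$codons[reads]) == w$amino_acid[r]))
      covered <- union(covered, reads)
    }
    expect_setequal(setdiff(sense_codons(code), covered), character(0))
  }
})

test_that("per-box brute force confirms the wobble minimum", {
  # independent exhaustive set cover over all (base34, stem class) units
  code <- genetic_code()
  sense <- sense_codons(code)
  total <- 0L
  boxes <- split(sense, paste0(substr(sense, 1, 2), code$codons[sense]))
  for (codons in boxes) {
    prefix <- substr(codons[1], 1, 2)
    aa <- unname(code$codons[codons[1]])
    units <- list()
    for (b34 in c("A", "C", "G", "U", "I")) {
      ac <- paste0(b34, chartr("ACGU", "UGCA", substr(prefix, 2, 2)),
                   chartr("ACGU", "UGCA", substr(prefix, 1, 1)))
      reads <- readable_codons(ac, "AS5", "wobble")
      ok <- !any(reads %in% code$stops |
                 (reads %in% sense & code$codons[reads] != aa))
      if (ok && length(intersect(reads, codons)))
        units[[length(units) + 1]] <- intersect(reads, codons)
    }
    best <- NA
    for (sz in seq_along(units)) {
      for (cmb in utils::combn(length(units), sz, simplify = FALSE)) {
        if (all(codons %in% unlist(units[cmb]))) { best <- sz; break }
      }
      if (!is.na(best)) break
    }
    expect_false(is.na(best))
    total <- total + best
  }
  expect_equal(minimal_anticodon_set("wobble")$size, total)
})
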