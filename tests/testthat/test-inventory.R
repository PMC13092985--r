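test_that("species abundance bins at 0.1% of the tRNA pool", {
  one <- fake_classification("g1", "Gly", "GCC", rep("AS5", 10))
  ab1 <- species_abundance(one)
  expect_equal(ab1$percent_of_total, 100)
  expect_equal(ab1$bin, "high")

  # one singleton among 2000 genes: 0.05%, low abundance
  cl <- rbind(fake_classification("g1", "Gly", "GCC", rep("AS5", 1999)),
              fake_classification("g2", "His", "AUG", "AS5"))
  ab <- species_abundance(cl)
  his <- ab[ab$isotype == "His", ]
  expect_equal(his$percent_of_total, 0.05)
  expect_equal(his$bin, "low")
  expect_equal(sum(ab$percent_of_total), 100)
  expect_error(species_abundance(cl[0, ]), "empty")
})

test_that("stop usage counts terminal codons under the genome's code", {
  b <- genome_bundle("g1", fake_classification("g1", "Trp", "CCA", "AS5"),
                     cds = fake_cds(c("UAA", "UAG", "UGA")))
  su <- stop_usage(b)
  expect_equal(c(su$UAA, su$UAG, su$UGA), c(1L, 1L, 1L))
  expect_equal(round(su$pct_UGA, 1), 33.3)

  # permutation invariance
  b2 <- b; b2$cds <- rev(b2$cds)
  expect_equal(stop_usage(b2)$pct_UGA, su$pct_UGA)

  # trp_uga genome: UGA is not a stop; UGA-terminated CDS are invalid
  bt <- genome_bundle("g2", b$trnas, cds = fake_cds(c("UAA", "UAA")),
                      code_label = "trp_uga")
  expect_equal(stop_usage(bt)$pct_UGA, 0)
  bt$cds <- fake_cds(c("UAA", "UGA"))
  expect_warning(su2 <- stop_usage(bt), "do not end in a stop")
  expect_equal(su2$n_cds_invalid, 1L)
  expect_equal(su2$n_cds_counted, 1L)

  expect_error(stop_usage(genome_bundle("g3", b$trnas)), "no coding")
})

test_that("planted stop-codon fractions are recovered within binomial error", {
  sim <- make_genome(genome_spec(n_cds = 400L, uga_stop_fraction = 0.25,
                                 seed = 51))
  su <- stop_usage(sim$bundle)
  expect_equal(su$n_cds_counted, 400L)
  ci <- qbinom(c(0.025, 0.975), 400, 0.25) / 4  # as a percentage
  expect_gte(su$pct_UGA, ci[1]); expect_lte(su$pct_UGA, ci[2])

  clean <- make_genome(genome_spec(n_cds = 100L, uga_stop_fraction = 0,
                                   code_label = "trp_uga", seed = 52))
  expect_equal(stop_usage(clean$bundle)$UGA, 0L)
})

test_that("4-bp fraction vs genome size recovers a planted correlation", {
  mk <- function(gid, size, frac, n = 50) {
    n4 <- round(frac * n)
    genome_bundle(gid, fake_classification(
      gid, "Gly", "GCC", c(rep("AS4_top", n4), rep("AS5", n - n4))),
      genome_size = size)
  }
  set.seed(53)
  size <- runif(40, 1e6, 8e6)
  frac <- pmin(pmax(0.5 - size / 2e7 + rnorm(40, sd = 0.08), 0), 1)
  bundles <- lapply(seq_along(size), function(k)
    mk(paste0("g", k), size[k], frac[k]))
  res <- fraction_4bp_vs_size(bundles)
  expect_lt(res$r, 0)
  expect_lt(res$p_value, 0.05)
  # interchanged axes give the identical coefficient
  expect_equal(pearson_cor(res$table$frac_4bp, res$table$genome_size)$r,
               res$r)

  flat <- lapply(1:5, function(k) mk(paste0("f", k), k * 1e6, 0.2))
  expect_error(fraction_4bp_vs_size(flat), "zero variance")
})

test_that("deviant-stem fraction vs abundance flags degenerate inputs", {
  all5 <- rbind(fake_classification("g1", "Gly", "GCC", rep("AS5", 5)),
                fake_classification("g1", "Ala", "AGC", rep("AS5", 3)),
                fake_classification("g1", "Trp", "CCA", rep("AS5", 2)))
  expect_error(deviant_fraction_vs_abundance(all5), "zero variance")
  expect_error(
    deviant_fraction_vs_abundance(
      fake_classification("g1", "Gly", "GCC", rep("AS5", 5))),
    ">= 3")

  # planted anti-correlation: rare species carry more deviant stems
  cl <- rbind(
    fake_classification("g1", "Gly", "GCC",
                        c(rep("AS5", 38), rep("AS4_top", 2))),
    fake_classification("g2", "Ala", "AGC",
                        c(rep("AS5", 16), rep("AS4_top", 4))),
    fake_classification("g3", "His", "GUG",
                        c(rep("AS5", 4), rep("AS4_top", 4))),
    fake_classification("g4", "Cys", "GCA",
                        c("AS5", rep("AS4_top", 3))))
  res <- deviant_fraction_vs_abundance(cl)
  expect_lt(res$r, 0)
})

test_that("genome summary aggregates bins and blasto-like counts", {
  tr <- rbind(fake_classification("g1", "Trp", "CCA",
                                  c("AS4_top", "AS5", "OTHER")),
              fake_classification("g1", "Gly", "GCC", "AS4_bottom"))
  tr$blasto_like <- c(TRUE, FALSE, FALSE, FALSE)
  gs <- genome_summary(genome_bundle("g1", tr, fake_cds(c("UAA", "UGA")),
                                     genome_size = 3e6,
                                     order_label = "ord1"))
  expect_equal(gs$n_trna, 4)
  expect_equal(gs$n_as5, 1)
  expect_equal(gs$n_as4, 2)
  expect_equal(gs$n_as4_top, 1)
  expect_equal(gs$n_blasto_trp, 1)
  expect_equal(gs$pct_UGA, 50)
})
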