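#' Simulate a complete fixture directory
#'
#' Builds a synthetic bacterial "world" exercising every pipeline stage
#' and writes it in the input layout consumed by [run_all()]:
#' `genomes.tsv` (metadata incl. rf2 / code-inference columns),
#' `trnas.ss`, per-genome CDS FASTA under `cds/`, tagged orthogroup FASTA
#' under `orthogroups/`, and planted ground truth under `truth/`.
#'
#' Planted conditions:
#' * each standard-code genome carries tRNA-Trp(CCA) genes that are
#'   exclusively 4-bp-stem, exclusively 5-bp-stem, or (rarely) both;
#' * when `uga_effect` is `TRUE`, exclusively-4-bp genomes draw their UGA
#'   stop fraction from a lower range than 5-bp genomes (the association
#'   the per-order comparison should recover);
#' * when `cooccur_effect` is `TRUE`, genomes whose tRNA(CNN) for the
#'   planted codon boxes has a 4-bp stem carry the tRNA(UNN) isoacceptor
#'   with probability `p_unn_as4`, versus `p_unn_as5` otherwise (the
#'   extended-superwobble co-occurrence signal);
#' * one additional genome uses the `trp_uga` code, carries a suppressor
#'   tRNA(UCA), ends no CDS in UGA, and is accompanied by orthogroups
#'   whose reassigned member has no C-terminal extension, so its
#'   reassignment evidence is `supported`.
#'
#' @param dir Output directory (created).
#' @param n_genomes Number of standard-code genomes.
#' @param n_orders Number of taxonomic orders they are spread over.
#' @param n_trnas Background tRNA genes per genome.
#' @param n_cds Coding sequences per genome.
#' @param uga_effect,cooccur_effect Plant the respective effects.
#' @param p_unn_as4,p_unn_as5 tRNA(UNN) carriage probabilities by
#'   tRNA(CNN) stem class.
#' @param n_families Orthogroup families for the reassigned genome.
#' @param extension_plan Planted C-terminal extensions (default none:
#'   clean reassignment evidence).
#' @param seed Integer RNG seed (the whole world is a pure function of
#'   it).
#' @return Invisibly, a list with the metadata and truth tables.
#' @export
simulate_fixtures <- function(dir, n_genomes = 60L, n_orders = 2L,
                              n_trnas = 24L, n_cds = 40L,
                              uga_effect = TRUE, cooccur_effect = TRUE,
                              p_unn_as4 = 0.2, p_unn_as5 = 0.8,
                              n_families = 5L, extension_plan = 0L,
                              seed = 1L) {
  dir.create(file.path(dir, "cds"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    gseeds <- sample.int(.Machine$integer.max - 1L, n_genomes + 2L)
    cooccur_boxes <- data.frame(  # Gly GGG/GGA and Ala GCG/GCA boxes
      aa = c("Gly", "Ala"), anticodon_cnn = c("CCC", "CGC"),
      anticodon_unn = c("UCC", "UGC"))
    # species whose presence must be controlled, not drawn at random
    controlled <- data.frame(
      isotype = c("Trp", rep(cooccur_boxes$aa, 2)),
      anticodon = c("CCA", cooccur_boxes$anticodon_cnn,
                    cooccur_boxes$anticodon_unn))
    meta_rows <- list(); ss_chunks <- list(); truth_rows <- list()
    bundles <- list()
    for (k in seq_len(n_genomes)) {
      gid <- sprintf("g%03d", k)
      order_label <- sprintf("order%d", 1L + (k - 1L) %% n_orders)
      variant <- sample(c("as4_only", "as5_only", "both"), 1,
                        prob = c(0.45, 0.45, 0.1))
      uga_frac <-
        if (!uga_effect) stats::runif(1, 0.05, 0.75)
        else if (variant == "as4_only") stats::runif(1, 0.05, 0.35)
        else stats::runif(1, 0.35, 0.75)
      plan <- switch(variant,
        as4_only = data.frame(isotype = "Trp", anticodon = "CCA",
                              as_bin = "AS4_top", n = 2L),
        as5_only = data.frame(isotype = "Trp", anticodon = "CCA",
                              as_bin = "AS5", n = 2L),
        both = data.frame(isotype = "Trp", anticodon = rep("CCA", 2),
                          as_bin = c("AS4_top", "AS5"), n = c(2L, 2L)))
      for (bx in seq_len(nrow(cooccur_boxes))) {
        cnn_as4 <- stats::runif(1) < 0.5
        plan <- rbind(plan, data.frame(
          isotype = cooccur_boxes$aa[bx],
          anticodon = cooccur_boxes$anticodon_cnn[bx],
          as_bin = if (cnn_as4) "AS4_top" else "AS5", n = 1L))
        p_unn <- if (!cooccur_effect) mean(c(p_unn_as4, p_unn_as5))
                 else if (cnn_as4) p_unn_as4 else p_unn_as5
        if (stats::runif(1) < p_unn)
          plan <- rbind(plan, data.frame(
            isotype = cooccur_boxes$aa[bx],
            anticodon = cooccur_boxes$anticodon_unn[bx],
            as_bin = "AS5", n = 1L))
      }
      gs <- genome_spec(genome_id = gid, n_trnas = n_trnas,
                        trna_plan = plan, exclude_species = controlled,
                        n_cds = n_cds,
                        cds_len_codons = c(30L, 60L),
                        uga_stop_fraction = uga_frac,
                        genome_size = round(stats::runif(1, 2e6, 6e6)),
                        order_label = order_label, seed = gseeds[k])
      sim <- make_genome(gs)
      bundles[[gid]] <- sim$bundle
      ss_chunks[[k]] <- sim$ss
      meta_rows[[k]] <- data.frame(
        genome_id = gid, size_bp = gs$genome_size,
        order_label = order_label, code_label = "standard",
        rf2_present = TRUE, codetta_support_columns = NA_real_)
      truth_rows[[k]] <- data.frame(
        genome_id = gid, order_label = order_label,
        trp_variant = variant, uga_stop_fraction = uga_frac)
      sq <- Biostrings::DNAStringSet(sim$bundle$cds)
      Biostrings::writeXStringSet(
        sq, file.path(dir, "cds", paste0(gid, ".fasta")), width = 80)
    }
    # the reassigned genome: suppressor tRNA(UCA), no UGA stop usage
    gid <- "gre001"
    plan <- data.frame(isotype = c("Trp", "Trp"),
                       anticodon = c("CCA", "UCA"),
                       as_bin = c("AS5", "AS5"), n = c(1L, 1L))
    gs <- genome_spec(genome_id = gid, n_trnas = n_trnas, trna_plan = plan,
                      exclude_species = controlled,
                      n_cds = n_cds, cds_len_codons = c(30L, 60L),
                      uga_stop_fraction = 0, code_label = "trp_uga",
                      genome_size = 1.5e6, order_label = "order_re",
                      seed = gseeds[n_genomes + 1L])
    sim <- make_genome(gs)
    bundles[[gid]] <- sim$bundle
    ss_chunks[[n_genomes + 1L]] <- sim$ss
    meta_rows[[n_genomes + 1L]] <- data.frame(
      genome_id = gid, size_bp = gs$genome_size, order_label = "order_re",
      code_label = "trp_uga", rf2_present = FALSE,
      codetta_support_columns = 150)
    truth_rows[[n_genomes + 1L]] <- data.frame(
      genome_id = gid, order_label = "order_re", trp_variant = "as5_only",
      uga_stop_fraction = 0)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$bundle$cds),
      file.path(dir, "cds", paste0(gid, ".fasta")), width = 80)

    og <- make_orthogroups(n_families = n_families,
                           extension_plan = extension_plan,
                           target_genome = gid,
                           seed = gseeds[n_genomes + 2L])
    write_orthogroup_fasta(og, file.path(dir, "orthogroups"))
    og_truth <- do.call(rbind, lapply(og, function(f)
      data.frame(family = f$family, truth_extension = f$truth_extension,
                 planted_gap = f$planted_gap)))

    meta <- do.call(rbind, meta_rows)
    truth <- do.call(rbind, truth_rows)
    writeLines(paste(unlist(ss_chunks), collapse = "\n"),
               file.path(dir, "trnas.ss"))
    write_tsv(meta, file.path(dir, "genomes.tsv"))
    write_tsv(truth, file.path(dir, "truth", "genomes.tsv"))
    write_tsv(og_truth, file.path(dir, "truth", "orthogroups.tsv"))
    invisible(list(meta = meta, truth = truth, orthogroups = og_truth))
  })
}
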