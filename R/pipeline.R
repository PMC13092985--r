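#' Pipeline orchestration
#'
#' End-to-end runs over a fixture/input directory: classify tRNAs,
#' summarize genomes, run the co-occurrence and per-order UGA-usage
#' comparisons, compare sequence conservation of the 4- and 5-bp-stem
#' tRNA-Trp(CCA) cohorts, validate stop-to-tryptophan reassignments, and
#' compute decoding coverage.  All outputs are tab-separated tables;
#' reruns on identical inputs, configuration and seed are bit-identical.
#'
#' @name pipeline_cli
NULL

#' Pipeline run configuration
#'
#' @param input_dir Directory with `genomes.tsv`, `trnas.ss`, `cds/` and
#'   optionally `orthogroups/` (the layout written by
#'   [simulate_fixtures()]).
#' @param output_dir Output directory (created).
#' @param abundance_threshold_pct Low-abundance cut (default 0.1% of all
#'   identified tRNAs).
#' @param alpha Significance level for all gates and calls (default 0.05).
#' @param cterm_k Conserved C-terminus window (default 5 columns).
#' @param codetta_min Code-inference support threshold (default 100
#'   consensus columns).
#' @param min_genomes_per_order Minimum genomes encoding exclusively
#'   4-bp-stem tRNA-Trp(CCA) for an order to enter the UGA comparison
#'   (default 10).
#' @param align_match,align_mismatch,align_gap Aligner scores.
#' @param seed Integer seed for any stochastic step.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir = ".", output_dir = "out",
                       abundance_threshold_pct = 0.1, alpha = 0.05,
                       cterm_k = 5L, codetta_min = 100,
                       min_genomes_per_order = 10L,
                       align_match = 1, align_mismatch = -1, align_gap = -2,
                       seed = 1L) {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 abundance_threshold_pct = abundance_threshold_pct,
                 alpha = alpha, cterm_k = as.integer(cterm_k),
                 codetta_min = codetta_min,
                 min_genomes_per_order = as.integer(min_genomes_per_order),
                 align_match = align_match, align_mismatch = align_mismatch,
                 align_gap = align_gap, seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @param config A [run_config()].
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# ---- input loading ----------------------------------------------------------

#' Load genome bundles from an input directory
#'
#' Expects `genomes.tsv` (genome_id, size_bp, order_label, code_label and
#' optional rf2_present / codetta_support_columns columns), `trnas.ss`,
#' and per-genome CDS FASTA under `cds/`.
#'
#' @param input_dir Input directory.
#' @return List with `bundles`, `classification`, `excluded`, `sequences`
#'   (record_id -> sequence), `meta`, `parse_errors`.
#' @export
load_genome_inputs <- function(input_dir) {
  meta_path <- file.path(input_dir, "genomes.tsv")
  ss_path <- file.path(input_dir, "trnas.ss")
  if (!file.exists(meta_path) || !file.exists(ss_path))
    stop("input directory lacks genomes.tsv / trnas.ss: ", input_dir,
         call. = FALSE)
  meta <- read_tsv(meta_path)
  parsed <- parse_ss_records(ss_path)
  cl <- classify_records(parsed$records)
  seqs <- stats::setNames(
    vapply(parsed$records, `[[`, "", "sequence"),
    vapply(parsed$records, `[[`, "", "record_id"))
  bundles <- lapply(seq_len(nrow(meta)), function(k) {
    gid <- meta$genome_id[k]
    cds_path <- file.path(input_dir, "cds", paste0(gid, ".fasta"))
    cds <- if (file.exists(cds_path))
      as.character(Biostrings::readDNAStringSet(cds_path))
    else character(0)
    genome_bundle(gid,
                  cl$classification[cl$classification$genome_id == gid, ],
                  cds, genome_size = meta$size_bp[k],
                  order_label = meta$order_label[k],
                  code_label = meta$code_label[k])
  })
  names(bundles) <- meta$genome_id
  list(bundles = bundles, classification = cl$classification,
       excluded = cl$excluded, sequences = seqs, meta = meta,
       parse_errors = parsed$errors)
}

# ---- co-occurrence analysis -------------------------------------------------

# (NNA, NNG) codon pairs sharing one amino acid in the standard code, for
# the 11 amino acids encoded by both; the tRNA-Arg CCG/UCG pair (codons
# CGG/CGA) is excluded because CGA is generally decoded by an I34 tRNA.
nna_nng_pairs <- function() {
  code <- genetic_code("standard")
  eleven <- c("A", "R", "Q", "E", "G", "L", "K", "P", "S", "T", "V")
  sc <- sense_codons(code)
  nna <- sc[substr(sc, 3, 3) == "A"]
  rows <- lapply(nna, function(ca) {
    cg <- paste0(substr(ca, 1, 2), "G")
    if (!cg %in% sc) return(NULL)
    if (code$codons[[ca]] != code$codons[[cg]]) return(NULL)
    if (!code$codons[[ca]] %in% eleven) return(NULL)
    if (ca == "CGA") return(NULL)  # excluded Arg CCG/UCG pair
    rc <- function(cd) paste(rev(wc_complement(strsplit(cd, "")[[1]])),
                             collapse = "")
    data.frame(aa = code$codons[[ca]], codon_a = ca, codon_g = cg,
               anticodon_unn = rc(ca), anticodon_cnn = rc(cg))
  })
  do.call(rbind, rows)
}

#' Co-occurrence of tRNA(UNN) with 4- versus 5-bp-stem tRNA(CNN)
#'
#' The extended superwobble hypothesis predicts that genomes carrying a
#' 4-bp-stem tRNA with C34 do not need the U34 isoacceptor for the same
#' codon box.  For each (NNA, NNG) codon pair sharing one amino acid,
#' genomes possessing at least one tRNA(CNN) gene are stratified by
#' whether any of those genes has a 4-bp stem, and the proportions of
#' genomes also encoding tRNA(UNN) are compared with the two-sample
#' proportion Z-test.  Genomes whose genetic code assigns the NNA and NNG
#' codons differently are excluded from the pair.
#'
#' @param bundles List of [genome_bundle()] objects.
#' @param alpha Significance level recorded in the `significant` column.
#' @return Data frame, one row per tested anticodon pair.
#' @export
run_cooccurrence <- function(bundles, alpha = 0.05) {
  pairs <- nna_nng_pairs()
  rows <- lapply(seq_len(nrow(pairs)), function(px) {
    pr <- pairs[px, ]
    has4 <- logical(0); has_unn <- logical(0)
    for (b in bundles) {
      gcode <- genetic_code(b$code_label)
      if (!identical(gcode$codons[[pr$codon_a]], gcode$codons[[pr$codon_g]]))
        next  # NNA and NNG mean different things in this genome
      tr <- b$trnas
      cnn <- tr[tr$anticodon == pr$anticodon_cnn, , drop = FALSE]
      if (nrow(cnn) == 0) next
      has4 <- c(has4, any(is_as4(cnn$as_bin)))
      has_unn <- c(has_unn, any(tr$anticodon == pr$anticodon_unn))
    }
    n4 <- sum(has4); n5 <- sum(!has4)
    k4 <- sum(has_unn[has4]); k5 <- sum(has_unn[!has4])
    base <- data.frame(aa = pr$aa, anticodon_cnn = pr$anticodon_cnn,
                       anticodon_unn = pr$anticodon_unn,
                       n_as4 = n4, k_unn_as4 = k4, n_as5 = n5,
                       k_unn_as5 = k5)
    if (n4 == 0 || n5 == 0) {
      return(cbind(base, z = NA_real_, p_value = NA_real_,
                   diff = NA_real_, significant = NA,
                   note = "empty stratum"))
    }
    res <- tryCatch(proportion_z_test(k4, n4, k5, n5), error = function(e) e)
    if (inherits(res, "error"))
      return(cbind(base, z = NA_real_, p_value = NA_real_, diff = NA_real_,
                   significant = NA, note = conditionMessage(res)))
    cbind(base, z = res$statistic, p_value = res$p_value,
          diff = res$effect_size, significant = res$p_value < alpha,
          note = "")
  })
  do.call(rbind, rows)
}

# ---- per-order UGA-usage comparison ----------------------------------------

#' Per-order UGA stop-usage comparison by tRNA-Trp(CCA) stem class
#'
#' Within each taxonomic order, genomes encoding exclusively 4-bp-stem
#' tRNA-Trp(CCA) (at least one 4-bp gene, no 5-bp gene) are compared
#' against genomes of the same order encoding only the 5-bp variant;
#' genomes carrying both variants are excluded from both strata.  Orders
#' with fewer than `min_genomes` exclusively-4-bp genomes are skipped.
#' The comparison is the normality-gated test of [gated_compare()] on the
#' per-genome percentage of UGA among stop codons.
#'
#' @param bundles List of [genome_bundle()] objects.
#' @param min_genomes Minimum 4-bp-stratum size per order (default 10).
#' @param alpha Significance level.
#' @return Data frame, one row per qualifying order, with the method
#'   label of the branch that ran and the direction of the difference.
#' @export
run_uga_compare <- function(bundles, min_genomes = 10L, alpha = 0.05) {
  per_genome <- lapply(bundles, function(b) {
    tr <- b$trnas
    trp <- tr[tr$isotype == "Trp" & tr$anticodon == "CCA", , drop = FALSE]
    n4 <- sum(is_as4(trp$as_bin)); n5 <- sum(trp$as_bin == "AS5")
    stratum <- if (n4 > 0 && n5 == 0) "as4_only"
               else if (n5 > 0 && n4 == 0) "as5_only"
               else if (n4 > 0 && n5 > 0) "mixed" else "none"
    pct <- if (length(b$cds))
      suppressWarnings(stop_usage(b)$pct_UGA) else NA_real_
    data.frame(genome_id = b$genome_id, order_label = b$order_label,
               stratum = stratum, pct_UGA = pct)
  })
  df <- do.call(rbind, per_genome)
  df <- df[!is.na(df$pct_UGA) & df$stratum %in% c("as4_only", "as5_only"), ]
  rows <- lapply(split(df, df$order_label), function(od) {
    x4 <- od$pct_UGA[od$stratum == "as4_only"]
    x5 <- od$pct_UGA[od$stratum == "as5_only"]
    base <- data.frame(order_label = od$order_label[1],
                       n_as4 = length(x4), n_as5 = length(x5))
    if (length(x4) < max(min_genomes, 3L))
      return(cbind(base, method = NA, statistic = NA_real_,
                   p_value = NA_real_, direction = NA, significant = NA,
                   note = sprintf("fewer than %d exclusively-4-bp genomes",
                                  max(min_genomes, 3L))))
    if (length(x5) < 3)
      return(cbind(base, method = NA, statistic = NA_real_,
                   p_value = NA_real_, direction = NA, significant = NA,
                   note = "fewer than 3 comparison genomes"))
    res <- gated_compare(x4, x5, alpha = alpha)
    cbind(base, method = res$method, statistic = res$statistic,
          p_value = res$p_value,
          direction = if (stats::median(x4) < stats::median(x5)) "lower"
                      else "higher",
          significant = res$p_value < alpha, note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- decoding coverage table ------------------------------------------------

#' Per-codon decoding coverage table
#'
#' @param trnas Classification data frame for one genome.
#' @param model Decoding model label.
#' @param code A [genetic_code()].
#' @return Data frame: codon, amino acid, covering tRNA ids, misread and
#'   stop-readthrough flags.
#' @export
decode_coverage_table <- function(trnas, model = "extended",
                                  code = genetic_code()) {
  cov <- coverage(trnas, model, code)
  all_codons <- names(code$codons)
  data.frame(
    codon = all_codons,
    amino_acid = unname(code$codons[all_codons]),
    trnas = vapply(all_codons, function(cd)
      paste(cov$decoded[[cd]] %||% cov$stop_readthrough[[cd]] %||%
              character(0), collapse = ","), ""),
    covered = all_codons %in% names(cov$decoded),
    misread_by = vapply(all_codons, function(cd)
      paste(cov$misread[[cd]] %||% character(0), collapse = ","), ""),
    stop_readthrough = all_codons %in% names(cov$stop_readthrough))
}

# ---- full run ---------------------------------------------------------------

#' Run the full pipeline over an input directory
#'
#' Stages: classify -> summarize -> co-occurrence -> UGA comparison ->
#' identity cohorts -> reassignment validation -> decode.  Each stage
#' writes a TSV into the output directory; a manifest records the package
#' version, seed and configuration hash.  Outputs are bit-identical
#' across reruns with identical inputs, configuration and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of the tables written.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  inputs <- load_genome_inputs(config$input_dir)
  bundles <- inputs$bundles
  results <- list()

  # classify
  results$classification <- inputs$classification
  write_tsv(inputs$classification, file.path(out, "classification.tsv"))
  write_tsv(inputs$excluded, file.path(out, "exclusions.tsv"))

  # summarize
  gsum <- do.call(rbind, lapply(bundles, function(b)
    suppressWarnings(genome_summary(b))))
  rownames(gsum) <- NULL
  results$genome_summary <- gsum
  write_tsv(gsum, file.path(out, "genome_summary.tsv"))
  ab <- species_abundance(inputs$classification,
                          threshold_pct = config$abundance_threshold_pct)
  ab$percent_of_total <- round(ab$percent_of_total, 1)
  results$species_abundance <- ab
  write_tsv(ab, file.path(out, "species_abundance.tsv"))
  corr <- list(
    frac4_vs_size = tryCatch(fraction_4bp_vs_size(bundles),
                             error = function(e) conditionMessage(e)),
    deviant_vs_abundance = tryCatch(
      deviant_fraction_vs_abundance(inputs$classification),
      error = function(e) conditionMessage(e)))
  corr_df <- do.call(rbind, lapply(names(corr), function(nm) {
    x <- corr[[nm]]
    if (is.character(x))
      data.frame(analysis = nm, r = NA_real_, n = NA_integer_,
                 p_value = NA_real_, note = x)
    else data.frame(analysis = nm, r = x$r, n = x$n, p_value = x$p_value,
                    note = "")
  }))
  results$correlations <- corr_df
  write_tsv(corr_df, file.path(out, "correlations.tsv"))

  # co-occurrence and UGA comparison
  results$cooccurrence <- run_cooccurrence(bundles, alpha = config$alpha)
  write_tsv(results$cooccurrence, file.path(out, "cooccurrence.tsv"))
  results$uga_compare <- run_uga_compare(
    bundles, min_genomes = config$min_genomes_per_order,
    alpha = config$alpha)
  write_tsv(results$uga_compare, file.path(out, "uga_compare.tsv"))

  # identity cohorts: genomes carrying both Trp(CCA) stem variants
  cl <- inputs$classification
  trp <- cl[cl$isotype == "Trp" & cl$anticodon == "CCA", , drop = FALSE]
  both_genomes <- intersect(trp$genome_id[is_as4(trp$as_bin)],
                            trp$genome_id[trp$as_bin == "AS5"])
  seq4 <- inputs$sequences[trp$record_id[is_as4(trp$as_bin) &
                                         trp$genome_id %in% both_genomes]]
  seq5 <- inputs$sequences[trp$record_id[trp$as_bin == "AS5" &
                                         trp$genome_id %in% both_genomes]]
  skipped_idc <- function(note)
    data.frame(n_genomes_both = length(both_genomes),
               n_seq4 = length(seq4), n_seq5 = length(seq5),
               median4 = NA_real_, median5 = NA_real_,
               t_statistic = NA_real_, p_value = NA_real_,
               cohens_d = NA_real_, note = note)
  idc <- if (length(seq4) >= 3 && length(seq5) >= 3) {
    tryCatch({
      ic <- identity_cohorts(seq4, seq5, match = config$align_match,
                             mismatch = config$align_mismatch,
                             gap = config$align_gap)
      data.frame(n_genomes_both = length(both_genomes),
                 n_seq4 = length(seq4), n_seq5 = length(seq5),
                 median4 = ic$median4, median5 = ic$median5,
                 t_statistic = ic$t_test$statistic,
                 p_value = ic$t_test$p_value, cohens_d = ic$d, note = "")
    }, error = function(e) skipped_idc(conditionMessage(e)))
  } else skipped_idc("fewer than 3 sequences per cohort")
  results$identity_cohorts <- idc
  write_tsv(idc, file.path(out, "identity_cohorts.tsv"))

  # reassignment validation
  og_paths <- sort(list.files(file.path(config$input_dir, "orthogroups"),
                              pattern = "\\.fasta$", full.names = TRUE))
  orthogroups <- if (length(og_paths)) read_orthogroup_fasta(og_paths)
                 else list()
  reassigned <- names(bundles)[vapply(bundles, function(b)
    b$code_label == "trp_uga", logical(1))]
  fam_rows <- list(); ev_rows <- list()
  for (gid in reassigned) {
    b <- bundles[[gid]]
    term <- vapply(b$cds, terminal_codon, "", USE.NAMES = FALSE)
    pct_uga_ends <- if (length(term)) 100 * mean(term == "UGA") else NA_real_
    fams <- Filter(function(f) gid %in% f$genomes[f$codes != "standard"],
                   orthogroups)
    n_ext <- 0L
    for (f in fams) {
      v <- tryCatch(validate_orthogroup(f$proteins, f$codes,
                                        k = config$cterm_k),
                    error = function(e) NULL)
      if (is.null(v)) next
      fam_rows[[length(fam_rows) + 1]] <-
        data.frame(genome_id = gid, family = f$family,
                   filter_pass = v$filter_pass,
                   extension = v$extension,
                   truncated = v$truncated)
      if (isTRUE(v$filter_pass) && !is.na(v$extension) && v$extension >= 1)
        n_ext <- n_ext + 1L
    }
    meta_row <- inputs$meta[inputs$meta$genome_id == gid, ]
    ev <- summarize_evidence(
      pct_uga_at_cds_ends = pct_uga_ends,
      n_cterm_extensions = n_ext,
      suppressor_uca_present = suppressor_check(b$trnas),
      codetta_support_columns =
        if ("codetta_support_columns" %in% names(meta_row))
          meta_row$codetta_support_columns else NA_real_,
      rf2_present = if ("rf2_present" %in% names(meta_row))
        meta_row$rf2_present else NA,
      codetta_min = config$codetta_min)
    ev_rows[[length(ev_rows) + 1]] <-
      data.frame(genome_id = gid,
                 suppressor_uca_present = ev$suppressor_uca_present,
                 rf2_present = ev$rf2_present,
                 pct_uga_at_cds_ends = ev$pct_uga_at_cds_ends,
                 n_cterm_extensions = ev$n_cterm_extensions,
                 codetta_support_columns = ev$codetta_support_columns,
                 verdict = ev$verdict,
                 reasons = paste(ev$reasons, collapse = "; "))
  }
  results$reassignment <- if (length(fam_rows)) do.call(rbind, fam_rows)
    else data.frame(genome_id = character(0), family = character(0),
                    filter_pass = logical(0), extension = integer(0),
                    truncated = logical(0))
  write_tsv(results$reassignment, file.path(out, "reassignment.tsv"))
  results$evidence <- if (length(ev_rows)) do.call(rbind, ev_rows)
    else data.frame(genome_id = character(0), verdict = character(0))
  write_tsv(results$evidence, file.path(out, "evidence.tsv"))

  # decoding coverage (extended superwobble model)
  dec <- do.call(rbind, lapply(bundles, function(b) {
    tb <- decode_coverage_table(b$trnas, "extended",
                                genetic_code(b$code_label))
    cbind(genome_id = b$genome_id, tb)
  }))
  rownames(dec) <- NULL
  results$decode <- dec
  write_tsv(dec, file.path(out, "decode.tsv"))

  # manifest (the configuration hash covers the analysis parameters, not
  # the output location, so reruns into different directories compare)
  cfg_for_hash <- unclass(config)
  cfg_for_hash$output_dir <- NULL
  cfg_lines <- yaml::as.yaml(cfg_for_hash)
  manifest <- data.frame(
    key = c("package", "version", "seed", "config_hash", "n_genomes",
            "n_trnas_retained", "n_trnas_excluded"),
    value = c("stemwobble",
              tryCatch(as.character(utils::packageVersion("stemwobble")),
                       error = function(e) "dev"),
              as.character(config$seed), content_hash(cfg_lines),
              as.character(length(bundles)),
              as.character(nrow(inputs$classification)),
              as.character(nrow(inputs$excluded))))
  write_tsv(manifest, file.path(out, "manifest.tsv"))
  results$manifest <- manifest
  invisible(results)
}
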