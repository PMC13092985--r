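#' Seeded synthetic genomes, orthogroups and quantification replicates
#'
#' Generators for every remaining input the pipeline consumes, each a pure
#' function of its seed, with planted ground truth carried alongside for
#' recovery tests.  Sequence content is deliberately simple (independent
#' random sites, uniform codon usage outside the controlled stop codons);
#' the generators emulate the study conditions, not realistic molecular
#' evolution.
#'
#' @name synthetic_data
NULL

#' Anticodon repertoire of a genetic code
#'
#' One Watson-Crick anticodon per sense codon, with the three-letter
#' isotype of the encoded amino acid.
#'
#' @param code A [genetic_code()].
#' @return Data frame with columns `codon`, `anticodon`, `isotype`.
#' @export
standard_anticodons <- function(code = genetic_code()) {
  aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
           E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
           M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
           Y = "Tyr", V = "Val")
  sc <- sense_codons(code)
  rc <- vapply(sc, function(cd) {
    paste(rev(wc_complement(strsplit(cd, "")[[1]])), collapse = "")
  }, "")
  data.frame(codon = sc, anticodon = unname(rc),
             isotype = unname(aa3[code$codons[sc]]))
}

#' Specification for one synthetic genome
#'
#' @param genome_id Genome identifier.
#' @param n_trnas Number of tRNA genes drawn from `class_mixture`.
#' @param class_mixture Named proportions over
#'   `AS5`, `AS4_top`, `AS4_bottom`, `OTHER` (must sum to 1).
#' @param trna_plan Optional data frame (`isotype`, `anticodon`, `as_bin`,
#'   `n`) of additional planted tRNA genes.
#' @param exclude_species Optional data frame (`isotype`, `anticodon`) of
#'   species removed from the background repertoire, so their presence is
#'   controlled solely by `trna_plan` (used when planting co-occurrence
#'   or stem-variant strata).
#' @param n_cds Number of coding sequences.
#' @param cds_len_codons Range of CDS lengths in codons (stop included).
#' @param uga_stop_fraction Probability that a CDS terminates in UGA
#'   (remainder split evenly between UAA and UAG); must be 0 under the
#'   `trp_uga` code.
#' @param internal_uga_rate Under `trp_uga`, per-codon rate of internal
#'   (tryptophan-encoding) UGA codons.
#' @param code_label Genetic-code label.
#' @param genome_size Assembly size in bp.
#' @param order_label Taxonomic order.
#' @param seed Integer RNG seed.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(genome_id = "synthg", n_trnas = 40L,
                        class_mixture = c(AS5 = 0.9, AS4_top = 0.06,
                                          AS4_bottom = 0.02, OTHER = 0.02),
                        trna_plan = NULL, exclude_species = NULL,
                        n_cds = 200L,
                        cds_len_codons = c(50L, 150L),
                        uga_stop_fraction = 0.3, internal_uga_rate = 0.02,
                        code_label = "standard", genome_size = 4e6,
                        order_label = "order1", seed = 1L) {
  stopifnot(abs(sum(class_mixture) - 1) < 1e-9)
  if (code_label == "trp_uga" && uga_stop_fraction != 0)
    stop("trp_uga genomes cannot use UGA as a stop codon", call. = FALSE)
  structure(list(genome_id = genome_id, n_trnas = as.integer(n_trnas),
                 class_mixture = class_mixture, trna_plan = trna_plan,
                 exclude_species = exclude_species,
                 n_cds = as.integer(n_cds),
                 cds_len_codons = as.integer(cds_len_codons),
                 uga_stop_fraction = uga_stop_fraction,
                 internal_uga_rate = internal_uga_rate,
                 code_label = code_label, genome_size = genome_size,
                 order_label = order_label, seed = as.integer(seed)),
            class = "genome_spec")
}

as_bin_to_spec <- function(as_bin, isotype, anticodon, seed) {
  switch(as_bin,
    AS5 = trna_spec(isotype, anticodon, as_pairs = 5, seed = seed),
    AS4_top = trna_spec(isotype, anticodon, as_pairs = 4, unpinned = "top",
                        seed = seed),
    AS4_bottom = trna_spec(isotype, anticodon, as_pairs = 4,
                           unpinned = "bottom", seed = seed),
    OTHER = trna_spec(isotype, anticodon,
                      as_pairs = sample(c(2L, 3L, 6L, 7L), 1), seed = seed),
    stop("unknown as_bin: ", as_bin, call. = FALSE))
}

#' Generate one synthetic genome bundle
#'
#' Draws tRNA genes from the class mixture (plus any planted plan rows),
#' generates in-frame coding sequences whose terminal stop codon is UGA
#' with the planted probability, classifies the tRNAs, and assembles a
#' [genome_bundle()].  Under the `trp_uga` code all coding sequences end
#' in UAA/UAG and internal UGA (tryptophan) codons are planted at
#' `internal_uga_rate`.
#'
#' @param spec A [genome_spec()].
#' @return List of class `genome_sim`: `bundle`, `records` (the raw tRNA
#'   records), `ss` (the "-ss" text), `truth` (planted per-record classes
#'   and the planted UGA stop fraction), `spec`.
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, make_genome_impl(spec))
}

make_genome_impl <- function(spec) {
  repertoire <- standard_anticodons(genetic_code("standard"))
  if (!is.null(spec$exclude_species)) {
    drop <- paste(spec$exclude_species$isotype, spec$exclude_species$anticodon)
    repertoire <- repertoire[!paste(repertoire$isotype,
                                    repertoire$anticodon) %in% drop, ]
  }
  bins <- sample(names(spec$class_mixture), spec$n_trnas, replace = TRUE,
                 prob = spec$class_mixture)
  draw <- repertoire[sample(nrow(repertoire), spec$n_trnas, replace = TRUE), ]
  plan <- data.frame(isotype = draw$isotype, anticodon = draw$anticodon,
                     as_bin = bins)
  if (!is.null(spec$trna_plan)) {
    extra <- spec$trna_plan[rep(seq_len(nrow(spec$trna_plan)),
                                spec$trna_plan$n), ]
    plan <- rbind(plan, extra[, c("isotype", "anticodon", "as_bin")])
  }
  seeds <- sample.int(.Machine$integer.max - 1L, nrow(plan))
  records <- vector("list", nrow(plan))
  truth_rows <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    tsp <- as_bin_to_spec(plan$as_bin[k], plan$isotype[k], plan$anticodon[k],
                          seeds[k])
    sim <- make_trna(tsp, record_id = sprintf("%s.trna%d", spec$genome_id, k))
    records[[k]] <- sim$record
    truth_rows[[k]] <- data.frame(record_id = sim$record$record_id,
                                  isotype = plan$isotype[k],
                                  anticodon = rna(plan$anticodon[k]),
                                  as_bin = sim$truth$as_bin,
                                  blasto_like = sim$truth$blasto_like)
  }
  truth <- do.call(rbind, truth_rows)

  code <- genetic_code(spec$code_label)
  internal_pool <- chartr("U", "T", sense_codons(code))
  stops_dna <- chartr("U", "T", code$stops)
  lens <- sample(spec$cds_len_codons[1]:spec$cds_len_codons[2], spec$n_cds,
                 replace = TRUE)
  cds <- vapply(seq_len(spec$n_cds), function(k) {
    body <- sample(internal_pool, lens[k] - 1, replace = TRUE)
    if (spec$code_label == "trp_uga" && spec$internal_uga_rate > 0) {
      flip <- stats::runif(length(body)) < spec$internal_uga_rate
      body[flip] <- "TGA"
    }
    stop_cod <- if (spec$code_label != "trp_uga" &&
                    stats::runif(1) < spec$uga_stop_fraction) "TGA"
                else sample(setdiff(stops_dna, "TGA"), 1)
    paste(c(body, stop_cod), collapse = "")
  }, "")
  names(cds) <- sprintf("%s.cds%d", spec$genome_id, seq_len(spec$n_cds))

  cl <- classify_records(records)
  bundle <- genome_bundle(spec$genome_id, cl$classification, cds,
                          genome_size = spec$genome_size,
                          order_label = spec$order_label,
                          code_label = spec$code_label)
  structure(list(bundle = bundle, records = records,
                 ss = write_ss_records(records),
                 truth = list(trnas = truth,
                              uga_stop_fraction = spec$uga_stop_fraction),
                 spec = spec),
            class = "genome_sim")
}

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate synthetic protein orthogroups with planted C-terminal features
#'
#' Each family descends from a common random ancestor protein; members
#' carry independent substitutions except in the last `conserved_tail`
#' residues, which stay identical (conserved C-termini by construction).
#' One member per family is labelled as coming from a reassigned-code
#' genome; for families in `extension_plan` it carries a planted
#' C-terminal extension of the stated length, simulating conceptual
#' translation through a genuine UGA stop to a downstream UAA/UAG.
#' Families listed in `cterm_gap_families` instead have one reference
#' member truncated by one residue, planting a gap within the last
#' alignment columns.
#'
#' @param n_families Number of families.
#' @param n_members Members per family (including the reassigned target).
#' @param extension_plan Integer vector (named by family index or
#'   recycled) of planted extension lengths; 0 = none.
#' @param cterm_gap_families Integer indices of families given a
#'   C-terminal gap in one reference member.
#' @param length_aa Ancestor protein length.
#' @param sub_rate Per-site substitution probability.
#' @param conserved_tail Number of conserved C-terminal residues.
#' @param target_genome Genome id tag recorded for the reassigned member.
#' @param seed Integer RNG seed.
#' @return List of class `orthogroup_sim`: one element per family with
#'   `proteins` (named), `codes`, `genomes`, `truth_extension`,
#'   `planted_gap`.
#' @export
make_orthogroups <- function(n_families = 10L, n_members = 5L,
                             extension_plan = 0L,
                             cterm_gap_families = integer(0),
                             length_aa = 60L, sub_rate = 0.05,
                             conserved_tail = 5L, target_genome = "reassigned",
                             seed = 1L) {
  stopifnot(n_members >= 3)
  plan <- rep_len(as.integer(extension_plan), n_families)
  with_seed(seed, {
    fams <- lapply(seq_len(n_families), function(f) {
      anc <- sample(AA_ALPHABET20, length_aa, replace = TRUE)
      mutate <- function(x) {
        head_len <- length(x) - conserved_tail
        flip <- which(stats::runif(head_len) < sub_rate)
        x[flip] <- sample(AA_ALPHABET20, length(flip), replace = TRUE)
        x
      }
      members <- lapply(seq_len(n_members), function(m) mutate(anc))
      # member n_members is the reassigned-code target
      ext <- plan[f]
      if (ext > 0)
        members[[n_members]] <- c(members[[n_members]],
                                  sample(AA_ALPHABET20, ext, replace = TRUE))
      gap <- f %in% cterm_gap_families
      if (gap) {
        # drop a residue near the C-terminus of one reference member
        v <- members[[1]]
        members[[1]] <- v[-(length(v) - 1L)]
      }
      proteins <- vapply(members, paste, "", collapse = "")
      names(proteins) <- sprintf("fam%d_m%d", f, seq_len(n_members))
      codes <- c(rep("standard", n_members - 1), "trp_uga")
      genomes <- c(sprintf("std%d", seq_len(n_members - 1)), target_genome)
      list(family = sprintf("fam%d", f), proteins = proteins, codes = codes,
           genomes = genomes, truth_extension = ext, planted_gap = gap)
    })
    structure(fams, class = "orthogroup_sim")
  })
}

#' Write orthogroup families as protein FASTA files
#'
#' One file per family; headers carry `code=` and `genome=` tags, e.g.
#' `>fam1_m5 code=trp_uga genome=g9`.
#'
#' @param orthogroups An `orthogroup_sim` (or compatible list).
#' @param dir Output directory (created).
#' @return Paths written, invisibly.
#' @export
write_orthogroup_fasta <- function(orthogroups, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(orthogroups, function(fam) {
    p <- file.path(dir, paste0(fam$family, ".fasta"))
    aa <- Biostrings::AAStringSet(fam$proteins)
    names(aa) <- sprintf("%s code=%s genome=%s", names(fam$proteins),
                         fam$codes, fam$genomes)
    Biostrings::writeXStringSet(aa, p, width = 80)
    p
  }, "")
  invisible(paths)
}

#' Read orthogroup families from tagged protein FASTA files
#'
#' @param paths FASTA files written by [write_orthogroup_fasta()].
#' @return List with one element per family: `family`, `proteins`,
#'   `codes`, `genomes`.
#' @export
read_orthogroup_fasta <- function(paths) {
  lapply(paths, function(p) {
    aa <- Biostrings::readAAStringSet(p)
    hdr <- names(aa)
    ids <- sub("\\s.*$", "", hdr)
    tag <- function(name) {
      m <- regmatches(hdr, regexec(paste0(name, "=(\\S+)"), hdr))
      vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
    }
    list(family = sub("\\.fasta$", "", basename(p)),
         proteins = stats::setNames(as.character(aa), ids),
         codes = tag("code"), genomes = tag("genome"))
  })
}

#' Normal replicate table for group comparisons
#'
#' Emulates replicated quantification (e.g. densitometry of a readthrough
#' reporter across conditions): independent normal draws around each group
#' mean.
#'
#' @param group_means Numeric vector of true group means.
#' @param sd Common standard deviation.
#' @param n_per_group Replicates per group.
#' @param seed Integer RNG seed.
#' @return Data frame with columns `group` (factor) and `value`.
#' @export
make_replicates <- function(group_means, sd = 1, n_per_group = 3L,
                            seed = 1L) {
  with_seed(seed, {
    k <- length(group_means)
    data.frame(
      group = factor(rep(paste0("g", seq_len(k)), each = n_per_group)),
      value = stats::rnorm(k * n_per_group,
                           mean = rep(group_means, each = n_per_group),
                           sd = sd))
  })
}
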