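#' Genome-level tRNA inventories and stop-codon usage
#'
#' A `genome_bundle` carries one genome's retained, classified tRNAs, its
#' coding sequences, and metadata (size, taxonomic order, genetic-code
#' label).  Inventory summaries follow the survey conventions: a tRNA
#' "species" is an (isotype, anticodon) pair; species below 0.1% of all
#' identified tRNAs are "low abundance"; stop-codon usage counts the
#' terminal codon of each coding sequence.
#'
#' @name inventory_stats
NULL

#' Construct a genome bundle
#'
#' @param genome_id Genome identifier.
#' @param trnas Classification data frame (rows of [classify_records()]
#'   output for this genome's retained tRNAs).
#' @param cds Character vector of in-frame, stop-terminated coding
#'   sequences (DNA or RNA).
#' @param genome_size Assembly size in bp.
#' @param order_label Taxonomic order.
#' @param code_label Genetic-code label (see [genetic_code()]).
#' @return Object of class `genome_bundle`.
#' @export
genome_bundle <- function(genome_id, trnas, cds = character(0),
                          genome_size = NA_real_, order_label = NA_character_,
                          code_label = "standard") {
  structure(list(genome_id = genome_id, trnas = trnas, cds = cds,
                 genome_size = genome_size, order_label = order_label,
                 code_label = code_label),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("<genome_bundle %s> %d tRNAs, %d CDS, %s bp, order %s, code %s\n",
              x$genome_id, nrow(x$trnas), length(x$cds),
              format(x$genome_size), x$order_label, x$code_label))
  invisible(x)
}

#' Per-species tRNA gene abundance
#'
#' @param classification Classification data frame (any number of
#'   genomes).
#' @param threshold_pct Low/high abundance cut (default 0.1% of all
#'   identified tRNAs).
#' @return Data frame: `species` (isotype-anticodon), `isotype`,
#'   `anticodon`, `count`, `percent_of_total`, `bin` (`low`/`high`),
#'   ordered by decreasing count.
#' @export
species_abundance <- function(classification, threshold_pct = 0.1) {
  if (nrow(classification) == 0) stop("empty classification", call. = FALSE)
  key <- paste(classification$isotype, classification$anticodon, sep = "-")
  tab <- table(key)
  total <- sum(tab)
  df <- data.frame(species = names(tab), count = as.integer(tab))
  parts <- strsplit(df$species, "-", fixed = TRUE)
  df$isotype <- vapply(parts, `[`, "", 1)
  df$anticodon <- vapply(parts, `[`, "", 2)
  df$percent_of_total <- 100 * df$count / total
  df$bin <- ifelse(df$percent_of_total < threshold_pct, "low", "high")
  df[order(-df$count, df$species),
     c("species", "isotype", "anticodon", "count", "percent_of_total", "bin")]
}

is_as4 <- function(as_bin) as_bin %in% c("AS4_top", "AS4_bottom", "AS4_other")

#' Fraction of 4-bp-stem tRNA genes versus genome size
#'
#' Per genome, y = (number of 4-bp-stem tRNAs) / (number of retained
#' tRNAs), correlated against assembly size (Pearson, two-sided p).
#'
#' @param bundles List of [genome_bundle()] objects (>= 3 with at least
#'   one retained tRNA each).
#' @return List with the correlation (`r`, `n`, `p_value`) and the
#'   per-genome table.
#' @export
fraction_4bp_vs_size <- function(bundles) {
  rows <- lapply(bundles, function(b) {
    if (nrow(b$trnas) == 0) return(NULL)
    data.frame(genome_id = b$genome_id, genome_size = b$genome_size,
               frac_4bp = mean(is_as4(b$trnas$as_bin)))
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) < 3)
    stop("need >= 3 genomes with retained tRNAs", call. = FALSE)
  ct <- pearson_cor(df$genome_size, df$frac_4bp)
  c(ct, list(table = df))
}

#' Deviant-stem fraction versus species abundance
#'
#' Per tRNA species, the fraction of its genes with a deviant (non-5-bp)
#' anticodon stem, correlated against the species' percentage of the
#' total tRNA pool.
#'
#' @param classification Classification data frame (>= 3 species).
#' @return List with the correlation and the per-species table
#'   (`species`, `percent_of_total`, `deviant_fraction`).
#' @export
deviant_fraction_vs_abundance <- function(classification) {
  ab <- species_abundance(classification)
  if (nrow(ab) < 3) stop("need >= 3 tRNA species", call. = FALSE)
  key <- paste(classification$isotype, classification$anticodon, sep = "-")
  dev <- tapply(classification$as_bin != "AS5", key, mean)
  ab$deviant_fraction <- as.numeric(dev[ab$species])
  ct <- pearson_cor(ab$percent_of_total, ab$deviant_fraction)
  c(ct, list(table = ab[, c("species", "count", "percent_of_total",
                            "deviant_fraction")]))
}

#' Stop-codon usage of a genome
#'
#' Counts the terminal codon of each coding sequence.  Under the
#' `trp_uga` code UGA is not a stop codon and must not terminate any CDS;
#' sequences not ending in a stop codon of the genome's code are excluded
#' from the denominator with a warning.
#'
#' @param bundle A [genome_bundle()] (or character vector of CDS plus a
#'   `code_label`).
#' @param code_label Overrides the bundle's code label.
#' @return List with counts `UAA`, `UAG`, `UGA`, `pct_UGA`,
#'   `n_cds_counted` and `n_cds_invalid`.
#' @export
stop_usage <- function(bundle, code_label = NULL) {
  if (inherits(bundle, "genome_bundle")) {
    cds <- bundle$cds
    code_label <- code_label %||% bundle$code_label
  } else {
    cds <- bundle
    code_label <- code_label %||% "standard"
  }
  if (!length(cds)) stop("no coding sequences", call. = FALSE)
  code <- genetic_code(code_label)
  term <- vapply(cds, terminal_codon, "", USE.NAMES = FALSE)
  valid <- term %in% code$stops
  if (any(!valid))
    warning(sprintf("%d CDS do not end in a stop codon under code '%s'",
                    sum(!valid), code_label), call. = FALSE)
  term <- term[valid]
  counts <- c(UAA = sum(term == "UAA"), UAG = sum(term == "UAG"),
              UGA = sum(term == "UGA"))
  denom <- sum(counts)
  list(UAA = unname(counts["UAA"]), UAG = unname(counts["UAG"]),
       UGA = unname(counts["UGA"]),
       pct_UGA = if (denom > 0) 100 * unname(counts["UGA"]) / denom
                 else NA_real_,
       n_cds_counted = denom, n_cds_invalid = sum(!valid))
}

#' Per-genome summary row
#'
#' @param bundle A [genome_bundle()].
#' @return One-row data frame: genome id, metadata, tRNA counts by stem
#'   bin, Blastocrithidia-like Trp(CCA) count, and stop-codon usage.
#' @export
genome_summary <- function(bundle) {
  tr <- bundle$trnas
  su <- if (length(bundle$cds)) stop_usage(bundle)
        else list(UAA = NA, UAG = NA, UGA = NA, pct_UGA = NA_real_)
  data.frame(genome_id = bundle$genome_id,
             genome_size = bundle$genome_size,
             order_label = bundle$order_label,
             code_label = bundle$code_label,
             n_trna = nrow(tr),
             n_as5 = sum(tr$as_bin == "AS5"),
             n_as4 = sum(is_as4(tr$as_bin)),
             n_as4_top = sum(tr$as_bin == "AS4_top"),
             n_as4_bottom = sum(tr$as_bin == "AS4_bottom"),
             n_other = sum(tr$as_bin == "OTHER"),
             n_blasto_trp = sum(is_blasto_trp(tr)),
             stops_UAA = su$UAA, stops_UAG = su$UAG, stops_UGA = su$UGA,
             pct_UGA = su$pct_UGA)
}
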