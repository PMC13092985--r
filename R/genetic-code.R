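#' Genetic code tables
#'
#' Built-in codes keyed by label.  `standard` follows the bacterial usage
#' of the canonical code (NCBI table 11 codon semantics: stops UAA, UAG,
#' UGA); `trp_uga` reassigns UGA to tryptophan (table 4 UGA->W semantics,
#' stops UAA and UAG); `gly_uga` reassigns UGA to glycine; `met_agg`
#' reassigns AGG from arginine to methionine.  The codon map is derived
#' from `Biostrings::GENETIC_CODE` and covers all 64 codons (RNA alphabet).
#'
#' @param label One of `"standard"`, `"trp_uga"`, `"gly_uga"`, `"met_agg"`.
#' @return An object of class `genetic_code`: list with `label`, `codons`
#'   (named character vector codon -> one-letter amino acid, `*` for stop)
#'   and `stops` (the stop-codon set).
#' @export
genetic_code <- function(label = c("standard", "trp_uga", "gly_uga",
                                   "met_agg")) {
  label <- match.arg(label)
  codons <- Biostrings::GENETIC_CODE
  names(codons) <- rna(names(codons))
  if (label == "trp_uga") codons["UGA"] <- "W"
  if (label == "gly_uga") codons["UGA"] <- "G"
  if (label == "met_agg") codons["AGG"] <- "M"
  structure(list(label = label, codons = codons,
                 stops = names(codons)[codons == "*"]),
            class = "genetic_code")
}

#' Sense codons of a code
#' @param code A [genetic_code()].
#' @return Character vector of non-stop codons.
#' @export
sense_codons <- function(code) setdiff(names(code$codons), code$stops)

#' Conceptual translation of a coding sequence
#'
#' Translates codon by codon, halting at the first stop codon of the given
#' code.  Under the `trp_uga` code an internal UGA yields tryptophan
#' instead of halting.
#'
#' @param cds Nucleotide string, length divisible by 3 (DNA or RNA).
#' @param code A [genetic_code()] (default standard).
#' @return Protein string (may be empty).  When translation halts before
#'   the final codon the attribute `premature_stop` carries the 1-based
#'   codon index of the internal stop.
#' @examples
#' translate_cds("ATGTGATAA", genetic_code("trp_uga"))  # "MW"
#' @export
translate_cds <- function(cds, code = genetic_code("standard")) {
  s <- rna(cds)
  if (nchar(s) %% 3 != 0)
    stop("CDS length must be divisible by 3", call. = FALSE)
  n_codons <- nchar(s) %/% 3
  if (n_codons == 0) return("")
  cod <- substring(s, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
  aa <- code$codons[cod]
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    prot <- paste(aa[seq_len(stop_at[1] - 1)], collapse = "")
    if (stop_at[1] < n_codons) attr(prot, "premature_stop") <- unname(stop_at[1])
    prot
  } else paste(aa, collapse = "")
}

#' Terminal stop codon of a CDS
#' @param cds Nucleotide string.
#' @return The final codon in the RNA alphabet.
#' @keywords internal
terminal_codon <- function(cds) {
  s <- rna(cds)
  substring(s, nchar(s) - 2, nchar(s))
}
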