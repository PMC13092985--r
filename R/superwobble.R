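#' Codon-decoding rule engine: wobble, superwobble, extended superwobble
#'
#' Codon positions 1-2 are read by Watson-Crick pairing with anticodon
#' bases 36 and 35; the rule set governs which third-codon-position bases
#' the wobble base 34 can read.  Anticodons are written 5'->3' (bases
#' 34,35,36) and codons 5'->3'; the pairing is 34<->codon 3, 35<->codon 2,
#' 36<->codon 1.
#'
#' Models:
#' * `strict` - Watson-Crick only (inosine reads C).
#' * `wobble` - Crick's rules: G34 reads U/C, U34 reads A/G, I34 reads
#'   U/C/A.
#' * `superwobble` - additionally, an unmodified U34 reads all four third
#'   bases.
#' * `extended` - the extended superwobble rule: on a tRNA with a 4-bp
#'   anticodon stem unpinned at the top (`AS4_top`), C34 additionally
#'   reads A-ending codons via C:A pairing (so C34 reads G and A).
#'
#' @name superwobble
NULL

#' Construct a decoding model
#'
#' @param label One of `"strict"`, `"wobble"`, `"superwobble"`,
#'   `"extended"`.
#' @return Object of class `decoding_model`.
#' @export
decoding_model <- function(label = c("strict", "wobble", "superwobble",
                                     "extended")) {
  label <- match.arg(label)
  structure(list(label = label), class = "decoding_model")
}

# Third-codon-position bases readable by wobble base `b34` under `model`.
wobble_third_bases <- function(b34, model, as_bin = "AS5") {
  label <- if (inherits(model, "decoding_model")) model$label else model
  wc <- c(A = "U", C = "G", G = "C", U = "A", I = "C")
  if (!b34 %in% names(wc))
    stop("ambiguous anticodon base: ", b34, call. = FALSE)
  third <- wc[[b34]]
  if (label %in% c("wobble", "superwobble", "extended")) {
    third <- switch(b34,
                    G = c("C", "U"),
                    U = c("A", "G"),
                    I = c("U", "C", "A"),
                    third)
  }
  if (label %in% c("superwobble", "extended") && b34 == "U")
    third <- c("A", "G", "C", "U")
  if (label == "extended" && b34 == "C" && identical(as_bin, "AS4_top"))
    third <- c("G", "A")
  third
}

#' Codons readable by one tRNA under a decoding model
#'
#' @param anticodon Anticodon 5'->3' over `A,C,G,U,I` (T accepted and
#'   normalized).
#' @param as_bin Anticodon-stem bin of the tRNA (only `"AS4_top"` changes
#'   behaviour, under the `extended` model).
#' @param model A [decoding_model()] or its label.
#' @return Character vector of readable codons (RNA alphabet), always
#'   containing the strict Watson-Crick codon.
#' @examples
#' readable_codons("CCA", "AS5", "wobble")        # UGG
#' readable_codons("CCA", "AS4_top", "extended")  # UGG and UGA
#' @export
readable_codons <- function(anticodon, as_bin = "AS5", model = "wobble") {
  ac <- strsplit(rna(anticodon), "")[[1]]
  if (length(ac) != 3 || any(!ac %in% c("A", "C", "G", "U", "I")))
    stop("ambiguous anticodon: ", anticodon, call. = FALSE)
  if (any(ac[2:3] == "I"))
    stop("inosine is only modelled at the wobble position 34", call. = FALSE)
  c1 <- wc_complement(ac[3])
  c2 <- wc_complement(ac[2])
  third <- wobble_third_bases(ac[1], model, as_bin)
  paste0(c1, c2, third)
}

#' Decoding coverage of a tRNA set
#'
#' @param trnas Data frame with columns `record_id` (or `id`), `anticodon`,
#'   `as_bin`, and optionally `isotype`.
#' @param model A [decoding_model()] or label.
#' @param code A [genetic_code()].
#' @return Object of class `coverage_report`: `decoded` (named list,
#'   sense codon -> decoding tRNA ids), `uncovered_sense`,
#'   `stop_readthrough` (stop codon -> tRNA ids reading it) and `misread`
#'   (sense codon -> ids of tRNAs whose isotype amino acid differs from
#'   the codon's assignment, e.g. a 4-bp-stem elongator Met tRNA reading
#'   AUA).
#' @export
coverage <- function(trnas, model = "wobble", code = genetic_code()) {
  ids <- trnas$record_id %||% trnas$id
  if (is.null(ids)) ids <- paste0("trna", seq_len(nrow(trnas)))
  sense <- sense_codons(code)
  decoded <- stats::setNames(vector("list", length(sense)), sense)
  readthrough <- list()
  misread <- list()
  iso_aa <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
              Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
              Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
              Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
              fMet = "M", iMet = "M")
  for (r in seq_len(nrow(trnas))) {
    cods <- tryCatch(
      readable_codons(trnas$anticodon[r], trnas$as_bin[r], model),
      error = function(e) character(0))
    for (cd in cods) {
      if (cd %in% sense) {
        decoded[[cd]] <- c(decoded[[cd]], ids[r])
        iso <- if ("isotype" %in% names(trnas)) trnas$isotype[r] else NA
        if (!is.na(iso) && iso %in% names(iso_aa) &&
            iso_aa[[iso]] != code$codons[[cd]])
          misread[[cd]] <- c(misread[[cd]], ids[r])
      } else if (cd %in% code$stops) {
        readthrough[[cd]] <- c(readthrough[[cd]], ids[r])
      }
    }
  }
  covered <- names(decoded)[vapply(decoded, length, 1L) > 0]
  structure(list(decoded = decoded[covered],
                 uncovered_sense = setdiff(sense, covered),
                 stop_readthrough = readthrough, misread = misread,
                 model = if (inherits(model, "decoding_model")) model$label
                         else model),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report %s> %d sense codons covered, %d uncovered; %d stop-readthrough, %d misread\n",
              x$model, length(x$decoded), length(x$uncovered_sense),
              length(x$stop_readthrough), length(x$misread)))
  invisible(x)
}

#' Minimal anticodon set decoding all sense codons
#'
#' Exact minimum-cardinality set of (anticodon, stem-class) units whose
#' joint coverage includes every sense codon while no chosen unit reads a
#' codon assigned to a different amino acid or a stop (misreading
#' constraint; Crick's classic count of 32 tRNAs for the 61 sense codons
#' is the wobble-rule benchmark).  Because wobble only moves the third
#' position, the problem decomposes into independent exact set covers per
#' codon box (first two codon positions) within each amino acid, solved
#' exhaustively.
#'
#' @param model A [decoding_model()] or label.
#' @param code A [genetic_code()].
#' @param forbid_misreading Disallow units reading differently assigned
#'   codons or stops (default `TRUE`; toggleable to reproduce alternative
#'   published counts).
#' @param allow_inosine Allow I at the wobble position (default `TRUE`).
#' @return List with `size` and `witness` (data frame: amino acid,
#'   anticodon, stem class, codons read).
#' @export
minimal_anticodon_set <- function(model = "wobble", code = genetic_code(),
                                  forbid_misreading = TRUE,
                                  allow_inosine = TRUE) {
  sense <- sense_codons(code)
  aa <- code$codons[sense]
  boxes <- split(sense, paste0(substr(sense, 1, 2), ":", aa))
  b34_alphabet <- c("A", "C", "G", "U", if (allow_inosine) "I")
  witness <- list()
  total <- 0L
  for (bx in names(boxes)) {
    codons <- boxes[[bx]]
    prefix <- substr(codons[1], 1, 2)
    this_aa <- aa[codons[1]]
    label <- if (inherits(model, "decoding_model")) model$label else model
    units <- list()
    seen <- character(0)
    add_unit <- function(ac, cls, reads) {
      if (forbid_misreading) {
        bad <- reads[reads %in% code$stops |
                     (reads %in% sense & code$codons[reads] != this_aa)]
        if (length(bad)) return()
      }
      hit <- intersect(reads, codons)
      if (!length(hit)) return()
      key <- paste(ac, cls, paste(sort(hit), collapse = ""))
      if (key %in% seen) return()
      seen <<- c(seen, key)
      units[[length(units) + 1]] <<-
        list(anticodon = ac, as_class = cls, reads = hit)
    }
    for (b34 in b34_alphabet) for (cls in c("AS5", "AS4_top")) {
      ac <- paste0(b34, wc_complement(substr(prefix, 2, 2)),
                   wc_complement(substr(prefix, 1, 1)))
      add_unit(ac, cls, readable_codons(ac, cls, model))
      # superwobbling is a capability of unmodified U34; a (modified) U34
      # restricted to the Crick wobble range remains available to the code
      if (b34 == "U" && label %in% c("superwobble", "extended"))
        add_unit(ac, cls, readable_codons(ac, cls, "wobble"))
      if (cls == "AS5" && identical(
            sort(readable_codons(ac, "AS4_top", model)),
            sort(readable_codons(ac, "AS5", model))))
        break  # stem class irrelevant for this base: keep one copy
    }
    if (!length(units))
      stop("infeasible under model: no legal unit covers box ", bx,
           call. = FALSE)
    best <- NULL
    for (size in seq_along(units)) {
      combos <- utils::combn(length(units), size, simplify = FALSE)
      for (cmb in combos) {
        cov <- unique(unlist(lapply(units[cmb], `[[`, "reads")))
        if (all(codons %in% cov)) { best <- cmb; break }
      }
      if (!is.null(best)) break
    }
    if (is.null(best))
      stop("infeasible under model: box ", bx, " cannot be covered",
           call. = FALSE)
    total <- total + length(best)
    for (u in units[best])
      witness[[length(witness) + 1]] <-
        data.frame(amino_acid = this_aa, anticodon = u$anticodon,
                   as_class = u$as_class,
                   codons = paste(u$reads, collapse = ","))
  }
  list(size = total, witness = do.call(rbind, witness))
}
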