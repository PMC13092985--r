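#' Cloverleaf arm annotation and anticodon-stem classification
#'
#' The cloverleaf secondary structure of a tRNA consists of the acceptor,
#' D, anticodon, (optional) variable and T arms.  Helices are recovered from
#' the pair map as maximal runs of stacked pairs, tolerating at most one
#' single-nucleotide bulge per strand per helix; a second bulge on the same
#' strand (or a 1x1 internal loop) splits the helix.  The anticodon stem (AS)
#' is the helix whose innermost pair most tightly encloses the anticodon
#' triplet; the acceptor is the outermost helix; the D stem is the first
#' remaining helix 5' of the AS and the T stem the last helix 3' of it.
#'
#' @name arm_annotation
NULL

# Split a pair matrix (sorted by i) into helices.
segment_helices <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0) return(list())
  helices <- list()
  cur <- 1L
  b5 <- FALSE; b3 <- FALSE
  start <- 1L
  for (k in seq_len(n - 1)[n > 1]) {
    gap5 <- pairs[k + 1, "i"] - pairs[k, "i"] - 1L
    gap3 <- pairs[k, "j"] - pairs[k + 1, "j"] - 1L
    stacked <- FALSE
    if (pairs[k + 1, "j"] < pairs[k, "j"] && gap5 >= 0 && gap3 >= 0) {
      if (gap5 == 0 && gap3 == 0) stacked <- TRUE
      else if (gap5 == 1 && gap3 == 0 && !b5) { stacked <- TRUE; b5 <- TRUE }
      else if (gap5 == 0 && gap3 == 1 && !b3) { stacked <- TRUE; b3 <- TRUE }
    }
    if (!stacked) {
      helices[[length(helices) + 1]] <- pairs[start:k, , drop = FALSE]
      start <- k + 1L
      b5 <- FALSE; b3 <- FALSE
    }
  }
  helices[[length(helices) + 1]] <- pairs[start:n, , drop = FALSE]
  helices
}

#' Annotate the arms of a tRNA cloverleaf
#'
#' @param record A [trna_record()].
#' @param pairs Pair map from [pair_map()]; computed from the record's
#'   structure when omitted.
#' @return An object of class `arm_annotation`: a list with the pair
#'   matrices `acceptor`, `d_stem`, `anticodon_stem`, `variable_stem`,
#'   `t_stem` (any of which may be `NULL`), the helix list, `al_length`
#'   (anticodon-loop length in nt), and `as_span5`/`as_span3`
#'   (bulge-inclusive strand spans).  When no helix distinct from the
#'   acceptor encloses the anticodon, `anticodon_stem` is `NULL` and the
#'   record falls through to the `OTHER` bin downstream.
#' @export
annotate_arms <- function(record, pairs = NULL) {
  if (is.null(pairs)) pairs <- pair_map(record$structure)
  helices <- segment_helices(pairs)
  out <- list(acceptor = NULL, d_stem = NULL, anticodon_stem = NULL,
              variable_stem = NULL, t_stem = NULL, helices = helices,
              al_length = NA_integer_, as_span5 = NA_integer_,
              as_span3 = NA_integer_)
  class(out) <- "arm_annotation"
  if (!length(helices)) return(out)
  outermost <- which.min(vapply(helices, function(h) min(h[, "i"]), 1))
  out$acceptor <- helices[[outermost]]
  ac_lo <- record$anticodon_start
  ac_hi <- ac_lo + 2L
  # tightest helix enclosing the anticodon triplet, other than the acceptor
  encl <- which(vapply(helices, function(h) {
    max(h[, "i"]) < ac_lo && min(h[, "j"]) > ac_hi
  }, logical(1)))
  encl <- setdiff(encl, outermost)
  if (!length(encl)) return(out)
  as_idx <- encl[which.max(vapply(encl, function(k) max(helices[[k]][, "i"]), 1))]
  as_h <- helices[[as_idx]]
  out$anticodon_stem <- as_h
  inner <- which.max(as_h[, "i"])
  out$al_length <- unname(as_h[inner, "j"] - as_h[inner, "i"] - 1L)
  out$as_span5 <- unname(max(as_h[, "i"]) - min(as_h[, "i"]) + 1L)
  out$as_span3 <- unname(max(as_h[, "j"]) - min(as_h[, "j"]) + 1L)
  rest <- setdiff(seq_along(helices), c(outermost, as_idx))
  if (length(rest)) {
    firsts <- vapply(rest, function(k) min(helices[[k]][, "i"]), 1)
    before <- rest[firsts < min(as_h[, "i"])]
    after <- rest[firsts > max(as_h[, "j"])]
    if (length(before))
      out$d_stem <- helices[[before[which.min(vapply(before, function(k)
        min(helices[[k]][, "i"]), 1))]]]
    if (length(after)) {
      ord <- after[order(vapply(after, function(k) min(helices[[k]][, "i"]), 1))]
      out$t_stem <- helices[[ord[length(ord)]]]
      if (length(ord) > 1)
        out$variable_stem <- helices[[ord[1]]]
    }
  }
  out
}

#' Bulge-inclusive anticodon-stem span
#'
#' The stem length bin counts, per strand, the total number of nucleotides
#' between and including the outermost paired nucleotides; the larger strand
#' span defines the bin, so a stem of four pairs with one unpaired
#' nucleotide in between bins as 5 bp.
#'
#' @param arm An [annotate_arms()] result with a non-`NULL` anticodon stem.
#' @return List with `span5`, `span3` and `bin_length = max(span5, span3)`.
#' @export
as_span <- function(arm) {
  stopifnot(!is.null(arm$anticodon_stem))
  list(span5 = arm$as_span5, span3 = arm$as_span3,
       bin_length = max(arm$as_span5, arm$as_span3))
}

#' Map canonical tRNA positions 9, 24, 27 and 43
#'
#' Positions follow the conventional cloverleaf numbering: position 8 is the
#' first unpaired nucleotide after the acceptor 5' strand and position 9 the
#' next one (undefined when only a single nucleotide separates the acceptor
#' strand from the D stem); position 24 pairs with the second nucleotide of
#' the D-stem 5' strand; positions 27 and 43 are the outermost anticodon-stem
#' pair for a 5-bp stem, or, for a 4-bp stem unpinned at the top, the
#' unpaired nucleotides immediately flanking the outermost remaining pair.
#'
#' @param record A [trna_record()].
#' @param arm An [annotate_arms()] result.
#' @return List of 1-based sequence indices `pos8`, `pos9`, `pos24`,
#'   `pos27`, `pos43`; `NA` where a position cannot be mapped.
#' @export
canonical_positions <- function(record, arm) {
  out <- list(pos8 = NA_integer_, pos9 = NA_integer_, pos24 = NA_integer_,
              pos27 = NA_integer_, pos43 = NA_integer_)
  if (is.null(arm$acceptor)) return(out)
  acc5_last <- max(arm$acceptor[, "i"])
  out$pos8 <- acc5_last + 1L
  if (!is.null(arm$d_stem)) {
    d <- arm$d_stem
    d_first <- min(d[, "i"])
    if (d_first - acc5_last - 1L >= 2L) out$pos9 <- acc5_last + 2L
    if (nrow(d) >= 2) {
      second <- d[order(d[, "i"]), , drop = FALSE][2, ]
      if (second["i"] == d_first + 1L) out$pos24 <- unname(second["j"])
    }
  } else if (!is.null(arm$anticodon_stem)) {
    # no D stem: position 9 still maps if at least two nt follow the acceptor
    if (min(arm$anticodon_stem[, "i"]) - acc5_last - 1L >= 2L)
      out$pos9 <- acc5_last + 2L
  }
  if (!is.null(arm$anticodon_stem)) {
    as_h <- arm$anticodon_stem
    sp <- as_span(arm)
    i_out <- min(as_h[, "i"]); j_out <- max(as_h[, "j"])
    inner <- which.max(as_h[, "i"])
    al <- as_h[inner, "j"] - as_h[inner, "i"] - 1L
    if (sp$bin_length == 4L && al == 7L) {
      out$pos27 <- i_out - 1L
      out$pos43 <- j_out + 1L
    } else {
      out$pos27 <- i_out
      out$pos43 <- j_out
    }
  }
  out
}

#' Classify the anticodon-stem architecture of one tRNA
#'
#' Bins the anticodon stem by its bulge-inclusive span: 5 -> `AS5`; 4 with a
#' 7-nt anticodon loop -> `AS4_top` (unpinned at the top), 4 with a 9-nt
#' loop -> `AS4_bottom`, 4 otherwise -> `AS4_other`; anything else ->
#' `OTHER`.  The A9C and G24A flags are identity checks at the mapped
#' canonical positions.  A tRNA is Blastocrithidia-like when it is
#' `AS4_top` and carries neither substitution; unknown positions make the
#' flag `FALSE` by caution (and leave the flags `NA`).
#'
#' @param record A [trna_record()].
#' @return An object of class `as_classification`: record/genome ids,
#'   isotype, anticodon (RNA alphabet), `as_bin`, `as_paired_count`,
#'   `al_length`, bases at positions 9/24/27/43 (`NA` = unknown),
#'   `flag_A9C`, `flag_G24A`, `unpinned_pair` (e.g. `"A:G"`, only for
#'   `AS4_top`), `blasto_like`, and a `note`.
#' @export
classify <- function(record) {
  res <- list(record_id = record$record_id, genome_id = record$genome_id,
              isotype = record$isotype, anticodon = rna(record$anticodon),
              as_bin = "OTHER", as_paired_count = NA_integer_,
              al_length = NA_integer_,
              pos9 = NA_character_, pos24 = NA_character_,
              pos27 = NA_character_, pos43 = NA_character_,
              flag_A9C = NA, flag_G24A = NA,
              unpinned_pair = NA_character_, blasto_like = FALSE,
              note = "")
  class(res) <- "as_classification"
  pairs <- tryCatch(pair_map(record$structure), error = function(e) e)
  if (inherits(pairs, "error")) {
    res$note <- conditionMessage(pairs)
    return(res)
  }
  arm <- annotate_arms(record, pairs)
  if (is.null(arm$anticodon_stem)) {
    res$note <- "no helix encloses the anticodon"
    return(res)
  }
  sp <- as_span(arm)
  res$as_paired_count <- nrow(arm$anticodon_stem)
  res$al_length <- arm$al_length
  res$as_bin <-
    if (sp$bin_length == 5L) "AS5"
    else if (sp$bin_length == 4L) {
      if (arm$al_length == 7L) "AS4_top"
      else if (arm$al_length == 9L) "AS4_bottom"
      else "AS4_other"
    } else "OTHER"
  pos <- canonical_positions(record, arm)
  seq_u <- strsplit(rna(record$sequence), "")[[1]]
  base_at <- function(idx) {
    if (is.na(idx) || idx < 1 || idx > length(seq_u)) NA_character_
    else seq_u[idx]
  }
  res$pos9 <- base_at(pos$pos9)
  res$pos24 <- base_at(pos$pos24)
  res$pos27 <- base_at(pos$pos27)
  res$pos43 <- base_at(pos$pos43)
  res$flag_A9C <- if (is.na(res$pos9)) NA else res$pos9 == "C"
  res$flag_G24A <- if (is.na(res$pos24)) NA else res$pos24 == "A"
  if (res$as_bin == "AS4_top" && !is.na(res$pos27) && !is.na(res$pos43))
    res$unpinned_pair <- paste0(res$pos27, ":", res$pos43)
  res$blasto_like <- isTRUE(res$as_bin == "AS4_top" &&
                            isFALSE(res$flag_A9C) && isFALSE(res$flag_G24A))
  res
}

#' @export
print.as_classification <- function(x, ...) {
  cat(sprintf("<as_classification %s> %s-%s %s (pairs %s, AL %s)%s\n",
              x$record_id, x$isotype, x$anticodon, x$as_bin,
              x$as_paired_count, x$al_length,
              if (x$blasto_like) " blasto-like" else ""))
  invisible(x)
}

#' Filter tRNA records before classification
#'
#' Excludes putative pseudogenes, records of undetermined type, records
#' whose anticodon contains characters outside `A,C,G,T,U`, and records
#' whose anticodon triplet does not lie fully within sequence positions
#' 33-37 (triplet start in 33-35).  Every exclusion carries a
#' machine-readable reason code: `pseudogene`, `undetermined`,
#' `anticodon_nonstandard`, `anticodon_window`.
#'
#' @param records List of [trna_record()] objects.
#' @return List with `kept` (records) and `excluded` (data frame with
#'   columns `record_id`, `genome_id`, `reason`).
#' @export
filter_records <- function(records) {
  if (inherits(records, "trna_record")) records <- list(records)
  reason <- vapply(records, function(r) {
    if (r$pseudogene) return("pseudogene")
    if (identical(r$isotype, "Undet")) return("undetermined")
    if (grepl("[^ACGUacgu]", rna(r$anticodon))) return("undetermined")
    if (r$anticodon_start < 33L || r$anticodon_start > 35L)
      return("anticodon_window")
    ""
  }, character(1))
  keep <- reason == ""
  excluded <- data.frame(
    record_id = vapply(records[!keep], `[[`, "", "record_id"),
    genome_id = vapply(records[!keep], `[[`, "", "genome_id"),
    reason = reason[!keep])
  list(kept = records[keep], excluded = excluded)
}

#' Classify a set of tRNA records into a table
#'
#' Applies [filter_records()] and then [classify()] to every retained
#' record, returning the per-tRNA classification table written by the
#' pipeline.
#'
#' @param records List of [trna_record()] objects.
#' @return List with `classification` (data frame, one row per retained
#'   tRNA) and `excluded` (the exclusions data frame).
#' @export
classify_records <- function(records) {
  flt <- filter_records(records)
  rows <- lapply(flt$kept, function(r) {
    cl <- classify(r)
    data.frame(record_id = cl$record_id, genome_id = cl$genome_id,
               isotype = cl$isotype, anticodon = cl$anticodon,
               as_bin = cl$as_bin, as_paired_count = cl$as_paired_count,
               al_length = cl$al_length,
               pos9 = cl$pos9, pos24 = cl$pos24,
               pos27 = cl$pos27, pos43 = cl$pos43,
               flag_A9C = cl$flag_A9C, flag_G24A = cl$flag_G24A,
               unpinned_pair = cl$unpinned_pair,
               blasto_like = cl$blasto_like, note = cl$note)
  })
  classification <- if (length(rows)) do.call(rbind, rows)
    else utils::read.table(text = paste(
      "record_id genome_id isotype anticodon as_bin as_paired_count",
      "al_length pos9 pos24 pos27 pos43 flag_A9C flag_G24A unpinned_pair",
      "blasto_like note"), header = TRUE)[0, ]
  list(classification = classification, excluded = flt$excluded)
}

#' Flag Blastocrithidia-like tRNA-Trp(CCA) rows
#'
#' The tryptophan-specific report additionally requires the isotype to be
#' Trp and the anticodon CCA.
#'
#' @param classification Classification data frame from [classify_records()].
#' @return Logical vector over rows.
#' @export
is_blasto_trp <- function(classification) {
  classification$blasto_like &
    classification$isotype == "Trp" &
    classification$anticodon == "CCA"
}
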