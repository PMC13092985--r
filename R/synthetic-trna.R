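#' Seeded synthetic tRNA genes with planted structure
#'
#' [make_trna()] emits a cloverleaf tRNA gene with controlled anticodon-stem
#' geometry together with its ground-truth classification, for recovery
#' testing of the structural classifier.  The baseline geometry is a 76-nt
#' bacterial consensus: 7-bp acceptor stem, 4-bp D stem, 5-bp anticodon
#' stem, 7-nt anticodon loop (anticodon at positions 34-36), 5-nt variable
#' loop and 5-bp T stem.  The D loop absorbs length changes so that the
#' anticodon always starts at position 34.
#'
#' Unpinning is encoded as a genuine mispair: the lost base pair keeps both
#' nucleotides in the sequence, rendered as unpaired dots in the structure
#' string (exactly how tRNAscan-SE renders a non-Watson-Crick pair), either
#' distal from the loop ("top", anticodon loop stays 7 nt) or adjacent to
#' it ("bottom", loop grows to 9 nt).  A bulge inserts one extra unpaired
#' nucleotide inside the chosen strand next to the outermost pair, so a
#' 4-pair stem with a bulge spans - and bins as - 5 bp.
#'
#' @name synthetic_trna
NULL

#' Specification for one synthetic tRNA
#'
#' @param isotype Isotype label (default `"Trp"`).
#' @param anticodon Anticodon, 5'->3' (default `"CCA"`).
#' @param as_pairs Number of Watson-Crick pairs in the anticodon stem after
#'   any unpinning, 2-7.
#' @param unpinned `"none"`, `"top"` or `"bottom"`; requires `as_pairs == 4`.
#' @param bulge `"none"`, `"five_prime"` or `"three_prime"`.
#' @param plant_A9C,plant_G24A Plant the respective substitution at the
#'   mapped canonical position.
#' @param unpinned_bases Length-2 bases written at the mispaired (unpinned)
#'   positions, 5' then 3'; the default `c("A","G")` mimics a C27A
#'   substitution on a former C:G pair.
#' @param seed Integer RNG seed.
#' @return A `trna_spec` list.
#' @export
trna_spec <- function(isotype = "Trp", anticodon = "CCA", as_pairs = 5L,
                      unpinned = c("none", "top", "bottom"),
                      bulge = c("none", "five_prime", "three_prime"),
                      plant_A9C = FALSE, plant_G24A = FALSE,
                      unpinned_bases = c("A", "G"), seed = 1L) {
  unpinned <- match.arg(unpinned)
  bulge <- match.arg(bulge)
  if (as_pairs < 2 || as_pairs > 7)
    stop("as_pairs must be between 2 and 7", call. = FALSE)
  if (unpinned != "none" && as_pairs != 4L)
    stop("unpinned stems must have as_pairs == 4", call. = FALSE)
  if (nchar(anticodon) != 3)
    stop("anticodon must be a triplet", call. = FALSE)
  structure(list(isotype = isotype, anticodon = anticodon,
                 as_pairs = as.integer(as_pairs), unpinned = unpinned,
                 bulge = bulge, plant_A9C = isTRUE(plant_A9C),
                 plant_G24A = isTRUE(plant_G24A),
                 unpinned_bases = toupper(unpinned_bases),
                 seed = as.integer(seed)),
            class = "trna_spec")
}

DNA_BASES <- c("A", "C", "G", "T")
dna_complement <- function(x) chartr("ACGTU", "TGCAA", toupper(x))

#' Generate one synthetic tRNA gene
#'
#' @param spec A [trna_spec()].
#' @param record_id Record identifier (default `"synth.trna1"`).
#' @return List of class `trna_sim` with elements `record` (a
#'   [trna_record()]), `ss` (the record rendered in the "-ss" dialect),
#'   `truth` (the expected classification: `as_bin`, `as_paired_count`,
#'   `al_length`, `pos9`, `pos24`, `pos27`, `pos43`, `flag_A9C`,
#'   `flag_G24A`, `unpinned_pair`, `blasto_like`) and `spec`.
#' @export
make_trna <- function(spec, record_id = "synth.trna1") {
  stopifnot(inherits(spec, "trna_spec"))
  with_seed(spec$seed, make_trna_impl(spec, record_id))
}

make_trna_impl <- function(spec, record_id) {
  p <- spec$as_pairs
  b5 <- as.integer(spec$bulge == "five_prime")
  b3 <- as.integer(spec$bulge == "three_prime")
  top <- as.integer(spec$unpinned == "top")
  bot <- as.integer(spec$unpinned == "bottom")
  dl <- 13L - top - (p + b5) - bot          # D-loop length keeps anticodon at 34
  seg_len <- c(acc5 = 7L, linker = 2L, d5 = 4L, dloop = dl, d3 = 4L,
               link26 = 1L, top5 = top, stem5 = p + b5, bot5 = bot,
               al = 7L, bot3 = bot, stem3 = p + b3, top3 = top,
               var = 5L, t5 = 5L, tloop = 7L, t3 = 5L, acc3 = 7L, tail = 4L)
  ends <- cumsum(seg_len)
  seg <- lapply(seq_along(seg_len), function(k)
    if (seg_len[k] == 0) integer(0)
    else (ends[k] - seg_len[k] + 1L):ends[k])
  names(seg) <- names(seg_len)
  total <- ends[length(ends)]

  # pairing positions of the anticodon stem (outermost -> innermost)
  s5 <- seg$stem5
  p5 <- if (b5) s5[-2L] else s5
  s3 <- seg$stem3
  p3 <- if (b3) rev(s3)[-2L] else rev(s3)
  as_pairs_idx <- cbind(i = p5, j = p3)

  pairs <- rbind(
    cbind(i = seg$acc5, j = rev(seg$acc3)),
    cbind(i = seg$d5, j = rev(seg$d3)),
    as_pairs_idx,
    cbind(i = seg$t5, j = rev(seg$t3)))

  sq <- sample(DNA_BASES, total, replace = TRUE)
  for (k in seq_len(nrow(pairs)))
    sq[pairs[k, "j"]] <- dna_complement(sq[pairs[k, "i"]])

  # canonical positions and planted substitutions
  sq[seg$linker[2]] <- if (spec$plant_A9C) "C" else sample(c("A", "G", "T"), 1)
  d_partner <- rev(seg$d3)[2]               # pairs with the 2nd D-stem 5' base
  if (spec$plant_G24A) {
    sq[d_partner] <- "A"; sq[seg$d5[2]] <- "T"
  } else {
    sq[d_partner] <- "G"; sq[seg$d5[2]] <- "C"
  }
  if (top) {
    sq[seg$top5] <- chartr("U", "T", spec$unpinned_bases[1])
    sq[seg$top3] <- chartr("U", "T", spec$unpinned_bases[2])
  }
  if (bot) {
    sq[seg$bot5] <- chartr("U", "T", spec$unpinned_bases[1])
    sq[seg$bot3] <- chartr("U", "T", spec$unpinned_bases[2])
  }
  ac_dna <- strsplit(chartr("Uu", "Tt", toupper(spec$anticodon)), "")[[1]]
  sq[seg$al[3:5]] <- ac_dna
  sq[seg$tail] <- c(sample(DNA_BASES, 1), "C", "C", "A")

  st <- rep(".", total)
  st[pairs[, "i"]] <- ">"
  st[pairs[, "j"]] <- "<"

  record <- trna_record(record_id = record_id,
                        sequence = paste(sq, collapse = ""),
                        structure = paste(st, collapse = ""),
                        isotype = spec$isotype, anticodon = spec$anticodon,
                        anticodon_start = seg$al[3], score = 60)

  # ground truth from the planted geometry
  span5 <- p + b5; span3 <- p + b3
  bin_len <- max(span5, span3)
  al_len <- if (bot) 9L else 7L
  as_bin <-
    if (bin_len == 5L) "AS5"
    else if (bin_len == 4L) {
      if (al_len == 7L) "AS4_top" else "AS4_bottom"
    } else "OTHER"
  pos27_idx <- if (as_bin == "AS4_top") p5[1] - 1L else p5[1]
  pos43_idx <- if (as_bin == "AS4_top") p3[1] + 1L else p3[1]
  seq_u <- rna(sq)
  truth <- list(
    as_bin = as_bin, as_paired_count = p, al_length = al_len,
    pos9 = seq_u[seg$linker[2]], pos24 = seq_u[d_partner],
    pos27 = seq_u[pos27_idx], pos43 = seq_u[pos43_idx],
    flag_A9C = spec$plant_A9C, flag_G24A = spec$plant_G24A,
    unpinned_pair = if (as_bin == "AS4_top")
      paste0(seq_u[pos27_idx], ":", seq_u[pos43_idx]) else NA_character_,
    blasto_like = as_bin == "AS4_top" && !spec$plant_A9C && !spec$plant_G24A)

  structure(list(record = record, ss = write_ss_records(record),
                 truth = truth, spec = spec),
            class = "trna_sim")
}
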