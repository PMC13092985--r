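#' tRNA gene records and the tRNAscan-SE secondary-structure dialect
#'
#' A `trna_record` holds one predicted tRNA gene: its sequence, the
#' dot-bracket-style pairing string emitted by tRNAscan-SE (`>` opens a pair,
#' `<` closes it, `.` is unpaired), the isotype and anticodon, and provenance
#' flags (pseudogene, undetermined type).  Coordinates are 1-based and fully
#' closed, matching the display convention of tRNAscan-SE.
#'
#' @name trna_record
NULL

#' Construct a tRNA record
#'
#' @param record_id Record identifier, conventionally `<genome>.trna<k>`.
#' @param sequence Nucleotide sequence (DNA or RNA alphabet; case kept).
#' @param structure Pairing string of the same length over `>`, `<`, `.`.
#' @param isotype Amino-acid isotype label (`"Trp"`, `"Gly"`, ..., or
#'   `"fMet"`, `"iMet"`, `"Sup"`, `"Undet"`).
#' @param anticodon Three-letter anticodon as printed by the predictor.
#' @param anticodon_start 1-based index of the first anticodon base.
#' @param genome_id Genome identifier; defaults to the part of `record_id`
#'   before the final `.trna<k>` suffix.
#' @param pseudogene Logical, pseudogene note present.
#' @param undetermined Logical; set automatically when the isotype is
#'   `"Undet"` or the anticodon contains characters outside `A,C,G,T,U`.
#' @param score Optional covariance-model score.
#' @param validate Check the record invariants (default `TRUE`).
#'
#' @return An object of class `trna_record`.
#' @export
trna_record <- function(record_id, sequence, structure, isotype, anticodon,
                        anticodon_start, genome_id = NULL,
                        pseudogene = FALSE, undetermined = NA, score = NA_real_,
                        validate = TRUE) {
  if (is.null(genome_id)) genome_id <- sub("\\.trna[0-9]+$", "", record_id)
  if (is.na(undetermined)) {
    undetermined <- identical(isotype, "Undet") ||
      grepl("[^ACGTUacgtu]", anticodon)
  }
  rec <- structure(
    list(record_id = record_id, genome_id = genome_id,
         isotype = isotype, anticodon = anticodon,
         sequence = sequence, structure = structure,
         anticodon_start = as.integer(anticodon_start),
         pseudogene = isTRUE(pseudogene), undetermined = isTRUE(undetermined),
         score = as.numeric(score)),
    class = "trna_record")
  if (validate) {
    msg <- check_trna_record(rec)
    if (!is.null(msg)) stop(msg, call. = FALSE)
  }
  rec
}

#' @export
print.trna_record <- function(x, ...) {
  cat(sprintf("<trna_record %s> %s-%s at %d, %d nt%s\n", x$record_id,
              x$isotype, x$anticodon, x$anticodon_start, nchar(x$sequence),
              if (x$pseudogene) " [pseudogene]" else ""))
  invisible(x)
}

# Returns NULL if the record satisfies its invariants, else a message.
check_trna_record <- function(rec) {
  if (nchar(rec$sequence) != nchar(rec$structure))
    return(sprintf("%s: Seq length %d != Str length %d", rec$record_id,
                   nchar(rec$sequence), nchar(rec$structure)))
  s <- strsplit(rec$structure, "")[[1]]
  if (sum(s == ">") != sum(s == "<"))
    return(sprintf("%s: unbalanced '>'/'<' in structure", rec$record_id))
  i <- rec$anticodon_start
  if (!rec$undetermined && i >= 1 && i + 2 <= nchar(rec$sequence)) {
    got <- rna(substr(rec$sequence, i, i + 2))
    if (!identical(got, rna(rec$anticodon)))
      return(sprintf("%s: anticodon %s does not match sequence %s at %d",
                     rec$record_id, rec$anticodon, got, i))
  }
  NULL
}

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and replaces `T` with `U`.  Used for all anticodon and codon
#' comparisons; writers preserve the input alphabet.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector in the RNA alphabet.
#' @export
rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' Watson-Crick complement of RNA bases
#'
#' @param x Character vector of single RNA bases.
#' @return Complement bases; `I` (inosine) maps to `NA` (no canonical
#'   Watson-Crick partner).
#' @keywords internal
wc_complement <- function(x) {
  out <- chartr("ACGU", "UGCA", rna(x))
  out[!out %in% c("A", "C", "G", "U")] <- NA_character_
  out
}

#' Extract the base-pair map from a pairing string
#'
#' Matches each `>` with its closing `<` by stack discipline, yielding a
#' properly nested set of index pairs.
#'
#' @param structure Pairing string over `>`, `<`, `.`.
#' @return Integer matrix with columns `i`, `j` (1-based, `i < j`), ordered
#'   by `i`.  Zero rows when the string contains no pairs.
#' @examples
#' pair_map(">>..<<")   # pairs (1,6) and (2,5)
#' @export
pair_map <- function(structure) {
  s <- strsplit(structure, "")[[1]]
  bad <- which(!s %in% c(">", "<", "."))
  if (length(bad))
    stop(sprintf("invalid structure character '%s' at index %d", s[bad[1]],
                 bad[1]), call. = FALSE)
  open <- integer(0)
  res_i <- integer(0); res_j <- integer(0)
  for (k in seq_along(s)) {
    if (s[k] == ">") {
      open <- c(open, k)
    } else if (s[k] == "<") {
      if (!length(open))
        stop(sprintf("unmatched '<' at index %d", k), call. = FALSE)
      res_i <- c(res_i, open[length(open)])
      res_j <- c(res_j, k)
      open <- open[-length(open)]
    }
  }
  if (length(open))
    stop(sprintf("unmatched '>' at index %d", open[1]), call. = FALSE)
  m <- cbind(i = res_i, j = res_j)
  m[order(m[, "i"]), , drop = FALSE]
}

# ---- tRNAscan-SE "-ss" dialect ---------------------------------------------

#' Parse tRNAscan-SE secondary-structure ("-ss") output
#'
#' Reads the block dialect written by `tRNAscan-SE -f` (and by
#' [write_ss_records()]): a header line with the record name and genomic
#' coordinates, a `Type:` line carrying the isotype, anticodon and its
#' position, optional note lines (a line containing "pseudogene" sets the
#' pseudogene flag), and `Seq:`/`Str:` lines.  Malformed blocks are collected
#' as record-level errors and parsing continues.
#'
#' @param path_or_text Path to a file, or a character vector of lines, or a
#'   single string containing the whole stream.
#' @return A list with elements `records` (list of [trna_record()]) and
#'   `errors` (data frame with columns `block`, `record_id`, `message`).
#' @export
parse_ss_records <- function(path_or_text) {
  lines <-
    if (length(path_or_text) == 1 && !grepl("\n", path_or_text) &&
        file.exists(path_or_text)) readLines(path_or_text, warn = FALSE)
    else unlist(strsplit(path_or_text, "\n"))
  # blocks are separated by blank lines
  blank <- grepl("^\\s*$", lines)
  grp <- cumsum(blank)[!blank]
  chunks <- split(lines[!blank], grp)
  records <- list()
  errs <- list()
  for (bi in seq_along(chunks)) {
    blk <- chunks[[bi]]
    rec_id <- sub("\\s.*$", "", blk[1])
    res <- tryCatch(parse_ss_block(blk), error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1]] <-
        data.frame(block = bi, record_id = rec_id,
                   message = conditionMessage(res))
    } else {
      records[[length(records) + 1]] <- res
    }
  }
  errors <- if (length(errs)) do.call(rbind, errs)
            else data.frame(block = integer(0), record_id = character(0),
                            message = character(0))
  list(records = records, errors = errors)
}

parse_ss_block <- function(blk) {
  head <- blk[1]
  m <- regmatches(head, regexec("^(\\S+)\\s+\\((\\-?[0-9]+)-(\\-?[0-9]+)\\)", head))[[1]]
  if (length(m) < 4) stop("malformed header line: ", head)
  record_id <- m[2]
  type_line <- grep("^Type:", blk, value = TRUE)
  if (!length(type_line)) stop("missing Type: line")
  tm <- regmatches(type_line[1],
        regexec("^Type:\\s*(\\S+)\\s+Anticodon:\\s*(\\S+)\\s+at\\s+([0-9]+)-([0-9]+)",
                type_line[1]))[[1]]
  if (length(tm) < 5) stop("malformed Type: line: ", type_line[1])
  isotype <- tm[2]; anticodon <- tm[3]
  ac_start <- as.integer(tm[4])
  score <- NA_real_
  sm <- regmatches(type_line[1], regexec("Score:\\s*(\\-?[0-9.]+)", type_line[1]))[[1]]
  if (length(sm) == 2) score <- as.numeric(sm[2])
  seq_line <- grep("^Seq:", blk, value = TRUE)
  str_line <- grep("^Str:", blk, value = TRUE)
  if (!length(seq_line) || !length(str_line)) stop("missing Seq:/Str: line")
  sequence <- sub("^Seq:\\s*", "", seq_line[1])
  structure <- sub("^Str:\\s*", "", str_line[1])
  pseudo <- any(grepl("pseudogene", blk, ignore.case = TRUE))
  trna_record(record_id = record_id, sequence = sequence,
              structure = structure, isotype = isotype, anticodon = anticodon,
              anticodon_start = ac_start, pseudogene = pseudo, score = score)
}

#' Write tRNA records in the "-ss" dialect
#'
#' Inverse of [parse_ss_records()]: emits one block per record, so that
#' `parse_ss_records(write_ss_records(r))` round-trips field for field.
#'
#' @param records A `trna_record` or list of them.
#' @param path Optional output file; when `NULL` the text is returned.
#' @return The text (invisibly when written to `path`).
#' @export
write_ss_records <- function(records, path = NULL) {
  if (inherits(records, "trna_record")) records <- list(records)
  blocks <- vapply(records, function(r) {
    ac_end <- r$anticodon_start + 2L
    paste0(
      sprintf("%s (1-%d)\tLength: %d bp\n", r$record_id, nchar(r$sequence),
              nchar(r$sequence)),
      sprintf("Type: %s\tAnticodon: %s at %d-%d (%d-%d)\tScore: %s\n",
              r$isotype, r$anticodon, r$anticodon_start, ac_end,
              r$anticodon_start, ac_end,
              ifelse(is.na(r$score), "0.0", format(r$score, nsmall = 1))),
      if (r$pseudogene) "Possible pseudogene:  HMM Sc=0.00\n" else "",
      sprintf("Seq: %s\n", r$sequence),
      sprintf("Str: %s\n", r$structure))
  }, character(1))
  txt <- paste(blocks, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read the tRNAscan-SE tabular (".out") dialect
#'
#' Parses the whitespace/tab-delimited summary table (sequence name, tRNA
#' number, begin, end, type, anticodon, intron begin/end, score, optional
#' note column).  Lines starting with `Sequence`, `Name` or `----` are
#' treated as the header and skipped.
#'
#' @param path Path to the `.out` file.
#' @return A data frame with one row per predicted tRNA.
#' @export
read_trnascan_out <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(Sequence|Name|--------)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(genome_id = character(0), trna_no = integer(0),
                      begin = integer(0), end = integer(0),
                      isotype = character(0), anticodon = character(0),
                      intron_begin = integer(0), intron_end = integer(0),
                      score = numeric(0), note = character(0)))
  fields <- strsplit(trimws(lines), "\t|\\s{2,}|\\s+")
  df <- do.call(rbind, lapply(fields, function(f) {
    data.frame(genome_id = f[1], trna_no = as.integer(f[2]),
               begin = as.integer(f[3]), end = as.integer(f[4]),
               isotype = f[5], anticodon = f[6],
               intron_begin = as.integer(f[7]), intron_end = as.integer(f[8]),
               score = as.numeric(f[9]),
               note = if (length(f) >= 10) paste(f[-(1:9)], collapse = " ")
                      else "")
  }))
  df
}
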