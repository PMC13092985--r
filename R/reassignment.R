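#' Stop-to-tryptophan UGA reassignment validation
#'
#' A genome where UGA has been reassigned to tryptophan should show (i) no
#' UGA at the ends of its coding sequences, (ii) no artificial C-terminal
#' protein extensions when its proteins are conceptually translated under
#' the reassigned code and aligned against standard-code orthologues
#' (translation through a genuine UGA stop would run on to the next
#' UAA/UAG), and often (iii) a suppressor tRNA with a UCA anticodon, or a
#' strong codon-inference signal.  These checks are combined into an
#' evidence summary with a supported / contradicted / inconclusive verdict.
#'
#' @name reassignment
NULL

#' Center-star multiple sequence alignment
#'
#' Picks as center the sequence maximizing the summed pairwise alignment
#' scores, then merges all center-pairwise alignments with the
#' "once a gap, always a gap" rule.  Adequate for the conserved, sparsely
#' gapped protein families the validation procedure consumes.
#'
#' @param proteins Named character vector of >= 2 sequences.
#' @param ... Scoring parameters passed to [nw_align()].
#' @return Object of class `orthogroup_alignment`: list with `rows`
#'   (named character vector of gapped rows, equal lengths) and `center`
#'   (name of the center sequence).
#' @export
center_star_msa <- function(proteins, ...) {
  n <- length(proteins)
  if (n < 1) stop("empty input", call. = FALSE)
  if (is.null(names(proteins)))
    names(proteins) <- paste0("seq", seq_len(n))
  if (n == 1)
    return(structure(list(rows = proteins, center = names(proteins)),
                     class = "orthogroup_alignment"))
  alns <- matrix(list(), n, n)
  scores <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- nw_align(proteins[[i]], proteins[[j]], ...)
    alns[[i, j]] <- al
    scores[i, j] <- scores[j, i] <- al$score
  }
  center <- which.max(rowSums(scores))
  # progressive merge against the center
  msa_center <- strsplit(toupper(proteins[[center]]), "")[[1]]
  rows <- list()
  rows[[names(proteins)[center]]] <- msa_center
  for (k in setdiff(seq_len(n), center)) {
    al <- if (k > center) alns[[center, k]] else {
      a <- alns[[k, center]]
      list(aligned_a = a$aligned_b, aligned_b = a$aligned_a)
    }
    ca <- strsplit(al$aligned_a, "")[[1]]  # center with pairwise gaps
    ka <- strsplit(al$aligned_b, "")[[1]]
    # map the pairwise center row onto the current master center row
    master <- rows[[names(proteins)[center]]]
    mi <- 1L; pi <- 1L
    new_master_cols <- character(0)
    merged_rows <- lapply(rows, function(r) character(0))
    new_row <- character(0)
    while (mi <= length(master) || pi <= length(ca)) {
      m_gap <- mi <= length(master) && master[mi] == "-"
      p_gap <- pi <= length(ca) && ca[pi] == "-"
      if (mi <= length(master) && pi <= length(ca) && !m_gap && !p_gap) {
        merged_rows <- Map(function(r, old) c(r, old[mi]), merged_rows, rows)
        new_row <- c(new_row, ka[pi])
        mi <- mi + 1L; pi <- pi + 1L
      } else if (m_gap || pi > length(ca)) {
        merged_rows <- Map(function(r, old) c(r, old[mi]), merged_rows, rows)
        new_row <- c(new_row, "-")
        mi <- mi + 1L
      } else {
        merged_rows <- Map(function(r, old) c(r, "-"), merged_rows, rows)
        new_row <- c(new_row, ka[pi])
        pi <- pi + 1L
      }
    }
    rows <- merged_rows
    rows[[names(proteins)[k]]] <- new_row
  }
  rows <- vapply(rows[names(proteins)], paste, "", collapse = "")
  structure(list(rows = rows, center = names(proteins)[center]),
            class = "orthogroup_alignment")
}

#' Conserved C-terminus filter
#'
#' Retains an orthogroup alignment only when no gap character appears in
#' any of its last `k` columns - a proxy for proteins with conserved
#' C-terminal regions.
#'
#' @param alignment An `orthogroup_alignment` (or named character vector
#'   of gapped rows) of standard-code members only.
#' @param k Number of terminal columns to inspect (default 5).
#' @return `TRUE`/`FALSE`.
#' @export
conserved_cterm_filter <- function(alignment, k = 5) {
  rows <- if (inherits(alignment, "orthogroup_alignment")) alignment$rows
          else alignment
  stopifnot(length(rows) >= 2)
  width <- nchar(rows[[1]])
  if (k == 0) return(TRUE)
  if (width < k) stop("alignment shorter than k columns", call. = FALSE)
  tails <- substring(rows, width - k + 1, width)
  !any(grepl("-", tails, fixed = TRUE))
}

#' Measure a C-terminal extension of a reassigned-code protein
#'
#' The reference end column is the rightmost column holding the C-terminal
#' residue of any standard-code row (the maximum over references, the most
#' conservative choice against false extension calls).  The extension is
#' the number of non-gap target residues strictly after that column.
#' Target rows shorter than the references count as 0 (truncations are
#' reported separately by callers).
#'
#' @param alignment An `orthogroup_alignment` (or named vector of gapped
#'   rows) containing the target and the standard-code references.
#' @param target Name of the single reassigned-code row.
#' @param reference_end `"max"` (default), `"min"` or `"median"` over the
#'   reference end columns.
#' @return Integer extension length in residues.
#' @export
cterm_extension <- function(alignment, target,
                            reference_end = c("max", "min", "median")) {
  reference_end <- match.arg(reference_end)
  rows <- if (inherits(alignment, "orthogroup_alignment")) alignment$rows
          else alignment
  if (!target %in% names(rows)) stop("target row absent", call. = FALSE)
  last_residue_col <- function(row) {
    v <- strsplit(row, "")[[1]]
    w <- which(v != "-")
    if (length(w)) max(w) else 0L
  }
  ref_rows <- rows[setdiff(names(rows), target)]
  stopifnot(length(ref_rows) >= 1)
  ends <- vapply(ref_rows, last_residue_col, 1L)
  ref_end <- switch(reference_end, max = max(ends), min = min(ends),
                    median = as.integer(stats::median(ends)))
  tv <- strsplit(rows[[target]], "")[[1]]
  if (ref_end >= length(tv)) return(0L)
  sum(tv[(ref_end + 1):length(tv)] != "-")
}

#' Validate one orthogroup for an artificial C-terminal extension
#'
#' Runs the full per-family procedure: aligns the standard-code members
#' (center-star), applies the conserved C-terminus filter, then realigns
#' all members including the reassigned-code target and measures its
#' extension.
#'
#' @param proteins Named character vector of member proteins.
#' @param codes Character vector (same order) of code labels; exactly one
#'   member must be `"trp_uga"` (the target), the rest `"standard"`.
#' @param k Conserved C-terminus window (default 5 columns).
#' @return List with `filter_pass`, `extension` (NA when the filter
#'   fails), `truncated` (logical), and `target`.
#' @export
validate_orthogroup <- function(proteins, codes, k = 5) {
  stopifnot(length(proteins) == length(codes))
  target_ix <- which(codes != "standard")
  if (length(target_ix) != 1)
    stop("exactly one reassigned-code member expected", call. = FALSE)
  if (is.null(names(proteins)))
    names(proteins) <- paste0("seq", seq_along(proteins))
  target <- names(proteins)[target_ix]
  refs <- proteins[-target_ix]
  if (length(refs) < 2)
    stop("need >= 2 standard-code references", call. = FALSE)
  ref_aln <- center_star_msa(refs)
  pass <- conserved_cterm_filter(ref_aln, k = k)
  if (!pass)
    return(list(filter_pass = FALSE, extension = NA_integer_,
                truncated = NA, target = target))
  full_aln <- center_star_msa(proteins)
  ext <- cterm_extension(full_aln, target)
  tv <- strsplit(full_aln$rows[[target]], "")[[1]]
  last_t <- max(which(tv != "-"))
  ends <- vapply(full_aln$rows[setdiff(names(full_aln$rows), target)],
                 function(r) {
                   v <- strsplit(r, "")[[1]]
                   max(which(v != "-"))
                 }, 1L)
  list(filter_pass = TRUE, extension = ext, truncated = last_t < min(ends),
       target = target)
}

#' Suppressor-tRNA check
#'
#' @param classification Classification data frame from
#'   [classify_records()] (retained records).
#' @return `TRUE` iff any retained record carries a UCA anticodon (fully
#'   cognate to the UGA stop codon).
#' @export
suppressor_check <- function(classification) {
  nrow(classification) > 0 && any(classification$anticodon == "UCA")
}

#' Summarize reassignment evidence for one genome
#'
#' The verdict is `supported` when no UGA terminates a coding sequence, no
#' orthogroup shows a C-terminal extension, and either a suppressor
#' tRNA(UCA) is present or the upstream codon-inference support reaches
#' `codetta_min` consensus columns; `contradicted` when UGA stop usage or
#' extensions are observed; otherwise `inconclusive`.
#'
#' @param pct_uga_at_cds_ends Percentage of coding sequences ending in UGA.
#' @param n_cterm_extensions Number of orthogroups with a positive
#'   C-terminal extension.
#' @param suppressor_uca_present Logical.
#' @param codetta_support_columns Input support value (consensus columns)
#'   from upstream genetic-code inference; `NA` when unavailable.
#' @param rf2_present Input flag: release factor 2 found in the genome.
#' @param codetta_min Support threshold (default 100 columns).
#' @return List of class `evidence_summary` with the inputs, `verdict` and
#'   `reasons`.
#' @export
summarize_evidence <- function(pct_uga_at_cds_ends, n_cterm_extensions,
                               suppressor_uca_present,
                               codetta_support_columns = NA_real_,
                               rf2_present = NA, codetta_min = 100) {
  reasons <- character(0)
  if (pct_uga_at_cds_ends > 0)
    reasons <- c(reasons, sprintf("UGA terminates %.1f%% of coding sequences",
                                  pct_uga_at_cds_ends))
  if (n_cterm_extensions > 0)
    reasons <- c(reasons, sprintf("%d orthogroup(s) show C-terminal extensions",
                                  n_cterm_extensions))
  support <- isTRUE(suppressor_uca_present) ||
    (!is.na(codetta_support_columns) && codetta_support_columns >= codetta_min)
  if (!support)
    reasons <- c(reasons,
                 "no suppressor tRNA(UCA) and insufficient code-inference support")
  if (isTRUE(rf2_present))
    reasons <- c(reasons, "release factor 2 present")
  verdict <- if (pct_uga_at_cds_ends == 0 && n_cterm_extensions == 0 && support)
    "supported"
  else if (pct_uga_at_cds_ends > 0 || n_cterm_extensions > 0)
    "contradicted"
  else "inconclusive"
  structure(list(suppressor_uca_present = isTRUE(suppressor_uca_present),
                 rf2_present = rf2_present,
                 pct_uga_at_cds_ends = pct_uga_at_cds_ends,
                 n_cterm_extensions = n_cterm_extensions,
                 codetta_support_columns = codetta_support_columns,
                 verdict = verdict, reasons = reasons),
            class = "evidence_summary")
}

#' @export
print.evidence_summary <- function(x, ...) {
  cat(sprintf("<evidence_summary> verdict: %s\n", x$verdict))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}
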