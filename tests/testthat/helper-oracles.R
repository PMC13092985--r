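# Independent oracles used across tests.  These deliberately use different
# algorithms from the package implementations they check.

# Pair matcher oracle: repeatedly pair an innermost "> ... <" with no
# brackets in between, remove it, repeat.
brute_pair_map <- function(structure) {
  s <- strsplit(structure, "")[[1]]
  res <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  repeat {
    opens <- which(s == ">")
    found <- FALSE
    for (i in opens) {
      after <- if (i < length(s)) s[(i + 1):length(s)] else character(0)
      br <- which(after %in% c(">", "<"))
      if (length(br) && after[br[1]] == "<") {
        j <- i + br[1]
        res <- rbind(res, c(i, j))
        s[i] <- "."; s[j] <- "."
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  res[order(res[, 1]), , drop = FALSE]
}

# Random properly nested structure string of length n.
random_structure <- function(n) {
  s <- character(n)
  open <- 0L
  for (k in seq_len(n)) {
    r <- stats::runif(1)
    if (r < 0.35 && (n - k) > open) { s[k] <- ">"; open <- open + 1L }
    else if (r < 0.65 && open > 0) { s[k] <- "<"; open <- open - 1L }
    else s[k] <- "."
  }
  # blank any opens left unmatched on the stack
  stack <- integer(0)
  for (k in seq_len(n)) {
    if (s[k] == ">") stack <- c(stack, k)
    else if (s[k] == "<") stack <- stack[-length(stack)]
  }
  s[stack] <- "."
  paste(s, collapse = "")
}

# Exhaustive global-alignment score by plain recursion (n, m <= 8).
brute_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  f <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, f(i - 1, j - 1) +
                        if (av[i] == bv[j]) match else mismatch)
    if (i > 0) best <- max(best, f(i - 1, j) + gap)
    if (j > 0) best <- max(best, f(i, j - 1) + gap)
    best
  }
  f(length(av), length(bv))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Random tRNA repertoire rows for coverage tests.
random_trna_set <- function(n) {
  rep <- stemwobble::standard_anticodons()
  rows <- rep[sample(nrow(rep), n, replace = TRUE), ]
  rows$as_bin <- sample(c("AS5", "AS4_top", "AS4_bottom"), n,
                        replace = TRUE, prob = c(0.7, 0.2, 0.1))
  rows$record_id <- paste0("t", seq_len(n))
  rows
}

# Minimal classification data frame for pipeline tests (no real records).
fake_classification <- function(genome_id, isotype, anticodon, as_bin) {
  n <- max(length(isotype), length(anticodon), length(as_bin))
  data.frame(record_id = paste0(genome_id, ".trna", seq_len(n)),
             genome_id = genome_id, isotype = isotype,
             anticodon = anticodon, as_bin = as_bin,
             blasto_like = FALSE)
}

# Quick stop-terminated CDS: all-sense body plus the requested stop.
fake_cds <- function(stops) {
  vapply(stops, function(st) paste0("ATGGCTGCA", chartr("U", "T", st)), "",
         USE.NAMES = FALSE)
}
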