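# Independent brute-force oracles. These deliberately re-derive each
# quantity with the most naive algorithm available so the package
# implementations are checked against something structurally different.

# position-by-position dinucleotide recount
naive_dinuc_count <- function(sequences) {
  bases <- c("A", "C", "G", "T")
  dinucs <- as.vector(outer(bases, bases, paste0))
  counts <- setNames(integer(16), dinucs)
  for (s in sequences) {
    s <- toupper(s)
    if (nchar(s) < 2) next
    for (i in seq_len(nchar(s) - 1)) {
      d <- substr(s, i, i + 1)
      if (d %in% dinucs) counts[d] <- counts[d] + 1L
    }
  }
  counts
}

# per-base window fractions
naive_window_fracs <- function(seq_chars, iv, win_start, win_end) {
  covered <- rep(FALSE, length(seq_chars))
  for (k in seq_len(nrow(iv))) {
    if (iv$end[k] > iv$start[k]) {
      covered[(iv$start[k] + 1):iv$end[k]] <- TRUE
    }
  }
  span <- (win_start + 1):win_end
  mean(covered[span])
}

# Gotoh affine-gap global alignment score; match +1 / mismatch -1,
# a gap of length k costs 1 + k (same convention as alignment_stats)
gotoh_score <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  open <- 2; ext <- 1   # first gap char costs `open`, further chars `ext`
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in y (consume x)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in x (consume y)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - (i - 2) * ext
  for (j in 2:(m + 1)) Iy[1, j] <- -open - (j - 2) * ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) 1 else -1
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open, Iy[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# independent greedy clustering (same contract, separate implementation)
oracle_greedy <- function(seqs, threshold) {
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  assign <- character(length(seqs))
  for (i in seq_along(seqs)) {
    found <- NA_character_
    for (r in reps) {
      if (pairwise_identity(seqs[[i]], seqs[[r]]) >= threshold) {
        found <- r
        break
      }
    }
    if (is.na(found)) {
      reps <- c(reps, names(seqs)[i])
      assign[i] <- names(seqs)[i]
    } else {
      assign[i] <- found
    }
  }
  split(names(seqs), assign)
}

random_aa <- function(n) {
  paste(sample(LETTERS[1:20], n, replace = TRUE), collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a tiny deterministic genome object for interval-based tests
toy_genome <- function(seq, repeats = NULL, genes = NULL) {
  empty <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), type = character(),
                      stringsAsFactors = FALSE)
  g <- list(seqs = c(scf1 = seq),
            repeats = if (is.null(repeats)) empty else repeats,
            genes = if (is.null(genes)) empty else genes)
  class(g) <- "rip_genome"
  g
}

iv_df <- function(starts, ends, scaffold = "scf1", type = "x") {
  data.frame(scaffold = scaffold, start = starts, end = ends, type = type,
             stringsAsFactors = FALSE)
}
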