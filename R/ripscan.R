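#' Count overlapping dinucleotides in a set of sequences
#'
#' Dinucleotides are counted on the forward strand, overlapping within each
#' sequence but never across sequence boundaries. Pairs containing `N` are
#' skipped so assembly gaps do not dilute the frequencies.
#'
#' @param sequences character vector of nucleotide strings over
#'   `A, C, G, T, N`.
#' @return list of class `dinuc_profile` with `counts` (named integer vector
#'   over the 16 dinucleotides), `frequencies` (counts / n_sites), and
#'   `n_sites` (number of counted pairs).
#' @examples
#' count_dinucleotides(c("ACGT", "ACGT"))
#' @export
count_dinucleotides <- function(sequences) {
  if (length(sequences) == 0L || all(nchar(sequences) == 0L)) {
    stop("empty input: no sequences to count")
  }
  bases <- c("A", "C", "G", "T")
  dinucs <- as.vector(outer(bases, bases, paste0))
  counts <- stats::setNames(integer(16), dinucs)
  for (s in sequences) {
    n <- nchar(s)
    if (n < 2L) next
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(chars), c(bases, "N"))
    if (length(bad)) stop("unexpected characters in sequence: ",
                          paste(bad, collapse = ", "))
    pairs <- paste0(chars[-n], chars[-1L])
    pairs <- pairs[!grepl("N", pairs, fixed = TRUE)]
    if (length(pairs)) {
      tab <- table(factor(pairs, levels = dinucs))
      counts <- counts + as.integer(tab)
    }
  }
  n_sites <- sum(counts)
  if (n_sites == 0L) stop("all dinucleotide pairs contain N; empty profile")
  structure(list(counts = counts,
                 frequencies = counts / n_sites,
                 n_sites = n_sites),
            class = "dinuc_profile")
}

#' Dinucleotide fold change between repeat and control profiles
#'
#' For each of the 16 dinucleotides, computes the ratio and difference of
#' its frequency in repeats versus controls, the headline statistic of the
#' RIP analysis (CpA -> TpA mutation inflates TpA and depletes CpA/TpG in
#' repeats). Significance of over/underrepresentation is assessed with a
#' per-dinucleotide chi-square goodness-of-fit test of the repeat counts
#' against the control frequency, Bonferroni-corrected over the 16 tests.
#'
#' @param repeats,controls `dinuc_profile` objects from
#'   [count_dinucleotides()].
#' @param alpha significance level after Bonferroni correction.
#' @return data.frame with one row per dinucleotide: `repeat_freq`,
#'   `control_freq`, `fold`, `diff`, `p`, `p_adj`, `flag` (`"over"`,
#'   `"under"`, `"ns"`, or `"undefined"` where the control frequency is 0).
#' @export
fold_change <- function(repeats, controls, alpha = 0.05) {
  stopifnot(inherits(repeats, "dinuc_profile"),
            inherits(controls, "dinuc_profile"))
  dinucs <- names(repeats$counts)
  rf <- repeats$frequencies
  cf <- controls$frequencies
  fold <- ifelse(cf > 0, rf / cf, NA_real_)
  p <- vapply(dinucs, function(d) {
    if (cf[d] <= 0 || cf[d] >= 1) return(NA_real_)
    obs <- c(repeats$counts[d], repeats$n_sites - repeats$counts[d])
    suppressWarnings(stats::chisq.test(obs, p = c(cf[d], 1 - cf[d]))$p.value)
  }, numeric(1))
  p_adj <- pmin(p * length(dinucs), 1)
  flag <- ifelse(is.na(fold), "undefined",
          ifelse(!is.na(p_adj) & p_adj < alpha & fold > 1, "over",
          ifelse(!is.na(p_adj) & p_adj < alpha & fold < 1, "under", "ns")))
  data.frame(dinucleotide = dinucs,
             repeat_freq = as.numeric(rf),
             control_freq = as.numeric(cf),
             fold = as.numeric(fold),
             diff = as.numeric(rf - cf),
             p = as.numeric(p),
             p_adj = as.numeric(p_adj),
             flag = flag,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

.interval_gaps <- function(len, intervals) {
  # complement of half-open intervals within [0, len)
  if (nrow(intervals) == 0L) return(data.frame(start = 0L, end = len))
  iv <- intervals[order(intervals$start), , drop = FALSE]
  starts <- c(0L, iv$end)
  ends <- c(iv$start, len)
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

#' Sample non-repetitive control segments length-matched to the repeat set
#'
#' Draws one control segment per repeat, of the same length, uniformly from
#' the non-repeat portion of the genome, without overlap among controls or
#' with repeats. Deterministic under `seed`.
#'
#' @param genome a `rip_genome` (or any list with `seqs` and `repeats` in
#'   the same shape).
#' @param seed integer seed.
#' @param max_tries rejection-sampling retries per control.
#' @return character vector of control sequences (one per repeat).
#' @export
sample_controls <- function(genome, seed = 1L, max_tries = 1000L) {
  reps <- genome$repeats
  total_repeat <- sum(reps$end - reps$start)
  scf_len <- nchar(genome$seqs)
  if (sum(scf_len) - total_repeat < total_repeat) {
    stop("insufficient non-repeat sequence to sample length-matched controls")
  }
  withr::with_seed(seed, {
    controls <- character(nrow(reps))
    occupied <- lapply(scf_len, function(L) logical(L))
    names(occupied) <- names(genome$seqs)
    for (k in seq_len(nrow(reps))) {
      occupied[[reps$scaffold[k]]][(reps$start[k] + 1L):reps$end[k]] <- TRUE
    }
    for (k in seq_len(nrow(reps))) {
      len <- reps$end[k] - reps$start[k]
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        scf <- sample(names(genome$seqs), 1L,
                      prob = scf_len / sum(scf_len))
        L <- scf_len[[scf]]
        if (L < len) next
        s <- sample.int(L - len + 1L, 1L) - 1L
        span <- (s + 1L):(s + len)
        if (!any(occupied[[scf]][span])) {
          occupied[[scf]][span] <- TRUE
          controls[k] <- substr(genome$seqs[[scf]], s + 1L, s + len)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place control segment ", k,
                    " without overlap")
    }
    controls
  })
}

#' Extract repeat sequences from a repeat-annotated genome
#' @param genome a `rip_genome`.
#' @return character vector of repeat sequences.
#' @export
repeat_sequences <- function(genome) {
  vapply(seq_len(nrow(genome$repeats)), function(k) {
    with(genome$repeats[k, ],
         substr(genome$seqs[[scaffold]], start + 1L, end))
  }, "")
}

#' Sliding-window gene, repeat and GC content tracks
#'
#' Tiles every scaffold with fixed windows and reports, per window, the
#' fraction of bases covered by gene and repeat intervals (half-open
#' arithmetic) and the GC fraction (ignoring N). A trailing window shorter
#' than `window` is flagged `partial`.
#'
#' @param genome a `rip_genome`.
#' @param window,step window size and step in bp (the defaults give
#'   non-overlapping 1 kb windows).
#' @return data.frame with columns `scaffold`, `start`, `end`,
#'   `gene_fraction`, `repeat_fraction`, `gc_fraction`, `partial`.
#' @export
window_tracks <- function(genome, window = 1000L, step = 1000L) {
  stopifnot(window > 0, step > 0)
  out <- list()
  for (scf in names(genome$seqs)) {
    L <- nchar(genome$seqs[[scf]])
    chars <- strsplit(genome$seqs[[scf]], "", fixed = TRUE)[[1]]
    cover_vec <- function(iv) {
      v <- logical(L)
      iv <- iv[iv$scaffold == scf, , drop = FALSE]
      for (k in seq_len(nrow(iv))) {
        if (iv$end[k] > L || iv$start[k] < 0 || iv$start[k] >= iv$end[k]) {
          stop("interval outside scaffold or malformed")
        }
        v[(iv$start[k] + 1L):iv$end[k]] <- TRUE
      }
      v
    }
    gene_cov <- cover_vec(genome$genes)
    rep_cov <- cover_vec(genome$repeats)
    is_gc <- chars %in% c("G", "C")
    is_n <- chars == "N"
    starts <- seq(0L, max(0L, L - 1L), by = step)
    rows <- lapply(starts, function(s) {
      e <- min(s + window, L)
      span <- (s + 1L):e
      n_eff <- sum(!is_n[span])
      data.frame(scaffold = scf, start = s, end = e,
                 gene_fraction = mean(gene_cov[span]),
                 repeat_fraction = mean(rep_cov[span]),
                 gc_fraction = if (n_eff > 0) sum(is_gc[span]) / n_eff
                               else NA_real_,
                 partial = (e - s) < window,
                 stringsAsFactors = FALSE)
    })
    out[[scf]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter repeat candidates by length, genome copy number and redundancy
#'
#' Mirrors the repeat-library construction filter: candidates shorter than
#' `min_len` bases or with fewer than `min_hits` genomic hits are excluded;
#' the survivors are collapsed by greedy centroid clustering (identity >=
#' `cluster_identity` over >= `cluster_coverage` of the shorter sequence)
#' and one representative per cluster is retained (the longest; ties broken
#' by lexicographically smallest id).
#'
#' @param cands data.frame with columns `id`, `sequence`, `genome_hits`
#'   (a `length` column is derived from the sequence if absent).
#' @param min_len minimum candidate length in bases.
#' @param min_hits minimum number of genomic hits.
#' @param cluster_identity,cluster_coverage clustering thresholds.
#' @return the retained rows of `cands` (one representative per cluster).
#' @export
filter_repeat_candidates <- function(cands, min_len = 50L, min_hits = 10L,
                                     cluster_identity = 0.90,
                                     cluster_coverage = 0.90) {
  if (nrow(cands) == 0L) return(cands)
  cands$length <- nchar(cands$sequence)
  keep <- cands$length >= min_len & cands$genome_hits >= min_hits
  surv <- cands[keep, , drop = FALSE]
  if (nrow(surv) == 0L) return(surv)
  # greedy centroid clustering, longest-first (ties: id ascending)
  ord <- order(-surv$length, surv$id)
  surv <- surv[ord, , drop = FALSE]
  centroids <- integer(0)
  assignment <- integer(nrow(surv))
  for (i in seq_len(nrow(surv))) {
    hit <- 0L
    for (c_idx in centroids) {
      st <- alignment_stats(surv$sequence[i], surv$sequence[c_idx])
      shorter <- min(surv$length[i], surv$length[c_idx])
      if (st$aligned / shorter >= cluster_coverage &&
          st$matches / st$alnlen >= cluster_identity) {
        hit <- c_idx
        break
      }
    }
    if (hit == 0L) {
      centroids <- c(centroids, i)
      assignment[i] <- i
    } else {
      assignment[i] <- hit
    }
  }
  # representative per cluster: longest, ties lexicographically smallest id
  reps <- vapply(centroids, function(c_idx) {
    members <- which(assignment == c_idx)
    lens <- surv$length[members]
    cand <- members[lens == max(lens)]
    cand[order(surv$id[cand])][1L]
  }, integer(1))
  out <- surv[sort(reps), , drop = FALSE]
  rownames(out) <- NULL
  out
}
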