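#' Filter raw homolog hits by coverage and identity
#'
#' Load-time filter for per-gene BLAST-style hit tables: hits below the
#' coverage or identity floors are removed, the remainder is sorted by bit
#' score (descending) and truncated to the best `max_hits`.
#'
#' @param hits data.frame with columns `hit_id`, `taxon`, `kingdom`
#'   (`"fungal"`/`"non_fungal"`), `bit_score`, `identity`, `coverage`.
#' @param min_coverage,min_identity inclusive thresholds.
#' @param max_hits maximum number of retained hits.
#' @return the filtered, sorted data.frame; zero surviving rows are returned
#'   as an empty table (attribute `empty = TRUE`), not an error.
#' @export
filter_hits <- function(hits, min_coverage = 0.40, min_identity = 0.20,
                        max_hits = 1000L) {
  stopifnot(all(c("kingdom", "bit_score", "identity", "coverage") %in%
                names(hits)))
  keep <- hits$coverage >= min_coverage & hits$identity >= min_identity
  out <- hits[keep, , drop = FALSE]
  out <- out[order(-out$bit_score), , drop = FALSE]
  out <- utils::head(out, max_hits)
  rownames(out) <- NULL
  attr(out, "empty") <- nrow(out) == 0L
  out
}

#' Call a gene as an HGT candidate from its hit table
#'
#' A gene is a candidate if (i) its taxonomic distribution is skewed (the
#' fungal fraction of hits is below `fungal_frac_threshold`), and/or (ii)
#' the best fungal bit score is smaller than the best non-fungal bit score.
#' A gene with no fungal hits at all triggers both reasons; a gene with no
#' hits is reported not evaluable rather than called.
#'
#' @param table filtered hit data.frame (see [filter_hits()]).
#' @param fungal_frac_threshold taxonomic-skew threshold on the fungal
#'   fraction of hits.
#' @param score_stat `"max"` (default; robust to hit-list truncation) or
#'   `"mean"` for the bit-score dominance comparison.
#' @return list of class `hgt_call` with `fungal_fraction`,
#'   `max_fungal_bit`, `max_nonfungal_bit`, `reasons` (character subset of
#'   `taxonomic_skew`, `bitscore_dominance`), `is_candidate`, `evaluable`.
#' @export
call_candidate <- function(table, fungal_frac_threshold = 0.15,
                           score_stat = c("max", "mean")) {
  score_stat <- match.arg(score_stat)
  if (nrow(table) == 0L) {
    return(structure(list(fungal_fraction = NA_real_,
                          max_fungal_bit = NA_real_,
                          max_nonfungal_bit = NA_real_,
                          reasons = character(),
                          is_candidate = FALSE,
                          evaluable = FALSE),
                     class = "hgt_call"))
  }
  fun <- table$kingdom == "fungal"
  frac <- mean(fun)
  stat <- if (score_stat == "max") max else mean
  fb <- if (any(fun)) stat(table$bit_score[fun]) else NA_real_
  nb <- if (any(!fun)) stat(table$bit_score[!fun]) else NA_real_
  reasons <- character()
  if (frac < fungal_frac_threshold) reasons <- c(reasons, "taxonomic_skew")
  if (!any(fun)) {
    reasons <- union(reasons, c("taxonomic_skew", "bitscore_dominance"))
  } else if (!is.na(nb) && fb < nb) {
    reasons <- c(reasons, "bitscore_dominance")
  }
  structure(list(fungal_fraction = frac,
                 max_fungal_bit = fb,
                 max_nonfungal_bit = nb,
                 reasons = reasons,
                 is_candidate = length(reasons) > 0L,
                 evaluable = TRUE),
            class = "hgt_call")
}

.align_many <- function(patterns, subject) {
  letters <- sort(unique(strsplit(paste0(paste(patterns, collapse = ""),
                                         subject), "", fixed = TRUE)[[1]]))
  mat <- matrix(-1, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(mat) <- 1
  Biostrings::pairwiseAlignment(Biostrings::BStringSet(patterns), subject,
                                type = "global",
                                substitutionMatrix = mat,
                                gapOpening = 1, gapExtension = 1)
}

# identities of one subject against many patterns in a single call
.identity_many <- function(patterns, subject) {
  aln <- .align_many(patterns, subject)
  Biostrings::nmatch(aln) / nchar(aln)
}

#' Global-alignment statistics for a sequence pair
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, affine gaps:
#' a gap of length k costs 2 + (k - 1), i.e. open -2 and extend -1) via
#' Biostrings. Returns the match count, the number of aligned (both
#' non-gap) columns, and the total alignment length.
#'
#' @param a,b non-empty sequences (character scalars).
#' @return list with `matches`, `aligned`, `alnlen`.
#' @export
alignment_stats <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- .align_many(a, b)
  matches <- Biostrings::nmatch(aln)
  # aligned columns (both residues) are exactly matches plus mismatches
  list(matches = matches,
       aligned = matches + Biostrings::nmismatch(aln),
       alnlen = nchar(aln))
}

#' Pairwise global-alignment identity
#'
#' Identity is the number of identical aligned positions divided by the
#' total alignment length (gap columns included), a symmetric measure in
#' \[0, 1\].
#'
#' @inheritParams alignment_stats
#' @return identity fraction.
#' @examples
#' pairwise_identity("ACGT", "ACGT")  # 1
#' pairwise_identity("AAAA", "TTTT")  # 0
#' @export
pairwise_identity <- function(a, b) {
  st <- alignment_stats(a, b)
  st$matches / st$alnlen
}

#' Greedy centroid clustering of sequences at an identity threshold
#'
#' Sequences are sorted by length (descending; ties by id ascending) and
#' processed in order: each sequence joins the first existing centroid with
#' pairwise identity at or above the threshold, otherwise it founds a new
#' cluster. Centroids are the founding sequences, mirroring uclust-style
#' `cluster_fast` behaviour with length pre-sorting.
#'
#' @param seqs named character vector of sequences.
#' @param threshold identity threshold in (0, 1].
#' @return list of class `cluster_set` with `threshold_used` and `clusters`
#'   (list of `list(representative, members)`).
#' @export
greedy_cluster <- function(seqs, threshold) {
  .greedy_cluster_memo(seqs, threshold, .new_identity_memo(seqs))
}

# identity cache shared across adaptive re-clustering rounds: identities do
# not depend on the threshold, so each pair is aligned at most once
.new_identity_memo <- function(seqs) {
  memo <- new.env(parent = emptyenv())
  memo$ids <- names(seqs)
  memo$mat <- matrix(NA_real_, length(seqs), length(seqs),
                     dimnames = list(names(seqs), names(seqs)))
  memo
}

.greedy_cluster_memo <- function(seqs, threshold, memo) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("seqs must be uniquely named")
  }
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  ids <- names(seqs)
  centroids <- integer(0)
  members <- list()
  for (i in seq_along(seqs)) {
    placed <- 0L
    if (length(centroids)) {
      cent_ids <- ids[centroids]
      known <- memo$mat[cent_ids, ids[i]]
      todo <- cent_ids[is.na(known)]
      if (length(todo)) {
        vals <- .identity_many(seqs[todo], seqs[[i]])
        memo$mat[todo, ids[i]] <- vals
        memo$mat[ids[i], todo] <- vals
        known <- memo$mat[cent_ids, ids[i]]
      }
      hit <- which(known >= threshold)
      if (length(hit)) placed <- hit[1]
    }
    if (placed > 0L) {
      members[[placed]] <- c(members[[placed]], ids[i])
    } else {
      centroids <- c(centroids, i)
      members[[length(centroids)]] <- ids[i]
    }
  }
  clusters <- lapply(seq_along(centroids), function(k) {
    list(representative = ids[centroids[k]], members = members[[k]])
  })
  structure(list(threshold_used = threshold, clusters = clusters),
            class = "cluster_set")
}

#' Adaptive greedy clustering with a shrinking identity threshold
#'
#' Clusters at the starting threshold; while the number of clusters exceeds
#' `max_clusters` and the threshold is above the floor, the threshold is
#' reduced by `step` and the set re-clustered. The procedure therefore
#' always stops with a threshold on the grid
#' `start, start - step, ..., floor`.
#'
#' @inheritParams greedy_cluster
#' @param start,step,floor threshold schedule.
#' @param max_clusters target maximum number of clusters.
#' @return a `cluster_set` (see [greedy_cluster()]) with the final
#'   `threshold_used`.
#' @export
adaptive_cluster <- function(seqs, start = 0.95, step = 0.05,
                             max_clusters = 40L, floor = 0.50) {
  stopifnot(start > floor, step > 0)
  memo <- .new_identity_memo(seqs)
  thr <- start
  cs <- .greedy_cluster_memo(seqs, thr, memo)
  while (length(cs$clusters) > max_clusters && thr - step >= floor - 1e-9) {
    thr <- thr - step
    cs <- .greedy_cluster_memo(seqs, thr, memo)
  }
  cs
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}) on a symmetric, zero-diagonal,
#' non-negative distance matrix with at least three taxa. The result is an
#' unrooted tree; set `as_newick = TRUE` to get its newick serialization.
#'
#' @param d symmetric numeric matrix with row/column names, or a `dist`.
#' @param as_newick return a newick string instead of a `phylo` object.
#' @return `phylo` tree or newick character scalar.
#' @export
nj_tree <- function(d, as_newick = FALSE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(abs(d - t(d)) > 1e-9) || any(diag(d) != 0) || any(d < 0)) {
    stop("distance matrix must be symmetric, non-negative, zero-diagonal")
  }
  tr <- ape::nj(d)
  if (as_newick) ape::write.tree(tr) else tr
}

#' Sister-clade origin call for a focal leaf
#'
#' Roots the tree at the leaf farthest from the focal leaf (midpoint rooting
#' as fallback when the farthest leaf is tied), then inspects the smallest
#' clade enclosing the focal leaf together with at least one other leaf.
#' The call is `non_fungal` if all non-focal members of that clade are
#' non-fungal (supporting HGT), `fungal` if all are fungal, `mixed`
#' otherwise.
#'
#' @param tree `phylo` tree containing the focal leaf.
#' @param focal_leaf tip label of the focal gene.
#' @param leaf_kingdoms named character vector mapping every non-focal tip
#'   label to `"fungal"` or `"non_fungal"`.
#' @return list of class `sister_call` with `sister_members`, `origin`,
#'   `supported_hgt`.
#' @export
sister_clade_call <- function(tree, focal_leaf, leaf_kingdoms) {
  stopifnot(inherits(tree, "phylo"))
  if (!focal_leaf %in% tree$tip.label) stop("focal leaf not in tree")
  others <- setdiff(tree$tip.label, focal_leaf)
  missing <- setdiff(others, names(leaf_kingdoms))
  if (length(missing)) {
    stop("unlabeled leaves: ", paste(missing, collapse = ", "))
  }
  if (!all(leaf_kingdoms[others] %in% c("fungal", "non_fungal"))) {
    stop("leaf kingdoms must be 'fungal' or 'non_fungal'")
  }
  dmat <- ape::cophenetic.phylo(tree)
  dfoc <- dmat[focal_leaf, others]
  far <- others[dfoc == max(dfoc)]
  if (length(far) == 1L) {
    rooted <- ape::root(tree, outgroup = far, resolve.root = TRUE)
  } else {
    rooted <- phangorn::midpoint(tree)
  }
  tip <- match(focal_leaf, rooted$tip.label)
  parent <- rooted$edge[rooted$edge[, 2] == tip, 1]
  clade_tips <- phangorn::Descendants(rooted, parent, type = "tips")[[1]]
  sisters <- setdiff(rooted$tip.label[clade_tips], focal_leaf)
  kingdoms <- leaf_kingdoms[sisters]
  origin <- if (all(kingdoms == "non_fungal")) "non_fungal"
            else if (all(kingdoms == "fungal")) "fungal"
            else "mixed"
  structure(list(sister_members = sisters,
                 origin = origin,
                 supported_hgt = origin == "non_fungal"),
            class = "sister_call")
}

#' Clustering preset for the conserved-gene negative control
#'
#' Parameters used when screening a highly conserved housekeeping gene
#' (RNA polymerase II second subunit) as a negative control: only hits with
#' identity above 0.75 enter, and clustering runs at a 0.90 threshold.
#'
#' @return list with `identity_floor` and `cluster_threshold`.
#' @export
rpb2_control_settings <- function() {
  list(identity_floor = 0.75, cluster_threshold = 0.90)
}

#' End-to-end HGT screen of one gene: candidate call and tree confirmation
#'
#' Applies the hit filter and candidate rules; for candidates, clusters the
#' non-fungal hit sequences adaptively (and the fungal ones at 0.95 with
#' the same shrink rule only if they exceed the cluster cap), builds a
#' neighbor-joining tree on 1 - identity distances over the cluster
#' representatives plus the focal sequence, and makes the sister-clade
#' origin call.
#'
#' @param hits per-gene hit data.frame (see [filter_hits()]).
#' @param sequences named character vector holding the focal gene sequence
#'   (named `gene_id`) and one sequence per hit id.
#' @param gene_id id of the focal gene.
#' @param fungal_frac_threshold see [call_candidate()].
#' @param max_clusters cluster cap for the adaptive threshold schedule.
#' @return list with `call` (`hgt_call`), and for evaluable candidates
#'   `clusters_non_fungal`, `clusters_fungal`, `tree` (`phylo`), and
#'   `sister` (`sister_call`).
#' @export
screen_hgt_gene <- function(hits, sequences, gene_id,
                            fungal_frac_threshold = 0.15,
                            max_clusters = 40L) {
  tab <- filter_hits(hits)
  call <- call_candidate(tab, fungal_frac_threshold)
  out <- list(call = call)
  if (!call$evaluable || !call$is_candidate) return(out)

  kingdoms <- stats::setNames(tab$kingdom, tab$hit_id)
  nf_ids <- tab$hit_id[tab$kingdom == "non_fungal"]
  f_ids <- tab$hit_id[tab$kingdom == "fungal"]
  nf_cs <- if (length(nf_ids)) adaptive_cluster(sequences[nf_ids],
                                                max_clusters = max_clusters)
  f_cs <- NULL
  if (length(f_ids)) {
    f_cs <- greedy_cluster(sequences[f_ids], 0.95)
    if (length(f_cs$clusters) > max_clusters) {
      f_cs <- adaptive_cluster(sequences[f_ids], max_clusters = max_clusters)
    }
  }
  reps <- c(gene_id,
            if (!is.null(nf_cs)) vapply(nf_cs$clusters, `[[`, "",
                                        "representative"),
            if (!is.null(f_cs)) vapply(f_cs$clusters, `[[`, "",
                                       "representative"))
  out$clusters_non_fungal <- nf_cs
  out$clusters_fungal <- f_cs
  if (length(reps) >= 3L) {
    n <- length(reps)
    d <- matrix(0, n, n, dimnames = list(reps, reps))
    for (i in seq_len(n - 1L)) {
      rest <- reps[(i + 1L):n]
      d[i, rest] <- d[rest, i] <-
        1 - .identity_many(sequences[rest], sequences[[reps[i]]])
    }
    tr <- nj_tree(d)
    out$tree <- tr
    out$sister <- sister_clade_call(tr, gene_id, kingdoms)
  }
  out
}
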