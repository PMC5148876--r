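make_hits <- function(n_fungal, n_nonfungal, fungal_bits, nonfungal_bits) {
  n <- n_fungal + n_nonfungal
  data.frame(
    hit_id = sprintf("h%03d", seq_len(n)),
    taxon = c(rep("fungus", n_fungal), rep("bacterium", n_nonfungal)),
    kingdom = c(rep("fungal", n_fungal), rep("non_fungal", n_nonfungal)),
    bit_score = c(fungal_bits, nonfungal_bits),
    identity = rep(0.5, n), coverage = rep(0.8, n),
    stringsAsFactors = FALSE)
}

test_that("hit filtering applies inclusive boundaries and truncation", {
  hits <- make_hits(2, 2, c(100, 90), c(80, 70))
  hits$coverage <- c(0.39, 0.40, 0.80, 0.80)
  hits$identity <- c(0.50, 0.50, 0.19, 0.20)
  out <- filter_hits(hits)
  expect_setequal(out$hit_id, c("h002", "h004"))

  withr::with_seed(4, {
    big <- make_hits(0, 50, numeric(), runif(50, 30, 500))
    out <- filter_hits(big, max_hits = 10)
    expect_equal(nrow(out), 10)
    expect_equal(out$bit_score, sort(big$bit_score, decreasing = TRUE)[1:10])
    # survivors equal a brute-force filter
    keep <- big[big$coverage >= 0.4 & big$identity >= 0.2, ]
    keep <- keep[order(-keep$bit_score), ][1:10, ]
    expect_equal(out$hit_id, keep$hit_id)
  })
})

test_that("candidate calling follows the skew and/or dominance rules", {
  # skew only: 10% fungal but fungal bit scores dominate
  c1 <- call_candidate(make_hits(10, 90, rep(400, 10), rep(300, 90)))
  expect_true(c1$is_candidate)
  expect_setequal(c1$reasons, "taxonomic_skew")

  # dominance only: half fungal with lower max bit score
  c2 <- call_candidate(make_hits(50, 50, rep(200, 50), rep(250, 50)))
  expect_true(c2$is_candidate)
  expect_setequal(c2$reasons, "bitscore_dominance")

  # no fungal hits: both reasons
  c3 <- call_candidate(make_hits(0, 20, numeric(), rep(100, 20)))
  expect_setequal(c3$reasons, c("taxonomic_skew", "bitscore_dominance"))

  # majority fungal and dominant: clean negative
  c4 <- call_candidate(make_hits(80, 20, rep(350, 80), rep(200, 20)))
  expect_false(c4$is_candidate)

  # empty table: not evaluable, not a candidate
  c5 <- call_candidate(make_hits(0, 0, numeric(), numeric()))
  expect_false(c5$evaluable)
  expect_false(c5$is_candidate)
})

test_that("candidate calling is invariant to bit-score rescaling", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      nf <- sample(0:20, 1); nn <- sample(1:20, 1)
      hits <- make_hits(nf, nn, runif(nf, 50, 500), runif(nn, 50, 500))
      base <- call_candidate(hits)
      scaled <- hits
      scaled$bit_score <- scaled$bit_score * runif(1, 0.1, 10)
      expect_identical(call_candidate(scaled)$reasons, base$reasons)
    }
  })
})

test_that("pairwise identity behaves on forced cases and is symmetric", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0)
  expect_error(pairwise_identity("", "ACGT"), "empty")
  withr::with_seed(8, {
    for (rep in 1:10) {
      a <- random_dna(sample(10:60, 1))
      b <- random_dna(sample(10:60, 1))
      expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    }
  })
})

test_that("alignment scores equal an independent Gotoh reimplementation", {
  withr::with_seed(17, {
    for (rep in 1:30) {
      a <- random_dna(sample(5:40, 1))
      b <- random_dna(sample(5:40, 1))
      st <- alignment_stats(a, b)
      # recompute the score of the produced alignment under our scheme
      # and compare its optimum with the independent DP
      letters <- sort(unique(strsplit(paste0(a, b), "")[[1]]))
      mat <- matrix(-1, length(letters), length(letters),
                    dimnames = list(letters, letters))
      diag(mat) <- 1
      aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                           substitutionMatrix = mat,
                                           gapOpening = 1, gapExtension = 1)
      expect_equal(Biostrings::score(aln), gotoh_score(a, b))
    }
  })
})

test_that("greedy clustering matches forced cases and a reimplementation", {
  seqs <- setNames(rep(strrep("ACGT", 10), 4), paste0("s", 1:4))
  cs <- greedy_cluster(seqs, 0.95)
  expect_length(cs$clusters, 1)
  expect_equal(cs$clusters[[1]]$representative, "s1")

  fam1 <- strrep("ACGT", 15)
  fam2 <- strrep("TTGA", 15)
  seqs2 <- setNames(c(fam1, fam1, fam2, fam2), paste0("s", 1:4))
  expect_length(greedy_cluster(seqs2, 0.95)$clusters, 2)

  withr::with_seed(23, {
    for (rep in 1:5) {
      base <- replicate(4, random_dna(sample(30:60, 1)))
      seqs <- c(base, vapply(base[1:2], function(s) {
        ch <- strsplit(s, "")[[1]]
        i <- sample(length(ch), 1)
        ch[i] <- sample(c("A", "C", "G", "T"), 1)
        paste(ch, collapse = "")
      }, ""))
      names(seqs) <- sprintf("q%02d", seq_along(seqs))
      thr <- sample(c(0.5, 0.8, 0.95), 1)
      cs <- greedy_cluster(seqs, thr)
      oracle <- oracle_greedy(seqs, thr)
      expect_equal(length(cs$clusters), length(oracle))
      got <- lapply(cs$clusters, function(cl) sort(cl$members))
      expect_setequal(lapply(oracle, sort), got)
      # clusters partition the input
      expect_setequal(unlist(got), names(seqs))
    }
  })
})

test_that("adaptive clustering shrinks the threshold along the fixed grid", {
  seqs <- setNames(rep(strrep("ACGT", 10), 10), paste0("s", 1:10))
  cs <- adaptive_cluster(seqs)
  expect_equal(cs$threshold_used, 0.95)
  expect_length(cs$clusters, 1)

  # 60 mutually dissimilar sequences hit the floor with 60 clusters
  withr::with_seed(29, {
    dis <- vapply(1:60, function(i) random_aa(40), "")
    names(dis) <- sprintf("d%02d", 1:60)
    cs2 <- adaptive_cluster(dis)
    expect_equal(cs2$threshold_used, 0.50)
    expect_length(cs2$clusters, 60)
  })
})

test_that("adaptive threshold stops at the first level meeting the cap", {
  # 35 near-identical pairs: split at 0.95 (70 clusters) but merged at
  # 0.90 (35 clusters), so the schedule must stop at 0.90
  withr::with_seed(37, {
    bases <- replicate(35, random_aa(100))
    seqs <- character(0)
    for (i in seq_along(bases)) {
      ch <- strsplit(bases[i], "")[[1]]
      idx <- sample(100, 8)  # 8% divergence: joined at 0.90, split at 0.95
      ch2 <- ch
      for (k in idx) ch2[k] <- sample(setdiff(LETTERS[1:20], ch[k]), 1)
      seqs <- c(seqs, bases[i], paste(ch2, collapse = ""))
    }
    names(seqs) <- sprintf("p%03d", seq_along(seqs))
    at95 <- greedy_cluster(seqs, 0.95)
    at90 <- greedy_cluster(seqs, 0.90)
    expect_gt(length(at95$clusters), 40)
    expect_lte(length(at90$clusters), 40)
    cs <- adaptive_cluster(seqs)
    expect_equal(cs$threshold_used, 0.90)
    expect_equal(length(cs$clusters), length(at90$clusters))
  })
})

test_that("neighbor joining solves the 3-taxon system and additive trees", {
  d3 <- matrix(c(0, 5, 9,
                 5, 0, 10,
                 9, 10, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d3)
  # closed form: la = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr$edge.length[order(tr$edge[, 2])][1:3], tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(2, 3, 7))

  # additive 4-taxon matrix from tree ((A:1,B:2):1,(C:3,D:1));
  taxa <- c("A", "B", "C", "D")
  d4 <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  d4["A", "B"] <- d4["B", "A"] <- 3
  d4["A", "C"] <- d4["C", "A"] <- 5
  d4["A", "D"] <- d4["D", "A"] <- 3
  d4["B", "C"] <- d4["C", "B"] <- 6
  d4["B", "D"] <- d4["D", "B"] <- 4
  d4["C", "D"] <- d4["D", "C"] <- 4
  tr4 <- nj_tree(d4)
  # AB vs CD split recovered
  expect_true(ape::is.monophyletic(ape::root(tr4, "C"), c("A", "B")))
  # input order does not change the topology
  perm <- c("D", "B", "A", "C")
  tr4p <- nj_tree(d4[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(tr4), ape::unroot(tr4p))[1], 0)

  expect_error(nj_tree(d3[1:2, 1:2]), "3 taxa")
  bad <- d3; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
  # newick serialization round-trips through ape
  nwk <- nj_tree(d3, as_newick = TRUE)
  expect_s3_class(ape::read.tree(text = nwk), "phylo")
})

test_that("sister-clade calls identify the focal leaf's neighbors", {
  # focal sits next to a bacterial leaf; a fungal leaf is far away
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3,
              dimnames = list(c("focal", "bact", "fung"),
                              c("focal", "bact", "fung")))
  tr <- nj_tree(d)
  call <- sister_clade_call(tr, "focal",
                            c(bact = "non_fungal", fung = "fungal"))
  expect_equal(call$origin, "non_fungal")
  expect_true(call$supported_hgt)

  # focal nested among fungi
  d2 <- d
  dimnames(d2) <- list(c("focal", "f1", "b1"), c("focal", "f1", "b1"))
  call2 <- sister_clade_call(nj_tree(d2), "focal",
                             c(f1 = "fungal", b1 = "non_fungal"))
  expect_equal(call2$origin, "fungal")
  expect_false(call2$supported_hgt)

  expect_error(sister_clade_call(tr, "focal", c(bact = "non_fungal")),
               "unlabeled")
})

test_that("the conserved-gene control preset is as published", {
  preset <- rpb2_control_settings()
  expect_equal(preset$identity_floor, 0.75)
  expect_equal(preset$cluster_threshold, 0.90)
})

test_that("a fungal-only family is not called as transferred under the control preset", {
  withr::with_seed(41, {
    base <- random_dna(80)
    mutate <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      idx <- sample(length(ch), k)
      for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
      paste(ch, collapse = "")
    }
    hits <- make_hits(6, 0, seq(400, 350, length.out = 6), numeric())
    seqs <- c(gene = base,
              setNames(vapply(1:6, function(i) mutate(base, i), ""),
                       hits$hit_id))
    res <- screen_hgt_gene(hits, seqs, "gene")
    expect_false(res$call$is_candidate)
  })
})
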