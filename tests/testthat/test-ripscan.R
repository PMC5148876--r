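test_that("dinucleotide counting matches the definition on forced cases", {
  p <- count_dinucleotides("AAAA")
  expect_equal(unname(p$counts["AA"]), 3)
  expect_equal(unname(p$frequencies["AA"]), 1)

  p2 <- count_dinucleotides(c("ACGT", "ACGT"))
  expect_equal(unname(p2$counts[c("AC", "CG", "GT")]), c(2, 2, 2))
  expect_equal(unname(p2$frequencies["AC"]), 1 / 3)
  expect_equal(p2$n_sites, 6)

  # pairs containing N are skipped, never counted across boundaries
  p3 <- count_dinucleotides(c("ANGT", "CC"))
  expect_equal(p3$n_sites, 2)
  expect_equal(unname(p3$counts[c("GT", "CC")]), c(1, 1))

  expect_error(count_dinucleotides(character()), "empty")
  expect_error(count_dinucleotides("NNNN"), "N")
  expect_error(count_dinucleotides("ACXG"), "unexpected")
})

test_that("dinucleotide counts equal a naive per-position recount", {
  withr::with_seed(42, {
    for (rep in 1:100) {
      seqs <- replicate(sample(1:4, 1),
                        random_dna(sample(2:80, 1), runif(1, 0.2, 0.8)))
      p <- count_dinucleotides(seqs)
      expect_identical(p$counts, naive_dinuc_count(seqs))
      expect_equal(sum(p$frequencies), 1, tolerance = 1e-12)
    }
  })
})

test_that("fold change of a profile against itself is the identity table", {
  withr::with_seed(1, p <- count_dinucleotides(random_dna(5000)))
  fc <- fold_change(p, p)
  expect_equal(fc$fold, rep(1, 16))
  expect_equal(fc$diff, rep(0, 16))
  expect_true(all(fc$flag == "ns"))
})

test_that("a doubled dinucleotide frequency yields the largest fold", {
  ctrl <- count_dinucleotides(strrep("ACGT", 500))
  # repeats enriched for CG pairs relative to the same backbone
  reps <- count_dinucleotides(paste0(strrep("ACGT", 500), strrep("CG", 250)))
  fc <- fold_change(reps, ctrl)
  defined <- !is.na(fc$fold)
  expect_equal(fc$dinucleotide[defined][which.max(fc$fold[defined])], "CG")
  # dinucleotides absent from the control are flagged undefined
  expect_true(all(fc$flag[fc$control_freq == 0 & fc$repeat_freq > 0] ==
                  "undefined"))
})

test_that("control sampling is length-matched, non-overlapping and seeded", {
  withr::with_seed(9, seq <- random_dna(5000))
  g <- toy_genome(seq, repeats = iv_df(c(100, 1000), c(300, 1400),
                                       type = "repeat"))
  c1 <- sample_controls(g, seed = 11)
  c2 <- sample_controls(g, seed = 11)
  expect_identical(c1, c2)
  expect_equal(nchar(c1), c(200, 400))
  # controls are substrings of the genome outside the repeats
  for (ctrl in c1) {
    pos <- regexpr(ctrl, g$seqs[["scf1"]], fixed = TRUE)[1]
    expect_gt(pos, 0)
  }
  expect_equal(sum(nchar(c1)), sum(g$repeats$end - g$repeats$start))

  # a genome with more repeat than non-repeat sequence errors out
  g_small <- toy_genome(random_dna(300),
                        repeats = iv_df(0, 200, type = "repeat"))
  expect_error(sample_controls(g_small, seed = 1), "insufficient")
})

test_that("window tracks tile scaffolds and flag trailing partial windows", {
  g <- toy_genome(strrep("A", 2500),
                  genes = iv_df(0, 2500, type = "gene"))
  wt <- window_tracks(g, window = 1000, step = 1000)
  expect_equal(wt$start, c(0, 1000, 2000))
  expect_equal(wt$end, c(1000, 2000, 2500))
  expect_equal(wt$partial, c(FALSE, FALSE, TRUE))
  expect_equal(wt$gene_fraction, rep(1, 3))
  expect_equal(wt$repeat_fraction, rep(0, 3))
})

test_that("window fractions equal a per-base oracle and survive interval splits", {
  withr::with_seed(7, {
    for (rep in 1:30) {
      L <- sample(300:900, 1)
      seq <- random_dna(L)
      n_iv <- sample(1:6, 1)
      starts <- sort(sample(0:(L - 20), n_iv))
      ends <- pmin(L, starts + sample(5:120, n_iv, replace = TRUE))
      genes <- iv_df(starts, ends, type = "gene")
      g <- toy_genome(seq, genes = genes)
      wt <- window_tracks(g, window = 100, step = 100)
      chars <- strsplit(seq, "")[[1]]
      for (w in seq_len(nrow(wt))) {
        expect_equal(wt$gene_fraction[w],
                     naive_window_fracs(chars, genes, wt$start[w], wt$end[w]))
        span <- (wt$start[w] + 1):wt$end[w]
        expect_equal(wt$gc_fraction[w], mean(chars[span] %in% c("G", "C")))
      }
      # splitting an interval into adjacent pieces changes nothing
      split_genes <- do.call(rbind, lapply(seq_len(nrow(genes)), function(k) {
        mid <- floor((genes$start[k] + genes$end[k]) / 2)
        if (mid > genes$start[k] && mid < genes$end[k]) {
          iv_df(c(genes$start[k], mid), c(mid, genes$end[k]), type = "gene")
        } else {
          genes[k, ]
        }
      }))
      g2 <- toy_genome(seq, genes = split_genes)
      expect_equal(window_tracks(g2, 100, 100), wt)
    }
  })
})

test_that("repeat-candidate filtering applies the length/copy-number boundary", {
  withr::with_seed(55, cands <- data.frame(
    id = c("r1", "r2", "r3", "r4"),
    sequence = c(random_dna(49), random_dna(50), random_dna(200),
                 random_dna(200)),
    genome_hits = c(100, 10, 9, 10),
    stringsAsFactors = FALSE))
  out <- filter_repeat_candidates(cands)
  expect_setequal(out$id, c("r2", "r4"))
})

test_that("redundant repeat candidates collapse to one representative", {
  withr::with_seed(13, base <- random_dna(200))
  cands <- data.frame(id = c("b", "a"), sequence = c(base, base),
                      genome_hits = c(20, 20), stringsAsFactors = FALSE)
  out <- filter_repeat_candidates(cands)
  expect_equal(nrow(out), 1)
  expect_equal(out$id, "a")  # tie on length broken by smallest id
})

test_that("candidate clustering matches an exhaustive all-pairs oracle", {
  withr::with_seed(21, {
    originals <- replicate(10, random_dna(sample(80:150, 1)))
    dup_idx <- sample(10, 5)
    seqs <- c(originals, originals[dup_idx])
    ids <- sprintf("c%02d", seq_along(seqs))
    cands <- data.frame(id = ids, sequence = seqs,
                        genome_hits = 50, stringsAsFactors = FALSE)
    out <- filter_repeat_candidates(cands)
    # brute force: connected components under the pair predicate
    n <- length(seqs)
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        st <- alignment_stats(seqs[i], seqs[j])
        shorter <- min(nchar(seqs[i]), nchar(seqs[j]))
        adj[i, j] <- adj[j, i] <- st$aligned / shorter >= 0.9 &&
          st$matches / st$alnlen >= 0.9
      }
    }
    comp <- seq_len(n)
    for (i in 1:n) for (j in 1:n) {
      if (adj[i, j]) comp[comp == comp[j]] <- comp[i]
    }
    expect_equal(nrow(out), length(unique(comp)))
  })
})
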