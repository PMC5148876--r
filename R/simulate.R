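#' Simulation configuration for the synthetic-data generators
#'
#' Bundles all tunable parameters of the synthetic comparative-genomics
#' inputs. Every generator derives a deterministic sub-seed from `seed`
#' (seed + a fixed stage offset) so individual stages can be regenerated
#' independently and the whole simulation is bit-reproducible.
#'
#' @param seed integer master seed.
#' @param n_clusters number of ortholog clusters in the presence/absence
#'   matrix.
#' @param n_planted_pathogen_clusters,n_planted_saprotroph_clusters number
#'   of rows planted to satisfy the pathogen / saprotroph enrichment rule
#'   exactly.
#' @param background_presence_prob per-cell Bernoulli presence probability
#'   for non-planted rows.
#' @param n_accessions number of annotation accessions in the count table.
#' @param baseline_count_mean mean of the negative binomial baseline count
#'   per accession and species.
#' @param nb_size negative binomial size (dispersion) parameter; variance is
#'   `mu + mu^2/size`.
#' @param overrep_fold multiplicative fold applied to the focal mean of
#'   planted overrepresented accessions.
#' @param n_planted_overrep number of planted overrepresented accessions
#'   (ignored when `overrep_fold == 1`).
#' @param genome_length,gc_content length (bp) and GC fraction of the
#'   simulated genome scaffold.
#' @param n_repeats,repeat_length number and length (bp) of non-overlapping
#'   planted repeat intervals.
#' @param rip_rate per-site probability that a CpA (or TpG) dinucleotide
#'   inside a repeat is converted to TpA.
#' @param n_genes,gene_length number and length of non-overlapping gene
#'   intervals (used by the window-track analysis).
#' @param n_genes_hit_tables number of genes receiving homolog hit tables.
#' @param n_planted_hgt number of genes planted as horizontally acquired.
#' @param hits_per_gene homolog hits per gene (must be >= 2).
#' @param null_fungal_prob probability that a hit of a non-HGT gene is
#'   fungal.
#' @param hgt_fungal_prob probability that a hit of a planted HGT gene is
#'   fungal (0 gives the extreme all-non-fungal setting).
#' @param hit_seq_length length of the per-hit sequences generated for the
#'   tree-based confirmation stage.
#'
#' @return list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_clusters = 200)
#' @export
sim_config <- function(seed = 1L,
                       n_clusters = 500L,
                       n_planted_pathogen_clusters = 20L,
                       n_planted_saprotroph_clusters = 10L,
                       background_presence_prob = 0.5,
                       n_accessions = 1000L,
                       baseline_count_mean = 20,
                       nb_size = 50,
                       overrep_fold = 4,
                       n_planted_overrep = 50L,
                       genome_length = 500000L,
                       gc_content = 0.459,
                       n_repeats = 100L,
                       repeat_length = 600L,
                       rip_rate = 0.5,
                       n_genes = 60L,
                       gene_length = 1500L,
                       n_genes_hit_tables = 200L,
                       n_planted_hgt = 10L,
                       hits_per_gene = 50L,
                       null_fungal_prob = 0.85,
                       hgt_fungal_prob = 0.05,
                       hit_seq_length = 120L) {
  cfg <- list(seed = as.integer(seed),
              n_clusters = as.integer(n_clusters),
              n_planted_pathogen_clusters = as.integer(n_planted_pathogen_clusters),
              n_planted_saprotroph_clusters = as.integer(n_planted_saprotroph_clusters),
              background_presence_prob = background_presence_prob,
              n_accessions = as.integer(n_accessions),
              baseline_count_mean = baseline_count_mean,
              nb_size = nb_size,
              overrep_fold = overrep_fold,
              n_planted_overrep = as.integer(n_planted_overrep),
              genome_length = as.integer(genome_length),
              gc_content = gc_content,
              n_repeats = as.integer(n_repeats),
              repeat_length = as.integer(repeat_length),
              rip_rate = rip_rate,
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              n_genes_hit_tables = as.integer(n_genes_hit_tables),
              n_planted_hgt = as.integer(n_planted_hgt),
              hits_per_gene = as.integer(hits_per_gene),
              null_fungal_prob = null_fungal_prob,
              hgt_fungal_prob = hgt_fungal_prob,
              hit_seq_length = as.integer(hit_seq_length))
  counts <- unlist(cfg[c("n_clusters", "n_planted_pathogen_clusters",
                         "n_planted_saprotroph_clusters", "n_accessions",
                         "n_planted_overrep", "genome_length", "n_repeats",
                         "repeat_length", "n_genes", "n_genes_hit_tables",
                         "n_planted_hgt", "hits_per_gene")])
  if (any(counts < 0)) stop("all counts must be >= 0")
  probs <- unlist(cfg[c("background_presence_prob", "gc_content", "rip_rate",
                        "null_fungal_prob", "hgt_fungal_prob")])
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$baseline_count_mean <= 0) stop("baseline_count_mean must be > 0")
  if (cfg$nb_size <= 0) stop("nb_size must be > 0")
  if (cfg$overrep_fold <= 0) stop("overrep_fold must be > 0")
  with_planted <- cfg$n_planted_pathogen_clusters + cfg$n_planted_saprotroph_clusters
  if (with_planted > cfg$n_clusters) {
    stop("planted cluster counts exceed n_clusters")
  }
  if (cfg$n_planted_overrep > cfg$n_accessions) {
    stop("n_planted_overrep exceeds n_accessions")
  }
  if (cfg$n_planted_hgt > cfg$n_genes_hit_tables) {
    stop("n_planted_hgt exceeds n_genes_hit_tables")
  }
  class(cfg) <- "sim_config"
  cfg
}

# stage offsets keep sub-seeds distinct but reproducible from one master seed
.stage_seed <- function(cfg, stage) {
  offset <- c(clusters = 1L, counts = 2L, genome = 3L, hits = 4L,
              controls = 5L)[[stage]]
  cfg$seed + offset
}

#' Simulate an ortholog-cluster presence/absence matrix with planted
#' lifestyle-enriched rows
#'
#' Background rows have i.i.d. Bernoulli cells. Planted rows are constructed
#' to satisfy the corresponding lifestyle-enrichment rule exactly: pathogen
#' rows have >= 4 of 5 pathogens present, at most one saprotroph, at most one
#' mycorrhizal species, and the focal species present (saprotroph rows
#' analogously with >= 5 of 6 saprotrophs).
#'
#' @param panel a [species_panel()].
#' @param cfg a [sim_config()].
#' @return list with `matrix` (binary cluster x species matrix with cluster
#'   row names) and `truth` (planted row ids by lifestyle).
#' @export
simulate_cluster_matrix <- function(panel, cfg) {
  panel <- assert_panel(panel)
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(.stage_seed(cfg, "clusters"), {
    n <- cfg$n_clusters
    codes <- panel$code
    m <- matrix(stats::rbinom(n * length(codes), 1L,
                              cfg$background_presence_prob),
                nrow = n, dimnames = list(sprintf("CL%05d", seq_len(n)),
                                          codes))
    n_planted <- cfg$n_planted_pathogen_clusters +
      cfg$n_planted_saprotroph_clusters
    planted_rows <- if (n_planted > 0) sample.int(n, n_planted) else integer()
    path_rows <- utils::head(planted_rows, cfg$n_planted_pathogen_clusters)
    sap_rows <- utils::tail(planted_rows, cfg$n_planted_saprotroph_clusters)
    plant_row <- function(target, others_capped) {
      row <- stats::setNames(integer(length(codes)), codes)
      tgt <- lifestyle_species(panel, target)
      k <- sample(c(length(tgt) - 1L, length(tgt)), 1L)
      row[sample(tgt, k)] <- 1L
      for (ls in others_capped) {
        sp <- lifestyle_species(panel, ls)
        k_other <- sample(0:1, 1L)
        if (k_other > 0) row[sample(sp, k_other)] <- 1L
      }
      row[focal_species(panel)] <- 1L
      row
    }
    for (i in path_rows) {
      m[i, ] <- plant_row("pathogen", c("saprotroph", "mycorrhizal"))
    }
    for (i in sap_rows) {
      m[i, ] <- plant_row("saprotroph", c("pathogen", "mycorrhizal"))
    }
    list(matrix = m,
         truth = list(pathogen = rownames(m)[sort(path_rows)],
                      saprotroph = rownames(m)[sort(sap_rows)]))
  })
}

#' Simulate an annotation count table with planted overrepresented accessions
#'
#' Counts are negative binomial with a common baseline mean. For planted
#' accessions the focal species' mean is multiplied by `overrep_fold`; with
#' `overrep_fold == 1` nothing is planted and the ground truth is empty.
#'
#' @inheritParams simulate_cluster_matrix
#' @return list with `counts` (accession x species integer matrix) and
#'   `truth` (planted accession ids and the true fold).
#' @export
simulate_annotation_counts <- function(panel, cfg) {
  panel <- assert_panel(panel)
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$baseline_count_mean <= 0) stop("baseline_count_mean must be > 0")
  withr::with_seed(.stage_seed(cfg, "counts"), {
    codes <- panel$code
    n <- cfg$n_accessions
    mu <- matrix(cfg$baseline_count_mean, nrow = n, ncol = length(codes),
                 dimnames = list(sprintf("ACC%05d", seq_len(n)), codes))
    planted <- character()
    if (cfg$overrep_fold != 1 && cfg$n_planted_overrep > 0) {
      idx <- sample.int(n, cfg$n_planted_overrep)
      mu[idx, focal_species(panel)] <-
        mu[idx, focal_species(panel)] * cfg$overrep_fold
      planted <- rownames(mu)[sort(idx)]
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$nb_size),
                     nrow = n, dimnames = dimnames(mu))
    list(counts = counts,
         truth = list(accessions = planted, fold = cfg$overrep_fold))
  })
}

.random_dna <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Simulate a repeat-annotated genome mutated by a CpA -> TpA RIP process
#'
#' Generates one scaffold of i.i.d. background sequence at the requested GC
#' content, places non-overlapping repeat and gene intervals, and then
#' applies RIP-style mutation within repeats: each CpA dinucleotide (and its
#' reverse-complement TpG, treated symmetrically on the forward strand) is
#' converted to TpA independently with probability `rip_rate`.
#'
#' @param cfg a [sim_config()].
#' @param max_tries placement retries per interval before giving up.
#' @return list of class `rip_genome` with elements `seqs` (named character
#'   vector), `repeats` and `genes` (interval data.frames with 0-based
#'   half-open `start`/`end`), and `truth` (mutated 0-based positions per
#'   repeat).
#' @export
simulate_ripped_genome <- function(cfg, max_tries = 1000L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$genome_length <= cfg$repeat_length * cfg$n_repeats) {
    stop("genome_length must exceed total repeat length")
  }
  withr::with_seed(.stage_seed(cfg, "genome"), {
    L <- cfg$genome_length
    chars <- .random_dna(L, cfg$gc_content)

    # place intervals by sampling uniformly over all feasible start
    # positions given the current free gaps (exact, no rejection)
    place <- function(n_iv, len, gaps) {
      starts <- integer(0)
      for (i in seq_len(n_iv)) {
        room <- pmax(0L, (gaps$end - gaps$start) - len + 1L)
        if (sum(room) == 0L) {
          stop("could not place non-overlapping intervals; ",
               "genome too small or too fragmented")
        }
        g <- sample.int(nrow(gaps), 1L, prob = room)
        s <- gaps$start[g] + sample.int(room[g], 1L) - 1L
        starts <- c(starts, s)
        left <- data.frame(start = gaps$start[g], end = s)
        right <- data.frame(start = s + len, end = gaps$end[g])
        gaps <- rbind(gaps[-g, , drop = FALSE],
                      left[left$end > left$start, , drop = FALSE],
                      right[right$end > right$start, , drop = FALSE])
      }
      list(starts = sort(starts), gaps = gaps)
    }

    gaps0 <- data.frame(start = 0L, end = L)
    rep_placed <- place(cfg$n_repeats, cfg$repeat_length, gaps0)
    gene_placed <- place(cfg$n_genes, cfg$gene_length, rep_placed$gaps)

    repeats <- data.frame(scaffold = "scf1",
                          start = rep_placed$starts,
                          end = rep_placed$starts + cfg$repeat_length,
                          type = "repeat", stringsAsFactors = FALSE)
    genes <- data.frame(scaffold = "scf1",
                        start = gene_placed$starts,
                        end = gene_placed$starts + cfg$gene_length,
                        type = "gene", stringsAsFactors = FALSE)

    mutated <- vector("list", nrow(repeats))
    for (r in seq_len(nrow(repeats))) {
      lo <- repeats$start[r] + 1L           # 1-based index of first base
      hi <- repeats$end[r]
      pos <- lo:(hi - 1L)                   # dinucleotide start positions
      first <- chars[pos]
      second <- chars[pos + 1L]
      is_cpa <- first == "C" & second == "A"
      is_tpg <- first == "T" & second == "G"
      hit <- (is_cpa | is_tpg) & stats::runif(length(pos)) < cfg$rip_rate
      cpa_hit <- pos[is_cpa & hit]
      tpg_hit <- pos[is_tpg & hit]
      chars[cpa_hit] <- "T"                 # CpA -> TpA
      chars[tpg_hit + 1L] <- "A"            # TpG -> TpA
      mutated[[r]] <- sort(c(cpa_hit, tpg_hit + 1L)) - 1L  # 0-based
    }

    genome <- list(seqs = c(scf1 = paste(chars, collapse = "")),
                   repeats = repeats, genes = genes,
                   truth = list(mutated_positions = mutated))
    class(genome) <- "rip_genome"
    genome
  })
}

.mutate_seq <- function(chars, rate) {
  idx <- which(stats::runif(length(chars)) < rate)
  if (length(idx)) {
    bases <- c("A", "C", "G", "T")
    chars[idx] <- vapply(chars[idx],
                         function(b) sample(setdiff(bases, b), 1L), "")
  }
  chars
}

#' Simulate per-gene homolog hit tables with planted HGT genes
#'
#' Non-HGT genes receive majority-fungal hits whose bit scores stochastically
#' dominate the non-fungal ones. Planted HGT genes receive mostly non-fungal
#' hits (fraction `hgt_fungal_prob`, below the 15% screening threshold) with
#' the top bit score on the non-fungal side. Per-hit sequences are generated
#' so that for planted genes the focal sequence is closest to the non-fungal
#' hits, supporting the downstream tree-based confirmation.
#'
#' @param cfg a [sim_config()].
#' @return list with `tables` (named list of per-gene hit data.frames with
#'   columns `hit_id`, `taxon`, `kingdom`, `bit_score`, `identity`,
#'   `coverage`), `sequences` (named list: per gene, named character vector
#'   of the focal sequence plus hit sequences), and `truth` (planted HGT
#'   gene ids).
#' @export
simulate_hit_tables <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$hits_per_gene < 2L) stop("hits_per_gene must be >= 2")
  withr::with_seed(.stage_seed(cfg, "hits"), {
    n <- cfg$n_genes_hit_tables
    genes <- sprintf("G%04d", seq_len(n))
    hgt_idx <- if (cfg$n_planted_hgt > 0) sample.int(n, cfg$n_planted_hgt)
               else integer()
    is_hgt <- seq_len(n) %in% hgt_idx

    tables <- vector("list", n)
    seqs <- vector("list", n)
    names(tables) <- names(seqs) <- genes
    for (i in seq_len(n)) {
      h <- cfg$hits_per_gene
      p_fungal <- if (is_hgt[i]) cfg$hgt_fungal_prob else cfg$null_fungal_prob
      kingdom <- ifelse(stats::runif(h) < p_fungal, "fungal", "non_fungal")
      # bit scores: the dominant side (fungal for null genes, non-fungal for
      # planted HGT genes) is centered 100 units higher
      near_mean <- 300; far_mean <- 200
      mean_of <- function(k) {
        if (is_hgt[i]) ifelse(k == "non_fungal", near_mean, far_mean)
        else ifelse(k == "fungal", near_mean, far_mean)
      }
      bit <- stats::rnorm(h, mean_of(kingdom), 30)
      bit <- pmax(bit, 25)
      tab <- data.frame(hit_id = sprintf("%s_h%03d", genes[i], seq_len(h)),
                        taxon = ifelse(kingdom == "fungal",
                                       sprintf("fungus_sp%02d", sample.int(20, h, TRUE)),
                                       sprintf("bacterium_sp%02d", sample.int(20, h, TRUE))),
                        kingdom = kingdom,
                        bit_score = bit,
                        identity = stats::runif(h, 0.25, 0.95),
                        coverage = stats::runif(h, 0.45, 1),
                        stringsAsFactors = FALSE)
      tables[[i]] <- tab

      focal <- .random_dna(cfg$hit_seq_length, 0.5)
      near <- which(kingdom == (if (is_hgt[i]) "non_fungal" else "fungal"))
      rate <- ifelse(seq_len(h) %in% near, 0.05, 0.40)
      hit_seqs <- vapply(seq_len(h), function(j) {
        paste(.mutate_seq(focal, rate[j]), collapse = "")
      }, "")
      names(hit_seqs) <- tab$hit_id
      seqs[[i]] <- c(stats::setNames(paste(focal, collapse = ""), genes[i]),
                     hit_seqs)
    }
    list(tables = tables, sequences = seqs,
         truth = list(hgt_genes = genes[sort(hgt_idx)]))
  })
}
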