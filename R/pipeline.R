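#' Cluster short-lived chase time courses and fit decay kinetics
#'
#' The pattern-classification stage: all short-lived (gene, stimulation
#' time) courses are pooled, clustered by density peaks on the
#' arccos-Pearson distance, each cluster's core-mean course is fitted with
#' the four-model decay family (AIC-selected), and clusters are ranked from
#' quickest to slowest.
#'
#' @param timecourses long data.frame from [preprocess_study()]
#' @param labels genes x lps label matrix from [preprocess_study()]
#' @param k number of kinetic clusters (the study used 16, chosen from the
#'   gamma-rank plot)
#' @param dc_quantile density-peak neighbourhood quantile
#' @return list: `courses` (matrix of short-lived courses, rownames
#'   `gene@lps`), `dp` (clustering), `fits` (per-cluster selected
#'   `decay_fit`s), `ranks`, `core_means` (rank-named list of mean core
#'   courses), `long_lived_mean`, `assignments` (data.frame gene, lps_time,
#'   cluster, rank, delta), `chase_times`
#' @export
cluster_kinetics <- function(timecourses, labels, k = 16, dc_quantile = 0.02) {
  tc <- timecourses
  key <- paste(tc$gene, tc$lps_time, sep = "@")
  chase <- sort(unique(tc$chase_time))
  wide <- matrix(NA_real_, length(unique(key)), length(chase),
                 dimnames = list(unique(key), as.character(chase)))
  wide[cbind(key, as.character(tc$chase_time))] <- tc$relative_level

  info <- do.call(rbind, strsplit(rownames(wide), "@"))
  lab <- labels[cbind(info[, 1], info[, 2])]
  short <- wide[lab == "OK_SHORT", , drop = FALSE]
  longl <- wide[lab == "LONG_LIVED", , drop = FALSE]
  ## constant courses carry no shape; they cannot enter a correlation
  ## distance
  v <- apply(short, 1, stats::sd)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant short-lived course(s) excluded")
    short <- short[v > 0, , drop = FALSE]
  }

  D <- arccos_pearson_dist(short)
  dp <- density_peak_cluster(D, k = k, dc_quantile = dc_quantile)

  cluster_mean <- function(cl) {
    core <- dp$assignment == cl & dp$is_core
    if (!any(core)) core <- dp$assignment == cl  # degenerate all-halo cluster
    colMeans(short[core, , drop = FALSE])
  }
  means <- lapply(seq_len(k), cluster_mean)
  fits <- lapply(means, function(m) fit_decay_models(chase, m))
  deltas <- vapply(fits, function(f) if (f$flagged) NA_real_ else f$delta, 1)
  ok <- !is.na(deltas)
  ranks <- rep(NA_integer_, k)
  ranks[ok] <- rank_clusters(deltas[ok])

  sinfo <- do.call(rbind, strsplit(rownames(short), "@"))
  assignments <- data.frame(
    gene = sinfo[, 1], lps_time = as.numeric(sinfo[, 2]),
    cluster = dp$assignment, rank = ranks[dp$assignment],
    delta = deltas[dp$assignment], is_core = dp$is_core,
    stringsAsFactors = FALSE)

  ## key the core means by cluster rank (the pattern symbols downstream)
  core_means <- setNames(means[ok], as.character(ranks[ok]))
  core_means <- core_means[order(as.integer(names(core_means)))]
  list(courses = short, dp = dp, fits = fits, ranks = ranks,
       core_means = core_means,
       long_lived_mean = if (nrow(longl) > 0) colMeans(longl) else NULL,
       assignments = assignments, chase_times = chase)
}

#' Per-gene rate and rank matrices from a kinetic clustering
#'
#' @param ck result of [cluster_kinetics()]
#' @param labels genes x lps label matrix (supplies the output shape)
#' @return list of genes x lps matrices `rate` and `rank` (NA where no
#'   short-lived assignment exists)
#' @export
assignment_matrices <- function(ck, labels) {
  rate <- matrix(NA_real_, nrow(labels), ncol(labels), dimnames = dimnames(labels))
  rnk <- matrix(NA_integer_, nrow(labels), ncol(labels), dimnames = dimnames(labels))
  a <- ck$assignments
  idx <- cbind(a$gene, as.character(a$lps_time))
  rate[idx] <- a$delta
  rnk[idx] <- a$rank
  list(rate = rate, rank = rnk)
}

#' Run the degradation-kinetics analysis end to end
#'
#' Preprocessing (filters, quantile normalization, lifetime labels),
#' kinetic clustering with decay fits, and gene categorization.
#'
#' @param counts,rpkm genes x samples matrices
#' @param k kinetic cluster count (default 16)
#' @param dc_quantile density-peak neighbourhood quantile
#' @return list: `preprocess`, `kinetics`, `matrices` (rate/rank),
#'   `categories`
#' @export
classify_degradation <- function(counts, rpkm, k = 16, dc_quantile = 0.02) {
  pre <- preprocess_study(counts, rpkm)
  ck <- cluster_kinetics(pre$timecourses, pre$labels, k = k,
                         dc_quantile = dc_quantile)
  am <- assignment_matrices(ck, pre$labels)
  cats <- categorize_genes(pre$labels, am$rate)
  list(preprocess = pre, kinetics = ck, matrices = am, categories = cats)
}

#' Discover structure motifs in a gene cluster end to end
#'
#' Bins the cluster's UTRs, samples one bin per transcript, folds and
#' pairwise-aligns the set, selects conserved high-scoring seeds, iterates
#' each seed's profile to a fixed point, and reports motifs over-represented
#' in the cluster versus the universe.
#'
#' @param cluster_seqs named character vector of the cluster's 3' UTRs
#' @param universe_seqs all UTRs (background for over-representation)
#' @param conservation named list of per-base tracks
#' @param params alignment scoring from [struct_align_params()]
#' @param min_len,min_cons,top_frac seed filters (see [select_seeds()])
#' @param max_seeds cap on seeds iterated (top-score first)
#' @param q_max,min_hits reporting gates (see [report_motifs()])
#' @param max_evalue,n_decoys search parameters
#' @param seed RNG seed
#' @return list: `seeds` (table), `motifs` (iterated), `report`
#' @export
find_structure_motifs <- function(cluster_seqs, universe_seqs, conservation,
                                  params = struct_align_params(),
                                  min_len = 15, min_cons = 0.7,
                                  top_frac = 0.002, max_seeds = 10,
                                  q_max = 1e-4, min_hits = 10,
                                  max_evalue = 1, n_decoys = 200, seed = 1L) {
  bins <- bin_utrs(cluster_seqs)
  set <- sample_bin_sets(bins, 1, seed = seed)[[1]]
  aln <- pairwise_struct_alignments(set, params)
  seeds <- select_seeds(aln, conservation, min_len, min_cons, top_frac)
  if (nrow(seeds) == 0) {
    return(list(seeds = seeds, motifs = list(), report = NULL))
  }
  seeds <- seeds[order(-seeds$score), ]
  ## drop seeds that rediscover an already-taken window (same plant found
  ## by many pairs): greedy by score, overlap on either member disqualifies
  taken <- data.frame(gene = character(), start = integer(), end = integer())
  keep <- logical(nrow(seeds))
  overlaps <- function(g, s, e) {
    any(taken$gene == g & taken$start < e & s < taken$end)
  }
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ]
    if (overlaps(s$a_gene, s$a_start, s$a_end) ||
        overlaps(s$b_gene, s$b_start, s$b_end)) next
    keep[i] <- TRUE
    taken <- rbind(taken,
                   data.frame(gene = c(s$a_gene, s$b_gene),
                              start = c(s$a_start, s$b_start),
                              end = c(s$a_end, s$b_end)))
    if (sum(keep) >= max_seeds) break
  }
  seeds <- seeds[keep, ]
  bg <- background_freq(universe_seqs)
  motifs <- lapply(seq_len(nrow(seeds)), function(i) {
    s <- seeds[i, ]
    W <- min(s$a_end - s$a_start, s$b_end - s$b_start)
    wa <- clip_window(s$a_start, W, nchar(cluster_seqs[[s$a_gene]]))
    wb <- clip_window(s$b_start, W, nchar(cluster_seqs[[s$b_gene]]))
    members <- data.frame(
      gene = c(s$a_gene, s$b_gene), start = c(wa[1], wb[1]),
      seq = c(substr(cluster_seqs[[s$a_gene]], wa[1] + 1, wa[2]),
              substr(cluster_seqs[[s$b_gene]], wb[1] + 1, wb[2])),
      stringsAsFactors = FALSE)
    prof <- build_profile(members, background = bg)
    iterate_motif(prof, cluster_seqs, max_evalue = max_evalue,
                  n_decoys = n_decoys, seed = seed + 101L * i)
  })
  report <- report_motifs(motifs, names(cluster_seqs), universe_seqs,
                          q_max = q_max, min_hits = min_hits,
                          max_evalue = max_evalue, n_decoys = n_decoys,
                          seed = seed + 9999L)
  list(seeds = seeds, motifs = motifs, report = report)
}
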