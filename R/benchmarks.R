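#' Monte-Carlo benchmark: decay-rate recovery and model selection
#'
#' For each rate in `deltas` and each run, generates a cluster-mean chase
#' course (mean of `n_courses` noisy courses at `cv` multiplicative noise),
#' fits the generating single-exponential model and records the relative
#' error of the fitted rate.  A second arm generates plateau (r1 = 0.2)
#' courses and records how often AIC prefers the plateau model over pure
#' exponential decay — selection accuracy, measured separately because on a
#' 4 h 5-point chase a slow exponential is nearly linear and the plateau
#' model can absorb part of the rate.
#'
#' @param seed integer seed
#' @param n_runs Monte-Carlo runs per condition (default 100)
#' @param deltas true decay rates per hour
#' @param cv multiplicative noise CV (default 0.05)
#' @param n_courses courses averaged per cluster mean (default 50)
#' @param chase_times chase grid
#' @return list: `recovery_rate` (fraction of fits with relative rate error
#'   <= 10%), `median_rel_error`, `model_selection_rate` (fraction of
#'   plateau runs where model 2 is selected)
#' @export
benchmark_delta_recovery <- function(seed = 1L, n_runs = 100,
                                     deltas = c(0.1, 0.25, 0.5, 1, 2),
                                     cv = 0.05, n_courses = 50,
                                     chase_times = c(0, 0.5, 1, 2, 4)) {
  rel_err <- c()
  for (d in deltas) {
    errs <- vapply(seq_len(n_runs), function(r) {
      with_substream(seed, r * 131L + round(1000 * d), {
        reps <- replicate(n_courses,
          decay_level(chase_times, d) *
            (1 + stats::rnorm(length(chase_times), 0, cv)))
        m <- rowMeans(reps)
        ## recovery arm: fit the generating model; selection accuracy is
        ## measured separately below
        fit <- fit_decay(chase_times, pmax(m / m[1], 0), 1)
        abs(fit$delta - d) / d
      })
    }, 1)
    rel_err <- c(rel_err, errs)
  }
  sel <- vapply(seq_len(n_runs), function(r) {
    with_substream(seed, 900000L + r, {
      reps <- replicate(n_courses,
        decay_level(chase_times, 1, r0 = 1, r1 = 0.2) *
          (1 + stats::rnorm(length(chase_times), 0, cv)))
      m <- rowMeans(reps)
      fit_decay_models(chase_times, pmax(m / m[1], 0))$model_id == 2
    })
  }, TRUE)
  list(recovery_rate = mean(rel_err <= 0.10),
       median_rel_error = stats::median(rel_err),
       model_selection_rate = mean(sel))
}

#' Benchmark: density-peak recovery of four kinetic classes
#'
#' 50 genes per class with half-lives 0.25 / 1 / 4 / 24 h, 5% CV noise on
#' the relative levels; clustering on the Euclidean distance between
#' relative courses (the 4 h and 24 h classes are nearly collinear in
#' shape, so a level distance is the discriminating choice).
#'
#' @param seed integer seed
#' @param half_lives class half-lives (hours)
#' @param n_per_class genes per class
#' @param cv noise CV
#' @param dc_quantile neighbourhood quantile (default 0.1: with four
#'   equal-size classes, within-class pairs are ~25% of all distances, so
#'   the kernel scale must sit inside the within-class distance range)
#' @return adjusted Rand index between recovered and true classes
#' @export
benchmark_dp_recovery <- function(seed = 1L,
                                  half_lives = c(0.25, 1, 4, 24),
                                  n_per_class = 50, cv = 0.05,
                                  dc_quantile = 0.1) {
  chase <- c(0, 0.5, 1, 2, 4)
  truth <- rep(seq_along(half_lives), each = n_per_class)
  courses <- with_substream(seed, 17L, t(vapply(truth, function(cl) {
    lv <- 2^(-chase / half_lives[cl])
    lv * (1 + stats::rnorm(length(chase), 0, cv))
  }, numeric(length(chase)))))
  courses <- courses / courses[, 1]
  D <- as.matrix(stats::dist(courses))
  dimnames(D) <- NULL
  r <- density_peak_cluster(D, k = length(half_lives),
                            dc_quantile = dc_quantile)
  adjusted_rand_index(r$assignment, truth)
}

#' Adjusted Rand index between two labelings
#' @param a,b equal-length label vectors
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

#' Benchmark: category partition on noiseless synthetic data
#'
#' Runs the full pipeline (simulation, preprocessing, kinetic clustering,
#' decay fits, categorization) on noiseless data from six kinetic classes
#' straddling the quick/slow threshold plus a long-lived class, and scores
#' the recovered categories against the classes' analytic expectations.
#'
#' @param seed integer seed
#' @param n_per_class genes per class (default 30)
#' @return list: `stable_rate` (fraction of long-lived-class genes labelled
#'   STABLE), `split_rate` (fraction of unstable genes on the correct side
#'   of the 0.325 threshold), `categories`, `truth_delta`
#' @export
benchmark_categories <- function(seed = 1L, n_per_class = 30) {
  deltas <- c(2.5, 0.9, 0.4, 0.27, 0.12)
  classes <- c(
    lapply(seq_along(deltas), function(i) kinetic_class(i, delta = deltas[i])),
    list(kinetic_class(6, half_life = 30, long_lived = TRUE)))
  nc <- length(classes)
  d <- study_design(n_genes = n_per_class * nc)
  assign <- rep(seq_len(nc), each = n_per_class)
  sim <- simulate_counts(d, classes, assign, noise = FALSE, seed = seed,
                         baseline_tags = 1000)
  res <- classify_degradation(sim$counts, sim$rpkm, k = length(deltas),
                              dc_quantile = 0.05)
  cats <- res$categories
  cats <- cats[match(rownames(sim$counts), cats$gene), ]
  true_delta <- c(deltas, 0)[assign]
  is_ll <- assign == nc
  stable_rate <- mean(cats$category[is_ll] == "STABLE")
  want <- ifelse(true_delta[!is_ll] > quick_slow_threshold(), "QUICK", "SLOW")
  split_rate <- mean(cats$category[!is_ll] == want)
  list(stable_rate = stable_rate, split_rate = split_rate,
       categories = cats, truth_delta = true_delta)
}

#' Benchmark: planted AU-rich-element discovery and enrichment
#'
#' Each run plants UAUUUAU in 40% of the quick set's UTRs, runs multi-set
#' enumerative discovery on the quick set's bins, and tests quick-vs-stable
#' over-representation of the discovered motif's carrier genes.
#'
#' @param seed integer seed
#' @param n_runs runs (default 25)
#' @param n_per_set genes per category set (default 100)
#' @param n_bin_sets sampled bin sets per run (default 20)
#' @return list: `consensus_rate` (runs recovering >= 6/7 consensus
#'   positions), `enrichment_rate` (runs with quick-vs-stable Bonferroni
#'   p < 0.01), `joint_rate`
#' @export
benchmark_seq_motif <- function(seed = 1L, n_runs = 25, n_per_set = 100,
                                n_bin_sets = 20) {
  plant <- strsplit("UAUUUAU", "")[[1]]
  res <- vapply(seq_len(n_runs), function(r) {
    rs <- substream_seed(seed, 5000L + r)
    are <- plant_spec("sequence", consensus = "UAUUUAU", mutation_rate = 0,
                      carrier_fraction = 0.4)
    ids <- c(sprintf("q%04d", seq_len(n_per_set)),
             sprintf("s%04d", seq_len(n_per_set)))
    quick <- ids[seq_len(n_per_set)]
    utr <- simulate_utrs(2 * n_per_set, plants = list(are),
                         target_genes = list(quick), seed = rs,
                         gene_ids = ids)
    bg <- background_freq(utr$seqs)
    sets <- sample_bin_sets(bin_utrs(utr$seqs[quick]), n_bin_sets, seed = rs)
    mot <- find_motifs_sets(sets, k = 7, max_mismatch = 1, top_m = 3,
                            background = bg)
    ok_cons <- sum(strsplit(mot[[1]]$consensus, "")[[1]] == plant) >= 6
    cmp <- compare_hit_counts(
      motif_carriers(mot[[1]], utr$seqs),
      list(quick = quick, stable = setdiff(ids, quick)))
    ok_enr <- cmp$p_bonferroni[cmp$set_a == "quick"] < 0.01
    c(ok_cons, ok_enr)
  }, logical(2))
  list(consensus_rate = mean(res[1, ]), enrichment_rate = mean(res[2, ]),
       joint_rate = mean(res[1, ] & res[2, ]))
}

#' Benchmark: planted stem-loop discovery, iteration and reporting
#'
#' Each run plants a 6-bp-stem / 5-nt-loop hairpin (10% arm mutation
#' preserving complementarity) in 15% of a 150-gene cluster's UTRs, with a
#' conservation boost over the plant, then runs the full seed -> iterate ->
#' report procedure against a 450-gene universe.
#'
#' @param seed integer seed
#' @param n_runs runs (default 25)
#' @param n_cluster,n_background cluster / extra universe genes
#' @return list: `report_rate` (runs where a motif passes q < 1e-4 with
#'   >= 10 cluster instances), `runs` (per-run detail)
#' @export
benchmark_struct_motif <- function(seed = 1L, n_runs = 25, n_cluster = 150,
                                   n_background = 300) {
  runs <- lapply(seq_len(n_runs), function(r) {
    rs <- substream_seed(seed, 7000L + r)
    sl <- plant_spec("stemloop", arm5 = "GGCAGC", loop = "AUAUU",
                     arm3 = "GCUGCC", mutation_rate = 0.1,
                     carrier_fraction = 0.15, conservation_boost = 0.6)
    n <- n_cluster + n_background
    ids <- sprintf("gene%04d", seq_len(n))
    cluster_ids <- ids[seq_len(n_cluster)]
    utr <- simulate_utrs(n, plants = list(sl),
                         target_genes = list(cluster_ids), seed = rs)
    res <- find_structure_motifs(utr$seqs[cluster_ids], utr$seqs,
                                 utr$conservation, max_seeds = 5, seed = rs)
    reported <- !is.null(res$report) && any(res$report$reported)
    list(reported = reported, n_seeds = nrow(res$seeds))
  })
  list(report_rate = mean(vapply(runs, `[[`, TRUE, "reported")), runs = runs)
}

#' Benchmark: iteration fixed point on exact plants
#'
#' Plants one identical stem-loop in 10 of `n` UTRs, seeds a profile from
#' two carriers and iterates; reports the iteration counts to convergence.
#'
#' @param seed integer seed
#' @param n_runs runs (default 5)
#' @param n UTR count per run (default 60)
#' @return integer vector of iterations used per run (NA if unconverged)
#' @export
benchmark_iteration_fixed_point <- function(seed = 1L, n_runs = 5, n = 60) {
  sl <- paste0("GGCAGCAG", "AAUC", "CUGCUGCC")
  vapply(seq_len(n_runs), function(r) {
    rs <- substream_seed(seed, 8000L + r)
    seqs <- with_substream(rs, 1L, {
      s <- vapply(seq_len(n), function(i)
        paste(sample(RNA_BASES, 80, TRUE), collapse = ""), "")
      names(s) <- sprintf("g%03d", seq_len(n))
      offs <- sample(55, 10)
      for (i in seq_len(10)) substr(s[[i]], offs[i], offs[i] + 19) <- sl
      attr(s, "offs") <- offs
      s
    })
    offs <- attr(seqs, "offs")
    seed_members <- data.frame(gene = names(seqs)[1:2], start = offs[1:2] - 1L,
                               seq = sl, stringsAsFactors = FALSE)
    prof <- build_profile(seed_members, background = background_freq(seqs))
    res <- iterate_motif(prof, seqs, n_decoys = 100, seed = rs)
    if (res$converged) res$iterations else NA_integer_
  }, 1L)
}
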