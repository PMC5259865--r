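#' Pre-shutoff expression profiles and fold changes
#'
#' Extracts the chase-0 (pre-actinomycin-D) RPKM level at every stimulation
#' time and the log2 fold change versus stimulation time 0, with a
#' pseudocount guarding zero baselines.
#'
#' @param rpkm genes x samples matrix
#' @param pseudocount RPKM added before ratios (default 0.1)
#' @return list: `levels` (genes x lps RPKM), `log2fc` (genes x lps)
#' @export
expression_profiles <- function(rpkm, pseudocount = 0.1) {
  info <- parse_sample_names(colnames(rpkm))
  t0 <- info[info$chase_time == 0, ]
  t0 <- t0[order(t0$lps_time), ]
  lev <- rpkm[, t0$sample, drop = FALSE]
  colnames(lev) <- as.character(t0$lps_time)
  lfc <- log2(lev + pseudocount) - log2(lev[, 1] + pseudocount)
  list(levels = lev, log2fc = lfc)
}

#' Select regulated genes by fold change
#'
#' Up-regulated iff the (pseudocounted) maximum level exceeds `fold` times
#' the time-0 level; down-regulated iff the time-0 level exceeds `fold`
#' times the minimum.  A gene satisfying both goes to the direction with the
#' larger magnitude.
#'
#' @param profiles from [expression_profiles()]
#' @param fold fold-change threshold (default 3, strict)
#' @param pseudocount RPKM pseudocount (default 0.1)
#' @return list of gene-id vectors `up` and `down`
#' @export
select_regulated <- function(profiles, fold = 3, pseudocount = 0.1) {
  lev <- profiles$levels + pseudocount
  base <- lev[, 1]
  up_ratio <- apply(lev, 1, max) / base
  down_ratio <- base / apply(lev, 1, min)
  up <- up_ratio > fold
  down <- down_ratio > fold
  both <- up & down
  up[both] <- up_ratio[both] >= down_ratio[both]
  down[both] <- !up[both]
  list(up = rownames(lev)[up], down = rownames(lev)[down])
}

#' k-means clustering of regulated genes into temporal classes
#'
#' Profiles are per-gene standardized (z-score of the log2 fold changes)
#' and clustered by k-means (fixed seed, `nstart` restarts).  Clusters are
#' labelled by the stimulation time of their centroid's extremum (maximum
#' for `direction = "up"`, minimum for `"down"`): `immediate` if <= 1 h,
#' `early` if <= 3 h, else `late`.
#'
#' @param log2fc genes x lps matrix restricted to the regulated set
#' @param direction `"up"` or `"down"`
#' @param k number of clusters (default 3)
#' @param seed RNG seed
#' @param nstart k-means restarts (default 50)
#' @return data.frame (gene, cluster id, label); attribute `"centers"` holds
#'   the centroids
#' @export
kmeans_temporal <- function(log2fc, direction = c("up", "down"), k = 3,
                            seed = 1L, nstart = 50) {
  direction <- match.arg(direction)
  if (nrow(log2fc) < k) stop("k exceeds set size")
  z <- t(apply(log2fc, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) v - mean(v) else (v - mean(v)) / s
  }))
  km <- with_substream(seed, 1L, stats::kmeans(z, centers = k, nstart = nstart))
  times <- as.numeric(colnames(log2fc))
  ext_time <- apply(km$centers, 1, function(ce)
    times[if (direction == "up") which.max(ce) else which.min(ce)])
  lab <- ifelse(ext_time <= 1, "immediate", ifelse(ext_time <= 3, "early", "late"))
  out <- data.frame(gene = rownames(log2fc), cluster = km$cluster,
                    label = lab[km$cluster], stringsAsFactors = FALSE)
  attr(out, "centers") <- km$centers
  attr(out, "extremum_time") <- ext_time
  out
}

#' Degradation-category composition of expression clusters
#'
#' Per expression cluster, the fractions of quick / slow / stable /
#' low-reliability genes; pairwise one-sided Fisher exact tests comparing
#' the number of quick genes between clusters, and pairwise one-sided
#' Mann-Whitney tests on mean degradation rates, both Bonferroni-corrected.
#'
#' @param clusters named list of gene-id vectors (e.g. immediate/early/late
#'   up and down sets)
#' @param categories data.frame from [categorize_genes()]
#' @return list: `fractions` (cluster x category), `fisher` and
#'   `mann_whitney` data.frames with raw and Bonferroni p
#' @export
category_composition <- function(clusters, categories) {
  cats <- c("QUICK", "SLOW", "STABLE", "LOW_RELIABILITY")
  cat_of <- setNames(categories$category, categories$gene)
  rate_of <- setNames(categories$mean_rate, categories$gene)
  clusters <- Filter(function(g) {
    if (length(g) == 0) warning("empty cluster skipped")
    length(g) > 0
  }, clusters)

  frac <- t(vapply(clusters, function(g) {
    tb <- table(factor(cat_of[g], levels = cats))
    as.numeric(tb / max(sum(tb), 1))
  }, numeric(length(cats))))
  colnames(frac) <- cats

  nm <- names(clusters)
  fr <- list(); mw <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i == j) next
    gi <- clusters[[nm[i]]]; gj <- clusters[[nm[j]]]
    qi <- sum(cat_of[gi] == "QUICK", na.rm = TRUE)
    qj <- sum(cat_of[gj] == "QUICK", na.rm = TRUE)
    tab <- matrix(c(qi, length(gi) - qi, qj, length(gj) - qj), 2,
                  byrow = TRUE)
    pf <- stats::fisher.test(tab, alternative = "greater")$p.value
    ri <- rate_of[gi]; rj <- rate_of[gj]
    ri <- ri[!is.na(ri)]; rj <- rj[!is.na(rj)]
    pm <- if (length(ri) && length(rj))
      suppressWarnings(
        stats::wilcox.test(ri, rj, alternative = "greater")$p.value)
    else NA_real_
    fr[[length(fr) + 1]] <- data.frame(a = nm[i], b = nm[j], quick_a = qi,
                                       quick_b = qj, p = pf)
    mw[[length(mw) + 1]] <- data.frame(a = nm[i], b = nm[j], p = pm)
  }
  fisher <- do.call(rbind, fr)
  mann <- do.call(rbind, mw)
  fisher$p_bonferroni <- pmin(1, fisher$p * nrow(fisher))
  mann$p_bonferroni <- pmin(1, mann$p * nrow(mann))
  list(fractions = frac, fisher = fisher, mann_whitney = mann)
}
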