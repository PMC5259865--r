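#' Build per-gene degradation-pattern profiles
#'
#' One symbol per stimulation time point: the gene's kinetic-cluster rank
#' (`"1"`..`"K"`), `"LONG_LIVED"`, or `NA` where the course was unlabelled.
#'
#' @param labels genes x lps character matrix from [preprocess_study()]
#' @param cluster_rank genes x lps matrix of cluster ranks at OK_SHORT
#'   points (NA elsewhere)
#' @return genes x lps character matrix of pattern symbols
#' @export
pattern_profiles <- function(labels, cluster_rank) {
  stopifnot(all(dim(labels) == dim(cluster_rank)))
  out <- matrix(NA_character_, nrow(labels), ncol(labels),
                dimnames = dimnames(labels))
  out[labels == "LONG_LIVED"] <- "LONG_LIVED"
  sel <- labels == "OK_SHORT"
  out[sel] <- as.character(cluster_rank[sel])
  out
}

#' Symbol-to-symbol pattern distance table
#'
#' The distance between two pattern symbols is the arccos-Pearson distance
#' between the mean chase time courses of the corresponding cluster cores;
#' the long-lived symbol is represented by the mean of all long-lived
#' courses.
#'
#' @param core_means named list: symbol -> mean core time course (numeric
#'   vector over the chase grid)
#' @return symmetric matrix of distances with zero diagonal
#' @export
pattern_distance_table <- function(core_means) {
  syms <- names(core_means)
  if (any(vapply(core_means, length, 1L) < 3)) stop("courses too short")
  m <- do.call(rbind, core_means)
  d <- arccos_pearson_dist(m)
  dimnames(d) <- list(syms, syms)
  d
}

#' Distance between two pattern profiles
#'
#' Mean of the symbol-distance table over the stimulation time points where
#' both profiles are non-NA; undefined (NA, with warning from callers) when
#' fewer than 2 slots are shared.
#'
#' @param a,b character profiles (same length)
#' @param table symbol distance matrix from [pattern_distance_table()]
#' @return numeric distance or NA
#' @export
profile_distance <- function(a, b, table) {
  sh <- !is.na(a) & !is.na(b)
  if (sum(sh) < 2) return(NA_real_)
  mean(table[cbind(a[sh], b[sh])])
}

#' Pairwise profile-distance matrix
#'
#' Genes involved in undefined pairs (< 2 shared non-NA slots) are dropped
#' greedily (most-undefined first) with a warning.
#'
#' @param profiles genes x lps symbol matrix
#' @param table symbol distance matrix
#' @return list: `D` distance matrix, `genes` retained ids
#' @export
profile_distance_matrix <- function(profiles, table) {
  ng <- nrow(profiles)
  D <- matrix(0, ng, ng, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(ng - 1)) {
    for (j in seq(i + 1, ng)) {
      D[i, j] <- D[j, i] <- profile_distance(profiles[i, ], profiles[j, ], table)
    }
  }
  while (anyNA(D)) {
    bad <- which.max(rowSums(is.na(D)))
    warning("dropping gene with undefined profile pairs: ", rownames(D)[bad])
    D <- D[-bad, -bad, drop = FALSE]
  }
  list(D = D, genes = rownames(D))
}

#' Cluster genes by degradation-pattern profiles
#'
#' Stable genes (>= 4 long-lived time points) are separated first; the
#' remaining (unstable) genes are clustered by density peaks on the profile
#' distance, and clusters are relabelled `I`, `II`, ... by decreasing mean
#' degradation rate of their members.  Stable genes come back as the
#' `"stable"` group.
#'
#' @param profiles genes x lps symbol matrix (genes should have <= 4 NA
#'   slots)
#' @param table symbol distance matrix
#' @param categories data.frame from [categorize_genes()] (supplies the
#'   STABLE split and mean rates)
#' @param k number of profile clusters (default 9)
#' @param dc_quantile passed to [density_peak_cluster()]
#' @return data.frame (gene, cluster (`"I"`.. or `"stable"`), is_core,
#'   mean_rate), plus attribute `"dp"` with the raw clustering
#' @export
cluster_profiles <- function(profiles, table, categories, k = 9,
                             dc_quantile = 0.02) {
  rates <- setNames(categories$mean_rate, categories$gene)
  stable <- categories$gene[categories$category == "STABLE"]
  unstable <- setdiff(rownames(profiles), stable)
  pm <- profile_distance_matrix(profiles[unstable, , drop = FALSE], table)
  dp <- density_peak_cluster(pm$D, k = k, dc_quantile = dc_quantile)
  cl_rate <- tapply(rates[pm$genes], dp$assignment, mean, na.rm = TRUE)
  ord <- order(-cl_rate, as.integer(names(cl_rate)))
  relabel <- setNames(seq_along(ord), names(cl_rate)[ord])
  roman <- as.character(utils::as.roman(relabel[as.character(dp$assignment)]))
  out <- data.frame(
    gene = c(pm$genes, stable),
    cluster = c(roman, rep("stable", length(stable))),
    is_core = c(dp$is_core, rep(TRUE, length(stable))),
    mean_rate = rates[c(pm$genes, stable)],
    stringsAsFactors = FALSE
  )
  attr(out, "dp") <- dp
  out
}

#' Hypergeometric overlap significance between two clusterings
#'
#' For every pair of clusters from two clusterings over one universe, the
#' upper-tail hypergeometric p of the observed overlap given the cluster
#' sizes; raw p is reported (matching the usual overlap-heat-map
#' presentation) alongside a BH q over all pairs.  Empty clusters give p = 1.
#'
#' @param a,b named lists of gene-id vectors
#' @param universe background gene ids
#' @return data.frame (cluster_a, cluster_b, overlap, size_a, size_b, p, q)
#' @export
overlap_significance <- function(a, b, universe) {
  N <- length(unique(universe))
  rows <- list()
  for (na_ in names(a)) for (nb in names(b)) {
    ga <- intersect(a[[na_]], universe); gb <- intersect(b[[nb]], universe)
    k <- length(intersect(ga, gb))
    p <- if (length(ga) == 0 || length(gb) == 0) 1
         else hypergeom_upper(k, length(ga), length(gb), N)
    rows[[length(rows) + 1]] <- data.frame(
      cluster_a = na_, cluster_b = nb, overlap = k,
      size_a = length(ga), size_b = length(gb), p = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}
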