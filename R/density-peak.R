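#' Arccosine-of-Pearson distance
#'
#' `arccos(r)` of the Pearson correlation, in `[0, pi]`: 0 for perfectly
#' correlated series, `pi/2` for uncorrelated, `pi` for anticorrelated.
#' Shape-sensitive and scale-free, which suits decay time courses.
#'
#' @param x,y numeric series of equal length >= 3 with nonzero variance
#' @return distance in `[0, pi]`
#' @export
arccos_pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance series")
  acos(max(-1, min(1, stats::cor(x, y))))
}

#' Pairwise arccos-Pearson distance matrix for rows of a matrix
#'
#' @param m items x observations numeric matrix
#' @return symmetric items x items distance matrix
#' @export
arccos_pearson_dist <- function(m) {
  if (ncol(m) < 3) stop("need >= 3 observations per item")
  v <- apply(m, 1, stats::sd)
  if (any(v == 0)) stop("zero-variance rows: ", paste(which(v == 0), collapse = ","))
  r <- stats::cor(t(m))
  d <- acos(pmin(pmax(r, -1), 1))
  diag(d) <- 0
  d
}

#' Density-peak clustering
#'
#' Implements clustering by fast search-and-find of density peaks: each item
#' gets a local density `rho` (Gaussian kernel at scale `dc`, the
#' `dc_quantile` quantile of off-diagonal distances) and a separation `sep`,
#' the distance to the nearest item of higher density (the global density
#' maximum takes the overall maximum distance).  The product
#' `gamma = rho * sep` singles out cluster centers; the `k` largest-gamma
#' items seed the clusters and remaining items are assigned, in decreasing
#' density order, to the cluster of their nearest denser already-assigned
#' neighbour.  Cluster "cores" are the non-halo items: a cluster's halo is
#' its members whose density falls below the cluster's maximal border
#' density (borders = pairs of items from different clusters closer than
#' `dc`, scored by the mean of the two densities).
#'
#' Ties are broken deterministically: centers by larger gamma, then larger
#' rho, then smaller item index; assignment order by decreasing rho then
#' smaller index.
#'
#' @param D symmetric distance matrix with zero diagonal
#' @param k number of clusters (the gamma-rank table supports choosing it)
#' @param dc_quantile neighbourhood-scale quantile (default 0.02)
#' @return list (class `dp_result`): `rho`, `sep`, `gamma`, `centers`,
#'   `assignment`, `is_core`, `dc`
#' @export
density_peak_cluster <- function(D, k, dc_quantile = 0.02) {
  n <- nrow(D)
  if (k < 1) stop("k must be >= 1")
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix not symmetric")
  if (any(diag(D) != 0)) stop("nonzero diagonal")
  off <- D[upper.tri(D)]
  if (k > 1 && sum(off > 0) < 1) stop("all items coincide; k too large")
  dc <- stats::quantile(off[off > 0], dc_quantile, names = FALSE)
  if (!is.finite(dc) || dc <= 0) dc <- max(off, mean(off), na.rm = TRUE)

  rho <- rowSums(exp(-(D / dc)^2)) - 1  # exclude self term
  ord <- order(-rho, seq_len(n))        # decreasing density, index tie-break
  sep <- numeric(n)
  nn_higher <- integer(n)
  sep[ord[1]] <- max(D[ord[1], ])
  nn_higher[ord[1]] <- NA_integer_
  for (i in seq(2, length.out = n - 1)) {
    me <- ord[i]
    denser <- ord[seq_len(i - 1)]
    j <- denser[which.min(D[me, denser])]
    sep[me] <- D[me, j]
    nn_higher[me] <- j
  }
  gamma <- rho * sep

  cen_ord <- order(-gamma, -rho, seq_len(n))
  centers <- cen_ord[seq_len(k)]
  assignment <- integer(n)
  assignment[centers] <- seq_len(k)
  for (i in seq_len(n)) {
    me <- ord[i]
    if (assignment[me] == 0) assignment[me] <- assignment[nn_higher[me]]
  }

  is_core <- rep(TRUE, n)
  if (k > 1) {
    border_rho <- rep(-Inf, k)
    pr <- which(upper.tri(D) & D < dc, arr.ind = TRUE)
    pr <- pr[assignment[pr[, 1]] != assignment[pr[, 2]], , drop = FALSE]
    if (nrow(pr) > 0) {
      rb <- (rho[pr[, 1]] + rho[pr[, 2]]) / 2
      for (cl in unique(c(assignment[pr[, 1]], assignment[pr[, 2]]))) {
        sel <- assignment[pr[, 1]] == cl | assignment[pr[, 2]] == cl
        border_rho[cl] <- max(rb[sel])
      }
    }
    is_core <- rho >= border_rho[assignment]
  }
  structure(
    list(rho = rho, sep = sep, gamma = gamma, centers = centers,
         assignment = assignment, is_core = is_core, dc = dc),
    class = "dp_result"
  )
}

#' @export
print.dp_result <- function(x, ...) {
  cat(sprintf("density-peak clustering: %d items, %d clusters, %d core members (dc = %.4g)\n",
              length(x$rho), length(x$centers), sum(x$is_core), x$dc))
  invisible(x)
}

#' Gamma-rank table for choosing the cluster count
#'
#' Emits gamma = rho x sep in decreasing order with 1-based ranks, the plot
#' one inspects to pick `k` (cluster centers stand out as high-gamma
#' outliers).
#'
#' @param result a [density_peak_cluster()] result
#' @return data.frame (rank, item, gamma)
#' @export
gamma_rank_table <- function(result) {
  ord <- order(-result$gamma, -result$rho, seq_along(result$gamma))
  data.frame(rank = seq_along(ord), item = ord, gamma = result$gamma[ord])
}
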