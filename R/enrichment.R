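#' Upper-tail hypergeometric probability
#'
#' Exact probability of drawing `k` or more annotated genes when `n` genes
#' are sampled without replacement from a universe of `N` containing `K`
#' annotated ones.
#'
#' @param k hits in the set
#' @param n set size
#' @param K hits in the universe
#' @param N universe size
#' @return `P(X >= k)`
#' @export
hypergeom_upper <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > n || n > N || K > N)
    stop("inconsistent counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR control: `q_(i) = min_{j >= i} p_(j) * m / j` mapped back to
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`
#' @return q-values in input order
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Read a GMT term-to-gene file
#'
#' @param path GMT path (term, description, genes..., tab-separated)
#' @return named list of gene-id character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(out) <- vapply(strsplit(lines, "\t"), `[[`, "", 1)
  out
}

#' Write a GMT term-to-gene file
#' @param terms named list of gene-id vectors
#' @param path output path
#' @export
write_gmt <- function(terms, path) {
  writeLines(vapply(names(terms), function(nm)
    paste(c(nm, nm, terms[[nm]]), collapse = "\t"), ""), path)
}

#' Over-representation of annotation terms in a gene set
#'
#' One upper-tail hypergeometric test per term with at least one universe
#' hit, BH correction across terms, and a q-value cutoff.
#'
#' @param set character vector of genes (must lie within `universe`)
#' @param term_map named list of term gene sets (intersected with `universe`)
#' @param universe background gene ids
#' @param alpha q-value cutoff for the `enriched` table (default 0.05)
#' @return list with `table` (all tested terms: term, k, n, K, N, p, q,
#'   sorted by q then p) and `enriched` (rows with q < alpha)
#' @export
enrich <- function(set, term_map, universe, alpha = 0.05) {
  extra <- setdiff(set, universe)
  if (length(extra) > 0)
    stop("set genes outside universe: ", paste(extra, collapse = ", "))
  set <- unique(set); universe <- unique(universe)
  N <- length(universe); n <- length(set)
  rows <- lapply(names(term_map), function(tm) {
    tg <- intersect(term_map[[tm]], universe)
    K <- length(tg)
    if (K == 0) return(NULL)
    k <- length(intersect(tg, set))
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               p = hypergeom_upper(k, n, K, N), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(), q = numeric())
    return(list(table = tab, enriched = tab))
  }
  tab$q <- bh_adjust(tab$p)
  tab <- tab[order(tab$q, tab$p), ]
  rownames(tab) <- NULL
  list(table = tab, enriched = tab[tab$q < alpha, ])
}
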