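#' The long-lived relative-level threshold
#'
#' A chase time course retaining more than `2^(-4/24)` (about 89%) of its
#' initial level 4 h after transcription shutoff would correspond to a
#' half-life above 24 h and is labelled long-lived.
#'
#' @return the constant `2^(-4/24)`
#' @export
long_lived_threshold <- function() 2^(-4 / 24)

#' Select expressed genes
#'
#' A gene is expressed iff it has RPKM >= 1 in at least one pre-shutoff
#' sample (chase time 0, any stimulation time).
#'
#' @param rpkm genes x samples matrix with `LPS<h>_ActD<h>` column names
#' @param min_rpkm threshold (default 1)
#' @return character vector of expressed gene ids
#' @export
filter_expressed <- function(rpkm, min_rpkm = 1) {
  info <- parse_sample_names(colnames(rpkm))
  t0 <- info$sample[info$chase_time == 0]
  if (length(t0) == 0) stop("no chase-time-0 samples in table")
  if (nrow(rpkm) == 0) return(character(0))
  keep <- apply(rpkm[, t0, drop = FALSE], 1, max) >= min_rpkm
  rownames(rpkm)[keep]
}

#' Tag-depth reliability of each (gene, stimulation time) time course
#'
#' Courses with fewer than `min_tags` tags at chase time 0 carry too little
#' information for kinetic estimation and are dropped (marked NA downstream).
#'
#' @param counts genes x samples raw tag-count matrix
#' @param min_tags minimum chase-0 tag count (default 20)
#' @return logical matrix genes x stimulation times (TRUE = reliable)
#' @export
filter_reliable <- function(counts, min_tags = 20) {
  if (any(counts < 0)) stop("negative counts")
  info <- parse_sample_names(colnames(counts))
  t0 <- info[info$chase_time == 0, ]
  t0 <- t0[order(t0$lps_time), ]
  m <- counts[, t0$sample, drop = FALSE] >= min_tags
  colnames(m) <- as.character(t0$lps_time)
  m
}

#' Quantile-normalize samples within each chase-time group
#'
#' All samples sharing one chase time (i.e. one time point after shutoff,
#' across stimulation times) are quantile-normalized together, so that each
#' carries the identical sorted value multiset (the per-rank group means,
#' ties averaged).  Groups of size 1 pass through unchanged with a warning.
#'
#' @param x genes x samples matrix, `LPS<h>_ActD<h>` columns
#' @return matrix of the same shape
#' @export
quantile_normalize <- function(x) {
  info <- parse_sample_names(colnames(x))
  out <- x
  for (ch in unique(info$chase_time)) {
    cols <- info$sample[info$chase_time == ch]
    if (length(cols) < 2) {
      warning(sprintf("chase-time group %g has a single sample; passed through", ch))
      next
    }
    out[, cols] <- limma::normalizeQuantiles(x[, cols, drop = FALSE], ties = TRUE)
  }
  out
}

#' Relative chase time courses
#'
#' Divides each gene's (quantile-normalized) chase series at one stimulation
#' time by its chase-0 value, yielding the fraction of the original RNA
#' level remaining.
#'
#' @param norm_rpkm normalized genes x samples matrix
#' @return data.frame (gene, lps_time, chase_time, relative_level); courses
#'   with a zero chase-0 value are dropped
#' @export
relative_timecourses <- function(norm_rpkm) {
  info <- parse_sample_names(colnames(norm_rpkm))
  info <- info[order(info$lps_time, info$chase_time), ]
  out <- lapply(unique(info$lps_time), function(lp) {
    blk <- info[info$lps_time == lp, ]
    v0 <- norm_rpkm[, blk$sample[blk$chase_time == 0]]
    keep <- v0 > 0
    if (!any(keep)) return(NULL)
    rel <- norm_rpkm[keep, blk$sample, drop = FALSE] / v0[keep]
    data.frame(
      gene = rep(rownames(norm_rpkm)[keep], times = nrow(blk)),
      lps_time = lp,
      chase_time = rep(blk$chase_time, each = sum(keep)),
      relative_level = as.vector(rel),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Label one relative time course long- or short-lived
#'
#' @param chase_times,levels the course (must include chase time 4 h; level
#'   relative to chase 0)
#' @return `"LONG_LIVED"` if the 4 h level strictly exceeds
#'   [long_lived_threshold()], else `"OK_SHORT"`
#' @export
label_lifetime <- function(chase_times, levels) {
  i <- which(chase_times == 4)
  if (length(i) != 1) stop("course must contain exactly one 4 h chase point")
  if (levels[chase_times == 0] != 1) stop("course is not normalized to chase 0")
  if (levels[i] > long_lived_threshold()) "LONG_LIVED" else "OK_SHORT"
}

#' Run the full preprocessing stage
#'
#' Expressed-gene selection, chase-time-group quantile normalization,
#' relative-level computation and per-(gene, stimulation time) reliability /
#' lifetime labelling.
#'
#' @param counts,rpkm genes x samples matrices from the same design
#' @return list with `expressed` (gene ids), `timecourses` (long data.frame,
#'   reliable short+long courses of expressed genes), `labels` (genes x
#'   stimulation-times character matrix over OK_SHORT / LONG_LIVED /
#'   NA_LOW_TAGS / NA_NOT_EXPRESSED)
#' @export
preprocess_study <- function(counts, rpkm) {
  expressed <- filter_expressed(rpkm)
  reliable <- filter_reliable(counts)
  normed <- quantile_normalize(rpkm)
  tc <- relative_timecourses(normed)

  lps <- sort(unique(tc$lps_time))
  genes <- rownames(rpkm)
  labels <- matrix("NA_NOT_EXPRESSED", length(genes), length(lps),
                   dimnames = list(genes, as.character(lps)))
  for (g in intersect(expressed, genes)) {
    for (lp in lps) {
      if (!reliable[g, as.character(lp)]) {
        labels[g, as.character(lp)] <- "NA_LOW_TAGS"
        next
      }
      crs <- tc[tc$gene == g & tc$lps_time == lp, ]
      if (nrow(crs) == 0) {
        labels[g, as.character(lp)] <- "NA_LOW_TAGS"
        next
      }
      labels[g, as.character(lp)] <-
        label_lifetime(crs$chase_time, crs$relative_level)
    }
  }
  keep <- tc$gene %in% expressed &
    labels[cbind(tc$gene, as.character(tc$lps_time))] %in% c("OK_SHORT", "LONG_LIVED")
  list(expressed = expressed, timecourses = tc[keep, ], labels = labels)
}
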