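#' Cut 3' UTR sequences into overlapping bins
#'
#' 100-base bins stepping by 50 (adjacent bins overlap by 50).  If the
#' length is not an exact multiple of the step, one extra end-anchored bin
#' `[L-100, L)` covers the tail; UTRs shorter than the bin length yield a
#' single whole-UTR bin.
#'
#' @param seqs named character vector of RNA sequences (T normalized to U)
#' @param bin_length,step bin geometry (defaults 100/50)
#' @return data.frame (gene, start, end, seq), 0-based half-open coordinates
#' @export
bin_utrs <- function(seqs, bin_length = 100, step = 50) {
  rows <- lapply(names(seqs), function(g) {
    s <- chartr("T", "U", toupper(seqs[[g]]))
    L <- nchar(s)
    if (L == 0) {
      warning("empty record skipped: ", g)
      return(NULL)
    }
    if (L < bin_length) {
      starts <- 0L; ends <- as.integer(L)
    } else {
      starts <- as.integer(seq(0L, L - bin_length, by = step))
      ends <- starts + as.integer(bin_length)
      if (L %% step != 0) {
        starts <- c(starts, as.integer(L - bin_length))
        ends <- c(ends, as.integer(L))
      }
    }
    data.frame(gene = g, start = starts, end = ends,
               seq = substring(s, starts + 1, ends), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sample sets of one bin per transcript
#'
#' @param bins data.frame from [bin_utrs()]
#' @param n_sets number of sets (the discovery procedure uses at most 700)
#' @param seed RNG seed
#' @return list of data.frames, each with exactly one bin per gene
#' @export
sample_bin_sets <- function(bins, n_sets = 700, seed = 1L) {
  if (n_sets == 0) return(list())
  by_gene <- split(seq_len(nrow(bins)), bins$gene)
  lapply(seq_len(n_sets), function(s) {
    idx <- with_substream(seed, s, vapply(by_gene, function(ii) {
      if (length(ii) == 1) ii else sample(ii, 1)
    }, 1L))
    bins[idx, , drop = FALSE]
  })
}

#' Single-nucleotide background frequencies of a sequence pool
#' @param seqs character vector of RNA sequences
#' @return named numeric vector over A, C, G, U summing to 1
#' @export
background_freq <- function(seqs) {
  tab <- table(factor(strsplit(paste(chartr("T", "U", toupper(seqs)),
                                     collapse = ""), "")[[1]],
                      levels = RNA_BASES))
  p <- as.numeric(tab) / sum(tab)
  setNames(p, RNA_BASES)
}

## integer codes of all k-mer windows of each sequence (base-4 encoding)
kmer_codes <- function(seq, k) {
  x <- encode_rna(seq)
  n <- length(x)
  if (n < k) return(integer(0))
  idx <- outer(seq_len(n - k + 1) - 1L, seq_len(k) - 1L, "+") + 1L
  m <- matrix(x[idx], ncol = k)
  as.integer(m %*% (4L^((k - 1):0)))
}

decode_kmer <- function(code, k) {
  digits <- integer(k)
  for (i in k:1) {
    digits[i] <- code %% 4L
    code <- code %/% 4L
  }
  decode_rna(digits)
}

## all codes within Hamming distance <= m of each input code (k <= 8, m <= 2)
hamming_ball <- function(codes, k, m) {
  pow <- 4L^((k - 1):0)
  out <- list(codes)
  if (m >= 1) {
    for (p in seq_len(k)) {
      dig <- (codes %/% pow[p]) %% 4L
      for (b in 0:3) {
        out[[length(out) + 1]] <- codes + (b - dig) * pow[p]
      }
    }
  }
  if (m >= 2 && k >= 2) {
    for (p in seq_len(k - 1)) for (q in seq(p + 1, k)) {
      dp <- (codes %/% pow[p]) %% 4L
      dq <- (codes %/% pow[q]) %% 4L
      for (b1 in 0:3) for (b2 in 0:3) {
        out[[length(out) + 1]] <-
          codes + (b1 - dp) * pow[p] + (b2 - dq) * pow[q]
      }
    }
  }
  out
}

## P(random background k-mer within Hamming distance <= m of given kmer)
## Poisson-binomial over positions via elementary symmetric sums
match_prob <- function(codes, k, m, q) {
  pow <- 4L^((k - 1):0)
  qm <- vapply(seq_len(k), function(p) q[(codes %/% pow[p]) %% 4L + 1L], numeric(length(codes)))
  qm <- matrix(qm, ncol = k)  # per-position prob of matching
  p0 <- apply(qm, 1, prod)
  res <- p0
  if (m >= 1) {
    s1 <- rowSums((1 - qm) / qm)
    res <- res + p0 * s1
    if (m >= 2) {
      s2 <- 0.5 * (s1^2 - rowSums(((1 - qm) / qm)^2))
      res <- res + p0 * s2
    }
  }
  pmin(res, 1)
}

#' Enumerative mismatch-tolerant k-mer motif discovery
#'
#' Exhaustive oligo search in the spirit of classic enumeration-based motif
#' finders: every k-mer over ACGU is scored by the binomial upper-tail
#' significance (-log p) of the number of set sequences containing an exact
#' occurrence, given the k-mer's containment probability under the
#' single-nucleotide background of the full UTR pool.  Tail significance
#' rather than a raw observed/expected ratio normalizes both the mean and
#' the variance of the containment count, so composition-biased k-mers
#' (e.g. AU-rich ones with high background rates) compete fairly with rare
#' ones; exact rather than mismatch-tolerant counting keeps a planted
#' word's one-off neighbours (whose mismatch neighbourhoods contain the
#' plant but whose own background rate is lower) from outranking the word
#' itself.  The `top_m` k-mers are kept after greedy redundancy removal (no
#' two kept k-mers within Hamming distance 1), and each kept k-mer's
#' position frequency matrix is built from all of its occurrences within
#' `max_mismatch` in the set.
#'
#' @param seqs character vector of bin sequences (one per transcript)
#' @param k motif width (6 or 8 are the defaults upstream)
#' @param max_mismatch mismatch budget (default 1 for k = 6, 2 for k = 8)
#' @param top_m number of motifs to keep
#' @param background named ACGU frequency vector (default: from `seqs`)
#' @return list of motifs, each a list (consensus, score, pfm (4 x k counts
#'   matrix), n_sites)
#' @export
find_motifs <- function(seqs, k = 6, max_mismatch = if (k <= 6) 1 else 2,
                        top_m = 5, background = NULL) {
  if (length(seqs) == 0) stop("empty bin set")
  if (is.null(background)) background <- background_freq(seqs)
  nk <- 4L^k
  ## exact-containment count per k-mer
  present <- integer(nk)
  win_codes <- lapply(seqs, kmer_codes, k = k)
  n_win <- vapply(win_codes, length, 1L)
  for (wc in win_codes) {
    if (length(wc) == 0) next
    u <- unique(wc)
    present[u + 1L] <- present[u + 1L] + 1L
  }
  ## containment probability per sequence under the background, then the
  ## binomial upper tail of the observed containment count
  all_codes <- 0:(nk - 1L)
  pm <- match_prob(all_codes, k, 0L, background)
  nseq <- sum(n_win > 0)
  p_contain <- numeric(nk)
  for (nw in unique(n_win[n_win > 0])) {
    cnt <- sum(n_win == nw)
    p_contain <- p_contain + (cnt / nseq) * (1 - (1 - pm)^nw)
  }
  score <- -stats::pbinom(present - 1L, nseq, pmin(p_contain, 1),
                          lower.tail = FALSE, log.p = TRUE)

  ord <- order(-score, all_codes)
  kept <- integer(0)
  for (cd in all_codes[ord]) {
    if (length(kept) >= top_m) break
    if (length(kept) > 0) {
      near <- unlist(hamming_ball(cd, k, 1))
      if (any(kept %in% near)) next
    }
    kept <- c(kept, cd)
  }
  lapply(kept, function(cd) {
    ball <- unique(unlist(hamming_ball(cd, k, max_mismatch)))
    pfm <- matrix(0, 4, k, dimnames = list(RNA_BASES, NULL))
    n_sites <- 0L
    for (wc in win_codes) {
      hits <- wc[wc %in% ball]
      for (h in hits) {
        dig <- integer(k); c2 <- h
        for (i in k:1) { dig[i] <- c2 %% 4L; c2 <- c2 %/% 4L }
        pfm[cbind(dig + 1L, seq_len(k))] <- pfm[cbind(dig + 1L, seq_len(k))] + 1
        n_sites <- n_sites + 1L
      }
    }
    list(consensus = decode_kmer(cd, k), score = score[cd + 1L],
         pfm = pfm, n_sites = n_sites)
  })
}

#' Discover motifs across many sampled bin sets and merge by consensus
#'
#' Runs [find_motifs()] independently on each sampled set and merges the
#' per-set results by consensus identity, mirroring the observation that a
#' genuine motif recurs across independently sampled sets while background
#' k-mers do not.  Merged motifs are ranked by the number of sets whose
#' top list contains them, then by mean enrichment score; PFMs of merged
#' occurrences are summed.
#'
#' @param sets list of bin data.frames from [sample_bin_sets()] (or of
#'   character vectors)
#' @param k,max_mismatch,top_m,background as in [find_motifs()]
#' @return list of motifs (consensus, score = mean per-set score, n_sets,
#'   pfm, n_sites), ordered by recurrence
#' @export
find_motifs_sets <- function(sets, k = 6, max_mismatch = if (k <= 6) 1 else 2,
                             top_m = 5, background = NULL) {
  per_set <- lapply(sets, function(s) {
    seqs <- if (is.data.frame(s)) s$seq else s
    find_motifs(seqs, k = k, max_mismatch = max_mismatch, top_m = top_m,
                background = background)
  })
  flat <- unlist(per_set, recursive = FALSE)
  cons <- vapply(flat, `[[`, "", "consensus")
  merged <- lapply(unique(cons), function(cs) {
    hits <- flat[cons == cs]
    list(consensus = cs,
         score = mean(vapply(hits, `[[`, 1, "score")),
         n_sets = length(hits),
         pfm = Reduce(`+`, lapply(hits, `[[`, "pfm")),
         n_sites = sum(vapply(hits, `[[`, 1L, "n_sites")))
  })
  ord <- order(-vapply(merged, `[[`, 1L, "n_sets"),
               -vapply(merged, `[[`, 1, "score"))
  merged[ord]
}

#' Convert a position frequency matrix to a log-odds weight matrix
#'
#' Pseudocounted frequencies `p_b = (count_b + pc * q_b) / (n + pc)` with
#' total pseudocount `pc` (default 0.8) distributed by the background `q`,
#' then `weight = log2(p_b / q_b)`.
#'
#' @param pfm 4 x width counts matrix (rows A, C, G, U)
#' @param pseudocount total pseudocount per column (default 0.8)
#' @param background named ACGU frequency vector (default uniform)
#' @return 4 x width numeric weight matrix (class `pwm`)
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.8, background = NULL) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (is.null(background)) background <- setNames(rep(0.25, 4), RNA_BASES)
  n <- colSums(pfm)
  if (any(n == 0)) stop("zero-site column in PFM")
  q <- background[RNA_BASES]
  p <- sweep(pfm + pseudocount * q, 2, n + pseudocount, "/")
  w <- log2(p / q)
  structure(w, class = "pwm", background = q)
}

## exact null score distribution of a PWM under an i.i.d. background,
## discretized; returns (scores, probabilities)
pwm_score_distribution <- function(pwm, background, bin = 1e-3) {
  wq <- round(unclass(pwm) / bin)  # integer column scores on the bin grid
  lo_tot <- sum(apply(wq, 2, min))
  hi_tot <- sum(apply(wq, 2, max))
  dist <- numeric(hi_tot - lo_tot + 1)  # index i <-> score lo_tot + i - 1
  ## start: point mass at 0 relative to running offset
  dist[1] <- 1
  off <- 0  # current distribution starts at score `off`
  cur_len <- 1L
  for (j in seq_len(ncol(wq))) {
    lo_j <- min(wq[, j]); hi_j <- max(wq[, j])
    new_len <- cur_len + (hi_j - lo_j)
    new <- numeric(new_len)
    for (b in 1:4) {
      sh <- wq[b, j] - lo_j
      idx <- seq_len(cur_len) + sh
      new[idx] <- new[idx] + dist[seq_len(cur_len)] * background[b]
    }
    dist <- new
    off <- off + lo_j
    cur_len <- new_len
  }
  keep <- dist > 0
  s <- (off + which(keep) - 1) * bin
  list(score = s, prob = dist[keep])
}

#' Scan sequences with a PWM, with exact per-position p-values
#'
#' Sense strand only (3' UTRs).  Each position's score is the sum of column
#' weights; its p-value is the exact upper tail of the score distribution
#' under the i.i.d. background (dynamic-programming convolution of the
#' per-column score distributions, scores discretized to `bin`).  BH
#' correction runs across all scanned positions of the run; hits are
#' positions with q < `alpha`.
#'
#' @param pwm from [pfm_to_pwm()]
#' @param seqs named character vector
#' @param alpha FDR cutoff (default 0.05)
#' @param background ACGU frequencies (default: the PWM's)
#' @param bin score discretization (default 1e-3)
#' @return data.frame (gene, position (0-based), score, p, q) of hits; the
#'   full scan is in attribute `"all_positions"`
#' @export
scan_pwm <- function(pwm, seqs, alpha = 0.05, background = NULL, bin = 1e-3) {
  if (is.null(background)) background <- attr(pwm, "background")
  background <- background[RNA_BASES]
  w <- ncol(pwm)
  nd <- pwm_score_distribution(pwm, background, bin)
  tailp <- rev(cumsum(rev(nd$prob)))  # P(S >= score_i)

  rows <- lapply(names(seqs), function(g) {
    x <- encode_rna(seqs[[g]])
    if (length(x) < w) return(NULL)
    n_off <- length(x) - w + 1
    sc <- vapply(seq_len(n_off), function(off)
      sum(unclass(pwm)[cbind(x[off:(off + w - 1)] + 1L, seq_len(w))]), 1)
    ## round to the same grid as the null distribution
    i <- findInterval(round(sc / bin) * bin, nd$score - bin / 2)
    p <- ifelse(i < 1, 1, ifelse(i > length(tailp), 0, tailp[pmax(i, 1)]))
    p <- pmin(1, pmax(0, p))  # guard cumsum roundoff
    data.frame(gene = g, position = seq_len(n_off) - 1L, score = sc, p = p,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  if (is.null(all)) {
    out <- data.frame(gene = character(), position = integer(),
                      score = numeric(), p = numeric(), q = numeric())
    attr(out, "all_positions") <- out
    return(out)
  }
  all$q <- bh_adjust(all$p)
  hits <- all[all$q < alpha, ]
  rownames(hits) <- NULL
  attr(hits, "all_positions") <- all
  hits
}

#' Genes whose sequence contains a motif occurrence
#'
#' The enumerative finder's own gene-level site query: a gene carries the
#' motif iff its sequence contains a window within `max_mismatch`
#' substitutions of the consensus.  The default is exact matching — for
#' short low-complexity motifs a mismatch-tolerant neighbourhood is carried
#' by most sequences at random, while the exact word remains rare, so exact
#' containment is the discriminative gene-level statistic where
#' position-level FDR calling cannot resolve single sites.
#'
#' @param motif a motif from [find_motifs()] / [find_motifs_sets()] (or a
#'   consensus string)
#' @param seqs named character vector
#' @param max_mismatch substitution budget (default 0, exact)
#' @return character vector of gene ids containing >= 1 occurrence
#' @export
motif_carriers <- function(motif, seqs, max_mismatch = 0) {
  cons <- if (is.list(motif)) motif$consensus else motif
  k <- nchar(cons)
  ball <- unique(unlist(hamming_ball(kmer_codes(cons, k), k, max_mismatch)))
  carries <- vapply(seqs, function(s) {
    any(kmer_codes(s, k) %in% ball)
  }, TRUE)
  names(seqs)[carries]
}

#' Compare motif-hit gene counts across degradation categories
#'
#' Counts genes with at least one hit per set and tests every pair of sets
#' by the upper-tail hypergeometric on the pooled two-set universe, with
#' Bonferroni correction over the pairs.
#'
#' @param hit_genes character vector of genes with >= 1 motif hit
#' @param sets named list of disjoint gene-id vectors (e.g. quick / slow /
#'   stable)
#' @return data.frame (set_a, set_b, hits_a, size_a, hits_b, size_b, p,
#'   p_bonferroni); p tests enrichment of hits in set_a vs set_b
#' @export
compare_hit_counts <- function(hit_genes, sets) {
  nm <- names(sets)
  if (length(unique(unlist(sets))) != length(unlist(sets)))
    stop("sets must be disjoint")
  sets <- Filter(length, sets)
  nm <- names(sets)
  rows <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i >= j) next
    ga <- sets[[nm[i]]]; gb <- sets[[nm[j]]]
    ka <- sum(ga %in% hit_genes); kb <- sum(gb %in% hit_genes)
    ## pooled universe of the two sets; is set_a enriched for hit genes?
    p <- hypergeom_upper(ka, length(ga), ka + kb, length(ga) + length(gb))
    rows[[length(rows) + 1]] <- data.frame(
      set_a = nm[i], set_b = nm[j], hits_a = ka, size_a = length(ga),
      hits_b = kb, size_b = length(gb), p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' Write motifs in MEME minimal format
#'
#' @param motifs list from [find_motifs()]
#' @param path output path
#' @param background ACGU frequencies for the header
#' @export
write_meme <- function(motifs, path, background = NULL) {
  if (is.null(background)) background <- setNames(rep(0.25, 4), RNA_BASES)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", RNA_BASES, background[RNA_BASES]),
                     collapse = " "), ""), con)
  for (m in motifs) {
    freq <- sweep(m$pfm, 2, pmax(colSums(m$pfm), 1), "/")
    writeLines(sprintf("MOTIF %s", m$consensus), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(m$pfm), m$n_sites), con)
    writeLines(apply(freq, 2, function(col)
      paste(sprintf("%.6f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(NULL)
}
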