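#' Fold one sequence by base-pair maximization
#'
#' Nussinov-style dynamic program: maximizes the number of nested
#' Watson-Crick / wobble pairs (AU, GC, GU) with hairpin loops of at least 3
#' unpaired bases, no pseudoknots.  The traceback is deterministic (leftmost
#' admissible partner preferred), so the same sequence always folds the same
#' way.
#'
#' @param seq RNA string
#' @return list (class `folded_bin`): `seq`, `pairing` (1-based partner
#'   index, NA if unpaired), `dotbracket`, `n_pairs`
#' @export
fold_bin <- function(seq) {
  seq <- chartr("T", "U", toupper(seq))
  codes <- encode_rna(seq)
  pr <- .nussinov_fold(codes)
  pairing <- ifelse(pr < 0, NA_integer_, pr + 1L)
  db <- rep(".", length(codes))
  db[!is.na(pairing) & pairing > seq_along(pairing)] <- "("
  db[!is.na(pairing) & pairing < seq_along(pairing)] <- ")"
  structure(
    list(seq = seq, pairing = pairing, dotbracket = paste(db, collapse = ""),
         n_pairs = sum(!is.na(pairing)) / 2),
    class = "folded_bin"
  )
}

## structure codes for the alignment kernel: 0 unpaired, 1 '(', 2 ')'
struct_codes <- function(folded) {
  db <- strsplit(folded$dotbracket, "")[[1]]
  ifelse(db == "(", 1L, ifelse(db == ")", 2L, 0L))
}

#' Default scoring for structure-aware alignment
#'
#' Nucleotide match +2 / mismatch -3; structure bonus +1 when both columns
#' are paired in the same orientation (both opening or both closing), -3
#' when the structures disagree (one paired and one unpaired, or opposite
#' orientations); affine gaps (open -4, extend -1).  Base-pair-maximizing
#' folds leave most positions paired, with orientation correlated along the
#' sequence, so mismatch penalties must outweigh the agreement bonus or
#' random local alignments drift long and dilute seed conservation; these
#' defaults give random 100-nt bin pairs a negative per-column drift while
#' conserved stem-loops still align end to end.
#'
#' @param match_nt,mismatch_nt,struct_bonus,struct_mismatch,gap_open,gap_extend
#'   scoring constants
#' @param min_score minimum reported local-alignment score
#' @param max_alignments cap on non-overlapping local maxima per pair
#' @export
struct_align_params <- function(match_nt = 2, mismatch_nt = -3,
                                struct_bonus = 1, struct_mismatch = -3,
                                gap_open = -4, gap_extend = -1,
                                min_score = 12, max_alignments = 5) {
  list(match_nt = match_nt, mismatch_nt = mismatch_nt,
       struct_bonus = struct_bonus, struct_mismatch = struct_mismatch,
       gap_open = gap_open, gap_extend = gap_extend, min_score = min_score,
       max_alignments = max_alignments)
}

#' Structure-aware local alignment of two folded bins
#'
#' Smith-Waterman local alignment over sequences annotated with their fold:
#' columns are rewarded for matching bases and for agreeing pairing
#' orientation, so conserved stem-loops align even with arm substitutions.
#' All non-overlapping local maxima above `params$min_score` are returned
#' (greedy by score).
#'
#' @param a,b `folded_bin` objects
#' @param params from [struct_align_params()]
#' @return list of alignments: `score`, `a_pos` / `b_pos` (0-based, -1 =
#'   gap), `length` (columns), `a_span` / `b_span` (0-based half-open
#'   within the bin)
#' @export
struct_align <- function(a, b, params = struct_align_params()) {
  res <- .sw_struct_align(encode_rna(a$seq), struct_codes(a),
                          encode_rna(b$seq), struct_codes(b),
                          params$match_nt, params$mismatch_nt,
                          params$struct_bonus, params$struct_mismatch,
                          params$gap_open, params$gap_extend,
                          params$min_score, params$max_alignments)
  lapply(res, function(al) {
    ap <- al$a_pos[al$a_pos >= 0]; bp <- al$b_pos[al$b_pos >= 0]
    list(score = al$score, a_pos = al$a_pos, b_pos = al$b_pos,
         length = length(al$a_pos),
         a_span = c(min(ap), max(ap) + 1L), b_span = c(min(bp), max(bp) + 1L))
  })
}

#' All pairwise structure alignments over a bin set
#'
#' Folds each bin once, aligns every pair, and tabulates the local
#' alignments with bin-set coordinates, ready for seed selection.
#'
#' @param bins data.frame (gene, start, end, seq) — one bin per transcript
#' @param params from [struct_align_params()]
#' @return data.frame (a_gene, b_gene, score, length, a_start, a_end,
#'   b_start, b_end) with global UTR coordinates (0-based half-open)
#' @export
pairwise_struct_alignments <- function(bins, params = struct_align_params()) {
  folded <- lapply(bins$seq, fold_bin)
  codes <- lapply(folded, function(f) encode_rna(f$seq))
  strs <- lapply(folded, struct_codes)
  flat <- .sw_struct_align_all(codes, strs, params$match_nt,
                               params$mismatch_nt, params$struct_bonus,
                               params$struct_mismatch, params$gap_open,
                               params$gap_extend, params$min_score,
                               params$max_alignments)
  if (nrow(flat) == 0) {
    return(data.frame(a_gene = character(), b_gene = character(),
                      score = numeric(), length = integer(),
                      a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer()))
  }
  data.frame(
    a_gene = bins$gene[flat$i], b_gene = bins$gene[flat$j],
    score = flat$score, length = flat$length,
    a_start = bins$start[flat$i] + flat$a_start,
    a_end = bins$start[flat$i] + flat$a_end,
    b_start = bins$start[flat$j] + flat$b_start,
    b_end = bins$start[flat$j] + flat$b_end,
    stringsAsFactors = FALSE)
}

#' Select motif seeds from pairwise alignments
#'
#' Three filters: (i) alignment length >= `min_len` columns; (ii) mean
#' conservation strictly above `min_cons` for BOTH aligned regions; (iii)
#' within each exact-length stratum, the top `ceil(top_frac * stratum
#' size)` alignments by score.
#'
#' @param alignments data.frame from [pairwise_struct_alignments()]
#' @param conservation named list of per-base tracks in `[0, 1]`
#' @param min_len minimum aligned length (default 15)
#' @param min_cons conservation threshold (default 0.7, strict)
#' @param top_frac per-length-stratum score fraction kept (default 0.002)
#' @return the selected rows, with `cons_a`, `cons_b` columns added
#' @export
select_seeds <- function(alignments, conservation, min_len = 15,
                         min_cons = 0.7, top_frac = 0.002) {
  if (nrow(alignments) == 0) return(alignments)
  mean_cons <- function(g, s, e) {
    tr <- conservation[[g]]
    if (is.null(tr)) return(NA_real_)
    mean(tr[(s + 1):e])
  }
  alignments$cons_a <- mapply(mean_cons, alignments$a_gene,
                              alignments$a_start, alignments$a_end)
  alignments$cons_b <- mapply(mean_cons, alignments$b_gene,
                              alignments$b_start, alignments$b_end)
  miss <- is.na(alignments$cons_a) | is.na(alignments$cons_b)
  if (any(miss)) {
    warning(sum(miss), " alignment(s) without conservation track excluded")
    alignments <- alignments[!miss, ]
  }
  keep <- alignments$length >= min_len &
    alignments$cons_a > min_cons & alignments$cons_b > min_cons
  al <- alignments[keep, ]
  if (nrow(al) == 0) return(al)
  sel <- unlist(lapply(split(seq_len(nrow(al)), al$length), function(ii) {
    n_keep <- ceiling(top_frac * length(ii))
    ii[order(-al$score[ii])[seq_len(n_keep)]]
  }))
  out <- al[sort(sel), ]
  rownames(out) <- NULL
  out
}

## clip a window [start, start + w) into [0, L); returns c(start, end)
clip_window <- function(start, w, L) {
  start <- max(0L, min(start, L - w))
  c(start, start + w)
}

#' Build a structure profile from gapless member windows
#'
#' The profile is a column model with consensus pairing: per-column base
#' frequencies (pseudocount `pc * background`), plus joint 16-way pair
#' frequencies on the consensus-paired columns.  Consensus pairing = column
#' pairs paired (in that orientation) in more than half of the members'
#' individual folds, made mutually consistent greedily (by frequency) under
#' nestedness.
#'
#' @param members data.frame (gene, start, seq) of equal-length windows
#' @param background named ACGU frequency vector
#' @param pseudocount total pseudocount (default 0.8)
#' @return list of class `structure_profile`: `width`, `col_freq` (4 x W),
#'   `pair_cols` (2-column matrix), `pair_freq` (pairs x 16),
#'   `consensus_db`, `members`, `background`
#' @export
build_profile <- function(members, background = NULL, pseudocount = 0.8) {
  if (nrow(members) < 2) stop("need >= 2 members")
  W <- unique(nchar(members$seq))
  if (length(W) != 1) stop("member windows must have equal length")
  if (is.null(background)) background <- background_freq(members$seq)
  q <- background[RNA_BASES]

  mat <- do.call(rbind, lapply(members$seq, function(s) encode_rna(s)))
  counts <- apply(mat, 2, function(col) tabulate(col + 1L, 4))
  col_freq <- sweep(counts + pseudocount * q, 2,
                    colSums(counts) + pseudocount, "/")
  rownames(col_freq) <- RNA_BASES

  ## consensus pairing from per-member folds
  pair_count <- new.env(hash = TRUE)
  for (s in members$seq) {
    f <- fold_bin(s)
    op <- which(!is.na(f$pairing) & f$pairing > seq_along(f$pairing))
    for (i in op) {
      key <- paste(i, f$pairing[i])
      pair_count[[key]] <- (if (is.null(pair_count[[key]])) 0 else pair_count[[key]]) + 1
    }
  }
  keys <- ls(pair_count)
  freq <- vapply(keys, function(k) pair_count[[k]], 1) / nrow(members)
  cand <- keys[freq > 0.5]
  cand <- cand[order(-freq[freq > 0.5],
                     vapply(strsplit(cand, " "), function(x) as.integer(x[1]), 1L))]
  chosen <- matrix(integer(0), 0, 2)
  used <- logical(W)
  for (k in cand) {
    ij <- as.integer(strsplit(k, " ")[[1]])
    if (used[ij[1]] || used[ij[2]]) next
    ## nested inside, enclosing, or disjoint with every chosen pair
    nested <- apply(chosen, 1, function(p)
      (ij[1] > p[1] && ij[2] < p[2]) || (ij[1] < p[1] && ij[2] > p[2]) ||
        ij[2] < p[1] || ij[1] > p[2])
    if (nrow(chosen) > 0 && !all(nested)) next
    chosen <- rbind(chosen, ij)
    used[ij] <- TRUE
  }
  pair_cols <- chosen[order(chosen[, 1]), , drop = FALSE]

  npair <- nrow(pair_cols)
  pair_freq <- matrix(0, npair, 16)
  if (npair > 0) {
    qq <- as.vector(outer(q, q))  # symmetric: q_i * q_j for code i*4+j
    for (p in seq_len(npair)) {
      code <- mat[, pair_cols[p, 1]] * 4L + mat[, pair_cols[p, 2]]
      cnt <- tabulate(code + 1L, 16)
      pair_freq[p, ] <- (cnt + pseudocount * qq) / (sum(cnt) + pseudocount)
    }
  }
  db <- rep(".", W)
  if (npair > 0) {
    db[pair_cols[, 1]] <- "("
    db[pair_cols[, 2]] <- ")"
  }
  structure(
    list(width = W, col_freq = col_freq, pair_cols = pair_cols,
         pair_freq = pair_freq, consensus_db = paste(db, collapse = ""),
         members = members, background = q),
    class = "structure_profile"
  )
}

#' @export
print.structure_profile <- function(x, ...) {
  cat(sprintf("structure profile: width %d, %d consensus pairs, %d members\n%s\n",
              x$width, nrow(x$pair_cols), nrow(x$members), x$consensus_db))
  invisible(x)
}

## log-odds components for the scan kernel
profile_lod <- function(profile) {
  q <- profile$background
  paired <- unique(as.vector(profile$pair_cols))
  unpaired <- setdiff(seq_len(profile$width), paired)
  W <- log2(t(profile$col_freq[, unpaired, drop = FALSE]) /
              matrix(q, length(unpaired), 4, byrow = TRUE))
  qq <- as.vector(t(outer(q, q)))
  P <- if (nrow(profile$pair_cols) > 0) {
    log2(sweep(profile$pair_freq, 2, qq, "/"))
  } else matrix(0, 0, 16)
  list(unpaired = unpaired, W = W, pair_cols = profile$pair_cols, P = P)
}

#' Order-1 (dinucleotide-preserving) sequence shuffle
#'
#' Resamples a sequence from its own first-order Markov transition
#' frequencies (same start base), preserving dinucleotide composition in
#' expectation — the decoy model for E-value calibration.
#'
#' @param seq RNA string
#' @return shuffled string of the same length
#' @export
shuffle_dinucleotide <- function(seq) {
  x <- encode_rna(seq) + 1L
  n <- length(x)
  if (n < 3) return(seq)
  tb <- table(factor(x[-n], levels = 1:4), factor(x[-1], levels = 1:4))
  trans <- (unclass(tb) + 0.25) / (rowSums(tb) + 1)
  out <- integer(n)
  out[1] <- x[1]
  for (i in 2:n) out[i] <- sample.int(4, 1, prob = trans[out[i - 1], ])
  decode_rna(out - 1L)
}

#' Search sequences with a structure profile
#'
#' Gapless log-odds scan at every offset (unpaired columns score
#' `log2(p_b/q_b)`; consensus-paired columns score the joint
#' `log2(p_pair/(q_b q_b'))`).  The bit score of a candidate region is its
#' best-offset score; the E-value is `N_eff` (number of scanned windows)
#' times the empirical tail probability of that score among windows of
#' `n_decoys` dinucleotide-shuffled decoy sequences.  Hits are
#' non-overlapping windows with `E <= max_evalue` (greedy by score within a
#' gene).
#'
#' @param profile a [build_profile()] result
#' @param seqs named character vector of target sequences
#' @param max_evalue E-value cutoff (default 1)
#' @param n_decoys decoy sequences for the null (default 200)
#' @param seed RNG seed for the decoys
#' @return data.frame (gene, start, end, score, evalue), 0-based half-open
#' @export
search_profile <- function(profile, seqs, max_evalue = 1, n_decoys = 200,
                           seed = 1L) {
  lod <- profile_lod(profile)
  scan1 <- function(s) {
    .profile_scan(encode_rna(s), profile$width,
                  lod$unpaired - 1L, lod$W,
                  lod$pair_cols[, 1] - 1L, lod$pair_cols[, 2] - 1L, lod$P)
  }
  scores <- lapply(seqs, scan1)
  n_eff <- sum(vapply(scores, length, 1L))
  if (n_eff == 0) {
    return(data.frame(gene = character(), start = integer(), end = integer(),
                      score = numeric(), evalue = numeric()))
  }
  ## decoy null: shuffle sequences round-robin from the target pool
  pool <- rep(seq_along(seqs), length.out = n_decoys)
  decoy_scores <- with_substream(seed, 777L, unlist(lapply(pool, function(i)
    scan1(shuffle_dinucleotide(seqs[[i]])))))
  nd <- length(decoy_scores)
  sorted_decoy <- sort(decoy_scores)
  ## empirical tail within the decoy support; exponential tail fitted to the
  ## top 5% of decoy scores extrapolates beyond it (the usual EVD-style
  ## calibration for profile searches)
  u <- stats::quantile(sorted_decoy, 0.95, names = FALSE)
  exceed <- sorted_decoy[sorted_decoy > u] - u
  lambda <- if (length(exceed) > 1 && mean(exceed) > 0) 1 / mean(exceed) else Inf
  p_u <- (sum(sorted_decoy > u) + 1) / (nd + 1)
  tail_prob <- function(s) {
    emp <- (nd - findInterval(s - 1e-9, sorted_decoy) + 1) / (nd + 1)
    ifelse(s <= u | !is.finite(lambda), emp,
           pmin(emp, p_u * exp(-lambda * (s - u))))
  }
  rows <- lapply(names(seqs), function(g) {
    sc <- scores[[g]]
    if (length(sc) == 0) return(NULL)
    ev <- n_eff * tail_prob(sc)
    cand <- which(ev <= max_evalue)
    if (length(cand) == 0) return(NULL)
    cand <- cand[order(-sc[cand])]
    taken <- integer(0)
    keep <- integer(0)
    for (o in cand) {
      if (any(abs(o - taken) < profile$width)) next
      taken <- c(taken, o)
      keep <- c(keep, o)
    }
    data.frame(gene = g, start = keep - 1L, end = keep - 1L + profile$width,
               score = sc[keep], evalue = ev[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), start = integer(), end = integer(),
                      score = numeric(), evalue = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Iterate a structure motif to a fixed point
#'
#' The build-search-align cycle: search the cluster's sequences with the
#' current profile, convert hits to gapless member windows at their best
#' offsets, union them with the existing members (members are never
#' dropped, so the member set grows monotonically and the loop must
#' terminate), rebuild the profile, and stop when no novel member appears
#' or `max_iter` is reached (then flagged).
#'
#' @param profile the seed profile
#' @param seqs named character vector (the cluster's UTRs)
#' @param max_iter iteration cap (default 20)
#' @param max_evalue,n_decoys,seed passed to [search_profile()]
#' @return list: `profile`, `hits` (final search), `iterations`,
#'   `converged`
#' @export
iterate_motif <- function(profile, seqs, max_iter = 20, max_evalue = 1,
                          n_decoys = 200, seed = 1L) {
  if (max_iter == 0) {
    return(list(profile = profile, hits = NULL, iterations = 0L,
                converged = FALSE))
  }
  member_key <- function(m) paste(m$gene, m$start)
  members <- profile$members
  hits <- NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    hits <- search_profile(profile, seqs, max_evalue, n_decoys,
                           seed = seed + it)
    new_members <- if (nrow(hits) > 0) {
      data.frame(gene = hits$gene, start = hits$start,
                 seq = substring(seqs[hits$gene], hits$start + 1, hits$end),
                 stringsAsFactors = FALSE)
    } else members[0, ]
    all_members <- rbind(members, new_members)
    all_members <- all_members[!duplicated(member_key(all_members)), ]
    if (setequal(member_key(all_members), member_key(members))) {
      converged <- TRUE
      break
    }
    members <- all_members
    profile <- build_profile(members, background = profile$background)
  }
  list(profile = profile, hits = hits, iterations = it, converged = converged)
}

#' Filter and report structure motifs by cluster over-representation
#'
#' For each motif, genes with at least one hit are counted in the cluster
#' (k) and in the universe (K); the upper-tail hypergeometric p is
#' BH-corrected across motifs.  Reported motifs must pass `q < q_max` and
#' carry at least `min_hits` member genes in the cluster.
#'
#' @param motifs list of [iterate_motif()] results (each with a profile)
#' @param cluster_genes gene ids of the cluster
#' @param universe_seqs named character vector of ALL universe UTRs
#' @param q_max FDR gate (default 1e-4)
#' @param min_hits minimum cluster instances (default 10)
#' @param max_evalue,n_decoys,seed passed to [search_profile()]
#' @return data.frame (motif, k, n, K, N, p, q, reported) sorted by q
#' @export
report_motifs <- function(motifs, cluster_genes, universe_seqs, q_max = 1e-4,
                          min_hits = 10, max_evalue = 1, n_decoys = 200,
                          seed = 1L) {
  N <- length(universe_seqs)
  n <- length(cluster_genes)
  rows <- lapply(seq_along(motifs), function(i) {
    hits <- search_profile(motifs[[i]]$profile, universe_seqs, max_evalue,
                           n_decoys, seed = seed + 31L * i)
    hg <- unique(hits$gene)
    k <- length(intersect(hg, cluster_genes))
    K <- length(hg)
    data.frame(motif = i, k = k, n = n, K = K, N = N,
               p = if (K == 0) 1 else hypergeom_upper(k, n, K, N))
  })
  tab <- do.call(rbind, rows)
  tab$q <- bh_adjust(tab$p)
  tab$reported <- tab$q < q_max & tab$k >= min_hits
  tab[order(tab$q, tab$p), ]
}

#' Write a structure profile as a Stockholm alignment
#'
#' Members as gapless rows with a `#=GC SS_cons` consensus-structure line.
#'
#' @param profile a [build_profile()] result
#' @param path output path
#' @export
write_stockholm <- function(profile, path) {
  m <- profile$members
  nm <- sprintf("%s/%d-%d", m$gene, m$start, m$start + profile$width)
  pad <- max(nchar(nm), nchar("#=GC SS_cons"))
  lines <- c("# STOCKHOLM 1.0",
             sprintf(paste0("%-", pad, "s %s"), nm, m$seq),
             sprintf(paste0("%-", pad, "s %s"), "#=GC SS_cons",
                     chartr("()", "<>", profile$consensus_db)),
             "//")
  writeLines(lines, path)
  invisible(NULL)
}
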