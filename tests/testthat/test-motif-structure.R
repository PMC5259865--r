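# a 20-nt stem-loop: 8-bp stem, 4-nt loop
SL_ARM5 <- "GGCAGCAG"
SL_LOOP <- "AAUC"
SL_ARM3 <- "CUGCUGCC"
SL20 <- paste0(SL_ARM5, SL_LOOP, SL_ARM3)

test_that("folding matches hand-checked structures", {
  f <- fold_bin("GGGAAACCC")
  expect_equal(f$dotbracket, "(((...)))")
  expect_equal(f$n_pairs, 3)
  expect_equal(fold_bin("AAAA")$n_pairs, 0)
  expect_equal(fold_bin("GAAAC")$dotbracket, "(...)")
  ## pairing is an involution
  p <- fold_bin(SL20)$pairing
  ok <- !is.na(p)
  expect_equal(p[p[ok]], which(ok))
})

test_that("folding attains the brute-force maximal pair count", {
  set.seed(12)
  for (i in seq_len(200)) {
    len <- sample(5:12, 1)
    s <- random_rna(len)
    expect_equal(fold_bin(s)$n_pairs, max_pairs_bf(s), info = s)
  }
})

test_that("folds obey hairpin and pair-legality constraints", {
  set.seed(13)
  legal <- c("AU", "UA", "GC", "CG", "GU", "UG")
  for (i in seq_len(50)) {
    s <- random_rna(60)
    f <- fold_bin(s)
    p <- f$pairing
    for (k in which(!is.na(p) & p > seq_along(p))) {
      expect_gte(p[k] - k, 4)  # >= 3 unpaired between partners
      b <- strsplit(f$seq, "")[[1]]
      expect_true(paste0(b[k], b[p[k]]) %in% legal)
    }
  }
})

test_that("self-alignment scores match + bonus on every column", {
  set.seed(14)
  s <- random_rna(60)
  f <- fold_bin(s)
  al <- struct_align(f, f)
  expect_gt(length(al), 0)
  ## every column: nt match (+2), plus the structure bonus (+1) on the
  ## paired columns: score = 2L + (L - unpaired)
  n_unpaired <- sum(is.na(f$pairing))
  expect_equal(al[[1]]$score, 3 * 60 - n_unpaired)
  expect_equal(al[[1]]$length, 60)
})

test_that("alignment score is symmetric in its arguments", {
  set.seed(15)
  a <- fold_bin(random_rna(50))
  b <- fold_bin(random_rna(50))
  sa <- struct_align(a, b)
  sb <- struct_align(b, a)
  if (length(sa) > 0 || length(sb) > 0) {
    expect_equal(sa[[1]]$score, sb[[1]]$score)
  }
  succeed()
})

test_that("a shared planted stem-loop is found by local alignment", {
  set.seed(16)
  hits <- vapply(seq_len(50), function(i) {
    a <- random_rna(80); b <- random_rna(80)
    oa <- sample(60, 1); ob <- sample(60, 1)
    substr(a, oa, oa + 19) <- SL20
    substr(b, ob, ob + 19) <- SL20
    al <- struct_align(fold_bin(a), fold_bin(b))
    if (length(al) == 0) return(FALSE)
    top <- al[[1]]
    cov_a <- sum(top$a_pos >= oa - 1 & top$a_pos <= oa + 18)
    cov_b <- sum(top$b_pos >= ob - 1 & top$b_pos <= ob + 18)
    cov_a >= 14 && cov_b >= 14
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("alphabet-disjoint unpaired sequences never align", {
  a <- fold_bin(strrep("A", 40))
  b <- fold_bin(strrep("C", 40))
  expect_length(struct_align(a, b), 0)
})

test_that("seed selection applies length, conservation and stratum filters", {
  set.seed(17)
  ## 1000 alignments of length 20 passing (i) and (ii): exactly 2 kept
  aln <- data.frame(
    a_gene = "a", b_gene = "b", score = rnorm(1000), length = 20L,
    a_start = 0L, a_end = 20L, b_start = 0L, b_end = 20L,
    stringsAsFactors = FALSE)
  cons <- list(a = rep(0.9, 100), b = rep(0.9, 100))
  sel <- select_seeds(aln, cons)
  expect_equal(nrow(sel), 2)
  expect_equal(sort(sel$score, decreasing = TRUE),
               sort(aln$score, decreasing = TRUE)[1:2])
  ## length 14 excluded regardless of score
  short <- aln[1, ]; short$length <- 14L; short$score <- 1e9
  expect_equal(nrow(select_seeds(short, cons)), 0)
  ## conservation exactly 0.7 is excluded (strict >)
  cons07 <- list(a = rep(0.7, 100), b = rep(0.9, 100))
  expect_equal(nrow(select_seeds(aln[1, ], cons07)), 0)
  ## missing track -> excluded with warning
  expect_warning(sel2 <- select_seeds(aln[1:3, ], list(a = rep(0.9, 100))),
                 "without conservation")
  expect_equal(nrow(sel2), 0)
})

test_that("profiles from identical stem-loops recover the common fold", {
  members <- data.frame(gene = sprintf("m%d", 1:10), start = 0L, seq = SL20,
                        stringsAsFactors = FALSE)
  prof <- build_profile(members, background = setNames(rep(0.25, 4),
                                                       c("A", "C", "G", "U")))
  expect_equal(prof$width, 20)
  f <- fold_bin(SL20)
  expect_equal(prof$consensus_db, f$dotbracket)
  ## column frequencies concentrate on the member base (up to pseudocount)
  bases <- strsplit(SL20, "")[[1]]
  for (j in c(1, 5, 10, 20)) {
    expect_gt(prof$col_freq[bases[j], j], 0.9)
  }
  expect_equal(unname(colSums(prof$col_freq)), rep(1, 20), tolerance = 1e-9)
})

test_that("a disagreeing unpaired column splits its frequencies", {
  s2 <- SL20
  substr(s2, 10, 10) <- "G"  # loop position, unpaired
  members <- data.frame(gene = c("a", "b"), start = 0L, seq = c(SL20, s2),
                        stringsAsFactors = FALSE)
  prof <- build_profile(members)
  expect_lt(abs(prof$col_freq["G", 10] - 0.5), 0.15)
  expect_error(build_profile(members[1, , drop = FALSE]), ">= 2")
  expect_error(build_profile(data.frame(gene = c("a", "b"), start = 0L,
                                        seq = c("ACGU", "ACG"))),
               "equal length")
})

test_that("an exact planted instance is the top-scoring window", {
  set.seed(18)
  members <- data.frame(gene = c("a", "b"), start = 0L, seq = SL20,
                        stringsAsFactors = FALSE)
  prof <- build_profile(members)
  target <- random_rna(100)
  substr(target, 41, 60) <- SL20
  lodscan <- search_profile(prof, c(t1 = target), max_evalue = 1e9,
                            n_decoys = 50, seed = 2)
  expect_equal(lodscan$start[which.max(lodscan$score)], 40)
})

test_that("E-values are calibrated on shuffled sequences", {
  set.seed(19)
  members <- data.frame(gene = c("a", "b"), start = 0L, seq = SL20,
                        stringsAsFactors = FALSE)
  prof <- build_profile(members)
  n_hits <- vapply(seq_len(20), function(i) {
    seqs <- setNames(vapply(1:30, function(j) random_rna(120), ""),
                     sprintf("s%02d", 1:30))
    nrow(search_profile(prof, seqs, max_evalue = 1, n_decoys = 100,
                        seed = 100 + i))
  }, 1)
  ## about one expected hit per scan at E <= 1 (Poisson noise band)
  expect_gt(mean(n_hits), 0.2)
  expect_lt(mean(n_hits), 3)
})

test_that("motif iteration reaches a fixed point and recovers carriers", {
  set.seed(20)
  n <- 60
  seqs <- setNames(vapply(seq_len(n), function(i) random_rna(80), ""),
                   sprintf("g%03d", seq_len(n)))
  carriers <- sprintf("g%03d", 1:10)
  offs <- setNames(sample(55, 10), carriers)
  for (g in carriers) substr(seqs[[g]], offs[g], offs[g] + 19) <- SL20
  seed_members <- data.frame(gene = carriers[1:2],
                             start = offs[carriers[1:2]] - 1L, seq = SL20,
                             stringsAsFactors = FALSE)
  prof <- build_profile(seed_members, background = background_freq(seqs))
  res <- iterate_motif(prof, seqs, n_decoys = 100, seed = 5)
  expect_true(res$converged)
  expect_lte(res$iterations, 5)
  expect_true(all(carriers %in% res$profile$members$gene))
})

test_that("a seed matching nothing converges to itself", {
  set.seed(21)
  seqs <- setNames(c(strrep("A", 60), strrep("AC", 30)), c("x", "y"))
  members <- data.frame(gene = c("m1", "m2"), start = 0L, seq = SL20,
                        stringsAsFactors = FALSE)
  prof <- build_profile(members)
  res <- iterate_motif(prof, seqs, n_decoys = 40, seed = 9)
  expect_true(res$converged)
  expect_equal(nrow(res$profile$members), 2)
  ## max_iter = 0 returns the seed unchanged, flagged unconverged
  res0 <- iterate_motif(prof, seqs, max_iter = 0)
  expect_false(res0$converged)
  expect_equal(res0$iterations, 0L)
  expect_identical(res0$profile, prof)
})

test_that("reporting enforces both the q and the instance-count gates", {
  set.seed(22)
  universe <- setNames(vapply(seq_len(300), function(i) random_rna(70), ""),
                       sprintf("u%03d", seq_len(300)))
  cluster_genes <- names(universe)[1:60]
  ## motif planted in 15 cluster genes and 5 background genes
  for (g in names(universe)[c(1:15, 290:294)]) {
    substr(universe[[g]], 20, 39) <- SL20
  }
  members <- data.frame(gene = c("a", "b"), start = 0L, seq = SL20,
                        stringsAsFactors = FALSE)
  prof <- build_profile(members, background = background_freq(universe))
  rep1 <- report_motifs(list(list(profile = prof)), cluster_genes, universe,
                        n_decoys = 100, seed = 31)
  expect_gte(rep1$k[1], 10)
  expect_true(rep1$reported[1])
  ## fewer than 10 cluster instances -> excluded regardless of q
  cluster_small <- names(universe)[c(1:9, 100:150)]
  rep2 <- report_motifs(list(list(profile = prof)), cluster_small, universe,
                        n_decoys = 100, seed = 32)
  expect_false(rep2$reported[1])
})

test_that("stockholm output carries the consensus structure line", {
  members <- data.frame(gene = c("a", "b"), start = 0L, seq = SL20,
                        stringsAsFactors = FALSE)
  prof <- build_profile(members)
  f <- tempfile(fileext = ".sto")
  write_stockholm(prof, f)
  lines <- readLines(f)
  expect_equal(lines[1], "# STOCKHOLM 1.0")
  expect_true(any(grepl("^#=GC SS_cons", lines)))
  expect_equal(lines[length(lines)], "//")
})
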