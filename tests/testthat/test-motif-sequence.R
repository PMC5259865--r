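test_that("UTR binning follows the 100/50 overlap rule", {
  b250 <- bin_utrs(c(g = strrep("A", 250)))
  expect_equal(b250$start, c(0, 50, 100, 150))
  expect_equal(b250$end, c(100, 150, 200, 250))
  b80 <- bin_utrs(c(g = strrep("A", 80)))
  expect_equal(b80$start, 0); expect_equal(b80$end, 80)
  b130 <- bin_utrs(c(g = strrep("A", 130)))
  expect_equal(b130$start, c(0, 30))
  expect_equal(b130$end, c(100, 130))
  expect_warning(bin_utrs(c(g = "ACGU", h = "")), "empty")
})

test_that("binning preserves sequence content", {
  set.seed(2)
  s <- random_rna(230)
  b <- bin_utrs(setNames(s, "g"))
  ## non-overlapping halves reconstruct the UTR
  for (i in seq_len(nrow(b))) {
    expect_equal(b$seq[i], substr(s, b$start[i] + 1, b$end[i]))
  }
})

test_that("bin sets hold one uniformly sampled bin per transcript", {
  seqs <- setNames(rep(strrep("ACGU", 50), 10), sprintf("g%02d", 1:10))  # 200 nt -> 4 bins
  bins <- bin_utrs(seqs)
  sets <- sample_bin_sets(bins, 700, seed = 4)
  expect_length(sets, 700)
  expect_true(all(vapply(sets, nrow, 1L) == 10))
  ## per-transcript bin frequencies uniform within 3 sigma binomial bounds
  starts <- vapply(sets, function(s) s$start[s$gene == "g01"], numeric(1))
  tab <- table(factor(starts, levels = c(0, 50, 100)))
  expect_true(all(abs(tab - 700 / 3) < 3 * sqrt(700 * (1 / 3) * (2 / 3))))
  expect_equal(sample_bin_sets(bins, 0, seed = 1), list())
  ## single-bin transcripts give identical sets
  one <- bin_utrs(c(a = strrep("ACGU", 10)))
  s2 <- sample_bin_sets(one, 3, seed = 1)
  expect_equal(s2[[1]], s2[[2]])
})

test_that("a planted heptamer is recovered by enumeration", {
  set.seed(17)
  n <- 100
  seqs <- vapply(seq_len(n), function(i) random_rna(100), "")
  carriers <- sample(n, 40)
  for (i in carriers) {
    off <- sample(94, 1)
    substr(seqs[i], off, off + 6) <- "UAUUUAU"
  }
  mot <- find_motifs(seqs, k = 7, max_mismatch = 1, top_m = 3)
  cons <- strsplit(mot[[1]]$consensus, "")[[1]]
  plant <- strsplit("UAUUUAU", "")[[1]]
  expect_gte(sum(cons == plant), 6)
})

test_that("homopolymer input yields the homopolymer motif", {
  seqs <- rep(strrep("A", 40), 10)
  mot <- find_motifs(seqs, k = 6, max_mismatch = 1, top_m = 1)
  expect_equal(mot[[1]]$consensus, "AAAAAA")
})

test_that("null sequences score below planted sequences", {
  set.seed(23)
  top_null <- vapply(seq_len(50), function(i) {
    seqs <- vapply(seq_len(60), function(j) random_rna(60), "")
    find_motifs(seqs, k = 6, top_m = 1)[[1]]$score
  }, 1)
  seqs <- vapply(seq_len(60), function(j) random_rna(60), "")
  for (i in seq_len(24)) {
    off <- sample(54, 1)
    substr(seqs[i], off, off + 5) <- "UAUUUA"
  }
  planted_score <- find_motifs(seqs, k = 6, top_m = 1)[[1]]$score
  expect_gte(mean(top_null < planted_score), 0.95)
})

test_that("kept motifs are never within Hamming distance 1 of each other", {
  set.seed(3)
  seqs <- vapply(seq_len(50), function(j) random_rna(80), "")
  mot <- find_motifs(seqs, k = 6, top_m = 5)
  cons <- vapply(mot, `[[`, "", "consensus")
  for (i in seq_along(cons)) for (j in seq_along(cons)) {
    if (i < j) {
      hd <- sum(strsplit(cons[i], "")[[1]] != strsplit(cons[j], "")[[1]])
      expect_gte(hd, 2)
    }
  }
})

test_that("PWM conversion matches the pseudocount arithmetic", {
  pfm <- matrix(c(8, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "U"), NULL))
  pwm <- pfm_to_pwm(pfm, pseudocount = 0.8)
  ## p_A = (8 + 0.8 * 0.25) / 8.8 = 8.2 / 8.8
  expect_equal(unname(unclass(pwm)["A", 1]), log2((8.2 / 8.8) / 0.25),
               tolerance = 1e-9)
  expect_equal(round(unname(unclass(pwm)["A", 1]), 3), 1.898)
  expect_equal(round(unname(unclass(pwm)["C", 1]), 3), -3.459)
  ## counts proportional to background -> weights shrink to 0 with n
  pfm2 <- matrix(2500, 4, 1, dimnames = list(c("A", "C", "G", "U"), NULL))
  expect_lt(max(abs(pfm_to_pwm(pfm2))), 1e-4)
  expect_error(pfm_to_pwm(pfm * 0), "zero-site")
})

test_that("width-2 scan p-values equal brute-force enumeration", {
  pfm <- matrix(c(6, 1, 2, 1,  1, 7, 1, 1), 4, 2,
                dimnames = list(c("A", "C", "G", "U"), NULL))
  pwm <- pfm_to_pwm(pfm)
  dinucs <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                            paste0))
  hits <- scan_pwm(pwm, setNames(dinucs, dinucs), alpha = 1.01)
  all_pos <- attr(hits, "all_positions")
  w <- unclass(pwm)
  score_bf <- function(d) {
    b <- strsplit(d, "")[[1]]
    w[b[1], 1] + w[b[2], 2]
  }
  for (d in dinucs) {
    sc <- score_bf(d)
    ## exact null tail: sum of background probs of dinucleotides scoring >= sc
    p_bf <- sum(vapply(dinucs, function(e)
      ifelse(score_bf(e) >= sc - 1e-9, 0.25 * 0.25, 0), 1))
    expect_equal(all_pos$p[all_pos$gene == d], p_bf, tolerance = 1e-6,
                 info = d)
  }
  ## best possible site has the tail of a single point
  best <- dinucs[which.max(vapply(dinucs, score_bf, 1))]
  expect_equal(all_pos$p[all_pos$gene == best], 0.0625, tolerance = 1e-9)
})

test_that("null scans control the hit rate at q < 0.05", {
  set.seed(8)
  pfm <- matrix(c(20, 1, 1, 1), 4, 6, dimnames = list(c("A", "C", "G", "U"), NULL))
  pwm <- pfm_to_pwm(pfm)
  rates <- vapply(seq_len(100), function(i) {
    seqs <- setNames(vapply(1:20, function(j) random_rna(105), ""),
                     sprintf("s%02d", 1:20))
    h <- scan_pwm(pwm, seqs, alpha = 0.05)
    nrow(h) / (20 * 100)
  }, 1)
  expect_lte(mean(rates), 0.05)
})

test_that("scan p-values are uniform under the null", {
  set.seed(9)
  ## a non-degenerate width-7 column model keeps the score atoms small, so
  ## the exact p-values are near-continuous uniform under the null
  pfm <- matrix(c(5, 3, 2, 1,  1, 5, 3, 2,  3, 1, 5, 2,  2, 3, 1, 5,
                  5, 2, 3, 1,  1, 3, 2, 5,  4, 2, 1, 3), 4, 7,
                dimnames = list(c("A", "C", "G", "U"), NULL))
  pwm <- pfm_to_pwm(pfm)
  seqs <- setNames(vapply(1:50, function(j) random_rna(206), ""),
                   sprintf("s%02d", 1:50))
  all_pos <- attr(scan_pwm(pwm, seqs, alpha = 0.05), "all_positions")
  ## 1e4 null positions; KS against uniform
  p <- all_pos$p
  ks <- max(abs(sort(p) - seq_along(p) / length(p)))
  expect_lt(ks, 0.05)
})

test_that("hit-count comparison flags a quick-only motif", {
  quick <- sprintf("q%03d", 1:100)
  stable <- sprintf("s%03d", 1:100)
  hits <- c(quick[1:50], stable[1:5])
  res <- compare_hit_counts(hits, list(quick = quick, stable = stable))
  row <- res[res$set_a == "quick" & res$set_b == "stable", ]
  expect_equal(row$hits_a, 50); expect_equal(row$hits_b, 5)
  expect_lt(row$p_bonferroni, 0.01)
  expect_equal(row$p, hypergeom_upper(50, 100, 55, 200))
  ## all genes hit -> p = 1
  res2 <- compare_hit_counts(c(quick, stable),
                             list(quick = quick, stable = stable))
  expect_equal(res2$p, 1)
  expect_error(compare_hit_counts(hits, list(a = quick, b = quick)),
               "disjoint")
})

test_that("sequences shorter than the motif yield no positions", {
  pfm <- matrix(1, 4, 6, dimnames = list(c("A", "C", "G", "U"), NULL))
  pwm <- pfm_to_pwm(pfm)
  h <- scan_pwm(pwm, c(tiny = "ACG"))
  expect_equal(nrow(h), 0)
})

test_that("MEME minimal output is well formed", {
  seqs <- rep(strrep("ACGU", 25), 5)
  mot <- find_motifs(seqs, k = 6, top_m = 2)
  f <- tempfile(fileext = ".meme")
  write_meme(mot, f)
  lines <- readLines(f)
  expect_equal(lines[1], "MEME version 4")
  expect_equal(sum(grepl("^MOTIF ", lines)), length(mot))
  expect_true(any(grepl("letter-probability matrix", lines)))
})

test_that("motifs recurring across bin sets merge by consensus", {
  set.seed(41)
  n <- 60
  seqs <- setNames(vapply(seq_len(n), function(i) random_rna(200), ""),
                   sprintf("g%03d", seq_len(n)))
  for (i in 1:30) {
    off <- sample(194, 1)
    substr(seqs[[i]], off, off + 5) <- "UAUUUA"
  }
  bins <- bin_utrs(seqs)
  sets <- sample_bin_sets(bins, 10, seed = 6)
  mot <- find_motifs_sets(sets, k = 6, top_m = 3)
  expect_equal(mot[[1]]$consensus, "UAUUUA")
  expect_gte(mot[[1]]$n_sets, 5)
  ## merged PFM columns sum to the merged site count
  expect_equal(unique(colSums(mot[[1]]$pfm)), mot[[1]]$n_sites)
})

test_that("motif_carriers finds exactly the containing genes", {
  seqs <- c(a = "GGGGUAUUUAUGGGG", b = "GGGGGGGGGGGGGGG", c = "CCUAUUUAUCC",
            d = "GGGGUAUUGAUGGGG")  # d: 1 mismatch
  expect_setequal(motif_carriers("UAUUUAU", seqs), c("a", "c"))
  expect_setequal(motif_carriers("UAUUUAU", seqs, max_mismatch = 1),
                  c("a", "c", "d"))
})

test_that("a planted ARE separates quick from stable carriers end to end", {
  runs <- vapply(1:5, function(seed) {
    are <- plant_spec("sequence", consensus = "UAUUUAU", mutation_rate = 0,
                      carrier_fraction = 0.4)
    ids <- c(sprintf("q%03d", 1:60), sprintf("s%03d", 1:60))
    utr <- simulate_utrs(120, plants = list(are),
                         target_genes = list(ids[1:60]), seed = seed,
                         gene_ids = ids)
    bg <- background_freq(utr$seqs)
    sets <- sample_bin_sets(bin_utrs(utr$seqs[1:60]), 15, seed = seed)
    mot <- find_motifs_sets(sets, k = 7, max_mismatch = 1, top_m = 3,
                            background = bg)
    carriers <- motif_carriers(mot[[1]], utr$seqs)
    cmp <- compare_hit_counts(carriers, list(quick = ids[1:60],
                                             stable = ids[-(1:60)]))
    ok_cons <- sum(strsplit(mot[[1]]$consensus, "")[[1]] ==
                     strsplit("UAUUUAU", "")[[1]]) >= 6
    ok_cons && cmp$p_bonferroni[cmp$set_a == "quick"] < 0.01
  }, TRUE)
  expect_gte(mean(runs), 0.8)
})
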