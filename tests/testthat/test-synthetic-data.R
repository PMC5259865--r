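test_that("expected decay levels follow the closed form", {
  cl <- kinetic_class(1, delta = log(2))  # half-life 1 h
  expect_equal(expected_level(cl, c(0, 0.5, 1, 2, 4)),
               c(1, 2^-0.5, 0.5, 0.25, 0.0625), tolerance = 1e-12)
  # 24 h half-life sits exactly at the long-lived boundary at 4 h
  cl24 <- kinetic_class(2, delta = log(2) / 24)
  expect_equal(expected_level(cl24, 4), 2^(-4 / 24), tolerance = 1e-12)
  expect_equal(expected_level(cl24, 4), long_lived_threshold())
  # plateau and delayed forms
  cl2 <- kinetic_class(3, delta = 1, r1 = 0.2, shutoff = "incomplete")
  expect_equal(expected_level(cl2, Inf), 0.2)
  cl3 <- kinetic_class(4, delta = 1, r0 = 1.5, shutoff = "delayed")
  expect_equal(expected_level(cl3, 0), 1.5)
})

test_that("kinetic class invariants are enforced", {
  expect_error(kinetic_class(1, delta = -1), "delta")
  expect_error(kinetic_class(1, delta = 1, r1 = 1.2), "r1")
  expect_error(kinetic_class(1, delta = 1, r1 = 0.3), "complete")
  expect_error(expected_level(kinetic_class(1, delta = 1), -1), "negative")
})

test_that("the default design emits the 8 x 5 sample grid", {
  d <- study_design()
  expect_equal(n_samples(d), 40)
  expect_equal(d$chase_times[1], 0)
  sim <- simulate_counts(d, list(kinetic_class(1, delta = 1)),
                         rep(1L, d$n_genes), noise = FALSE, seed = 1)
  expect_equal(ncol(sim$counts), 40)
  expect_true(all(grepl("^LPS[0-9.]+_ActD[0-9.]+$", colnames(sim$counts))))
  expect_error(study_design(chase_times = c(1, 2)), "start at 0")
})

test_that("RPKM follows tags / (kb * millions)", {
  cnt <- matrix(100, 1, 1, dimnames = list("g", sample_name(0, 0)))
  expect_equal(as.numeric(rpkm_from_counts(cnt, gene_length_kb = 2,
                                           library_sizes = 1e6)), 50)
})

test_that("noiseless simulation reproduces the decay law exactly", {
  d <- study_design(n_genes = 6)
  classes <- list(kinetic_class(1, delta = log(2)),
                  kinetic_class(2, delta = 0.3, r1 = 0.25, shutoff = "incomplete"))
  sim <- simulate_counts(d, classes, rep(c(1L, 2L), 3), noise = FALSE,
                         seed = 7, baseline_tags = 1000)
  for (lp in d$lps_times) {
    blk <- sapply(d$chase_times, function(ch) sim$counts[, sample_name(lp, ch)])
    rel <- blk / blk[, 1]
    expect_equal(rel[1, ], expected_level(classes[[1]], d$chase_times),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(rel[2, ], expected_level(classes[[2]], d$chase_times),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(unique(sim$truth$delta[sim$truth$gene == "gene0001"]), log(2))
})

test_that("noisy count means converge to the noiseless expectation", {
  d <- study_design(lps_times = 0, chase_times = c(0, 2), n_genes = 1)
  cl <- list(kinetic_class(1, delta = 0.5))
  mu <- 400 * expected_level(cl[[1]], 2)
  ## 1e4 replicate genes of the same class = 1e4 independent draws
  d <- study_design(lps_times = 0, chase_times = c(0, 2), n_genes = 1e4)
  sim <- simulate_counts(d, cl, rep(1L, 1e4), dispersion = 0.01, seed = 5,
                         baseline_tags = 400)
  expect_lt(abs(mean(sim$counts[, 2]) - mu) / mu, 0.02)
})

test_that("gene substreams are stable when the gene set grows", {
  d1 <- study_design(n_genes = 3)
  d2 <- study_design(n_genes = 6)
  cl <- list(kinetic_class(1, delta = 1))
  s1 <- simulate_counts(d1, cl, rep(1L, 3), seed = 42, baseline_tags = 300)
  s2 <- simulate_counts(d2, cl, rep(1L, 6), seed = 42, baseline_tags = 300)
  expect_equal(s1$counts[1:3, ], s2$counts[1:3, ])
})

test_that("simulate_counts rejects bad inputs", {
  d <- study_design(n_genes = 2)
  cl <- list(kinetic_class(1, delta = 1))
  expect_error(simulate_counts(d, cl, c(1L, 9L)), "unknown class")
  expect_error(simulate_counts(d, cl, rep(1L, 2), dispersion = -1), ">= 0")
})

test_that("planted motifs appear once per carrier with boosted conservation", {
  spec <- plant_spec("sequence", consensus = "UAUUUAU", mutation_rate = 0,
                     carrier_fraction = 0.4, conservation_boost = 0.6)
  utr <- simulate_utrs(100, plants = list(spec), seed = 3,
                       conservation_baseline = 0.2)
  expect_equal(nrow(utr$plants), 40)  # floor(0.4 * 100)
  expect_equal(anyDuplicated(utr$plants$gene), 0)
  for (i in seq_len(10)) {
    rec <- utr$plants[i, ]
    expect_equal(substr(utr$seqs[[rec$gene]], rec$start + 1, rec$end),
                 "UAUUUAU")
    expect_equal(utr$conservation[[rec$gene]][(rec$start + 1):rec$end],
                 rep(0.8, 7))
  }
  off_plant <- utr$conservation[[utr$plants$gene[1]]][-((utr$plants$start[1] + 1):utr$plants$end[1])]
  expect_true(all(off_plant == 0.2))
})

test_that("mutated plants still match their consensus in expectation", {
  spec <- plant_spec("sequence", consensus = "GGAUACGUAUCCAAAGG",
                     mutation_rate = 0.1, carrier_fraction = 1)
  utr <- simulate_utrs(200, plants = list(spec), seed = 11)
  cons <- strsplit(spec$consensus, "")[[1]]
  match_frac <- vapply(seq_len(nrow(utr$plants)), function(i) {
    mean(strsplit(utr$plants$seq[i], "")[[1]] == cons)
  }, 1)
  n <- length(cons)
  sigma <- sqrt(0.1 * 0.9 / n)
  expect_gte(mean(match_frac), 1 - 0.1 - 3 * sigma / sqrt(200))
})

test_that("planted stem-loops fold into their designed stem", {
  spec <- plant_spec("stemloop", arm5 = "GGCAGC", loop = "AUAUU",
                     arm3 = "GCUGCC", mutation_rate = 0)
  f <- fold_bin(spec$consensus)
  # brute-force oracle agrees on the maximal pair count
  expect_equal(f$n_pairs, max_pairs_bf(spec$consensus))
  # the designed 6-bp stem is part of the fold: arm position i pairs 17-i+1
  for (i in 1:6) expect_equal(f$pairing[i], 17L - i + 1L)
})

test_that("plants longer than their UTR are rejected by name", {
  spec <- plant_spec("sequence", consensus = paste(rep("A", 80), collapse = ""),
                     carrier_fraction = 1)
  expect_error(
    simulate_utrs(3, length_meanlog = log(60), length_sdlog = 0,
                  min_length = 50, plants = list(spec),
                  target_genes = list(c("gene0001")), seed = 1),
    "gene0001")
})
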