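#' Describe one kinetic class of transcripts
#'
#' A kinetic class fixes the parameters of the first-order decay law
#' \eqn{r(t) = r_1 + (r_0 - r_1) e^{-\delta t}} followed, in expectation, by
#' every gene assigned to the class during an actinomycin-D chase.  The
#' `shutoff` mode maps onto the nested decay-model family: `"complete"`
#' (r0 = 1, r1 = 0), `"incomplete"` (residual plateau r1 > 0) and
#' `"delayed"` (free r0, possibly > 1, mimicking the apparent rise of
#' long-persisting signal before decay; r1 = 0).
#'
#' @param class_id integer class label
#' @param delta decay rate per hour (> 0); ignored if `half_life` given
#' @param half_life alternative parameterization, hours (`delta = ln2 / half_life`)
#' @param r0 initial relative level (default 1; > 1 only meaningful for
#'   `"delayed"` shutoff)
#' @param r1 residual plateau in `[0, r0)`
#' @param shutoff one of `"complete"`, `"incomplete"`, `"delayed"`
#' @param long_lived logical; flags a class whose half-life exceeds the 24 h
#'   detection horizon of a 4 h chase
#' @return object of class `kinetic_class`
#' @export
kinetic_class <- function(class_id, delta = NULL, half_life = NULL, r0 = 1,
                          r1 = 0, shutoff = c("complete", "incomplete", "delayed"),
                          long_lived = FALSE) {
  shutoff <- match.arg(shutoff)
  if (is.null(delta)) {
    if (is.null(half_life)) stop("give delta or half_life")
    delta <- log(2) / half_life
  }
  if (delta <= 0) stop("delta must be > 0")
  if (r1 < 0 || r1 >= r0) stop("need 0 <= r1 < r0")
  if (shutoff == "complete" && (r0 != 1 || r1 != 0))
    stop("complete shutoff fixes r0 = 1, r1 = 0")
  if (shutoff == "incomplete" && r0 != 1)
    stop("incomplete shutoff fixes r0 = 1")
  if (shutoff == "delayed" && r1 != 0)
    stop("delayed shutoff fixes r1 = 0")
  structure(
    list(class_id = as.integer(class_id), delta = delta, r0 = r0, r1 = r1,
         shutoff = shutoff, long_lived = isTRUE(long_lived)),
    class = "kinetic_class"
  )
}

#' Expected relative RNA level of a kinetic class at given chase times
#'
#' @param class a [kinetic_class()]
#' @param t chase times, hours
#' @return numeric vector of expected levels relative to the pre-shutoff level
#' @export
expected_level <- function(class, t) {
  stopifnot(inherits(class, "kinetic_class"))
  if (any(t < 0)) stop("negative chase times")
  class$r1 + (class$r0 - class$r1) * exp(-class$delta * t)
}

#' The two-way chase study design
#'
#' Default layout: 8 stimulation time points crossed with a 5-point chase,
#' i.e. 40 samples.
#'
#' @param lps_times stimulation times, hours
#' @param chase_times chase times, hours; first must be 0
#' @param library_size expected mapped tags per sample
#' @param n_genes number of genes to simulate
#' @return object of class `study_design`
#' @export
study_design <- function(lps_times = c(0, 0.5, 1, 2, 3, 4, 6, 8),
                         chase_times = c(0, 0.5, 1, 2, 4),
                         library_size = 2e6, n_genes = 200L) {
  if (chase_times[1] != 0) stop("chase_times must start at 0")
  if (any(chase_times < 0) || any(lps_times < 0)) stop("negative times")
  structure(
    list(lps_times = lps_times, chase_times = chase_times,
         library_size = library_size, n_genes = as.integer(n_genes)),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("chase study design: %d LPS x %d ActD time points = %d samples, %d genes\n",
              length(x$lps_times), length(x$chase_times),
              length(x$lps_times) * length(x$chase_times), x$n_genes))
  invisible(x)
}

#' Number of samples a design emits
#' @param design a [study_design()]
#' @export
n_samples <- function(design) length(design$lps_times) * length(design$chase_times)

#' RPKM from tag counts
#'
#' RPKM = tags / (gene length in kb x mapped tags in millions).
#'
#' @param counts genes x samples integer matrix
#' @param gene_length_kb per-gene lengths in kb (recycled)
#' @param library_sizes per-sample mapped-tag totals; defaults to the column
#'   sums of `counts`
#' @return numeric matrix of RPKM values, same dimnames as `counts`
#' @export
rpkm_from_counts <- function(counts, gene_length_kb = 1,
                             library_sizes = colSums(counts)) {
  len <- rep_len(gene_length_kb, nrow(counts))
  sweep(counts / len, 2, library_sizes / 1e6, "/")
}

#' Simulate a chase-design tag-count table with known kinetics
#'
#' Models the shutoff experiment as first-order decay: after transcription
#' stops, the expected relative level of a gene follows its class's decay law;
#' tag counts are drawn from a mean-preserving overdispersed counting
#' distribution (negative binomial with `dispersion`; `dispersion = 0` means
#' Poisson).  Baseline (chase-0) expression varies across genes on a
#' log-normal scale.  Each gene consumes an RNG substream derived from `seed`
#' and its index, so extending the gene set leaves earlier genes unchanged.
#'
#' @param design a [study_design()]
#' @param classes list of [kinetic_class()] objects
#' @param assignment class ids per gene: either a vector of length `n_genes`
#'   (same class at every stimulation time) or an `n_genes x n_lps` matrix
#' @param dispersion negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2); 0 gives Poisson; negative rejected
#' @param seed integer seed
#' @param gene_length_kb gene lengths in kb (default 1 so tags and RPKM are
#'   proportional)
#' @param baseline_tags expected chase-0 tags per gene; default draws from a
#'   log-normal centred at 500
#' @param induction optional `n_genes x n_lps` matrix of multiplicative
#'   expression changes across stimulation times (pre-shutoff dynamics)
#' @param noise if `FALSE`, emit the (non-integer) noiseless expectations
#'   instead of sampled counts, so analytic fixtures follow the decay law
#'   exactly
#' @return list with `counts`, `rpkm` (matrices genes x samples, columns named
#'   `LPS<h>_ActD<h>`), and `truth` (data.frame: gene, lps_time, class_id,
#'   delta, half_life, long_lived)
#' @export
simulate_counts <- function(design, classes, assignment, dispersion = 0.01,
                            seed = 1L, gene_length_kb = 1,
                            baseline_tags = NULL, induction = NULL,
                            noise = TRUE) {
  stopifnot(inherits(design, "study_design"))
  if (dispersion < 0) stop("dispersion must be >= 0")
  ids <- vapply(classes, function(cl) cl$class_id, 1L)
  if (anyDuplicated(ids)) stop("duplicate class ids")
  ng <- design$n_genes
  nl <- length(design$lps_times)
  nc <- length(design$chase_times)
  if (is.matrix(assignment)) {
    if (!all(dim(assignment) == c(ng, nl))) stop("assignment matrix must be n_genes x n_lps")
    amat <- assignment
  } else {
    if (length(assignment) != ng) stop("assignment must have one class per gene")
    amat <- matrix(assignment, ng, nl)
  }
  if (!all(amat %in% ids)) {
    stop("unknown class id(s): ", paste(setdiff(unique(c(amat)), ids), collapse = ", "))
  }
  if (is.null(baseline_tags)) {
    baseline_tags <- with_substream(seed, 0L, round(stats::rlnorm(ng, log(500), 0.8)) + 20)
  } else {
    baseline_tags <- rep_len(baseline_tags, ng)
  }
  if (is.null(induction)) induction <- matrix(1, ng, nl)

  genes <- sprintf("gene%04d", seq_len(ng))
  ## column order: lps major, chase minor
  cols <- unlist(lapply(design$lps_times, function(lp)
    vapply(design$chase_times, function(ch) sample_name(lp, ch), "")))
  counts <- matrix(0, ng, nl * nc, dimnames = list(genes, cols))
  class_by_id <- setNames(classes, as.character(ids))

  for (g in seq_len(ng)) {
    mu <- numeric(nl * nc)
    for (l in seq_len(nl)) {
      cl <- class_by_id[[as.character(amat[g, l])]]
      lev <- expected_level(cl, design$chase_times)
      mu[(l - 1) * nc + seq_len(nc)] <- baseline_tags[g] * induction[g, l] * lev
    }
    counts[g, ] <- with_substream(seed, g, {
      if (!noise) {
        mu  # noiseless expectation, exact closed form for analytic fixtures
      } else if (dispersion == 0) {
        stats::rpois(length(mu), mu)
      } else {
        as.numeric(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion))
      }
    })
  }

  truth <- do.call(rbind, lapply(seq_len(nl), function(l) {
    cl <- class_by_id[as.character(amat[, l])]
    data.frame(
      gene = genes, lps_time = design$lps_times[l],
      class_id = vapply(cl, function(x) x$class_id, 1L),
      delta = vapply(cl, function(x) x$delta, 1),
      half_life = vapply(cl, function(x) log(2) / x$delta, 1),
      long_lived = vapply(cl, function(x) x$long_lived, TRUE),
      stringsAsFactors = FALSE
    )
  }))
  ## depth divisor = the design's nominal mapped library size, emulating
  ## spike-in-anchored normalization: during a chase the realized mRNA mass
  ## shrinks, and dividing by realized totals would re-inflate every late
  ## sample and erase absolute decay
  rpkm <- rpkm_from_counts(counts, gene_length_kb,
                           library_sizes = design$library_size)
  list(counts = counts, rpkm = rpkm, truth = truth)
}

#' Specify a motif to plant in synthetic 3' UTRs
#'
#' @param kind `"sequence"` or `"stemloop"`
#' @param consensus IUPAC-free RNA string (sequence kind)
#' @param arm5,loop,arm3 stem-loop parts; `arm3` must reverse-complement
#'   `arm5` (G-U wobble allowed)
#' @param mutation_rate per-base substitution probability in `[0, 0.5]`
#' @param carrier_fraction fraction of the target set's UTRs carrying one
#'   instance (carriers = `floor(fraction * n_targets)`)
#' @param conservation_boost value added to the conservation track over the
#'   planted interval (clipped at 1)
#' @param preserve_pairing for stem-loops, mutate arm bases jointly so the
#'   stem stays complementary
#' @return object of class `plant_spec`
#' @export
plant_spec <- function(kind = c("sequence", "stemloop"), consensus = NULL,
                       arm5 = NULL, loop = NULL, arm3 = NULL,
                       mutation_rate = 0, carrier_fraction = 1,
                       conservation_boost = 0.6, preserve_pairing = TRUE) {
  kind <- match.arg(kind)
  if (mutation_rate < 0 || mutation_rate > 0.5) stop("mutation_rate in [0, 0.5]")
  if (kind == "sequence") {
    if (is.null(consensus)) stop("sequence plant needs a consensus")
    consensus <- chartr("T", "U", toupper(consensus))
  } else {
    if (is.null(arm5) || is.null(loop) || is.null(arm3)) stop("stemloop needs arm5/loop/arm3")
    arm5 <- chartr("T", "U", toupper(arm5)); loop <- chartr("T", "U", toupper(loop))
    arm3 <- chartr("T", "U", toupper(arm3))
    if (nchar(arm5) != nchar(arm3)) stop("arms must have equal length")
    a <- strsplit(arm5, "")[[1]]
    b <- rev(strsplit(arm3, "")[[1]])
    ok <- paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
    if (!all(ok)) stop("arm3 must reverse-complement arm5 (G-U wobble allowed)")
    consensus <- paste0(arm5, loop, arm3)
  }
  structure(
    list(kind = kind, consensus = consensus, arm5 = arm5, loop = loop,
         arm3 = arm3, mutation_rate = mutation_rate,
         carrier_fraction = carrier_fraction,
         conservation_boost = conservation_boost,
         preserve_pairing = isTRUE(preserve_pairing)),
    class = "plant_spec"
  )
}

mutate_plant <- function(spec) {
  x <- strsplit(spec$consensus, "")[[1]]
  n <- length(x)
  if (spec$mutation_rate == 0) return(paste(x, collapse = ""))
  if (spec$kind == "stemloop" && spec$preserve_pairing) {
    na <- nchar(spec$arm5); nl <- nchar(spec$loop)
    hit <- which(stats::runif(na + nl) < spec$mutation_rate)
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    for (i in hit) {
      if (i <= na) {
        b <- sample(setdiff(RNA_BASES, x[i]), 1)
        x[i] <- b
        x[n - i + 1] <- comp[[b]]   # keep the stem paired (Watson-Crick)
      } else {
        x[i] <- sample(setdiff(RNA_BASES, x[i]), 1)
      }
    }
  } else {
    hit <- which(stats::runif(n) < spec$mutation_rate)
    for (i in hit) x[i] <- sample(setdiff(RNA_BASES, x[i]), 1)
  }
  paste(x, collapse = "")
}

#' Simulate 3' UTR sequences with planted motifs and a conservation track
#'
#' Backgrounds are i.i.d. with the given GC fraction; each plant spec places
#' exactly `floor(carrier_fraction * n_targets)` instances, one per carrier,
#' at uniformly random valid offsets.  The conservation track (one value per
#' base, in `[0, 1]`) equals `baseline` everywhere except over planted
#' intervals, where `conservation_boost` is added and clipped at 1 —
#' standing in for a phastCons-like score that is elevated over functional
#' elements.
#'
#' @param n number of UTRs (ids `gene0001`...)
#' @param length_meanlog,length_sdlog log-normal UTR length parameters
#' @param min_length shortest UTR emitted
#' @param gc background GC fraction
#' @param plants list of [plant_spec()]s
#' @param target_genes list (parallel to `plants`) of gene-id vectors each
#'   spec may land in; default all genes
#' @param conservation_baseline background track value
#' @param seed integer seed
#' @param gene_ids optional explicit ids
#' @return list: `seqs` (named character, RNA), `plants` (BED-like
#'   data.frame: gene, start, end (0-based half-open), name, planted
#'   sequence), `conservation` (named list of per-base numeric vectors)
#' @export
simulate_utrs <- function(n, length_meanlog = log(300), length_sdlog = 0.4,
                          min_length = 60, gc = 0.4, plants = list(),
                          target_genes = NULL, conservation_baseline = 0.2,
                          seed = 1L, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%04d", seq_len(n))
  stopifnot(length(gene_ids) == n)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  lens <- with_substream(seed, 0L,
    pmax(min_length, round(stats::rlnorm(n, length_meanlog, length_sdlog))))
  seqs <- vapply(seq_len(n), function(g) {
    with_substream(seed, g,
      paste(sample(RNA_BASES, lens[g], TRUE, prob = probs), collapse = ""))
  }, "")
  names(seqs) <- gene_ids
  cons <- lapply(lens, function(L) rep(conservation_baseline, L))
  names(cons) <- gene_ids

  bed <- data.frame(gene = character(), start = integer(), end = integer(),
                    name = character(), seq = character(), stringsAsFactors = FALSE)
  for (pi in seq_along(plants)) {
    spec <- plants[[pi]]
    targets <- if (is.null(target_genes)) gene_ids else target_genes[[pi]]
    if (!all(targets %in% gene_ids)) stop("unknown target gene ids")
    w <- nchar(spec$consensus)
    too_short <- targets[nchar(seqs[targets]) < w]
    if (length(too_short) > 0) {
      stop("plant longer than UTR(s): ", paste(too_short, collapse = ", "))
    }
    n_car <- floor(spec$carrier_fraction * length(targets))
    carriers <- with_substream(seed, 100000L + pi, sample(targets, n_car))
    for (ci in seq_along(carriers)) {
      g <- carriers[ci]
      res <- with_substream(seed, 200000L + pi * 4999L + match(g, gene_ids), {
        inst <- mutate_plant(spec)
        off <- sample.int(nchar(seqs[[g]]) - w + 1L, 1L) - 1L
        list(inst = inst, off = off)
      })
      substr(seqs[[g]], res$off + 1L, res$off + w) <- res$inst
      idx <- res$off + seq_len(w)
      cons[[g]][idx] <- pmin(1, cons[[g]][idx] + spec$conservation_boost)
      bed <- rbind(bed, data.frame(
        gene = g, start = res$off, end = res$off + w,
        name = sprintf("plant%d", pi), seq = res$inst, stringsAsFactors = FALSE))
    }
  }
  list(seqs = seqs, plants = bed, conservation = cons)
}

#' Write simulated UTRs to FASTA, BED and bedGraph files
#'
#' BED records are 0-based half-open on the UTR-local coordinate system, as
#' is the bedGraph conservation track.
#'
#' @param utrs result of [simulate_utrs()]
#' @param fasta,bed,bedgraph output paths (NULL skips)
#' @export
write_utrs <- function(utrs, fasta = NULL, bed = NULL, bedgraph = NULL) {
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(Biostrings::RNAStringSet(utrs$seqs), fasta)
  }
  if (!is.null(bed)) {
    utils::write.table(utrs$plants[, c("gene", "start", "end", "name")], bed,
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(bedgraph)) {
    rows <- do.call(rbind, lapply(names(utrs$conservation), function(g) {
      v <- utrs$conservation[[g]]
      r <- rle(v)
      e <- cumsum(r$lengths)
      data.frame(gene = g, start = c(0L, e[-length(e)]), end = e, value = r$values)
    }))
    utils::write.table(rows, bedgraph, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}
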