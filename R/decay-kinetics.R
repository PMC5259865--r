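#' The quick/slow mean-degradation-rate threshold (per hour)
#' @export
quick_slow_threshold <- function() 0.325

## nested family: which parameters are free per model
## model 1: delta             (complete shutoff; r0 = 1, r1 = 0)
## model 2: delta, r1         (incomplete shutoff; r0 = 1)
## model 3: delta, r0         (delayed shutoff; r1 = 0)
## model 4: delta, r0, r1     (both)
model_free_params <- function(model_id) {
  switch(model_id, c("delta"), c("delta", "r1"), c("delta", "r0"),
         c("delta", "r0", "r1"))
}

#' Evaluate the decay law r(t) = r1 + (r0 - r1) exp(-delta t)
#' @param t chase times (hours)
#' @param delta decay rate per hour
#' @param r0,r1 initial level and residual plateau
#' @export
decay_level <- function(t, delta, r0 = 1, r1 = 0) {
  r1 + (r0 - r1) * exp(-delta * t)
}

#' AIC for a least-squares fit
#'
#' Gaussian-error AIC with the variance profiled out:
#' `n * log(max(rss, eps) / n) + 2p`, where the floor
#' `eps = n * (1e-6)^2` keeps noiseless fixtures finite.
#'
#' @param rss residual sum of squares
#' @param n number of fitted points
#' @param p number of free parameters
#' @export
aic_ls <- function(rss, n, p) {
  eps <- n * (1e-6)^2
  n * log(max(rss, eps) / n) + 2 * p
}

#' Fit one decay model to a chase time course
#'
#' Box-constrained least squares (`0 < delta <= 20` per hour,
#' `0 <= r1 < r0 <= 5`) via Levenberg-Marquardt from a deterministic
#' multistart grid (delta in 0.1/0.5/1/4, crossed with r1 in 0/0.25 and r0
#' in 1/max(level) where free); the best residual sum of squares is kept, so
#' the fit needs no RNG.  A fit is flagged when the optimizer fails from
#' every start or delta sticks at the box boundary (degenerate, e.g. a flat
#' course).
#'
#' @param chase_times,levels the course (levels relative to chase 0)
#' @param model_id 1..4
#' @return list of class `decay_fit`: model_id, r0, r1, delta, rss, n_obs,
#'   aic, half_life, flagged
#' @export
fit_decay <- function(chase_times, levels, model_id) {
  stopifnot(model_id %in% 1:4)
  free <- model_free_params(model_id)
  n <- length(chase_times)
  if (n < length(free) + 1) stop("need >= free parameters + 1 time points")
  if (any(levels < 0)) stop("negative levels")

  lo <- c(delta = 1e-3, r0 = 1e-6, r1 = 0)
  ## with r0 fixed at 1 (model 2) the plateau cannot reach it
  hi <- c(delta = 20, r0 = 5, r1 = if ("r0" %in% free) 5 else 1 - 1e-9)
  resid_fn <- function(par) {
    p <- c(delta = NA, r0 = 1, r1 = 0)
    p[free] <- par
    decay_level(chase_times, p[["delta"]], p[["r0"]], p[["r1"]]) - levels
  }
  d_starts <- c(0.1, 0.5, 1, 4)
  r1_starts <- if ("r1" %in% free) c(0, 0.25) else 0
  r0_starts <- if ("r0" %in% free) unique(c(1, max(max(levels), 1e-3))) else 1

  best <- NULL
  for (d0 in d_starts) for (a0 in r0_starts) for (b0 in r1_starts) {
    start <- c(delta = d0, r0 = a0, r1 = b0)[free]
    res <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lo[free], upper = hi[free],
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(par = res$par, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(model_id = model_id, r0 = NA, r1 = NA, delta = NA,
                          rss = NA, n_obs = n, aic = NA, half_life = NA,
                          flagged = TRUE), class = "decay_fit"))
  }
  p <- c(delta = NA, r0 = 1, r1 = 0)
  p[free] <- best$par
  flagged <- p[["delta"]] <= lo[["delta"]] * 1.001 || p[["r1"]] >= p[["r0"]]
  structure(
    list(model_id = model_id, r0 = unname(p[["r0"]]), r1 = unname(p[["r1"]]),
         delta = unname(p[["delta"]]), rss = best$rss, n_obs = n,
         aic = aic_ls(best$rss, n, length(free)),
         half_life = log(2) / unname(p[["delta"]]), flagged = flagged),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay fit (model %d): delta = %.4g /h (t1/2 = %.3g h), r0 = %.3g, r1 = %.3g, rss = %.3g, AIC = %.3g%s\n",
              x$model_id, x$delta, x$half_life, x$r0, x$r1, x$rss, x$aic,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Select among the four decay-model fits by AIC
#'
#' Minimum AIC wins; ties go to the model with fewer free parameters, then
#' the smaller model id.  Flagged fits are ineligible; if all four are
#' flagged the selection itself is flagged.
#'
#' @param fits list of 4 `decay_fit`s of the same course
#' @return the winning `decay_fit`
#' @export
select_model <- function(fits) {
  ok <- !vapply(fits, `[[`, TRUE, "flagged")
  if (!any(ok)) {
    f <- fits[[1]]
    f$flagged <- TRUE
    return(f)
  }
  cand <- fits[ok]
  aics <- vapply(cand, `[[`, 1, "aic")
  np <- vapply(cand, function(f) length(model_free_params(f$model_id)), 1L)
  mid <- vapply(cand, `[[`, 1L, "model_id")
  cand[[order(aics, np, mid)[1]]]
}

#' Fit all four decay models and select one by AIC
#' @inheritParams fit_decay
#' @return the selected `decay_fit`
#' @export
fit_decay_models <- function(chase_times, levels) {
  select_model(lapply(1:4, function(m) fit_decay(chase_times, levels, m)))
}

#' Rank kinetic clusters from quickest to slowest degradation
#'
#' @param deltas named numeric vector of selected-fit decay rates per cluster
#' @return integer ranks (1 = largest delta); ties broken by cluster order
#' @export
rank_clusters <- function(deltas) {
  ord <- order(-deltas, seq_along(deltas))
  ranks <- integer(length(deltas))
  ranks[ord] <- seq_along(ord)
  names(ranks) <- names(deltas)
  ranks
}

#' Categorize genes as quick, slow, stable or low-reliability
#'
#' Per gene over the 8 stimulation time points: `STABLE` if labelled
#' long-lived at >= 4 of them; otherwise `LOW_RELIABILITY` if fewer than 4
#' time points carry any kinetics label; otherwise the mean degradation rate
#' (arithmetic mean of the assigned clusters' rates over labelled time
#' points, long-lived points contributing rate 0) splits the gene at
#' [quick_slow_threshold()]: `QUICK` strictly above, `SLOW` otherwise.
#'
#' @param labels genes x lps character matrix (OK_SHORT / LONG_LIVED /
#'   NA_LOW_TAGS / NA_NOT_EXPRESSED)
#' @param rates genes x lps numeric matrix of assigned-cluster decay rates
#'   (NA where unlabelled; ignored at LONG_LIVED points)
#' @return data.frame (gene, category, mean_rate, n_labeled, n_long_lived)
#' @export
categorize_genes <- function(labels, rates) {
  stopifnot(all(dim(labels) == dim(rates)))
  genes <- rownames(labels)
  out <- lapply(seq_len(nrow(labels)), function(g) {
    lab <- labels[g, ]
    n_ll <- sum(lab == "LONG_LIVED")
    labeled <- lab %in% c("OK_SHORT", "LONG_LIVED")
    ## a short-lived point without an assigned-cluster rate carries no
    ## kinetics information
    labeled <- labeled & !(lab == "OK_SHORT" & is.na(rates[g, ]))
    if (n_ll >= 4) {
      cat_ <- "STABLE"; mr <- NA_real_
    } else if (sum(labeled) < 4) {
      cat_ <- "LOW_RELIABILITY"; mr <- NA_real_
    } else {
      r <- ifelse(lab == "LONG_LIVED", 0, rates[g, ])
      mr <- mean(r[labeled])
      cat_ <- if (mr > quick_slow_threshold()) "QUICK" else "SLOW"
    }
    data.frame(gene = genes[g], category = cat_, mean_rate = mr,
               n_labeled = sum(labeled), n_long_lived = n_ll,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
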