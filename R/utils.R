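#' @useDynLib decaypatterns, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
NULL

RNA_BASES <- c("A", "C", "G", "U")

#' Build the sample identifier for one (stimulation, chase) cell
#'
#' Samples are laid out on a two-way grid: hours of stimulation before
#' transcription shutoff crossed with hours of chase after actinomycin D.
#'
#' @param lps_time stimulation time in hours
#' @param chase_time chase time in hours
#' @return character id of the form `LPS<h>_ActD<h>`
#' @export
sample_name <- function(lps_time, chase_time) {
  sprintf("LPS%g_ActD%g", lps_time, chase_time)
}

#' Parse sample identifiers back to their grid coordinates
#'
#' @param ids character vector of `LPS<h>_ActD<h>` ids
#' @return data.frame with columns `sample`, `lps_time`, `chase_time`
#' @export
parse_sample_names <- function(ids) {
  m <- regmatches(ids, regexec("^LPS([0-9.]+)_ActD([0-9.]+)$", ids))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed sample ids: ", paste(ids[bad], collapse = ", "))
  }
  data.frame(
    sample = ids,
    lps_time = vapply(m, function(x) as.numeric(x[2]), 1),
    chase_time = vapply(m, function(x) as.numeric(x[3]), 1),
    stringsAsFactors = FALSE
  )
}

## integer encoding used by the C++ kernels: A=0, C=1, G=2, U=3
encode_rna <- function(seq) {
  x <- match(strsplit(toupper(chartr("T", "U", seq)), "")[[1]], RNA_BASES) - 1L
  if (anyNA(x)) stop("sequence contains non-ACGU characters")
  x
}

decode_rna <- function(codes) paste(RNA_BASES[codes + 1L], collapse = "")

## per-stream RNG seeds derived from one master seed, stable under stream
## count (adding genes never perturbs earlier genes); 32-bit-safe
substream_seed <- function(seed, stream) {
  ## arithmetic in doubles (exact below 2^53), reduced into 32-bit range
  as.integer(((as.numeric(seed) %% 1e6) * 2011 + as.numeric(stream) * 7919) %%
               2147483647)
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, stream))
  force(expr)
}
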