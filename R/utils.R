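#' @keywords internal
#' @importFrom withr with_seed
"_PACKAGE"

# Derive a reproducible child seed from a parent seed and a stream index.
# Keeps results < 2^31 so they remain valid R integer seeds.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 1000003) %%
               2147483587)
}

# Internal guard helpers -------------------------------------------------

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x >= 0

#' Benjamini-Hochberg adjustment with NA propagation
#'
#' Thin, audited wrapper around the textbook step-up procedure. NA or NaN
#' p-values are propagated to the output with a warning rather than dropped
#' silently.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Numeric vector of BH-adjusted q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stopf("`p` must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stopf("p-values outside [0, 1]")
  if (anyNA(p)) warnf("%d NA/NaN p-values propagated", sum(is.na(p)))
  stats::p.adjust(p, method = "BH")
}

# File hashing for run manifests (text outputs only).
file_md5 <- function(paths) {
  h <- tools::md5sum(paths)
  names(h) <- basename(paths)
  h
}
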