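# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check that a window is a length-2 increasing numeric vector
#' @keywords internal
check_window <- function(window, name = "window") {
  if (!is.numeric(window) || length(window) != 2L || !all(is.finite(window)) ||
      window[2] <= window[1]) {
    stop(sprintf("'%s' must be a finite numeric vector c(start, end) with end > start", name),
         call. = FALSE)
  }
  invisible(window)
}

#' Column-wise z-score; errors on constant columns
#' @keywords internal
zscore_cols <- function(x, what = "measure") {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(x)[sds == 0 | !is.finite(sds)]
    stop("constant or non-finite column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  scale(x)
}

#' FNV-1a hash of an R object's serialization, as a hex string.
#'
#' Used for run manifests so identical configurations map to identical
#' hashes within a given R serialization version.
#' @keywords internal
object_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 3))
  # polynomial rolling hash mod a Mersenne prime, in exact double arithmetic
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Derive a deterministic 32-bit sub-seed from a base seed and a string key
#' @keywords internal
derive_seed <- function(seed, key) {
  s <- (as.numeric(seed) + sum(utf8ToInt(as.character(key))) * 7919) %% 2147483647
  as.integer(s)
}

#' Round times to microsecond resolution (the on-disk resolution)
#'
#' Rounds through the decimal representation so the value equals the parse
#' of its own 6-decimal string and write/read round-trips are bit-exact.
#' @keywords internal
round_us <- function(x) {
  if (!length(x)) return(x)
  as.numeric(sprintf("%.6f", x))
}
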