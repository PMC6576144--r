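#' Harmonic number a_n used by Watterson's estimator
#'
#' \eqn{a_n = \sum_{i=1}^{n-1} 1/i} for a sample of \code{n} haploid genomes.
#'
#' @param n Number of haploid genomes (>= 2).
#' @return The harmonic number as a double.
#' @keywords internal
harmonicNumber <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1L))
}

# Numerically stable log(sum(exp(x))) along rows of a matrix (or a vector).
logSumExp <- function(x) {
  if (is.matrix(x)) {
    m <- apply(x, 1L, max)
    m + log(rowSums(exp(x - m)))
  } else {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
}

# internal: consistent slope label checking
.checkSlopes <- function(slope) {
  slope <- as.character(slope)
  bad <- !slope %in% c("NFS", "SFS")
  if (any(bad)) {
    stop("slope labels must be 'NFS' or 'SFS'; offending: ",
         paste(unique(slope[bad]), collapse = ", "))
  }
  slope
}
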