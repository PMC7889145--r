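#' @useDynLib BACtrace, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rbinom rnorm runif median setNames
#' @importFrom utils read.table write.table
NULL

# random uniform DNA as a DNAStringSet; deterministic under set.seed()
randomDna <- function(lengths) {
  seqs <- vapply(lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, names(lengths)))
}

# lower median: for even n take the lower of the two central values
lowerMedian <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, what) {
  if (length(x) != 1 || is.na(x)) stop(what, " must be a non-missing scalar", call. = FALSE)
  invisible(x)
}
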