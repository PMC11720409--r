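#' @keywords internal
"_PACKAGE"

# Valid platform and scale tags used across the package.
.platforms <- c("SOMA_A", "SOMA_B", "OLINK")
.scales <- c("LINEAR_RFU", "NPX_LOG2", "LOG2", "ZSCORED")

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the random-number generator seeded at `seed`, then
#' restores the previous RNG state so surrounding code is unaffected.
#' With `seed = NULL` the code runs under the ambient RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Row standard deviations with the n-1 denominator, no NA handling.
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least two columns to compute row SDs")
  mu <- rowMeans(x)
  sqrt(rowSums((x - mu)^2) / (n - 1))
}

# Row-wise average ranks (ties get their mean rank), applied across columns.
row_ranks <- function(x) {
  t(apply(x, 1L, rank, ties.method = "average"))
}
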