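#' @importFrom stats aov approx cor dist kmeans lm median p.adjust
#'   pchisq prcomp quantile rbinom rexp rlnorm rnbinom rnorm runif sd
#'   setNames t.test var wilcox.test predict coef
#' @importFrom utils head read.delim write.table
NULL

## log2(expected count + 1), the working scale shared by the single-cell stages
log2p1 <- function(x) log2(x + 1)

## Derive independent sub-seeds from a master seed so that each artifact
## (UMI matrix, bulk table, qPCR plate, count table, ...) is reproducible on
## its own. Kept below 2^31 - 1 to stay a valid R integer.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(umi = 101L, bulk = 211L, qpcr = 307L, counts = 401L,
               tsne = 503L, tree = 601L, split = 701L, pipeline = 811L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 1000L + off) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_counts <- function(m) {
  if (!is.matrix(m) || any(m < 0) || any(m != round(m)))
    stop("expected a matrix of non-negative integer counts")
  invisible(m)
}
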