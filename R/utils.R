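#' @import methods
#' @importFrom stats rnorm runif sd approx var fft t.test
#' @importFrom utils read.csv write.csv head
NULL

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All seeded operations in the package go through
# this so that user-level RNG state is never disturbed.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a stage seed from a master seed and a tag.
# Kept strictly below 2^31 so it is always a valid R integer.
deriveSeed <- function(master, tag, index = 0L) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  val <- (as.double(master) %% 1e6) * 2011 + h * 131 + as.double(index) * 9973
  as.integer(val %% 2147483647) + 1L
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Jaccard index between two binary masks on the same grid.
jaccardIndex <- function(a, b) {
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# Total variation (isotropic, forward differences, Neumann boundary).
totalVariation <- function(x) {
  gx <- rbind(diff(x), 0)
  gy <- cbind(t(diff(t(x))), 0)
  sum(sqrt(gx^2 + gy^2))
}

stopIfNot01 <- function(x, what = "image") {
  if (min(x) < -1e-9 || max(x) > 1 + 1e-9)
    stop(sprintf("%s must be in the unit intensity range [0, 1]", what))
  invisible(TRUE)
}

# EBImage results back to plain numeric matrices
asPlainMatrix <- function(x) {
  m <- EBImage::imageData(x)
  matrix(as.numeric(m), nrow(m), ncol(m))
}
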