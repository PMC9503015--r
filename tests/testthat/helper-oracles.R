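# Independent oracles used by the tests; kept deliberately separate from
# the package implementations they check.

# Brute-force AUC: concordance probability over all (positive, negative)
# pairs, ties counted one half.
bruteForceAUC <- function(scores, labels) {
  sp <- scores[labels == "presentMCs"]
  sn <- scores[labels == "absent"]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

# Independent ROF solver: Chambolle-Pock primal-dual iteration for
# min_u lambda/2 ||u - f||^2 + TV(u) (isotropic). Different algorithm and
# code path from the package's dual projection solver; both converge to
# the unique minimizer of the strictly convex objective.
rofPrimalDual <- function(f, lambda, iter = 3000L) {
  n <- nrow(f); m <- ncol(f)
  tau <- sigma <- 1 / sqrt(8)
  u <- f; ubar <- f
  px <- py <- matrix(0, n, m)
  gradOf <- function(v) {
    gx <- rbind(v[-1, , drop = FALSE] - v[-n, , drop = FALSE], rep(0, m))
    gy <- cbind(v[, -1, drop = FALSE] - v[, -m, drop = FALSE], rep(0, n))
    list(x = gx, y = gy)
  }
  divOf <- function(qx, qy) {
    dx <- qx - rbind(rep(0, m), qx[-n, , drop = FALSE])
    dx[n, ] <- -qx[n - 1, ]
    dy <- qy - cbind(rep(0, n), qy[, -m, drop = FALSE])
    dy[, m] <- -qy[, m - 1]
    dx + dy
  }
  for (i in seq_len(iter)) {
    g <- gradOf(ubar)
    px <- px + sigma * g$x; py <- py + sigma * g$y
    nrm <- pmax(1, sqrt(px^2 + py^2))
    px <- px / nrm; py <- py / nrm
    v <- u + tau * divOf(px, py)
    uNew <- (v + tau * lambda * f) / (1 + tau * lambda)
    ubar <- 2 * uNew - u
    u <- uNew
  }
  u
}

# closed-form pooled-variance two-sample t-test p-value
pooledTTestP <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(tstat), df = na + nb - 2)
}

# small cohort reused across tests (cached per session)
.testCohort <- local({
  env <- new.env()
  function(nCases = 8L, seed = 42L, gridSize = 64L, contrast = 0.4) {
    key <- paste(nCases, seed, gridSize, contrast, sep = "_")
    if (is.null(env[[key]]))
      env[[key]] <- generateCohort(CohortSpec(
        nCases = nCases, seed = seed, gridSize = gridSize,
        clusterSpec = MCClusterSpec(contrast = contrast)))
    env[[key]]
  }
})
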