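# Minimal CPU engine for convolutional layer graphs.
#
# Activations are dense matrices of shape (H*W*C, N) with flat index
# ordered h (fastest), then w, then c; fully connected activations are
# (features, N). Convolution and pooling use precomputed sparse gather
# matrices (im2col) so the heavy lifting is one BLAS GEMM per layer and
# batch; the transposed gather performs the col2im scatter in backward
# passes, which also handles overlapping windows correctly. Layer graphs
# are DAGs (concat/add nodes), executed in the listed topological order.

#' @useDynLib DBTmc, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

convOutDim <- function(n, k, s, p) floor((n + 2 * p - k) / s) + 1L

# sparse gather for convolution: rows ordered (channel-in-group, kh, kw)
# fastest, then output location l = oh + Ho*ow
convGather <- function(H, W, C, channels, k, s, p) {
  Cg <- length(channels)
  Ho <- convOutDim(H, k, s, p); Wo <- convOutDim(W, k, s, p)
  L <- Ho * Wo
  ciV <- rep(channels, times = k * k * L)
  khV <- rep(rep(0:(k - 1), each = Cg), times = k * L)
  kwV <- rep(rep(0:(k - 1), each = Cg * k), times = L)
  lV  <- rep(0:(L - 1), each = Cg * k * k)
  ih <- (lV %% Ho) * s - p + khV
  iw <- (lV %/% Ho) * s - p + kwV
  ok <- ih >= 0 & ih < H & iw >= 0 & iw < W
  M <- Cg * k * k * L
  idx <- rep.int(H * W * C + 1L, M)   # padding entries read zero
  idx[ok] <- as.integer(ih[ok] + H * iw[ok] + H * W * (ciV[ok] - 1) + 1)
  list(idx = idx, rows = Cg * k * k, L = L, Ho = Ho, Wo = Wo)
}

# sparse gather for pooling: rows ordered window offset j fastest,
# then l, then channel
poolGather <- function(H, W, C, k, s, p) {
  Ho <- convOutDim(H, k, s, p); Wo <- convOutDim(W, k, s, p)
  L <- Ho * Wo
  k2 <- k * k
  jV <- rep(0:(k2 - 1), times = L * C)
  lV <- rep(rep(0:(L - 1), each = k2), times = C)
  cV <- rep(0:(C - 1), each = k2 * L)
  khV <- jV %% k; kwV <- jV %/% k
  ih <- (lV %% Ho) * s - p + khV
  iw <- (lV %/% Ho) * s - p + kwV
  ok <- ih >= 0 & ih < H & iw >= 0 & iw < W
  M <- k2 * L * C
  idx <- rep.int(H * W * C + 1L, M)   # padding entries never win the max
  idx[ok] <- as.integer(ih[ok] + H * iw[ok] + H * W * cV[ok] + 1)
  list(idx = idx, k2 = k2, L = L, Ho = Ho, Wo = Wo)
}

nd <- function(name, op, inputs, ...) {
  c(list(name = name, op = op, inputs = inputs), list(...))
}

# ---- shape propagation -------------------------------------------------

# shapes: list(H, W, C) for spatial nodes or list(F) after flatten
propagateShapes <- function(nodes, inputSize) {
  shapes <- list()
  for (i in seq_along(nodes)) {
    node <- nodes[[i]]
    ins <- lapply(node$inputs, function(nm) shapes[[nm]])
    sh <- switch(node$op,
      input = list(H = inputSize, W = inputSize, C = 1L),
      conv = {
        s <- ins[[1]]
        Ho <- convOutDim(s$H, node$kernel, node$stride, node$pad)
        Wo <- convOutDim(s$W, node$kernel, node$stride, node$pad)
        if (Ho < 1L || Wo < 1L)
          stop(sprintf("input too small at layer '%s' (%dx%d, kernel %d, stride %d, pad %d)",
                       node$name, s$H, s$W, node$kernel, node$stride, node$pad))
        if (s$C %% node$groups != 0L || node$outChannels %% node$groups != 0L)
          stop(sprintf("channels not divisible by groups at layer '%s'", node$name))
        list(H = Ho, W = Wo, C = node$outChannels)
      },
      maxpool = {
        s <- ins[[1]]
        Ho <- convOutDim(s$H, node$kernel, node$stride, node$pad)
        Wo <- convOutDim(s$W, node$kernel, node$stride, node$pad)
        if (Ho < 1L || Wo < 1L)
          stop(sprintf("input too small at layer '%s' (%dx%d, kernel %d, stride %d, pad %d)",
                       node$name, s$H, s$W, node$kernel, node$stride, node$pad))
        list(H = Ho, W = Wo, C = s$C)
      },
      gap = list(F = ins[[1]]$C),
      flatten = list(F = ins[[1]]$H * ins[[1]]$W * ins[[1]]$C),
      fc = list(F = node$outFeatures),
      relu = , bn = , lrn = , dropout = ins[[1]],
      concat = {
        H <- ins[[1]]$H; W <- ins[[1]]$W
        for (s in ins) stopifnot(s$H == H, s$W == W)
        list(H = H, W = W, C = sum(vapply(ins, function(s) s$C, integer(1))))
      },
      add = { stopifnot(identical(ins[[1]], ins[[2]])); ins[[1]] },
      stop("unknown op: ", node$op))
    shapes[[node$name]] <- sh
  }
  shapes
}

# ---- initialization ----------------------------------------------------

initWeights <- function(nodes, shapes, seed) {
  withSeed(seed, {
    w <- list()
    for (node in nodes) {
      inSh <- if (length(node$inputs)) shapes[[node$inputs[[1]]]] else NULL
      if (node$op == "conv") {
        Cg <- inSh$C %/% node$groups
        Og <- node$outChannels %/% node$groups
        fanIn <- node$kernel^2 * Cg
        fanOut <- node$kernel^2 * Og
        sd <- sqrt(2 / (fanIn + fanOut))   # Glorot, fan-in/out scaled
        W <- lapply(seq_len(node$groups), function(g)
          matrix(stats::rnorm(Og * fanIn, sd = sd), Og, fanIn))
        w[[node$name]] <- list(W = W, b = numeric(node$outChannels))
      } else if (node$op == "fc") {
        fanIn <- inSh$F
        sd <- sqrt(2 / (fanIn + node$outFeatures))
        w[[node$name]] <- list(
          W = matrix(stats::rnorm(node$outFeatures * fanIn, sd = sd),
                     node$outFeatures, fanIn),
          b = numeric(node$outFeatures))
      } else if (node$op == "bn") {
        C <- inSh$C
        w[[node$name]] <- list(gamma = rep(1, C), beta = numeric(C))
      }
    }
    w
  })
}

buildModel <- function(arch, nodes, inputSize, nClasses, seed = 1L) {
  names(nodes) <- vapply(nodes, `[[`, character(1L), "name")
  shapes <- propagateShapes(nodes, inputSize)
  weights <- initWeights(nodes, shapes, seed)
  state <- new.env(parent = emptyenv())
  state$shapes <- shapes
  state$gather <- list()
  state$running <- list()
  for (node in nodes) if (node$op == "bn")
    state$running[[node$name]] <- list(mean = numeric(shapes[[node$name]]$C),
                                       var = rep(1, shapes[[node$name]]$C))
  new("CNNModel", arch = arch, inputSize = as.integer(inputSize),
      nClasses = as.integer(nClasses), nodes = nodes, weights = weights,
      state = state)
}

#' Number of trainable parameters of a model
#' @param model a \code{CNNModel}.
#' @return Integer parameter count.
#' @export
parameterCount <- function(model) {
  tot <- 0
  for (w in model@weights)
    for (x in w) tot <- tot + if (is.list(x)) sum(vapply(x, length, 1)) else length(x)
  as.integer(tot)
}

# ---- per-op forward/backward ------------------------------------------

channelStat <- function(M, HW, C, N, fun = colMeans) {
  v <- fun(matrix(M, HW, C * N))
  rowMeans(matrix(v, C, N))
}

getGather <- function(model, node, inSh) {
  key <- node$name
  g <- model@state$gather[[key]]
  if (is.null(g)) {
    g <- if (node$op == "conv") {
      Cg <- inSh$C %/% node$groups
      lapply(seq_len(node$groups), function(gr)
        convGather(inSh$H, inSh$W, inSh$C, ((gr - 1) * Cg + 1):(gr * Cg),
                   node$kernel, node$stride, node$pad))
    } else {
      poolGather(inSh$H, inSh$W, inSh$C, node$kernel, node$stride, node$pad)
    }
    model@state$gather[[key]] <- g
  }
  g
}

forwardNode <- function(model, node, X, ins, training, cache) {
  sh <- model@state$shapes
  switch(node$op,
    input = X,
    conv = {
      inSh <- sh[[node$inputs[[1]]]]
      gs <- getGather(model, node, inSh)
      w <- model@weights[[node$name]]
      convFwdCpp(ins[[1]], lapply(gs, `[[`, "idx"), w$W, w$b, gs[[1]]$L)
    },
    maxpool = {
      inSh <- sh[[node$inputs[[1]]]]
      g <- getGather(model, node, inSh)
      r <- poolFwdCpp(ins[[1]], g$idx, g$k2)
      cache$argmax <- r$argmax
      r$max
    },
    gap = {
      inSh <- sh[[node$inputs[[1]]]]
      HW <- inSh$H * inSh$W
      N <- ncol(ins[[1]])
      v <- colMeans(matrix(ins[[1]], HW, inSh$C * N))
      dim(v) <- c(inSh$C, N)
      v
    },
    flatten = ins[[1]],
    fc = {
      w <- model@weights[[node$name]]
      fcFwdCpp(ins[[1]], w$W, w$b)
    },
    relu = pmax(ins[[1]], 0),
    bn = {
      inSh <- sh[[node$inputs[[1]]]]
      HW <- inSh$H * inSh$W; C <- inSh$C
      X1 <- ins[[1]]; N <- ncol(X1)
      w <- model@weights[[node$name]]
      eps <- 1e-5
      if (training) {
        mu <- channelStat(X1, HW, C, N)
        ex2 <- channelStat(X1 * X1, HW, C, N)
        va <- pmax(ex2 - mu^2, 0)
        r <- model@state$running[[node$name]]
        model@state$running[[node$name]] <- list(
          mean = 0.9 * r$mean + 0.1 * mu, var = 0.9 * r$var + 0.1 * va)
      } else {
        r <- model@state$running[[node$name]]
        mu <- r$mean; va <- r$var
      }
      chIdx <- rep(seq_len(C), each = HW)
      invstd <- 1 / sqrt(va + eps)
      xhat <- (X1 - mu[chIdx]) * invstd[chIdx]
      cache$xhat <- xhat; cache$invstd <- invstd
      w$gamma[chIdx] * xhat + w$beta[chIdx]
    },
    lrn = {
      inSh <- sh[[node$inputs[[1]]]]
      HW <- inSh$H * inSh$W; C <- inSh$C; N <- ncol(ins[[1]])
      A <- array(ins[[1]], c(HW, C, N))
      S <- A * A
      Ssum <- array(0, dim(A))
      for (off in -2:2) {
        cs <- seq_len(C)
        src <- cs + off
        keep <- src >= 1 & src <= C
        Ssum[, cs[keep], ] <- Ssum[, cs[keep], ] + S[, src[keep], ]
      }
      denom <- node$k + (node$alpha / node$nwin) * Ssum
      cache$denom <- denom
      out <- A * denom^(-node$beta)
      dim(out) <- c(HW * C, N)
      out
    },
    dropout = {
      if (!training) return(ins[[1]])
      p <- node$p
      mask <- (stats::runif(length(ins[[1]])) >= p) / (1 - p)
      dim(mask) <- dim(ins[[1]])
      cache$mask <- mask
      ins[[1]] * mask
    },
    concat = do.call(rbind, ins),
    add = ins[[1]] + ins[[2]],
    stop("unknown op: ", node$op))
}

backwardNode <- function(model, node, dOut, acts, cache) {
  sh <- model@state$shapes
  ins <- lapply(node$inputs, function(nm) acts[[nm]])
  switch(node$op,
    input = list(),
    conv = {
      inSh <- sh[[node$inputs[[1]]]]
      gs <- getGather(model, node, inSh)
      w <- model@weights[[node$name]]
      fromInput <- node$inputs[[1]] == "input"
      r <- convBwdCpp(ins[[1]], dOut, lapply(gs, `[[`, "idx"), w$W,
                      gs[[1]]$L, !fromInput)
      list(dIns = if (fromInput) list() else
             setNames(list(r$dX), node$inputs[[1]]),
           pgrad = list(W = r$dW, b = as.numeric(r$db)))
    },
    maxpool = {
      inSh <- sh[[node$inputs[[1]]]]
      g <- getGather(model, node, inSh)
      list(dIns = setNames(list(poolBwdCpp(dOut, cache$argmax, g$idx, g$k2,
                                           nrow(ins[[1]]))),
                           node$inputs[[1]]),
           pgrad = NULL)
    },
    gap = {
      inSh <- sh[[node$inputs[[1]]]]
      HW <- inSh$H * inSh$W
      N <- ncol(dOut)
      dX <- matrix(rep(as.vector(dOut) / HW, each = HW), HW * inSh$C, N)
      list(dIns = setNames(list(dX), node$inputs[[1]]), pgrad = NULL)
    },
    flatten = list(dIns = setNames(list(dOut), node$inputs[[1]]), pgrad = NULL),
    fc = {
      w <- model@weights[[node$name]]
      r <- fcBwdCpp(ins[[1]], w$W, dOut)
      list(dIns = setNames(list(r$dX), node$inputs[[1]]),
           pgrad = list(W = r$dW, b = as.numeric(r$db)))
    },
    relu = list(dIns = setNames(list(dOut * (ins[[1]] > 0)), node$inputs[[1]]),
                pgrad = NULL),
    bn = {
      inSh <- sh[[node$inputs[[1]]]]
      HW <- inSh$H * inSh$W; C <- inSh$C
      N <- ncol(dOut)
      m <- HW * N
      w <- model@weights[[node$name]]
      xhat <- cache$xhat; invstd <- cache$invstd
      S1 <- channelStat(dOut, HW, C, N, colSums) * N
      S2 <- channelStat(dOut * xhat, HW, C, N, colSums) * N
      chIdx <- rep(seq_len(C), each = HW)
      dX <- (w$gamma[chIdx] * invstd[chIdx]) *
        (dOut - S1[chIdx] / m - xhat * S2[chIdx] / m)
      list(dIns = setNames(list(dX), node$inputs[[1]]),
           pgrad = list(gamma = S2, beta = S1))
    },
    lrn = {
      inSh <- sh[[node$inputs[[1]]]]
      HW <- inSh$H * inSh$W; C <- inSh$C; N <- ncol(dOut)
      A <- array(ins[[1]], c(HW, C, N))
      dY <- array(dOut, c(HW, C, N))
      denom <- cache$denom
      G <- dY * A * denom^(-node$beta - 1)
      Tm <- array(0, dim(A))
      for (off in -2:2) {
        cs <- seq_len(C)
        src <- cs + off
        keep <- src >= 1 & src <= C
        Tm[, cs[keep], ] <- Tm[, cs[keep], ] + G[, src[keep], ]
      }
      dX <- denom^(-node$beta) * dY -
        (2 * node$alpha * node$beta / node$nwin) * A * Tm
      dim(dX) <- c(HW * C, N)
      list(dIns = setNames(list(dX), node$inputs[[1]]), pgrad = NULL)
    },
    dropout = list(dIns = setNames(list(dOut * cache$mask), node$inputs[[1]]),
                   pgrad = NULL),
    concat = {
      offs <- 0L
      out <- list()
      for (j in seq_along(node$inputs)) {
        nr <- nrow(ins[[j]])
        out[[node$inputs[[j]]]] <- dOut[(offs + 1L):(offs + nr), , drop = FALSE]
        offs <- offs + nr
      }
      list(dIns = out, pgrad = NULL)
    },
    add = list(dIns = setNames(list(dOut, dOut), node$inputs), pgrad = NULL),
    stop("unknown op: ", node$op))
}

# full forward pass; returns logits and (optionally) all activations
forwardModel <- function(model, X, training = FALSE, keepActs = FALSE) {
  acts <- new.env(parent = emptyenv())
  caches <- if (training || keepActs) new.env(parent = emptyenv()) else NULL
  out <- NULL
  for (node in model@nodes) {
    ins <- lapply(node$inputs, function(nm) get(nm, envir = acts))
    cache <- new.env(parent = emptyenv())
    out <- forwardNode(model, node, X, ins, training, cache)
    assign(node$name, out, envir = acts)
    if (!is.null(caches)) assign(node$name, cache, envir = caches)
  }
  list(logits = out, acts = acts, caches = caches)
}

backwardModel <- function(model, fwd, dLogits) {
  dacts <- new.env(parent = emptyenv())
  lastName <- model@nodes[[length(model@nodes)]]$name
  assign(lastName, dLogits, envir = dacts)
  actsList <- as.list(fwd$acts)
  pgrads <- list()
  for (i in rev(seq_along(model@nodes))) {
    node <- model@nodes[[i]]
    if (!exists(node$name, envir = dacts, inherits = FALSE)) next
    dOut <- get(node$name, envir = dacts)
    res <- backwardNode(model, node, dOut, actsList,
                        get(node$name, envir = fwd$caches))
    if (!is.null(res$pgrad)) pgrads[[node$name]] <- res$pgrad
    for (nm in names(res$dIns)) {
      if (exists(nm, envir = dacts, inherits = FALSE))
        assign(nm, get(nm, envir = dacts) + res$dIns[[nm]], envir = dacts)
      else assign(nm, res$dIns[[nm]], envir = dacts)
    }
  }
  pgrads
}

softmaxProbs <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

softmaxCE <- function(logits, yIdx) {
  N <- ncol(logits)
  p <- softmaxProbs(logits)
  loss <- -mean(log(pmax(p[cbind(yIdx, seq_len(N))], 1e-12)))
  d <- p
  d[cbind(yIdx, seq_len(N))] <- d[cbind(yIdx, seq_len(N))] - 1
  list(loss = loss, dLogits = d / N)
}
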