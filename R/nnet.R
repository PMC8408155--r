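# Internal neural-network machinery: a stack of multi-head graph-attention
# layers, each paired with a node-wise linear shortcut whose output is summed
# with the attention output before the ELU nonlinearity, followed by a
# multilayer-perceptron regressor ending in a sigmoid. Forward, backward and
# the Adam update are written against dense per-graph masks, which is exact
# (no neighborhood sampling) and fast for the network sizes this model is
# meant to score. All math is plain double-precision linear algebra, so a
# fixed seed gives bitwise-reproducible training.

.elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
.eluDeriv <- function(x) ifelse(x > 0, 1, exp(x))

# attention mask: adjacency (in sorted-id order) plus self-loops, so an
# isolated node aggregates only itself
.graphMask <- function(g) {
  g <- .ensureIds(g)
  adj <- igraph::as_adjacency_matrix(g, type = "both", sparse = FALSE)
  ord <- order(as.integer(igraph::V(g)$name))
  m <- adj[ord, ord, drop = FALSE] > 0
  diag(m) <- TRUE
  # 0/1 integer matrix: negatable in R and convertible to an arma::umat
  m * 1L
}

.glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -s, s), nin, nout)
}

# parameter tree; shapes are fully determined by the config and input width
.initParams <- function(cfg, inputDim) {
  H <- cfg@attentionHeads
  d <- inputDim
  conv <- lapply(seq_len(cfg@nConvLayers), function(l) {
    C <- cfg@convChannels[l]
    layer <- list(W = .glorot(d, C * H),
                  aSrc = .glorot(C, H), aDst = .glorot(C, H),
                  b = numeric(C * H),
                  V = .glorot(d, C * H), c = numeric(C * H))
    d <<- C * H
    layer
  })
  reg <- list()
  din <- d
  for (w in cfg@regressorWidths) {
    reg[[length(reg) + 1L]] <- list(W = .glorot(din, w), b = numeric(w))
    din <- w
  }
  reg[[length(reg) + 1L]] <- list(W = .glorot(din, 1L), b = numeric(1L))
  list(conv = conv, reg = reg)
}

# elementwise map over parallel parameter trees
.treeMap <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- lapply(seq_along(trees[[1]]), function(i) {
      do.call(.treeMap, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(trees[[1]])
    out
  } else {
    do.call(f, trees)
  }
}

# forward pass; returns node scores and (optionally) the caches needed for
# backprop. X rows must be in sorted-id order matching `mask`.
.gdmForward <- function(params, X, mask, cfg, training = FALSE,
                        keepCache = training) {
  N <- nrow(X)
  H <- cfg@attentionHeads
  slope <- cfg@negativeSlope
  p <- cfg@dropout
  convCache <- vector("list", length(params$conv))
  Xl <- X
  for (l in seq_along(params$conv)) {
    layer <- params$conv[[l]]
    C <- cfg@convChannels[l]
    Z <- Xl %*% layer$W
    O <- matrix(0, N, C * H)
    heads <- if (keepCache) vector("list", H) else NULL
    for (h in seq_len(H)) {
      idx <- ((h - 1L) * C + 1L):(h * C)
      Zh <- Z[, idx, drop = FALSE]
      f <- drop(Zh %*% layer$aSrc[, h])
      gv <- drop(Zh %*% layer$aDst[, h])
      E <- matrix(f, N, N) + matrix(gv, N, N, byrow = TRUE)
      pre <- E * (E > 0) + (slope * E) * (E <= 0)
      pre[!mask] <- -Inf
      mx <- pre[cbind(seq_len(N), max.col(pre, ties.method = "first"))]
      w <- exp(pre - mx)
      A <- w / rowSums(w)
      if (training && p > 0) {
        D <- matrix((runif(N * N) >= p) / (1 - p), N, N)
        Ad <- A * D
      } else {
        D <- NULL
        Ad <- A
      }
      O[, idx] <- Ad %*% Zh
      if (keepCache) {
        lgrad <- (E > 0) + slope * (E <= 0)
        lgrad[!mask] <- 0
        heads[[h]] <- list(A = A, Ad = Ad, D = D, lgrad = lgrad)
      }
    }
    U <- O + rep(layer$b, each = N) + Xl %*% layer$V + rep(layer$c, each = N)
    Y <- .elu(U)
    if (keepCache) convCache[[l]] <- list(X = Xl, Z = Z, U = U, heads = heads)
    Xl <- Y
  }
  regCache <- if (keepCache) vector("list", length(params$reg)) else NULL
  Hin <- Xl
  nReg <- length(params$reg)
  for (j in seq_len(nReg)) {
    layer <- params$reg[[j]]
    U <- Hin %*% layer$W + rep(layer$b, each = N)
    if (keepCache) regCache[[j]] <- list(H = Hin, U = U)
    Hin <- if (j < nReg) .elu(U) else U
  }
  scores <- drop(1 / (1 + exp(-Hin)))
  list(p = scores,
       cache = if (keepCache) list(conv = convCache, reg = regCache) else NULL)
}

# gradient of mean((p - y)^2) with respect to every parameter
.gdmBackward <- function(params, cfg, fw, y) {
  N <- length(y)
  H <- cfg@attentionHeads
  p <- fw$p
  dU <- matrix((2 / N) * (p - y) * p * (1 - p), ncol = 1)
  gReg <- vector("list", length(params$reg))
  for (j in rev(seq_along(params$reg))) {
    cc <- fw$cache$reg[[j]]
    gReg[[j]] <- list(W = crossprod(cc$H, dU), b = colSums(dU))
    if (j > 1L) {
      dH <- dU %*% t(params$reg[[j]]$W)
      dU <- dH * .eluDeriv(fw$cache$reg[[j - 1L]]$U)
    } else {
      dY <- dU %*% t(params$reg[[1L]]$W)
    }
  }
  gConv <- vector("list", length(params$conv))
  for (l in rev(seq_along(params$conv))) {
    layer <- params$conv[[l]]
    cc <- fw$cache$conv[[l]]
    C <- cfg@convChannels[l]
    dUc <- dY * .eluDeriv(cc$U)
    db <- colSums(dUc)
    dV <- crossprod(cc$X, dUc)
    dc <- db
    dXlin <- dUc %*% t(layer$V)
    dZ <- matrix(0, nrow(cc$Z), ncol(cc$Z))
    daSrc <- matrix(0, C, H)
    daDst <- matrix(0, C, H)
    for (h in seq_len(H)) {
      idx <- ((h - 1L) * C + 1L):(h * C)
      hc <- cc$heads[[h]]
      Zh <- cc$Z[, idx, drop = FALSE]
      dOh <- dUc[, idx, drop = FALSE]
      dAd <- tcrossprod(dOh, Zh)          # N x N
      dZh <- crossprod(hc$Ad, dOh)        # C cols
      dA <- if (is.null(hc$D)) dAd else dAd * hc$D
      rs <- rowSums(hc$A * dA)
      dPre <- hc$A * (dA - rs)
      dE <- dPre * hc$lgrad
      df <- rowSums(dE)
      dg <- colSums(dE)
      dZh <- dZh + outer(df, layer$aSrc[, h]) + outer(dg, layer$aDst[, h])
      daSrc[, h] <- drop(crossprod(Zh, df))
      daDst[, h] <- drop(crossprod(Zh, dg))
      dZ[, idx] <- dZh
    }
    dW <- crossprod(cc$X, dZ)
    gConv[[l]] <- list(W = dW, aSrc = daSrc, aDst = daDst, b = db,
                       V = dV, c = dc)
    dY <- dZ %*% t(layer$W) + dXlin
  }
  list(conv = gConv, reg = gReg)
}

# in-place style Adam step over a parameter tree; returns updated
# list(params, m, v)
.adamStep <- function(params, grads, state, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- .treeMap(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- .treeMap(function(v, g) beta2 * v + (1 - beta2) * g * g,
                      state$v, grads)
  c1 <- 1 - beta1^step
  c2 <- 1 - beta2^step
  params <- .treeMap(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

# flatten/unflatten a parameter tree for the text checkpoint format
.flattenParams <- function(params, prefix = "") {
  if (is.list(params)) {
    out <- list()
    nm <- names(params)
    if (is.null(nm)) nm <- as.character(seq_along(params))
    for (i in seq_along(params)) {
      out <- c(out, .flattenParams(params[[i]],
                                   paste0(prefix, if (nzchar(prefix)) "." else "",
                                          nm[i])))
    }
    out
  } else {
    stats::setNames(list(params), prefix)
  }
}

.fillParams <- function(template, flat, prefix = "") {
  if (is.list(template)) {
    nm <- names(template)
    if (is.null(nm)) nm <- as.character(seq_along(template))
    for (i in seq_along(template)) {
      template[[i]] <- .fillParams(template[[i]], flat,
                                   paste0(prefix, if (nzchar(prefix)) "." else "",
                                          nm[i]))
    }
    template
  } else {
    v <- flat[[prefix]]
    if (is.null(v)) stop("checkpoint is missing parameter ", prefix)
    if (is.matrix(template)) {
      matrix(v, nrow(template), ncol(template))
    } else {
      v
    }
  }
}
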