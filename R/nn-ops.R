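# Low-level neural-network primitives on batched feature maps.
#
# A batched feature map is a dense (C x (B * r^2)) matrix: C channels of B
# images at resolution r x r (column-major pixel order within each image,
# images stacked block-wise along columns).  In this channels-first layout
# every spatial shift is a contiguous column-range operation, so 3x3
# convolutions reduce to nine small BLAS products plus cheap range
# additions — which is what makes CPU training feasible without a
# deep-learning framework.

.nn_cache <- new.env(parent = emptyenv())

.cache_get <- function(key, make) {
  if (is.null(.nn_cache[[key]])) .nn_cache[[key]] <- make()
  .nn_cache[[key]]
}

.offsets3 <- cbind(dy = rep(-1:1, times = 3), dx = rep(-1:1, each = 3))

# Per tap k: the flat shift s, and the border-correction column sets:
# `out` = output pixels whose shifted source lies inside the flat array but
# outside the image (they receive a spurious contribution), `src` = those
# sources (out + s).
conv3_taps <- function(r, B) {
  key <- sprintf("tap:%d:%d", r, B)
  .cache_get(key, function() {
    n <- B * r * r
    i <- rep(seq_len(r), times = r)
    j <- rep(seq_len(r), each = r)
    off <- (seq_len(B) - 1L) * r * r
    lapply(1:9, function(k) {
      dy <- .offsets3[k, 1]; dx <- .offsets3[k, 2]
      s <- dy + dx * r
      bad <- which(i + dy < 1L | i + dy > r | j + dx < 1L | j + dx > r)
      out <- as.integer(rep(bad, B) + rep(off, each = length(bad)))
      keepq <- out + s >= 1L & out + s <= n
      out <- out[keepq]
      list(s = as.integer(s), out = out, src = out + s)
    })
  })
}

# shared core: Y[, p] = b + sum_k (Wl[[k]] %*% X)[, p + s_k] over in-image
# sources.  Used forward (Wl[[k]] = t(W[k,,])) and for the input gradient
# (flipped taps, untransposed weights).
.conv3_core <- function(X, Wl, b, B, r, taps) {
  n <- ncol(X)
  cout <- nrow(Wl[[1]])
  Y <- matrix(b, cout, n)
  for (k in 1:9) {
    Zk <- Wl[[k]] %*% X
    s <- taps[[k]]$s
    if (s > 0) {
      Y[, 1:(n - s)] <- Y[, 1:(n - s)] + Zk[, (1 + s):n]
    } else if (s < 0) {
      Y[, (1 - s):n] <- Y[, (1 - s):n] + Zk[, 1:(n + s)]
    } else {
      Y <- Y + Zk
    }
    tk <- taps[[k]]
    if (length(tk$out)) Y[, tk$out] <- Y[, tk$out] - Zk[, tk$src]
  }
  Y
}

# 3x3 convolution; W is an array [9, Cin, Cout], b a length-Cout vector.
conv3_fwd <- function(X, W, b, B, r) {
  cin <- dim(W)[2]; cout <- dim(W)[3]
  Wl <- lapply(1:9, function(k) t(matrix(W[k, , ], cin, cout)))
  .conv3_core(X, Wl, b, B, r, conv3_taps(r, B))
}

# Backward pass; needs the forward input X for parameter gradients.
conv3_bwd <- function(dY, X, W, B, r, wrt_params = TRUE, wrt_input = TRUE) {
  cin <- dim(W)[2]; cout <- dim(W)[3]
  n <- ncol(dY)
  taps <- conv3_taps(r, B)
  dW <- NULL; db <- NULL; dX <- NULL
  if (wrt_params) {
    dW <- array(0, dim(W))
    for (k in 1:9) {
      s <- taps[[k]]$s
      T <- matrix(0, cout, n)
      if (s > 0) T[, (1 + s):n] <- dY[, 1:(n - s)]
      else if (s < 0) T[, 1:(n + s)] <- dY[, (1 - s):n]
      else T <- dY
      tk <- taps[[k]]
      if (length(tk$src)) T[, tk$src] <- 0
      dW[k, , ] <- tcrossprod(X, T)
    }
    db <- rowSums(dY)
  }
  if (wrt_input) {
    # transposed conv == conv with flipped taps and untransposed weights
    Wl <- lapply(1:9, function(k) matrix(W[10 - k, , ], cin, cout))
    dX <- .conv3_core(dY, Wl, 0, B, r, taps)
  }
  list(dX = dX, dW = dW, db = db)
}

leaky_fwd <- function(Z, alpha = 0.2) {
  pmax(Z, 0) + alpha * pmin(Z, 0)
}

leaky_bwd <- function(dY, Z, alpha = 0.2) {
  dY * (alpha + (1 - alpha) * (Z > 0))
}

# 2x2 average pooling: four disjoint column-index vectors into the input at
# resolution r (also the children sets for upsampling backward).
pool2_index <- function(r, B) {
  key <- sprintf("pl:%d:%d", r, B)
  .cache_get(key, function() {
    h <- r %/% 2L
    i <- rep(seq_len(h), times = h)
    j <- rep(seq_len(h), each = h)
    p11 <- (2L * i - 1L) + (2L * j - 2L) * r
    p21 <- (2L * i) + (2L * j - 2L) * r
    p12 <- (2L * i - 1L) + (2L * j - 1L) * r
    p22 <- (2L * i) + (2L * j - 1L) * r
    off <- rep((seq_len(B) - 1L) * r * r, each = h * h)
    lapply(list(p11, p21, p12, p22), function(p) as.integer(rep(p, B) + off))
  })
}

pool2_fwd <- function(X, B, r) {
  ix <- pool2_index(r, B)
  (X[, ix[[1]], drop = FALSE] + X[, ix[[2]], drop = FALSE] +
     X[, ix[[3]], drop = FALSE] + X[, ix[[4]], drop = FALSE]) / 4
}

pool2_bwd <- function(dY, B, r) {
  ix <- pool2_index(r, B)
  dX <- matrix(0, nrow(dY), B * r * r)
  q <- dY / 4
  dX[, ix[[1]]] <- q; dX[, ix[[2]]] <- q; dX[, ix[[3]]] <- q; dX[, ix[[4]]] <- q
  dX
}

# Nearest-neighbour 2x upsampling r -> 2r.
up2_index <- function(r, B) {
  key <- sprintf("up:%d:%d", r, B)
  .cache_get(key, function() {
    R <- 2L * r
    i <- rep(seq_len(R), times = R)
    j <- rep(seq_len(R), each = R)
    src <- ((i + 1L) %/% 2L) + (((j + 1L) %/% 2L) - 1L) * r
    off <- rep((seq_len(B) - 1L) * r * r, each = R * R)
    as.integer(rep(src, B) + off)
  })
}

up2_fwd <- function(X, B, r) X[, up2_index(r, B), drop = FALSE]

up2_bwd <- function(dY, B, r) {
  # each source pixel has exactly the four children pool2_index(2r) lists
  ix <- pool2_index(2L * r, B)
  dY[, ix[[1]], drop = FALSE] + dY[, ix[[2]], drop = FALSE] +
    dY[, ix[[3]], drop = FALSE] + dY[, ix[[4]], drop = FALSE]
}

batch_col_index <- function(r, B) {
  key <- sprintf("bi:%d:%d", r, B)
  .cache_get(key, function() rep(seq_len(B), each = r * r))
}

# per-image row sums: (C x B*npx) -> (C x B)
rowsum_by_image <- function(X, B, npx) {
  out <- matrix(0, nrow(X), B)
  for (b in seq_len(B))
    out[, b] <- rowSums(X[, ((b - 1) * npx + 1):(b * npx), drop = FALSE])
  out
}

# Flatten a (C x B*16) 4x4 feature map into (B x 16*C) (channel-fastest)
# and back.
flatten4_fwd <- function(X, B) {
  C <- nrow(X)
  t(matrix(X, 16L * C, B))
}

flatten4_bwd <- function(dF, B, C) {
  matrix(t(dF), C, 16L * B)
}

# ---- generic parameter-tree arithmetic (for Adam) ----

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    stopifnot(is.list(y), length(x) == length(y))
    out <- mapply(function(a, b) tree_map2(f, a, b), x, y, SIMPLIFY = FALSE)
    names(out) <- names(x)
    out
  } else f(x, y)
}

tree_zeros <- function(x) tree_map(function(e) e * 0, x)

# rebuild a parameter tree from a flat vector (inverse of unlist on
# numeric-leaf trees)
tree_unflatten <- function(skeleton, vec) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(out) <- attributes(x)
    out
  }
  walk(skeleton)
}

# Adam runs fully vectorized over the flattened parameter vector.
adam_init <- function(params) {
  n <- length(unlist(params, use.names = FALSE))
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0, beta2 = 0.99, eps = 1e-8) {
  p <- unlist(params, use.names = FALSE)
  g <- unlist(grads, use.names = FALSE)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  p <- p - lr * mh / (sqrt(vh) + eps)
  list(params = tree_unflatten(params, p), state = state)
}
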