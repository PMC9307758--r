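#' Backbone configuration for the style-based generator/encoder/discriminator
#'
#' The architecture is scale-configurable.  At full scale (512 x 512) the
#' synthesis network has 16 style layers of 512 dimensions each, i.e. an
#' 8192-dimensional extended latent code (one style vector per layer, the
#' W+ convention).  At reduced "desk" scale the layer count shrinks with the
#' resolution and the code size becomes `n_layers * style_dim`.
#'
#' @param resolution output resolution in pixels (power of two, >= 8).
#' @param style_dim dimension of each per-layer style vector. Default 512 at
#'   full scale (>= 512 px), 16 otherwise.
#' @param channels integer vector of channel counts per synthesis level
#'   (level 1 is the 4x4 base). Defaults scale with resolution.
#' @param d_fc_dim width of the discriminator's penultimate dense layer.
#' @param hu_window two HU values; images are clipped to this window and
#'   affinely mapped to \eqn{[-1, 1]} before entering the networks, and
#'   mapped back on output. Masks and thresholds are always applied in HU.
#' @param percep_resolution working resolution for the perceptual distance:
#'   images are downsampled to it before feature comparison.  Defaults to
#'   half the image resolution (256 at full 512-px scale).
#' @param point_levels number of top (highest-resolution) levels whose
#'   convolutions are pointwise (1x1) instead of 3x3 -- a desk-scale CPU
#'   economy (spatial detail there comes from upsampling and the noise
#'   maps).  Default 1 for resolutions up to 64, otherwise 0.
#' @return a list of class `backbone_config`.
#' @export
backbone_config <- function(resolution = 64, style_dim = NULL, channels = NULL,
                            d_fc_dim = 64, hu_window = c(-20, 120),
                            percep_resolution = NULL, point_levels = NULL) {
  if (length(resolution) != 1 || resolution < 8 ||
      abs(log2(resolution) - round(log2(resolution))) > 1e-9)
    stop("`resolution` must be a power of two >= 8", call. = FALSE)
  n_levels <- as.integer(log2(resolution) - 1)
  if (is.null(style_dim)) style_dim <- if (resolution >= 512) 512L else 16L
  if (is.null(channels)) {
    channels <- if (resolution >= 128) {
      pmin(512L, as.integer(2^(12 - seq_len(n_levels))))
    } else {
      pmax(2L, as.integer(2^(6 - seq_len(n_levels))))
    }
  }
  if (length(channels) != n_levels)
    stop("`channels` must have one entry per synthesis level (", n_levels, ")",
         call. = FALSE)
  if (length(hu_window) != 2 || hu_window[1] >= hu_window[2])
    stop("`hu_window` must be c(lo, hi) with lo < hi", call. = FALSE)
  if (is.null(percep_resolution)) percep_resolution <- max(8L, resolution %/% 2L)
  if (is.null(point_levels))
    point_levels <- if (resolution <= 64) min(2L, n_levels - 1L) else 0L
  structure(list(
    resolution = as.integer(resolution),
    n_levels = n_levels,
    n_layers = 2L * n_levels,
    style_dim = as.integer(style_dim),
    code_dim = 2L * n_levels * as.integer(style_dim),
    channels = as.integer(channels),
    d_fc_dim = as.integer(d_fc_dim),
    hu_window = as.numeric(hu_window),
    percep_resolution = as.integer(percep_resolution),
    point_levels = as.integer(point_levels)
  ), class = "backbone_config")
}

level_resolution <- function(cfg, v) as.integer(4 * 2^(v - 1))
layer_level <- function(l) as.integer(ceiling(l / 2))

#' @export
print.backbone_config <- function(x, ...) {
  cat("<backbone_config> ", x$resolution, "x", x$resolution,
      ", ", x$n_layers, " style layers x ", x$style_dim,
      " dims (code ", x$code_dim, "), channels ",
      paste(x$channels, collapse = "/"), "\n", sep = "")
  invisible(x)
}

# ---- HU <-> network-unit mapping -------------------------------------------

hu_to_unit <- function(x, cfg) {
  lo <- cfg$hu_window[1]; hi <- cfg$hu_window[2]
  2 * (pmin(pmax(x, lo), hi) - lo) / (hi - lo) - 1
}

unit_to_hu <- function(z, cfg) {
  lo <- cfg$hu_window[1]; hi <- cfg$hu_window[2]
  (z + 1) / 2 * (hi - lo) + lo
}

# ---- parameter initialization ----------------------------------------------

.rnorm_mat <- function(n, m, sd) matrix(stats::rnorm(n * m, sd = sd), n, m)

.init_conv <- function(cin, cout, zero = FALSE) {
  sd <- if (zero) 0 else sqrt(2 / (9 * cin))
  array(stats::rnorm(9 * cin * cout, sd = sd), dim = c(9, cin, cout))
}

# pointwise (1x1) convolution weights are stored as a plain cin x cout matrix
.init_conv1 <- function(cin, cout, zero = FALSE) {
  sd <- if (zero) 0 else sqrt(2 / cin)
  matrix(stats::rnorm(cin * cout, sd = sd), cin, cout)
}

conv_any_fwd <- function(X, W, b, B, r) {
  if (is.matrix(W)) crossprod(W, X) + b else conv3_fwd(X, W, b, B, r)
}

conv_any_bwd <- function(dY, X, W, B, r, wrt_params = TRUE, wrt_input = TRUE) {
  if (is.matrix(W)) {
    list(dX = if (wrt_input) W %*% dY else NULL,
         dW = if (wrt_params) tcrossprod(X, dY) else NULL,
         db = if (wrt_params) rowSums(dY) else NULL)
  } else conv3_bwd(dY, X, W, B, r, wrt_params = wrt_params,
                   wrt_input = wrt_input)
}

#' Initialize backbone weights
#'
#' @param cfg a [backbone_config()].
#' @param seed integer seed; initialization is deterministic given the seed.
#' @param init `"random"` (default) or `"zero"` (architecture sanity checks:
#'   a zero generator emits a constant image).
#' @return a model list with components `cfg`, `G`, `E`, `D`.
#' @export
init_backbone <- function(cfg, seed = 1L, init = c("random", "zero")) {
  init <- match.arg(init)
  zero <- init == "zero"
  set.seed(as.integer(seed))
  V <- cfg$n_levels; ch <- cfg$channels; d <- cfg$style_dim

  g_levels <- vector("list", V)
  for (v in seq_len(V)) {
    cin1 <- if (v == 1) ch[1] else ch[v - 1]
    pointwise <- v > V - cfg$point_levels
    mk_layer <- function(cin, cout) list(
      A = if (zero) matrix(0, cin, d) else .rnorm_mat(cin, d, 0.2 / sqrt(d)),
      W = if (pointwise) .init_conv1(cin, cout, zero) else .init_conv(cin, cout, zero),
      b = numeric(cout),
      sigma = rep(if (zero) 0 else 0.1, cout)
    )
    g_levels[[v]] <- list(mk_layer(cin1, ch[v]), mk_layer(ch[v], ch[v]))
  }
  G <- list(
    const = if (zero) matrix(0, ch[1], 16) else .rnorm_mat(ch[1], 16, 1),
    levels = g_levels,
    rgbW = if (zero) matrix(0, ch[V], 1) else .rnorm_mat(ch[V], 1, sqrt(1 / ch[V])),
    rgbb = 0
  )

  mk_trunk <- function() {
    # one conv per resolution level: ch[V-i+1] -> ch[V-i], leaky, 2x pool
    blocks <- vector("list", V)
    for (i in seq_len(V - 1)) {
      c_here <- ch[V - i + 1]; c_next <- ch[V - i]
      pointwise <- i <= cfg$point_levels
      blocks[[i]] <- list(W1 = if (pointwise) .init_conv1(c_here, c_next, zero)
                          else .init_conv(c_here, c_next, zero),
                          b1 = numeric(c_next))
    }
    blocks[[V]] <- list(W1 = .init_conv(ch[1], ch[1], zero), b1 = numeric(ch[1]))
    list(rgbW = if (zero) matrix(0, ch[V], 1) else .rnorm_mat(ch[V], 1, 1),
         rgbb = numeric(ch[V]), blocks = blocks)
  }

  E <- mk_trunk()
  E$fcW <- if (zero) matrix(0, 16 * ch[1], cfg$code_dim) else
    .rnorm_mat(16 * ch[1], cfg$code_dim, sqrt(2 / (16 * ch[1])))
  E$fcb <- numeric(cfg$code_dim)

  D <- mk_trunk()
  D$fc1W <- if (zero) matrix(0, 16 * ch[1], cfg$d_fc_dim) else
    .rnorm_mat(16 * ch[1], cfg$d_fc_dim, sqrt(2 / (16 * ch[1])))
  D$fc1b <- numeric(cfg$d_fc_dim)
  D$fc2W <- if (zero) matrix(0, cfg$d_fc_dim, 1) else
    .rnorm_mat(cfg$d_fc_dim, 1, sqrt(1 / cfg$d_fc_dim))
  D$fc2b <- 0

  structure(list(cfg = cfg, G = G, E = E, D = D), class = "ct_backbone")
}

#' @export
print.ct_backbone <- function(x, ...) {
  cat("<ct_backbone> ")
  print(x$cfg)
  invisible(x)
}

# ---- latent code and noise helpers -----------------------------------------

# internal batched code: list of L (B x d) matrices
w_to_list <- function(w, cfg) {
  if (is.list(w)) return(w)
  stopifnot(is.matrix(w))
  if (!all(dim(w) == c(cfg$n_layers, cfg$style_dim)))
    stop("latent code must be ", cfg$n_layers, " x ", cfg$style_dim, call. = FALSE)
  lapply(seq_len(cfg$n_layers), function(l) matrix(w[l, ], 1, cfg$style_dim))
}

w_from_codes <- function(codes, cfg, b = 1) {
  # codes: list of L (B x d) -> single L x d matrix for image b
  do.call(rbind, lapply(codes, function(m) m[b, ]))
}

#' Sample per-layer spatial noise maps
#'
#' One standard-normal noise map per synthesis layer, at that layer's
#' resolution.
#'
#' @param model_or_cfg a backbone model or config.
#' @param n_images batch size.
#' @param seed optional seed.
#' @return list with one numeric vector per layer (length `n_images * r_l^2`).
#' @export
sample_noise_maps <- function(model_or_cfg, n_images = 1, seed = NULL) {
  cfg <- if (inherits(model_or_cfg, "backbone_config")) model_or_cfg else model_or_cfg$cfg
  if (!is.null(seed)) set.seed(as.integer(seed))
  lapply(seq_len(cfg$n_layers), function(l) {
    r <- level_resolution(cfg, layer_level(l))
    stats::rnorm(n_images * r * r)
  })
}

zero_noise_maps <- function(cfg, n_images = 1) {
  lapply(seq_len(cfg$n_layers), function(l) {
    r <- level_resolution(cfg, layer_level(l))
    numeric(n_images * r * r)
  })
}

check_noise <- function(noise, cfg, B) {
  if (length(noise) != cfg$n_layers)
    stop("noise maps must have one entry per synthesis layer", call. = FALSE)
  for (l in seq_along(noise)) {
    r <- level_resolution(cfg, layer_level(l))
    if (length(noise[[l]]) != B * r * r)
      stop("noise map ", l, " has length ", length(noise[[l]]),
           ", expected ", B * r * r, call. = FALSE)
  }
  invisible(TRUE)
}

# ---- generator forward / backward ------------------------------------------

g_forward <- function(model, codes, noise, B, keep = FALSE) {
  cfg <- model$cfg; G <- model$G; V <- cfg$n_levels
  cache <- if (keep) list(layers = vector("list", cfg$n_layers)) else NULL
  X <- G$const[, rep(seq_len(16L), B), drop = FALSE]
  l <- 0L
  for (v in seq_len(V)) {
    r <- level_resolution(cfg, v)
    if (v > 1) X <- up2_fwd(X, B, r %/% 2L)
    for (j in 1:2) {
      l <- l + 1L
      lay <- G$levels[[v]][[j]]
      s <- 1 + codes[[l]] %*% t(lay$A)                    # B x cin
      Sf <- t(s)[, batch_col_index(r, B), drop = FALSE]   # cin x n
      Xm <- X * Sf
      Z <- conv_any_fwd(Xm, lay$W, lay$b, B, r)
      nv <- noise[[l]]
      Z <- Z + outer(lay$sigma, nv)
      Y <- leaky_fwd(Z)
      if (keep) cache$layers[[l]] <- list(X = X, s = s, Xm = Xm, Z = Z, nv = nv)
      X <- Y
    }
  }
  img <- crossprod(G$rgbW, X) + G$rgbb                    # 1 x n
  if (keep) { cache$Xtop <- X; cache$codes <- codes }
  list(img = img, cache = cache)
}

g_backward <- function(model, cache, dimg, B,
                       wrt_params = TRUE, wrt_w = FALSE, wrt_noise = FALSE) {
  cfg <- model$cfg; G <- model$G; V <- cfg$n_levels
  dG <- if (wrt_params) tree_zeros(G) else NULL
  dw <- if (wrt_w) vector("list", cfg$n_layers) else NULL
  dnoise <- if (wrt_noise) vector("list", cfg$n_layers) else NULL

  if (wrt_params) {
    dG$rgbW <- tcrossprod(cache$Xtop, dimg)
    dG$rgbb <- sum(dimg)
  }
  dX <- G$rgbW %*% dimg                                   # cV x n
  l <- cfg$n_layers
  for (v in rev(seq_len(V))) {
    r <- level_resolution(cfg, v)
    for (j in 2:1) {
      cl <- cache$layers[[l]]
      lay <- G$levels[[v]][[j]]
      dZ <- leaky_bwd(dX, cl$Z)
      if (wrt_params) dG$levels[[v]][[j]]$sigma <- as.vector(dZ %*% cl$nv)
      if (wrt_noise) dnoise[[l]] <- as.vector(crossprod(lay$sigma, dZ))
      cb <- conv_any_bwd(dZ, cl$Xm, lay$W, B, r, wrt_params = wrt_params)
      if (wrt_params) {
        dG$levels[[v]][[j]]$W <- cb$dW
        dG$levels[[v]][[j]]$b <- cb$db
      }
      dXm <- cb$dX
      ds <- t(rowsum_by_image(dXm * cl$X, B, r * r))       # B x cin
      if (wrt_params) dG$levels[[v]][[j]]$A <- crossprod(ds, cache$codes[[l]])
      if (wrt_w) dw[[l]] <- ds %*% lay$A
      Sf <- t(cl$s)[, batch_col_index(r, B), drop = FALSE]
      dX <- dXm * Sf
      l <- l - 1L
    }
    if (v > 1) dX <- up2_bwd(dX, B, r %/% 2L)
  }
  if (wrt_params)
    dG$const <- rowSums(array(dX, c(nrow(dX), 16L, B)), dims = 2)
  list(dG = dG, dw = dw, dnoise = dnoise)
}

# ---- shared encoder/discriminator trunk ------------------------------------

trunk_forward <- function(T, X0, B, cfg, keep = FALSE) {
  V <- cfg$n_levels
  cache <- if (keep) list(blocks = vector("list", V)) else NULL
  Z0 <- T$rgbW %*% X0 + T$rgbb                            # cV x n
  X <- leaky_fwd(Z0)
  if (keep) { cache$X0 <- X0; cache$Z0 <- Z0 }
  r <- cfg$resolution
  for (i in seq_len(V - 1)) {
    blk <- T$blocks[[i]]
    Z1 <- conv_any_fwd(X, blk$W1, blk$b1, B, r)
    A1 <- leaky_fwd(Z1)
    P <- pool2_fwd(A1, B, r)
    if (keep) cache$blocks[[i]] <- list(Xin = X, Z1 = Z1, r = r)
    X <- P
    r <- r %/% 2L
  }
  blk <- T$blocks[[V]]
  Z1 <- conv3_fwd(X, blk$W1, blk$b1, B, 4L)
  A1 <- leaky_fwd(Z1)
  if (keep) cache$blocks[[V]] <- list(Xin = X, Z1 = Z1, r = 4L)
  F <- flatten4_fwd(A1, B)
  if (keep) cache$Ftop <- F
  list(F = F, cache = cache)
}

# Backward through the trunk.  For the linearized (tangent) pass used by
# R1, activations come from `cache` while the leaky masks come from
# `mask_cache` (defaults to `cache` itself).
trunk_backward <- function(T, cache, dF, B, cfg, wrt_params = TRUE,
                           mask_cache = NULL) {
  if (is.null(mask_cache)) mask_cache <- cache
  V <- cfg$n_levels
  dT <- if (wrt_params) tree_zeros(T) else NULL
  blk <- T$blocks[[V]]
  dA1 <- flatten4_bwd(dF, B, nrow(cache$blocks[[V]]$Z1))
  dZ1 <- leaky_bwd(dA1, mask_cache$blocks[[V]]$Z1)
  cb <- conv3_bwd(dZ1, cache$blocks[[V]]$Xin, blk$W1, B, 4L,
                  wrt_params = wrt_params)
  if (wrt_params) { dT$blocks[[V]]$W1 <- cb$dW; dT$blocks[[V]]$b1 <- cb$db }
  dX <- cb$dX
  r <- 4L
  for (i in rev(seq_len(V - 1))) {
    r <- 2L * r
    blk <- T$blocks[[i]]
    cl <- cache$blocks[[i]]; ml <- mask_cache$blocks[[i]]
    dA1 <- pool2_bwd(dX, B, r)
    dZ1 <- leaky_bwd(dA1, ml$Z1)
    cb1 <- conv_any_bwd(dZ1, cl$Xin, blk$W1, B, r, wrt_params = wrt_params)
    if (wrt_params) { dT$blocks[[i]]$W1 <- cb1$dW; dT$blocks[[i]]$b1 <- cb1$db }
    dX <- cb1$dX
  }
  dZ0 <- leaky_bwd(dX, mask_cache$Z0)
  if (wrt_params) {
    dT$rgbW <- tcrossprod(dZ0, cache$X0)
    dT$rgbb <- rowSums(dZ0)
  }
  dX0 <- crossprod(T$rgbW, dZ0)
  list(dT = dT, dX0 = dX0)
}

# Linearized trunk forward (for R1 double-backward): propagates a tangent
# through the network using the primal leaky masks.
trunk_tangent_forward <- function(T, T0, B, cfg, mask_cache) {
  V <- cfg$n_levels
  cache <- list(blocks = vector("list", V))
  mask_mult <- function(TT, Z) TT * (0.2 + 0.8 * (Z > 0))
  Z0 <- T$rgbW %*% T0
  X <- mask_mult(Z0, mask_cache$Z0)
  cache$X0 <- T0; cache$Z0 <- mask_cache$Z0
  r <- cfg$resolution
  for (i in seq_len(V - 1)) {
    blk <- T$blocks[[i]]
    Z1 <- conv_any_fwd(X, blk$W1, numeric(length(blk$b1)), B, r)
    A1 <- mask_mult(Z1, mask_cache$blocks[[i]]$Z1)
    P <- pool2_fwd(A1, B, r)
    cache$blocks[[i]] <- list(Xin = X, Z1 = mask_cache$blocks[[i]]$Z1, r = r)
    X <- P
    r <- r %/% 2L
  }
  blk <- T$blocks[[V]]
  Z1 <- conv3_fwd(X, blk$W1, numeric(length(blk$b1)), B, 4L)
  A1 <- mask_mult(Z1, mask_cache$blocks[[V]]$Z1)
  cache$blocks[[V]] <- list(Xin = X, Z1 = mask_cache$blocks[[V]]$Z1, r = 4L)
  F <- flatten4_fwd(A1, B)
  cache$Ftop <- F
  list(F = F, cache = cache)
}

# ---- encoder ----------------------------------------------------------------

e_forward <- function(model, X0, B, keep = FALSE) {
  cfg <- model$cfg; E <- model$E
  tf <- trunk_forward(E, X0, B, cfg, keep)
  Zc <- tf$F %*% E$fcW + matrix(E$fcb, B, cfg$code_dim, byrow = TRUE)
  codes_flat <- leaky_fwd(Zc)
  codes <- lapply(seq_len(cfg$n_layers), function(l) {
    codes_flat[, ((l - 1) * cfg$style_dim + 1):(l * cfg$style_dim), drop = FALSE]
  })
  cache <- if (keep) list(trunk = tf$cache, Zc = Zc, F = tf$F) else NULL
  list(codes = codes, codes_flat = codes_flat, cache = cache)
}

e_backward <- function(model, cache, dcodes, B, wrt_params = TRUE, wrt_input = FALSE) {
  cfg <- model$cfg; E <- model$E
  dflat <- do.call(cbind, dcodes)
  dZc <- leaky_bwd(dflat, cache$Zc)
  dE <- NULL
  if (wrt_params) {
    dE_fcW <- crossprod(cache$F, dZc)
    dE_fcb <- colSums(dZc)
  }
  dF <- tcrossprod(dZc, E$fcW)
  tb <- trunk_backward(E, cache$trunk, dF, B, cfg, wrt_params = wrt_params)
  if (wrt_params) {
    dE <- tb$dT
    dE$fcW <- dE_fcW
    dE$fcb <- dE_fcb
  }
  list(dE = dE, dX0 = if (wrt_input) tb$dX0 else NULL)
}

# ---- discriminator ----------------------------------------------------------

d_forward <- function(model, X0, B, keep = FALSE) {
  cfg <- model$cfg; D <- model$D
  tf <- trunk_forward(D, X0, B, cfg, keep)
  Z1 <- tf$F %*% D$fc1W + matrix(D$fc1b, B, cfg$d_fc_dim, byrow = TRUE)
  A1 <- leaky_fwd(Z1)
  score <- A1 %*% D$fc2W + D$fc2b
  cache <- if (keep) list(trunk = tf$cache, F = tf$F, Z1 = Z1, A1 = A1) else NULL
  list(score = score, cache = cache)
}

d_backward <- function(model, cache, dscore, B, wrt_params = TRUE, wrt_input = FALSE) {
  cfg <- model$cfg; D <- model$D
  dA1 <- tcrossprod(dscore, D$fc2W)
  dZ1 <- leaky_bwd(dA1, cache$Z1)
  dD <- NULL
  if (wrt_params) {
    dD_fc2W <- crossprod(cache$A1, dscore)
    dD_fc2b <- sum(dscore)
    dD_fc1W <- crossprod(cache$F, dZ1)
    dD_fc1b <- colSums(dZ1)
  }
  dF <- tcrossprod(dZ1, D$fc1W)
  tb <- trunk_backward(D, cache$trunk, dF, B, cfg, wrt_params = wrt_params)
  if (wrt_params) {
    dD <- tb$dT
    dD$fc1W <- dD_fc1W; dD$fc1b <- dD_fc1b
    dD$fc2W <- dD_fc2W; dD$fc2b <- dD_fc2b
  }
  list(dD = dD, dX0 = if (wrt_input) tb$dX0 else NULL)
}

# gradient of sum(D(x)) w.r.t. the input image batch; returns 1 x n
d_input_grad <- function(model, cache, B) {
  d_backward(model, cache,
             dscore = matrix(1, B, 1), B,
             wrt_params = FALSE, wrt_input = TRUE)$dX0
}

# R1 penalty value and its exact parameter gradient (the network is piecewise
# linear, so a tangent pass through the local linearization gives the exact
# double-backward almost everywhere).
r1_penalty <- function(model, cache, B, with_grads = TRUE) {
  cfg <- model$cfg; D <- model$D
  g <- d_input_grad(model, cache, B)             # 1 x n
  npx <- cfg$resolution^2
  value <- sum(g^2) / B
  if (!with_grads) return(list(value = value, grads = NULL))
  # tangent pass with v = g through the linearized network
  tt <- trunk_tangent_forward(D, g, B, cfg, cache$trunk)
  Z1t <- tt$F %*% D$fc1W
  A1t <- Z1t * (0.2 + 0.8 * (cache$Z1 > 0))
  # s_b = g_b . g_b ; backprop d(sum(s)/B) with tangent activations
  ds <- matrix(1 / B, B, 1)
  dA1t <- tcrossprod(ds, D$fc2W)
  dZ1t <- leaky_bwd(dA1t, cache$Z1)
  dD <- tree_zeros(D)
  dD$fc2W <- crossprod(A1t, ds)
  dD$fc2b <- 0
  dD$fc1W <- crossprod(tt$F, dZ1t)
  dD$fc1b <- numeric(length(D$fc1b))
  dF <- tcrossprod(dZ1t, D$fc1W)
  tb <- trunk_backward(D, tt$cache, dF, B, cfg, wrt_params = TRUE,
                       mask_cache = cache$trunk)
  for (nm in c("rgbW", "rgbb", "blocks")) dD[[nm]] <- tb$dT[[nm]]
  # biases never enter the input gradient, so their R1 gradient is exactly 0
  dD$rgbb <- numeric(length(D$rgbb))
  for (i in seq_along(dD$blocks))
    dD$blocks[[i]]$b1 <- numeric(length(D$blocks[[i]]$b1))
  # d||g||^2 = 2 * d(g . g_bar) with g_bar held fixed
  dD <- tree_map(function(x) 2 * x, dD)
  list(value = value, grads = dD)
}

# ---- public single-image operations ----------------------------------------

#' Generate an image from a W+ latent code
#'
#' Runs the style-based synthesis network: a learned 4x4 constant is
#' progressively upsampled; each layer modulates channels with its style
#' vector, convolves, adds its spatial noise map and applies a leaky ReLU.
#'
#' @param model a backbone from [init_backbone()] or [train_backbone()].
#' @param w latent code, a `n_layers x style_dim` matrix.
#' @param noise list of per-layer noise vectors (see [sample_noise_maps()]),
#'   or `NULL` for all-zero noise.
#' @param units `"hu"` (default) to return Hounsfield units, `"unit"` for the
#'   network's internal \eqn{[-1, 1]} scale.
#' @return an `resolution x resolution` image matrix.
#' @export
generate_image <- function(model, w, noise = NULL, units = c("hu", "unit")) {
  units <- match.arg(units)
  cfg <- model$cfg
  codes <- w_to_list(w, cfg)
  if (is.null(noise)) noise <- zero_noise_maps(cfg, 1)
  check_noise(noise, cfg, 1)
  if (any(!vapply(codes, function(m) all(is.finite(m)), TRUE)))
    stop("latent code contains non-finite values", call. = FALSE)
  img <- g_forward(model, codes, noise, B = 1, keep = FALSE)$img
  m <- matrix(img[1, ], cfg$resolution, cfg$resolution)
  if (units == "hu") unit_to_hu(m, cfg) else m
}

#' Encode an image into a W+ latent code
#'
#' The encoder follows the discriminator architecture; its last dense layer
#' outputs the full `n_layers * style_dim` code, followed by a leaky ReLU
#' with slope 0.2.
#'
#' @param model a backbone model.
#' @param x an `resolution x resolution` image matrix.
#' @param units `"hu"` if `x` is in Hounsfield units (default), `"unit"` if
#'   already on the network scale.
#' @return a `n_layers x style_dim` latent-code matrix.
#' @export
encode_image <- function(model, x, units = c("hu", "unit")) {
  units <- match.arg(units)
  cfg <- model$cfg
  if (!is.matrix(x) || !all(dim(x) == cfg$resolution))
    stop("image must be ", cfg$resolution, " x ", cfg$resolution, call. = FALSE)
  z <- if (units == "hu") hu_to_unit(x, cfg) else x
  ef <- e_forward(model, matrix(as.vector(z), nrow = 1), B = 1, keep = FALSE)
  w_from_codes(ef$codes, cfg, 1)
}

# batched encode on unit-scale row-stacked images; returns codes list
encode_batch <- function(model, Z, B, keep = FALSE) {
  e_forward(model, Z, B, keep = keep)
}

#' Save / load a backbone checkpoint
#'
#' Checkpoints are single-file archives containing the weights, the
#' configuration and a config hash; reloading reproduces [generate_image()]
#' bit-exactly.
#'
#' @param model a backbone model.
#' @param path file path.
#' @return `load_checkpoint` returns the model; `save_checkpoint` the path,
#'   invisibly.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(model = model, hash = config_hash(model$cfg))
  atomic_save_rds(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no checkpoint at ", path, call. = FALSE)
  obj <- readRDS(path)
  if (!identical(obj$hash, config_hash(obj$model$cfg)))
    stop("checkpoint config hash mismatch", call. = FALSE)
  obj$model
}
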