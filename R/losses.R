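# Training losses: perceptual (feature-pyramid) distance, domain-guided
# consistency, non-saturating adversarial losses with scheduled R1, and
# random erasing.

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

# [1 4 6 4 1]/16 blur + stride-2 downsampling operator (r/2 x r), border
# weights accumulated at the clamped position.
down_op <- function(r) {
  key <- sprintf("dop:%d", r)
  .cache_get(key, function() {
    h <- r %/% 2L
    kern <- c(1, 4, 6, 4, 1) / 16
    D <- matrix(0, h, r)
    for (i in seq_len(h)) {
      for (k in -2:2) {
        j <- min(max(2L * i - 1L + k, 1L), r)
        D[i, j] <- D[i, j] + kern[k + 3]
      }
    }
    D
  })
}

blur_downsample <- function(m, r) {
  D <- down_op(r)
  D %*% m %*% t(D)
}

#' Perceptual distance between two images
#'
#' A deterministic multi-scale feature distance: both images are resampled
#' to a working resolution (blur + 2x decimation), then compared with mean
#' squared error across a Gaussian pyramid down to 4 x 4.  It is symmetric,
#' zero iff the inputs are identical, and differentiable, and serves as the
#' offline stand-in for a pretrained perceptual feature network.  At full
#' scale the working resolution is 256 px.
#'
#' @param x,y square image matrices with power-of-two side length.
#' @param work_resolution resolution the images are resampled to before
#'   feature comparison; defaults to the input resolution.
#' @return a non-negative scalar.
#' @export
perceptual_distance <- function(x, y, work_resolution = NULL) {
  if (!is.matrix(x) || !identical(dim(x), dim(y)))
    stop("`x` and `y` must be matrices of identical shape", call. = FALSE)
  r <- nrow(x)
  if (ncol(x) != r || abs(log2(r) - round(log2(r))) > 1e-9)
    stop("images must be square with power-of-two side", call. = FALSE)
  if (is.null(work_resolution)) work_resolution <- r
  if (work_resolution > r)
    stop("`work_resolution` cannot exceed the input resolution", call. = FALSE)
  while (r > work_resolution) {
    x <- blur_downsample(x, r); y <- blur_downsample(y, r)
    r <- r %/% 2L
  }
  d <- 0
  repeat {
    d <- d + mean((x - y)^2)
    if (r <= 4L) break
    x <- blur_downsample(x, r); y <- blur_downsample(y, r)
    r <- r %/% 2L
  }
  d
}

# Batched perceptual loss on unit-scale stacked columns, with gradient w.r.t.
# Y. Value is the mean over the batch of per-image pyramid distances.
percep_loss_grad <- function(X0, Y0, B, r, work_resolution) {
  xs <- lapply(seq_len(B), function(b) matrix(X0[1, ((b - 1) * r * r + 1):(b * r * r)], r, r))
  ys <- lapply(seq_len(B), function(b) matrix(Y0[1, ((b - 1) * r * r + 1):(b * r * r)], r, r))
  total <- 0
  per_image <- numeric(B)
  gys <- vector("list", B)
  for (b in seq_len(B)) {
    x <- xs[[b]]; y <- ys[[b]]; rr <- r
    pre <- list()  # resolutions traversed during resampling to work res
    while (rr > work_resolution) {
      pre[[length(pre) + 1]] <- rr
      x <- blur_downsample(x, rr); y <- blur_downsample(y, rr)
      rr <- rr %/% 2L
    }
    lv_x <- list(x); lv_y <- list(y); lv_r <- rr
    while (lv_r > 4L) {
      x <- blur_downsample(x, lv_r); y <- blur_downsample(y, lv_r)
      lv_r <- lv_r %/% 2L
      lv_x[[length(lv_x) + 1]] <- x; lv_y[[length(lv_y) + 1]] <- y
    }
    nl <- length(lv_x)
    g <- NULL
    for (li in rev(seq_len(nl))) {
      rl <- nrow(lv_x[[li]])
      gl <- 2 * (lv_y[[li]] - lv_x[[li]]) / (rl * rl) / B
      lvl_val <- mean((lv_x[[li]] - lv_y[[li]])^2)
      per_image[b] <- per_image[b] + lvl_val
      total <- total + lvl_val / B
      if (is.null(g)) g <- gl else {
        D <- down_op(rl)      # operator that produced the next-finer level
        g <- t(D) %*% g %*% D + gl
      }
    }
    # back through the initial resampling chain
    for (rr2 in rev(pre)) {
      D <- down_op(rr2)
      g <- t(D) %*% g %*% D
    }
    gys[[b]] <- g
  }
  dY <- matrix(unlist(gys), nrow = 1)
  list(value = total, dY = dY, per_image = per_image)
}

#' Domain-guided consistency loss
#'
#' The L1 distance between `encode(x)` and `encode(synthesize(encode(x)))`:
#' small when the encoder maps an image into a region of latent space whose
#' reconstruction re-encodes to the same code (the in-domain property).
#'
#' @param x an image (passed to `encode`).
#' @param encode function mapping an image to a numeric code.
#' @param synthesize function mapping a code back to an image.
#' @return mean absolute difference between the two codes.
#' @export
domain_guided_loss <- function(x, encode, synthesize) {
  c1 <- encode(x)
  c2 <- encode(synthesize(c1))
  mean(abs(as.numeric(c1) - as.numeric(c2)))
}

#' Non-saturating adversarial losses with scheduled R1 penalty
#'
#' Computes the generator loss `mean(softplus(-D(fake)))`, the discriminator
#' loss `mean(softplus(D(fake))) + mean(softplus(-D(real)))`, and the R1
#' gradient penalty on real images, which is included (non-zero) only on
#' every 16th step (`step_index %% r1_interval == 0`).
#'
#' @param real,fake lists of image matrices (the two batches).
#' @param step_index integer training step.
#' @param model a backbone model (its discriminator is used).
#' @param r1_interval R1 schedule period (default 16).
#' @param units `"hu"` or `"unit"` for the input scale.
#' @return list with `g_loss`, `d_loss`, `r1_term`.
#' @export
adversarial_step_losses <- function(real, fake, step_index, model,
                                    r1_interval = 16L, units = c("hu", "unit")) {
  units <- match.arg(units)
  if (length(real) < 1 || length(fake) < 1)
    stop("`real` and `fake` batches must be non-empty", call. = FALSE)
  cfg <- model$cfg
  stack <- function(lst) {
    z <- lapply(lst, function(m) {
      if (!is.matrix(m) || !all(dim(m) == cfg$resolution))
        stop("images must be ", cfg$resolution, " x ", cfg$resolution, call. = FALSE)
      if (units == "hu") as.vector(hu_to_unit(m, cfg)) else as.vector(m)
    })
    matrix(unlist(z), nrow = 1)
  }
  Xr <- stack(real); Xf <- stack(fake)
  Br <- length(real); Bf <- length(fake)
  sr <- d_forward(model, Xr, Br, keep = step_index %% r1_interval == 0)
  sf <- d_forward(model, Xf, Bf, keep = FALSE)
  g_loss <- mean(softplus(-sf$score))
  d_loss <- mean(softplus(sf$score)) + mean(softplus(-sr$score))
  r1_term <- 0
  if (step_index %% r1_interval == 0)
    r1_term <- r1_penalty(model, sr$cache, Br, with_grads = FALSE)$value
  list(g_loss = g_loss, d_loss = d_loss, r1_term = r1_term)
}

# internal erase without touching the RNG seed
.erase_impl <- function(x, area_range, aspect_range, fill) {
  r <- nrow(x); cc <- ncol(x)
  for (i in 1:100) {
    frac <- stats::runif(1, area_range[1], area_range[2])
    asp <- exp(stats::runif(1, log(aspect_range[1]), log(aspect_range[2])))
    h <- round(sqrt(frac * r * cc * asp))
    w <- round(sqrt(frac * r * cc / asp))
    if (h < 1 || w < 1 || h > r || w > cc) next
    got <- (h * w) / (r * cc)
    if (got < area_range[1] * 0.8 || got > area_range[2] * 1.2) next
    i0 <- sample.int(r - h + 1L, 1L)
    j0 <- sample.int(cc - w + 1L, 1L)
    rect <- c(row0 = i0, row1 = i0 + h - 1L, col0 = j0, col1 = j0 + w - 1L)
    x[i0:(i0 + h - 1L), j0:(j0 + w - 1L)] <- if (is.null(fill)) mean(x) else fill
    attr(x, "erase_rect") <- rect
    return(x)
  }
  attr(x, "erase_rect") <- NULL
  x
}

#' Random erasing augmentation
#'
#' Replaces exactly one axis-aligned rectangle of the image with a fill
#' value, leaving every other pixel bit-identical; used during encoder
#' training so the encoder learns to fill in missing anatomy.  The chosen
#' rectangle is attached as attribute `"erase_rect"`.
#'
#' @param x image matrix.
#' @param seed integer seed (the draw is deterministic given it).
#' @param area_range erased-area fraction range (default 0.05--0.25).
#' @param aspect_range rectangle aspect-ratio range.
#' @param fill fill value; default the image mean.
#' @return the erased image with attribute `erase_rect`.
#' @export
random_erase <- function(x, seed, area_range = c(0.05, 0.25),
                         aspect_range = c(0.4, 2.5), fill = NULL) {
  stopifnot(area_range[1] > 0, area_range[2] < 1, area_range[1] <= area_range[2])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  .erase_impl(x, area_range, aspect_range, fill)
}
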