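# Shared fixtures.  Tiny (16 x 16) backbones keep unit tests fast; the
# desk-scale trained pipeline lives in helper-acceptance.R and is built
# lazily, once, by the acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- make()
  .fixture_env[[name]]
}

tiny_cfg <- function() backbone_config(resolution = 16)

tiny_model <- function() fixture("tiny_model", function()
  init_backbone(tiny_cfg(), seed = 42))

tiny_zero_model <- function() fixture("tiny_zero", function()
  init_backbone(tiny_cfg(), seed = 42, init = "zero"))

# latent-Gaussian statistics fitted from the tiny model's encodings of a
# few phantom slices (slice orders 1 and 32)
tiny_latent_stats <- function() fixture("tiny_stats", function() {
  m <- tiny_model()
  codes <- list()
  for (i in 1:6) {
    sc <- generate_normal_scan(300 + i, c(16, 16), 2)
    for (k in 1:2)
      codes[[length(codes) + 1]] <- list(order = sc$slice_orders[k],
                                         w = encode_image(m, sc$slices[[k]]))
  }
  fit_latent_gaussian(codes = codes)
})

# hand-built single-layer latent_gaussian for closed-form deviation checks
manual_latent_stats <- function(mu, sigma, order = 1L) {
  structure(list(
    orders = as.integer(order),
    layers = stats::setNames(list(list(list(mu = mu, sigma = sigma,
                                            inv = solve(sigma),
                                            eps = 0, n = 2L))),
                             as.character(order)),
    L = 1L, d = length(mu), shrinkage = 0,
    backbone_hash = NA_character_), class = "latent_gaussian")
}

# brute-force reference median filter (independent double-loop oracle)
oracle_median_filter <- function(m, window) {
  k <- (window - 1) / 2
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- c()
    for (di in -k:k) for (dj in -k:k) {
      ii <- i + di; jj <- j + dj
      vals <- c(vals, if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
        m[ii, jj] else 0)
    }
    out[i, j] <- stats::median(vals)
  }
  out
}
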