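# Gaussian model of the normal-scan latent codes, per slice order and per
# synthesis layer (block-diagonal across layers: the statistics are
# accumulated "for each layer", so no cross-layer covariance is kept).

#' Fit per-slice-order, per-layer latent Gaussians
#'
#' Encodes every slice of a normal cohort and accumulates the sample mean
#' and covariance of the codes, separately for each slice order and each
#' synthesis layer.  The covariance is shrunk by `eps * I` (with
#' `eps = shrinkage * trace(S)/d` by default) to guarantee positive
#' definiteness at small sample counts.
#'
#' @param model a trained backbone (used through its encoder), or `NULL`
#'   when `codes` are supplied directly.
#' @param scans list of normal [ct_scan()] objects.
#' @param codes optional precomputed codes: a list with one element per
#'   slice, each a list `(order, w)` with `w` an `L x d` matrix.  Overrides
#'   `model`/`scans`.
#' @param shrinkage relative ridge added to each covariance (default 1e-4).
#' @param cond_floor when forming the inverse, eigenvalues are floored at
#'   `cond_floor` times the layer's largest eigenvalue (default 1e-2),
#'   capping the condition number of the whitening transform.
#' @return object of class `latent_gaussian`: per slice order, per layer,
#'   `mu` (length d) and `sigma` (d x d), plus inverses for fast Mahalanobis
#'   evaluation.
#' @export
fit_latent_gaussian <- function(model = NULL, scans = NULL, codes = NULL,
                                shrinkage = 1e-4, cond_floor = 1e-2) {
  if (is.null(codes)) {
    stopifnot(!is.null(model), !is.null(scans))
    codes <- list()
    for (sc in scans) {
      for (k in seq_along(sc$slices)) {
        codes[[length(codes) + 1]] <- list(
          order = sc$slice_orders[k],
          w = encode_image(model, sc$slices[[k]]))
      }
    }
  }
  orders <- sort(unique(vapply(codes, function(x) as.integer(x$order), 1L)))
  L <- nrow(codes[[1]]$w); d <- ncol(codes[[1]]$w)
  # first pass: sample moments per (order, layer), and the global variance
  # scale of the code space
  by_order <- list()
  total_var <- 0; n_var <- 0L
  for (s in orders) {
    ws <- Filter(function(x) x$order == s, codes)
    n <- length(ws)
    if (n < 2)
      stop("slice order ", s, " has ", n, " sample(s); need at least 2",
           call. = FALSE)
    layers <- vector("list", L)
    for (l in seq_len(L)) {
      Wm <- do.call(rbind, lapply(ws, function(x) x$w[l, ]))
      mu <- colMeans(Wm)
      S <- stats::cov(Wm)
      eps <- shrinkage * max(sum(diag(S)) / d, 1e-12)
      S <- S + diag(eps, d)
      layers[[l]] <- list(mu = mu, sigma = S, n = n, eps = eps)
      total_var <- total_var + sum(diag(S)); n_var <- n_var + d
    }
    by_order[[as.character(s)]] <- layers
  }
  # second pass: inverses with eigenvalues floored at cond_floor times the
  # global mean variance.  Near-null sample directions (including wholly
  # collapsed encoder layers) are statistical artifacts at small n; an
  # uncapped condition number makes whitened (Mahalanobis) gradients
  # explode during inversion.
  lam_floor <- cond_floor * max(total_var / max(n_var, 1L), 1e-12)
  for (s in names(by_order)) {
    for (l in seq_len(L)) {
      S <- by_order[[s]][[l]]$sigma
      ev <- eigen(S, symmetric = TRUE)
      lam <- pmax(ev$values, lam_floor)
      by_order[[s]][[l]]$inv <- ev$vectors %*% (t(ev$vectors) / lam)
    }
  }
  structure(list(orders = orders, layers = by_order, L = L, d = d,
                 shrinkage = shrinkage, cond_floor = cond_floor,
                 backbone_hash = if (!is.null(model)) config_hash(model$cfg) else NA_character_),
            class = "latent_gaussian")
}

#' Mahalanobis deviation of a latent code from the normal distribution
#'
#' The whitened distance of `w` from the per-layer means, summed over
#' layers: `sum_l sqrt((w_l - mu_l)' Sigma_l^{-1} (w_l - mu_l))`.  Zero iff
#' `w` equals the mean in every layer.
#'
#' @param w an `L x d` latent-code matrix.
#' @param stats a [fit_latent_gaussian()] result.
#' @param slice_order slice order whose statistics to use.
#' @return non-negative scalar.
#' @export
gaussian_deviation <- function(w, stats, slice_order) {
  layers <- stats$layers[[as.character(as.integer(slice_order))]]
  if (is.null(layers))
    stop("slice order ", slice_order, " is not represented in the statistics",
         call. = FALSE)
  tot <- 0
  for (l in seq_len(stats$L)) {
    v <- w[l, ] - layers[[l]]$mu
    q <- drop(t(v) %*% layers[[l]]$inv %*% v)
    tot <- tot + sqrt(max(q, 0))
  }
  tot
}

# deviation + gradient w.r.t. w (for the in-domain inversion term)
gaussian_deviation_grad <- function(w, stats, slice_order) {
  layers <- stats$layers[[as.character(as.integer(slice_order))]]
  g <- matrix(0, nrow(w), ncol(w))
  tot <- 0
  for (l in seq_len(stats$L)) {
    v <- w[l, ] - layers[[l]]$mu
    iv <- layers[[l]]$inv %*% v
    q <- sqrt(max(drop(t(v) %*% iv), 1e-12))
    tot <- tot + q
    g[l, ] <- as.vector(iv) / q
  }
  list(value = tot, grad = g)
}
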