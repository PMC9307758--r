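#' Training configuration
#'
#' Two-phase training: phase 1 trains the generator and discriminator
#' adversarially; phase 2 freezes the generator and trains the encoder and
#' discriminator with perceptual, domain-guided and adversarial losses plus
#' random erasing.  Adam hyper-parameters default to `beta1 = 0`,
#' `beta2 = 0.99`, `eps = 1e-8`.  The phase-2 full-scale learning rates are
#' 1e-5 (encoder) and 1e-6 (discriminator) over 200k iterations; desk-scale
#' defaults are larger because only a few thousand steps are taken.
#'
#' @param iters_phase1,iters_phase2 iteration counts for the two phases.
#' @param batch_size minibatch size (full scale: 32).
#' @param lr_g,lr_d1 phase-1 learning rates (generator / discriminator).
#' @param lr_e,lr_d phase-2 learning rates (encoder / discriminator).
#' @param beta1,beta2,eps Adam moment parameters.
#' @param r1_interval apply the R1 penalty on every `r1_interval`-th step.
#' @param r1_weight R1 penalty weight (applied as `weight/2 * penalty`).
#' @param erase_prob probability a phase-2 image is randomly erased.
#' @param erase_area erased-area fraction range.
#' @param w_percep,w_domain,w_adv phase-2 loss weights.
#' @param seed global training seed.
#' @return list of class `train_config`.
#' @export
train_config <- function(iters_phase1 = 500L, iters_phase2 = 1500L,
                         batch_size = 4L,
                         lr_g = 2e-3, lr_d1 = 2e-3,
                         lr_e = 1e-3, lr_d = 5e-4,
                         beta1 = 0, beta2 = 0.99, eps = 1e-8,
                         r1_interval = 16L, r1_weight = 10,
                         erase_prob = 0.5, erase_area = c(0.05, 0.25),
                         w_percep = 1, w_domain = 1, w_adv = 0.1,
                         seed = 1L) {
  stopifnot(iters_phase1 >= 0, iters_phase2 >= 0, batch_size >= 1,
            lr_g > 0, lr_d1 > 0, lr_e > 0, lr_d > 0, r1_interval >= 1)
  structure(as.list(environment()), class = "train_config")
}

# stack a list of unit-scale slice matrices into a (B*r^2) x 1 column
stack_units <- function(lst) matrix(unlist(lapply(lst, as.vector)), nrow = 1)

#' Train the backbone on normal scans
#'
#' @param dataset a list of slice matrices in HU, or a list of `ct_scan`
#'   objects (their slices are pooled).
#' @param cfg a [backbone_config()].
#' @param config a [train_config()].
#' @param verbose print progress every 100 steps.
#' @return list with `model` (the trained backbone) and `log` (a data frame
#'   with one row per step and every loss term).
#' @export
train_backbone <- function(dataset, cfg = backbone_config(), config = train_config(),
                           verbose = FALSE) {
  slices <- if (length(dataset) && inherits(dataset[[1]], "ct_scan"))
    unlist(lapply(dataset, function(s) s$slices), recursive = FALSE) else dataset
  if (length(slices) == 0) stop("empty training dataset", call. = FALSE)
  r <- cfg$resolution
  if (!all(vapply(slices, function(m) is.matrix(m) && all(dim(m) == r), TRUE)))
    stop("all training slices must be ", r, " x ", r, call. = FALSE)

  set.seed(as.integer(config$seed))
  units <- lapply(slices, function(m) hu_to_unit(m, cfg))
  model <- init_backbone(cfg, seed = config$seed)
  B <- min(config$batch_size, length(units))
  L <- cfg$n_layers; d <- cfg$style_dim

  stateG <- adam_init(model$G)
  stateD <- adam_init(model$D)
  logs <- list()
  adam <- function(p, g, s, lr) adam_step(p, g, s, lr, config$beta1, config$beta2, config$eps)

  sample_batch <- function() {
    idx <- sample.int(length(units), B, replace = length(units) < B)
    stack_units(units[idx])
  }

  # ---- phase 1: adversarial training of G and D ----
  for (step in seq_len(config$iters_phase1)) {
    Xr <- sample_batch()
    codes <- lapply(seq_len(L), function(l) matrix(stats::rnorm(B * d), B, d))
    noise <- sample_noise_maps(cfg, B)
    gf <- g_forward(model, codes, noise, B, keep = TRUE)

    # discriminator update
    fr <- d_forward(model, Xr, B, keep = TRUE)
    ff <- d_forward(model, gf$img, B, keep = TRUE)
    d_loss <- mean(softplus(ff$score)) + mean(softplus(-fr$score))
    dD <- d_backward(model, ff$cache, sigmoid(ff$score) / B, B)$dD
    dDr <- d_backward(model, fr$cache, -sigmoid(-fr$score) / B, B)$dD
    dD <- tree_map2(`+`, dD, dDr)
    r1v <- 0
    if (step %% config$r1_interval == 0) {
      r1 <- r1_penalty(model, fr$cache, B)
      r1v <- r1$value
      dD <- tree_map2(function(a, b) a + config$r1_weight / 2 * b, dD, r1$grads)
    }
    up <- adam(model$D, dD, stateD, config$lr_d1); model$D <- up$params; stateD <- up$state

    # generator update (fresh D scores on the same fake batch)
    ff2 <- d_forward(model, gf$img, B, keep = TRUE)
    g_loss <- mean(softplus(-ff2$score))
    dimg <- d_backward(model, ff2$cache, -sigmoid(-ff2$score) / B, B,
                       wrt_params = FALSE, wrt_input = TRUE)$dX0
    dG <- g_backward(model, gf$cache, dimg, B)$dG
    up <- adam(model$G, dG, stateG, config$lr_g); model$G <- up$params; stateG <- up$state

    logs[[length(logs) + 1]] <- data.frame(
      phase = 1L, step = step, g_loss = g_loss, d_loss = d_loss, r1 = r1v,
      percep = NA_real_, domain = NA_real_, adv = NA_real_)
    if (verbose && step %% 100 == 0)
      message(sprintf("phase1 %d: g=%.3f d=%.3f", step, g_loss, d_loss))
  }

  # ---- phase 2: E and D trained, G frozen ----
  stateE <- adam_init(model$E)
  stateD <- adam_init(model$D)
  for (step in seq_len(config$iters_phase2)) {
    idx <- sample.int(length(units), B, replace = length(units) < B)
    xs <- units[idx]
    xe <- lapply(xs, function(m) {
      if (stats::runif(1) < config$erase_prob)
        .erase_impl(m, config$erase_area, c(0.4, 2.5), fill = mean(m)) else m
    })
    X <- stack_units(xs)
    Xe <- stack_units(lapply(xe, function(m) { attributes(m) <- list(dim = dim(m)); m }))

    ef <- e_forward(model, Xe, B, keep = TRUE)
    noise <- sample_noise_maps(cfg, B)
    gf <- g_forward(model, ef$codes, noise, B, keep = TRUE)
    ef2 <- e_forward(model, gf$img, B, keep = TRUE)

    # perceptual
    pl <- percep_loss_grad(X, gf$img, B, r, cfg$percep_resolution)
    # domain-guided: mean |E(x) - E(G(E(x)))|
    diff <- ef2$codes_flat - ef$codes_flat
    dg_loss <- mean(abs(diff))
    sgn <- sign(diff) / length(diff)
    # adversarial (E acts as generator through frozen G)
    df <- d_forward(model, gf$img, B, keep = TRUE)
    adv_loss <- mean(softplus(-df$score))
    dimg_adv <- d_backward(model, df$cache, -sigmoid(-df$score) / B, B,
                           wrt_params = FALSE, wrt_input = TRUE)$dX0

    # backprop into E: path through E(G(E(x)))
    dcodes2 <- lapply(seq_len(L), function(l)
      config$w_domain * sgn[, ((l - 1) * d + 1):(l * d), drop = FALSE])
    eb2 <- e_backward(model, ef2$cache, dcodes2, B, wrt_params = TRUE, wrt_input = TRUE)
    dimg_total <- config$w_percep * pl$dY + config$w_adv * dimg_adv + eb2$dX0
    dw <- g_backward(model, gf$cache, dimg_total, B,
                     wrt_params = FALSE, wrt_w = TRUE)$dw
    dcodes1 <- lapply(seq_len(L), function(l)
      dw[[l]] - config$w_domain * sgn[, ((l - 1) * d + 1):(l * d), drop = FALSE])
    eb1 <- e_backward(model, ef$cache, dcodes1, B, wrt_params = TRUE)
    dE <- tree_map2(`+`, eb1$dE, eb2$dE)
    up <- adam(model$E, dE, stateE, config$lr_e); model$E <- up$params; stateE <- up$state

    # discriminator update on real vs reconstructed (reuses the fake pass:
    # the E update above does not touch D)
    fr <- d_forward(model, X, B, keep = TRUE)
    d_loss <- mean(softplus(df$score)) + mean(softplus(-fr$score))
    dD <- d_backward(model, df$cache, sigmoid(df$score) / B, B)$dD
    dDr <- d_backward(model, fr$cache, -sigmoid(-fr$score) / B, B)$dD
    dD <- tree_map2(`+`, dD, dDr)
    r1v <- 0
    if (step %% config$r1_interval == 0) {
      r1 <- r1_penalty(model, fr$cache, B)
      r1v <- r1$value
      dD <- tree_map2(function(a, b) a + config$r1_weight / 2 * b, dD, r1$grads)
    }
    up <- adam(model$D, dD, stateD, config$lr_d); model$D <- up$params; stateD <- up$state

    logs[[length(logs) + 1]] <- data.frame(
      phase = 2L, step = step, g_loss = adv_loss, d_loss = d_loss, r1 = r1v,
      percep = pl$value, domain = dg_loss, adv = adv_loss)
    if (verbose && step %% 100 == 0)
      message(sprintf("phase2 %d: percep=%.4f dg=%.4f adv=%.3f d=%.3f",
                      step, pl$value, dg_loss, adv_loss, d_loss))
  }

  list(model = model, log = do.call(rbind, logs))
}
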