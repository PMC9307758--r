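# Anomaly scoring: masked per-slice reconstruction error, slice-order
# calibration on normal scans, and the scan-level anomaly score (the sum of
# slice-order z-normalized errors over the scan's up-to-32 slices).

#' Masked per-slice reconstruction error
#'
#' The binary-masked density error between a slice and its reconstruction,
#' `|| M * (x - recon) ||`, in HU.  The norm defaults to L1 (sum of absolute
#' masked differences); L2 is available by configuration.
#'
#' @param x,recon HU matrices of one shape.
#' @param M binary mask matrix.
#' @param norm `"l1"` (default) or `"l2"`.
#' @return non-negative scalar.
#' @export
slice_reconstruction_error <- function(x, recon, M, norm = c("l1", "l2")) {
  norm <- match.arg(norm)
  if (!identical(dim(x), dim(recon)) || !identical(dim(x), dim(M)))
    stop("`x`, `recon` and `M` must share a shape", call. = FALSE)
  d <- (M > 0) * (x - recon)
  if (norm == "l1") sum(abs(d)) else sqrt(sum(d * d))
}

#' Calibrate reconstruction-error statistics on normal scans
#'
#' Per slice order, the sample mean and SD of the raw masked errors over a
#' seeded random subset of `n_scans` calibration scans (the full-scale
#' procedure draws 1000 scans from the training data).  The SD is floored
#' at `1e-6 * max(Rmu, 1)` so a degenerate perfectly-reconstructed slice
#' order cannot divide by zero.
#'
#' @param normal_results list with one element per scan, each a list with
#'   `orders` (integer vector) and `errors` (numeric vector, same length).
#' @param n_scans number of scans to sample (capped at the number
#'   available).
#' @param seed sampling seed.
#' @return object of class `recon_stats` with per-order `mu`, `sigma`, `n`.
#' @export
fit_error_stats <- function(normal_results, n_scans = length(normal_results),
                            seed = 1L) {
  stopifnot(length(normal_results) >= 1)
  set.seed(as.integer(seed))
  n_scans <- min(n_scans, length(normal_results))
  pick <- sample.int(length(normal_results), n_scans)
  orders <- unlist(lapply(normal_results[pick], `[[`, "orders"))
  errors <- unlist(lapply(normal_results[pick], `[[`, "errors"))
  stopifnot(length(orders) == length(errors))
  tab <- split(errors, orders)
  mu <- vapply(tab, mean, 0)
  nn <- vapply(tab, length, 0L)
  short <- names(tab)[nn < 2]
  if (length(short))
    stop("slice order(s) ", paste(short, collapse = ", "),
         " have fewer than 2 samples", call. = FALSE)
  sdv <- vapply(tab, stats::sd, 0)
  floorv <- 1e-6 * pmax(mu, 1)
  sigma <- pmax(sdv, floorv)
  structure(list(orders = as.integer(names(tab)), mu = mu, sigma = sigma,
                 n = nn, n_scans = n_scans, seed = as.integer(seed)),
            class = "recon_stats")
}

#' Scan-level anomaly score
#'
#' Each slice's raw error is z-normalized by its slice order's calibration
#' statistics and the z-scores are summed over the scan's present slices
#' (up to 32; shorter scans sum over what they have, with no imputation).
#'
#' @param per_slice_errors named numeric vector, names = slice orders.
#' @param stats a [fit_error_stats()] result.
#' @return object of class `anomaly_result` with `score`, `z` and `errors`.
#' @export
anomaly_score <- function(per_slice_errors, stats) {
  ords <- suppressWarnings(as.integer(names(per_slice_errors)))
  if (length(ords) == 0 || anyNA(ords))
    stop("`per_slice_errors` must be named by slice order", call. = FALSE)
  idx <- match(ords, stats$orders)
  if (anyNA(idx))
    stop("no calibration statistics for slice order(s) ",
         paste(ords[is.na(idx)], collapse = ", "), call. = FALSE)
  z <- (as.numeric(per_slice_errors) - stats$mu[idx]) / stats$sigma[idx]
  names(z) <- ords
  structure(list(score = sum(z), z = z,
                 errors = stats::setNames(as.numeric(per_slice_errors), ords)),
            class = "anomaly_result")
}

#' @export
print.anomaly_result <- function(x, ...) {
  cat("<anomaly_result> score ", format(x$score, digits = 4),
      " over ", length(x$z), " slice(s)\n", sep = "")
  invisible(x)
}

# ---- the full per-scan pipeline --------------------------------------------

# run inversion + masked noise optimization for a set of slices (batched);
# slices: list of HU matrices, orders: their slice orders,
# brain: list of logical masks.  Returns per-slice list(recon, mask, error).
reconstruct_slices <- function(model, slices, orders, stats, icfg,
                               batch_size = 16L, norm = "l1") {
  out <- vector("list", length(slices))
  i <- 1L
  while (i <= length(slices)) {
    j <- min(i + batch_size - 1L, length(slices))
    idx <- i:j
    zs <- matrix(unlist(lapply(slices[idx], function(m)
      as.vector(hu_to_unit(m, model$cfg)))), nrow = 1)
    inv <- invert_batch(model, zs, orders[idx], stats, icfg)
    brain <- lapply(slices[idx], extract_brain_mask)
    mn <- masked_noise_batch(model, slices[idx], inv$codes, brain, icfg)
    for (q in seq_along(idx)) {
      err <- slice_reconstruction_error(slices[[idx[q]]], mn$recons[[q]],
                                        mn$masks[[q]], norm)
      out[[idx[q]]] <- list(w = w_from_codes(inv$codes, model$cfg, q),
                            recon = mn$recons[[q]], mask = mn$masks[[q]],
                            error = err, mask_sizes = mn$hist_sizes[[q]],
                            brain = brain[[q]])
    }
    i <- j + 1L
  }
  out
}

#' Score one scan
#'
#' Runs the full inference pipeline on every slice: encoder initialization,
#' latent optimization, masked noise optimization, masked error, and (when
#' calibration statistics are supplied) slice-order z-normalization into the
#' scan-level anomaly score.
#'
#' @param scan a [ct_scan()].
#' @param model trained backbone.
#' @param stats latent Gaussian statistics ([fit_latent_gaussian()]).
#' @param error_stats optional [fit_error_stats()] result.
#' @param icfg an [inversion_config()].
#' @param norm error norm, `"l1"` or `"l2"`.
#' @return an `anomaly_result` (score `NA` if `error_stats` is missing),
#'   with per-slice `recons` and `masks` attached.
#' @export
score_scan <- function(scan, model, stats, error_stats = NULL,
                       icfg = inversion_config(), norm = "l1") {
  res <- reconstruct_slices(model, scan$slices, scan$slice_orders, stats,
                            icfg, norm = norm)
  errors <- stats::setNames(vapply(res, `[[`, 0, "error"), scan$slice_orders)
  out <- if (!is.null(error_stats)) anomaly_score(errors, error_stats) else
    structure(list(score = NA_real_, z = NULL, errors = errors),
              class = "anomaly_result")
  out$recons <- lapply(res, `[[`, "recon")
  out$masks <- lapply(res, `[[`, "mask")
  out$case_id <- scan$case_id
  out
}

#' Score a cohort of scans (batched across scans)
#'
#' @param scans list of [ct_scan()].
#' @param model,stats,error_stats,icfg,norm as in [score_scan()].
#' @param batch_size slices per inversion batch.
#' @return data frame `case_id, n_slices, score` plus a list-column-free
#'   attribute `results` with the per-scan `anomaly_result`s.
#' @export
score_cohort <- function(scans, model, stats, error_stats = NULL,
                         icfg = inversion_config(), norm = "l1",
                         batch_size = 16L) {
  slices <- unlist(lapply(scans, `[[`, "slices"), recursive = FALSE)
  orders <- unlist(lapply(scans, `[[`, "slice_orders"))
  res <- reconstruct_slices(model, slices, orders, stats, icfg,
                            batch_size = batch_size, norm = norm)
  results <- vector("list", length(scans))
  pos <- 0L
  for (q in seq_along(scans)) {
    ns <- length(scans[[q]]$slices)
    sub <- res[(pos + 1):(pos + ns)]
    pos <- pos + ns
    errors <- stats::setNames(vapply(sub, `[[`, 0, "error"),
                              scans[[q]]$slice_orders)
    ar <- if (!is.null(error_stats)) anomaly_score(errors, error_stats) else
      structure(list(score = NA_real_, z = NULL, errors = errors),
                class = "anomaly_result")
    ar$case_id <- scans[[q]]$case_id
    ar$masks <- lapply(sub, `[[`, "mask")
    ar$recons <- lapply(sub, `[[`, "recon")
    results[[q]] <- ar
  }
  df <- data.frame(case_id = vapply(scans, `[[`, "", "case_id"),
                   n_slices = vapply(scans, function(s) length(s$slices), 0L),
                   score = vapply(results, `[[`, 0, "score"),
                   stringsAsFactors = FALSE)
  attr(df, "results") <- results
  df
}

#' Calibrate error statistics by scoring normal scans
#'
#' Runs the reconstruction pipeline on a normal calibration cohort and fits
#' the per-slice-order error statistics.
#'
#' @param scans list of normal [ct_scan()].
#' @param model,stats,icfg,norm as in [score_scan()].
#' @param n_scans,seed passed to [fit_error_stats()].
#' @param batch_size slices per inversion batch.
#' @return a [fit_error_stats()] result.
#' @export
calibrate_error_stats <- function(scans, model, stats,
                                  icfg = inversion_config(), norm = "l1",
                                  n_scans = length(scans), seed = 1L,
                                  batch_size = 16L) {
  slices <- unlist(lapply(scans, `[[`, "slices"), recursive = FALSE)
  orders <- unlist(lapply(scans, `[[`, "slice_orders"))
  res <- reconstruct_slices(model, slices, orders, stats, icfg,
                            batch_size = batch_size, norm = norm)
  normal_results <- list()
  pos <- 0L
  for (q in seq_along(scans)) {
    ns <- length(scans[[q]]$slices)
    sub <- res[(pos + 1):(pos + ns)]
    pos <- pos + ns
    normal_results[[q]] <- list(orders = scans[[q]]$slice_orders,
                                errors = vapply(sub, `[[`, 0, "error"))
  }
  out <- fit_error_stats(normal_results, n_scans = n_scans, seed = seed)
  attr(out, "raw") <- normal_results
  out
}
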