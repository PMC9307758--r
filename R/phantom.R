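# Synthetic head-CT phantoms in Hounsfield units.
#
# The phantoms emulate the statistical structure the anomaly detector
# assumes: a learnable "normal" appearance (elliptical skull ring, brain
# parenchyma, paired ventricles whose area grows with slice order, mild
# texture) plus density-deviating lesions with exact ground-truth masks.
# They are not anatomically realistic and model no acquisition physics.

#' Construct a CT scan object
#'
#' An ordered stack of up to 32 axial slices in Hounsfield units,
#' bottom-to-top, with strictly increasing slice-order indices in 1..32.
#'
#' @param case_id character id.
#' @param slices list of numeric matrices (HU), all of one shape.
#' @param slice_orders integer vector, strictly increasing, in 1..32.
#' @param pixel_size_mm positive pixel spacing.
#' @param labels optional list of integer region-label matrices
#'   (0 air, 1 skull, 2 parenchyma, 3 ventricle) kept as internal ground
#'   truth for brain-extraction tests.
#' @return object of class `ct_scan`.
#' @export
ct_scan <- function(case_id, slices, slice_orders, pixel_size_mm = 3.6,
                    labels = NULL) {
  n <- length(slices)
  if (n < 1 || n > 32) stop("a scan must hold 1..32 slices", call. = FALSE)
  if (length(slice_orders) != n) stop("one slice order per slice", call. = FALSE)
  slice_orders <- as.integer(slice_orders)
  if (any(slice_orders < 1 | slice_orders > 32))
    stop("slice orders must lie in 1..32", call. = FALSE)
  if (any(diff(slice_orders) <= 0))
    stop("slice orders must be strictly increasing", call. = FALSE)
  shp <- dim(slices[[1]])
  for (s in slices) {
    if (!is.matrix(s) || !identical(dim(s), shp))
      stop("all slices must share one shape", call. = FALSE)
    if (!all(is.finite(s))) stop("HU values must be finite", call. = FALSE)
  }
  if (pixel_size_mm <= 0) stop("pixel_size_mm must be positive", call. = FALSE)
  structure(list(case_id = as.character(case_id), slices = slices,
                 slice_orders = slice_orders,
                 pixel_size_mm = as.numeric(pixel_size_mm),
                 labels = labels),
            class = "ct_scan")
}

#' @export
print.ct_scan <- function(x, ...) {
  cat("<ct_scan> ", x$case_id, ": ", length(x$slices), " slices ",
      nrow(x$slices[[1]]), "x", ncol(x$slices[[1]]),
      ", orders ", paste(x$slice_orders, collapse = ","), "\n", sep = "")
  invisible(x)
}

# bilinear interpolation weight matrix from m points to H points
lin_interp_mat <- function(H, m) {
  W <- matrix(0, H, m)
  pos <- seq(1, m, length.out = H)
  lo <- pmin(floor(pos), m - 1L)
  fr <- pos - lo
  for (i in seq_len(H)) {
    W[i, lo[i]] <- 1 - fr[i]
    W[i, lo[i] + 1] <- fr[i]
  }
  W
}

# geometry + labels for one slice order; kx/ky/kv are case-level factors
.slice_labels <- function(shape, order, kx, ky, kv) {
  h <- shape[1]; w <- shape[2]
  f <- (order - 1) / 31
  sh <- 1 - 0.18 * f                      # head narrows toward the vertex
  ci <- (h + 1) / 2; cj <- (w + 1) / 2
  ry <- 0.44 * h * sh * ky
  rx <- 0.36 * w * sh * kx
  i <- matrix(rep(seq_len(h), w), h, w)
  j <- matrix(rep(seq_len(w), each = h), h, w)
  u <- sqrt(((i - ci) / ry)^2 + ((j - cj) / rx)^2)
  lab <- matrix(0L, h, w)
  lab[u <= 1] <- 1L                        # skull ring (outer shell)
  lab[u <= 0.9] <- 2L                      # parenchyma
  # paired ventricles, area grows monotonically with slice order
  vrr <- (0.05 + 0.08 * f) * h * kv
  vrc <- 0.6 * vrr
  for (sgn in c(-1, 1)) {
    vj <- cj + sgn * 0.11 * w * sh
    vent <- (((i - ci) / vrr)^2 + ((j - vj) / vrc)^2) <= 1
    lab[vent & lab == 2L] <- 3L
  }
  lab
}

#' Generate a normal (lesion-free) head-CT phantom
#'
#' Deterministic given `seed`.  Air is about -1000 HU, the skull ring
#' 800--1200 HU, parenchyma 20--50 HU, and ventricles 0--12 HU; ventricle
#' area grows monotonically with slice order so that slice-order-dependent
#' calibration is meaningful.  Region labels are retained in `$labels`.
#'
#' @param seed integer seed.
#' @param shape `c(rows, cols)` in pixels (default 64 x 64).
#' @param n_slices number of slices (1..32); slice orders are spread evenly
#'   over 1..32.
#' @return a [ct_scan()].
#' @export
generate_normal_scan <- function(seed, shape = c(64, 64), n_slices = 8) {
  if (n_slices < 1 || n_slices > 32)
    stop("`n_slices` must lie in 1..32", call. = FALSE)
  set.seed(as.integer(seed))
  h <- shape[1]; w <- shape[2]
  orders <- unique(as.integer(round(seq(1, 32, length.out = n_slices))))
  stopifnot(length(orders) == n_slices)
  kx <- stats::runif(1, 0.95, 1.05)
  ky <- stats::runif(1, 0.95, 1.05)
  kv <- stats::runif(1, 0.85, 1.15)
  skull_hu <- 950 + stats::runif(1, -50, 50)
  slices <- vector("list", n_slices)
  labels <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    lab <- .slice_labels(c(h, w), orders[k], kx, ky, kv)
    img <- matrix(-1000 + stats::rnorm(h * w, sd = 5), h, w)
    # smooth low-frequency parenchymal field
    g <- matrix(stats::rnorm(36, sd = 3), 6, 6)
    field <- lin_interp_mat(h, 6) %*% g %*% t(lin_interp_mat(w, 6))
    par <- 35 + field + matrix(stats::rnorm(h * w, sd = 1.5), h, w)
    img[lab == 2L] <- pmin(pmax(par[lab == 2L], 22), 48)
    vent <- 6 + matrix(stats::rnorm(h * w, sd = 1), h, w)
    img[lab == 3L] <- pmin(pmax(vent[lab == 3L], 2), 10)
    sk <- skull_hu + matrix(stats::rnorm(h * w, sd = 30), h, w)
    img[lab == 1L] <- pmin(pmax(sk[lab == 1L], 810), 1190)
    # quantize to 1/64 HU (real CT quantizes to 1 HU); dyadic values keep
    # lesion injection exactly invertible in floating point
    slices[[k]] <- round(img * 64) / 64
    labels[[k]] <- lab
  }
  ct_scan(sprintf("phantom-%d", as.integer(seed)), slices, orders,
          pixel_size_mm = 0.45 * 512 / w, labels = labels)
}

#' Specify a lesion to inject
#'
#' @param kind one of `"hyperdense"`, `"hypodense"`, `"mass"`.
#' @param center `c(slice_index, row, col)` (slice index within the stack).
#' @param radius_px lesion radius, > 0.
#' @param delta_hu added density; positive for hyperdense, negative for
#'   hypodense.
#' @param midline_shift_px lateral tissue displacement (mass only).
#' @return list of class `lesion_spec`.
#' @export
lesion_spec <- function(kind = c("hyperdense", "hypodense", "mass"),
                        center, radius_px, delta_hu, midline_shift_px = 0) {
  kind <- match.arg(kind)
  if (radius_px <= 0) stop("radius_px must be > 0", call. = FALSE)
  if (kind == "hyperdense" && delta_hu <= 0)
    stop("hyperdense lesions need delta_hu > 0", call. = FALSE)
  if (kind == "hypodense" && delta_hu >= 0)
    stop("hypodense lesions need delta_hu < 0", call. = FALSE)
  if (midline_shift_px < 0) stop("midline_shift_px must be >= 0", call. = FALSE)
  structure(list(kind = kind, center = as.numeric(center),
                 radius_px = as.numeric(radius_px),
                 delta_hu = as.numeric(delta_hu),
                 midline_shift_px = as.numeric(midline_shift_px)),
            class = "lesion_spec")
}

#' Inject a lesion into a phantom scan
#'
#' Returns a modified copy plus the exact binary footprint of modified
#' pixels.  For non-mass kinds the lesion is a constant offset on a disc
#' (`delta_hu` quantized to 1/64 HU, so subtracting it inside the mask
#' restores the original bit-exactly); `"mass"` lesions additionally
#' displace surrounding tissue laterally by `midline_shift_px`.
#'
#' @param scan a [ct_scan()] with region labels (a phantom).
#' @param spec a [lesion_spec()].
#' @param seed integer seed (the operation is deterministic given it).
#' @return list with `scan` (modified) and `mask` (list of binary matrices,
#'   one per slice).
#' @export
inject_lesion <- function(scan, spec, seed = 1L) {
  stopifnot(inherits(scan, "ct_scan"), inherits(spec, "lesion_spec"))
  set.seed(as.integer(seed))
  k <- spec$center[1]; r0 <- spec$center[2]; c0 <- spec$center[3]
  if (k < 1 || k > length(scan$slices)) stop("lesion slice index out of range", call. = FALSE)
  lab <- scan$labels[[k]]
  if (is.null(lab)) stop("scan carries no region labels", call. = FALSE)
  if (!(lab[r0, c0] %in% c(2L, 3L)))
    stop("lesion center must lie inside the brain region", call. = FALSE)
  h <- nrow(lab); w <- ncol(lab)
  i <- matrix(rep(seq_len(h), w), h, w)
  j <- matrix(rep(seq_len(w), each = h), h, w)
  d2 <- (i - r0)^2 + (j - c0)^2
  brain <- lab %in% c(2L, 3L)
  dim(brain) <- dim(lab)
  disc <- d2 <= spec$radius_px^2
  disc[r0, c0] <- TRUE                       # radius -> 0 keeps >= 1 pixel
  core <- disc & brain
  old <- scan$slices[[k]]
  new <- old
  delta <- round(spec$delta_hu * 64) / 64     # keep additions exact (dyadic)
  if (delta == 0) delta <- sign(spec$delta_hu) / 64
  if (spec$kind == "mass" && spec$midline_shift_px > 0) {
    s <- round(spec$midline_shift_px)
    dir <- if (c0 <= (w + 1) / 2) 1L else -1L  # push toward the far hemisphere
    zone <- (d2 <= (2 * spec$radius_px)^2) & brain & !core
    src_j <- pmin(pmax(j - dir * s, 1L), w)
    shifted <- old[cbind(as.vector(i), as.vector(src_j))]
    dim(shifted) <- dim(old)
    new[zone] <- shifted[zone]
  }
  new[core] <- new[core] + delta
  mask <- lapply(seq_along(scan$slices), function(q) matrix(0L, h, w))
  mask[[k]] <- matrix(as.integer(new != old), h, w)
  scan$slices[[k]] <- new
  list(scan = scan, mask = mask)
}

#' Generate a screening cohort of phantoms
#'
#' About `prevalence * n` scans carry lesions and are labeled urgent or
#' immediate (larger/denser lesions are immediate); the remainder are
#' normal or benign (small incidental hypodensities).  Emergency is defined
#' as urgent-or-immediate.  Deterministic given `seed`.
#'
#' @param n cohort size, >= 1.
#' @param prevalence emergency prevalence in `[0, 1]` (the emergency
#'   fraction of the screening cohorts is about 0.11--0.15).
#' @param seed integer seed.
#' @param shape,n_slices passed to [generate_normal_scan()].
#' @return list with `scans` (list of [ct_scan()]), `manifest` (data frame
#'   `case_id, category, is_emergency`), and `masks` (named list of
#'   ground-truth masks, `NULL` for lesion-free cases).
#' @export
generate_cohort <- function(n, prevalence = 0.11, seed = 1L,
                            shape = c(64, 64), n_slices = 8) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (prevalence < 0 || prevalence > 1)
    stop("`prevalence` must lie in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  emerg <- stats::rbinom(n, 1, prevalence) == 1
  case_seeds <- sample.int(2^31 - 2, n)
  draw <- function(lo, hi) stats::runif(1, lo, hi)
  scans <- vector("list", n)
  masks <- vector("list", n)
  category <- character(n)
  ids <- sprintf("case-%04d", seq_len(n))
  for (q in seq_len(n)) {
    sc <- generate_normal_scan(case_seeds[q], shape, n_slices)
    sc$case_id <- ids[q]
    if (emerg[q]) {
      kind <- sample(c("hyperdense", "mass", "hypodense"), 1,
                     prob = c(0.6, 0.2, 0.2))
      radius <- draw(4, 9) * shape[2] / 64
      delta <- switch(kind,
                      hyperdense = draw(40, 80),
                      mass = draw(40, 80),
                      hypodense = -draw(15, 30))
      shift <- if (kind == "mass") draw(2, 4) * shape[2] / 64 else 0
      ctr <- .pick_brain_center(sc)
      spec <- lesion_spec(kind, ctr, radius, delta, shift)
      inj <- inject_lesion(sc, spec, seed = case_seeds[q])
      scans[[q]] <- inj$scan
      masks[[q]] <- inj$mask
      severity <- abs(delta) * radius^2 * (64 / shape[2])^2
      category[q] <- if (severity > 2000) "immediate" else "urgent"
    } else {
      if (stats::runif(1) < 0.2) {
        ctr <- .pick_brain_center(sc)
        spec <- lesion_spec("hypodense", ctr, draw(2, 3.5) * shape[2] / 64,
                            -draw(10, 15))
        inj <- inject_lesion(sc, spec, seed = case_seeds[q])
        scans[[q]] <- inj$scan
        masks[[q]] <- inj$mask
        category[q] <- "benign"
      } else {
        scans[[q]] <- sc
        category[q] <- "normal"
      }
    }
  }
  manifest <- data.frame(case_id = ids, category = category,
                         is_emergency = category %in% c("urgent", "immediate"),
                         stringsAsFactors = FALSE)
  names(masks) <- ids
  list(scans = scans, manifest = manifest, masks = masks)
}

# sample a well-interior parenchyma pixel of a random slice
.pick_brain_center <- function(scan) {
  k <- sample.int(length(scan$slices), 1)
  lab <- scan$labels[[k]]
  h <- nrow(lab); w <- ncol(lab)
  # stay clear of the skull: erode by distance from center
  i <- matrix(rep(seq_len(h), w), h, w)
  j <- matrix(rep(seq_len(w), each = h), h, w)
  interior <- lab == 2L &
    sqrt(((i - (h + 1) / 2) / (0.30 * h))^2 + ((j - (w + 1) / 2) / (0.24 * w))^2) <= 1
  cand <- which(interior)
  p <- cand[sample.int(length(cand), 1)]
  c(k, ((p - 1) %% h) + 1, ((p - 1) %/% h) + 1)
}
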