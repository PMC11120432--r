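#' Two-point mono-exponential relaxation fit
#'
#' Closed-form inverse of the mono-exponential decay through two prepared
#' signals: `t = tau / ln(s1/s2)`. Valid only for genuinely decaying
#' signals above the noise floor (`s1 > s2 > floor`); fitted times are
#' clamped to `(0, t_max]`.
#'
#' @param s1 Signal at preparation time 0 (vectorized).
#' @param s2 Signal at preparation time `tau_ms` (vectorized).
#' @param tau_ms Preparation time difference in ms, `> 0`.
#' @param floor Validity signal threshold (typically `3 * sigma`).
#' @param t_max Upper clamp for the fitted time in ms.
#'
#' @return List with numeric `t_ms` (NA where invalid) and logical `valid`.
#' @export
fit_t2_two_point <- function(s1, s2, tau_ms, floor = 0, t_max = 2000) {
  if (tau_ms <= 0) stop("tau_ms must be > 0", call. = FALSE)
  valid <- is.finite(s1) & is.finite(s2) & s1 > s2 & s2 > floor
  t_ms <- rep(NA_real_, length(s1))
  t_ms[valid] <- pmin(tau_ms / log(s1[valid] / s2[valid]), t_max)
  list(t_ms = t_ms, valid = valid)
}

#' Log-linear mono-exponential fit
#'
#' Ordinary least squares of `ln(signal)` on preparation time; the
#' relaxation time is `-1/slope`. Valid iff all signals exceed `floor` and
#' the slope is negative. With exactly two points this reduces to the
#' closed-form two-point fit.
#'
#' @param signals Numeric vector of magnitudes (>= 2 points).
#' @param times_ms Matching preparation times in ms (distinct, `>= 0`).
#' @param floor Validity signal threshold.
#' @param t_max Upper clamp for the fitted time in ms.
#'
#' @return List with `s0` (amplitude at time 0), `t_ms`, `rsq`
#'   (log-domain coefficient of determination; 1 by convention for
#'   two-point fits), `valid`.
#' @export
fit_monoexp_loglinear <- function(signals, times_ms, floor = 0,
                                  t_max = 2000) {
  if (length(signals) < 2L || length(times_ms) != length(signals)) {
    stop("need >= 2 (signal, time) pairs", call. = FALSE)
  }
  if (anyDuplicated(times_ms)) stop("duplicated times_ms", call. = FALSE)
  if (any(times_ms < 0)) stop("times_ms must be >= 0", call. = FALSE)
  fit <- monoexp_loglinear_matrix(matrix(signals, nrow = 1), times_ms,
                                  floor = floor, t_max = t_max)
  list(s0 = fit$s0[1], t_ms = fit$t_ms[1], rsq = fit$rsq[1],
       valid = fit$valid[1], max_abs_resid = fit$max_abs_resid[1])
}

# Vectorized log-linear fit over rows of a signal matrix (n_voxels x n_times).
monoexp_loglinear_matrix <- function(S, times_ms, floor = 0, t_max = 2000) {
  k <- length(times_ms)
  above <- rowSums(S > pmax(floor, 0) & is.finite(S)) == k
  Y <- log(pmax(S, .Machine$double.xmin))
  tbar <- mean(times_ms)
  w <- times_ms - tbar
  sxx <- sum(w^2)
  slope <- as.vector(Y %*% w) / sxx
  ybar <- rowMeans(Y)
  fitted_dev <- outer(slope, w)                  # fitted minus row mean
  resid <- Y - ybar - fitted_dev
  ss_res <- rowSums(resid^2)
  ss_tot <- rowSums((Y - ybar)^2)
  rsq <- ifelse(ss_tot > 1e-300, 1 - ss_res / ss_tot, 1)
  if (k == 2L) rsq <- rep(1, nrow(S))
  valid <- above & slope < 0
  t_ms <- rep(NA_real_, nrow(S))
  t_ms[valid] <- pmin(-1 / slope[valid], t_max)
  list(s0 = exp(ybar - slope * tbar), t_ms = t_ms, rsq = rsq, valid = valid,
       max_abs_resid = apply(abs(resid), 1, max))
}

select_map_blocks <- function(stack, kind) {
  prep_family <- if (kind == "T2") "t2prep" else "spinlock"
  types <- vapply(stack$sequence$blocks, `[[`, "", "prep_type")
  times <- vapply(stack$sequence$blocks, `[[`, 0, "prep_time_ms")
  usable <- types %in% c("none", prep_family)
  if (!any(types == prep_family & times > 0)) {
    stop(sprintf("prep family mismatch: no positive-time %s block in sequence '%s'",
                 prep_family, stack$sequence$name), call. = FALSE)
  }
  if (!any(usable & times == 0)) {
    stop("stack lacks a zero-preparation block", call. = FALSE)
  }
  which(usable)
}

#' Fat validity mask from phantom ground truth
#'
#' @param phantom A `tissue_phantom`.
#' @param threshold Fat-fraction threshold above which a voxel is masked.
#'
#' @return Logical array, TRUE where the tissue's fat fraction exceeds the
#'   threshold.
#' @export
fat_mask_from_phantom <- function(phantom, threshold = 0.5) {
  tt <- phantom$tissue_table
  ff <- tt$fat_fraction[match(as.vector(phantom$labels), tt$id)]
  array(ff > threshold, dim = dim(phantom$labels))
}

#' Reconstruct a voxel-wise relaxation map from an image stack
#'
#' Applies the closed-form two-point fit when the stack provides exactly
#' two usable blocks of the requested preparation family, and the
#' log-linear least-squares fit when it provides three or more. The map
#' covers the whole grid; voxels are marked invalid by diagnostics (any
#' signal at or below `floor`, non-decaying signal, or — for fits with
#' three or more points — a log-domain residual exceeding `resid_tol`,
#' which catches voxels whose signal is dominated by incompletely
#' suppressed fat and therefore inconsistent with a single exponential) or
#' by an explicit `fat_mask` (ground-truth masking mode).
#'
#' @param stack An `image_stack`.
#' @param kind `"T2"` (T2-prepared blocks) or `"T1rho"` (spin-lock blocks).
#' @param floor Validity signal threshold; default `3 * noise_sigma` of
#'   the stack.
#' @param fat_mask Optional logical array; TRUE voxels are forced invalid
#'   (see [fat_mask_from_phantom()]). `NULL` (default) uses diagnostics
#'   only.
#' @param resid_tol Maximum absolute log-domain residual tolerated for
#'   fits with >= 3 points (diagnostics mode); roughly the tolerated
#'   fractional signal deviation from mono-exponential decay.
#' @param t_max Upper clamp for fitted times in ms.
#'
#' @return A `parameter_map`: list with `values_ms` (3D array, NA where no
#'   finite fit exists), `valid` (logical array), `s0`, `rsq`, `kind`,
#'   `times_ms`, `floor`, provenance.
#' @export
reconstruct_map <- function(stack, kind = c("T2", "T1rho"), floor = NULL,
                            fat_mask = NULL, resid_tol = 0.15,
                            t_max = 2000) {
  kind <- match.arg(kind)
  stopifnot(inherits(stack, "image_stack"))
  floor <- floor %||% (3 * stack$noise_sigma)
  idx <- select_map_blocks(stack, kind)
  times <- vapply(stack$sequence$blocks[idx], `[[`, 0, "prep_time_ms")
  ord <- order(times)
  idx <- idx[ord]; times <- times[ord]
  d <- stack$phantom_ref$dim
  S <- vapply(stack$volumes[idx], as.vector, numeric(prod(d)))

  if (length(idx) == 2L) {
    fit <- fit_t2_two_point(S[, 1], S[, 2], times[2] - times[1],
                            floor = floor, t_max = t_max)
    s0 <- S[, 1]
    rsq <- rep(1, nrow(S))
    t_ms <- fit$t_ms
    valid <- fit$valid
  } else {
    fit <- monoexp_loglinear_matrix(S, times, floor = floor, t_max = t_max)
    s0 <- fit$s0
    rsq <- fit$rsq
    t_ms <- fit$t_ms
    valid <- fit$valid & fit$max_abs_resid <= resid_tol
  }
  if (!is.null(fat_mask)) {
    stopifnot(identical(dim(fat_mask), d))
    valid <- valid & !as.vector(fat_mask)
  }
  structure(
    list(values_ms = array(t_ms, dim = d), valid = array(valid, dim = d),
         s0 = array(s0, dim = d), rsq = array(rsq, dim = d), kind = kind,
         times_ms = times, floor = floor, resid_tol = resid_tol,
         sequence_name = stack$sequence$name,
         spacing_mm = stack$phantom_ref$spacing_mm),
    class = "parameter_map"
  )
}

#' @export
print.parameter_map <- function(x, ...) {
  d <- dim(x$values_ms)
  cat(sprintf("<parameter_map> %s from %s: %d x %d x %d, %.1f%% valid\n",
              x$kind, x$sequence_name, d[1], d[2], d[3],
              100 * mean(x$valid)))
  invisible(x)
}

#' Segmented-region summaries of a parameter map
#'
#' Mean and SD of the fitted relaxation times over the valid voxels of
#' each requested labeled region, the per-region analogue of reporting
#' segmented cartilage values as mean +/- SD.
#'
#' @param map A `parameter_map`.
#' @param labels A `tissue_phantom` or a 3D integer label array of the
#'   same shape as the map.
#' @param regions Region ids (or tissue names when `labels` is a phantom);
#'   default: all non-background tissues present.
#'
#' @return A tibble with columns `region`, `mean_ms`, `sd_ms`
#'   (population SD), `n_voxels`.
#' @export
summarize_region <- function(map, labels, regions = NULL) {
  stopifnot(inherits(map, "parameter_map"))
  phantom <- NULL
  if (inherits(labels, "tissue_phantom")) {
    phantom <- labels
    labels <- phantom$labels
  }
  stopifnot(identical(dim(labels), dim(map$values_ms)))
  if (is.null(regions)) {
    regions <- setdiff(sort(unique(as.vector(labels))), 0L)
  }
  ids <- if (!is.null(phantom)) {
    vapply(regions, function(r) resolve_tissue_id(phantom, r), 0L)
  } else {
    as.integer(regions)
  }
  region_names <- if (!is.null(phantom)) {
    phantom$tissue_table$name[match(ids, phantom$tissue_table$id)]
  } else {
    as.character(ids)
  }
  purrr::map2_dfr(ids, region_names, function(id, nm) {
    sel <- labels == id & map$valid
    n <- sum(sel)
    if (n == 0L) {
      stop("no valid voxels in region ", nm, call. = FALSE)
    }
    vals <- map$values_ms[sel]
    tibble::tibble(region = nm, mean_ms = mean(vals),
                   sd_ms = sqrt(mean((vals - mean(vals))^2)),
                   n_voxels = as.integer(n))
  })
}
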