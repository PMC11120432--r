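#' Magnetization preparation block
#'
#' One interleaved TSE block of a sequence: an optional relaxation
#' preparation module (T2 preparation with echo time `prep_time_ms`, or
#' spin-lock preparation with spin-lock time `prep_time_ms`) and an
#' optional spectral fat-saturation prepulse.
#'
#' @param prep_type One of `"none"`, `"t2prep"`, `"spinlock"`.
#' @param prep_time_ms Preparation duration in ms (`>= 0`; must be 0 when
#'   `prep_type` is `"none"`).
#' @param fat_sat Logical; apply the fat-saturation prepulse in this block.
#' @param label Free-text block label, e.g. `"PD-w FS"`.
#'
#' @return A `prep_block` list.
#' @export
prep_block <- function(prep_type = c("none", "t2prep", "spinlock"),
                       prep_time_ms = 0, fat_sat = FALSE, label = "") {
  prep_type <- match.arg(prep_type)
  if (prep_time_ms < 0) stop("prep_time_ms must be >= 0", call. = FALSE)
  if (prep_type == "none" && prep_time_ms != 0) {
    stop("prep_type 'none' requires prep_time_ms = 0", call. = FALSE)
  }
  structure(list(prep_type = prep_type, prep_time_ms = prep_time_ms,
                 fat_sat = isTRUE(fat_sat), label = label),
            class = "prep_block")
}

#' Sequence specification
#'
#' A named acquisition: repetition time, scalar equivalent readout echo
#' time (the single TE for 2D TSE with constant refocusing flip angle, the
#' equivalent TE for variable-flip-angle 3D TSE trains), and an ordered
#' list of interleaved preparation blocks.
#'
#' @param name Sequence identifier.
#' @param tr_ms Repetition time in ms, `> 0`.
#' @param te_equiv_ms Equivalent readout echo time in ms, `>= 0`.
#' @param blocks List of [prep_block()] objects (at least one).
#' @param spinlock_freq_hz Spin-lock offset frequency in Hz (metadata;
#'   `NA` when no spin-lock block is present).
#'
#' @return A `sequence_spec` list.
#' @export
sequence_spec <- function(name, tr_ms, te_equiv_ms, blocks,
                          spinlock_freq_hz = NA_real_) {
  stopifnot(tr_ms > 0, te_equiv_ms >= 0, length(blocks) >= 1L)
  blocks <- lapply(blocks, function(b) {
    if (inherits(b, "prep_block")) b else do.call(prep_block, b)
  })
  has_sl <- any(vapply(blocks, function(b) b$prep_type == "spinlock", TRUE))
  if (has_sl && !is.finite(spinlock_freq_hz)) {
    stop("spin-lock blocks require a spinlock_freq_hz", call. = FALSE)
  }
  structure(list(name = name, tr_ms = tr_ms, te_equiv_ms = te_equiv_ms,
                 blocks = blocks, spinlock_freq_hz = spinlock_freq_hz),
            class = "sequence_spec")
}

#' @export
print.sequence_spec <- function(x, ...) {
  cat(sprintf("<sequence_spec> %s: TR %g ms, TE_equiv %g ms, %d block(s)\n",
              x$name, x$tr_ms, x$te_equiv_ms, length(x$blocks)))
  for (b in x$blocks) {
    cat(sprintf("  - %-8s prep %3g ms, fat-sat %-5s %s\n", b$prep_type,
                b$prep_time_ms, b$fat_sat, b$label))
  }
  invisible(x)
}

#' Steady-state signal of one tissue voxel in one block
#'
#' Two-compartment saturation-recovery TSE signal surrogate. For each
#' compartment c,
#' `S_c = PD * (1 - exp(-TR/T1_c)) * exp(-TE_equiv/T2_c) * P_c`
#' with preparation factor `P_c = 1` (no preparation),
#' `exp(-prep_time/T2_c)` (T2 preparation) or `exp(-prep_time/T1rho_c)`
#' (spin-lock preparation). The voxel signal is
#' `S = (1 - f) * S_water + f * kappa * S_fat`, where `f` is the tissue's
#' fat fraction and `kappa = fs_residual` when the block applies fat
#' saturation (1 otherwise). The water compartment uses the per-voxel
#' ground-truth T2/T1rho so the zonal cartilage modulation propagates; the
#' fat compartment uses [fat_compartment_params()].
#'
#' @param tissue One-row tissue parameter tibble (see [tissue_params()]).
#' @param truth_t2_ms Water-compartment T2 in ms (vectorized).
#' @param truth_t1rho_ms Water-compartment T1rho in ms (vectorized).
#' @param block A [prep_block()].
#' @param seq A [sequence_spec()].
#' @param fs_residual Residual fat signal fraction surviving fat
#'   saturation, in `[0, 1]`.
#'
#' @return Signal amplitude(s), arbitrary units, `>= 0`.
#' @export
steady_state_signal <- function(tissue, truth_t2_ms, truth_t1rho_ms, block,
                                seq, fs_residual = 0.05) {
  stopifnot(inherits(block, "prep_block"), inherits(seq, "sequence_spec"),
            fs_residual >= 0, fs_residual <= 1)
  pd <- tissue$proton_density
  if (pd == 0) return(rep(0, length(truth_t2_ms)))
  if (any(c(tissue$t1_ms, truth_t2_ms, truth_t1rho_ms) <= 0)) {
    stop("non-positive relaxation time", call. = FALSE)
  }
  f <- tissue$fat_fraction
  fat <- fat_compartment_params()
  kappa <- if (block$fat_sat) fs_residual else 1

  prep_factor <- function(t2, t1rho) {
    switch(block$prep_type,
           none = 1,
           t2prep = exp(-block$prep_time_ms / t2),
           spinlock = exp(-block$prep_time_ms / t1rho))
  }
  s_water <- pd * (1 - exp(-seq$tr_ms / tissue$t1_ms)) *
    exp(-seq$te_equiv_ms / truth_t2_ms) *
    prep_factor(truth_t2_ms, truth_t1rho_ms)
  s_fat <- pd * (1 - exp(-seq$tr_ms / fat$t1_ms)) *
    exp(-seq$te_equiv_ms / fat$t2_ms) *
    prep_factor(fat$t2_ms, fat$t1rho_ms)
  (1 - f) * s_water + f * kappa * s_fat
}

#' Add Rician noise to a magnitude volume
#'
#' Magnitude MR noise model: independent zero-mean Gaussian noise of SD
#' `sigma` on the real and imaginary channels, then the magnitude
#' `|(v + n_re) + i n_im|`. Output is non-negative everywhere.
#'
#' @param volume Numeric array of noiseless magnitudes.
#' @param sigma Gaussian channel SD, `>= 0`.
#' @param seed Integer seed; the caller's RNG state is preserved.
#'
#' @return Array of the same shape.
#' @export
add_rician_noise <- function(volume, sigma, seed) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(volume)
  with_seed(seed, {
    n <- length(volume)
    re <- volume + rnorm(n, sd = sigma)
    im <- rnorm(n, sd = sigma)
    out <- sqrt(re^2 + im^2)
    array(out, dim = dim(volume) %||% n)
  })
}

#' Simulate a magnitude image stack for one sequence
#'
#' Evaluates the steady-state signal model voxel-wise for every
#' preparation block of the sequence and corrupts each block volume with
#' Rician noise, using an independent, deterministically derived substream
#' per block (`substream = hash(seed, block index)`).
#'
#' @param phantom A `tissue_phantom`.
#' @param seq A [sequence_spec()] (or preset name, resolved via
#'   [load_sequence_presets()]).
#' @param noise_sigma Gaussian channel SD in signal units (proton density
#'   is on a 0-1 scale); default 0.005.
#' @param seed Master integer seed.
#' @param fs_residual Residual fat signal fraction under fat saturation.
#'
#' @return An `image_stack`: list with `volumes` (list of 3D arrays, one
#'   per block), `sequence`, `noise_sigma`, `seed`, `fs_residual`,
#'   `phantom_ref` (dims, spacing, phantom seed).
#' @export
simulate_stack <- function(phantom, seq, noise_sigma = 0.005, seed = 1L,
                           fs_residual = 0.05) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  if (is.character(seq)) seq <- load_sequence_presets()[[seq]]
  stopifnot(inherits(seq, "sequence_spec"))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)

  d <- dim(phantom$labels)
  tt <- phantom$tissue_table
  row_of <- match(as.vector(phantom$labels), tt$id)
  pd <- tt$proton_density[row_of]
  t1w <- tt$t1_ms[row_of]
  f <- tt$fat_fraction[row_of]
  t2w <- as.vector(phantom$truth_t2_ms)
  t1rhow <- as.vector(phantom$truth_t1rho_ms)
  live <- pd > 0
  fat <- fat_compartment_params()

  volumes <- vector("list", length(seq$blocks))
  for (i in seq_along(seq$blocks)) {
    block <- seq$blocks[[i]]
    kappa <- if (block$fat_sat) fs_residual else 1
    pw <- pfat <- rep(1, sum(live))
    if (block$prep_type == "t2prep") {
      pw <- exp(-block$prep_time_ms / t2w[live])
      pfat <- rep(exp(-block$prep_time_ms / fat$t2_ms), sum(live))
    } else if (block$prep_type == "spinlock") {
      pw <- exp(-block$prep_time_ms / t1rhow[live])
      pfat <- rep(exp(-block$prep_time_ms / fat$t1rho_ms), sum(live))
    }
    s <- numeric(prod(d))
    s_water <- pd[live] * (1 - exp(-seq$tr_ms / t1w[live])) *
      exp(-seq$te_equiv_ms / t2w[live]) * pw
    s_fat <- pd[live] * (1 - exp(-seq$tr_ms / fat$t1_ms)) *
      exp(-seq$te_equiv_ms / fat$t2_ms) * pfat
    s[live] <- (1 - f[live]) * s_water + f[live] * kappa * s_fat
    vol <- array(s, dim = d)
    volumes[[i]] <- add_rician_noise(vol, noise_sigma,
                                     substream_seed(seed, i))
  }
  structure(
    list(volumes = volumes, sequence = seq, noise_sigma = noise_sigma,
         seed = as.integer(seed), fs_residual = fs_residual,
         phantom_ref = list(dim = d, spacing_mm = phantom$spacing_mm,
                            phantom_seed = phantom$seed)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- x$phantom_ref$dim
  cat(sprintf("<image_stack> %s: %d block volume(s) of %d x %d x %d, sigma %g\n",
              x$sequence$name, length(x$volumes), d[1], d[2], d[3],
              x$noise_sigma))
  invisible(x)
}
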