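#' Load the packaged acquisition presets
#'
#' Reads the shipped YAML preset file describing the two interleaved
#' prepared-TSE variants (MIX1: TR 1200 ms, T2-preparation TE 0/50 ms,
#' fat saturation on the unprepared block; MIX2: TR 600 ms, spin-lock
#' times 0/25/50 ms at 500 Hz, fat saturation on the prepared blocks) and
#' the four 2D/3D TSE reference sequences.
#'
#' @param file Optional path to an alternative preset YAML.
#'
#' @return Named list of [sequence_spec()] objects.
#' @export
load_sequence_presets <- function(file = NULL) {
  file <- file %||% system.file("extdata", "sequence_presets.yaml",
                                package = "qmixture", mustWork = TRUE)
  raw <- yaml::read_yaml(file)
  out <- lapply(names(raw), function(nm) {
    spec <- raw[[nm]]
    sequence_spec(
      name = nm, tr_ms = spec$tr_ms, te_equiv_ms = spec$te_equiv_ms,
      blocks = lapply(spec$blocks, function(b) do.call(prep_block, b)),
      spinlock_freq_hz = spec$spinlock_freq_hz %||% NA_real_
    )
  })
  names(out) <- names(raw)
  out
}

as_nifti_vol <- function(arr, spacing_mm, descrip = NULL) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing_mm
  if (!is.null(descrip)) img$descrip <- descrip
  img
}

#' Write a phantom to disk
#'
#' Label map and ground-truth maps as NIfTI (identity-rotation affine
#' built from the voxel spacing), tissue table as JSON, configuration as
#' YAML.
#'
#' @param phantom A `tissue_phantom`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#'
#' @return Invisibly, the named character vector of files written.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  stopifnot(inherits(phantom, "tissue_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    labels = file.path(dir, paste0(prefix, "_labels.nii.gz")),
    truth_t2 = file.path(dir, paste0(prefix, "_truth_t2.nii.gz")),
    truth_t1rho = file.path(dir, paste0(prefix, "_truth_t1rho.nii.gz")),
    tissues = file.path(dir, paste0(prefix, "_tissues.json")),
    config = file.path(dir, paste0(prefix, "_config.yaml"))
  )
  RNifti::writeNifti(as_nifti_vol(phantom$labels * 1L, phantom$spacing_mm),
                     files[["labels"]])
  RNifti::writeNifti(as_nifti_vol(phantom$truth_t2_ms, phantom$spacing_mm),
                     files[["truth_t2"]])
  RNifti::writeNifti(as_nifti_vol(phantom$truth_t1rho_ms, phantom$spacing_mm),
                     files[["truth_t1rho"]])
  jsonlite::write_json(phantom$tissue_table, files[["tissues"]],
                       dataframe = "rows", digits = NA)
  cfg <- phantom$config
  yaml::write_yaml(list(grid_dim = cfg$grid_dim, spacing_mm = cfg$spacing_mm,
                        cartilage_t2_ms = cfg$cartilage_t2_ms,
                        cartilage_t1rho_ms = cfg$cartilage_t1rho_ms,
                        seed = phantom$seed),
                   files[["config"]])
  invisible(files)
}

#' Write an image stack to disk
#'
#' One NIfTI volume per preparation block (block label recorded in the
#' NIfTI description field) plus a JSON manifest with the sequence
#' parameters, noise level and seeds.
#'
#' @param stack An `image_stack`.
#' @param dir Output directory.
#' @param prefix File-name prefix; defaults to the sequence name.
#'
#' @return Invisibly, the character vector of files written (manifest
#'   last).
#' @export
write_stack <- function(stack, dir, prefix = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- prefix %||% gsub("[^A-Za-z0-9]+", "_", stack$sequence$name)
  spacing <- stack$phantom_ref$spacing_mm
  files <- character(0)
  for (i in seq_along(stack$volumes)) {
    f <- file.path(dir, sprintf("%s_block%d.nii.gz", prefix, i))
    img <- as_nifti_vol(stack$volumes[[i]], spacing,
                        descrip = stack$sequence$blocks[[i]]$label)
    RNifti::writeNifti(img, f)
    files <- c(files, f)
  }
  manifest <- list(
    sequence = list(
      name = stack$sequence$name, tr_ms = stack$sequence$tr_ms,
      te_equiv_ms = stack$sequence$te_equiv_ms,
      spinlock_freq_hz = stack$sequence$spinlock_freq_hz,
      blocks = lapply(stack$sequence$blocks, unclass)
    ),
    noise_sigma = stack$noise_sigma, seed = stack$seed,
    fs_residual = stack$fs_residual,
    block_files = basename(files),
    phantom_ref = stack$phantom_ref
  )
  mf <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, mf))
}

#' Write a parameter map to disk
#'
#' Fitted values and validity mask as NIfTI; invalid voxels are stored as
#' NA in the value volume.
#'
#' @param map A `parameter_map`.
#' @param dir Output directory.
#' @param prefix File-name prefix; defaults to the map kind.
#'
#' @return Invisibly, the named character vector of files written.
#' @export
write_parameter_map <- function(map, dir, prefix = NULL) {
  stopifnot(inherits(map, "parameter_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- prefix %||% paste0("map_", map$kind)
  files <- c(values = file.path(dir, paste0(prefix, "_values.nii.gz")),
             valid = file.path(dir, paste0(prefix, "_valid.nii.gz")))
  vals <- map$values_ms
  vals[!map$valid] <- NA_real_
  RNifti::writeNifti(as_nifti_vol(vals, map$spacing_mm), files[["values"]])
  RNifti::writeNifti(as_nifti_vol(map$valid * 1L, map$spacing_mm),
                     files[["valid"]])
  invisible(files)
}

#' Run the full simulation and evaluation pipeline
#'
#' phantom -> simulated stacks for the requested sequences -> T2/T1rho
#' maps from the interleaved variants -> region summaries -> ROI quality
#' metrics, with all artifacts written below `out_dir` and a JSON manifest
#' recording parameters, seeds and file hashes. Reruns with the same
#' configuration and seed are bit-identical.
#'
#' @param out_dir Output directory.
#' @param config [phantom_config()] for the phantom.
#' @param sequences Character vector of preset names (see
#'   [load_sequence_presets()]).
#' @param noise_sigma Gaussian channel noise SD.
#' @param seed Master seed; per-sequence substreams are derived from it.
#' @param fs_residual Residual fat signal under fat saturation.
#'
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, config = phantom_config(),
                         sequences = c("MIX1", "2D TSE PD-w FS",
                                       "3D TSE PD-w FS", "MIX2",
                                       "2D TSE T1-w", "3D TSE T1-w"),
                         noise_sigma = 0.005, seed = 1L,
                         fs_residual = 0.05) {
  presets <- load_sequence_presets()
  unknown <- setdiff(sequences, names(presets))
  if (length(unknown)) {
    stop("unknown sequence preset(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  phantom <- stage("phantom", build_knee_phantom(config, seed = seed))
  files <- as.list(stage("phantom", write_phantom(phantom, out_dir)))

  stacks <- list()
  for (i in seq_along(sequences)) {
    nm <- sequences[i]
    st <- stage(paste0("simulate:", nm),
                simulate_stack(phantom, presets[[nm]],
                               noise_sigma = noise_sigma,
                               seed = substream_seed(seed, 100 + i),
                               fs_residual = fs_residual))
    files[[paste0("stack_", nm)]] <- stage(
      paste0("simulate:", nm), write_stack(st, out_dir))
    stacks[[nm]] <- st
  }

  maps <- list()
  summaries <- list()
  if ("MIX1" %in% sequences) {
    maps$T2 <- stage("map:T2", reconstruct_map(stacks[["MIX1"]], "T2"))
    files$map_T2 <- write_parameter_map(maps$T2, out_dir)
    summaries$T2 <- summarize_region(maps$T2, phantom,
                                     c("femoral_cartilage",
                                       "tibial_cartilage"))
  }
  if ("MIX2" %in% sequences) {
    maps$T1rho <- stage("map:T1rho",
                        reconstruct_map(stacks[["MIX2"]], "T1rho"))
    files$map_T1rho <- write_parameter_map(maps$T1rho, out_dir)
    summaries$T1rho <- summarize_region(maps$T1rho, phantom,
                                        c("femoral_cartilage",
                                          "tibial_cartilage"))
  }
  if (length(summaries)) {
    summary_tbl <- dplyr::bind_rows(summaries, .id = "kind")
    utils::write.csv(summary_tbl, file.path(out_dir, "region_summaries.csv"),
                     row.names = FALSE)
    files$region_summaries <- file.path(out_dir, "region_summaries.csv")
  }

  metrics <- list()
  pd_seqs <- intersect(sequences, c("MIX1", "2D TSE PD-w FS", "3D TSE PD-w FS"))
  t1_seqs <- intersect(sequences, c("MIX2", "2D TSE T1-w", "3D TSE T1-w"))
  if (length(pd_seqs)) {
    metrics$pd <- stage("metrics",
                        compare_sequences(stacks[pd_seqs], phantom, "PD-w FS"))
  }
  if (length(t1_seqs)) {
    metrics$t1 <- stage("metrics",
                        compare_sequences(stacks[t1_seqs], phantom, "T1-w"))
  }
  if (length(metrics)) {
    metrics_tbl <- dplyr::bind_rows(metrics)
    long <- tidyr::pivot_longer(
      dplyr::mutate(metrics_tbl, phantom_id = sprintf("phantom_seed%d", seed)),
      cols = c("weber", "cnr", "cv"), names_to = "metric",
      values_to = "value")[, c("phantom_id", "sequence", "weighting",
                               "metric", "value")]
    utils::write.csv(long, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    files$metrics <- file.path(out_dir, "metrics.csv")
  }

  all_files <- unlist(files, use.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("qmixture")),
    seed = seed, noise_sigma = noise_sigma, fs_residual = fs_residual,
    sequences = sequences,
    files = lapply(stats::setNames(all_files, basename(all_files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
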