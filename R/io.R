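# Readers/writers and pipeline entry points tying the stages together.
# NIfTI for images and maps, JSON for echo trains / reports / manifests,
# CSV for grid tables, RDS for the complex k-space object.

#' Write a parameter map or image stack as NIfTI
#'
#' @param x matrix (2-d map) or array; a 2-d map is written as a single
#'   slice, a `read x phase x echo` stack with the echo dimension fourth.
#' @param path output `.nii`/`.nii.gz` path.
#' @param units units string recorded in the header description field
#'   (e.g. `"ms"`, `"um^2/ms"`).
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(x, path, units = "") {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  else if (length(dim(x)) == 3) dim(x) <- c(dim(x)[1:2], 1L, dim(x)[3])
  img <- RNifti::asNifti(x)
  img$descrip <- units
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a multi-echo magnitude stack from NIfTI
#' @param path NIfTI file with echoes along the 4th (or 3rd) dimension.
#' @return Numeric array `read x phase x echo`.
#' @export
read_stack_nifti <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file '%s' not found", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  a <- array(as.numeric(img), dim = d)
  if (length(d) == 4) dim(a) <- c(d[1], d[2], d[4] * d[3])
  if (length(d) == 2) dim(a) <- c(d, 1L)
  a
}

run_manifest <- function(stage, cfg = NULL, seed = NULL, files = character(0)) {
  sums <- if (length(files)) as.list(tools::md5sum(files)) else NULL
  list(stage = stage, tool = "esmgre",
       version = as.character(packageVersion("esmgre")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed, config = if (!is.null(cfg)) unclass(cfg),
       outputs = sums)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Pipeline stage: simulate an acquisition
#'
#' Builds the phantom and echo train for a protocol, acquires (optionally
#' corrupted, optionally noisy) k-space, and writes the uncorrected
#' magnitude images (NIfTI), the k-space object (RDS), the echo-train
#' table (JSON) and a run manifest.
#'
#' @param config an `es_protocol`, a YAML config path, or a preset name.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for the noise.
#' @param snr signal-to-noise ratio; `NULL` or `Inf` for noiseless.
#' @param fluctuation an [fluctuation_model()] object or `NULL`.
#' @param tissues tissue parameter table.
#' @return Invisibly, a named list of the written file paths.
#' @export
cli_simulate <- function(config = "phantom_64echo_K10", out_dir = ".",
                         seed = 1, snr = 50, fluctuation = NULL,
                         tissues = es_tissue_defaults()) {
  cfg <- resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  phantom <- build_figure2_phantom(cfg, tissues)
  train <- build_echo_train(cfg)
  noise <- if (is.null(snr) || !is.finite(snr)) NULL else
    es_noise(sigma_for_snr(cfg, snr, tissues), seed = seed)
  ks <- acquire_kspace(phantom, train, cfg, fluctuation, noise)
  paths <- c(images = file.path(out_dir, "echoes_uncorrected.nii.gz"),
             kspace = file.path(out_dir, "kspace.rds"),
             train = file.path(out_dir, "echo_train.json"),
             manifest = file.path(out_dir, "manifest_simulate.json"))
  write_map_nifti(reconstruct_magnitude(ks), paths["images"], units = "a.u.")
  saveRDS(ks, paths["kspace"])
  write_echo_train(train, paths["train"])
  write_manifest(run_manifest("simulate", cfg, seed,
                              paths[c("images", "kspace", "train")]),
                 paths["manifest"])
  invisible(as.list(paths))
}

resolve_config <- function(config) {
  if (inherits(config, "es_protocol")) return(config)
  if (is.character(config) && file.exists(config)) return(read_protocol(config))
  if (is.character(config)) return(es_preset(config))
  stop_validation("config must be an es_protocol, a YAML path or a preset name")
}

#' Pipeline stage: navigator correction
#'
#' Loads a simulated k-space object, applies the two-step navigator phase
#' correction, and writes the corrected magnitude images, a correction
#' report (per-line phase summaries and ghost energy before/after) and a
#' manifest.
#'
#' @param kspace_path path to the `kspace.rds` written by [cli_simulate()].
#' @param out_dir output directory.
#' @return Invisibly, a named list of the written file paths.
#' @export
cli_correct <- function(kspace_path, out_dir = ".") {
  if (!file.exists(kspace_path))
    stop_validation(sprintf("k-space file '%s' not found", kspace_path))
  ks <- readRDS(kspace_path)
  if (!inherits(ks, "es_kspace"))
    stop_validation("file does not contain an es_kspace object")
  if (dim(ks$navs)[3] < 1)
    stop_validation("no navigator data present; cannot correct")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mag_before <- reconstruct_magnitude(ks)
  ks <- correct_step1(ks)
  ks <- correct_step2(ks)
  mag_after <- reconstruct_magnitude(ks)
  rep <- attr(ks, "report")
  report <- list(
    ghost_energy_before = ghost_energy(mag_before, ks$support),
    ghost_energy_after = ghost_energy(mag_after, ks$support),
    step1_phase_range_rad = range(rep$step1_phase),
    step2_applied = isTRUE(ks$step2_applied),
    fallback_used = isTRUE(rep$fallback_used))
  paths <- c(images = file.path(out_dir, "echoes_corrected.nii.gz"),
             kspace = file.path(out_dir, "kspace_corrected.rds"),
             report = file.path(out_dir, "correction_report.json"),
             manifest = file.path(out_dir, "manifest_correct.json"))
  write_map_nifti(mag_after, paths["images"], units = "a.u.")
  saveRDS(ks, paths["kspace"])
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE, digits = NA)
  write_manifest(run_manifest("correct", ks$config, NULL,
                              paths[c("images", "report")]), paths["manifest"])
  invisible(as.list(paths))
}

#' Pipeline stage: voxelwise fitting
#'
#' Fits a multi-echo magnitude stack voxelwise and writes T2*, D, M0 maps
#' (NIfTI with units in the header description), a JSON fit report and a
#' manifest. With `model = "both"` the stack is fitted with and without the
#' diffusion term and the corrected-AIC preference map is emitted as well.
#'
#' @param images_path 4-d NIfTI of magnitudes (echoes fourth).
#' @param train_path echo-train JSON written by [write_echo_train()].
#' @param out_dir output directory.
#' @param model `"with-diffusion"`, `"without-diffusion"` or `"both"`.
#' @param noise_model `"rician"` or `"gaussian"`.
#' @param sigma noise level; `NULL` estimates it from background corners.
#' @return Invisibly, a named list of the written file paths.
#' @export
cli_fit <- function(images_path, train_path, out_dir = ".",
                    model = c("both", "with-diffusion", "without-diffusion"),
                    noise_model = "rician", sigma = NULL) {
  model <- match.arg(model)
  stack <- read_stack_nifti(images_path)
  train <- read_echo_train(train_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(sigma))
    sigma <- estimate_noise_sigma(stack,
      corner_size = min(20, dim(stack)[1] %/% 4))$sigma
  paths <- list(manifest = file.path(out_dir, "manifest_fit.json"))
  fits <- list()
  if (model %in% c("both", "with-diffusion"))
    fits$with <- fit_map(stack, train,
                         fit_model(TRUE, noise_model = noise_model), sigma)
  if (model %in% c("both", "without-diffusion"))
    fits$without <- fit_map(stack, train,
                            fit_model(FALSE, noise_model = noise_model), sigma)
  primary <- if (!is.null(fits$with)) fits$with else fits$without
  paths$t2star <- file.path(out_dir, "t2star_ms.nii.gz")
  write_map_nifti(primary$T2star, paths$t2star, units = "T2* [ms]")
  paths$m0 <- file.path(out_dir, "m0.nii.gz")
  write_map_nifti(primary$M0, paths$m0, units = "M0 [a.u.]")
  if (!is.null(fits$with)) {
    paths$d <- file.path(out_dir, "d_um2_per_ms.nii.gz")
    write_map_nifti(fits$with$D, paths$d, units = "D [um^2/ms]")
  }
  if (model == "both") {
    cmp <- caic_compare(fits$with, fits$without)
    paths$caic <- file.path(out_dir, "caic_prefers_diffusion.nii.gz")
    write_map_nifti(cmp$prefers_diffusion + 0, paths$caic,
                    units = "1 = diffusion model preferred")
  }
  report <- list(model = model, noise_model = noise_model, sigma = sigma,
                 n_fitted = sum(primary$mask),
                 t2star_range_ms = range(primary$T2star, na.rm = TRUE))
  paths$report <- file.path(out_dir, "fit_report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA)
  write_manifest(run_manifest("fit", NULL, NULL,
                              unlist(paths[names(paths) != "manifest"])),
                 paths$manifest)
  invisible(paths)
}

#' Pipeline stage: simulation grid
#'
#' Runs [run_grid()] and writes the tidy cell x region table as CSV plus a
#' JSON manifest (spec, seeds, version). With `dry_run = TRUE` the cell
#' plan is printed and returned without computing.
#'
#' @param out_dir output directory.
#' @param spec an [grid_spec()] object.
#' @param dry_run print the plan only.
#' @return Invisibly, the written paths (or the plan if `dry_run`).
#' @export
cli_grid <- function(out_dir = ".", spec = grid_spec(), dry_run = FALSE) {
  cells <- grid_cells(spec)
  if (dry_run) {
    message(sprintf("simulation grid: %d cells x %d replicates", nrow(cells),
                    spec$replicates))
    print(cells)
    return(invisible(cells))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_grid(spec)
  paths <- c(table = file.path(out_dir, "grid_results.csv"),
             manifest = file.path(out_dir, "manifest_grid.json"))
  utils::write.csv(res, paths["table"], row.names = FALSE)
  write_manifest(c(run_manifest("grid", NULL, spec$base_seed, paths["table"]),
                   list(grid_spec = unclass(spec))), paths["manifest"])
  invisible(as.list(paths))
}
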