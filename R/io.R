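#' NIfTI image input/output
#'
#' Volumes are written as NIfTI-1 with the voxel size in the header, so a
#' reloaded image carries its grid geometry (and hence the voxel volume
#' used by reference normalization) with it.
#'
#' @param img an [image3d()] (or logical mask array for the mask variants).
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @return \code{read_image_nifti} returns an [image3d()];
#'   \code{read_mask_nifti} a logical array; writers return the path
#'   invisibly.
#' @export
write_image_nifti <- function(img, path) {
  stopifnot(inherits(img, "image3d"))
  nim <- RNifti::asNifti(img$values)
  RNifti::pixdim(nim) <- img$grid$voxel_size_mm
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' @rdname write_image_nifti
#' @export
read_image_nifti <- function(path) {
  nim <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(nim)[1:3]
  image3d(voxel_grid(dim(nim)[1:3], vs), array(as.numeric(nim), dim(nim)[1:3]))
}

#' @rdname write_image_nifti
#' @param mask logical array on the image grid.
#' @param grid the mask's [voxel_grid()].
#' @export
write_mask_nifti <- function(mask, grid, path) {
  stopifnot(is.logical(mask), inherits(grid, "voxel_grid"))
  nim <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(nim) <- grid$voxel_size_mm
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' @rdname write_image_nifti
#' @export
read_mask_nifti <- function(path) {
  nim <- RNifti::readNifti(path)
  array(as.numeric(nim) > 0.5, dim(nim)[1:3])
}

#' Write a simulated phantom to disk
#'
#' Writes the image, one mask file per compartment, and a YAML sidecar with
#' the ground truth (cell counts, loading, reference concentration, seed)
#' so a quantification run on the files can be checked against the truth.
#'
#' @param phantom a \code{phantom_image} from [generate_fluorine_image()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named list of written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  stopifnot(inherits(phantom, "phantom_image"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(image = file.path(dir, paste0(prefix, ".nii.gz")))
  write_image_nifti(phantom$image, paths$image)
  for (nm in names(phantom$masks)) {
    p <- file.path(dir, paste0(prefix, "_mask_", nm, ".nii.gz"))
    write_mask_nifti(phantom$masks[[nm]], phantom$image$grid, p)
    paths[[paste0("mask_", nm)]] <- p
  }
  spec <- phantom$spec
  truth <- list(
    seed = phantom$acq$seed,
    noise_sd = phantom$acq$noise_sd,
    gain = phantom$acq$gain,
    pulse = list(shape = phantom$acq$pulse$shape,
                 time_fwhm_ms = phantom$acq$pulse$time_fwhm_ms,
                 bandwidth_khz = phantom$acq$pulse$bandwidth_khz),
    voxel_size_mm = spec$grid$voxel_size_mm,
    pellets = lapply(spec$pellets, function(p)
      list(n_cells = p$n_cells, spins_per_cell = p$spins_per_cell,
           center_mm = p$center_mm, radius_mm = p$radius_mm)),
    reference = if (!is.null(spec$reference))
      list(concentration_spins_per_uL =
             spec$reference$concentration_spins_per_uL),
    off_resonance = if (!is.null(spec$off_resonance))
      list(offset_khz = spec$off_resonance$offset_khz,
           spin_density_spins_per_uL =
             spec$off_resonance$spin_density_spins_per_uL))
  paths$truth <- file.path(dir, paste0(prefix, "_truth.yaml"))
  yaml::write_yaml(truth, paths$truth)
  invisible(paths)
}

#' Read a two-column spectrum file
#'
#' Whitespace- or comma-separated text with frequency in the first column
#' and intensity in the second; lines starting with \code{#} are ignored.
#'
#' @param path file path.
#' @return An [nmr_spectrum()].
#' @export
read_spectrum <- function(path) {
  first <- readLines(path, n = 50)
  first <- first[!grepl("^\\s*#", first) & nzchar(first)]
  sep <- if (any(grepl(",", first))) "," else ""
  df <- utils::read.table(path, sep = sep, comment.char = "#",
                          header = FALSE, strip.white = TRUE)
  if (ncol(df) < 2) stop("spectrum file needs two columns")
  nmr_spectrum(df[[1]], df[[2]])
}

#' @rdname read_spectrum
#' @param s an [nmr_spectrum()].
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "nmr_spectrum"))
  utils::write.table(data.frame(frequency = s$axis, intensity = s$intensity),
                     path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Loading-result JSON input/output
#'
#' @param x a \code{loading_result} from [spins_per_cell()].
#' @param path JSON file path.
#' @return \code{read_loading} returns a \code{loading_result}.
#' @export
write_loading <- function(x, path) {
  stopifnot(inherits(x, "loading_result"))
  write_report_json(unclass(x), path)
}

#' @rdname write_loading
#' @export
read_loading <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spins_per_cell(x$cell_peak_area, x$ref_peak_area,
                 ref_spins = x$ref_spins, n_cells = x$n_cells)
}

#' Quantification-result JSON output
#'
#' @param x a \code{quant_result} from [quantify_cells()].
#' @param path JSON file path.
#' @export
write_quant_result <- function(x, path) {
  stopifnot(inherits(x, "quant_result"))
  write_report_json(unclass(x), path)
}

# Recursively sort names so reports are byte-stable for a given content.
sort_names_rec <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x)) {
    x <- x[order(names(x))]
    lapply(x, sort_names_rec)
  } else x
}

#' Write a report list as deterministic JSON
#'
#' Keys are sorted recursively and numbers written at full precision, so
#' identical results give byte-identical files.
#'
#' @param x a named list.
#' @param path JSON file path.
#' @export
write_report_json <- function(x, path) {
  x <- sort_names_rec(x)
  # Inf is not representable in JSON; encode as a string sentinel
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
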