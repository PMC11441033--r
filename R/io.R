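# NIfTI / JSON / CSV input-output and the run manifest.

aw_affine <- function(spacing, origin) {
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  m
}

write_nifti_vol <- function(arr, path, spacing, origin, frame_ms = NULL) {
  img <- RNifti::asNifti(arr)
  m <- structure(aw_affine(spacing, origin), code = 2L)
  RNifti::sform(img) <- m
  RNifti::qform(img) <- m
  pd <- spacing
  if (length(dim(arr)) >= 4 && !is.null(frame_ms)) pd <- c(pd, frame_ms)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (any(abs(rot - diag(diag(rot))) > 1e-6) || any(diag(rot) <= 0))
    stop("only axis-aligned NIfTI affines with positive spacing are ",
         "supported; ", path, " is oblique or flipped")
  hdr <- RNifti::niftiHeader(img)
  list(data = array(as.numeric(img), dim(img)),
       spacing = diag(rot), origin = xf[1:3, 4],
       frame_ms = if (length(dim(img)) >= 4) hdr$pixdim[5] else NULL)
}

#' Write a phantom bundle to disk
#'
#' Velocity goes out as three 4D NIfTI files (`<id>_vx/vy/vz.nii.gz`, m/s,
#' world component order x,y,z), the mask as uint8 NIfTI, landmarks and the
#' analytic reference as JSON.
#'
#' @param phantom a [build_phantom()] result.
#' @param dir output directory (created if needed).
#' @param id subject identifier used as the file prefix.
#' @return named list of paths (class `subject_bundle`).
#' @export
write_phantom_bundle <- function(phantom, dir, id = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fld <- phantom$velocity
  sp <- fld$spacing; org <- fld$origin; fms <- fld$frame_duration
  paths <- list(id = id)
  comps <- c("vx", "vy", "vz")
  for (ci in 1:3) {
    p <- file.path(dir, paste0(id, "_", comps[ci], ".nii.gz"))
    write_nifti_vol(fld$v[, , , , ci, drop = TRUE], p, sp, org, fms)
    paths[[comps[ci]]] <- p
  }
  paths$mask <- file.path(dir, paste0(id, "_mask.nii.gz"))
  write_nifti_vol(array(as.integer(phantom$seg$mask),
                        dim(phantom$seg$mask)),
                  paths$mask, sp, org, fms)
  paths$landmarks <- file.path(dir, paste0(id, "_landmarks.json"))
  jsonlite::write_json(list(valve = phantom$landmarks$valve,
                            bct = phantom$landmarks$bct,
                            frame_duration_ms = fms,
                            velocity_units = "m/s",
                            component_order = "x,y,z"),
                       paths$landmarks, digits = NA)
  paths$reference <- file.path(dir, paste0(id, "_reference.json"))
  jsonlite::write_json(phantom$reference, paths$reference, digits = NA,
                       auto_unbox = TRUE)
  structure(paths, class = "subject_bundle")
}

#' Read a subject bundle (velocity, mask, landmarks)
#'
#' Accepts three 4D velocity files or a single 5D file; validates that all
#' grids agree in shape, spacing and origin (within 1e-3 mm) and that the
#' mask is binary. Header/expectation mismatches are hard errors, never
#' silent rescaling.
#'
#' @param vx,vy,vz paths to the per-component 4D NIfTI files (m/s), or give
#'   `v5d` instead.
#' @param v5d optional single 5D NIfTI (x,y,z,t,component).
#' @param mask path to the binary mask NIfTI.
#' @param landmarks_json path to the landmarks JSON (`valve`, `bct`, mm).
#' @return list with `velocity` ([velocity_field()]), `seg`
#'   ([segmentation()]), `landmarks` ([landmarks()]).
#' @export
read_subject_bundle <- function(vx = NULL, vy = NULL, vz = NULL,
                                v5d = NULL, mask, landmarks_json) {
  for (p in c(vx, vy, vz, v5d, mask, landmarks_json))
    if (!file.exists(p)) stop("missing input file: ", p)
  if (!is.null(v5d)) {
    vol <- read_nifti_vol(v5d)
    if (length(dim(vol$data)) != 5 || dim(vol$data)[5] != 3)
      stop("5D velocity file must have dim (x,y,z,t,3): ", v5d)
    varr <- vol$data; vgrid <- vol
  } else {
    vols <- lapply(c(vx, vy, vz), read_nifti_vol)
    for (k in 2:3)
      if (!grid_match(vols[[1]], vols[[k]]))
        stop("velocity component grids disagree: ", vx, " vs ",
             c(vy, vz)[k - 1])
    d <- dim(vols[[1]]$data)
    if (length(d) == 3) d <- c(d, 1L)
    varr <- array(0, c(d, 3))
    for (k in 1:3) varr[, , , , k] <- vols[[k]]$data
    vgrid <- vols[[1]]
  }
  mvol <- read_nifti_vol(mask)
  if (!grid_match(vgrid, mvol))
    stop("velocity grid (", paste(dim(varr)[1:3], collapse = "x"),
         ", spacing ", paste(signif(vgrid$spacing, 6), collapse = "x"),
         ") and mask grid (", paste(dim(mvol$data)[1:3], collapse = "x"),
         ", spacing ", paste(signif(mvol$spacing, 6), collapse = "x"),
         ") disagree")
  marr <- mvol$data
  if (length(dim(marr)) == 3) dim(marr) <- c(dim(marr), 1L)
  lj <- jsonlite::read_json(landmarks_json, simplifyVector = TRUE)
  frame_ms <- vgrid$frame_ms %||% lj$frame_duration_ms %||% 1
  list(velocity = velocity_field(varr, vgrid$spacing, vgrid$origin, frame_ms),
       seg = segmentation(marr, mvol$spacing, mvol$origin),
       landmarks = landmarks(lj$valve, lj$bct))
}

grid_match <- function(a, b, tol = 1e-3) {
  all(dim(a$data)[1:3] == dim(b$data)[1:3]) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

#' Write result tables plus a reproducibility manifest
#'
#' Each element of `tables` (a named list of data.frames) is written as
#' `<name>.csv`; the manifest records the configuration, seeds, package
#' version and an md5 checksum per file. Re-running with identical inputs
#' and seeds reproduces identical bytes.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory.
#' @param config the [default_config()] used.
#' @param seeds named list/vector of seeds used.
#' @param overwrite allow overwriting existing files.
#' @return manifest (invisibly), also written as `manifest.json`.
#' @export
write_results <- function(tables, out_dir, config = default_config(),
                          seeds = list(), overwrite = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stopifnot(is.list(tables))
  files <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    if (file.exists(path) && !overwrite)
      stop("output file exists (use overwrite): ", path)
    write.csv(tables[[nm]], path, row.names = FALSE)
    files <- c(files, path)
  }
  manifest <- list(
    package = "aortaflow",
    version = as.character(utils::packageVersion("aortaflow")),
    config = unclass(config),
    config_hash = config_hash(config),
    seeds = seeds,
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' One-row data.frame from a haemodynamic summary
#'
#' @param x a `hemo_summary`.
#' @param id subject identifier.
#' @return data.frame with the ten scalars plus `peak_frame` and bookkeeping.
#' @export
summary_row <- function(x, id = "subject") {
  data.frame(id = id,
             mean_peak_wss = x$mean_peak_wss, max_peak_wss = x$max_peak_wss,
             mean_tawss = x$mean_tawss, max_tawss = x$max_tawss,
             mean_osi = x$mean_osi, max_osi = x$max_osi,
             mean_fd = x$mean_fd, max_fd = x$max_fd,
             axial_mean_wss_peak = x$axial_mean_wss_peak,
             circ_mean_wss_peak = x$circ_mean_wss_peak,
             peak_frame = x$peak_frame,
             n_wall_samples = x$n_wall_samples,
             n_planes_defined = x$n_planes_defined)
}
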