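# Lightweight S3 containers for the lattice data consumed by the pipeline.

#' Time-resolved 3-component velocity lattice
#'
#' @param v numeric array with dim `c(nx, ny, nz, n_frames, 3)`, m/s; the
#'   last axis holds the x, y, z velocity components in world order.
#' @param spacing voxel spacing, mm (length 3).
#' @param origin world coordinate of the first voxel center, mm.
#' @param frame_duration duration of one timeframe, ms.
#' @param venc optional velocity-encoding range, cm/s; when set, the fraction
#'   of non-zero samples exceeding it is stored as `aliased_fraction`
#'   (reported, never silently accepted).
#' @return object of class `velocity_field`.
#' @export
velocity_field <- function(v, spacing, origin = c(0, 0, 0),
                           frame_duration, venc = NULL) {
  stopifnot(length(dim(v)) == 5, dim(v)[5] == 3,
            length(spacing) == 3, all(spacing > 0),
            length(origin) == 3, frame_duration > 0)
  if (!all(is.finite(v))) stop("velocity field contains non-finite values")
  aliased <- NULL
  if (!is.null(venc)) {
    venc_ms <- venc / 100   # cm/s -> m/s
    nz <- v != 0
    aliased <- if (any(nz)) mean(abs(v[nz]) > venc_ms) else 0
    if (aliased > 0)
      warning(sprintf("%.2f%% of non-zero velocity samples exceed the VENC",
                      100 * aliased))
  }
  structure(list(v = v, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 frame_duration = frame_duration, venc = venc,
                 aliased_fraction = aliased),
            class = "velocity_field")
}

#' Time-resolved binary lumen segmentation
#'
#' @param mask integer/logical array with dim `c(nx, ny, nz, n_frames)`,
#'   values 0/1, on the same grid as the velocity field it accompanies.
#' @inheritParams velocity_field
#' @return object of class `segmentation`.
#' @export
segmentation <- function(mask, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(mask)) == 4, length(spacing) == 3, all(spacing > 0))
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1)))
    stop("segmentation mask must be binary (values 0/1); found: ",
         paste(utils::head(setdiff(vals, 0:1), 5), collapse = ", "))
  nt <- dim(mask)[4]
  for (k in seq_len(nt))
    if (sum(mask[, , , k]) == 0) stop("mask frame ", k, " is empty")
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "segmentation")
}

#' Anatomical landmarks delimiting the ascending aorta
#'
#' @param valve world coordinate of the aortic valve plane, mm.
#' @param bct world coordinate of the brachiocephalic trunk, mm.
#' @return object of class `landmarks`.
#' @export
landmarks <- function(valve, bct) {
  stopifnot(length(valve) == 3, length(bct) == 3)
  structure(list(valve = as.numeric(valve), bct = as.numeric(bct)),
            class = "landmarks")
}

grids_agree <- function(a, b, tol = 1e-3) {
  all(dim(a$mask %||% a$v)[1:3] == dim(b$mask %||% b$v)[1:3]) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$v)
  cat("<velocity_field>", paste(d[1:3], collapse = "x"), "voxels,",
      d[4], "frames,", "spacing", paste(x$spacing, collapse = "x"),
      "mm, frame", x$frame_duration, "ms\n")
  invisible(x)
}

#' @export
print.segmentation <- function(x, ...) {
  d <- dim(x$mask)
  cat("<segmentation>", paste(d[1:3], collapse = "x"), "voxels,", d[4],
      "frames,", sum(x$mask[, , , 1]), "lumen voxels in frame 1\n")
  invisible(x)
}
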