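# Analysis configuration: every tunable of the pipeline in one list.

#' Default analysis configuration
#'
#' @param mu blood dynamic viscosity, Pa s (4D-flow convention 3.2e-3).
#' @param fit near-wall fitting parameters: `n_points` sampling depths along
#'   the inward normal and `step_mm` between them (NULL = half the smallest
#'   voxel spacing).
#' @param peak_rule peak-systole selection: `"plane_flow"` (maximum net
#'   forward flow through the most proximal analysis plane) or
#'   `"mean_speed"`.
#' @param percentile percentile reported as the regional "maximum".
#' @param fd_scale `"fraction"` or `"percent"` for flow displacement.
#' @param area_weighting area-weight the regional mean (reserved; the
#'   boundary-face sampling is near-uniform in area and the default mean is
#'   unweighted).
#' @param smooth_normals smooth wall normals over a one-voxel radius.
#' @param n_planes number of equidistant analysis planes.
#' @param centerline_step_mm centerline resampling step.
#' @param alpha normality-test level.
#' @param q Benjamini-Hochberg false discovery rate.
#' @param ks_variant `"lilliefors"` (parameters estimated from the data) or
#'   `"ks"` (uncorrected one-sample Kolmogorov-Smirnov).
#' @param bh_family `"global"` (one family over all emitted correlations) or
#'   `"per_stratum"`.
#' @param seed integer seed for stochastic steps.
#' @return a named list of class `analysis_config`.
#' @export
default_config <- function(mu = 3.2e-3,
                           fit = list(n_points = 3L, step_mm = NULL),
                           peak_rule = c("plane_flow", "mean_speed"),
                           percentile = 99,
                           fd_scale = c("fraction", "percent"),
                           area_weighting = FALSE,
                           smooth_normals = TRUE,
                           n_planes = 7L,
                           centerline_step_mm = 1,
                           alpha = 0.05, q = 0.05,
                           ks_variant = c("lilliefors", "ks"),
                           bh_family = c("global", "per_stratum"),
                           seed = 1L) {
  peak_rule <- match.arg(peak_rule)
  fd_scale <- match.arg(fd_scale)
  ks_variant <- match.arg(ks_variant)
  bh_family <- match.arg(bh_family)
  stopifnot(mu > 0, alpha > 0, alpha < 1, q > 0, q < 1,
            percentile > 0, percentile <= 100, n_planes >= 1)
  structure(list(mu = mu, fit = fit, peak_rule = peak_rule,
                 percentile = percentile, fd_scale = fd_scale,
                 area_weighting = area_weighting,
                 smooth_normals = smooth_normals,
                 n_planes = as.integer(n_planes),
                 centerline_step_mm = centerline_step_mm,
                 alpha = alpha, q = q, ks_variant = ks_variant,
                 bh_family = bh_family, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read a configuration file (YAML)
#'
#' Keys missing from the file keep their [default_config()] values.
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_config()
  cfg <- utils::modifyList(unclass(base), raw)
  do.call(default_config, cfg[names(cfg) %in% names(formals(default_config))])
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(f))
}
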