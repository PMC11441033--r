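# Synthetic cohort generator: case/control tables with specified marginal
# distributions, planted rank correlations (Gaussian copula), and
# below-LLOQ censoring for the biomarker panel.

#' Specify a synthetic case-control cohort
#'
#' @param n_cases,n_controls group sizes.
#' @param marginals named list; each element is
#'   `list(dist, cases, controls, role, below_lloq_fraction, lloq)` where
#'   `dist` is `"normal"` (`c(mean, sd)`) or `"lognormal"`
#'   (`c(meanlog, sdlog)`), `role` is `"haemo"`, `"biomarker"` or
#'   `"covariate"`, `below_lloq_fraction` is the fraction of values forced
#'   below the lower limit of quantification (biomarkers only) and `lloq`
#'   the limit itself (derived from the marginal quantile when `NULL`).
#' @param copula data.frame with columns `var1`, `var2`, `stratum`
#'   (`"cases"`/`"controls"`) and `rho` (target Spearman rank correlation,
#'   in (-1, 1)); variables are otherwise independent within each group.
#' @param sex_p_female probability of female sex per group,
#'   `c(cases, controls)`.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, marginals,
                        copula = NULL,
                        sex_p_female = c(0.5, 0.5), seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, length(marginals) >= 1)
  for (nm in names(marginals)) {
    m <- marginals[[nm]]
    if (!m$dist %in% c("normal", "lognormal"))
      stop("unknown marginal distribution for ", nm, ": ", m$dist)
    if (m$dist == "normal" && (m$cases[2] <= 0 || m$controls[2] <= 0))
      stop("non-positive scale for ", nm)
    if (m$dist == "lognormal" && (m$cases[2] <= 0 || m$controls[2] <= 0))
      stop("non-positive sdlog for ", nm)
    f <- m$below_lloq_fraction %||% 0
    if (f < 0 || f > 1) stop("below_lloq_fraction must lie in [0, 1]")
  }
  if (!is.null(copula)) {
    stopifnot(all(c("var1", "var2", "stratum", "rho") %in% names(copula)))
    if (any(abs(copula$rho) >= 1))
      stop("copula correlations must lie in (-1, 1)")
    if (!all(copula$var1 %in% names(marginals)) ||
        !all(copula$var2 %in% names(marginals)))
      stop("copula refers to variables missing from the marginals")
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 marginals = marginals, copula = copula,
                 sex_p_female = sex_p_female, seed = as.integer(seed)),
            class = "cohort_spec")
}

lnorm_from_median_iqr <- function(med, q1, q3) {
  c(meanlog = log(med), sdlog = log(q3 / q1) / (2 * qnorm(0.75)))
}

#' Default synthetic cohort: the study conditions
#'
#' Parametrizes the generator with the printed group descriptives of the
#' case-control study this pipeline reproduces: 47 dilation cases vs 50
#' controls; mean (peak-systolic) WSS 0.62 +/- 0.15 vs 0.82 +/- 0.16 Pa;
#' mean OSI 0.16 +/- 0.023 vs 0.14 +/- 0.022; max WSS median (IQR)
#' 1.54 (1.46-1.78) vs 1.76 (1.59-1.95) Pa; mean flow displacement
#' 8.72 (5.52-10.41) vs 3.57 (2.67-5.39) percent; max flow displacement
#' 15.14 (10.46-17.8) vs 6.66 (4.14-10.0) percent; age 59.6 +/- 3.91 vs
#' 58.9 +/- 4.36 years; aortic diameter 42.8 +/- 2.48 vs 33.8 +/- 2.8 mm;
#' BSA 2.07 +/- 0.18 vs 1.98 +/- 0.21 m^2; women 6/47 vs 9/50. Non-printed
#' marginals (max/mean TAWSS, max OSI, biomarker panel) use plausible values
#' documented in the methods vignette; biomarkers are log-normal and do not
#' differ between groups. Two rank correlations are planted in the cases
#' stratum: Spearman 0.539 between max TAWSS and IL-6 and -0.575 between max
#' OSI and COL1a1. MMP-12 and TIMP-3 carry below-LLOQ fractions of 0.8 and
#' 0.85 so the LLOQ-exclusion rule removes exactly those two.
#'
#' @param seed integer seed.
#' @param null_cohort drop the planted correlations and group differences
#'   (global-null cohort for false-discovery checks).
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 1L, null_cohort = FALSE) {
  ln <- lnorm_from_median_iqr
  marg <- list(
    age      = list(dist = "normal", cases = c(59.6, 3.91),
                    controls = c(58.9, 4.36), role = "covariate"),
    diameter = list(dist = "normal", cases = c(42.8, 2.48),
                    controls = c(33.8, 2.8), role = "covariate"),
    bsa      = list(dist = "normal", cases = c(2.07, 0.18),
                    controls = c(1.98, 0.21), role = "covariate"),
    max_wss  = list(dist = "lognormal", cases = ln(1.54, 1.46, 1.78),
                    controls = ln(1.76, 1.59, 1.95), role = "haemo"),
    mean_wss = list(dist = "normal", cases = c(0.62, 0.15),
                    controls = c(0.82, 0.16), role = "haemo"),
    max_tawss  = list(dist = "lognormal", cases = ln(1.40, 1.25, 1.57),
                      controls = ln(1.40, 1.25, 1.57), role = "haemo"),
    mean_tawss = list(dist = "normal", cases = c(0.45, 0.10),
                      controls = c(0.45, 0.10), role = "haemo"),
    max_osi  = list(dist = "lognormal", cases = ln(0.35, 0.31, 0.40),
                    controls = ln(0.33, 0.29, 0.37), role = "haemo"),
    mean_osi = list(dist = "normal", cases = c(0.16, 0.023),
                    controls = c(0.14, 0.022), role = "haemo"),
    max_fd   = list(dist = "lognormal", cases = ln(15.14, 10.46, 17.8),
                    controls = ln(6.66, 4.14, 10.0), role = "haemo"),
    mean_fd  = list(dist = "lognormal", cases = ln(8.72, 5.52, 10.41),
                    controls = ln(3.57, 2.67, 5.39), role = "haemo"),
    IL6    = list(dist = "lognormal", cases = ln(0.9, 0.6, 1.5),
                  controls = ln(0.9, 0.6, 1.5), role = "biomarker"),
    COL1A1 = list(dist = "lognormal", cases = ln(120, 90, 160),
                  controls = ln(120, 90, 160), role = "biomarker"),
    MMP1   = list(dist = "lognormal", cases = ln(8, 5, 14),
                  controls = ln(8, 5, 14), role = "biomarker"),
    MMP2   = list(dist = "lognormal", cases = ln(180, 150, 210),
                  controls = ln(180, 150, 210), role = "biomarker"),
    MMP3   = list(dist = "lognormal", cases = ln(12, 8, 18),
                  controls = ln(12, 8, 18), role = "biomarker"),
    MMP9   = list(dist = "lognormal", cases = ln(40, 25, 65),
                  controls = ln(40, 25, 65), role = "biomarker"),
    MMP12  = list(dist = "lognormal", cases = ln(0.3, 0.15, 0.6),
                  controls = ln(0.3, 0.15, 0.6), role = "biomarker",
                  below_lloq_fraction = 0.8),
    TIMP1  = list(dist = "lognormal", cases = ln(90, 75, 110),
                  controls = ln(90, 75, 110), role = "biomarker"),
    TIMP2  = list(dist = "lognormal", cases = ln(70, 58, 85),
                  controls = ln(70, 58, 85), role = "biomarker"),
    TIMP3  = list(dist = "lognormal", cases = ln(2, 1.2, 3.3),
                  controls = ln(2, 1.2, 3.3), role = "biomarker",
                  below_lloq_fraction = 0.85),
    TIMP4  = list(dist = "lognormal", cases = ln(1.5, 1.1, 2.0),
                  controls = ln(1.5, 1.1, 2.0), role = "biomarker"))
  cop <- data.frame(var1 = c("max_tawss", "max_osi"),
                    var2 = c("IL6", "COL1A1"),
                    stratum = c("cases", "cases"),
                    rho = c(0.539, -0.575))
  sex_p <- c(6 / 47, 9 / 50)
  if (null_cohort) {
    cop <- NULL
    for (nm in names(marg)) marg[[nm]]$cases <- marg[[nm]]$controls
    sex_p <- c(9 / 50, 9 / 50)
  }
  cohort_spec(47L, 50L, marg, cop, sex_p, seed = seed)
}

#' Generate a synthetic cohort table
#'
#' Draws each group from a Gaussian copula whose Pearson parameters are
#' `2 sin(pi rho_S / 6)` for the planted Spearman targets (identity
#' otherwise), transforms to the specified marginals through their quantile
#' functions, and flags biomarker values falling below the lower limit of
#' quantification (the value is kept, censoring is a flag plus the LLOQ, not
#' a missing value). Reproducible from the seed.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per subject: `id`, `group`
#'   (`"case"`/`"control"`), `sex`, all numeric variables, and a
#'   `<biomarker>_below_lloq` logical column per biomarker; attributes
#'   `lloq` (named limits), `roles` (variable roles) and `spec_seed`.
#' @export
generate_cohort_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  vars <- names(spec$marginals)
  p <- length(vars)
  with_seed(spec$seed, {
    groups <- list(cases = spec$n_cases, controls = spec$n_controls)
    out <- vector("list", 2)
    for (gi in 1:2) {
      gname <- names(groups)[gi]
      n <- groups[[gi]]
      sigma <- diag(p)
      cop <- spec$copula
      if (!is.null(cop)) {
        cop_g <- cop[cop$stratum == gname, , drop = FALSE]
        for (r in seq_len(nrow(cop_g))) {
          i <- match(cop_g$var1[r], vars); j <- match(cop_g$var2[r], vars)
          rho_p <- 2 * sin(pi * cop_g$rho[r] / 6)
          sigma[i, j] <- sigma[j, i] <- rho_p
        }
      }
      ch <- tryCatch(chol(sigma), error = function(e)
        stop("non-positive-definite copula correlation matrix for the ",
             gname, " stratum", call. = FALSE))
      z <- matrix(rnorm(n * p), n, p) %*% ch
      u <- pnorm(z)
      x <- matrix(NA_real_, n, p, dimnames = list(NULL, vars))
      for (j in seq_len(p)) {
        m <- spec$marginals[[vars[j]]]
        par <- m[[gname]]
        x[, j] <- if (m$dist == "normal") qnorm(u[, j], par[1], par[2])
                  else qlnorm(u[, j], par[1], par[2])
      }
      sexp <- spec$sex_p_female[gi]
      df <- data.frame(
        id = paste0(substr(gname, 1, 2), sprintf("%03d", seq_len(n))),
        group = if (gname == "cases") "case" else "control",
        sex = ifelse(rbinom(n, 1, sexp) == 1, "F", "M"),
        x, check.names = FALSE)
      out[[gi]] <- df
    }
    tab <- rbind(out[[1]], out[[2]])
    lloq <- c()
    for (nm in vars) {
      m <- spec$marginals[[nm]]
      if ((m$role %||% "") != "biomarker") next
      f <- m$below_lloq_fraction %||% 0
      lim <- m$lloq %||% if (f > 0) {
        # pooled limit hitting the target censored fraction in expectation
        pc <- qlnorm(f, m$cases[1], m$cases[2])
        pn <- qlnorm(f, m$controls[1], m$controls[2])
        (spec$n_cases * pc + spec$n_controls * pn) /
          (spec$n_cases + spec$n_controls)
      } else 0
      tab[[paste0(nm, "_below_lloq")]] <- tab[[nm]] < lim
      lloq[nm] <- lim
    }
    attr(tab, "lloq") <- lloq
    attr(tab, "roles") <- vapply(spec$marginals, function(m)
      m$role %||% "covariate", character(1))
    attr(tab, "spec_seed") <- spec$seed
    tab
  })
}

#' Enrollment bookkeeping fixture
#'
#' Builds the per-subject enrollment flag table matching the study's
#' recruitment flow: 70 invited cases of whom 58 consented, 3 were
#' non-evaluable on image quality, 7 had a bicuspid valve and 1 a mechanical
#' valve prosthesis (leaving 47); 58 invited controls of whom 2 declined,
#' 1 acquisition was aborted and 4 were non-evaluable, and 1 lacked a blood
#' sample (leaving 50).
#'
#' @return data.frame with columns `id`, `group`, `consented`,
#'   `image_evaluable`, `valve_type` (`"TAV"`/`"BAV"`), `prosthesis`,
#'   `blood_sample_available`.
#' @export
enrollment_fixture <- function() {
  mk <- function(group, n, n_declined, n_noneval, n_bav, n_prosth, n_noblood) {
    df <- data.frame(
      id = paste0(substr(group, 1, 2), sprintf("%03d", seq_len(n))),
      group = group,
      consented = TRUE, image_evaluable = TRUE, valve_type = "TAV",
      prosthesis = FALSE, blood_sample_available = TRUE)
    i <- 0
    if (n_declined) { df$consented[i + seq_len(n_declined)] <- FALSE
                      i <- i + n_declined }
    if (n_noneval) { df$image_evaluable[i + seq_len(n_noneval)] <- FALSE
                     i <- i + n_noneval }
    if (n_bav) { df$valve_type[i + seq_len(n_bav)] <- "BAV"; i <- i + n_bav }
    if (n_prosth) { df$prosthesis[i + seq_len(n_prosth)] <- TRUE
                    i <- i + n_prosth }
    if (n_noblood) df$blood_sample_available[i + seq_len(n_noblood)] <- FALSE
    df
  }
  rbind(mk("case", 70, 12, 3, 7, 1, 0),
        mk("control", 58, 2, 1 + 4, 0, 0, 1))
}
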