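# Cohort statistics: enrollment filtering, LLOQ exclusion, normality-gated
# descriptives/comparisons/correlations, Fisher's exact test and
# Benjamini-Hochberg false-discovery-rate control.

#' Apply the enrollment filters and emit the audit trail
#'
#' Filters, in order: consent, image evaluability, valve morphology (only
#' tricuspid aortic valves retained), valve prosthesis, blood-sample
#' availability. Counts removed/remaining are recorded per group at each
#' step.
#'
#' @param tab data.frame with columns `group`, `consented`,
#'   `image_evaluable`, `valve_type` (`"TAV"`/`"BAV"`), `prosthesis`,
#'   `blood_sample_available` (see [enrollment_fixture()]).
#' @return object of class `cohort_filter_report`: `steps` (data.frame of
#'   step, group, n_removed, n_remaining), `final_n` (named per group) and
#'   `retained` (the filtered table).
#' @export
apply_cohort_filters <- function(tab) {
  need <- c("group", "consented", "image_evaluable", "valve_type",
            "prosthesis", "blood_sample_available")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("enrollment table lacks flag(s): ",
                         paste(miss, collapse = ", "))
  bad_valve <- !tab$valve_type %in% c("TAV", "BAV")
  if (any(bad_valve))
    stop("unknown valve label in rows: ",
         paste(utils::head(which(bad_valve), 10), collapse = ", "),
         " (labels: ", paste(unique(tab$valve_type[bad_valve]), collapse = ", "), ")")
  steps <- list(consented = quote(consented),
                image_evaluable = quote(image_evaluable),
                tricuspid_valve = quote(valve_type == "TAV"),
                no_prosthesis = quote(!prosthesis),
                blood_sample = quote(blood_sample_available))
  groups <- unique(tab$group)
  audit <- list()
  cur <- tab
  for (s in names(steps)) {
    keep <- eval(steps[[s]], cur)
    for (g in groups) {
      audit[[length(audit) + 1]] <- data.frame(
        step = s, group = g,
        n_removed = sum(cur$group == g & !keep),
        n_remaining = sum(cur$group == g & keep))
    }
    cur <- cur[keep, , drop = FALSE]
  }
  steps_df <- do.call(rbind, audit)
  final_n <- vapply(groups, function(g) sum(cur$group == g), integer(1))
  names(final_n) <- groups
  structure(list(steps = steps_df, final_n = final_n, retained = cur),
            class = "cohort_filter_report")
}

#' @export
print.cohort_filter_report <- function(x, ...) {
  cat("<cohort_filter_report>\n")
  print(x$steps, row.names = FALSE)
  cat("final n:", paste(names(x$final_n), x$final_n, collapse = ", "), "\n")
  invisible(x)
}

#' Exclude biomarkers quantified below the LLOQ in most participants
#'
#' A biomarker is dropped when its below-LLOQ fraction across all subjects
#' exceeds `threshold_fraction`; retained below-LLOQ values are kept as-is,
#' flagged.
#'
#' @param tab cohort table with `<biomarker>_below_lloq` flag columns.
#' @param threshold_fraction exclusion threshold (default 0.5).
#' @return list with `table` (flagged columns of excluded biomarkers removed)
#'   and `excluded` (character vector of biomarker names).
#' @export
lloq_exclude <- function(tab, threshold_fraction = 0.5) {
  flag_cols <- grep("_below_lloq$", names(tab), value = TRUE)
  excluded <- character(0)
  for (fc in flag_cols) {
    bm <- sub("_below_lloq$", "", fc)
    if (mean(tab[[fc]]) > threshold_fraction) excluded <- c(excluded, bm)
  }
  keep <- !(names(tab) %in% c(excluded, paste0(excluded, "_below_lloq")))
  out <- tab[, keep, drop = FALSE]
  for (a in c("lloq", "roles")) {
    at <- attr(tab, a)
    if (!is.null(at)) attr(out, a) <- at[setdiff(names(at), excluded)]
  }
  list(table = out, excluded = excluded)
}

#' Normality test (Kolmogorov-Smirnov family)
#'
#' Default is the Lilliefors variant: the one-sample KS distance to a normal
#' distribution with mean and SD estimated from the data, with the
#' correspondingly corrected p-value (Dallal-Wilkinson approximation via
#' `nortest::lillie.test`). `variant = "ks"` gives the uncorrected one-sample
#' KS test against the fitted normal. A zero-variance sample is non-normal
#' with p = 0 by convention.
#'
#' @param x numeric vector, n >= 4.
#' @param alpha decision level (normal when p > alpha).
#' @param variant `"lilliefors"` or `"ks"`.
#' @return list with `statistic`, `p`, `is_normal`.
#' @export
ks_normality <- function(x, alpha = 0.05,
                         variant = c("lilliefors", "ks")) {
  variant <- match.arg(variant)
  x <- x[is.finite(x)]
  if (length(x) < 4) stop("normality testing needs n >= 4")
  if (sd(x) == 0) {
    warning("zero-variance sample: declared non-normal by convention")
    return(list(statistic = NA_real_, p = 0, is_normal = FALSE))
  }
  res <- if (variant == "lilliefors") nortest::lillie.test(x)
         else suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  list(statistic = unname(res$statistic), p = res$p.value,
       is_normal = res$p.value > alpha)
}

#' Compare a variable between cases and controls
#'
#' When both groups pass [ks_normality()], a two-sided pooled-variance
#' Student t-test with mean +/- SD descriptives; otherwise a two-sided
#' Mann-Whitney U test (exact enumeration when both groups have n <= 10,
#' normal approximation with tie and continuity corrections otherwise) with
#' median (IQR) descriptives.
#'
#' @param x_cases,x_controls numeric vectors (n >= 4 each).
#' @param alpha normality-gate level.
#' @param ks_variant passed to [ks_normality()].
#' @param welch use the Welch t-test instead of pooled-variance Student.
#' @return object of class `group_comparison`: `normality` (per group),
#'   `test` (`"t"` or `"mann_whitney"`), `statistic`, `p`, `descriptives`.
#' @export
compare_groups <- function(x_cases, x_controls, alpha = 0.05,
                           ks_variant = "lilliefors", welch = FALSE) {
  x_cases <- x_cases[is.finite(x_cases)]
  x_controls <- x_controls[is.finite(x_controls)]
  stopifnot(length(x_cases) >= 4, length(x_controls) >= 4)
  if (length(unique(c(x_cases, x_controls))) == 1) {
    warning("all values tied across both groups; p = 1")
    nrm <- list(statistic = NA_real_, p = 0, is_normal = FALSE)
    return(structure(list(normality = list(cases = nrm, controls = nrm),
                          test = "mann_whitney", statistic = NA_real_, p = 1,
                          descriptives = describe_groups(x_cases, x_controls,
                                                         FALSE)),
                     class = "group_comparison"))
  }
  nc <- suppressWarnings(ks_normality(x_cases, alpha, ks_variant))
  nn <- suppressWarnings(ks_normality(x_controls, alpha, ks_variant))
  both_normal <- nc$is_normal && nn$is_normal
  if (both_normal) {
    tt <- stats::t.test(x_cases, x_controls, var.equal = !welch)
    test <- "t"; stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    mw <- mann_whitney_u(x_cases, x_controls)
    test <- "mann_whitney"; stat <- mw$U; p <- mw$p
  }
  structure(list(normality = list(cases = nc, controls = nn),
                 test = test, statistic = stat, p = p,
                 descriptives = describe_groups(x_cases, x_controls,
                                                both_normal)),
            class = "group_comparison")
}

describe_groups <- function(xc, xn, normal) {
  fmt <- function(x) {
    if (normal) sprintf("%.3g ± %.3g", mean(x), sd(x))
    else sprintf("%.3g (%.3g–%.3g)", median(x),
                 quantile(x, 0.25, names = FALSE),
                 quantile(x, 0.75, names = FALSE))
  }
  list(style = if (normal) "mean_sd" else "median_iqr",
       cases = fmt(xc), controls = fmt(xn))
}

# Two-sided Mann-Whitney U: exact enumeration (tie-safe) when both n <= 10,
# else normal approximation with tie and continuity corrections.
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= 10 && n2 <= 10) {
    combs <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    dev <- abs(u_all - n1 * n2 / 2)
    p <- mean(dev >= abs(u - n1 * n2 / 2) - 1e-9)
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    n <- n1 + n2
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(U = u, p = p)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p by the point-probability method: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table.
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows: case/control;
#'   columns: trait present/absent).
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0)) stop("negative counts in the contingency table")
  if (any(tab != round(tab))) stop("counts must be integers")
  if (all(rowSums(tab) == 0) || all(colSums(tab) == 0))
    stop("contingency table needs at least one positive margin")
  stats::fisher.test(tab)$p.value
}

#' Correlation with a normality-gated method choice
#'
#' Pearson (t-distribution p, df = n - 2) when both variables pass
#' [ks_normality()] on the stratum, otherwise Spearman computed as Pearson on
#' average ranks with the same t approximation. Pairwise deletion of missing
#' values. Zero variance in either variable yields an undefined (missing) r.
#'
#' @param x,y paired numeric vectors.
#' @param stratum label stored in the result (`"all"`, `"cases"`,
#'   `"controls"`, ...).
#' @param alpha normality-gate level.
#' @param ks_variant passed to [ks_normality()].
#' @return object of class `correlation_result`: `stratum`, `method`, `r`,
#'   `p`, `n`.
#' @export
correlate_auto <- function(x, y, stratum = "all", alpha = 0.05,
                           ks_variant = "lilliefors") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("correlation needs n >= 4 after pairwise deletion")
  if (sd(x) == 0 || sd(y) == 0)
    return(structure(list(stratum = stratum, method = NA_character_,
                          r = NA_real_, p = NA_real_, n = n),
                     class = "correlation_result"))
  normal <- suppressWarnings(ks_normality(x, alpha, ks_variant))$is_normal &&
            suppressWarnings(ks_normality(y, alpha, ks_variant))$is_normal
  if (normal) {
    method <- "pearson"; r <- cor(x, y)
  } else {
    method <- "spearman"; r <- cor(rank(x), rank(y))
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tstat), df = n - 2)
  structure(list(stratum = stratum, method = method, r = r, p = p, n = n),
            class = "correlation_result")
}

#' Benjamini-Hochberg step-up false-discovery-rate control
#'
#' Standard step-up rule at level `q`: with the sorted p-values, find the
#' largest k with `p(k) <= q k/m` and reject the k smallest; adjusted
#' p-values by the monotone cumulative-minimum construction
#' (`stats::p.adjust(method = "BH")`). Ties share a decision.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param q target false discovery rate.
#' @return list with `rejected` (logical) and `p_adjusted`.
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  if (!length(p)) return(list(rejected = logical(0), p_adjusted = numeric(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  list(rejected = !is.na(adj) & adj <= q, p_adjusted = adj)
}

#' Biomarker-by-haemodynamics correlation table with BH control
#'
#' One [correlate_auto()] cell per (biomarker, haemodynamic marker, stratum);
#' Benjamini-Hochberg control applied once over the whole emitted family
#' (or per stratum via `bh_family`). Both the unadjusted-significant and the
#' BH-significant flags are reported.
#'
#' @param tab cohort table (after [lloq_exclude()]); needs a `group` column
#'   with values `"case"`/`"control"`.
#' @param haemo_vars,bio_vars variable names; default: the table's `roles`
#'   attribute.
#' @param strata subset of `c("all", "cases", "controls")`.
#' @param q false discovery rate.
#' @param alpha normality-gate and unadjusted-significance level.
#' @param ks_variant passed to [ks_normality()].
#' @param bh_family `"global"` or `"per_stratum"`.
#' @return data.frame with columns `x` (biomarker), `y` (haemodynamic
#'   marker), `stratum`, `method`, `r`, `p`, `n`, `p_adjusted`,
#'   `bh_rejected`, `sig_unadjusted`.
#' @export
build_correlation_table <- function(tab, haemo_vars = NULL, bio_vars = NULL,
                                    strata = c("all", "cases", "controls"),
                                    q = 0.05, alpha = 0.05,
                                    ks_variant = "lilliefors",
                                    bh_family = c("global", "per_stratum")) {
  bh_family <- match.arg(bh_family)
  roles <- attr(tab, "roles")
  if (is.null(haemo_vars)) haemo_vars <- names(roles)[roles == "haemo"]
  if (is.null(bio_vars)) bio_vars <- names(roles)[roles == "biomarker"]
  miss <- setdiff(c(haemo_vars, bio_vars), names(tab))
  if (length(miss)) stop("variables missing from the cohort table: ",
                         paste(miss, collapse = ", "))
  sel <- list(all = rep(TRUE, nrow(tab)),
              cases = tab$group == "case",
              controls = tab$group == "control")
  rows <- list()
  for (st in strata) for (bm in bio_vars) for (hv in haemo_vars) {
    res <- correlate_auto(tab[[bm]][sel[[st]]], tab[[hv]][sel[[st]]],
                          stratum = st, alpha = alpha,
                          ks_variant = ks_variant)
    rows[[length(rows) + 1]] <- data.frame(
      x = bm, y = hv, stratum = st, method = res$method %||% NA_character_,
      r = res$r, p = res$p, n = res$n)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  out$bh_rejected <- FALSE
  fam <- if (bh_family == "global") list(seq_len(nrow(out)))
         else split(seq_len(nrow(out)), out$stratum)
  for (idx in fam) {
    bh <- benjamini_hochberg(out$p[idx], q)
    out$p_adjusted[idx] <- bh$p_adjusted
    out$bh_rejected[idx] <- bh$rejected
  }
  out$sig_unadjusted <- !is.na(out$p) & out$p <= alpha
  out
}
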