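# Statistical kernels against independent oracles, and the cohort-level
# filtering / exclusion / comparison / correlation machinery.

test_that("Fisher exact p matches exhaustive hypergeometric enumeration", {
  for (N in 2:15) for (r1 in 0:N) for (c1 in 0:N) {
    if (r1 + c1 == 0 || c1 > N) next
    lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
    for (a in lo:hi) {
      tab <- matrix(c(a, r1 - a, c1 - a, N - r1 - c1 + a), 2, byrow = TRUE)
      if (all(rowSums(tab) == 0) || all(colSums(tab) == 0)) next
      expect_equal(fisher_exact_2x2(tab), fisher_oracle(tab),
                   tolerance = 1e-12)
    }
  }
})

test_that("Fisher exact reproduces the printed worked examples", {
  expect_equal(round(fisher_exact_2x2(matrix(c(6, 41, 9, 41), 2,
                                             byrow = TRUE)), 3), 0.579)
  expect_equal(fisher_exact_2x2(matrix(c(3, 44, 3, 47), 2, byrow = TRUE)),
               1.0, tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(matrix(c(5, 10, 5, 10), 2, byrow = TRUE)),
               1.0, tolerance = 1e-9)  # equal rows are the modal table
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "negative")
})

test_that("Benjamini-Hochberg equals the brute-force step-up rule", {
  set.seed(31)
  for (i in 1:400) {
    m <- sample(1:80, 1)
    p <- runif(m)^sample(c(1, 2, 3), 1)   # mix of null-ish and signal-ish
    bh <- benjamini_hochberg(p, q = 0.05)
    expect_identical(bh$rejected, bh_oracle(p, 0.05))
    expect_identical(bh$rejected, unname(bh$p_adjusted <= 0.05))
  }
  expect_identical(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))$rejected,
                   rep(TRUE, 4))
  expect_identical(benjamini_hochberg(c(0.2, 0.9))$rejected, rep(FALSE, 2))
  expect_identical(benjamini_hochberg(numeric(0))$rejected, logical(0))
})

test_that("Spearman equals Pearson on average ranks", {
  set.seed(5)
  for (i in 1:60) {
    n <- sample(8:60, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.4 * x
    if (i %% 3 == 0) { x <- round(x, 1); y <- round(y, 1) }  # force ties
    x[1] <- 1e6  # guarantees the normality gate routes to Spearman
    r_impl <- correlate_auto(x, y)
    expect_equal(r_impl$method, "spearman")
    expect_equal(r_impl$r, cor(rank(x), rank(y)), tolerance = 1e-12)
  }
  # worked example: ranks (1,2,3,4,5) vs (2,1,4,3,5), sum d^2 = 4
  r <- cor(rank(c(1, 2, 3, 4, 5)), rank(c(2, 1, 4, 3, 5)))
  expect_equal(r, 1 - 6 * 4 / (5 * 24), tolerance = 1e-12)  # 0.8
})

test_that("correlate_auto handles perfect, gated and degenerate input", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 6.0, 0.3, 2.8)
  perfect <- correlate_auto(x, 2 * x + 1)
  expect_equal(perfect$r, 1, tolerance = 1e-12)
  # the method choice is exactly the two-variable normality gate
  set.seed(9)
  for (i in 1:10) {
    xn <- rnorm(60); yn <- 0.5 * xn + rnorm(60, sd = 0.8)
    if (i %% 2 == 0) xn <- exp(2 * xn)
    res <- correlate_auto(xn, yn)
    gate <- ks_normality(xn)$is_normal && ks_normality(yn)$is_normal
    expect_equal(res$method, if (gate) "pearson" else "spearman")
  }
  degen <- correlate_auto(rep(1, 10), rnorm(10))
  expect_true(is.na(degen$r))
  expect_error(correlate_auto(1:3, 1:3), "n >= 4")
})

test_that("normality gate: null acceptance, exponential rejection, constant", {
  set.seed(12)
  x <- rnorm(10000)
  expect_true(ks_normality(x)$is_normal)
  expect_false(ks_normality(rexp(10000))$is_normal)
  expect_warning(res <- ks_normality(rep(2, 10)), "zero-variance")
  expect_false(res$is_normal)
  expect_equal(res$p, 0)
  expect_error(ks_normality(c(1, 2, 3)), "n >= 4")
  # uncorrected variant exists and is more lenient than Lilliefors
  set.seed(13)
  y <- rexp(80)
  expect_gte(ks_normality(y, variant = "ks")$p, ks_normality(y)$p)
})

test_that("Mann-Whitney exact enumeration matches the closed case", {
  mw <- aortaflow:::mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p, 0.1, tolerance = 1e-12)   # 2/20 arrangements
  expect_equal(mw$U, 0)
  # tie-safe: enumeration runs with tied observations
  mwt <- aortaflow:::mann_whitney_u(c(1, 2, 2), c(2, 3, 4))
  expect_true(mwt$p > 0 && mwt$p <= 1)
  # large-sample branch agrees with wilcox.test's corrected approximation
  set.seed(21)
  x <- rnorm(25); y <- rnorm(30, 0.4)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(aortaflow:::mann_whitney_u(x, y)$p, ref$p.value,
               tolerance = 1e-9)
})

test_that("group comparison gates the test on normality and reports style", {
  set.seed(14)
  xc <- rnorm(47, 0.62, 0.15); xn <- rnorm(50, 0.82, 0.16)
  gc <- compare_groups(xc, xn)
  expect_equal(gc$test, "t")
  expect_equal(gc$descriptives$style, "mean_sd")
  expect_lt(gc$p, 0.001)
  gs <- compare_groups(exp(3 * rnorm(47)), exp(3 * rnorm(50) + 1))
  expect_equal(gs$test, "mann_whitney")
  expect_equal(gs$descriptives$style, "median_iqr")
  x <- rep(c(1, 2, 3, 4, 5), 2)
  same <- suppressWarnings(compare_groups(x, x))
  expect_equal(same$p, 1, tolerance = 1e-9)
  expect_warning(compare_groups(rep(1, 5), rep(1, 6)), "tied")
})

test_that("gated comparison keeps its type-I error near the nominal level", {
  set.seed(15)
  rej <- logical(400)
  for (i in seq_along(rej)) {
    g <- compare_groups(rnorm(47), rnorm(50))
    rej[i] <- g$p < 0.05
  }
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("enrollment filters reproduce the 47/50 bookkeeping with audit", {
  rep <- apply_cohort_filters(enrollment_fixture())
  expect_equal(unname(rep$final_n["case"]), 47L)
  expect_equal(unname(rep$final_n["control"]), 50L)
  # remaining counts non-increasing; removals sum to input minus final
  for (g in c("case", "control")) {
    s <- rep$steps[rep$steps$group == g, ]
    expect_true(all(diff(s$n_remaining) <= 0))
    n0 <- sum(enrollment_fixture()$group == g)
    expect_equal(n0 - sum(s$n_removed), unname(rep$final_n[g]))
  }
  # all-pass input removes nobody
  clean <- enrollment_fixture()
  clean$consented <- TRUE; clean$image_evaluable <- TRUE
  clean$valve_type <- "TAV"; clean$prosthesis <- FALSE
  clean$blood_sample_available <- TRUE
  rep2 <- apply_cohort_filters(clean)
  expect_true(all(rep2$steps$n_removed == 0))
  expect_equal(sum(rep2$final_n), nrow(clean))
  bad <- clean; bad$valve_type[3] <- "unicuspid"
  expect_error(apply_cohort_filters(bad), "unknown valve label")
})

test_that("LLOQ exclusion drops exactly the mostly-censored biomarkers", {
  tab <- data.frame(group = rep(c("case", "control"), c(47, 50)),
                    A = runif(97), B = runif(97),
                    A_below_lloq = c(rep(TRUE, 60), rep(FALSE, 37)),
                    B_below_lloq = rep(FALSE, 97))
  ex <- lloq_exclude(tab)
  expect_equal(ex$excluded, "A")          # 60/97 = 0.62 > 0.5
  expect_true(all(c("B", "B_below_lloq") %in% names(ex$table)))
  expect_false("A" %in% names(ex$table))
  # generator ground truth: the two planted high-censoring biomarkers
  tb <- generate_cohort_table(default_cohort_spec(seed = 3))
  ex2 <- lloq_exclude(tb)
  expect_setequal(ex2$excluded, c("MMP12", "TIMP3"))
})

test_that("correlation table enumerates 216 cells and applies one BH family", {
  tb <- generate_cohort_table(default_cohort_spec(seed = 7))
  ex <- lloq_exclude(tb)
  ct <- build_correlation_table(ex$table)
  expect_equal(nrow(ct), 9 * 8 * 3)
  expect_equal(sort(unique(ct$stratum)), c("all", "cases", "controls"))
  expect_true(all(ct$n[ct$stratum == "cases"] == 47))
  expect_true(all(abs(ct$r) <= 1, na.rm = TRUE))
  # BH flags equal the oracle applied to the whole family
  expect_identical(ct$bh_rejected, bh_oracle(ct$p, 0.05))
  # single-cell family: BH decision reduces to p <= q
  ct1 <- build_correlation_table(ex$table, haemo_vars = "max_tawss",
                                 bio_vars = "IL6", strata = "cases")
  expect_equal(nrow(ct1), 1)
  expect_identical(ct1$bh_rejected, ct1$p <= 0.05)
})
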