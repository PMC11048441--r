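#' Two-sample Hotelling's T-squared test
#'
#' Multivariate generalisation of the pooled two-sample t-test:
#' `T2 = n1*n2/(n1+n2) * (m1 - m2)' S^-1 (m1 - m2)` with `S` the pooled
#' covariance, converted to an F statistic
#' `F = T2 * (n1 + n2 - p - 1) / (p * (n1 + n2 - 2))` on
#' `(p, n1 + n2 - p - 1)` degrees of freedom. The reported effect size is
#' partial eta squared, `T2 / (T2 + n1 + n2 - 2)`.
#'
#' @param a,b Numeric matrices (subjects in rows, the same variables in
#'   columns). Rows containing missing values are dropped listwise.
#' @return List of class `vot_test` with `statistic` (T2), `F`, `df`,
#'   `p_raw`, `effect` (partial eta squared), `n` used per group.
#' @export
hotelling_t2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b))
    stop("groups measure different variable sets", call. = FALSE)
  a <- a[stats::complete.cases(a), , drop = FALSE]
  b <- b[stats::complete.cases(b), , drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(b); p <- ncol(a)
  if (min(n1, n2) < 2L) stop("need at least 2 complete subjects per group", call. = FALSE)
  if (n1 + n2 - 2 <= p)
    stop("too few subjects (", n1 + n2, ") for ", p, " variables", call. = FALSE)
  S <- ((n1 - 1) * stats::cov(a) + (n2 - 1) * stats::cov(b)) / (n1 + n2 - 2)
  d <- colMeans(a) - colMeans(b)
  si <- tryCatch(solve(S, d), error = function(e)
    stop("collinear variables: pooled covariance is singular", call. = FALSE))
  t2 <- (n1 * n2 / (n1 + n2)) * sum(d * si)
  f <- t2 * (n1 + n2 - p - 1) / (p * (n1 + n2 - 2))
  df <- c(p, n1 + n2 - p - 1)
  structure(list(
    test_kind = "hotelling", statistic = t2, F = f, df = df,
    p_raw = stats::pf(f, df[1], df[2], lower.tail = FALSE), p_adj = NA_real_,
    effect = t2 / (t2 + n1 + n2 - 2), effect_kind = "partial_eta_sq",
    transform = "none", n = c(n1, n2)), class = "vot_test")
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(a) - mean(b)) / s_pooled`, where
#' `s_pooled^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`.
#'
#' @param a,b Numeric vectors (missing values dropped).
#' @return Signed effect size (positive when `a` has the larger mean).
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 observations per group", call. = FALSE)
  cohens_d_from_summary(mean(a), stats::sd(a), length(a),
                        mean(b), stats::sd(b), length(b))
}

#' Cohen's d from group summaries
#'
#' Same pooled-SD effect size as [cohens_d()], computed from reported group
#' means, standard deviations and sizes — useful for checking published
#' summary tables.
#'
#' @param mean1,sd1,n1 First group's mean, SD, size.
#' @param mean2,sd2,n2 Second group's mean, SD, size.
#' @return Signed effect size.
#' @export
cohens_d_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation", call. = FALSE)
  (mean1 - mean2) / sqrt(sp2)
}

#' Two-group comparison of one variable under a transform policy
#'
#' Applies the variable's designated treatment and tests for a group
#' difference: `"none"` and `"log"` use the pooled-variance (Student) two
#' sample t-test, with Cohen's d on the same (possibly transformed) scale;
#' `"mann_whitney"` uses the rank-sum U test (exact when both groups are
#' small and untied, normal approximation with tie correction otherwise)
#' and reports no d.
#'
#' @param a,b Numeric vectors (missing values dropped); by convention `a` is
#'   the first (e.g. climber) group.
#' @param policy `"none"`, `"log"` or `"mann_whitney"`.
#' @return List of class `vot_test` with `statistic`, `df`, `p_raw`,
#'   `effect` (Cohen's d or `NA`), `transform`, `n`.
#' @export
pairwise_compare <- function(a, b, policy = c("none", "log", "mann_whitney")) {
  policy <- match.arg(policy)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 observations per group", call. = FALSE)
  if (policy == "mann_whitney") {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
    return(structure(list(
      test_kind = "mann_whitney", statistic = unname(wt$statistic),
      F = NA_real_, df = c(NA_real_, NA_real_), p_raw = wt$p.value,
      p_adj = NA_real_, effect = NA_real_, effect_kind = "none",
      transform = "rank", n = c(length(a), length(b))), class = "vot_test"))
  }
  if (policy == "log") {
    if (any(a <= 0) || any(b <= 0))
      stop("log transform undefined for non-positive values", call. = FALSE)
    a <- log(a); b <- log(b)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  structure(list(
    test_kind = "t", statistic = unname(tt$statistic), F = NA_real_,
    df = c(unname(tt$parameter), NA_real_), p_raw = tt$p.value,
    p_adj = NA_real_, effect = cohens_d(a, b), effect_kind = "cohens_d",
    transform = policy, n = c(length(a), length(b))), class = "vot_test")
}

#' @export
print.vot_test <- function(x, ...) {
  cat(sprintf("<vot_test> %s%s: statistic = %.4g, p = %.4g%s%s\n",
              x$test_kind,
              if (x$transform != "none") paste0(" (", x$transform, ")") else "",
              x$statistic, x$p_raw,
              if (!is.na(x$p_adj)) sprintf(" (adj %.4g)", x$p_adj) else "",
              if (is.finite(x$effect))
                sprintf(", %s = %.3g", x$effect_kind, x$effect) else ""))
  invisible(x)
}

#' Bonferroni adjustment for a planned family of comparisons
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Family size; must be at least `length(p_values)`.
#' @return `pmin(1, m * p_values)`, order preserved.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (length(p_values) == 0L) return(numeric(0))
  if (m < length(p_values))
    stop("family size m smaller than the number of p-values", call. = FALSE)
  pmin(1, m * p_values)
}

#' Shapiro-Wilk normality screen
#'
#' @param values Numeric vector, 3 to 5000 non-missing observations.
#' @param alpha Decision threshold, default 0.05.
#' @return List with `statistic`, `p`, and `decision`
#'   (`"normal"`/`"non-normal"`).
#' @export
normality_check <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3L || length(values) > 5000L)
    stop("Shapiro-Wilk requires between 3 and 5000 observations", call. = FALSE)
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p = sw$p.value,
       decision = if (sw$p.value < alpha) "non-normal" else "normal")
}

#' Default per-variable transform policy
#'
#' Log transforms for the strongly right-skewed flow variables
#' (`oc_rbf_min`, `hy_rbf_max`, `hy_rbf_slope`) and `hy_d_tsi_max`; the
#' rank-sum test for `hy_rbf_htr`, which resists transformation; plain
#' t-tests elsewhere.
#'
#' @return Named character vector mapping every [vot_feature_names] entry to
#'   `"none"`, `"log"` or `"mann_whitney"`.
#' @export
default_transform_policy <- function() {
  pol <- stats::setNames(rep("none", length(vot_feature_names)), vot_feature_names)
  pol[c("oc_rbf_min", "hy_rbf_max", "hy_d_tsi_max", "hy_rbf_slope")] <- "log"
  pol["hy_rbf_htr"] <- "mann_whitney"
  pol
}

#' Default comparison families
#'
#' The planned-comparison families over which the multivariate tests run and
#' within which the Bonferroni correction is scoped: NIRS variables of the
#' occlusion phase, NIRS variables of the hyperemia phase, DCS variables of
#' the hyperemia phase, the baseline means, and the lone occlusion DCS
#' variable (`oc_rbf_min`, compared by a single t-test, not a multivariate
#' family).
#'
#' @return Named list of character vectors of feature names.
#' @export
default_family_map <- function() {
  list(
    ba = c("ba_o2hb", "ba_hhb", "ba_tsi", "ba_bfi"),
    oc_nirs = c("oc_d_o2hb_slope", "oc_d_hhb_slope", "oc_d_tsi_slope",
                "oc_d_o2hb_min", "oc_d_hhb_max", "oc_d_tsi_min",
                "oc_d_o2hb_tmin", "oc_d_hhb_tmax", "oc_d_tsi_tmin"),
    oc_dcs = "oc_rbf_min",
    hy_nirs = c("hy_d_o2hb_max", "hy_d_hhb_min", "hy_d_tsi_max",
                "hy_d_o2hb_tmax", "hy_d_hhb_tmin", "hy_d_tsi_tmax",
                "hy_d_o2hb_slope", "hy_d_hhb_slope", "hy_d_tsi_slope",
                "hy_d_o2hb_htr", "hy_d_hhb_htr", "hy_d_tsi_htr"),
    hy_dcs = c("hy_rbf_max", "hy_rbf_tmax", "hy_rbf_slope", "hy_rbf_htr"))
}

# families tested multivariately (the single-variable oc_dcs family and the
# baseline block are compared pairwise only)
.hotelling_families <- c("oc_nirs", "hy_nirs", "hy_dcs")

#' Full two-group statistical analysis of a cohort feature table
#'
#' Reproduces the study's statistical layer on a feature table from
#' [extract_cohort()]: one Hotelling's T-squared test per multivariate
#' family (occlusion NIRS, hyperemia NIRS, hyperemia DCS — on the same
#' per-variable scale as the pairwise tests, i.e. log where the policy says
#' so), a lone Student's t-test for the occlusion RBF floor, pairwise
#' comparisons for every variable under the transform policy, Bonferroni
#' correction scoped to each family, and Cohen's d effect sizes. Subjects
#' with missing values are dropped listwise within a multivariate family and
#' per-variable in pairwise tests.
#'
#' @param features Data frame with `group` plus the [vot_feature_names]
#'   columns.
#' @param groups Character pair naming the two group levels; the first is
#'   the reference whose larger mean yields positive d.
#' @param transform_policy See [default_transform_policy()].
#' @param family_map See [default_family_map()].
#' @param alpha Significance level applied to adjusted p-values.
#' @return List of class `vot_report` with data frames `families` and
#'   `pairwise`.
#' @export
run_family_analysis <- function(features,
                                groups = c("climber", "nonclimber"),
                                transform_policy = default_transform_policy(),
                                family_map = default_family_map(),
                                alpha = 0.05) {
  stopifnot(is.data.frame(features), "group" %in% names(features))
  g1 <- features[features$group == groups[1], , drop = FALSE]
  g2 <- features[features$group == groups[2], , drop = FALSE]
  if (nrow(g1) < 3L || nrow(g2) < 3L)
    stop("need at least 3 subjects per group", call. = FALSE)

  txf <- function(mat, vars) {
    for (v in vars)
      if (identical(transform_policy[[v]], "log")) mat[[v]] <- log(mat[[v]])
    as.matrix(mat[vars])
  }

  fam_rows <- list()
  skipped <- character(0)
  for (fam in intersect(.hotelling_families, names(family_map))) {
    vars <- intersect(family_map[[fam]], names(features))
    if (length(vars) < 2L) next
    n_complete <- sum(stats::complete.cases(g1[vars])) +
      sum(stats::complete.cases(g2[vars]))
    if (n_complete - 2 <= length(vars)) {
      skipped <- c(skipped, fam)  # too few complete subjects for the family
      next
    }
    ht <- hotelling_t2(txf(g1, vars), txf(g2, vars))
    fam_rows[[fam]] <- data.frame(
      family = fam, n_vars = length(vars), T2 = ht$statistic, F = ht$F,
      df1 = ht$df[1], df2 = ht$df[2], p = ht$p_raw,
      partial_eta_sq = ht$effect, n1 = ht$n[1], n2 = ht$n[2])
  }
  families <- do.call(rbind, fam_rows)
  rownames(families) <- NULL

  pw_rows <- list()
  for (fam in names(family_map)) {
    vars <- intersect(family_map[[fam]], names(features))
    m <- length(vars)
    for (v in vars) {
      pol <- if (is.null(transform_policy[[v]])) "none" else transform_policy[[v]]
      res <- pairwise_compare(g1[[v]], g2[[v]], pol)
      pw_rows[[v]] <- data.frame(
        variable = v, family = fam, m = m,
        mean1 = mean(g1[[v]], na.rm = TRUE), sd1 = stats::sd(g1[[v]], na.rm = TRUE),
        mean2 = mean(g2[[v]], na.rm = TRUE), sd2 = stats::sd(g2[[v]], na.rm = TRUE),
        n1 = res$n[1], n2 = res$n[2],
        test = res$test_kind, transform = res$transform,
        statistic = res$statistic, p_raw = res$p_raw, d = res$effect)
    }
  }
  pairwise <- do.call(rbind, pw_rows[vot_feature_names[vot_feature_names %in% names(pw_rows)]])
  # Bonferroni scoped to each family's planned comparisons
  pairwise$p_adj <- NA_real_
  for (fam in unique(pairwise$family)) {
    sel <- pairwise$family == fam
    pairwise$p_adj[sel] <- bonferroni_adjust(pairwise$p_raw[sel],
                                             m = pairwise$m[sel][1])
  }
  pairwise$significant <- pairwise$p_adj <= alpha
  rownames(pairwise) <- NULL
  structure(list(families = families, pairwise = pairwise,
                 skipped_families = skipped, groups = groups, alpha = alpha),
            class = "vot_report")
}

#' @export
print.vot_report <- function(x, ...) {
  cat("<vot_report> groups:", paste(x$groups, collapse = " vs "), "\n\n")
  cat("Multivariate family tests (Hotelling's T2):\n")
  if (is.null(x$families) || nrow(x$families) == 0L) cat("  none run\n") else
    print(transform(x$families, T2 = signif(T2, 4), F = signif(F, 4),
                    p = signif(p, 3), partial_eta_sq = signif(partial_eta_sq, 3)),
          row.names = FALSE)
  if (length(x$skipped_families))
    cat("  skipped (too few complete subjects):",
        paste(x$skipped_families, collapse = ", "), "\n")
  cat("\nSignificant pairwise comparisons (p_adj <= ", x$alpha, "):\n", sep = "")
  sig <- x$pairwise[!is.na(x$pairwise$p_adj) & x$pairwise$significant, ]
  if (nrow(sig) == 0L) cat("  none\n") else
    print(sig[c("variable", "test", "transform", "p_raw", "p_adj", "d")],
          row.names = FALSE)
  invisible(x)
}
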