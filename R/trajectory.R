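#' Per-sample median methylation over a CpG context
#'
#' Joins probe-level annotation to a beta table and computes, per sample, the
#' median beta over probes matching the filter. The canonical PMD solo-WCGW
#' series uses `domain == "commonPMD", solo, flank_class == "WCGW", !in_cgi`.
#'
#' @param beta Tibble with `probe_id` plus sample columns.
#' @param annotation Probe-level annotation with a `probe_id` column.
#' @param ... Filter expressions evaluated on the annotation columns.
#' @return Tibble with `sample_id`, `median_beta`, `n_probes` (non-missing
#'   probes per sample; `median_beta` is NA when all are missing).
#' @export
median_context_methylation <- function(beta, annotation, ...) {
  if (!"probe_id" %in% names(annotation)) {
    fail("`annotation` must carry a probe_id column (see annotate_manifest())")
  }
  sel <- dplyr::filter(as_tibble(annotation), ...)
  keep <- intersect(beta$probe_id, sel$probe_id)
  if (length(keep) == 0) {
    flt <- paste(purrr::map_chr(rlang::enquos(...), rlang::as_label),
                 collapse = " & ")
    fail("no probes match context filter: ",
         if (nzchar(flt)) flt else "<none given>")
  }
  m <- beta_as_matrix(beta)[keep, , drop = FALSE]
  tibble(
    sample_id = colnames(m),
    median_beta = unname(apply(m, 2, median, na.rm = TRUE)),
    n_probes = unname(colSums(!is.na(m)))
  ) |>
    dplyr::mutate(median_beta = ifelse(.data$n_probes == 0, NA_real_,
                                       .data$median_beta))
}

#' Per-CpG ordinary least squares of methylation on population doublings
#'
#' Regresses each probe's beta values on the samples' cumulative PDs. Slopes
#' are on the beta scale (change in fractional methylation per doubling).
#' Probes with fewer than 3 non-missing samples are returned with NA fit
#' fields.
#'
#' @param beta Tibble with `probe_id` plus sample columns.
#' @param sample_pds Tibble (`sample_id`, `pd`) or named numeric vector
#'   covering every sample column.
#' @return Tibble: `probe_id`, `slope`, `intercept`, `n`, `r_squared`,
#'   `slope_se`.
#' @export
fit_cpg_slopes <- function(beta, sample_pds) {
  m <- beta_as_matrix(beta)
  x <- as_pd_vector(sample_pds, colnames(m))
  if (length(unique(x)) < 2) fail("sample PDs are constant; cannot fit slopes")

  obs <- !is.na(m)
  m0 <- ifelse(obs, m, 0)
  n <- rowSums(obs)
  sx <- obs %*% x
  sxx <- obs %*% x^2
  sy <- rowSums(m0)
  sxy <- m0 %*% x
  syy <- rowSums(m0^2)

  sxx_c <- sxx - sx^2 / n
  sxy_c <- sxy - sx * sy / n
  syy_c <- syy - sy^2 / n

  slope <- as.numeric(sxy_c / sxx_c)
  intercept <- as.numeric(sy / n - slope * sx / n)
  ss_res <- pmax(as.numeric(syy_c) - slope^2 * as.numeric(sxx_c), 0)
  r_squared <- ifelse(as.numeric(syy_c) > 0,
                      1 - ss_res / as.numeric(syy_c), NA_real_)
  slope_se <- ifelse(n > 2,
                     sqrt(ss_res / (n - 2) / as.numeric(sxx_c)), NA_real_)

  ok <- unname(n >= 3 & as.numeric(sxx_c) > 0)
  n <- unname(n)
  tibble(
    probe_id = rownames(m),
    slope = ifelse(ok, slope, NA_real_),
    intercept = ifelse(ok, intercept, NA_real_),
    n = as.integer(n),
    r_squared = ifelse(ok, r_squared, NA_real_),
    slope_se = ifelse(ok, slope_se, NA_real_)
  )
}

#' Categorise CpG behaviour across a culture series
#'
#' Anchors each probe at the mean beta of the earliest-PD samples (parallel
#' subcultures averaged) and of the latest-PD samples. A probe is `variable`
#' when `|last - first| > change_threshold`; otherwise `stable_methylated`
#' when its starting beta is at or above `high`, `stable_unmethylated` when at
#' or below `low`, and otherwise assigned to the nearer stable bound.
#' Variable probes carry a loss/gain direction and a quartile (1-4) of
#' starting beta within the variable set.
#'
#' @param beta Tibble with `probe_id` plus sample columns.
#' @param sample_pds Tibble (`sample_id`, `pd`) or named vector.
#' @param change_threshold Minimum absolute change to call a probe variable
#'   (default 0.10).
#' @param high,low Stable-group starting-beta bounds (defaults 0.70 / 0.30).
#' @return Tibble: `probe_id`, `beta_first`, `beta_last`, `category`,
#'   `direction`, `quartile`.
#' @export
categorize_cpgs <- function(beta, sample_pds, change_threshold = 0.10,
                            high = 0.70, low = 0.30) {
  if (low >= high) fail("`low` must be below `high`")
  if (change_threshold <= 0) fail("`change_threshold` must be positive")
  m <- beta_as_matrix(beta)
  x <- as_pd_vector(sample_pds, colnames(m))
  first_cols <- which(x == min(x))
  last_cols <- which(x == max(x))
  if (min(x) == max(x)) fail("sample PDs are constant; no first/last anchor")
  beta_first <- rowMeans(m[, first_cols, drop = FALSE], na.rm = TRUE)
  beta_last <- rowMeans(m[, last_cols, drop = FALSE], na.rm = TRUE)

  delta <- beta_last - beta_first
  category <- dplyr::case_when(
    is.na(delta) ~ NA_character_,
    abs(delta) > change_threshold ~ "variable",
    beta_first >= high ~ "stable_methylated",
    beta_first <= low ~ "stable_unmethylated",
    # intermediate start, stable trajectory: nearest stable bound
    (high - beta_first) <= (beta_first - low) ~ "stable_methylated",
    TRUE ~ "stable_unmethylated"
  )
  out <- tibble(
    probe_id = rownames(m),
    beta_first = as.numeric(beta_first),
    beta_last = as.numeric(beta_last),
    category = category,
    direction = ifelse(category == "variable",
                       ifelse(delta < 0, "loss", "gain"), NA_character_)
  )
  out$quartile <- NA_integer_
  vr <- which(out$category == "variable")
  if (length(vr) > 0) {
    out$quartile[vr] <- dplyr::ntile(out$beta_first[vr], 4)
  }
  out
}

#' Compare methylation-loss slopes between groups
#'
#' Fixed-effects interaction test on M-values: fits
#' `m ~ pd * group (+ subculture)` by OLS and tests the PD-by-group
#' interaction against the no-interaction model. For two groups the
#' interaction coefficient is the slope difference.
#'
#' @param data Long tibble with one row per observation.
#' @param value,pd,group Columns holding the methylation value, population
#'   doublings, and group label (tidy-eval; defaults `beta`, `pd`, `group`).
#' @param subculture Optional column identifying parallel subcultures, added
#'   as a fixed covariate.
#' @param transform `"m"` (default) logit-transforms beta-scale values before
#'   fitting; `"none"` fits the values as given.
#' @param eps Clipping constant for the M-transform.
#' @return One-row tibble: `estimate` (slope difference; NA for > 2 groups),
#'   `std_error`, `statistic` (interaction F), `df`, `df_residual`,
#'   `p_value`, `n_groups`.
#' @export
compare_slopes <- function(data, value = beta, pd = pd, group = group,
                           subculture = NULL, transform = c("m", "none"),
                           eps = 1e-6) {
  transform <- match.arg(transform)
  y <- dplyr::pull(data, {{ value }})
  x <- dplyr::pull(data, {{ pd }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  sub_q <- rlang::enquo(subculture)
  has_sub <- !rlang::quo_is_null(sub_q)

  if (nlevels(g) < 2) fail("need at least 2 groups to compare slopes")
  sizes <- table(g)
  if (any(sizes < 3)) {
    fail("group(s) with fewer than 3 samples: ",
         paste(names(sizes)[sizes < 3], collapse = ", "))
  }
  spread <- tapply(x, g, function(v) length(unique(v)))
  if (any(spread < 2)) fail("PDs do not vary within every group")
  if (transform == "m") y <- beta_to_m(y, eps = eps)

  df <- data.frame(y = y, x = x, g = g)
  if (has_sub) {
    df$sub <- as.factor(dplyr::pull(data, !!sub_q))
    full <- lm(y ~ x * g + sub, data = df)
    reduced <- lm(y ~ x + g + sub, data = df)
  } else {
    full <- lm(y ~ x * g, data = df)
    reduced <- lm(y ~ x + g, data = df)
  }
  an <- anova(reduced, full)
  fstat <- an$F[2]
  p <- an$`Pr(>F)`[2]
  df_num <- an$Df[2]
  df_res <- an$Res.Df[2]

  est <- se <- NA_real_
  if (nlevels(g) == 2) {
    cf <- summary(full)$coefficients
    term <- grep("^x:g", rownames(cf), value = TRUE)
    est <- unname(cf[term, "Estimate"])
    se <- unname(cf[term, "Std. Error"])
  }
  # degenerate identical groups: zero interaction SS and zero residual noise
  if (!is.finite(p)) {
    if (isTRUE(abs(an$`Sum of Sq`[2]) < 1e-12) ||
        (is.finite(est) && abs(est) < 1e-12)) {
      p <- 1
      fstat <- 0
      if (is.finite(est) && abs(est) < 1e-12) est <- 0
    }
  }
  tibble(estimate = est, std_error = se, statistic = fstat,
         df = df_num, df_residual = df_res, p_value = p,
         n_groups = nlevels(g))
}

#' Test for methylation change between two sample groups
#'
#' Paired location test across probes of mean M-values: each probe
#' contributes its mean M over the `post` samples minus its mean M over the
#' `pre` samples, and the differences are tested against zero with a t-test.
#' `alternative = "less"` tests for methylation loss.
#'
#' @param beta Tibble with `probe_id` plus sample columns.
#' @param pre,post Character vectors of sample ids.
#' @param alternative `"less"` (default), `"greater"` or `"two.sided"`.
#' @param eps Clipping constant for the M-transform.
#' @return One-row tibble: `estimate` (mean M difference), `statistic`,
#'   `p_value`, `n_probes`, `alternative`.
#' @export
test_methylation_change <- function(beta, pre, post,
                                    alternative = c("less", "greater",
                                                    "two.sided"),
                                    eps = 1e-6) {
  alternative <- match.arg(alternative)
  if (length(pre) == 0 || length(post) == 0) {
    fail("`pre` and `post` sample groups must be non-empty")
  }
  m <- beta_as_matrix(beta)
  absent <- setdiff(c(pre, post), colnames(m))
  if (length(absent) > 0) {
    fail("sample(s) not in beta table: ", paste(absent, collapse = ", "))
  }
  mv <- matrix(beta_to_m(m, eps = eps), nrow = nrow(m),
               dimnames = dimnames(m))
  pre_mean <- rowMeans(mv[, pre, drop = FALSE], na.rm = TRUE)
  post_mean <- rowMeans(mv[, post, drop = FALSE], na.rm = TRUE)
  d <- post_mean - pre_mean
  d <- d[is.finite(d)]
  if (length(d) < 2) fail("need at least 2 probes with complete values")
  est <- mean(d)
  s <- sd(d)
  if (s == 0) {
    # all differences identical: degenerate t
    p <- if (est == 0) 0.5 else {
      switch(alternative,
             less = as.numeric(est < 0),
             greater = as.numeric(est > 0),
             two.sided = 0)
    }
    stat <- if (est == 0) 0 else sign(est) * Inf
  } else {
    stat <- est / (s / sqrt(length(d)))
    p <- switch(alternative,
                less = pt(stat, df = length(d) - 1),
                greater = pt(stat, df = length(d) - 1, lower.tail = FALSE),
                two.sided = 2 * pt(abs(stat), df = length(d) - 1,
                                   lower.tail = FALSE))
  }
  tibble(estimate = est, statistic = stat, p_value = p,
         n_probes = length(d), alternative = alternative)
}

#' Bin per-CpG slopes by a covariate and test for a bin effect
#'
#' Splits probes into `k` equal-count covariate bins (quantile bins, ties
#' broken by order) and applies a Kruskal-Wallis rank test of the slope
#' distributions across bins.
#'
#' @param data Tibble with at least the slope and covariate columns.
#' @param covariate Column to bin on (tidy-eval).
#' @param slope Column of per-probe slopes (default `slope`).
#' @param k Number of bins (default 5, quintiles).
#' @return A `bin_comparison` object; see [tidy()] for per-bin summaries and
#'   [glance()] for the omnibus test.
#' @export
bin_and_compare <- function(data, covariate, slope = slope, k = 5) {
  if (!is_scalar_number(k) || k < 2) fail("`k` must be an integer >= 2")
  cov <- dplyr::pull(data, {{ covariate }})
  sl <- dplyr::pull(data, {{ slope }})
  keep <- !is.na(cov) & !is.na(sl)
  cov <- cov[keep]
  sl <- sl[keep]
  if (length(cov) < k) {
    fail("need at least k probes with covariate values (have ",
         length(cov), ", k = ", k, ")")
  }
  bin <- dplyr::ntile(cov, k)
  kw <- kruskal.test(sl, factor(bin))
  bins <- tibble(bin = bin, covariate = cov, slope = sl) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     covariate_median = median(.data$covariate),
                     median_slope = median(.data$slope),
                     q1_slope = quantile(.data$slope, 0.25),
                     q3_slope = quantile(.data$slope, 0.75),
                     .groups = "drop")
  structure(
    list(bins = bins,
         data = tibble(bin = bin, covariate = cov, slope = sl),
         statistic = unname(kw$statistic),
         df = unname(kw$parameter),
         p_value = kw$p.value,
         k = k),
    class = "bin_comparison"
  )
}

#' @export
print.bin_comparison <- function(x, ...) {
  cat("CpG slope distribution across", x$k, "covariate bins\n")
  cat(sprintf("Kruskal-Wallis chi-squared = %.3g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  print(x$bins)
  invisible(x)
}

#' @rdname bin_and_compare
#' @param x A `bin_comparison` object.
#' @param ... Unused.
#' @export
#' @method tidy bin_comparison
tidy.bin_comparison <- function(x, ...) x$bins

#' @rdname bin_and_compare
#' @export
#' @method glance bin_comparison
glance.bin_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value, k = x$k)
}
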