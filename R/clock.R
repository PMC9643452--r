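#' Construct a replicative-history clock object
#'
#' Low-level constructor; most users obtain clocks from
#' [train_reference_model()], [train_replitali()] or [read_clock()].
#'
#' @param intercept Intercept in population doublings.
#' @param coefficients Tibble with `probe_id`, `coefficient`,
#'   `training_mean` (mean training beta, used for opt-in imputation).
#' @param metadata Named list of training metadata (alpha, lambda, seed, ...).
#' @param test Optional tibble of held-out `sample_id`, `observed`,
#'   `predicted` pairs.
#' @return A `replitali_clock` object.
#' @export
new_replitali_clock <- function(intercept, coefficients,
                                metadata = list(), test = NULL) {
  stopifnot(is_scalar_number(intercept),
            is.data.frame(coefficients),
            all(c("probe_id", "coefficient", "training_mean") %in%
                  names(coefficients)))
  if (nrow(coefficients) < 1) {
    fail("a clock needs at least one nonzero probe coefficient")
  }
  structure(list(intercept = intercept,
                 coefficients = as_tibble(coefficients),
                 metadata = metadata,
                 test = test),
            class = "replitali_clock")
}

#' @export
print.replitali_clock <- function(x, ...) {
  cat("Replicative-history clock:", nrow(x$coefficients),
      "probes, intercept", signif(x$intercept, 5), "PD\n")
  md <- x$metadata
  if (!is.null(md$alpha)) {
    cat(sprintf("  elastic net alpha = %s, lambda = %s\n",
                format(md$alpha), format(signif(md$lambda %||% NA, 4))))
  }
  if (!is.null(md$test_rmse)) {
    cat(sprintf("  test RMSE = %.3g PD, test R^2 = %.3f (n = %d)\n",
                md$test_rmse, md$test_r_squared, nrow(x$test)))
  }
  invisible(x)
}

#' @rdname new_replitali_clock
#' @param x A `replitali_clock` object.
#' @param ... Unused.
#' @export
#' @method tidy replitali_clock
tidy.replitali_clock <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "(Intercept)", estimate = x$intercept,
           training_mean = NA_real_),
    tibble(term = x$coefficients$probe_id,
           estimate = x$coefficients$coefficient,
           training_mean = x$coefficients$training_mean)
  )
}

#' @rdname new_replitali_clock
#' @export
#' @method glance replitali_clock
glance.replitali_clock <- function(x, ...) {
  md <- x$metadata
  tibble(n_probes = nrow(x$coefficients),
         alpha = md$alpha %||% NA_real_,
         lambda = md$lambda %||% NA_real_,
         seed = md$seed %||% NA_integer_,
         n_train = length(md$training_samples %||% character()),
         n_test = if (is.null(x$test)) 0L else nrow(x$test),
         test_rmse = md$test_rmse %||% NA_real_,
         test_r_squared = md$test_r_squared %||% NA_real_)
}

# shared elastic-net core: X samples x probes (may contain NA), y doublings.
# lambda = NULL -> 10-fold CV at alpha with seeded folds, take lambda.min.
fit_elastic_net <- function(X, y, alpha, seed, nfolds = 10, lambda = NULL) {
  all_missing <- colSums(!is.na(X)) == 0
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing), " probe(s) with no observed beta",
            call. = FALSE)
    X <- X[, !all_missing, drop = FALSE]
  }
  col_means <- colMeans(X, na.rm = TRUE)
  na_idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na_idx) > 0) X[na_idx] <- col_means[na_idx[, 2]]
  if (length(unique(y)) < 2) fail("training PDs are constant")

  set.seed(seed)
  if (is.null(lambda)) {
    # keep at least 3 observations per CV fold
    nfolds <- max(3, min(nfolds, floor(nrow(X) / 3)))
    foldid <- sample(rep(seq_len(nfolds), length.out = nrow(X)))
    cvfit <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                               standardize = TRUE)
    lambda <- cvfit$lambda.min
    fit <- cvfit$glmnet.fit
  } else {
    # explicit path ending at the requested penalty keeps the fit
    # independent of the data-derived default path
    fit <- glmnet::glmnet(X, y, alpha = alpha, standardize = TRUE,
                          lambda = lambda * c(100, 10, 1))
  }
  cf <- as.matrix(coef(fit, s = lambda, exact = FALSE))
  intercept <- cf[1, 1]
  w <- cf[-1, 1]
  nz <- which(w != 0)
  if (length(nz) == 0) {
    fail("elastic net selected no probes; training signal too weak")
  }
  list(intercept = intercept,
       coefficients = tibble(probe_id = colnames(X)[nz],
                             coefficient = unname(w[nz]),
                             training_mean = unname(col_means[nz])),
       lambda = lambda)
}

#' Train a reference elastic-net model of population doublings
#'
#' Fits an elastic net (default alpha 0.5, glmnet) of cumulative PD on beta
#' values of a single reference culture. The penalty is chosen by seeded
#' 10-fold cross-validation (minimum mean CV error) unless `lambda` is given.
#' Used to predict the starting replicative age of other lineages in
#' [normalize_pds()].
#'
#' @param beta Tibble with `probe_id` plus sample columns.
#' @param sample_pds Tibble (`sample_id`, `pd`) or named vector for every
#'   sample column.
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param seed Integer seed controlling fold assignment.
#' @param nfolds Cross-validation folds (default 10).
#' @param lambda Optional fixed penalty, skipping cross-validation.
#' @return A `replitali_clock`.
#' @export
train_reference_model <- function(beta, sample_pds, alpha = 0.5, seed = 1,
                                  nfolds = 10, lambda = NULL) {
  m <- beta_as_matrix(beta)
  y <- as_pd_vector(sample_pds, colnames(m))
  if (ncol(m) < 8) fail("need at least 8 reference samples")
  fit <- fit_elastic_net(t(m), unname(y), alpha = alpha, seed = seed,
                         nfolds = nfolds, lambda = lambda)
  new_replitali_clock(fit$intercept, fit$coefficients,
                      metadata = list(alpha = alpha, lambda = fit$lambda,
                                      seed = seed, nfolds = nfolds,
                                      training_samples = colnames(m)))
}

#' Apply a clock to a beta table
#'
#' Linear predictor `intercept + sum(coef_i * beta_i)` per sample. Probes
#' absent from the table (or missing in a sample) are a hard error unless
#' `impute = TRUE`, in which case stored training means are substituted and
#' the per-sample imputation count reported.
#'
#' @param clock A `replitali_clock`.
#' @param beta Tibble with `probe_id` plus sample columns.
#' @param impute Impute missing clock probes with training means
#'   (default `FALSE`).
#' @return Tibble: `sample_id`, `estimate` (doublings), `n_imputed`.
#' @export
apply_clock <- function(clock, beta, impute = FALSE) {
  stopifnot(inherits(clock, "replitali_clock"))
  m <- beta_as_matrix(beta)
  probes <- clock$coefficients$probe_id
  absent <- setdiff(probes, rownames(m))
  sub <- matrix(NA_real_, nrow = length(probes), ncol = ncol(m),
                dimnames = list(probes, colnames(m)))
  present <- intersect(probes, rownames(m))
  sub[present, ] <- m[present, , drop = FALSE]
  n_missing <- colSums(is.na(sub))
  if (!impute && (length(absent) > 0 || any(n_missing > 0))) {
    miss <- union(absent, probes[rowSums(is.na(sub)) > 0])
    fail("clock probe(s) missing from beta table: ",
         paste(head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (+%d more)", length(miss) - 10),
         "; rerun with impute = TRUE to use training means")
  }
  if (impute && any(n_missing > 0)) {
    tm <- clock$coefficients$training_mean
    if (anyNA(tm)) fail("clock has no stored training means; cannot impute")
    na_idx <- which(is.na(sub), arr.ind = TRUE)
    sub[na_idx] <- tm[na_idx[, 1]]
  }
  est <- clock$intercept +
    as.numeric(crossprod(sub, clock$coefficients$coefficient))
  tibble(sample_id = colnames(m), estimate = est,
         n_imputed = unname(as.integer(n_missing)))
}

#' @export
predict.replitali_clock <- function(object, beta, impute = FALSE, ...) {
  apply_clock(object, beta, impute = impute)
}

#' Normalise culture PDs onto a reference replicative-age scale
#'
#' For each lineage, the reference model predicts the replicative age of the
#' lineage's earliest-PD sample; that prediction becomes the lineage's
#' normalised starting PD, and every later sample adds its observed PD
#' increment to it. The reference lineage itself keeps its observed PDs.
#'
#' @param reference A `replitali_clock` trained on the reference culture.
#' @param sheet Sample sheet with `sample_id`, `lineage`, `cumulative_pd`
#'   (see [read_sample_sheet()]).
#' @param beta Tibble with `probe_id` plus sample columns covering at least
#'   each lineage's earliest sample.
#' @param reference_lineage Lineage name to pass through unchanged (optional).
#' @param impute Passed to [apply_clock()] for the start-sample predictions.
#' @return Tibble: `sample_id`, `lineage`, `observed_pd`, `normalized_pd`,
#'   `start_pd` (predicted start), `is_reference`.
#' @export
normalize_pds <- function(reference, sheet, beta, reference_lineage = NULL,
                          impute = FALSE) {
  stopifnot(inherits(reference, "replitali_clock"))
  need <- c("sample_id", "lineage", "cumulative_pd")
  if (!all(need %in% names(sheet))) {
    fail("`sheet` must have columns ", paste(need, collapse = ", "),
         " (see read_sample_sheet())")
  }
  sheet <- dplyr::arrange(as_tibble(sheet), .data$lineage,
                          .data$cumulative_pd)
  starts <- sheet |>
    dplyr::group_by(.data$lineage) |>
    dplyr::slice_min(.data$cumulative_pd, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  missing_start <- setdiff(starts$sample_id, names(beta))
  if (length(missing_start) > 0) {
    fail("no beta values for lineage start sample(s): ",
         paste(missing_start, collapse = ", "))
  }
  start_beta <- dplyr::select(beta, "probe_id",
                              dplyr::all_of(starts$sample_id))
  pred <- apply_clock(reference, start_beta, impute = impute)
  starts <- dplyr::left_join(
    starts, dplyr::select(pred, "sample_id", start_pred = "estimate"),
    by = "sample_id")

  out <- sheet |>
    dplyr::left_join(dplyr::select(starts, "lineage",
                                   start_obs = "cumulative_pd", "start_pred"),
                     by = "lineage") |>
    dplyr::mutate(
      is_reference = !is.null(reference_lineage) &
        .data$lineage %in% reference_lineage,
      start_pd = ifelse(.data$is_reference, .data$start_obs,
                        .data$start_pred),
      normalized_pd = ifelse(
        .data$is_reference, .data$cumulative_pd,
        .data$start_pred + (.data$cumulative_pd - .data$start_obs))
    )
  dplyr::select(out, "sample_id", "lineage",
                observed_pd = "cumulative_pd", "normalized_pd",
                "start_pd", "is_reference")
}

#' Train a replicative-history clock on common-PMD CpGs
#'
#' The RepliTali training procedure: eligible probes are restricted to those
#' inside common PMD boundaries (all flank contexts), samples are randomly
#' split into training and test sets, an elastic net of normalised PD on
#' beta is fitted on the training set (seeded 10-fold CV chooses the
#' penalty), and held-out performance is reported.
#'
#' @param beta Tibble with `probe_id` plus sample columns.
#' @param sample_pds Normalised PDs: tibble (`sample_id`, `pd`), a named
#'   vector, or the output of [normalize_pds()] (its `normalized_pd` is used).
#' @param annotation Probe-level annotation with `probe_id` and `domain`;
#'   only `domain == "commonPMD"` probes are eligible.
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param test_fraction Fraction of samples held out (default 1/3).
#' @param seed Integer seed for the split and CV folds.
#' @param nfolds Cross-validation folds (default 10).
#' @param stratify_by Optional vector (named by sample id) to stratify the
#'   split, e.g. cell line; off by default.
#' @return A `replitali_clock` with held-out pairs in `$test` and test RMSE /
#'   R-squared in the metadata.
#' @export
train_replitali <- function(beta, sample_pds, annotation, alpha = 0.5,
                            test_fraction = 1 / 3, seed = 1, nfolds = 10,
                            stratify_by = NULL) {
  if (is.data.frame(sample_pds) && "normalized_pd" %in% names(sample_pds)) {
    sample_pds <- tibble(sample_id = sample_pds$sample_id,
                         pd = sample_pds$normalized_pd)
  }
  m <- beta_as_matrix(beta)
  y <- as_pd_vector(sample_pds, colnames(m))
  if (ncol(m) < 20) fail("need at least 20 samples to train")
  if (test_fraction <= 0 || test_fraction >= 1) {
    fail("`test_fraction` must lie in (0, 1)")
  }
  if (!all(c("probe_id", "domain") %in% names(annotation))) {
    fail("`annotation` must have columns probe_id and domain")
  }
  pool <- intersect(rownames(m),
                    annotation$probe_id[annotation$domain == "commonPMD"])
  if (length(pool) == 0) fail("no probes inside common PMD boundaries")
  m <- m[pool, , drop = FALSE]

  set.seed(seed)
  n <- ncol(m)
  n_test <- max(1L, round(test_fraction * n))
  if (is.null(stratify_by)) {
    test_idx <- sort(sample(n, n_test))
  } else {
    strata <- split(seq_len(n), stratify_by[colnames(m)])
    test_idx <- sort(unlist(purrr::map(strata, function(ix) {
      sample(ix, max(1L, round(test_fraction * length(ix))))
    }), use.names = FALSE))
  }
  train_idx <- setdiff(seq_len(n), test_idx)

  fit <- fit_elastic_net(t(m[, train_idx, drop = FALSE]),
                         unname(y[train_idx]), alpha = alpha,
                         seed = seed, nfolds = nfolds)
  clock <- new_replitali_clock(
    fit$intercept, fit$coefficients,
    metadata = list(alpha = alpha, lambda = fit$lambda, seed = seed,
                    nfolds = nfolds, n_probe_pool = length(pool),
                    training_samples = colnames(m)[train_idx],
                    test_samples = colnames(m)[test_idx]))

  test_beta <- matrix_as_beta(m[, test_idx, drop = FALSE])
  pred <- apply_clock(clock, test_beta, impute = TRUE)
  obs <- unname(y[test_idx])
  resid <- obs - pred$estimate
  clock$test <- tibble(sample_id = pred$sample_id, observed = obs,
                       predicted = pred$estimate)
  clock$metadata$test_rmse <- sqrt(mean(resid^2))
  clock$metadata$test_r_squared <- cor(obs, pred$estimate)^2
  clock
}

#' Construct a dual-set (gain/loss) mitotic clock
#'
#' An epiCMIT-style estimator: one probe set gains methylation with
#' divisions, the other loses it; each set is scored linearly in its mean
#' methylation and the larger score wins.
#'
#' @param hyper_probes,hypo_probes Disjoint, non-empty probe id sets.
#' @param hyper_intercept,hyper_slope Linear score of the gaining set
#'   (`slope > 0`).
#' @param hypo_intercept,hypo_slope Linear score of the losing set
#'   (`slope < 0`).
#' @return A `dual_set_clock` object.
#' @export
dual_set_clock <- function(hyper_probes, hypo_probes,
                           hyper_intercept = 0, hyper_slope = 1,
                           hypo_intercept = 1, hypo_slope = -1) {
  if (length(hyper_probes) == 0 || length(hypo_probes) == 0) {
    fail("both probe sets must be non-empty")
  }
  if (length(intersect(hyper_probes, hypo_probes)) > 0) {
    fail("hyper and hypo probe sets must be disjoint")
  }
  if (hyper_slope <= 0 || hypo_slope >= 0) {
    fail("hyper_slope must be > 0 and hypo_slope < 0 ",
         "(scores increase with divisions)")
  }
  structure(list(hyper_probes = unique(hyper_probes),
                 hypo_probes = unique(hypo_probes),
                 hyper_intercept = hyper_intercept,
                 hyper_slope = hyper_slope,
                 hypo_intercept = hypo_intercept,
                 hypo_slope = hypo_slope),
            class = "dual_set_clock")
}

#' Apply a dual-set clock
#'
#' Per sample, scores the gaining and losing sets from their mean beta and
#' returns the maximum as the mitotic-age estimate.
#'
#' @param clock A [dual_set_clock()].
#' @param beta Tibble with `probe_id` plus sample columns.
#' @return Tibble: `sample_id`, `score_hyper`, `score_hypo`, `estimate`,
#'   `selected` ("hyper"/"hypo"), `tie`.
#' @export
apply_dual_clock <- function(clock, beta) {
  stopifnot(inherits(clock, "dual_set_clock"))
  m <- beta_as_matrix(beta)
  hyper <- intersect(clock$hyper_probes, rownames(m))
  hypo <- intersect(clock$hypo_probes, rownames(m))
  if (length(hyper) == 0) fail("no hypermethylation-set probes in beta table")
  if (length(hypo) == 0) fail("no hypomethylation-set probes in beta table")
  mean_hyper <- colMeans(m[hyper, , drop = FALSE], na.rm = TRUE)
  mean_hypo <- colMeans(m[hypo, , drop = FALSE], na.rm = TRUE)
  s_hyper <- clock$hyper_intercept + clock$hyper_slope * mean_hyper
  s_hypo <- clock$hypo_intercept + clock$hypo_slope * mean_hypo
  tibble(sample_id = colnames(m),
         score_hyper = unname(s_hyper),
         score_hypo = unname(s_hypo),
         estimate = unname(pmax(s_hyper, s_hypo)),
         selected = unname(ifelse(s_hyper >= s_hypo, "hyper", "hypo")),
         tie = unname(s_hyper == s_hypo))
}

#' Context composition of a clock's probes
#'
#' Cross-references a clock's coefficients with a probe annotation and
#' reports, per context class (PMD solo-WCGW, PMD other, non-PMD), the probe
#' count, fraction of the model, and mean coefficient, plus an `all` row over
#' every model probe. Unannotated probes are excluded from class rows with a
#' warning but still count toward `all`.
#'
#' @param clock A `replitali_clock`.
#' @param annotation Probe-level annotation with `probe_id`, `domain`,
#'   `solo`, `flank_class`.
#' @return Tibble: `class`, `n`, `fraction`, `mean_coefficient`.
#' @export
summarize_model <- function(clock, annotation) {
  stopifnot(inherits(clock, "replitali_clock"))
  need <- c("probe_id", "domain", "solo", "flank_class")
  if (!all(need %in% names(annotation))) {
    fail("`annotation` must have columns ", paste(need, collapse = ", "))
  }
  cf <- dplyr::left_join(clock$coefficients,
                         dplyr::select(annotation, dplyr::all_of(need)),
                         by = "probe_id")
  unann <- cf$probe_id[is.na(cf$domain)]
  if (length(unann) > 0) {
    warning(length(unann), " model probe(s) not in annotation: ",
            paste(head(unann, 5), collapse = ", "), call. = FALSE)
  }
  total <- nrow(cf)
  cls <- cf |>
    dplyr::filter(!is.na(.data$domain)) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$domain == "commonPMD" & .data$solo &
        .data$flank_class == "WCGW" ~ "PMD solo-WCGW",
      .data$domain == "commonPMD" ~ "PMD other",
      TRUE ~ "non-PMD"
    ))
  levels <- c("PMD solo-WCGW", "PMD other", "non-PMD")
  by_class <- purrr::map(levels, function(lv) {
    sub <- cls[cls$class == lv, , drop = FALSE]
    tibble(class = lv, n = nrow(sub), fraction = nrow(sub) / total,
           mean_coefficient = if (nrow(sub) > 0) mean(sub$coefficient)
                              else NA_real_)
  })
  dplyr::bind_rows(
    tibble(class = "all", n = total, fraction = 1,
           mean_coefficient = mean(cf$coefficient)),
    dplyr::bind_rows(by_class)
  )
}
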