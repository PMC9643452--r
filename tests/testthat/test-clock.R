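test_that("clock application is the linear predictor with strict missing policy", {
  clock <- new_replitali_clock(
    10, tibble::tibble(probe_id = "cg1", coefficient = -5,
                       training_mean = 0.6))
  beta <- toy_beta(matrix(0.5, 1, 1), probes = "cg1", samples = "s1")
  expect_equal(apply_clock(clock, beta)$estimate, 7.5)

  other <- toy_beta(matrix(0.5, 1, 1), probes = "cgX", samples = "s1")
  expect_error(apply_clock(clock, other), "cg1")
  imp <- apply_clock(clock, other, impute = TRUE)
  expect_equal(imp$estimate, 10 - 5 * 0.6)
  expect_equal(imp$n_imputed, 1L)

  # predict() dispatches to the same computation
  expect_equal(predict(clock, beta)$estimate, 7.5)
})

test_that("elastic-net training is deterministic and recovers dominant signal", {
  set.seed(31)
  n <- 24
  pd <- seq(2, 48, length.out = n)
  names(pd) <- sprintf("s%02d", 1:n)
  m <- matrix(runif(40 * n, 0.2, 0.8), 40, n)
  m[1, ] <- pmin(pmax(0.9 - 0.012 * pd, 0), 1) # single perfectly linear probe
  beta <- toy_beta(m, probes = sprintf("cg%03d", 1:40))

  fit1 <- train_reference_model(beta, pd, seed = 9)
  fit2 <- train_reference_model(beta, pd, seed = 9)
  expect_identical(fit1$coefficients, fit2$coefficients)
  expect_identical(fit1$intercept, fit2$intercept)
  expect_true("cg001" %in% fit1$coefficients$probe_id)
})

test_that("shifting all training PDs only shifts the intercept", {
  set.seed(32)
  n <- 30
  pd <- seq(0, 60, length.out = n)
  names(pd) <- sprintf("s%02d", 1:n)
  m <- matrix(pmin(pmax(
    outer(runif(60, -0.01, -0.002), pd) + runif(60, 0.5, 0.95) +
      rnorm(60 * n, 0, 0.02), 0), 1), 60, n)
  beta <- toy_beta(m, probes = sprintf("cg%03d", 1:60))
  f0 <- train_reference_model(beta, pd, seed = 4)
  f1 <- train_reference_model(beta, pd + 100, seed = 4)
  expect_equal(f1$intercept - f0$intercept, 100, tolerance = 1e-6)
  expect_equal(f1$coefficients$coefficient, f0$coefficients$coefficient,
               tolerance = 1e-6)
})

test_that("duplicating every training sample leaves the fit unchanged", {
  set.seed(33)
  n <- 16
  pd <- seq(0, 45, length.out = n)
  names(pd) <- sprintf("s%02d", 1:n)
  m <- matrix(pmin(pmax(
    outer(runif(30, -0.01, -0.002), pd) + 0.8 + rnorm(30 * n, 0, 0.02),
    0), 1), 30, n)
  beta <- toy_beta(m, probes = sprintf("cg%03d", 1:30))
  dup <- dplyr::bind_cols(beta,
                          stats::setNames(beta[-1], paste0(names(beta)[-1], "_b")))
  pd_dup <- c(pd, stats::setNames(pd, paste0(names(pd), "_b")))
  f1 <- train_reference_model(beta, pd, seed = 2, lambda = 0.05)
  f2 <- train_reference_model(dup, pd_dup, seed = 2, lambda = 0.05)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-6)
  expect_equal(f1$coefficients$coefficient, f2$coefficients$coefficient,
               tolerance = 1e-6)
})

test_that("reference model predicts held-out doublings within 10% of range", {
  cfg <- sim_config(n_probes = c(soloWCGW_PMD = 400L, social_PMD = 300L,
                                 solo_nonPMD = 150L, social_nonPMD = 150L))
  cult <- simulate_culture(
    cfg, scenario_standard(n_lineages = 1, n_passages = 40,
                           pd_per_passage = 1.5, start_pds = 20),
    seed = 8)
  pds <- stats::setNames(cult$sample_truth$culture_pd,
                         cult$sample_truth$sample_id)
  set.seed(34)
  hold <- sample(names(pds), 10)
  train <- setdiff(names(pds), hold)
  fit <- train_reference_model(
    dplyr::select(cult$beta, probe_id, dplyr::all_of(train)), pds[train],
    seed = 3)
  pred <- apply_clock(fit, dplyr::select(cult$beta, probe_id,
                                         dplyr::all_of(hold)), impute = TRUE)
  rmse <- sqrt(mean((pred$estimate - pds[pred$sample_id])^2))
  expect_lt(rmse, 0.1 * diff(range(pds)))
})

test_that("PD normalisation anchors lineages at their predicted start", {
  clock <- new_replitali_clock(
    30, tibble::tibble(probe_id = "cg1", coefficient = 0,
                       training_mean = 0.5))
  sheet <- tibble::tibble(sample_id = c("a1", "a2", "r1", "r2"),
                          lineage = c("A", "A", "R", "R"),
                          cumulative_pd = c(5, 8, 3, 6))
  beta <- toy_beta(matrix(0.5, 1, 4), probes = "cg1",
                   samples = c("a1", "a2", "r1", "r2"))
  out <- normalize_pds(clock, sheet, beta, reference_lineage = "R")
  a <- out[out$lineage == "A", ]
  expect_equal(a$normalized_pd, c(30, 33)) # zero-coef clock predicts 30
  r <- out[out$lineage == "R", ]
  expect_equal(r$normalized_pd, r$observed_pd)
  expect_true(all(r$is_reference))

  # per-lineage offset is constant
  expect_equal(unique(a$normalized_pd - a$observed_pd), 25)
  expect_error(
    normalize_pds(clock, sheet,
                  dplyr::select(beta, probe_id, "a2", "r1", "r2")),
    "a1")
})

test_that("normalisation recovers simulated in-vivo offsets", {
  fx <- trained_clock_fixture()
  lin <- fx$culture$scenario$lineages
  ref <- lin$lineage[which.min(lin$start_pd)]
  ref_start <- lin$start_pd[lin$lineage == ref]
  tr <- dplyr::inner_join(fx$normalized, fx$culture$sample_truth,
                          by = c("sample_id", "lineage"))
  err <- tr$normalized_pd - (tr$true_pd - ref_start)
  expect_lt(mean(abs(err)), 3)
})

test_that("common-PMD clock training is seeded, restricted and evaluated", {
  fx <- trained_clock_fixture()
  clock <- fx$clock
  # all selected probes are inside common PMDs
  pmd <- fx$annotation$probe_id[fx$annotation$domain == "commonPMD"]
  expect_true(all(clock$coefficients$probe_id %in% pmd))
  expect_gt(clock$metadata$test_r_squared, 0.9)

  clock2 <- train_replitali(fx$culture$beta, fx$normalized, fx$annotation,
                            seed = 7)
  expect_identical(clock$coefficients, clock2$coefficients)
  expect_identical(clock$metadata$test_rmse, clock2$metadata$test_rmse)

  no_pmd <- dplyr::mutate(fx$annotation, domain = "neither")
  expect_error(train_replitali(fx$culture$beta, fx$normalized, no_pmd),
               "common PMD")
})

test_that("dual-set clock takes the larger of gain and loss scores", {
  clock <- dual_set_clock(c("h1", "h2"), c("l1", "l2"),
                          hyper_intercept = 0, hyper_slope = 10,
                          hypo_intercept = 10, hypo_slope = -10)
  beta <- toy_beta(matrix(c(0.3, 0.3, 0.5, 0.5,   # s1: hyper 3, hypo 5
                            0.5, 0.5, 0.5, 0.5),  # s2: hyper 5, hypo 5 (tie)
                          4, 2),
                   probes = c("h1", "h2", "l1", "l2"))
  out <- apply_dual_clock(clock, beta)
  expect_equal(out$estimate, c(5, 5))
  expect_equal(out$selected, c("hypo", "hyper"))
  expect_equal(out$tie, c(FALSE, TRUE))

  expect_error(dual_set_clock(character(), "l1"), "non-empty")
  expect_error(dual_set_clock(c("x"), c("x", "y")), "disjoint")
  expect_error(dual_set_clock("h", "l", hypo_slope = 1), "hypo_slope")
  only_h <- toy_beta(matrix(0.5, 2, 1), probes = c("h1", "h2"))
  expect_error(apply_dual_clock(clock, only_h), "hypomethylation")
})

test_that("hypo-dominated erosion drives dual-clock selection at late PDs", {
  fx <- trained_clock_fixture()
  cult <- fx$culture
  truth <- fx$culture$probe_truth
  hypo <- truth$probe_id[truth$class == "soloWCGW_PMD"][1:100]
  hyper <- truth$probe_id[truth$class == "social_nonPMD"][1:100]
  # direction-signed linear scores on mean set methylation
  clock <- dual_set_clock(hyper, hypo,
                          hyper_intercept = -15, hyper_slope = 20,
                          hypo_intercept = 25, hypo_slope = -30)
  out <- apply_dual_clock(clock, cult$beta)
  st <- dplyr::inner_join(out, cult$sample_truth, by = "sample_id")
  late <- st[st$true_pd > stats::median(st$true_pd), ]
  expect_gte(mean(late$selected == "hypo"), 0.95)
})

test_that("model composition report computes class counts and mean weights", {
  clock <- new_replitali_clock(
    5, tibble::tibble(probe_id = c("s1", "s2", "o1"),
                      coefficient = c(-4, -2, -1),
                      training_mean = c(0.8, 0.8, 0.5)))
  ann <- tibble::tibble(
    probe_id = c("s1", "s2", "o1"),
    domain = c("commonPMD", "commonPMD", "neither"),
    solo = c(TRUE, TRUE, FALSE),
    flank_class = c("WCGW", "WCGW", "SCGS"))
  rep <- summarize_model(clock, ann)
  expect_equal(rep$mean_coefficient[rep$class == "all"], -7 / 3)
  expect_equal(rep$mean_coefficient[rep$class == "all"], -2.333,
               tolerance = 1e-3)
  expect_equal(rep$n[rep$class == "PMD solo-WCGW"], 2)
  expect_equal(rep$mean_coefficient[rep$class == "PMD solo-WCGW"], -3)
  expect_equal(rep$fraction[rep$class == "PMD solo-WCGW"], 2 / 3)

  # class with zero probes stays in the report with NA mean
  expect_equal(rep$n[rep$class == "PMD other"], 0)
  expect_true(is.na(rep$mean_coefficient[rep$class == "PMD other"]))

  # unannotated probes are excluded from class rows with a warning
  expect_warning(rep2 <- summarize_model(clock, ann[1:2, ]), "o1")
  expect_equal(rep2$n[rep2$class == "all"], 3)
  expect_equal(sum(rep2$n[rep2$class != "all"]), 2)
})
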