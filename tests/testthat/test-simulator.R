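test_that("one division applies loss then compensatory gain", {
  expect_equal(step_methylation(0.7, 0, 0), 0.7)
  expect_equal(step_methylation(1, 0.1, 0), 0.9)
  expect_equal(step_methylation(0, 0, 0.05), 0.05)
  expect_error(step_methylation(1.5, 0.1, 0), "\\[0, 1\\]")
  expect_error(step_methylation(0.5, 1, 0), "\\[0, 1\\)")
})

test_that("the closed-form equilibrium is the fixed point of the dynamics", {
  expect_equal(equilibrium_beta(0.1, 0), 0)
  expect_equal(equilibrium_beta(0, 0.05), 1)
  expect_equal(equilibrium_beta(0.1, 0.01), 0.0917431, tolerance = 1e-6)
  expect_error(equilibrium_beta(0, 0), "no unique equilibrium")

  # independent oracle: iterate the one-step map to convergence
  for (rates in list(c(0.1, 0.01), c(0.009, 0.0008), c(0.3, 0.2))) {
    b <- 0.5
    for (i in 1:5000) b <- step_methylation(b, rates[1], rates[2])
    expect_equal(b, equilibrium_beta(rates[1], rates[2]), tolerance = 1e-10)
  }

  # fixed-point property on a grid
  r <- rep(c(0.001, 0.01, 0.1, 0.5), each = 4)
  g <- rep(c(0.0005, 0.005, 0.05, 0.3), times = 4)
  eq <- equilibrium_beta(r, g)
  expect_lt(max(abs(step_methylation(eq, r, g) - eq)), 1e-12)
})

test_that("approach to equilibrium is geometric with ratio (1-r)(1-g)", {
  r <- 0.02; g <- 0.002
  eq <- equilibrium_beta(r, g)
  b <- 0.9
  for (i in 1:50) {
    b2 <- step_methylation(b, r, g)
    expect_equal(abs(b2 - eq) / abs(b - eq), (1 - r) * (1 - g),
                 tolerance = 1e-9)
    b <- b2
  }
})

test_that("pure-loss dynamics are monotone non-increasing before noise", {
  rates <- dplyr::mutate(default_context_rates(), g = 0)
  cfg <- sim_config(rates = rates,
                    n_probes = c(soloWCGW_PMD = 50L, social_PMD = 50L,
                                 solo_nonPMD = 20L, social_nonPMD = 20L),
                    uds_rate = 0, noise_precision = Inf)
  cult <- simulate_culture(cfg, scenario_standard(n_lineages = 1,
                                                  n_passages = 10), seed = 1)
  m <- as.matrix(cult$beta_true[-1])
  expect_true(all(diff(t(m)) <= 1e-12))
})

test_that("observation noise is mean-preserving at the configured precision", {
  set.seed(51)
  nu <- 100
  for (mu in c(0.1, 0.5, 0.85)) {
    draws <- rbeta(1e4, mu * nu, (1 - mu) * nu)
    expect_lt(abs(mean(draws) - mu), 3 * sd(draws) / sqrt(1e4))
  }
  # the simulator draws from that law: noise-free run equals truth exactly
  cfg <- sim_config(n_probes = c(soloWCGW_PMD = 30L, social_PMD = 30L,
                                 solo_nonPMD = 10L, social_nonPMD = 10L),
                    noise_precision = Inf)
  cult <- simulate_culture(cfg, scenario_standard(n_lineages = 1,
                                                  n_passages = 4), seed = 2)
  expect_equal(cult$beta, cult$beta_true)
})

test_that("simulation is deterministic given config and seed", {
  cfg <- sim_config(n_probes = c(soloWCGW_PMD = 40L, social_PMD = 30L,
                                 solo_nonPMD = 15L, social_nonPMD = 15L))
  a <- simulate_culture(cfg, scenario_standard(n_lineages = 2,
                                               n_passages = 6), seed = 9)
  b <- simulate_culture(cfg, scenario_standard(n_lineages = 2,
                                               n_passages = 6), seed = 9)
  expect_identical(a$beta, b$beta)
  expect_identical(a$sheet, b$sheet)
  expect_identical(a$probe_truth, b$probe_truth)
})

test_that("arrest freezes methylation when noise and repair synthesis are off", {
  cfg <- sim_config(n_probes = c(soloWCGW_PMD = 30L, social_PMD = 20L,
                                 solo_nonPMD = 10L, social_nonPMD = 10L),
                    uds_rate = 0, noise_precision = Inf)
  cult <- simulate_culture(cfg, scenario_arrest(cell_lines = "lineA",
                                                start_pds = 30), seed = 3)
  mmc <- cult$sample_truth[cult$sample_truth$condition == "mmc_arrest", ]
  frozen <- mmc$sample_id[mmc$culture_pd == max(mmc$culture_pd)]
  expect_gte(length(frozen), 3) # last pre-arrest sample + arrest collections
  m <- as.matrix(cult$beta_true[frozen])
  expect_equal(max(apply(m, 1, function(x) diff(range(x)))), 0)
})

test_that("sample sheets invert exactly to the scheduled doublings", {
  cfg <- sim_config(n_probes = c(soloWCGW_PMD = 20L, social_PMD = 20L,
                                 solo_nonPMD = 10L, social_nonPMD = 10L))
  cult <- simulate_culture(cfg, scenario_serum(), seed = 4)
  sheet <- read_sample_sheet(cult$sheet)
  chk <- dplyr::inner_join(dplyr::filter(sheet, !is.na(sample_id)),
                           cult$sample_truth, by = "sample_id")
  expect_lt(max(abs(chk$cumulative_pd - chk$culture_pd)), 1e-8)
})

test_that("probe panel encodes the configured context ordering and modifiers", {
  cfg <- sim_config()
  panel <- probe_panel(cfg)
  expect_identical(panel, probe_panel(cfg)) # deterministic from config seed
  mean_r <- tapply(panel$r, panel$class, mean)
  expect_gt(mean_r[["soloWCGW_PMD"]], mean_r[["social_PMD"]])
  expect_gt(mean_r[["social_PMD"]], mean_r[["solo_nonPMD"]])
  expect_gt(mean_r[["solo_nonPMD"]], mean_r[["social_nonPMD"]])
  # timing coupling: within a class, later-replicating probes erode faster
  sw <- panel[panel$class == "soloWCGW_PMD" & !panel$protected, ]
  expect_lt(cor(sw$wa, sw$r), 0)
  expect_equal(panel$equilibrium, equilibrium_beta(panel$r, panel$g))
})

test_that("planted genomes recover requested class counts at the boundary", {
  sim <- simulate_genome(n_solo_wcgw = 10, seed = 6)
  ann <- annotate_cpgs(sim$genome, sim$intervals)
  got <- ann[ann$flank_class == "WCGW" & ann$solo, ]
  expect_equal(nrow(got), 10)

  b34 <- sim$truth[sim$truth$planted_class == "boundary_34", ]
  b35 <- sim$truth[sim$truth$planted_class == "boundary_35", ]
  expect_false(any(b34$solo))
  expect_true(all(b35$solo))
  ann_b <- dplyr::semi_join(ann,
                            dplyr::mutate(rbind(b34, b35),
                                          pos = as.numeric(pos)),
                            by = c("contig", "pos"))
  expect_equal(sort(ann_b$nearest_cpg_distance), c(34, 34, 35, 35))

  expect_error(simulate_genome(contig_length = 100, seed = 6),
               "infeasible packing")
})

test_that("random planted layouts never disagree with the annotator", {
  for (seed in 1:10) {
    sim <- simulate_genome(n_solo_wcgw = 6, n_social_wcgw = 6,
                           n_solo_scgs = 6, n_social_scgs = 6, seed = seed)
    ann <- annotate_cpgs(sim$genome, sim$intervals)
    truth <- dplyr::mutate(sim$truth, pos = as.numeric(pos))
    cmp <- dplyr::inner_join(truth, ann, by = c("contig", "pos"),
                             suffix = c(".t", ".a"))
    expect_equal(nrow(cmp), nrow(truth))
    expect_equal(cmp$flank_class.a, cmp$flank_class.t)
    expect_equal(cmp$solo.a, cmp$solo.t)
    expect_equal(cmp$domain.a, cmp$domain.t)
  }
})

test_that("early-culture slopes recover the configured net loss rates", {
  # 4 replicate lineages give enough samples for near-normal slope errors
  cfg <- sim_config()
  cult <- simulate_culture(
    cfg, scenario_standard(n_lineages = 4, n_passages = 26,
                           start_pds = rep(20, 4)), seed = 52)
  pds <- stats::setNames(cult$sample_truth$culture_pd,
                         cult$sample_truth$sample_id)
  fits <- fit_cpg_slopes(cult$beta, pds)
  truth_fit <- fit_cpg_slopes(cult$beta_true, pds) # noise-free target
  z <- (fits$slope - truth_fit$slope) / fits$slope_se
  # two-standard-error coverage: ~95.4% for a normal, slightly less at
  # finite df; allow binomial slack at this probe count
  expect_gte(mean(abs(z) <= 2), 0.935)
  # and the noise-free slopes match the configured initial net rate in sign
  joined <- dplyr::inner_join(truth_fit, cult$probe_truth, by = "probe_id")
  init_rate <- -joined$r * joined$beta0 + joined$g * (1 - joined$beta0)
  expect_gt(cor(joined$slope, init_rate), 0.95)
})

test_that("invalid schedules and configurations are rejected", {
  expect_error(sim_config(kappa = -1), "kappa")
  expect_error(sim_config(uds_rate = 1), "uds_rate")
  expect_error(sim_config(n_probes = c(bogus = 10L)), "named by classes")
  lineages <- tibble::tibble(lineage = "x", start_pd = 10,
                             condition = "standard", oxygen = "ambient")
  schedule <- tibble::tibble(lineage = "x", passage = 1, delta_pd = -1,
                             days = 3, collect = TRUE)
  expect_error(replitali:::new_culture_scenario(lineages, schedule),
               "negative growth")
})
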