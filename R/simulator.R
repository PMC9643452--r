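#' One cell division of maintenance-failure methylation dynamics
#'
#' At each division a methylated CpG fails to be re-methylated with
#' probability `r` (maintenance failure) and an unmethylated CpG gains
#' methylation with probability `g` (compensatory de novo methylation):
#' `beta' = beta * (1 - r) + g * (1 - beta * (1 - r))`. Values stay in
#' `[0, 1]`.
#'
#' @param beta Fractional methylation in `[0, 1]` (vectorised).
#' @param r Maintenance failure rate per division in `[0, 1)` (vectorised).
#' @param g De novo gain rate per division in `[0, 1)` (vectorised).
#' @return Updated beta values.
#' @export
step_methylation <- function(beta, r, g) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) fail("beta must lie in [0, 1]")
  if (any(r < 0 | r >= 1) || any(g < 0 | g >= 1)) {
    fail("rates r and g must lie in [0, 1)")
  }
  b <- beta * (1 - r)
  b + g * (1 - b)
}

#' Equilibrium methylation of the division-coupled dynamics
#'
#' The fixed point where compensatory de novo methylation offsets further
#' maintenance failure: `beta* = g / (1 - (1 - r) * (1 - g))`. Trajectories
#' approach it geometrically with ratio `(1 - r) * (1 - g)`.
#'
#' @inheritParams step_methylation
#' @return Equilibrium beta values.
#' @export
equilibrium_beta <- function(r, g) {
  if (any(r < 0 | r >= 1) || any(g < 0 | g >= 1)) {
    fail("rates r and g must lie in [0, 1)")
  }
  if (any(r + g == 0)) {
    fail("r = g = 0 has no unique equilibrium")
  }
  g / (1 - (1 - r) * (1 - g))
}

# closed form for n (integer) iterations of step_methylation; exact because
# the per-division map is affine with slope (1 - r)(1 - g)
evolve_beta <- function(beta, r, g, n_div) {
  f <- (1 - r) * (1 - g)
  beq <- ifelse(r + g > 0, g / (1 - f), beta)
  beq + (beta - beq) * f^n_div
}

#' Default per-context division-coupled rates
#'
#' Maintenance-failure (`r`) and de novo gain (`g`) rates per division, and
#' starting beta, for the four canonical CpG context classes. Defaults are
#' ordered `r(soloWCGW_PMD) > r(social_PMD) > r(non-PMD classes)` so that PMD
#' solo-WCGWs erode fastest and social non-PMD CpGs drift slightly upward.
#'
#' @return Tibble: `class`, `r`, `g`, `beta0`.
#' @export
default_context_rates <- function() {
  tibble(
    class = c("soloWCGW_PMD", "social_PMD", "solo_nonPMD", "social_nonPMD"),
    r = c(0.009, 0.004, 0.0015, 0.0002),
    g = c(0.0008, 0.0008, 0.0005, 0.002),
    beta0 = c(0.85, 0.85, 0.85, 0.80)
  )
}

#' Simulation configuration
#'
#' Parameters of the division-coupled erosion model and of the synthetic
#' probe panel. The panel (per-probe contexts, rate modifiers, baseline
#' methylation) is drawn deterministically from `seed`, so different culture
#' scenarios built from the same configuration share probe identities.
#'
#' @param rates Per-class rate table (see [default_context_rates()]).
#' @param n_probes Named integer vector of probes per class; names must
#'   match `rates$class`.
#' @param kappa Replication-timing coupling (>= 0): per-probe multiplier
#'   `1 + kappa * (0.917 - WA) / 0.917`, so the latest-replicating CpGs lose
#'   methylation fastest.
#' @param rate_sd Log-sd of the mean-one lognormal per-probe rate jitter.
#' @param protected_fraction Fraction of probes linked to expressed genes.
#' @param expression_protection Multiplicative rate reduction `e` in
#'   `[0, 1]` applied to protected probes (`r -> r * (1 - e)`).
#' @param uds_rate Extra per-day loss rate from unscheduled (repair)
#'   DNA synthesis under ambient oxygen; low-oxygen lineages use a quarter
#'   of it. Applied per probe scaled by its maintenance vulnerability
#'   relative to the PMD solo-WCGW class, so robust contexts are barely
#'   touched by repair synthesis.
#' @param noise_precision Precision `nu` of the mean-preserving beta-law
#'   measurement noise (`Inf` disables noise).
#' @param baseline_precision Beta-law precision of per-probe starting betas
#'   around the class baseline.
#' @param seed Integer seed for the probe panel.
#' @return A `sim_config` object (named list).
#' @export
sim_config <- function(rates = default_context_rates(),
                       n_probes = c(soloWCGW_PMD = 1200L, social_PMD = 1000L,
                                    solo_nonPMD = 400L, social_nonPMD = 400L),
                       kappa = 0.5,
                       rate_sd = 0.25,
                       protected_fraction = 0.15,
                       expression_protection = 0.5,
                       uds_rate = 2e-4,
                       noise_precision = 100,
                       baseline_precision = 30,
                       seed = 20201L) {
  stopifnot(is.data.frame(rates),
            all(c("class", "r", "g", "beta0") %in% names(rates)))
  if (any(rates$r < 0 | rates$r >= 1) || any(rates$g < 0 | rates$g >= 1)) {
    fail("class rates r and g must lie in [0, 1)")
  }
  if (is.null(names(n_probes)) || !all(names(n_probes) %in% rates$class)) {
    fail("`n_probes` must be named by classes present in `rates`")
  }
  if (kappa < 0) fail("`kappa` must be >= 0")
  if (rate_sd < 0) fail("`rate_sd` must be >= 0")
  if (protected_fraction < 0 || protected_fraction > 1 ||
      expression_protection < 0 || expression_protection > 1) {
    fail("protection parameters must lie in [0, 1]")
  }
  if (uds_rate < 0 || uds_rate >= 1) fail("`uds_rate` must lie in [0, 1)")
  if (!(is_scalar_number(noise_precision) && noise_precision > 0) &&
      !identical(noise_precision, Inf)) {
    fail("`noise_precision` must be a positive number or Inf")
  }
  structure(list(rates = as_tibble(rates), n_probes = n_probes,
                 kappa = kappa, rate_sd = rate_sd,
                 protected_fraction = protected_fraction,
                 expression_protection = expression_protection,
                 uds_rate = uds_rate, noise_precision = noise_precision,
                 baseline_precision = baseline_precision,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Synthetic probe panel of a simulation configuration
#'
#' Draws the per-probe attributes (context class, baseline beta, replication
#' timing, rate modifiers, effective rates and equilibrium) from the
#' configuration seed. PMD probes replicate late (low WA), non-PMD probes
#' early.
#'
#' @param config A [sim_config()].
#' @return Tibble: `probe_id`, `class`, `beta0`, `wa`, `protected`, `r`,
#'   `g`, `equilibrium`.
#' @export
probe_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rates <- config$rates
  panels <- purrr::imap(config$n_probes, function(n, cls) {
    row <- rates[rates$class == cls, ]
    beta0 <- rbeta(n, row$beta0 * config$baseline_precision,
                   (1 - row$beta0) * config$baseline_precision)
    mult <- exp(rnorm(n, -config$rate_sd^2 / 2, config$rate_sd))
    late <- !grepl("nonPMD", cls)
    wa <- if (late) runif(n, 0, 0.45) else runif(n, 0.5, 0.917)
    protected <- runif(n) < config$protected_fraction
    timing <- 1 + config$kappa * (0.917 - wa) / 0.917
    r_eff <- clamp(row$r * mult * timing *
                     (1 - config$expression_protection * protected),
                   0, 0.99)
    tibble(class = cls, beta0 = clamp(beta0, 0.02, 0.98), wa = wa,
           protected = protected, r = r_eff, g = row$g)
  })
  out <- dplyr::bind_rows(panels)
  out <- dplyr::bind_cols(
    tibble(probe_id = sprintf("sim%05d", seq_len(nrow(out)))), out)
  dplyr::mutate(out, equilibrium = equilibrium_beta(.data$r, .data$g))
}

new_culture_scenario <- function(lineages, schedule) {
  stopifnot(all(c("lineage", "start_pd", "condition", "oxygen") %in%
                  names(lineages)),
            all(c("lineage", "passage", "delta_pd", "days", "collect") %in%
                  names(schedule)))
  if (any(schedule$delta_pd < 0)) {
    fail("schedule implies a negative growth ratio (delta_pd < 0)")
  }
  if (any(schedule$days < 0)) fail("schedule days must be >= 0")
  if (anyDuplicated(lineages$lineage)) fail("duplicate lineage names")
  structure(list(lineages = as_tibble(lineages),
                 schedule = as_tibble(schedule)),
            class = "culture_scenario")
}

#' Serial-culture scenarios
#'
#' Constructors for the passage schedules the simulator consumes:
#' * `scenario_standard()`: several primary lineages with distinct in-vivo
#'   starting PDs, passaged at a constant split ratio through senescence.
#' * `scenario_serum()`: one cell line grown at several serum levels; equal
#'   elapsed time per passage but serum-dependent division rates, so time
#'   and divisions decouple.
#' * `scenario_arrest()`: cell lines split into a replication-arrested arm
#'   (PDs frozen while days advance, as after Mitomycin C) and a freely
#'   proliferating control arm.
#' * `scenario_immortalized()`: a single telomerase-immortalised lineage
#'   carried far beyond the primary lifespan until methylation plateaus.
#'
#' @param n_lineages,n_passages,pd_per_passage,days_per_passage Schedule
#'   shape; `pd_per_passage` is the doubling increment of a full passage.
#' @param start_pds,start_pd In-vivo replicative age(s) at culture start.
#' @param collect_every Collect a methylation sample every k-th passage.
#' @param oxygen `"ambient"` or `"low"`.
#' @param serum_levels,division_rates Serum percentages and their relative
#'   division rates (same length).
#' @param cell_lines Names of the arrest-experiment cell lines.
#' @param pre_passages Passages before the arrest split.
#' @param arrest_days Collection days (since arrest) of the arrested arm.
#' @return A `culture_scenario` object.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_standard <- function(n_lineages = 7, n_passages = 26,
                              pd_per_passage = 2, days_per_passage = 3.5,
                              start_pds = seq(15, 45,
                                              length.out = n_lineages),
                              collect_every = 1, oxygen = "ambient") {
  stopifnot(length(start_pds) == n_lineages)
  lineages <- tibble(lineage = sprintf("line%d", seq_len(n_lineages)),
                     start_pd = start_pds, condition = "standard",
                     oxygen = oxygen)
  schedule <- tidyr::expand_grid(lineage = lineages$lineage,
                                 passage = seq_len(n_passages)) |>
    dplyr::mutate(delta_pd = pd_per_passage, days = days_per_passage,
                  collect = .data$passage %% collect_every == 0 |
                    .data$passage == n_passages)
  new_culture_scenario(lineages, schedule)
}

#' @rdname scenarios
#' @export
scenario_serum <- function(serum_levels = c(15, 5, 1, 0.5),
                           division_rates = c(1, 0.7, 0.45, 0.25),
                           n_passages = 22, pd_per_passage = 2,
                           days_per_passage = 7, start_pd = 15) {
  stopifnot(length(serum_levels) == length(division_rates))
  if (any(division_rates <= 0)) fail("division rates must be positive")
  lineages <- tibble(
    lineage = sprintf("serum%g", serum_levels),
    start_pd = start_pd,
    condition = sprintf("serum_%g", serum_levels),
    oxygen = "ambient")
  schedule <- purrr::map2(lineages$lineage, division_rates, function(ln, rate) {
    tibble(lineage = ln, passage = seq_len(n_passages),
           delta_pd = pd_per_passage * rate, days = days_per_passage,
           collect = TRUE)
  }) |> dplyr::bind_rows()
  new_culture_scenario(lineages, schedule)
}

#' @rdname scenarios
#' @export
scenario_arrest <- function(cell_lines = c("lineA", "lineB", "lineC"),
                            start_pds = c(25, 35, 45),
                            pre_passages = 4, pd_per_passage = 2,
                            days_per_passage = 3.5,
                            arrest_days = c(18, 25)) {
  stopifnot(length(start_pds) == length(cell_lines))
  arms <- purrr::map2(cell_lines, start_pds, function(cl, sp) {
    pre <- tibble(passage = seq_len(pre_passages),
                  delta_pd = pd_per_passage, days = days_per_passage,
                  collect = TRUE)
    arrest <- tibble(passage = pre_passages + seq_along(arrest_days),
                     delta_pd = 0, days = diff(c(0, arrest_days)),
                     collect = TRUE)
    n_post <- ceiling(max(arrest_days) / days_per_passage)
    ctrl_post <- tibble(passage = pre_passages + seq_len(n_post),
                        delta_pd = pd_per_passage, days = days_per_passage,
                        collect = TRUE)
    list(
      lineages = tibble(lineage = paste0(cl, c("_mmc", "_ctrl")),
                        start_pd = sp,
                        condition = c("mmc_arrest", "control"),
                        oxygen = "ambient"),
      schedule = dplyr::bind_rows(
        dplyr::mutate(dplyr::bind_rows(pre, arrest),
                      lineage = paste0(cl, "_mmc")),
        dplyr::mutate(dplyr::bind_rows(pre, ctrl_post),
                      lineage = paste0(cl, "_ctrl")))
    )
  })
  new_culture_scenario(
    dplyr::bind_rows(purrr::map(arms, "lineages")),
    dplyr::bind_rows(purrr::map(arms, "schedule")))
}

#' @rdname scenarios
#' @export
scenario_immortalized <- function(n_passages = 130, pd_per_passage = 3.32,
                                  days_per_passage = 5, start_pd = 20,
                                  collect_every = 10) {
  lineages <- tibble(lineage = "tert", start_pd = start_pd,
                     condition = "immortalized", oxygen = "ambient")
  schedule <- tibble(lineage = "tert", passage = seq_len(n_passages),
                     delta_pd = pd_per_passage, days = days_per_passage,
                     collect = seq_len(n_passages) %% collect_every == 0 |
                       seq_len(n_passages) == n_passages)
  new_culture_scenario(lineages, schedule)
}

#' Simulate a serially passaged methylation dataset
#'
#' Runs the division-coupled erosion dynamics over a passage schedule.
#' Each passage applies whole-division updates for the integer part of its
#' doubling increment and a linearly scaled partial step for the remainder,
#' then a small per-day loss from unscheduled DNA synthesis (quartered under
#' low oxygen). Collected samples are observed through mean-preserving
#' beta-law noise; exact values are kept in the truth tables. The sample
#' sheet carries yields and inocula that invert exactly to the scheduled
#' doubling increments.
#'
#' @param config A [sim_config()]; fixes the probe panel via its own seed.
#' @param scenario A `culture_scenario` (see [scenarios]).
#' @param seed Integer seed for observation noise.
#' @param inoculum Viable cells seeded at each passage.
#' @return A `culture_sim` list: `beta` (observed, probe_id + samples),
#'   `sheet` (one row per passage; `sample_id` NA when not collected),
#'   `probe_truth`, `sample_truth` (`true_pd` includes the in-vivo offset),
#'   `beta_true` (noise-free), `config`, `scenario`, `seed`.
#' @export
simulate_culture <- function(config, scenario, seed = 1, inoculum = 3e5) {
  stopifnot(inherits(config, "sim_config"),
            inherits(scenario, "culture_scenario"))
  panel <- probe_panel(config)
  set.seed(seed)
  nu <- config$noise_precision

  beta_obs <- list()
  beta_exact <- list()
  sheet_rows <- list()
  truth_rows <- list()

  for (i in seq_len(nrow(scenario$lineages))) {
    ln <- scenario$lineages[i, ]
    sched <- dplyr::arrange(
      scenario$schedule[scenario$schedule$lineage == ln$lineage, ],
      .data$passage)
    if (nrow(sched) == 0) next
    b <- evolve_beta(panel$beta0, panel$r, panel$g, ln$start_pd)
    culture_pd <- 0
    days_total <- 0
    u <- config$uds_rate * if (identical(ln$oxygen, "low")) 0.25 else 1
    # repair-synthesis loss is maintenance-failure-coupled: contexts that are
    # vulnerable per division are equally vulnerable per repair patch, so the
    # per-day rate is scaled by each probe's vulnerability relative to the
    # most erosion-prone class
    ref_r <- mean(panel$r[panel$class == "soloWCGW_PMD"])
    if (!is.finite(ref_r) || ref_r == 0) ref_r <- max(panel$r, 1e-12)
    u_probe <- clamp(u * panel$r / ref_r, 0, 0.99)

    for (j in seq_len(nrow(sched))) {
      row <- sched[j, ]
      if (row$delta_pd > 0) {
        n_int <- floor(row$delta_pd)
        frac <- row$delta_pd - n_int
        if (n_int > 0) b <- evolve_beta(b, panel$r, panel$g, n_int)
        if (frac > 0) b <- b + frac * (step_methylation(b, panel$r, panel$g) - b)
      }
      if (u > 0 && row$days > 0) b <- b * (1 - u_probe)^row$days
      prev_pd <- culture_pd
      culture_pd <- culture_pd + row$delta_pd
      days_total <- days_total + row$days

      sample_id <- if (row$collect) {
        sprintf("%s_p%02d", ln$lineage, row$passage)
      } else NA_character_
      sheet_rows[[length(sheet_rows) + 1]] <- tibble(
        sample_id = sample_id, lineage = ln$lineage, passage = row$passage,
        yield = inoculum * 10^(row$delta_pd / 3.32), inoculum = inoculum,
        inoculum_pd = prev_pd, days = row$days,
        condition = ln$condition, oxygen = ln$oxygen)

      if (row$collect) {
        mu <- clamp(b, 1e-3, 1 - 1e-3)
        obs <- if (is.finite(nu)) rbeta(length(mu), mu * nu, (1 - mu) * nu)
               else b
        beta_obs[[sample_id]] <- obs
        beta_exact[[sample_id]] <- b
        truth_rows[[length(truth_rows) + 1]] <- tibble(
          sample_id = sample_id, lineage = ln$lineage, passage = row$passage,
          culture_pd = culture_pd, true_pd = ln$start_pd + culture_pd,
          days = days_total, condition = ln$condition, oxygen = ln$oxygen)
      }
    }
  }

  obs_mat <- do.call(cbind, beta_obs)
  exact_mat <- do.call(cbind, beta_exact)
  rownames(obs_mat) <- rownames(exact_mat) <- panel$probe_id
  structure(list(
    beta = matrix_as_beta(obs_mat),
    sheet = dplyr::bind_rows(sheet_rows),
    probe_truth = panel,
    sample_truth = dplyr::bind_rows(truth_rows),
    beta_true = matrix_as_beta(exact_mat),
    config = config, scenario = scenario, seed = seed
  ), class = "culture_sim")
}

#' @export
print.culture_sim <- function(x, ...) {
  cat("Simulated culture:", nrow(x$probe_truth), "probes,",
      nrow(x$sample_truth), "samples,",
      nrow(x$scenario$lineages), "lineage(s), seed", x$seed, "\n")
  invisible(x)
}
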