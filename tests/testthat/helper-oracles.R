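# Independent brute-force reimplementations and small fixture builders used
# across the suite. Deliberately naive: character loops and O(n * m) interval
# scans, no shared code with the package internals.

random_genome <- function(n_contigs = 1, len = 2000,
                          alphabet = c("A", "C", "G", "T", "N"),
                          weights = c(0.3, 0.2, 0.2, 0.28, 0.02)) {
  g <- vapply(seq_len(n_contigs), function(i) {
    paste(sample(alphabet, len, replace = TRUE, prob = weights),
          collapse = "")
  }, character(1))
  names(g) <- sprintf("ctg%d", seq_len(n_contigs))
  g
}

random_intervals <- function(genome, n = 3) {
  rows <- lapply(names(genome), function(ctg) {
    len <- nchar(genome[[ctg]])
    start <- sort(sample(0:(len - 2), n))
    end <- pmin(start + sample(50:400, n, replace = TRUE), len)
    tibble::tibble(contig = ctg, start = start, end = end)
  })
  dplyr::bind_rows(rows)
}

# per-site recomputation of every annotation field with character vectors
oracle_annotate <- function(genome, intervals = list(), threshold = 35) {
  rows <- list()
  for (ctg in names(genome)) {
    chars <- strsplit(toupper(genome[[ctg]]), "")[[1]]
    n <- length(chars)
    pos <- integer(0)
    for (i in seq_len(max(n - 1, 0))) {
      if (chars[i] == "C" && chars[i + 1] == "G") pos <- c(pos, i - 1L)
    }
    for (p in pos) {
      left <- if (p >= 1) chars[p] else NA_character_
      right <- if (p + 2 <= n - 1) chars[p + 3] else NA_character_
      fc <- if (is.na(left) || is.na(right) || left == "N" || right == "N") {
        "ambiguous"
      } else if (left %in% c("A", "T") && right %in% c("A", "T")) {
        "WCGW"
      } else if (left %in% c("C", "G") && right %in% c("C", "G")) {
        "SCGS"
      } else {
        "intermediate"
      }
      others <- pos[pos != p]
      nd <- if (length(others) == 0) Inf else min(abs(others - p))
      hit <- function(nm) {
        iv <- intervals[[nm]]
        if (is.null(iv) || nrow(iv) == 0) return(FALSE)
        any(iv$contig == ctg & iv$start <= p & p < iv$end)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        contig = ctg, pos = as.numeric(p), flank_class = fc,
        solo = nd >= threshold, nearest_cpg_distance = nd,
        domain = if (hit("commonPMD")) "commonPMD"
                 else if (hit("HMD")) "HMD" else "neither",
        in_cgi = hit("CGI"))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(contig = character(), pos = numeric(),
                          flank_class = character(), solo = logical(),
                          nearest_cpg_distance = numeric(),
                          domain = character(), in_cgi = logical())
  }
  dplyr::arrange(out, contig, pos)
}

expect_annotation_equal <- function(ann, oracle) {
  ann <- dplyr::arrange(ann, contig, pos)
  cols <- c("contig", "pos", "flank_class", "solo",
            "nearest_cpg_distance", "domain", "in_cgi")
  expect_equal(as.data.frame(ann[cols]), as.data.frame(oracle[cols]),
               tolerance = 0)
}

# beta table fixture: probes x samples from a matrix
toy_beta <- function(m, probes = sprintf("cg%03d", seq_len(nrow(m))),
                     samples = sprintf("s%02d", seq_len(ncol(m)))) {
  dimnames(m) <- list(probes, samples)
  dplyr::bind_cols(tibble::tibble(probe_id = probes),
                   tibble::as_tibble(as.data.frame(m)))
}

# full simulated training pipeline shared by the clock acceptance analogs;
# memoised so several tests can reuse one trained clock
trained_clock_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config()
    cult <- simulate_culture(cfg, scenario_standard(), seed = 101)
    obs <- dplyr::filter(read_sample_sheet(cult$sheet), !is.na(sample_id))
    lin <- cult$scenario$lineages
    ref <- lin$lineage[which.min(lin$start_pd)]
    ref_samples <- obs$sample_id[obs$lineage == ref]
    ref_beta <- dplyr::select(cult$beta, probe_id,
                              dplyr::all_of(ref_samples))
    pds <- stats::setNames(obs$cumulative_pd, obs$sample_id)
    refmod <- train_reference_model(ref_beta, pds[ref_samples], seed = 5)
    norm <- normalize_pds(refmod, obs, cult$beta, reference_lineage = ref)
    ann <- sim_truth_annotation(cult$probe_truth)
    clock <- train_replitali(cult$beta, norm, ann, seed = 7)
    cache <<- list(config = cfg, culture = cult, sheet = obs,
                   reference = refmod, normalized = norm,
                   annotation = ann, clock = clock)
    cache
  }
})

# probe truth table -> the annotation columns the clock functions expect
sim_truth_annotation <- function(probe_truth) {
  dplyr::mutate(
    probe_truth,
    domain = ifelse(grepl("nonPMD", class), "neither", "commonPMD"),
    solo = grepl("solo", class),
    flank_class = ifelse(grepl("WCGW", class), "WCGW", "SCGS"),
    in_cgi = FALSE)
}
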