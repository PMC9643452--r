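#' Simulate a genome with planted CpG contexts
#'
#' Builds a synthetic contig whose CpGs have known flank classes, solo/social
#' status and domain membership, as a fixture generator for the annotator.
#' The background alphabet is A/T only, so no CpG exists except the planted
#' ones. Planted elements are separated by gaps of at least the solo
#' threshold; social CpGs are planted as pairs 10-30 bp apart. When
#' `boundary_pairs` is set, three extra pairs straddle the solo boundary at
#' start-to-start distances 34, 35 and 36 bp (with intermediate flanks, so
#' they do not inflate the WCGW/SCGS class counts). A leading edge CpG with
#' no left flank exercises the ambiguous class. Requested counts are split
#' between a common-PMD region (first part of the contig) and an HMD region
#' (remainder); one SCGS social pair in the PMD region is covered by a CpG
#' island interval.
#'
#' @param n_solo_wcgw,n_social_wcgw,n_solo_scgs,n_social_scgs Planted CpG
#'   counts per flank/spacing class (social counts must be even: pairs).
#' @param n_intermediate,n_ambiguous Counts of isolated intermediate-flank
#'   and N-flank CpGs.
#' @param contig_length Optional total contig length; an error is raised if
#'   the planted layout cannot be packed into it, otherwise the contig is
#'   padded to this length.
#' @param solo_threshold Solo distance threshold in bp (default 35).
#' @param boundary_pairs Plant the 34/35/36 bp boundary pairs
#'   (default `TRUE`).
#' @param seed Integer seed.
#' @return List with `genome` (named character vector, one contig
#'   `chrSim`), `intervals` (named list: commonPMD, HMD, CGI), and `truth`
#'   (tibble: `contig`, `pos`, `flank_class`, `solo`,
#'   `nearest_cpg_distance`, `domain`, `in_cgi`, `planted_class`).
#' @export
simulate_genome <- function(n_solo_wcgw = 10, n_social_wcgw = 10,
                            n_solo_scgs = 10, n_social_scgs = 10,
                            n_intermediate = 4, n_ambiguous = 2,
                            contig_length = NULL, solo_threshold = 35,
                            boundary_pairs = TRUE, seed = 1) {
  if (n_social_wcgw %% 2 != 0 || n_social_scgs %% 2 != 0) {
    fail("social CpG counts must be even (planted as pairs)")
  }
  set.seed(seed)
  w <- c("A", "T")
  s <- c("C", "G")
  bg <- function(n) if (n > 0) sample(w, n, replace = TRUE) else character()

  # an element is a charvec plus 0-based CpG offsets and their flank classes
  single <- function(left, right, class) {
    list(chars = c(left, "C", "G", right), offsets = 1L,
         flank_class = class)
  }
  pair <- function(d, l1, r1, l2, r2, class) {
    stopifnot(d >= 4)
    list(chars = c(l1, "C", "G", r1, bg(d - 4), l2, "C", "G", r2),
         offsets = c(1L, d + 1L), flank_class = rep(class, 2))
  }
  rw <- function() sample(w, 1)
  rs <- function() sample(s, 1)

  make_elements <- function(counts) {
    el <- list()
    for (k in seq_len(counts[["solo_wcgw"]])) {
      el <- c(el, list(c(single(rw(), rw(), "WCGW"),
                         planted = "solo_WCGW")))
    }
    for (k in seq_len(counts[["social_wcgw"]] / 2)) {
      el <- c(el, list(c(pair(sample(10:30, 1), rw(), rw(), rw(), rw(),
                              "WCGW"), planted = "social_WCGW")))
    }
    for (k in seq_len(counts[["solo_scgs"]])) {
      el <- c(el, list(c(single(rs(), rs(), "SCGS"),
                         planted = "solo_SCGS")))
    }
    for (k in seq_len(counts[["social_scgs"]] / 2)) {
      el <- c(el, list(c(pair(sample(10:30, 1), rs(), rs(), rs(), rs(),
                              "SCGS"), planted = "social_SCGS")))
    }
    for (k in seq_len(counts[["intermediate"]])) {
      el <- c(el, list(c(single(rw(), rs(), "intermediate"),
                         planted = "solo_intermediate")))
    }
    for (k in seq_len(counts[["ambiguous"]])) {
      el <- c(el, list(c(single("N", rw(), "ambiguous"),
                         planted = "N_flank")))
    }
    if (length(el) > 0) el <- el[sample(length(el))]
    el
  }

  half <- function(n) c(ceiling(n / 2), floor(n / 2))
  counts <- list(solo_wcgw = half(n_solo_wcgw),
                 social_wcgw = 2 * half(n_social_wcgw / 2),
                 solo_scgs = half(n_solo_scgs),
                 social_scgs = 2 * half(n_social_scgs / 2),
                 intermediate = half(n_intermediate),
                 ambiguous = half(n_ambiguous))
  pmd_elements <- make_elements(purrr::map_dbl(counts, 1))
  hmd_elements <- make_elements(purrr::map_dbl(counts, 2))
  if (boundary_pairs) {
    bp <- purrr::map(c(34, 35, 36), function(d) {
      c(pair(d, rw(), rs(), rs(), rw(), "intermediate"),
        planted = sprintf("boundary_%d", d))
    })
    pmd_elements <- c(pmd_elements, bp)
  }

  chars <- character(0)
  cpg <- tibble(pos = integer(), flank_class = character(),
                planted_class = character(), region = character())
  last_cpg <- -Inf

  emit <- function(elements, region) {
    for (el in elements) {
      # gap keeps this element's first CpG >= threshold from the previous one
      first_off <- el$offsets[1]
      need <- solo_threshold + sample(5:40, 1)
      gap <- max(0, need - (length(chars) + first_off - last_cpg))
      chars <<- c(chars, bg(gap), el$chars)
      base <- length(chars) - length(el$chars)
      pos <- base + el$offsets
      cpg <<- dplyr::bind_rows(cpg, tibble(
        pos = as.integer(pos), flank_class = el$flank_class,
        planted_class = el$planted, region = region))
      last_cpg <<- max(pos)
    }
  }

  # edge CpG: no left flank -> ambiguous
  chars <- c("C", "G", bg(2))
  cpg <- tibble(pos = 0L, flank_class = "ambiguous",
                planted_class = "edge", region = "PMD")
  last_cpg <- 0L

  emit(pmd_elements, "PMD")
  chars <- c(chars, bg(solo_threshold + 10))
  pmd_end <- length(chars)
  emit(hmd_elements, "HMD")
  chars <- c(chars, bg(10))

  if (!is.null(contig_length)) {
    if (length(chars) > contig_length) {
      fail("infeasible packing: planted layout needs ", length(chars),
           " bp but contig_length is ", contig_length)
    }
    chars <- c(chars, bg(contig_length - length(chars)))
  }
  genome <- c(chrSim = paste(chars, collapse = ""))

  # CGI over the first social SCGS pair in the PMD region, if present
  cgi <- tibble(contig = character(), start = numeric(), end = numeric())
  scgs_pmd <- cpg[cpg$planted_class == "social_SCGS" & cpg$region == "PMD", ]
  if (nrow(scgs_pmd) >= 2) {
    cgi <- tibble(contig = "chrSim", start = scgs_pmd$pos[1] - 2,
                  end = scgs_pmd$pos[2] + 3)
  }
  intervals <- list(
    commonPMD = tibble(contig = "chrSim", start = 0, end = pmd_end),
    HMD = tibble(contig = "chrSim", start = pmd_end,
                 end = nchar(genome[[1]])),
    CGI = cgi
  )

  # nearest-neighbour distances by brute force over planted positions
  pos <- sort(cpg$pos)
  nearest <- purrr::map_dbl(cpg$pos, function(p) {
    other <- pos[pos != p]
    if (length(other) == 0) Inf else min(abs(other - p))
  })
  truth <- cpg |>
    dplyr::mutate(
      contig = "chrSim",
      nearest_cpg_distance = nearest,
      solo = nearest >= solo_threshold,
      domain = ifelse(.data$region == "PMD", "commonPMD", "HMD"),
      in_cgi = if (nrow(cgi) > 0) {
        .data$pos >= cgi$start & .data$pos < cgi$end
      } else FALSE
    ) |>
    dplyr::arrange(.data$pos) |>
    dplyr::select("contig", "pos", "flank_class", "solo",
                  "nearest_cpg_distance", "domain", "in_cgi",
                  "planted_class")

  list(genome = genome, intervals = intervals, truth = truth)
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- validate_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}
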