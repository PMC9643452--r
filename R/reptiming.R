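wa_weights <- c(G1b = 0.917, S1 = 0.750, S2 = 0.583, S3 = 0.417,
                S4 = 0.250, G2 = 0)

#' Weighted-average replication-timing score
#'
#' Combines six-fraction Repli-seq signal (G1b, S1, S2, S3, S4, G2) into a
#' single score: `WA = 0.917*G1b + 0.750*S1 + 0.583*S2 + 0.417*S3 +
#' 0.250*S4 + 0*G2`, computed on fraction values normalised to sum to 1.
#' Higher scores mean earlier replication; the range is `[0, 0.917]`.
#'
#' @param profile Numeric vector of six fraction signals in the order G1b,
#'   S1, S2, S3, S4, G2; or a data frame / matrix with those six columns
#'   (one row per genomic bin).
#' @param normalize Rescale each profile to proportions before weighting
#'   (default `TRUE`); the score is then invariant to positive rescaling of
#'   the raw signal.
#' @return Numeric WA score(s); NA with a warning for an all-zero profile.
#' @export
wa_score <- function(profile, normalize = TRUE) {
  if (is.data.frame(profile) || is.matrix(profile)) {
    df <- as.data.frame(profile)
    if (all(names(wa_weights) %in% names(df))) {
      p <- as.matrix(df[, names(wa_weights)])
    } else if (ncol(df) == 6) {
      p <- as.matrix(df) # columns taken as G1b, S1, S2, S3, S4, G2 in order
      colnames(p) <- names(wa_weights)
    } else {
      fail("profile table must have columns G1b, S1, S2, S3, S4, G2")
    }
  } else {
    if (length(profile) != 6) {
      fail("a profile vector must have 6 values (G1b, S1, S2, S3, S4, G2)")
    }
    p <- matrix(as.numeric(profile), nrow = 1,
                dimnames = list(NULL, names(wa_weights)))
  }
  if (any(p < 0, na.rm = TRUE)) fail("fraction signals must be >= 0")
  tot <- rowSums(p)
  zero <- !is.na(tot) & tot == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero profile(s); WA set to NA", call. = FALSE)
  }
  if (normalize) p <- p / ifelse(tot == 0, NA_real_, tot)
  out <- as.numeric(p %*% wa_weights)
  out[zero] <- NA_real_
  out
}

#' Read a long-format six-fraction Repli-seq table
#'
#' Expects columns `contig`, `start`, `end`, `fraction`, `value` with
#' fraction labels among G1b, S1, S2, S3, S4, G2; pivots to one row per bin
#' (missing fractions filled with 0).
#'
#' @param path Path to a TSV (plain or gzipped), or an equivalent data frame.
#' @return Tibble: `contig`, `start`, `end`, G1b...G2.
#' @export
read_repliseq <- function(path) {
  if (is.data.frame(path)) {
    tbl <- as_tibble(path)
  } else {
    if (!file.exists(path)) fail("Repli-seq file not found: ", path)
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  need <- c("contig", "start", "end", "fraction", "value")
  if (!all(need %in% names(tbl))) {
    fail("Repli-seq table must have columns ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(tbl$fraction), names(wa_weights))
  if (length(bad) > 0) {
    fail("unknown Repli-seq fraction label(s): ", paste(bad, collapse = ", "))
  }
  wide <- tidyr::pivot_wider(tbl, names_from = "fraction",
                             values_from = "value", values_fill = 0)
  for (f in setdiff(names(wa_weights), names(wide))) wide[[f]] <- 0
  dplyr::select(wide, "contig", "start", "end", dplyr::all_of(names(wa_weights)))
}

#' Assign each CpG the WA score of its containing bin
#'
#' Bins are 0-based half-open and must not overlap; CpGs outside every bin
#' receive NA.
#'
#' @param sites Tibble with columns `contig`, `pos` (e.g. an annotation).
#' @param bins Tibble with columns `contig`, `start`, `end`, `wa`.
#' @return `sites` with an added `wa` column.
#' @export
map_cpgs_to_wa <- function(sites, bins) {
  stopifnot(all(c("contig", "pos") %in% names(sites)))
  if (!all(c("contig", "start", "end", "wa") %in% names(bins))) {
    fail("`bins` must have columns contig, start, end, wa")
  }
  validate_intervals(bins)
  wa <- rep(NA_real_, nrow(sites))
  for (ctg in unique(sites$contig)) {
    iv <- bins[bins$contig == ctg, , drop = FALSE]
    sel <- which(sites$contig == ctg)
    if (nrow(iv) == 0) next
    ir <- IRanges::IRanges(iv$start + 1, iv$end)
    if (any(IRanges::countOverlaps(ir, ir) > 1)) {
      fail("overlapping bins on contig ", ctg)
    }
    q <- IRanges::IRanges(sites$pos[sel] + 1, width = 1)
    hit <- IRanges::findOverlaps(q, ir, select = "first")
    wa[sel] <- iv$wa[hit]
  }
  dplyr::mutate(as_tibble(sites), wa = wa)
}
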