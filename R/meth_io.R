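#' Population doublings from a passage count
#'
#' Cumulative cell divisions accrued over one passage, from viable cell yield
#' and viable cell inoculum, added to the inoculum's prior doubling count:
#' `PD = 3.32 * (log10(yield) - log10(inoculum)) + inoculum_pd`.
#'
#' @param yield Viable cell yield at harvest (> 0). Vectorised.
#' @param inoculum Viable cell inoculum seeded (> 0). Vectorised.
#' @param inoculum_pd Cumulative PD of the inoculum (>= 0, default 0).
#' @return Cumulative population doublings (numeric).
#' @export
compute_population_doublings <- function(yield, inoculum, inoculum_pd = 0) {
  if (any(!is.finite(yield)) || any(yield <= 0) ||
      any(!is.finite(inoculum)) || any(inoculum <= 0)) {
    fail("`yield` and `inoculum` must be positive finite counts")
  }
  if (any(inoculum_pd < 0)) fail("`inoculum_pd` must be >= 0")
  3.32 * (log10(yield) - log10(inoculum)) + inoculum_pd
}

#' Logit (M-value) transform of beta values
#'
#' `m = log2(b / (1 - b))` after clipping beta into `[eps, 1 - eps]`.
#' Strictly increasing in beta; [m_to_beta()] is its exact inverse on the
#' clipped range.
#'
#' @param beta Fractional methylation in `[0, 1]` (NA passed through).
#' @param eps Clipping constant in (0, 0.5).
#' @return M-values (numeric).
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (!is_scalar_number(eps) || eps <= 0 || eps >= 0.5) {
    fail("`eps` must lie in (0, 0.5)")
  }
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    fail("beta values must lie in [0, 1]")
  }
  b <- clamp(beta, eps, 1 - eps)
  log2(b / (1 - b))
}

#' Inverse of the M-value transform
#'
#' @param m M-values.
#' @return Beta values in (0, 1).
#' @export
m_to_beta <- function(m) {
  x <- 2^m
  x / (1 + x)
}

sniff_delim <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a beta-value matrix
#'
#' Expects a delimited file whose first column holds probe ids and remaining
#' columns one sample each. Values must lie in `[0, 1]` or be missing.
#'
#' @param path Path to a TSV/CSV file (plain or gzipped).
#' @param delim Field delimiter; sniffed from the header when `NULL`.
#' @return Tibble with `probe_id` plus one numeric column per sample.
#' @export
read_beta_matrix <- function(path, delim = NULL) {
  if (!file.exists(path)) fail("beta matrix file not found: ", path)
  delim <- delim %||% sniff_delim(path)
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  names(tbl)[1] <- "probe_id"
  tbl$probe_id <- as.character(tbl$probe_id)
  if (anyDuplicated(tbl$probe_id)) {
    fail("duplicate probe id in ", path, ": ",
         tbl$probe_id[anyDuplicated(tbl$probe_id)])
  }
  if (anyDuplicated(names(tbl))) fail("duplicate sample id in ", path)
  beta_as_matrix(tbl) # bounds check with probe/sample id in message
  tbl
}

#' Write a beta-value matrix
#'
#' @param beta Tibble with `probe_id` plus sample columns.
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path, delim = "\t") {
  beta_as_matrix(beta)
  readr::write_delim(beta, path, delim = delim)
  invisible(path)
}

#' Read a culture sample sheet and compute cumulative population doublings
#'
#' Required columns: `sample_id`, `lineage`, `passage`, `yield`, `inoculum`.
#' Optional: `inoculum_pd` (starting PD of each lineage's first inoculum;
#' default 0), `days`, and arbitrary condition columns, all carried through.
#' Cumulative PDs chain the per-passage doubling increments within each
#' lineage in passage order.
#'
#' @param path Path to a CSV/TSV file, or a data frame with the same columns.
#' @param delim Field delimiter; sniffed when `NULL` (files only).
#' @return The sheet ordered by lineage and passage with an added
#'   `cumulative_pd` column.
#' @export
read_sample_sheet <- function(path, delim = NULL) {
  if (is.data.frame(path)) {
    sheet <- as_tibble(path)
  } else {
    if (!file.exists(path)) fail("sample sheet not found: ", path)
    delim <- delim %||% sniff_delim(path)
    sheet <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                               progress = FALSE)
  }
  required <- c("sample_id", "lineage", "passage", "yield", "inoculum")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0) {
    fail("sample sheet is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"inoculum_pd" %in% names(sheet)) sheet$inoculum_pd <- 0
  if (any(!is.finite(sheet$yield)) || any(sheet$yield <= 0) ||
      any(!is.finite(sheet$inoculum)) || any(sheet$inoculum <= 0)) {
    fail("sample sheet yields and inocula must be positive")
  }
  if ("days" %in% names(sheet) && any(sheet$days < 0, na.rm = TRUE)) {
    fail("sample sheet days must be >= 0")
  }
  sheet <- dplyr::arrange(sheet, .data$lineage, .data$passage)
  sheet <- sheet |>
    dplyr::group_by(.data$lineage) |>
    dplyr::mutate(
      cumulative_pd = dplyr::first(.data$inoculum_pd) +
        cumsum(3.32 * (log10(.data$yield) - log10(.data$inoculum)))
    ) |>
    dplyr::ungroup()
  dec <- sheet |>
    dplyr::group_by(.data$lineage) |>
    dplyr::summarise(bad = any(diff(.data$cumulative_pd) < -1e-8),
                     .groups = "drop")
  if (any(dec$bad)) {
    warning("cumulative PD decreases within lineage(s): ",
            paste(dec$lineage[dec$bad], collapse = ", "), call. = FALSE)
  }
  sheet
}

#' Read a clock coefficient file
#'
#' TSV with columns `term`, `coefficient`, `training_mean`; one row must be
#' the `(Intercept)`, the rest are probe coefficients.
#'
#' @param path Path to the clock TSV.
#' @return A `replitali_clock` object.
#' @export
read_clock <- function(path) {
  if (!file.exists(path)) fail("clock file not found: ", path)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("term", "coefficient")
  if (!all(need %in% names(tbl))) {
    fail("clock file must have columns term, coefficient[, training_mean]")
  }
  if (!"training_mean" %in% names(tbl)) tbl$training_mean <- NA_real_
  ic <- tbl$term == "(Intercept)"
  if (sum(ic) != 1) fail("clock file must contain exactly one (Intercept) row")
  new_replitali_clock(
    intercept = tbl$coefficient[ic],
    coefficients = tibble(probe_id = tbl$term[!ic],
                          coefficient = tbl$coefficient[!ic],
                          training_mean = tbl$training_mean[!ic]),
    metadata = list(source = path)
  )
}

#' Write a clock coefficient file
#'
#' @param clock A `replitali_clock` object.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_clock <- function(clock, path) {
  stopifnot(inherits(clock, "replitali_clock"))
  tbl <- dplyr::bind_rows(
    tibble(term = "(Intercept)", coefficient = clock$intercept,
           training_mean = NA_real_),
    tibble(term = clock$coefficients$probe_id,
           coefficient = clock$coefficients$coefficient,
           training_mean = clock$coefficients$training_mean)
  )
  readr::write_tsv(tbl, path)
  invisible(path)
}
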