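# internal helpers shared across modules

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stop() wrapper keeping call noise out of user-facing messages
fail <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# coerce a (sample_id, pd) tibble or a named numeric vector to a named vector
as_pd_vector <- function(sample_pds, samples = NULL) {
  if (is.data.frame(sample_pds)) {
    need <- c("sample_id", "pd")
    missing_cols <- setdiff(need, names(sample_pds))
    if (length(missing_cols) > 0) {
      fail("`sample_pds` is missing required column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    pds <- setNames(as.numeric(sample_pds$pd), sample_pds$sample_id)
  } else if (is.numeric(sample_pds) && !is.null(names(sample_pds))) {
    pds <- sample_pds
  } else {
    fail("`sample_pds` must be a data frame with columns sample_id, pd, ",
         "or a named numeric vector")
  }
  if (!is.null(samples)) {
    absent <- setdiff(samples, names(pds))
    if (length(absent) > 0) {
      fail("no PD available for sample(s): ", paste(head(absent, 5), collapse = ", "))
    }
    pds <- pds[samples]
  }
  pds
}

# beta table (probe_id + one column per sample) -> numeric matrix probes x samples
beta_as_matrix <- function(beta) {
  if (!is.data.frame(beta) || !"probe_id" %in% names(beta)) {
    fail("a beta table must be a data frame with a `probe_id` column ",
         "followed by one numeric column per sample")
  }
  if (anyDuplicated(beta$probe_id)) fail("duplicate probe ids in beta table")
  sample_cols <- setdiff(names(beta), "probe_id")
  if (length(sample_cols) == 0) fail("beta table has no sample columns")
  m <- as.matrix(beta[sample_cols])
  if (!is.numeric(m)) fail("beta values must be numeric")
  rownames(m) <- beta$probe_id
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    fail("beta value outside [0, 1] at probe ", rownames(m)[bad[1, 1]],
         ", sample ", colnames(m)[bad[1, 2]])
  }
  m
}

matrix_as_beta <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(probe_id = rownames(m)), out)
}
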