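#' Read a genome from a FASTA file
#'
#' Loads a (multi-)contig genome, uppercases the sequence and checks the
#' alphabet. Contig names are truncated at the first whitespace, following
#' common FASTA header conventions.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return A named character vector, one element per contig, over the
#'   alphabet A, C, G, T, N.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) fail("FASTA file not found: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(dss))
  names(g) <- sub("\\s.*$", "", names(dss))
  validate_genome(g)
}

#' Validate a genome represented as named character strings
#'
#' @param genome Named character vector of contig sequences.
#' @return The genome, uppercased, invisibly checked.
#' @export
validate_genome <- function(genome) {
  if (!is.character(genome) || length(genome) == 0) {
    fail("genome must be a non-empty named character vector of contig sequences")
  }
  if (is.null(names(genome)) || any(names(genome) == "") ||
      anyDuplicated(names(genome))) {
    fail("contig names must be present and unique")
  }
  genome <- toupper(genome)
  if (any(nchar(genome) == 0)) fail("empty contig sequence in genome")
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad)) {
    fail("contig ", names(genome)[which(bad)[1]],
         " contains characters outside {A,C,G,T,N}")
  }
  genome
}

#' Find all plus-strand CpG dinucleotides
#'
#' Scans every contig for occurrences of the CG dinucleotide. Because CG is
#' its own reverse complement, plus-strand positions represent both strands.
#'
#' @param genome Named character vector of contig sequences (see
#'   [read_genome()]).
#' @return A tibble with columns `contig` and `pos` (0-based position of the
#'   C), sorted by contig then position.
#' @export
find_cpgs <- function(genome) {
  genome <- validate_genome(genome)
  res <- purrr::map2(names(genome), unname(genome), function(ctg, seq) {
    hits <- gregexpr("CG", seq, fixed = TRUE)[[1]]
    if (hits[1] == -1) return(tibble(contig = character(), pos = integer()))
    tibble(contig = ctg, pos = as.integer(hits) - 1L)
  })
  dplyr::bind_rows(res)
}

#' Classify the immediate flanks of CpG sites
#'
#' The base immediately 5' of the C and immediately 3' of the G define the
#' context: `WCGW` when both are A or T, `SCGS` when both are C or G,
#' `intermediate` when one of each, and `ambiguous` when a flank is N or the
#' CpG touches a contig edge.
#'
#' @param sites Tibble with columns `contig`, `pos` (0-based C position).
#' @param genome Named character vector of contig sequences.
#' @return `sites` with added columns `flank_left`, `flank_right`,
#'   `flank_class`.
#' @export
classify_flanks <- function(sites, genome) {
  genome <- validate_genome(genome)
  stopifnot(all(c("contig", "pos") %in% names(sites)))
  unknown <- setdiff(unique(sites$contig), names(genome))
  if (length(unknown) > 0) {
    fail("site contig(s) not in genome: ", paste(unknown, collapse = ", "))
  }
  seqs <- genome[sites$contig]
  len <- nchar(seqs)
  # 0-based pos -> 1-based substr indices: left flank at pos, right at pos + 3
  left <- ifelse(sites$pos >= 1L, substr(seqs, sites$pos, sites$pos), "")
  right <- ifelse(sites$pos + 3L <= len,
                  substr(seqs, sites$pos + 3L, sites$pos + 3L), "")
  w <- c("A", "T")
  s <- c("C", "G")
  flank_class <- dplyr::case_when(
    left == "" | right == "" | left == "N" | right == "N" ~ "ambiguous",
    left %in% w & right %in% w ~ "WCGW",
    left %in% s & right %in% s ~ "SCGS",
    TRUE ~ "intermediate"
  )
  dplyr::mutate(as_tibble(sites), flank_left = left, flank_right = right,
                flank_class = flank_class)
}

#' Solo/social classification of CpG sites
#'
#' Distance is measured start-to-start between the C positions of neighbouring
#' CpGs on the same contig. A site is solo when its nearest neighbour is at
#' least `threshold` bp away; a contig's only CpG has infinite distance and is
#' solo.
#'
#' @param sites Tibble with columns `contig`, `pos`.
#' @param threshold Solo distance threshold in bp (default 35; the boundary is
#'   assigned to solo).
#' @return `sites` with added columns `nearest_cpg_distance` (bp, `Inf` for a
#'   lone CpG) and `solo` (logical).
#' @export
classify_solo <- function(sites, threshold = 35) {
  if (!is_scalar_number(threshold) || threshold <= 0) {
    fail("`threshold` must be a positive number")
  }
  sites <- dplyr::arrange(as_tibble(sites), .data$contig, .data$pos)
  sites$pos <- as.numeric(sites$pos)
  out <- sites |>
    dplyr::group_by(.data$contig) |>
    dplyr::mutate(
      nearest_cpg_distance = pmin(
        .data$pos - dplyr::lag(.data$pos, default = -Inf),
        dplyr::lead(.data$pos, default = Inf) - .data$pos
      )
    ) |>
    dplyr::ungroup()
  dplyr::mutate(out, solo = .data$nearest_cpg_distance >= threshold)
}

#' Read a BED3+ interval file
#'
#' Reads the first three columns (contig, start, end; 0-based half-open) of a
#' BED file, skipping `track`/`browser`/`#` lines, and optionally merges
#' overlapping intervals.
#'
#' @param path Path to a BED file (plain or gzipped).
#' @param merge Union overlapping intervals per contig (default `TRUE`).
#' @return Tibble with columns `contig`, `start`, `end`.
#' @export
read_bed <- function(path, merge = TRUE) {
  if (!file.exists(path)) fail("BED file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  out <- purrr::map2(fields, idx, function(f, i) {
    if (length(f) < 3) fail("malformed BED line ", i, " in ", path,
                            ": fewer than 3 fields")
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end)) {
      fail("malformed BED line ", i, " in ", path, ": non-numeric coordinates")
    }
    if (start >= end) {
      fail("malformed BED line ", i, " in ", path, ": start >= end")
    }
    tibble(contig = f[1], start = start, end = end)
  })
  iv <- dplyr::bind_rows(out)
  if (merge && nrow(iv) > 0) iv <- merge_intervals(iv)
  iv
}

#' Merge overlapping intervals
#'
#' @param intervals Tibble with columns `contig`, `start`, `end`
#'   (0-based half-open).
#' @return Tibble of unioned intervals.
#' @export
merge_intervals <- function(intervals) {
  validate_intervals(intervals)
  intervals |>
    dplyr::group_by(.data$contig) |>
    dplyr::group_modify(function(df, key) {
      ir <- IRanges::reduce(IRanges::IRanges(df$start + 1, df$end))
      tibble(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$contig, .data$start)
}

validate_intervals <- function(intervals) {
  if (!is.data.frame(intervals) ||
      !all(c("contig", "start", "end") %in% names(intervals))) {
    fail("an interval set must have columns contig, start, end")
  }
  if (any(intervals$start >= intervals$end)) {
    fail("interval with start >= end")
  }
  invisible(intervals)
}

# membership of 0-based positions in 0-based half-open intervals
pos_in_intervals <- function(contig, pos, intervals) {
  hit <- logical(length(pos))
  if (nrow(intervals) == 0) return(hit)
  for (ctg in unique(contig)) {
    sel <- contig == ctg
    iv <- intervals[intervals$contig == ctg, , drop = FALSE]
    if (nrow(iv) == 0) next
    q <- IRanges::IRanges(pos[sel] + 1, width = 1)
    s <- IRanges::IRanges(iv$start + 1, iv$end)
    hit[sel] <- IRanges::countOverlaps(q, s) > 0
  }
  hit
}

#' Annotate every CpG in a genome
#'
#' Composes [find_cpgs()], [classify_flanks()] and [classify_solo()] with
#' interval membership. Interval sets named `commonPMD` and `HMD` define the
#' mutually exclusive `domain` column (PMD membership wins); a set named `CGI`
#' sets the independent `in_cgi` flag; any other named set becomes an extra
#' logical column of the same name.
#'
#' @param genome Named character vector of contig sequences.
#' @param intervals Named list of interval tibbles (`contig`, `start`, `end`;
#'   0-based half-open). Intervals on contigs absent from the genome are
#'   skipped with a warning.
#' @param solo_threshold Solo distance threshold in bp (default 35).
#' @return A tibble with one row per CpG: `contig`, `pos`, `flank_class`,
#'   `solo`, `nearest_cpg_distance`, `domain`, `in_cgi`, plus one logical
#'   column per extra interval set.
#' @export
annotate_cpgs <- function(genome, intervals = list(), solo_threshold = 35) {
  genome <- validate_genome(genome)
  if (length(intervals) > 0 &&
      (is.null(names(intervals)) || any(names(intervals) == ""))) {
    fail("`intervals` must be a named list of interval sets")
  }
  intervals <- purrr::imap(intervals, function(iv, nm) {
    validate_intervals(iv)
    unknown <- setdiff(unique(iv$contig), names(genome))
    if (length(unknown) > 0) {
      warning("interval set '", nm, "': skipping unknown contig(s) ",
              paste(unknown, collapse = ", "), call. = FALSE)
      iv <- iv[!iv$contig %in% unknown, , drop = FALSE]
    }
    merge_intervals(iv)
  })

  ann <- find_cpgs(genome) |>
    classify_flanks(genome) |>
    classify_solo(threshold = solo_threshold) |>
    dplyr::select(-"flank_left", -"flank_right")

  in_pmd <- pos_in_intervals(ann$contig, ann$pos,
                             intervals[["commonPMD"]] %||% tibble(contig = character(), start = numeric(), end = numeric()))
  in_hmd <- pos_in_intervals(ann$contig, ann$pos,
                             intervals[["HMD"]] %||% tibble(contig = character(), start = numeric(), end = numeric()))
  ann$domain <- dplyr::case_when(in_pmd ~ "commonPMD",
                                 in_hmd ~ "HMD",
                                 TRUE ~ "neither")
  ann$in_cgi <- pos_in_intervals(ann$contig, ann$pos,
                                 intervals[["CGI"]] %||% tibble(contig = character(), start = numeric(), end = numeric()))
  extra <- setdiff(names(intervals), c("commonPMD", "HMD", "CGI"))
  for (nm in extra) {
    ann[[nm]] <- pos_in_intervals(ann$contig, ann$pos, intervals[[nm]])
  }
  ann
}

#' Join a probe manifest to a genome annotation
#'
#' Attaches per-CpG context columns to array probes by genomic coordinate.
#' The manifest declares its coordinate base; positions are converted to the
#' package's internal 0-based convention before joining.
#'
#' @param manifest Tibble with columns `probe_id`, `contig`, `pos`.
#' @param annotation Output of [annotate_cpgs()].
#' @param manifest_base 0 or 1: coordinate base of `manifest$pos` (default 1).
#' @return The manifest with annotation columns joined; probes without a
#'   matching CpG carry NA annotation.
#' @export
annotate_manifest <- function(manifest, annotation, manifest_base = 1) {
  stopifnot(all(c("probe_id", "contig", "pos") %in% names(manifest)))
  if (!manifest_base %in% c(0, 1)) fail("`manifest_base` must be 0 or 1")
  if (anyDuplicated(manifest$probe_id)) fail("duplicate probe ids in manifest")
  m <- dplyr::mutate(as_tibble(manifest),
                     pos = as.integer(.data$pos) - as.integer(manifest_base))
  dplyr::left_join(m, annotation, by = c("contig", "pos"))
}
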