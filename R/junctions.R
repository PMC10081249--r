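#' Read a per-sample split-read junction table
#'
#' Supported dialects:
#' \describe{
#'   \item{`regtools_bed12`}{Output of `regtools junctions extract`: BED12
#'     where the two blocks are the anchoring exonic overhangs and the score
#'     column carries the read count. The implied intron interval is the gap
#'     between the blocks, converted from 0-based half-open to 1-based
#'     closed coordinates.}
#'   \item{`star_sj`}{STAR `SJ.out.tab`: columns chrom, intron start, intron
#'     end (both 1-based closed), strand code (0 = undetermined, 1 = `+`,
#'     2 = `-`), intron motif, annotation flag, unique reads, multimapping
#'     reads; the unique-read count is used.}
#'   \item{`generic_tsv`}{A TSV with header `chrom, start, end, strand, count`
#'     (1-based closed).}
#' }
#'
#' @param path File path.
#' @param dialect One of `"regtools_bed12"`, `"star_sj"`, `"generic_tsv"`.
#' @param sample_id Sample identifier attached to every row.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`
#'   (`"+"`, `"-"` or `"?"`), `sample_id`, `count`; one row per junction.
#' @export
read_junctions <- function(path, dialect = c("regtools_bed12", "star_sj",
                                             "generic_tsv"),
                           sample_id = basename(path)) {
  dialect <- match.arg(dialect)
  res <- switch(dialect,
    regtools_bed12 = read_regtools_bed12(path),
    star_sj = read_star_sj(path),
    generic_tsv = read_generic_junctions(path)
  )
  if (nrow(res) == 0) {
    rlang::warn(paste0("empty junction table: ", path))
  }
  res$sample_id <- sample_id
  res[, c("chrom", "start", "end", "strand", "sample_id", "count")]
}

read_regtools_bed12 <- function(path) {
  cols <- c("chrom", "chromStart", "chromEnd", "name", "score", "strand",
            "thickStart", "thickEnd", "itemRgb", "blockCount", "blockSizes",
            "blockStarts")
  df <- readr::read_tsv(path, col_names = cols, col_types = readr::cols(
    chrom = "c", chromStart = "i", chromEnd = "i", name = "c", score = "i",
    strand = "c", thickStart = "i", thickEnd = "i", itemRgb = "c",
    blockCount = "i", blockSizes = "c", blockStarts = "c"
  ), progress = FALSE)
  if (nrow(df) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          count = integer()))
  }
  bad <- which(df$blockCount != 2L | is.na(df$blockCount))
  if (length(bad) > 0) {
    rlang::abort(paste0("regtools BED12 format error at line ", bad[1],
                        " of ", path, ": expected 2 blocks"))
  }
  sizes <- strsplit(df$blockSizes, ",", fixed = TRUE)
  size1 <- vapply(sizes, function(x) as.integer(x[1]), integer(1))
  size2 <- vapply(sizes, function(x) as.integer(x[2]), integer(1))
  tibble::tibble(
    chrom = df$chrom,
    # BED is 0-based half-open; trim the exonic anchors to the intron
    start = df$chromStart + size1 + 1L,
    end = df$chromEnd - size2,
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "?"),
    count = df$score
  )
}

read_star_sj <- function(path) {
  df <- readr::read_tsv(path, col_names = c(
    "chrom", "start", "end", "strand_code", "motif", "annotated",
    "unique_reads", "multi_reads", "max_overhang"
  ), col_types = "ciiiiiiii", progress = FALSE)
  if (nrow(df) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          count = integer()))
  }
  if (any(!df$strand_code %in% 0:2)) {
    bad <- which(!df$strand_code %in% 0:2)[1]
    rlang::abort(paste0("SJ.out.tab format error at line ", bad, " of ", path,
                        ": strand code must be 0, 1 or 2"))
  }
  tibble::tibble(
    chrom = df$chrom,
    start = df$start,
    end = df$end,
    strand = c("?", "+", "-")[df$strand_code + 1L],
    count = df$unique_reads
  )
}

read_generic_junctions <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "i", end = "i", strand = "c", count = "i"
  ), progress = FALSE)
}

#' Write a junction table in a supported dialect
#'
#' Inverse of [read_junctions()] for a single sample; used for round-trip
#' checks and for emitting synthetic data.
#'
#' @param junctions Tibble with `chrom`, `start`, `end`, `strand`, `count`
#'   (1-based closed intron coordinates).
#' @param path Output path.
#' @param dialect Output dialect (see [read_junctions()]).
#' @param anchor Exonic anchor length written on both sides of a BED12 block
#'   pair (regtools dialect only).
#' @export
write_junctions <- function(junctions, path,
                            dialect = c("regtools_bed12", "star_sj",
                                        "generic_tsv"),
                            anchor = 8L) {
  dialect <- match.arg(dialect)
  j <- tibble::as_tibble(junctions)
  if (dialect == "generic_tsv") {
    readr::write_tsv(j[, c("chrom", "start", "end", "strand", "count")], path)
    return(invisible(path))
  }
  if (dialect == "star_sj") {
    out <- data.frame(
      chrom = j$chrom, start = j$start, end = j$end,
      strand_code = match(j$strand, c("?", "+", "-")) - 1L,
      motif = 0L, annotated = 0L, unique_reads = j$count, multi_reads = 0L,
      max_overhang = anchor
    )
    readr::write_tsv(out, path, col_names = FALSE)
    return(invisible(path))
  }
  chrom_start <- j$start - 1L - anchor
  chrom_end <- j$end + anchor
  out <- data.frame(
    chrom = j$chrom,
    chromStart = chrom_start,
    chromEnd = chrom_end,
    name = paste0("JUNC", seq_len(nrow(j))),
    score = j$count,
    strand = ifelse(j$strand %in% c("+", "-"), j$strand, "."),
    thickStart = chrom_start,
    thickEnd = chrom_end,
    itemRgb = "255,0,0",
    blockCount = 2L,
    blockSizes = paste0(anchor, ",", anchor),
    blockStarts = paste0(0L, ",", j$end - j$start + 1L + anchor)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path TSV with header; must contain `sample_id` and `rin`, and may
#'   contain `tissue`, `age` and arbitrary grouping columns.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("sample_id", "rin") %in% names(md))) {
    rlang::abort("sample metadata must contain sample_id and rin columns")
  }
  md
}

#' Read a region blacklist in BED format
#'
#' BED coordinates (0-based half-open) are converted to 1-based closed.
#'
#' @param path BED file (at least 3 columns, no header).
#' @return Tibble with `chrom`, `start`, `end` (1-based closed).
#' @export
read_blacklist <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                         progress = FALSE)
  tibble::tibble(chrom = as.character(bed[[1]]),
                 start = as.integer(bed[[2]]) + 1L,
                 end = as.integer(bed[[3]]))
}

#' Quality-control filtering of junctions and samples
#'
#' Applies the standard filters for splicing-noise analysis: junctions with
#' an implied intron shorter than `min_intron` or longer than `max_intron`
#' are removed, as are junctions on chromosomes outside `allowed_chroms`
#' (unplaced contigs) and junctions overlapping a blacklist region by at
#' least one base. Samples with RIN below `min_rin` are dropped together
#' with their counts; junctions left with no reads in any retained sample
#' are removed.
#'
#' @param junctions Long junction tibble (`chrom`, `start`, `end`, `strand`,
#'   `sample_id`, `count`).
#' @param samples Sample metadata tibble with `sample_id` and `rin`
#'   (optional; `NULL` skips the RIN filter).
#' @param blacklist Tibble of 1-based closed intervals (`chrom`, `start`,
#'   `end`), e.g. from [read_blacklist()]; `NULL` skips.
#' @param min_intron,max_intron Implied intron length bounds in bp
#'   (defaults 25 and 1,000,000).
#' @param allowed_chroms Character vector of chromosomes to keep; `NULL`
#'   keeps all.
#' @param min_rin Minimum RIN for a sample to be retained (default 6).
#' @return A list with `junctions` (filtered, same shape), `samples`
#'   (retained metadata) and `report` (tibble of removal counts per rule;
#'   junction rules count unique junction intervals, applied in the order
#'   short, long, unplaced, blacklist).
#' @export
qc_filter <- function(junctions, samples = NULL, blacklist = NULL,
                      min_intron = 25L, max_intron = 1000000L,
                      allowed_chroms = NULL, min_rin = 6) {
  j <- tibble::as_tibble(junctions)
  uniq <- dplyr::distinct(j, .data$chrom, .data$start, .data$end, .data$strand)
  n_input <- nrow(uniq)

  len <- uniq$end - uniq$start + 1L
  short <- len < min_intron
  long <- !short & len > max_intron
  unplaced <- if (is.null(allowed_chroms)) rep(FALSE, nrow(uniq)) else
    (!short & !long & !(uniq$chrom %in% allowed_chroms))
  bl <- rep(FALSE, nrow(uniq))
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    cand <- !short & !long & !unplaced
    bl[cand] <- overlaps_any(uniq[cand, ], blacklist)
  }
  keep <- !(short | long | unplaced | bl)

  samples_removed <- 0L
  if (!is.null(samples)) {
    samples <- tibble::as_tibble(samples)
    low <- samples$rin < min_rin
    samples_removed <- sum(low)
    dropped_ids <- samples$sample_id[low]
    samples <- samples[!low, , drop = FALSE]
    j <- j[!j$sample_id %in% dropped_ids, , drop = FALSE]
  }

  uniq_keep <- uniq[keep, , drop = FALSE]
  j <- dplyr::semi_join(j, uniq_keep,
                        by = c("chrom", "start", "end", "strand"))
  # drop junctions left with all-zero counts after sample removal
  j <- j |>
    dplyr::group_by(.data$chrom, .data$start, .data$end, .data$strand) |>
    dplyr::filter(sum(.data$count) > 0) |>
    dplyr::ungroup()
  j <- j[j$count > 0, , drop = FALSE]

  n_retained <- nrow(dplyr::distinct(j, .data$chrom, .data$start, .data$end,
                                     .data$strand))
  report <- tibble::tibble(
    rule = c("short", "long", "unplaced", "blacklist", "zero_count",
             "low_rin_samples"),
    removed = c(sum(short), sum(long), sum(unplaced), sum(bl),
                n_input - sum(short) - sum(long) - sum(unplaced) - sum(bl) -
                  n_retained,
                samples_removed)
  )
  list(junctions = j, samples = samples, report = report)
}

# any >=1 bp overlap of 1-based closed query intervals with subject intervals
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  q <- GenomicRanges::GRanges(query$chrom,
                              IRanges::IRanges(query$start, query$end))
  s <- GenomicRanges::GRanges(subject$chrom,
                              IRanges::IRanges(subject$start, subject$end))
  IRanges::overlapsAny(q, s)
}
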