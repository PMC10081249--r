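#' Build an intron catalog from transcript exon structures
#'
#' Derives the set of unique annotated introns from a table of exons. Each
#' intron is the gap between two consecutive exons of a transcript, expressed
#' in 1-based closed coordinates on the first/last intronic base. Introns
#' shared by several transcripts (or genes) are deduplicated by
#' (chrom, start, end, strand) and carry aggregated transcript-level
#' attributes: the fraction of containing transcripts that are protein-coding,
#' whether all of them are, and whether any is a MANE Select transcript.
#'
#' @param exons A data frame of exons with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (`"+"`/`"-"`), `start`, `end` (1-based closed).
#' @param transcripts A data frame with one row per transcript: columns
#'   `transcript_id`, `gene_id`, `biotype`, `is_mane_select` (logical).
#' @param version_label Free-text label for the annotation version.
#'
#' @return A `genome_annotation` object: a list with elements
#'   `version_label`, `transcripts`, `exons`, `introns` (one row per unique
#'   intron, with `intron_id`, coordinates, `donor_pos`/`acceptor_pos`,
#'   `length`, `transcript_ids` and `gene_ids` list-columns, `gene_id`,
#'   `n_transcripts`, `protein_coding_fraction`, `exclusively_protein_coding`,
#'   `in_mane`, `minor_spliceosome`) and `gene_index` (per-gene length and
#'   transcript count).
#'
#' Transcripts with fewer than two exons contribute no introns. On the plus
#' strand the donor position is the intron start; on the minus strand it is
#' the intron end (and conversely for the acceptor).
#'
#' @export
extract_introns <- function(exons, transcripts, version_label = "custom") {
  required <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("exons is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  exons <- tibble::as_tibble(exons)
  transcripts <- tibble::as_tibble(transcripts)
  if (!"is_mane_select" %in% names(transcripts)) {
    transcripts$is_mane_select <- FALSE
  }
  if (!"biotype" %in% names(transcripts)) transcripts$biotype <- NA_character_

  per_tx <- exons |>
    dplyr::arrange(.data$transcript_id, .data$start) |>
    dplyr::group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    dplyr::reframe(exon_gaps(.data$start, .data$end)) |>
    dplyr::filter(.data$end >= .data$start)

  tx_attr <- transcripts |>
    dplyr::select("transcript_id",
                  tx_biotype = "biotype",
                  "is_mane_select")

  introns <- per_tx |>
    dplyr::left_join(tx_attr, by = "transcript_id") |>
    dplyr::group_by(.data$chrom, .data$start, .data$end, .data$strand) |>
    dplyr::summarise(
      transcript_ids = list(sort(unique(.data$transcript_id))),
      gene_ids = list(sort(unique(.data$gene_id))),
      n_transcripts = dplyr::n_distinct(.data$transcript_id),
      protein_coding_fraction =
        mean(.data$tx_biotype == "protein_coding", na.rm = FALSE),
      exclusively_protein_coding =
        all(.data$tx_biotype == "protein_coding"),
      in_mane = any(.data$is_mane_select),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$strand) |>
    dplyr::mutate(
      intron_id = dplyr::row_number(),
      gene_id = purrr::map_chr(.data$gene_ids, 1L),
      length = .data$end - .data$start + 1L,
      donor_pos = ifelse(.data$strand == "+", .data$start, .data$end),
      acceptor_pos = ifelse(.data$strand == "+", .data$end, .data$start),
      minor_spliceosome = FALSE
    ) |>
    dplyr::select(
      "intron_id", "chrom", "start", "end", "strand",
      "donor_pos", "acceptor_pos", "length",
      "transcript_ids", "gene_ids", "gene_id", "n_transcripts",
      "protein_coding_fraction", "exclusively_protein_coding",
      "in_mane", "minor_spliceosome"
    )

  gene_index <- exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      gene_length = max(.data$end) - min(.data$start) + 1L,
      merged_exonic_length = merged_interval_length(.data$start, .data$end),
      n_transcripts = dplyr::n_distinct(.data$transcript_id),
      .groups = "drop"
    )

  structure(
    list(
      version_label = version_label,
      transcripts = transcripts,
      exons = exons,
      introns = introns,
      gene_index = gene_index
    ),
    class = "genome_annotation"
  )
}

# gaps between consecutive (genomically sorted) exons of one transcript
exon_gaps <- function(exon_start, exon_end) {
  if (length(exon_start) < 2L) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  gap_start <- utils::head(exon_end, -1L) + 1L
  gap_end <- utils::tail(exon_start, -1L) - 1L
  tibble::tibble(start = gap_start, end = gap_end)
}

# total length covered by the union of 1-based closed intervals
merged_interval_length <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0L
  cur_s <- start[1L]; cur_e <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s + 1L)
}

#' Read a GTF annotation into a genome_annotation object
#'
#' Parses an Ensembl/GENCODE-dialect GTF and builds the unique-intron catalog
#' with [extract_introns()]. Transcript biotype is taken from the
#' `transcript_biotype` or `transcript_type` attribute (whichever is present);
#' MANE Select status from a `tag` attribute equal to (or containing)
#' `"MANE_Select"`.
#'
#' @param path Path to a GTF file.
#' @param version_label Free-text label stored on the returned object.
#' @return A `genome_annotation` object (see [extract_introns()]).
#' @export
read_gtf_annotation <- function(path, version_label = basename(path)) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) rlang::abort(paste0("GTF parse error in ", path, ": ",
                                            conditionMessage(e)))
  )
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  exon_df <- df[df$type == "exon", , drop = FALSE]
  if (nrow(exon_df) == 0) {
    rlang::abort("GTF contains no exon features")
  }
  if (is.null(exon_df$transcript_id) || is.null(exon_df$gene_id)) {
    rlang::abort("GTF exon features lack transcript_id/gene_id attributes")
  }
  biotype_col <- intersect(c("transcript_biotype", "transcript_type"), names(df))
  exons <- tibble::tibble(
    transcript_id = exon_df$transcript_id,
    gene_id = exon_df$gene_id,
    chrom = as.character(exon_df$seqnames),
    strand = as.character(exon_df$strand),
    start = exon_df$start,
    end = exon_df$end,
    biotype = if (length(biotype_col)) exon_df[[biotype_col[1]]] else NA_character_,
    tag = if ("tag" %in% names(exon_df)) flatten_tag(exon_df$tag) else NA_character_
  )
  transcripts <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      gene_id = .data$gene_id[1L],
      biotype = .data$biotype[1L],
      is_mane_select = any(grepl("MANE_Select", .data$tag, fixed = TRUE) &
                             !is.na(.data$tag)),
      chrom = .data$chrom[1L],
      strand = .data$strand[1L],
      .groups = "drop"
    )
  extract_introns(exons[required_exon_cols()], transcripts,
                  version_label = version_label)
}

required_exon_cols <- function() {
  c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
}

flatten_tag <- function(tag) {
  if (is.list(tag)) {
    vapply(tag, function(x) paste(as.character(x), collapse = ","), character(1))
  } else {
    as.character(tag)
  }
}

#' Flag introns spliced by the minor spliceosome
#'
#' Marks introns whose coordinates exactly match an entry of a supplied
#' minor-spliceosome intron list. Matching is exact on
#' (chrom, start, end, strand); flagged introns are excluded from
#' classification and every downstream statistic.
#'
#' @param annotation A `genome_annotation` object.
#' @param minor_list Data frame with columns `chrom`, `start`, `end`,
#'   `strand` (1-based closed coordinates).
#' @return The annotation with `minor_spliceosome` updated.
#' @export
flag_minor_introns <- function(annotation, minor_list) {
  stopifnot(inherits(annotation, "genome_annotation"))
  minor_list <- tibble::as_tibble(minor_list)
  if (nrow(minor_list) == 0) return(annotation)
  key <- paste(minor_list$chrom, minor_list$start, minor_list$end,
               minor_list$strand)
  ik <- with(annotation$introns, paste(chrom, start, end, strand))
  annotation$introns$minor_spliceosome <-
    annotation$introns$minor_spliceosome | (ik %in% key)
  annotation
}

#' Read a minor-spliceosome intron list
#'
#' @param path Path to a 4-column TSV (`chrom`, `start`, `end`, `strand`),
#'   1-based closed coordinates, with a header line.
#' @return A tibble.
#' @export
read_minor_intron_list <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    strand = readr::col_character()
  ))
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", x$version_label, "\n", sep = "")
  cat("  transcripts: ", nrow(x$transcripts),
      "  unique introns: ", nrow(x$introns),
      "  genes: ", nrow(x$gene_index), "\n", sep = "")
  invisible(x)
}

#' Gene lengths under a chosen definition
#'
#' @param annotation A `genome_annotation` object.
#' @param method `"span"` (genomic span of the gene's exons, default) or
#'   `"merged_exons"` (sum of merged exon lengths, the definition used for
#'   TPM denominators).
#' @return A tibble with `gene_id` and `gene_length`.
#' @export
gene_lengths <- function(annotation, method = c("span", "merged_exons")) {
  method <- match.arg(method)
  gi <- annotation$gene_index
  tibble::tibble(
    gene_id = gi$gene_id,
    gene_length = if (method == "span") gi$gene_length else gi$merged_exonic_length
  )
}
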