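#' Per-intron mis-splicing ratios (MSR_D and MSR_A)
#'
#' For each annotated intron, reads are pooled across the sample subset
#' before forming the ratio: the donor-side mis-splicing ratio is
#' `MSR_D = D / (D + S)` where `D` is the cumulative read count of novel
#' donor junctions assigned to the intron and `S` the cumulative read count
#' of the annotated junction itself; `MSR_A` is the acceptor analogue.
#' `MSR = 0` represents fully accurate splicing at that site and `MSR = 1`
#' complete mis-splicing. Ratios are pooled over reads, not averaged over
#' per-sample ratios. A zero denominator yields `NA` (no pseudocounts);
#' introns with no reads in any category are omitted.
#'
#' @param classified Classified-and-assigned junction tibble
#'   ([classify_and_assign()]).
#' @param counts Long junction tibble with per-sample `count`s.
#' @param sample_subset Character vector of sample ids to pool over
#'   (default: all samples present in `counts`). Unknown ids are an error.
#' @return A tibble with one row per intron: `intron_id`,
#'   `sum_annotated_reads`, `sum_novel_donor_reads`,
#'   `sum_novel_acceptor_reads`, `msr_d`, `msr_a`, `n_samples`.
#' @export
compute_msr <- function(classified, counts, sample_subset = NULL) {
  counts <- tibble::as_tibble(counts)
  if (!is.null(sample_subset)) {
    unknown <- setdiff(sample_subset, unique(counts$sample_id))
    if (length(unknown) > 0) {
      rlang::abort(paste0("unknown sample id(s): ",
                          paste(unknown, collapse = ", ")))
    }
    counts <- counts[counts$sample_id %in% sample_subset, , drop = FALSE]
    n_samples <- length(unique(sample_subset))
  } else {
    n_samples <- length(unique(counts$sample_id))
  }
  if (nrow(counts) == 0 || n_samples == 0) {
    rlang::abort("sample subset is empty")
  }

  joined <- classified |>
    dplyr::filter(.data$category %in% c("annotated", "novel_donor",
                                        "novel_acceptor"),
                  !is.na(.data$assigned_intron_id)) |>
    dplyr::inner_join(counts,
                      by = c("chrom", "start", "end",
                             orig_strand = "strand"))

  joined |>
    dplyr::group_by(intron_id = .data$assigned_intron_id) |>
    dplyr::summarise(
      sum_annotated_reads = sum(.data$count[.data$category == "annotated"]),
      sum_novel_donor_reads = sum(.data$count[.data$category == "novel_donor"]),
      sum_novel_acceptor_reads =
        sum(.data$count[.data$category == "novel_acceptor"]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$sum_annotated_reads + .data$sum_novel_donor_reads +
                    .data$sum_novel_acceptor_reads > 0) |>
    dplyr::mutate(
      msr_d = msr_ratio(.data$sum_novel_donor_reads,
                        .data$sum_annotated_reads),
      msr_a = msr_ratio(.data$sum_novel_acceptor_reads,
                        .data$sum_annotated_reads),
      n_samples = n_samples
    )
}

msr_ratio <- function(novel, annotated) {
  denom <- novel + annotated
  ifelse(denom > 0, novel / denom, NA_real_)
}

#' Category percentages of unique junctions and of read counts
#'
#' Two complementary composition summaries over the categories
#' annotated / novel donor / novel acceptor. `p_unique` is based on
#' junction-sample occurrences: within each sample the unique junctions of
#' each category are counted (a junction seen in k samples contributes k),
#' the per-sample counts are summed and converted to percentages.
#' `p_unique_distinct` deduplicates junctions across samples instead.
#' `p_reads` uses cumulative read counts.
#'
#' @inheritParams compute_msr
#' @return A tibble with `category`, `p_unique`, `p_unique_distinct`,
#'   `p_reads`; each percentage column sums to 100.
#' @export
category_percentages <- function(classified, counts, sample_subset = NULL) {
  counts <- tibble::as_tibble(counts)
  if (!is.null(sample_subset)) {
    counts <- counts[counts$sample_id %in% sample_subset, , drop = FALSE]
  }
  cats <- c("annotated", "novel_donor", "novel_acceptor")
  joined <- classified |>
    dplyr::filter(.data$category %in% cats) |>
    dplyr::inner_join(counts, by = c("chrom", "start", "end",
                                     orig_strand = "strand")) |>
    dplyr::filter(.data$count > 0)
  if (nrow(joined) == 0) {
    rlang::warn("no junction reads in any category; percentages undefined")
    return(tibble::tibble(category = cats, p_unique = NA_real_,
                          p_unique_distinct = NA_real_, p_reads = NA_real_))
  }
  occ <- joined |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      occurrences = dplyr::n(),
      distinct_junctions = dplyr::n_distinct(paste(.data$chrom, .data$start,
                                                   .data$end, .data$strand)),
      reads = sum(.data$count),
      .groups = "drop"
    )
  tibble::tibble(category = cats) |>
    dplyr::left_join(occ, by = "category") |>
    dplyr::mutate(dplyr::across(c("occurrences", "distinct_junctions",
                                  "reads"),
                                ~ dplyr::coalesce(.x, 0L))) |>
    dplyr::mutate(
      p_unique = 100 * .data$occurrences / sum(.data$occurrences),
      p_unique_distinct =
        100 * .data$distinct_junctions / sum(.data$distinct_junctions),
      p_reads = 100 * .data$reads / sum(.data$reads)
    ) |>
    dplyr::select("category", "p_unique", "p_unique_distinct", "p_reads")
}

#' Transcripts per million
#'
#' Length-normalized within-sample expression: reads per kilobase
#' (`rpk = count / (length/1000)`) scaled so each sample sums to one
#' million (`tpm = rpk / (sum(rpk) / 1e6)`).
#'
#' @param gene_counts Numeric matrix (genes x samples) of read counts, with
#'   gene ids as row names, or a data frame with a `gene_id` column and one
#'   numeric column per sample.
#' @param gene_length Named numeric vector of gene lengths in bp (names =
#'   gene ids), or a tibble `gene_id`, `gene_length` as from
#'   [gene_lengths()].
#' @return A tibble: `gene_id` plus one TPM column per sample. Samples with
#'   zero total RPK give an all-`NA` column with a warning.
#' @export
tpm <- function(gene_counts, gene_length) {
  if (is.data.frame(gene_counts)) {
    ids <- gene_counts$gene_id
    m <- as.matrix(gene_counts[setdiff(names(gene_counts), "gene_id")])
    rownames(m) <- ids
  } else {
    m <- as.matrix(gene_counts)
  }
  if (is.data.frame(gene_length)) {
    gene_length <- stats::setNames(gene_length$gene_length,
                                   gene_length$gene_id)
  }
  lens <- gene_length[rownames(m)]
  if (anyNA(lens)) {
    rlang::abort("gene_length missing for some genes in the count matrix")
  }
  if (any(lens <= 0)) rlang::abort("gene lengths must be positive")
  rpk <- m / (lens / 1000)
  scale_f <- colSums(rpk) / 1e6
  if (any(scale_f == 0)) {
    rlang::warn("sample(s) with zero total RPK; TPM undefined there")
    scale_f[scale_f == 0] <- NA_real_
  }
  out <- sweep(rpk, 2, scale_f, "/")
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(out))
}
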