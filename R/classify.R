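#' Classify split-read junctions against an intron catalog
#'
#' Each unique junction interval is compared with the annotated introns of
#' the supplied annotation (introns flagged as minor-spliceosome are excluded
#' from the index). A junction whose interval exactly matches an annotated
#' intron is `annotated`. Otherwise the two boundaries are tested against the
#' catalog's donor and acceptor positions on the same chromosome and strand:
#' the *novel* end names the category, so a junction whose acceptor boundary
#' matches annotation but whose donor does not is a `novel_donor`, and vice
#' versa for `novel_acceptor`. Junctions whose two ends each match a boundary
#' but whose pairing is unannotated are `novel_combination` (putative exon
#' skipping); junctions matching nothing are `unclassified`. Both of the
#' latter are excluded from downstream mis-splicing statistics.
#'
#' Strand-unknown junctions (`"?"`) adopt the strand under which they match;
#' if they match annotation on both strands they are `unclassified`.
#'
#' @param junctions A junction tibble (long, as returned by
#'   [read_junctions()]) or a distinct interval table with `chrom`, `start`,
#'   `end`, `strand`.
#' @param annotation A `genome_annotation` object.
#' @return A tibble with one row per unique junction interval: `chrom`,
#'   `start`, `end`, `strand` (resolved), `orig_strand` (as read), `category`,
#'   `shared_site` (`"both"`, `"donor"`, `"acceptor"`, `"none"`),
#'   `assigned_intron_id` (set for annotated junctions; novel junctions are
#'   assigned by [assign_novel()]).
#' @export
classify_junctions <- function(junctions, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  jx <- tibble::as_tibble(junctions) |>
    dplyr::distinct(.data$chrom, .data$start, .data$end, .data$strand)
  introns <- annotation$introns[!annotation$introns$minor_spliceosome, ,
                                drop = FALSE]

  known <- jx[jx$strand %in% c("+", "-"), , drop = FALSE]
  unknown <- jx[!jx$strand %in% c("+", "-"), , drop = FALSE]

  res_known <- classify_with_strand(known, known$strand, introns)
  res_known$orig_strand <- known$strand

  if (nrow(unknown) > 0) {
    plus <- classify_with_strand(unknown, rep("+", nrow(unknown)), introns)
    minus <- classify_with_strand(unknown, rep("-", nrow(unknown)), introns)
    plus_hit <- plus$category != "unclassified"
    minus_hit <- minus$category != "unclassified"
    res_unknown <- plus # shape template
    take_plus <- plus_hit & !minus_hit
    take_minus <- minus_hit & !plus_hit
    ambiguous <- plus_hit & minus_hit
    res_unknown[take_minus, ] <- minus[take_minus, ]
    res_unknown$category[ambiguous | (!plus_hit & !minus_hit)] <- "unclassified"
    res_unknown$shared_site[ambiguous | (!plus_hit & !minus_hit)] <- "none"
    res_unknown$assigned_intron_id[res_unknown$category == "unclassified"] <-
      NA_integer_
    res_unknown$strand[res_unknown$category == "unclassified"] <- "?"
    res_unknown$orig_strand <- unknown$strand
    out <- dplyr::bind_rows(res_known, res_unknown)
  } else {
    out <- res_known
  }
  out |>
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$orig_strand)
}

classify_with_strand <- function(jx, strand, introns) {
  n <- nrow(jx)
  if (n == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          category = character(), shared_site = character(),
                          assigned_intron_id = integer()))
  }
  donor_coord <- ifelse(strand == "+", jx$start, jx$end)
  acceptor_coord <- ifelse(strand == "+", jx$end, jx$start)

  exact_key <- paste(jx$chrom, jx$start, jx$end, strand)
  intron_key <- paste(introns$chrom, introns$start, introns$end, introns$strand)
  exact_idx <- match(exact_key, intron_key)

  donor_set <- paste(introns$chrom, introns$strand, introns$donor_pos)
  acceptor_set <- paste(introns$chrom, introns$strand, introns$acceptor_pos)
  donor_match <- paste(jx$chrom, strand, donor_coord) %in% donor_set
  acceptor_match <- paste(jx$chrom, strand, acceptor_coord) %in% acceptor_set

  category <- dplyr::case_when(
    !is.na(exact_idx) ~ "annotated",
    acceptor_match & !donor_match ~ "novel_donor",
    donor_match & !acceptor_match ~ "novel_acceptor",
    donor_match & acceptor_match ~ "novel_combination",
    TRUE ~ "unclassified"
  )
  shared_site <- dplyr::case_when(
    category == "annotated" ~ "both",
    category == "novel_donor" ~ "acceptor",
    category == "novel_acceptor" ~ "donor",
    category == "novel_combination" ~ "both",
    TRUE ~ "none"
  )
  tibble::tibble(
    chrom = jx$chrom, start = jx$start, end = jx$end, strand = strand,
    category = category, shared_site = shared_site,
    assigned_intron_id = ifelse(category == "annotated",
                                introns$intron_id[exact_idx], NA_integer_)
  )
}

#' Total annotated reads per intron
#'
#' Sums read counts of annotated junctions over a sample set, keyed by the
#' intron each junction matches. Used as the support measure for unique
#' assignment of novel junctions.
#'
#' @param classified Output of [classify_junctions()].
#' @param counts Long junction tibble with per-sample `count`s.
#' @return Tibble `intron_id`, `total_reads`.
#' @export
counts_by_intron <- function(classified, counts) {
  classified |>
    dplyr::filter(.data$category == "annotated") |>
    dplyr::inner_join(tibble::as_tibble(counts),
                      by = c("chrom", "start", "end", orig_strand = "strand")) |>
    dplyr::group_by(.data$assigned_intron_id) |>
    dplyr::summarise(total_reads = sum(.data$count), .groups = "drop") |>
    dplyr::rename(intron_id = "assigned_intron_id")
}

#' Uniquely assign novel junctions to annotated introns
#'
#' A novel donor junction shares its acceptor boundary with annotation and a
#' novel acceptor junction its donor boundary. When that boundary belongs to
#' more than one annotated intron (annotation-level alternative donors or
#' acceptors), the junction is assigned to the candidate intron with the
#' highest total annotated read count; ties go to the shortest intron, then
#' to the smallest start coordinate, so the assignment is deterministic.
#'
#' @param classified Output of [classify_junctions()].
#' @param annotation A `genome_annotation` object.
#' @param intron_reads Tibble `intron_id`, `total_reads` from
#'   [counts_by_intron()]; candidates absent from it count as zero reads.
#' @return `classified` with `assigned_intron_id` filled for novel donor and
#'   novel acceptor junctions.
#' @export
assign_novel <- function(classified, annotation, intron_reads = NULL) {
  introns <- annotation$introns[!annotation$introns$minor_spliceosome, ,
                                drop = FALSE]
  if (is.null(intron_reads)) {
    intron_reads <- tibble::tibble(intron_id = integer(),
                                   total_reads = numeric())
  }
  cand_tbl <- introns |>
    dplyr::select("intron_id", "chrom", "strand", "donor_pos", "acceptor_pos",
                  "length", "start") |>
    dplyr::left_join(intron_reads, by = "intron_id") |>
    dplyr::mutate(total_reads = dplyr::coalesce(.data$total_reads, 0))

  novel <- classified |>
    dplyr::filter(.data$category %in% c("novel_donor", "novel_acceptor")) |>
    dplyr::mutate(
      shared_coord = ifelse(.data$category == "novel_donor",
                            ifelse(.data$strand == "+", .data$end, .data$start),
                            ifelse(.data$strand == "+", .data$start, .data$end)),
      .jid = dplyr::row_number()
    )
  if (nrow(novel) == 0) return(classified)

  nd <- novel |>
    dplyr::filter(.data$category == "novel_donor") |>
    dplyr::inner_join(cand_tbl,
                      by = c(chrom = "chrom", strand = "strand",
                             shared_coord = "acceptor_pos"),
                      suffix = c("", ".intron"),
                      relationship = "many-to-many")
  na_ <- novel |>
    dplyr::filter(.data$category == "novel_acceptor") |>
    dplyr::inner_join(cand_tbl,
                      by = c(chrom = "chrom", strand = "strand",
                             shared_coord = "donor_pos"),
                      suffix = c("", ".intron"),
                      relationship = "many-to-many")
  best <- dplyr::bind_rows(nd, na_) |>
    dplyr::group_by(.data$.jid) |>
    dplyr::arrange(dplyr::desc(.data$total_reads), .data$length,
                   .data$start.intron, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select(".jid", best_intron = "intron_id")

  novel <- dplyr::left_join(novel, best, by = ".jid")
  key_novel <- paste(novel$chrom, novel$start, novel$end, novel$orig_strand,
                     novel$category)
  key_all <- paste(classified$chrom, classified$start, classified$end,
                   classified$orig_strand, classified$category)
  idx <- match(key_all, key_novel)
  fill <- !is.na(idx)
  classified$assigned_intron_id[fill] <- novel$best_intron[idx[fill]]
  classified
}

#' Classify and assign in one step
#'
#' Convenience wrapper: [classify_junctions()], annotated-read support via
#' [counts_by_intron()], then [assign_novel()].
#'
#' @inheritParams classify_junctions
#' @param counts Long junction tibble with per-sample counts (defaults to
#'   `junctions` itself when it carries a `count` column).
#' @return A classified-and-assigned junction tibble.
#' @export
classify_and_assign <- function(junctions, annotation, counts = junctions) {
  cls <- classify_junctions(junctions, annotation)
  support <- counts_by_intron(cls, counts)
  assign_novel(cls, annotation, support)
}

#' Cross-annotation contamination rate
#'
#' Classifies the same junction set under an older and a newer annotation.
#' Junctions called novel (novel donor or novel acceptor) under the old
#' annotation but annotated under the new one are counted as `j`; junctions
#' novel under both as `y`. The contamination rate is `100 * j / y`.
#'
#' @param junctions Junction table (distinct intervals are used).
#' @param annotation_old,annotation_new `genome_annotation` objects on the
#'   same assembly.
#' @return A tibble with `j`, `y`, `ct_percent` (NA with a warning when
#'   `y == 0`) and a `flag` column noting degenerate cases.
#' @export
contamination_rate <- function(junctions, annotation_old, annotation_new) {
  old <- classify_junctions(junctions, annotation_old)
  new <- classify_junctions(junctions, annotation_new)
  key <- function(x) paste(x$chrom, x$start, x$end, x$orig_strand)
  novel_cat <- c("novel_donor", "novel_acceptor")
  old_novel <- key(old)[old$category %in% novel_cat]
  new_annot <- key(new)[new$category == "annotated"]
  new_novel <- key(new)[new$category %in% novel_cat]
  j <- length(intersect(old_novel, new_annot))
  y <- length(intersect(old_novel, new_novel))
  ct <- if (y == 0) NA_real_ else 100 * j / y
  flag <- if (y == 0) "undefined: no junction stayed novel" else
    if (!is.na(ct) && ct > 100) "ct_percent exceeds 100 (j > y)" else NA_character_
  if (y == 0) rlang::warn("contamination rate undefined: y = 0")
  tibble::tibble(j = j, y = y, ct_percent = ct, flag = flag)
}
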