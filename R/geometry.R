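#' Signed distance between an annotated and a novel splice site
#'
#' Distances are differences of genomic coordinates, oriented so that the
#' sign is biologically interpretable on both strands and at both site
#' kinds: a negative distance always places the novel site on the intronic
#' side of the annotated boundary and a positive distance on the exonic
#' side. For donor (5'ss) sites the distance is `annotated - novel` on the
#' plus strand and `novel - annotated` on the minus strand; for acceptor
#' (3'ss) sites the formula is mirrored. Under this convention the
#' AG-exclusion-zone suppression of novel acceptors appears as a gap at
#' small negative acceptor distances on either strand.
#'
#' @param annotated_pos,novel_pos Genomic coordinates (same chromosome).
#' @param strand `"+"` or `"-"` (vectorised).
#' @param kind `"donor"` (default) or `"acceptor"` (vectorised).
#' @return Signed integer distance(s) in bp.
#' @export
site_distance <- function(annotated_pos, novel_pos, strand, kind = "donor") {
  stopifnot(all(strand %in% c("+", "-")), all(kind %in% c("donor",
                                                          "acceptor")))
  base <- ifelse(strand == "+", annotated_pos - novel_pos,
                 novel_pos - annotated_pos)
  ifelse(kind == "acceptor", -base, base)
}

#' Distances of assigned novel junctions to their annotated sites
#'
#' Computes the signed distance ([site_distance()]) between each assigned
#' novel junction's novel boundary and the matching boundary of its linked
#' annotated intron, together with the reading-frame class
#' `mod3 = distance mod 3` (mathematical modulus, in \{0, 1, 2\}).
#'
#' @param classified Classified-and-assigned junction tibble.
#' @param annotation A `genome_annotation` object.
#' @return A tibble: junction coordinates, `intron_id`, `kind`
#'   (`"donor"`/`"acceptor"`), `distance`, `mod3`, plus the linked intron's
#'   `in_mane` and `exclusively_protein_coding` flags.
#' @export
junction_distances <- function(classified, annotation) {
  novel <- classified |>
    dplyr::filter(.data$category %in% c("novel_donor", "novel_acceptor"),
                  !is.na(.data$assigned_intron_id))
  introns <- annotation$introns
  idx <- match(novel$assigned_intron_id, introns$intron_id)
  kind <- ifelse(novel$category == "novel_donor", "donor", "acceptor")
  ann_pos <- ifelse(kind == "donor", introns$donor_pos[idx],
                    introns$acceptor_pos[idx])
  novel_pos <- ifelse(kind == "donor",
                      ifelse(novel$strand == "+", novel$start, novel$end),
                      ifelse(novel$strand == "+", novel$end, novel$start))
  d <- site_distance(ann_pos, novel_pos, novel$strand, kind)
  tibble::tibble(
    chrom = novel$chrom, start = novel$start, end = novel$end,
    strand = novel$strand, intron_id = novel$assigned_intron_id,
    kind = kind, distance = d, mod3 = d %% 3L,
    in_mane = introns$in_mane[idx],
    exclusively_protein_coding = introns$exclusively_protein_coding[idx]
  )
}

#' Distance histogram around annotated splice sites
#'
#' Bins signed novel-to-annotated distances within `±window` bp, stratified
#' by site kind and by whether the linked intron is exclusively used in
#' protein-coding transcripts. Records outside the window are excluded.
#'
#' @param distances Output of [junction_distances()], optionally carrying a
#'   `weight` column (e.g. read counts); unweighted rows count 1.
#' @param window Half-width of the window in bp (default 30).
#' @return A tibble `kind`, `coding` (logical), `distance`, `n` with one row
#'   per occupied bin.
#' @export
distance_profile <- function(distances, window = 30L) {
  d <- tibble::as_tibble(distances)
  if (!"weight" %in% names(d)) d$weight <- 1L
  d |>
    dplyr::filter(abs(.data$distance) <= window) |>
    dplyr::group_by(.data$kind,
                    coding = .data$exclusively_protein_coding,
                    .data$distance) |>
    dplyr::summarise(n = sum(.data$weight), .groups = "drop") |>
    dplyr::arrange(.data$kind, .data$coding, .data$distance)
}

#' Reading-frame (modulo-3) analysis of novel splice sites
#'
#' Restricts to novel junctions within `max_dist` bp (strictly less than) of
#' their annotated site and to introns passing the restriction flags
#' (MANE Select membership and/or exclusive protein-coding use), then
#' summarises the distance-modulo-3 classes. Distances not divisible by 3
#' imply a frameshift in the downstream reading frame.
#'
#' @param distances Output of [junction_distances()].
#' @param max_dist Maximum absolute distance, exclusive (default 100 bp).
#' @param restrict Character vector among `"mane"` and
#'   `"exclusively_protein_coding"`; both by default, applied jointly.
#' @return A one-row tibble: `n`, `frac_mod0`, `frac_mod1`, `frac_mod2`,
#'   `frameshift_fraction`. All-`NA` with a warning when nothing survives
#'   the filters.
#' @export
modulo3_analysis <- function(distances, max_dist = 100L,
                             restrict = c("mane",
                                          "exclusively_protein_coding")) {
  restrict <- match.arg(restrict, several.ok = TRUE)
  d <- tibble::as_tibble(distances) |>
    dplyr::filter(abs(.data$distance) < max_dist)
  if ("mane" %in% restrict) d <- dplyr::filter(d, .data$in_mane)
  if ("exclusively_protein_coding" %in% restrict) {
    d <- dplyr::filter(d, .data$exclusively_protein_coding)
  }
  if (nrow(d) == 0) {
    rlang::warn("no novel junctions pass the modulo-3 filters")
    return(tibble::tibble(n = 0L, frac_mod0 = NA_real_, frac_mod1 = NA_real_,
                          frac_mod2 = NA_real_,
                          frameshift_fraction = NA_real_))
  }
  fr <- vapply(0:2, function(k) mean(d$mod3 == k), numeric(1))
  tibble::tibble(n = nrow(d), frac_mod0 = fr[1], frac_mod1 = fr[2],
                 frac_mod2 = fr[3], frameshift_fraction = 1 - fr[1])
}

#' Plot a splice-site distance profile
#'
#' @param profile Output of [distance_profile()].
#' @return A ggplot: distance histograms faceted by site kind and coding
#'   status; for acceptors the negative side is the intronic
#'   (AG-exclusion-zone) side.
#' @export
plot_distance_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$distance, y = .data$n)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::facet_grid(ggplot2::vars(.data$coding),
                        ggplot2::vars(.data$kind),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "distance to annotated site (bp, transcript-oriented)",
                  y = "novel junctions") +
    ggplot2::theme_minimal()
}

#' Plot mis-splicing ratio distributions
#'
#' @param msr Output of [compute_msr()].
#' @return A ggplot comparing the donor- and acceptor-side mis-splicing
#'   ratio distributions on a log10 x scale (zeros shown at the axis floor).
#' @export
plot_msr <- function(msr) {
  long <- msr |>
    tidyr::pivot_longer(c("msr_d", "msr_a"), names_to = "measure",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  floor_val <- min(long$value[long$value > 0], 1e-6) / 2
  long$value <- pmax(long$value, floor_val)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     colour = .data$measure)) +
    ggplot2::stat_ecdf() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mis-splicing ratio", y = "ECDF",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
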