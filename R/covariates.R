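#' Read a per-base score track in bedGraph format
#'
#' @param path bedGraph file (0-based half-open intervals with a score).
#' @return Tibble `chrom`, `start`, `end` (1-based closed), `score`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr),
                 score = gr$score)
}

#' Mean track score over a splice-site proximal window
#'
#' Windows are transcript-oriented around the splice-site boundary: the
#' donor (5'ss) window spans `upstream` exonic bases and `downstream`
#' intronic bases around the exon-intron junction (default -5/+35), the
#' acceptor (3'ss) window `downstream` intronic and `upstream` exonic bases
#' around the intron-exon junction (default -35/+5). The mean is the
#' arithmetic mean over track-covered bases; bases with no track data are
#' excluded, and windows with less than `min_coverage` of their bases
#' covered return `NA`.
#'
#' @param track Per-base score tibble (`chrom`, `start`, `end`, `score`,
#'   1-based closed), e.g. from [read_bedgraph()].
#' @param chrom Chromosome.
#' @param pos Genomic coordinate of the boundary intronic base (donor_pos or
#'   acceptor_pos of the intron).
#' @param strand `"+"` or `"-"`.
#' @param kind `"donor"` or `"acceptor"`.
#' @param exonic,intronic Window extent in bp on the exonic/intronic side
#'   (defaults 5 and 35).
#' @param min_coverage Minimum covered fraction for a defined mean.
#' @return Mean score, or `NA_real_`.
#' @export
window_mean_score <- function(track, chrom, pos, strand, kind,
                              exonic = 5L, intronic = 35L,
                              min_coverage = 0.5) {
  kind <- match.arg(kind, c("donor", "acceptor"))
  stopifnot(strand %in% c("+", "-"))
  # genomic window: intronic side starts at pos and extends into the intron
  into_intron <- if (kind == "donor") strand == "+" else strand == "-"
  win <- if (into_intron) c(pos - exonic, pos + intronic - 1L)
  else c(pos - intronic + 1L, pos + exonic)
  width <- win[2] - win[1] + 1L

  t <- track[track$chrom == chrom & track$end >= win[1] &
               track$start <= win[2], , drop = FALSE]
  if (nrow(t) == 0) return(NA_real_)
  s <- pmax(t$start, win[1])
  e <- pmin(t$end, win[2])
  covered <- sum(e - s + 1L)
  if (covered / width < min_coverage) return(NA_real_)
  sum(t$score * (e - s + 1L)) / covered
}

#' Assemble the intron covariate table for mis-splicing models
#'
#' One row per intron in the supplied mis-splicing table, carrying the ten
#' covariates used to model mis-splicing rates plus the intron length:
#' gene length (bp), median gene TPM across samples, number of transcripts
#' of the gene, the intron's protein-coding-transcript fraction, the
#' maximum-entropy scores of its 5'ss and 3'ss, and the mean conservation
#' and constraint scores over the -5/+35 (5'ss) and -35/+5 (3'ss) proximal
#' windows. Rows with any undefined covariate are dropped and tallied in the
#' `n_dropped` attribute.
#'
#' @param annotation A `genome_annotation` object.
#' @param msr Output of [compute_msr()].
#' @param gene_tpm Tibble `gene_id` plus per-sample TPM columns (from
#'   [tpm()]), used for the median-TPM covariate.
#' @param genome Genome sequence.
#' @param model Splice-site model.
#' @param conservation_track,constraint_track Per-base score tibbles
#'   (see [window_mean_score()]); conservation is a phastCons-like
#'   probability of negative selection, constraint a CDTS-like human
#'   sequence-constraint score.
#' @return A tibble: `intron_id`, `msr_d`, `msr_a`, `gene_length`,
#'   `median_tpm`, `n_transcripts_gene`, `protein_coding_fraction`,
#'   `mes_5ss`, `mes_3ss`, `conservation_5ss`, `conservation_3ss`,
#'   `constraint_5ss`, `constraint_3ss`, `intron_length`.
#' @export
build_covariates <- function(annotation, msr, gene_tpm, genome, model,
                             conservation_track, constraint_track) {
  genome <- as_genome(genome)
  introns <- annotation$introns
  idx <- match(msr$intron_id, introns$intron_id)
  if (anyNA(idx)) rlang::abort("msr contains intron ids absent from annotation")
  it <- introns[idx, , drop = FALSE]

  gi <- annotation$gene_index
  gidx <- match(it$gene_id, gi$gene_id)
  med_tpm <- apply(as.matrix(gene_tpm[setdiff(names(gene_tpm), "gene_id")]),
                   1, stats::median)
  tpm_map <- stats::setNames(med_tpm, gene_tpm$gene_id)

  site_score <- function(pos, chrom, strand, kind) {
    s <- tryCatch(extract_site_sequence(genome, chrom, pos, strand, kind),
                  error = function(e) NA_character_)
    if (is.na(s)) NA_real_ else score_splice_site(s, model, kind)
  }
  n <- nrow(it)
  mes5 <- mes3 <- cons5 <- cons3 <- cdts5 <- cdts3 <- numeric(n)
  for (i in seq_len(n)) {
    mes5[i] <- site_score(it$donor_pos[i], it$chrom[i], it$strand[i], "donor")
    mes3[i] <- site_score(it$acceptor_pos[i], it$chrom[i], it$strand[i],
                          "acceptor")
    cons5[i] <- window_mean_score(conservation_track, it$chrom[i],
                                  it$donor_pos[i], it$strand[i], "donor")
    cons3[i] <- window_mean_score(conservation_track, it$chrom[i],
                                  it$acceptor_pos[i], it$strand[i], "acceptor")
    cdts5[i] <- window_mean_score(constraint_track, it$chrom[i],
                                  it$donor_pos[i], it$strand[i], "donor")
    cdts3[i] <- window_mean_score(constraint_track, it$chrom[i],
                                  it$acceptor_pos[i], it$strand[i], "acceptor")
  }

  out <- tibble::tibble(
    intron_id = msr$intron_id,
    msr_d = msr$msr_d,
    msr_a = msr$msr_a,
    gene_length = gi$gene_length[gidx],
    median_tpm = unname(tpm_map[it$gene_id]),
    n_transcripts_gene = gi$n_transcripts[gidx],
    protein_coding_fraction = it$protein_coding_fraction,
    mes_5ss = mes5, mes_3ss = mes3,
    conservation_5ss = cons5, conservation_3ss = cons3,
    constraint_5ss = cdts5, constraint_3ss = cdts3,
    intron_length = it$length
  )
  complete <- stats::complete.cases(out)
  res <- out[complete, , drop = FALSE]
  attr(res, "n_dropped") <- sum(!complete)
  res
}

#' Integer-encode categorical columns
#'
#' Maps each categorical (character or factor) column to consecutive
#' integers in sorted-level order. A crude encoding, but it reproduces the
#' treatment of categorical sample covariates as numeric predictors in the
#' reused linear-model machinery.
#'
#' @param data A data frame.
#' @param cols Columns to encode (default: all character/factor columns).
#' @return The data frame with those columns replaced by integers.
#' @export
encode_categorical <- function(data, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, function(x)
      is.character(x) || is.factor(x), logical(1))]
  }
  for (cl in cols) {
    data[[cl]] <- as.integer(factor(data[[cl]]))
  }
  data
}

#' Ordinary least squares fit with multiplicity adjustment
#'
#' Fits `response ~ covariates` by OLS and reports per-term estimates,
#' standard errors, two-sided p-values and adjusted q-values. Covariates
#' with zero variance are dropped with a warning; rank deficiency among the
#' remaining columns is an error naming the collinear terms. Covariates are
#' used untransformed by default (`scale_covariates = TRUE` z-scores them).
#'
#' @param data Data frame holding response and covariates.
#' @param response Name of the response column.
#' @param covariates Character vector of covariate column names (default:
#'   every other numeric column).
#' @param adjust `"BH"`, `"bonferroni"` or `"none"`; applied across the
#'   non-intercept coefficient p-values of this fit. Use
#'   [adjust_across_fits()] to adjust across a family of fits instead.
#' @param scale_covariates z-score covariates before fitting.
#' @return An object of class `fidelity_fit` with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
fit_linear <- function(data, response, covariates = NULL,
                       adjust = c("BH", "bonferroni", "none"),
                       scale_covariates = FALSE) {
  adjust <- match.arg(adjust)
  data <- tibble::as_tibble(data)
  if (is.null(covariates)) {
    covariates <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          c(response, "intron_id"))
  }
  keep <- vapply(covariates, function(cl) {
    v <- stats::var(data[[cl]], na.rm = TRUE)
    is.finite(v) && v > 0
  }, logical(1))
  if (any(!keep)) {
    rlang::warn(paste0("dropping zero-variance covariate(s): ",
                       paste(covariates[!keep], collapse = ", ")))
    covariates <- covariates[keep]
  }
  if (nrow(data) <= length(covariates) + 1) {
    rlang::abort("need more observations than model terms")
  }
  if (scale_covariates) {
    data[covariates] <- lapply(data[covariates], function(x)
      as.numeric(scale(x)))
  }
  fit <- stats::lm(stats::reformulate(covariates, response), data = data)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased) > 0) {
    rlang::abort(paste0("rank-deficient design; collinear term(s): ",
                        paste(aliased, collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)
  p <- sm[, "Pr(>|t|)"]
  q <- rep(NA_real_, length(p))
  non_int <- terms != "(Intercept)"
  q[non_int] <- if (adjust == "none") p[non_int] else
    stats::p.adjust(p[non_int], method = ifelse(adjust == "BH", "BH",
                                                "bonferroni"))
  structure(list(
    response = response,
    coefficients = tibble::tibble(
      term = terms,
      estimate = unname(sm[, "Estimate"]),
      std_error = unname(sm[, "Std. Error"]),
      statistic = unname(sm[, "t value"]),
      p_value = unname(p),
      q_value = unname(q)
    ),
    adjust = adjust,
    n = stats::nobs(fit),
    r_squared = summary(fit)$r.squared,
    adj_r_squared = summary(fit)$adj.r.squared,
    sigma = summary(fit)$sigma,
    lm = fit
  ), class = "fidelity_fit")
}

#' @export
print.fidelity_fit <- function(x, ...) {
  cat("<fidelity_fit> response:", x$response, " n =", x$n,
      " R^2 =", signif(x$r_squared, 3), "\n")
  print(x$coefficients)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy fidelity_fit
#' @export
tidy.fidelity_fit <- function(x, ...) x$coefficients

#' @method glance fidelity_fit
#' @export
glance.fidelity_fit <- function(x, ...) {
  tibble::tibble(response = x$response, n = x$n, r_squared = x$r_squared,
                 adj_r_squared = x$adj_r_squared, sigma = x$sigma,
                 adjust = x$adjust)
}

#' Re-adjust p-values across a family of fits
#'
#' Pools the non-intercept coefficient p-values of several `fidelity_fit`
#' objects (e.g. the donor- and acceptor-side models across tissues) and
#' recomputes q-values across the whole family.
#'
#' @param fits A list of `fidelity_fit` objects.
#' @param method `"BH"` or `"bonferroni"`.
#' @return A tibble: `response`, `term`, `estimate`, `std_error`, `p_value`,
#'   `q_value`.
#' @export
adjust_across_fits <- function(fits, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  tab <- purrr::map_dfr(fits, function(f)
    dplyr::mutate(tidy(f), response = f$response))
  tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
  tab$q_value <- stats::p.adjust(tab$p_value, method = method)
  tab[, c("response", "term", "estimate", "std_error", "p_value", "q_value")]
}

#' Fit donor- and acceptor-side mis-splicing models
#'
#' Fits one OLS model per response (`msr_d`, `msr_a`) on a covariate table
#' from [build_covariates()] and adjusts q-values across the two fits
#' jointly.
#'
#' @param covariates Output of [build_covariates()].
#' @param adjust Adjustment method across the combined coefficient family.
#' @return A list with elements `fits` (named list of `fidelity_fit`) and
#'   `coefficients` (family-adjusted tidy table).
#' @export
fit_msr_models <- function(covariates, adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  covs <- setdiff(names(covariates), c("intron_id", "msr_d", "msr_a"))
  fits <- list(
    msr_d = fit_linear(dplyr::filter(covariates, !is.na(.data$msr_d)),
                       "msr_d", covs, adjust = "none"),
    msr_a = fit_linear(dplyr::filter(covariates, !is.na(.data$msr_a)),
                       "msr_a", covs, adjust = "none")
  )
  list(fits = fits, coefficients = adjust_across_fits(fits, adjust))
}
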