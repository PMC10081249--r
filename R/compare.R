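#' Greedy caliper matching of two groups by a scalar value
#'
#' Pairs members of group A with members of group B whose (optionally
#' log10-transformed) values differ by at most `max_diff`. The algorithm is
#' greedy nearest-neighbour without replacement: group A is traversed in
#' descending value order and each member takes the closest still-unused B
#' within the caliper; ties break on smaller B value, then B id. The result
#' is deterministic given the input.
#'
#' @param a,b Named numeric vectors (names are ids), or tibbles with columns
#'   `id` and `value`.
#' @param max_diff Caliper: maximum allowed |scaled difference| in a pair.
#' @param scale `"raw"` or `"log10"` (log10 requires positive values).
#' @return A list of class `match_result`: `pairs` (tibble `id_a`, `id_b`,
#'   `value_a`, `value_b`), `unmatched_a`, `unmatched_b`, `max_diff`,
#'   `scale`.
#' @export
match_by_value <- function(a, b, max_diff, scale = c("raw", "log10")) {
  scale <- match.arg(scale)
  a <- as_named_values(a); b <- as_named_values(b)
  if (any(!is.finite(a)) || any(!is.finite(b)) ||
      (scale == "log10" && (any(a <= 0) || any(b <= 0)))) {
    rlang::abort("matching values must be finite (and positive for log10)")
  }
  sa <- if (scale == "log10") log10(a) else a
  sb <- if (scale == "log10") log10(b) else b
  ord_a <- order(-sa, names(a))
  used_b <- rep(FALSE, length(b))
  pair_a <- character(0); pair_b <- character(0)
  ord_b_tiebreak <- order(sb, names(b))
  for (i in ord_a) {
    d <- abs(sb - sa[i])
    d[used_b] <- Inf
    if (all(is.infinite(d)) || min(d) > max_diff) next
    cand <- which(d == min(d))
    if (length(cand) > 1) cand <- cand[order(match(cand, ord_b_tiebreak))][1]
    used_b[cand] <- TRUE
    pair_a <- c(pair_a, names(a)[i])
    pair_b <- c(pair_b, names(b)[cand])
  }
  structure(list(
    pairs = tibble::tibble(id_a = pair_a, id_b = pair_b,
                           value_a = unname(a[pair_a]),
                           value_b = unname(b[pair_b])),
    unmatched_a = setdiff(names(a), pair_a),
    unmatched_b = setdiff(names(b), pair_b),
    max_diff = max_diff, scale = scale
  ), class = "match_result")
}

as_named_values <- function(x) {
  if (is.data.frame(x)) {
    stats::setNames(x$value, as.character(x$id))
  } else {
    if (is.null(names(x))) rlang::abort("values must be named by id")
    x
  }
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", nrow(x$pairs), " pairs (caliper ", x$max_diff,
      " on ", x$scale, " scale); unmatched A: ", length(x$unmatched_a),
      ", B: ", length(x$unmatched_b), "\n", sep = "")
  invisible(x)
}

# Z statistic of the Wilcoxon signed-rank test (zeros dropped, tie-corrected
# variance, continuity correction toward the mean)
signed_rank_z <- function(x, y, correct = TRUE) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(z = NA_real_, n = 0L, v = NA_real_))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- if (correct) sign(v - mu) * 0.5 else 0
  z <- (v - mu - cc) / sqrt(sigma2)
  list(z = z, n = n, v = v)
}

# Z statistic of the rank-sum (Mann-Whitney) test with tie correction
rank_sum_z <- function(x, y, correct = TRUE) {
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  cc <- if (correct) sign(w - mu) * 0.5 else 0
  z <- (w - mu - cc) / sqrt(sigma2)
  list(z = z, n = n, w = w)
}

#' Paired Wilcoxon signed-rank test with continuity correction
#'
#' Zero differences are dropped per the signed-rank convention (this
#' materially affects n on mis-splicing tables, which contain many exact
#' zeros). The exact null distribution is used for 25 or fewer non-zero
#' pairs without ties; otherwise the normal approximation with continuity
#' correction.
#'
#' @param x,y Numeric vectors of equal length (paired observations).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return A one-row tibble: `statistic` (V), `p_value`, `effect_size_r`,
#'   `superiority`, `alternative`, `n` (non-zero pairs), `n_input`.
#'   All-zero differences give an `NA` p-value with a warning.
#' @export
paired_wilcoxon <- function(x, y,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  d <- x - y
  n_nonzero <- sum(d != 0)
  if (n_nonzero == 0) {
    rlang::warn("all paired differences are zero; test undefined")
    return(tibble::tibble(statistic = 0, p_value = NA_real_,
                          effect_size_r = 0, superiority = 0.5,
                          alternative = alternative, n = 0L,
                          n_input = length(x)))
  }
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, paired = TRUE, alternative = alternative,
    correct = TRUE, exact = n_nonzero <= 25
  ))
  es <- superiority_effect_size(x, y, paired = TRUE)
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 effect_size_r = es$effect_size_r,
                 superiority = es$superiority,
                 alternative = alternative, n = n_nonzero,
                 n_input = length(x))
}

#' Unpaired (Mann-Whitney) Wilcoxon rank-sum test
#'
#' @inheritParams paired_wilcoxon
#' @return A one-row tibble like [paired_wilcoxon()]'s, with `statistic` the
#'   rank-sum W.
#' @export
unpaired_wilcoxon <- function(x, y,
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, paired = FALSE, alternative = alternative, correct = TRUE,
    exact = length(x) < 50 && length(y) < 50
  ))
  es <- superiority_effect_size(x, y, paired = FALSE)
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 effect_size_r = es$effect_size_r,
                 superiority = es$superiority,
                 alternative = alternative,
                 n = length(x) + length(y), n_input = length(x) + length(y))
}

#' Rank-based effect sizes for a case/control comparison
#'
#' The effect size `r = |Z| / sqrt(N)` uses the Z statistic of the
#' signed-rank (paired) or rank-sum (unpaired) test with tie correction and
#' continuity correction; N is the number of pairs for paired comparisons
#' and the total number of observations otherwise. The superiority
#' probability is the probability that a case value exceeds a control value
#' (ties counted half): across pairs for paired input, across all
#' case-control combinations otherwise.
#'
#' @param case,control Numeric vectors (equal length when `paired`).
#' @param paired Logical.
#' @return A one-row tibble: `effect_size_r`, `superiority`, `z`, `n`.
#' @export
superiority_effect_size <- function(case, control, paired = FALSE) {
  if (paired) {
    stopifnot(length(case) == length(control))
    st <- signed_rank_z(case, control)
    if (st$n == 0) {
      return(tibble::tibble(effect_size_r = 0, superiority = 0.5,
                            z = NA_real_, n = 0L))
    }
    sup <- mean(case > control) + 0.5 * mean(case == control)
    tibble::tibble(effect_size_r = abs(st$z) / sqrt(st$n), superiority = sup,
                   z = st$z, n = st$n)
  } else {
    st <- rank_sum_z(case, control)
    # U / (n1 n2), ties counted half: the common-language effect size
    u <- st$w
    sup <- u / (length(case) * length(control))
    tibble::tibble(effect_size_r = abs(st$z) / sqrt(st$n), superiority = sup,
                   z = st$z, n = st$n)
  }
}

#' Compare mis-splicing between two matched groups of samples
#'
#' Intersects the annotated introns present in the case and control
#' mis-splicing tables (only introns common to both are compared), then runs
#' a Wilcoxon test per response (donor- and acceptor-side ratios) with the
#' chosen adjustment across the comparisons submitted together.
#'
#' @param case_msr,control_msr Outputs of [compute_msr()] for the two
#'   groups.
#' @param responses Response columns to compare (default `msr_d`, `msr_a`).
#' @param alternative Test alternative; `"greater"` tests for higher
#'   mis-splicing in cases.
#' @param paired Paired (per-intron) test, the default, or unpaired.
#' @param adjust `"bonferroni"` (knockdown-style batches), `"BH"`, or
#'   `"none"`.
#' @return A tibble with one row per response: `response`, `statistic`,
#'   `p_value`, `p_adj`, `effect_size_r`, `superiority`, `n_introns`, `n`.
#' @export
compare_msr_groups <- function(case_msr, control_msr,
                               responses = c("msr_d", "msr_a"),
                               alternative = c("greater", "two.sided",
                                               "less"),
                               paired = TRUE,
                               adjust = c("bonferroni", "BH", "none")) {
  alternative <- match.arg(alternative)
  adjust <- match.arg(adjust)
  common <- intersect(case_msr$intron_id, control_msr$intron_id)
  if (length(common) == 0) rlang::abort("no introns common to both groups")
  ca <- case_msr[match(common, case_msr$intron_id), , drop = FALSE]
  co <- control_msr[match(common, control_msr$intron_id), , drop = FALSE]
  res <- purrr::map_dfr(responses, function(resp) {
    x <- ca[[resp]]; y <- co[[resp]]
    ok <- !is.na(x) & !is.na(y)
    out <- if (paired) paired_wilcoxon(x[ok], y[ok], alternative) else
      unpaired_wilcoxon(x[ok], y[ok], alternative)
    dplyr::mutate(out, response = resp, n_introns = sum(ok),
                  .before = 1)
  })
  res$p_adj <- if (adjust == "none") res$p_value else
    stats::p.adjust(res$p_value, method = ifelse(adjust == "BH", "BH",
                                                 "bonferroni"))
  res
}

#' Stratify samples into age bins with RIN-matched downsampling
#'
#' Bins samples into the closed age intervals 20-39, 40-59 and 60-79 years
#' within each tissue, keeps only tissues with at least `min_per_bin`
#' samples in every bin (and `min_total` overall), and downsamples the two
#' older bins by greedy RIN matching against the youngest bin
#' ([match_by_value()] on the raw scale with caliper `rin_match`).
#'
#' @param samples Sample metadata tibble with `sample_id`, `tissue`, `age`,
#'   `rin`.
#' @param bins A list of `c(lower, upper)` closed age intervals.
#' @param min_per_bin,min_total Minimum samples per bin / per tissue.
#' @param rin_match RIN caliper for matching (default 0.05).
#' @return A list: `samples` (retained samples with an `age_bin` column),
#'   `excluded_tissues`, `matches` (per tissue and older bin, the
#'   `match_result`).
#' @export
age_stratify <- function(samples,
                         bins = list(c(20, 39), c(40, 59), c(60, 79)),
                         min_per_bin = 25L, min_total = 75L,
                         rin_match = 0.05) {
  samples <- tibble::as_tibble(samples)
  bin_label <- function(age) {
    lab <- rep(NA_character_, length(age))
    for (b in bins) {
      lab[age >= b[1] & age <= b[2]] <- paste0(b[1], "-", b[2])
    }
    lab
  }
  samples$age_bin <- bin_label(samples$age)
  samples <- samples[!is.na(samples$age_bin), , drop = FALSE]
  labels <- vapply(bins, function(b) paste0(b[1], "-", b[2]), character(1))

  kept <- list(); matches <- list(); excluded <- character(0)
  for (tis in unique(samples$tissue)) {
    st <- samples[samples$tissue == tis, , drop = FALSE]
    sizes <- vapply(labels, function(l) sum(st$age_bin == l), integer(1))
    if (any(sizes < min_per_bin) || nrow(st) < min_total) {
      excluded <- c(excluded, tis)
      next
    }
    young <- st[st$age_bin == labels[1], , drop = FALSE]
    keep_tissue <- young
    for (l in labels[-1]) {
      older <- st[st$age_bin == l, , drop = FALSE]
      m <- match_by_value(
        stats::setNames(young$rin, young$sample_id),
        stats::setNames(older$rin, older$sample_id),
        max_diff = rin_match, scale = "raw"
      )
      matches[[paste(tis, l)]] <- m
      keep_tissue <- dplyr::bind_rows(
        keep_tissue, older[older$sample_id %in% m$pairs$id_b, , drop = FALSE])
    }
    kept[[tis]] <- keep_tissue
  }
  list(samples = dplyr::bind_rows(kept), excluded_tissues = excluded,
       matches = matches)
}
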