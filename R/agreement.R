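#' Cohen's kappa between two voxel masks
#'
#' Chance-corrected voxelwise agreement between two raters' binary
#' segmentations over the full bounding grid (background concordance
#' counts): observed agreement `p0` is the fraction of voxels with the
#' same label, chance agreement `pe` comes from the two raters' marginal
#' label frequencies, and `kappa = (p0 - pe) / (1 - pe)`. When both
#' raters assign a single identical label everywhere, `pe = 1` and kappa
#' is undefined (`NA`).
#'
#' @param mask_a,mask_b [mask_stack()] objects (or binary arrays) of
#'   identical shape.
#' @return An object of class `agreement_report` with `p0`, `pe`,
#'   `kappa`, `n_voxels` (and `dice` when computed via
#'   [segmentation_agreement()]).
#' @export
cohens_kappa <- function(mask_a, mask_b) {
  a <- as_mask_array(mask_a, "mask_a")
  b <- as_mask_array(mask_b, "mask_b")
  if (!identical(dim(a), dim(b))) abort("Mask shapes differ.")
  n <- length(a)
  n11 <- sum(a == 1L & b == 1L)
  n00 <- sum(a == 0L & b == 0L)
  p0 <- (n11 + n00) / n
  pa1 <- sum(a) / n
  pb1 <- sum(b) / n
  pe <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  kappa <- if (pe >= 1) NA_real_ else (p0 - pe) / (1 - pe)
  if (is.na(kappa)) {
    inform("Both raters constant and identical: kappa is undefined (pe = 1).")
  }
  structure(
    list(p0 = p0, pe = pe, kappa = kappa, dice = NULL, n_voxels = n),
    class = "agreement_report"
  )
}

#' Dice similarity coefficient
#'
#' Overlap between two foreground voxel sets: `2 |A n B| / (|A| + |B|)`.
#' Undefined (`NA`) when both masks are empty.
#'
#' @inheritParams cohens_kappa
#' @return A single number in `[0, 1]`, or `NA` if both masks are empty.
#' @examples
#' dice_coefficient(array(c(1, 1, 0), c(1, 1, 3)), array(c(0, 1, 1), c(1, 1, 3)))
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  a <- as_mask_array(mask_a, "mask_a")
  b <- as_mask_array(mask_b, "mask_b")
  if (!identical(dim(a), dim(b))) abort("Mask shapes differ.")
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    inform("Both masks empty: Dice is undefined.")
    return(NA_real_)
  }
  2 * sum(a == 1L & b == 1L) / denom
}

#' Consensus segmentation of two raters
#'
#' The voxelwise union of two manual annotations, used as the reference
#' standard against which an automated segmentation is scored.
#'
#' @inheritParams cohens_kappa
#' @return A [mask_stack()].
#' @export
consensus_union <- function(mask_a, mask_b) {
  a <- as_mask_array(mask_a, "mask_a")
  b <- as_mask_array(mask_b, "mask_b")
  if (!identical(dim(a), dim(b))) abort("Mask shapes differ.")
  mask_stack((a | b) * 1L)
}

#' Full agreement report between two segmentations
#'
#' Cohen's kappa and the Dice coefficient in one report.
#'
#' @inheritParams cohens_kappa
#' @return An `agreement_report` with `p0`, `pe`, `kappa`, `dice`,
#'   `n_voxels`.
#' @export
segmentation_agreement <- function(mask_a, mask_b) {
  rep <- cohens_kappa(mask_a, mask_b)
  rep$dice <- dice_coefficient(mask_a, mask_b)
  rep
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> n = %d voxels: p0 = %.4f, pe = %.4f, kappa = %s%s\n",
    x$n_voxels, x$p0, x$pe,
    if (is.na(x$kappa)) "undefined" else sprintf("%.4f", x$kappa),
    if (is.null(x$dice)) "" else sprintf(", Dice = %.4f", x$dice)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.agreement_report <- function(x, ...) {
  tibble(
    p0 = x$p0, pe = x$pe, kappa = x$kappa,
    dice = if (is.null(x$dice)) NA_real_ else x$dice,
    n_voxels = x$n_voxels
  )
}

#' Paired pre/post cohort summary
#'
#' Per-sample relative volume changes plus the cohort statistics used to
#' summarise a pre/post surgical series: mean relative change, sample
#' standard deviation (n - 1 denominator), a two-sided Student-t
#' confidence interval `mean +/- t_{1-alpha/2, n-1} * sd / sqrt(n)`, and
#' group means/SDs of the raw pre and post volumes.
#'
#' @param data Data frame with one row per sample.
#' @param pre,post Column names (tidy-eval) holding preoperative and
#'   postoperative volumes. Defaults `v_pre`, `v_post`.
#' @param alpha Two-sided significance level; default 0.05 (a 95% CI).
#' @return An object of class `cohort_summary`; see [tidy.cohort_summary()]
#'   for the per-sample table and [glance.cohort_summary()] for the
#'   one-row cohort statistics.
#' @examples
#' cohort <- tibble::tibble(
#'   v_pre = c(19734.1, 18990.2, 15959.7, 20756.2, 10525.6, 10860.4),
#'   v_post = c(19521.9, 18087.4, 14552.6, 18313.2, 8083.3, 8197.4)
#' )
#' glance(cohort_summary(cohort))
#' @export
cohort_summary <- function(data, pre = "v_pre", post = "v_post",
                           alpha = 0.05) {
  stopifnot(is.data.frame(data))
  pre_q <- rlang::enquo(pre)
  post_q <- rlang::enquo(post)
  v_pre <- pull_column(data, pre_q, "v_pre")
  v_post <- pull_column(data, post_q, "v_post")
  n <- length(v_pre)
  if (n < 2) abort("At least two pre/post pairs are required for a CI.")
  if (length(v_post) != n) abort("`pre` and `post` must have equal length.")
  if (any(v_pre <= 0)) abort("All preoperative volumes must be positive.")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).")
  }
  samples <- relative_change(v_pre, v_post)
  if (!is.null(data[["sample_id"]])) {
    samples <- dplyr::bind_cols(
      tibble(sample_id = data[["sample_id"]]), samples
    )
  }
  d <- samples$delta_rel
  mean_rel <- mean(d)
  sd_rel <- sd(d)
  df <- n - 1L
  t_crit <- qt(1 - alpha / 2, df)
  hw <- t_crit * sd_rel / sqrt(n)
  structure(
    list(
      samples = samples,
      n = n, df = df, alpha = alpha, t_crit = t_crit,
      mean_rel = mean_rel, sd_rel = sd_rel,
      ci95 = c(lower = mean_rel - hw, upper = mean_rel + hw),
      mean_pre = mean(v_pre), sd_pre = sd(v_pre),
      mean_post = mean(v_post), sd_post = sd(v_post)
    ),
    class = "cohort_summary"
  )
}

pull_column <- function(data, q, default) {
  expr <- rlang::quo_get_expr(q)
  if (is.character(expr)) {
    return(data[[expr]])
  }
  v <- rlang::eval_tidy(q, data)
  if (is.character(v) && length(v) == 1) {
    return(data[[v]])
  }
  v
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "<cohort_summary> n = %d paired samples (df = %d)\n", x$n, x$df
  ))
  cat(sprintf(
    "  relative change: mean %.1f%%, SD %.1f pp, %d%% CI (%.1f%%, %.1f%%)\n",
    round_half_up(100 * x$mean_rel, 1), round_half_up(100 * x$sd_rel, 1),
    round((1 - x$alpha) * 100),
    round_half_up(100 * x$ci95[["lower"]], 1),
    round_half_up(100 * x$ci95[["upper"]], 1)
  ))
  cat(sprintf(
    "  volumes: pre %.1f (SD %.1f) -> post %.1f (SD %.1f)\n",
    x$mean_pre, x$sd_pre, x$mean_post, x$sd_post
  ))
  invisible(x)
}

#' Per-sample relative changes of a cohort
#'
#' @param x A [cohort_summary()] object.
#' @param ... Unused.
#' @return A tibble with one row per sample: `v_pre`, `v_post`,
#'   `delta_rel`, `pct` (and `sample_id` when present in the input).
#' @exportS3Method generics::tidy
tidy.cohort_summary <- function(x, ...) {
  x$samples
}

#' One-row cohort statistics
#'
#' @param x A [cohort_summary()] object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `df`, `mean_rel`, `sd_rel`, `t_crit`,
#'   `ci_lower`, `ci_upper` (fractions), and the group volume means/SDs.
#' @exportS3Method generics::glance
glance.cohort_summary <- function(x, ...) {
  tibble(
    n = x$n, df = x$df,
    mean_rel = x$mean_rel, sd_rel = x$sd_rel,
    t_crit = x$t_crit,
    ci_lower = x$ci95[["lower"]], ci_upper = x$ci95[["upper"]],
    mean_pre = x$mean_pre, sd_pre = x$sd_pre,
    mean_post = x$mean_post, sd_post = x$sd_post
  )
}
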