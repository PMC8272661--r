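check_mask_pair <- function(v_gt, v_seg) {
  if (length(v_gt) != length(v_seg) ||
      (!is.null(dim(v_gt)) && !is.null(dim(v_seg)) &&
       !identical(dim(v_gt), dim(v_seg))))
    stop("ground-truth and predicted masks must have identical shapes")
  if (any(v_gt != 0 & v_gt != 1) || any(v_seg != 0 & v_seg != 1))
    stop("masks must be strictly binary")
}

#' Dice similarity coefficient
#'
#' Volumetric overlap ratio `2*|V_gt ∩ V_seg| / (|V_gt| + |V_seg|)` between a
#' ground-truth and a predicted binary mask. When both masks are empty there
#' is nothing to miss and nothing spurious, so 1 is returned by convention
#' (with a warning).
#'
#' @param v_gt Binary ground-truth mask (any shape).
#' @param v_seg Binary predicted mask, congruent with `v_gt`.
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(v_gt, v_seg) {
  check_mask_pair(v_gt, v_seg)
  denom <- sum(v_gt) + sum(v_seg)
  if (denom == 0) {
    warning("both masks empty; DSC = 1 by convention")
    return(1)
  }
  2 * sum(v_gt * v_seg) / denom
}

#' Segmentation precision
#'
#' Proportion of predicted voxels that are truly positive:
#' `|V_gt ∩ V_seg| / |V_seg|`. An empty prediction scores 1 if the ground
#' truth is also empty, otherwise 0 (warning in both cases).
#'
#' @inheritParams dsc
#' @return Scalar in `[0, 1]`.
#' @export
precision <- function(v_gt, v_seg) {
  check_mask_pair(v_gt, v_seg)
  if (sum(v_seg) == 0) {
    warning("empty prediction; precision set by convention")
    return(if (sum(v_gt) == 0) 1 else 0)
  }
  sum(v_gt * v_seg) / sum(v_seg)
}

#' Segmentation recall
#'
#' Proportion of ground-truth positives that are correctly identified:
#' `|V_gt ∩ V_seg| / |V_gt|`. An empty ground truth scores 1 if the
#' prediction is also empty, otherwise 0 (warning in both cases).
#'
#' @inheritParams dsc
#' @return Scalar in `[0, 1]`.
#' @export
recall <- function(v_gt, v_seg) {
  check_mask_pair(v_gt, v_seg)
  if (sum(v_gt) == 0) {
    warning("empty ground truth; recall set by convention")
    return(if (sum(v_seg) == 0) 1 else 0)
  }
  sum(v_gt * v_seg) / sum(v_gt)
}

#' F-measure
#'
#' Harmonic mean of precision and recall,
#' `2 * P * R / (P + R)`; 0 when both are 0. For strictly binary masks this
#' is algebraically identical to the Dice similarity coefficient.
#'
#' @inheritParams dsc
#' @return Scalar in `[0, 1]`.
#' @export
f_measure <- function(v_gt, v_seg) {
  p <- suppressWarnings(precision(v_gt, v_seg))
  r <- suppressWarnings(recall(v_gt, v_seg))
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Per-case metrics and cohort summary
#'
#' Computes DSC, precision, recall and F-measure for each (ground truth,
#' prediction) pair and aggregates them: mean, standard deviation, min and
#' max of DSC, plus means of the other metrics — the reporting convention
#' used for cohort evaluations.
#'
#' @param gt_masks Named list of binary ground-truth masks (names are case
#'   ids), or unnamed (ids are generated).
#' @param seg_masks List of predicted masks, congruent case-by-case.
#' @param sd_type `"sample"` (default, n-1 denominator) or `"population"`.
#' @return A `cohort_report`: list with `per_case` (tibble: case_id, dsc,
#'   precision, recall, f_measure) and `summary` (tibble with dsc_mean,
#'   dsc_sd, dsc_min, dsc_max and the other metric means).
#' @export
cohort_summary <- function(gt_masks, seg_masks,
                           sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(gt_masks) == 0) stop("empty case list")
  if (length(gt_masks) != length(seg_masks))
    stop("gt and prediction lists differ in length")
  ids <- names(gt_masks)
  if (is.null(ids)) ids <- sprintf("case_%03d", seq_along(gt_masks))
  per <- lapply(seq_along(gt_masks), function(i) {
    gt <- gt_masks[[i]]; sg <- seg_masks[[i]]
    tibble::tibble(case_id = ids[i],
                   dsc = dsc(gt, sg),
                   precision = suppressWarnings(precision(gt, sg)),
                   recall = suppressWarnings(recall(gt, sg)),
                   f_measure = f_measure(gt, sg))
  })
  per <- do.call(rbind, per)
  n <- nrow(per)
  sdv <- if (n == 1) 0 else {
    s <- stats::sd(per$dsc)
    if (sd_type == "population") s * sqrt((n - 1) / n) else s
  }
  summary <- tibble::tibble(
    n_cases = n,
    dsc_mean = mean(per$dsc), dsc_sd = sdv,
    dsc_min = min(per$dsc), dsc_max = max(per$dsc),
    precision_mean = mean(per$precision),
    recall_mean = mean(per$recall),
    f_measure_mean = mean(per$f_measure))
  structure(list(per_case = per, summary = summary, sd_type = sd_type),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cohort_report> %d cases: DSC %.4f +/- %.4f (min %.4f, max %.4f)\n",
              s$n_cases, s$dsc_mean, s$dsc_sd, s$dsc_min, s$dsc_max))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cohort report
#'
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @return The per-case tibble (`tidy`) or the one-row summary tibble
#'   (`glance`).
#' @exportS3Method generics::tidy
tidy.cohort_report <- function(x, ...) x$per_case

#' @rdname tidy.cohort_report
#' @exportS3Method generics::glance
glance.cohort_report <- function(x, ...) x$summary

#' Write a cohort report to disk
#'
#' Serializes the per-case table as CSV and the summary as JSON.
#'
#' @param report A `cohort_report`.
#' @param csv_path,json_path Output file paths (either may be `NULL` to
#'   skip).
#' @return `report`, invisibly.
#' @export
write_cohort_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$per_case, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.list(report$summary), json_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Plot per-case DSC of a cohort report
#'
#' @param object A `cohort_report`.
#' @param ... Unused.
#' @return A ggplot object: per-case DSC with the cohort mean.
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_report <- function(object, ...) {
  df <- object$per_case
  ggplot2::ggplot(df, ggplot2::aes(x = .data$case_id, y = .data$dsc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$summary$dsc_mean,
                        linetype = "dashed") +
    ggplot2::labs(x = "case", y = "DSC",
                  title = "Per-case Dice similarity coefficient") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
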