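# MTTSI-stratified evaluation and model comparison.
#
# Each test query is scored by each enzyme predictor; results are binned
# by the maximal test-to-training sequence identity (MTTSI) and precision
# = TP/(TP+FP), recall = TP/(TP+FN) are computed per enzyme per bin, then
# macro-averaged over the enzymes for which the measure is defined.

MTTSI_BREAKS <- c(0, 30, 40, 50, 60, 70, 80, 90, 100)

mttsi_bin_labels <- function() {
  paste0("[", head(MTTSI_BREAKS, -1), ",", MTTSI_BREAKS[-1],
         c(rep(")", length(MTTSI_BREAKS) - 2), "]"))
}

#' Maximal test-to-training sequence identity (MTTSI)
#'
#' The highest global-alignment identity (identities over alignment
#' length, as a percentage) between the query and any sequence of the
#' reference set — by default the predictor's positive training sequences.
#'
#' @param query Record-like list or character scalar.
#' @param training_positives Tibble of training sequences.
#' @param matrix Substitution matrix.
#' @return Percentage in \[0, 100\].
#' @export
compute_mttsi <- function(query, training_positives, matrix = NULL) {
  if (nrow(training_positives) == 0L) {
    stop("MTTSI reference set is empty", call. = FALSE)
  }
  q <- as_seq(query)
  max(batch_identity(q$seq, training_positives$sequence,
                     denominator = "alignment", matrix = matrix))
}

#' Assign MTTSI values to the eight evaluation bins
#'
#' Bins are left-closed: \[0,30), \[30,40), ..., \[90,100\].
#'
#' @param mttsi Numeric vector of percentages.
#' @return Factor of bin labels.
#' @export
mttsi_bin <- function(mttsi) {
  cut(mttsi, breaks = MTTSI_BREAKS, labels = mttsi_bin_labels(),
      right = FALSE, include.lowest = TRUE) |>
    (\(f) { f[mttsi >= 100] <- "[90,100]"; f })()
}

#' Per-enzyme, per-bin confusion counts and metrics
#'
#' @param results Tibble of prediction results with columns `enzyme_ec`,
#'   `truth` (logical), `predicted` (logical), `mttsi`.
#' @return Tibble per (enzyme_ec, bin): `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f_measure` (NA where undefined).
#' @export
bin_results <- function(results) {
  results |>
    dplyr::mutate(bin = mttsi_bin(.data$mttsi)) |>
    dplyr::group_by(.data$enzyme_ec, .data$bin, .drop = FALSE) |>
    dplyr::summarise(
      tp = sum(.data$truth & .data$predicted),
      fp = sum(!.data$truth & .data$predicted),
      fn = sum(.data$truth & !.data$predicted),
      tn = sum(!.data$truth & !.data$predicted),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      precision = ifelse(.data$tp + .data$fp > 0,
                         .data$tp / (.data$tp + .data$fp), NA_real_),
      recall = ifelse(.data$tp + .data$fn > 0,
                      .data$tp / (.data$tp + .data$fn), NA_real_),
      f_measure = ifelse(!is.na(.data$precision) & !is.na(.data$recall) &
                           (.data$precision + .data$recall) > 0,
                         2 * .data$precision * .data$recall /
                           (.data$precision + .data$recall), NA_real_)
    )
}

#' Macro-average per-enzyme bin metrics
#'
#' Unweighted mean over the enzymes for which the metric is defined in the
#' bin, with a normal-approximation 95% confidence interval. Bins where no
#' enzyme has a defined metric are absent from the output.
#'
#' @param per_enzyme_bins Tibble from [bin_results()].
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble per (bin, metric): `mean`, `n_enzymes`, `ci_lo`, `ci_hi`.
#' @export
macro_average <- function(per_enzyme_bins, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  per_enzyme_bins |>
    tidyr::pivot_longer(c("precision", "recall", "f_measure"),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$bin, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      n_enzymes = dplyr::n(),
      se = ifelse(dplyr::n() > 1, sd(.data$value) / sqrt(dplyr::n()), 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(ci_lo = .data$mean - z * .data$se,
                  ci_hi = .data$mean + z * .data$se) |>
    dplyr::select(-"se")
}

#' Paired t-test between two models' per-enzyme metrics
#'
#' Two-sided paired t-test; when every paired difference is exactly zero
#' the comparison is degenerate and `p = 1` is reported with a flag.
#'
#' @param metric_a,metric_b Paired numeric vectors (one value per enzyme).
#' @return Tibble `t`, `p`, `mean_difference`, `n`, `degenerate`.
#' @export
paired_t_test <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b))
  keep <- !is.na(metric_a) & !is.na(metric_b)
  a <- metric_a[keep]; b <- metric_b[keep]
  if (length(a) < 2L) stop("paired t-test needs at least 2 pairs",
                           call. = FALSE)
  d <- a - b
  if (sd(d) < 1e-12 && abs(mean(d)) < 1e-12) {
    return(tibble::tibble(t = 0, p = 1, mean_difference = 0, n = length(d),
                          degenerate = TRUE))
  }
  if (sd(d) < 1e-12) {
    return(tibble::tibble(t = sign(mean(d)) * Inf, p = 0,
                          mean_difference = mean(d), n = length(d),
                          degenerate = TRUE))
  }
  ht <- t.test(a, b, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), p = ht$p.value,
                 mean_difference = unname(ht$estimate), n = length(d),
                 degenerate = FALSE)
}

#' Wilcoxon rank-sum test between two groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum with tie correction (normal
#' approximation in the presence of ties, exact otherwise).
#'
#' @param group_1,group_2 Numeric vectors.
#' @return Tibble `w`, `p`.
#' @export
rank_sum_test <- function(group_1, group_2) {
  stopifnot(length(group_1) > 0, length(group_2) > 0)
  ht <- suppressWarnings(wilcox.test(group_1, group_2,
                                     alternative = "two.sided"))
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # fully tied pooled sample carries no evidence
  tibble::tibble(w = unname(ht$statistic), p = p)
}

#' Evaluate a trained superfamily model set on test queries
#'
#' Every query is scored by every enzyme predictor in the set; the truth
#' label is EC equality. MTTSI is computed against each predictor's
#' positive training sequences.
#'
#' @param model_set Model set from [train_superfamily()].
#' @param queries Tibble of test records (with `ec` truth labels).
#' @param model Which model to evaluate: `"forest"` or `"simple"`.
#' @return Tibble of prediction results: `query_id`, `enzyme_ec`, `truth`,
#'   `predicted`, `vote_fraction`, `mttsi`.
#' @export
evaluate_model_set <- function(model_set, queries,
                               model = c("forest", "simple")) {
  model <- match.arg(model)
  res <- purrr::map(model_set$enzymes, function(em) {
    spec <- em$spec
    attrs <- build_attribute_table(queries, spec, training = FALSE)
    pred <- if (model == "forest") {
      predict(em$forest, attrs)
    } else {
      predict(em$simple, attrs$blast)
    }
    mttsi <- purrr::map_dbl(seq_len(nrow(queries)), function(i)
      compute_mttsi(as.list(queries[i, ]), spec$training_positives,
                    matrix = spec$matrix))
    tibble::tibble(query_id = queries$id, enzyme_ec = em$ec,
                   truth = queries$ec == em$ec,
                   predicted = pred$predicted,
                   vote_fraction = pred$vote_fraction,
                   mttsi = mttsi)
  })
  dplyr::bind_rows(res)
}
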