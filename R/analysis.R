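# Downstream analyses: superfamily functional entropy and diversity
# classes, amino-acid propensity of rf-SDRs, and the fraction of annotated
# ASR/LBR positions recovered as rf-SDRs.

#' Functional entropy of a superfamily
#'
#' Shannon entropy (nats) of the predictor counts over distinct
#' third-digit EC prefixes: `S_func = -sum (n_abc / N) ln(n_abc / N)`,
#' where `n_abc` is the number of predictors sharing EC prefix `a.b.c` and
#' `N` the total number of predictors in the superfamily.
#'
#' @param roster_ecs Character vector of the superfamily's predictor ECs.
#' @return Non-negative entropy in nats.
#' @export
functional_entropy <- function(roster_ecs) {
  stopifnot(length(roster_ecs) >= 1L)
  p <- table(ec3_prefix(roster_ecs)) / length(roster_ecs)
  -sum(p * log(p))
}

#' Classify a superfamily's functional diversity
#'
#' Third-digit classification by functional-entropy thresholds: least
#' diverged for `S_func < 0.5`, moderately diverged for
#' `0.5 <= S_func < 1.5`, highly diverged for `S_func >= 1.5` (with
#' natural-log entropy these bands correspond to roughly one, two to four,
#' and more than four distinct third-digit EC prefixes). Fourth-digit
#' classification by distinct full EC counts: 1-5 low, 6-10 medium, >10
#' high.
#'
#' @param roster_ecs Character vector of predictor ECs.
#' @return Tibble `superfamily_n`, `s_func`, `class_3`, `n_ec4`,
#'   `class_4`.
#' @export
classify_diversity <- function(roster_ecs) {
  s <- functional_entropy(roster_ecs)
  n4 <- length(unique(roster_ecs))
  class_3 <- if (s < 0.5) "low" else if (s < 1.5) "medium" else "high"
  class_4 <- if (n4 <= 5) "low" else if (n4 <= 10) "medium" else "high"
  tibble::tibble(superfamily_n = length(roster_ecs), s_func = s,
                 class_3 = class_3, n_ec4 = n4, class_4 = class_4)
}

#' Amino-acid propensity of rf-SDR positions
#'
#' For each residue type, the fraction among rf-SDR residues (the
#' representative-sequence letters at rf-SDR positions, pooled over
#' enzymes) divided by its fraction among all pooled representative domain
#' residues. Residues absent from the rf-SDR pool get propensity 0;
#' residues absent from the background are undefined and flagged.
#'
#' @param rf_sdr_sets Named list (by enzyme) of rf-SDR tibbles from
#'   [extract_rf_sdrs()].
#' @param representatives Named list (by enzyme) of representative
#'   records.
#' @return Tibble per residue: `residue`, `sdr_fraction`,
#'   `background_fraction`, `propensity`, `defined`.
#' @export
aa_propensity <- function(rf_sdr_sets, representatives) {
  sdr_res <- purrr::imap(rf_sdr_sets, function(sdrs, ec) {
    rep_seq <- as_seq(representatives[[ec]])$seq
    if (nrow(sdrs) == 0L) return(character())
    substring(rep_seq, sdrs$position, sdrs$position)
  })
  sdr_res <- unlist(sdr_res, use.names = FALSE)
  if (length(sdr_res) == 0L) {
    stop("no rf-SDR positions available for the propensity analysis",
         call. = FALSE)
  }
  bg_res <- unlist(purrr::map(representatives, function(r)
    seq_chars(as_seq(r)$seq)), use.names = FALSE)
  sdr_frac <- as.numeric(table(factor(sdr_res, levels = AA20))) /
    length(sdr_res)
  bg_frac <- as.numeric(table(factor(bg_res, levels = AA20))) /
    length(bg_res)
  tibble::tibble(
    residue = AA20,
    sdr_fraction = sdr_frac,
    background_fraction = bg_frac,
    propensity = ifelse(bg_frac > 0, sdr_frac / bg_frac, NA_real_),
    defined = bg_frac > 0
  )
}

#' Fraction of a site category recovered as rf-SDRs
#'
#' Per enzyme, `|rf-SDRs intersect category set| / |category set|`.
#' Enzymes with an empty category set are skipped (the measure is
#' undefined for them). The superfamily value is the mean over included
#' enzymes.
#'
#' @param rf_sdr_sets Named list (by enzyme) of rf-SDR tibbles.
#' @param site_sets Named list (by enzyme) of site-set lists.
#' @param category `"asr"` or `"lbr"`.
#' @return Tibble per enzyme: `ec`, `n_sites`, `n_selected`, `fraction`;
#'   the superfamily mean is attached as attribute `superfamily_mean`.
#' @export
site_fraction_selected <- function(rf_sdr_sets, site_sets,
                                   category = c("asr", "lbr")) {
  category <- match.arg(category)
  rows <- purrr::imap(rf_sdr_sets, function(sdrs, ec) {
    cat_set <- site_sets[[ec]][[category]]
    if (length(cat_set) == 0L) {
      message("enzyme ", ec, " has no annotated ", toupper(category),
              " positions; skipped")
      return(NULL)
    }
    tibble::tibble(ec = ec, n_sites = length(cat_set),
                   n_selected = length(intersect(sdrs$position, cat_set)),
                   fraction = length(intersect(sdrs$position, cat_set)) /
                     length(cat_set))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "superfamily_mean") <- if (nrow(out)) mean(out$fraction) else
    NA_real_
  out
}

#' Box-plot statistics of selection fractions grouped by diversity class
#'
#' @param fractions Tibble with columns `class` (diversity class) and
#'   `fraction`.
#' @return Tibble per class: quartiles, 10th/90th percentiles, mean, n.
#' @export
fraction_by_class <- function(fractions) {
  fractions |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      p10 = stats::quantile(.data$fraction, 0.10),
      q1 = stats::quantile(.data$fraction, 0.25),
      median = stats::median(.data$fraction),
      q3 = stats::quantile(.data$fraction, 0.75),
      p90 = stats::quantile(.data$fraction, 0.90),
      mean = mean(.data$fraction),
      .groups = "drop"
    )
}
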