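# End-to-end workflow: train every roster enzyme's predictor pair
# (random forest + simple baseline), extract rf-SDRs, evaluate, analyze.
# These functions are the programmatic surface behind the `efprf`
# command-line wrapper (inst/exec/efprf).

#' Train predictors for every roster enzyme of a superfamily dataset
#'
#' For each eligible enzyme: the training sequences are star-aligned onto
#' the representative, the site sets (ASR/LBR from annotations, CSR from
#' conservation) and the PSSM are built, attribute vectors are computed
#' for the training positives (in training mode, so the BLAST-type
#' attribute excludes self-hits) and for the other enzymes' training
#' sequences (negatives), and both the random-forest model and the
#' single-attribute baseline tree are fitted.
#'
#' @param dataset An `efprf_dataset`.
#' @param annotations Site-annotation tibble (all enzymes).
#' @param essts Optional named list (by EC) of external profile matrices.
#' @param ntree Trees per forest.
#' @param seed Integer seed; per-enzyme training seeds are derived from
#'   it.
#' @param csr_fraction,gap_threshold Annotation-stage parameters.
#' @param matrix Substitution matrix.
#' @return An `efprf_model_set`: list with `superfamily`, `seed`, and
#'   `enzymes` — a named list of per-enzyme entries (`ec`, `spec`,
#'   `forest`, `simple`).
#' @export
train_superfamily <- function(dataset, annotations, essts = NULL,
                              ntree = 500L, seed = 1L,
                              csr_fraction = 0.10, gap_threshold = 0.20,
                              matrix = NULL) {
  matrix <- matrix %||% efprf_blosum62()
  if (length(dataset$roster) == 0L) {
    stop("dataset roster is empty; no enzyme satisfies the eligibility ",
         "rules", call. = FALSE)
  }
  enzymes <- list()
  for (i in seq_along(dataset$roster)) {
    ec <- dataset$roster[i]
    train_pos <- dataset_part(dataset, ec, "train")
    negatives <- dplyr::bind_rows(purrr::map(
      setdiff(names(dataset$groups), ec),
      function(other) dataset_part(dataset, other, "train")))
    ann <- dplyr::filter(annotations, .data$ec == !!ec)
    rep <- dataset$representatives[[ec]]
    spec <- build_enzyme_spec(train_pos, as.list(rep), ann,
                              matrix = matrix, esst = essts[[ec]],
                              csr_fraction = csr_fraction,
                              gap_threshold = gap_threshold)
    pos_attrs <- build_attribute_table(train_pos, spec, training = TRUE)
    neg_attrs <- build_attribute_table(negatives, spec, training = FALSE)
    attrs <- dplyr::bind_rows(pos_attrs, neg_attrs)
    labels <- c(rep(TRUE, nrow(pos_attrs)), rep(FALSE, nrow(neg_attrs)))
    forest <- train_forest(attrs, labels, spec$schema, ntree = ntree,
                           seed = seed + i)
    simple <- train_simple(attrs$blast, labels)
    enzymes[[ec]] <- list(ec = ec, spec = spec, forest = forest,
                          simple = simple)
  }
  structure(list(superfamily = dataset$superfamily, seed = seed,
                 enzymes = enzymes),
            class = "efprf_model_set")
}

#' @export
print.efprf_model_set <- function(x, ...) {
  cat("EFPrf model set for superfamily", x$superfamily, "-",
      length(x$enzymes), "enzyme predictor(s)\n")
  invisible(x)
}

#' rf-SDR sets of every enzyme in a model set
#'
#' @param model_set An `efprf_model_set`.
#' @param multiplier Highly-contributing prefix multiplier (default 3).
#' @return Named list (by EC) of rf-SDR tibbles (see
#'   [extract_rf_sdrs()]).
#' @export
model_set_sdrs <- function(model_set, multiplier = 3L) {
  purrr::map(model_set$enzymes, function(em) {
    extract_rf_sdrs(rank_importance(em$forest, multiplier = multiplier))
  })
}

#' Write an rf-SDR report TSV
#'
#' One row per (enzyme, position): 1-based representative position, site
#' category, the matrices under which the position was selected, and the
#' rank of its best attribute.
#'
#' @param model_set An `efprf_model_set`.
#' @param path Output path.
#' @param multiplier Prefix multiplier.
#' @return The combined tibble, invisibly.
#' @export
write_sdr_report <- function(model_set, path, multiplier = 3L) {
  sdrs <- model_set_sdrs(model_set, multiplier = multiplier)
  out <- dplyr::bind_rows(purrr::imap(sdrs, function(s, ec)
    dplyr::mutate(s, ec = ec, .before = 1)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Diversity summary of a model set's superfamily
#'
#' @param model_set An `efprf_model_set`.
#' @return Tibble from [classify_diversity()] with the superfamily id.
#' @export
model_set_diversity <- function(model_set) {
  dplyr::mutate(classify_diversity(names(model_set$enzymes)),
                superfamily = model_set$superfamily, .before = 1)
}
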