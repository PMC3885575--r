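# Superfamily dataset assembly: redundancy clustering at 95% identity,
# representative selection, predictor-eligibility rules, and the 80/20
# train/test split.

#' Single-linkage redundancy clustering at a sequence-identity cutoff
#'
#' Pairwise identities come from global alignment, with the shorter
#' sequence length as denominator; pairs at or above the cutoff share a
#' cluster (single linkage). Records are pre-sorted by id, so the result
#' is invariant to input order.
#'
#' @param records Tibble of sequence records from one (superfamily, EC)
#'   group.
#' @param identity_cutoff Fractional identity cutoff (default 0.95).
#' @param matrix Substitution matrix for the alignments.
#' @return Tibble `id`, `cluster` (integer cluster ids numbered by first
#'   appearance in id order).
#' @export
cluster_redundancy <- function(records, identity_cutoff = 0.95,
                               matrix = NULL) {
  if (nrow(records) == 0L) {
    return(tibble::tibble(id = character(), cluster = integer()))
  }
  records <- dplyr::arrange(records, .data$id)
  n <- nrow(records)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      js <- seq(i + 1L, n)
      idents <- batch_identity(records$sequence[i], records$sequence[js],
                               denominator = "shorter", matrix = matrix)
      for (jj in seq_along(js)) {
        j <- js[jj]
        if (find(i) == find(j)) next
        if (idents[jj] >= identity_cutoff * 100) parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  tibble::tibble(id = records$id,
                 cluster = as.integer(factor(roots, levels = unique(roots))))
}

#' Select the representative of one enzyme group
#'
#' Among structure-linked members: the longest sequence, ties broken by
#' best (numerically lowest) resolution, remaining ties by lexicographic
#' id. Groups without any structure-linked member are ineligible.
#'
#' @param group Tibble of sequence records sharing one (superfamily, EC).
#' @return The representative record (one-row tibble), or NULL when no
#'   member carries a structure reference.
#' @export
select_representative <- function(group) {
  cand <- dplyr::filter(group, !is.na(.data$structure_id))
  if (nrow(cand) == 0L) return(NULL)
  cand |>
    dplyr::mutate(len = nchar(.data$sequence),
                  res = dplyr::coalesce(.data$resolution, Inf)) |>
    dplyr::arrange(dplyr::desc(.data$len), .data$res, .data$id) |>
    dplyr::slice(1L) |>
    dplyr::select(-"len", -"res")
}

#' Reduce a group to its redundancy-cluster representatives
#'
#' One sequence is retained per 95%-identity cluster: the structure-linked
#' representative in its own cluster, the longest sequence elsewhere.
#'
#' @param group Tibble of records of one enzyme group.
#' @param clusters Cluster map from [cluster_redundancy()].
#' @param representative The group representative (or NULL).
#' @return Tibble of retained (non-redundant) records.
#' @export
reduce_redundancy <- function(group, clusters, representative = NULL) {
  g <- dplyr::left_join(group, clusters, by = "id")
  rep_cluster <- if (!is.null(representative))
    g$cluster[g$id == representative$id] else integer()
  g |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_modify(function(df, key) {
      if (length(rep_cluster) && key$cluster == rep_cluster) {
        df[df$id == representative$id, ]
      } else {
        df[order(-nchar(df$sequence), df$id)[1], ]
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-"cluster")
}

#' Assemble a superfamily dataset
#'
#' Runs, per enzyme group (distinct four-digit EC in the superfamily):
#' redundancy clustering, representative selection and redundancy removal;
#' then applies the three predictor-eligibility rules and draws the 80/20
#' train/test split. A predictor is built for an enzyme iff (1) the
#' superfamily contains at least one other enzyme, (2) the enzyme has a
#' representative structure and at least `min_positives` non-redundant
#' sequences, and (3) the other enzymes together contribute at least
#' `min_negatives` non-redundant sequences.
#'
#' @param records Tibble of sequence records of one superfamily.
#' @param split_seed Seed for the train/test split.
#' @param identity_cutoff Redundancy-clustering identity cutoff.
#' @param min_positives,min_negatives Eligibility rule thresholds (both 10
#'   by default).
#' @param cluster Set FALSE to skip redundancy clustering (inputs already
#'   non-redundant).
#' @param matrix Substitution matrix.
#' @return An `efprf_dataset`: list with `superfamily`, `groups` (named
#'   list of per-EC tibbles of retained records), `representatives` (named
#'   list), `roster` (character vector of eligible ECs), `split` (tibble
#'   id/ec/part), `split_seed`, `cluster_maps`.
#' @export
build_superfamily_dataset <- function(records, split_seed = 1L,
                                      identity_cutoff = 0.95,
                                      min_positives = 10L,
                                      min_negatives = 10L,
                                      cluster = TRUE, matrix = NULL) {
  sf <- unique(records$superfamily)
  if (length(sf) != 1L) {
    stop("records span ", length(sf),
         " superfamilies; build one dataset per superfamily", call. = FALSE)
  }
  if (any(is.na(records$ec))) {
    stop("all records need complete EC annotations", call. = FALSE)
  }
  ecs <- sort(unique(records$ec))
  groups <- list(); reps <- list(); cluster_maps <- list()
  for (ec in ecs) {
    g <- dplyr::filter(records, .data$ec == !!ec)
    cm <- if (cluster) cluster_redundancy(g, identity_cutoff, matrix) else
      tibble::tibble(id = g$id, cluster = seq_len(nrow(g)))
    rep <- select_representative(g)
    kept <- reduce_redundancy(g, cm, rep)
    groups[[ec]] <- kept
    reps[[ec]] <- rep
    cluster_maps[[ec]] <- cm
  }
  counts <- vapply(groups, nrow, integer(1))
  roster <- character()
  for (ec in ecs) {
    others <- sum(counts[setdiff(ecs, ec)])
    rule1 <- length(ecs) >= 2L
    rule2 <- !is.null(reps[[ec]]) && counts[[ec]] >= min_positives
    rule3 <- others >= min_negatives
    if (rule1 && rule2 && rule3) roster <- c(roster, ec)
  }
  ds <- structure(list(superfamily = sf, groups = groups,
                       representatives = reps, roster = roster,
                       cluster_maps = cluster_maps, split_seed = split_seed),
                  class = "efprf_dataset")
  ds$split <- split_train_test(ds, seed = split_seed)
  ds
}

#' @export
print.efprf_dataset <- function(x, ...) {
  cat("Superfamily dataset", x$superfamily, "\n")
  cat("  enzymes:", length(x$groups), " roster:",
      length(x$roster), "\n")
  cat("  sequences (non-redundant):",
      sum(vapply(x$groups, nrow, integer(1))), "\n")
  invisible(x)
}

#' Draw the 80/20 train/test split of a superfamily dataset
#'
#' Per enzyme group, `round(0.8 n)` sequences (half away from zero) go to
#' training and the rest to test; the group representative is always
#' placed on the training side because its PSSM and conservation profile
#' are built from training data. Reproducible under `seed`.
#'
#' @param dataset An `efprf_dataset`.
#' @param seed Integer seed.
#' @param train_fraction Training fraction (default 0.8).
#' @return Tibble `id`, `ec`, `part` ("train" or "test").
#' @export
split_train_test <- function(dataset, seed = 1L, train_fraction = 0.8) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code
  }
  withr_seed({
    parts <- purrr::imap(dataset$groups, function(g, ec) {
      n <- nrow(g)
      n_train <- round_half_up(train_fraction * n)
      if (n < 2L) {
        warning("enzyme group ", ec, " has fewer than 2 sequences; ",
                "all assigned to training", call. = FALSE)
        return(tibble::tibble(id = g$id, ec = ec, part = "train"))
      }
      rep <- dataset$representatives[[ec]]
      ids <- g$id
      forced <- if (!is.null(rep) && rep$id %in% ids) rep$id else character()
      pool <- setdiff(ids, forced)
      extra <- max(0L, n_train - length(forced))
      train_ids <- c(forced, sample(pool, min(extra, length(pool))))
      tibble::tibble(id = ids, ec = ec,
                     part = ifelse(ids %in% train_ids, "train", "test"))
    })
    dplyr::bind_rows(parts)
  })
}

#' Training (or test) records of one enzyme group
#'
#' @param dataset An `efprf_dataset`.
#' @param ec EC number of the group.
#' @param part `"train"` or `"test"`.
#' @return Tibble of records.
#' @export
dataset_part <- function(dataset, ec, part = c("train", "test")) {
  part <- match.arg(part)
  ids <- dataset$split$id[dataset$split$ec == ec & dataset$split$part == part]
  dplyr::filter(dataset$groups[[ec]], .data$id %in% ids)
}

#' Write a dataset manifest (JSON)
#'
#' Records the roster, per-enzyme counts, the split assignment and the
#' split seed, for provenance and staged pipelines.
#'
#' @param dataset An `efprf_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_manifest <- function(dataset, path) {
  manifest <- list(
    superfamily = dataset$superfamily,
    roster = dataset$roster,
    counts = lapply(dataset$groups, nrow),
    split_seed = dataset$split_seed,
    split = dataset$split
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
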