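# Synthetic superfamily generator with known ground truth.
#
# Emulates a CATH-style homologous superfamily: several enzyme classes
# share one ancestral scaffold; some positions are invariant across all
# classes (shared conserved), some are invariant within a class but carry
# mutually dissimilar residues between classes (planted SDRs), and the
# rest drift i.i.d. at a configured substitution rate. ASR/LBR
# annotations are drawn from a declared mixture of shared and
# class-discriminative positions, so recovery of the planted positions by
# the rf-SDR procedure is directly measurable.

#' Configuration of a synthetic superfamily
#'
#' Defaults describe the standard validation condition used throughout
#' the package: 3 enzyme classes x 20 sequences of length 150, five
#' shared conserved positions, five planted SDR positions per class, a
#' background substitution probability of 0.08 per position per sequence,
#' and annotations covering all planted and shared special positions
#' (ASR = 3 planted + 2 shared, LBR = 2 planted + 3 shared).
#'
#' @param n_enzymes Number of enzyme classes.
#' @param seqs_per_enzyme Sequences per class (the first is the class
#'   prototype/consensus, tagged with a dummy structure reference and used
#'   as the representative).
#' @param length Scaffold length in residues.
#' @param n_shared_conserved Positions invariant across all classes.
#' @param n_planted_sdr Positions invariant within a class but different
#'   (pairwise BLOSUM62 score <= -1) between classes.
#' @param asr_discriminative,asr_shared Planted / shared positions
#'   annotated as active sites.
#' @param lbr_discriminative,lbr_shared Planted / shared positions
#'   annotated as ligand-binding sites.
#' @param subst_rate Background substitution probability per position per
#'   sequence.
#' @param indel_rate Indel probability (default 0; truth bookkeeping is
#'   alignment-free).
#' @param superfamily Dotted superfamily id for the emitted records.
#' @param ec_numbers Optional character vector of class EC numbers.
#' @param seed Integer seed; all outputs are reproducible under it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_enzymes = 3L, seqs_per_enzyme = 20L,
                             length = 150L, n_shared_conserved = 5L,
                             n_planted_sdr = 5L,
                             asr_discriminative = 3L, asr_shared = 2L,
                             lbr_discriminative = 2L, lbr_shared = 3L,
                             subst_rate = 0.08, indel_rate = 0,
                             superfamily = "9.10.20.30",
                             ec_numbers = NULL, seed = 1L) {
  stopifnot(n_enzymes >= 2L, seqs_per_enzyme >= 2L,
            subst_rate >= 0, subst_rate <= 1, indel_rate == 0,
            asr_discriminative + lbr_discriminative <= n_planted_sdr,
            asr_shared + lbr_shared <= n_shared_conserved)
  if (length < n_shared_conserved + n_planted_sdr) {
    stop("scaffold length smaller than the number of special positions",
         call. = FALSE)
  }
  ec_numbers <- ec_numbers %||% paste0("1.1.1.", seq_len(n_enzymes))
  stopifnot(length(ec_numbers) == n_enzymes, all(is_valid_ec(ec_numbers)))
  structure(list(n_enzymes = n_enzymes, seqs_per_enzyme = seqs_per_enzyme,
                 length = length, n_shared_conserved = n_shared_conserved,
                 n_planted_sdr = n_planted_sdr,
                 asr_discriminative = asr_discriminative,
                 asr_shared = asr_shared,
                 lbr_discriminative = lbr_discriminative,
                 lbr_shared = lbr_shared,
                 subst_rate = subst_rate, indel_rate = indel_rate,
                 superfamily = superfamily, ec_numbers = ec_numbers,
                 seed = seed),
            class = "synthetic_config")
}

# choose, for one planted position, one residue per class such that all
# pairwise BLOSUM62 scores are <= max_pair_score (mutually dissimilar)
pick_class_residues <- function(n, matrix, max_pair_score = -1) {
  pool <- sample(AA20)
  chosen <- character()
  for (r in pool) {
    if (length(chosen) == 0L || all(matrix[r, chosen] <= max_pair_score)) {
      chosen <- c(chosen, r)
    }
    if (length(chosen) == n) return(chosen)
  }
  stop("could not find ", n, " mutually dissimilar residues", call. = FALSE)
}

#' Generate a synthetic superfamily with planted ground truth
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (sequence tibble in the [read_fasta()]
#'   layout), `annotations` (site-annotation tibble), and `truth` (planted
#'   and shared positions, per-class residues, annotation types, per-class
#'   prototypes).
#' @export
generate_superfamily <- function(config) {
  set.seed(config$seed)
  L <- config$length
  mat <- efprf_blosum62()
  special_n <- config$n_shared_conserved + config$n_planted_sdr
  special <- sort(sample(seq_len(L), special_n))
  shared_pos <- sort(sample(special, config$n_shared_conserved))
  planted_pos <- sort(setdiff(special, shared_pos))
  scaffold <- sample(AA20, L, replace = TRUE)
  class_residues <- vapply(planted_pos, function(p)
    pick_class_residues(config$n_enzymes, mat), character(config$n_enzymes))
  # class_residues: n_enzymes x n_planted matrix
  if (is.null(dim(class_residues)))
    class_residues <- matrix(class_residues, nrow = config$n_enzymes)
  colnames(class_residues) <- planted_pos

  prototypes <- list(); rec_rows <- list()
  for (k in seq_len(config$n_enzymes)) {
    proto <- scaffold
    proto[planted_pos] <- class_residues[k, ]
    prototypes[[k]] <- paste(proto, collapse = "")
    background <- setdiff(seq_len(L), c(shared_pos, planted_pos))
    for (s in seq_len(config$seqs_per_enzyme)) {
      if (s == 1L) {
        seqv <- proto  # prototype = class consensus, the representative
      } else {
        seqv <- proto
        mut <- background[stats::runif(length(background)) < config$subst_rate]
        if (length(mut)) {
          seqv[mut] <- vapply(seqv[mut], function(r)
            sample(setdiff(AA20, r), 1L), character(1))
        }
      }
      rec_rows[[length(rec_rows) + 1L]] <- tibble::tibble(
        id = sprintf("C%d_S%02d", k, s),
        sequence = paste(seqv, collapse = ""),
        ec = config$ec_numbers[k],
        superfamily = config$superfamily,
        is_representative = s == 1L,
        structure_id = if (s == 1L) sprintf("SYN%d", k) else NA_character_,
        chain = if (s == 1L) "A" else NA_character_,
        resolution = if (s == 1L) 1.5 else NA_real_
      )
    }
  }
  records <- dplyr::bind_rows(rec_rows)

  asr_disc <- planted_pos[seq_len(config$asr_discriminative)]
  lbr_disc <- planted_pos[config$asr_discriminative +
                            seq_len(config$lbr_discriminative)]
  asr_sh <- shared_pos[seq_len(config$asr_shared)]
  lbr_sh <- shared_pos[config$asr_shared + seq_len(config$lbr_shared)]
  ann_rows <- purrr::map(seq_len(config$n_enzymes), function(k) {
    mk <- function(pos, category) tibble::tibble(
      superfamily = config$superfamily, ec = config$ec_numbers[k],
      representative_id = sprintf("C%d_S01", k),
      structure_id = sprintf("SYN%d", k), position = pos,
      category = category, evidence = "synthetic"
    )
    dplyr::bind_rows(mk(c(asr_disc, asr_sh), "active"),
                     mk(c(lbr_disc, lbr_sh), "binding"))
  })
  annotations <- dplyr::bind_rows(ann_rows)

  truth <- list(
    planted_positions = planted_pos,
    shared_positions = shared_pos,
    class_residues = class_residues,
    asr = list(discriminative = asr_disc, shared = asr_sh),
    lbr = list(discriminative = lbr_disc, shared = lbr_sh),
    annotated_discriminative = sort(c(asr_disc, lbr_disc)),
    annotated_shared = sort(c(asr_sh, lbr_sh)),
    prototypes = setNames(unlist(prototypes),
                          sprintf("C%d_S01", seq_len(config$n_enzymes))),
    config = config
  )
  list(records = records, annotations = annotations, truth = truth)
}

#' Generate test queries whose identity to their class prototype falls in
#' a band
#'
#' Queries are derived from the class prototype by mutating background
#' positions until the realized global-alignment identity (identities over
#' alignment length) lies in `band`. Planted SDR positions are never
#' mutated, so the class label is preserved by construction.
#'
#' @param sim Output of [generate_superfamily()].
#' @param band Numeric `c(lo, hi)` identity band in percent.
#' @param n_per_class Queries per enzyme class.
#' @param seed Integer seed.
#' @param max_iter Adjustment iterations per query.
#' @return Tibble of query records (with truth `ec` labels) and a
#'   `realized_identity` column.
#' @export
identity_band_queries <- function(sim, band, n_per_class = 5L, seed = 1L,
                                  max_iter = 25L) {
  set.seed(seed)
  cfg <- sim$truth$config
  L <- cfg$length
  planted <- sim$truth$planted_positions
  floor_ident <- 100 * length(planted) / L
  if (band[2] <= floor_ident) {
    stop("identity band [", band[1], ",", band[2],
         "] infeasible: preserved planted positions impose a floor of ",
         round(floor_ident, 1), "%", call. = FALSE)
  }
  mutable <- setdiff(seq_len(L), planted)
  rows <- list()
  for (k in seq_len(cfg$n_enzymes)) {
    proto <- seq_chars(sim$truth$prototypes[k])
    for (qi in seq_len(n_per_class)) {
      target <- stats::runif(1, band[1], band[2]) / 100
      n_keep_total <- round(target * L)
      n_mut <- L - n_keep_total
      n_mut <- min(max(n_mut, 0L), length(mutable))
      qv <- NULL; realized <- NA_real_
      for (it in seq_len(max_iter)) {
        mut <- sample(mutable, n_mut)
        qv <- proto
        if (n_mut > 0) {
          qv[mut] <- vapply(qv[mut], function(r)
            sample(setdiff(AA20, r), 1L), character(1))
        }
        realized <- pairwise_identity(paste(qv, collapse = ""),
                                      sim$truth$prototypes[k],
                                      denominator = "alignment")
        if (realized >= band[1] && realized <= band[2]) break
        # adjust the mutation count toward the band
        if (realized > band[2]) n_mut <- min(n_mut + 2L, length(mutable))
        else n_mut <- max(n_mut - 2L, 0L)
      }
      if (realized < band[1] || realized > band[2]) {
        stop("could not realize identity in band [", band[1], ",", band[2],
             "] for class ", k, call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sprintf("Q%d_%02d_%s", k, qi, paste(band, collapse = "_")),
        sequence = paste(qv, collapse = ""),
        ec = cfg$ec_numbers[k], superfamily = cfg$superfamily,
        is_representative = FALSE, structure_id = NA_character_,
        chain = NA_character_, resolution = NA_real_,
        realized_identity = realized
      )
    }
  }
  dplyr::bind_rows(rows)
}
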