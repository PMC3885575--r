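# Pairwise alignment and attribute computation.
#
# A query is aligned globally to an enzyme's representative sequence
# (Needleman-Wunsch with affine gaps; externally produced alignments can be
# supplied as aligned FASTA instead) and the predictor's attribute vector
# is computed from that alignment: one BLAST-type top-hit bit score, one
# full-length score per scoring matrix, and one score per annotated
# functional position per scoring matrix.

# Karlin-Altschul constants for gapped BLOSUM62 with open 11 / extend 1
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Global pairwise alignment of a query to a representative
#'
#' Needleman-Wunsch with affine gap penalties (a gap of length L costs
#' `gap_open + L * gap_extend`). The result carries, for every
#' representative position, the aligned query residue or gap, which is the
#' coordinate system all positional attributes use.
#'
#' @param query,representative Named list-like or character scalars; if
#'   character, sequences with `names()` used as ids when present.
#' @param matrix Substitution matrix (default packaged BLOSUM62).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return An `efprf_alignment`: list with `query_id`, `rep_id`,
#'   `aligned_query`, `aligned_rep`, `score`, and `map` — an integer vector
#'   over representative positions giving the aligned query position (NA
#'   where the query has a gap).
#' @export
align_global <- function(query, representative, matrix = NULL,
                         gap_open = 10, gap_extend = 1) {
  matrix <- matrix %||% efprf_blosum62()
  q <- as_seq(query); r <- as_seq(representative)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q$seq), Biostrings::AAString(r$seq),
    substitutionMatrix = matrix, type = "global",
    gapOpening = gap_open, gapExtension = gap_extend
  )
  aq <- as.character(Biostrings::alignedPattern(pa))
  ar <- as.character(Biostrings::alignedSubject(pa))
  build_alignment(q$id, r$id, aq, ar, Biostrings::score(pa))
}

as_seq <- function(x) {
  if (is.list(x)) return(list(id = x$id %||% "query", seq = x$sequence))
  id <- names(x) %||% "query"
  list(id = id[1] %||% "query", seq = unname(x)[1])
}

# Vectorized global alignment of many queries against one subject; one
# Biostrings call amortizes the per-alignment overhead.
batch_align_global <- function(seqs, ids, representative, matrix = NULL,
                               gap_open = 10, gap_extend = 1) {
  matrix <- matrix %||% efprf_blosum62()
  r <- as_seq(representative)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(seqs), Biostrings::AAString(r$seq),
    substitutionMatrix = matrix, type = "global",
    gapOpening = gap_open, gapExtension = gap_extend
  )
  aq <- as.character(Biostrings::alignedPattern(pa))
  ar <- as.character(Biostrings::alignedSubject(pa))
  sc <- Biostrings::score(pa)
  purrr::map(seq_along(seqs), function(i)
    build_alignment(ids[i], r$id, aq[i], ar[i], sc[i]))
}

# Vectorized raw local-alignment scores of one query against many refs.
batch_local_scores <- function(query_seq, ref_seqs, matrix = NULL,
                               gap_open = 11, gap_extend = 1) {
  matrix <- matrix %||% efprf_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(ref_seqs), Biostrings::AAString(query_seq),
    substitutionMatrix = matrix, type = "local",
    gapOpening = gap_open, gapExtension = gap_extend,
    scoreOnly = TRUE
  )
  pa
}

# Vectorized global-alignment identities (%) of one query against many
# refs; denominator "shorter" or "alignment".
batch_identity <- function(query_seq, ref_seqs,
                           denominator = c("shorter", "alignment"),
                           matrix = NULL) {
  denominator <- match.arg(denominator)
  matrix <- matrix %||% efprf_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(ref_seqs), Biostrings::AAString(query_seq),
    substitutionMatrix = matrix, type = "global",
    gapOpening = 10, gapExtension = 1
  )
  ident <- Biostrings::nmatch(pa)
  denom <- switch(denominator,
                  shorter = pmin(nchar(ref_seqs), nchar(query_seq)),
                  alignment = nchar(as.character(Biostrings::alignedPattern(pa))))
  100 * ident / denom
}

build_alignment <- function(query_id, rep_id, aligned_query, aligned_rep,
                            score) {
  qc <- seq_chars(aligned_query); rc <- seq_chars(aligned_rep)
  stopifnot(length(qc) == length(rc))
  rep_pos <- cumsum(rc != GAP)
  q_pos <- cumsum(qc != GAP)
  keep <- rc != GAP
  map <- ifelse(qc[keep] == GAP, NA_integer_, q_pos[keep])
  structure(list(query_id = query_id, rep_id = rep_id,
                 aligned_query = aligned_query, aligned_rep = aligned_rep,
                 score = score, map = as.integer(map)),
            class = "efprf_alignment")
}

#' Percent identity of two sequences from their global alignment
#'
#' @param a,b Sequences (character scalars or record-like lists).
#' @param denominator `"shorter"` (identities over the shorter sequence
#'   length, the redundancy-clustering convention) or `"alignment"`
#'   (identities over the full alignment length including gap columns, the
#'   MTTSI convention).
#' @param matrix Substitution matrix for the alignment.
#' @return Identity as a percentage in \[0, 100\].
#' @export
pairwise_identity <- function(a, b, denominator = c("shorter", "alignment"),
                              matrix = NULL) {
  denominator <- match.arg(denominator)
  sa <- as_seq(a); sb <- as_seq(b)
  al <- align_global(a, b, matrix = matrix)
  qc <- seq_chars(al$aligned_query); rc <- seq_chars(al$aligned_rep)
  ident <- sum(qc == rc & qc != GAP)
  denom <- switch(denominator,
                  shorter = min(nchar(sa$seq), nchar(sb$seq)),
                  alignment = length(qc))
  100 * ident / denom
}

#' Local alignment bit score (BLAST-style)
#'
#' Smith-Waterman local alignment under BLAST default gap penalties
#' (open 11, extend 1) with the raw score converted to bits by the
#' Karlin-Altschul formula `bits = (lambda * S - ln K) / ln 2` using the
#' published gapped-BLOSUM62 constants. Degenerate comparisons whose bits
#' would be negative are reported as 0. Precomputed BLAST tabular scores
#' can be used instead via [top_hit_score()].
#'
#' @param query,subject Sequences.
#' @param matrix Substitution matrix (default packaged BLOSUM62).
#' @param gap_open,gap_extend Affine gap penalties.
#' @param lambda,K Karlin-Altschul parameters.
#' @return Bit score (non-negative).
#' @export
local_bitscore <- function(query, subject, matrix = NULL,
                           gap_open = 11, gap_extend = 1,
                           lambda = KA_LAMBDA, K = KA_K) {
  matrix <- matrix %||% efprf_blosum62()
  q <- as_seq(query); s <- as_seq(subject)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q$seq), Biostrings::AAString(s$seq),
    substitutionMatrix = matrix, type = "local",
    gapOpening = gap_open, gapExtension = gap_extend
  )
  s_raw <- max(0, Biostrings::score(pa))
  max(0, (lambda * s_raw - log(K)) / log(2))
}

#' Top-hit bit score of a query against an enzyme's training sequences
#'
#' In training mode the query's own record is excluded by id, so a training
#' sequence is scored against its best hit among the *other* training
#' sequences.
#'
#' @param query A record-like list or named character scalar with an id.
#' @param training_positives Tibble of training sequences (`id`,
#'   `sequence`).
#' @param mode `"internal"` (compute via [local_bitscore()]) or
#'   `"blast_tabular"` (look up in a precomputed hit table).
#' @param training Logical; exclude the query's own id.
#' @param blast_hits Tibble from [read_blast_tabular()] (required for
#'   `mode = "blast_tabular"`).
#' @param matrix Substitution matrix for internal mode.
#' @return Maximum bit score over the training sequences.
#' @export
top_hit_score <- function(query, training_positives,
                          mode = c("internal", "blast_tabular"),
                          training = FALSE, blast_hits = NULL,
                          matrix = NULL) {
  mode <- match.arg(mode)
  q <- as_seq(query)
  refs <- training_positives
  if (training) refs <- dplyr::filter(refs, .data$id != q$id)
  if (nrow(refs) == 0L) {
    stop("no training sequences left after self-exclusion for query '",
         q$id, "'", call. = FALSE)
  }
  if (mode == "blast_tabular") {
    if (is.null(blast_hits)) stop("blast_hits table required", call. = FALSE)
    hits <- dplyr::filter(blast_hits, .data$query_id == q$id,
                          .data$subject_id %in% refs$id)
    if (nrow(hits) == 0L) return(0)
    return(max(hits$bit_score))
  }
  matrix <- matrix %||% efprf_blosum62()
  s_raw <- pmax(0, batch_local_scores(q$seq, refs$sequence, matrix = matrix))
  max(pmax(0, (KA_LAMBDA * s_raw - log(KA_K)) / log(2)))
}

#' Score of an aligned query at one annotated representative position
#'
#' In matrix mode the score is `sim(rep_residue, query_residue)` under the
#' substitution matrix; in profile mode it is the profile column's value
#' for the query residue. A query gap at the position receives the
#' documented fill value — the scorer's minimum at that position — with the
#' mask flag set (a gap is maximally unlike the representative residue).
#'
#' @param alignment An `efprf_alignment` from [align_global()].
#' @param position 1-based representative position.
#' @param scorer A substitution matrix, or a profile matrix (PSSM/external)
#'   with rows indexed by representative position.
#' @param rep_sequence The representative sequence (needed for matrix
#'   mode).
#' @return List with `value` and `masked`.
#' @export
position_score <- function(alignment, position, scorer, rep_sequence = NULL) {
  rep_len <- length(alignment$map)
  if (position < 1L || position > rep_len) {
    stop("position ", position, " outside representative length ", rep_len,
         call. = FALSE)
  }
  qpos <- alignment$map[position]
  qres <- if (is.na(qpos)) NA_character_ else
    substr(alignment$query_nogap %||%
             gsub(GAP, "", alignment$aligned_query, fixed = TRUE),
           qpos, qpos)
  if (is_profile(scorer)) {
    col <- scorer[as.character(position), , drop = TRUE]
    if (is.na(qres) || !qres %in% names(col)) {
      list(value = min(col), masked = TRUE)
    } else {
      list(value = unname(col[qres]), masked = FALSE)
    }
  } else {
    rres <- substr(as_seq(rep_sequence %||% stop("rep_sequence required for matrix mode",
                                                 call. = FALSE))$seq,
                   position, position)
    row <- scorer[rres, intersect(AA20, colnames(scorer))]
    if (is.na(qres) || !qres %in% names(row)) {
      list(value = min(row), masked = TRUE)
    } else {
      list(value = unname(scorer[rres, qres]), masked = FALSE)
    }
  }
}

is_profile <- function(scorer) {
  !is.null(rownames(scorer)) &&
    !any(rownames(scorer) %in% AA20) &&
    all(AA20 %in% colnames(scorer))
}

#' Full-length score of an aligned query
#'
#' Mean per-aligned-column score over the columns where both sequences
#' carry residues. The mean (rather than the raw sum) keeps the attribute
#' from trivially encoding sequence length; `normalize = FALSE` gives the
#' raw sum.
#'
#' @inheritParams position_score
#' @param normalize Divide by the number of scored columns (default).
#' @return Numeric score.
#' @export
full_length_score <- function(alignment, scorer, rep_sequence = NULL,
                              normalize = TRUE) {
  qc <- seq_chars(alignment$aligned_query)
  rc <- seq_chars(alignment$aligned_rep)
  both <- qc != GAP & rc != GAP
  if (!any(both)) stop("alignment has no columns with residues on both rows",
                       call. = FALSE)
  if (is_profile(scorer)) {
    rep_pos <- cumsum(rc != GAP)
    idx <- which(both)
    vals <- purrr::map_dbl(idx, function(i) {
      col <- scorer[as.character(rep_pos[i]), , drop = TRUE]
      if (qc[i] %in% names(col)) unname(col[qc[i]]) else min(col)
    })
  } else {
    idx <- which(both)
    ok <- qc[idx] %in% rownames(scorer) & rc[idx] %in% colnames(scorer)
    vals <- ifelse(ok, scorer[cbind(rc[idx], qc[idx])],
                   attr(scorer, "gap_score") %||% min(scorer))
  }
  if (normalize) mean(vals) else sum(vals)
}

# ---- Attribute schema and vectors ------------------------------------------

#' Build the attribute schema of one enzyme predictor
#'
#' The schema is a pure function of the enzyme's functional-site sets and
#' the scorers available: one BLAST-type attribute, one full-length
#' attribute per matrix, and one attribute per annotated position per
#' matrix. With all three matrices (BLOSUM62, PSSM, ESST profile) the
#' attribute count is `n = 3 m + 4` for `m` annotated positions; without an
#' external profile the ESST slots are dropped and `n = 2 m + 3`.
#'
#' @param sites A site-set list with elements `asr`, `lbr`, `csr` (integer
#'   representative positions).
#' @param has_esst Whether an external structural profile is available.
#' @return Tibble with columns `name`, `kind` (`blast`, `full_length`,
#'   `position`), `matrix` (`blosum62`, `pssm`, `esst`, or NA for blast),
#'   `position` (NA except for position attributes), `category` (site
#'   category of position attributes).
#' @export
attribute_schema <- function(sites, has_esst = FALSE) {
  matrices <- c("blosum62", "pssm", if (has_esst) "esst")
  pos <- sort(unique(c(sites$asr, sites$lbr, sites$csr)))
  category <- dplyr::case_when(pos %in% sites$asr ~ "asr",
                               pos %in% sites$lbr ~ "lbr",
                               TRUE ~ "csr")
  rows <- list(
    tibble::tibble(name = "blast", kind = "blast", matrix = NA_character_,
                   position = NA_integer_, category = NA_character_),
    tibble::tibble(name = paste0("full_", matrices), kind = "full_length",
                   matrix = matrices, position = NA_integer_,
                   category = NA_character_)
  )
  if (length(pos)) {
    grid <- tidyr::expand_grid(position = pos, matrix = matrices)
    grid$category <- category[match(grid$position, pos)]
    rows <- c(rows, list(tibble::tibble(
      name = paste0("pos", grid$position, "_", grid$matrix),
      kind = "position", matrix = grid$matrix,
      position = as.integer(grid$position), category = grid$category
    )))
  }
  schema <- dplyr::bind_rows(rows)
  stopifnot(!anyDuplicated(schema$name))
  schema
}

#' Compute one query's attribute vector under an enzyme model spec
#'
#' @param query Record-like list or named character scalar.
#' @param spec An enzyme model spec: list with `representative` (record),
#'   `sites`, `pssm`, optional `esst`, `schema`, `training_positives`,
#'   and optional `matrix` (substitution matrix).
#' @param training Training mode: the query's own id is excluded from the
#'   BLAST-type top-hit reference set.
#' @param blast_hits Optional precomputed BLAST tabular table.
#' @param alignment Optional precomputed `efprf_alignment` of the query to
#'   the representative (e.g. from an external aligner).
#' @return Tibble in schema order: schema columns plus `query_id`, `value`,
#'   `masked`.
#' @export
build_attribute_vector <- function(query, spec, training = FALSE,
                                   blast_hits = NULL, alignment = NULL) {
  q <- as_seq(query)
  matrix <- spec$matrix %||% efprf_blosum62()
  schema <- spec$schema %||% attribute_schema(spec$sites,
                                              has_esst = !is.null(spec$esst))
  al <- alignment %||% align_global(query, spec$representative,
                                    matrix = matrix)
  if (length(al$map) != nchar(as_seq(spec$representative)$seq)) {
    stop("alignment does not cover the representative sequence",
         call. = FALSE)
  }
  max_pos <- max(c(0L, schema$position), na.rm = TRUE)
  if (max_pos > length(al$map)) {
    stop("schema annotates position ", max_pos,
         " beyond the representative length ", length(al$map), call. = FALSE)
  }
  scorer_for <- function(mx) switch(mx,
                                    blosum62 = matrix,
                                    pssm = spec$pssm,
                                    esst = spec$esst)
  res <- purrr::pmap(schema, function(name, kind, matrix = NA, position = NA,
                                      ...) {
    if (kind == "blast") {
      mode <- if (is.null(blast_hits)) "internal" else "blast_tabular"
      v <- top_hit_score(list(id = q$id, sequence = q$seq),
                         spec$training_positives, mode = mode,
                         training = training, blast_hits = blast_hits,
                         matrix = scorer_for("blosum62"))
      list(value = v, masked = FALSE)
    } else if (kind == "full_length") {
      list(value = full_length_score(al, scorer_for(matrix),
                                     rep_sequence = spec$representative),
           masked = FALSE)
    } else {
      position_score(al, position, scorer_for(matrix),
                     rep_sequence = spec$representative)
    }
  })
  out <- schema
  out$query_id <- q$id
  out$value <- purrr::map_dbl(res, "value")
  out$masked <- purrr::map_lgl(res, "masked")
  out
}

#' Attribute table for a set of queries
#'
#' Wide layout consumed by the predictor trainer: one row per query, one
#' column per schema attribute (gap-masked entries carry their documented
#' fill values).
#'
#' @param queries Tibble of sequence records.
#' @param spec Enzyme model spec (see [build_attribute_vector()]).
#' @inheritParams build_attribute_vector
#' @return Tibble: `query_id` plus one numeric column per attribute, in
#'   schema order.
#' @export
build_attribute_table <- function(queries, spec, training = FALSE,
                                  blast_hits = NULL) {
  als <- batch_align_global(queries$sequence, queries$id,
                            spec$representative,
                            matrix = spec$matrix %||% efprf_blosum62())
  vecs <- purrr::map(seq_len(nrow(queries)), function(i) {
    rec <- as.list(queries[i, ])
    v <- build_attribute_vector(rec, spec, training = training,
                                blast_hits = blast_hits,
                                alignment = als[[i]])
    tibble::as_tibble(c(list(query_id = rec$id),
                        setNames(as.list(v$value), v$name)))
  })
  dplyr::bind_rows(vecs)
}

#' Star-align training sequences onto a representative
#'
#' Each sequence is globally aligned to the representative and its residues
#' are projected onto representative coordinates (columns inserted relative
#' to the representative are dropped). The result is an alignment whose
#' columns coincide with representative positions, the coordinate system
#' used for functional-site annotation, conservation and PSSMs.
#'
#' @param records Tibble of sequence records (the representative may be
#'   among them; it is always included as the first row).
#' @param representative Representative record.
#' @param matrix Substitution matrix.
#' @return An `efprf_msa` with `ncol` equal to the representative length.
#' @export
star_align <- function(records, representative, matrix = NULL) {
  matrix <- matrix %||% efprf_blosum62()
  rep <- as_seq(representative)
  others <- dplyr::filter(records, .data$id != rep$id)
  als <- batch_align_global(others$sequence, others$id, representative,
                            matrix = matrix)
  rows <- purrr::map_chr(seq_len(nrow(others)), function(i) {
    al <- als[[i]]
    qseq <- others$sequence[i]
    paste(ifelse(is.na(al$map), GAP,
                 substring(qseq, al$map, al$map)), collapse = "")
  })
  new_msa(c(rep$id, others$id), c(rep$seq, rows))
}
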