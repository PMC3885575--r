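# Functional-position sets (ASR / LBR / CSR), conservation profile and
# PSSM of one enzyme's training alignment.
#
# ASR = active-site residue positions (annotated catalytic, or annotated
# both catalytic and ligand-binding); LBR = ligand-binding-only positions;
# CSR = conserved-site residues, the top-10% lowest-entropy eligible
# alignment columns not already claimed by ASR/LBR. Precedence is
# ASR > LBR > CSR.

#' Assemble ASR/LBR site sets from annotation rows
#'
#' Annotations from several structures are unioned: a position annotated as
#' an active site by at least one structure (or as both active and
#' ligand-binding anywhere) becomes an ASR; positions annotated only as
#' ligand-binding become LBRs. Structure coordinates are mapped onto the
#' representative through supplied pairwise mapping alignments; annotations
#' already in representative coordinates use the identity mapping.
#'
#' @param annotations Tibble of annotation rows (see
#'   [read_site_annotations()]).
#' @param mappings Named list (by `structure_id`) of integer vectors
#'   mapping structure positions to representative positions (NA = gap in
#'   the mapping), or NULL when all annotations are already in
#'   representative coordinates.
#' @param representative_length Length of the representative sequence, for
#'   bounds checking.
#' @return List with integer vectors `asr`, `lbr`, empty `csr`, and a
#'   `provenance` tibble (position, category, structure_id).
#' @export
assemble_sites <- function(annotations, mappings = NULL,
                           representative_length = Inf) {
  if (nrow(annotations) == 0L) {
    return(list(asr = integer(), lbr = integer(), csr = integer(),
                provenance = tibble::tibble(position = integer(),
                                            category = character(),
                                            structure_id = character())))
  }
  mapped <- purrr::pmap(annotations, function(structure_id, position,
                                              category, ...) {
    if (!is.null(mappings) && !structure_id %in% c(NA, "", "rep")) {
      if (is.null(mappings[[structure_id]])) {
        stop("no mapping alignment supplied for structure '", structure_id,
             "'", call. = FALSE)
      }
      map <- mappings[[structure_id]]
      rp <- if (position <= length(map)) map[position] else NA_integer_
      if (is.na(rp)) {
        warning("annotation at ", structure_id, ":", position,
                " falls in a mapping gap; dropped", call. = FALSE)
        return(NULL)
      }
      position <- rp
    }
    if (position > representative_length) {
      stop("annotated position ", position,
           " exceeds the representative length", call. = FALSE)
    }
    tibble::tibble(position = as.integer(position), category = category,
                   structure_id = as.character(structure_id))
  })
  prov <- dplyr::bind_rows(mapped)
  if (nrow(prov) == 0L) {
    return(list(asr = integer(), lbr = integer(), csr = integer(),
                provenance = prov))
  }
  by_pos <- prov |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(active = any(.data$category == "active"),
                     binding = any(.data$category == "binding"),
                     .groups = "drop")
  asr <- by_pos$position[by_pos$active]
  lbr <- by_pos$position[by_pos$binding & !by_pos$active]
  list(asr = sort(asr), lbr = sort(lbr), csr = integer(), provenance = prov)
}

#' Distance-based ligand-contact detection on a PDB file
#'
#' A clearly-labelled substitute for atom-level interaction classification:
#' a residue is returned as ligand-binding iff it has at least one
#' nitrogen/oxygen donor-acceptor pair within `hbond_cutoff` of a ligand
#' N/O atom AND at least one carbon-carbon contact within
#' `hydrophobic_cutoff` of a ligand carbon (the conjunction mirrors the
#' requirement that binding residues interact through both hydrogen bonds
#' and hydrophobic contacts). Intended for preliminary annotation only;
#' curated annotation tables are the primary input path.
#'
#' @param pdb_path Path to a PDB-format coordinate file.
#' @param ligand_ids Character vector of HET residue names to treat as
#'   ligands.
#' @param hbond_cutoff Donor-acceptor distance cutoff in Angstrom.
#' @param hydrophobic_cutoff Carbon-carbon distance cutoff in Angstrom.
#' @param chain Optional protein chain to restrict to.
#' @return Sorted integer vector of contacting residue numbers.
#' @export
detect_ligand_contacts <- function(pdb_path, ligand_ids,
                                   hbond_cutoff = 3.5,
                                   hydrophobic_cutoff = 3.9,
                                   chain = NULL) {
  pdb <- bio3d::read.pdb(pdb_path)
  at <- tibble::as_tibble(pdb$atom)
  # first-altloc rule
  at <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$resid, .data$elety) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  lig <- dplyr::filter(at, .data$resid %in% ligand_ids)
  if (nrow(lig) == 0L) {
    stop("ligand id(s) not found in ", pdb_path, ": ",
         paste(ligand_ids, collapse = ", "), call. = FALSE)
  }
  prot <- dplyr::filter(at, .data$type == "ATOM")
  if (!is.null(chain)) prot <- dplyr::filter(prot, .data$chain == !!chain)
  elem <- function(d) substr(gsub("[0-9']", "", d$elety), 1, 1)
  prot$elem <- elem(prot); lig$elem <- elem(lig)
  contact <- function(pe, le, cutoff) {
    p <- dplyr::filter(prot, .data$elem %in% pe)
    l <- dplyr::filter(lig, .data$elem %in% le)
    if (nrow(p) == 0L || nrow(l) == 0L) return(integer())
    d2 <- outer(p$x, l$x, "-")^2 + outer(p$y, l$y, "-")^2 +
      outer(p$z, l$z, "-")^2
    unique(p$resno[rowSums(d2 <= cutoff^2) > 0])
  }
  polar <- contact(c("N", "O"), c("N", "O"), hbond_cutoff)
  hydrophobic <- contact("C", "C", hydrophobic_cutoff)
  sort(intersect(polar, hydrophobic))
}

#' Per-column conservation profile of an alignment
#'
#' Shannon entropy in nats over 21 symbols (20 residues plus the gap):
#' `S_k = -sum_i P_i ln P_i` with `0 ln 0 = 0`, where `P_i` is the fraction
#' of symbol `i` in column `k`. Columns whose gap fraction exceeds 20% are
#' excluded from the entropy calculation (entropy reported as NA,
#' `eligible = FALSE`).
#'
#' @param msa An `efprf_msa`.
#' @param gap_threshold Maximum tolerated gap fraction (strictly above ->
#'   ineligible).
#' @return Tibble with one row per column: `position`, `gap_fraction`,
#'   `entropy`, `eligible`; the 21-symbol fraction matrix is attached as
#'   attribute `fractions`.
#' @export
column_entropy <- function(msa, gap_threshold = 0.20) {
  m <- msa_matrix(msa)
  symbols <- c(AA20, GAP)
  fracs <- apply(m, 2, function(col) {
    tab <- table(factor(col, levels = symbols))
    as.numeric(tab) / length(col)
  })
  fracs <- t(fracs)  # columns of the alignment as rows
  colnames(fracs) <- symbols
  gap_fraction <- fracs[, GAP]
  entropy <- apply(fracs, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  eligible <- gap_fraction <= gap_threshold
  out <- tibble::tibble(position = seq_len(nrow(fracs)),
                        gap_fraction = unname(gap_fraction),
                        entropy = ifelse(eligible, entropy, NA_real_),
                        eligible = eligible)
  attr(out, "fractions") <- fracs
  out
}

#' Select conserved-site residues (CSRs)
#'
#' Among eligible columns, the `ceiling(fraction * n_eligible)` lowest-
#' entropy positions are selected as conserved sites (ties broken by
#' position index ascending). Selected positions already defined as ASRs or
#' LBRs remain in those sets; the CSR set receives only the remainder.
#'
#' @param profile Conservation profile from [column_entropy()].
#' @param sites Site-set list with `asr` and `lbr` filled.
#' @param fraction Fraction of eligible columns to select (default 0.10).
#' @return `sites` with `csr` filled.
#' @export
select_csrs <- function(profile, sites, fraction = 0.10) {
  elig <- dplyr::filter(profile, .data$eligible)
  if (nrow(elig) == 0L) {
    warning("no alignment columns eligible for conservation ranking",
            call. = FALSE)
    sites$csr <- integer()
    return(sites)
  }
  k <- ceiling(fraction * nrow(elig))
  chosen <- elig |>
    dplyr::arrange(.data$entropy, .data$position) |>
    head(k)
  sites$csr <- sort(setdiff(chosen$position, c(sites$asr, sites$lbr)))
  sites$conserved_selected <- sort(chosen$position)
  sites
}

#' Build a position-specific scoring matrix from a training alignment
#'
#' `score(i, j) = sum_k W_ki * sim(k, j)` over the residue types `k`
#' present at column `i`, where `sim` is the substitution matrix and the
#' logarithmic occurrence weight is `W_ki = ln(c_ki + 1) / ln(N + 1)` with
#' `c_ki` the count of residue `k` in column `i` and `N` the number of
#' aligned sequences. Gaps contribute no counts. `W_ki` is 0 for absent
#' residues and 1 exactly when the column is single-residue and gap-free.
#'
#' @param msa An `efprf_msa` (at least two sequences).
#' @param matrix Substitution matrix (default packaged BLOSUM62).
#' @return An `efprf_pssm`: numeric matrix positions x 20 residues with
#'   attributes `weights` (positions x 20), `counts`, and `N`.
#' @export
build_pssm <- function(msa, matrix = NULL) {
  if (msa$nrow < 2L) {
    stop("PSSM construction needs at least two aligned sequences",
         call. = FALSE)
  }
  matrix <- matrix %||% efprf_blosum62()
  m <- msa_matrix(msa)
  N <- nrow(m)
  counts <- t(apply(m, 2, function(col)
    as.numeric(table(factor(col, levels = AA20)))))
  colnames(counts) <- AA20
  weights <- log(counts + 1) / log(N + 1)
  sim <- matrix[AA20, AA20]
  scores <- weights %*% sim
  rownames(scores) <- as.character(seq_len(nrow(scores)))
  rownames(weights) <- rownames(counts) <- rownames(scores)
  structure(scores, weights = weights, counts = counts, N = N,
            class = c("efprf_pssm", class(scores)))
}

#' Build the full site/profile model of one enzyme from training data
#'
#' Convenience wrapper running the annotation stage end to end for one
#' enzyme: star-align the training sequences onto the representative,
#' compute the conservation profile, assemble ASR/LBR from annotations,
#' fill CSRs, and build the PSSM.
#'
#' @param training Tibble of training sequence records (including the
#'   representative).
#' @param representative Representative record.
#' @param annotations Annotation tibble for this enzyme (may be empty).
#' @param matrix Substitution matrix.
#' @param esst Optional external profile matrix.
#' @param csr_fraction Top fraction of eligible columns selected as
#'   conserved.
#' @param gap_threshold Gap-fraction eligibility cutoff.
#' @return An enzyme model spec: list with `representative`, `msa`,
#'   `profile`, `sites`, `pssm`, `esst`, `schema`, `training_positives`,
#'   `matrix`.
#' @export
build_enzyme_spec <- function(training, representative, annotations,
                              matrix = NULL, esst = NULL,
                              csr_fraction = 0.10, gap_threshold = 0.20) {
  matrix <- matrix %||% efprf_blosum62()
  msa <- star_align(training, representative, matrix = matrix)
  profile <- column_entropy(msa, gap_threshold = gap_threshold)
  sites <- assemble_sites(annotations,
                          representative_length = nchar(representative$sequence))
  sites <- select_csrs(profile, sites, fraction = csr_fraction)
  pssm <- build_pssm(msa, matrix = matrix)
  spec <- list(representative = representative, msa = msa, profile = profile,
               sites = sites, pssm = pssm, esst = esst,
               training_positives = training, matrix = matrix)
  spec$schema <- attribute_schema(sites, has_esst = !is.null(esst))
  spec
}
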