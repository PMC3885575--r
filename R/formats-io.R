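# Readers and writers for every external representation the pipeline
# touches: FASTA with metadata headers, multiple sequence alignments
# (aligned FASTA and CLUSTAL), NCBI-format substitution matrices, BLAST
# tabular hit files, site-annotation and profile-matrix TSVs, and JSON
# model bundles.
#
# Coordinate convention: everything user-facing (files, reports, printed
# positions) is 1-based; internal column indexing of alignments is also
# 1-based (R convention), so no conversion layer is needed beyond gap
# bookkeeping.

BUNDLE_SCHEMA_VERSION <- 1L

# ---- FASTA -----------------------------------------------------------------

#' Read a FASTA file of enzyme domain sequences
#'
#' Sequence metadata rides in the FASTA header as `|key=value` tokens after
#' the identifier: `ec` (four-digit EC number), `sf` (CATH-style superfamily
#' id), `rep` (1 if the record is a representative), `pdb` (structure
#' reference as `id:chain:resolution`). Example:
#' `>E1|ec=3.2.1.8|sf=3.20.20.80|pdb=1abc:A:1.8`.
#'
#' Sequences are upper-cased and `*` stop characters stripped. Incomplete
#' EC annotations (e.g. `3.2.1.-`) are rejected, mirroring the dataset
#' filter that only admits sequences annotated with complete four-digit EC
#' numbers. Ambiguity codes other than X (B, Z, U, ...) are rejected: the
#' scoring tables used downstream do not define them.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record: `id`, `sequence`, `ec`,
#'   `superfamily`, `is_representative`, `structure_id`, `chain`,
#'   `resolution`. Input order is preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  seqs <- toupper(gsub("*", "", as.character(set), fixed = TRUE))
  recs <- purrr::map2(headers, seqs, parse_fasta_record)
  dplyr::bind_rows(recs)
}

parse_fasta_record <- function(header, sequence) {
  parts <- strsplit(header, "|", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  id <- parts[1]
  if (!nzchar(id)) stop("FASTA header with empty identifier: '", header, "'",
                        call. = FALSE)
  if (!nzchar(sequence)) stop("empty sequence for record '", id, "'",
                              call. = FALSE)
  check_residues(sequence, id)
  kv <- parts[-1]
  fields <- list()
  for (tok in kv) {
    if (!grepl("=", tok, fixed = TRUE)) {
      stop("malformed FASTA header token '", tok, "' in record '", id,
           "' (expected key=value)", call. = FALSE)
    }
    key <- sub("=.*$", "", tok)
    val <- sub("^[^=]*=", "", tok)
    fields[[key]] <- val
  }
  ec <- fields[["ec"]] %||% NA_character_
  if (!is.na(ec) && !is_valid_ec(ec)) {
    stop("record '", id, "' has an incomplete or malformed EC number '", ec,
         "'; only complete four-digit EC annotations are accepted",
         call. = FALSE)
  }
  sf <- fields[["sf"]] %||% NA_character_
  if (!is.na(sf) && !is_valid_superfamily(sf)) {
    stop("record '", id, "' has a malformed superfamily id '", sf, "'",
         call. = FALSE)
  }
  pdb <- fields[["pdb"]] %||% NA_character_
  structure_id <- NA_character_; chain <- NA_character_; resolution <- NA_real_
  if (!is.na(pdb)) {
    sp <- strsplit(pdb, ":", fixed = TRUE)[[1]]
    structure_id <- sp[1]
    chain <- if (length(sp) >= 2) sp[2] else NA_character_
    resolution <- if (length(sp) >= 3) as.numeric(sp[3]) else NA_real_
  }
  tibble::tibble(
    id = id, sequence = sequence, ec = ec, superfamily = sf,
    is_representative = identical(fields[["rep"]], "1"),
    structure_id = structure_id, chain = chain, resolution = resolution
  )
}

#' Write enzyme records to FASTA
#'
#' Inverse of [read_fasta()]: metadata is serialized back into `|key=value`
#' header tokens. Sequences are written unwrapped (one line each).
#'
#' @param records Tibble as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- purrr::pmap_chr(records, function(id, ec, superfamily,
                                               is_representative,
                                               structure_id, chain,
                                               resolution, ...) {
    h <- id
    if (!is.na(ec)) h <- paste0(h, "|ec=", ec)
    if (!is.na(superfamily)) h <- paste0(h, "|sf=", superfamily)
    if (isTRUE(is_representative)) h <- paste0(h, "|rep=1")
    if (!is.na(structure_id)) {
      h <- paste0(h, "|pdb=", structure_id,
                  ifelse(is.na(chain), "", paste0(":", chain)),
                  ifelse(is.na(resolution), "", paste0(":", resolution)))
    }
    h
  })
  writeLines(paste0(">", headers, "\n", records$sequence), path)
  invisible(path)
}

# ---- Multiple sequence alignments ------------------------------------------

#' Construct a multiple sequence alignment object
#'
#' @param ids Character vector of row identifiers.
#' @param seqs Character vector of aligned sequences (equal lengths, gap
#'   character `-`; `.` is normalized to `-`).
#' @return An `efprf_msa` object.
#' @export
new_msa <- function(ids, seqs) {
  seqs <- toupper(gsub(".", "-", unname(seqs), fixed = TRUE))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(unique(widths), collapse = ", "), call. = FALSE)
  }
  structure(list(ids = unname(ids), seqs = setNames(seqs, ids),
                 nrow = length(seqs), ncol = unname(widths[1])),
            class = "efprf_msa")
}

#' @export
print.efprf_msa <- function(x, ...) {
  cat("Multiple sequence alignment:", x$nrow, "sequences x", x$ncol,
      "columns\n")
  invisible(x)
}

#' Alignment as a character matrix
#'
#' @param msa An `efprf_msa`.
#' @return Character matrix, rows = sequences, columns = alignment columns.
#' @export
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unname(msa$seqs), "", fixed = TRUE))
  rownames(m) <- msa$ids
  m
}

#' Read a multiple sequence alignment
#'
#' @param path Path to the alignment file.
#' @param dialect `"aligned-fasta"` or `"clustal"`.
#' @return An `efprf_msa` object.
#' @export
read_alignment <- function(path, dialect = c("aligned-fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "aligned-fasta") {
    set <- Biostrings::readBStringSet(path)
    new_msa(names(set), as.character(set))
  } else {
    read_clustal(path)
  }
}

# CLUSTAL block format: header line, then blocks of "<id> <chunk>" rows
# separated by blank/conservation lines.
read_clustal <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^CLUSTAL", lines[1])) {
    stop("not a CLUSTAL file (missing CLUSTAL header line): ", path,
         call. = FALSE)
  }
  body <- lines[-1]
  chunks <- list()
  order_seen <- character()
  for (ln in body) {
    if (!nzchar(trimws(ln))) next
    # conservation lines contain only * : . and spaces
    if (grepl("^[\\s*:.]+$", ln, perl = TRUE)) next
    m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)", ln))[[1]]
    if (length(m) < 3) next
    id <- m[2]; chunk <- m[3]
    chunk <- gsub("[0-9]", "", chunk)  # optional trailing residue counts
    if (!id %in% order_seen) order_seen <- c(order_seen, id)
    chunks[[id]] <- paste0(chunks[[id]] %||% "", chunk)
  }
  if (length(order_seen) == 0L) stop("no sequences in CLUSTAL file: ", path,
                                     call. = FALSE)
  new_msa(order_seen, unlist(chunks[order_seen], use.names = FALSE))
}

#' Write an alignment as aligned FASTA
#'
#' @param msa An `efprf_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  writeLines(paste0(">", msa$ids, "\n", unname(msa$seqs)), path)
  invisible(path)
}

# ---- Substitution matrices -------------------------------------------------

#' Read an NCBI-format substitution matrix
#'
#' Whitespace-separated matrix with a header row of residue letters and `#`
#' comment lines, as distributed with BLAST. The matrix must be symmetric.
#'
#' @param path Path to the matrix file.
#' @param gap_score Score attached to gap comparisons (stored as an
#'   attribute; the matrix itself covers residue pairs only).
#' @return A symmetric numeric matrix with residue-letter dimnames and a
#'   `gap_score` attribute.
#' @export
read_scoring_matrix <- function(path, gap_score = -4) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix file: ", path,
                               call. = FALSE)
  letters_row <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- length(letters_row)
  rows <- lapply(lines[-1], function(ln) strsplit(trimws(ln), "\\s+")[[1]])
  mat <- matrix(NA_real_, n, n, dimnames = list(letters_row, letters_row))
  for (r in rows) {
    if (length(r) != n + 1L) {
      stop("matrix row for '", r[1], "' has ", length(r) - 1L,
           " entries, expected ", n, call. = FALSE)
    }
    if (!r[1] %in% letters_row) {
      stop("matrix row letter '", r[1], "' missing from header", call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(vals)) stop("non-numeric score in row '", r[1], "'",
                          call. = FALSE)
    mat[r[1], ] <- vals
  }
  if (anyNA(mat)) {
    stop("matrix is missing rows for: ",
         paste(letters_row[rowSums(is.na(mat)) > 0], collapse = ", "),
         call. = FALSE)
  }
  if (!isTRUE(all.equal(mat, t(mat)))) {
    stop("substitution matrix is not symmetric: ", path, call. = FALSE)
  }
  attr(mat, "gap_score") <- gap_score
  mat
}

#' The packaged BLOSUM62 matrix
#'
#' Reads the canonical NCBI-format BLOSUM62 file shipped with the package.
#'
#' @inheritParams read_scoring_matrix
#' @return Symmetric numeric matrix (see [read_scoring_matrix()]).
#' @export
efprf_blosum62 <- function(gap_score = -4) {
  read_scoring_matrix(system.file("extdata", "BLOSUM62.txt",
                                  package = "efprf", mustWork = TRUE),
                      gap_score = gap_score)
}

# ---- BLAST tabular ---------------------------------------------------------

#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Retains the maximum bit score per (query, subject) pair. An empty file
#' yields an empty table, not an error.
#'
#' @param path Path to a 12-column BLAST tabular file.
#' @return Tibble with columns `query_id`, `subject_id`, `bit_score`.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(query_id = character(), subject_id = character(),
                          bit_score = numeric()))
  }
  rows <- purrr::imap(lines, function(ln, i) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 12L) {
      stop("line ", i, ": expected 12 tab-separated columns, got ",
           length(f), call. = FALSE)
    }
    bs <- suppressWarnings(as.numeric(f[12]))
    if (is.na(bs)) stop("line ", i, ": non-numeric bit score '", f[12], "'",
                        call. = FALSE)
    tibble::tibble(query_id = f[1], subject_id = f[2], bit_score = bs)
  })
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$query_id, .data$subject_id) |>
    dplyr::summarise(bit_score = max(.data$bit_score), .groups = "drop")
}

# ---- Site annotations and profile matrices ---------------------------------

#' Read a site-annotation TSV
#'
#' Columns: `superfamily`, `ec`, `representative_id`, `structure_id`,
#' `position` (1-based residue index on the representative or on the
#' annotating structure), `category` (`active` or `binding`), `evidence`.
#'
#' @param path Path to the TSV file.
#' @return Tibble of annotation rows.
#' @export
read_site_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  required <- c("superfamily", "ec", "representative_id", "structure_id",
                "position", "category")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("site-annotation file lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(df$category %in% c("active", "binding"))) {
    stop("site-annotation category must be 'active' or 'binding'",
         call. = FALSE)
  }
  if (any(df$position < 1L)) stop("positions must be 1-based and positive",
                                  call. = FALSE)
  if (!"evidence" %in% names(df)) df$evidence <- NA_character_
  df
}

#' Write a site-annotation TSV
#'
#' @param annotations Tibble as returned by [read_site_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an externally supplied per-position profile matrix
#'
#' TSV with a `position` column (1-based representative positions) and one
#' column per residue letter; used to plug in externally computed
#' structure-conditioned profiles (e.g. ESST-based ones).
#'
#' @param path Path to the TSV file.
#' @param source_tag Provenance label stored on the matrix.
#' @return Numeric matrix positions x 20 residues with a `source_tag`
#'   attribute.
#' @export
read_profile_matrix <- function(path, source_tag = "external") {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"position" %in% names(df)) {
    stop("profile matrix needs a 'position' column", call. = FALSE)
  }
  missing <- setdiff(AA20, names(df))
  if (length(missing)) {
    stop("profile matrix lacks residue column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, AA20])
  if (!all(is.finite(m))) stop("profile matrix has non-finite values",
                               call. = FALSE)
  rownames(m) <- df$position
  attr(m, "source_tag") <- source_tag
  m
}

# ---- Model bundles ---------------------------------------------------------

#' Save a trained model set to a JSON bundle
#'
#' The bundle records the package version, bundle schema version, seeds and
#' the full serialized model set; [load_model_bundle()] restores an object
#' whose predictions and importance rankings are identical to the original.
#'
#' @param model_set A model set as returned by [train_superfamily()] (or any
#'   serializable model object).
#' @param path Output path for the JSON bundle.
#' @return `path`, invisibly.
#' @export
save_model_bundle <- function(model_set, path) {
  payload <- list(
    bundle_schema = BUNDLE_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("efprf")),
    payload = jsonlite::serializeJSON(model_set, digits = NA)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model bundle saved by [save_model_bundle()]
#'
#' @param path Path to the JSON bundle.
#' @return The restored model set.
#' @export
load_model_bundle <- function(path) {
  payload <- jsonlite::read_json(path)
  if (!identical(as.integer(payload$bundle_schema), BUNDLE_SCHEMA_VERSION)) {
    stop("incompatible model bundle: bundle schema version ",
         payload$bundle_schema, ", this package reads version ",
         BUNDLE_SCHEMA_VERSION, call. = FALSE)
  }
  jsonlite::unserializeJSON(payload$payload)
}
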