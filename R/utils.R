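# Shared constants and small validators.

# the 20 standard residues, in the fixed order used for profile columns
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

GAP <- "-"

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residue one-letter codes in the fixed column order used
#' by profile matrices and PSSMs.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() AA20

is_valid_ec <- function(ec) {
  grepl("^\\d+\\.\\d+\\.\\d+\\.\\d+$", ec)
}

is_valid_superfamily <- function(sf) {
  grepl("^\\d+\\.\\d+\\.\\d+\\.\\d+$", sf)
}

ec3_prefix <- function(ec) {
  sub("\\.\\d+$", "", ec)
}

# Residue validation: 20 standard letters plus X. B/Z/U and other ambiguity
# codes are rejected because the scoring tables used here do not define them.
check_residues <- function(seq, id = "<sequence>") {
  bad <- gsub(paste0("[", paste(AA20, collapse = ""), "X]"), "", seq)
  if (nzchar(bad)) {
    stop("sequence '", id, "' contains unsupported residue letter(s): ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         " (only the 20 standard residues plus X are accepted)",
         call. = FALSE)
  }
  invisible(TRUE)
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
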