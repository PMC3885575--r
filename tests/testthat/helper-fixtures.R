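# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# small two-class synthetic superfamily for module-level tests
small_config <- function(seed = 11L) {
  synthetic_config(n_enzymes = 2L, seqs_per_enzyme = 14L, length = 80L,
                   n_shared_conserved = 4L, n_planted_sdr = 4L,
                   asr_discriminative = 2L, asr_shared = 2L,
                   lbr_discriminative = 2L, lbr_shared = 2L,
                   subst_rate = 0.10, seed = seed)
}

small_sim <- function() {
  if (is.null(.fixtures$sim)) .fixtures$sim <- generate_superfamily(small_config())
  .fixtures$sim
}

small_dataset <- function() {
  if (is.null(.fixtures$ds)) {
    .fixtures$ds <- build_superfamily_dataset(small_sim()$records,
                                              split_seed = 7L)
  }
  .fixtures$ds
}

small_model_set <- function() {
  if (is.null(.fixtures$ms)) {
    .fixtures$ms <- train_superfamily(small_dataset(),
                                      small_sim()$annotations,
                                      ntree = 300L, seed = 5L)
  }
  .fixtures$ms
}

# records tibble from bare sequences
make_records <- function(seqs, ec = "1.1.1.1", sf = "1.2.3.4",
                         structure = FALSE, resolution = NA_real_) {
  n <- length(seqs)
  ids <- names(seqs) %||% sprintf("S%02d", seq_len(n))
  tibble::tibble(
    id = ids, sequence = unname(seqs),
    ec = rep_len(ec, n), superfamily = rep_len(sf, n),
    is_representative = FALSE,
    structure_id = if (isTRUE(structure)) paste0("P", seq_len(n)) else
      rep_len(NA_character_, n),
    chain = NA_character_,
    resolution = rep_len(resolution, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

random_aa <- function(n, len, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(aa_alphabet(), len, replace = TRUE), collapse = ""),
    character(1))
}
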