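test_that("generated superfamilies honour the planted structure", {
  cfg <- synthetic_config(n_enzymes = 2L, seqs_per_enzyme = 12L,
                          length = 120L, n_shared_conserved = 4L,
                          n_planted_sdr = 4L, asr_discriminative = 2L,
                          asr_shared = 2L, lbr_discriminative = 2L,
                          lbr_shared = 2L, subst_rate = 0.05, seed = 1L)
  sim <- generate_superfamily(cfg)
  expect_equal(nrow(sim$records), 24L)
  tr <- sim$truth
  m <- do.call(rbind, strsplit(sim$records$sequence, ""))
  for (p in tr$planted_positions) {
    for (k in 1:2) {
      cls <- sim$records$ec == cfg$ec_numbers[k]
      expect_equal(length(unique(m[cls, p])), 1L)  # invariant within class
    }
    expect_equal(length(unique(m[, p])), 2L)       # differs between
  }
  for (p in tr$shared_positions) {
    expect_equal(length(unique(m[, p])), 1L)       # invariant everywhere
  }
  # planted residues mutually dissimilar under BLOSUM62
  b62 <- efprf_blosum62()
  for (j in seq_along(tr$planted_positions)) {
    rs <- tr$class_residues[, j]
    expect_lte(b62[rs[1], rs[2]], -1)
  }
  # annotations span both shared and discriminative positions
  expect_setequal(c(tr$annotated_discriminative, tr$annotated_shared),
                  sort(c(tr$asr$discriminative, tr$asr$shared,
                         tr$lbr$discriminative, tr$lbr$shared)))
  expect_true(all(tr$annotated_discriminative %in% tr$planted_positions))
  expect_true(all(tr$annotated_shared %in% tr$shared_positions))

  # zero substitution rate: all class members identical
  sim0 <- generate_superfamily(synthetic_config(n_enzymes = 2L,
                                                seqs_per_enzyme = 5L,
                                                length = 60L,
                                                subst_rate = 0, seed = 2L))
  for (k in 1:2) {
    cls <- sim0$records$sequence[sim0$records$ec ==
                                   sim0$truth$config$ec_numbers[k]]
    expect_equal(length(unique(cls)), 1L)
  }

  expect_error(synthetic_config(length = 8L, n_shared_conserved = 5L,
                                n_planted_sdr = 5L), "smaller")
})

test_that("same seed reproduces the superfamily byte for byte", {
  cfg <- small_config()
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(generate_superfamily(cfg)$records, f1)
  write_fasta(generate_superfamily(cfg)$records, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted ground truth is perfectly label-informative at rate 0", {
  sim0 <- generate_superfamily(synthetic_config(n_enzymes = 3L,
                                                seqs_per_enzyme = 6L,
                                                length = 60L,
                                                subst_rate = 0, seed = 3L))
  p <- sim0$truth$planted_positions[1]
  residue_at_p <- substring(sim0$records$sequence, p, p)
  # a one-rule classifier on any single planted position is perfect
  expect_equal(length(unique(paste(residue_at_p, sim0$records$ec))), 3L)
  expect_equal(unname(table(residue_at_p, sim0$records$ec) > 0) |> rowSums(),
               rep(1, 3), ignore_attr = TRUE)
})

test_that("generated files round-trip through the readers", {
  sim <- small_sim()
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(sim$records, f)
  expect_equal(read_fasta(f), sim$records)
  a <- withr::local_tempfile(fileext = ".tsv")
  write_site_annotations(sim$annotations, a)
  expect_equal(read_site_annotations(a), sim$annotations)
})

test_that("identity-band queries land in the requested band", {
  sim <- small_sim()
  q_hi <- identity_band_queries(sim, c(90, 100), n_per_class = 3, seed = 4)
  expect_true(all(q_hi$realized_identity >= 90 &
                    q_hi$realized_identity <= 100))
  # re-verify by independent alignment
  for (i in seq_len(nrow(q_hi))) {
    proto <- sim$truth$prototypes[paste0(sub("Q(\\d+).*", "C\\1",
                                             q_hi$id[i]), "_S01")]
    expect_equal(pairwise_identity(q_hi$sequence[i], unname(proto),
                                   denominator = "alignment"),
                 q_hi$realized_identity[i])
  }
  q_lo <- identity_band_queries(sim, c(25, 30), n_per_class = 3, seed = 4)
  expect_true(all(q_lo$realized_identity >= 25 &
                    q_lo$realized_identity <= 30))
  # planted positions never mutated
  m <- do.call(rbind, strsplit(q_lo$sequence, ""))
  for (k in 1:2) {
    cls <- q_lo$ec == sim$truth$config$ec_numbers[k]
    proto <- chars(unname(sim$truth$prototypes[k]))
    for (p in sim$truth$planted_positions) {
      expect_true(all(m[cls, p] == proto[p]))
    }
  }
  # infeasible band is refused
  expect_error(identity_band_queries(sim, c(0, 3), n_per_class = 1),
               "infeasible")
})
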