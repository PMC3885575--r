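b62 <- efprf_blosum62()

test_that("global alignment matches the brute-force Gotoh oracle", {
  expect_equal(align_global("HEAGAWGHEE", "PAWHEAE")$score,
               oracle_global_score("HEAGAWGHEE", "PAWHEAE", b62))

  # identical sequences: identity mapping, score = sum of diagonal values
  s <- "MKTAYIAW"
  al <- align_global(s, s)
  expect_equal(al$map, 1:8)
  expect_equal(al$score, sum(b62[cbind(chars(s), chars(s))]))

  # random pairs, including short ones over a 4-letter alphabet
  set.seed(21)
  for (i in 1:12) {
    len_a <- sample(3:9, 1); len_b <- sample(3:9, 1)
    a <- paste(sample(c("A", "C", "G", "W"), len_a, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "W"), len_b, TRUE), collapse = "")
    expect_equal(align_global(a, b)$score, oracle_global_score(a, b, b62),
                 info = paste(a, b))
  }

  # mapping totality: every representative position mapped or gapped
  al <- align_global("MKT", "MKTAYIAW")
  expect_equal(length(al$map), 8L)
  expect_true(all(is.na(al$map) | (al$map >= 1 & al$map <= 3)))
})

test_that("local bit scores follow Smith-Waterman plus Karlin-Altschul", {
  s <- "MKTAYIAWQR"
  raw <- sum(b62[cbind(chars(s), chars(s))])
  expect_equal(local_bitscore(s, s),
               (0.267 * raw - log(0.041)) / log(2))
  set.seed(4)
  for (i in 1:8) {
    a <- random_aa(1, sample(6:14, 1), seed = i)
    b <- random_aa(1, sample(6:14, 1), seed = i + 100)
    expect_equal(local_bitscore(a, b),
                 max(0, (0.267 * oracle_local_score(a, b, b62) -
                           log(0.041)) / log(2)))
  }
  # appending an identical block never lowers the bit score
  a <- random_aa(1, 10, seed = 5); b <- random_aa(1, 10, seed = 6)
  block <- "WWCHHKY"
  expect_gte(local_bitscore(paste0(a, block), paste0(b, block)),
             local_bitscore(a, b))
})

test_that("top-hit scoring excludes self in training mode", {
  refs <- make_records(c(T1 = "MKTAYIAWQR", T2 = "MKTAYIAWQA",
                         T3 = "CCHGWKLMNP"))
  q <- list(id = "T1", sequence = "MKTAYIAWQR")
  # prediction mode: the self-like hit wins
  expect_equal(top_hit_score(q, refs),
               local_bitscore("MKTAYIAWQR", "MKTAYIAWQR"))
  # training mode: self excluded, second best returned
  expect_equal(top_hit_score(q, refs, training = TRUE),
               local_bitscore("MKTAYIAWQR", "MKTAYIAWQA"))
  expect_error(top_hit_score(q, refs[1, ], training = TRUE), "no training")

  # tabular mode honours the same contract, values read not computed
  hits <- tibble::tibble(query_id = c("T1", "T1"),
                         subject_id = c("T2", "T3"),
                         bit_score = c(77, 33))
  expect_equal(top_hit_score(q, refs, mode = "blast_tabular",
                             training = TRUE, blast_hits = hits), 77)
})

test_that("position scores cover matrix mode, profile mode and gap fill", {
  rep <- list(id = "R", sequence = "WACDH")
  al <- align_global("WACDH", rep)
  expect_equal(position_score(al, 1, b62, rep)$value, 11)  # sim(W,W)
  # symmetry of matrix mode under residue swap
  al2 <- align_global("YACDH", rep)
  expect_equal(position_score(al2, 1, b62, rep)$value, b62["W", "Y"])
  expect_equal(b62["W", "Y"], b62["Y", "W"])

  # PSSM of an all-W column scores W as 11 (chained from the weight form)
  pssm <- build_pssm(new_msa(paste0("s", 1:5), rep("WA", 5)), b62)
  al3 <- align_global("WA", list(id = "R2", sequence = "WA"))
  expect_equal(position_score(al3, 1, pssm)$value, 11)

  # query gap at the position -> scorer minimum, masked
  al4 <- align_global("ACDH", rep)  # W unmatched
  ps <- position_score(al4, 1, b62, rep)
  expect_true(ps$masked)
  expect_equal(ps$value, min(b62["W", aa_alphabet()]))
  expect_error(position_score(al, 99, b62, rep), "outside")
})

test_that("full-length scores are per-column means over residue columns", {
  rep <- list(id = "R", sequence = "MKWC")
  al <- align_global("MKWC", rep)
  expect_equal(full_length_score(al, b62, rep),
               mean(b62[cbind(c("M", "K", "W", "C"),
                              c("M", "K", "W", "C"))]))
  expect_equal(full_length_score(al, b62, rep, normalize = FALSE),
               sum(b62[cbind(c("M", "K", "W", "C"),
                             c("M", "K", "W", "C"))]))
  # padding both sequences with an identical residue moves the mean
  # toward that residue's diagonal value, in closed form
  al2 <- align_global("MKWCAAAA", list(id = "R", sequence = "MKWCAAAA"))
  expect_equal(full_length_score(al2, b62, rep),
               (full_length_score(al, b62, rep) * 4 + 4 * b62["A", "A"]) / 8)
})

test_that("attribute schemas and vectors obey the layout rules", {
  sites <- list(asr = c(12L, 40L), lbr = 7L, csr = integer())
  sch3 <- attribute_schema(sites, has_esst = TRUE)
  expect_equal(nrow(sch3), 3 * 3 + 4)
  sch2 <- attribute_schema(sites, has_esst = FALSE)
  expect_equal(nrow(sch2), 2 * 3 + 3)
  expect_equal(sum(sch2$kind == "blast"), 1L)
  expect_equal(sum(sch2$kind == "full_length"), 2L)
  expect_equal(anyDuplicated(sch2$name), 0L)

  # vectors from one schema are index-compatible and respect locality
  sim <- small_sim()
  ms <- small_model_set()
  em <- ms$enzymes[[1]]
  expect_equal(nrow(em$spec$schema),
               2 * length(unique(c(em$spec$sites$asr, em$spec$sites$lbr,
                                   em$spec$sites$csr))) + 3)
  rep_rec <- em$spec$representative
  v_self <- build_attribute_vector(rep_rec, em$spec)
  pos_rows <- v_self[v_self$kind == "position" & v_self$matrix == "blosum62", ]
  rep_res <- substring(rep_rec$sequence, pos_rows$position,
                       pos_rows$position)
  expect_equal(pos_rows$value, unname(b62[cbind(rep_res, rep_res)]))

  # two queries differing only at a non-annotated position: identical
  # position attributes, different full-length attributes
  annotated <- sort(unique(c(em$spec$sites$asr, em$spec$sites$lbr,
                             em$spec$sites$csr)))
  free <- setdiff(seq_len(nchar(rep_rec$sequence)), annotated)[1]
  ch <- chars(rep_rec$sequence)
  ch[free] <- setdiff(aa_alphabet(), ch[free])[1]
  mutant <- list(id = "mut", sequence = paste(ch, collapse = ""))
  v_mut <- build_attribute_vector(mutant, em$spec)
  expect_equal(v_mut$value[v_mut$kind == "position"],
               v_self$value[v_self$kind == "position"])
  expect_false(isTRUE(all.equal(
    v_mut$value[v_mut$kind == "full_length"],
    v_self$value[v_self$kind == "full_length"])))
})
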