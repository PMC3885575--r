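test_that("ASR/LBR assembly applies the union and precedence rules", {
  ann <- tibble::tibble(
    superfamily = "1.2.3.4", ec = "1.1.1.1", representative_id = "R",
    structure_id = c("rep", "rep", "rep"),
    position = c(12L, 12L, 40L),
    category = c("active", "binding", "binding"),
    evidence = NA_character_
  )
  sites <- assemble_sites(ann, representative_length = 100)
  expect_equal(sites$asr, 12L)  # both active and binding -> ASR
  expect_equal(sites$lbr, 40L)

  # union over structures, with a mapping for the second structure
  ann2 <- dplyr::bind_rows(
    ann[3, ],
    dplyr::mutate(ann[3, ], structure_id = "2xyz", position = 17L)
  )
  map <- setNames(rep(NA_integer_, 20), NULL); map[17] <- 41L
  sites2 <- assemble_sites(ann2, mappings = list(`2xyz` = map),
                           representative_length = 100)
  expect_equal(sites2$lbr, c(40L, 41L))

  expect_error(assemble_sites(ann2, mappings = list(),
                              representative_length = 100),
               "no mapping")
  empty <- assemble_sites(ann[0, ])
  expect_equal(empty$asr, integer())
})

test_that("column entropy matches the brute-force oracle and the gap rule", {
  msa <- new_msa(paste0("s", 1:4),
                 c("AAAV-A", "AAVV-A", "AVVVAA", "AVAV-A"))
  prof <- column_entropy(msa)
  expect_equal(prof$entropy[1], 0)               # all 'A'
  expect_equal(prof$entropy[2], log(2))          # half A / half V
  expect_true(!prof$eligible[5])                 # 75% gaps -> excluded
  expect_true(is.na(prof$entropy[5]))
  m <- msa_matrix(msa)
  for (k in which(prof$eligible)) {
    expect_equal(prof$entropy[k], oracle_column_entropy(m[, k]))
  }
  # gap threshold is strict: exactly 20% gaps stays eligible
  msa5 <- new_msa(paste0("s", 1:5), c("-A", "AA", "AA", "AA", "AA"))
  expect_true(column_entropy(msa5)$eligible[1])
  msa4 <- new_msa(paste0("s", 1:4), c("-A", "AA", "AA", "AA"))
  expect_false(column_entropy(msa4)$eligible[1])  # 25% gaps
})

test_that("entropy never increases when duplicating a majority-agreeing row", {
  set.seed(3)
  for (rep_i in 1:5) {
    seqs <- random_aa(5, 12, seed = rep_i)
    msa <- new_msa(paste0("s", 1:5), seqs)
    m <- msa_matrix(msa)
    maj <- apply(m, 2, function(col) names(sort(table(col),
                                                decreasing = TRUE))[1])
    msa2 <- new_msa(c(msa$ids, "dup"), c(unname(msa$seqs),
                                         paste(maj, collapse = "")))
    e1 <- column_entropy(msa)$entropy
    e2 <- column_entropy(msa2)$entropy
    expect_true(all(e2 <= e1 + 1e-12))
  }
})

test_that("CSR selection takes the top 10% of eligible columns with precedence", {
  set.seed(9)
  seqs <- random_aa(6, 100, seed = 42)
  # make columns 3, 7, 50 perfectly conserved (entropy 0)
  seqs <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]; ch[c(3, 7, 50)] <- c("W", "C", "H")
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  prof <- column_entropy(new_msa(paste0("s", 1:6), seqs))
  sites <- list(asr = 3L, lbr = integer(), csr = integer())
  out <- select_csrs(prof, sites, fraction = 0.10)
  expect_equal(length(out$conserved_selected), ceiling(0.10 * 100))
  expect_true(all(c(7L, 50L) %in% out$csr))
  expect_false(3L %in% out$csr)            # already ASR, stays ASR
  expect_equal(out$asr, 3L)
  expect_equal(intersect(out$csr, c(out$asr, out$lbr)), integer())

  # all-equal entropies: lowest indices win the tie
  const <- new_msa(paste0("s", 1:3), rep(strrep("A", 30), 3))
  p2 <- column_entropy(const)
  out2 <- select_csrs(p2, list(asr = integer(), lbr = integer(),
                               csr = integer()))
  expect_equal(out2$csr, 1:3)  # ceiling(0.1*30) = 3 lowest positions
})

test_that("PSSM weights and scores follow the logarithmic-weight form", {
  b62 <- efprf_blosum62()
  msa <- new_msa(paste0("s", 1:5), rep("WA", 5))
  pssm <- build_pssm(msa, b62)
  w <- attr(pssm, "weights")
  expect_equal(w["1", "W"], 1)               # ln 6 / ln 6
  expect_equal(unname(pssm["1", "W"]), 11)   # weight 1 x sim(W,W)
  expect_equal(w["1", "A"], 0)               # absent residue, ln 1 = 0

  # oracle equivalence on a mixed alignment, and weight bounds
  seqs <- c("WAC-H", "WACDH", "WVCDH", "YVCDH")
  msa2 <- new_msa(paste0("s", 1:4), seqs)
  pssm2 <- build_pssm(msa2, b62)
  expect_equal(unclass(pssm2)[, aa_alphabet()],
               oracle_pssm(msa_matrix(msa2), b62)[, aa_alphabet()],
               ignore_attr = TRUE)
  w2 <- attr(pssm2, "weights")
  expect_true(all(w2 >= 0 & w2 <= 1))
  expect_equal(unname(w2 == 1),
               unname(attr(pssm2, "counts") == attr(pssm2, "N")))

  # convex-cone bound: scores bounded by matrix extremes times total weight
  tot_w <- rowSums(attr(pssm2, "weights"))
  b <- b62[aa_alphabet(), aa_alphabet()]
  expect_true(all(unclass(pssm2) <= max(b) * tot_w + 1e-9))
  expect_true(all(unclass(pssm2) >= min(b) * tot_w - 1e-9))

  expect_error(build_pssm(new_msa("s1", "WA")), "at least two")
})

test_that("distance-based ligand contacts require both contact types", {
  # hand-built coordinates: residue 2 has OG 3.0 A and CB 3.5 A from the
  # ligand; residue 1 only a hydrophobic contact; residue 3 is remote
  pdb_line <- function(serial, name, res, chain, resno, x, y, z,
                       record = "ATOM") {
    sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            record, serial, name, res, chain, resno, x, y, z,
            substr(name, 1, 1))
  }
  lines <- c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CB", "ALA", "A", 1, 1.5, 0, 0),
    pdb_line(3, "CA", "SER", "A", 2, 6, 0, 0),
    pdb_line(4, "CB", "SER", "A", 2, 7.5, 0, 0),
    pdb_line(5, "OG", "SER", "A", 2, 8.0, 0, 0),
    pdb_line(6, "CA", "GLY", "A", 3, 50, 50, 50),
    pdb_line(7, "O1", "LIG", "A", 9, 11.0, 0, 0, "HETATM"),
    pdb_line(8, "C1", "LIG", "A", 9, 4.0, 0, 0, "HETATM"),
    "END"
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  # Ser2: OG-O1 3.0 A (<= 3.5), CB-C1 3.5 A (<= 3.9) -> contact
  # Ala1: CB-C1 2.5 A hydrophobic only -> excluded by the AND rule
  expect_equal(detect_ligand_contacts(f, "LIG"), 2L)
  expect_error(detect_ligand_contacts(f, "XYZ"), "not found")
  # ligand far from everything
  lines2 <- c(lines[1:6],
              pdb_line(7, "O1", "LIG", "A", 9, 500, 0, 0, "HETATM"),
              pdb_line(8, "C1", "LIG", "A", 9, 500, 0, 0, "HETATM"), "END")
  writeLines(lines2, f)
  expect_equal(detect_ligand_contacts(f, "LIG"), integer(0))
})
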