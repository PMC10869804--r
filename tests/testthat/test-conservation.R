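test_that("alignment reading validates shape and identifiers", {
  msa <- read_alignment(write_fasta(c("s1", "s2", "s3"), c("ACD-", "ACDE", "AC-E")))
  expect_equal(length(msa$ids), 3L)
  expect_equal(msa$width, 4L)
  expect_error(read_alignment(write_fasta(c("a", "b"), c("ACD", "AC"))), "ragged")
  expect_error(read_alignment(write_fasta(c("a", "a"), c("ACD", "ACD"))), "duplicate")
  ## a gap-only column is accepted and visible in the stats
  m2 <- read_alignment(write_fasta(c("a", "b"), c("A-C", "A-C")))
  st <- column_stats(m2, "a")
  expect_equal(st$gap_fraction[2], 1)
  expect_true(is.na(st$information[2]))
})

test_that("column statistics match hand counts", {
  ## AAAA: pure nonpolar, zero entropy
  st <- column_stats(dimerlab:::msa_from_strings(paste0("s", 1:4),
                                                 c("A", "A", "A", "A")), "s1")
  expect_equal(st$freq_A, 1)
  expect_equal(st$class_nonpolar, 1)
  expect_equal(st$information, log2(20), tolerance = 1e-9)
  ## DDEE: all acidic, 1 bit of entropy
  st2 <- column_stats(dimerlab:::msa_from_strings(paste0("s", 1:4),
                                                  c("D", "D", "E", "E")), "s1")
  expect_equal(st2$class_acidic, 1)
  expect_equal(st2$freq_D, 0.5)
  expect_equal(st2$freq_E, 0.5)
  expect_equal(st2$information, log2(20) - 1, tolerance = 1e-9)
  ## AAAG-: gaps count in the denominator
  st3 <- column_stats(dimerlab:::msa_from_strings(paste0("s", 1:5),
                                                  c("A", "A", "A", "G", "-")), "s1")
  expect_equal(st3$gap_fraction, 0.2)
  expect_equal(st3$class_nonpolar, 0.8)   # A and G are both nonpolar
  expect_equal(st3$freq_A, 0.6)
  ## a uniform 20-residue column carries zero information
  st4 <- column_stats(dimerlab:::msa_from_strings(sprintf("u%02d", 1:20),
                                                  dimerlab:::.aa20), "u01")
  expect_equal(st4$information, 0, tolerance = 1e-9)
})

test_that("reference numbering skips reference gaps and covers each position once", {
  msa <- dimerlab:::msa_from_strings(c("ref", "h1"), c("A-CD-E", "AQCDWE"))
  st <- column_stats(msa, "ref")
  expect_equal(st$native_num, c(1L, NA, 2L, 3L, NA, 4L))
  nn <- st$native_num[!is.na(st$native_num)]
  expect_equal(sort(nn), seq_along(nn))
})

test_that("conservation flags use a strict threshold and shrink as it rises", {
  ## 4/5 = 0.8 exactly: NOT flagged under the strict > rule
  msa <- dimerlab:::msa_from_strings(paste0("s", 1:5), c("A", "A", "A", "A", "D"))
  st <- column_stats(msa, "s1")
  expect_equal(nrow(flag_conserved(st, 0.8)), 0L)
  expect_equal(flag_conserved(st, 0.79)$class, "nonpolar")
  msa2 <- dimerlab:::msa_from_strings(paste0("s", 1:5), rep("A", 5))
  expect_equal(flag_conserved(column_stats(msa2, "s1"), 0.8)$class, "nonpolar")
  ## monotone in the threshold on a random alignment
  sim <- simulate_msa(paste(rep("ADKL", 8), collapse = ""), rep(0.7, 32),
                      n_seqs = 60, seed = 12)
  stats <- column_stats(sim$msa, "reference")
  f1 <- flag_conserved(stats, 0.6)$column
  f2 <- flag_conserved(stats, 0.75)$column
  f3 <- flag_conserved(stats, 0.9)$column
  expect_true(all(f2 %in% f1))
  expect_true(all(f3 %in% f2))
  ## permuting sequence order changes nothing
  perm <- sim$msa
  o <- sample(seq_along(perm$ids))
  perm$ids <- perm$ids[o]
  perm$matrix <- perm$matrix[o, , drop = FALSE]
  rownames(perm$matrix) <- perm$ids
  expect_equal(column_stats(perm, "reference")[, -1],
               column_stats(sim$msa, "reference")[, -1])
})

test_that("majority consensus follows the documented tie and gap rules", {
  msa <- dimerlab:::msa_from_strings(paste0("s", 1:4),
                                     c("ACAA", "AC--", "CA--", "CAA-"))
  ## col1 50/50 A/C -> A (alphabetical); col4 gap fraction 0.75 -> lowercase
  expect_equal(consensus(msa), "AAAa")
  same <- dimerlab:::msa_from_strings(c("x", "y"), c("MKV", "MKV"))
  expect_equal(consensus(same), "MKV")
})

test_that("a simulated homolog set hands back its designed conservation pattern", {
  ref <- paste(rep(c("A", "L", "E", "K", "V", "F", "D", "R", "S", "T"), 4),
               collapse = "")
  profile <- rep(0.3, 40)
  conserved <- c(5L, 12L, 19L, 26L, 33L)
  profile[conserved] <- 0.85
  sim <- simulate_msa(ref, profile, n_seqs = 200, seed = 42)
  fl <- flag_conserved(column_stats(sim$msa, "reference"), 0.80)
  expect_setequal(fl$column, sim$truth$conserved_gt80)
  ## column 19 (Ser) belongs to no coloured class, so the ground truth
  ## excludes it even at 85% identity
  expect_false(19L %in% sim$truth$conserved_gt80)
  ## full conservation reproduces the reference in every row
  all1 <- simulate_msa("ALEK", rep(1, 4), n_seqs = 10, seed = 1)
  expect_true(all(apply(all1$msa$matrix, 1, paste, collapse = "") == "ALEK"))
})
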