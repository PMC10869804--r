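test_that("PDB write/read round trip preserves topology, coordinates and B-factors", {
  toy <- make_toy_dimer()
  tmp <- tempfile(fileext = ".pdb")
  write_annotated_structure(toy$structure, NULL, tmp)
  s2 <- read_structure(tmp)
  expect_equal(nrow(s2$atoms), nrow(toy$structure$atoms))
  expect_equal(sort(unique(s2$atoms$chain)), c("A", "B"))
  ## PDB fixed format carries 3 decimals
  expect_lt(max(abs(model_coords(s2, 1) - model_coords(toy$structure, 1))), 1e-3)

  ## annotation lands in the B column of the right residue, 0 elsewhere
  vals <- data.frame(chain = "A", resno = 5L, value = 0.12)
  tmp2 <- tempfile(fileext = ".pdb")
  write_annotated_structure(toy$structure, vals, tmp2)
  p <- bio3d::read.pdb(tmp2)
  expect_equal(unique(p$atom$b[p$atom$chain == "A" & p$atom$resno == 5]), 0.12)
  expect_equal(unique(p$atom$b[p$atom$resno != 5]), 0)
  ## empty annotation map -> all-zero B
  tmp3 <- tempfile(fileext = ".pdb")
  write_annotated_structure(toy$structure, NULL, tmp3)
  expect_equal(unique(bio3d::read.pdb(tmp3)$atom$b), 0)
})

test_that("multi-model ensembles read back whole; topology mismatches are rejected", {
  toy <- make_toy_dimer()
  ens <- perturb_ensemble(toy$structure, 0.3, 0.5, n_models = 4L, seed = 2)
  tmp <- tempfile(fileext = ".pdb")
  write_annotated_structure(ens$structure, NULL, tmp, model = NULL)
  s2 <- read_structure(tmp)
  expect_equal(n_models(s2), 4L)
  expect_lt(max(abs(s2$xyz - ens$structure$xyz)), 1e-3)

  ## hand-build a file whose second MODEL lost an atom
  lines <- readLines(tmp)
  starts <- grep("^MODEL", lines)
  atom2 <- grep("^ATOM", lines)
  drop <- atom2[atom2 > starts[2]][1]
  writeLines(lines[-drop], tmp)
  expect_error(read_structure(tmp), "topology mismatch.*model 2")
})

test_that("mmCIF input parses identically to the equivalent PDB", {
  cs <- read_structure(test_path("fixtures", "mini_synthetic.cif"))
  ## the fixture is the first 8 residues of chain A of the deterministic toy dimer
  toy <- make_toy_dimer()
  keep <- toy$structure$atoms$chain == "A" & toy$structure$atoms$resno <= 8
  expect_equal(nrow(cs$atoms), sum(keep))
  expect_equal(cs$atoms$elety, toy$structure$atoms$elety[keep])
  expect_lt(max(abs(model_coords(cs, 1) - model_coords(toy$structure, 1)[keep, ])), 1e-3)
})

test_that("numbering map adds/subtracts the offset and round-trips exactly", {
  expect_identical(map_numbering(36L, numbering_map(14L), "native_to_file"), 50L)
  expect_identical(map_numbering(36L, numbering_map(0L), "native_to_file"), 36L)
  expect_identical(map_numbering(50L, numbering_map(14L), "file_to_native"), 36L)
  for (off in c(-7L, 0L, 3L, 14L)) {
    m <- numbering_map(off)
    x <- -50:120
    expect_identical(map_numbering(map_numbering(x, m, "native_to_file"), m,
                                   "file_to_native"), x)
  }
})

test_that("selections filter by chain, native range and atom class", {
  toy <- make_toy_dimer()
  s <- toy$structure
  ca <- apply_selection(s, 1, selection(chains = "A", ranges = c(1, 10),
                                        atom_class = "calpha"))
  expect_equal(nrow(ca), 10L)
  bb <- apply_selection(s, 1, selection(chains = "A", ranges = c(3, 14),
                                        atom_class = "backbone"))
  expect_equal(nrow(bb), 12L * 4L)
  ## backbone subset heavy subset all, on a hydrogen-free structure
  n_all <- nrow(apply_selection(s, 1, selection(chains = "A")))
  n_heavy <- nrow(apply_selection(s, 1, selection(chains = "A", atom_class = "heavy")))
  n_bb <- nrow(apply_selection(s, 1, selection(chains = "A", atom_class = "backbone")))
  expect_lte(n_bb, n_heavy)
  expect_lte(n_heavy, n_all)
  ## native ranges are translated through the map before filtering
  off <- apply_selection(s, 1, selection(chains = "A", ranges = c(-13, -4),
                                         atom_class = "calpha"),
                         map = numbering_map(14L))
  expect_equal(off$resno, 1:10)
  expect_error(apply_selection(s, 1, selection(chains = "A", ranges = c(200, 300))),
               class = "dimerlab_empty_selection")
  expect_error(selection(ranges = list(c(5, 1))), "empty selection range")
  expect_error(selection(ranges = list(c(1, 10), c(5, 20))), "overlap")
})
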