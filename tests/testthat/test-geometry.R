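test_that("Kabsch superposition recovers rigid motions and beats random rotations", {
  set.seed(7)
  A <- matrix(stats::rnorm(30), 10, 3)
  ## identical sets: identity rotation, zero rmsd
  sp0 <- kabsch_superpose(A, A)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-10)
  ## 90 degrees about z plus translation: zero rmsd, proper rotation
  R90 <- dimerlab:::rotation_about(c(0, 0, 1), pi / 2)
  B <- A %*% t(R90) + matrix(rep(c(3, -1, 7), each = 10), 10, 3)
  sp <- kabsch_superpose(A, B)
  expect_lt(sp$rmsd, 1e-10)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(apply_superposition(B, sp) - A)), 1e-9)
  ## optimality: no rotation out of 1000 random ones does better on a noisy copy
  noisy <- A + matrix(stats::rnorm(30, sd = 0.3), 10, 3)
  spn <- kabsch_superpose(A, noisy)
  Ac <- scale(A, scale = FALSE)
  nc <- scale(noisy, scale = FALSE)
  oracle <- vapply(seq_len(1000), function(i) {
    sqrt(mean(rowSums((nc %*% random_rotation() - Ac)^2)))
  }, numeric(1))
  expect_lte(spn$rmsd, min(oracle) + 1e-12)
  ## degenerate input is refused
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("ensemble RMSD-to-mean matches the Gaussian closed form and orders atom classes", {
  toy <- make_toy_dimer()
  ## identical models: zero spread
  ens0 <- perturb_ensemble(toy$structure, 0, 0, n_models = 5L, seed = 1)
  expect_equal(ensemble_rmsd(ens0$structure, selection(atom_class = "backbone"))$mean_rmsd,
               0, tolerance = 1e-9)
  ## sigma > 0: mean RMSD-to-mean ~ sigma*sqrt(3)*sqrt((m-1)/m) within 5%
  ens <- perturb_ensemble(toy$structure, 0.45, 0.75, n_models = 20L, seed = 7)
  bb <- ensemble_rmsd(ens$structure, selection(atom_class = "backbone"))
  expect_equal(bb$mean_rmsd, ens$truth$expected_rmsd_backbone, tolerance = 0.05)
  ## heavier side-chain noise makes heavy-atom spread exceed backbone spread
  hv <- ensemble_rmsd(ens$structure, selection(atom_class = "heavy"))
  expect_gt(hv$mean_rmsd, bb$mean_rmsd)
  ## rigid-motion invariance: pre-rotating one model changes nothing
  ens2 <- ens$structure
  R <- dimerlab:::rotation_about(c(1, 2, -1), 0.8)
  ens2$xyz[, , 3] <- ens2$xyz[, , 3] %*% t(R) + matrix(rep(c(4, 4, -2), each = dim(ens2$xyz)[1]), ncol = 3)
  bb2 <- ensemble_rmsd(ens2, selection(atom_class = "backbone"))
  expect_equal(bb2$mean_rmsd, bb$mean_rmsd, tolerance = 1e-6)
  expect_error(ensemble_rmsd(toy$structure), "at least 2 models")
})

test_that("dihedral windows assign helix, strand and coil as constructed", {
  ## ideal poly-Ala helix: one helix segment over all assignable residues
  ss <- assign_secondary_structure(poly_ala_helix(12))
  hel <- ss$segments[ss$segments$kind == "helix", ]
  expect_equal(nrow(hel), 1L)
  expect_equal(c(hel$start, hel$end), c(2L, 11L))
  ## paired extended strands with an inter-chain ladder: strand on both chains
  ss2 <- assign_secondary_structure(toy_sheet(n = 8))
  str_seg <- ss2$segments[ss2$segments$kind == "strand", ]
  expect_equal(sort(unique(str_seg$chain)), c("A", "B"))
  expect_true(all(str_seg$end - str_seg$start + 1 >= 2))
  ## the toy dimer's designed boundaries are recovered exactly on both chains
  toy <- make_toy_dimer()
  ss3 <- assign_secondary_structure(toy$structure)
  for (ch in c("A", "B")) {
    segs <- ss3$segments[ss3$segments$chain == ch & ss3$segments$kind != "coil", ]
    expect_equal(segs$kind, c("helix", "helix", "strand"))
    expect_equal(segs$start, c(toy$truth$helices$alpha1[1], toy$truth$helices$alpha2[1],
                               toy$truth$strand[1]))
    expect_equal(segs$end, c(toy$truth$helices$alpha1[2], toy$truth$helices$alpha2[2],
                             toy$truth$strand[2]))
  }
})

test_that("helix axes align with construction and transform equivariantly", {
  ca <- ideal_helix_ca(12)
  ax <- helix_axis(ca)
  expect_lt(interhelix_angle(ax, c(0, 0, 1)), 1)
  R <- dimerlab:::rotation_about(c(1, -1, 2), 1.2)
  ax_r <- helix_axis(ca %*% t(R))
  expect_lt(interhelix_angle(ax_r, as.numeric(R %*% c(0, 0, 1))), 1)
  expect_error(helix_axis(ca[1:4, ]), "at least 5")
})

test_that("inter-helix angles respect orientation and symmetry", {
  expect_equal(interhelix_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(interhelix_angle(c(0, 0, 1), c(0, 1, 0)), 90)
  a <- dimerlab:::unit(c(1, 2, 3))
  b <- dimerlab:::unit(c(-2, 1, 0.5))
  expect_equal(interhelix_angle(a, b), interhelix_angle(b, a))
  expect_equal(interhelix_angle(a, -b), 180 - interhelix_angle(a, b))
})

test_that("structure comparison is zero for rigid copies and optimal for a bent copy", {
  toy <- make_toy_dimer()
  expect_equal(compare_structures(toy$structure, toy$structure,
                                  chains_a = "A", chains_b = "A")$rmsd, 0,
               tolerance = 1e-9)
  moved <- toy$structure
  R <- dimerlab:::rotation_about(c(0, 1, 1), 2.1)
  moved$xyz[, , 1] <- moved$xyz[, , 1] %*% t(R) + 8
  expect_lt(compare_structures(toy$structure, moved, chains_a = "A", chains_b = "A")$rmsd,
            1e-9)
  ## hinge-bent copy: Kabsch result is no worse than any candidate rotation,
  ## including a fine grid about the known hinge axis and the identity
  ca <- apply_selection(toy$structure, 1, selection(chains = "A", atom_class = "calpha"))
  ref <- as.matrix(ca[, c("x", "y", "z")])
  hinge_axis <- c(0, 0, 1)
  pivot <- ref[16, ]
  bent <- ref
  Rh <- dimerlab:::rotation_about(hinge_axis, 15 * pi / 180)
  bent[17:36, ] <- sweep(sweep(bent[17:36, ], 2, pivot) %*% t(Rh), 2, pivot, `+`)
  sp <- kabsch_superpose(ref, bent)
  refc <- scale(ref, scale = FALSE)
  bentc <- scale(bent, scale = FALSE)
  grid <- seq(-20, 20, by = 0.5) * pi / 180
  cand <- vapply(grid, function(th) {
    Rc <- dimerlab:::rotation_about(hinge_axis, th)
    sqrt(mean(rowSums((bentc %*% t(Rc) - refc)^2)))
  }, numeric(1))
  set.seed(3)
  cand_rand <- vapply(seq_len(2000), function(i) {
    sqrt(mean(rowSums((bentc %*% random_rotation() - refc)^2)))
  }, numeric(1))
  expect_lte(sp$rmsd, min(cand) + 1e-12)
  expect_lte(sp$rmsd, min(cand_rand) + 1e-12)
  ## and the dense 1D grid about the true hinge axis comes close to optimal,
  ## confirming the superposition engine finds the genuine minimum
  expect_equal(sp$rmsd, min(cand), tolerance = 0.05)
})
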