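test_that("shift tables parse and malformed input is rejected with clear errors", {
  df <- data.frame(residue = c(3L, 5L, 20L), aa = c("A", "L", "K"),
                   H_ppm = c(8.1, 7.9, 8.5), N_ppm = c(118.2, 121.0, 125.5))
  tab <- read_shift_table(write_shift_tsv(df))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$residue, c(3L, 5L, 20L))
  ## prolines are simply absent rows, not errors
  expect_false(4L %in% tab$residue)
  dup <- rbind(df, data.frame(residue = 20L, aa = "K", H_ppm = 8.5, N_ppm = 125.5))
  expect_error(read_shift_table(write_shift_tsv(dup)), "duplicate residue.*20")
  expect_error(read_shift_table(write_shift_tsv(df[, -4])), "missing column")
  bad <- df
  bad$H_ppm <- as.character(bad$H_ppm)
  bad$H_ppm[2] <- "x"
  expect_error(read_shift_table(write_shift_tsv(bad)), "non-numeric")
})

test_that("weighted CSP formulas reproduce hand-computed values in both variants", {
  mk <- function(res, h, n) data.frame(residue = res, aa = "A", H_ppm = h, N_ppm = n)
  ## no change: d = 0, not significant
  r0 <- compute_csp(mk(1, 8, 120), mk(1, 8, 120))
  expect_equal(r0$csp$d, 0)
  expect_false(r0$csp$significant)
  ## dH = 0.1, dN = 0: d = 0.1*sqrt(0.5) = 0.070711 > 0.05
  r1 <- compute_csp(mk(1, 8, 120), mk(1, 8.1, 120))
  expect_equal(r1$csp$d, 0.070711, tolerance = 1e-4)
  expect_true(r1$csp$significant)
  ## dH = 0, dN = 0.5: conventional weighting 0.049497 (below threshold),
  ## as-printed weighting 0.132288 (above) -- the variant flips the call
  free <- mk(1, 8, 120)
  bound <- mk(1, 8, 120.5)
  rd <- compute_csp(free, bound, csp_config())
  expect_equal(rd$csp$d, 0.049497, tolerance = 1e-4)
  expect_false(rd$csp$significant)
  rp <- compute_csp(free, bound, csp_config(formula_variant = "as_printed"))
  expect_equal(rp$csp$d, 0.132288, tolerance = 1e-4)
  expect_true(rp$csp$significant)
})

test_that("CSP obeys its symmetry, scaling and bounding properties", {
  set.seed(11)
  n <- 30
  free <- data.frame(residue = 1:n, aa = "A", H_ppm = runif(n, 7, 9.5),
                     N_ppm = runif(n, 105, 130))
  bound <- free
  bound$H_ppm <- bound$H_ppm + rnorm(n, sd = 0.05)
  bound$N_ppm <- bound$N_ppm + rnorm(n, sd = 0.3)
  d_fb <- compute_csp(free, bound)$csp$d
  ## swap-invariance: depends only on |delta|
  expect_equal(compute_csp(bound, free)$csp$d, d_fb)
  ## linear scaling of both deltas scales d linearly
  bound3 <- free
  bound3$H_ppm <- free$H_ppm + 3 * (bound$H_ppm - free$H_ppm)
  bound3$N_ppm <- free$N_ppm + 3 * (bound$N_ppm - free$N_ppm)
  expect_equal(compute_csp(free, bound3)$csp$d, 3 * d_fb, tolerance = 1e-12)
  ## lower bound: d >= sqrt(0.5)*|dH|, equality at dN = 0
  expect_true(all(d_fb >= sqrt(0.5) * abs(bound$H_ppm - free$H_ppm) - 1e-12))
  boundH <- free
  boundH$H_ppm <- free$H_ppm + 0.2
  expect_equal(compute_csp(free, boundH)$csp$d,
               rep(sqrt(0.5) * 0.2, n), tolerance = 1e-12)
  ## significant set shrinks monotonically with the threshold
  sets <- lapply(c(0.01, 0.05, 0.1), function(th) {
    r <- compute_csp(free, bound, csp_config(threshold = th))
    r$csp$native_num[r$csp$significant]
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("unmatched residues are reported, never dropped silently", {
  sim <- simulate_shift_tables(n_residues = 40, binding_site = 20:25,
                               effect_size = 0.3, prolines = c(7L, 18L),
                               dropped_bound = c(22L, 30L), seed = 5)
  res <- compute_csp(sim$free, sim$bound)
  expect_setequal(res$unmatched_free, c(22L, 30L))
  expect_equal(length(res$unmatched_bound), 0L)
  expect_false(any(c(22L, 30L) %in% res$csp$native_num))
  expect_error(compute_csp(sim$free, transform(sim$free, residue = residue + 100)),
               "share no residues")
})

test_that("titration saturation is declared once consecutive spectra stop moving", {
  tt <- simulate_shift_titration(ratios = c(0.25, 0.5, 0.75, 1, 1.2),
                                 effect_size = 0.2, noise = 0.001, seed = 3)
  sat <- saturation_check(tt$tables)
  ## identical-state pair (1:1 vs 1.2:1) differs only by sigma = 0.001 noise
  expect_true(sat$saturated[nrow(sat)])
  ## sub-stoichiometric steps move by effect_size/4 >> threshold
  expect_false(any(sat$saturated[1:3]))
  ## identical tables give exactly zero change
  same <- saturation_check(list(tt$tables[[1]], tt$tables[[1]]))
  expect_equal(same$max_delta_d, 0)
  expect_true(same$saturated)
  expect_error(saturation_check(tt$tables[1]), "at least 2")
})

test_that("CSP mapping annotates structures and localises the binding site", {
  toy <- make_toy_dimer()
  sim <- simulate_shift_tables(n_residues = 36, binding_site = 20:28,
                               effect_size = 0.2, seed = 9)
  res <- compute_csp(sim$free, sim$bound)
  tmp <- tempfile(fileext = ".pdb")
  mp <- map_csp(res, toy$structure, numbering_map(0L), path = tmp,
                region = c(17, 28))
  expect_setequal(mp$significant, 20:28)
  expect_equal(mp$fraction_in_region, 1)
  expect_equal(length(mp$unmapped), 0L)
  p <- bio3d::read.pdb(tmp)
  b25 <- unique(p$atom$b[p$atom$resno == 25 & p$atom$chain == "A"])
  expect_equal(b25, round(res$csp$d[res$csp$native_num == 25], 2))
  ## all-zero CSPs: all-zero B, empty significant set
  res0 <- compute_csp(sim$free, sim$free)
  tmp0 <- tempfile(fileext = ".pdb")
  mp0 <- map_csp(res0, toy$structure, numbering_map(0L), path = tmp0)
  expect_equal(length(mp0$significant), 0L)
  expect_equal(unique(bio3d::read.pdb(tmp0)$atom$b), 0)
  ## residues beyond the coordinates land in the unmapped report
  sim2 <- simulate_shift_tables(n_residues = 40, binding_site = 38:40,
                                effect_size = 0.2, seed = 10)
  mp2 <- map_csp(compute_csp(sim2$free, sim2$bound), toy$structure, numbering_map(0L))
  expect_setequal(mp2$unmapped, 37:40)
})
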