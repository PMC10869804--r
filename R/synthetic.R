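## ---- internal-coordinate backbone construction ------------------------------

## Place atom D given atoms A, B, C with bond |CD|, angle B-C-D (deg) and
## torsion A-B-C-D (deg) -- the NeRF construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  chi <- torsion * pi / 180
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  M <- cbind(bc, pracma_cross(n, bc), n)
  d_local <- c(-bond * cos(th), bond * sin(th) * cos(chi), -bond * sin(th) * sin(chi))
  as.numeric(c + M %*% d_local)
}

## Ideal peptide geometry (Engh-Huber-like averages)
.bb <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.521,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.8, ang_c_ca_cb = 110.1, tor_cb = 122.6)

## Build an ideal-geometry backbone (N, CA, C, O + CB) from per-residue
## phi/psi. phi[1] is unused. Returns a list of n x 3 matrices.
build_backbone <- function(phi, psi, omega = 180, with_cb = TRUE) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.bb$n_ca, 0, 0)
  th <- (180 - .bb$ang_n_ca_c) * pi / 180
  C[1, ] <- CA[1, ] + .bb$ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], .bb$c_n, .bb$ang_ca_c_n, psi[i])
      CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], .bb$n_ca, .bb$ang_c_n_ca, omega)
      C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], .bb$ca_c,
                               .bb$ang_n_ca_c, phi[i + 1])
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], .bb$c_o, .bb$ang_ca_c_o, psi[i] + 180)
    } else {
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], .bb$c_o, .bb$ang_ca_c_o, 0)
    }
    if (with_cb) {
      CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ], .bb$ca_cb, .bb$ang_c_ca_cb,
                            -.bb$tor_cb)
    }
  }
  out <- list(N = N, CA = CA, C = C, O = O)
  if (with_cb) out$CB <- CB
  out
}

backbone_to_atoms <- function(bb, chain, resname = "ALA", resno = NULL) {
  n <- nrow(bb$N)
  if (is.null(resno)) resno <- seq_len(n)
  names <- c("N", "CA", "C", "O", if (!is.null(bb$CB)) "CB")
  rows <- list()
  for (i in seq_len(n)) {
    for (nm in names) {
      ## glycine carries no CB
      if (nm == "CB" && resname[min(i, length(resname))] == "GLY") next
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = resno[i],
        resname = if (length(resname) == 1L) resname else resname[i],
        elety = nm, element = substr(nm, 1, 1), is_h = FALSE,
        x = bb[[nm]][i, 1], y = bb[[nm]][i, 2], z = bb[[nm]][i, 3],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

atoms_to_structure <- function(at, id = "synthetic") {
  new_structure(at[, c("chain", "resno", "resname", "elety", "element", "is_h")],
                as.matrix(at[, c("x", "y", "z")]), id = id)
}

#' Ideal parametric alpha-helix Calpha trace
#'
#' @param n number of residues.
#' @param rise rise per residue, Angstroms (default 1.5).
#' @param twist turn per residue, degrees (default 100).
#' @param radius helix radius of the Calpha atoms, Angstroms (default 2.3).
#' @return `n x 3` matrix; the helix axis is +z.
#' @export
ideal_helix_ca <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  t <- (seq_len(n) - 1) * twist * pi / 180
  cbind(radius * cos(t), radius * sin(t), (seq_len(n) - 1) * rise)
}

## ---- toy dimer --------------------------------------------------------------

.toy_phi_psi <- function() {
  ## 36 residues: coil 1-2, helix 3-14, loop 15-16, helix 17-28, loop 29-30,
  ## strand 31-34, tail 35-36
  kind <- rep("coil", 36)
  kind[3:14] <- "helix"
  kind[17:28] <- "helix"
  kind[31:34] <- "strand"
  phi <- ifelse(kind == "helix", -57, ifelse(kind == "strand", -120, 60))
  psi <- ifelse(kind == "helix", -47, ifelse(kind == "strand", 130, 40))
  list(phi = phi, psi = psi, kind = kind)
}

#' Synthetic C2-symmetric two-chain dimer with known ground truth
#'
#' Builds one 36-residue protomer with ideal backbone geometry -- two
#' alpha-helices (native 3-14 and 17-28) and one extended strand (31-34)
#' joined by short loops -- orients it so the strand lies along the y axis
#' at `x = contact_distance / 2`, and generates the partner chain by an
#' exact C2 rotation about z. At the default contact distance the two
#' strands pair into a small antiparallel inter-chain sheet; moving the
#' chains apart removes all contacts. Residues are ALA (full N, CA, C, O,
#' CB), coordinate numbering equals native numbering.
#'
#' @param contact_distance distance between the two strand centres,
#'   Angstroms. The default gives a packed interface with an inter-chain
#'   backbone hydrogen-bond pair across the strand seam; 100 gives two
#'   isolated protomers.
#' @param registry_shift relative shift of the two strands along the strand
#'   axis, Angstroms; the default places the seam in antiparallel
#'   beta-sheet-like registry.
#' @param seed unused for geometry (the construction is deterministic) but
#'   recorded in the ground truth for provenance.
#' @return list with `structure` (a 2-chain `structure3d`) and `truth`
#'   (helix/strand boundaries, contact distance, geometric interface
#'   residues: residues with a heavy atom within 6 Angstroms of the partner
#'   chain).
#' @export
make_toy_dimer <- function(contact_distance = 5.25, registry_shift = -2.6, seed = 1L) {
  tors <- .toy_phi_psi()
  bb <- build_backbone(tors$phi, tors$psi)
  ca <- bb$CA
  ## orient: strand axis (31-34) -> +y, strand centre -> origin
  v <- unit(ca[34, ] - ca[31, ])
  R1 <- rotation_to(v, c(0, 1, 0))
  ctr <- colMeans(ca[31:34, ])
  tf <- function(m) sweep(m, 2, ctr) %*% t(R1)
  bb <- lapply(bb, tf)
  ## rotate about y so the chain body points to +x
  c_all <- colMeans(do.call(rbind, bb))
  cp <- c(c_all[1], 0, c_all[3])
  ang <- atan2(cp[3], cp[1])
  R2 <- rotation_about(c(0, 1, 0), ang)   # maps cp into +x half-plane
  bb <- lapply(bb, function(m) m %*% t(R2))
  bb <- lapply(bb, function(m) sweep(m, 2, c(contact_distance / 2, registry_shift / 2, 0), `+`))
  at_a <- backbone_to_atoms(bb, chain = "A")
  flip <- diag(c(-1, -1, 1))
  at_b <- at_a
  at_b$chain <- "B"
  at_b[, c("x", "y", "z")] <- as.matrix(at_a[, c("x", "y", "z")]) %*% t(flip)
  at <- rbind(at_a, at_b)
  s <- atoms_to_structure(at, id = "toy_dimer")
  ## geometric interface ground truth: any heavy atom within 6 A of partner
  xa <- as.matrix(at_a[, c("x", "y", "z")])
  xb <- as.matrix(at_b[, c("x", "y", "z")])
  d <- sqrt(pmax(outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb), 0))
  close_a <- unique(at_a$resno[apply(d, 1, min) < 6])
  truth <- list(seed = seed,
                helices = list(alpha1 = c(3L, 14L), alpha2 = c(17L, 28L)),
                strand = c(31L, 34L),
                n_res = 36L,
                contact_distance = contact_distance,
                interface_residues = sort(close_a))
  list(structure = s, truth = truth)
}

## rotation matrix taking unit vector a to unit vector b
rotation_to <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- pracma_cross(a, b)
  s <- vnorm(v)
  if (s < 1e-12) {
    if (sum(a * b) > 0) return(diag(3))
    ## opposite: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) unit(pracma_cross(a, c(1, 0, 0))) else unit(pracma_cross(a, c(0, 1, 0)))
    return(rotation_about(p, pi))
  }
  rotation_about(v / s, atan2(s, sum(a * b)))
}

#' Gaussian coordinate-scatter ensemble from a single-model structure
#'
#' Emulates the positional scatter of an NMR ensemble: each model is an
#' independent copy with isotropic Gaussian displacements, backbone atoms
#' (N, CA, C, O) with `sigma_backbone` and all other atoms with
#' `sigma_sidechain`. For m models the expected RMSD-to-mean is
#' `sigma * sqrt(3) * sqrt((m - 1) / m)`.
#'
#' @param structure single-model `structure3d`.
#' @param sigma_backbone,sigma_sidechain per-coordinate displacement SD,
#'   Angstroms.
#' @param n_models ensemble size.
#' @param seed RNG seed.
#' @return list with `structure` (the ensemble) and `truth` (sigmas, the
#'   closed-form expected RMSD-to-mean per atom class).
#' @export
perturb_ensemble <- function(structure, sigma_backbone = 0.5, sigma_sidechain = 1.0,
                             n_models = 20L, seed = 1L) {
  stopifnot(n_models(structure) == 1L, n_models >= 2L)
  at <- structure$atoms
  sig <- ifelse(at$elety %in% c("N", "CA", "C", "O"), sigma_backbone, sigma_sidechain)
  base <- model_coords(structure, 1L)
  arr <- array(NA_real_, dim = c(nrow(at), 3, n_models))
  with_seed(seed, {
    for (m in seq_len(n_models)) {
      arr[, , m] <- base + matrix(stats::rnorm(3 * nrow(at), sd = rep(sig, 3)),
                                  ncol = 3)
    }
  })
  fac <- sqrt(3) * sqrt((n_models - 1) / n_models)
  truth <- list(seed = seed, sigma_backbone = sigma_backbone,
                sigma_sidechain = sigma_sidechain, n_models = n_models,
                expected_rmsd_backbone = sigma_backbone * fac,
                expected_rmsd_sidechain = sigma_sidechain * fac)
  list(structure = new_structure(at, arr, id = paste0(structure$id, "_ensemble")),
       truth = truth)
}

## ---- chemical shifts --------------------------------------------------------

#' Simulate free/bound amide shift tables with a known binding site
#'
#' Baseline amide shifts are drawn uniformly from realistic ranges (1H:
#' 7-9.5 ppm, 15N: 105-130 ppm). Binding-site residues are displaced by
#' `effect_size` ppm in both dimensions in the bound state; Gaussian noise
#' of SD `noise` (ppm) is added to the bound table. Prolines (no amide) are
#' dropped from both tables; `dropped_bound` residues are removed from the
#' bound table only, emulating peaks broadened beyond detection in slow
#' exchange.
#'
#' @param n_residues chain length (native numbering 1..n).
#' @param binding_site integer vector of perturbed residues.
#' @param effect_size displacement, ppm, applied to both 1H and 15N.
#' @param noise Gaussian SD, ppm.
#' @param seed RNG seed.
#' @param prolines residues absent from both tables.
#' @param dropped_bound residues absent from the bound table only.
#' @return list `free`, `bound` (shift tables) and `truth` (site, expected
#'   weighted CSP at zero noise for both formula variants).
#' @export
simulate_shift_tables <- function(n_residues = 63L, binding_site = 45:54,
                                  effect_size = 0.2, noise = 0, seed = 1L,
                                  prolines = integer(0), dropped_bound = integer(0)) {
  res <- setdiff(seq_len(n_residues), prolines)
  with_seed(seed, {
    free <- data.frame(residue = res,
                       aa = sample(setdiff(.aa20, "P"), length(res), replace = TRUE),
                       H_ppm = stats::runif(length(res), 7, 9.5),
                       N_ppm = stats::runif(length(res), 105, 130),
                       stringsAsFactors = FALSE)
    bound <- free
    hit <- bound$residue %in% binding_site
    bound$H_ppm[hit] <- bound$H_ppm[hit] + effect_size
    bound$N_ppm[hit] <- bound$N_ppm[hit] + effect_size
    if (noise > 0) {
      bound$H_ppm <- bound$H_ppm + stats::rnorm(nrow(bound), sd = noise)
      bound$N_ppm <- bound$N_ppm + stats::rnorm(nrow(bound), sd = noise)
    }
    bound$exchange <- ifelse(hit, "slow", "fast")
    bound <- bound[!bound$residue %in% dropped_bound, , drop = FALSE]
  })
  truth <- list(seed = seed, binding_site = sort(intersect(binding_site, res)),
                effect_size = effect_size, noise = noise,
                expected_d_default = csp_formula(effect_size, effect_size, csp_config()),
                expected_d_as_printed = csp_formula(effect_size, effect_size,
                                                    csp_config(formula_variant = "as_printed")))
  list(free = free, bound = bound, truth = truth)
}

#' Simulate a titration series of bound-state shift tables
#'
#' Point k displaces binding-site residues by
#' `effect_size * min(ratio_k, 1)` (fast-exchange averaging up to
#' saturation at a 1:1 ligand:protomer ratio) plus Gaussian noise, so
#' consecutive points beyond saturation differ only by noise.
#'
#' @inheritParams simulate_shift_tables
#' @param ratios ligand:protomer ratios of the titration points.
#' @return list `tables` (list of shift tables, free state first), `truth`.
#' @export
simulate_shift_titration <- function(n_residues = 63L, binding_site = 45:54,
                                     effect_size = 0.2, ratios = c(0.25, 0.5, 0.75, 1, 1.25),
                                     noise = 0.001, seed = 1L) {
  base <- simulate_shift_tables(n_residues, binding_site, effect_size = 0,
                                noise = 0, seed = seed)
  free <- base$free
  tabs <- list(free)
  with_seed(seed + 1L, {
    for (r in ratios) {
      b <- free
      hit <- b$residue %in% binding_site
      b$H_ppm[hit] <- b$H_ppm[hit] + effect_size * min(r, 1)
      b$N_ppm[hit] <- b$N_ppm[hit] + effect_size * min(r, 1)
      if (noise > 0) {
        b$H_ppm <- b$H_ppm + stats::rnorm(nrow(b), sd = noise)
        b$N_ppm <- b$N_ppm + stats::rnorm(nrow(b), sd = noise)
      }
      tabs[[length(tabs) + 1L]] <- b
    }
  })
  list(tables = tabs,
       truth = list(seed = seed, ratios = ratios, effect_size = effect_size,
                    noise = noise, binding_site = binding_site,
                    saturated_from = which(ratios >= 1)[1] + 1L))
}

## ---- curves -----------------------------------------------------------------

#' Simulate a fluorescence-polarization titration
#'
#' Hyperbolic 1:1 binding signal plus Gaussian noise.
#'
#' @param kd dissociation constant, micromolar (protomer units).
#' @param p_free,p_bound baseline and saturation polarization, mP.
#' @param concs protomer concentrations, micromolar.
#' @param noise_sd Gaussian noise SD, mP.
#' @param seed RNG seed.
#' @return list `conc`, `polarization`, `truth`.
#' @export
simulate_fp_titration <- function(kd = 3.1, p_free = 50, p_bound = 150,
                                  concs = exp(seq(log(0.25), log(50), length.out = 8)),
                                  noise_sd = 0.02 * abs(p_bound - p_free), seed = 1L) {
  p <- p_free + (p_bound - p_free) * concs / (kd + concs)
  if (noise_sd > 0) p <- with_seed(seed, p + stats::rnorm(length(p), sd = noise_sd))
  list(conc = concs, polarization = p,
       truth = list(kd = kd, p_free = p_free, p_bound = p_bound,
                    noise_sd = noise_sd, seed = seed))
}

#' Simulate a two-state thermal melt
#'
#' Forward model identical to [fit_two_state_thermal()]. With
#' `folded = FALSE` only the unfolded baseline is emitted (no transition),
#' emulating the melt of an already-unfolded variant.
#'
#' @param tm midpoint, Celsius.
#' @param dh van't Hoff enthalpy, kJ/mol.
#' @param baselines list with `folded` and `unfolded` `c(intercept, slope)`
#'   (signal units vs Kelvin).
#' @param T_grid temperatures, Celsius.
#' @param noise_sd Gaussian noise SD, signal units.
#' @param seed RNG seed.
#' @param folded emit the two-state transition (FALSE: baseline only).
#' @return list `temperature`, `signal`, `truth`.
#' @export
simulate_melt <- function(tm = 75, dh = 300,
                          baselines = list(folded = c(-20, 0.01), unfolded = c(-80, 0.08)),
                          T_grid = seq(25, 95, by = 1), noise_sd = 0, seed = 1L,
                          folded = TRUE) {
  T_K <- T_grid + 273.15
  bf <- baselines$folded[1] + baselines$folded[2] * T_K
  bu <- baselines$unfolded[1] + baselines$unfolded[2] * T_K
  f <- if (folded) two_state_fraction_thermal(T_K, tm + 273.15, dh) else rep(1, length(T_K))
  y <- (1 - f) * bf + f * bu
  if (noise_sd > 0) y <- with_seed(seed, y + stats::rnorm(length(y), sd = noise_sd))
  list(temperature = T_grid, signal = y,
       truth = list(tm = if (folded) tm else NA_real_, dh = dh,
                    baselines = baselines, noise_sd = noise_sd, seed = seed,
                    folded = folded))
}

#' Simulate a two-state urea denaturation
#'
#' Linear-extrapolation forward model identical to
#' [fit_two_state_chemical()]; the midpoint is `Cm = dg0 / m`.
#'
#' @param dg0 unfolding free energy in water, kJ/mol.
#' @param m m-value, kJ/mol/M.
#' @param baselines list `folded`/`unfolded` `c(intercept, slope)` (vs M).
#' @param u_grid denaturant concentrations, M.
#' @param noise_sd Gaussian noise SD.
#' @param seed RNG seed.
#' @param folded emit the transition (FALSE: unfolded baseline only).
#' @return list `denaturant`, `signal`, `truth` (including `cm`).
#' @export
simulate_urea <- function(dg0 = 25, m = 10,
                          baselines = list(folded = c(-20, 0.2), unfolded = c(-5, 0.3)),
                          u_grid = seq(0, 6, by = 0.25), noise_sd = 0, seed = 1L,
                          folded = TRUE) {
  bf <- baselines$folded[1] + baselines$folded[2] * u_grid
  bu <- baselines$unfolded[1] + baselines$unfolded[2] * u_grid
  f <- if (folded) two_state_fraction_chemical(u_grid, dg0, m) else rep(1, length(u_grid))
  y <- (1 - f) * bf + f * bu
  if (noise_sd > 0) y <- with_seed(seed, y + stats::rnorm(length(y), sd = noise_sd))
  list(denaturant = u_grid, signal = y,
       truth = list(dg0 = dg0, m = m, cm = if (folded) dg0 / m else NA_real_,
                    baselines = baselines, noise_sd = noise_sd, seed = seed,
                    folded = folded))
}

## ---- alignments -------------------------------------------------------------

#' Simulate a homolog alignment with a known conservation profile
#'
#' Sequence 1 is the reference itself; each of the remaining `n_seqs - 1`
#' rows keeps the reference residue at column j with probability
#' `profile[j]` and otherwise draws uniformly from the residues outside the
#' reference residue's class (so a column's class fraction tracks its
#' conservation level).
#'
#' @param reference reference sequence (1-letter string, no gaps).
#' @param profile per-column probability of keeping the reference residue.
#' @param n_seqs total number of sequences including the reference.
#' @param seed RNG seed.
#' @param classes class sets, see [residue_classes()].
#' @return list `msa`, `truth` (profile, per-column reference class,
#'   intended conserved columns at the 0.8 threshold).
#' @export
simulate_msa <- function(reference, profile, n_seqs = 200L, seed = 1L,
                         classes = residue_classes()) {
  ref <- strsplit(toupper(reference), "")[[1]]
  L <- length(ref)
  stopifnot(length(profile) == L, all(profile >= 0 & profile <= 1), n_seqs >= 2)
  class_of <- function(a) {
    for (cl in names(classes)) if (a %in% classes[[cl]]) return(cl)
    NA_character_
  }
  ref_class <- vapply(ref, class_of, character(1))
  pools <- lapply(seq_len(L), function(j) {
    if (!is.na(ref_class[j])) setdiff(.aa20, classes[[ref_class[j]]])
    else setdiff(.aa20, ref[j])
  })
  rows <- with_seed(seed, {
    vapply(seq_len(n_seqs - 1L), function(k) {
      keep <- stats::runif(L) < profile
      s <- ref
      for (j in which(!keep)) s[j] <- sample(pools[[j]], 1L)
      paste(s, collapse = "")
    }, character(1))
  })
  ids <- c("reference", sprintf("homolog_%03d", seq_len(n_seqs - 1L)))
  msa <- msa_from_strings(ids, c(paste(ref, collapse = ""), rows))
  truth <- list(seed = seed, profile = profile, ref_class = unname(ref_class),
                conserved_gt80 = which(profile > 0.8 & !is.na(ref_class)))
  list(msa = msa, truth = truth)
}

## ---- bundles ----------------------------------------------------------------

#' Write a complete synthetic input bundle to disk
#'
#' Generates every input the pipeline consumes (toy-dimer ensemble PDB,
#' free/bound shift tables, FP titration, thermal melt, urea curve, homolog
#' alignment) in the same formats real data would arrive in, plus a
#' `truth.json` recording every generating parameter.
#'
#' @param dir output directory (created).
#' @param seed master seed; sub-generators use fixed offsets from it.
#' @return invisibly, the truth list.
#' @export
write_synthetic_bundle <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  toy <- make_toy_dimer(seed = seed)
  write_annotated_structure(toy$structure, NULL, file.path(dir, "structure.pdb"))
  ens <- perturb_ensemble(toy$structure, sigma_backbone = 0.45,
                          sigma_sidechain = 0.75, n_models = 20L, seed = seed + 1L)
  write_annotated_structure(ens$structure, NULL,
                            file.path(dir, "structure_ensemble.pdb"), model = NULL)
  sh <- simulate_shift_tables(seed = seed + 2L, noise = 0.002)
  utils::write.table(sh$free, file.path(dir, "shifts_free.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sh$bound, file.path(dir, "shifts_bound.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fp <- simulate_fp_titration(seed = seed + 3L)
  utils::write.csv(data.frame(conc_uM = fp$conc, polarization_mP = fp$polarization),
                   file.path(dir, "fp_titration.csv"), row.names = FALSE)
  melt <- simulate_melt(noise_sd = 0.3, seed = seed + 4L)
  utils::write.csv(data.frame(temperature_C = melt$temperature, signal = melt$signal),
                   file.path(dir, "thermal_melt.csv"), row.names = FALSE)
  urea <- simulate_urea(noise_sd = 0.15, seed = seed + 5L)
  utils::write.csv(data.frame(urea_M = urea$denaturant, signal = urea$signal),
                   file.path(dir, "urea_denaturation.csv"), row.names = FALSE)
  ref <- paste(rep(c("A", "L", "E", "K", "V", "F", "D", "R", "G", "I"), length.out = 40),
               collapse = "")
  profile <- rep(0.3, 40)
  profile[c(5, 12, 19, 26, 33)] <- 0.9
  msa <- simulate_msa(ref, profile, n_seqs = 200L, seed = seed + 6L)
  lines <- paste0(">", msa$msa$ids, "\n",
                  apply(msa$msa$matrix, 1, paste, collapse = ""))
  writeLines(lines, file.path(dir, "homologs.fasta"))
  truth <- list(seed = seed, toy = toy$truth, ensemble = ens$truth,
                shifts = sh$truth, fp = fp$truth, melt = melt$truth,
                urea = urea$truth, msa = msa$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(truth)
}
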