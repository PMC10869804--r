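## ---- shared fixture builders -------------------------------------------------

atoms_df <- function(chain, resno, resname, elety, x, y, z) {
  data.frame(chain = chain, resno = resno, resname = resname, elety = elety,
             element = substr(gsub("[0-9]", "", elety), 1, 1), is_h = FALSE,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

single_atom_structure <- function(element = "C", elety = "CB") {
  at <- atoms_df("A", 1L, "ALA", elety, 0, 0, 0)
  at$element <- element
  dimerlab:::atoms_to_structure(at, "single")
}

## hand-built Glu/Lys pair: carboxylate O at origin, ammonium N on +x
make_glu_lys <- function(no_dist = 3.0) {
  glu <- atoms_df("A", rep(1L, 9), "GLU",
                  c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
                  x = c(-6.0, -5.0, -4.8, -5.2, -4.3, -3.0, -1.5, 0.0, -1.3),
                  y = c(1.0, 0.3, 1.0, 2.1, -0.8, -0.4, -0.2, 0.0, 0.9),
                  z = rep(0, 9))
  lys <- atoms_df("B", rep(1L, 9), "LYS",
                  c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
                  x = no_dist + c(6.0, 5.0, 4.8, 5.2, 4.3, 3.2, 2.1, 1.0, 0.0),
                  y = c(1.0, 0.3, 1.0, 2.1, -0.8, -0.4, -0.6, -0.3, 0.0),
                  z = rep(0, 9))
  dimerlab:::atoms_to_structure(rbind(glu, lys), "glu_lys")
}

## ideal poly-Ala helix as a single chain
poly_ala_helix <- function(n = 12) {
  bb <- dimerlab:::build_backbone(rep(-57, n), rep(-47, n))
  dimerlab:::atoms_to_structure(dimerlab:::backbone_to_atoms(bb, "A"), "poly_ala")
}

## antiparallel two-strand toy sheet (C2 image of one extended strand)
toy_sheet <- function(gap = 5.1, shift = 3.4, n = 6) {
  bb <- dimerlab:::build_backbone(rep(-120, n), rep(130, n), with_cb = FALSE)
  ca <- bb$CA
  v <- dimerlab:::unit(ca[n, ] - ca[1, ])
  R1 <- dimerlab:::rotation_to(v, c(0, 1, 0))
  ctr <- colMeans(ca)
  bb <- lapply(bb, function(m) sweep(m, 2, ctr) %*% t(R1))
  bb <- lapply(bb, function(m) sweep(m, 2, c(gap / 2, shift / 2, 0), `+`))
  at_a <- dimerlab:::backbone_to_atoms(bb, "A")
  at_b <- at_a
  at_b$chain <- "B"
  at_b[, c("x", "y", "z")] <- as.matrix(at_a[, c("x", "y", "z")]) %*%
    t(diag(c(-1, -1, 1)))
  dimerlab:::atoms_to_structure(rbind(at_a, at_b), "toy_sheet")
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotate_atoms <- function(at, R, shift = c(0, 0, 0)) {
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + shift[1]
  at$y <- xyz[, 2] + shift[2]
  at$z <- xyz[, 3] + shift[3]
  at
}

write_shift_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_fasta <- function(ids, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

## ---- independent brute-force SASA oracle ------------------------------------
## A deliberately plain reimplementation (own spiral derivation, per-neighbour
## point rejection loop) used only to cross-check the package engine.

oracle_sphere <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (1 + sqrt(5)) * (k - 0.5)
  cbind(r * cos(th), r * sin(th), z)
}

oracle_sasa <- function(atoms, n_points = 10000, probe = 1.4) {
  atoms <- atoms[!atoms$is_h, , drop = FALSE]
  rad <- dimerlab:::atom_radius(atoms$elety, atoms$resname, atoms$element,
                                dimerlab::default_radii())
  rp <- rad + probe
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  pts <- oracle_sphere(n_points)
  n <- nrow(xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * rp[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dij >= rp[i] + rp[j]) next    # sphere j cannot occlude sphere i
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
      free <- free & dj2 > rp[j]^2
      if (!any(free)) break
    }
    area[i] <- sum(free) / n_points * 4 * pi * rp[i]^2
  }
  data.frame(chain = atoms$chain, resno = atoms$resno, area = area,
             stringsAsFactors = FALSE)
}

oracle_dasa <- function(structure, n_points = 10000) {
  at <- apply_selection(structure, 1L, selection(atom_class = "heavy"))
  full <- oracle_sasa(at, n_points)
  out <- list()
  for (ch in unique(at$chain)) {
    alone <- oracle_sasa(at[at$chain == ch, , drop = FALSE], n_points)
    cplx <- full[full$chain == ch, , drop = FALSE]
    a_res <- tapply(alone$area, alone$resno, sum)
    c_res <- tapply(cplx$area, cplx$resno, sum)
    out[[ch]] <- data.frame(chain = ch, resno = as.integer(names(a_res)),
                            dasa = pmax(0, as.numeric(a_res) - as.numeric(c_res)),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
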