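#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets via the SVD of the cross-covariance matrix. The
#' returned transform maps the moving set onto the reference:
#' `aligned = (mov - centroid_mov) %*% rotation + centroid_ref`.
#'
#' @param coords_ref,coords_mov `n x 3` matrices, n >= 3, paired row-wise.
#' @return list of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (length-3), `rmsd` (Angstroms).
#' @export
kabsch_superpose <- function(coords_ref, coords_mov) {
  coords_ref <- as.matrix(coords_ref)
  coords_mov <- as.matrix(coords_mov)
  stopifnot(ncol(coords_ref) == 3, ncol(coords_mov) == 3)
  n <- nrow(coords_ref)
  if (n != nrow(coords_mov)) stop("coordinate sets must be paired (equal length)")
  if (n < 3) stop("need at least 3 paired points for superposition")
  cm_r <- colMeans(coords_ref)
  cm_m <- colMeans(coords_mov)
  rc <- sweep(coords_ref, 2, cm_r)
  mc <- sweep(coords_mov, 2, cm_m)
  H <- t(mc) %*% rc
  sv <- svd(H)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12)) {
    stop("degenerate (rank-deficient) coordinate spread; superposition is ill-defined")
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- mc %*% R
  rmsd <- sqrt(mean(rowSums((aligned - rc)^2)))
  structure(list(rotation = R, translation = as.numeric(cm_r - cm_m %*% R),
                 rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#' @param coords `n x 3` matrix.
#' @param sp a [kabsch_superpose()] result.
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% sp$rotation, 2, sp$translation, `+`)
}

#' Ensemble precision: average RMSD to the mean structure
#'
#' All models are iteratively superposed on the ensemble mean coordinates
#' (two refinement rounds, the convention of NMR ensemble statistics
#' reports), then the RMSD of each model to the final mean over the selected
#' atoms is computed and averaged.
#'
#' @param structure a multi-model `structure3d`.
#' @param sel an [selection()]; defaults to the ordered-region backbone.
#' @param atom_class optional override of `sel`'s atom class.
#' @param map a [numbering_map()].
#' @param iterations mean-structure refinement rounds.
#' @return list with `mean_rmsd` (Angstroms), `per_model` (numeric vector),
#'   `n_atoms`.
#' @export
ensemble_rmsd <- function(structure, sel = ordered_region(), atom_class = NULL,
                          map = numbering_map(0L), iterations = 2L) {
  if (n_models(structure) < 2L) stop("ensemble statistics need at least 2 models")
  if (!is.null(atom_class)) sel$atom_class <- match.arg(atom_class, c("all", "heavy", "backbone", "calpha"))
  m <- n_models(structure)
  ref <- apply_selection(structure, 1L, sel, map)
  idx <- match(paste(ref$chain, ref$resno, ref$elety),
               paste(structure$atoms$chain, structure$atoms$resno, structure$atoms$elety))
  arr <- structure$xyz[idx, , , drop = FALSE]
  for (it in seq_len(iterations)) {
    mean_xyz <- apply(arr, c(1, 2), mean)
    for (k in seq_len(m)) {
      sp <- kabsch_superpose(mean_xyz, arr[, , k])
      arr[, , k] <- apply_superposition(arr[, , k], sp)
    }
  }
  mean_xyz <- apply(arr, c(1, 2), mean)
  per_model <- vapply(seq_len(m), function(k) {
    sqrt(mean(rowSums((arr[, , k] - mean_xyz)^2)))
  }, numeric(1))
  list(mean_rmsd = mean(per_model), per_model = per_model, n_atoms = nrow(mean_xyz))
}

backbone_dihedrals <- function(at) {
  ## at: atoms of one chain ordered by resno, with N/CA/C rows present
  resnos <- sort(unique(at$resno))
  get <- function(rn, name) {
    i <- which(at$resno == rn & at$elety == name)
    if (!length(i)) return(NULL)
    c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
  }
  out <- data.frame(resno = resnos, phi = NA_real_, psi = NA_real_)
  for (r in seq_along(resnos)) {
    rn <- resnos[r]
    N <- get(rn, "N"); CA <- get(rn, "CA"); C <- get(rn, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (r > 1 && resnos[r - 1] == rn - 1) {
      Cp <- get(rn - 1, "C")
      if (!is.null(Cp)) out$phi[r] <- dihedral(Cp, N, CA, C)
    }
    if (r < length(resnos) && resnos[r + 1] == rn + 1) {
      Nn <- get(rn + 1, "N")
      if (!is.null(Nn)) out$psi[r] <- dihedral(N, CA, C, Nn)
    }
  }
  out
}

#' Dihedral-window secondary-structure assignment
#'
#' Assigns helix where phi is in `[-100, -30]` and psi in `[-80, -5]` over at
#' least 4 consecutive residues, and strand where phi is in `[-180, -40]` and
#' psi in `[50, 180]` (or below -170, the periodic wrap) over at least 2
#' consecutive residues supported by at least one inter-strand backbone
#' hydrogen bond (sequence separation >= 3 or a different chain, from
#' [find_hbonds()]). Everything else, including residues with incomplete
#' backbone (flagged with a warning), is coil. This windowed scheme is
#' sufficient for the small two-helix/one-strand topologies the package
#' targets; it is not a DSSP reimplementation.
#'
#' @param structure a `structure3d`.
#' @param model model index.
#' @param map a [numbering_map()]; segment boundaries are reported in native
#'   numbering.
#' @param helix_phi,helix_psi,strand_phi,strand_psi numeric length-2 windows
#'   (degrees).
#' @return list of class `secondary_structure`: `segments` data.frame (kind,
#'   chain, start, end in native numbering), `per_residue` data.frame with
#'   phi/psi and the assigned kind.
#' @export
assign_secondary_structure <- function(structure, model = 1L, map = numbering_map(0L),
                                       helix_phi = c(-100, -30), helix_psi = c(-80, -5),
                                       strand_phi = c(-180, -40), strand_psi = c(50, 180)) {
  hb <- find_hbonds(structure, model, map = map)
  chains <- unique(structure$atoms$chain)
  per <- list()
  for (ch in chains) {
    at <- apply_selection(structure, model, selection(chains = ch, atom_class = "all"), map)
    dh <- backbone_dihedrals(at)
    if (any(is.na(dh$phi) & is.na(dh$psi) &
              !dh$resno %in% range(dh$resno))) {
      warning("chain ", ch, ": residues with incomplete backbone assigned coil")
    }
    in_win <- function(x, w) !is.na(x) & x >= w[1] & x <= w[2]
    helix_ok <- in_win(dh$phi, helix_phi) & in_win(dh$psi, helix_psi)
    strand_ok <- in_win(dh$phi, strand_phi) &
      (in_win(dh$psi, strand_psi) | (!is.na(dh$psi) & dh$psi < -170))
    ## residue has an inter-strand backbone H-bond (donor or acceptor)
    hb_res <- rep(FALSE, nrow(dh))
    if (nrow(hb)) {
      far <- hb$chain_donor != hb$chain_acceptor |
        abs(hb$resno_donor - hb$resno_acceptor) >= 3
      hbf <- hb[far, , drop = FALSE]
      hb_res <- dh$resno %in% c(hbf$resno_donor[hbf$chain_donor == ch],
                                hbf$resno_acceptor[hbf$chain_acceptor == ch])
    }
    kind <- rep("coil", nrow(dh))
    kind[mark_runs(helix_ok, dh$resno, 4L)] <- "helix"
    strand_runs <- run_list(strand_ok & kind == "coil", dh$resno, 2L)
    for (rn in strand_runs) {
      if (any(hb_res[rn])) kind[rn] <- "strand"
    }
    per[[ch]] <- data.frame(chain = ch,
                            native_num = map_numbering(dh$resno, map, "file_to_native"),
                            resno = dh$resno, phi = dh$phi, psi = dh$psi,
                            kind = kind, stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  segs <- list()
  for (ch in chains) {
    p <- per[per$chain == ch, , drop = FALSE]
    r <- rle(p$kind)
    stop_i <- cumsum(r$lengths)
    start_i <- stop_i - r$lengths + 1L
    for (s in seq_along(r$values)) {
      segs[[length(segs) + 1L]] <- data.frame(
        kind = r$values[s], chain = ch,
        start = p$native_num[start_i[s]], end = p$native_num[stop_i[s]],
        stringsAsFactors = FALSE)
    }
  }
  segs <- do.call(rbind, segs)
  rownames(segs) <- NULL
  structure(list(segments = segs, per_residue = per), class = "secondary_structure")
}

## indices belonging to runs of TRUE (over consecutive residue numbers) of
## length >= min_len
run_list <- function(flag, resno, min_len) {
  out <- list()
  i <- 1L
  n <- length(flag)
  while (i <= n) {
    if (!flag[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && flag[j + 1L] && resno[j + 1L] == resno[j] + 1L) j <- j + 1L
    if (j - i + 1L >= min_len) out[[length(out) + 1L]] <- i:j
    i <- j + 1L
  }
  out
}

mark_runs <- function(flag, resno, min_len) {
  unlist(run_list(flag, resno, min_len)) %||% integer(0)
}

#' Helix axis by principal component of the Calpha cloud
#'
#' @param ca_coords `n x 3` matrix of Calpha coordinates (n >= 5), N- to
#'   C-terminal order.
#' @return list of class `helix_axis`: `origin` (centroid) and `direction`
#'   (unit vector oriented N to C).
#' @export
helix_axis <- function(ca_coords) {
  ca_coords <- as.matrix(ca_coords)
  if (nrow(ca_coords) < 5) stop("need at least 5 Calpha positions to fit a helix axis")
  ctr <- colMeans(ca_coords)
  n <- nrow(ca_coords)
  ## bisector construction: for an ideal helix the vectors
  ## h_i = (p_i - p_{i+1}) + (p_{i+2} - p_{i+1}) point radially at the axis,
  ## so successive cross products h_i x h_{i+1} are exactly axial; averaging
  ## them is exact on ideal geometry and averages out coordinate noise
  H <- ca_coords[1:(n - 2), ] - 2 * ca_coords[2:(n - 1), ] + ca_coords[3:n, ]
  ax <- colSums(t(vapply(seq_len(nrow(H) - 1), function(i) {
    pracma_cross(H[i, ], H[i + 1, ])
  }, numeric(3))))
  span <- ca_coords[n, ] - ca_coords[1, ]
  if (vnorm(ax) < 1e-8 * max(vnorm(span), 1)) {
    ## (near-)straight trace: cross products vanish, use the principal component
    cc <- sweep(ca_coords, 2, ctr)
    ax <- svd(cc)$v[, 1]
  }
  d <- unit(ax)
  if (sum(d * span) < 0) d <- -d
  structure(list(origin = ctr, direction = as.numeric(d)), class = "helix_axis")
}

#' Angle between two helix axes
#'
#' N-to-C orientation is preserved: antiparallel helices report close to 180
#' degrees.
#'
#' @param axis1,axis2 [helix_axis()] objects or unit 3-vectors.
#' @return angle in degrees, in [0, 180].
#' @export
interhelix_angle <- function(axis1, axis2) {
  d1 <- if (inherits(axis1, "helix_axis")) axis1$direction else unit(axis1)
  d2 <- if (inherits(axis2, "helix_axis")) axis2$direction else unit(axis2)
  acos(max(-1, min(1, sum(d1 * d2)))) * 180 / pi
}

#' Calpha RMSD between two structures after optimal superposition
#'
#' Pairs Calpha atoms of the two structures by native residue number (or an
#' explicit pairing table), superposes them with [kabsch_superpose()] and
#' returns the RMSD.
#'
#' @param structure_a,structure_b `structure3d` objects.
#' @param chains_a,chains_b chain ids to compare (NULL: all chains).
#' @param model_a,model_b model indices.
#' @param map_a,map_b [numbering_map()]s for each structure.
#' @param pairing optional data.frame with columns `native_a`, `native_b`;
#'   default pairs equal native numbers present in both.
#' @return list with `rmsd` (Angstroms), `n_pairs` and the `superposition`.
#' @export
compare_structures <- function(structure_a, structure_b,
                               chains_a = NULL, chains_b = NULL,
                               model_a = 1L, model_b = 1L,
                               map_a = numbering_map(0L), map_b = numbering_map(0L),
                               pairing = NULL) {
  ca_a <- apply_selection(structure_a, model_a,
                          selection(chains = chains_a, atom_class = "calpha"), map_a)
  ca_b <- apply_selection(structure_b, model_b,
                          selection(chains = chains_b, atom_class = "calpha"), map_b)
  if (is.null(pairing)) {
    shared <- intersect(ca_a$native_num, ca_b$native_num)
    pairing <- data.frame(native_a = shared, native_b = shared)
  }
  if (nrow(pairing) < 3) stop("need at least 3 paired residues")
  ia <- match(pairing$native_a, ca_a$native_num)
  ib <- match(pairing$native_b, ca_b$native_num)
  if (anyNA(ia) || anyNA(ib)) stop("pairing refers to residues absent from a structure")
  A <- cbind(ca_a$x, ca_a$y, ca_a$z)[ia, , drop = FALSE]
  B <- cbind(ca_b$x, ca_b$y, ca_b$z)[ib, , drop = FALSE]
  sp <- kabsch_superpose(A, B)
  list(rmsd = sp$rmsd, n_pairs = nrow(pairing), superposition = sp)
}
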