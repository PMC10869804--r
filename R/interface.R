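#' Dimer-interface decomposition by buried surface area
#'
#' For a binary complex of chain sets A and B, the area buried on a residue is
#' `dASA = SASA(own chain set alone) - SASA(in complex)`, clamped at zero. A
#' residue is an interface residue when `dASA > cutoff`; per-chain-set buried
#' totals are the sums of its residues' `dASA`.
#'
#' @param structure a `structure3d`.
#' @param model model index.
#' @param chains_a,chains_b disjoint character vectors of chain ids.
#' @param params a [sasa_params()].
#' @param cutoff interface-residue threshold in Angstrom^2 (default 0.1,
#'   suppresses sampling noise).
#' @param map a [numbering_map()] used to report native numbering.
#' @return list of class `interface_report`: `per_residue` (chain, resno,
#'   native_num, resname, asa_alone, asa_complex, dasa, interface flag),
#'   `interface_residues` (subset with `dasa > cutoff`), `buried_total`
#'   (named by chain set), `buried_total_complexwide`, `n_interface` (named by
#'   chain set).
#' @export
interface_analysis <- function(structure, model = 1L, chains_a, chains_b,
                               params = sasa_params(), cutoff = 0.1,
                               map = numbering_map(0L)) {
  if (length(intersect(chains_a, chains_b))) stop("chain sets must be disjoint")
  present <- unique(structure$atoms$chain)
  missing <- setdiff(c(chains_a, chains_b), present)
  if (length(missing)) stop("chain(s) absent from model: ", paste(missing, collapse = ", "))
  sel_ab <- apply_selection(structure, model, selection(chains = c(chains_a, chains_b),
                                                        atom_class = "heavy"), map)
  sel_a <- sel_ab[sel_ab$chain %in% chains_a, , drop = FALSE]
  sel_b <- sel_ab[sel_ab$chain %in% chains_b, , drop = FALSE]
  s_ab <- compute_sasa(sel_ab, params)
  s_a <- compute_sasa(sel_a, params)
  s_b <- compute_sasa(sel_b, params)
  alone <- rbind(s_a$per_residue, s_b$per_residue)
  cplx <- s_ab$per_residue
  key_a <- paste(alone$chain, alone$resno)
  key_c <- paste(cplx$chain, cplx$resno)
  m <- match(key_a, key_c)
  per <- data.frame(chain = alone$chain, resno = alone$resno,
                    native_num = map_numbering(alone$resno, map, "file_to_native"),
                    resname = alone$resname,
                    asa_alone = alone$area, asa_complex = cplx$area[m],
                    stringsAsFactors = FALSE)
  per$dasa <- pmax(0, per$asa_alone - per$asa_complex)
  per$interface <- per$dasa > cutoff
  per <- per[order(match(per$chain, c(chains_a, chains_b)), per$resno), ]
  rownames(per) <- NULL
  in_a <- per$chain %in% chains_a
  buried <- c(sum(per$dasa[in_a]), sum(per$dasa[!in_a]))
  names(buried) <- c(paste(chains_a, collapse = "+"), paste(chains_b, collapse = "+"))
  n_int <- c(sum(per$interface[in_a]), sum(per$interface[!in_a]))
  names(n_int) <- names(buried)
  structure(list(per_residue = per,
                 interface_residues = per[per$interface, , drop = FALSE],
                 buried_total = buried,
                 buried_total_complexwide = sum(buried),
                 n_interface = n_int,
                 cutoff = cutoff),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("<interface_report: %s interface residues, buried %s A^2, complex-wide %.0f A^2>\n",
              paste(x$n_interface, collapse = "/"),
              paste(sprintf("%.0f", x$buried_total), collapse = "/"),
              x$buried_total_complexwide))
  invisible(x)
}

.acidic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.basic_atoms <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
.his_atoms <- list(HIS = c("ND1", "NE2"))

#' Detect salt bridges
#'
#' Reports Asp/Glu carboxylate-oxygen to Lys/Arg side-chain-nitrogen pairs
#' whose minimum charged-group heavy-atom distance is within the cutoff. Each
#' bridge is annotated with the relative side-chain accessibility of its
#' acidic residue in the complex (see [relative_sidechain_asa()]): a bridge
#' with high accessibility is solvent-exposed and expected to contribute
#' little to stability.
#'
#' @param structure a `structure3d`.
#' @param model model index.
#' @param distance_cutoff maximum charged-group distance in Angstroms.
#' @param include_his also treat His (ND1/NE2) as basic.
#' @param params a [sasa_params()] for the accessibility annotation.
#' @param map a [numbering_map()] for native numbering in the report.
#' @param asa_ratio compute the accessibility annotation (set FALSE to skip
#'   the relatively expensive SASA evaluation).
#' @return data.frame with one row per bridge: acidic/basic chain, residue
#'   numbers (file and native), residue names, closest atom pair, distance,
#'   inter_chain flag and `asa_ratio` (percent, NA when `asa_ratio = FALSE`).
#' @export
find_salt_bridges <- function(structure, model = 1L, distance_cutoff = 4.0,
                              include_his = FALSE, params = sasa_params(),
                              map = numbering_map(0L), asa_ratio = TRUE) {
  at <- apply_selection(structure, model, selection(atom_class = "heavy"), map)
  basic_set <- c(.basic_atoms, if (include_his) .his_atoms)
  pick <- function(defs) {
    idx <- integer(0)
    for (res in names(defs)) {
      idx <- c(idx, which(at$resname == res & at$elety %in% defs[[res]]))
    }
    idx
  }
  ai <- pick(.acidic_atoms)
  bi <- pick(basic_set)
  empty <- data.frame(chain_acid = character(), resno_acid = integer(),
                      native_acid = integer(), resname_acid = character(),
                      chain_base = character(), resno_base = integer(),
                      native_base = integer(), resname_base = character(),
                      atom_acid = character(), atom_base = character(),
                      distance = numeric(), inter_chain = logical(),
                      asa_ratio = numeric(), stringsAsFactors = FALSE)
  if (!length(ai) || !length(bi)) return(empty)
  A <- cbind(at$x, at$y, at$z)[ai, , drop = FALSE]
  B <- cbind(at$x, at$y, at$z)[bi, , drop = FALSE]
  d <- sqrt(outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B))
  res_a <- paste(at$chain[ai], at$resno[ai])
  res_b <- paste(at$chain[bi], at$resno[bi])
  rows <- list()
  sasa_cache <- NULL
  for (ra in unique(res_a)) {
    for (rb in unique(res_b)) {
      sub <- d[res_a == ra, res_b == rb, drop = FALSE]
      if (min(sub) <= distance_cutoff) {
        w <- which(sub == min(sub), arr.ind = TRUE)[1, ]
        i <- ai[which(res_a == ra)[w[1]]]
        j <- bi[which(res_b == rb)[w[2]]]
        ratio <- NA_real_
        if (asa_ratio) {
          if (is.null(sasa_cache)) sasa_cache <- compute_sasa(at, params)
          ratio <- relative_sidechain_asa(structure, model, at$chain[i], at$resno[i],
                                          params, complex_sasa = sasa_cache)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          chain_acid = at$chain[i], resno_acid = at$resno[i],
          native_acid = at$native_num[i], resname_acid = at$resname[i],
          chain_base = at$chain[j], resno_base = at$resno[j],
          native_base = at$native_num[j], resname_base = at$resname[j],
          atom_acid = at$elety[i], atom_base = at$elety[j],
          distance = min(sub), inter_chain = at$chain[i] != at$chain[j],
          asa_ratio = ratio, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$chain_acid, out$resno_acid), , drop = FALSE]
}

.backbone_names <- c("N", "CA", "C", "O", "OXT")

#' Relative side-chain accessibility
#'
#' Percent accessibility of a residue's side chain: its side-chain SASA in
#' the full assembly divided by the side-chain SASA of the same residue in a
#' Gly-X-Gly reference tripeptide carved from the structure (the residue in
#' its observed conformation plus the backbone atoms of its two sequence
#' neighbours). Both numerator and denominator use the same surface engine
#' and radii, so the ratio is internally consistent; values are clamped at
#' 100.
#'
#' @param structure a `structure3d`.
#' @param model model index.
#' @param chain chain id.
#' @param resno residue number (coordinate-file numbering).
#' @param params a [sasa_params()].
#' @param complex_sasa optional precomputed [compute_sasa()] result for the
#'   full heavy-atom assembly of this model (reused when annotating many
#'   residues).
#' @return percent accessibility in [0, 100].
#' @export
relative_sidechain_asa <- function(structure, model = 1L, chain, resno,
                                   params = sasa_params(), complex_sasa = NULL) {
  at <- apply_selection(structure, model, selection(atom_class = "heavy"))
  res_rows <- at$chain == chain & at$resno == resno
  if (!any(res_rows)) stop("residue ", chain, ":", resno, " not found")
  resname <- at$resname[res_rows][1]
  sc_rows <- res_rows & !(at$elety %in% .backbone_names)
  if (!any(sc_rows)) {
    stop(structure(class = c("dimerlab_no_sidechain", "error", "condition"),
                   list(message = paste0("residue ", resname, " ", chain, ":", resno,
                                         " has no side-chain atoms"), call = NULL)))
  }
  if (is.null(complex_sasa)) complex_sasa <- compute_sasa(at, params)
  ctx <- sum(complex_sasa$per_atom$area[sc_rows[!at$is_h]])
  ## reference: residue + flanking backbone (Gly-X-Gly carved in place)
  ref_rows <- res_rows | (at$chain == chain & at$resno %in% c(resno - 1, resno + 1) &
                            at$elety %in% .backbone_names)
  ref_at <- at[ref_rows, , drop = FALSE]
  ref_sasa <- compute_sasa(ref_at, params)
  ref_sc <- ref_at$chain == chain & ref_at$resno == resno &
    !(ref_at$elety %in% .backbone_names)
  ref <- sum(ref_sasa$per_atom$area[ref_sc])
  min(100, 100 * ctx / ref)
}

#' Detect backbone hydrogen bonds
#'
#' Geometric criteria: donor backbone N to acceptor backbone O distance
#' within `max_no`; when the amide H is present additionally H...O within
#' `max_ho` and an N-H...O angle of at least `min_angle`. Pairs closer than
#' two residues apart in the same chain are excluded (the peptide bond places
#' N(i) next to O(i-1) trivially).
#'
#' @param structure a `structure3d`.
#' @param model model index.
#' @param max_no maximum N...O distance, Angstroms.
#' @param max_ho maximum H...O distance, Angstroms (only applied when an
#'   amide H is present on the donor).
#' @param min_angle minimum N-H...O angle, degrees.
#' @param map a [numbering_map()] for native numbering in the report.
#' @return data.frame with donor/acceptor chain and residue numbers, the
#'   N...O distance, H...O distance and angle (NA without H) and an
#'   `inter_chain` flag.
#' @export
find_hbonds <- function(structure, model = 1L, max_no = 3.5, max_ho = 2.5,
                        min_angle = 120, map = numbering_map(0L)) {
  at <- apply_selection(structure, model, selection(atom_class = "all"), map)
  don <- which(at$elety == "N")
  acc <- which(at$elety == "O")
  out <- data.frame(chain_donor = character(), resno_donor = integer(),
                    native_donor = integer(), chain_acceptor = character(),
                    resno_acceptor = integer(), native_acceptor = integer(),
                    dist_no = numeric(), dist_ho = numeric(), angle = numeric(),
                    inter_chain = logical(), stringsAsFactors = FALSE)
  if (!length(don) || !length(acc)) return(out)
  D <- cbind(at$x, at$y, at$z)[don, , drop = FALSE]
  A <- cbind(at$x, at$y, at$z)[acc, , drop = FALSE]
  dm <- sqrt(pmax(outer(rowSums(D^2), rowSums(A^2), `+`) - 2 * D %*% t(A), 0))
  hits <- which(dm <= max_no, arr.ind = TRUE)
  rows <- list()
  for (k in seq_len(nrow(hits))) {
    i <- don[hits[k, 1]]
    j <- acc[hits[k, 2]]
    same_chain <- at$chain[i] == at$chain[j]
    if (same_chain && abs(at$resno[i] - at$resno[j]) <= 1) next
    dho <- NA_real_
    ang <- NA_real_
    h <- which(at$chain == at$chain[i] & at$resno == at$resno[i] &
                 at$elety %in% c("H", "HN"))
    if (length(h)) {
      hp <- c(at$x[h[1]], at$y[h[1]], at$z[h[1]])
      op <- c(at$x[j], at$y[j], at$z[j])
      np <- c(at$x[i], at$y[i], at$z[i])
      dho <- vnorm(op - hp)
      ang <- bond_angle(np, hp, op)
      if (dho > max_ho || ang < min_angle) next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chain_donor = at$chain[i], resno_donor = at$resno[i],
      native_donor = at$native_num[i],
      chain_acceptor = at$chain[j], resno_acceptor = at$resno[j],
      native_acceptor = at$native_num[j],
      dist_no = dm[hits[k, 1], hits[k, 2]], dist_ho = dho, angle = ang,
      inter_chain = !same_chain, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(out)
  out <- do.call(rbind, rows)
  out[order(out$chain_donor, out$resno_donor), , drop = FALSE]
}
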