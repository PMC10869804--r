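#' Parameters for solvent-accessible surface area computation
#'
#' @param probe_radius solvent probe radius in Angstroms (water: 1.4).
#' @param n_points number of sphere sample points per atom (>= 100). Sampling
#'   is a deterministic golden-section spiral, so areas are exactly
#'   reproducible for a given `n_points`.
#' @param radii_set named numeric vector of van der Waals radii. Names are
#'   either atom classes (`"C.carbonyl"`) or element symbols used as
#'   fallback. The default is the Chothia-style heavy-atom set used by
#'   NACCESS-class programs.
#' @return An object of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_points = 960L,
                        radii_set = default_radii()) {
  stopifnot(probe_radius > 0, n_points >= 100L)
  structure(list(probe_radius = probe_radius, n_points = as.integer(n_points),
                 radii_set = radii_set),
            class = "sasa_params")
}

#' Default van der Waals radii (Angstroms)
#'
#' Chothia (1976)-style heavy-atom values: backbone carbonyl / carboxylate
#' carbons 1.76, other carbons 1.87, nitrogen 1.65, oxygen 1.40, sulfur 1.85,
#' phosphorus 1.80. Hydrogens are excluded from area computations.
#'
#' @return named numeric vector.
#' @export
default_radii <- function() {
  c(C.carbonyl = 1.76, C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.80)
}

## sp2 carbonyl/carboxylate/guanidinium carbons by atom name
.trigonal_c <- c("C", "CG.ASP", "CD.GLU", "CZ.ARG", "CG.ASN", "CD.GLN")

atom_radius <- function(elety, resname, element, radii_set) {
  key <- ifelse(elety == "C" | paste(elety, resname, sep = ".") %in% .trigonal_c,
                "C.carbonyl", element)
  r <- radii_set[key]
  miss <- is.na(r)
  r[miss] <- radii_set[element[miss]]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    stop("no radius for atom '", elety[bad], "' (element '", element[bad],
         "') and no element fallback in the radii set")
  }
  unname(r)
}

#' Deterministic unit-sphere sample points (golden-section spiral)
#'
#' @param n number of points.
#' @return `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the heavy atoms of `atoms` using deterministic
#' golden-spiral sampling: the accessible area of atom i is
#' `(exposed points / n_points) * 4 * pi * (r_i + probe)^2`. Hydrogens are
#' ignored. This is the package's PISA-equivalent surface engine; per-residue
#' areas sum exactly to the total.
#'
#' @param atoms data.frame as returned by [apply_selection()] (columns
#'   `chain`, `resno`, `resname`, `elety`, `element`, `is_h`, `x`, `y`, `z`).
#' @param params a [sasa_params()].
#' @return list of class `sasa_result` with elements `per_atom` (data.frame
#'   with an `area` column parallel to the heavy-atom rows of `atoms`),
#'   `per_residue` (chain, resno, resname, area) and `total` (Angstrom^2).
#' @export
compute_sasa <- function(atoms, params = sasa_params()) {
  stopifnot(inherits(params, "sasa_params"))
  if (!is.null(atoms$is_h)) atoms <- atoms[!atoms$is_h, , drop = FALSE]
  n <- nrow(atoms)
  if (n < 1L) stop("no non-hydrogen atoms to compute SASA for")
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  rad <- atom_radius(atoms$elety, atoms$resname, atoms$element, params$radii_set)
  rp <- rad + params$probe_radius
  pts <- sphere_points(params$n_points)
  area <- numeric(n)
  ## neighbour lists from the full pairwise distance matrix; assemblies here
  ## are a few thousand atoms at most
  d2 <- as.matrix(stats::dist(xyz))^2
  cut2 <- outer(rp, rp, `+`)^2
  for (i in seq_len(n)) {
    nbr <- which(d2[i, ] < cut2[i, ] & seq_len(n) != i)
    if (!length(nbr)) {
      area[i] <- 4 * pi * rp[i]^2
      next
    }
    p <- pts * rp[i]
    p <- sweep(p, 2, xyz[i, ], `+`)                  # n_points x 3
    cn <- xyz[nbr, , drop = FALSE]                   # k x 3
    ## squared distances point-to-neighbour via the expanded inner product
    cross <- p %*% t(cn)
    pd2 <- outer(rowSums(p^2), rowSums(cn^2), `+`) - 2 * cross
    buried <- pd2 < matrix(rp[nbr]^2, nrow(p), length(nbr), byrow = TRUE)
    n_exposed <- sum(rowSums(buried) == 0L)
    area[i] <- n_exposed / params$n_points * 4 * pi * rp[i]^2
  }
  per_atom <- data.frame(chain = atoms$chain, resno = atoms$resno,
                         resname = atoms$resname, elety = atoms$elety,
                         area = area, stringsAsFactors = FALSE)
  key <- paste(per_atom$chain, per_atom$resno)
  agg <- stats::aggregate(area ~ chain + resno + resname, data = per_atom, FUN = sum)
  agg <- agg[order(agg$chain, agg$resno), ]
  rownames(agg) <- NULL
  structure(list(per_atom = per_atom, per_residue = agg, total = sum(area)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result: %d atoms, %d residues, total %.1f A^2>\n",
              nrow(x$per_atom), nrow(x$per_residue), x$total))
  invisible(x)
}
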