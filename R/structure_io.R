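#' Multi-model structure container
#'
#' `structure3d` is the coordinate container used throughout dimerlab: an atom
#' table shared by all models (the topology) plus a coordinate array with one
#' slab per model. All models of an ensemble are required to share an
#' identical chain/residue/atom topology, which is enforced on construction
#' and on read.
#'
#' @param atoms data.frame with one row per atom and columns `chain`, `resno`
#'   (coordinate-file numbering), `resname` (3-letter code), `elety` (atom
#'   name), `element`, `is_h` (logical).
#' @param xyz numeric array of dimension `c(n_atoms, 3, n_models)` in
#'   Angstroms, or an `n_atoms x 3` matrix for a single model.
#' @param id entry label.
#'
#' @return An object of class `structure3d`.
#' @export
new_structure <- function(atoms, xyz, id = "synthetic") {
  stopifnot(is.data.frame(atoms))
  req <- c("chain", "resno", "resname", "elety", "element", "is_h")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), ncol(xyz), 1L))
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[2] == 3L)
  if (dim(xyz)[1] != nrow(atoms)) {
    stop("coordinate array has ", dim(xyz)[1], " atoms but the atom table has ", nrow(atoms))
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (any(!nzchar(atoms$element))) stop("empty element symbols in atom table")
  ## atom names must be unique within each residue
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate atom name within a residue: ", d)
  }
  structure(list(atoms = atoms, xyz = xyz, id = id), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d '%s': %d model(s), %d chain(s), %d atoms>\n",
              x$id, n_models(x), length(unique(x$atoms$chain)), nrow(x$atoms)))
  invisible(x)
}

#' Number of models in an ensemble
#' @param structure a `structure3d`.
#' @return integer count of models.
#' @export
n_models <- function(structure) dim(structure$xyz)[3]

#' Coordinates of one model
#' @param structure a `structure3d`.
#' @param model model index (1-based).
#' @return `n_atoms x 3` numeric matrix (Angstroms).
#' @export
model_coords <- function(structure, model = 1L) {
  if (model < 1L || model > n_models(structure)) {
    stop("model index ", model, " out of range (1..", n_models(structure), ")")
  }
  m <- structure$xyz[, , model, drop = FALSE]
  dim(m) <- dim(structure$xyz)[1:2]
  m
}

element_from_name <- function(elety) {
  nm <- gsub("[0-9'\"]", "", trimws(elety))
  ifelse(substr(nm, 1, 1) == "H", "H", substr(nm, 1, 1))
}

## Count atoms in each MODEL block of a PDB file so that a topology mismatch
## can be reported with the offending model, which bio3d does not surface.
check_pdb_model_topology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) < 2L) return(invisible(TRUE))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL records in ", path)
  counts <- mapply(function(s, e) sum(grepl("^(ATOM  |HETATM)", lines[s:e])), starts, ends)
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf(
      "topology mismatch across models in %s: model %d has %d atoms, model 1 has %d",
      path, bad, counts[bad], counts[1]))
  }
  invisible(TRUE)
}

#' Read a (possibly multi-model) structure file
#'
#' Parses PDB or mmCIF through bio3d and returns a topology-checked
#' [new_structure()] ensemble. Alternate locations are resolved to the highest
#' occupancy conformer (ties: first encountered). Hydrogens are retained; the
#' surface module excludes them itself.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A `structure3d` with one model per MODEL record.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  if (format == "pdb") check_pdb_model_topology(path)
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  nmod <- nrow(xyz)
  keep <- resolve_altloc(at)
  at <- at[keep, , drop = FALSE]
  cols <- as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep))
  xyz <- xyz[, cols, drop = FALSE]
  element <- at$elesy
  if (is.null(element)) element <- rep("", nrow(at))
  element <- trimws(ifelse(is.na(element) | !nzchar(trimws(element)),
                           element_from_name(at$elety), element))
  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    resname = as.character(at$resid),
    elety = as.character(at$elety),
    element = element,
    is_h = element %in% c("H", "D"),
    stringsAsFactors = FALSE)
  arr <- array(NA_real_, dim = c(nrow(atoms), 3, nmod))
  for (m in seq_len(nmod)) arr[, , m] <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
  new_structure(atoms, arr, id = tools::file_path_sans_ext(basename(path)))
}

## indices of atoms to keep after alternate-location resolution
resolve_altloc <- function(at) {
  alt <- at$alt
  if (is.null(alt)) return(seq_len(nrow(at)))
  alt[is.na(alt)] <- ""
  plain <- !nzchar(alt)
  if (all(plain)) return(seq_len(nrow(at)))
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert %||% "", at$elety)
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[!plain])) {
    idx <- which(key == k & !plain)
    if (length(idx) > 1L) {
      best <- idx[which.max(occ[idx])]   # which.max: first on ties
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  which(keep)
}

#' Residue-numbering map between native and coordinate-file numbering
#'
#' Expression constructs commonly carry affinity tags, so the residue numbers
#' in a deposited coordinate file differ from the native sequence numbering by
#' a constant offset (file = native + offset). The study construct analysed
#' here carries an N-terminal 6xHis-Flag tag adding 14 residues, so native E36
#' is E50 in the coordinate file; hence the default.
#'
#' @param offset integer, coordinate-file number minus native number.
#' @return An object of class `numbering_map`.
#' @export
numbering_map <- function(offset = 14L) {
  stopifnot(length(offset) == 1L, offset == round(offset))
  structure(list(offset = as.integer(offset)), class = "numbering_map")
}

#' Translate residue numbers between native and file numbering
#'
#' @param seq_num integer vector of residue numbers.
#' @param map a [numbering_map()].
#' @param direction `"native_to_file"` (adds the offset) or
#'   `"file_to_native"` (subtracts it).
#' @return integer vector of translated numbers.
#' @examples
#' map_numbering(36, numbering_map(14), "native_to_file")  # 50
#' @export
map_numbering <- function(seq_num, map, direction = c("native_to_file", "file_to_native")) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "numbering_map"))
  if (direction == "native_to_file") as.integer(seq_num + map$offset)
  else as.integer(seq_num - map$offset)
}

#' Atom selection in native numbering
#'
#' @param chains character vector of chain ids, or NULL for all chains.
#' @param ranges residue ranges in native numbering: a single `c(start, end)`
#'   vector, a list of such vectors, or NULL for all residues. Ranges are
#'   1-based closed intervals and must be ordered and non-overlapping.
#' @param atom_class one of `"all"`, `"heavy"`, `"backbone"` (N, CA, C, O) or
#'   `"calpha"`.
#' @return An object of class `atom_selection`.
#' @export
selection <- function(chains = NULL, ranges = NULL,
                      atom_class = c("all", "heavy", "backbone", "calpha")) {
  atom_class <- match.arg(atom_class)
  if (!is.null(ranges)) {
    if (is.numeric(ranges)) ranges <- list(ranges)
    rng <- do.call(rbind, lapply(ranges, function(r) {
      stopifnot(length(r) == 2L)
      if (r[1] > r[2]) stop("empty selection range: [", r[1], ", ", r[2], "]")
      as.integer(r)
    }))
    if (nrow(rng) > 1L) {
      o <- order(rng[, 1])
      rng <- rng[o, , drop = FALSE]
      if (any(rng[-1, 1] <= rng[-nrow(rng), 2])) stop("selection ranges overlap")
    }
    ranges <- rng
  }
  structure(list(chains = chains, ranges = ranges, atom_class = atom_class),
            class = "atom_selection")
}

#' Default ordered-region selection of the folded protomer
#'
#' The study protein is a 63-residue chain whose first 11 and last 9 residues
#' are unstructured, leaving a 43-residue folded protomer spanning native
#' residues 12-54; this helper returns that selection.
#'
#' @inheritParams selection
#' @export
ordered_region <- function(chains = NULL, atom_class = "backbone") {
  selection(chains = chains, ranges = c(12L, 54L), atom_class = atom_class)
}

#' Apply a selection to one model of a structure
#'
#' Native-numbered selection ranges are translated to coordinate-file
#' numbering through `map` before filtering.
#'
#' @param structure a `structure3d`.
#' @param model model index.
#' @param sel an [selection()].
#' @param map a [numbering_map()]; default offset 0.
#' @return data.frame of selected atoms with columns `chain`, `resno` (file
#'   numbering), `native_num`, `resname`, `elety`, `element`, `is_h`,
#'   `x`, `y`, `z`.
#' @export
apply_selection <- function(structure, model = 1L, sel = selection(),
                            map = numbering_map(0L)) {
  stopifnot(inherits(structure, "structure3d"), inherits(sel, "atom_selection"))
  at <- structure$atoms
  co <- model_coords(structure, model)
  keep <- rep(TRUE, nrow(at))
  if (!is.null(sel$chains)) keep <- keep & at$chain %in% sel$chains
  native <- map_numbering(at$resno, map, "file_to_native")
  if (!is.null(sel$ranges)) {
    in_rng <- rep(FALSE, nrow(at))
    for (i in seq_len(nrow(sel$ranges))) {
      in_rng <- in_rng | (native >= sel$ranges[i, 1] & native <= sel$ranges[i, 2])
    }
    keep <- keep & in_rng
  }
  keep <- keep & switch(sel$atom_class,
    all = TRUE,
    heavy = !at$is_h,
    backbone = !at$is_h & at$elety %in% c("N", "CA", "C", "O"),
    calpha = at$elety == "CA")
  if (!any(keep)) {
    stop(structure(class = c("dimerlab_empty_selection", "error", "condition"),
                   list(message = "selection matches no atoms", call = sys.call(-1))))
  }
  out <- at[keep, , drop = FALSE]
  out$native_num <- native[keep]
  out$x <- co[keep, 1]
  out$y <- co[keep, 2]
  out$z <- co[keep, 3]
  rownames(out) <- NULL
  out
}

#' Write a structure to PDB with per-residue values in the B-factor column
#'
#' Used to export CSP or interface values for molecular-graphics colouring.
#' Residues without an annotation get B = 0.00.
#'
#' @param structure a `structure3d`.
#' @param values NULL, or a data.frame with columns `chain`, `resno`
#'   (coordinate-file numbering) and `value`.
#' @param path output file.
#' @param model model index to write, or NULL for the whole ensemble.
#' @return `path`, invisibly.
#' @export
write_annotated_structure <- function(structure, values = NULL, path, model = 1L) {
  stopifnot(inherits(structure, "structure3d"))
  at <- structure$atoms
  b <- rep(0, nrow(at))
  if (!is.null(values) && nrow(values)) {
    stopifnot(all(c("chain", "resno", "value") %in% names(values)))
    key <- paste(at$chain, at$resno)
    vkey <- paste(values$chain, values$resno)
    hit <- match(key, vkey)
    b[!is.na(hit)] <- values$value[hit[!is.na(hit)]]
  }
  models <- if (is.null(model)) seq_len(n_models(structure)) else model
  xyz <- t(vapply(models, function(m) as.vector(t(model_coords(structure, m))),
                  numeric(3 * nrow(at))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = at$resno, resid = at$resname, chain = at$chain,
                   elety = at$elety, elesy = at$element,
                   o = rep(1, nrow(at)), b = b)
  invisible(path)
}

#' Local cache directory for downloaded structures
#'
#' @return path (not created) where [fetch_pdb()] stores files; override with
#'   the `DIMERLAB_PDB_DIR` environment variable.
#' @export
dimerlab_cache_dir <- function() {
  Sys.getenv("DIMERLAB_PDB_DIR", tools::R_user_dir("dimerlab", "cache"))
}

#' Fetch a PDB entry into the local cache
#'
#' Downloads `https://files.rcsb.org/download/<id>.pdb` once and reuses the
#' cached copy afterwards. Analyses that reproduce the study's deposited
#' ensemble (PDB 8DSB) need this file; everything else in the package runs on
#' synthetic data without any download.
#'
#' @param id 4-character PDB id.
#' @param dir cache directory.
#' @return path to the cached file.
#' @export
fetch_pdb <- function(id = "8DSB", dir = dimerlab_cache_dir()) {
  dest <- file.path(dir, paste0(toupper(id), ".pdb"))
  if (file.exists(dest)) return(dest)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
  status <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stop("could not download PDB entry ", id,
         " (no network access?); place the file at ", dest, " manually")
  }
  dest
}
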