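#' Coordinate model container
#'
#' A flat atom table with chain identifiers, author residue numbers, atom
#' names, elements and coordinates in Angstrom. Calpha-only bead models and
#' full heavy-atom models use the same container; operations that need heavy
#' atoms (SASA) check for them explicitly.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid` (residue
#'   name), `elety` (atom name), `element`, `x`, `y`, `z` and optionally `o`
#'   (occupancy)
#' @return an object of class `structure_model`
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (is.null(atoms$o)) atoms$o <- 1
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure_model")
}

#' Build a bead (Calpha-only) model from per-chain coordinate matrices
#'
#' @param chains named list of n x 3 coordinate matrices (chain names default
#'   to A, B, ...); residues are numbered 1..n per chain
#' @param resno optional list of residue-number vectors matching `chains`
#' @return a [structure_model()]
#' @export
structure_from_chains <- function(chains, resno = NULL) {
  if (is.null(names(chains))) names(chains) <- LETTERS[seq_along(chains)]
  rows <- lapply(seq_along(chains), function(k) {
    xyz <- chains[[k]]
    rn <- if (is.null(resno)) seq_len(nrow(xyz)) else resno[[k]]
    data.frame(chain = names(chains)[k], resno = rn, resid = "GLY",
               elety = "CA", element = "C",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  })
  structure_model(do.call(rbind, rows))
}

#' @export
print.structure_model <- function(x, ...) {
  ca <- ca_coords(x)
  cat(sprintf("<structure_model> %d atoms, %d residues with Calpha, chains: %s\n",
              nrow(x$atoms), nrow(ca),
              paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

#' Read a coordinate model from PDB or mmCIF
#'
#' First model of multi-model files; for alternate locations the
#' highest-occupancy copy of each atom is kept. Residues lacking a Calpha are
#' retained in the atom table but excluded from Calpha distance operations
#' (with a warning from those operations).
#'
#' @param path file path
#' @param format "pdb" or "mmcif" (guessed from the extension by default)
#' @return a [structure_model()]
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  format <- match.arg(format, c("pdb", "mmcif"))
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                         verbose = FALSE)
    else bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("format error: cannot parse ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  at$o[is.na(at$o)] <- 1
  # altloc: keep the highest-occupancy copy per (chain, resno, insert, atom)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  at <- at[order(key, -at$o), , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")), ,
           drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == ""))
    elem <- suppressWarnings(bio3d::atom2ele(at$elety))
  elem[is.na(elem) | elem == ""] <- "C"
  structure_model(data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
                             resno = at$resno, resid = at$resid,
                             elety = at$elety, element = toupper(elem),
                             x = at$x, y = at$y, z = at$z, o = at$o,
                             stringsAsFactors = FALSE))
}

#' Write a model to PDB
#'
#' @param model a [structure_model()]
#' @param path output file
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resid,
                   elety = a$elety, o = a$o)
  invisible(path)
}

#' Calpha coordinate table of a model
#'
#' @param model a [structure_model()]
#' @return data.frame with `chain`, `resno`, `x`, `y`, `z`, one row per
#'   residue that has a Calpha
#' @export
ca_coords <- function(model) {
  a <- model$atoms
  ca <- a[a$elety == "CA", c("chain", "resno", "x", "y", "z")]
  ca[!duplicated(paste(ca$chain, ca$resno)), , drop = FALSE]
}

residue_keys <- function(model) {
  a <- model$atoms
  unique(paste(a$chain, a$resno))
}

#' Calpha-Calpha distance between two residues
#'
#' @param model a [structure_model()]
#' @param chain_a,res_a,chain_b,res_b chain id and author residue number of
#'   the two residues
#' @return distance in Angstrom
#' @export
ca_distance <- function(model, chain_a, res_a, chain_b, res_b) {
  ca <- ca_coords(model)
  ia <- which(ca$chain == chain_a & ca$resno == res_a)
  ib <- which(ca$chain == chain_b & ca$resno == res_b)
  if (length(ia) != 1 || length(ib) != 1)
    stop("residue lookup failed (missing residue or Calpha): ",
         chain_a, ":", res_a, " / ", chain_b, ":", res_b)
  sqrt(sum((unlist(ca[ia, c("x", "y", "z")]) -
            unlist(ca[ib, c("x", "y", "z")]))^2))
}

#' Residue contact map of a model
#'
#' All residue pairs within `cutoff` under the chosen metric: `"ca"` uses
#' Calpha-Calpha distance, `"heavy"` the minimum over all non-hydrogen atom
#' pairs. Intra-chain pairs can be excluded. The map is stored with each
#' unordered pair once; [in_contact()] tests membership symmetrically.
#'
#' @param model a [structure_model()]
#' @param cutoff distance cutoff in Angstrom (default 8, the common
#'   coevolution contact convention)
#' @param metric "ca" or "heavy"
#' @param inter_chain_only drop intra-chain pairs
#' @param min_seq_sep minimum |i - j| for intra-chain pairs (0 keeps all
#'   pairs except self)
#' @return a `contact_map`: data.frame `chain_i`, `res_i`, `chain_j`,
#'   `res_j`, `distance`, with `cutoff` and `metric` attributes
#' @export
structure_contacts <- function(model, cutoff = 8, metric = c("ca", "heavy"),
                               inter_chain_only = FALSE, min_seq_sep = 0L) {
  metric <- match.arg(metric)
  if (metric == "ca") {
    pts <- ca_coords(model)
    grp <- paste(pts$chain, pts$resno)
  } else {
    a <- model$atoms[model$atoms$element != "H", , drop = FALSE]
    if (nrow(a) == 0) stop("heavy-atom metric requires heavy atoms")
    pts <- a[, c("chain", "resno", "x", "y", "z")]
    grp <- paste(pts$chain, pts$resno)
  }
  xyz <- as.matrix(pts[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  keys <- unique(grp)
  # minimum inter-residue distance per residue pair
  out <- list()
  idx_by_key <- split(seq_along(grp), grp)[keys]
  kk <- length(keys)
  ch <- vapply(idx_by_key, function(i) pts$chain[i[1]], character(1))
  rn <- vapply(idx_by_key, function(i) pts$resno[i[1]], numeric(1))
  for (p in seq_len(kk - 1)) {
    for (qq in (p + 1):kk) {
      same_chain <- ch[p] == ch[qq]
      if (inter_chain_only && same_chain) next
      if (same_chain && abs(rn[p] - rn[qq]) <= min_seq_sep && min_seq_sep > 0) next
      dm <- min(d[idx_by_key[[p]], idx_by_key[[qq]]])
      if (dm <= cutoff)
        out[[length(out) + 1L]] <- data.frame(
          chain_i = ch[p], res_i = rn[p], chain_j = ch[qq], res_j = rn[qq],
          distance = dm, stringsAsFactors = FALSE)
    }
  }
  cm <- if (length(out)) do.call(rbind, out)
        else data.frame(chain_i = character(0), res_i = numeric(0),
                        chain_j = character(0), res_j = numeric(0),
                        distance = numeric(0))
  attr(cm, "cutoff") <- cutoff
  attr(cm, "metric") <- metric
  class(cm) <- c("contact_map", "data.frame")
  cm
}

#' Symmetric membership test against a contact map
#'
#' @param contacts a contact map from [structure_contacts()]
#' @param chain_i,res_i,chain_j,res_j vectors describing residue pairs
#' @return logical vector
#' @export
in_contact <- function(contacts, chain_i, res_i, chain_j, res_j) {
  have <- c(paste(contacts$chain_i, contacts$res_i, contacts$chain_j, contacts$res_j),
            paste(contacts$chain_j, contacts$res_j, contacts$chain_i, contacts$res_i))
  paste(chain_i, res_i, chain_j, res_j) %in% have
}

# van der Waals radii (Angstrom), element-keyed; Bondi-type published set
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
                I = 1.98, FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.31)

vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Per-atom solvent-accessible surface area
#'
#' Shrake-Rupley numerical SASA: a golden-spiral lattice of test points on
#' each atom's probe-expanded sphere, counting points not buried inside any
#' neighbour's expanded sphere.
#'
#' @param model a [structure_model()]
#' @param probe probe radius in Angstrom (default 1.4, water)
#' @param n_points sphere test points per atom (default 960)
#' @return the model's atom table with an added `sasa` column (A^2)
#' @export
atom_sasa <- function(model, probe = 1.4, n_points = 960L) {
  a <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  if (nrow(a) == 0) stop("SASA requires heavy atoms")
  if (all(a$elety == "CA") && nrow(a) > 1 &&
      !any(duplicated(paste(a$chain, a$resno))) && all(a$resid == "GLY"))
    stop("Calpha-only bead model: SASA requires heavy-atom coordinates")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  a$sasa <- sasa_cpp(xyz, vdw_radius(a$element), probe, as.integer(n_points))
  a
}

#' Per-residue solvent-accessible surface area
#'
#' Sums atomic Shrake-Rupley SASA over each residue's heavy atoms.
#'
#' @inheritParams atom_sasa
#' @return data.frame `chain`, `resno`, `sasa` (A^2)
#' @export
residue_sasa <- function(model, probe = 1.4, n_points = 960L) {
  a <- atom_sasa(model, probe, n_points)
  agg <- stats::aggregate(a$sasa, by = list(chain = a$chain, resno = a$resno), FUN = sum)
  names(agg)[3] <- "sasa"
  agg[order(agg$chain, agg$resno), , drop = FALSE]
}
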