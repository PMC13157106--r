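#' Build a structure with global residue indexing
#'
#' Assembles atom records into a `cv_structure`, assigning a global 1-based
#' residue index that increases within each chain and continues across chains
#' in input order (chain B's first residue follows chain A's last). This is
#' the indexing convention used by all residue groups, domain annotations and
#' CV terms in the package: for a two-chain complex of 466 + 40 residues the
#' last global index is 506, and indices above 466 address the second chain.
#'
#' @param records data.frame with columns `chain`, `resno` (author residue
#'   number, used only to delimit residues within a chain), `resname`
#'   (3-letter code), `atom` (atom name, e.g. "CA"), `x`, `y`, `z`
#'   (Angstrom). An optional `element` column overrides element inference
#'   from the atom name.
#' @return Object of class `cv_structure`: a list with `$atom` (data.frame
#'   of atoms carrying the global `resid`), `$n_res`, `$chains`.
#' @examples
#' rec <- data.frame(chain = "A", resno = 1, resname = "GLY", atom = "CA",
#'                   x = 0, y = 0, z = 0)
#' build_structure(rec)
#' @export
build_structure <- function(records) {
  req <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0L)
    stop("atom records lack required column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) == 0L) stop("no atom records")
  xyz <- as.matrix(records[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    bad <- which(!apply(xyz, 1L, function(v) all(is.finite(v))))[1L]
    stop(sprintf("non-finite coordinate in atom record %d (%s %s%s)",
                 bad, records$atom[bad], records$chain[bad], records$resno[bad]))
  }
  chain <- as.character(records$chain)
  resno <- as.integer(records$resno)
  # residue boundaries: change of chain (input order) or of author resno
  key <- paste(chain, resno, sep = "\r")
  new_res <- c(TRUE, key[-1L] != key[-length(key)])
  resid <- cumsum(new_res)

  element <- if ("element" %in% names(records)) {
    toupper(trimws(as.character(records$element)))
  } else {
    infer_element(records$atom)
  }
  atom <- data.frame(
    resid = resid,
    resname = toupper(as.character(records$resname)),
    atom = as.character(records$atom),
    chain = chain,
    resno = resno,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    element = element,
    heavy = element != "H",
    stringsAsFactors = FALSE
  )
  dup <- duplicated(paste(atom$resid, atom$atom, sep = "\r"))
  if (any(dup)) {
    d <- which(dup)[1L]
    stop(sprintf("duplicate atom '%s' within residue %s%d (global index %d)",
                 atom$atom[d], atom$chain[d], atom$resno[d], atom$resid[d]))
  }
  out <- structure(
    list(atom = atom,
         n_res = max(resid),
         chains = unique(chain)),
    class = "cv_structure"
  )
  out
}

# element from PDB atom name: strip leading digits, take the leading letter(s);
# anything starting with H (after digits) is hydrogen in protein context
infer_element <- function(atom_names) {
  nm <- toupper(trimws(as.character(atom_names)))
  nm <- sub("^[0-9]+", "", nm)
  first <- substr(nm, 1L, 1L)
  ifelse(first == "H", "H", first)
}

#' @export
print.cv_structure <- function(x, ...) {
  cat(sprintf("cv_structure: %d residues, %d atoms, %d chain(s) [%s]\n",
              x$n_res, nrow(x$atom), length(x$chains),
              paste(x$chains, collapse = ", ")))
  inc <- incomplete_residues(x)
  if (length(inc) > 0L)
    cat(sprintf("  %d residue(s) without a single CA atom: %s%s\n",
                length(inc), paste(utils::head(inc, 5L), collapse = ", "),
                if (length(inc) > 5L) ", ..." else ""))
  invisible(x)
}

#' Global residue indices lacking exactly one CA atom
#' @param structure a `cv_structure`
#' @return integer vector of incomplete global residue indices
#' @export
incomplete_residues <- function(structure) {
  ca <- structure$atom[structure$atom$atom == "CA", "resid"]
  n_ca <- tabulate(ca, nbins = structure$n_res)
  which(n_ca != 1L)
}

#' Extract Calpha coordinates
#'
#' Returns an n x 3 matrix of CA coordinates with rownames equal to the
#' global residue indices. Operations that require CA positions reject
#' residues that do not expose exactly one CA.
#'
#' @param structure a `cv_structure`
#' @param indices optional global residue indices (default: all residues)
#' @return numeric matrix, rownames = global residue indices
#' @export
ca_coords <- function(structure, indices = NULL) {
  if (is.null(indices)) indices <- seq_len(structure$n_res)
  indices <- as.integer(indices)
  bad <- indices[indices < 1L | indices > structure$n_res]
  if (length(bad) > 0L)
    stop("residue index out of range: ", paste(bad, collapse = ", "),
         " (structure has ", structure$n_res, " residues)")
  inc <- intersect(indices, incomplete_residues(structure))
  if (length(inc) > 0L)
    stop("residue(s) without a single CA atom: ", paste(inc, collapse = ", "))
  at <- structure$atom
  ca <- at[at$atom == "CA" & at$resid %in% indices, , drop = FALSE]
  ca <- ca[order(ca$resid), , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resid
  m[as.character(indices), , drop = FALSE]
}

#' Replace Calpha coordinates (and rigidly carry the rest of each residue)
#'
#' Every atom of a residue is translated by the displacement applied to its
#' CA, so side-chain geometry is preserved. Used by generators to materialize
#' optimized coordinates back into a full structure.
#'
#' @param structure a `cv_structure`
#' @param coords n x 3 matrix with rownames = global residue indices
#' @return a `cv_structure` with updated coordinates
#' @export
set_ca_coords <- function(structure, coords) {
  idx <- as.integer(rownames(coords))
  old <- ca_coords(structure, idx)
  delta <- coords - old
  at <- structure$atom
  for (k in seq_along(idx)) {
    rows <- at$resid == idx[k]
    at$x[rows] <- at$x[rows] + delta[k, 1L]
    at$y[rows] <- at$y[rows] + delta[k, 2L]
    at$z[rows] <- at$z[rows] + delta[k, 3L]
  }
  structure$atom <- at
  structure
}

#' Domain annotation over global residue indices
#'
#' Named, disjoint, ordered ranges of global residue indices, each flagged
#' structured or disordered. Structured ranges are the ones eligible for
#' positional restraints and for superposition.
#'
#' @param label character vector of range labels (e.g. "NTF2L", "IDR1")
#' @param start,end integer vectors of 1-based global residue bounds
#'   (inclusive)
#' @param structured logical vector
#' @return data.frame of class `domain_annotation`
#' @examples
#' domain_annotation(c("NTF2L", "IDR1"), c(1, 143), c(142, 225),
#'                   c(TRUE, FALSE))
#' @export
domain_annotation <- function(label, start, end, structured) {
  ann <- data.frame(label = as.character(label),
                    start = as.integer(start), end = as.integer(end),
                    structured = as.logical(structured),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$label)) stop("duplicate domain labels")
  if (any(ann$end < ann$start)) stop("domain end before start")
  if (any(ann$start < 1L)) stop("domain start below 1")
  o <- order(ann$start)
  ann <- ann[o, , drop = FALSE]
  if (nrow(ann) > 1L && any(ann$start[-1L] <= ann$end[-nrow(ann)]))
    stop("domain ranges overlap")
  rownames(ann) <- NULL
  class(ann) <- c("domain_annotation", "data.frame")
  ann
}

#' Residue indices of an annotated domain
#' @param annotation a `domain_annotation`
#' @param label domain label
#' @return integer vector of global residue indices
#' @export
domain_indices <- function(annotation, label) {
  i <- match(label, annotation$label)
  if (is.na(i))
    stop(sprintf("unknown domain label '%s'; available: %s", label,
                 paste(annotation$label, collapse = ", ")))
  seq.int(annotation$start[i], annotation$end[i])
}

#' Slice a structure to one annotated domain
#'
#' Returns the atoms of that residue range only, preserving global residue
#' indices (e.g. the NTF2L slice of a 506-residue complex keeps indices
#' 1-142).
#'
#' @inheritParams domain_indices
#' @param structure a `cv_structure`
#' @return a `cv_structure` restricted to the domain
#' @export
slice_domain <- function(structure, annotation, label) {
  idx <- domain_indices(annotation, label)
  bad <- idx[idx > structure$n_res]
  if (length(bad) > 0L)
    stop(sprintf("domain '%s' extends beyond the structure (%d residues)",
                 label, structure$n_res))
  at <- structure$atom[structure$atom$resid %in% idx, , drop = FALSE]
  rownames(at) <- NULL
  structure(list(atom = at, n_res = structure$n_res,
                 chains = unique(at$chain)),
            class = "cv_structure")
}

#' Default schematic-derived G3BP1-GR20 domain annotation
#'
#' NTF2L = residues 1-142 is the only boundary stated numerically in the
#' source domain map; the IDR1/IDR2/RRM/IDR3 boundaries below are
#' schematic-derived defaults (conventional G3BP1 domain organization), NOT
#' literature-stated coordinates, and should be overridden when exact
#' boundaries are known. GR20 occupies global indices 467-506 (40 residues,
#' 20 Gly-Arg repeats) after the 466-residue G3BP1 chain.
#'
#' @return a `domain_annotation` covering residues 1-506
#' @export
g3bp1_gr20_annotation <- function() {
  domain_annotation(
    label = c("NTF2L", "IDR1", "IDR2", "RRM", "IDR3", "GR20"),
    start = c(1L, 143L, 226L, 340L, 416L, 467L),
    end = c(142L, 225L, 339L, 415L, 466L, 506L),
    structured = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
}
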