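#' Read a PDB file as a structure or ensemble
#'
#' Single-MODEL files give a `cv_structure`; multi-MODEL files give a
#' `cv_ensemble` (or the first model only, under `model_policy =
#' "single"`). Parsing is delegated to bio3d after a validation pass that
#' reports malformed ATOM records with their line numbers. Global 1-based
#' residue indexing is assigned across chains in file order.
#'
#' @param path PDB file path
#' @param model_policy "auto" (default), "single" (first model), or
#'   "ensemble" (always a `cv_ensemble`)
#' @param replicate optional replicate label per model (ensembles)
#' @return a `cv_structure` or `cv_ensemble`
#' @export
read_pdb <- function(path, model_policy = c("auto", "single", "ensemble"),
                     replicate = NULL) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM records in ", path)
  for (ln in which(is_atom)) {
    l <- lines[ln]
    if (nchar(l) < 54L)
      stop(sprintf("malformed ATOM record at line %d (truncated)", ln))
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31L, 38L),
                                         substr(l, 39L, 46L),
                                         substr(l, 47L, 54L))))
    if (any(is.na(xyz)))
      stop(sprintf("malformed ATOM record at line %d (bad coordinates)", ln))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  n_atoms <- nrow(at)
  records <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno, resname = at$resid, atom = at$elety,
    x = at$x, y = at$y, z = at$z,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     infer_element(at$elety), at$elesy),
    stringsAsFactors = FALSE)
  n_models <- nrow(pdb$xyz)
  if (ncol(pdb$xyz) != 3L * n_atoms)
    stop("inconsistent topology across MODEL blocks in ", path)
  if (n_models == 1L || model_policy == "single")
    return(build_structure(records))
  frames <- lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    records$x <- xyz[, 1L]; records$y <- xyz[, 2L]; records$z <- xyz[, 3L]
    build_structure(records)
  })
  if (model_policy == "auto" && n_models == 1L) return(frames[[1L]])
  cv_ensemble(frames, replicate = replicate)
}

format_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                             element) {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else
    sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm, resname, chain, resno %% 10000L,
          x, y, z, 1.0, 0.0, element)
}

structure_atom_lines <- function(structure) {
  at <- structure$atom
  mapply(format_atom_line, seq_len(nrow(at)), at$atom, at$resname,
         at$chain, at$resno, at$x, at$y, at$z, at$element,
         USE.NAMES = FALSE)
}

#' Write a structure or ensemble as PDB
#'
#' Ensembles are written as MODEL/ENDMDL blocks sharing one topology.
#' Output round-trips through [read_pdb()] (and through standard parsers)
#' at PDB coordinate precision (3 decimals).
#'
#' @param x a `cv_structure` or `cv_ensemble`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "cv_structure")) {
    writeLines(c(structure_atom_lines(x), "END"), path)
  } else if (inherits(x, "cv_ensemble")) {
    out <- character(0)
    for (f in seq_len(n_frames(x))) {
      out <- c(out, sprintf("MODEL     %4d", f),
               structure_atom_lines(ensemble_frame(x, f)), "ENDMDL")
    }
    writeLines(c(out, "END"), path)
  } else stop("x must be a cv_structure or cv_ensemble")
  invisible(path)
}

#' Read predictor confidence output from JSON
#'
#' Best-effort reader for AF-style confidence JSON: accepts pLDDT under
#' keys `plddt`/`pLDDT`/`plddts`, pTM under `ptm`/`pTM`, ipTM under
#' `iptm`/`ipTM`, and PAE under `pae`/`predicted_aligned_error`/`PAE`.
#' pLDDT given on the 0-100 predictor scale is divided by 100; the bundle
#' is always on the internal `[0, 1]` scale. Unknown layouts fail with the
#' key inventory of the file.
#'
#' @param path JSON file
#' @return a `confidence_bundle`; the matched key spellings are recorded in
#'   the `"source_keys"` attribute
#' @export
read_confidence_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  pick <- function(aliases) {
    hit <- intersect(aliases, names(obj))
    if (length(hit) == 0L) NULL else hit[1L]
  }
  k_plddt <- pick(c("plddt", "pLDDT", "plddts"))
  k_ptm <- pick(c("ptm", "pTM"))
  k_iptm <- pick(c("iptm", "ipTM"))
  k_pae <- pick(c("pae", "predicted_aligned_error", "PAE"))
  missing <- c(if (is.null(k_plddt)) "plddt", if (is.null(k_ptm)) "ptm",
               if (is.null(k_iptm)) "iptm")
  if (length(missing) > 0L)
    stop(sprintf("confidence JSON lacks %s; keys found: %s",
                 paste(missing, collapse = ", "),
                 paste(names(obj), collapse = ", ")))
  plddt <- as.numeric(obj[[k_plddt]])
  if (any(plddt > 1)) plddt <- plddt / 100
  pae <- if (!is.null(k_pae)) {
    m <- obj[[k_pae]]
    if (is.list(m)) m <- do.call(rbind, m)
    as.matrix(m)
  } else NULL
  b <- confidence_bundle(plddt, as.numeric(obj[[k_ptm]]),
                         as.numeric(obj[[k_iptm]]), pae)
  attr(b, "source_keys") <- c(plddt = k_plddt, ptm = k_ptm, iptm = k_iptm,
                              pae = if (is.null(k_pae)) NA_character_ else k_pae)
  b
}

#' Write a data frame as TSV
#'
#' Tab-separated, header row, '.' decimal separator — the format used for
#' all tabular outputs (loss traces, satisfaction reports, rankings,
#' contact maps, RMSD traces).
#'
#' @param df data.frame (or matrix)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
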