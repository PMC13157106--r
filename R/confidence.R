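#' Predictor confidence bundle
#'
#' Per-residue pLDDT, global pTM and interface ipTM, and optionally a PAE
#' matrix. pLDDT is held internally on `[0, 1]` so that the three
#' regularizer terms are commensurate; readers of predictor JSON divide
#' AF-style 0-100 values by 100 and reports multiply back.
#'
#' @param plddt per-residue vector on `[0, 1]`
#' @param ptm,iptm scalars on `[0, 1]`
#' @param pae optional square predicted-aligned-error matrix (Angstrom,
#'   non-negative); entry `[i, j]` is the expected error of residue j when
#'   the prediction is aligned on residue i
#' @return object of class `confidence_bundle`
#' @export
confidence_bundle <- function(plddt, ptm, iptm, pae = NULL) {
  plddt <- as.numeric(plddt)
  if (length(plddt) == 0L) stop("plddt is empty")
  v <- c(plddt, ptm, iptm)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("plddt, ptm and iptm must lie in [0, 1] (internal scale)")
  if (!is.null(pae)) {
    pae <- as.matrix(pae)
    if (nrow(pae) != ncol(pae)) stop("pae must be square")
    if (nrow(pae) != length(plddt))
      stop(sprintf("pae dimension (%d) does not match residue count (%d)",
                   nrow(pae), length(plddt)))
    if (any(!is.finite(pae)) || any(pae < 0)) stop("pae must be non-negative")
  }
  structure(list(plddt = plddt, ptm = as.numeric(ptm),
                 iptm = as.numeric(iptm), pae = pae),
            class = "confidence_bundle")
}

#' @export
print.confidence_bundle <- function(x, ...) {
  cat(sprintf(
    "confidence_bundle: %d residues, mean pLDDT %.1f, pTM %.3f, ipTM %.3f%s\n",
    length(x$plddt), 100 * mean(x$plddt), x$ptm, x$iptm,
    if (is.null(x$pae)) "" else sprintf(", PAE %dx%d", nrow(x$pae), ncol(x$pae))))
  invisible(x)
}

#' Multimer confidence score
#'
#' The ranking score for multimer predictions, `0.8 * ipTM + 0.2 * pTM`:
#' interface accuracy dominates, global topology contributes the rest.
#'
#' @param ptm,iptm scalars in `[0, 1]`
#' @return scalar in `[0, 1]`
#' @examples
#' multimer_confidence(ptm = 0.5, iptm = 0.75)  # 0.7
#' @export
multimer_confidence <- function(ptm, iptm) {
  v <- c(ptm, iptm)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("ptm and iptm must lie in [0, 1]")
  0.8 * iptm + 0.2 * ptm
}

#' Mean pLDDT on the 0-100 reporting scale
#'
#' @param bundle a `confidence_bundle`
#' @param subset optional residue indices to average over (default: all)
#' @return scalar on 0-100
#' @export
mean_plddt <- function(bundle, subset = NULL) {
  p <- bundle$plddt
  if (!is.null(subset)) {
    subset <- as.integer(subset)
    if (length(subset) == 0L) stop("empty residue subset")
    if (any(subset < 1L | subset > length(p)))
      stop("subset index out of range")
    p <- p[subset]
  }
  100 * mean(p)
}

#' Rank predictor models by multimer confidence
#'
#' Descending by `0.8 * ipTM + 0.2 * pTM`; ties are broken by mean pLDDT
#' (higher first), then label (alphabetical). The tie-breaks are a
#' convention of this package, chosen for reproducible output.
#'
#' @param records list of model records, each a list with `label` (unique)
#'   and `bundle` (a `confidence_bundle`)
#' @return data.frame with columns `label`, `confidence`, `mean_plddt`,
#'   ordered best first
#' @export
rank_models <- function(records) {
  if (length(records) == 0L) stop("no model records to rank")
  labels <- vapply(records, function(r) as.character(r$label), "")
  if (anyDuplicated(labels)) stop("model labels must be unique")
  conf <- vapply(records, function(r)
    multimer_confidence(r$bundle$ptm, r$bundle$iptm), 0)
  mp <- vapply(records, function(r) mean_plddt(r$bundle), 0)
  o <- order(-conf, -mp, labels)
  out <- data.frame(label = labels[o], confidence = conf[o],
                    mean_plddt = mp[o], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Domain-block summary of a PAE matrix
#'
#' For each ordered pair of annotated domains (aligned-on, scored), the
#' mean PAE over the corresponding block. Asymmetric by construction, as
#' PAE itself is.
#'
#' @param pae square PAE matrix in Angstrom
#' @param annotation a `domain_annotation` whose ranges lie within the
#'   matrix dimension
#' @return square matrix (domains x domains) of block means, rows =
#'   aligned-on domain
#' @export
pae_block_summary <- function(pae, annotation) {
  pae <- as.matrix(pae)
  if (nrow(pae) != ncol(pae)) stop("pae must be square")
  if (max(annotation$end) > nrow(pae))
    stop(sprintf("annotation extends to residue %d but pae is %d x %d",
                 max(annotation$end), nrow(pae), ncol(pae)))
  labs <- annotation$label
  out <- matrix(NA_real_, length(labs), length(labs),
                dimnames = list(aligned_on = labs, scored = labs))
  for (i in seq_along(labs)) {
    ri <- domain_indices(annotation, labs[i])
    for (j in seq_along(labs)) {
      rj <- domain_indices(annotation, labs[j])
      out[i, j] <- mean(pae[ri, rj])
    }
  }
  out
}
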