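# Pairwise CA distances for a CV term: the distance array d and, on
# demand, the residue-pair index matrix used by the gradient.
term_distances <- function(coords, term, with_pairs = FALSE) {
  a <- term$group_a$indices
  b <- term$group_b$indices
  ka <- as.character(a); kb <- as.character(b)
  miss <- setdiff(c(ka, kb), rownames(coords))
  if (length(miss) > 0L)
    stop("coordinates lack CA position for residue(s): ",
         paste(miss, collapse = ", "))
  A <- coords[ka, , drop = FALSE]
  B <- coords[kb, , drop = FALSE]
  if (term$pairing == "positional") {
    if (length(a) != length(b))
      stop("positional pairing requires equal group sizes")
    pairs <- cbind(seq_along(a), seq_along(b))
  } else {
    pairs <- as.matrix(expand.grid(seq_along(a), seq_along(b),
                                   KEEP.OUT.ATTRS = FALSE))
  }
  diff <- A[pairs[, 1L], , drop = FALSE] - B[pairs[, 2L], , drop = FALSE]
  d <- sqrt(rowSums(diff^2))
  if (!with_pairs) return(d)
  list(d = d, pairs = pairs, diff = diff, a = a, b = b)
}

#' Positional restraint loss (Angstrom^2)
#'
#' Mean over the restrained residues of the squared Euclidean CA
#' displacement from the reference snapshot: the sum over x, y, z runs
#' inside, the mean over residues outside, so the value is in Angstrom^2
#' and independent of how many residues are restrained.
#'
#' @param coords n x 3 CA coordinate matrix, rownames = global residue
#'   indices
#' @param spec a `restraint_spec`
#' @return scalar loss in Angstrom^2 (>= 0)
#' @examples
#' ref <- matrix(0, 2, 3, dimnames = list(1:2, NULL))
#' sp <- restraint_spec(1:2, ref)
#' restraint_loss(ref + rep(c(3, 0, 0), each = 2), sp)  # 9
#' @export
restraint_loss <- function(coords, spec) {
  stopifnot(inherits(spec, "restraint_spec"))
  keys <- as.character(spec$indices)
  miss <- setdiff(keys, rownames(coords))
  if (length(miss) > 0L)
    stop("coordinates lack CA position for restrained residue(s): ",
         paste(miss, collapse = ", "))
  disp <- coords[keys, , drop = FALSE] - spec$reference
  mean(rowSums(disp^2))
}

#' Attractive distance loss (Angstrom)
#'
#' `max(mean(d - d_c), 0)` over the term's CA-CA distance array: the clamp
#' applies to the mean, not per pair, so pairs already inside the cutoff
#' offset pairs outside it. Zero when the mean distance is within the
#' cutoff.
#'
#' @inheritParams restraint_loss
#' @param term a `cv_term` of kind "attractive"
#' @param per_pair_clamp if TRUE use the flat-bottom variant
#'   `mean(max(d - d_c, 0))` instead (off by default; the mean-then-clamp
#'   form is the canonical one here)
#' @return scalar loss in Angstrom (>= 0)
#' @export
attractive_loss <- function(coords, term, per_pair_clamp = FALSE) {
  stopifnot(inherits(term, "cv_term"))
  if (term$kind != "attractive") stop("term kind is not 'attractive'")
  d <- term_distances(coords, term)
  if (per_pair_clamp) mean(pmax(d - term$cutoff, 0)) else
    max(mean(d - term$cutoff), 0)
}

#' Repulsive distance loss (Angstrom)
#'
#' `max(mean(d_c - d), 0)`: penalizes group proximity below the cutoff,
#' with the same mean-then-clamp semantics as [attractive_loss()].
#'
#' @inheritParams attractive_loss
#' @param term a `cv_term` of kind "repulsive"
#' @return scalar loss in Angstrom (>= 0)
#' @export
repulsive_loss <- function(coords, term, per_pair_clamp = FALSE) {
  stopifnot(inherits(term, "cv_term"))
  if (term$kind != "repulsive") stop("term kind is not 'repulsive'")
  d <- term_distances(coords, term)
  if (per_pair_clamp) mean(pmax(term$cutoff - d, 0)) else
    max(mean(term$cutoff - d), 0)
}

#' Confidence regularization loss
#'
#' `(1 - mean(pLDDT)) + (1 - pTM) + (1 - ipTM)` with all inputs on the
#' internal `[0, 1]` scale; bounded in `[0, 3]`. Perfect confidence gives 0.
#'
#' @param confidence a `confidence_bundle` (or any list with `plddt`,
#'   `ptm`, `iptm` on `[0, 1]`)
#' @return scalar in `[0, 3]`
#' @export
regularization_loss <- function(confidence) {
  v <- c(confidence$plddt, confidence$ptm, confidence$iptm)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("confidence values must lie in [0, 1] (internal scale)")
  (1 - mean(confidence$plddt)) + (1 - confidence$ptm) + (1 - confidence$iptm)
}

#' Gradient of the regularization loss w.r.t. the confidence values
#'
#' @inheritParams regularization_loss
#' @return list with `plddt` (per-residue vector), `ptm`, `iptm`
#' @export
regularization_gradient <- function(confidence) {
  n <- length(confidence$plddt)
  list(plddt = rep(-1 / n, n), ptm = -1, iptm = -1)
}

#' Composite constraint-conditioning loss
#'
#' Evaluates every term and assembles the breakdown
#' `l_cv = l_rest + l_attr + l_repl` and
#' `l_afex = w_c * l_cv + w_r * l_regular`, the composite that the
#' conditioning optimizer descends. Attractive and repulsive contributions
#' are summed over all terms of each kind.
#'
#' @inheritParams restraint_loss
#' @param restraint a `restraint_spec`, or NULL for no positional restraint
#' @param cv_terms list of `cv_term` objects (possibly empty)
#' @param confidence a `confidence_bundle`, or NULL (treated as perfect
#'   confidence: l_regular = 0)
#' @param w_c,w_r non-negative weights of the CV and regularization terms
#' @param per_pair_clamp see [attractive_loss()]
#' @return object of class `loss_breakdown` with fields `l_rest`, `l_attr`,
#'   `l_repl`, `l_cv`, `l_regular`, `l_afex`, `w_c`, `w_r`
#' @export
afex_loss <- function(coords, restraint = NULL, cv_terms = list(),
                      confidence = NULL, w_c = 1, w_r = 0,
                      per_pair_clamp = FALSE) {
  if (w_c < 0 || w_r < 0) stop("weights must be >= 0")
  l_rest <- if (is.null(restraint)) 0 else restraint_loss(coords, restraint)
  l_attr <- 0
  l_repl <- 0
  for (term in cv_terms) {
    if (term$kind == "attractive")
      l_attr <- l_attr + attractive_loss(coords, term, per_pair_clamp)
    else
      l_repl <- l_repl + repulsive_loss(coords, term, per_pair_clamp)
  }
  l_regular <- if (is.null(confidence)) 0 else regularization_loss(confidence)
  l_cv <- l_rest + l_attr + l_repl
  structure(list(l_rest = l_rest, l_attr = l_attr, l_repl = l_repl,
                 l_cv = l_cv, l_regular = l_regular,
                 l_afex = w_c * l_cv + w_r * l_regular,
                 w_c = w_c, w_r = w_r),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(paste0("loss_breakdown: l_afex = %.6g ",
                     "(w_c = %g, w_r = %g)\n"), x$l_afex, x$w_c, x$w_r))
  cat(sprintf("  l_cv = %.6g  [l_rest = %.6g A^2, l_attr = %.6g A, l_repl = %.6g A]\n",
              x$l_cv, x$l_rest, x$l_attr, x$l_repl))
  cat(sprintf("  l_regular = %.6g\n", x$l_regular))
  invisible(x)
}

#' Analytic gradient of the coordinate-dependent loss terms
#'
#' Gradient of `w_c * (l_rest + l_attr + l_repl)` with respect to the CA
#' coordinates. The regularizer has no coordinate gradient here (a
#' generator that ties confidence to its parameters adds that contribution
#' in its own pullback). At a clamp boundary (the mean distance exactly at
#' the cutoff) the zero-side subgradient is returned, so satisfied
#' constraints exert no force. Coincident residue pairs (d = 0) contribute
#' a zero direction.
#'
#' @inheritParams afex_loss
#' @return matrix of the same shape and rownames as `coords`: one 3-vector
#'   per residue
#' @export
loss_gradient <- function(coords, restraint = NULL, cv_terms = list(),
                          w_c = 1, per_pair_clamp = FALSE) {
  g <- matrix(0, nrow(coords), 3L, dimnames = dimnames(coords))
  if (w_c == 0) return(g)
  if (!is.null(restraint)) {
    keys <- as.character(restraint$indices)
    miss <- setdiff(keys, rownames(coords))
    if (length(miss) > 0L)
      stop("coordinates lack CA position for restrained residue(s): ",
           paste(miss, collapse = ", "))
    disp <- coords[keys, , drop = FALSE] - restraint$reference
    g[keys, ] <- g[keys, , drop = FALSE] +
      2 * disp / length(restraint$indices)
  }
  for (term in cv_terms) {
    td <- term_distances(coords, term, with_pairs = TRUE)
    n_pairs <- length(td$d)
    sign_term <- if (term$kind == "attractive") 1 else -1
    if (per_pair_clamp) {
      active <- if (term$kind == "attractive") td$d > term$cutoff
                else td$d < term$cutoff
      weight <- as.numeric(active) / n_pairs
    } else {
      mean_excess <- if (term$kind == "attractive")
        mean(td$d - term$cutoff) else mean(term$cutoff - td$d)
      if (mean_excess <= 0) next  # clamped: zero-side subgradient
      weight <- rep(1 / n_pairs, n_pairs)
    }
    ok <- td$d > 0 & weight > 0
    if (!any(ok)) next
    unit <- td$diff[ok, , drop = FALSE] / td$d[ok]
    contrib <- sign_term * weight[ok] * unit
    ia <- as.character(td$a[td$pairs[ok, 1L]])
    ib <- as.character(td$b[td$pairs[ok, 2L]])
    for (p in seq_len(nrow(contrib))) {
      g[ia[p], ] <- g[ia[p], ] + contrib[p, ]
      g[ib[p], ] <- g[ib[p], ] - contrib[p, ]
    }
  }
  w_c * g
}
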