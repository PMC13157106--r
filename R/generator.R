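#' Toy differentiable structure generator
#'
#' A desk-scale stand-in for a full structure predictor, satisfying the
#' generator contract that the conditioning optimizer requires: a parameter
#' vector theta, a deterministic `produce(theta)` returning CA coordinates
#' plus a confidence bundle, and a gradient pullback mapping coordinate and
#' confidence gradients back to theta.
#'
#' Here theta is a per-residue CA displacement field over the flexible
#' residues; `theta = 0` reproduces the reference exactly. The confidence
#' surrogate ties per-residue pLDDT to the displacement magnitude,
#' `plddt_i = exp(-||delta_i||^2 / sigma^2)` (so large excursions from the
#' reference read as low confidence), with fixed pTM/ipTM constants. The
#' surrogate is internal to this generator and is not a predictor's
#' confidence model; it exists so that the annealing between constraint
#' pressure and confidence pressure can be exercised end to end.
#'
#' @param reference a `cv_structure` supplying the reference CA coordinates
#'   (and topology for materialization)
#' @param flexible global residue indices allowed to move (default: all
#'   residues); others are pinned to the reference
#' @param sigma pLDDT decay length in Angstrom (larger = more tolerant);
#'   `Inf` gives a perfect-confidence surrogate
#' @param ptm,iptm fixed surrogate values in `[0, 1]`
#' @return object of class `toy_generator` with elements `n_theta`,
#'   `theta_init`, `produce(theta)`, `pullback(theta, g_coords, g_conf)`,
#'   `materialize(theta)`
#' @export
toy_chain_generator <- function(reference, flexible = NULL, sigma = 4,
                                ptm = 1, iptm = 1) {
  stopifnot(inherits(reference, "cv_structure"))
  if (any(c(ptm, iptm) < 0) || any(c(ptm, iptm) > 1))
    stop("surrogate ptm/iptm must lie in [0, 1]")
  if (!(is.numeric(sigma) && length(sigma) == 1L && sigma > 0))
    stop("sigma must be a single positive number (Inf allowed)")
  ref_ca <- ca_coords(reference)
  n_res <- nrow(ref_ca)
  if (is.null(flexible)) flexible <- as.integer(rownames(ref_ca))
  flexible <- sort(unique(as.integer(flexible)))
  if (!all(as.character(flexible) %in% rownames(ref_ca)))
    stop("flexible indices outside the reference structure")
  fkeys <- as.character(flexible)
  n_flex <- length(flexible)

  produce <- function(theta) {
    theta <- check_theta(theta, n_flex)
    coords <- ref_ca
    coords[fkeys, ] <- coords[fkeys, , drop = FALSE] + theta
    plddt <- rep(1, n_res)
    if (is.finite(sigma))
      plddt[match(fkeys, rownames(ref_ca))] <-
        exp(-rowSums(theta^2) / sigma^2)
    list(coords = coords,
         confidence = confidence_bundle(plddt, ptm, iptm))
  }

  # dL/dtheta = dL/dcoords (flexible rows) + dL/dplddt * dplddt/dtheta
  pullback <- function(theta, g_coords, g_conf = NULL) {
    theta <- check_theta(theta, n_flex)
    g <- g_coords[fkeys, , drop = FALSE]
    if (!is.null(g_conf) && is.finite(sigma)) {
      fpos <- match(fkeys, rownames(ref_ca))
      p <- exp(-rowSums(theta^2) / sigma^2)
      g <- g + (g_conf$plddt[fpos] * p * (-2 / sigma^2)) * theta
    }
    g
  }

  materialize <- function(theta) {
    out <- produce(theta)
    set_ca_coords(reference, out$coords)
  }

  structure(list(n_res = n_res, n_theta = n_flex, flexible = flexible,
                 sigma = sigma,
                 theta_init = matrix(0, n_flex, 3L,
                                     dimnames = list(fkeys, NULL)),
                 produce = produce, pullback = pullback,
                 materialize = materialize),
            class = "toy_generator")
}

check_theta <- function(theta, n_flex) {
  theta <- as.matrix(theta)
  if (nrow(theta) != n_flex || ncol(theta) != 3L)
    stop(sprintf("theta must be %d x 3", n_flex))
  if (any(!is.finite(theta))) stop("theta contains non-finite values")
  theta
}

#' @export
print.toy_generator <- function(x, ...) {
  cat(sprintf(
    "toy_generator: %d residues, %d flexible, sigma = %g A\n",
    x$n_res, x$n_theta, x$sigma))
  invisible(x)
}
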