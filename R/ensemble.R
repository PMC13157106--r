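#' Conformational ensemble with shared topology
#'
#' An ordered set of frames (snapshots) over one atom topology, each frame
#' carrying a replicate label so that replicate statistics (e.g. RMSD
#' mean/SD shading) can be computed.
#'
#' @param structures list of `cv_structure` frames with identical atom
#'   count, names, residue indexing and chains
#' @param replicate integer/character replicate label per frame (default:
#'   all frames in replicate 1)
#' @return object of class `cv_ensemble`: `$atom` (topology table without
#'   coordinates), `$coords` (atoms x 3 x frames array), `$replicate`,
#'   `$n_res`
#' @export
cv_ensemble <- function(structures, replicate = NULL) {
  if (length(structures) == 0L) stop("ensemble needs at least one frame")
  ref <- structures[[1L]]
  stopifnot(inherits(ref, "cv_structure"))
  topo_cols <- c("resid", "resname", "atom", "chain", "element", "heavy")
  topo <- ref$atom[, topo_cols]
  n_atoms <- nrow(topo)
  coords <- array(NA_real_, c(n_atoms, 3L, length(structures)))
  for (f in seq_along(structures)) {
    s <- structures[[f]]
    if (!inherits(s, "cv_structure") || nrow(s$atom) != n_atoms ||
        !identical(s$atom[, topo_cols], topo))
      stop(sprintf("frame %d topology differs from frame 1", f))
    coords[, , f] <- as.matrix(s$atom[, c("x", "y", "z")])
  }
  if (is.null(replicate)) replicate <- rep(1L, length(structures))
  if (length(replicate) != length(structures))
    stop("replicate labels must match the number of frames")
  structure(list(atom = topo, coords = coords, replicate = replicate,
                 n_res = ref$n_res),
            class = "cv_ensemble")
}

#' @export
print.cv_ensemble <- function(x, ...) {
  cat(sprintf("cv_ensemble: %d frames (%d replicate(s)), %d residues, %d atoms\n",
              n_frames(x), length(unique(x$replicate)), x$n_res,
              nrow(x$atom)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `cv_ensemble`
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3L]

#' One frame of an ensemble as a structure
#' @param ensemble a `cv_ensemble`
#' @param frame frame index
#' @return a `cv_structure`
#' @export
ensemble_frame <- function(ensemble, frame) {
  at <- ensemble$atom
  at$x <- ensemble$coords[, 1L, frame]
  at$y <- ensemble$coords[, 2L, frame]
  at$z <- ensemble$coords[, 3L, frame]
  at$resno <- at$resid
  structure(list(atom = at[, c("resid", "resname", "atom", "chain", "resno",
                               "x", "y", "z", "element", "heavy")],
                 n_res = ensemble$n_res, chains = unique(at$chain)),
            class = "cv_structure")
}

ensemble_ca_rows <- function(ensemble) {
  rows <- which(ensemble$atom$atom == "CA")
  resid <- ensemble$atom$resid[rows]
  n_ca <- tabulate(resid, nbins = ensemble$n_res)
  bad <- which(n_ca != 1L)
  if (length(bad) > 0L)
    stop("residue(s) without a single CA atom: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  rows[order(resid)]
}

#' Calpha contact-probability map of an ensemble
#'
#' A residue pair is in contact in a frame when its CA-CA distance is
#' within the cutoff (inclusive: exactly 12.0 A counts). The probability is
#' the pooled fraction of contact frames over all frames of all replicates
#' — contacts are summed across every frame and normalized once.
#'
#' @param ensemble a `cv_ensemble`
#' @param cutoff contact cutoff in Angstrom (default 12)
#' @return object of class `contact_map`: `$p` (symmetric residue x residue
#'   probability matrix with unit diagonal), `$cutoff`, `$n_frames`,
#'   `$replicates`
#' @export
contact_map <- function(ensemble, cutoff = 12) {
  stopifnot(inherits(ensemble, "cv_ensemble"))
  if (cutoff <= 0) stop("cutoff must be positive")
  rows <- ensemble_ca_rows(ensemble)
  nf <- n_frames(ensemble)
  counts <- matrix(0, length(rows), length(rows))
  for (f in seq_len(nf)) {
    ca <- ensemble$coords[rows, , f]
    D <- as.matrix(stats::dist(ca))
    counts <- counts + (D <= cutoff)
  }
  p <- counts / nf
  dimnames(p) <- list(seq_len(ensemble$n_res), seq_len(ensemble$n_res))
  structure(list(p = p, cutoff = cutoff, n_frames = nf,
                 replicates = table(ensemble$replicate)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "contact_map: %d residues, cutoff %g A, %d frames (%d replicate(s))\n",
    nrow(x$p), x$cutoff, x$n_frames, length(x$replicates)))
  invisible(x)
}

#' Contact map over a set of predicted models
#'
#' Treats each model as one frame — the averaging used for predictor
#' outputs, where contact probabilities are averaged across all relaxed
#' models rather than over a trajectory.
#'
#' @param structures list of `cv_structure` models sharing topology
#' @param cutoff contact cutoff in Angstrom (default 12)
#' @return a `contact_map`
#' @export
contact_map_from_models <- function(structures, cutoff = 12) {
  contact_map(cv_ensemble(structures), cutoff = cutoff)
}

#' Domain-aggregated contact summary
#'
#' Mean contact probability over each inter-domain block; intra-domain
#' blocks exclude the diagonal (self-contacts are trivially 1). Symmetric.
#'
#' @param map a `contact_map`
#' @param annotation a `domain_annotation` covering every residue of the
#'   map
#' @return square matrix (domains x domains) of mean probabilities
#' @export
domain_contact_summary <- function(map, annotation) {
  stopifnot(inherits(map, "contact_map"))
  n <- nrow(map$p)
  covered <- unlist(lapply(annotation$label, domain_indices,
                           annotation = annotation))
  uncovered <- setdiff(seq_len(n), covered)
  if (length(uncovered) > 0L)
    stop("annotation does not cover residue(s): ",
         paste(utils::head(uncovered, 10L), collapse = ", "),
         if (length(uncovered) > 10L) ", ..." else "")
  if (max(annotation$end) > n)
    stop("annotation extends beyond the map")
  labs <- annotation$label
  out <- matrix(NA_real_, length(labs), length(labs),
                dimnames = list(labs, labs))
  for (i in seq_along(labs)) {
    ri <- domain_indices(annotation, labs[i])
    for (j in seq_along(labs)) {
      rj <- domain_indices(annotation, labs[j])
      block <- map$p[ri, rj, drop = FALSE]
      if (i == j) {
        if (length(ri) < 2L) { out[i, j] <- NA_real_; next }
        diag(block) <- NA_real_
        out[i, j] <- mean(block, na.rm = TRUE)
      } else {
        out[i, j] <- mean(block)
      }
    }
  }
  out
}

#' Optimal rigid superposition (least-squares fit)
#'
#' Kabsch algorithm: the rotation + translation minimizing the RMSD
#' between matched point sets, with the reflection corrected so a proper
#' rotation is always returned.
#'
#' @param P n x 3 matrix of points to move
#' @param Q n x 3 matrix of target points (same n >= 3)
#' @return list with `rotation` (3 x 3), `transform(X)` applying the fit
#'   to arbitrary coordinates, and `rmsd` of the fitted points
#' @export
kabsch_fit <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L)
    stop("P and Q must be matched n x 3 matrices")
  if (nrow(P) < 3L) stop("superposition needs at least 3 points")
  cP <- colMeans(P); cQ <- colMeans(Q)
  Pc <- sweep(P, 2L, cP); Qc <- sweep(Q, 2L, cQ)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  transform <- function(X) sweep(sweep(as.matrix(X), 2L, cP) %*% R, 2L, cQ, "+")
  fitted <- transform(P)
  list(rotation = R, transform = transform,
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

#' Per-domain RMSD of an ensemble against a reference
#'
#' Each frame is first superposed onto the reference by a least-squares
#' rigid fit of the CA atoms of the `align_on` domain (or taken as-is with
#' `align_on = "none"`); the RMSD of each annotated domain is then computed
#' over its heavy atoms (default) without re-fitting, so domain motions
#' relative to the alignment frame are measured, not removed. When several
#' replicates of equal length are present, the per-time-point mean and
#' population standard deviation (n divisor) across replicates are
#' attached.
#'
#' @param ensemble a `cv_ensemble`
#' @param reference a `cv_structure` with the same topology
#' @param annotation a `domain_annotation`
#' @param align_on label of the domain used for superposition (needs >= 3
#'   residues), or "none"
#' @param heavy_only measure over heavy atoms only (default TRUE)
#' @return object of class `rmsd_trace`: `$values` (frames x domains
#'   matrix, Angstrom), `$replicate`, `$align_on`, and — when computable —
#'   `$mean` and `$sd` (time x domains, across replicates)
#' @export
per_domain_rmsd <- function(ensemble, reference, annotation,
                            align_on = "NTF2L", heavy_only = TRUE) {
  stopifnot(inherits(ensemble, "cv_ensemble"),
            inherits(reference, "cv_structure"))
  topo_cols <- c("resid", "resname", "atom", "chain", "element", "heavy")
  if (!identical(reference$atom[, topo_cols], ensemble$atom))
    stop("reference topology differs from the ensemble")
  ref_xyz <- as.matrix(reference$atom[, c("x", "y", "z")])
  ca_rows <- ensemble_ca_rows(ensemble)
  ca_resid <- ensemble$atom$resid[ca_rows]

  fit_rows <- NULL
  if (!identical(align_on, "none")) {
    idx <- domain_indices(annotation, align_on)
    fit_rows <- ca_rows[ca_resid %in% idx]
    if (length(fit_rows) < 3L)
      stop(sprintf("align_on domain '%s' has %d CA atom(s); the rigid fit needs >= 3",
                   align_on, length(fit_rows)))
  }
  labs <- annotation$label
  dom_rows <- lapply(labs, function(lab) {
    idx <- domain_indices(annotation, lab)
    r <- which(ensemble$atom$resid %in% idx)
    if (heavy_only) r <- r[ensemble$atom$heavy[r]]
    r
  })
  names(dom_rows) <- labs
  if (any(lengths(dom_rows) == 0L))
    stop("domain(s) with no measurable atoms: ",
         paste(labs[lengths(dom_rows) == 0L], collapse = ", "))

  nf <- n_frames(ensemble)
  values <- matrix(NA_real_, nf, length(labs),
                   dimnames = list(NULL, labs))
  for (f in seq_len(nf)) {
    X <- ensemble$coords[, , f]
    if (!is.null(fit_rows)) {
      fit <- kabsch_fit(X[fit_rows, , drop = FALSE],
                        ref_xyz[fit_rows, , drop = FALSE])
      X <- fit$transform(X)
    }
    for (k in seq_along(labs)) {
      r <- dom_rows[[k]]
      values[f, k] <- sqrt(mean(rowSums((X[r, , drop = FALSE] -
                                         ref_xyz[r, , drop = FALSE])^2)))
    }
  }
  out <- list(values = values, replicate = ensemble$replicate,
              align_on = align_on, heavy_only = heavy_only)
  reps <- split(seq_len(nf), ensemble$replicate)
  if (length(reps) > 1L && length(unique(lengths(reps))) == 1L) {
    nt <- lengths(reps)[[1L]]
    arr <- array(NA_real_, c(nt, length(labs), length(reps)))
    for (r in seq_along(reps)) arr[, , r] <- values[reps[[r]], , drop = FALSE]
    out$mean <- apply(arr, c(1L, 2L), mean)
    out$sd <- apply(arr, c(1L, 2L), function(v)
      sqrt(mean((v - mean(v))^2)))  # population SD across replicates
    dimnames(out$mean) <- dimnames(out$sd) <- list(NULL, labs)
  }
  class(out) <- "rmsd_trace"
  out
}

#' @export
print.rmsd_trace <- function(x, ...) {
  cat(sprintf(
    "rmsd_trace: %d frames x %d domains (align_on = %s, %s atoms)\n",
    nrow(x$values), ncol(x$values), x$align_on,
    if (x$heavy_only) "heavy" else "all"))
  cat("  final-frame RMSD (A):\n")
  print(round(x$values[nrow(x$values), ], 3))
  invisible(x)
}

#' @export
as.data.frame.rmsd_trace <- function(x, ...) {
  nf <- nrow(x$values)
  labs <- colnames(x$values)
  data.frame(frame = rep(seq_len(nf), times = length(labs)),
             replicate = rep(x$replicate, times = length(labs)),
             domain = rep(labs, each = nf),
             rmsd = as.vector(x$values),
             stringsAsFactors = FALSE)
}
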