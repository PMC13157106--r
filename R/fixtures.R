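# Deterministic toy structures and ensembles with planted properties.
# Geometry is synthetic: structured ranges are ideal helical CA traces,
# disordered ranges are self-avoiding 3.8 A random walks. Adequate for
# exercising losses, optimization and analytics; not physically realistic
# conformers (no sequence-dependent geometry).

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Fixture specification for a toy multi-domain complex
#'
#' @param chains list of chains; each chain is a list with `id` (chain
#'   letter) and `segments`, a list of segments each carrying `label`,
#'   `length` (residues), `structured` (logical) and optionally `resname`
#'   (3-letter code(s), recycled; default "ALA" for structured, "GLY" for
#'   disordered segments)
#' @return object of class `fixture_spec`
#' @export
fixture_spec <- function(chains) {
  if (length(chains) == 0L) stop("fixture needs at least one chain")
  for (ch in chains) {
    if (length(ch$segments) == 0L) stop("chain with no segments")
    for (seg in ch$segments)
      if (is.null(seg$length) || seg$length < 1L)
        stop("zero-length segment in fixture spec")
  }
  structure(list(chains = chains), class = "fixture_spec")
}

#' Single-chain fixture spec
#'
#' @param n number of residues
#' @param label segment label
#' @param structured helix (TRUE) or random walk (FALSE)
#' @return a `fixture_spec`
#' @export
toy_fixture_spec <- function(n = 30L, label = "CHAIN", structured = FALSE) {
  fixture_spec(list(list(id = "A", segments = list(
    list(label = label, length = as.integer(n), structured = structured)))))
}

# ideal helix CA trace: 100 deg turn, 1.5 A rise, radius chosen so the
# consecutive CA distance is exactly 3.8 A
helix_trace <- function(n) {
  turn <- 100 * pi / 180
  rise <- 1.5
  radius <- sqrt(3.8^2 - rise^2) / (2 * sin(turn / 2))
  t <- seq_len(n) - 1L
  cbind(radius * cos(turn * t), radius * sin(turn * t), rise * t)
}

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# fixed-step random walk with minimal self-avoidance: reject steps closer
# than 2 A to any of the last 20 placed residues
walk_trace <- function(n, start, recent = NULL, min_sep = 2, window = 20L) {
  pts <- matrix(NA_real_, n, 3L)
  pts[1L, ] <- start
  for (i in seq_len(n)[-1L]) {
    prev <- pts[i - 1L, ]
    look <- rbind(recent, pts[max(1L, i - window):(i - 1L), , drop = FALSE])
    for (try in seq_len(200L)) {
      cand <- prev + 3.8 * random_unit()
      d2 <- rowSums(sweep(look, 2L, cand)^2)
      if (all(d2[-nrow(look)] >= min_sep^2)) break
    }
    pts[i, ] <- cand
  }
  pts
}

#' Build a deterministic toy multi-domain complex
#'
#' Structured segments are ideal helical CA traces, disordered segments are
#' self-avoiding random walks; consecutive CA atoms are 3.8 A apart within
#' a chain. Chains are laid out left to right with a fixed offset so that
#' inter-chain contacts start unformed. Identical spec + seed gives
#' identical coordinates.
#'
#' @param spec a `fixture_spec`
#' @param seed RNG seed controlling disordered geometry and helix placement
#' @param with_cb add a CB heavy atom to every non-glycine residue
#' @param with_h add an HA hydrogen to every residue (to exercise
#'   heavy-atom filtering)
#' @return list with `structure` (a `cv_structure`) and `annotation`
#'   (a `domain_annotation` over the segments)
#' @export
make_toy_complex <- function(spec, seed = 1L, with_cb = TRUE,
                             with_h = FALSE) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(seed, {
    ca <- NULL
    ann <- list()
    rec <- list()
    chain_offset <- c(0, 0, 0)
    global <- 0L
    for (ch in spec$chains) {
      prev_pt <- NULL
      chain_pts <- NULL
      for (seg in ch$segments) {
        n <- as.integer(seg$length)
        if (isTRUE(seg$structured)) {
          h <- helix_trace(n) %*% random_rotation()
          anchor <- if (is.null(prev_pt)) chain_offset else
            prev_pt + 3.8 * random_unit()
          h <- sweep(h, 2L, h[1L, ] - anchor, "-")
          pts <- h
        } else {
          start <- if (is.null(prev_pt)) chain_offset else
            prev_pt + 3.8 * random_unit()
          pts <- walk_trace(n, start, recent = chain_pts)
        }
        default_name <- if (isTRUE(seg$structured)) "ALA" else "GLY"
        resnames <- rep(if (is.null(seg$resname)) default_name else
          seg$resname, length.out = n)
        ann[[length(ann) + 1L]] <- data.frame(
          label = seg$label, start = global + 1L, end = global + n,
          structured = isTRUE(seg$structured))
        for (i in seq_len(n)) {
          rec[[length(rec) + 1L]] <- data.frame(
            chain = ch$id, resno = global + i, resname = resnames[i],
            atom = "CA", x = pts[i, 1L], y = pts[i, 2L], z = pts[i, 3L])
        }
        chain_pts <- rbind(chain_pts, pts)
        prev_pt <- pts[n, ]
        global <- global + n
      }
      ca <- rbind(ca, chain_pts)
      # next chain starts well clear of this one, along +x
      chain_offset <- c(max(ca[, 1L]) + 40, 0, 0)
    }
    records <- do.call(rbind, rec)
    ann <- do.call(rbind, ann)

    if (with_cb || with_h) {
      extra <- list()
      n_tot <- nrow(records)
      for (i in seq_len(n_tot)) {
        prev <- ca[max(1L, i - 1L), ]
        nxt <- ca[min(n_tot, i + 1L), ]
        t <- nxt - prev
        tn <- sqrt(sum(t^2))
        t <- if (tn > 1e-8) t / tn else c(1, 0, 0)
        u <- c(t[2L], -t[1L], 0)
        un <- sqrt(sum(u^2))
        u <- if (un > 1e-8) u / un else c(0, 0, 1)
        if (with_cb && records$resname[i] != "GLY")
          extra[[length(extra) + 1L]] <- data.frame(
            chain = records$chain[i], resno = records$resno[i],
            resname = records$resname[i], atom = "CB",
            x = ca[i, 1L] + 1.53 * u[1L], y = ca[i, 2L] + 1.53 * u[2L],
            z = ca[i, 3L] + 1.53 * u[3L])
        if (with_h)
          extra[[length(extra) + 1L]] <- data.frame(
            chain = records$chain[i], resno = records$resno[i],
            resname = records$resname[i], atom = "HA",
            x = ca[i, 1L] - 1.0 * u[1L], y = ca[i, 2L] - 1.0 * u[2L],
            z = ca[i, 3L] - 1.0 * u[3L])
      }
      if (length(extra) > 0L) {
        records <- rbind(records, do.call(rbind, extra))
        records <- records[order(records$resno,
                                 records$atom != "CA"), , drop = FALSE]
      }
    }
    list(structure = build_structure(records),
         annotation = domain_annotation(ann$label, ann$start, ann$end,
                                        ann$structured))
  })
}

#' Toy G3BP1-GR20 complex at the published topology
#'
#' A 506-residue two-chain synthetic complex: chain A mimics full-length
#' G3BP1 (466 residues; NTF2L 1-142 and RRM 340-415 as structured helical
#' traces, the IDRs as random walks) and chain B mimics GR20 (40 residues,
#' 20 Gly-Arg repeats, global indices 467-506). The geometry is synthetic;
#' only the topology, indexing and domain layout follow the real system.
#'
#' @inheritParams make_toy_complex
#' @return list with `structure` and `annotation`
#' @export
g3bp1_gr20_fixture <- function(seed = 1L, with_cb = TRUE) {
  ann <- g3bp1_gr20_annotation()
  seg <- function(lab) {
    i <- match(lab, ann$label)
    list(label = lab, length = ann$end[i] - ann$start[i] + 1L,
         structured = ann$structured[i])
  }
  chains <- list(
    list(id = "A", segments = lapply(
      c("NTF2L", "IDR1", "IDR2", "RRM", "IDR3"), seg)),
    list(id = "B", segments = list(
      c(seg("GR20"), list(resname = c("GLY", "ARG"))))))
  make_toy_complex(fixture_spec(chains), seed = seed, with_cb = with_cb)
}

#' Synthetic ensemble with planted contact occupancies
#'
#' Perturbs a base structure with Gaussian CA noise and plants contacts:
#' for each planned residue pair, the second residue is rigidly moved so
#' the pair's CA-CA distance is below the 12 A contact cutoff in exactly
#' `round(occupancy * n_frames)` frames (chosen in seed-randomized order)
#' and above it in the rest. Occupancies are therefore recovered exactly
#' by [contact_map()], not statistically. Planted pairs should not share
#' residues.
#'
#' @param base a `cv_structure`
#' @param contact_plan NULL or data.frame with columns `i`, `j` (global
#'   residue indices) and `occupancy` in `[0, 1]`
#' @param n_frames number of frames (>= 1)
#' @param noise_sd per-coordinate Gaussian noise SD in Angstrom (default 0)
#' @param seed RNG seed
#' @param replicate optional replicate label per frame (default: frames
#'   split evenly into `n_replicates` consecutive blocks)
#' @param n_replicates number of replicates when `replicate` is NULL
#' @param contact_distance,noncontact_distance planted CA-CA distances for
#'   in-contact and out-of-contact frames (defaults 6 and 20 A)
#' @return a `cv_ensemble`
#' @export
make_synthetic_ensemble <- function(base, contact_plan = NULL, n_frames,
                                    noise_sd = 0, seed = 1L,
                                    replicate = NULL, n_replicates = 1L,
                                    contact_distance = 6,
                                    noncontact_distance = 20) {
  stopifnot(inherits(base, "cv_structure"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (!is.null(contact_plan)) {
    if (!all(c("i", "j", "occupancy") %in% names(contact_plan)))
      stop("contact_plan needs columns i, j, occupancy")
    if (any(contact_plan$occupancy < 0 | contact_plan$occupancy > 1))
      stop("occupancy must lie in [0, 1]")
    if (any(contact_plan$i > base$n_res | contact_plan$j > base$n_res))
      stop("contact_plan residue index beyond the structure")
  }
  with_seed(seed, {
    base_xyz <- as.matrix(base$atom[, c("x", "y", "z")])
    resid <- base$atom$resid
    ca_row_of <- function(r) which(resid == r & base$atom$atom == "CA")[1L]
    plan_frames <- list()
    if (!is.null(contact_plan)) {
      for (p in seq_len(nrow(contact_plan))) {
        k <- round(contact_plan$occupancy[p] * n_frames)
        plan_frames[[p]] <- sample.int(n_frames, k)
      }
    }
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      xyz <- base_xyz
      if (noise_sd > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sd),
                            ncol = 3L)
      if (!is.null(contact_plan)) {
        for (p in seq_len(nrow(contact_plan))) {
          ri <- contact_plan$i[p]; rj <- contact_plan$j[p]
          target <- if (f %in% plan_frames[[p]]) contact_distance
                    else noncontact_distance
          ci <- xyz[ca_row_of(ri), ]
          cj <- xyz[ca_row_of(rj), ]
          u <- cj - ci
          un <- sqrt(sum(u^2))
          u <- if (un > 1e-8) u / un else c(1, 0, 0)
          shift <- (ci + target * u) - cj
          rows_j <- which(resid == rj)
          xyz[rows_j, ] <- sweep(xyz[rows_j, , drop = FALSE], 2L, shift, "+")
        }
      }
      s <- base
      s$atom$x <- xyz[, 1L]; s$atom$y <- xyz[, 2L]; s$atom$z <- xyz[, 3L]
      frames[[f]] <- s
    }
    if (is.null(replicate))
      replicate <- rep(seq_len(n_replicates), each = ceiling(n_frames / n_replicates))[seq_len(n_frames)]
    cv_ensemble(frames, replicate = replicate)
  })
}
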