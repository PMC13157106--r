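#' Residue group
#'
#' A labelled set of global residue indices used as one side of a CV term.
#'
#' @param label group name
#' @param indices 1-based global residue indices
#' @return object of class `residue_group`
#' @export
residue_group <- function(label, indices) {
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop("residue group '", label, "' is empty")
  if (any(indices < 1L)) stop("residue group '", label, "' has indices < 1")
  structure(list(label = as.character(label), indices = indices),
            class = "residue_group")
}

#' Collective-variable distance term
#'
#' An attractive term penalizes group separation beyond the cutoff via
#' max(mean(d - d_c), 0); a repulsive term penalizes proximity via
#' max(mean(d_c - d), 0), where d are CA-CA distances between the two
#' groups. Pairing `all_pairs` takes the Cartesian product of the groups;
#' `positional` pairs i-th with i-th and requires equal sizes.
#'
#' @param kind "attractive" or "repulsive"
#' @param group_a,group_b `residue_group` objects
#' @param cutoff distance cutoff d_c in Angstrom (> 0); default 8
#' @param pairing "all_pairs" (default) or "positional"
#' @return object of class `cv_term`
#' @export
cv_term <- function(kind = c("attractive", "repulsive"), group_a, group_b,
                    cutoff = 8, pairing = c("all_pairs", "positional")) {
  kind <- match.arg(kind)
  pairing <- match.arg(pairing)
  stopifnot(inherits(group_a, "residue_group"),
            inherits(group_b, "residue_group"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff d_c must be a single positive number")
  if (pairing == "positional" &&
      length(group_a$indices) != length(group_b$indices))
    stop(sprintf("positional pairing requires equal group sizes (%d vs %d)",
                 length(group_a$indices), length(group_b$indices)))
  structure(list(kind = kind, group_a = group_a, group_b = group_b,
                 cutoff = cutoff, pairing = pairing),
            class = "cv_term")
}

#' @export
print.cv_term <- function(x, ...) {
  cat(sprintf("cv_term [%s] %s(%d) ~ %s(%d), d_c = %g A, %s\n",
              x$kind, x$group_a$label, length(x$group_a$indices),
              x$group_b$label, length(x$group_b$indices),
              x$cutoff, x$pairing))
  invisible(x)
}

#' Positional restraint specification
#'
#' Anchors the CA atoms of selected residues (typically the structured
#' domains) to a reference snapshot; the loss is the mean squared CA
#' displacement from that reference, in Angstrom^2.
#'
#' @param indices restrained global residue indices
#' @param reference n x 3 matrix of reference CA coordinates with rownames
#'   equal to global residue indices, covering every restrained index
#'   (typically `ca_coords(ref_structure)`)
#' @return object of class `restraint_spec`
#' @export
restraint_spec <- function(indices, reference) {
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop("restraint index set is empty")
  if (is.null(rownames(reference)))
    stop("reference coordinates need rownames = global residue indices")
  missing <- setdiff(as.character(indices), rownames(reference))
  if (length(missing) > 0L)
    stop("reference lacks coordinates for restrained residue(s): ",
         paste(missing, collapse = ", "))
  structure(list(indices = indices,
                 reference = reference[as.character(indices), , drop = FALSE]),
            class = "restraint_spec")
}

#' Restraint spec over the structured domains of an annotation
#'
#' @param structure reference `cv_structure` supplying the snapshot
#' @param annotation a `domain_annotation`; all ranges with
#'   `structured = TRUE` are restrained
#' @param domains optional character vector restricting to specific labels
#' @return a `restraint_spec`
#' @export
structured_restraint <- function(structure, annotation, domains = NULL) {
  if (is.null(domains)) domains <- annotation$label[annotation$structured]
  if (length(domains) == 0L)
    stop("annotation has no structured domain to restrain")
  not_structured <- setdiff(
    domains, annotation$label[annotation$structured])
  if (length(not_structured) > 0L)
    stop("domain(s) not flagged structured: ",
         paste(not_structured, collapse = ", "))
  idx <- unlist(lapply(domains, domain_indices, annotation = annotation))
  restraint_spec(idx, ca_coords(structure, idx))
}

#' Annealing schedule for the constraint and regularizer weights
#'
#' Over `n_steps` optimization steps the constraint weight w_c is annealed
#' from `w_c_start` to `w_c_end` and the regularizer weight w_r from
#' `w_r_start` to `w_r_end`. The defaults follow the published protocol:
#' w_c starts at 1 to strongly enforce the spatial constraints and is
#' gradually reduced to 0.1, while w_r starts at 0 and is incrementally
#' increased to 1, letting late iterates trade constraint pressure for
#' model confidence.
#'
#' @param n_steps number of optimization steps (>= 1)
#' @param w_c_start,w_c_end constraint-weight endpoints (>= 0)
#' @param w_r_start,w_r_end regularizer-weight endpoints (>= 0)
#' @param interpolation "linear", or "staircase" with `k` levels
#' @param k number of staircase levels (>= 2), used only for staircase
#' @return object of class `weight_schedule`
#' @export
weight_schedule <- function(n_steps, w_c_start = 1, w_c_end = 0.1,
                            w_r_start = 0, w_r_end = 1,
                            interpolation = c("linear", "staircase"),
                            k = 5L) {
  interpolation <- match.arg(interpolation)
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  w <- c(w_c_start, w_c_end, w_r_start, w_r_end)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  if (interpolation == "staircase" && k < 2L)
    stop("staircase interpolation needs k >= 2 levels")
  structure(list(n_steps = n_steps,
                 w_c_start = w_c_start, w_c_end = w_c_end,
                 w_r_start = w_r_start, w_r_end = w_r_end,
                 interpolation = interpolation, k = as.integer(k)),
            class = "weight_schedule")
}

#' Evaluate the weight schedule at one step
#'
#' Steps are 0-based: step 0 returns the start weights exactly and step
#' `n_steps - 1` the end weights exactly. A schedule of length 1 returns the
#' end weights.
#'
#' @param schedule a `weight_schedule`
#' @param step integer in `[0, n_steps - 1]`
#' @return named numeric vector `c(w_c = ..., w_r = ...)`
#' @examples
#' s <- weight_schedule(500)
#' schedule_weights(s, 0)    # c(w_c = 1,   w_r = 0)
#' schedule_weights(s, 499)  # c(w_c = 0.1, w_r = 1)
#' @export
schedule_weights <- function(schedule, step) {
  stopifnot(inherits(schedule, "weight_schedule"))
  step <- as.integer(step)
  n <- schedule$n_steps
  if (step < 0L || step >= n)
    stop(sprintf("step %d out of range [0, %d]", step, n - 1L))
  t <- if (n == 1L) 1 else step / (n - 1L)
  if (schedule$interpolation == "staircase") {
    k <- schedule$k
    level <- min(floor(t * k), k - 1L)
    t <- level / (k - 1L)
  }
  # convex-combination form: endpoints are exact, not within rounding
  c(w_c = (1 - t) * schedule$w_c_start + t * schedule$w_c_end,
    w_r = (1 - t) * schedule$w_r_start + t * schedule$w_r_end)
}
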