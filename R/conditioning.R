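#' Constraint-conditioned structure optimization
#'
#' Runs the scheduled gradient-descent conditioning: at each step the
#' generator produces coordinates and a confidence bundle from its
#' parameters theta, the composite loss
#' `l_afex = w_c * (l_rest + l_attr + l_repl) + w_r * l_regular`
#' is evaluated at the step's annealed weights, and its gradient is pulled
#' back through the generator to update theta (plain gradient descent with
#' optional momentum). The returned fit keeps the full per-step trace and
#' the best-by-composite-loss iterate — under annealing the composite can
#' rise late in the run, so the best iterate need not be the last.
#'
#' @param generator a generator honouring the contract of
#'   [toy_chain_generator()] (`theta_init`, `produce`, `pullback`,
#'   optionally `materialize`)
#' @param restraint a `restraint_spec` or NULL
#' @param cv_terms list of `cv_term` objects
#' @param schedule a `weight_schedule`; its `n_steps` is the number of
#'   optimization steps
#' @param step_size gradient-descent step size (default 0.05)
#' @param momentum momentum coefficient in `[0, 1)` (default 0, plain
#'   descent)
#' @param seed integer recorded with the fit and applied to R's RNG for
#'   any stochastic generator; the bundled toy generator is deterministic
#' @param per_pair_clamp see [attractive_loss()]
#' @return object of class `afex_fit`: `trace` (data.frame of step, w_c,
#'   w_r and every loss term), `theta` (best iterate), `best_step`,
#'   `coords`, `confidence`, `structure` (if the generator materializes),
#'   `satisfaction` (per-term report at the best iterate), `seed`,
#'   `converged`
#' @examples
#' fx <- make_toy_complex(toy_fixture_spec(n = 30), seed = 1)
#' gen <- toy_chain_generator(fx$structure)
#' tm <- cv_term("attractive", residue_group("a", 5), residue_group("b", 25))
#' fit <- afex_condition(gen, cv_terms = list(tm),
#'                       schedule = weight_schedule(50), seed = 1)
#' @export
afex_condition <- function(generator, restraint = NULL, cv_terms = list(),
                           schedule, step_size = 0.05, momentum = 0,
                           seed = 1L, per_pair_clamp = FALSE) {
  stopifnot(inherits(schedule, "weight_schedule"))
  if (momentum < 0 || momentum >= 1) stop("momentum must lie in [0, 1)")
  if (step_size <= 0) stop("step_size must be positive")
  n_steps <- schedule$n_steps

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  theta <- generator$theta_init
  velocity <- theta * 0
  cols <- c("step", "w_c", "w_r", "l_rest", "l_attr", "l_repl", "l_cv",
            "l_regular", "l_afex")
  trace <- matrix(NA_real_, n_steps, length(cols),
                  dimnames = list(NULL, cols))
  best <- list(l_afex = Inf)

  for (step in seq_len(n_steps) - 1L) {
    w <- schedule_weights(schedule, step)
    out <- generator$produce(theta)
    lb <- afex_loss(out$coords, restraint, cv_terms, out$confidence,
                    w_c = w[["w_c"]], w_r = w[["w_r"]],
                    per_pair_clamp = per_pair_clamp)
    if (!is.finite(lb$l_afex)) {
      bad <- c(l_rest = lb$l_rest, l_attr = lb$l_attr, l_repl = lb$l_repl,
               l_regular = lb$l_regular)
      stop(sprintf("non-finite loss at step %d (offending term: %s)",
                   step, names(bad)[which(!is.finite(bad))[1L]]))
    }
    trace[step + 1L, ] <- c(step, w[["w_c"]], w[["w_r"]], lb$l_rest,
                            lb$l_attr, lb$l_repl, lb$l_cv, lb$l_regular,
                            lb$l_afex)
    if (lb$l_afex < best$l_afex)
      best <- list(l_afex = lb$l_afex, theta = theta, step = step,
                   coords = out$coords, confidence = out$confidence)

    g_coords <- loss_gradient(out$coords, restraint, cv_terms,
                              w_c = w[["w_c"]],
                              per_pair_clamp = per_pair_clamp)
    g_conf <- if (w[["w_r"]] > 0) {
      gr <- regularization_gradient(out$confidence)
      gr$plddt <- w[["w_r"]] * gr$plddt
      gr$ptm <- w[["w_r"]] * gr$ptm
      gr$iptm <- w[["w_r"]] * gr$iptm
      gr
    } else NULL
    g_theta <- generator$pullback(theta, g_coords, g_conf)
    if (any(!is.finite(g_theta)))
      stop(sprintf("non-finite gradient at step %d", step))
    velocity <- momentum * velocity - step_size * g_theta
    theta <- theta + velocity
  }

  final_grad_norm <- sqrt(sum(g_theta^2))
  struct <- if (is.function(generator$materialize))
    generator$materialize(best$theta) else NULL
  sat <- cv_satisfaction(best$coords, restraint, cv_terms)
  structure(list(trace = as.data.frame(trace),
                 theta = best$theta, best_step = best$step,
                 coords = best$coords, confidence = best$confidence,
                 structure = struct, satisfaction = sat,
                 schedule = schedule, step_size = step_size,
                 momentum = momentum, seed = as.integer(seed),
                 converged = final_grad_norm < 1e-6,
                 final_grad_norm = final_grad_norm),
            class = "afex_fit")
}

#' @export
print.afex_fit <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf("afex_fit: %d steps, best l_afex = %.6g at step %d\n",
              n, x$trace$l_afex[x$best_step + 1L], x$best_step))
  cat(sprintf("  weights: w_c %g -> %g, w_r %g -> %g; step size %g; seed %d\n",
              x$trace$w_c[1L], x$trace$w_c[n], x$trace$w_r[1L],
              x$trace$w_r[n], x$step_size, x$seed))
  cat(sprintf("  final |grad| = %.3g (%s)\n", x$final_grad_norm,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
summary.afex_fit <- function(object, ...) {
  tr <- object$trace
  n <- nrow(tr)
  out <- list(
    n_steps = n, best_step = object$best_step,
    initial = tr[1L, ], final = tr[n, ],
    best = tr[object$best_step + 1L, ],
    satisfaction = object$satisfaction,
    converged = object$converged)
  class(out) <- "summary.afex_fit"
  out
}

#' @export
print.summary.afex_fit <- function(x, ...) {
  cat(sprintf("Constraint-conditioning fit over %d steps (best at step %d)\n",
              x$n_steps, x$best_step))
  tab <- rbind(initial = x$initial, best = x$best, final = x$final)
  print(round(tab[, -1L], 4))
  cat("\nCV satisfaction at best iterate:\n")
  print(x$satisfaction)
  invisible(x)
}

#' @export
coef.afex_fit <- function(object, ...) object$theta

#' @export
fitted.afex_fit <- function(object, ...) object$coords

#' Loss and weight traces of a conditioning run
#'
#' @param x an `afex_fit`
#' @param which trace columns to draw (default: the three CV components and
#'   the composite)
#' @param ... passed to [graphics::matplot()]
#' @export
plot.afex_fit <- function(x, which = c("l_cv", "l_regular", "l_afex"), ...) {
  tr <- x$trace
  graphics::matplot(tr$step, tr[, which, drop = FALSE], type = "l", lty = 1,
                    xlab = "step", ylab = "loss", ...)
  graphics::legend("topright", legend = which, col = seq_along(which),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Per-term constraint satisfaction report
#'
#' Audits a set of coordinates against the restraint and CV terms: for each
#' distance term the current mean pair distance, cutoff, clamped loss and a
#' satisfied flag (attractive: mean <= d_c; repulsive: mean >= d_c); for
#' the positional restraint the RMSD from its reference.
#'
#' @param coords CA coordinate matrix (rownames = global residue indices)
#'   or a `cv_structure`
#' @param restraint a `restraint_spec` or NULL
#' @param cv_terms list of `cv_term`
#' @return data.frame with one row per term (restraint last when present):
#'   `term`, `kind`, `pairing`, `n_pairs`, `mean_distance`, `cutoff`,
#'   `loss`, `satisfied`
#' @export
cv_satisfaction <- function(coords, restraint = NULL, cv_terms = list()) {
  if (inherits(coords, "cv_structure")) coords <- ca_coords(coords)
  rows <- list()
  for (term in cv_terms) {
    d <- term_distances(coords, term)
    loss <- if (term$kind == "attractive")
      max(mean(d) - term$cutoff, 0) else max(term$cutoff - mean(d), 0)
    rows[[length(rows) + 1L]] <- data.frame(
      term = sprintf("%s~%s", term$group_a$label, term$group_b$label),
      kind = term$kind, pairing = term$pairing, n_pairs = length(d),
      mean_distance = mean(d), cutoff = term$cutoff, loss = loss,
      satisfied = loss == 0, stringsAsFactors = FALSE)
  }
  if (!is.null(restraint)) {
    l <- restraint_loss(coords, restraint)
    rows[[length(rows) + 1L]] <- data.frame(
      term = "restraint", kind = "restraint", pairing = NA_character_,
      n_pairs = length(restraint$indices), mean_distance = NA_real_,
      cutoff = NA_real_, loss = l, satisfied = NA,
      stringsAsFactors = FALSE)
    # loss column for the restraint row is the mean squared displacement
    # (A^2); its square root is the positional RMSD from the reference
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term = character(), kind = character(),
                      pairing = character(), n_pairs = integer(),
                      mean_distance = numeric(), cutoff = numeric(),
                      loss = numeric(), satisfied = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-pair distance detail for the satisfaction report
#'
#' @inheritParams cv_satisfaction
#' @param term a single `cv_term`
#' @return data.frame of `res_a`, `res_b`, `distance`, `within_cutoff`
#' @export
cv_pair_distances <- function(coords, term) {
  if (inherits(coords, "cv_structure")) coords <- ca_coords(coords)
  td <- term_distances(coords, term, with_pairs = TRUE)
  data.frame(res_a = td$a[td$pairs[, 1L]], res_b = td$b[td$pairs[, 2L]],
             distance = td$d, within_cutoff = td$d <= term$cutoff)
}
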