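#' Load and validate a CV configuration file
#'
#' The configuration is declarative YAML: named residue groups, CV terms
#' referencing them, the restrained structured domains, the weight
#' schedule, and optimizer options. Group entries are global 1-based
#' residue indices; the alternative `"chain:resno"` addressing (e.g.
#' `"B:11"`) is accepted and normalized against the structure. Unknown
#' keys are rejected with their location.
#'
#' @param path YAML config file
#' @param structure the `cv_structure` the config applies to (for index
#'   validation and the restraint reference snapshot)
#' @param annotation a `domain_annotation` resolving the restraint's
#'   domain labels
#' @return object of class `cv_config`: list with `groups` (named list of
#'   `residue_group`), `terms` (list of `cv_term`), `restraint`
#'   (`restraint_spec` or NULL), `restraint_domains`, `schedule`
#'   (`weight_schedule`), `optimizer` (list), `seed`
#' @export
load_cv_config <- function(path, structure, annotation = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("groups", "terms", "restraint", "schedule", "optimizer", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$groups) || length(raw$groups) == 0L)
    stop("config has no 'groups' section")
  if (is.null(raw$terms) || length(raw$terms) == 0L)
    stop("config has no 'terms' section")

  groups <- lapply(names(raw$groups), function(gname) {
    idx <- vapply(raw$groups[[gname]], normalize_residue_ref, 0L,
                  structure = structure,
                  where = sprintf("groups/%s", gname))
    residue_group(gname, idx)
  })
  names(groups) <- names(raw$groups)

  terms <- lapply(seq_along(raw$terms), function(t) {
    tm <- raw$terms[[t]]
    where <- sprintf("terms[%d]", t)
    unknown <- setdiff(names(tm), c("kind", "group_a", "group_b", "cutoff",
                                    "pairing"))
    if (length(unknown) > 0L)
      stop(sprintf("unknown key(s) in %s: %s", where,
                   paste(unknown, collapse = ", ")))
    for (g in c("group_a", "group_b")) {
      if (is.null(tm[[g]]) || is.null(groups[[tm[[g]]]]))
        stop(sprintf("%s: %s references unknown group '%s'", where, g,
                     if (is.null(tm[[g]])) "<missing>" else tm[[g]]))
    }
    if (is.null(tm$kind) || !tm$kind %in% c("attractive", "repulsive"))
      stop(sprintf("%s: kind must be 'attractive' or 'repulsive'", where))
    cutoff <- if (is.null(tm$cutoff)) 8 else tm$cutoff
    if (!is.numeric(cutoff) || cutoff <= 0)
      stop(sprintf("%s: cutoff d_c must be positive", where))
    cv_term(tm$kind, groups[[tm$group_a]], groups[[tm$group_b]],
            cutoff = cutoff,
            pairing = if (is.null(tm$pairing)) "all_pairs" else tm$pairing)
  })

  restraint <- NULL
  restraint_domains <- character(0)
  if (!is.null(raw$restraint)) {
    unknown <- setdiff(names(raw$restraint), "domains")
    if (length(unknown) > 0L)
      stop("unknown key(s) in restraint: ", paste(unknown, collapse = ", "))
    restraint_domains <- as.character(unlist(raw$restraint$domains))
    if (length(restraint_domains) > 0L) {
      if (is.null(annotation))
        stop("config restrains domains but no annotation was supplied")
      restraint <- structured_restraint(structure, annotation,
                                        restraint_domains)
    }
  }

  sch <- raw$schedule
  if (is.null(sch)) sch <- list()
  unknown <- setdiff(names(sch), c("n_steps", "w_c", "w_r",
                                   "interpolation", "k"))
  if (length(unknown) > 0L)
    stop("unknown key(s) in schedule: ", paste(unknown, collapse = ", "))
  w_c <- if (is.null(sch$w_c)) c(1, 0.1) else as.numeric(unlist(sch$w_c))
  w_r <- if (is.null(sch$w_r)) c(0, 1) else as.numeric(unlist(sch$w_r))
  if (length(w_c) != 2L || length(w_r) != 2L)
    stop("schedule w_c and w_r must each give [start, end]")
  schedule <- weight_schedule(
    n_steps = if (is.null(sch$n_steps)) 500L else sch$n_steps,
    w_c_start = w_c[1L], w_c_end = w_c[2L],
    w_r_start = w_r[1L], w_r_end = w_r[2L],
    interpolation = if (is.null(sch$interpolation)) "linear" else
      sch$interpolation,
    k = if (is.null(sch$k)) 5L else sch$k)

  opt <- raw$optimizer
  if (is.null(opt)) opt <- list()
  unknown <- setdiff(names(opt), c("step_size", "momentum"))
  if (length(unknown) > 0L)
    stop("unknown key(s) in optimizer: ", paste(unknown, collapse = ", "))
  optimizer <- list(
    step_size = if (is.null(opt$step_size)) 0.05 else opt$step_size,
    momentum = if (is.null(opt$momentum)) 0 else opt$momentum)

  structure(list(groups = groups, terms = terms, restraint = restraint,
                 restraint_domains = restraint_domains,
                 schedule = schedule, optimizer = optimizer,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)),
            class = "cv_config")
}

# one residue reference: a global 1-based index, or "chain:resno"
normalize_residue_ref <- function(entry, structure, where) {
  if (is.numeric(entry)) {
    idx <- as.integer(entry)
  } else if (is.character(entry) && grepl(":", entry)) {
    parts <- strsplit(entry, ":", fixed = TRUE)[[1L]]
    at <- structure$atom
    hit <- unique(at$resid[at$chain == parts[1L] &
                           at$resno == as.integer(parts[2L])])
    if (length(hit) != 1L)
      stop(sprintf("%s: cannot resolve residue '%s'", where, entry))
    idx <- hit
  } else {
    stop(sprintf("%s: residue reference '%s' is neither an index nor chain:resno",
                 where, as.character(entry)))
  }
  if (idx < 1L || idx > structure$n_res)
    stop(sprintf("%s: residue index %d beyond the structure (%d residues)",
                 where, idx, structure$n_res))
  idx
}

#' @export
print.cv_config <- function(x, ...) {
  kinds <- vapply(x$terms, function(t) t$kind, "")
  cat(sprintf(
    "cv_config: %d group(s); %d attractive + %d repulsive term(s); %s; %d steps\n",
    length(x$groups), sum(kinds == "attractive"), sum(kinds == "repulsive"),
    if (is.null(x$restraint)) "no restraint" else
      paste("restraint on", paste(x$restraint_domains, collapse = "+")),
    x$schedule$n_steps))
  invisible(x)
}

#' Write a CV configuration back to YAML
#'
#' Emits the normalized form (global residue indices); loading the dumped
#' file reproduces identical groups, terms and schedule.
#'
#' @param config a `cv_config`
#' @param path output YAML file
#' @return `path`, invisibly
#' @export
dump_cv_config <- function(config, path) {
  stopifnot(inherits(config, "cv_config"))
  group_names <- names(config$groups)
  raw <- list(
    groups = lapply(config$groups, function(g) as.integer(g$indices)),
    terms = lapply(config$terms, function(t) list(
      kind = t$kind, group_a = t$group_a$label, group_b = t$group_b$label,
      cutoff = t$cutoff, pairing = t$pairing)),
    schedule = list(n_steps = config$schedule$n_steps,
                    w_c = c(config$schedule$w_c_start,
                            config$schedule$w_c_end),
                    w_r = c(config$schedule$w_r_start,
                            config$schedule$w_r_end),
                    interpolation = config$schedule$interpolation,
                    k = config$schedule$k),
    optimizer = config$optimizer,
    seed = config$seed)
  if (length(config$restraint_domains) > 0L)
    raw$restraint <- list(domains = as.list(config$restraint_domains))
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Path to a packaged CV preset
#'
#' `"g3bp1-gr20"` ships the published G3BP1-GR20 constraint set verbatim:
#' attractive terms between IDR1 anchors \{174, 187, 167, 163, 154\} and
#' GR20 anchors \{477, 475, 493, 495, 501\} and between IDR1 \{202\} and
#' IDR3 \{452\}; a repulsive term within GR20 between \{469, 473, 478,
#' 474\} and \{503, 492, 498, 502\}; d_c = 8 A throughout; positional
#' restraint on the structured NTF2L and RRM domains; w_c annealed 1 to
#' 0.1 and w_r 0 to 1.
#'
#' @param name preset name
#' @return path to the packaged YAML file
#' @export
cv_preset <- function(name = "g3bp1-gr20") {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "cvfold")
  if (path == "") stop("unknown preset '", name, "'")
  path
}
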