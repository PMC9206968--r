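#' Define a recovery archetype template
#'
#' An archetype is a latent severity surface over items and timepoints:
#' entry `[v, t]` is the expected latent severity (on `[0, 1]`) of item `v`
#' at visit `t` for patients drawn from this archetype, before noise,
#' treatment effect and discretization.
#'
#' @param name archetype name.
#' @param severity numeric matrix `[item, timepoint]` with entries in
#'   `[0, 1]`.
#' @param prevalence mixing proportion in `[0, 1]`.
#' @return An object of class `archetype_template`.
#' @export
archetype_template <- function(name, severity, prevalence) {
  severity <- as.matrix(severity)
  if (any(severity < 0) || any(severity > 1))
    stop("severity entries must lie in [0, 1]")
  if (prevalence < 0 || prevalence > 1)
    stop("prevalence must lie in [0, 1]")
  structure(list(name = name, severity = severity, prevalence = prevalence),
            class = "archetype_template")
}

#' Default planted recovery archetypes
#'
#' Three archetypes over the 15-item NIHSS catalog and 5 visits, mirroring
#' the lateralized subtype structure of ischemic stroke: a *left motor*
#' archetype (left arm/leg weakness with extinction and gaze deviation —
#' right-hemisphere lesions), a *right motor* archetype (right arm/leg
#' weakness with aphasia and impaired command following — left-hemisphere
#' lesions), and a *mildly affected* archetype with uniformly low severity.
#' Severity decays over visits (recovery); lateralized archetypes carry
#' essentially no contralateral motor involvement.
#'
#' @param catalog item catalog; defaults to [nihss_catalog()].
#' @param n_timepoints number of visits (default 5).
#' @return A list of three [archetype_template()] objects with equal
#'   prevalence 1/3.
#' @export
default_templates <- function(catalog = nihss_catalog(), n_timepoints = 5) {
  it <- catalog$item
  base <- function(x) {
    v <- stats::setNames(rep(0.08, length(it)), it)
    v[names(x)] <- x
    v
  }
  left <- base(c(
    MOTORLA = 0.95, MOTORLL = 0.90, EXTIN = 0.85, GAZE = 0.85,
    PALSY = 0.60, SENSORY = 0.55, VISUAL = 0.50, ATAXIA = 0.40,
    DYSAR = 0.35, CONSCIO = 0.10, MOTORRA = 0.05, MOTORRL = 0.05,
    LANG = 0.05, LOCCOM = 0.05, LOCQU = 0.05
  ))
  right <- base(c(
    MOTORRA = 0.95, MOTORRL = 0.90, LANG = 0.85, LOCCOM = 0.85,
    DYSAR = 0.60, PALSY = 0.60, SENSORY = 0.55, LOCQU = 0.55,
    VISUAL = 0.50, ATAXIA = 0.40, GAZE = 0.30, CONSCIO = 0.15,
    MOTORLA = 0.05, MOTORLL = 0.05, EXTIN = 0.05
  ))
  mild <- base(c(
    MOTORLA = 0.15, MOTORLL = 0.15, MOTORRA = 0.15, MOTORRL = 0.15,
    PALSY = 0.15, DYSAR = 0.12, SENSORY = 0.12
  ))
  # recovery: severity shrinks towards 0.3x the admission level by the
  # final visit, linearly in visit rank
  decay <- seq(1, 0.3, length.out = n_timepoints)
  tps <- as.character(seq_len(n_timepoints) - 1L)
  mk <- function(name, b) {
    sev <- outer(b, decay)
    dimnames(sev) <- list(it, tps)
    archetype_template(name, sev, 1 / 3)
  }
  list(mk("left_motor", left), mk("right_motor", right), mk("mild", mild))
}

#' Simulation configuration
#'
#' @param n_patients cohort size (default 300).
#' @param templates list of [archetype_template()]s; prevalences must sum
#'   to 1. Default [default_templates()].
#' @param treatment_fraction probability a patient is assigned to the
#'   treated arm (default 0.5).
#' @param treatment_recovery_boost extra per-visit decay of latent severity
#'   for treated patients (default 0.05 per visit).
#' @param noise_sd standard deviation of Gaussian noise on the latent
#'   severity before discretization (default 0.05).
#' @param seed RNG seed (default 42).
#' @param catalog item catalog matching the templates' item axis.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 300, templates = default_templates(),
                       treatment_fraction = 0.5,
                       treatment_recovery_boost = 0.05, noise_sd = 0.05,
                       seed = 42, catalog = nihss_catalog()) {
  if (length(templates) < 1L) stop("config error: at least one template required")
  if (!all(vapply(templates, inherits, TRUE, "archetype_template")))
    stop("templates must be archetype_template objects")
  if (n_patients < 2L) stop("config error: n_patients must be at least 2")
  prev <- vapply(templates, `[[`, 0, "prevalence")
  if (abs(sum(prev) - 1) > 1e-8)
    stop("config error: template prevalences must sum to 1")
  if (treatment_fraction < 0 || treatment_fraction > 1)
    stop("config error: treatment_fraction must lie in [0, 1]")
  if (treatment_recovery_boost < 0 || noise_sd < 0)
    stop("config error: boost and noise_sd must be nonnegative")
  dims <- vapply(templates, function(tp) dim(tp$severity), integer(2))
  if (any(dims != dims[, 1]))
    stop("config error: all templates must share one item x timepoint shape")
  if (dims[1, 1] != nrow(validate_item_catalog(catalog)))
    stop("config error: template item axis must match the catalog")
  structure(list(n_patients = as.integer(n_patients), templates = templates,
                 treatment_fraction = treatment_fraction,
                 treatment_recovery_boost = treatment_recovery_boost,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 catalog = validate_item_catalog(catalog)),
            class = "sim_config")
}

#' Generate a synthetic cohort with planted recovery archetypes
#'
#' Each patient draws an archetype by prevalence and a treatment arm by
#' `treatment_fraction`. The score of item `v` at visit `t` discretizes a
#' latent severity
#' `template_severity[v, t] - boost * t * I(treated) + N(0, noise_sd)`,
#' clamped to `[0, 1]` and mapped to `{0..max_score(v)}` by scaling and
#' rounding. Identical configurations (including seed) give bit-identical
#' cohorts. True archetype labels are returned alongside, never inside, the
#' cohort, so downstream stages cannot consume them by accident.
#'
#' @param config a [sim_config()].
#' @return A list with elements `cohort` (a [cohort_tensor()] with arm
#'   labels), `archetype` (named character vector of true labels) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_patients
  v <- nrow(config$catalog)
  m <- ncol(config$templates[[1]]$severity)
  k <- length(config$templates)
  set.seed(config$seed)
  prev <- vapply(config$templates, `[[`, 0, "prevalence")
  arch <- sample.int(k, n, replace = TRUE, prob = prev)
  treated <- stats::rbinom(n, 1L, config$treatment_fraction)
  noise <- array(stats::rnorm(n * v * m, 0, config$noise_sd), dim = c(n, v, m))
  sev <- array(0, dim = c(n, v, m))
  for (a in seq_len(k))
    sev[arch == a, , ] <- rep(config$templates[[a]]$severity,
                              each = sum(arch == a))
  # treatment accelerates recovery: extra linear decay of latent severity
  boost <- outer(treated * config$treatment_recovery_boost,
                 seq_len(m) - 1L)                          # n x m
  sev <- sev - aperm(array(boost, dim = c(n, m, v)), c(1, 3, 2)) + noise
  sev <- pmin(pmax(sev, 0), 1)
  maxes <- config$catalog$max_score
  scores <- round(sev * rep(maxes, each = n))
  width <- max(3L, nchar(as.character(n)))
  ids <- sprintf(paste0("P%0", width, "d"), seq_len(n))
  dimnames(scores) <- list(ids, config$catalog$item,
                           as.character(seq_len(m) - 1L))
  arm <- stats::setNames(c("placebo", "treated")[treated + 1L], ids)
  cohort <- cohort_tensor(scores, config$catalog, arm = arm)
  nm <- vapply(config$templates, `[[`, "", "name")
  list(cohort = cohort,
       archetype = stats::setNames(nm[arch], ids),
       config = config)
}

#' Empirical affected fraction per archetype
#'
#' For each true archetype, the fraction of its patients whose binarized
#' score (threshold `kappa`, see [binarize()]) equals 1, per item and
#' timepoint. With severities far from the discretization threshold and
#' small noise this converges to the template severity surface.
#'
#' @param cohort a [cohort_tensor()].
#' @param labels named archetype labels covering every patient.
#' @param kappa binarization threshold fraction in `(0, 1]`.
#' @return A named list of `[item, timepoint]` matrices, one per label.
#' @export
empirical_affected_fraction <- function(cohort, labels, kappa) {
  stopifnot(inherits(cohort, "cohort_tensor"))
  if (is.null(names(labels)) && length(labels) == length(cohort$patients))
    names(labels) <- cohort$patients
  if (!all(cohort$patients %in% names(labels)))
    stop("labels must cover every patient in the cohort")
  if (!all(names(labels) %in% cohort$patients))
    stop("unknown patient in labels: ",
         setdiff(names(labels), cohort$patients)[1])
  prof <- binarize(cohort, kappa)
  labs <- labels[cohort$patients]
  out <- lapply(sort(unique(labs)), function(l) {
    idx <- which(labs == l)
    f <- apply(prof[idx, , , drop = FALSE], c(2, 3), mean)
    dimnames(f) <- dimnames(prof)[2:3]
    f
  })
  stats::setNames(out, sort(unique(labs)))
}
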