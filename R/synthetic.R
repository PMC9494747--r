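#' Default ground-truth direct-influence matrix
#'
#' A plausible category-level direct-influence matrix (0-4 scale) for the
#' default protocol, constructed so that the climate categories (CL, LTCL)
#' and general site information (SI) are net influencers while SOI, MPDE,
#' LTMP and EDS are net receivers, matching the qualitative causal structure
#' expected of a staged calibration protocol (climate and site conditions
#' drive the value of soils, management and experimental data, not the
#' reverse).
#'
#' For protocols that do not use the 7 standard category codes, a
#' deterministic asymmetric fallback pattern is generated instead
#' (`1 + (2 i + j) mod k` off the diagonal), so any valid protocol can be
#' simulated.
#'
#' @param protocol the protocol whose category codes the matrix is indexed
#'   by (default: [default_protocol()]).
#' @return a [direct_influence()] matrix.
#' @export
default_influence_truth <- function(protocol = default_protocol()) {
  codes <- protocol_categories(protocol)
  if (!setequal(codes, c("SOI", "CL", "MPDE", "SI", "LTCL", "LTMP", "EDS"))) {
    k <- length(codes)
    m <- outer(seq_len(k), seq_len(k),
               function(i, j) 1 + (2 * i + j) %% k)
    diag(m) <- 0
    return(direct_influence(m, items = codes))
  }
  base <- matrix(c(
    ## SOI   CL MPDE  SI LTCL LTMP EDS   (columns = receiving category)
       0,    0,  1,   0,  0,   1,  2,  # SOI
       3,    0,  3,   1,  2,   2,  4,  # CL
       2,    0,  0,   0,  0,   2,  3,  # MPDE
       2,    1,  2,   0,  1,   2,  3,  # SI
       2,    2,  2,   1,  0,   2,  3,  # LTCL
       2,    0,  2,   0,  0,   0,  2,  # LTMP
       1,    0,  1,   0,  0,   1,  0   # EDS
  ), nrow = 7, byrow = TRUE,
  dimnames = list(c("SOI", "CL", "MPDE", "SI", "LTCL", "LTMP", "EDS"),
                  c("SOI", "CL", "MPDE", "SI", "LTCL", "LTMP", "EDS")))
  direct_influence(base[codes, codes])
}

#' Specification of a synthetic survey
#'
#' Fixes every knob of the synthetic survey generator. Defaults emulate the
#' study design the package targets: 20 modelers using 12 model types across
#' 4 experience classes, judging the default 7-category / 55-variable
#' protocol; latent importance weights are Dirichlet draws mixed between a
#' shared consensus component (weight `agreement`) and an idiosyncratic
#' per-modeler component, and pairwise judgments carry multiplicative
#' log-normal noise of sd `judgment_noise_sigma` (which drives the
#' consistency ratio).
#'
#' @param protocol an `mcdm_protocol` (default [default_protocol()]).
#' @param n_modelers number of synthetic modelers.
#' @param seed integer RNG seed used by [generate_survey()].
#' @param judgment_noise_sigma log-scale sd of the multiplicative PCM noise;
#'   a scalar, or one value per modeler.
#' @param agreement mixture weight `alpha` in `[0, 1]` of the shared versus
#'   idiosyncratic latent weights (1 = full consensus).
#' @param dirichlet_conc concentration of the Dirichlet weight draws.
#' @param group_effects optional list of effects, each a list with elements
#'   `factor` (`"model_type"` or `"experience_class"`), `level`, `category`
#'   (a category code or `"categories"`) and `shift` (numeric vector, one
#'   entry per item of that category, added to the latent weights before
#'   renormalization).
#' @param influence_truth ground-truth [direct_influence()] matrix.
#' @param influence_noise_sd sd of the half-normal (non-negative) noise
#'   added element-wise to each modeler's influence matrix.
#' @param model_types,experience_classes labels cycled over the modelers.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(protocol = default_protocol(),
                           n_modelers = 20L,
                           seed = 1L,
                           judgment_noise_sigma = 0.5,
                           agreement = 0.7,
                           dirichlet_conc = 5,
                           group_effects = NULL,
                           influence_truth = default_influence_truth(protocol),
                           influence_noise_sd = 0.05,
                           model_types = c("APSIM", "CERES-EGC", "DayCent",
                                           "DNDC", "Landscape-DNDC", "DSSAT",
                                           "EPIC", "PaSim", "DairyMod/SGS",
                                           "FASSET", "STICS", "INFOCROP"),
                           experience_classes = c("<5", "5-10", "10-20", ">20")) {
  validate_protocol(protocol)
  if (!is_count(n_modelers)) stop_("n_modelers must be a positive integer")
  sig <- judgment_noise_sigma
  if (!(length(sig) %in% c(1L, n_modelers)) || any(sig < 0))
    stop_("judgment_noise_sigma must be a non-negative scalar or one value per modeler")
  if (!is.numeric(agreement) || agreement < 0 || agreement > 1)
    stop_("agreement must be in [0, 1]")
  if (influence_noise_sd < 0) stop_("influence_noise_sd must be >= 0")
  codes <- protocol_categories(protocol)
  if (!identical(attr(influence_truth, "items"), as.character(codes)))
    stop_("influence_truth items must match the protocol categories")
  for (ge in group_effects %||% list()) {
    if (!ge$factor %in% c("model_type", "experience_class"))
      stop_("group effect factor must be model_type or experience_class")
    pool <- if (ge$factor == "model_type") model_types else experience_classes
    if (!ge$level %in% pool)
      stop_("group effect level '%s' not among the %s labels", ge$level, ge$factor)
    n_items <- if (identical(ge$category, "categories")) length(codes)
    else length(category_items(protocol, ge$category))
    if (length(ge$shift) != n_items)
      stop_("group effect shift for %s must have length %d", ge$category, n_items)
  }
  structure(list(protocol = protocol, n_modelers = as.integer(n_modelers),
                 seed = as.integer(seed),
                 judgment_noise_sigma = rep_len(sig, n_modelers),
                 agreement = agreement, dirichlet_conc = dirichlet_conc,
                 group_effects = group_effects,
                 influence_truth = influence_truth,
                 influence_noise_sd = influence_noise_sd,
                 model_types = model_types,
                 experience_classes = experience_classes),
            class = "generator_spec")
}

#' Generate one reciprocal PCM from latent weights
#'
#' Builds the upper triangle as `a_ij = (w_i / w_j) * exp(eps_ij)` with
#' independent `eps ~ Normal(0, sigma^2)`, clips entries to the judgment
#' scale range `[1/9, 9]`, and mirrors the reciprocal lower triangle from
#' the (clipped) upper triangle. With `sigma = 0` and a ratio-bounded weight
#' vector the result is the exactly consistent matrix of `w`. Uses the
#' current RNG state; seed outside for reproducibility.
#'
#' @param weights positive latent weights summing to 1 (named for item
#'   labels).
#' @param sigma log-scale noise sd (>= 0).
#' @return a [pcm()].
#' @export
generate_pcm <- function(weights, sigma = 0) {
  w <- as.numeric(weights)
  if (any(w <= 0)) stop_("latent weights must be positive")
  n <- length(w)
  items <- names(weights) %||% paste0("V", seq_len(n))
  a <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    val <- (w[i] / w[j]) * exp(rnorm(1L, 0, sigma))
    val <- min(max(val, 1 / 9), 9)
    a[i, j] <- val
    a[j, i] <- 1 / val
  }
  pcm(a, items = items)
}

## latent weights for one modeler: consensus/idiosyncratic mixture plus any
## group shift, renormalized and ratio-bounded to the judgment scale
mix_weights <- function(shared, alpha, conc, shift = NULL) {
  idio <- rdirichlet1(conc, k = length(shared))
  w <- alpha * shared + (1 - alpha) * idio
  if (!is.null(shift)) w <- w + shift
  w <- pmax(w, 1e-8)
  bound_ratio(normalize_weights(w))
}

#' Generate a synthetic survey bundle with known ground truth
#'
#' Draws shared (consensus) latent weight vectors per category and at the
#' category level, realizes each modeler's weights as the
#' `agreement`-weighted mixture of the shared and an idiosyncratic Dirichlet
#' draw (plus any configured group shift), turns them into noisy reciprocal
#' PCMs via [generate_pcm()], and perturbs the ground-truth influence matrix
#' with element-wise non-negative noise. Fully deterministic given
#' `spec$seed`.
#'
#' The returned ground truth records everything a parameter-recovery test
#' needs: the shared and realized weights, the true total-relation matrix
#' and influence profiles, the true stationary category weights, the true
#' global per-variable priorities (local weight times stationary category
#' weight) and the true per-stage and cumulative importances.
#'
#' @param spec a [generator_spec()].
#' @return list with elements `bundle` (a [survey_bundle()]) and `truth`.
#' @export
generate_survey <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  protocol <- spec$protocol
  codes <- protocol_categories(protocol)
  vars <- protocol_variables(protocol)
  n <- spec$n_modelers
  ids <- sprintf("M%02d", seq_len(n))
  profiles <- data.frame(
    modeler_id = ids,
    model_type = rep_len(spec$model_types, n),
    experience_class = rep_len(spec$experience_classes, n),
    stringsAsFactors = FALSE)

  shared <- lapply(codes, function(code) {
    items <- category_items(protocol, code)
    stats::setNames(bound_ratio(rdirichlet1(spec$dirichlet_conc, length(items))),
                    items)
  })
  names(shared) <- codes
  shared_cat <- stats::setNames(
    bound_ratio(rdirichlet1(spec$dirichlet_conc, length(codes))), codes)

  shift_for <- function(id, category) {
    total <- NULL
    for (ge in spec$group_effects %||% list()) {
      if (!identical(ge$category, category)) next
      if (profiles[[ge$factor]][profiles$modeler_id == id] == ge$level)
        total <- (total %||% 0) + ge$shift
    }
    total
  }

  pcms <- list(); category_pcm <- list(); influence <- list()
  per_modeler_weights <- list()
  for (k in seq_len(n)) {
    id <- ids[k]
    sig <- spec$judgment_noise_sigma[k]
    wlist <- list()
    pm <- list()
    for (code in codes) {
      w <- mix_weights(shared[[code]], spec$agreement, spec$dirichlet_conc,
                       shift_for(id, code))
      names(w) <- category_items(protocol, code)
      wlist[[code]] <- w
      pm[[code]] <- generate_pcm(w, sig)
    }
    wc <- mix_weights(shared_cat, spec$agreement, spec$dirichlet_conc,
                      shift_for(id, "categories"))
    names(wc) <- codes
    wlist$categories <- wc
    pcms[[id]] <- pm
    category_pcm[[id]] <- generate_pcm(wc, sig)
    noise <- matrix(abs(rnorm(length(codes)^2, 0, spec$influence_noise_sd)),
                    length(codes), length(codes))
    if (spec$influence_noise_sd == 0) noise[] <- 0
    m <- unclass(as.matrix(spec$influence_truth)) + noise
    diag(m) <- 0
    influence[[id]] <- direct_influence(m, items = codes)
    per_modeler_weights[[id]] <- wlist
  }

  bundle <- survey_bundle(protocol, profiles, pcms, category_pcm, influence)

  t_true <- total_relation(normalize_direct(spec$influence_truth))
  cw_true <- cluster_weights(t_true)
  ev <- eigen(cw_true)
  k1 <- which.min(abs(ev$values - 1))
  stat <- Re(ev$vectors[, k1])
  stat <- stats::setNames(stat / sum(stat), codes)
  global <- numeric(nrow(vars))
  for (code in codes) {
    sel <- vars$category == code
    global[sel] <- shared[[code]] * stat[code]
  }
  names(global) <- paste0(vars$category, ": ", vars$variable)
  stage_imp <- vapply(seq_len(protocol$n_stages), function(s)
    sum(global[vars$stage == s]), 0)
  truth <- list(shared_weights = shared,
                shared_category_weights = shared_cat,
                per_modeler_weights = per_modeler_weights,
                influence_truth = spec$influence_truth,
                total_relation = t_true,
                influence_profiles = influence_profiles(t_true),
                category_weights = stat,
                global_priorities = global,
                stage_importance = stage_imp,
                stage_cumulative = cumsum(stage_imp))
  list(bundle = bundle, truth = truth)
}

#' Generate a per-stage RRMSE series consistent with a target MER profile
#'
#' Inverts the error-rate definition: `rrmse_s = mer_truth_s * sigma_p_s`
#' (with `sigma_p` the ground-truth cumulative stage importance), plus
#' optional Gaussian noise truncated at zero. With `noise = 0`, [mer()]
#' applied to the result recovers `mer_truth` exactly.
#'
#' @param truth the `truth` element of a [generate_survey()] result (or any
#'   list with a `stage_cumulative` vector).
#' @param mer_truth positive per-stage target error rates.
#' @param noise sd of the additive noise (default 0).
#' @param output output label for the series.
#' @param unit recorded unit.
#' @return an [rrmse_series()].
#' @export
generate_rrmse <- function(truth, mer_truth, noise = 0, output = "synthetic",
                           unit = "fraction") {
  sp <- truth$stage_cumulative
  if (length(mer_truth) != length(sp))
    stop_("mer_truth must have one value per stage (%d)", length(sp))
  if (any(mer_truth <= 0)) stop_("mer_truth must be positive")
  vals <- mer_truth * sp
  if (noise > 0) vals <- pmax(0, vals + rnorm(length(vals), 0, noise))
  rrmse_series(output, vals, unit = unit)
}
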