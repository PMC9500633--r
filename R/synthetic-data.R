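#' Configuration for the synthetic mixture-toxicity generator
#'
#' Describes a study in which `n_components` heavy-metal compounds, falling
#' into `n_clusters` latent descriptor categories, are each combined with a
#' fixed nanomaterial co-component (25 umol/L by default) over a
#' `n_concentrations`-point arithmetic concentration series, and cell
#' viability declines with dose following a logistic curve whose potency is a
#' cluster-specific linear function of the mixture descriptors.
#'
#' Cluster centroids are specified through the four free descriptors (HOMO,
#' LUMO, molecular energy, adsorption energy); the derived descriptors
#' (ionization potential, electron affinity, electronegativity, hardness)
#' always satisfy the conceptual-DFT identities, at zero within-cluster
#' spread a component equals its centroid exactly.
#'
#' @param n_components Number of variable components (default 8).
#' @param n_concentrations Points per concentration series (default 9).
#' @param n_clusters Latent descriptor categories (default 2).
#' @param cluster_centroids List of length `n_clusters`; each element a named
#'   numeric vector with `homo`, `lumo` (eV), `molecular_energy`,
#'   `adsorption_energy`.
#' @param within_cluster_sd Named numeric vector of per-descriptor standard
#'   deviations for the four free descriptors; all >= 0.
#' @param co_component Named list: `name` and the four free descriptors of
#'   the fixed co-component.
#' @param co_concentration Fixed co-component concentration, umol/L.
#' @param step_choices Candidate arithmetic step sizes (umol/L) for the
#'   per-component concentration series.
#' @param dose_response_params List of length `n_clusters`; each element a
#'   list with `intercept` and named `weights` (over descriptor names)
#'   defining the log-potency surface, plus shared `slope`, `upper`, `lower`
#'   logistic parameters taken from the first element.
#' @param noise_sd Gaussian noise standard deviation on the viability scale.
#' @param seed Integer seed; the whole dataset is a pure function of this
#'   configuration.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_components = 8L,
                             n_concentrations = 9L,
                             n_clusters = 2L,
                             cluster_centroids = default_centroids(),
                             within_cluster_sd = c(homo = 0.15, lumo = 0.15,
                                                   molecular_energy = 8,
                                                   adsorption_energy = 0.2),
                             co_component = list(name = "nano-TiO2",
                                                 homo = -7.0, lumo = -3.4,
                                                 molecular_energy = -200,
                                                 adsorption_energy = 0),
                             co_concentration = 25,
                             step_choices = c(5, 10, 30, 100),
                             dose_response_params = default_dose_response(),
                             noise_sd = 0.05,
                             seed = 1L) {
  cfg <- list(n_components = as.integer(n_components),
              n_concentrations = as.integer(n_concentrations),
              n_clusters = as.integer(n_clusters),
              cluster_centroids = cluster_centroids,
              within_cluster_sd = within_cluster_sd,
              co_component = co_component,
              co_concentration = co_concentration,
              step_choices = step_choices,
              dose_response_params = dose_response_params,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' @keywords internal
default_centroids <- function() {
  list(c(homo = -6.2, lumo = -3.8, molecular_energy = -150,
         adsorption_energy = -1.0),
       c(homo = -7.6, lumo = -1.8, molecular_energy = -60,
         adsorption_energy = -3.0))
}

#' Default cluster-specific dose-response parameters
#'
#' Log-potency (log EC50 in umol/L total dose) is a linear function of the
#' mixture descriptors with weights concentrated on absolute hardness and
#' adsorption energy, with opposite orientation in the two clusters so the
#' descriptor-to-toxicity mapping genuinely differs between categories.
#' @keywords internal
default_dose_response <- function() {
  list(list(intercept = 3.2, slope = 0.9, upper = 1.0, lower = 0.05,
            weights = c(hardness = 1.0, adsorption_energy = -0.5)),
       list(intercept = 6.3, slope = 0.9, upper = 1.0, lower = 0.05,
            weights = c(hardness = -0.55, adsorption_energy = 0.55)))
}

#' @keywords internal
validate_synthetic_config <- function(cfg) {
  bad <- function(field, msg) {
    stop("invalid synthetic configuration: field '", field, "' ", msg,
         call. = FALSE)
  }
  if (cfg$n_clusters < 1L) bad("n_clusters", "must be >= 1")
  if (cfg$n_components < cfg$n_clusters)
    bad("n_components", "must be >= n_clusters")
  if (cfg$n_concentrations < 1L) bad("n_concentrations", "must be >= 1")
  if (any(cfg$within_cluster_sd < 0)) bad("within_cluster_sd", "must be >= 0")
  if (cfg$noise_sd < 0) bad("noise_sd", "must be >= 0")
  if (length(cfg$cluster_centroids) != cfg$n_clusters)
    bad("cluster_centroids", "must have one centroid per cluster")
  if (length(cfg$dose_response_params) != cfg$n_clusters)
    bad("dose_response_params", "must have one element per cluster")
  free <- c("homo", "lumo", "molecular_energy", "adsorption_energy")
  for (cen in cfg$cluster_centroids) {
    if (!all(free %in% names(cen)))
      bad("cluster_centroids", "centroids need homo, lumo, molecular_energy, adsorption_energy")
    if (cen[["lumo"]] < cen[["homo"]])
      bad("cluster_centroids", "must satisfy lumo >= homo")
  }
  if (cfg$co_concentration <= 0) bad("co_concentration", "must be > 0")
  invisible(cfg)
}

#' Generate a synthetic component descriptor panel with ground truth
#'
#' Components are assigned to clusters as evenly as possible (round-robin);
#' each component's free descriptors (HOMO, LUMO, molecular energy,
#' adsorption energy) are drawn Gaussian around its cluster centroid with the
#' configured within-cluster spread, then the derived descriptors are filled
#' in by [derive_electronic_descriptors()]. Draws where LUMO would fall below
#' HOMO are resampled.
#'
#' @param config A [synthetic_config()].
#' @return List with `panel` (data frame: component rows plus the fixed
#'   co-component row, `name` + eight descriptor columns) and `truth`
#'   (class `synthetic_truth`: `component_cluster_labels`,
#'   `dose_response_params`, `noise_sd`, `steps`).
#' @export
generate_component_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  k <- config$n_clusters
  m <- config$n_components
  labels <- rep(seq_len(k), length.out = m)
  sdv <- config$within_cluster_sd
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    cen <- config$cluster_centroids[[labels[i]]]
    repeat {
      homo <- stats::rnorm(1, cen[["homo"]], sdv[["homo"]])
      lumo <- stats::rnorm(1, cen[["lumo"]], sdv[["lumo"]])
      if (lumo >= homo) break
    }
    rows[[i]] <- derive_electronic_descriptors(
      name = sprintf("M%02d", i),
      homo = homo, lumo = lumo,
      molecular_energy = stats::rnorm(1, cen[["molecular_energy"]],
                                      sdv[["molecular_energy"]]),
      adsorption_energy = stats::rnorm(1, cen[["adsorption_energy"]],
                                       sdv[["adsorption_energy"]]))
  }
  co <- config$co_component
  rows[[m + 1L]] <- derive_electronic_descriptors(
    name = co$name, homo = co$homo, lumo = co$lumo,
    molecular_energy = co$molecular_energy,
    adsorption_energy = co$adsorption_energy)
  panel <- do.call(rbind, rows)
  steps <- sample(config$step_choices, m, replace = TRUE)
  names(steps) <- panel$name[seq_len(m)]
  names(labels) <- panel$name[seq_len(m)]
  truth <- structure(
    list(component_cluster_labels = labels,
         dose_response_params = config$dose_response_params,
         noise_sd = config$noise_sd,
         steps = steps),
    class = "synthetic_truth")
  list(panel = panel, truth = truth)
}

#' Generate the mixture design grid
#'
#' For every variable component, an arithmetic concentration series
#' step, 2*step, ..., n_concentrations*step (umol/L), each point paired with
#' the fixed co-component concentration.
#'
#' @param panel_truth Output of [generate_component_panel()] (or a list with
#'   `panel` and `truth$steps`).
#' @param config The [synthetic_config()] used to generate the panel.
#' @return Design data frame with columns `sample_id`, `component`,
#'   `concentration_umol_L`, `co_component`, `co_concentration_umol_L`;
#'   `n_components * n_concentrations` rows.
#' @export
generate_concentration_grid <- function(panel_truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  panel <- panel_truth$panel
  steps <- panel_truth$truth$steps
  comps <- names(steps)
  if (length(comps) == 0L) stop("empty panel", call. = FALSE)
  nconc <- config$n_concentrations
  design <- do.call(rbind, lapply(comps, function(cm) {
    data.frame(component = cm,
               concentration_umol_L = steps[[cm]] * seq_len(nconc),
               co_component = config$co_component$name,
               co_concentration_umol_L = config$co_concentration,
               stringsAsFactors = FALSE)
  }))
  design <- cbind(sample_id = sprintf("S%03d", seq_len(nrow(design))), design)
  design
}

#' Expected (noise-free) viability under the generative dose-response model
#'
#' Four-parameter logistic decline in log total dose:
#' S = lower + (upper - lower) * plogis(slope * (m - log(dose))), where the
#' log-potency m = intercept + weights . D_mix is cluster-specific.
#'
#' @param dmix Matrix of mixture descriptors (rows = samples, named columns).
#' @param dose Total molar dose per sample (umol/L).
#' @param params One cluster's dose-response parameter list.
#' @return Numeric vector of expected viabilities.
#' @export
expected_viability <- function(dmix, dose, params) {
  w <- rep(0, 8)
  names(w) <- descriptor_names()
  w[names(params$weights)] <- params$weights
  m <- params$intercept + drop(dmix %*% w)
  unname(params$lower + (params$upper - params$lower) *
           stats::plogis(params$slope * (m - log(dose))))
}

#' Simulate viability responses for mixed samples
#'
#' Adds the generative dose-response mean for each sample's latent cluster
#' plus homoscedastic Gaussian noise, truncated to [0, 1.2] (survival rates
#' relative to controls can slightly exceed 1).
#'
#' @param mixed Mixed design: output of [mix_design()] (the eight mixture
#'   descriptor columns must be present).
#' @param truth `synthetic_truth` from [generate_component_panel()].
#' @param seed Integer seed for the noise draws.
#' @return `mixed` with a `viability` column appended.
#' @export
generate_viability <- function(mixed, truth, seed = 1L) {
  if (!all(descriptor_names() %in% names(mixed))) {
    stop("mixed descriptors must be computed before generating viability",
         call. = FALSE)
  }
  labels <- truth$component_cluster_labels
  if (!all(mixed$component %in% names(labels))) {
    stop("unknown component(s) in design", call. = FALSE)
  }
  dmix <- as.matrix(mixed[, descriptor_names(), drop = FALSE])
  dose <- mixed$concentration_umol_L + mixed$co_concentration_umol_L
  mu <- numeric(nrow(mixed))
  cl <- labels[mixed$component]
  for (g in unique(cl)) {
    sel <- cl == g
    mu[sel] <- expected_viability(dmix[sel, , drop = FALSE], dose[sel],
                                  truth$dose_response_params[[g]])
  }
  set.seed(seed)
  s <- mu + stats::rnorm(nrow(mixed), 0, truth$noise_sd)
  mixed$viability <- pmin(pmax(s, 0), 1.2)
  mixed
}

#' Simulate a plate-absorbance table consistent with given viabilities
#'
#' Inverts the viability formula so that recomputing survival from the
#' emitted absorbances reproduces each sample's viability to floating-point
#' accuracy.
#'
#' @param mixed Mixed design with a `viability` column.
#' @param control_abs Control-well absorbance (must exceed `blank_abs`).
#' @param blank_abs Blank-well absorbance.
#' @return Data frame `sample_id`, `a_exp`, `a_control`, `a_blank`.
#' @export
generate_absorbances <- function(mixed, control_abs = 0.9, blank_abs = 0.1) {
  if (control_abs <= blank_abs) {
    stop("degenerate plate: control_abs must exceed blank_abs", call. = FALSE)
  }
  if (!"viability" %in% names(mixed)) {
    stop("viability column required", call. = FALSE)
  }
  data.frame(sample_id = mixed$sample_id,
             a_exp = viability_to_absorbance(mixed$viability,
                                             control_abs, blank_abs),
             a_control = control_abs,
             a_blank = blank_abs,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic mixture-toxicity dataset
#'
#' Convenience wrapper chaining panel, grid, descriptor mixing, viability and
#' absorbance generation. Bit-identical for identical configurations.
#'
#' @param config A [synthetic_config()].
#' @param weighting Descriptor-mixing mode, see [mix_descriptors()].
#' @return List: `panel`, `truth`, `design`, `mixed` (with viability),
#'   `plate`, `config`.
#' @export
simulate_mixture_study <- function(config = synthetic_config(),
                                   weighting = c("fraction",
                                                 "concentration")) {
  weighting <- match.arg(weighting)
  pt <- generate_component_panel(config)
  design <- generate_concentration_grid(pt, config)
  mixed <- mix_design(pt$panel, design, weighting = weighting)
  mixed <- generate_viability(mixed, pt$truth, seed = config$seed + 1L)
  plate <- generate_absorbances(mixed)
  list(panel = pt$panel, truth = pt$truth, design = design,
       mixed = mixed, plate = plate, config = config)
}
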