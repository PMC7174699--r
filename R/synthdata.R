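#' Ground truth record for a synthetic dataset
#'
#' Every synthetic dataset is generated from an explicit ground-truth
#' record so that parameter-recovery tests can check the analysis against
#' what was planted: which regions are network hubs, which regions carry
#' elevated strain, how much concussive impacts elevate the latent impact
#' severity, and how tightly MPS95 is coupled to peak angular acceleration.
#'
#' @param hub_ids region ids planted as connectivity hubs.
#' @param high_strain_ids region ids planted with elevated strain.
#' @param concussion_strain_shift multiplicative severity elevation for
#'   concussive cases (> 0; 1 = no effect, a null generator).
#' @param kinematic_strain_coupling target Pearson correlation between
#'   MPS95 and peak angular acceleration, in (0, 1].
#' @param seed integer seed the dataset was generated from.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(hub_ids, high_strain_ids, concussion_strain_shift = 1.5,
                         kinematic_strain_coupling = 0.83, seed = 1L) {
  if (concussion_strain_shift <= 0) stop_param("concussion_strain_shift must be positive")
  if (kinematic_strain_coupling <= 0 || kinematic_strain_coupling > 1) {
    stop_param("kinematic_strain_coupling must be in (0, 1]")
  }
  structure(list(hub_ids = sort(as.integer(hub_ids)),
                 high_strain_ids = sort(as.integer(high_strain_ids)),
                 concussion_strain_shift = concussion_strain_shift,
                 kinematic_strain_coupling = kinematic_strain_coupling,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Generate a synthetic parcellation atlas
#'
#' Produces an n-region parcellation in the style of a two-hemisphere
#' cortical/subcortical atlas: regions split between left and right
#' hemispheres with one midline (brainstem-like) region, roughly 12% of
#' regions labeled subcortical. Hub roles are planted among subcortical
#' regions and high-strain roles among cortical regions, mirroring the
#' empirical picture that network-critical regions concentrate in the
#' subcortex while impact strain concentrates in the lateral cortex; the
#' two planted sets are therefore disjoint.
#'
#' @param n_regions number of parcels (the reference scale is 129).
#' @param n_hubs number of planted hub regions.
#' @param n_strain_regions number of planted high-strain regions.
#' @param seed integer seed; identical arguments reproduce the atlas
#'   bit-identically.
#' @return a `parcellation_atlas` data.frame with columns `region_id`
#'   (0-based, contiguous), `region_name`, `hemisphere` (L/R/midline),
#'   `tissue_class` (cortical/subcortical) and `planted_role`
#'   (hub/lateral_high_strain/neither).
#' @export
gen_atlas <- function(n_regions, n_hubs, n_strain_regions, seed = 1L) {
  if (n_regions < 3) stop_param("n_regions must be >= 3, got %d", n_regions)
  if (n_hubs < 1) stop_param("n_hubs must be >= 1, got %d", n_hubs)
  if (n_strain_regions < 1) stop_param("n_strain_regions must be >= 1, got %d", n_strain_regions)
  if (n_hubs + n_strain_regions > n_regions) {
    stop_param("n_hubs + n_strain_regions = %d exceeds n_regions = %d",
               n_hubs + n_strain_regions, n_regions)
  }
  region_id <- seq_len(n_regions) - 1L
  hemisphere <- rep(c("L", "R"), length.out = n_regions)
  hemisphere[n_regions] <- "midline"
  # subcortical share mimics a two-hemisphere atlas (7 structures/hemisphere
  # + brainstem at the 129-region scale); grown if needed to host the hubs
  n_sub <- max(n_hubs, min(n_regions - n_strain_regions, ceiling(0.12 * n_regions)))
  tissue_class <- rep("cortical", n_regions)
  tissue_class[n_regions] <- "subcortical"  # brainstem-like midline region
  # remaining subcortical parcels interleave the two hemispheres
  extra <- n_sub - 1L
  if (extra > 0) {
    lateral <- which(hemisphere != "midline")
    tissue_class[utils::tail(lateral, extra)] <- "subcortical"
  }
  withr::with_seed(derive_seed(seed, "atlas"), {
    sub_ids <- region_id[tissue_class == "subcortical"]
    cort_ids <- region_id[tissue_class == "cortical"]
    if (length(sub_ids) < n_hubs) stop_param("n_hubs = %d exceeds available subcortical regions", n_hubs)
    if (length(cort_ids) < n_strain_regions) {
      stop_param("n_strain_regions = %d exceeds available cortical regions", n_strain_regions)
    }
    hubs <- sort(sample(sub_ids, n_hubs))
    strain <- sort(sample(cort_ids, n_strain_regions))
  })
  planted_role <- rep("neither", n_regions)
  planted_role[region_id %in% hubs] <- "hub"
  planted_role[region_id %in% strain] <- "lateral_high_strain"
  region_name <- sprintf("%s %s %d", hemisphere, tissue_class,
                         as.integer(stats::ave(region_id, hemisphere, tissue_class,
                                               FUN = seq_along)))
  structure(data.frame(region_id = region_id, region_name = region_name,
                       hemisphere = hemisphere, tissue_class = tissue_class,
                       planted_role = planted_role),
            class = c("parcellation_atlas", "data.frame"))
}

atlas_roles <- function(atlas, role) atlas$region_id[atlas$planted_role == role]

atlas_modules <- function(atlas) {
  # four spatial communities: hemisphere x anterior/posterior half
  n <- nrow(atlas)
  half <- ifelse(atlas$region_id < stats::median(atlas$region_id), "ant", "post")
  m <- paste(atlas$hemisphere, half)
  m[atlas$hemisphere == "midline"] <- "L ant"  # midline region joins a module
  m
}

#' Generate one synthetic structural connectome
#'
#' Builds a weighted, symmetric, zero-diagonal connectivity matrix with the
#' statistical structure the lesion analysis assumes: modular community
#' organization (four hemisphere-by-lobe communities with an
#' `intra_module_bias`-fold elevated connection probability inside a
#' community), log-normal edge weights emulating volume-normalized
#' streamline counts, and planted hub regions that connect across
#' communities with both elevated degree and `hub_weight_boost`-fold
#' elevated weights. Generation rejection-samples until the network is a
#' single connected component.
#'
#' @param atlas a [gen_atlas] result.
#' @param density target edge density in (0, 1].
#' @param hub_weight_boost weight (and connection-probability) multiplier
#'   for edges incident to planted hubs (>= 1).
#' @param intra_module_bias within-community connection-probability
#'   multiplier (>= 1).
#' @param seed integer seed.
#' @param max_attempts rejection-sampling bound for connectedness.
#' @return a [connectome].
#' @export
gen_connectome <- function(atlas, density = 0.15, hub_weight_boost = 3,
                           intra_module_bias = 2, seed = 1L, max_attempts = 50L) {
  stopifnot(inherits(atlas, "parcellation_atlas"))
  if (density <= 0 || density > 1) stop_param("density must be in (0, 1], got %g", density)
  if (hub_weight_boost < 1) stop_param("hub_weight_boost must be >= 1, got %g", hub_weight_boost)
  if (intra_module_bias < 1) stop_param("intra_module_bias must be >= 1, got %g", intra_module_bias)
  n <- nrow(atlas)
  ids <- atlas$region_id
  hubs <- atlas_roles(atlas, "hub")
  modules <- atlas_modules(atlas)
  same_module <- outer(modules, modules, "==")
  is_hub <- ids %in% hubs
  hub_pair <- outer(is_hub, is_hub, "|")
  upper <- upper.tri(same_module)
  # solve the between-community probability so expected density matches
  n_within <- sum(same_module[upper])
  n_between <- sum(upper) - n_within
  p_between <- density * (n_within + n_between) / (n_within * intra_module_bias + n_between)
  p_within <- min(1, intra_module_bias * p_between)
  p_between <- min(1, p_between)
  pmat <- ifelse(same_module, p_within, p_between)
  # hubs reach into every community with boosted probability
  pmat[hub_pair] <- pmin(1, p_within * hub_weight_boost)
  withr::with_seed(derive_seed(seed, "connectome"), {
    for (attempt in seq_len(max_attempts)) {
      w <- matrix(0, n, n)
      present <- stats::runif(sum(upper)) < pmat[upper]
      wts <- stats::rlnorm(sum(upper), meanlog = 0, sdlog = 0.6)
      wts[hub_pair[upper]] <- wts[hub_pair[upper]] * hub_weight_boost
      w[upper] <- present * wts
      w <- w + t(w)
      conn <- connectome(w, region_ids = ids, atlas_ref = "synthetic")
      g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
      if (igraph::is_connected(g)) return(conn)
    }
  })
  stop_param("could not generate a connected network in %d attempts", max_attempts)
}

#' Generate a cohort of subject connectomes
#'
#' All subjects share the atlas, community plan and edge topology of a base
#' connectome generated at `seed`; each subject's weights are perturbed by
#' independent multiplicative log-normal noise of scale
#' `between_subject_noise` (per-edge coefficient of variation across
#' subjects grows monotonically with it; at 0 all subjects are identical to
#' the base network).
#'
#' @inheritParams gen_connectome
#' @param n_subjects number of subjects (the reference cohort is 30).
#' @param between_subject_noise log-scale sd of subject weight noise (>= 0).
#' @return list of [connectome]s of length `n_subjects`.
#' @export
gen_cohort <- function(atlas, n_subjects = 30, between_subject_noise = 0.3,
                       seed = 1L, density = 0.15, hub_weight_boost = 3,
                       intra_module_bias = 2) {
  if (n_subjects < 1) stop_param("n_subjects must be >= 1, got %d", n_subjects)
  if (between_subject_noise < 0) stop_param("between_subject_noise must be >= 0")
  base <- gen_connectome(atlas, density = density, hub_weight_boost = hub_weight_boost,
                         intra_module_bias = intra_module_bias, seed = seed)
  n <- nrow(base$weights)
  upper <- upper.tri(base$weights)
  lapply(seq_len(n_subjects), function(s) {
    withr::with_seed(derive_seed(seed, "cohort_subject", s), {
      z <- matrix(0, n, n)
      z[upper] <- stats::rnorm(sum(upper))
      z <- z + t(z)
      w <- base$weights * exp(between_subject_noise * z)
    })
    connectome(w, region_ids = base$region_ids, atlas_ref = base$atlas_ref)
  })
}

# exact channel-noise variance giving target raw-scale Pearson correlation
# between two lognormal channels sharing the latent log-severity L
coupling_noise_sd <- function(coupling, p_conc, log_shift, sigma_sev) {
  # moments of exp(L), L = log_shift * 1{concussive} + N(0, sigma_sev^2)
  m1 <- (1 - p_conc) + p_conc * exp(log_shift)
  m2 <- (1 - p_conc) + p_conc * exp(2 * log_shift)
  A <- m1 * exp(sigma_sev^2 / 2)
  B <- m2 * exp(2 * sigma_sev^2)
  tau2 <- log((A^2 + (B - A^2) / coupling) / B)
  sqrt(max(tau2, 0))
}

#' Generate a synthetic impact dataset
#'
#' Emulates a set of reconstructed head impacts. A single latent severity
#' scalar per case — elevated `concussion_strain_shift`-fold (on the
#' multiplicative scale) for concussive cases — drives all four peak
#' kinematics and the strain field, each through independent multiplicative
#' log-normal channel noise, which reproduces the strong empirical coupling
#' between whole-brain strain and angular head acceleration. The angular
#' acceleration and strain channel noise is solved in closed form so the
#' Pearson correlation between MPS95 and peak angular acceleration matches
#' `truth$kinematic_strain_coupling` in expectation. Per case, each region
#' receives `n_elements` element-strain draws from a region-scaled gamma
#' distribution whose scale follows a spatial profile elevated in the
#' planted high-strain (lateral cortical) regions; rMPS is the per-region
#' 95th percentile and MPS95 the 95th percentile of the pooled elements.
#'
#' @param atlas a [gen_atlas] result.
#' @param n_cases number of impacts (the reference set is 53).
#' @param n_concussive number of concussive impacts (reference 20).
#' @param truth a [ground_truth]; its `high_strain_ids` place the strain
#'   profile and its shift/coupling set the effect sizes.
#' @param seed integer seed.
#' @param n_elements element-strain draws per region per case (default 200).
#' @return an [impact_set].
#' @export
gen_impacts <- function(atlas, n_cases = 53, n_concussive = 20, truth,
                        seed = 1L, n_elements = 200L) {
  stopifnot(inherits(atlas, "parcellation_atlas"), inherits(truth, "ground_truth"))
  if (n_cases < 2) stop_param("n_cases must be >= 2, got %d", n_cases)
  if (n_concussive > n_cases) {
    stop_param("n_concussive = %d exceeds n_cases = %d", n_concussive, n_cases)
  }
  n_reg <- nrow(atlas)
  ids <- atlas$region_id
  conc <- c(rep(1L, n_concussive), rep(0L, n_cases - n_concussive))
  log_shift <- log(truth$concussion_strain_shift)
  sigma_sev <- 0.25          # within-group log-severity spread
  profile_sd <- 0.15         # region-to-region spatial heterogeneity (log scale)
  strain_elev <- 1.6         # profile elevation in planted high-strain regions
  base_strain <- 0.12        # baseline mean element strain (dimensionless)
  gamma_shape <- 6           # element-strain concentration within a region
  kin_base <- c(peak_lin_vel = 8, peak_ang_vel = 35, peak_lin_acc = 80,
                peak_ang_acc = 5000)
  tau <- coupling_noise_sd(truth$kinematic_strain_coupling,
                           p_conc = n_concussive / n_cases,
                           log_shift = log_shift, sigma_sev = sigma_sev)
  # angular acceleration and strain share the calibrated noise; the other
  # kinematic channels are progressively noisier, so angular acceleration
  # remains the strongest kinematic predictor
  kin_tau <- c(peak_lin_vel = 1.7, peak_ang_vel = 1.5, peak_lin_acc = 1.3,
               peak_ang_acc = 1.0) * tau
  withr::with_seed(derive_seed(seed, "impacts"), {
    profile <- base_strain *
      ifelse(ids %in% truth$high_strain_ids, strain_elev, 1) *
      exp(profile_sd * stats::rnorm(n_reg))
    sev <- log_shift * conc + sigma_sev * stats::rnorm(n_cases)
    kin <- sapply(names(kin_base), function(ch) {
      kin_base[[ch]] * exp(sev + kin_tau[[ch]] * stats::rnorm(n_cases))
    })
    strain_scale <- exp(sev + tau * stats::rnorm(n_cases))
    rmps <- matrix(0, n_cases, n_reg, dimnames = list(NULL, as.character(ids)))
    mps95 <- numeric(n_cases)
    for (i in seq_len(n_cases)) {
      elements <- matrix(stats::rgamma(n_reg * n_elements, shape = gamma_shape,
                                       scale = rep(profile * strain_scale[i] / gamma_shape,
                                                   each = n_elements)),
                         nrow = n_elements)
      rmps[i, ] <- apply(elements, 2, percentile95)
      mps95[i] <- percentile95(elements)
    }
  })
  cases <- data.frame(
    case_id = sprintf("case_%03d", seq_len(n_cases)),
    outcome = ifelse(conc == 1, "concussion", "no_concussion"),
    peak_lin_vel = kin[, "peak_lin_vel"], peak_ang_vel = kin[, "peak_ang_vel"],
    peak_lin_acc = kin[, "peak_lin_acc"], peak_ang_acc = kin[, "peak_ang_acc"],
    mps95 = mps95)
  impact_set(cases, rmps)
}
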