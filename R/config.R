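#' Simulation configuration for synthetic biocrust study data
#'
#' Bundles and validates every tunable of the synthetic-data generators:
#' the quadrat survey, the drought-physiology assay table, the two-moss
#' three-habitat microbiome (18 composite samples = 2 moss species x 3
#' karst rocky desertification classes x 3 replicates), and the guild
#' rule table. One master seed fans out to independent child seeds so
#' each generator is reproducible on its own.
#'
#' @param seed integer master seed; all randomness in the generators
#'   derives from it.
#' @param n_sites number of survey sites.
#' @param quadrats_per_site integer vector of quadrat counts per site
#'   (recycled to `n_sites`). The default distributes 185 quadrats over
#'   14 sites.
#' @param n_species_pool number of moss species in the survey pool.
#' @param occupancy_probs optional matrix (species x sites) of Bernoulli
#'   occupancy probabilities in [0, 1]; a default geometric-decay pool is
#'   built when `NULL`.
#' @param n_samples number of microbiome samples; must be divisible by
#'   (2 moss species x 3 desertification classes).
#' @param n_features number of OTUs per marker.
#' @param n_genera number of genera the OTUs are spread over.
#' @param n_phyla number of phyla the genera are spread over.
#' @param library_size_mean expected reads per sample (Poisson).
#' @param species_effect log-scale standard deviation of the per-OTU
#'   moss-species compositional shift.
#' @param class_effect log-scale standard deviation of the per-OTU
#'   desertification-class shift; smaller than `species_effect` under
#'   defaults, mirroring the species-dominated structure the field data
#'   shows.
#' @param n_planted_biomarkers number of genera planted as differentially
#'   abundant between the two moss species.
#' @param biomarker_fold fold-change applied to planted biomarkers; 1
#'   plants none.
#' @param n_modules number of planted major co-abundance modules.
#' @param module_size genera per major module.
#' @param module_strength log-scale loading of the latent module factor.
#' @param n_minor_modules number of small satellite co-abundance
#'   clusters planted alongside the major modules (real co-occurrence
#'   networks always carry such small correlated clusters, and they are
#'   what lifts modularity above the two-equal-module ceiling of 0.5).
#' @param minor_module_size genera per satellite cluster.
#' @param dm_concentration Dirichlet concentration governing
#'   overdispersion of sample compositions.
#' @param n_phys_species number of moss species in the physiology table.
#' @param phys_replicates replicates per species x index.
#' @param phys_separation_sd spacing, in within-species replicate
#'   standard deviations, between the index means of adjacently ranked
#'   species (controls how recoverable the embedded drought ranking is).
#' @param guild_mapped_fraction fraction of genera covered by the
#'   synthetic guild rule table.
#' @param covariate_module_cor strength with which the first planted
#'   module's latent factor is mixed into the enzymatic drought
#'   covariates (makes genus-covariate correlation testable).
#' @param marker `"bacteria"` or `"fungi"`; selects the guild label set.
#'
#' @return A list of class `mosscrust_config`, including `$child_seeds`.
#' @export
sim_config <- function(seed = 1L,
                       n_sites = 14L,
                       quadrats_per_site = NULL,
                       n_species_pool = 30L,
                       occupancy_probs = NULL,
                       n_samples = 18L,
                       n_features = 300L,
                       n_genera = 80L,
                       n_phyla = 8L,
                       library_size_mean = 20000,
                       species_effect = 1.0,
                       class_effect = 0.4,
                       n_planted_biomarkers = 10L,
                       biomarker_fold = 100,
                       n_modules = 2L,
                       module_size = 12L,
                       module_strength = 2.5,
                       n_minor_modules = 4L,
                       minor_module_size = 3L,
                       dm_concentration = 200,
                       n_phys_species = 7L,
                       phys_replicates = 3L,
                       phys_separation_sd = 2,
                       guild_mapped_fraction = 0.7,
                       covariate_module_cor = 0.6,
                       marker = c("bacteria", "fungi")) {
  marker <- match.arg(marker)
  if (is.null(quadrats_per_site)) {
    quadrats_per_site <- rep(185 %/% n_sites, n_sites)
    extra <- 185 - sum(quadrats_per_site)
    if (extra > 0) quadrats_per_site[seq_len(extra)] <-
        quadrats_per_site[seq_len(extra)] + 1L
  }
  quadrats_per_site <- rep_len(as.integer(quadrats_per_site), n_sites)

  stop_cfg <- function(msg) stop("invalid simulation configuration: ", msg,
                                 call. = FALSE)
  counts <- c(n_sites = n_sites, n_species_pool = n_species_pool,
              n_samples = n_samples, n_features = n_features,
              n_genera = n_genera, n_phyla = n_phyla,
              n_phys_species = n_phys_species,
              phys_replicates = phys_replicates)
  if (any(counts < 1) || any(counts != round(counts)))
    stop_cfg("all counts must be positive integers")
  if (any(quadrats_per_site < 1)) stop_cfg("quadrats_per_site must be >= 1")
  if (library_size_mean <= 0) stop_cfg("library_size_mean must be > 0")
  if (n_samples %% 6 != 0)
    stop_cfg("n_samples must be divisible by 6 (2 species x 3 classes)")
  if (species_effect < 0 || class_effect < 0)
    stop_cfg("effect sizes must be >= 0")
  if (biomarker_fold < 1) stop_cfg("biomarker_fold must be >= 1")
  if (n_planted_biomarkers < 0 || n_modules < 0 || module_size < 0 ||
      n_minor_modules < 0 || minor_module_size < 0)
    stop_cfg("planted structure counts must be >= 0")
  if (guild_mapped_fraction < 0 || guild_mapped_fraction > 1)
    stop_cfg("guild_mapped_fraction must be in [0, 1]")
  if (!is.null(occupancy_probs)) {
    occupancy_probs <- as.matrix(occupancy_probs)
    if (any(!is.finite(occupancy_probs)) || any(occupancy_probs < 0) ||
        any(occupancy_probs > 1))
      stop_cfg("occupancy_probs must be probabilities in [0, 1]")
    if (nrow(occupancy_probs) != n_species_pool ||
        ncol(occupancy_probs) != n_sites)
      stop_cfg("occupancy_probs must be n_species_pool x n_sites")
  }
  if (n_phys_species < 2) stop_cfg("need at least 2 physiology species")
  if (phys_separation_sd < 0) stop_cfg("phys_separation_sd must be >= 0")

  # one master seed fans out to per-generator child seeds
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  child <- sample.int(.Machine$integer.max, 6L)
  names(child) <- c("survey", "physiology", "microbiome", "guilds",
                    "tree", "spare")
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  cfg <- list(seed = seed, child_seeds = child,
              n_sites = as.integer(n_sites),
              quadrats_per_site = quadrats_per_site,
              n_species_pool = as.integer(n_species_pool),
              occupancy_probs = occupancy_probs,
              n_samples = as.integer(n_samples),
              n_features = as.integer(n_features),
              n_genera = as.integer(n_genera),
              n_phyla = as.integer(n_phyla),
              library_size_mean = library_size_mean,
              species_effect = species_effect,
              class_effect = class_effect,
              n_planted_biomarkers = as.integer(n_planted_biomarkers),
              biomarker_fold = biomarker_fold,
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              module_strength = module_strength,
              n_minor_modules = as.integer(n_minor_modules),
              minor_module_size = as.integer(minor_module_size),
              dm_concentration = dm_concentration,
              n_phys_species = as.integer(n_phys_species),
              phys_replicates = as.integer(phys_replicates),
              phys_separation_sd = phys_separation_sd,
              guild_mapped_fraction = guild_mapped_fraction,
              covariate_module_cor = covariate_module_cor,
              marker = marker)
  class(cfg) <- "mosscrust_config"
  cfg
}

#' @export
print.mosscrust_config <- function(x, ...) {
  cat("mosscrust simulation config (seed ", x$seed, ")\n", sep = "")
  cat("  survey:    ", x$n_sites, " sites, ", sum(x$quadrats_per_site),
      " quadrats, ", x$n_species_pool, " species pool\n", sep = "")
  cat("  microbiome:", x$n_samples, "samples,", x$n_features, "OTUs in",
      x$n_genera, "genera; species/class effect",
      x$species_effect, "/", x$class_effect, "\n")
  cat("  planted:   ", x$n_planted_biomarkers, " biomarkers (fold ",
      x$biomarker_fold, "), ", x$n_modules, " modules of ",
      x$module_size, "\n", sep = "")
  invisible(x)
}
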