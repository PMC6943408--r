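# Synthetic-data generators. Each generator seeds its own RNG from the
# config's child seeds, so stages are independently reproducible.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  force(expr)
}

default_occupancy <- function(cfg) {
  # geometric decay across the species pool, with mild site-to-site
  # variation: a handful of widespread species and a long rare tail,
  # the shape quadrat surveys of biocrust mosses typically show
  base <- 0.45 * 0.85^(seq_len(cfg$n_species_pool) - 1)
  site_mult <- matrix(stats::runif(cfg$n_species_pool * cfg$n_sites, 0.7, 1.3),
                      cfg$n_species_pool, cfg$n_sites)
  pmin(base * site_mult, 1)
}

#' Simulate a quadrat presence survey
#'
#' Draws per-quadrat Bernoulli presence of each moss species with
#' per-species, per-site occupancy probabilities, emulating a field
#' survey of 1 m x 1 m quadrats across karst rocky desertification
#' sites. Each presence record doubles as one collected specimen, so the
#' record count plays the role of the survey's sample total S.
#'
#' @param cfg a [sim_config()].
#' @return list with `records` (site_id, quadrat_id, species_id),
#'   `total_quadrats`, `total_samples`, `total_sites`, and a `truth`
#'   record holding the occupancy matrix, the expected quadrat count per
#'   species, and the implied true dominance ranking.
#' @export
simulate_survey <- function(cfg) {
  stopifnot(inherits(cfg, "mosscrust_config"))
  with_seed(cfg$child_seeds[["survey"]], {
    probs <- cfg$occupancy_probs
    if (is.null(probs)) probs <- default_occupancy(cfg)
    species <- sprintf("species_%02d", seq_len(cfg$n_species_pool))
    sites <- sprintf("site_%02d", seq_len(cfg$n_sites))
    recs <- vector("list", cfg$n_sites)
    for (a in seq_len(cfg$n_sites)) {
      nq <- cfg$quadrats_per_site[a]
      pres <- matrix(stats::rbinom(cfg$n_species_pool * nq, 1,
                                   rep(probs[, a], nq)),
                     cfg$n_species_pool, nq)
      idx <- which(pres == 1, arr.ind = TRUE)
      if (nrow(idx)) {
        recs[[a]] <- data.frame(site_id = sites[a],
                                quadrat_id = sprintf("%s_q%03d", sites[a],
                                                     idx[, "col"]),
                                species_id = species[idx[, "row"]],
                                stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    expected <- as.numeric(probs %*% cfg$quadrats_per_site)
    names(expected) <- species
    list(records = records,
         total_quadrats = sum(cfg$quadrats_per_site),
         total_samples = nrow(records),
         total_sites = cfg$n_sites,
         truth = list(occupancy_probs = probs,
                      expected_quadrats = expected,
                      ranking = species[order(-expected, species)]))
  })
}

# built-in physiological index parameters: direction, baseline and
# within-species replicate SD on each assay's natural scale
phys_index_params <- function() {
  data.frame(index = c("MP", "Pro", "MDA", "SOD", "POD"),
             direction = c("harmful", "beneficial", "harmful",
                           "beneficial", "beneficial"),
             base = c(35, 1.0, 6, 220, 60),
             sd_rep = c(2.5, 0.06, 0.4, 12, 5),
             stringsAsFactors = FALSE)
}

#' Simulate the drought-physiology assay table
#'
#' Builds replicate-level values of the five drought-resistance indexes
#' (MP membrane permeability %, free proline, MDA, SOD and POD activity)
#' for a panel of moss species with an embedded true resistance ranking:
#' adjacently ranked species are separated by `phys_separation_sd`
#' replicate standard deviations on every index, beneficial indexes
#' increasing and harmful ones decreasing with resistance.
#'
#' @param cfg a [sim_config()].
#' @return list with `values` (species, index, replicate, value),
#'   `directions` (named character), and `truth` (`ranking`: most
#'   resistant first; `means`: species x index).
#' @export
simulate_physiology <- function(cfg) {
  stopifnot(inherits(cfg, "mosscrust_config"))
  with_seed(cfg$child_seeds[["physiology"]], {
    par <- phys_index_params()
    ns <- cfg$n_phys_species
    species <- sprintf("moss_%02d", seq_len(ns))
    ranking <- sample(species)                # true order, most resistant first
    rank_of <- match(species, ranking)        # 1 = most resistant
    means <- matrix(NA_real_, ns, nrow(par),
                    dimnames = list(species, par$index))
    for (k in seq_len(nrow(par))) {
      step <- cfg$phys_separation_sd * par$sd_rep[k]
      means[, k] <- if (par$direction[k] == "beneficial")
        par$base[k] + (ns - rank_of) * step
      else par$base[k] + (rank_of - 1) * step
    }
    grid <- expand.grid(species = species, index = par$index,
                        replicate = seq_len(cfg$phys_replicates),
                        stringsAsFactors = FALSE)
    sd_rep <- par$sd_rep[match(grid$index, par$index)]
    mu <- means[cbind(grid$species, grid$index)]
    grid$value <- stats::rnorm(nrow(grid), mu, sd_rep)
    # keep assays on their physical support
    grid$value <- pmax(grid$value, 0)
    grid$value[grid$index == "MP"] <- pmin(grid$value[grid$index == "MP"], 100)
    directions <- stats::setNames(par$direction, par$index)
    list(values = grid, directions = directions,
         truth = list(ranking = ranking, means = means))
  })
}

rank_names <- function() c("domain", "phylum", "class", "order", "family",
                           "genus", "species")

synth_taxonomy <- function(cfg) {
  genera <- sprintf("genus_%03d", seq_len(cfg$n_genera))
  phyla <- sprintf("Phylum_%02d", seq_len(cfg$n_phyla))
  genus_phylum <- sample(phyla, cfg$n_genera, replace = TRUE)
  feat <- sprintf("OTU_%04d", seq_len(cfg$n_features))
  feat_genus <- sample(genera, cfg$n_features, replace = TRUE)
  gp <- genus_phylum[match(feat_genus, genera)]
  tax <- data.frame(feature_id = feat,
                    domain = if (cfg$marker == "bacteria") "Bacteria" else "Fungi",
                    phylum = gp,
                    class = paste0(gp, "_c"),
                    order = paste0(gp, "_o"),
                    family = sub("genus", "family", feat_genus),
                    genus = feat_genus,
                    species = NA_character_,
                    stringsAsFactors = FALSE)
  list(taxonomy = tax, genera = genera, genus_phylum = genus_phylum)
}

#' Simulate an 18-sample two-moss microbiome
#'
#' Generates Dirichlet-multinomial OTU counts for the standard design of
#' 2 moss species (Hyp, Hyo) x 3 karst rocky desertification classes
#' (Ve, Se, Sl) x replicates, with (i) per-OTU log-scale compositional
#' shifts for moss species and class (species stronger than class under
#' defaults), (ii) planted genus-level biomarkers differing between the
#' two mosses by `biomarker_fold`, (iii) planted latent-factor
#' co-abundance modules among high-abundance genera (alternating-sign
#' loadings, so a module's total mass stays balanced), and (iv)
#' per-sample drought-physiology and climate covariates, the enzymatic
#' ones mixed with the first module's factor so genus-covariate
#' association is testable. A random coalescent tree over all OTUs
#' supplies the phylogeny for UniFrac and Faith's PD.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (samples x features integer matrix),
#'   `taxonomy` (feature_id + seven ranks), `metadata` (sample factors +
#'   covariates), `tree` (rooted `phylo`), and `truth` (planted
#'   biomarkers, module membership, factors, effect draws).
#' @export
simulate_microbiome <- function(cfg) {
  stopifnot(inherits(cfg, "mosscrust_config"))
  with_seed(cfg$child_seeds[["microbiome"]], {
    n <- cfg$n_samples; p <- cfg$n_features
    reps <- n / 6L
    meta <- expand.grid(replicate = seq_len(reps),
                        desert_class = c("Ve", "Se", "Sl"),
                        moss_species = c("Hyp", "Hyo"),
                        stringsAsFactors = FALSE)[, 3:1]
    meta$sample_id <- sprintf("%s_%s_%d", meta$moss_species,
                              meta$desert_class, meta$replicate)
    tx <- synth_taxonomy(cfg)
    base_log <- stats::rnorm(p, 0, 1.5)

    # per-OTU design shifts, applied on the log-relative-abundance scale
    d_spec <- stats::rnorm(p, 0, cfg$species_effect)
    d_class <- matrix(stats::rnorm(p * 3, 0, cfg$class_effect), p, 3,
                      dimnames = list(NULL, c("Ve", "Se", "Sl")))

    # genus ordering by expected mass, for placing planted structure
    genus_mass <- tapply(exp(base_log), tx$taxonomy$genus, sum)
    top_genera <- names(sort(genus_mass, decreasing = TRUE))

    # planted biomarkers: whole genera shifted between the two mosses
    bm_genera <- character(0); bm_class <- character(0)
    if (cfg$biomarker_fold > 1 && cfg$n_planted_biomarkers > 0) {
      pool <- top_genera[seq_len(max(cfg$n_planted_biomarkers,
                                     ceiling(length(top_genera) / 2)))]
      bm_genera <- sample(pool, cfg$n_planted_biomarkers)
      bm_class <- rep(c("Hyp", "Hyo"), length.out = length(bm_genera))
    }
    bm_features <- tx$taxonomy$feature_id[tx$taxonomy$genus %in% bm_genera]
    # per-feature enrichment class (NA for unplanted features)
    bm_feat_class <- rep(NA_character_, p)
    if (length(bm_genera))
      bm_feat_class <- unname(stats::setNames(bm_class, bm_genera)[tx$taxonomy$genus])

    # planted co-abundance modules among remaining top genera: the major
    # modules first, then the small satellite clusters
    sizes <- c(rep(cfg$module_size, cfg$n_modules),
               rep(cfg$minor_module_size, cfg$n_minor_modules))
    sizes <- sizes[sizes > 0]
    module_of <- stats::setNames(rep(NA_integer_, cfg$n_genera), tx$genera)
    module_type <- character(0)
    loading <- rep(0, p)
    mod_idx <- rep(NA_integer_, p)
    if (length(sizes)) {
      avail <- setdiff(top_genera, bm_genera)
      if (length(avail) < sum(sizes))
        stop("not enough genera to plant the requested modules")
      offset <- 0L
      for (m in seq_along(sizes)) {
        gm <- avail[(offset + 1):(offset + sizes[m])]
        offset <- offset + sizes[m]
        module_of[gm] <- m
        module_type[m] <- if (m <= cfg$n_modules) "major" else "minor"
        feats <- which(tx$taxonomy$genus %in% gm)
        mod_idx[feats] <- m
        sgn <- (-1)^(match(tx$taxonomy$genus[feats], gm))
        loading[feats] <- cfg$module_strength * sgn
      }
    }
    factors <- matrix(stats::rnorm(n * max(length(sizes), 1)), n,
                      max(length(sizes), 1))

    counts <- matrix(0L, n, p,
                     dimnames = list(meta$sample_id, tx$taxonomy$feature_id))
    lib <- stats::rpois(n, cfg$library_size_mean)
    lib[lib == 0] <- 1L
    for (s in seq_len(n)) {
      eta <- base_log +
        ifelse(meta$moss_species[s] == "Hyp", 0.5, -0.5) * d_spec +
        d_class[, meta$desert_class[s]]
      enriched <- !is.na(bm_feat_class) & bm_feat_class == meta$moss_species[s]
      if (any(enriched)) eta[enriched] <- eta[enriched] + log(cfg$biomarker_fold)
      if (length(sizes)) {
        # mass-preserving within-module redistribution: the latent factor
        # moves abundance among a module's members without changing the
        # module's total share, so planting modules does not impose
        # compositional closure effects on the rest of the community
        for (m in seq_along(sizes)) {
          mem <- which(!is.na(mod_idx) & mod_idx == m)
          if (!length(mem)) next
          delta <- loading[mem] * factors[s, m]
          shift <- log(sum(exp(eta[mem] + delta)) / sum(exp(eta[mem])))
          eta[mem] <- eta[mem] + delta - shift
        }
      }
      pr <- exp(eta - max(eta)); pr <- pr / sum(pr)
      g <- stats::rgamma(p, shape = cfg$dm_concentration * pr, rate = 1)
      if (all(g == 0)) g[which.max(pr)] <- 1
      counts[s, ] <- as.integer(stats::rmultinom(1, lib[s], g / sum(g)))
    }

    # covariates: moss-species means anchored to the field physiology
    # (SOD 292/229, Pro 1.42/1.16 for Hyp/Hyo), climate tied to class
    hyp <- meta$moss_species == "Hyp"
    f1 <- factors[, 1]
    rmix <- cfg$covariate_module_cor
    meta$SOD <- ifelse(hyp, 292.03, 229.18) + stats::rnorm(n, 0, 15) +
      rmix * 15 * f1
    meta$Pro <- ifelse(hyp, 1.42, 1.16) + stats::rnorm(n, 0, 0.08) +
      rmix * 0.08 * f1
    meta$POD <- ifelse(hyp, 75, 60) + stats::rnorm(n, 0, 6) + rmix * 6 * f1
    meta$MP <- ifelse(hyp, 42, 48) + stats::rnorm(n, 0, 3)
    meta$MDA <- ifelse(hyp, 5.2, 6.0) + stats::rnorm(n, 0, 0.5)
    climate <- list(rain = c(Ve = 900, Se = 1050, Sl = 1200),
                    TEM = c(Ve = 16, Se = 15, Sl = 14),
                    sun = c(Ve = 1400, Se = 1300, Sl = 1200),
                    elevation = c(Ve = 1300, Se = 1000, Sl = 1100))
    csd <- c(rain = 40, TEM = 0.8, sun = 50, elevation = 60)
    for (v in names(climate))
      meta[[v]] <- climate[[v]][meta$desert_class] + stats::rnorm(n, 0, csd[[v]])
    rownames(meta) <- meta$sample_id
    meta <- meta[, c("sample_id", "moss_species", "desert_class", "replicate",
                     "SOD", "Pro", "POD", "MP", "MDA",
                     "rain", "TEM", "sun", "elevation")]

    tree <- with_seed(cfg$child_seeds[["tree"]],
                      ape::rcoal(p, tip.label = tx$taxonomy$feature_id))

    list(counts = counts, taxonomy = tx$taxonomy, metadata = meta,
         tree = tree,
         truth = list(
           biomarker_genera = bm_genera,
           biomarker_class = stats::setNames(bm_class, bm_genera),
           biomarker_features = bm_features,
           modules = module_of[!is.na(module_of)],
           module_type = module_type,
           factors = factors,
           species_effect = d_spec, class_effect = d_class,
           covariate_module_cor = rmix))
  })
}

#' Simulate a guild rule table
#'
#' Maps a configured fraction of the synthetic genera to ecological
#' function groups in the style of the FAPROTAX (bacteria) and FUNGuild
#' (fungi) annotation tables, with confidence labels drawn from
#' \{possible, probable, highly probable\}.
#'
#' @param cfg a [sim_config()].
#' @param taxonomy taxonomy table as returned by [simulate_microbiome()].
#' @return list with `rules` (rank, taxon, guild, confidence) and
#'   `truth` (named genus -> guild map).
#' @export
simulate_guild_rules <- function(cfg, taxonomy) {
  stopifnot(inherits(cfg, "mosscrust_config"))
  with_seed(cfg$child_seeds[["guilds"]], {
    guild_sets <- list(
      bacteria = c("photoautotrophy", "chemoheterotrophy",
                   "nitrate_reduction", "methanotrophy", "human_pathogens"),
      fungi = c("plant_pathogen", "plant_saprotroph", "dung_saprotroph",
                "undefined_saprotroph", "endophyte", "ectomycorrhizal",
                "animal_pathogen", "fungal_parasite"))
    genera <- sort(unique(taxonomy$genus))
    n_map <- round(cfg$guild_mapped_fraction * length(genera))
    mapped <- sort(sample(genera, n_map))
    guilds <- sample(guild_sets[[cfg$marker]], n_map, replace = TRUE)
    conf <- sample(c("possible", "probable", "highly probable"), n_map,
                   replace = TRUE, prob = c(0.2, 0.5, 0.3))
    rules <- data.frame(rank = "genus", taxon = mapped, guild = guilds,
                        confidence = conf, stringsAsFactors = FALSE)
    list(rules = rules, truth = stats::setNames(guilds, mapped))
  })
}
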