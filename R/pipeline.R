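#' Default pipeline configuration
#'
#' Thresholds follow the conventions of the study design: ANOVA /
#' Kruskal-Wallis alpha 0.05, LDA score cut 2.0, network |rho| cuts 0.6
#' (bacteria) / 0.7 (fungi) at p <= 0.01, dominance top-k 20, DCA
#' method-selection boundary 3.5 SD.
#'
#' @param seed master seed for the run (drives the simulation and every
#'   permutation test).
#' @param out_dir output directory (`NULL` disables file output).
#' @param stages character vector of stages to run, in dependency order;
#'   any subset of `simulate`, `survey`, `drought`, `diversity`,
#'   `stats`, `guilds`, `network`.
#' @param ... overrides for individual entries (`alpha`, `lda_cut`,
#'   `rho_cut`, `p_cut`, `top_k`, `top_n_genera`, `n_perm`, `sim` a
#'   [sim_config()]).
#' @return list of class `mosscrust_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            stages = c("simulate", "survey", "drought",
                                       "diversity", "stats", "guilds",
                                       "network"),
                            ...) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
              alpha = 0.05, lda_cut = 2.0, rho_cut = 0.6, p_cut = 0.01,
              top_k = 20, top_n_genera = 50, n_perm = 999,
              dca_boundary = 3.5, rho = 0.5,
              sim = sim_config(seed = seed))
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "mosscrust_pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments/overrides; a
#' `sim:` block maps to [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return a `mosscrust_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  seed <- if (!is.null(y$seed)) y$seed else 1L
  y$seed <- NULL
  cfg <- do.call(pipeline_config, c(list(seed = seed), y))
  if (!is.null(sim_args))
    cfg$sim <- do.call(sim_config, c(list(seed = seed), sim_args))
  cfg
}

stage_out <- function(cfg, ...) {
  if (is.null(cfg$out_dir)) return(NULL)
  file.path(cfg$out_dir, ...)
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order — simulate the
#' inputs, screen dominant species from the survey, score drought
#' resistance, compute community diversity (alpha metrics, Bray-Curtis
#' and unweighted UniFrac, NMDS, UPGMA, Venn core/exclusive OTUs,
#' dominant phyla), run the hypothesis tests (ANOVA on the covariates,
#' PERMANOVA, LEfSe, DCA-selected constrained ordination, genus-factor
#' Spearman heatmap), annotate guilds, and build the genus co-occurrence
#' network. All randomness derives from the config seed, so the same
#' config yields an identical report. When `out_dir` is set each stage
#' writes its tables as TSV and the whole report as JSON.
#'
#' @param cfg a [pipeline_config()] (or path to a YAML file).
#' @return nested list report with one element per executed stage.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "mosscrust_pipeline_config"))
  known <- c("simulate", "survey", "drought", "diversity", "stats",
             "guilds", "network")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- known[known %in% cfg$stages]
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = list(seed = cfg$seed, alpha = cfg$alpha,
                               lda_cut = cfg$lda_cut, rho_cut = cfg$rho_cut,
                               p_cut = cfg$p_cut, top_k = cfg$top_k,
                               n_perm = cfg$n_perm))
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- run_stage("simulate", function() {
    sv <- simulate_survey(cfg$sim)
    ph <- simulate_physiology(cfg$sim)
    mb <- simulate_microbiome(cfg$sim)
    gr <- simulate_guild_rules(cfg$sim, mb$taxonomy)
    if (!is.null(cfg$out_dir)) {
      write_tsv(sv$records, stage_out(cfg, "survey.tsv"))
      write_tsv(ph$values, stage_out(cfg, "physiology.tsv"))
      write_otu_tsv(mb$counts, stage_out(cfg, "otu_table.tsv"))
      write_taxonomy_tsv(mb$taxonomy, stage_out(cfg, "taxonomy.tsv"))
      write_tsv(mb$metadata, stage_out(cfg, "metadata.tsv"))
      ape::write.tree(mb$tree, stage_out(cfg, "tree.nwk"))
      write_tsv(gr$rules, stage_out(cfg, "guild_rules.tsv"))
    }
    list(survey = sv, physiology = ph, microbiome = mb, guild_rules = gr)
  })
  report$simulate <- list(
    n_survey_records = nrow(sim$survey$records),
    n_samples = nrow(sim$microbiome$counts),
    n_features = ncol(sim$microbiome$counts))
  if (identical(cfg$stages, "simulate") ||
      length(setdiff(stages, "simulate")) == 0) {
    finish_report(report, cfg)
    return(invisible(report))
  }

  if ("survey" %in% stages) report$survey <- run_stage("survey", function() {
    ds <- survey_dataset(sim$survey$records,
                         total_quadrats = sim$survey$total_quadrats,
                         total_samples = sim$survey$total_samples,
                         total_sites = sim$survey$total_sites)
    tab <- dominance_indices(ds)
    summ <- summarize_dominants(tab, min(cfg$top_k, nrow(tab)))
    if (!is.null(cfg$out_dir))
      write_tsv(tab, stage_out(cfg, "dominance_indices.tsv"))
    list(table = tab, top = summ$selection$species_id,
         total_sn_s = summ$total_sn_s, total_na_ta = summ$total_na_ta)
  })

  if ("drought" %in% stages) report$drought <- run_stage("drought", function() {
    means <- physiology_means(sim$physiology$values)
    z <- membership_matrix(means, sim$physiology$directions)
    sc <- comprehensive_score(z)
    gr <- grey_relational_grades(
      sc$score[match(rownames(z), sc$species)], z, rho = cfg$rho)
    cls <- classify_resistance(stats::setNames(sc$score, sc$species))
    if (!is.null(cfg$out_dir)) {
      write_tsv(sc, stage_out(cfg, "drought_scores.tsv"))
      write_tsv(gr, stage_out(cfg, "grey_relation.tsv"))
    }
    list(scores = sc, grey = gr, classes = as.list(cls),
         recovered_ranking = sc$species,
         true_ranking = sim$physiology$truth$ranking)
  })

  mb <- sim$microbiome
  if ("diversity" %in% stages) report$diversity <- run_stage("diversity", function() {
    alpha <- alpha_diversity(mb$counts,
                             c("chao1", "shannon", "goods_coverage",
                               "faith_pd"), tree = mb$tree)
    bc <- bray_curtis(mb$counts)
    uf <- unweighted_unifrac(mb$counts, mb$tree)
    nm <- nmds(uf, dims = 2, restarts = 10, seed = cfg$seed)
    up <- upgma(uf)
    groups <- stats::setNames(paste(mb$metadata$moss_species,
                                    mb$metadata$desert_class, sep = "-"),
                              mb$metadata$sample_id)
    venn <- core_and_exclusive(mb$counts, groups)
    dom <- dominant_taxa(mb$counts, mb$taxonomy, "phylum")
    if (!is.null(cfg$out_dir)) {
      write_tsv(alpha, stage_out(cfg, "alpha_diversity.tsv"))
      write_distance_tsv(bc, stage_out(cfg, "bray_curtis.tsv"))
      write_distance_tsv(uf, stage_out(cfg, "unifrac.tsv"))
      writeLines(up$newick, stage_out(cfg, "upgma.nwk"))
      jsonlite::write_json(venn[c("core_count", "exclusive")],
                           stage_out(cfg, "venn.json"), auto_unbox = TRUE)
    }
    list(alpha = alpha, nmds_stress = nm$stress,
         core_otus = venn$core_count,
         exclusive = as.list(venn$exclusive),
         dominant_phyla = dom$taxon,
         mean_goods_coverage = mean(alpha$goods_coverage),
         bray_curtis = bc, unifrac = uf, upgma_newick = up$newick)
  })

  if ("stats" %in% stages) report$stats <- run_stage("stats", function() {
    meta <- mb$metadata
    bc <- if (!is.null(report$diversity)) report$diversity$bray_curtis
          else bray_curtis(mb$counts)
    perm <- permanova(bc, ~ moss_species * desert_class, meta,
                      n_perm = cfg$n_perm, seed = cfg$seed)
    anova_tab <- do.call(rbind, lapply(c("SOD", "Pro", "POD", "MP", "MDA"),
      function(v) {
        a <- one_way_anova(meta[[v]], meta$moss_species)
        data.frame(index = v, F = a$F, p = a$p, stringsAsFactors = FALSE)
      }))
    lef <- lefse(mb$counts, mb$taxonomy, stats::setNames(
      meta$moss_species, meta$sample_id), alpha = cfg$alpha,
      lda_cut = cfg$lda_cut, seed = cfg$seed)
    sel <- gradient_length_select(mb$counts)
    covs <- meta[, c("SOD", "Pro", "POD", "MP", "MDA", "rain", "TEM",
                     "sun", "elevation")]
    ord <- constrained_ordination(mb$counts, covs, method = sel$method,
                                  n_perm = cfg$n_perm, seed = cfg$seed)
    genus <- select_top_features(mb$counts, mb$taxonomy, "genus",
                                 cfg$top_n_genera)
    hm <- factor_taxon_heatmap(genus, covs)
    if (!is.null(cfg$out_dir)) {
      write_tsv(perm, stage_out(cfg, "permanova.tsv"))
      write_tsv(anova_tab, stage_out(cfg, "anova.tsv"))
      write_tsv(lef, stage_out(cfg, "biomarkers.tsv"))
      write_tsv(ord$covariates, stage_out(cfg, "ordination_covariates.tsv"))
      write_tsv(data.frame(taxon = rownames(hm$rho), hm$rho,
                           check.names = FALSE),
                stage_out(cfg, "heatmap_rho.tsv"))
    }
    list(permanova = perm, anova = anova_tab, biomarkers = lef,
         dca = sel, ordination_method = ord$method,
         ordination_covariates = ord$covariates)
  })

  if ("guilds" %in% stages) report$guilds <- run_stage("guilds", function() {
    assignment <- assign_guilds(mb$taxonomy, sim$guild_rules$rules,
                                min_confidence = "probable")
    prof <- guild_profile(mb$counts, assignment)
    if (!is.null(cfg$out_dir))
      write_tsv(data.frame(sample_id = rownames(prof), prof,
                           check.names = FALSE),
                stage_out(cfg, "guild_profile.tsv"))
    list(guilds = colnames(prof),
         mean_profile = as.list(colMeans(prof)))
  })

  if ("network" %in% stages) report$network <- run_stage("network", function() {
    genus <- select_top_features(mb$counts, mb$taxonomy, "genus",
                                 cfg$top_n_genera)
    tl <- taxon_labels(mb$taxonomy, "genus")
    phyl <- tapply(mb$taxonomy$phylum, tl[mb$taxonomy$feature_id],
                   function(x) x[1])
    net <- build_network(genus, rho_cut = cfg$rho_cut, p_cut = cfg$p_cut,
                         phylum = phyl)
    mt <- if (nrow(net$edges)) network_metrics(net) else NULL
    if (!is.null(cfg$out_dir)) {
      write_tsv(net$edges, stage_out(cfg, "network_edges.tsv"))
      if (!is.null(mt))
        write_tsv(mt$node_metrics, stage_out(cfg, "network_nodes.tsv"))
    }
    list(n_edges = nrow(net$edges),
         n_positive = sum(net$edges$sign == "positive"),
         n_negative = sum(net$edges$sign == "negative"),
         metrics = if (is.null(mt)) NULL else
           mt[c("average_path_length", "diameter", "transitivity",
                "modularity", "n_major_modules", "keystone_taxa")])
  })

  finish_report(report, cfg)
  invisible(report)
}

finish_report <- function(report, cfg) {
  if (is.null(cfg$out_dir)) return(invisible(NULL))
  slim <- report
  # distance matrices and newick strings stay in their TSV twins
  if (!is.null(slim$diversity))
    slim$diversity[c("bray_curtis", "unifrac", "upgma_newick")] <- NULL
  jsonlite::write_json(slim, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns", force = TRUE)
  invisible(NULL)
}
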