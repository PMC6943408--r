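#' Construct a quadrat survey dataset
#'
#' Holds presence records of moss species in quadrats nested in sites,
#' together with the survey-wide totals the dominance indices need: the
#' total quadrat count, the total number of collected samples S (each
#' presence record is one specimen), and the total number of sites T_a.
#'
#' @param records data.frame with columns `site_id`, `quadrat_id`,
#'   `species_id`. Quadrat ids must be unique within a site (they are
#'   keyed as site:quadrat internally).
#' @param total_quadrats total quadrats surveyed, including empty ones;
#'   defaults to the number of distinct (site, quadrat) pairs observed.
#' @param total_samples total specimens collected (S); defaults to
#'   `nrow(records)`.
#' @param total_sites total sites surveyed (T_a); defaults to the number
#'   of distinct sites observed.
#' @param coverage optional named numeric vector of per-species cover
#'   fractions in [0, 1] (an externally measured quantity).
#' @return object of class `survey_dataset`.
#' @export
survey_dataset <- function(records, total_quadrats = NULL,
                           total_samples = NULL, total_sites = NULL,
                           coverage = NULL) {
  need <- c("site_id", "quadrat_id", "species_id")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  records <- as.data.frame(records)[, need]
  records[] <- lapply(records, as.character)
  quad_key <- paste(records$site_id, records$quadrat_id, sep = ":")
  n_quads_obs <- length(unique(quad_key))
  if (is.null(total_quadrats)) total_quadrats <- n_quads_obs
  if (total_quadrats < n_quads_obs)
    stop("total_quadrats (", total_quadrats, ") is smaller than the ",
         n_quads_obs, " distinct quadrats referenced")
  if (is.null(total_samples)) total_samples <- nrow(records)
  if (is.null(total_sites)) total_sites <- length(unique(records$site_id))
  if (total_samples <= 0 && nrow(records) > 0)
    stop("total_samples must be > 0")
  if (total_sites <= 0 && nrow(records) > 0)
    stop("total_sites must be > 0")
  if (!is.null(coverage)) {
    if (is.null(names(coverage)))
      stop("coverage must be a named vector keyed by species_id")
    if (any(coverage < 0 | coverage > 1))
      stop("coverage fractions must be in [0, 1]")
  }
  structure(list(records = records, quad_key = quad_key,
                 total_quadrats = as.integer(total_quadrats),
                 total_samples = as.integer(total_samples),
                 total_sites = as.integer(total_sites),
                 coverage = coverage),
            class = "survey_dataset")
}

#' Species frequency in a quadrat survey
#'
#' Frequency of one species as a percentage: 100 x (number of distinct
#' quadrats in which it occurs) / (total quadrats surveyed).
#'
#' @param dataset a [survey_dataset()].
#' @param species_id species to look up; an unknown species returns 0
#'   with a warning (legitimately unobserved, not an error).
#' @return percentage in [0, 100].
#' @export
species_frequency <- function(dataset, species_id) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (dataset$total_quadrats <= 0) stop("total_quadrats must be > 0")
  hit <- dataset$records$species_id == species_id
  if (!any(hit)) {
    warning("species '", species_id, "' not present in the survey; frequency 0")
    return(0)
  }
  100 * length(unique(dataset$quad_key[hit])) / dataset$total_quadrats
}

#' Dominance indices of every surveyed species
#'
#' For each species N computes the four screening indices used to rank
#' dominant biocrust bryophytes: the quadrat frequency (percent), S_N/S
#' (quadrats with the species over total samples collected), S_N/N_a
#' (quadrats with the species over sites with the species; the
#' sub-standard), and N_a/T_a (sites with the species over total sites;
#' the assessment index). Values are returned at full precision; round
#' only for presentation (1 d.p. frequency, 3 d.p. ratios).
#'
#' @param dataset a [survey_dataset()].
#' @return data.frame sorted by `sn_s` (desc) with columns `species_id`,
#'   `s_n`, `n_a`, `species_frequency`, `sn_s`, `sn_na`, `na_ta`, and
#'   `coverage` when the dataset carries it.
#' @export
dominance_indices <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  rec <- dataset$records
  if (nrow(rec) == 0) {
    out <- data.frame(species_id = character(), s_n = integer(),
                      n_a = integer(), species_frequency = numeric(),
                      sn_s = numeric(), sn_na = numeric(), na_ta = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  sp <- sort(unique(rec$species_id))
  s_n <- vapply(sp, function(s)
    length(unique(dataset$quad_key[rec$species_id == s])), integer(1))
  n_a <- vapply(sp, function(s)
    length(unique(rec$site_id[rec$species_id == s])), integer(1))
  out <- data.frame(species_id = sp, s_n = s_n, n_a = n_a,
                    species_frequency = 100 * s_n / dataset$total_quadrats,
                    sn_s = s_n / dataset$total_samples,
                    sn_na = ifelse(n_a > 0, s_n / n_a, NA_real_),
                    na_ta = n_a / dataset$total_sites,
                    stringsAsFactors = FALSE)
  if (!is.null(dataset$coverage))
    out$coverage <- unname(dataset$coverage[out$species_id])
  out <- out[order(-out$sn_s, -out$species_frequency, out$species_id), ]
  rownames(out) <- NULL
  out
}

#' Summarize the top dominant species
#'
#' Selects the `top_k` species by S_N/S (ties broken by frequency, then
#' species id) and reports the selection along with the column totals of
#' S_N/S and N_a/T_a over it, the summary used to state how much of the
#' moss flora the dominants account for.
#'
#' @param table a dominance table from [dominance_indices()] (any
#'   data.frame with `species_id`, `sn_s`, `na_ta`, `species_frequency`).
#' @param top_k how many species to keep; must not exceed the table size.
#' @return list with `selection`, `total_sn_s`, `total_na_ta`.
#' @export
summarize_dominants <- function(table, top_k) {
  stopifnot(is.data.frame(table))
  if (top_k > nrow(table))
    stop("top_k (", top_k, ") exceeds the ", nrow(table), " species available")
  if (top_k == 0)
    return(list(selection = table[0, , drop = FALSE],
                total_sn_s = 0, total_na_ta = 0))
  ord <- order(-table$sn_s, -table$species_frequency, table$species_id)
  sel <- table[ord[seq_len(top_k)], , drop = FALSE]
  rownames(sel) <- NULL
  list(selection = sel,
       total_sn_s = sum(sel$sn_s),
       total_na_ta = sum(sel$na_ta))
}

#' Select candidate dominant species by frequency and coverage
#'
#' Union of two arms: the top `frequency_rank_cut` species by frequency,
#' and every species whose cover fraction reaches `coverage_cut` — the
#' comprehensive frequency-plus-coverage screen that yields the
#' candidate panel for drought-resistance testing.
#'
#' @param table dominance table; needs a `coverage` column when
#'   `coverage_cut` is used.
#' @param frequency_rank_cut keep this many top-frequency species
#'   (`NULL` disables the arm).
#' @param coverage_cut minimal cover fraction (`NULL` disables the arm).
#' @return character vector of selected species ids (sorted).
#' @export
select_candidates <- function(table, frequency_rank_cut = NULL,
                              coverage_cut = NULL) {
  stopifnot(is.data.frame(table))
  picked <- character(0)
  if (!is.null(frequency_rank_cut) && frequency_rank_cut > 0) {
    ord <- order(-table$species_frequency, table$species_id)
    picked <- table$species_id[ord[seq_len(min(frequency_rank_cut,
                                               nrow(table)))]]
  }
  if (!is.null(coverage_cut)) {
    if (is.null(table$coverage))
      stop("coverage_cut was given but the table has no coverage column")
    picked <- union(picked,
                    table$species_id[!is.na(table$coverage) &
                                       table$coverage >= coverage_cut])
  }
  sort(picked)
}
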