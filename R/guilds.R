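# Ecological guild annotation from user-supplied rule tables
# (FAPROTAX / FUNGuild style) and per-sample guild profiles.

confidence_levels <- function() c("possible", "probable", "highly probable")

#' Assign guilds to features from a rule table
#'
#' Each rule maps a taxon name at a stated rank to a guild with a
#' confidence label. Rules below `min_confidence` are ignored. For a
#' feature matched by several rules, the rule at the deepest rank wins;
#' conflicting rules at the same rank resolve to the first listed, with
#' a warning. Matching is case-insensitive exact match on the taxon name
#' at the rule's rank. Unmatched features map to `"unassigned"`.
#'
#' @param taxonomy taxonomy table (feature_id + rank columns).
#' @param rules data.frame with `rank`, `taxon`, `guild`, `confidence`.
#' @param min_confidence minimal confidence retained; one of
#'   `"possible"`, `"probable"`, `"highly probable"`.
#' @return named character vector feature_id -> guild.
#' @export
assign_guilds <- function(taxonomy, rules, min_confidence = "probable") {
  lv <- confidence_levels()
  min_confidence <- match.arg(min_confidence, lv)
  need <- c("rank", "taxon", "guild", "confidence")
  if (!all(need %in% names(rules)))
    stop("rules must have columns ", paste(need, collapse = ", "))
  bad <- !rules$confidence %in% lv
  if (any(bad)) stop("unknown confidence label(s): ",
                     paste(unique(rules$confidence[bad]), collapse = ", "))
  if (any(is.na(rules$taxon) | rules$taxon == ""))
    stop("rule taxon patterns must be non-empty")
  rules <- rules[match(rules$confidence, lv) >= match(min_confidence, lv), ,
                 drop = FALSE]
  out <- stats::setNames(rep("unassigned", nrow(taxonomy)),
                         taxonomy$feature_id)
  if (!nrow(rules)) return(out)
  ranks <- rank_names()
  if (!all(rules$rank %in% ranks))
    stop("unknown rank(s) in rules: ",
         paste(setdiff(unique(rules$rank), ranks), collapse = ", "))
  depth <- stats::setNames(rep(0L, nrow(taxonomy)), taxonomy$feature_id)
  for (rk in ranks) {    # shallow to deep, so deeper matches overwrite
    rr <- rules[rules$rank == rk, , drop = FALSE]
    if (!nrow(rr)) next
    dup <- duplicated(tolower(rr$taxon))
    if (any(dup)) {
      warning("conflicting same-rank rules for: ",
              paste(unique(rr$taxon[dup]), collapse = ", "),
              "; first listed wins")
      rr <- rr[!dup, , drop = FALSE]
    }
    tax_at <- tolower(as.character(taxonomy[[rk]]))
    hit <- match(tax_at, tolower(rr$taxon))
    found <- !is.na(hit)
    out[found] <- rr$guild[hit[found]]
    depth[found] <- match(rk, ranks)
  }
  out
}

#' Per-sample guild relative-abundance profile
#'
#' Pools feature counts by assigned guild and converts to per-sample
#' relative abundances (fractions summing to 1 including the
#' `"unassigned"` residual). With `drop_unassigned = TRUE` the
#' unassigned mass is removed before renormalization, preserving the
#' ratios among assigned guilds.
#'
#' @param table OTU table (samples x features).
#' @param assignment named feature -> guild map from [assign_guilds()].
#' @param drop_unassigned drop and renormalize.
#' @return samples x guilds matrix of fractions.
#' @export
guild_profile <- function(table, assignment, drop_unassigned = FALSE) {
  table <- otu_table(table)
  miss <- setdiff(colnames(table), names(assignment))
  if (length(miss))
    stop("assignment does not cover feature(s): ",
         paste(utils::head(miss, 3), collapse = ", "))
  grp <- assignment[colnames(table)]
  agg <- t(rowsum(t(table), group = grp))
  if (drop_unassigned && "unassigned" %in% colnames(agg)) {
    agg <- agg[, colnames(agg) != "unassigned", drop = FALSE]
    if (any(rowSums(agg) == 0))
      stop("a sample has no assigned reads; cannot renormalize")
  }
  agg / rowSums(agg)
}
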