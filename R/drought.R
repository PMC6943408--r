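#' Electrolyte leakage from paired conductivity readings
#'
#' Membrane permeability (MP) as the percentage of the initial
#' conductivity of the bathing solution (EC1) over the conductivity
#' after boiling the tissue (EC2): 100 x EC1/EC2.
#'
#' @param ec1 conductivity before boiling (vectorized).
#' @param ec2 conductivity after boiling; must be > 0.
#' @return percentage(s). Readings with `ec1 > ec2` are physically
#'   suspect and raise a warning.
#' @export
electrolyte_leakage <- function(ec1, ec2) {
  if (any(ec2 <= 0)) stop("ec2 must be > 0")
  if (any(ec1 > ec2)) warning("ec1 > ec2: physically suspect reading(s)")
  100 * ec1 / ec2
}

#' Membership (subordinate) function transform of one index
#'
#' Min-max normalizes a physiological index across species, direction
#' adjusted: beneficial indexes (Pro, SOD, POD) map as
#' (x - min)/(max - min) so the best species gets 1; harmful indexes
#' (MP, MDA) are reflected, (max - x)/(max - min). In a non-constant
#' column both endpoints 0 and 1 are attained.
#'
#' @param values numeric vector, one entry per species.
#' @param direction `"beneficial"` or `"harmful"`.
#' @param constant what to do with a constant column: `"error"`
#'   (default) or `"midpoint"` (all memberships 0.5).
#' @return memberships in [0, 1].
#' @export
membership_transform <- function(values,
                                 direction = c("beneficial", "harmful"),
                                 constant = c("error", "midpoint")) {
  direction <- match.arg(direction)
  constant <- match.arg(constant)
  if (length(values) < 2) stop("need at least 2 species")
  if (any(!is.finite(values))) stop("values must be finite")
  rng <- range(values)
  if (diff(rng) == 0) {
    if (constant == "error")
      stop("DegenerateIndex: column is constant; no membership is defined")
    return(rep(0.5, length(values)))
  }
  z <- (values - rng[1]) / diff(rng)
  if (direction == "harmful") z <- 1 - z
  z
}

#' Membership matrix from per-species index means
#'
#' Applies [membership_transform()] column-wise to a species x index
#' matrix of raw means.
#'
#' @param means species x index numeric matrix (dimnames required).
#' @param directions named character vector mapping each index to
#'   `"beneficial"` or `"harmful"`. Defaults to the standard map for the
#'   five drought indexes (Pro/SOD/POD beneficial, MP/MDA harmful).
#' @param constant passed to [membership_transform()].
#' @return matrix of memberships with the same dimnames.
#' @export
membership_matrix <- function(means, directions = default_directions(),
                              constant = c("error", "midpoint")) {
  constant <- match.arg(constant)
  means <- as.matrix(means)
  if (is.null(colnames(means))) stop("means must have index column names")
  miss <- setdiff(colnames(means), names(directions))
  if (length(miss))
    stop("no direction given for index(es): ", paste(miss, collapse = ", "))
  z <- means
  for (j in colnames(means))
    z[, j] <- membership_transform(means[, j], directions[[j]], constant)
  z
}

#' Default directionality of the five drought indexes
#'
#' Proline, SOD and POD rise with stress tolerance (beneficial); membrane
#' permeability and MDA indicate membrane damage (harmful, membership
#' reflected).
#' @return named character vector.
#' @export
default_directions <- function() {
  c(MP = "harmful", Pro = "beneficial", MDA = "harmful",
    SOD = "beneficial", POD = "beneficial")
}

#' Comprehensive drought-resistance score and ranking
#'
#' The comprehensive score of a species is the arithmetic mean of its
#' index memberships; the larger the mean, the stronger the drought
#' resistance, so rank 1 is the largest score. Ties share the smallest
#' rank (flagged with a warning) and the output is ordered by score,
#' then species id.
#'
#' @param memberships species x index membership matrix, no missing
#'   values.
#' @return data.frame with `species`, `score`, `rank`.
#' @export
comprehensive_score <- function(memberships) {
  z <- as.matrix(memberships)
  if (any(is.na(z))) stop("memberships contain missing values")
  if (is.null(rownames(z))) rownames(z) <- paste0("species_", seq_len(nrow(z)))
  score <- rowMeans(z)
  rk <- rank(-score, ties.method = "min")
  if (anyDuplicated(score)) warning("tied comprehensive scores; ranks shared")
  out <- data.frame(species = rownames(z), score = unname(score),
                    rank = unname(as.integer(rk)), stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$species), ]
  rownames(out) <- NULL
  out
}

#' Grey relational grades of the indexes against the comprehensive score
#'
#' Deng's grey relational analysis: with reference sequence x0 (the
#' comprehensive scores) and comparison sequences xi (the membership
#' columns), Delta_i(k) = |x0(k) - xi(k)|; the relational coefficient is
#' xi_i(k) = (Dmin + rho * Dmax) / (Delta_i(k) + rho * Dmax) with Dmin,
#' Dmax global over all i, k; the grade of sequence i is the mean
#' coefficient over k. Grades lie in (rho/(1+rho), 1] and equal 1 only
#' when a sequence coincides with the reference. Indexes are ranked by
#' grade, descending.
#'
#' @param reference numeric vector (one value per species).
#' @param comparisons matrix with one column per index, same row count.
#' @param rho distinguishing coefficient in (0, 1]; 0.5 is the usual
#'   Deng convention.
#' @return data.frame with `index`, `grade`, `rank`.
#' @export
grey_relational_grades <- function(reference, comparisons, rho = 0.5) {
  comparisons <- as.matrix(comparisons)
  if (length(reference) != nrow(comparisons))
    stop("reference and comparison sequences must have the same length")
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  if (is.null(colnames(comparisons)))
    colnames(comparisons) <- paste0("index_", seq_len(ncol(comparisons)))
  delta <- abs(comparisons - reference)
  dmin <- min(delta); dmax <- max(delta)
  if (dmax == 0) {
    grades <- rep(1, ncol(comparisons))
  } else {
    xi <- (dmin + rho * dmax) / (delta + rho * dmax)
    grades <- colMeans(xi)
  }
  rk <- rank(-grades, ties.method = "min")
  out <- data.frame(index = colnames(comparisons), grade = unname(grades),
                    rank = unname(as.integer(rk)), rho = rho,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$grade, out$index), ]
  rownames(out) <- NULL
  out
}

#' Classify drought resistance from comprehensive scores
#'
#' Three-way labels by score thresholds with closed boundaries: `high`
#' for score >= `high_cut`, `low` for score <= `low_cut`, otherwise
#' `intermediate`. The defaults (0.55 / 0.42) split the bundled
#' reference panel of seven karst mosses into clear high / intermediate /
#' low groups.
#'
#' @param scores numeric vector (optionally named).
#' @param high_cut,low_cut thresholds with `low_cut < high_cut`.
#' @return character vector of labels.
#' @export
classify_resistance <- function(scores, high_cut = 0.55, low_cut = 0.42) {
  if (low_cut >= high_cut) stop("low_cut must be < high_cut")
  lab <- ifelse(scores >= high_cut, "high",
                ifelse(scores <= low_cut, "low", "intermediate"))
  if (!is.null(names(scores))) names(lab) <- names(scores)
  lab
}

#' Per-species replicate means of a long physiology table
#'
#' @param values data.frame with `species`, `index`, `value` (replicate
#'   level).
#' @return species x index matrix of means.
#' @export
physiology_means <- function(values) {
  need <- c("species", "index", "value")
  if (!all(need %in% names(values)))
    stop("values must have columns ", paste(need, collapse = ", "))
  tab <- tapply(values$value, list(values$species, values$index), mean)
  tab[, unique(values$index), drop = FALSE]
}
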