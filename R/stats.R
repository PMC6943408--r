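# Hypothesis-testing layer: one-way ANOVA, distance-based PERMANOVA
# with sequential sums of squares, LEfSe-style biomarker discovery, and
# Spearman genus-by-factor heatmaps.

#' One-way ANOVA
#'
#' Classical F test of equal group means.
#'
#' @param values numeric vector.
#' @param groups grouping vector (>= 2 levels, >= 2 residual df unless
#'   variance is degenerate).
#' @return list with `F`, `p`, `df`, and `degenerate` (TRUE when all
#'   within-group variances are zero, in which case p is set to 0 if the
#'   means differ and 1 if they coincide).
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(values) != length(groups)) stop("length mismatch")
  n <- length(values)
  k <- nlevels(groups)
  gm <- tapply(values, groups, mean)
  ssb <- sum(tapply(values, groups, length) * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- k - 1; df2 <- n - k
  if (df2 < 1) stop("need at least 2 total residual degrees of freedom")
  if (ssw <= .Machine$double.eps * sum(values^2)) {
    # all groups internally constant: distribution degenerates
    p <- if (ssb > 0) 0 else 1
    return(list(F = if (ssb > 0) Inf else NaN, p = p, df = c(df1, df2),
                degenerate = TRUE))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df = c(df1, df2), degenerate = FALSE)
}

gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

hat_matrix <- function(x) {
  q <- qr(x)
  qq <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(qq)
}

all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(nrow(sub))) for (pos in seq_len(n)) {
    r <- r + 1L
    out[r, ] <- append(sub[i, ], n, after = pos - 1L)
  }
  out
}

#' PERMANOVA: permutational multivariate ANOVA on a distance matrix
#'
#' McArdle-Anderson decomposition of a Gower-centered distance matrix
#' with sequential (Type I) sums of squares, supporting factors,
#' continuous covariates, and interactions. For each term,
#' R2 = SS_term / SS_total and a pseudo-F against the residual; p-values
#' come from free permutation of sample labels with the add-one
#' estimator p = (1 + #\{F* >= F\}) / (1 + n_perm), or from exhaustive
#' enumeration of all n! relabelings when `exact = TRUE` (n <= 8), where
#' p = #\{F* >= F\} / n! including the identity.
#'
#' @param dist symmetric distance matrix with sample labels.
#' @param formula right-hand-side formula over columns of `data`, e.g.
#'   `~ moss_species * desert_class` or `~ SOD`.
#' @param data data.frame of sample metadata, aligned to `dist` by row
#'   names when present.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param exact exhaustively enumerate all permutations instead.
#' @return data.frame with one row per term plus Residual and Total:
#'   `term`, `df`, `SumOfSqs`, `R2`, `F`, `p`.
#' @export
permanova <- function(dist, formula, data, n_perm = 999, seed = NULL,
                      exact = FALSE) {
  d <- check_distance(dist)
  n <- nrow(d)
  data <- as.data.frame(data)
  if (!is.null(rownames(d)) && all(rownames(d) %in% rownames(data)))
    data <- data[rownames(d), , drop = FALSE]
  if (nrow(data) != n) stop("data must have one row per sample")
  tl <- attr(stats::terms(formula), "term.labels")
  if (!length(tl)) stop("formula has no terms")
  fvars <- intersect(all.vars(formula), names(data))
  bad <- fvars[vapply(data[fvars], function(x)
    !is.numeric(x) && any(table(x) < 2), logical(1))]
  if (length(bad))
    stop("factor level(s) with < 2 samples in: ", paste(bad, collapse = ", "))

  g <- gower_center(d)
  ss_total <- sum(diag(g))
  hats <- vector("list", length(tl) + 1)
  hats[[1]] <- matrix(1 / n, n, n)
  dfs <- numeric(length(tl))
  for (j in seq_along(tl)) {
    x <- stats::model.matrix(stats::reformulate(tl[seq_len(j)]), data)
    hats[[j + 1]] <- hat_matrix(x)
    dfs[j] <- qr(x)$rank - qr(stats::model.matrix(
      if (j == 1) ~1 else stats::reformulate(tl[seq_len(j - 1)]), data))$rank
    if (dfs[j] == 0)
      stop("term '", tl[j], "' is aliased with earlier terms: ",
           paste(tl[seq_len(j - 1)], collapse = ", "))
  }
  h_res <- diag(n) - hats[[length(hats)]]
  df_res <- n - qr(stats::model.matrix(stats::reformulate(tl), data))$rank

  term_ss <- function(gm) {
    vapply(seq_along(tl), function(j)
      sum((hats[[j + 1]] - hats[[j]]) * gm), numeric(1))
  }
  ss_obs <- term_ss(g)
  ss_res <- sum(h_res * g)
  f_obs <- (ss_obs / dfs) / (ss_res / df_res)

  if (exact) {
    perms <- all_permutations(n)
    f_perm <- matrix(NA_real_, nrow(perms), length(tl))
    for (r in seq_len(nrow(perms))) {
      gp <- g[perms[r, ], perms[r, ]]
      f_perm[r, ] <- (term_ss(gp) / dfs) / (sum(h_res * gp) / df_res)
    }
    p <- colMeans(sweep(f_perm, 2, f_obs - 1e-12, ">="))
  } else {
    if (!is.null(seed)) set.seed(seed)
    exceed <- numeric(length(tl))
    for (r in seq_len(n_perm)) {
      prm <- sample.int(n)
      gp <- g[prm, prm]
      fp <- (term_ss(gp) / dfs) / (sum(h_res * gp) / df_res)
      exceed <- exceed + (fp >= f_obs - 1e-12)
    }
    p <- (1 + exceed) / (1 + n_perm)
  }

  data.frame(term = c(tl, "Residual", "Total"),
             df = c(dfs, df_res, n - 1),
             SumOfSqs = c(ss_obs, ss_res, ss_total),
             R2 = c(ss_obs, ss_res, ss_total) / ss_total,
             F = c(f_obs, NA, NA),
             p = c(p, NA, NA),
             stringsAsFactors = FALSE)
}

#' Spearman correlation with p-value
#'
#' rho on ranks; the p-value is exact (via the null permutation
#' distribution of rho as implemented in `stats::cor.test`) for n <= 10
#' without ties, and the t approximation
#' t = rho sqrt((n-2)/(1-rho^2)) otherwise. Two-sided.
#'
#' @param x,y numeric vectors.
#' @return list with `rho` and `p`. Constant input gives `rho = NA`.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("length mismatch")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !ties) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = TRUE))
    return(list(rho = unname(ct$estimate), p = ct$p.value))
  }
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Taxonomic levels scanned by the biomarker analysis
#' @return character vector, phylum through genus.
#' @export
lefse_levels <- function() c("phylum", "class", "order", "family", "genus")

#' LEfSe-style biomarker discovery
#'
#' Relative abundances (scaled to 1e6 per sample) are aggregated at each
#' taxonomic level; each taxon is screened with a Kruskal-Wallis test
#' across the classes, and survivors (p < `alpha`) are scored with a
#' bootstrapped one-component linear discriminant analysis. Per
#' bootstrap, samples are resampled within class, an LDA is fitted on
#' the surviving taxa, and a taxon's effect size combines its raw
#' class-mean separation with its share of the discriminant-axis
#' separation; the LDA score is the log10 of that quantity averaged over
#' bootstraps. Reported biomarkers must pass both p < `alpha` and
#' LDA score > `lda_cut`, and carry the class in which they are enriched
#' (largest mean). Taxa constant across all samples are skipped. The
#' within-class subclass stage of the original procedure is omitted:
#' this design has no subclasses.
#'
#' @param table OTU table (samples x features).
#' @param taxonomy taxonomy table covering the features.
#' @param classes per-sample class labels (named by sample or aligned).
#' @param alpha Kruskal-Wallis significance cut.
#' @param lda_cut LDA score cut (log10 scale).
#' @param n_boot LDA bootstraps.
#' @param seed RNG seed.
#' @param levels taxonomic levels to scan.
#' @return data.frame `taxon`, `level`, `enriched_class`, `kw_p`,
#'   `lda_score` for taxa passing both cuts (possibly empty).
#' @export
lefse <- function(table, taxonomy, classes, alpha = 0.05, lda_cut = 2.0,
                  n_boot = 30, seed = NULL, levels = lefse_levels()) {
  table <- otu_table(table)
  classes <- as.character(classes)
  if (!is.null(names(classes)) && all(rownames(table) %in% names(classes)))
    classes <- classes[rownames(table)]
  if (length(classes) != nrow(table))
    stop("classes must map every sample")
  if (length(unique(classes)) < 2) stop("need at least 2 classes")
  if (!is.null(seed)) set.seed(seed)

  rel <- 1e6 * table / rowSums(table)
  mats <- lapply(levels, function(lv) {
    m <- aggregate_taxa(rel, taxonomy, lv)
    colnames(m) <- paste0(substr(lv, 1, 1), "__", colnames(m))
    m
  })
  big <- do.call(cbind, mats)
  level_of <- rep(levels, vapply(mats, ncol, integer(1)))

  keep <- apply(big, 2, function(x) stats::sd(x) > 0)
  big <- big[, keep, drop = FALSE]
  level_of <- level_of[keep]
  if (!ncol(big))
    return(data.frame(taxon = character(), level = character(),
                      enriched_class = character(), kw_p = numeric(),
                      lda_score = numeric(), stringsAsFactors = FALSE))

  kw_p <- apply(big, 2, function(x)
    suppressWarnings(stats::kruskal.test(x, factor(classes))$p.value))
  surv <- which(kw_p < alpha)
  if (!length(surv))
    return(data.frame(taxon = character(), level = character(),
                      enriched_class = character(), kw_p = numeric(),
                      lda_score = numeric(), stringsAsFactors = FALSE))

  X <- big[, surv, drop = FALSE]
  cls <- factor(classes)
  idx_by_class <- split(seq_len(nrow(X)), cls)
  scores <- matrix(NA_real_, n_boot, ncol(X))
  for (b in seq_len(n_boot)) {
    take <- unlist(lapply(idx_by_class, function(ii)
      sample(ii, length(ii), replace = TRUE)))
    xb <- X[take, , drop = FALSE]
    yb <- cls[take]
    # tiny noise keeps the within-class covariance non-singular, as in
    # the original procedure
    xb <- xb + matrix(stats::rnorm(length(xb), 0,
                                   pmax(abs(xb) * 1e-6, 1e-8)),
                      nrow(xb))
    fit <- tryCatch(suppressWarnings(MASS::lda(xb, grouping = yb)),
                    error = function(e) NULL)
    gm <- apply(xb, 2, function(v) tapply(v, yb, mean))
    raw_sep <- apply(gm, 2, function(m) max(m) - min(m))
    if (is.null(fit)) {
      scores[b, ] <- log10(1 + raw_sep)
      next
    }
    w <- fit$scaling[, 1]
    w_unit <- w / sqrt(sum(w^2))
    proj_means <- gm %*% w_unit
    axis_sep <- max(proj_means) - min(proj_means)
    coeff <- abs(w_unit) * axis_sep
    scores[b, ] <- log10(1 + (raw_sep + coeff) / 2)
  }
  lda_score <- colMeans(scores, na.rm = TRUE)
  enriched <- apply(X, 2, function(v) {
    m <- tapply(v, cls, mean)
    names(m)[which.max(m)]
  })
  out <- data.frame(taxon = colnames(X), level = level_of[surv],
                    enriched_class = unname(enriched),
                    kw_p = unname(kw_p[surv]),
                    lda_score = unname(lda_score),
                    stringsAsFactors = FALSE)
  out <- out[out$lda_score > lda_cut, , drop = FALSE]
  out <- out[order(-out$lda_score, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Significance stars for p-values
#'
#' `"*"` for 0.01 < p <= 0.05, `"**"` for 0.001 < p <= 0.01, `"***"`
#' for p <= 0.001, `""` otherwise (including missing).
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p <= 0.001, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", ""))))
}

#' Spearman genus-by-factor correlation heatmap matrix
#'
#' For the `top_n` most abundant features (or a supplied taxon list),
#' computes Spearman rho and p against each covariate, attaches
#' significance stars ("*" 0.01 < p <= 0.05, "**" 0.001 < p <= 0.01,
#' "***" p <= 0.001), and orders rows and columns by average-linkage
#' clustering of the rho matrix. Constant taxa get missing rho.
#'
#' @param table abundance matrix (samples x taxa), e.g. genus-aggregated.
#' @param covariates data.frame of numeric per-sample factors.
#' @param top_n how many taxa to keep by total abundance.
#' @param taxa optional explicit taxon selection overriding `top_n`
#'   (e.g. differentially abundant genera from [lefse()]).
#' @return list with matrices `rho`, `p`, `stars` (taxa x factors, in
#'   clustered order).
#' @export
factor_taxon_heatmap <- function(table, covariates, top_n = 50,
                                 taxa = NULL) {
  table <- as.matrix(table)
  covariates <- as.data.frame(covariates)
  if (!all(vapply(covariates, is.numeric, logical(1))))
    stop("covariates must be numeric")
  if (is.null(taxa)) {
    tot <- colSums(table)
    ord <- order(-tot, colnames(table))
    taxa <- colnames(table)[ord[seq_len(min(top_n, ncol(table)))]]
  } else {
    miss <- setdiff(taxa, colnames(table))
    if (length(miss)) stop("unknown taxa: ", paste(miss, collapse = ", "))
  }
  rel <- table / rowSums(table)
  rho <- p <- matrix(NA_real_, length(taxa), ncol(covariates),
                     dimnames = list(taxa, names(covariates)))
  for (i in seq_along(taxa)) for (j in seq_len(ncol(covariates))) {
    st <- spearman_test(rel[, taxa[i]], covariates[[j]])
    rho[i, j] <- st$rho; p[i, j] <- st$p
  }
  ok <- !apply(is.na(rho), 1, all)
  row_ord <- rownames(rho)
  if (sum(ok) > 2) {
    hc <- stats::hclust(stats::dist(rho[ok, , drop = FALSE]),
                        method = "average")
    row_ord <- c(rownames(rho)[ok][hc$order], rownames(rho)[!ok])
  }
  col_ord <- colnames(rho)
  if (ncol(rho) > 2 && sum(ok) > 1) {
    hc2 <- stats::hclust(stats::dist(t(rho[ok, , drop = FALSE])),
                         method = "average")
    col_ord <- colnames(rho)[hc2$order]
  }
  rho <- rho[row_ord, col_ord, drop = FALSE]
  p <- p[row_ord, col_ord, drop = FALSE]
  list(rho = rho, p = p,
       stars = matrix(significance_stars(p), nrow(p),
                      dimnames = dimnames(p)))
}
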