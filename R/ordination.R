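# Ordination layer: NMDS on a distance matrix, DCA gradient-length
# method selection, and constrained ordination (RDA/CCA) with
# permutation tests on the covariates.

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS of a distance matrix via `vegan::metaMDS`
#' (monotone regression on ranks, multiple random restarts); returns the
#' configuration with the lowest stress across restarts.
#'
#' @param dist symmetric distance matrix.
#' @param dims target dimensionality.
#' @param restarts number of random restarts.
#' @param maxit iteration cap per restart.
#' @param seed RNG seed.
#' @return list with `points` (samples x dims), `stress` in [0, 1], and
#'   `converged` (best solution repeated within tolerance; when `FALSE`
#'   the best-so-far configuration is returned).
#' @export
nmds <- function(dist, dims = 2, restarts = 20, maxit = 500, seed = NULL) {
  d <- check_distance(dist)
  if (nrow(d) < dims + 1) stop("need at least dims + 1 samples")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(stats::as.dist(d), k = dims, try = restarts,
                        trymax = restarts, maxit = maxit,
                        autotransform = FALSE, wascores = FALSE,
                        trace = 0)
  list(points = fit$points, stress = fit$stress,
       converged = isTRUE(fit$converged) || fit$converged > 0)
}

#' Choose RDA or CCA by DCA gradient length
#'
#' Runs detrended correspondence analysis (Hill's detrending by 26
#' segments, with rescaling) and measures the axis-1 gradient length in
#' standard-deviation units of species turnover. Gradient length >= 3.5
#' indicates enough turnover for the unimodal model (CCA); shorter
#' gradients call for the linear model (RDA). The boundary is closed:
#' exactly 3.5 selects CCA.
#'
#' @param table OTU table (samples x features).
#' @return list with `method` ("RDA" or "CCA") and `axis1_length`.
#' @export
gradient_length_select <- function(table) {
  table <- otu_table(table)
  if (nrow(table) < 2) stop("need at least 2 samples for DCA")
  # features absent everywhere carry no information for CA
  table <- table[, colSums(table) > 0, drop = FALSE]
  dca <- vegan::decorana(table)
  sc <- vegan::scores(dca, display = "sites", choices = 1)
  len <- diff(range(sc))
  list(method = if (len >= 3.5) "CCA" else "RDA", axis1_length = len)
}

#' Constrained ordination with permutation tests
#'
#' RDA on Hellinger-transformed abundances or CCA on the raw
#' (chi-square weighted) abundances, constrained by numeric covariates.
#' Reports axis eigenvalues with percent variance explained, and for
#' each covariate its marginal goodness of fit (squared correlation with
#' the ordination) and permutation p-value via `vegan::envfit`.
#'
#' @param table OTU table.
#' @param covariates data.frame of numeric covariates (no missing
#'   values); a zero-variance covariate is an error, collinear ones get
#'   a warning.
#' @param method `"RDA"` or `"CCA"`; default picks by
#'   [gradient_length_select()].
#' @param n_perm permutations for the covariate tests.
#' @param seed RNG seed.
#' @return list with `method`, `eigenvalues`, `percent_explained`,
#'   `site_scores`, and `covariates` (data.frame covariate, r2, p).
#' @export
constrained_ordination <- function(table, covariates, method = NULL,
                                   n_perm = 999, seed = NULL) {
  table <- otu_table(table)
  covariates <- as.data.frame(covariates)
  if (!all(vapply(covariates, is.numeric, logical(1))))
    stop("covariates must be numeric")
  if (anyNA(covariates)) stop("covariates contain missing values")
  sds <- vapply(covariates, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("zero-variance covariate(s): ",
         paste(names(covariates)[sds == 0], collapse = ", "))
  X <- scale(as.matrix(covariates))
  if (ncol(X) > 1 && kappa(X) > 1e6)
    warning("covariates look collinear (condition number ",
            format(kappa(X), digits = 3), "): ",
            paste(colnames(X), collapse = ", "))
  if (is.null(method)) method <- gradient_length_select(table)$method
  method <- match.arg(method, c("RDA", "CCA"))
  if (!is.null(seed)) set.seed(seed)
  ord <- if (method == "RDA")
    vegan::rda(vegan::decostand(table, "hellinger") ~ ., data = covariates)
  else
    vegan::cca(table ~ ., data = covariates)
  eig <- ord$CCA$eig
  pct <- 100 * eig / ord$tot.chi
  ef <- vegan::envfit(ord, covariates, permutations = n_perm)
  cov_tab <- data.frame(covariate = rownames(ef$vectors$arrows),
                        r2 = unname(ef$vectors$r),
                        p = unname(ef$vectors$pvals),
                        stringsAsFactors = FALSE)
  list(method = method,
       eigenvalues = eig,
       percent_explained = pct,
       site_scores = vegan::scores(ord, display = "sites",
                                   choices = seq_len(min(2, length(eig)))),
       covariates = cov_tab,
       ordination = ord)
}
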