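#' Z-score covariate columns
#'
#' Centers and scales named numeric columns to mean 0, sample SD 1
#' ((x - mean) / sd), the standardization applied to every numeric covariate
#' before modeling so that slope coefficients are directly comparable.
#' Missing cells propagate (means/SDs use complete values).
#'
#' @param table data.frame keyed by `station_id`.
#' @param columns character vector of numeric columns to scale; default all
#'   numeric columns except `station_id`.
#' @return the table with the named columns scaled.
#' @export
zscore <- function(table, columns = NULL) {
  if (is.null(columns))
    columns <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                       "station_id")
  for (cl in columns) {
    if (!cl %in% names(table)) stop("unknown column: ", cl)
    x <- table[[cl]]
    if (!is.numeric(x)) stop("column not numeric: ", cl)
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("constant column cannot be scaled: ", cl)
    table[[cl]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  table
}

#' Screen covariate pairs for collinearity
#'
#' Reports every unordered pair of numeric columns whose pairwise-complete
#' Pearson correlation exceeds the threshold in absolute value (strictly:
#' |r| = threshold passes). The screen reports; it never drops — which member
#' of a flagged pair to discard is an analyst's ecological decision.
#'
#' @param table data.frame of covariates.
#' @param threshold flag pairs with |r| > threshold (default 0.65).
#' @param columns numeric columns to screen; default all numeric.
#' @return data.frame (class `correlation_screen`) of all pairs with columns
#'   `var1, var2, r, n, flagged, evaluable`; `r` also provided rounded to two
#'   decimals as `r_2dp`. Pairs with fewer than 3 complete rows are marked
#'   not evaluable.
#' @export
correlation_screen <- function(table, threshold = 0.65, columns = NULL) {
  if (is.null(columns))
    columns <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                       "station_id")
  if (length(columns) < 2) stop("need at least two numeric columns")
  pairs <- utils::combn(columns, 2)
  out <- data.frame(var1 = pairs[1, ], var2 = pairs[2, ], r = NA_real_,
                    n = NA_integer_, flagged = FALSE, evaluable = TRUE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    x <- table[[pairs[1, k]]]; y <- table[[pairs[2, k]]]
    cc <- complete.cases(x, y)
    out$n[k] <- sum(cc)
    if (sum(cc) < 3) { out$evaluable[k] <- FALSE; next }
    out$r[k] <- cor(x[cc], y[cc])
    out$flagged[k] <- is.finite(out$r[k]) && abs(out$r[k]) > threshold
  }
  out$r_2dp <- round(out$r, 2)
  attr(out, "threshold") <- threshold
  class(out) <- c("correlation_screen", "data.frame")
  out
}

#' PCA summary of landscape metrics
#'
#' Principal component analysis on the correlation matrix of landscape
#' metrics (heterogeneity, forest amount, edge density, patch cohesion, ...),
#' retaining components with eigenvalue > 1 (Kaiser criterion). Because PCA
#' signs are arbitrary, the component signs are fixed so that the loading of
#' the first-listed metric (conventionally the forest-amount style metric) on
#' PC1 is negative: negative scores then read as a gradient of increasing
#' forest amount/cohesion, the orientation used when a single landscape
#' structure covariate (LS) is carried into occupancy models.
#'
#' @param metrics data.frame or matrix of numeric metric columns, no missing
#'   cells; the first column anchors the sign convention.
#' @return object of class `pca_summary`: `eigenvalues` (descending),
#'   `loadings` (metrics x components, unit-norm columns), `scores`
#'   (stations x all components), `n_retained`, `retained` (column indices).
#' @export
pca_landscape <- function(metrics) {
  m <- as.matrix(metrics[, vapply(as.data.frame(metrics), is.numeric,
                                  logical(1)), drop = FALSE])
  if (ncol(m) < 2) stop("need at least two metric columns")
  if (anyNA(m)) stop("missing cells not allowed in landscape metrics")
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop("constant metric column: ", paste(colnames(m)[sds == 0], collapse = ", "))
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  load <- pc$rotation
  scores <- pc$x
  # sign convention: forest-amount (first) metric loads negatively on PC1
  if (load[1, 1] > 0) { load[, 1] <- -load[, 1]; scores[, 1] <- -scores[, 1] }
  structure(list(eigenvalues = eig, loadings = load, scores = scores,
                 n_retained = sum(eig > 1), retained = which(eig > 1)),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat("Correlation-matrix PCA of", nrow(x$loadings), "landscape metrics\n")
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = ", "),
      "\n  retained (eigenvalue > 1):", x$n_retained, "\n")
  invisible(x)
}

# expand one term against the covariate table; returns a named column matrix
expand_term <- function(term, table, n) {
  if (grepl("\\^2$", term)) {
    base <- sub("\\^2$", "", term)
    if (!base %in% names(table)) stop("unknown term: ", base)
    if (!is.numeric(table[[base]]))
      stop("quadratic term on a categorical covariate: ", term)
    return(matrix(table[[base]]^2, ncol = 1, dimnames = list(NULL, term)))
  }
  if (!term %in% names(table)) stop("unknown term: ", term)
  x <- table[[term]]
  if (is.numeric(x))
    return(matrix(x, ncol = 1, dimnames = list(NULL, term)))
  lev <- sort(unique(as.character(x)))      # alphabetical; first = reference
  if (length(lev) < 2) stop("categorical term has a single level: ", term)
  cols <- lapply(lev[-1], function(l) as.numeric(as.character(x) == l))
  m <- do.call(cbind, cols)
  colnames(m) <- paste0(term, lev[-1])
  m
}

#' Assemble occupancy and detection design matrices
#'
#' Builds the occupancy design `X` (sites x terms) and the occasion-level
#' detection design `W` (sites x occasions x terms) from a covariate table.
#' The first column of each is the intercept. `"name^2"` requests the
#' cellwise square of the (already scaled) base column; categoricals expand
#' to dummies against the alphabetically-first reference level; the special
#' detection term `"effort"` draws from the per-occasion effort matrix,
#' z-scored across all active cells.
#'
#' @param table covariate data.frame (one row per station, model columns
#'   already scaled via [zscore()]).
#' @param psi_terms,p_terms character vectors of term names (may be empty:
#'   intercept-only).
#' @param effort optional sites x occasions effort matrix, required when
#'   `"effort"` appears in `p_terms`; also sets the occasion count of `W`.
#' @return object of class `design_matrices`: `X`, `W`, `psi_terms`,
#'   `p_terms`, and `reference_levels`.
#' @export
build_design <- function(table, psi_terms = character(), p_terms = character(),
                         effort = NULL) {
  n <- nrow(table)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (t in psi_terms) X <- cbind(X, expand_term(t, table, n))
  J <- if (!is.null(effort)) ncol(effort) else 1L
  site_cols <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  eff_col <- NULL
  for (t in p_terms) {
    if (t == "effort") {
      if (is.null(effort)) stop("p term 'effort' requires the effort matrix")
      e <- effort
      mu <- mean(e); s <- sd(as.vector(e))
      if (s == 0) stop("constant column cannot be scaled: effort")
      eff_col <- (e - mu) / s
    } else {
      site_cols <- cbind(site_cols, expand_term(t, table, n))
    }
  }
  kp <- ncol(site_cols) + !is.null(eff_col)
  W <- array(NA_real_, dim = c(n, J, kp))
  wn <- colnames(site_cols)
  for (k in seq_len(ncol(site_cols)))
    W[, , k] <- matrix(site_cols[, k], n, J)
  if (!is.null(eff_col)) {
    W[, , kp] <- eff_col
    wn <- c(wn, "effort")
  }
  dimnames(W) <- list(NULL, NULL, wn)
  ref <- list()
  for (t in c(psi_terms, setdiff(p_terms, "effort"))) {
    tt <- sub("\\^2$", "", t)
    if (tt %in% names(table) && !is.numeric(table[[tt]]))
      ref[[tt]] <- sort(unique(as.character(table[[tt]])))[1]
  }
  structure(list(X = X, W = W, psi_terms = psi_terms, p_terms = p_terms,
                 reference_levels = ref),
            class = "design_matrices")
}
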