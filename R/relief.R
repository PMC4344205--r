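#' Relief mismatch indicator
#'
#' The elementary comparison used throughout Relief: 0 when two items share a
#' value for a feature, 1 otherwise. Vectorized over features, so passing two
#' item rows returns the per-feature mismatch vector whose sum is the Hamming
#' distance between the items.
#'
#' @param a,b feature values (vectors of equal length).
#' @return integer vector of 0/1 mismatches.
#' @export
relief_diff <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("Relief requires complete data (impute first)", call. = FALSE)
  as.integer(as.character(a) != as.character(b))
}

# Coerce a feature table (data.frame of factors, discretized_matrix, or plain
# matrix) to a character matrix for Hamming-distance computations.
as_relief_matrix <- function(items) {
  if (inherits(items, "discretized_matrix")) {
    m <- items$codes
    storage.mode(m) <- "character"
    return(m)
  }
  if (is.data.frame(items)) {
    m <- vapply(items, as.character, character(nrow(items)))
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(items))
    dimnames(m) <- list(rownames(items), names(items))
    return(m)
  }
  m <- as.matrix(items)
  storage.mode(m) <- "character"
  m
}

# Integer-encode a character feature matrix column-wise (codes are arbitrary
# but consistent within a column; only equality matters for Relief).
encode_int_matrix <- function(X) {
  out <- matrix(0L, nrow(X), ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    col <- X[, j]
    out[, j] <- match(col, unique(col))
  }
  out
}

# Shared weight-update engine: iterate over `schedule` (item indices), find
# nearest hit/miss under Hamming distance (self excluded, ties to the lowest
# index) and apply the +/- Diff update divided by `denom`.
relief_core <- function(X, target, schedule, denom) {
  X <- encode_int_matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  W <- numeric(p)
  tgt <- as.character(target)
  for (i in schedule) {
    mism <- X != matrix(X[i, ], n, p, byrow = TRUE)
    d <- rowSums(mism)
    same <- tgt == tgt[i]
    d_hit <- d; d_hit[!same] <- Inf; d_hit[i] <- Inf
    d_miss <- d; d_miss[same] <- Inf
    h <- which.min(d_hit)
    m <- which.min(d_miss)
    W <- W - mism[h, ] / denom + mism[m, ] / denom
  }
  names(W) <- colnames(X)
  W
}

check_relief_input <- function(X, target) {
  if (nrow(X) < 2) stop("Relief needs at least 2 items", call. = FALSE)
  if (anyNA(X)) stop("Relief requires complete data (impute first)", call. = FALSE)
  if (anyNA(target)) {
    stop("target contains NA; exclude items with unknown landmark status first",
         call. = FALSE)
  }
  classes <- unique(as.character(target))
  if (length(classes) != 2) {
    stop("Relief assumes the target variable is binary with both classes present; got ",
         length(classes), " class(es)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Relief feature weighting (sampled)
#'
#' Estimates a predictive-strength weight `W[F]` for each feature against a
#' binary target. `m` items are sampled uniformly with replacement; for each
#' sampled item its nearest same-class neighbour (hit) and nearest
#' other-class neighbour (miss) under Hamming distance are found (the item
#' itself excluded, distance ties resolved to the lowest item index), and
#' each feature's weight is decreased by `Diff(F, D, hit)/m` and increased by
#' `Diff(F, D, miss)/m`. Weights therefore lie in `[-1, 1]`: a feature that
#' always separates misses and never separates hits reaches +1.
#'
#' @param items feature table: data.frame of factors, a
#'   [discretize_matrix()] result, or a matrix of discrete values. Rows are
#'   items.
#' @param target binary labels, both classes present, no `NA`.
#' @param m number of sampled items; defaults to the number of items.
#' @param seed RNG seed for the sampling schedule.
#' @return list of class `relief_weights`: `W` (named weights), `m`, `seed`.
#' @seealso [relief_rank_exhaustive()] for the deterministic full-pass
#'   variant used as an oracle in tests.
#' @export
relief_rank <- function(items, target, m = NULL, seed = 1) {
  X <- as_relief_matrix(items)
  check_relief_input(X, target)
  n <- nrow(X)
  if (is.null(m)) m <- n
  if (m < 1) stop("m must be positive", call. = FALSE)
  schedule <- with_seed(seed, sample.int(n, m, replace = TRUE))
  W <- relief_core(X, target, schedule, denom = m)
  structure(list(W = W, m = m, seed = seed), class = "relief_weights")
}

#' Relief feature weighting (exhaustive full pass)
#'
#' Deterministic variant of [relief_rank()]: every item is visited exactly
#' once and updates are divided by the number of items. Its output equals the
#' expectation of the sampled variant over sampling schedules, which makes it
#' a convenient reference.
#'
#' @inheritParams relief_rank
#' @return list of class `relief_weights`.
#' @export
relief_rank_exhaustive <- function(items, target) {
  X <- as_relief_matrix(items)
  check_relief_input(X, target)
  n <- nrow(X)
  W <- relief_core(X, target, seq_len(n), denom = n)
  structure(list(W = W, m = n, seed = NA), class = "relief_weights")
}

#' Order features by Relief weight
#'
#' @param weights a `relief_weights` object.
#' @return data.frame with columns `rank`, `feature`, `weight`, ordered by
#'   decreasing weight; ties keep the original column order (deterministic).
#' @export
rank_features <- function(weights) {
  stopifnot(inherits(weights, "relief_weights"))
  ord <- order(-weights$W, seq_along(weights$W))
  data.frame(rank = seq_along(ord), feature = names(weights$W)[ord],
             weight = unname(weights$W[ord]), stringsAsFactors = FALSE)
}

#' Integrated clinical + gene feature selection (Method 1)
#'
#' Pools clinical and gene features into one table, runs Relief on the pooled
#' table and keeps the `k` top-weighted features; the result may contain any
#' mix of clinical and gene features.
#'
#' @param features combined feature table (clinical + genes), rows = items.
#' @param target binary labels.
#' @param k number of features to keep; conventional grid 30/50/100/150.
#' @param m,seed passed to [relief_rank()]; `exhaustive = TRUE` uses the
#'   deterministic variant instead.
#' @param exhaustive use [relief_rank_exhaustive()] (default `FALSE`).
#' @return character vector of `k` selected feature names, with the full
#'   ranking as attribute `"ranking"`.
#' @export
method1_select <- function(features, target, k, m = NULL, seed = 1,
                           exhaustive = FALSE) {
  X <- as_relief_matrix(features)
  if (k > ncol(X)) {
    stop("k (", k, ") exceeds the number of features (", ncol(X), ")",
         call. = FALSE)
  }
  w <- if (exhaustive) relief_rank_exhaustive(features, target) else
    relief_rank(features, target, m = m, seed = seed)
  rk <- rank_features(w)
  structure(rk$feature[seq_len(k)], ranking = rk)
}

#' Gene-only selection joined with all clinical features (Method 2)
#'
#' Runs Relief on the gene features alone, keeps the
#' `k_total - length(clinical_names)` top genes and unions them with every
#' clinical feature, so the total feature count is exactly `k_total`
#' (e.g. 9/29/79/129 genes with 21 clinical features for totals
#' 30/50/100/150).
#'
#' @param gene_features gene-only feature table, rows = items.
#' @param target binary labels.
#' @param k_total total feature count after adding all clinical features;
#'   must exceed the number of clinical features.
#' @param clinical_names character vector of clinical feature names.
#' @inheritParams method1_select
#' @return character vector of `k_total` names (clinical first, then selected
#'   genes), with the gene ranking as attribute `"ranking"`.
#' @export
method2_select <- function(gene_features, target, k_total, clinical_names,
                           m = NULL, seed = 1, exhaustive = FALSE) {
  n_clin <- length(clinical_names)
  if (k_total <= n_clin) {
    stop("k_total (", k_total, ") must exceed the number of clinical features (",
         n_clin, ")", call. = FALSE)
  }
  k_genes <- k_total - n_clin
  X <- as_relief_matrix(gene_features)
  if (k_genes > ncol(X)) {
    stop("k_total - n_clinical (", k_genes, ") exceeds the number of genes (",
         ncol(X), ")", call. = FALSE)
  }
  w <- if (exhaustive) relief_rank_exhaustive(gene_features, target) else
    relief_rank(gene_features, target, m = m, seed = seed)
  rk <- rank_features(w)
  structure(c(clinical_names, rk$feature[seq_len(k_genes)]), ranking = rk)
}

#' Export a feature ranking as CSV
#'
#' Writes `rank, feature_name, weight, feature_class` where `feature_class`
#' is `clinical` or `gene` according to membership in `clinical_names`.
#'
#' @param weights a `relief_weights` object.
#' @param path output file.
#' @param clinical_names names treated as clinical features.
#' @return `path`, invisibly.
#' @export
write_ranked_features <- function(weights, path, clinical_names = character(0)) {
  rk <- rank_features(weights)
  rk$feature_class <- ifelse(rk$feature %in% clinical_names, "clinical", "gene")
  names(rk)[2] <- "feature_name"
  utils::write.csv(rk, path, row.names = FALSE)
  invisible(path)
}
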