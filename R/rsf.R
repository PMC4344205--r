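#' Random survival forest configuration
#'
#' @param n_trees number of bootstrap samples / trees grown.
#' @param n_candidates covariates tried per node; default `ceiling(sqrt(p))`,
#'   resolved at fit time.
#' @param min_unique_deaths minimum number of distinct event times each
#'   daughter must retain for a split to be admissible; trees are grown until
#'   no admissible split remains.
#' @param seed integer seed for bootstrap and candidate sampling.
#' @return list of class `rsf_config`.
#' @export
rsf_config <- function(n_trees = 500, n_candidates = NULL,
                       min_unique_deaths = 3, seed = 1) {
  check_count <- function(v, nm, allow_null = FALSE) {
    if (allow_null && is.null(v)) return(invisible(NULL))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != floor(v)) {
      stop("invalid RSF config: '", nm, "' must be a positive integer",
           call. = FALSE)
    }
  }
  check_count(n_trees, "n_trees")
  check_count(n_candidates, "n_candidates", allow_null = TRUE)
  check_count(min_unique_deaths, "min_unique_deaths")
  check_count(seed, "seed")
  structure(list(n_trees = as.integer(n_trees),
                 n_candidates = if (is.null(n_candidates)) NULL else as.integer(n_candidates),
                 min_unique_deaths = as.integer(min_unique_deaths),
                 seed = as.integer(seed)),
            class = "rsf_config")
}

# Integer-encode categorical features for the compiled tree grower.
# Ordered factors keep their level order (threshold splits); unordered
# factors get one-level-vs-rest splits. At predict time, a level unseen in
# training encodes as -1 and is routed to the majority daughter.
rsf_encode <- function(features, meta = NULL) {
  if (inherits(features, "discretized_matrix")) {
    features <- discretized_as_factors(features)
  }
  stopifnot(is.data.frame(features))
  if (is.null(meta)) {
    meta <- lapply(names(features), function(nm) {
      col <- features[[nm]]
      if (is.numeric(col)) {
        stop("RSF features must be categorical; discretize numeric feature '",
             nm, "' first", call. = FALSE)
      }
      f <- if (is.factor(col)) col else factor(as.character(col))
      list(levels = levels(f), ordered = is.ordered(col))
    })
    names(meta) <- names(features)
  }
  codes <- matrix(0L, nrow(features), length(meta))
  for (j in seq_along(meta)) {
    nm <- names(meta)[j]
    if (!nm %in% names(features)) stop("missing covariate '", nm, "'", call. = FALSE)
    v <- as.character(features[[nm]])
    code <- match(v, meta[[j]]$levels) - 1L
    code[is.na(code)] <- -1L
    codes[, j] <- code
  }
  colnames(codes) <- names(meta)
  list(codes = codes,
       n_levels = vapply(meta, function(m) length(m$levels), integer(1)),
       ordered = vapply(meta, function(m) isTRUE(m$ordered), logical(1)),
       meta = meta)
}

#' Two-sample log-rank split score
#'
#' Standardized two-sample log-rank statistic `|O - E| / sqrt(V)` comparing
#' the survival experience of the two daughter nodes induced by a candidate
#' split; larger values mean greater survival difference. Returns 0 when the
#' variance is 0 (identical survival in both daughters).
#'
#' @param day observed times within the node.
#' @param status `"dead"`/`"alive"` or 0/1 event indicator.
#' @param group logical or 0/1 membership of the first daughter.
#' @return the standardized log-rank score (non-negative).
#' @export
log_rank_split_score <- function(day, status, group) {
  ev <- as_event_indicator(status)
  g <- as.integer(as.logical(group))
  if (all(g == 1) || all(g == 0)) {
    stop("both daughters must be non-empty", call. = FALSE)
  }
  if (sum(ev) == 0) stop("node has no events", call. = FALSE)
  logrank_score_cpp(as.numeric(day), ev, g)
}

#' Fit a random survival forest
#'
#' Grows `n_trees` survival trees, one per bootstrap sample of the cohort
#' (drawn with replacement, so each sample leaves out about 37% of patients).
#' At each node, `n_candidates` covariates are drawn at random and the
#' level-set split maximizing the standardized log-rank difference between
#' daughters is taken; a split is admissible only if each daughter retains at
#' least `min_unique_deaths` distinct event times. When no admissible split
#' exists the node becomes a leaf whose cumulative hazard is the Nelson-Aalen
#' estimator on the leaf's bootstrap rows, evaluated on the cohort
#' event-time grid.
#'
#' @param features data.frame of categorical covariates (factors; ordered
#'   factors split by threshold) or a [discretize_matrix()] result.
#' @param day observed follow-up days.
#' @param status `"dead"`/`"alive"` or 0/1 per patient.
#' @param horizon fitting horizon in days; later events count as censored at
#'   the horizon.
#' @param config an [rsf_config()].
#' @return object of class `rsf_fit` with the compiled forest, the encoding
#'   metadata, the event-time `grid`, per-tree `inbag` counts and the
#'   resolved `config`.
#' @export
fit_rsf <- function(features, day, status, horizon = Inf, config = rsf_config()) {
  stopifnot(inherits(config, "rsf_config"))
  enc <- rsf_encode(features)
  tr <- truncate_followup(day, status, horizon)
  if (sum(tr$event) == 0) {
    stop("no events within the horizon; cannot fit a survival forest", call. = FALSE)
  }
  p <- ncol(enc$codes)
  ncand <- config$n_candidates %||% as.integer(ceiling(sqrt(p)))
  grid <- sort(unique(tr$day[tr$event == 1]))
  forest <- rsf_fit_cpp(enc$codes, enc$n_levels, enc$ordered,
                        as.numeric(tr$day), as.integer(tr$event),
                        config$n_trees, ncand, config$min_unique_deaths,
                        as.numeric(config$seed), as.numeric(grid))
  structure(list(forest = forest, meta = enc$meta,
                 n_levels = enc$n_levels, grid = grid,
                 inbag = forest$inbag,
                 config = within(unclass(config), n_candidates <- ncand),
                 horizon = horizon,
                 n_train = nrow(enc$codes)),
            class = "rsf_fit")
}

rsf_chf <- function(fit, features, use_tree = NULL) {
  enc <- rsf_encode(features, meta = fit$meta)
  rsf_predict_cpp(fit$forest, enc$codes, fit$n_levels, use_tree)
}

#' Per-patient survival curves from a random survival forest
#'
#' Routes each patient down every tree, averages the leaf cumulative hazards
#' into the ensemble CHF, and returns `S(t) = exp(-CHF(t))` on the fit's
#' event-time grid restricted to `[0, horizon]`.
#'
#' @param fit an [fit_rsf()] result.
#' @param features new covariate table (same columns as at fit time); levels
#'   unseen in training are routed to the daughter that received the majority
#'   of training rows.
#' @param horizon evaluation horizon in days.
#' @return a `survival_curves` object (`time`, `surv`, `horizon`).
#' @export
predict_survival_curve_rsf <- function(fit, features, horizon = fit$horizon) {
  stopifnot(inherits(fit, "rsf_fit"))
  pred <- rsf_chf(fit, features)
  keep <- fit$grid <= horizon
  surv <- exp(-pred$chf[, keep, drop = FALSE])
  rn <- if (inherits(features, "discretized_matrix")) rownames(features$codes) else rownames(features)
  rownames(surv) <- rn
  structure(list(time = fit$grid[keep], surv = surv, horizon = horizon),
            class = "survival_curves")
}

#' Out-of-bag prediction error of a random survival forest
#'
#' For each training patient, the out-of-bag (OOB) ensemble averages only the
#' trees whose bootstrap sample excluded that patient; patients in-bag for
#' every tree cannot be scored and are excluded (their ids are reported).
#' The error is one minus the area-based concordance index of the OOB curves.
#'
#' @param fit an [fit_rsf()] result.
#' @param features the training covariate table.
#' @param day,status the training follow-up.
#' @param horizon evaluation horizon in days.
#' @return list with `error` (1 - concordance), `concordance` (a
#'   `concordance_result`), and `excluded` (indices of patients OOB for no
#'   tree).
#' @export
oob_error <- function(fit, features, day, status, horizon = fit$horizon) {
  stopifnot(inherits(fit, "rsf_fit"))
  if (!is.finite(horizon)) horizon <- max(fit$grid)  # last observed event time
  n <- nrow(fit$inbag)
  mask <- matrix(as.integer(fit$inbag == 0L), n, ncol(fit$inbag))
  pred <- rsf_chf(fit, features, use_tree = mask)
  excluded <- which(pred$n_trees_used == 0)
  keep <- fit$grid <= horizon
  surv <- exp(-pred$chf[, keep, drop = FALSE])
  curves <- structure(list(time = fit$grid[keep], surv = surv, horizon = horizon),
                      class = "survival_curves")
  idx <- setdiff(seq_len(n), excluded)
  curves$surv <- curves$surv[idx, , drop = FALSE]
  conc <- concordance_index(curves, day[idx], status[idx], horizon)
  list(error = 1 - conc$index, concordance = conc, excluded = excluded)
}

#' Serialize / restore a random survival forest as JSON
#'
#' @param fit an `rsf_fit`.
#' @param path file path.
#' @return `read_rsf_fit` returns the `rsf_fit`; `write_rsf_fit` returns
#'   `path` invisibly.
#' @export
write_rsf_fit <- function(fit, path) {
  stopifnot(inherits(fit, "rsf_fit"))
  obj <- list(trees = lapply(fit$forest$trees, function(tr) {
    list(nodes = tr$nodes, leaf_chf = tr$leaf_chf)
  }),
  grid = fit$grid, inbag = fit$inbag,
  meta = fit$meta, n_levels = as.list(fit$n_levels),
  config = fit$config, horizon = fit$horizon, n_train = fit$n_train)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_rsf_fit
#' @export
read_rsf_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trees <- lapply(seq_len(nrow_or_len(obj$trees)), function(i) {
    tr <- if (is.data.frame(obj$trees)) obj$trees[i, ] else obj$trees[[i]]
    nodes <- tr$nodes
    if (is.list(nodes) && !is.matrix(nodes)) nodes <- nodes[[1]]
    lc <- tr$leaf_chf
    if (is.list(lc) && !is.matrix(lc)) lc <- lc[[1]]
    nodes <- matrix(as.integer(nodes), nrow = nrow(nodes))
    lc <- matrix(as.numeric(lc), nrow = nrow(lc))
    list(nodes = nodes, leaf_chf = lc)
  })
  meta <- lapply(obj$meta, function(m) list(levels = unlist(m$levels),
                                            ordered = isTRUE(m$ordered)))
  n_levels <- unlist(obj$n_levels)
  inbag <- matrix(as.integer(obj$inbag), nrow = nrow(obj$inbag))
  grid <- as.numeric(obj$grid)
  forest <- list(trees = trees, inbag = inbag, grid = grid)
  structure(list(forest = forest, meta = meta, n_levels = n_levels,
                 grid = grid, inbag = inbag, config = obj$config,
                 horizon = if (is.null(obj$horizon)) Inf else obj$horizon,
                 n_train = obj$n_train),
            class = "rsf_fit")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
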