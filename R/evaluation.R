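#' Area under a predicted survival step curve
#'
#' Exact integral of a right-continuous survival step function over
#' `[0, horizon]`: `S(t) = 1` before the first grid time, constant between
#' grid times, constant extrapolation from the last grid time to the
#' horizon. The area summarizes a curve as expected survival time within the
#' horizon, and orders patients for the concordance estimator.
#'
#' @param curves a `survival_curves` object (from [predict_survival_curve()]
#'   or [predict_survival_curve_rsf()]), or a list with `time` and `surv`
#'   (vector for a single curve).
#' @param horizon integration horizon in days; defaults to the curves'
#'   horizon.
#' @return numeric vector of per-patient areas.
#' @export
survival_curve_area <- function(curves, horizon = NULL) {
  if (is.null(horizon)) horizon <- curves$horizon
  if (is.null(horizon)) stop("horizon must be supplied", call. = FALSE)
  if (!is.finite(horizon)) {
    stop("the curve area needs a finite integration horizon", call. = FALSE)
  }
  surv <- curves$surv
  if (is.null(dim(surv))) surv <- matrix(surv, nrow = 1)
  time <- curves$time
  keep <- time <= horizon
  time <- time[keep]
  surv <- surv[, keep, drop = FALSE]
  if (any(surv > 1 + 1e-9) || any(surv < -1e-9)) {
    stop("survival values must lie in [0, 1]", call. = FALSE)
  }
  if (ncol(surv) > 1) {
    inc <- surv[, -1, drop = FALSE] - surv[, -ncol(surv), drop = FALSE]
    if (any(inc > 1e-9)) stop("survival curves must be non-increasing", call. = FALSE)
  }
  if (length(time) == 0) return(rep(horizon, nrow(surv)))
  widths <- diff(c(time, horizon))
  as.numeric(time[1] * 1 + surv %*% c(widths))
}

#' Area-based concordance index for right-censored predictions
#'
#' Pairs every patient `j` who died within the horizon with every patient
#' `k` whose observed time (death or censoring) is strictly later than `j`'s
#' death time. A pair is concordant when `area_j < area_k` — the patient who
#' died earlier has the strictly smaller area under their predicted survival
#' curve — and the count of concordant pairs (`total`) divided by the number
#' of evaluable pairs is the index. Ties in area count as discordant under
#' the strict inequality.
#'
#' @param curves a `survival_curves` object with one curve per patient, or a
#'   numeric vector of precomputed per-patient areas.
#' @param day observed follow-up days.
#' @param status `"dead"`/`"alive"` or 0/1 per patient.
#' @param horizon evaluation horizon in days; deaths after the horizon do
#'   not anchor pairs.
#' @return list of class `concordance_result`: `index`, `total` (concordant
#'   pairs), `n_pairs` (evaluable pairs).
#' @export
concordance_index <- function(curves, day, status, horizon = NULL) {
  if (is.numeric(curves)) {
    areas <- curves
    if (is.null(horizon)) horizon <- Inf
  } else {
    areas <- survival_curve_area(curves, horizon)
    if (is.null(horizon)) horizon <- curves$horizon %||% Inf
  }
  ev <- as_event_indicator(status)
  n <- length(day)
  if (length(areas) != n) {
    stop("need one curve/area per patient (", length(areas), " vs ", n, ")",
         call. = FALSE)
  }
  dead_j <- which(ev == 1 & day <= horizon)
  total <- 0L
  n_pairs <- 0L
  for (j in dead_j) {
    later <- day > day[j]
    n_pairs <- n_pairs + sum(later)
    total <- total + sum(later & (areas[j] < areas))
  }
  if (n_pairs == 0) {
    stop("no evaluable pairs (no death is followed by a later observation)",
         call. = FALSE)
  }
  structure(list(index = total / n_pairs, total = total, n_pairs = n_pairs),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Concordance index %.4f (%d concordant of %d evaluable pairs)\n",
              x$index, x$total, x$n_pairs))
  invisible(x)
}

#' Chi-square comparison of two concordance results
#'
#' Compares two concordance proportions via a 2x2 chi-square test (no
#' continuity correction) on the concordant/discordant pair counts of each
#' method.
#'
#' @param a,b `concordance_result` objects.
#' @return the p-value, with the chi-square statistic as attribute
#'   `"statistic"`.
#' @export
compare_concordance_chisq <- function(a, b) {
  stopifnot(inherits(a, "concordance_result"), inherits(b, "concordance_result"))
  tab <- rbind(c(a$total, a$n_pairs - a$total),
               c(b$total, b$n_pairs - b$total))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate contingency table (zero row or column total)", call. = FALSE)
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  structure(p, statistic = stat)
}

variant_features <- function(cohort, variant) {
  clin <- cohort$clinical
  switch(variant,
         Clinical_Only = clin[, setdiff(names(clin), "subtype"), drop = FALSE],
         Clinical_PAM = clin,
         Clinical_Gene = clin[, setdiff(names(clin), "subtype"), drop = FALSE],
         stop("unknown dataset variant '", variant, "'", call. = FALSE))
}

#' Cross-validated concordance of one pipeline configuration
#'
#' 5-fold cross-validation of the full pipeline on one dataset variant:
#' within each training split the clinical table is imputed (mode/median),
#' gene expression is discretized with training-derived equal-width edges,
#' Relief selects features against the landmark survival target at `year`
#' (patients censored before the landmark are excluded from selection only),
#' and a Cox or RSF model is fitted on follow-up truncated at the horizon.
#' Each held-out patient receives one predicted curve; the pooled areas are
#' scored with one [concordance_index()] over the whole cohort.
#'
#' Dataset variants: `Clinical_Only` (clinical without the subtype label),
#' `Clinical_PAM` (clinical including subtype), `Clinical_Gene` (clinical
#' without subtype plus gene features, Relief-reduced to `k`). Feature
#' selection applies only to `Clinical_Gene`.
#'
#' @param cohort a [generate_cohort()] (or [read_cohort()]) result.
#' @param variant `"Clinical_Only"`, `"Clinical_PAM"` or `"Clinical_Gene"`.
#' @param model `"cox"` or `"rsf"`.
#' @param year landmark/prediction year (horizon = `year * days_per_year`).
#' @param k total number of features for `Clinical_Gene` (grid convention
#'   30/50/100/150).
#' @param method feature-integration method for `Clinical_Gene`: 1 = Relief
#'   over pooled clinical + genes; 2 = Relief over genes only, then all
#'   clinical features added so the total is `k`.
#' @param folds number of folds (default 5).
#' @param seed master seed; fold assignment and per-stage seeds derive from
#'   it.
#' @param rsf_config an [rsf_config()] for `model = "rsf"`.
#' @param days_per_year year length in days (default 365).
#' @param use_discretized_genes feed discretized (default) or raw expression
#'   to the models; Relief always sees discretized values.
#' @return a `concordance_result` with attributes `per_fold` (per-fold
#'   indices), `areas` (pooled per-patient areas) and `folds` (assignment).
#' @export
cross_validate <- function(cohort, variant, model = c("cox", "rsf"), year = 5,
                           k = NULL, method = 1, folds = 5, seed = 1,
                           rsf_config = survcompare::rsf_config(),
                           days_per_year = 365,
                           use_discretized_genes = TRUE) {
  model <- match.arg(model)
  n <- length(cohort$patient_id)
  if (n < folds) stop("cohort smaller than the number of folds", call. = FALSE)
  horizon <- year * days_per_year
  fold_of <- with_seed(derive_seed(seed, 1), sample(rep(seq_len(folds), length.out = n)))
  clin_all <- variant_features(cohort, variant)
  use_genes <- variant == "Clinical_Gene"
  areas <- rep(NA_real_, n)
  per_fold <- numeric(folds)
  selected <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    if (sum(cohort$status[train] == "dead" & cohort$day[train] <= horizon) == 0) {
      stop("training split for fold ", f, " contains no events within the horizon",
           call. = FALSE)
    }
    clin_tr <- impute_clinical(clin_all[train, , drop = FALSE])
    clin_te <- impute_clinical(clin_all[test, , drop = FALSE],
                               stats = attr(clin_tr, "impute_stats"))
    feats_tr <- clin_tr
    feats_te <- clin_te
    if (use_genes) {
      dm_tr <- discretize_matrix(cohort$expression[train, , drop = FALSE])
      dm_te <- discretize_matrix(cohort$expression[test, , drop = FALSE],
                                 edges = dm_tr$edges)
      genes_tr <- discretized_as_factors(dm_tr)
      genes_te <- discretized_as_factors(dm_te)
      yt <- build_year_table(cohort$day[train], cohort$status[train],
                             horizon_years = year, days_per_year = days_per_year)
      target <- landmark_target(yt, year)
      known <- !is.na(target)
      rel_seed <- derive_seed(seed, 100 + f)
      if (is.null(k)) stop("k must be supplied for Clinical_Gene", call. = FALSE)
      if (method == 1) {
        sel <- method1_select(cbind(clin_tr, genes_tr)[known, , drop = FALSE],
                              target[known], k = k, seed = rel_seed)
      } else if (method == 2) {
        sel <- method2_select(genes_tr[known, , drop = FALSE], target[known],
                              k_total = k, clinical_names = names(clin_tr),
                              seed = rel_seed)
      } else {
        stop("method must be 1 or 2", call. = FALSE)
      }
      selected[[f]] <- as.character(sel)
      if (!use_discretized_genes) {
        gene_sel <- intersect(sel, colnames(cohort$expression))
        genes_tr <- as.data.frame(cohort$expression[train, gene_sel, drop = FALSE])
        genes_te <- as.data.frame(cohort$expression[test, gene_sel, drop = FALSE])
        clin_sel <- intersect(sel, names(clin_tr))
        feats_tr <- cbind(clin_tr[, clin_sel, drop = FALSE], genes_tr)
        feats_te <- cbind(clin_te[, clin_sel, drop = FALSE], genes_te)
      } else {
        feats_tr <- cbind(clin_tr, genes_tr)[, as.character(sel), drop = FALSE]
        feats_te <- cbind(clin_te, genes_te)[, as.character(sel), drop = FALSE]
      }
    }
    if (model == "cox") {
      fit <- fit_cox(feats_tr, cohort$day[train], cohort$status[train],
                     horizon = horizon)
      curves <- predict_survival_curve(fit, feats_te, horizon = horizon)
    } else {
      cfg <- rsf_config
      cfg$seed <- derive_seed(seed, 200 + f)
      fit <- fit_rsf(feats_tr, cohort$day[train], cohort$status[train],
                     horizon = horizon, config = cfg)
      curves <- predict_survival_curve_rsf(fit, feats_te, horizon = horizon)
    }
    fold_areas <- survival_curve_area(curves, horizon)
    areas[test] <- fold_areas
    pf <- tryCatch(concordance_index(fold_areas, cohort$day[test],
                                     cohort$status[test], horizon)$index,
                   error = function(e) NA_real_)
    per_fold[f] <- pf
  }
  out <- concordance_index(areas, cohort$day, cohort$status, horizon)
  attr(out, "per_fold") <- per_fold
  attr(out, "areas") <- areas
  attr(out, "folds") <- fold_of
  attr(out, "selected") <- selected
  out
}

#' Experiment grid definition
#'
#' @param variants dataset variants to run.
#' @param models prediction models to run.
#' @param years landmark years.
#' @param k_grid feature-count grid for `Clinical_Gene`.
#' @param methods feature-integration methods for `Clinical_Gene`.
#' @param folds CV folds.
#' @param seed master seed.
#' @return list of class `experiment_grid`.
#' @export
experiment_grid <- function(variants = c("Clinical_Only", "Clinical_PAM", "Clinical_Gene"),
                            models = c("cox", "rsf"),
                            years = c(5, 10, 15),
                            k_grid = c(30, 50, 100, 150),
                            methods = c(1, 2),
                            folds = 5, seed = 1) {
  structure(list(variants = variants, models = models, years = years,
                 k_grid = k_grid, methods = methods, folds = folds,
                 seed = as.integer(seed)),
            class = "experiment_grid")
}

#' Run the full benchmarking grid
#'
#' Cross-validates every combination of dataset variant, model, landmark
#' year and — for the gene variant — integration method and feature count,
#' then derives the comparisons of interest: Cox vs RSF per variant and year
#' (best over the feature grid), and each gene-bearing variant vs
#' `Clinical_Only` per year (best over models and feature counts), each with
#' a chi-square p-value on the concordant/discordant pair counts.
#'
#' @param cohort a cohort.
#' @param grid an [experiment_grid()].
#' @param rsf_config an [rsf_config()] used for every RSF run.
#' @param days_per_year year length in days.
#' @return list of class `experiment_result`: `results` (one row per run:
#'   `variant, model, year, method, k, concordance, total, n_pairs`),
#'   `model_comparisons` and `variant_comparisons` data.frames.
#' @export
run_experiment <- function(cohort, grid = experiment_grid(),
                           rsf_config = survcompare::rsf_config(),
                           days_per_year = 365) {
  stopifnot(inherits(grid, "experiment_grid"))
  rows <- list()
  store <- list()
  for (variant in grid$variants) {
    for (model in grid$models) {
      for (year in grid$years) {
        combos <- if (variant == "Clinical_Gene") {
          expand.grid(method = grid$methods, k = grid$k_grid)
        } else {
          data.frame(method = NA_integer_, k = NA_integer_)
        }
        for (i in seq_len(nrow(combos))) {
          cr <- tryCatch(
            cross_validate(cohort, variant, model = model, year = year,
                           k = if (is.na(combos$k[i])) NULL else combos$k[i],
                           method = if (is.na(combos$method[i])) 1 else combos$method[i],
                           folds = grid$folds, seed = grid$seed,
                           rsf_config = rsf_config,
                           days_per_year = days_per_year),
            error = function(e) {
              stop("[variant=", variant, " model=", model, " year=", year,
                   " method=", combos$method[i], " k=", combos$k[i], "] ",
                   conditionMessage(e), call. = FALSE)
            })
          key <- paste(variant, model, year, combos$method[i], combos$k[i], sep = "|")
          store[[key]] <- cr
          rows[[key]] <- data.frame(variant = variant, model = model,
                                    year = year, method = combos$method[i],
                                    k = combos$k[i], concordance = cr$index,
                                    total = cr$total, n_pairs = cr$n_pairs)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  best_for <- function(df) df[which.max(df$concordance), , drop = FALSE]

  model_cmp <- list()
  for (variant in grid$variants) {
    for (year in grid$years) {
      sub <- results[results$variant == variant & results$year == year, ]
      if (!all(c("cox", "rsf") %in% sub$model)) next
      bc <- best_for(sub[sub$model == "cox", ])
      br <- best_for(sub[sub$model == "rsf", ])
      p <- compare_concordance_chisq(store[[row_key(bc)]], store[[row_key(br)]])
      model_cmp[[paste(variant, year)]] <- data.frame(
        variant = variant, year = year,
        cox = bc$concordance, rsf = br$concordance,
        cox_k = bc$k, rsf_k = br$k, p_value = as.numeric(p))
    }
  }
  variant_cmp <- list()
  if ("Clinical_Only" %in% grid$variants) {
    for (variant in setdiff(grid$variants, "Clinical_Only")) {
      for (year in grid$years) {
        base <- results[results$variant == "Clinical_Only" & results$year == year, ]
        sub <- results[results$variant == variant & results$year == year, ]
        if (nrow(base) == 0 || nrow(sub) == 0) next
        bb <- best_for(base)
        bs <- best_for(sub)
        p <- compare_concordance_chisq(store[[row_key(bb)]], store[[row_key(bs)]])
        variant_cmp[[paste(variant, year)]] <- data.frame(
          variant = variant, year = year,
          clinical_only = bb$concordance, best = bs$concordance,
          best_model = bs$model, best_k = bs$k, p_value = as.numeric(p))
      }
    }
  }
  structure(list(results = results,
                 model_comparisons = do.call(rbind, model_cmp),
                 variant_comparisons = do.call(rbind, variant_cmp),
                 grid = grid),
            class = "experiment_result")
}

row_key <- function(row) {
  paste(row$variant, row$model, row$year, row$method, row$k, sep = "|")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Benchmark over", nrow(x$results), "pipeline runs\n")
  print(x$results)
  invisible(x)
}
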