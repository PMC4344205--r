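#' Specification of a synthetic breast-cancer-like cohort
#'
#' Describes the generating model for [generate_cohort()]: cohort size, an
#' expression matrix with a small planted informative subset, categorical
#' clinical covariates with optional per-level log-hazard contributions, and
#' a right-censoring mechanism (random study dropout plus an administrative
#' cutoff). Survival times follow a proportional-hazards Weibull model whose
#' log hazard is
#' `log(h0) + clinical effects + gene effects * z(expression) + interactions`,
#' with `shape = 1` (the default) giving the exponential special case.
#'
#' Interaction terms multiply standardized expression of consecutive pairs of
#' informative genes, planting a non-additive signal that linear models
#' cannot represent directly.
#'
#' @param n_patients number of patients.
#' @param n_genes number of expression features.
#' @param n_informative_genes number of genes carrying survival signal.
#' @param clinical_effects named numeric vector of log-hazard contributions,
#'   names of the form `"covariate=level"` (e.g. `"grade=3"`). Defaults plant
#'   a modest conventional clinical gradient (grade, nodal burden, tumour
#'   size, ER status).
#' @param gene_effects numeric vector of per-informative-gene log-hazard
#'   coefficients (recycled to `n_informative_genes`), applied to
#'   standardized expression.
#' @param interaction_strength coefficient for pairwise products of
#'   consecutive informative genes; 0 disables interactions.
#' @param baseline_hazard baseline event rate per day.
#' @param censor_dropout_rate per-day hazard of leaving the study; 0 disables
#'   random dropout.
#' @param admin_end_day administrative study cutoff in days.
#' @param weibull_shape Weibull shape of the event-time model (1 =
#'   exponential).
#' @param missing_rate fraction of clinical cells set missing (default 0).
#' @param clinical_level_probs optional named list of per-covariate level
#'   probabilities; defaults to uniform over each covariate's levels.
#' @param seed integer RNG seed; identical spec + seed gives an identical
#'   cohort.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 500,
                        n_genes = 200,
                        n_informative_genes = 10,
                        clinical_effects = default_clinical_effects(),
                        gene_effects = 0.5,
                        interaction_strength = 0.5,
                        baseline_hazard = 3e-4,
                        censor_dropout_rate = 1e-4,
                        admin_end_day = 5475,
                        weibull_shape = 1,
                        missing_rate = 0,
                        clinical_level_probs = NULL,
                        seed = 1) {
  spec <- structure(list(
    n_patients = n_patients, n_genes = n_genes,
    n_informative_genes = n_informative_genes,
    clinical_effects = clinical_effects,
    gene_effects = rep_len(gene_effects, n_informative_genes),
    interaction_strength = interaction_strength,
    baseline_hazard = baseline_hazard,
    censor_dropout_rate = censor_dropout_rate,
    admin_end_day = admin_end_day,
    weibull_shape = weibull_shape,
    missing_rate = missing_rate,
    clinical_level_probs = clinical_level_probs,
    seed = as.integer(seed)), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

# Levels of the categorical clinical covariates the generator emulates
# (age bands, tumour size bands, nodal burden, grade, ER status, treatment).
clinical_covariate_levels <- function() {
  list(
    age_at_diagnosis = c("0-39", "39-54", "54-69", "69-84", "84-100"),
    size = c("0-20", "20-50", "50-180"),
    lymph_nodes_positive = c("0", "1", "2-3", "4-5", "6-9", ">=10"),
    grade = c("1", "2", "3"),
    ER_Expr = c("+", "-"),
    treatment = c("None", "HT", "RT", "CT", "HT/RT", "HT/CT", "RT/CT", "HT/RT/CT")
  )
}

#' Default clinical log-hazard contributions
#'
#' A modest conventional gradient: higher grade, heavier nodal burden, larger
#' tumours, older age and ER-negative status increase the hazard.
#'
#' @return named numeric vector, names `"covariate=level"`.
#' @export
default_clinical_effects <- function() {
  c("grade=2" = 0.2, "grade=3" = 0.5,
    "lymph_nodes_positive=2-3" = 0.2, "lymph_nodes_positive=4-5" = 0.4,
    "lymph_nodes_positive=6-9" = 0.6, "lymph_nodes_positive=>=10" = 0.8,
    "size=20-50" = 0.2, "size=50-180" = 0.5,
    "age_at_diagnosis=69-84" = 0.2, "age_at_diagnosis=84-100" = 0.5,
    "ER_Expr=-" = 0.3)
}

validate_cohort_spec <- function(spec) {
  err <- function(field, msg) {
    stop("invalid cohort spec: field '", field, "' ", msg, call. = FALSE)
  }
  counts <- c(n_patients = spec$n_patients, n_genes = spec$n_genes,
              n_informative_genes = spec$n_informative_genes)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v != floor(v)) {
      err(nm, "must be a positive integer count")
    }
  }
  if (spec$n_informative_genes > spec$n_genes) {
    err("n_informative_genes", "must not exceed n_genes")
  }
  rates <- c(baseline_hazard = spec$baseline_hazard,
             censor_dropout_rate = spec$censor_dropout_rate,
             missing_rate = spec$missing_rate)
  for (nm in names(rates)) {
    v <- rates[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      err(nm, "must be a non-negative rate")
    }
  }
  if (spec$baseline_hazard == 0) err("baseline_hazard", "must be positive")
  if (spec$missing_rate >= 1) err("missing_rate", "must be below 1")
  if (!is.numeric(spec$admin_end_day) || spec$admin_end_day <= 0) {
    err("admin_end_day", "must be a positive number of days")
  }
  if (!is.numeric(spec$weibull_shape) || spec$weibull_shape <= 0) {
    err("weibull_shape", "must be positive")
  }
  if (length(spec$clinical_effects) > 0 &&
      (is.null(names(spec$clinical_effects)) ||
       any(!grepl("=", names(spec$clinical_effects)))) ) {
    err("clinical_effects", "must be named 'covariate=level'")
  }
  invisible(spec)
}

#' Generate a synthetic cohort with known prognostic ground truth
#'
#' Draws a cohort per the spec: standard-normal expression levels, uniform
#' (or configured) categorical clinical covariates, proportional-hazards
#' Weibull event times, exponential dropout and an administrative cutoff.
#' The observed `day` is the minimum of event, dropout and cutoff times
#' (rounded up to whole days) and `status` is `dead` exactly when the event
#' came first. A four-level synthetic molecular subtype, standing in for an
#' expression-derived subtype label, is computed from the sign pattern of the
#' first two informative genes, so it carries (coarse) expression signal just
#' as a real expression-composite subtype would.
#'
#' The returned `truth` record stores informative gene indices and their
#' coefficients so recovery can be scored downstream.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `cohort` with elements `patient_id`, `clinical`
#'   (data.frame of factors, including `subtype`), `expression` (numeric
#'   matrix, patients x genes), `day`, `status`, `truth`, `spec`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 50, n_genes = 20, seed = 7))
#' table(coh$status)
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_patients
    p <- spec$n_genes
    patient_id <- sprintf("P%04d", seq_len(n))
    gene_names <- sprintf("gene_%04d", seq_len(p))

    expression <- matrix(rnorm(n * p), n, p,
                         dimnames = list(patient_id, gene_names))
    informative <- sort(sample.int(p, spec$n_informative_genes))

    lv <- clinical_covariate_levels()
    clinical <- as.data.frame(lapply(names(lv), function(nm) {
      pr <- spec$clinical_level_probs[[nm]] %||% rep(1, length(lv[[nm]]))
      factor(sample(lv[[nm]], n, replace = TRUE, prob = pr), levels = lv[[nm]])
    }), optional = TRUE)
    names(clinical) <- names(lv)

    # NPI-like prognostic composite of size, nodal burden and grade.
    npi_score <- as.integer(clinical$size) + as.integer(clinical$lymph_nodes_positive) / 2 +
      as.integer(clinical$grade)
    clinical$NPI <- cut(npi_score, breaks = c(-Inf, 4, 6, Inf),
                        labels = c("low", "moderate", "high"))

    # Clinical linear predictor from per-level effects.
    lp_clin <- rep(0, n)
    for (nm in names(spec$clinical_effects)) {
      parts <- strsplit(nm, "=", fixed = TRUE)[[1]]
      cov <- parts[1]; level <- paste(parts[-1], collapse = "=")
      if (!cov %in% names(clinical)) {
        stop("clinical_effects refers to unknown covariate '", cov, "'", call. = FALSE)
      }
      lp_clin <- lp_clin + spec$clinical_effects[[nm]] *
        (as.character(clinical[[cov]]) == level)
    }

    z <- scale(expression[, informative, drop = FALSE])
    lp_gene <- as.numeric(z %*% spec$gene_effects)
    lp_int <- rep(0, n)
    pairs <- NULL
    if (spec$interaction_strength != 0 && spec$n_informative_genes >= 2) {
      idx <- seq_len(spec$n_informative_genes %/% 2 * 2)
      first <- idx[seq(1, length(idx), by = 2)]
      second <- idx[seq(2, length(idx), by = 2)]
      pairs <- cbind(informative[first], informative[second])
      lp_int <- spec$interaction_strength *
        rowSums(z[, first, drop = FALSE] * z[, second, drop = FALSE])
    }
    lp <- lp_clin + lp_gene + lp_int

    # Event times: PH Weibull with hazard
    # h(t) = shape * b^shape * t^(shape-1) * exp(lp).
    shape <- spec$weibull_shape
    b <- spec$baseline_hazard
    e <- rexp(n, rate = 1)
    t_event <- (e / (b^shape * exp(lp)))^(1 / shape)
    t_drop <- if (spec$censor_dropout_rate > 0) {
      rexp(n, rate = spec$censor_dropout_rate)
    } else rep(Inf, n)
    t_obs <- pmin(t_event, t_drop, spec$admin_end_day)
    status <- unname(ifelse(t_event <= t_drop & t_event <= spec$admin_end_day,
                            "dead", "alive"))
    day <- unname(pmax(ceiling(t_obs), 1))

    # Synthetic molecular subtype: coarse sign pattern of the first two
    # informative genes (one gene if only one is informative).
    sub_levels <- c("LumA-like", "LumB-like", "Her2-like", "Basal-like")
    if (spec$n_informative_genes >= 2) {
      pat <- (z[, 1] > 0) * 2L + (z[, 2] > 0) + 1L
      sub_levels <- sub_levels[1:4]
    } else {
      pat <- (z[, 1] > 0) + 1L
      sub_levels <- sub_levels[1:2]
    }
    clinical$subtype <- factor(sub_levels[pat], levels = sub_levels)

    if (spec$missing_rate > 0) {
      for (nm in setdiff(names(clinical), "subtype")) {
        hit <- runif(n) < spec$missing_rate
        clinical[[nm]][hit] <- NA
      }
    }

    truth <- list(informative_genes = gene_names[informative],
                  informative_indices = informative,
                  gene_effects = spec$gene_effects,
                  interaction_strength = spec$interaction_strength,
                  interaction_pairs = if (is.null(pairs)) NULL else
                    matrix(gene_names[pairs], ncol = 2))

    structure(list(patient_id = patient_id, clinical = clinical,
                   expression = expression, day = as.numeric(day),
                   status = status, truth = truth, spec = spec),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic survival cohort:", length(x$patient_id), "patients,",
      ncol(x$expression), "genes (", length(x$truth$informative_indices),
      "informative ),", sum(x$status == "dead"), "deaths\n")
  invisible(x)
}

#' Write / read a cohort as delimited text files
#'
#' Serializes a cohort to a directory of plain-text files: `clinical.csv`
#' (one row per patient), `expression.csv` (patients x genes),
#' `followup.csv` (`patient_id, day, status`) and a JSON sidecar
#' `truth.json` holding the ground-truth record and generating spec.
#' `read_cohort()` inverts the writer; the round trip preserves all fields.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir directory to write to (created if absent).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns the
#'   `cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  clin <- data.frame(patient_id = cohort$patient_id, cohort$clinical,
                     check.names = FALSE)
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE, na = "NA")
  expr <- data.frame(patient_id = cohort$patient_id, cohort$expression,
                     check.names = FALSE)
  utils::write.csv(expr, file.path(dir, "expression.csv"), row.names = FALSE)
  fu <- data.frame(patient_id = cohort$patient_id, day = cohort$day,
                   status = cohort$status)
  utils::write.csv(fu, file.path(dir, "followup.csv"), row.names = FALSE)
  sidecar <- list(truth = cohort$truth,
                  spec = unclass(cohort$spec),
                  clinical_levels = lapply(cohort$clinical, levels))
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  paths <- file.path(dir, c("clinical.csv", "expression.csv",
                            "followup.csv", "truth.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("cohort directory is missing: ", paste(basename(missing), collapse = ", "),
         call. = FALSE)
  }
  sidecar <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  clin_raw <- utils::read.csv(paths[1], stringsAsFactors = FALSE,
                              check.names = FALSE, na.strings = "NA",
                              colClasses = "character")
  fu <- utils::read.csv(paths[3], stringsAsFactors = FALSE)
  if (!is.numeric(fu$day)) {
    bad <- which(is.na(suppressWarnings(as.numeric(fu$day))))[1]
    stop("followup.csv: non-numeric 'day' at row ", bad, ", column 'day'",
         call. = FALSE)
  }
  expr_raw <- utils::read.csv(paths[2], check.names = FALSE)
  patient_id <- clin_raw$patient_id
  expression <- as.matrix(expr_raw[, -1, drop = FALSE])
  rownames(expression) <- expr_raw$patient_id
  clinical <- clin_raw[, setdiff(names(clin_raw), "patient_id"), drop = FALSE]
  for (nm in names(clinical)) {
    lv <- sidecar$clinical_levels[[nm]]
    clinical[[nm]] <- factor(clinical[[nm]], levels = lv)
  }
  spec <- sidecar$spec
  spec$clinical_effects <- unlist(spec$clinical_effects)
  spec <- structure(spec, class = "cohort_spec")
  truth <- sidecar$truth
  if (!is.null(truth$interaction_pairs)) {
    truth$interaction_pairs <- matrix(truth$interaction_pairs, ncol = 2)
  }
  structure(list(patient_id = patient_id, clinical = clinical,
                 expression = expression, day = as.numeric(fu$day),
                 status = fu$status, truth = truth, spec = spec),
            class = "cohort")
}
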