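#' Equal-width discretization of a continuous feature
#'
#' Splits the observed range of `x` into `M` equally wide intervals and maps
#' each value to its interval; with the default `M = 3` the intervals are
#' labelled `low`, `medium`, `high`. The top boundary is closed, so the
#' maximum falls in the last bin. When training-derived `breaks` are supplied,
#' values outside the training range are clamped into the first or last bin.
#'
#' A constant feature has no width to divide: every value is assigned `low`
#' and the result is flagged degenerate.
#'
#' @param x numeric vector, non-empty.
#' @param M number of intervals (default 3).
#' @param breaks optional numeric vector of `M + 1` increasing cut points
#'   from a previous (training) call; used to discretize held-out data
#'   without recomputing the range.
#' @return a list of class `discretized_feature` with elements `codes`
#'   (integer bin index in `1..M`), `labels` (bin labels), `breaks`
#'   (cut points) and `degenerate` (logical).
#' @examples
#' equal_width_discretize(0:9, M = 3)$codes
#' @export
equal_width_discretize <- function(x, M = 3, breaks = NULL) {
  if (length(x) == 0L) stop("x must be non-empty", call. = FALSE)
  if (M < 2) stop("M must be at least 2", call. = FALSE)
  if (anyNA(x)) stop("x must not contain missing values (impute first)", call. = FALSE)
  labels <- if (M == 3) c("low", "medium", "high") else paste0("bin", seq_len(M))
  degenerate <- FALSE
  if (is.null(breaks)) {
    lo <- min(x); hi <- max(x)
    if (hi == lo) {
      return(structure(list(codes = rep(1L, length(x)), labels = labels,
                            breaks = rep(lo, M + 1), degenerate = TRUE),
                       class = "discretized_feature"))
    }
    breaks <- seq(lo, hi, length.out = M + 1)
  } else {
    if (length(breaks) != M + 1) stop("breaks must have length M + 1", call. = FALSE)
    if (breaks[1] == breaks[M + 1]) degenerate <- TRUE
  }
  if (degenerate) {
    codes <- rep(1L, length(x))
  } else {
    width <- (breaks[M + 1] - breaks[1]) / M
    codes <- floor((x - breaks[1]) / width)
    codes <- pmin(pmax(codes, 0), M - 1)
    codes <- as.integer(codes) + 1L
  }
  structure(list(codes = codes, labels = labels, breaks = breaks,
                 degenerate = degenerate),
            class = "discretized_feature")
}

#' Discretize every column of an expression matrix
#'
#' Applies [equal_width_discretize()] column-wise. Bin edges can be taken
#' from a previous call (training folds) so held-out samples are binned with
#' training-derived edges.
#'
#' @param mat numeric matrix, samples in rows, features in columns.
#' @param M number of intervals per feature (default 3).
#' @param edges optional `(M + 1) x p` matrix of cut points from a previous
#'   call (its `edges` element).
#' @return object of class `discretized_matrix`: list with `codes` (integer
#'   matrix, values `1..M`), `labels`, `edges`, `degenerate` (logical per
#'   feature).
#' @export
discretize_matrix <- function(mat, M = 3, edges = NULL) {
  mat <- as.matrix(mat)
  p <- ncol(mat)
  codes <- matrix(0L, nrow(mat), p, dimnames = dimnames(mat))
  out_edges <- matrix(NA_real_, M + 1, p)
  degenerate <- logical(p)
  labels <- if (M == 3) c("low", "medium", "high") else paste0("bin", seq_len(M))
  for (j in seq_len(p)) {
    br <- if (is.null(edges)) NULL else edges[, j]
    d <- equal_width_discretize(mat[, j], M = M, breaks = br)
    codes[, j] <- d$codes
    out_edges[, j] <- d$breaks
    degenerate[j] <- d$degenerate
  }
  colnames(out_edges) <- colnames(mat)
  structure(list(codes = codes, labels = labels, edges = out_edges,
                 degenerate = degenerate),
            class = "discretized_matrix")
}

# Convert a discretized_matrix to a data.frame of ordered factors
# (low < medium < high), suitable for model fitting.
discretized_as_factors <- function(dm) {
  stopifnot(inherits(dm, "discretized_matrix"))
  out <- as.data.frame(lapply(seq_len(ncol(dm$codes)), function(j) {
    factor(dm$labels[dm$codes[, j]], levels = dm$labels, ordered = TRUE)
  }), optional = TRUE)
  names(out) <- colnames(dm$codes)
  rownames(out) <- rownames(dm$codes)
  out
}

#' Impute missing clinical values
#'
#' Deterministic single imputation: missing categorical cells are filled with
#' the covariate's mode (ties broken by level order), numeric cells with the
#' median. Imputation statistics can be computed on training data and applied
#' to held-out data via `stats`.
#'
#' @param clinical data.frame of clinical covariates (factors, characters or
#'   numerics), possibly with `NA` cells.
#' @param stats optional list of per-column fill values from a previous call
#'   (attribute `"impute_stats"` of its result); when supplied, those values
#'   are used instead of recomputing.
#' @return the completed data.frame, with attribute `"impute_stats"` holding
#'   the per-column fill values.
#' @export
impute_clinical <- function(clinical, stats = NULL) {
  stopifnot(is.data.frame(clinical))
  if (is.null(stats)) {
    stats <- lapply(names(clinical), function(nm) {
      col <- clinical[[nm]]
      obs <- col[!is.na(col)]
      if (length(obs) == 0L) {
        stop("covariate '", nm, "' is fully missing; cannot impute", call. = FALSE)
      }
      if (is.numeric(col)) {
        median(obs)
      } else {
        tab <- table(as.character(obs))
        lv <- if (is.factor(col)) levels(col) else sort(unique(as.character(obs)))
        lv <- lv[lv %in% names(tab)]
        lv[which.max(tab[lv])]
      }
    })
    names(stats) <- names(clinical)
  }
  for (nm in names(clinical)) {
    miss <- is.na(clinical[[nm]])
    if (any(miss)) {
      if (is.factor(clinical[[nm]])) {
        clinical[[nm]][miss] <- factor(stats[[nm]], levels = levels(clinical[[nm]]))
      } else {
        clinical[[nm]][miss] <- stats[[nm]]
      }
    }
  }
  attr(clinical, "impute_stats") <- stats
  clinical
}

#' Build the per-year status grid from follow-up data
#'
#' Expands `(day, status)` follow-up into one row per patient and one column
#' per year, each cell `alive`, `dead` or `NA`. A death observed `day` days
#' after initial consultation is recorded in year `ceiling(day /
#' days_per_year)` and all later years; a censored patient is `alive` up to
#' and including their last-seen year and unknown (`NA`) afterwards, encoding
#' right censoring.
#'
#' @param day positive follow-up days, one per patient.
#' @param status `"dead"` / `"alive"` per patient.
#' @param horizon_years number of year columns (default 15).
#' @param days_per_year year length in days (default 365).
#' @param patient_id optional ids; defaults to `1..n`.
#' @return data.frame of class `year_table` with columns `patient_id`,
#'   `Year_1` .. `Year_<horizon>`, values `"alive"`, `"dead"` or `NA`.
#' @examples
#' build_year_table(c(500, 600), c("dead", "alive"), horizon_years = 3)
#' @export
build_year_table <- function(day, status, horizon_years = 15, days_per_year = 365,
                             patient_id = NULL) {
  if (any(day <= 0)) stop("day must be positive for every patient", call. = FALSE)
  if (horizon_years < 1) stop("horizon_years must be at least 1", call. = FALSE)
  ev <- as_event_indicator(status)
  n <- length(day)
  if (is.null(patient_id)) patient_id <- seq_len(n)
  event_year <- ceiling(day / days_per_year)
  years <- seq_len(horizon_years)
  grid <- matrix(NA_character_, n, horizon_years)
  for (i in seq_len(n)) {
    if (ev[i] == 1L) {
      grid[i, ] <- ifelse(years < event_year[i], "alive", "dead")
    } else {
      grid[i, ] <- ifelse(years <= event_year[i], "alive", NA_character_)
    }
  }
  out <- data.frame(patient_id = patient_id, grid, stringsAsFactors = FALSE)
  names(out) <- c("patient_id", paste0("Year_", years))
  class(out) <- c("year_table", "data.frame")
  out
}

#' Landmark survival target at a fixed year
#'
#' Extracts the status column for year `Y` from a year table: `dead`, `alive`
#' or `NA` for patients censored before the landmark. The `NA` patients have
#' unknown landmark status and must be excluded from binary-target feature
#' selection.
#'
#' @param year_table a [build_year_table()] result.
#' @param year the landmark year `Y`, at most the table horizon.
#' @return factor with levels `alive`, `dead` and `NA` for unknown.
#' @export
landmark_target <- function(year_table, year) {
  stopifnot(inherits(year_table, "year_table"))
  col <- paste0("Year_", year)
  if (!col %in% names(year_table)) {
    stop("year ", year, " exceeds the table horizon", call. = FALSE)
  }
  factor(year_table[[col]], levels = c("alive", "dead"))
}

#' Write / read a year table as CSV
#'
#' @param year_table a [build_year_table()] result.
#' @param path file path.
#' @return `read_year_table` returns the `year_table`; `write_year_table`
#'   returns `path` invisibly.
#' @export
write_year_table <- function(year_table, path) {
  utils::write.csv(year_table, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_year_table
#' @export
read_year_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "NA")
  class(out) <- c("year_table", "data.frame")
  out
}
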