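#' @useDynLib survcompare, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median pchisq rexp rnorm runif sd
NULL

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so seeded helpers do not perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage seed from a master seed; keeps results reproducible while
# decorrelating stages. Stays below 2^31 - 1.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 7919 + as.numeric(offset)) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nelson-Aalen cumulative hazard estimator
#'
#' Nonparametric estimate of the cumulative hazard \eqn{\Lambda(t)} from
#' right-censored data: at each distinct event time, the increment is the
#' number of deaths divided by the number at risk. Optional case weights
#' support bootstrap resamples via multiplicity counts.
#'
#' @param day observed times (event or censoring), all positive.
#' @param status character or factor with values `"dead"` / `"alive"`, or a
#'   0/1 numeric event indicator.
#' @param weights optional non-negative case weights (default all 1).
#' @return a data.frame with columns `time` (distinct event times, increasing)
#'   and `chf` (cumulative hazard, non-decreasing, starting above 0).
#' @export
nelson_aalen <- function(day, status, weights = NULL) {
  ev <- as_event_indicator(status)
  if (is.null(weights)) weights <- rep(1, length(day))
  stopifnot(length(day) == length(ev), length(weights) == length(day))
  keep <- weights > 0
  day <- day[keep]; ev <- ev[keep]; weights <- weights[keep]
  times <- sort(unique(day[ev == 1]))
  if (length(times) == 0L) {
    return(data.frame(time = numeric(0), chf = numeric(0)))
  }
  chf <- numeric(length(times))
  acc <- 0
  for (i in seq_along(times)) {
    t <- times[i]
    at_risk <- sum(weights[day >= t])
    d <- sum(weights[day == t & ev == 1])
    acc <- acc + d / at_risk
    chf[i] <- acc
  }
  data.frame(time = times, chf = chf)
}

as_event_indicator <- function(status) {
  if (is.numeric(status)) {
    if (!all(status %in% c(0, 1))) stop("numeric status must be 0/1", call. = FALSE)
    return(as.integer(status))
  }
  s <- as.character(status)
  bad <- setdiff(unique(s), c("dead", "alive"))
  if (length(bad) > 0) {
    stop("status values must be 'dead' or 'alive'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  as.integer(s == "dead")
}

# Truncate follow-up at a horizon: events after the horizon become censored
# observations at the horizon.
truncate_followup <- function(day, status, horizon) {
  ev <- as_event_indicator(status)
  over <- day > horizon
  day[over] <- horizon
  ev[over] <- 0L
  list(day = day, event = ev)
}
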