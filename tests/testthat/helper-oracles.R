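# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation: plain double loops and
# textbook formulas only.

# Concordance by exhaustive pair enumeration: j dead within horizon, k with
# observed time strictly later; concordant iff area_j < area_k.
brute_concordance <- function(areas, day, status, horizon) {
  dead <- status == "dead"
  total <- 0L
  pairs <- 0L
  n <- length(day)
  for (j in seq_len(n)) {
    if (!dead[j] || day[j] > horizon) next
    for (k in seq_len(n)) {
      if (day[k] > day[j]) {
        pairs <- pairs + 1L
        if (areas[j] < areas[k]) total <- total + 1L
      }
    }
  }
  list(index = total / pairs, total = total, n_pairs = pairs)
}

# Relief with an explicit visit schedule, naive loops throughout.
brute_relief <- function(X, target, schedule, denom) {
  X <- as.matrix(X)
  storage.mode(X) <- "character"
  n <- nrow(X)
  p <- ncol(X)
  tgt <- as.character(target)
  W <- numeric(p)
  for (d in schedule) {
    best_h <- NA; best_hd <- Inf
    best_m <- NA; best_md <- Inf
    for (x in seq_len(n)) {
      if (x == d) next
      dist <- 0L
      for (f in seq_len(p)) dist <- dist + (X[d, f] != X[x, f])
      if (tgt[x] == tgt[d]) {
        if (dist < best_hd) { best_hd <- dist; best_h <- x }
      } else {
        if (dist < best_md) { best_md <- dist; best_m <- x }
      }
    }
    for (f in seq_len(p)) {
      W[f] <- W[f] - (X[d, f] != X[best_h, f]) / denom +
        (X[d, f] != X[best_m, f]) / denom
    }
  }
  names(W) <- colnames(X)
  W
}

# Breslow partial log-likelihood for a single covariate, naive sums.
brute_cox_loglik_1d <- function(x, day, event, beta) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(day >= day[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Nelson-Aalen with case weights, naive formula.
brute_nelson_aalen <- function(day, event, w, at_times) {
  vapply(at_times, function(t) {
    ts <- sort(unique(day[event == 1 & day <= t]))
    sum(vapply(ts, function(s) {
      d <- sum(w[day == s & event == 1])
      atrisk <- sum(w[day >= s])
      if (d == 0 || atrisk == 0) 0 else d / atrisk
    }, numeric(1)))
  }, numeric(1))
}

# Small random right-censored dataset for oracle comparisons.
random_survival_data <- function(n, seed, p_censor = 0.3, max_day = 1000) {
  set.seed(seed)
  day <- sample.int(max_day, n, replace = TRUE)
  status <- ifelse(runif(n) < p_censor, "alive", "dead")
  list(day = as.numeric(day), status = status, areas = runif(n, 0, max_day))
}

small_cohort <- function(seed = 1, n = 80, genes = 20, ...) {
  generate_cohort(cohort_spec(n_patients = n, n_genes = genes,
                              n_informative_genes = min(4, genes),
                              seed = seed, ...))
}

clinical_wo_subtype <- function(cohort) {
  cohort$clinical[, setdiff(names(cohort$clinical), "subtype"), drop = FALSE]
}
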