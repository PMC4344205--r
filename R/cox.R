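#' Encode a table of categorical covariates as indicator columns
#'
#' Reference-level one-hot encoding: for each factor column the most frequent
#' level (ties to the earlier level) becomes the reference and every other
#' level gets an indicator column `name=level`. Numeric columns pass through.
#' The returned map re-encodes new data identically; an unseen level at
#' prediction time is an error naming the level.
#'
#' @param features data.frame (factors / characters / numerics).
#' @param map optional encoding map from a previous call (training data).
#' @return list with `X` (numeric matrix) and `map` (per-column levels and
#'   reference).
#' @export
encode_features <- function(features, map = NULL) {
  stopifnot(is.data.frame(features))
  if (is.null(map)) {
    map <- lapply(names(features), function(nm) {
      col <- features[[nm]]
      if (is.numeric(col)) return(list(type = "numeric"))
      f <- factor(as.character(col))
      tab <- table(f)
      ref <- names(tab)[which.max(tab)]
      list(type = "factor", levels = levels(f), ref = ref)
    })
    names(map) <- names(features)
  }
  cols <- list()
  for (nm in names(map)) {
    if (!nm %in% names(features)) stop("missing covariate '", nm, "'", call. = FALSE)
    enc <- map[[nm]]
    col <- features[[nm]]
    if (enc$type == "numeric") {
      cols[[nm]] <- as.numeric(col)
    } else {
      vals <- as.character(col)
      unseen <- setdiff(unique(vals), enc$levels)
      if (length(unseen) > 0) {
        stop("unseen level '", unseen[1], "' for covariate '", nm, "'",
             call. = FALSE)
      }
      for (lv in setdiff(enc$levels, enc$ref)) {
        cols[[paste0(nm, "=", lv)]] <- as.numeric(vals == lv)
      }
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- rownames(features)
  list(X = X, map = map)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Breslow-tie partial likelihood by Newton-Raphson with
#' step-halving, starting from zero coefficients; convergence when the
#' largest score component falls below `tol` (default 1e-6) or after
#' `max_iter` iterations. The baseline cumulative hazard is the Breslow
#' estimator on the event-time grid. No shrinkage of any kind is applied, so
#' the fit degrades when given many covariates relative to events — a
#' property the surrounding benchmarking machinery is designed to expose.
#'
#' Follow-up is truncated at `horizon`: events after the horizon count as
#' censored at the horizon, so the fit only uses information from within the
#' prediction timeframe. Constant (zero-variance) encoded columns carry no
#' contrast and are dropped with their names recorded in `dropped`.
#'
#' @param features data.frame of covariates (factors/numerics), or a
#'   [discretize_matrix()] result.
#' @param day observed follow-up days.
#' @param status `"dead"`/`"alive"` (or 0/1) per patient.
#' @param horizon fitting horizon in days (default `Inf` = no truncation).
#' @param max_iter,tol Newton-Raphson controls.
#' @return object of class `cox_fit`: `coefficients`, `baseline` (data.frame
#'   `time`, `hazard` = cumulative baseline hazard), `map` (encoding),
#'   `centers`, `dropped`, `loglik`, `iterations`, `converged`.
#' @export
fit_cox <- function(features, day, status, horizon = Inf,
                    max_iter = 50, tol = 1e-6) {
  if (inherits(features, "discretized_matrix")) {
    features <- discretized_as_factors(features)
  }
  tr <- truncate_followup(day, status, horizon)
  day <- tr$day; event <- tr$event
  if (sum(event) == 0) {
    stop("no events within the horizon; cannot fit a Cox model", call. = FALSE)
  }
  enc <- encode_features(features)
  X <- enc$X
  keep <- apply(X, 2, function(v) stats::var(v) > 0)
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) stop("no covariate provides any contrast", call. = FALSE)
  if (ncol(X) >= sum(event)) {
    stop("unidentifiable fit: ", ncol(X), " encoded covariate columns but only ",
         sum(event), " events; the unpenalized partial likelihood cannot ",
         "identify this many coefficients", call. = FALSE)
  }
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)

  res <- cox_newton(Xc, day, event, max_iter = max_iter, tol = tol)

  # Breslow baseline cumulative hazard on the event-time grid (centered
  # covariates, i.e. the baseline refers to an average patient).
  w <- exp(as.numeric(Xc %*% res$beta))
  etimes <- sort(unique(day[event == 1]))
  haz <- numeric(length(etimes))
  acc <- 0
  for (i in seq_along(etimes)) {
    t <- etimes[i]
    acc <- acc + sum(event == 1 & day == t) / sum(w[day >= t])
    haz[i] <- acc
  }

  structure(list(coefficients = res$beta, baseline = data.frame(time = etimes,
                                                                hazard = haz),
                 map = enc$map, centers = centers, dropped = dropped,
                 loglik = res$loglik, iterations = res$iter,
                 converged = res$converged, horizon = horizon),
            class = "cox_fit")
}

# Breslow partial log-likelihood, score and information at beta.
cox_partial_loglik <- function(Xc, day, event, beta, want_derivs = TRUE) {
  eta <- as.numeric(Xc %*% beta)
  w <- exp(eta)
  ord <- order(day, decreasing = TRUE)  # add patients to the risk set as t decreases
  p <- ncol(Xc)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  i <- 1
  n <- length(day)
  while (i <= n) {
    t <- day[ord[i]]
    # absorb all patients with time == t into the risk set
    while (i <= n && day[ord[i]] == t) {
      k <- ord[i]
      S0 <- S0 + w[k]
      S1 <- S1 + w[k] * Xc[k, ]
      if (want_derivs) S2 <- S2 + w[k] * tcrossprod(Xc[k, ])
      i <- i + 1
    }
    ev <- which(event == 1 & day == t)
    d <- length(ev)
    if (d > 0) {
      ll <- ll + sum(eta[ev]) - d * log(S0)
      if (want_derivs) {
        xbar <- S1 / S0
        U <- U + colSums(Xc[ev, , drop = FALSE]) - d * xbar
        I <- I + d * (S2 / S0 - tcrossprod(xbar))
      }
    }
  }
  list(loglik = ll, score = U, info = I)
}

cox_newton <- function(Xc, day, event, max_iter = 50, tol = 1e-6) {
  p <- ncol(Xc)
  beta <- numeric(p)
  pl <- cox_partial_loglik(Xc, day, event, beta)
  for (iter in seq_len(max_iter)) {
    if (max(abs(pl$score)) < tol) {
      return(list(beta = stats::setNames(beta, colnames(Xc)), loglik = pl$loglik,
                  iter = iter - 1L, converged = TRUE))
    }
    step <- tryCatch(solve(pl$info, pl$score), error = function(e) NULL)
    if (is.null(step) || anyNA(step)) {
      stop("Cox information matrix is singular (separation or collinearity) ",
           "at iteration ", iter, "; log-likelihood ", signif(pl$loglik, 6),
           call. = FALSE)
    }
    # step-halving to guarantee ascent
    ok <- FALSE
    for (h in 0:20) {
      cand <- beta + step / 2^h
      pl_new <- cox_partial_loglik(Xc, day, event, cand)
      if (is.finite(pl_new$loglik) && pl_new$loglik >= pl$loglik - 1e-12) {
        beta <- cand; pl <- pl_new; ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("Cox partial likelihood failed to increase at iteration ", iter,
           "; log-likelihood ", signif(pl$loglik, 6), call. = FALSE)
    }
  }
  if (max(abs(pl$score)) < tol) {
    return(list(beta = stats::setNames(beta, colnames(Xc)), loglik = pl$loglik,
                iter = max_iter, converged = TRUE))
  }
  stop("Cox model did not converge in ", max_iter,
       " iterations; max |score| = ", signif(max(abs(pl$score)), 4), call. = FALSE)
}

#' Per-patient survival curves from a Cox fit
#'
#' Evaluates `S(t) = exp(-Lambda0(t) * exp(x beta))` on the fit's event-time
#' grid, restricted to `[0, horizon]`, with constant extrapolation beyond the
#' last event time. `S(0) = 1` and each curve is non-increasing.
#'
#' @param fit a [fit_cox()] result.
#' @param features new covariate table (same columns as at fit time).
#' @param horizon evaluation horizon in days.
#' @return object of class `survival_curves`: list with `time` (grid, first
#'   element > 0), `surv` (matrix patients x times) and `horizon`. `S(t)` for
#'   `t` before the first grid point is 1.
#' @export
predict_survival_curve <- function(fit, features, horizon = fit$horizon) {
  stopifnot(inherits(fit, "cox_fit"))
  if (inherits(features, "discretized_matrix")) {
    features <- discretized_as_factors(features)
  }
  enc <- encode_features(features, map = fit$map)
  X <- enc$X[, names(fit$centers), drop = FALSE]
  Xc <- sweep(X, 2, fit$centers)
  risk <- exp(as.numeric(Xc %*% fit$coefficients))
  keep <- fit$baseline$time <= horizon
  times <- fit$baseline$time[keep]
  Lam <- fit$baseline$hazard[keep]
  if (length(times) == 0) {
    times <- horizon
    Lam <- 0
  }
  surv <- exp(-outer(risk, Lam))
  dimnames(surv) <- list(rownames(features), NULL)
  structure(list(time = times, surv = surv, horizon = horizon),
            class = "survival_curves")
}

#' Serialize / restore a Cox fit as JSON
#'
#' @param fit a `cox_fit`.
#' @param path file path.
#' @return `read_cox_fit` returns the `cox_fit`; `write_cox_fit` returns
#'   `path` invisibly.
#' @export
write_cox_fit <- function(fit, path) {
  stopifnot(inherits(fit, "cox_fit"))
  obj <- unclass(fit)
  obj$coefficients <- as.list(obj$coefficients)  # keep names through JSON
  obj$centers <- as.list(obj$centers)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_cox_fit
#' @export
read_cox_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  obj$centers <- unlist(obj$centers)
  obj$dropped <- as.character(unlist(obj$dropped))
  obj$baseline <- as.data.frame(obj$baseline)
  structure(obj, class = "cox_fit")
}
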