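#' Logistic regression by iteratively reweighted least squares
#'
#' Maximises the Bernoulli log-likelihood with a logit link by Newton
#' iterations. The intercept starts at `logit(mean(y))` (clipped away from
#' the boundary), other coefficients at zero. Convergence when the
#' log-likelihood changes by less than `1e-10`, with a cap of 100 iterations.
#' The coefficient covariance is the inverse of the final Fisher
#' information. Complete separation is flagged (`status = "separated"`) when
#' any |coefficient| exceeds 30 or any standard error exceeds 1e3; the fit is
#' still returned. A rank-deficient design gives `status = "degenerate"` with
#' no estimates.
#'
#' @param y binary response vector (0/1, no NA).
#' @param X design matrix including the intercept column; rows complete.
#' @return List: `beta`, `loglik`, `vcov`, `se`, `status` (one of
#'   `"converged"`, `"separated"`, `"degenerate"`, `"not_converged"`),
#'   `iterations`.
#' @export
fit_logistic <- function(y, X) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  p <- ncol(X)
  if (qr(X)$rank < p)
    return(list(beta = NULL, loglik = NA_real_, vcov = NULL, se = NULL,
                status = "degenerate", iterations = 0L))
  pbar <- min(max(mean(y), 1e-8), 1 - 1e-8)
  beta <- c(qlogis(pbar), rep(0, p - 1L))
  ll_old <- -Inf
  status <- "not_converged"
  for (it in seq_len(100L)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    ll <- sum(y * .log_safe(mu) + (1 - y) * .log_safe(1 - mu))
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w)
    step <- tryCatch(solve(info, crossprod(X, y - mu)),
                     error = function(e) NULL)
    if (is.null(step)) {
      # full-rank design whose information degenerated mid-run: the fit is
      # diverging towards the boundary, i.e. separation
      status <- if (it > 1L) "separated" else "degenerate"
      break
    }
    if (is.finite(ll) && abs(ll - ll_old) < 1e-10 &&
        max(abs(step)) < 1e-8) {
      status <- "converged"
      break
    }
    ll_old <- ll
    beta <- pmin(pmax(beta + drop(step), -35), 35)   # keep finite under
    if (any(abs(beta) >= 30)) {                      # complete separation
      status <- "separated"
      break
    }
  }
  if (status == "degenerate")
    return(list(beta = NULL, loglik = NA_real_, vcov = NULL, se = NULL,
                status = status, iterations = it))
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  ll <- sum(y * .log_safe(mu) + (1 - y) * .log_safe(1 - mu))
  info <- crossprod(X, X * (mu * (1 - mu)))
  vc <- tryCatch(solve(info), error = function(e) NULL)
  se <- if (is.null(vc)) rep(Inf, p) else sqrt(pmax(diag(vc), 0))
  if (any(abs(beta) > 30) || any(se > 1e3)) status <- "separated"
  names(beta) <- colnames(X)
  list(beta = beta, loglik = ll, vcov = vc, se = se, status = status,
       iterations = it)
}

.log_safe <- function(x) log(pmax(x, .Machine$double.xmin))

#' Score one genotype indicator against environmental variables
#'
#' Fits the nested pair of logistic models on complete cases:
#' null = intercept (+ population covariates), full = null + the
#' environmental variable(s). Returns the likelihood-ratio statistic
#' `G = 2 (LL_full - LL_null)` and the Wald statistic
#' `b' V^-1 b` over the environmental coefficients (for a single variable,
#' `(beta / se)^2`), with `df` = number of environmental variables.
#'
#' @param ind binary indicator vector (0/1/NA) over samples.
#' @param env EnvTable aligned with `ind` (same sample order).
#' @param env_vars character: environmental variable name(s) to test.
#' @param pop_vars character: population covariates (default: the table's
#'   flagged population-structure columns; use `character()` for none).
#' @param label indicator label carried into the result.
#' @return One-row data.frame (a `ModelResult`): `indicator`, `env`, `n`,
#'   `beta_env`, `loglik_full`, `loglik_null`, `G`, `Wald`, `df`, `status`.
#' @export
score_model <- function(ind, env, env_vars,
                        pop_vars = env_variables(env, "pop"),
                        label = "indicator") {
  stopifnot(length(env_vars) >= 1L, !any(env_vars %in% pop_vars))
  res <- data.frame(indicator = label,
                    env = paste(env_vars, collapse = "+"),
                    n = NA_integer_, beta_env = NA_real_,
                    loglik_full = NA_real_, loglik_null = NA_real_,
                    G = NA_real_, Wald = NA_real_,
                    df = length(env_vars), status = "skipped",
                    stringsAsFactors = FALSE)
  cols <- c(env_vars, pop_vars)
  E <- as.matrix(as.data.frame(env)[, cols, drop = FALSE])
  cc <- !is.na(ind) & complete.cases(E)
  y <- as.numeric(ind[cc])
  E <- E[cc, , drop = FALSE]
  res$n <- length(y)
  if (length(y) < length(cols) + 2L || length(unique(y)) < 2L) return(res)
  if (any(apply(E[, env_vars, drop = FALSE], 2L, function(v)
    sd(v) == 0))) return(res)
  Xnull <- cbind(`(Intercept)` = 1,
                 E[, pop_vars, drop = FALSE])
  Xfull <- cbind(Xnull, E[, env_vars, drop = FALSE])
  f0 <- fit_logistic(y, Xnull)
  f1 <- fit_logistic(y, Xfull)
  if (is.null(f1$beta) || is.null(f0$beta)) {
    res$status <- "degenerate"
    return(res)
  }
  kenv <- seq.int(ncol(Xfull) - length(env_vars) + 1L, ncol(Xfull))
  b <- f1$beta[kenv]
  V <- f1$vcov[kenv, kenv, drop = FALSE]
  wald <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
  res$beta_env <- b[1L]
  res$loglik_full <- f1$loglik
  res$loglik_null <- f0$loglik
  res$G <- 2 * (f1$loglik - f0$loglik)
  res$Wald <- wald
  res$status <- if (f1$status == "separated" || f0$status == "separated")
    "separated" else f1$status
  res
}

#' Scan all genotype indicators against all environmental variables
#'
#' Runs [score_model()] over the Cartesian product of indicators and (each
#' single) environmental variable, optionally adjusting for population
#' covariates. The work is split into `chunks` blocks of indicators which
#' may be evaluated by `workers` parallel processes; results are merged in
#' deterministic (indicator, env) order, so the chunk and worker counts
#' never change the output.
#'
#' @param ind IndicatorSet.
#' @param env EnvTable; sample IDs and order must match `ind` exactly.
#' @param env_vars variables to test (default: all non-population columns).
#' @param pop_vars population covariates (default: the flagged columns).
#' @param chunks number of indicator blocks.
#' @param workers number of parallel processes (forked; 1 = serial).
#' @return A data.frame of stacked [score_model()] rows, ordered by
#'   indicator then environmental variable.
#' @export
run_scan <- function(ind, env, env_vars = env_variables(env, "env"),
                     pop_vars = env_variables(env, "pop"),
                     chunks = 1L, workers = 1L) {
  if (!identical(ind$samples, as.character(env$ID))) {
    bad <- union(setdiff(ind$samples, env$ID), setdiff(env$ID, ind$samples))
    if (length(bad) == 0L) bad <- "(same IDs, different order)"
    stop("sample IDs/order differ between genotypes and environment: ",
         paste(head(bad, 10L), collapse = ", "))
  }
  m <- ncol(ind$values)
  chunks <- max(1L, min(as.integer(chunks), m))
  bounds <- split(seq_len(m), ceiling(seq_len(m) * chunks / m))
  score_chunk <- function(cols) {
    out <- vector("list", length(cols) * length(env_vars))
    k <- 0L
    for (j in cols) {
      for (v in env_vars) {
        k <- k + 1L
        out[[k]] <- score_model(ind$values[, j], env, v, pop_vars,
                                label = ind$indicators$label[j])
      }
    }
    do.call(rbind, out)
  }
  parts <- if (workers > 1L) {
    parallel::mclapply(bounds, score_chunk, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(bounds, score_chunk)
  }
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

#' Write a scan result table as TSV
#'
#' Fixed 17-significant-digit formatting so that identical scans give
#' byte-identical files regardless of chunking or worker count.
#'
#' @param results data.frame from [run_scan()] (optionally extended by
#'   [add_significance()]).
#' @param path output path.
#' @param score_min optional writer-side filter: keep only rows with
#'   `max(G, Wald) > score_min` (default 0 stores all scored rows;
#'   unscored/skipped rows are always kept when `score_min <= 0`).
#' @return `path`, invisibly.
#' @export
write_scores <- function(results, path, score_min = 0) {
  if (score_min > 0) {
    s <- pmax(results$G, results$Wald)
    results <- results[!is.na(s) & s > score_min, , drop = FALSE]
  }
  num <- vapply(results, is.numeric, logical(1L))
  fmt <- results
  fmt[num] <- lapply(results[num], function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  })
  data.table::fwrite(fmt, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a scan result table written by [write_scores()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_scores <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE)
}
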