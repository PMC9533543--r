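#' Per-block median Ks
#'
#' Each syntenic block is summarized by the exact median of its anchor
#' pairs' Ks values (mean of the central pair for even counts). Missing
#' values are skipped; blocks left with no valid entry are omitted with
#' a warning.
#'
#' @param ks data frame with columns `block_id` and `ks`.
#' @return data frame `block_id`, `median_ks`, `n_pairs`.
#' @export
block_median_ks <- function(ks) {
  stopifnot(all(c("block_id", "ks") %in% names(ks)))
  sp <- split(ks$ks, ks$block_id)
  med <- vapply(sp, function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else stats::median(v)
  }, numeric(1))
  n <- vapply(sp, function(v) sum(is.finite(v)), integer(1))
  bad <- is.na(med)
  if (any(bad))
    warning(sum(bad), " block(s) without valid Ks entries omitted")
  data.frame(block_id = names(sp)[!bad], median_ks = unname(med[!bad]),
             n_pairs = unname(n[!bad]), stringsAsFactors = FALSE)
}

#' Fit polyploidy peaks to a Ks distribution
#'
#' Gaussian mixtures are fitted to log(Ks) by expectation-maximization
#' for 1..`max_components` components, each restarted from seeded
#' k-means initializations; the component count is chosen by minimum
#' BIC. Peaks are reported on the Ks scale as `exp(meanlog)` (the
#' component medians). Ks distributions are right-skewed, which is why
#' the mixture is fitted on the log scale.
#'
#' @param ks numeric vector of (block-median) Ks values.
#' @param max_components largest mixture size tried (default 4).
#' @param ks_window interval of Ks values used (default `c(0.01, 3)`);
#'   at least 20 values must fall inside.
#' @param n_restarts k-means restarts per component count.
#' @param seed integer seed.
#' @return a `ks_peak_model`: list with `components` (data frame
#'   `weight`, `meanlog`, `sdlog`, `mode`), `k`, `bic` (per candidate),
#'   `loglik`, `n`.
#' @export
fit_ks_peaks <- function(ks, max_components = 4, ks_window = c(0.01, 3),
                         n_restarts = 5, seed = 1) {
  ks <- ks[is.finite(ks) & ks >= ks_window[1] & ks <= ks_window[2]]
  if (length(ks) < 20)
    stop("need at least 20 Ks values inside ks_window")
  y <- log(ks)
  n <- length(y)
  fits <- vector("list", max_components)
  bic <- rep(NA_real_, max_components)
  for (k in seq_len(max_components)) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      set.seed(seed + 1000 * k + r)
      init <- if (k == 1L) list(cluster = rep(1L, n))
        else suppressWarnings(stats::kmeans(y, centers = k, nstart = 1))
      fit <- try(em_gmm1d(y, k, init$cluster), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (is.null(best)) next
    fits[[k]] <- best
    bic[k] <- -2 * best$loglik + (3 * k - 1) * log(n)
  }
  k <- which.min(bic)
  best <- fits[[k]]
  ord <- order(best$mu)
  comp <- data.frame(weight = best$w[ord], meanlog = best$mu[ord],
                     sdlog = best$sd[ord], mode = exp(best$mu[ord]))
  structure(list(components = comp, k = k, bic = bic,
                 loglik = best$loglik, n = n),
            class = "ks_peak_model")
}

#' @export
print.ks_peak_model <- function(x, ...) {
  cat("ks_peak_model:", x$k, "component(s), n =", x$n, "\n")
  print(round(x$components, 4))
  invisible(x)
}

# one-dimensional Gaussian mixture EM
em_gmm1d <- function(y, k, cluster, max_iter = 500, tol = 1e-8,
                     sd_floor = 1e-3) {
  n <- length(y)
  w <- as.vector(table(factor(cluster, levels = seq_len(k)))) / n
  mu <- vapply(seq_len(k), function(j) mean(y[cluster == j]), numeric(1))
  sd_ <- vapply(seq_len(k), function(j) {
    s <- stats::sd(y[cluster == j])
    if (!is.finite(s) || s < sd_floor) stats::sd(y) / k else s
  }, numeric(1))
  mu[!is.finite(mu)] <- mean(y)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(y, mu[j], sd_[j]), numeric(n))
    dens <- matrix(dens, n, k)
    rs <- rowSums(dens)
    rs[rs == 0] <- .Machine$double.xmin
    ll <- sum(log(rs))
    resp <- dens / rs
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * y) / nk
    sd_ <- sqrt(colSums(resp * (y - rep(mu, each = n))^2) / nk)
    sd_[!is.finite(sd_) | sd_ < sd_floor] <- sd_floor
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(w = w, mu = mu, sd = sd_, loglik = ll)
}

#' Write a Ks peak model as JSON
#' @param model a `ks_peak_model`.
#' @param path file path.
#' @export
write_ks_peaks <- function(model, path) {
  jsonlite::write_json(list(k = model$k, bic = model$bic,
                            loglik = model$loglik, n = model$n,
                            components = model$components),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
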