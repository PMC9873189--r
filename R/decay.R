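## Broken-line (changepoint) decay modelling on log-transformed counts.
##
## Per-treatment model:   y = alpha + B*min(t - t0, 0) + Bp*max(t - t0, 0) + e
## Multi-treatment model: y = b0[tr] + b1[tr]*min(t, t0[tr])
##                            + b2[tr]*max(t - t0[tr], 0) + e,   t0 fixed
## e ~ Normal(0, sigma^2). The changepoint t0 is profiled out by minimizing
## RSS over candidate values; slopes are per minute on the natural-log
## scale, so t_1/2 = ln(2) / k with k = -B.

#' Log-transform a normalized count matrix
#'
#' Returns \eqn{y = \ln(count + pseudocount)}. A pseudocount (default 1)
#' keeps zero counts in low-expression probes finite; it is recorded as an
#' attribute for provenance.
#'
#' @param matrix a stage-\code{fully_normalized} [count_matrix()], or a bare
#'   nonnegative numeric matrix.
#' @param pseudocount nonnegative offset added before taking logs.
#' @return Numeric matrix of natural-log counts with attribute
#'   \code{"pseudocount"}.
#' @export
log_transform <- function(matrix, pseudocount = 1) {
  vals <- if (inherits(matrix, "count_matrix")) {
    require_stage(matrix, "fully_normalized", "log_transform")
    matrix$counts
  } else as.matrix(matrix)
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (any(vals < 0)) stop("negative counts cannot be log-transformed")
  out <- log(vals + pseudocount)
  attr(out, "pseudocount") <- pseudocount
  out
}

## OLS on the broken-line basis at a fixed changepoint; returns NULL when
## the basis is rank-deficient at that t0
bl_ols <- function(times, y, t0) {
  X <- cbind(1, pmin(times - t0, 0), pmax(times - t0, 0))
  qr_ <- qr(X)
  if (qr_$rank < 3L) return(NULL)
  coef <- qr.coef(qr_, y)
  res <- y - X %*% coef
  list(coef = coef, rss = sum(res^2), qr = qr_, X = X)
}

bl_rss <- function(times, y, t0) {
  fit <- bl_ols(times, y, t0)
  if (is.null(fit)) Inf else fit$rss
}

#' Fit a broken-line model with unknown changepoint
#'
#' Fits \eqn{y = \alpha + B\,\min(t - t_0, 0) + B'\,\max(t - t_0, 0) + e}
#' by profiling the changepoint: for each candidate \eqn{t_0}, ordinary
#' least squares on the basis \eqn{\{1, \min(t - t_0, 0),
#' \max(t - t_0, 0)\}}; the fit minimizing the residual sum of squares is
#' returned. With \code{t0_candidates = "auto"} the candidate grid is every
#' observed time strictly between the first and last distinct times, refined
#' by a golden-section search between the best grid point's neighbours.
#' Ties are broken toward the earliest changepoint. The log-likelihood is
#' the Gaussian profile likelihood at \eqn{\hat\sigma^2 = RSS/n}.
#'
#' @param times numeric vector of sampling times (minutes).
#' @param y numeric vector of log counts, same length; at least 4
#'   observations at >= 3 distinct times.
#' @param t0_candidates \code{"auto"} or an explicit numeric vector of
#'   changepoint candidates.
#' @return An object of class \code{"broken_line_fit"}: list with
#'   \code{alpha} (log-count level at the changepoint), \code{B} and
#'   \code{Bp} (slopes before/after, per minute), \code{t0} (minutes),
#'   \code{sigma2}, \code{rss}, \code{loglik}, \code{n}, plus the design
#'   QR for downstream inference.
#' @seealso [half_life()], [slope_change_test()], [fit_multi_treatment()]
#' @export
fit_broken_line <- function(times, y, t0_candidates = "auto") {
  stopifnot(length(times) == length(y))
  ok <- is.finite(times) & is.finite(y)
  times <- times[ok]; y <- y[ok]
  n <- length(y)
  if (n < 4L) stop("need >= 4 observations, got ", n)
  ut <- sort(unique(times))
  if (length(ut) < 3L) stop("need >= 3 distinct times, got ", length(ut))

  auto <- identical(t0_candidates, "auto")
  grid <- if (auto) ut[ut > ut[1L] & ut < ut[length(ut)]] else
    sort(unique(as.numeric(t0_candidates)))
  if (!length(grid)) stop("no changepoint candidates in range")

  rss_grid <- vapply(grid, function(t0) bl_rss(times, y, t0), numeric(1))
  if (all(!is.finite(rss_grid)))
    stop("design collinear at every candidate changepoint")
  best_i <- which(rss_grid <= min(rss_grid) + 1e-12)[1L]  # earliest on ties
  t0_best <- grid[best_i]
  rss_best <- rss_grid[best_i]

  if (auto) {
    ## RSS(t0) is smooth between adjacent observed times but only piecewise
    ## so across them; golden-section refinement is run on every
    ## inter-observation interval and the overall best kept (earliest on
    ## effective ties)
    for (i in seq_len(length(ut) - 1L)) {
      opt <- stats::optimize(function(t0) bl_rss(times, y, t0),
                             lower = ut[i], upper = ut[i + 1L], tol = 1e-6)
      if (is.finite(opt$objective) && opt$objective < rss_best - 1e-12) {
        t0_best <- opt$minimum
        rss_best <- opt$objective
      }
    }
  }

  fit <- bl_ols(times, y, t0_best)
  sigma2 <- fit$rss / n
  loglik <- if (sigma2 > 0) -n / 2 * (log(2 * pi * sigma2) + 1) else Inf
  structure(list(alpha = unname(fit$coef[1L]), B = unname(fit$coef[2L]),
                 Bp = unname(fit$coef[3L]), t0 = t0_best,
                 sigma2 = sigma2, rss = fit$rss, loglik = loglik, n = n,
                 qr = fit$qr, times = times, y = y),
            class = "broken_line_fit")
}

#' @export
print.broken_line_fit <- function(x, ...) {
  cat(sprintf(paste0("broken-line fit: n=%d  t0=%.2f min  B=%.5f  ",
                     "Bp=%.5f  rss=%.4g\n"),
              x$n, x$t0, x$B, x$Bp, x$rss))
  invisible(x)
}

#' Exhaustive changepoint search on a fine grid
#'
#' Brute-force reference: evaluates the broken-line RSS on a regular grid of
#' changepoints (default spacing 0.1 min) across the observed time range and
#' returns the minimum. Used as an independent check of the profiled search
#' in [fit_broken_line()].
#'
#' @param times,y as in [fit_broken_line()].
#' @param step grid spacing in minutes.
#' @return List with \code{t0} and \code{rss} at the grid minimum.
#' @export
grid_search_changepoint <- function(times, y, step = 0.1) {
  ut <- sort(unique(times))
  grid <- seq(ut[1L], ut[length(ut)], by = step)
  rss <- vapply(grid, function(t0) bl_rss(times, y, t0), numeric(1))
  i <- which.min(rss)
  list(t0 = grid[i], rss = rss[i])
}

#' Fit the multi-treatment broken-line model with fixed changepoints
#'
#' Single OLS fit of
#' \eqn{y = \beta_0[tr] + \beta_1[tr]\min(t, t_0[tr]) +
#'      \beta_2[tr]\max(t - t_0[tr], 0) + e}
#' over all treatments jointly, with each treatment's changepoint supplied
#' (fixed, typically from a per-treatment [fit_broken_line()]). When
#' \code{tie_beta1} names a treatment pair, those two treatments share a
#' single pre-changepoint slope \eqn{\beta_1} (the constrained model of the
#' decay-rate equality test).
#'
#' @param y numeric vector of log counts.
#' @param times numeric vector of times (minutes).
#' @param treatments character/factor vector of treatment labels.
#' @param t0_fixed named numeric vector: changepoint (minutes) for every
#'   treatment present.
#' @param tie_beta1 optional character vector of length 2: treatments
#'   constrained to a common pre-changepoint slope.
#' @return An object of class \code{"treatment_decay_model"}: coefficient
#'   maps \code{beta0}, \code{beta1}, \code{beta2}, the fixed \code{t0},
#'   pooled \code{sigma2} (= RSS/n), \code{rss}, \code{loglik},
#'   \code{n_total}, \code{n_par}.
#' @export
fit_multi_treatment <- function(y, times, treatments, t0_fixed,
                                tie_beta1 = NULL) {
  stopifnot(length(y) == length(times), length(y) == length(treatments))
  treatments <- as.character(treatments)
  trs <- unique(treatments)
  miss <- setdiff(trs, names(t0_fixed))
  if (length(miss))
    stop("no fixed changepoint for treatment(s): ",
         paste(miss, collapse = ", "))
  for (tr in trs)
    if (sum(treatments == tr) < 4L)
      stop("treatment ", tr, " has fewer than 4 observations")
  if (!is.null(tie_beta1)) {
    if (length(tie_beta1) != 2L || !all(tie_beta1 %in% trs))
      stop("tie_beta1 must name two treatments present in the data")
  }

  cols <- list(); cnames <- character(0)
  for (tr in trs) {
    ind <- as.numeric(treatments == tr)
    cols[[length(cols) + 1L]] <- ind
    cnames <- c(cnames, paste0("b0.", tr))
    cols[[length(cols) + 1L]] <- ind * pmax(times - t0_fixed[[tr]], 0)
    cnames <- c(cnames, paste0("b2.", tr))
  }
  if (is.null(tie_beta1)) {
    for (tr in trs) {
      cols[[length(cols) + 1L]] <-
        as.numeric(treatments == tr) * pmin(times, t0_fixed[[tr]])
      cnames <- c(cnames, paste0("b1.", tr))
    }
  } else {
    shared <- rep(0, length(y))
    for (tr in tie_beta1)
      shared <- shared +
        as.numeric(treatments == tr) * pmin(times, t0_fixed[[tr]])
    cols[[length(cols) + 1L]] <- shared
    cnames <- c(cnames, paste0("b1.", paste(tie_beta1, collapse = "=")))
    for (tr in setdiff(trs, tie_beta1)) {
      cols[[length(cols) + 1L]] <-
        as.numeric(treatments == tr) * pmin(times, t0_fixed[[tr]])
      cnames <- c(cnames, paste0("b1.", tr))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- cnames
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    drop_col <- cnames[qr_$pivot[(qr_$rank + 1L):ncol(X)]][1L]
    stop("rank-deficient design (", drop_col,
         "): check the data for treatment ",
         sub("^b[012]\\.", "", drop_col))
  }
  coef <- qr.coef(qr_, y)
  res <- y - X %*% coef
  rss <- sum(res^2)
  n <- length(y)
  sigma2 <- rss / n
  loglik <- if (sigma2 > 0) -n / 2 * (log(2 * pi * sigma2) + 1) else Inf

  beta0 <- beta1 <- beta2 <- stats::setNames(numeric(length(trs)), trs)
  for (tr in trs) {
    beta0[tr] <- coef[paste0("b0.", tr)]
    beta2[tr] <- coef[paste0("b2.", tr)]
    beta1[tr] <- if (!is.null(tie_beta1) && tr %in% tie_beta1)
      coef[paste0("b1.", paste(tie_beta1, collapse = "="))]
    else coef[paste0("b1.", tr)]
  }
  structure(list(treatments = trs, beta0 = beta0, beta1 = beta1,
                 beta2 = beta2, t0 = t0_fixed[trs], sigma2 = sigma2,
                 rss = rss, loglik = loglik, n_total = n,
                 n_par = ncol(X), tie_beta1 = tie_beta1),
            class = "treatment_decay_model")
}

#' @export
print.treatment_decay_model <- function(x, ...) {
  cat(sprintf("multi-treatment decay model: n=%d, rss=%.4g%s\n", x$n_total,
              x$rss,
              if (is.null(x$tie_beta1)) "" else
                paste0(" [tied b1: ", paste(x$tie_beta1, collapse = "/"),
                       "]")))
  for (tr in x$treatments)
    cat(sprintf("  %-8s b0=%8.4f  b1=%9.5f  b2=%9.5f  t0=%6.1f\n", tr,
                x$beta0[tr], x$beta1[tr], x$beta2[tr], x$t0[tr]))
  invisible(x)
}

#' Likelihood-ratio test of decay-rate equality
#'
#' Compares the free multi-treatment model with the model in which two
#' treatments share one pre-changepoint slope (H0: the decay rates are the
#' same between the two treatments). Under the Gaussian profile likelihood
#' the statistic is \eqn{n \ln(RSS_0 / RSS_1)}, referred to a chi-square
#' distribution with 1 degree of freedom. An F-test variant
#' (\code{method = "ftest"}) refers \eqn{(RSS_0 - RSS_1) /
#' (RSS_1 / (n - p))} to \eqn{F(1, n - p)}.
#'
#' @param model_free unconstrained [fit_multi_treatment()] model.
#' @param model_tied the same model with exactly one \eqn{\beta_1}
#'   equality constraint, fit on the same data.
#' @param method \code{"lrt"} (default) or \code{"ftest"}.
#' @return An object of class \code{"lrt_result"}: \code{statistic},
#'   \code{df}, \code{p_value}, \code{null_hypothesis}.
#' @export
lrt_equal_decay <- function(model_free, model_tied,
                            method = c("lrt", "ftest")) {
  method <- match.arg(method)
  stopifnot(inherits(model_free, "treatment_decay_model"),
            inherits(model_tied, "treatment_decay_model"))
  if (model_free$n_total != model_tied$n_total)
    stop("models were not fit on the same data")
  if (model_tied$n_par != model_free$n_par - 1L)
    stop("tied model must have exactly one fewer parameter")
  n <- model_free$n_total
  if (model_tied$rss < model_free$rss * (1 - 1e-8) - 1e-12)
    stop("constrained RSS below unconstrained RSS: models are not nested")
  hyp <- paste0("beta1 equal between treatments ",
                paste(model_tied$tie_beta1, collapse = " and "))
  if (method == "lrt") {
    stat <- if (model_free$rss <= 0) 0 else
      max(0, n * log(model_tied$rss / model_free$rss))
    p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
    df <- 1L
  } else {
    df2 <- n - model_free$n_par
    stat <- max(0, (model_tied$rss - model_free$rss) /
                  (model_free$rss / df2))
    p <- stats::pf(stat, 1L, df2, lower.tail = FALSE)
    df <- 1L
  }
  structure(list(statistic = stat, df = df, p_value = p,
                 null_hypothesis = hyp, method = method),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT (%s): statistic=%.4g, df=%d, p=%.4g\n  H0: %s\n",
              x$method, x$statistic, x$df, x$p_value, x$null_hypothesis))
  invisible(x)
}

#' Half-life from a decay slope
#'
#' \eqn{t_{1/2} = \ln 2 / k} with \eqn{k = -\beta_1} the natural-log-scale
#' per-minute decay rate (the slope of the curve before the changepoint).
#' For a non-declining transcript (\eqn{k \le 0}) the half-life is
#' undefined and returned as \code{NA} with \code{reliable = FALSE}.
#'
#' @param fit a [fit_broken_line()] object, or a numeric pre-changepoint
#'   slope \eqn{\beta_1} (per minute, natural-log scale).
#' @param time_span_min optional observed time span; an estimate whose
#'   half-life exceeds the span is flagged unreliable.
#' @return List with \code{k} (per minute), \code{half_life_min} and
#'   \code{reliable}.
#' @export
half_life <- function(fit, time_span_min = NULL) {
  beta1 <- if (inherits(fit, "broken_line_fit")) fit$B else as.numeric(fit)
  k <- -beta1
  if (k > 0) {
    hl <- log(2) / k
    reliable <- is.null(time_span_min) || hl <= time_span_min
  } else {
    hl <- NA_real_
    reliable <- FALSE
  }
  list(k = k, half_life_min = hl, reliable = reliable)
}

#' Test for a slope change at the changepoint
#'
#' Two-sided t test of \eqn{B = B'} in a [fit_broken_line()] model via the
#' linear contrast \eqn{B' - B}, with the changepoint treated as fixed at
#' its estimate and \eqn{n - 4} residual degrees of freedom (three linear
#' coefficients plus the profiled changepoint).
#'
#' @param fit a [fit_broken_line()] object with \eqn{n > 4}.
#' @return List with \code{estimate} (\eqn{B' - B}), \code{t},
#'   \code{df} and \code{p_value}.
#' @export
slope_change_test <- function(fit) {
  stopifnot(inherits(fit, "broken_line_fit"))
  n <- fit$n
  if (n <= 4L) stop("slope-change test needs n > 4 observations")
  X <- cbind(1, pmin(fit$times - fit$t0, 0), pmax(fit$times - fit$t0, 0))
  XtX_inv <- chol2inv(chol(crossprod(X)))
  cvec <- c(0, -1, 1)
  s2 <- fit$rss / (n - 4L)
  se <- sqrt(s2 * drop(t(cvec) %*% XtX_inv %*% cvec))
  est <- fit$Bp - fit$B
  tstat <- if (se > 0) est / se else sign(est) * Inf
  p <- 2 * stats::pt(abs(tstat), df = n - 4L, lower.tail = FALSE)
  list(estimate = est, t = tstat, df = n - 4L, p_value = p)
}

#' Per-gene, per-treatment decay estimates
#'
#' Convenience wrapper running [fit_broken_line()] for each endogenous gene
#' within each requested treatment of the short-term experiment, then
#' deriving the decay rate, half-life, reliability flag and slope-change
#' p-value. Log-transformation uses [log_transform()].
#'
#' @param matrix a stage-\code{fully_normalized} [count_matrix()].
#' @param treatments treatments to fit (default the iron-recovery and the
#'   two transcription-inhibited arms).
#' @param genes probe ids to fit; default all endogenous probes.
#' @param experiment restrict to one experiment (default \code{"ST"}).
#' @param pseudocount passed to [log_transform()].
#' @return data.frame with columns \code{gene}, \code{treatment},
#'   \code{changepoint_min}, \code{k_per_min}, \code{half_life_min},
#'   \code{reliable}, \code{slope_change_p}, \code{slope_change_p_adj}
#'   (Benjamini-Hochberg across genes within treatment), \code{n_obs}.
#' @export
fit_decay_table <- function(matrix, treatments = c("rec", "actd", "actd_fe"),
                            genes = NULL, experiment = "ST",
                            pseudocount = 1) {
  stopifnot(inherits(matrix, "count_matrix"))
  logm <- log_transform(matrix, pseudocount)
  if (is.null(genes))
    genes <- matrix$probes$probe_id[matrix$probes$probe_class ==
                                      "endogenous"]
  smp <- matrix$samples
  out <- list()
  for (tr in treatments) {
    sel <- smp$treatment == tr & smp$experiment == experiment &
      !smp$is_reference_lane
    if (!any(sel)) next
    tt <- smp$time_min[sel]
    span <- diff(range(tt))
    rows <- lapply(genes, function(g) {
      yy <- logm[match(g, matrix$probes$probe_id), sel]
      fit <- fit_broken_line(tt, yy)
      hl <- half_life(fit, time_span_min = span)
      sc <- slope_change_test(fit)
      data.frame(gene = g, treatment = tr, changepoint_min = fit$t0,
                 k_per_min = hl$k, half_life_min = hl$half_life_min,
                 reliable = hl$reliable, slope_change_p = sc$p_value,
                 n_obs = fit$n, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$slope_change_p_adj <- stats::p.adjust(tab$slope_change_p,
                                              method = "BH")
    out[[tr]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare decay rates between two treatments for each gene
#'
#' For every gene, fixes each treatment's changepoint with
#' [fit_broken_line()], fits the free and slope-tied
#' [fit_multi_treatment()] models, and applies [lrt_equal_decay()].
#'
#' @param matrix a stage-\code{fully_normalized} [count_matrix()].
#' @param pair character vector of two treatments (e.g. \code{c("rec",
#'   "actd")}).
#' @param genes probe ids; default all endogenous probes.
#' @param experiment restrict to one experiment (default \code{"ST"}).
#' @param pseudocount passed to [log_transform()].
#' @param method passed to [lrt_equal_decay()].
#' @return data.frame with per-gene slopes in both treatments, the LRT
#'   statistic, raw and BH-adjusted p-values.
#' @export
compare_decay_rates <- function(matrix, pair, genes = NULL,
                                experiment = "ST", pseudocount = 1,
                                method = "lrt") {
  stopifnot(length(pair) == 2L)
  logm <- log_transform(matrix, pseudocount)
  if (is.null(genes))
    genes <- matrix$probes$probe_id[matrix$probes$probe_class ==
                                      "endogenous"]
  smp <- matrix$samples
  sel <- smp$treatment %in% pair & smp$experiment == experiment &
    !smp$is_reference_lane
  tt <- smp$time_min[sel]
  trt <- smp$treatment[sel]
  rows <- lapply(genes, function(g) {
    yy <- logm[match(g, matrix$probes$probe_id), sel]
    t0 <- vapply(pair, function(tr)
      fit_broken_line(tt[trt == tr], yy[trt == tr])$t0, numeric(1))
    free <- fit_multi_treatment(yy, tt, trt, t0)
    tied <- fit_multi_treatment(yy, tt, trt, t0, tie_beta1 = pair)
    lrt <- lrt_equal_decay(free, tied, method = method)
    data.frame(gene = g,
               beta1_a = unname(free$beta1[pair[1L]]),
               beta1_b = unname(free$beta1[pair[2L]]),
               treatment_a = pair[1L], treatment_b = pair[2L],
               statistic = lrt$statistic, p_value = lrt$p_value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- stats::p.adjust(tab$p_value, method = "BH")
  rownames(tab) <- NULL
  tab
}

#' Summarize half-lives across a gene panel
#'
#' Arithmetic mean of the half-lives within one treatment, with an
#' exclusion rule mirroring the presentation convention of flagging
#' long-lived outliers: estimates flagged unreliable are always dropped,
#' and genes in \code{exclude} are dropped from the average but kept in the
#' table (marked \code{excluded}).
#'
#' @param estimates data.frame from [fit_decay_table()] (one treatment).
#' @param exclude \code{"auto"} (drop only unreliable fits) or a character
#'   vector of gene names to exclude in addition.
#' @return List with the annotated \code{table}, the \code{average}
#'   half-life (minutes) over included genes, and the \code{excluded}
#'   gene names.
#' @export
summarize_half_lives <- function(estimates, exclude = "auto") {
  stopifnot(is.data.frame(estimates))
  if (length(unique(estimates$treatment)) > 1L)
    stop("summarize one treatment at a time")
  excl_genes <- if (identical(exclude, "auto")) character(0) else exclude
  tab <- estimates
  tab$excluded <- !tab$reliable | tab$gene %in% excl_genes
  keep <- !tab$excluded & is.finite(tab$half_life_min)
  if (!any(keep)) stop("no genes left after exclusions")
  list(table = tab, average = mean(tab$half_life_min[keep]),
       excluded = tab$gene[tab$excluded])
}
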