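## Downstream summaries: fold changes with Welch t-tests, Spearman
## correlation matrix with clustering order, PCA sample scores, growth
## rates from cell counts.

#' Fold changes between two sample groups
#'
#' Per endogenous gene: arithmetic group means, fold change
#' \code{group_a / group_b} (by convention iron-limited over iron-replete,
#' so induced genes have fold change > 1), a two-sided Welch (unequal
#' variance) t-test on the normalized counts, and Benjamini-Hochberg
#' adjustment across genes. Genes with a zero group mean get an undefined
#' fold change and are flagged.
#'
#' @param matrix a stage-\code{fully_normalized} [count_matrix()].
#' @param group_a,group_b character vectors of sample ids (e.g. all
#'   low-iron and all high-iron samples across both experiments), or
#'   treatment names, in which case all non-reference samples of those
#'   treatments are used.
#' @param log_scale if \code{TRUE}, the t-test is run on
#'   \code{log2(count + 1)} instead of the counts.
#' @return data.frame with \code{gene}, \code{mean_a}, \code{mean_b},
#'   \code{fold_change}, \code{log2_fc}, \code{t_statistic},
#'   \code{p_value}, \code{p_adjusted}, \code{undefined}.
#' @export
fold_change_table <- function(matrix, group_a = "low", group_b = "high",
                              log_scale = FALSE) {
  stopifnot(inherits(matrix, "count_matrix"))
  resolve <- function(g) {
    if (all(g %in% TREATMENTS))
      matrix$samples$sample_id[matrix$samples$treatment %in% g &
                                 !matrix$samples$is_reference_lane]
    else g
  }
  a <- match(resolve(group_a), matrix$samples$sample_id)
  b <- match(resolve(group_b), matrix$samples$sample_id)
  if (anyNA(a) || anyNA(b)) stop("unknown sample in group")
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  endo <- which(matrix$probes$probe_class == "endogenous")
  rows <- lapply(endo, function(i) {
    xa <- matrix$counts[i, a]
    xb <- matrix$counts[i, b]
    ma <- mean(xa); mb <- mean(xb)
    undef <- ma <= 0 || mb <= 0
    fc <- if (undef) NA_real_ else ma / mb
    ta <- if (log_scale) log2(xa + 1) else xa
    tb <- if (log_scale) log2(xb + 1) else xb
    tt <- tryCatch(stats::t.test(ta, tb, var.equal = FALSE),
                   error = function(e) NULL)
    data.frame(gene = matrix$probes$probe_id[i], mean_a = ma, mean_b = mb,
               fold_change = fc,
               log2_fc = if (undef) NA_real_ else log2(fc),
               t_statistic = if (is.null(tt)) NA_real_ else
                 unname(tt$statistic),
               p_value = if (is.null(tt)) NA_real_ else tt$p.value,
               undefined = undef, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- stats::p.adjust(tab$p_value, method = "BH")
  rownames(tab) <- NULL
  tab
}

#' Spearman correlation matrix of gene expression
#'
#' Gene-by-gene Spearman correlation of \code{log2(count + pseudocount)}
#' across samples, excluding the transcription-inhibited treatments by
#' default (their enforced global decay would dominate the correlation
#' structure) and reference-lane wells always. A hierarchical clustering
#' order (average linkage on \eqn{1 - \rho}) is returned alongside for
#' heatmap display. Constant genes have undefined correlations (NA).
#'
#' @param matrix a stage-\code{fully_normalized} [count_matrix()].
#' @param exclude_treatments treatments to drop (default
#'   \code{c("actd", "actd_fe")}).
#' @param genes probe ids; default all endogenous probes.
#' @param pseudocount offset inside the log.
#' @return List with \code{rho} (symmetric matrix, unit diagonal),
#'   \code{order} (clustering leaf order) and \code{hclust}.
#' @export
spearman_matrix <- function(matrix, exclude_treatments = c("actd",
                                                           "actd_fe"),
                            genes = NULL, pseudocount = 1) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (is.null(genes))
    genes <- matrix$probes$probe_id[matrix$probes$probe_class ==
                                      "endogenous"]
  keep <- !(matrix$samples$treatment %in% exclude_treatments) &
    !matrix$samples$is_reference_lane
  gi <- match(genes, matrix$probes$probe_id)
  logm <- log2(matrix$counts[gi, keep, drop = FALSE] + pseudocount)
  rho <- suppressWarnings(stats::cor(t(logm), method = "spearman"))
  diag(rho) <- ifelse(apply(logm, 1L, stats::sd) > 0, 1, NA_real_)
  hc <- NULL; ord <- seq_along(genes)
  ok <- !apply(is.na(rho), 1L, any)
  if (sum(ok) >= 2L) {
    hc <- stats::hclust(stats::as.dist(1 - rho[ok, ok]),
                        method = "average")
    ord <- c(which(ok)[hc$order], which(!ok))
  }
  list(rho = rho, order = ord, hclust = hc)
}

#' Squared correlation of a gene pair on log2 counts
#'
#' Both the squared Pearson and the squared Spearman correlation of
#' \code{log2(count + pseudocount)} between two genes, across the same
#' sample scope as [spearman_matrix()]. Useful for coordinated-regulation
#' summaries of co-expressed probe pairs.
#'
#' @inheritParams spearman_matrix
#' @param gene_a,gene_b probe ids.
#' @return List with \code{r2_pearson} and \code{r2_spearman}.
#' @export
pair_r2 <- function(matrix, gene_a, gene_b,
                    exclude_treatments = c("actd", "actd_fe"),
                    pseudocount = 1) {
  keep <- !(matrix$samples$treatment %in% exclude_treatments) &
    !matrix$samples$is_reference_lane
  ia <- match(gene_a, matrix$probes$probe_id)
  ib <- match(gene_b, matrix$probes$probe_id)
  if (anyNA(c(ia, ib))) stop("unknown gene")
  xa <- log2(matrix$counts[ia, keep] + pseudocount)
  xb <- log2(matrix$counts[ib, keep] + pseudocount)
  list(r2_pearson = stats::cor(xa, xb)^2,
       r2_spearman = stats::cor(xa, xb, method = "spearman")^2)
}

#' PCA sample scores
#'
#' Principal component analysis of the samples on gene-centered
#' \code{log2(count + pseudocount)} expression (samples as observations,
#' genes as variables; no scaling), excluding the transcription-inhibited
#' treatments by default and reference-lane wells always.
#'
#' @inheritParams spearman_matrix
#' @param n_components number of leading components to return scores for.
#' @return List with \code{scores} (samples x components),
#'   \code{explained_variance} (ratios over all components, summing to 1),
#'   and the retained \code{samples} metadata.
#' @export
pca_scores <- function(matrix, exclude_treatments = c("actd", "actd_fe"),
                       genes = NULL, pseudocount = 1, n_components = 2L) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (is.null(genes))
    genes <- matrix$probes$probe_id[matrix$probes$probe_class ==
                                      "endogenous"]
  keep <- !(matrix$samples$treatment %in% exclude_treatments) &
    !matrix$samples$is_reference_lane
  if (sum(keep) < 2L) stop("need >= 2 samples for PCA")
  gi <- match(genes, matrix$probes$probe_id)
  logm <- log2(matrix$counts[gi, keep, drop = FALSE] + pseudocount)
  pc <- stats::prcomp(t(logm), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained_variance = ev,
       samples = matrix$samples[keep, , drop = FALSE])
}

#' Specific growth rate from cell counts
#'
#' \eqn{\mu = ((\ln N_t - \ln N_0) / t) \times 24} per day, with
#' \eqn{N_0}, \eqn{N_t} the cell concentrations at the start and end of an
#' interval of \eqn{t} hours.
#'
#' @param n0,nt cell concentrations (cells/ml), positive.
#' @param t_hours interval length in hours, positive.
#' @return Growth rate in day^-1.
#' @export
growth_rate <- function(n0, nt, t_hours) {
  if (any(n0 <= 0) || any(nt <= 0)) stop("cell counts must be positive")
  if (any(t_hours <= 0)) stop("t_hours must be positive")
  ((log(nt) - log(n0)) / t_hours) * 24
}
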