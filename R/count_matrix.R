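#' @keywords internal
"_PACKAGE"

## Processing stages a count matrix moves through, in order. Transitions must
## be monotone (a later stage can never be followed by an earlier one).
STAGES <- c("raw", "pc_normalized", "calibrated", "attenuation_corrected",
            "fully_normalized")

PROBE_CLASSES <- c("endogenous", "positive_control", "housekeeping")
TREATMENTS <- c("high", "low", "rec", "actd", "actd_fe", "dmso", "dmso_fe")
EXPERIMENTS <- c("ST", "LT")

#' Construct a targeted-panel count matrix
#'
#' Container for a probes x samples table of nonnegative transcript counts
#' together with probe annotations, sample metadata and a processing-stage
#' tag. This is the object every normalization and modelling step operates
#' on, in the spirit of \code{edgeR}'s \code{DGEList}.
#'
#' @param counts numeric matrix, probes in rows, samples in columns. All
#'   values must be nonnegative; at stage \code{"raw"} they are counts.
#' @param probes data.frame of probe annotations with columns
#'   \code{probe_id}, \code{gene_name}, \code{probe_class} (one of
#'   \code{"endogenous"}, \code{"positive_control"}, \code{"housekeeping"}),
#'   \code{attenuated} (logical) and \code{attenuation_factor} (ratio of
#'   unattenuated to attenuated signal, 1 when not attenuated). Rows must
#'   match the rows of \code{counts}.
#' @param samples data.frame of sample metadata with columns
#'   \code{sample_id}, \code{treatment} (one of high, low, rec, actd,
#'   actd_fe, dmso, dmso_fe), \code{time_min} (minutes since the T0 addition
#'   event), \code{experiment} (\code{"ST"} or \code{"LT"}), \code{plate},
#'   \code{lane}, \code{replicate}, \code{rna_input_ng} and
#'   \code{is_reference_lane}. Rows must match the columns of \code{counts}.
#' @param stage processing stage, one of \code{"raw"}, \code{"pc_normalized"},
#'   \code{"calibrated"}, \code{"attenuation_corrected"},
#'   \code{"fully_normalized"}.
#' @param factors optional list of normalization factors already applied
#'   (audit trail); grown by the normalization functions.
#'
#' @return An object of class \code{"count_matrix"}: a list with elements
#'   \code{counts}, \code{probes}, \code{samples}, \code{stage},
#'   \code{factors}.
#' @seealso [read_count_matrix()], [normalize_pipeline()]
#' @export
count_matrix <- function(counts, probes, samples, stage = "raw",
                         factors = list()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  probes <- as.data.frame(probes)
  samples <- as.data.frame(samples)
  stage <- match.arg(stage, STAGES)

  if (nrow(probes) != nrow(counts))
    stop("probe annotation has ", nrow(probes), " rows but counts has ",
         nrow(counts))
  if (nrow(samples) != ncol(counts))
    stop("sample metadata has ", nrow(samples), " rows but counts has ",
         ncol(counts), " columns")
  if (nrow(samples) == 0L) stop("no samples")

  need_p <- c("probe_id", "gene_name", "probe_class", "attenuated",
              "attenuation_factor")
  miss <- setdiff(need_p, names(probes))
  if (length(miss))
    stop("probe annotation lacks column(s): ", paste(miss, collapse = ", "))
  need_s <- c("sample_id", "treatment", "time_min", "experiment", "plate",
              "lane", "replicate", "rna_input_ng", "is_reference_lane")
  miss <- setdiff(need_s, names(samples))
  if (length(miss))
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))

  probes$probe_id <- as.character(probes$probe_id)
  probes$attenuated <- as.logical(probes$attenuated)
  probes$attenuation_factor <- as.numeric(probes$attenuation_factor)
  samples$sample_id <- as.character(samples$sample_id)
  samples$is_reference_lane <- as.logical(samples$is_reference_lane)
  samples$time_min <- as.numeric(samples$time_min)

  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe_id: ",
         paste(unique(probes$probe_id[duplicated(probes$probe_id)]),
               collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  bad <- setdiff(probes$probe_class, PROBE_CLASSES)
  if (length(bad)) stop("unknown probe_class: ", paste(bad, collapse = ", "))
  bad <- setdiff(samples$treatment, TREATMENTS)
  if (length(bad)) stop("unknown treatment: ", paste(bad, collapse = ", "))
  bad <- setdiff(samples$experiment, EXPERIMENTS)
  if (length(bad)) stop("unknown experiment: ", paste(bad, collapse = ", "))

  if (any(!is.finite(counts)))
    stop("non-finite count values present")
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at probe ", probes$probe_id[idx[1L]],
         ", sample ", samples$sample_id[idx[2L]])
  }
  if (any(probes$attenuation_factor < 1))
    stop("attenuation_factor must be >= 1")
  if (any(!probes$attenuated & probes$attenuation_factor != 1))
    stop("attenuation_factor must be 1 for non-attenuated probes")

  rownames(counts) <- probes$probe_id
  colnames(counts) <- samples$sample_id

  structure(list(counts = counts, probes = probes, samples = samples,
                 stage = stage, factors = factors),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d probes x %d samples [stage: %s]\n",
              nrow(x$counts), ncol(x$counts), x$stage))
  cat(sprintf("  probe classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$probes$probe_class)),
                            table(x$probes$probe_class)), collapse = " ")))
  cat(sprintf("  treatments: %s\n",
              paste(unique(x$samples$treatment), collapse = " ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

## move to a later stage; enforces the monotone stage order
advance_stage <- function(x, to) {
  from_i <- match(x$stage, STAGES)
  to_i <- match(to, STAGES)
  if (is.na(to_i)) stop("unknown stage: ", to)
  if (to_i <= from_i)
    stop("cannot move stage backwards (", x$stage, " -> ", to, ")")
  x$stage <- to
  x
}

require_stage <- function(x, stage, op) {
  if (x$stage != stage)
    stop(op, " requires a stage=", stage, " matrix, got stage=", x$stage)
  invisible(x)
}

#' Subset a count matrix by probes and/or samples
#'
#' @param x a [count_matrix()].
#' @param probes,samples logical or index vectors (or probe/sample id
#'   character vectors) selecting rows/columns to keep.
#' @return A \code{count_matrix} with the selection applied; stage and factor
#'   audit are carried over.
#' @export
subset_counts <- function(x, probes = NULL, samples = NULL) {
  pi <- seq_len(nrow(x$counts))
  si <- seq_len(ncol(x$counts))
  if (!is.null(probes)) {
    pi <- if (is.character(probes)) match(probes, x$probes$probe_id) else
      pi[probes]
    if (anyNA(pi)) stop("unknown probe in selection")
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$samples$sample_id) else
      si[samples]
    if (anyNA(si)) stop("unknown sample in selection")
  }
  count_matrix(x$counts[pi, si, drop = FALSE], x$probes[pi, , drop = FALSE],
               x$samples[si, , drop = FALSE], stage = x$stage,
               factors = x$factors)
}

## columns that carry biological observations (reference-lane wells are
## retained in the object but excluded from analyses)
biological_samples <- function(x) !x$samples$is_reference_lane

## delimiter sniffing: supplementary tables are spreadsheet exports that may
## be comma- or tab-delimited; decimal point only
sniff_sep <- function(path) {
  lines <- readLines(path, n = 10L)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("no content in ", path)
  header <- lines[[1L]]
  if (lengths(regmatches(header, gregexpr("\t", header))) >=
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

read_table_auto <- function(path) {
  sep <- sniff_sep(path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  nfield <- lengths(strsplit(body, sep, fixed = TRUE))
  if (length(unique(nfield)) > 1L)
    stop("ragged rows in ", path, ": field counts ",
         paste(unique(nfield), collapse = "/"))
  utils::read.table(text = body, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA)
}

#' Read a raw count matrix with its annotations
#'
#' Reads a delimited text count table (probe IDs in the first column, sample
#' IDs as the header row), a probe-annotation table and a sample-metadata
#' table, and assembles a stage-\code{raw} [count_matrix()]. The delimiter
#' (comma or tab) is auto-detected per file. Row and column order is
#' preserved from the count file; annotation rows are matched by id.
#'
#' @param path count table file.
#' @param probe_annotation_path CSV/TSV with the [count_matrix()] probe
#'   annotation columns.
#' @param metadata_path CSV/TSV with the [count_matrix()] sample metadata
#'   columns.
#' @return A stage-\code{raw} \code{count_matrix}.
#' @export
read_count_matrix <- function(path, probe_annotation_path, metadata_path) {
  for (p in c(path, probe_annotation_path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p)

  tab <- read_table_auto(path)
  probe_ids <- as.character(tab[[1L]])
  sample_ids <- colnames(tab)[-1L]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1L, drop = FALSE], 2L,
                                              as.numeric))), arr.ind = TRUE)
    if (length(bad))
      stop("non-numeric count at probe ", probe_ids[bad[1L, 1L]],
           ", sample ", sample_ids[bad[1L, 2L]])
    storage.mode(vals) <- "double"
  }
  neg <- which(vals < 0, arr.ind = TRUE)
  if (length(neg))
    stop("negative count at probe ", probe_ids[neg[1L, 1L]],
         ", sample ", sample_ids[neg[1L, 2L]])
  if (anyDuplicated(probe_ids))
    stop("duplicate probe_id in ", path, ": ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))

  probes <- read_table_auto(probe_annotation_path)
  samples <- read_table_auto(metadata_path)
  miss <- setdiff(probe_ids, as.character(probes$probe_id))
  if (length(miss))
    stop("probe(s) missing from annotation: ", paste(miss, collapse = ", "))
  miss <- setdiff(sample_ids, as.character(samples$sample_id))
  if (length(miss))
    stop("sample(s) missing from metadata: ", paste(miss, collapse = ", "))

  probes <- probes[match(probe_ids, as.character(probes$probe_id)), ,
                   drop = FALSE]
  samples <- samples[match(sample_ids, as.character(samples$sample_id)), ,
                     drop = FALSE]
  rownames(probes) <- NULL
  rownames(samples) <- NULL

  stage <- "raw"
  first <- readLines(path, n = 1L)
  if (startsWith(first, "# stage:")) {
    st <- trimws(sub("# stage:", "", first, fixed = TRUE))
    if (st %in% STAGES) stage <- st
  }
  count_matrix(vals, probes, samples, stage = stage)
}

#' Write a count matrix to delimited text
#'
#' Writes the count table with a `# stage:` annotation comment line so the
#' processing stage survives a round trip. Values are written at full double
#' precision; \code{read_count_matrix(write_counts(x))} is the identity on
#' values.
#'
#' @param matrix a [count_matrix()].
#' @param path output file.
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(matrix, path, sep = ",") {
  stopifnot(inherits(matrix, "count_matrix"))
  if (ncol(matrix$counts) == 0L) stop("no samples")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# stage: ", matrix$stage), con)
  writeLines(paste(c("probe_id", matrix$samples$sample_id), collapse = sep),
             con)
  vals <- matrix$counts
  for (i in seq_len(nrow(vals))) {
    writeLines(paste(c(matrix$probes$probe_id[i],
                       sprintf("%.17g", vals[i, ])), collapse = sep), con)
  }
  invisible(path)
}

#' Write probe annotations and sample metadata
#'
#' Companion writers so a simulated or processed dataset can be re-read with
#' [read_count_matrix()].
#'
#' @param matrix a [count_matrix()].
#' @param probe_path,metadata_path output CSV files.
#' @return A character vector of the written paths, invisibly.
#' @export
write_annotations <- function(matrix, probe_path, metadata_path) {
  utils::write.csv(matrix$probes, probe_path, row.names = FALSE)
  utils::write.csv(matrix$samples, metadata_path, row.names = FALSE)
  invisible(c(probe_path, metadata_path))
}
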