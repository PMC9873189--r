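# Fixtures are built in code: a hand-sized count matrix with a full
# metadata complement, and writers for temp-file round trips.

toy_probes <- function() {
  data.frame(
    probe_id = c("G1", "G2", "G3", "HK", "PC1", "PC2", "PC3"),
    gene_name = c("G1", "G2", "G3", "HK", "PC1", "PC2", "PC3"),
    probe_class = c("endogenous", "endogenous", "endogenous",
                    "housekeeping", rep("positive_control", 3)),
    attenuated = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    attenuation_factor = c(10, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

toy_samples <- function(n = 4, treatment = "low", plate = "P1",
                        time_min = 0) {
  data.frame(
    sample_id = paste0("S", seq_len(n)),
    treatment = rep_len(treatment, n),
    time_min = rep_len(time_min, n),
    experiment = "ST",
    plate = rep_len(plate, n),
    lane = paste0(rep_len(plate, n), "_L", seq_len(n)),
    replicate = seq_len(n),
    rna_input_ng = 70,
    is_reference_lane = FALSE,
    stringsAsFactors = FALSE)
}

toy_matrix <- function(counts = NULL, n = 4, ...) {
  probes <- toy_probes()
  samples <- toy_samples(n = n, ...)
  if (is.null(counts)) {
    set.seed(42)
    counts <- matrix(round(runif(nrow(probes) * n, 50, 500)),
                     nrow(probes), n)
  }
  count_matrix(counts, probes, samples)
}

# write a count_matrix trio to a temp dir, returning the three paths
write_fixture_files <- function(m, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  cf <- file.path(dir, "counts.csv")
  pf <- file.path(dir, "probes.csv")
  mf <- file.path(dir, "meta.csv")
  write_counts(m, cf)
  write_annotations(m, pf, mf)
  list(counts = cf, probes = pf, meta = mf)
}

# two-group fixture with gene G1 carrying the signal
fc_fixture <- function(low_vals, high_vals) {
  n <- length(low_vals) + length(high_vals)
  counts <- matrix(100, 7, n)
  counts[1, ] <- c(low_vals, high_vals)
  m <- toy_matrix(counts = counts, n = n)
  m$samples$treatment <- rep(c("low", "high"),
                             c(length(low_vals), length(high_vals)))
  m$stage <- "fully_normalized"
  m
}

# random valid count matrix for round-trip properties
random_matrix <- function(seed) {
  set.seed(seed)
  n <- sample(2:6, 1)
  counts <- matrix(round(exp(rnorm(7 * n, 5, 2)), 3), 7, n)
  toy_matrix(counts = counts, n = n)
}
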