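# Shared fixture builders for the test suite.

# Long reporter table for a single protein from per-channel PSM vectors.
toy_reporter_row <- function(protein_id, psm, replicate = "rep1",
                             timepoints = c(0, 2, 4, 8, 16, 32),
                             values = NULL) {
  if (is.null(values)) values <- exp(-0.3 * timepoints)
  data.frame(protein_id = protein_id, replicate = replicate,
             channel = seq_along(timepoints), timepoint_days = timepoints,
             reporter_sn = 100 * values, psm_count = psm,
             stringsAsFactors = FALSE)
}

# Noiseless mono/di spectrum pair from pool parameters.
toy_spectra <- function(r, f_new, p_lab) {
  n <- length(p_lab)
  pool_pi <- precursor_distribution(r, p_lab)
  mono <- (1 - f_new) * c(1, numeric(n)) + f_new * pool_pi
  di <- (1 - f_new) * c(1, numeric(2 * n)) +
    f_new * predict_dinucleotide(pool_pi)
  list(mono = mono, di = di)
}

# Brute-force maximal-run finder used as the IDR oracle.
idr_oracle <- function(scores, threshold = 0.5, min_len = 40) {
  spans <- list()
  i <- 1
  n <- length(scores)
  while (i <= n) {
    if (scores[i] > threshold) {
      j <- i
      while (j < n && scores[j + 1] > threshold) j <- j + 1
      if (j - i + 1 >= min_len) spans[[length(spans) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(spans)) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, spans)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

# Henderson-Hasselbalch net charge with the EMBOSS pKa set (test-side
# reimplementation used as the pI grid-scan oracle).
charge_oracle <- function(seq, pH) {
  res <- strsplit(toupper(seq), "")[[1]]
  cnt <- function(a) sum(res == a)
  pos_pka <- c(8.6, rep(10.8, cnt("K")), rep(12.5, cnt("R")),
               rep(6.5, cnt("H")))
  neg_pka <- c(3.6, rep(3.9, cnt("D")), rep(4.1, cnt("E")),
               rep(8.5, cnt("C")), rep(10.1, cnt("Y")))
  sum(1 / (1 + 10^(pH - pos_pka))) - sum(1 / (1 + 10^(neg_pka - pH)))
}

pi_grid_oracle <- function(seq, step = 0.001) {
  grid <- seq(0, 14, by = step)
  q <- vapply(grid, function(p) charge_oracle(seq, p), numeric(1))
  grid[which.min(abs(q))]
}

random_aa_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
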