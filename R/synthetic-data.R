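#' Ground-truth simulators for labeling time courses
#'
#' Forward models of the two data streams the analysis consumes: (a) TMT
#' reporter time courses in which the unlabeled signal of each protein decays
#' as `baseline + (1 - baseline) * exp(-k_t * t)` with multiplicative
#' log-normal reporter noise (signal-to-noise-based reporter quantification
#' has roughly constant CV), and (b) genomic-DNA mono-/dinucleotide
#' isotopologue spectra generated from an old/new strand mixture with a
#' partially labeled precursor pool, a recycled-unlabeled fraction, and
#' natural-isotope convolution. Every generator records a truth manifest and
#' is byte-reproducible for a given seed.
#'
#' @name synthetic-data
NULL

#' Configuration for the proteome time-course simulator
#'
#' The default design mirrors a 6-timepoint, 32-day labeling study with three
#' replicates. Degradation rates are log-normal; a `dilution_fraction` of the
#' proteins can be made division-dominated (k_deg = 0, cleared purely by
#' dilution), as observed for cell-surface/ECM proteins in highly
#' proliferative tissue.
#'
#' @param n_proteins Number of proteins.
#' @param k_deg_meanlog,k_deg_sdlog Log-normal parameters of k_deg (1/day).
#' @param k_div Cell-division rate (1/day).
#' @param dilution_fraction Fraction of proteins with k_deg = 0.
#' @param baseline_max Baselines drawn uniform on [0, baseline_max].
#' @param noise_sigma SD of multiplicative log-normal reporter noise.
#' @param timepoints Days.
#' @param n_replicates Replicates.
#' @param psm_min,psm_lambda PSM count per channel is
#'   `psm_min + rpois(psm_lambda)`.
#' @param seed Integer seed (mandatory).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 200, k_deg_meanlog = log(0.2),
                       k_deg_sdlog = 0.8, k_div = 0, dilution_fraction = 0,
                       baseline_max = 0.1, noise_sigma = 0.05,
                       timepoints = c(0, 2, 4, 8, 16, 32), n_replicates = 3,
                       psm_min = 3, psm_lambda = 5, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_proteins >= 1, k_div >= 0, dilution_fraction >= 0,
            dilution_fraction <= 1, noise_sigma >= 0, baseline_max >= 0,
            baseline_max < 1, 0 %in% timepoints)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a TMT reporter time course
#'
#' @param cfg A [sim_config()].
#' @return List with `table` (long reporter table, see
#'   [read_reporter_table()]) and `truth` (per-protein `k_deg`, `k_div`,
#'   `k_t`, `baseline`, `division_dominated`); the config is attached as
#'   attribute `config`.
#' @export
simulate_proteome_timecourse <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  ids <- sprintf("P%05d", seq_len(n))
  n_dil <- round(cfg$dilution_fraction * n)
  k_deg <- c(rep(0, n_dil),
             stats::rlnorm(n - n_dil, cfg$k_deg_meanlog, cfg$k_deg_sdlog))
  baseline <- stats::runif(n, 0, cfg$baseline_max)
  k_t <- k_deg + cfg$k_div
  if (any(k_t <= 0)) {
    stop("every protein needs k_t > 0; set k_div > 0 or dilution_fraction = 0")
  }

  rows <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    # per-protein reporter amplitude at t0 (arbitrary scale)
    amp <- stats::rlnorm(n, log(100), 0.5)
    chunk <- expand.grid(protein_id = ids, channel = seq_along(cfg$timepoints),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tp <- cfg$timepoints[chunk$channel]
    trace <- baseline[match(chunk$protein_id, ids)] +
      (1 - baseline[match(chunk$protein_id, ids)]) *
      exp(-k_t[match(chunk$protein_id, ids)] * tp)
    noise <- if (cfg$noise_sigma > 0) {
      exp(stats::rnorm(nrow(chunk), 0, cfg$noise_sigma))
    } else 1
    chunk$replicate <- sprintf("rep%d", r)
    chunk$timepoint_days <- tp
    chunk$reporter_sn <- amp[match(chunk$protein_id, ids)] * trace * noise
    chunk$psm_count <- cfg$psm_min + stats::rpois(nrow(chunk),
                                                  cfg$psm_lambda)
    rows[[r]] <- chunk
  }
  table <- do.call(rbind, rows)
  table <- table[, c("protein_id", "replicate", "channel", "timepoint_days",
                     "reporter_sn", "psm_count")]
  rownames(table) <- NULL
  truth <- data.frame(protein_id = ids, k_deg = k_deg, k_div = cfg$k_div,
                      k_t = k_t, baseline = baseline,
                      division_dominated = k_t <= cfg$k_div,
                      stringsAsFactors = FALSE)
  structure(list(table = table, truth = truth), config = cfg)
}

#' Configuration for the DNA labeling simulator
#'
#' The precursor pool's labeled-species distribution is binomial over a
#' base's nitrogen sites at the precursor relative isotope abundance (RIA),
#' truncated to m >= 1; the RIA rises over the course of labeling as the
#' dietary label equilibrates, `ria(t) = ria_asym * (1 - exp(-t / ria_tau))`.
#' A fraction `r` of nucleotides in new strands is recycled and fully
#' unlabeled (empirically small).
#'
#' @param k_div Cell-division rate (1/day).
#' @param r Recycled-unlabeled fraction: scalar or one value per timepoint.
#' @param ria_asym,ria_tau Precursor RIA schedule parameters.
#' @param a15N Natural 15N abundance applied in the forward convolution.
#' @param noise_sigma SD of multiplicative log-normal intensity noise.
#' @param timepoints Days.
#' @param n_replicates Replicates per timepoint.
#' @param bases Bases simulated (homodimers for the di unit).
#' @param seed Integer seed (mandatory).
#' @return List of class `dna_sim_config`.
#' @export
dna_sim_config <- function(k_div, r = 0.02, ria_asym = 0.95, ria_tau = 2,
                           a15N = 0.00364, noise_sigma = 0.01,
                           timepoints = c(0, 2, 4, 8, 16, 32),
                           n_replicates = 3,
                           bases = c("dA", "dC", "dG", "dT"), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(k_div >= 0, all(r >= 0), all(r <= 1), noise_sigma >= 0,
            length(r) %in% c(1, length(timepoints)))
  structure(as.list(environment()), class = "dna_sim_config")
}

#' Simulate genomic-DNA isotopologue spectra
#'
#' For each base, timepoint, and replicate: the new-strand fraction is
#' `f_new(t) = 1 - exp(-k_div * t)`; the mono spectrum is
#' `(1 - f_new) * delta0 + f_new * pi` and the homodimer spectrum
#' `(1 - f_new) * delta0 + f_new * (pi (*) pi)`, with pi the precursor
#' distribution at that timepoint. Both are then forward-convolved with the
#' natural 15N envelope and perturbed by multiplicative noise.
#'
#' @param cfg A [dna_sim_config()].
#' @return List with `spectra` (long table: `tissue`, `timepoint_days`,
#'   `base`, `unit`, `replicate`, `m_shift`, `intensity`) and `truth`
#'   (`k_div`, per-timepoint `f_new`, `r`, `ria`); config attached as
#'   attribute.
#' @param tissue Tissue label stamped on the output.
#' @export
simulate_dna_labeling <- function(cfg, tissue = "tissue1") {
  stopifnot(inherits(cfg, "dna_sim_config"))
  set.seed(cfg$seed)
  r_sched <- if (length(cfg$r) == 1) rep(cfg$r, length(cfg$timepoints)) else
    cfg$r
  rows <- list()
  truth_rows <- list()
  for (i in seq_along(cfg$timepoints)) {
    tp <- cfg$timepoints[i]
    f_new <- 1 - exp(-cfg$k_div * tp)
    ria <- cfg$ria_asym * (1 - exp(-tp / cfg$ria_tau))
    truth_rows[[i]] <- data.frame(tissue = tissue, timepoint_days = tp,
                                  f_new = f_new, r = r_sched[i], ria = ria)
    for (b in cfg$bases) {
      nN <- n_nitrogen(b)
      p_lab <- stats::dbinom(1:nN, nN, max(ria, 1e-12))
      p_lab <- p_lab / sum(p_lab)
      pool_pi <- precursor_distribution(r_sched[i], p_lab)
      delta_mono <- c(1, numeric(nN))
      delta_di <- c(1, numeric(2 * nN))
      mono <- (1 - f_new) * delta_mono + f_new * pool_pi
      di <- (1 - f_new) * delta_di + f_new * predict_dinucleotide(pool_pi)
      mono <- natural_abundance_convolve(mono, cfg$a15N)
      di <- natural_abundance_convolve(di, cfg$a15N)
      for (rp in seq_len(cfg$n_replicates)) {
        noise_m <- if (cfg$noise_sigma > 0) {
          exp(stats::rnorm(length(mono), 0, cfg$noise_sigma))
        } else 1
        noise_d <- if (cfg$noise_sigma > 0) {
          exp(stats::rnorm(length(di), 0, cfg$noise_sigma))
        } else 1
        rows[[length(rows) + 1]] <- data.frame(
          tissue = tissue, timepoint_days = tp, base = b,
          unit = rep(c("mono", "di"), c(length(mono), length(di))),
          replicate = rp,
          m_shift = c(seq_along(mono), seq_along(di)) - 1L,
          intensity = c(mono * noise_m, di * noise_d),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(
    list(spectra = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))),
    config = cfg)
}

#' Reference tissue profiles for the four-tissue study design
#'
#' Study conditions of the labeled-mouse design: cell doubling times of 3
#' (large intestine), 51 (liver), 78 (white adipose) and 118 (heart) days,
#' median protein half-lives of 1.7, 2.4, 6.1 and 5.7 days, and a 15%
#' division-dominated fraction in the proliferative intestine. The log-normal
#' `k_deg_meanlog` is derived from the target median so that the simulated
#' median observed half-life matches the profile.
#'
#' @param k_deg_sdlog Log-normal spread of k_deg (default 0.8, about one
#'   order of magnitude across the proteome's interquartile span).
#' @return Data.frame with one row per tissue: `tissue`, `doubling_days`,
#'   `median_t_half`, `dilution_fraction`, `k_div`, `k_deg_meanlog`,
#'   `k_deg_sdlog`.
#' @export
tissue_profiles <- function(k_deg_sdlog = 0.8) {
  prof <- data.frame(
    tissue = c("intestine", "liver", "fat", "heart"),
    doubling_days = c(3, 51, 78, 118),
    median_t_half = c(1.7, 2.4, 6.1, 5.7),
    dilution_fraction = c(0.15, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  prof$k_div <- log(2) / prof$doubling_days
  target_median_kdeg <- log(2) / prof$median_t_half - prof$k_div
  if (any(target_median_kdeg <= 0)) stop("inconsistent tissue profile")
  # with a point mass of dilution-dominated proteins below the median, the
  # median of the mixture sits at quantile (0.5 - f) / (1 - f) of the
  # log-normal component
  q <- (0.5 - prof$dilution_fraction) / (1 - prof$dilution_fraction)
  prof$k_deg_meanlog <- log(target_median_kdeg) -
    k_deg_sdlog * stats::qnorm(q)
  prof$k_deg_sdlog <- k_deg_sdlog
  prof
}

#' Simulate correlated degradation rates across tissues
#'
#' Shared proteins receive correlated k_deg values across tissues: each
#' protein carries a latent quantile applied to every tissue's log-normal
#' rate distribution, then jittered by a log-normal cross-tissue spread.
#' Designated coherent complexes share a latent quantile among their
#' subunits with a small within-complex spread, giving low intracomplex
#' dispersion.
#'
#' @param tissues Data.frame like [tissue_profiles()] (columns `tissue`,
#'   `k_div`, `k_deg_meanlog`, `k_deg_sdlog`).
#' @param n_proteins Number of shared proteins.
#' @param cross_tissue_spread SD (log scale) of the per-tissue jitter; 0
#'   gives identical rates across tissues when the tissue distributions are
#'   identical.
#' @param n_complexes Number of coherent complexes.
#' @param subunits_per_complex Subunits per complex.
#' @param within_complex_spread SD (log scale) of subunit jitter around the
#'   complex rate.
#' @param seed Integer seed.
#' @return List with `rates` (`protein_id`, `tissue`, `k_deg`, `k_t`),
#'   `complexes` (`complex_id`, `protein_id`), and `truth` (per-protein
#'   cross-tissue dispersion `D` of the generated k_deg values).
#' @export
simulate_multi_tissue <- function(tissues, n_proteins = 500,
                                  cross_tissue_spread = 0.2,
                                  n_complexes = 10, subunits_per_complex = 6,
                                  within_complex_spread = 0.05, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(nrow(tissues) >= 2,
            all(c("tissue", "k_div", "k_deg_meanlog", "k_deg_sdlog") %in%
                  names(tissues)))
  set.seed(seed)
  ids <- sprintf("P%05d", seq_len(n_proteins))
  u <- stats::runif(n_proteins)

  # coherent complexes occupy the leading block of proteins
  n_cx_prot <- n_complexes * subunits_per_complex
  if (n_cx_prot > n_proteins) stop("not enough proteins for the complexes")
  complexes <- data.frame(
    complex_id = rep(sprintf("C%03d", seq_len(n_complexes)),
                     each = subunits_per_complex),
    protein_id = ids[seq_len(n_cx_prot)], stringsAsFactors = FALSE)
  u_complex <- stats::runif(n_complexes)
  u[seq_len(n_cx_prot)] <- rep(u_complex, each = subunits_per_complex)

  rates <- list()
  for (i in seq_len(nrow(tissues))) {
    base <- stats::qlnorm(u, tissues$k_deg_meanlog[i],
                          tissues$k_deg_sdlog[i])
    jitter <- if (cross_tissue_spread > 0) {
      exp(stats::rnorm(n_proteins, 0, cross_tissue_spread))
    } else 1
    cx_jitter <- rep(1, n_proteins)
    if (within_complex_spread > 0 && n_cx_prot > 0) {
      cx_jitter[seq_len(n_cx_prot)] <-
        exp(stats::rnorm(n_cx_prot, 0, within_complex_spread))
    }
    # complex subunits use the within-complex jitter instead of the free
    # cross-tissue jitter, keeping them coherent within each tissue
    j <- jitter
    if (n_cx_prot > 0) {
      if (length(j) == 1) j <- rep(j, n_proteins)
      j[seq_len(n_cx_prot)] <- cx_jitter[seq_len(n_cx_prot)]
    }
    k_deg <- base * j
    rates[[i]] <- data.frame(protein_id = ids, tissue = tissues$tissue[i],
                             k_deg = k_deg, k_t = k_deg + tissues$k_div[i],
                             stringsAsFactors = FALSE)
  }
  rates <- do.call(rbind, c(rates, list(make.row.names = FALSE)))

  truth_D <- vapply(ids, function(pid) {
    k <- rates$k_deg[rates$protein_id == pid]
    m <- mean(k)
    if (m <= 0) return(NA_real_)
    sum((k - m)^2) / length(k) / m
  }, numeric(1))
  list(rates = rates, complexes = complexes,
       truth = data.frame(protein_id = ids, D = as.numeric(truth_D),
                          stringsAsFactors = FALSE))
}
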