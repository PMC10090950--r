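#' Cell-division rate from genomic-DNA isotopologue spectra
#'
#' Nitrogen-15 labeling of replicating DNA shifts the isotopologue
#' distribution of mono- and dinucleotides digested from genomic DNA. New
#' strands draw nucleotides from a precursor pool that mixes fully and
#' partially labeled species with a fraction `r` of recycled, fully unlabeled
#' nucleotides. Because adjacent nucleotides on one strand were synthesized
#' together, the dinucleotide labeling pattern is the self-convolution of the
#' precursor distribution; this separates old strands from new strands that
#' contain recycled unlabeled nucleotides, which the mononucleotide spectrum
#' alone cannot do.
#'
#' @name dna-turnover
NULL

#' Nitrogen atom counts of the deoxyribonucleosides
#'
#' The deoxyribose contributes no nitrogen: dA and dG carry 5 nitrogens
#' (purines), dC carries 3, dT carries 2.
#'
#' @param base One of "dA", "dC", "dG", "dT".
#' @return Integer nitrogen count.
#' @export
n_nitrogen <- function(base) {
  counts <- c(dA = 5L, dC = 3L, dG = 5L, dT = 2L)
  if (any(!base %in% names(counts))) {
    stop("unknown base: ", paste(setdiff(base, names(counts)), collapse = ", "))
  }
  unname(counts[base])
}

# forward natural-abundance mixing matrix for n_sites nitrogen positions:
# a molecule with true shift j is observed at shift i >= j with probability
# dbinom(i - j, n_sites - j, a15N)
.na_matrix <- function(n_sites, a15N) {
  m <- matrix(0, n_sites + 1, n_sites + 1)
  for (j in 0:n_sites) {
    m[(j:n_sites) + 1, j + 1] <- stats::dbinom(0:(n_sites - j), n_sites - j,
                                               a15N)
  }
  m
}

#' Convolve a spectrum with the natural 15N envelope (forward model)
#'
#' @param intensities Vector over shifts m = 0..N.
#' @param a15N Natural 15N abundance (default 0.00364).
#' @return Vector of the same length.
#' @export
natural_abundance_convolve <- function(intensities, a15N = 0.00364) {
  n_sites <- length(intensities) - 1
  as.numeric(.na_matrix(n_sites, a15N) %*% intensities)
}

#' Deconvolve the natural-isotope envelope from an isotopologue spectrum
#'
#' Each of the molecule's nitrogen sites not already metabolically labeled is
#' naturally heavy with probability `a15N`, which smears intensity upward in
#' mass. The mixing system is lower-triangular and is solved exactly by
#' forward substitution; small negative artifacts from noise are clamped to
#' zero and the spectrum renormalized.
#'
#' @param intensities Vector over shifts m = 0..N (N = number of nitrogen
#'   sites: `n_nitrogen(base)` for mononucleosides, twice that for
#'   homodimeric dinucleotides).
#' @param a15N Natural 15N abundance in [0, 0.05]; 0 is the identity.
#' @return Corrected spectrum, normalized to sum 1 (if input has mass).
#' @export
natural_abundance_correct <- function(intensities, a15N = 0.00364) {
  if (length(a15N) != 1 || !is.finite(a15N) || a15N < 0 || a15N > 0.05) {
    stop("a15N must be a single value in [0, 0.05]")
  }
  if (any(!is.finite(intensities)) || length(intensities) < 2) {
    stop("intensities must be a finite vector over m = 0..N")
  }
  if (a15N == 0) return(intensities)
  n_sites <- length(intensities) - 1
  corrected <- forwardsolve(.na_matrix(n_sites, a15N), intensities)
  corrected[corrected < 0] <- 0
  s <- sum(corrected)
  if (s > 0) corrected <- corrected / s * sum(intensities)
  corrected
}

#' Precursor-pool distribution over labeling shifts
#'
#' @param r Recycled (fully unlabeled) fraction of the pool, in [0, 1].
#' @param p_lab Distribution over labeled shifts m = 1..N (sums to 1).
#' @return Vector pi over m = 0..N with pi[1] = r, pi[m + 1] = (1 - r) *
#'   p_lab[m].
#' @export
precursor_distribution <- function(r, p_lab) {
  if (!is.finite(r) || r < 0 || r > 1) stop("r must be in [0, 1]")
  if (any(p_lab < 0)) stop("p_lab must be non-negative")
  s <- sum(p_lab)
  if (abs(s - 1) > 1e-6 && s > 0) p_lab <- p_lab / s
  c(r, (1 - r) * p_lab)
}

#' Predicted dinucleotide labeling distribution of newly made strands
#'
#' Two adjacent nucleotides of a new strand are drawn independently from the
#' precursor pool, so the dinucleotide shift distribution is the
#' self-convolution of the per-position precursor distribution.
#'
#' @param pool_pi Precursor distribution over m = 0..N
#'   (see [precursor_distribution()]).
#' @return Distribution over m = 0..2N.
#' @export
predict_dinucleotide <- function(pool_pi) {
  n <- length(pool_pi)
  out <- numeric(2 * n - 1)
  for (i in seq_len(n)) {
    out[i:(i + n - 1)] <- out[i:(i + n - 1)] + pool_pi[i] * pool_pi
  }
  out
}

#' Estimate the precursor pool and new-strand fraction at one timepoint
#'
#' Model: the mononucleoside spectrum is
#' `M = (1 - f_new) * delta0 + f_new * pi` and the homodimer dinucleotide
#' spectrum is `O = (1 - f_new) * delta0 + f_new * (pi (*) pi)`, with
#' `pi(0) = r` (recycled unlabeled nucleotides in new strands) and
#' `pi(m >= 1) = (1 - r) * p_lab(m)`. `p_lab` is taken as the renormalized
#' labeled peaks of the mono spectrum. `r` is estimated by least squares on
#' the dinucleotide envelope over a coarse grid (step 0.01) with local
#' refinement; at each candidate `r` the optimal `f_new` is the exact linear
#' least-squares solution, since the model is linear in `f_new`.
#'
#' @param mono Natural-abundance-corrected mono spectrum (m = 0..N),
#'   normalized or raw (the estimate is scale-invariant).
#' @param di Corrected dinucleotide spectrum (m = 0..2N), same base.
#' @return List of class `precursor_pool`: `r`, `f_new`, `p_lab`, `pi`,
#'   `residual`, `identifiable`.
#' @export
estimate_pool <- function(mono, di) {
  n_sites <- length(mono) - 1
  if (length(di) != 2 * n_sites + 1) {
    stop("di spectrum must have length 2*N + 1 for a mono spectrum over 0..N")
  }
  if (sum(mono) <= 0 || sum(di) <= 0) stop("spectra must have positive mass")
  mono <- mono / sum(mono)
  di <- di / sum(di)

  labeled_mass <- sum(mono[-1])
  if (labeled_mass <= 0) {
    return(structure(
      list(r = NA_real_, f_new = 0, p_lab = rep(NA_real_, n_sites),
           pi = NULL, residual = 0, identifiable = FALSE),
      class = "precursor_pool"
    ))
  }
  p_lab <- mono[-1] / labeled_mass

  delta0 <- c(1, numeric(2 * n_sites))
  # profile f_new: O = delta0 + f * (conv(pi) - delta0)
  obj <- function(r) {
    conv <- predict_dinucleotide(precursor_distribution(r, p_lab))
    d <- conv - delta0
    denom <- sum(d^2)
    f <- if (denom > 0) sum((di - delta0) * d) / denom else 0
    f <- min(max(f, 0), 1)
    list(f = f, ss = sum((delta0 + f * d - di)^2))
  }
  grid <- seq(0, 0.99, by = 0.01)
  ss <- vapply(grid, function(r) obj(r)$ss, numeric(1))
  r0 <- grid[which.min(ss)]
  opt <- stats::optimize(function(r) obj(r)$ss,
                         interval = c(max(0, r0 - 0.01), min(1, r0 + 0.01)),
                         tol = 1e-8)
  r_hat <- opt$minimum
  # keep the exact boundary when it is at least as good (optimize() never
  # evaluates the interval endpoints themselves)
  if (obj(r0)$ss <= opt$objective) r_hat <- r0
  sol <- obj(r_hat)
  structure(
    list(r = r_hat, f_new = sol$f, p_lab = p_lab,
         pi = precursor_distribution(r_hat, p_lab),
         residual = sol$ss, identifiable = TRUE),
    class = "precursor_pool"
  )
}

#' Fraction of newly synthesized strands from a fitted precursor pool
#'
#' @param pool A `precursor_pool` from [estimate_pool()].
#' @return `f_new`, with attribute `identifiable`.
#' @export
fraction_new_strands <- function(pool) {
  stopifnot(inherits(pool, "precursor_pool"))
  structure(pool$f_new, identifiable = pool$identifiable)
}

#' Fraction of new strands implied by a mono spectrum alone, assuming r = 0
#'
#' When new strands contain no recycled unlabeled nucleotides, the labeled
#' (non-monoisotopic) mass of the corrected mono spectrum equals the fraction
#' of new strands directly.
#'
#' @param mono Corrected mono spectrum.
#' @return Labeled mass fraction.
#' @export
mono_fraction_new <- function(mono) {
  if (sum(mono) <= 0) stop("spectrum must have positive mass")
  sum(mono[-1]) / sum(mono)
}

#' Fit the cell-division rate from aggregated new-strand fractions
#'
#' All (base, unit, timepoint, replicate) observations are pooled with equal
#' weight and `fraction_new(t) = 1 - exp(-k_div * t)` is fit by least
#' squares. The doubling time is `log(2) / k_div`.
#'
#' @param timepoints Days.
#' @param fraction_new Observed new-strand fractions in [0, 1].
#' @return List of class `division_fit`: `k_div`, `se`, `doubling_time`,
#'   `n_observations`, `flag` ("ok" or "no_signal").
#' @export
fit_kdiv <- function(timepoints, fraction_new) {
  stopifnot(length(timepoints) == length(fraction_new))
  ok <- is.finite(timepoints) & is.finite(fraction_new)
  timepoints <- timepoints[ok]
  fraction_new <- fraction_new[ok]
  if (length(unique(timepoints)) < 3) {
    stop("fitting k_div requires at least 3 distinct timepoints")
  }
  if (any(fraction_new < -0.05) || any(fraction_new > 1.05)) {
    stop("fraction_new values must lie in [0, 1] (small overshoot tolerated)")
  }
  if (all(fraction_new[timepoints > 0] < 1e-4)) {
    return(structure(list(k_div = 0, se = Inf, doubling_time = Inf,
                          n_observations = length(timepoints),
                          flag = "no_signal"),
                     class = "division_fit"))
  }
  # start from log-linear decay of the unlabeled fraction
  u <- pmin(pmax(1 - fraction_new, 1e-6), 1)
  pos <- timepoints > 0
  k0 <- if (sum(pos) >= 2) {
    max(1e-4, -stats::coef(stats::lm(log(u[pos]) ~ timepoints[pos]))[2])
  } else 0.01
  fit <- .bounded_lm(
    resid_fn = function(p) fraction_new - (1 - exp(-p["k"] * timepoints)),
    jac_fn = function(p) cbind(k = -timepoints * exp(-p["k"] * timepoints)),
    start = c(k = min(as.numeric(k0), 5)), lower = c(k = 0),
    upper = c(k = 10))
  if (!fit$converged) {
    return(structure(list(k_div = NA_real_, se = NA_real_,
                          doubling_time = NA_real_,
                          n_observations = length(timepoints),
                          flag = "failed"),
                     class = "division_fit"))
  }
  k_hat <- fit$par[["k"]]
  structure(
    list(k_div = k_hat, se = fit$se[["k"]],
         doubling_time = if (k_hat > 0) log(2) / k_hat else Inf,
         n_observations = length(timepoints), flag = "ok"),
    class = "division_fit"
  )
}

#' Full division-rate estimation from an isotopologue table
#'
#' For each tissue: corrects every spectrum for natural isotope abundance,
#' estimates the precursor pool (r, f_new) per base and timepoint from the
#' mono/di pair, additionally takes the mono-only labeled fraction as an
#' independent observation, and fits a single exponential across all bases
#' and units.
#'
#' @param spectra Data.frame with columns `tissue`, `timepoint_days`, `base`,
#'   `unit` ("mono"/"di"), `m_shift`, `intensity`, optional `replicate`.
#' @param a15N Natural 15N abundance.
#' @return List with `fits` (data.frame per tissue: `tissue`, `k_div`, `se`,
#'   `doubling_time`, `n_observations`) and `pool_diagnostics` (per tissue,
#'   base, timepoint: `r`, `f_new_di`, `f_new_mono`).
#' @export
dna_turnover_pipeline <- function(spectra, a15N = 0.00364) {
  needed <- c("tissue", "timepoint_days", "base", "unit", "m_shift",
              "intensity")
  if (!all(needed %in% names(spectra))) {
    stop("isotopologue table needs columns: ", paste(needed, collapse = ", "))
  }
  if (!"replicate" %in% names(spectra)) spectra$replicate <- 1L
  fits <- list()
  diags <- list()
  for (ts in unique(spectra$tissue)) {
    sub <- spectra[spectra$tissue == ts, , drop = FALSE]
    obs_t <- numeric(0)
    obs_f <- numeric(0)
    for (b in unique(sub$base)) {
      nN <- n_nitrogen(b)
      for (tp in unique(sub$timepoint_days)) {
        for (rp in unique(sub$replicate)) {
          sel <- sub$base == b & sub$timepoint_days == tp & sub$replicate == rp
          mono_rows <- sub[sel & sub$unit == "mono", , drop = FALSE]
          di_rows <- sub[sel & sub$unit == "di", , drop = FALSE]
          if (!nrow(mono_rows) || !nrow(di_rows)) next
          mono <- numeric(nN + 1)
          mono[mono_rows$m_shift + 1] <- mono_rows$intensity
          di <- numeric(2 * nN + 1)
          di[di_rows$m_shift + 1] <- di_rows$intensity
          mono_c <- natural_abundance_correct(mono, a15N)
          di_c <- natural_abundance_correct(di, a15N)
          pool <- estimate_pool(mono_c, di_c)
          # the mono labeled mass is f_new * (1 - r); rescale by the fitted
          # recycling fraction so the mono-derived observation is unbiased
          f_mono <- mono_fraction_new(mono_c)
          f_di <- 0
          if (pool$identifiable) {
            f_di <- pool$f_new
            if (pool$r < 1) f_mono <- min(f_mono / (1 - pool$r), 1)
          }
          obs_t <- c(obs_t, tp, tp)
          obs_f <- c(obs_f, f_di, f_mono)
          diags[[length(diags) + 1]] <- data.frame(
            tissue = ts, base = b, timepoint_days = tp, replicate = rp,
            r = pool$r, f_new_di = f_di, f_new_mono = f_mono,
            identifiable = pool$identifiable, stringsAsFactors = FALSE)
        }
      }
    }
    fit <- fit_kdiv(obs_t, pmin(pmax(obs_f, 0), 1))
    fits[[ts]] <- data.frame(tissue = ts, k_div = fit$k_div, se = fit$se,
                             doubling_time = fit$doubling_time,
                             n_observations = fit$n_observations,
                             flag = fit$flag, stringsAsFactors = FALSE)
  }
  list(fits = do.call(rbind, c(fits, list(make.row.names = FALSE))),
       pool_diagnostics = do.call(rbind, c(diags,
                                           list(make.row.names = FALSE))))
}
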