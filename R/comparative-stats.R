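#' Comparative statistics on turnover rates
#'
#' Cross-tissue and within-complex variability of fitted rate constants,
#' quantified by the index of dispersion (population variance divided by
#' mean), with randomized nulls and rank-based tests.
#'
#' @name comparative-stats
NULL

#' Index of dispersion of a set of rates
#'
#' `D = variance / mean`, where the variance is the population variance (the
#' average of the squared differences from the mean, dividing by n). D is 0
#' iff all values are equal, and scales linearly with a common positive
#' factor: `dispersion(c * x) = c * dispersion(x)`.
#'
#' @param values At least 2 finite rates with positive mean.
#' @param sample_variance Divide by n - 1 instead of n.
#' @return Dispersion (1/day), or NA with a warning when the mean is not
#'   positive.
#' @export
dispersion <- function(values, sample_variance = FALSE) {
  if (length(values) < 2 || any(!is.finite(values))) {
    stop("dispersion requires at least 2 finite values")
  }
  m <- mean(values)
  if (m <= 0) {
    warning("dispersion undefined for non-positive mean")
    return(NA_real_)
  }
  v <- sum((values - m)^2) / (length(values) - if (sample_variance) 1 else 0)
  v / m
}

#' Within-complex dispersion of subunit rates, per tissue
#'
#' For each (complex, tissue) with at least `min_subunits` subunits detected,
#' computes the dispersion of the subunit rates in that tissue. Complexes
#' below the detection threshold are skipped (and reported in the
#' `n_subunits` column of the returned table only if `keep_skipped`).
#'
#' @param membership Data.frame with columns `complex_id`, `protein_id`.
#' @param rates Data.frame with columns `protein_id`, `tissue`, `k`.
#' @param min_subunits Minimum detected subunits (default 5).
#' @param keep_skipped Keep skipped complexes as NA rows.
#' @return Data.frame `complex_id`, `tissue`, `n_subunits`, `d`.
#' @export
intracomplex_dispersion <- function(membership, rates, min_subunits = 5,
                                    keep_skipped = FALSE) {
  stopifnot(all(c("complex_id", "protein_id") %in% names(membership)),
            all(c("protein_id", "tissue", "k") %in% names(rates)))
  out <- list()
  for (cx in unique(membership$complex_id)) {
    subunits <- membership$protein_id[membership$complex_id == cx]
    for (ts in unique(rates$tissue)) {
      k <- rates$k[rates$tissue == ts & rates$protein_id %in% subunits]
      k <- k[is.finite(k)]
      if (length(k) < min_subunits) {
        if (keep_skipped) {
          out[[length(out) + 1]] <- data.frame(
            complex_id = cx, tissue = ts, n_subunits = length(k),
            d = NA_real_, stringsAsFactors = FALSE)
        }
        next
      }
      out[[length(out) + 1]] <- data.frame(
        complex_id = cx, tissue = ts, n_subunits = length(k),
        d = dispersion(k), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(complex_id = character(0), tissue = character(0),
                      n_subunits = integer(0), d = numeric(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Null distribution of dispersion for random protein sets
#'
#' Draws `n_draws` subsets of `n_subunits` proteins uniformly without
#' replacement from the proteome's rates and computes the dispersion of each,
#' reproducibly for a given seed.
#'
#' @param n_subunits Subset size.
#' @param proteome_rates Rates to draw from.
#' @param n_draws Number of draws (default 1000).
#' @param seed Integer seed.
#' @return Numeric vector of null dispersions.
#' @export
random_complex_null <- function(n_subunits, proteome_rates, n_draws = 1000,
                                seed = 1L) {
  if (length(proteome_rates) < n_subunits) {
    stop("proteome smaller than requested subset size")
  }
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  vapply(seq_len(n_draws), function(i) {
    dispersion(sample(proteome_rates, n_subunits))
  }, numeric(1))
}

#' Are complexes more coherent than random protein sets?
#'
#' One-sided rank-sum (Mann-Whitney) comparison of the observed intracomplex
#' dispersions against a null of random-set dispersions, testing for lower
#' dispersion than expected by chance. A single observed complex falls back
#' to the empirical percentile within the null.
#'
#' @param observed_d Observed dispersions.
#' @param null_d Null dispersions.
#' @return p-value.
#' @export
coherence_test <- function(observed_d, null_d) {
  observed_d <- observed_d[is.finite(observed_d)]
  null_d <- null_d[is.finite(null_d)]
  if (!length(observed_d) || !length(null_d)) stop("empty input")
  if (length(unique(c(observed_d, null_d))) == 1) {
    warning("all dispersions tied; test uninformative")
    return(1)
  }
  if (length(observed_d) == 1) {
    return((sum(null_d <= observed_d) + 1) / (length(null_d) + 1))
  }
  stats::wilcox.test(observed_d, null_d, alternative = "less",
                     exact = FALSE)$p.value
}

#' Welch-type comparison of two fitted rates
#'
#' Tests whether two independently fitted rate constants differ, using the
#' fits' standard errors and a Welch-Satterthwaite degrees-of-freedom
#' approximation with per-fit df of `n_points - 2`. Symmetric in its
#' arguments.
#'
#' @param k1,k2 Fitted rates.
#' @param se1,se2 Their standard errors (> 0).
#' @param n1,n2 Numbers of points behind each fit.
#' @return List with `p_value`, `t`, `df`.
#' @export
rate_difference_test <- function(k1, se1, n1, k2, se2, n2) {
  if (!all(is.finite(c(k1, se1, k2, se2))) || se1 <= 0 || se2 <= 0) {
    stop("rate_difference_test requires finite rates and positive SEs")
  }
  df1 <- n1 - 2
  df2 <- n2 - 2
  if (df1 < 1 || df2 < 1) stop("each fit needs at least 3 points")
  v <- se1^2 + se2^2
  t <- (k1 - k2) / sqrt(v)
  df <- v^2 / (se1^4 / df1 + se2^4 / df2)
  list(p_value = 2 * stats::pt(abs(t), df = df, lower.tail = FALSE),
       t = t, df = df)
}

#' Fraction of the proteome diluted out by cell division
#'
#' Fraction of proteins whose observed turnover rate does not exceed the
#' cell-division rate (`k_t <= k_div`); such proteins are cleared primarily
#' by dilution during cell division rather than degradation. With
#' `se_tolerance` and per-protein SEs, proteins within `se_tolerance` SEs of
#' k_div also count (rates statistically indistinguishable from pure
#' dilution).
#'
#' @param k_t Observed rates.
#' @param k_div Cell-division rate (scalar, >= 0).
#' @param se Optional per-protein SEs.
#' @param se_tolerance SE multiplier for the tolerance band (default 0 =
#'   strict rule).
#' @return Fraction in [0, 1].
#' @export
division_dominated_fraction <- function(k_t, k_div, se = NULL,
                                        se_tolerance = 0) {
  if (!length(k_t)) stop("empty k_t input")
  if (!is.finite(k_div) || k_div < 0) stop("k_div must be non-negative")
  thresh <- k_div
  if (se_tolerance > 0 && !is.null(se)) {
    stopifnot(length(se) == length(k_t))
    return(mean(k_t - se_tolerance * se <= thresh))
  }
  mean(k_t <= thresh)
}

#' Compare a protein subset against the rest of the proteome
#'
#' Two-sided Mann-Whitney test of the subset's values against the complement,
#' reporting the direction of the shift in medians. Subsets smaller than 5
#' are skipped (NA with a warning).
#'
#' @param subset_values Values of the subset.
#' @param proteome_values Values of the whole proteome (a strict superset).
#' @return List with `p_value`, `direction` ("higher"/"lower"/"none"),
#'   `n_subset`.
#' @export
subset_vs_proteome_test <- function(subset_values, proteome_values) {
  if (length(subset_values) >= length(proteome_values)) {
    stop("subset must be strictly smaller than the proteome")
  }
  if (length(subset_values) < 5) {
    warning("subset smaller than 5; test skipped")
    return(list(p_value = NA_real_, direction = "none",
                n_subset = length(subset_values)))
  }
  # complement: remove one proteome instance per subset value
  complement <- proteome_values
  for (v in subset_values) {
    i <- match(v, complement)
    if (!is.na(i)) complement <- complement[-i]
  }
  p <- stats::wilcox.test(subset_values, complement, exact = FALSE)$p.value
  delta <- stats::median(subset_values) - stats::median(complement)
  list(p_value = p,
       direction = if (delta > 0) "higher" else if (delta < 0) "lower"
                   else "none",
       n_subset = length(subset_values))
}

#' Median rate decile of a complex, tested against the proteome median
#'
#' The median decile of a complex's subunits, with a one-sample t-test of the
#' subunit deciles against the proteome-median decile of 5.5. Complexes with
#' fewer than `min_subunits` subunits with deciles are skipped.
#'
#' @param subunit_deciles Decile indices (1..10) of the complex's subunits.
#' @param min_subunits Minimum subunits (default 5).
#' @return List with `median_decile`, `p_value`, `n_subunits`.
#' @export
complex_median_decile <- function(subunit_deciles, min_subunits = 5) {
  subunit_deciles <- subunit_deciles[is.finite(subunit_deciles)]
  if (length(subunit_deciles) < min_subunits) {
    warning("fewer than ", min_subunits, " subunits with deciles; skipped")
    return(list(median_decile = NA_real_, p_value = NA_real_,
                n_subunits = length(subunit_deciles)))
  }
  p <- if (stats::sd(subunit_deciles) == 0) {
    # all subunits in one decile: degenerate t-test
    if (subunit_deciles[1] == 5.5) 1 else 0
  } else {
    stats::t.test(subunit_deciles, mu = 5.5)$p.value
  }
  list(median_decile = stats::median(subunit_deciles), p_value = p,
       n_subunits = length(subunit_deciles))
}

#' Cross-tissue dispersion table for shared proteins
#'
#' For every protein with finite rates in at least `min_tissues` tissues,
#' computes the dispersion of its per-tissue rates.
#'
#' @param rates Data.frame `protein_id`, `tissue`, `k`.
#' @param min_tissues Minimum tissues per protein (default 2).
#' @return Data.frame `protein_id`, `n_tissues`, `D`.
#' @export
cross_tissue_dispersion <- function(rates, min_tissues = 2) {
  stopifnot(all(c("protein_id", "tissue", "k") %in% names(rates)))
  rows <- lapply(split(rates, rates$protein_id), function(sub) {
    k <- sub$k[is.finite(sub$k)]
    if (length(k) < min_tissues || mean(k) <= 0) return(NULL)
    data.frame(protein_id = sub$protein_id[1], n_tissues = length(k),
               D = dispersion(k), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), n_tissues = integer(0),
                      D = numeric(0))
  }
  out
}
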