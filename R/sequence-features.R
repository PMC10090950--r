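#' Protein sequence feature computation
#'
#' Physicochemical features used to probe sequence-encoded determinants of
#' protein turnover: Kyte-Doolittle hydropathy (GRAVY), isoelectric point,
#' amino-acid-class mole percentages, molecular weight, and long
#' intrinsically disordered regions (IDRs) from per-residue disorder scores.
#' Unknown/ambiguous residues (X, B, Z, U, O, J) are excluded from feature
#' arithmetic; all features are case-insensitive.
#'
#' @name sequence-features
NULL

.KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# average residue (i.e. water-subtracted) masses, Da
.RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

# EMBOSS pKa set (as used by pepstats)
.PKA <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

.POLAR_SET <- c("D", "E", "H", "K", "N", "Q", "R", "S", "T")
.ACIDIC_SET <- c("D", "E")
.BASIC_SET <- c("K", "R", "H")

# split into canonical residues, dropping unknowns with a count attribute
.canonical_residues <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  known <- chars %in% names(.KD_HYDROPATHY)
  structure(chars[known], n_unknown = sum(!known))
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the sequence's canonical residues.
#'
#' @param seq Amino-acid sequence string.
#' @return GRAVY score.
#' @examples
#' gravy("III") # 4.5
#' @export
gravy <- function(seq) {
  res <- .canonical_residues(seq)
  if (!length(res)) stop("sequence has no canonical residues")
  mean(.KD_HYDROPATHY[res])
}

# net charge at a given pH (Henderson-Hasselbalch over termini and side
# chains)
.net_charge <- function(counts, pH) {
  pos <- sum(c(1, counts[.names_in(counts, names(.PKA$positive))]) /
             (1 + 10^(pH - c(.PKA$nterm,
                             .PKA$positive[.names_in(counts,
                                                     names(.PKA$positive))]))))
  neg <- sum(c(1, counts[.names_in(counts, names(.PKA$negative))]) /
             (1 + 10^(c(.PKA$cterm,
                        .PKA$negative[.names_in(counts,
                                                names(.PKA$negative))]) - pH)))
  pos - neg
}

.names_in <- function(counts, nm) nm[nm %in% names(counts)]

#' Isoelectric point by bisection
#'
#' pH at which the net charge (Henderson-Hasselbalch sum over the termini and
#' the ionizable side chains D, E, C, Y, H, K, R, with the EMBOSS pKa set)
#' crosses zero; bisection until |charge| < 1e-4. Sequences without ionizable
#' side chains get the termini-only pI with a `note` attribute.
#'
#' @param seq Amino-acid sequence string.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq) {
  res <- .canonical_residues(seq)
  if (!length(res)) stop("sequence has no canonical residues")
  counts <- table(res)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  ionizable <- any(names(counts) %in% c(names(.PKA$positive),
                                        names(.PKA$negative)))
  lo <- 0
  hi <- 14
  # net charge is strictly decreasing in pH
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- .net_charge(counts, mid)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  if (!ionizable) attr(mid, "note") <- "termini-only pI"
  mid
}

#' Mole percentage of an amino-acid class
#'
#' @param seq Amino-acid sequence string.
#' @param class One of "polar" (D,E,H,K,N,Q,R,S,T), "acidic" (D,E), "basic"
#'   (K,R,H).
#' @return Percentage in [0, 100] of canonical residues in the class.
#' @export
class_mole_percent <- function(seq, class = c("polar", "acidic", "basic")) {
  class <- match.arg(class)
  set <- switch(class, polar = .POLAR_SET, acidic = .ACIDIC_SET,
                basic = .BASIC_SET)
  res <- .canonical_residues(seq)
  if (!length(res)) stop("sequence has no canonical residues")
  100 * mean(res %in% set)
}

#' @rdname class_mole_percent
#' @export
polar_mole_percent <- function(seq) class_mole_percent(seq, "polar")

#' Molecular weight (average mass, Da)
#'
#' @param seq Amino-acid sequence string.
#' @return Mass in Da (residue masses plus one water).
#' @export
molecular_weight <- function(seq) {
  res <- .canonical_residues(seq)
  if (!length(res)) stop("sequence has no canonical residues")
  sum(.RESIDUE_MASS[res]) + 18.0153
}

#' Find long intrinsically disordered regions
#'
#' Maximal runs of per-residue disorder scores strictly above `threshold`
#' with length at least `min_len` (default: score > 0.5 over >= 40 residues).
#'
#' @param scores Per-residue disorder scores in [0, 1].
#' @param threshold Strict lower bound on the score (default 0.5).
#' @param min_len Minimum run length (default 40).
#' @return Data.frame with columns `start`, `end` (1-based, inclusive); zero
#'   rows when no qualifying run exists.
#' @export
find_idrs <- function(scores, threshold = 0.5, min_len = 40) {
  if (any(!is.finite(scores))) stop("disorder scores must be finite")
  above <- scores > threshold
  r <- rle(above)
  ends <- as.integer(cumsum(r$lengths))
  starts <- ends - as.integer(r$lengths) + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Does the score track contain a long IDR?
#'
#' @inheritParams find_idrs
#' @return Logical.
#' @export
has_long_idr <- function(scores, threshold = 0.5, min_len = 40) {
  nrow(find_idrs(scores, threshold, min_len)) > 0
}

#' Feature table for a set of sequences
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param disorder Optional named list of per-residue score vectors.
#' @return Data.frame keyed by `protein_id` with `gravy`, `pI`,
#'   `polar_mole_pct`, `acidic_mole_pct`, `basic_mole_pct`, `mol_weight`,
#'   `length`, `has_long_idr` (NA without scores).
#' @export
sequence_feature_table <- function(sequences, disorder = NULL) {
  stopifnot(!is.null(names(sequences)))
  rows <- lapply(names(sequences), function(id) {
    s <- sequences[[id]]
    idr <- if (!is.null(disorder) && !is.null(disorder[[id]])) {
      has_long_idr(disorder[[id]])
    } else NA
    data.frame(protein_id = id, gravy = gravy(s),
               pI = as.numeric(isoelectric_point(s)),
               polar_mole_pct = class_mole_percent(s, "polar"),
               acidic_mole_pct = class_mole_percent(s, "acidic"),
               basic_mole_pct = class_mole_percent(s, "basic"),
               mol_weight = molecular_weight(s),
               length = length(.canonical_residues(s)),
               has_long_idr = idr, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Spearman correlation of sequence features with turnover rates
#'
#' Tie-corrected Spearman rank correlation of each numeric feature with the
#' matched rates, with a two-sided p-value. Constant features are flagged
#' (`rho = NA`).
#'
#' @param features Feature table from [sequence_feature_table()].
#' @param rates Data.frame `protein_id`, `k`.
#' @param min_pairs Minimum paired observations (default 10).
#' @return Data.frame `feature`, `rho`, `p_value`, `n`.
#' @export
feature_rate_correlation <- function(features, rates, min_pairs = 10) {
  stopifnot(all(c("protein_id", "k") %in% names(rates)))
  merged <- merge(features, rates, by = "protein_id")
  numeric_cols <- setdiff(names(merged)[vapply(merged, is.numeric,
                                               logical(1))],
                          c("k", "length", "protein_id"))
  if (nrow(merged) < min_pairs) {
    stop("need at least ", min_pairs, " paired observations")
  }
  rows <- lapply(numeric_cols, function(col) {
    x <- merged[[col]]
    y <- merged$k
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_pairs || stats::sd(x[ok]) == 0) {
      return(data.frame(feature = col, rho = NA_real_, p_value = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    data.frame(feature = col, rho = unname(ct$estimate),
               p_value = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
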