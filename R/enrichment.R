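# The statistical layer: hypergeometric association of system presence
# with multicellular habit, the chi-squared test for positional clustering
# of systems along the replicon, and peak detection in component length
# distributions.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= q)` for X hypergeometric with `m` trait-positive and `n`
#' trait-negative organisms and `k` draws (organisms carrying the system).
#' Computed in log space (via `phyper(..., log.p = TRUE)`) so that
#' p-values far below 1e-300 remain finite and positive on the log scale.
#'
#' @param q Number of system-bearing organisms that are trait-positive.
#' @param m Trait-positive organisms in the universe.
#' @param n Trait-negative organisms in the universe.
#' @param k Organisms carrying the system.
#' @param log10 If TRUE return log10(p) instead of p.
#' @return The upper-tail probability (or its log10).
#' @export
hypergeometric_upper_tail <- function(q, m, n, k, log10 = FALSE) {
  stopifnot(length(q) == 1, length(m) == 1, length(n) == 1,
            length(k) == 1)
  if (q < 0 || q > min(k, m) || k > m + n || m < 0 || n < 0 || k < 0)
    stop("invalid hypergeometric input: need 0 <= q <= min(k, m), ",
         "k <= m + n")
  lp <- phyper(q - 1, m, n, k, lower.tail = FALSE, log.p = TRUE)
  if (log10) lp / log(10) else exp(lp)
}

#' Multicellularity enrichment per system type
#'
#' For each system type: `k` = organisms with at least one instance
#' (presence/absence, not instance counts), `q` = those flagged
#' multicellular, with `m`/`n` from the metadata. Organisms whose flag is
#' `NA` (no information) are excluded from both the universe and the
#' counts. The fold enrichment is `(q/k) / (m/(m+n))`. A
#' Benjamini-Hochberg column is emitted for convenience.
#'
#' @param instances data.frame with `system_type`, `genome_id`.
#' @param metadata data.frame with `genome_id`, `multicellular`
#'   (logical, NA allowed).
#' @param system_types Types to report (default: those present in
#'   `instances`). A type with `k = 0` is reported with `p = NA`.
#' @return data.frame with columns `system_type`, `q`, `m`, `n`, `k`,
#'   `fold`, `p`, `p_bh`.
#' @export
multicell_enrichment <- function(instances, metadata,
                                 system_types = NULL) {
  meta <- metadata[!is.na(metadata$multicellular), , drop = FALSE]
  m <- sum(meta$multicellular)
  n <- sum(!meta$multicellular)
  if (is.null(system_types))
    system_types <- sort(unique(instances$system_type))
  mc_set <- meta$genome_id[meta$multicellular]
  rows <- lapply(system_types, function(st) {
    orgs <- unique(instances$genome_id[instances$system_type == st])
    orgs <- intersect(orgs, meta$genome_id)
    k <- length(orgs)
    q <- length(intersect(orgs, mc_set))
    p <- if (k == 0) NA_real_ else hypergeometric_upper_tail(q, m, n, k)
    fold <- if (k == 0 || m == 0) NA_real_ else (q / k) / (m / (m + n))
    data.frame(system_type = st, q = q, m = m, n = n, k = k,
               fold = fold, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Chi-squared test for positional clustering along the replicon
#'
#' Each instance contributes its normalized anchor position
#' `x = anchor_stop / replicon_length`. Positions are binned into
#' `n_bins` equal chromosomal intervals (default 20) and tested against
#' the uniform expectation `E = N / n_bins` with
#' `chi2 = sum (O_b - E)^2 / E` on `n_bins - 1` degrees of freedom.
#' With `fold = TRUE` positions are folded about the midpoint
#' (`x <- min(x, 1 - x)`, binned over `[0, 0.5]`), collapsing a
#' symmetric two-arm preference into one mode.
#'
#' @param x Either a numeric vector of normalized positions in `[0, 1]`
#'   or an instance data.frame with `anchor_stop` and `replicon_length`.
#' @param n_bins Number of chromosomal intervals (default 20).
#' @param fold Fold positions about the replicon midpoint.
#' @return Object of class `position_distribution`: list with
#'   `positions`, `counts`, `chi2`, `df`, `p`, `n_bins`, `fold`.
#' @export
position_chi_square <- function(x, n_bins = 20, fold = FALSE) {
  if (is.data.frame(x)) {
    stopifnot(all(c("anchor_stop", "replicon_length") %in% names(x)))
    x <- x$anchor_stop / x$replicon_length
  }
  x <- as.numeric(x)
  if (!length(x)) stop("no positions to test")
  if (any(x < 0 | x > 1)) stop("normalized positions must lie in [0, 1]")
  if (length(x) < n_bins)
    warning("fewer observations (", length(x), ") than bins (", n_bins,
            "); the chi-squared approximation is unreliable")
  upper <- if (fold) 0.5 else 1
  if (fold) x <- pmin(x, 1 - x)
  b <- pmin(pmax(ceiling(x / (upper / n_bins)), 1L), n_bins)
  counts <- tabulate(b, nbins = n_bins)
  E <- length(x) / n_bins
  chi2 <- sum((counts - E)^2 / E)
  df <- n_bins - 1
  structure(list(positions = x, counts = counts, chi2 = chi2, df = df,
                 p = pchisq(chi2, df, lower.tail = FALSE),
                 n_bins = n_bins, fold = fold),
            class = "position_distribution")
}

#' @export
print.position_distribution <- function(x, ...) {
  cat(sprintf(
    "<position_distribution> %d positions, %d bins%s: chi2 = %.3f (df %d), p = %.4g\n",
    length(x$positions), x$n_bins, if (x$fold) " (folded)" else "",
    x$chi2, x$df, x$p))
  invisible(x)
}

#' Peaks of a protein length distribution
#'
#' Histogram with fixed bin width, smoothed by a centred 3-bin moving
#' average (zero-padded at the edges); peaks are strict local maxima of
#' the smoothed counts whose height reaches `min_peak_fraction` of the
#' sample size. Peak centres are reported at bin midpoints, so their
#' resolution is half a bin width.
#'
#' @param lengths Numeric vector of protein lengths (residues).
#' @param bin_width Histogram bin width (default 50 residues).
#' @param min_peak_fraction Minimum smoothed peak height as a fraction of
#'   the number of observations (default 0.05).
#' @return List with `histogram` (data.frame `mid`, `count`, `smoothed`),
#'   `peaks` (centres), `bin_width`.
#' @export
length_peaks <- function(lengths, bin_width = 50,
                         min_peak_fraction = 0.05) {
  lengths <- as.numeric(lengths[is.finite(lengths)])
  if (length(lengths) < 10)
    warning("fewer than 10 lengths; peak detection is unreliable")
  if (!length(lengths)) stop("no lengths supplied")
  lo <- floor(min(lengths) / bin_width) * bin_width
  hi <- ceiling((max(lengths) + 1e-9) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (length(breaks) < 2) breaks <- c(lo, lo + bin_width)
  counts <- tabulate(pmin(findInterval(lengths, breaks,
                                       rightmost.closed = TRUE),
                          length(breaks) - 1L),
                     nbins = length(breaks) - 1L)
  padded <- c(0, counts, 0)
  smoothed <- vapply(seq_along(counts), function(i)
    mean(padded[i:(i + 2)]), numeric(1L))
  mids <- breaks[-length(breaks)] + bin_width / 2
  is_peak <- vapply(seq_along(smoothed), function(i) {
    left <- if (i == 1) 0 else smoothed[i - 1]
    right <- if (i == length(smoothed)) 0 else smoothed[i + 1]
    smoothed[i] > left && smoothed[i] > right
  }, logical(1L))
  is_peak <- is_peak & smoothed >= min_peak_fraction * length(lengths)
  list(histogram = data.frame(mid = mids, count = counts,
                              smoothed = smoothed),
       peaks = mids[is_peak], bin_width = bin_width)
}
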