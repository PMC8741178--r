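# In/out-of-corona labeling from quantitative abundances: an enrichment
# rule (corona abundance above the biofluid control) combined with an
# exponential-decay abundance threshold A_threshold = p / k fitted to the
# abundance distribution of the non-enriched proteins.

#' Fit the exponential abundance threshold
#'
#' Enriched proteins (`a_corona > a_biofluid`) are set aside; an
#' exponential decay `n = n0 * exp(-k * A)` is fitted to the corona
#' abundances of the remaining proteins, and the in-corona abundance
#' threshold is placed where the decay has fallen to `n0 * exp(-p)`, i.e.
#' `A_threshold = p / k`. The default fit is the maximum-likelihood
#' estimate of an exponential rate, `k = 1 / mean(a_corona)` over the
#' non-enriched proteins with positive corona abundance (bin-free and
#' deterministic); `method = "histogram"` instead least-squares fits
#' `(n0, k)` to the log-counts of equal-width abundance bins.
#'
#' @param records an [abundance_records] data frame.
#' @param p threshold power, `>= 0`; the default 2.25 is the power at
#'   which classifier performance is optimized.
#' @param method `"mle"` (default) or `"histogram"`.
#' @param bins number of equal-width bins for the histogram method.
#' @return An object of class `threshold_fit` with elements `k`, `n0`
#'   (histogram method only), `p`, `a_threshold`, `n_fit`, `method`.
#' @export
fit_threshold <- function(records, p = 2.25,
                          method = c("mle", "histogram"), bins = 30) {
  method <- match.arg(method)
  if (!is.numeric(p) || length(p) != 1L || p < 0)
    stop("p must be a single nonnegative number")
  keep <- !(records$a_corona > records$a_biofluid) & records$a_corona > 0
  a <- records$a_corona[keep]
  if (all(records$a_corona > records$a_biofluid))
    stop("all proteins are enriched: no distribution to fit")
  if (length(a) < 2L)
    stop("need at least 2 non-enriched proteins with positive corona ",
         "abundance to fit the threshold")
  if (method == "mle") {
    m <- mean(a)
    if (m <= 0) stop("non-positive mean abundance; cannot fit rate")
    k <- 1 / m
    n0 <- NA_real_
  } else {
    h <- graphics::hist(a, breaks = bins, plot = FALSE)
    pos <- h$counts > 0
    if (sum(pos) < 2L)
      stop("too few occupied bins for the histogram fit")
    fit <- stats::lm(log(h$counts[pos]) ~ h$mids[pos])
    k <- -unname(stats::coef(fit)[2])
    n0 <- exp(unname(stats::coef(fit)[1]))
    if (k <= 0) stop("histogram fit produced a non-positive rate")
  }
  out <- list(k = k, n0 = n0, p = p, a_threshold = p / k,
              n_fit = length(a), method = method)
  class(out) <- "threshold_fit"
  out
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("Exponential abundance threshold fit (", x$method, ")\n", sep = "")
  cat(sprintf("  rate k       = %g (fit on %d non-enriched proteins)\n",
              x$k, x$n_fit))
  if (!is.na(x$n0)) cat(sprintf("  n0           = %g\n", x$n0))
  cat(sprintf("  power p      = %g\n", x$p))
  cat(sprintf("  A_threshold  = %g\n", x$a_threshold))
  invisible(x)
}

#' Assign in/out-of-corona labels
#'
#' A protein is in the corona iff it is enriched (`a_corona > a_biofluid`)
#' or its corona abundance exceeds the fitted threshold
#' (`a_corona > a_threshold`, strict). Enrichment takes precedence in the
#' recorded reason. Ties at exactly the threshold, and undetected proteins
#' (`a_corona = 0`) that are not enriched, are out of the corona.
#'
#' @param records an [abundance_records] data frame.
#' @param fit a [fit_threshold] object (or a single numeric threshold).
#' @return A `data.frame` with columns `accession`, `in_corona`, `reason`
#'   (`"enriched"`, `"above_threshold"`, or `"below_threshold"`).
#' @export
assign_labels <- function(records, fit) {
  a_threshold <- if (inherits(fit, "threshold_fit")) fit$a_threshold
                 else as.numeric(fit)
  enriched <- records$a_corona > records$a_biofluid
  above <- records$a_corona > a_threshold
  reason <- ifelse(enriched, "enriched",
                   ifelse(above, "above_threshold", "below_threshold"))
  data.frame(accession = records$accession,
             in_corona = enriched | above,
             reason = reason, stringsAsFactors = FALSE)
}

#' Sweep the threshold power
#'
#' Fits the exponential rate once (it does not depend on `p`) and records
#' the number of in-corona proteins over a grid of threshold powers. The
#' in-corona count is monotone non-increasing in `p`, and enriched
#' proteins stay in the corona for every power.
#'
#' @param records an [abundance_records] data frame.
#' @param p_grid nonempty vector of nonnegative powers.
#' @inheritParams fit_threshold
#' @return A `data.frame` with columns `p`, `a_threshold`, `n_in_corona`;
#'   the shared rate fit is attached as attribute `"fit"`.
#' @export
threshold_sweep <- function(records, p_grid = seq(0, 3.5, by = 0.25),
                            method = c("mle", "histogram"), bins = 30) {
  if (length(p_grid) == 0L || any(p_grid < 0))
    stop("p_grid must be nonempty and nonnegative")
  base <- fit_threshold(records, p = p_grid[[1]], method = method,
                        bins = bins)
  rows <- lapply(p_grid, function(p) {
    labels <- assign_labels(records, p / base$k)
    data.frame(p = p, a_threshold = p / base$k,
               n_in_corona = sum(labels$in_corona))
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- base
  out
}
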