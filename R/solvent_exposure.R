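# Solvent-exposure features under the two normalizations, plus a
# deterministic heuristic exposure predictor used only as an offline
# stand-in for NetSurfP 2.0 output in tests and fixtures.

#' Call residues exposed or buried from relative solvent accessibility
#'
#' A residue is exposed iff its RSA is at or above the cutoff (inclusive
#' boundary, the NetSurfP 2.0 convention; default 0.25).
#'
#' @param residues residue table with columns `position`, `residue`,
#'   `rsa`, `asa`.
#' @param rsa_cutoff cutoff in the open interval (0, 1).
#' @return The same table with the `exposed` logical column set.
#' @export
classify_exposure <- function(residues, rsa_cutoff = 0.25) {
  if (!is.numeric(rsa_cutoff) || rsa_cutoff <= 0 || rsa_cutoff >= 1)
    stop("rsa_cutoff must lie strictly between 0 and 1")
  if (any(residues$rsa < 0 | residues$rsa > 1))
    stop("RSA values must lie in [0, 1]")
  residues$exposed <- residues$rsa >= rsa_cutoff
  residues
}

#' Per-amino-acid solvent-exposure fractions
#'
#' For each standard amino acid `a`, computes the count of exposed
#' residues of type `a` normalized by either the total number of standard
#' residues (`exposed_vs_total`) or the total number of exposed residues
#' (`exposed_vs_exposed`), together with the mean RSA, total ASA, and the
#' overall exposed-residue fraction. When no residue is exposed the
#' exposed-vs-exposed fractions are all zero (with a warning).
#'
#' @param sequence amino-acid sequence aligned with `residues`.
#' @param residues residue table with the `exposed` column set (see
#'   [classify_exposure]).
#' @return A list with elements `exposed_count`, `exposed_vs_total`,
#'   `exposed_vs_exposed` (each length 20), `mean_rsa`, `total_asa`,
#'   `exposed_fraction`.
#' @export
exposure_fractions <- function(sequence, residues) {
  ch <- seq_chars(toupper(sequence))
  if (length(ch) != nrow(residues))
    stop("residue table length (", nrow(residues),
         ") does not match sequence length (", length(ch), ")")
  if (!all(residues$residue == ch))
    stop("residue letters do not match the sequence")
  std <- residues$residue %in% AA_STANDARD
  n_std <- sum(std)
  if (n_std == 0L) stop("sequence contains no standard amino-acid residues")
  exposed <- residues$exposed & std
  counts <- table(factor(residues$residue[exposed], levels = AA_STANDARD))
  counts <- stats::setNames(as.numeric(counts), AA_STANDARD)
  n_exp <- sum(counts)
  vs_exposed <- if (n_exp > 0) counts / n_exp else {
    warning("no exposed residues; exposed-vs-exposed fractions set to 0")
    counts * 0
  }
  list(exposed_count = counts,
       exposed_vs_total = counts / n_std,
       exposed_vs_exposed = vs_exposed,
       mean_rsa = mean(residues$rsa[std]),
       total_asa = sum(residues$asa[std]),
       exposed_fraction = n_exp / n_std)
}

#' Heuristic per-residue exposure predictor (testing stand-in)
#'
#' A deliberately simple, non-scientific surrogate for NetSurfP 2.0 used
#' only to build offline fixtures: each residue's exposure probability is
#' `plogis(-hydropathy)`, so hydrophilic residues come out exposed and
#' hydrophobic ones buried. Without a seed the call is thresholded at
#' probability 0.5; with a seed the exposure is sampled Bernoulli. RSA is
#' set consistently with the exposed call relative to the 0.25 cutoff, and
#' ASA is RSA times the residue's theoretical maximum ASA. Real analyses
#' should ingest NetSurfP output via [read_netsurfp].
#'
#' @param sequence amino-acid sequence.
#' @param seed optional integer seed for sampled mode.
#' @return Residue table with columns `position`, `residue`, `rsa`,
#'   `asa`, `exposed`.
#' @export
heuristic_exposure <- function(sequence, seed = NULL) {
  ch <- seq_chars(toupper(sequence))
  hyd <- ifelse(ch %in% AA_STANDARD, KD_HYDROPATHY[ch], 0)
  prob <- stats::plogis(-hyd)
  if (is.null(seed)) {
    exposed <- prob >= 0.5
    # rsa = prob/2 maps the 0.5 probability threshold onto the 0.25 RSA
    # cutoff, keeping the exposed call and the RSA mutually consistent.
    rsa <- prob / 2
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    exposed <- stats::runif(length(ch)) < prob
    rsa <- ifelse(exposed, stats::runif(length(ch), 0.25, 1),
                  stats::runif(length(ch), 0, 0.2499))
  }
  max_asa <- ifelse(ch %in% AA_STANDARD, MAX_ASA[ch], 0)
  data.frame(position = seq_along(ch), residue = ch, rsa = rsa,
             asa = rsa * max_asa, exposed = exposed,
             stringsAsFactors = FALSE)
}
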