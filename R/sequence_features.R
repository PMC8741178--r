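# Sequence-global physicochemical descriptors.
#
# Ambiguity codes (X, B, Z, U, O) are retained in stored sequences but are
# excluded from every descriptor computation, numerators and denominators
# alike, so that all fractions stay normalized over standard residues.

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

# Standard residues only; errors if none remain.
seq_standard <- function(sequence) {
  ch <- seq_chars(toupper(sequence))
  ch <- ch[ch %in% AA_STANDARD]
  if (length(ch) == 0L)
    stop("sequence contains no standard amino-acid residues")
  ch
}

#' Amino-acid composition fractions
#'
#' Fraction of each of the 20 standard amino acids among the standard
#' residues of the sequence; the fractions sum to 1.
#'
#' @param sequence amino-acid sequence (one-letter codes).
#' @return Named numeric vector of length 20 (alphabetical by residue).
#' @export
aa_fractions <- function(sequence) {
  ch <- seq_standard(sequence)
  counts <- table(factor(ch, levels = AA_STANDARD))
  as.numeric(counts) / length(ch) -> f
  names(f) <- AA_STANDARD
  f
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the standard residues.
#'
#' @inheritParams aa_fractions
#' @return A single numeric value.
#' @export
gravy <- function(sequence) {
  ch <- seq_standard(sequence)
  mean(KD_HYDROPATHY[ch])
}

#' Secondary-structure propensity fractions
#'
#' Fractions of residues belonging to the helix-associated set
#' (V, I, Y, F, W, L), the turn-associated set (N, P, G, S), and the
#' sheet-associated set (E, M, A, L); `nonstructure` is the fraction of
#' residues in none of the three. The sets overlap (L is helix- and
#' sheet-associated), so the four fractions need not sum to 1.
#'
#' @inheritParams aa_fractions
#' @return Named numeric vector `c(helix, turn, sheet, nonstructure)`.
#' @export
ss_fractions <- function(sequence) {
  ch <- seq_standard(sequence)
  n <- length(ch)
  in_any <- ch %in% c(SS_HELIX_SET, SS_TURN_SET, SS_SHEET_SET)
  c(helix = sum(ch %in% SS_HELIX_SET) / n,
    turn = sum(ch %in% SS_TURN_SET) / n,
    sheet = sum(ch %in% SS_SHEET_SET) / n,
    nonstructure = sum(!in_any) / n)
}

# Net charge of the peptide at a given pH under the
# Henderson-Hasselbalch model with the Bjellqvist pKa set.
charge_at_ph <- function(sequence, ph) {
  ch <- seq_standard(sequence)
  counts <- table(factor(ch, levels = AA_STANDARD))
  nterm_pka <- PKA_POSITIVE[["Nterm"]]
  if (ch[1] %in% names(PKA_NTERM_BY_RESIDUE))
    nterm_pka <- PKA_NTERM_BY_RESIDUE[[ch[1]]]
  cterm_pka <- PKA_NEGATIVE[["Cterm"]]
  last <- ch[length(ch)]
  if (last %in% names(PKA_CTERM_BY_RESIDUE))
    cterm_pka <- PKA_CTERM_BY_RESIDUE[[last]]
  pos <- 1 / (1 + 10^(ph - nterm_pka))
  for (aa in c("K", "R", "H"))
    pos <- pos + counts[[aa]] / (1 + 10^(ph - PKA_POSITIVE[[aa]]))
  neg <- 1 / (1 + 10^(cterm_pka - ph))
  for (aa in c("D", "E", "C", "Y"))
    neg <- neg + counts[[aa]] / (1 + 10^(PKA_NEGATIVE[[aa]] - ph))
  pos - neg
}

# Isoelectric point by bisection of the net-charge curve, to a pH
# tolerance of `tol`.
isoelectric_point <- function(sequence, tol = 0.01) {
  lo <- 0
  hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (charge_at_ph(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Mean of the nine-residue windowed Vihinen flexibility profile. For
# sequences shorter than one full window the unweighted mean of the
# per-residue scale values is returned instead.
mean_flexibility <- function(sequence) {
  ch <- seq_standard(sequence)
  vals <- FLEXIBILITY[ch]
  w <- FLEX_WINDOW_WEIGHTS / sum(FLEX_WINDOW_WEIGHTS)
  n <- length(vals)
  if (n < 9L) {
    message("sequence shorter than the 9-residue flexibility window; ",
            "using the unweighted per-residue mean")
    return(mean(vals))
  }
  windows <- vapply(seq_len(n - 8L),
                    function(i) sum(w * vals[i:(i + 8L)]),
                    numeric(1))
  mean(windows)
}

# Guruprasad instability index: 10/L * sum of dipeptide weights.
instability_index <- function(sequence) {
  ch <- seq_standard(sequence)
  n <- length(ch)
  if (n < 2L) return(0)
  10 / n * sum(DIWV[cbind(ch[-n], ch[-1])])
}

#' Global physicochemical descriptors
#'
#' Computes the sequence-global descriptor block: length (standard
#' residues), molecular weight (Da; average residue masses minus one water
#' per peptide bond), aromaticity (fraction of F, W, Y), Guruprasad
#' instability index, isoelectric point (bisection of the
#' Henderson-Hasselbalch net-charge curve, 0.01 pH tolerance), net charge
#' at pH 7, and mean windowed Vihinen flexibility.
#'
#' @inheritParams aa_fractions
#' @return Named numeric vector of 7 descriptors.
#' @export
global_descriptors <- function(sequence) {
  ch <- seq_standard(sequence)
  n <- length(ch)
  c(length = n,
    molecular_weight = sum(RESIDUE_MASS[ch]) - (n - 1) * WATER_MASS,
    aromaticity = sum(ch %in% AROMATIC_SET) / n,
    instability_index = instability_index(sequence),
    isoelectric_point = isoelectric_point(sequence),
    charge_ph7 = charge_at_ph(sequence, 7),
    mean_flexibility = mean_flexibility(sequence))
}

#' The default descriptor registry
#'
#' Fixes the names and order of the feature vector: 20 amino-acid
#' fractions, 8 global descriptors, 4 secondary-structure fractions,
#' 20 exposed-versus-total fractions, 20 exposed-versus-exposed fractions,
#' and 3 global exposure descriptors (75 features).
#'
#' @return A `data.frame` with columns `name` and `group`.
#' @export
default_registry <- function() {
  df <- rbind(
    data.frame(name = paste0("aa_", AA_STANDARD), group = "aa_fraction"),
    data.frame(name = c("length", "molecular_weight", "aromaticity",
                        "instability_index", "gravy", "isoelectric_point",
                        "charge_ph7", "mean_flexibility"),
               group = "global"),
    data.frame(name = paste0("ss_", c("helix", "turn", "sheet",
                                      "nonstructure")),
               group = "structure"),
    data.frame(name = paste0("exp_total_", AA_STANDARD),
               group = "exposure_vs_total"),
    data.frame(name = paste0("exp_exposed_", AA_STANDARD),
               group = "exposure_vs_exposed"),
    data.frame(name = c("mean_rsa", "total_asa", "exposed_fraction"),
               group = "exposure_global"))
  stopifnot(!anyDuplicated(df$name))
  df
}

#' Compute the full feature vector for one protein
#'
#' Assembles, in registry order, the amino-acid fractions, global
#' descriptors, GRAVY, secondary-structure fractions, and solvent-exposure
#' fractions. When no per-residue exposure table is supplied, the exposure
#' block is filled from the deterministic heuristic predictor
#' ([heuristic_exposure], `fallback = "heuristic"`, flagged in the
#' `exposure_source` attribute) or set to zero (`fallback = "none"`).
#'
#' @param record a single-row [protein_records] data frame, or a plain
#'   sequence string.
#' @param exposure optional residue table (`position`, `residue`, `rsa`,
#'   `asa`, `exposed`) aligned with the sequence.
#' @param registry descriptor registry (see [default_registry]).
#' @param fallback exposure fallback mode when `exposure` is `NULL`.
#' @return Named numeric vector in registry order, with attribute
#'   `exposure_source` in `c("netsurfp", "heuristic", "none")`.
#' @export
featurize <- function(record, exposure = NULL, registry = default_registry(),
                      fallback = c("heuristic", "none")) {
  fallback <- match.arg(fallback)
  sequence <- if (is.character(record)) record else record$sequence[[1]]
  source <- "netsurfp"
  if (is.null(exposure)) {
    if (fallback == "heuristic") {
      exposure <- heuristic_exposure(sequence)
      source <- "heuristic"
    } else {
      source <- "none"
    }
  } else if (nchar(sequence) != nrow(exposure)) {
    stop("exposure table length (", nrow(exposure),
         ") does not match sequence length (", nchar(sequence), ")")
  }
  aa <- aa_fractions(sequence)
  glob <- global_descriptors(sequence)
  ss <- ss_fractions(sequence)
  if (is.null(exposure)) {
    expo <- list(exposed_vs_total = stats::setNames(numeric(20), AA_STANDARD),
                 exposed_vs_exposed = stats::setNames(numeric(20), AA_STANDARD),
                 mean_rsa = 0, total_asa = 0, exposed_fraction = 0)
  } else {
    expo <- exposure_fractions(sequence, exposure)
  }
  values <- c(stats::setNames(aa, paste0("aa_", names(aa))),
              glob["length"], glob["molecular_weight"], glob["aromaticity"],
              glob["instability_index"], gravy = gravy(sequence),
              glob["isoelectric_point"], glob["charge_ph7"],
              glob["mean_flexibility"],
              stats::setNames(ss, paste0("ss_", names(ss))),
              stats::setNames(expo$exposed_vs_total,
                              paste0("exp_total_", AA_STANDARD)),
              stats::setNames(expo$exposed_vs_exposed,
                              paste0("exp_exposed_", AA_STANDARD)),
              mean_rsa = expo$mean_rsa, total_asa = expo$total_asa,
              exposed_fraction = expo$exposed_fraction)
  missing <- setdiff(registry$name, names(values))
  if (length(missing))
    stop("registry names not computed: ", paste(missing, collapse = ", "))
  out <- values[registry$name]
  attr(out, "exposure_source") <- source
  out
}

#' Featurize a collection of proteins into a feature table
#'
#' @param records a [protein_records] data frame.
#' @param exposures optional named list of residue tables keyed by
#'   accession; proteins absent from the list use the fallback.
#' @inheritParams featurize
#' @return A `data.frame` with `accession`, one column per registry
#'   feature, and an `exposure_source` provenance column.
#' @export
featurize_set <- function(records, exposures = NULL,
                          registry = default_registry(),
                          fallback = c("heuristic", "none")) {
  fallback <- match.arg(fallback)
  rows <- vector("list", nrow(records))
  sources <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    acc <- records$accession[[i]]
    expo <- if (!is.null(exposures) && acc %in% names(exposures))
      exposures[[acc]] else NULL
    v <- featurize(records$sequence[[i]], exposure = expo,
                   registry = registry, fallback = fallback)
    sources[i] <- attr(v, "exposure_source")
    rows[[i]] <- v
  }
  mat <- do.call(rbind, rows)
  out <- data.frame(accession = records$accession, mat,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$exposure_source <- sources
  out
}

#' Fit a min-max scaler on a feature table
#'
#' Records per-feature minimum and maximum so that features can be mapped
#' to `[0, 1]` by `(x - min) / (max - min)`. Constant features map to 0;
#' unseen values are clipped into `[0, 1]` on application.
#'
#' @param x numeric matrix or data frame of feature columns (an
#'   `accession` / `exposure_source` column, if present, is ignored).
#' @return An object of class `minmax_fit`.
#' @export
minmax_fit <- function(x) {
  x <- feature_matrix(x)
  if (nrow(x) < 2L) stop("min-max scaling requires at least 2 rows")
  fit <- list(min = apply(x, 2, min), max = apply(x, 2, max),
              features = colnames(x))
  class(fit) <- "minmax_fit"
  fit
}

#' Apply a fitted min-max scaler
#'
#' @param fit a [minmax_fit] object.
#' @param x numeric matrix, data frame, or named vector whose feature
#'   names match the fit.
#' @return Scaled object of the same shape, all values in `[0, 1]`.
#' @export
minmax_apply <- function(fit, x) {
  single <- is.null(dim(x))
  m <- if (single) matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
       else feature_matrix(x)
  unknown <- setdiff(colnames(m), fit$features)
  missing <- setdiff(fit$features, colnames(m))
  if (length(unknown) || length(missing))
    stop("feature names do not match the scaler fit",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(unknown)) paste0("; unknown: ",
                                     paste(unknown, collapse = ", ")))
  m <- m[, fit$features, drop = FALSE]
  rng <- fit$max - fit$min
  out <- sweep(m, 2, fit$min, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (single) out[1, ] else out
}

# Extract the numeric feature columns of a feature table as a matrix.
feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  drop_cols <- intersect(c("accession", "exposure_source"), names(x))
  x <- x[, setdiff(names(x), drop_cols), drop = FALSE]
  as.matrix(x)
}
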