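# Synthetic-data generator: offline fixtures with the statistical
# structure the pipeline assumes -- class-dependent amino-acid
# composition (glycine-rich / leucine-poor in-corona class), exponential
# abundance decay with a known rate plus an enriched subset, and
# per-residue exposure calls from the heuristic stand-in predictor.

#' Synthetic scenario configuration
#'
#' @param n_in,n_out proteins per class (in-corona / out-of-corona);
#'   defaults 120/280 give the ~30% minority fraction typical of corona
#'   proteomics datasets.
#' @param length_range inclusive range of sequence lengths.
#' @param base_freq baseline amino-acid frequencies (default: UniProt-wide
#'   average composition).
#' @param delta named multiplicative composition deltas applied to the
#'   in-corona class (default: glycine x2, leucine x0.5); frequencies are
#'   renormalized afterwards.
#' @param k_true exponential abundance decay rate (1/abundance units).
#' @param enriched_fraction fraction of proteins whose corona abundance
#'   exceeds the biofluid control, in `[0, 1]`.
#' @param seed integer seed; all generators are pure functions of the
#'   configuration including this seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_in = 120, n_out = 280,
                            length_range = c(100, 400),
                            base_freq = UNIPROT_AA_FREQ,
                            delta = c(G = 2, L = 0.5),
                            k_true = 0.01, enriched_fraction = 0.3,
                            seed = 1) {
  if (length(length_range) != 2L || length_range[1] < 1 ||
      length_range[1] > length_range[2])
    stop("degenerate length range")
  if (any(base_freq <= 0) || !setequal(names(base_freq), AA_STANDARD))
    stop("base_freq must be positive and cover the 20 standard residues")
  if (enriched_fraction < 0 || enriched_fraction > 1)
    stop("enriched_fraction must lie in [0, 1]")
  if (k_true <= 0) stop("k_true must be positive")
  freq_in <- base_freq
  freq_in[names(delta)] <- freq_in[names(delta)] * delta
  structure(list(n_in = as.integer(n_in), n_out = as.integer(n_out),
                 length_range = as.integer(length_range),
                 freq_out = base_freq / sum(base_freq),
                 freq_in = freq_in / sum(freq_in),
                 k_true = k_true, enriched_fraction = enriched_fraction,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate synthetic protein sequences with planted class signal
#'
#' Sequences are drawn i.i.d. per residue from the class-specific
#' frequency vectors; lengths are uniform over the configured range.
#'
#' @param cfg a [scenario_config].
#' @return A list with `records` (a [protein_records] data frame) and
#'   `in_corona` (logical ground-truth class labels).
#' @export
gen_proteins <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_in + cfg$n_out
  in_corona <- c(rep(TRUE, cfg$n_in), rep(FALSE, cfg$n_out))
  lens <- sample(cfg$length_range[1]:cfg$length_range[2], n, replace = TRUE)
  sequences <- vapply(seq_len(n), function(i) {
    freq <- if (in_corona[i]) cfg$freq_in else cfg$freq_out
    paste(sample(AA_STANDARD, lens[i], replace = TRUE, prob = freq),
          collapse = "")
  }, character(1))
  records <- protein_records(sprintf("SYN%04d", seq_len(n)), sequences,
                             biofluid = "other")
  list(records = records, in_corona = in_corona)
}

#' Generate synthetic abundance records
#'
#' Non-enriched proteins draw `a_corona ~ Exp(k_true)` with
#' `a_biofluid = a_corona * Uniform(1, 3)` (guaranteeing non-enrichment);
#' the enriched subset draws `a_biofluid ~ Exp(k_true)` with
#' `a_corona = a_biofluid * Uniform(1.5, 5)`.
#'
#' @param cfg a [scenario_config].
#' @param accessions nonempty character vector of protein identifiers.
#' @param enriched optional logical vector selecting the enriched subset;
#'   by default the first `ceiling(enriched_fraction * n)` accessions.
#' @return A list with `records` (an [abundance_records] data frame, in
#'   accession order) and the ground-truth rate `k_true`.
#' @export
gen_abundances <- function(cfg, accessions, enriched = NULL) {
  if (length(accessions) == 0L) stop("accessions must be nonempty")
  set.seed(cfg$seed + 1L)
  n <- length(accessions)
  if (is.null(enriched)) {
    enriched <- rep(FALSE, n)
    n_enr <- ceiling(cfg$enriched_fraction * n)
    if (n_enr > 0) enriched[seq_len(n_enr)] <- TRUE
  }
  a_corona <- numeric(n)
  a_biofluid <- numeric(n)
  n_non <- sum(!enriched)
  a_corona[!enriched] <- stats::rexp(n_non, rate = cfg$k_true)
  a_biofluid[!enriched] <- a_corona[!enriched] * stats::runif(n_non, 1, 3)
  n_enr <- sum(enriched)
  if (n_enr > 0) {
    a_biofluid[enriched] <- stats::rexp(n_enr, rate = cfg$k_true)
    a_corona[enriched] <- a_biofluid[enriched] * stats::runif(n_enr, 1.5, 5)
  }
  list(records = abundance_records(accessions, a_corona, a_biofluid,
                                   biofluid = "other"),
       k_true = cfg$k_true)
}

#' Generate a complete synthetic scenario
#'
#' Builds a self-consistent bundle: glycine-rich/leucine-poor in-corona
#' sequences, abundances whose enriched subset is exactly the in-corona
#' class, and per-residue exposure calls from the (sampled-mode)
#' heuristic predictor. If `dir` is given, writes `proteins.fasta`,
#' `abundance.csv`, `netsurfp.csv`, and `truth.json` there.
#'
#' @param cfg a [scenario_config].
#' @param dir optional output directory for the fixture files.
#' @param force overwrite a nonempty existing directory.
#' @return (Invisibly when writing) a list with `records`, `in_corona`,
#'   `abundances`, `exposures`, `k_true`, and `cfg`.
#' @export
gen_scenario <- function(cfg, dir = NULL, force = FALSE) {
  prot <- gen_proteins(cfg)
  ab <- gen_abundances(cfg, prot$records$accession,
                       enriched = prot$in_corona)
  set.seed(cfg$seed + 2L)
  expo_seeds <- sample.int(.Machine$integer.max,
                           nrow(prot$records))
  exposures <- lapply(seq_len(nrow(prot$records)), function(i)
    heuristic_exposure(prot$records$sequence[i], seed = expo_seeds[i]))
  names(exposures) <- prot$records$accession
  bundle <- list(records = prot$records, in_corona = prot$in_corona,
                 abundances = ab$records, exposures = exposures,
                 k_true = ab$k_true, cfg = cfg)
  if (is.null(dir)) return(bundle)
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("directory '", dir, "' exists and is nonempty; use force = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(prot$records, file.path(dir, "proteins.fasta"))
  utils::write.csv(ab$records, file.path(dir, "abundance.csv"),
                   row.names = FALSE, quote = FALSE)
  write_netsurfp(exposures, file.path(dir, "netsurfp.csv"))
  jsonlite::write_json(
    list(accession = prot$records$accession, in_corona = prot$in_corona,
         k_true = ab$k_true, seed = cfg$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(bundle)
}
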