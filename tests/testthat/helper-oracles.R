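# Independent brute-force oracles and small fixture builders shared by
# the tests. Scale constants here are typed independently from the
# package internals so descriptor checks are genuine dual-route checks.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte & Doolittle (1982) hydropathy, typed from the published table.
ORACLE_KD <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)

oracle_gravy <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  ch <- ch[ch %in% AA20]
  s <- 0
  for (c in ch) s <- s + ORACLE_KD[[c]]
  s / length(ch)
}

oracle_aa_fractions <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  ch <- ch[ch %in% AA20]
  out <- stats::setNames(numeric(20), sort(AA20))
  for (c in ch) out[[c]] <- out[[c]] + 1
  out / length(ch)
}

oracle_aromaticity <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  ch <- ch[ch %in% AA20]
  sum(ch == "F" | ch == "W" | ch == "Y") / length(ch)
}

# Structure propensity sets, typed independently.
oracle_ss_fractions <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  ch <- ch[ch %in% AA20]
  helix <- c("V", "I", "Y", "F", "W", "L")
  turn <- c("N", "P", "G", "S")
  sheet <- c("E", "M", "A", "L")
  none <- sum(!(ch %in% helix) & !(ch %in% turn) & !(ch %in% sheet))
  c(helix = sum(ch %in% helix), turn = sum(ch %in% turn),
    sheet = sum(ch %in% sheet), nonstructure = none) / length(ch)
}

# Instability via an explicit position loop over the same published
# dipeptide weight table the package embeds (different code path).
oracle_instability <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  ch <- ch[ch %in% AA20]
  s <- 0
  for (i in seq_len(length(ch) - 1))
    s <- s + coronaRF:::DIWV[ch[i], ch[i + 1]]
  10 / length(ch) * s
}

random_sequence <- function(len, letters = AA20) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# A small feature table with two planted informative dimensions.
toy_classification_data <- function(n_per_class = 60, n_noise = 4,
                                    gap = 1.5, sd = 1, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(c(TRUE, FALSE), each = n_per_class)
  x <- matrix(stats::rnorm(n * (2 + n_noise), sd = sd), nrow = n)
  x[labels, 1] <- x[labels, 1] + gap
  x[labels, 2] <- x[labels, 2] - gap
  colnames(x) <- c("sig1", "sig2", paste0("noise", seq_len(n_noise)))
  list(x = x, labels = labels)
}

small_scenario <- function(seed = 5, n_in = 60, n_out = 140,
                           length_range = c(60, 150)) {
  gen_scenario(scenario_config(n_in = n_in, n_out = n_out,
                               length_range = length_range, seed = seed))
}

cli_path <- function() {
  p <- system.file("cli", "coronaRF.R", package = "coronaRF")
  stopifnot(nzchar(p))
  p
}

run_cli <- function(...) {
  out <- system2("Rscript", c(cli_path(), ...), stdout = TRUE,
                 stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("CLI failed (", status, "):\n", paste(out, collapse = "\n"))
  out
}
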