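#' Construct a collection of protein records
#'
#' A protein record holds an accession, an upper-case amino-acid sequence,
#' and optionally a biofluid tag and a free-text name. This is the unit of
#' featurization throughout the package.
#'
#' @param accession character vector of unique, non-empty identifiers.
#' @param sequence character vector of amino-acid sequences (standard
#'   one-letter codes; the ambiguity codes X, B, Z, U, O are tolerated).
#' @param biofluid optional biofluid of origin, one of `"plasma"`, `"csf"`,
#'   `"other"`, or `NA`.
#' @param name optional free-text protein name.
#' @return A `data.frame` of class `protein_records` with columns
#'   `accession`, `sequence`, `biofluid`, `name`.
#' @export
protein_records <- function(accession, sequence, biofluid = NA_character_,
                            name = NA_character_) {
  accession <- as.character(accession)
  sequence <- toupper(as.character(sequence))
  if (length(accession) != length(sequence))
    stop("accession and sequence must have the same length")
  if (any(!nzchar(accession)) || anyNA(accession))
    stop("accessions must be non-empty")
  dup <- unique(accession[duplicated(accession)])
  if (length(dup))
    stop("duplicate accession(s): ", paste(dup, collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("sequences must have length >= 1")
  check_sequence_letters(sequence, accession)
  biofluid <- check_biofluid(rep_len(as.character(biofluid), length(accession)))
  df <- data.frame(accession = accession, sequence = sequence,
                   biofluid = biofluid,
                   name = rep_len(as.character(name), length(accession)),
                   stringsAsFactors = FALSE)
  class(df) <- c("protein_records", "data.frame")
  df
}

check_biofluid <- function(x) {
  bad <- !is.na(x) & !x %in% c("plasma", "csf", "other")
  if (any(bad))
    stop("biofluid must be one of 'plasma', 'csf', 'other' (got: ",
         paste(unique(x[bad]), collapse = ", "), ")")
  x
}

check_sequence_letters <- function(sequence, accession) {
  ok <- c(AA_STANDARD, AA_AMBIGUOUS)
  for (i in seq_along(sequence)) {
    letters_i <- strsplit(sequence[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!letters_i %in% ok)
    if (length(bad))
      stop(sprintf("invalid residue letter '%s' at position %d in '%s'",
                   letters_i[bad[1]], bad[1], accession[[i]]))
  }
  invisible(sequence)
}

#' Read protein sequences from a FASTA file
#'
#' UniProt-style headers `>sp|ACC|NAME ...` (or `tr|`) are parsed so that
#' the accession is the middle field and the name the third; any other
#' header uses its first whitespace-delimited token as the accession.
#' Sequences are upper-cased and trailing `*` stop codons stripped.
#'
#' @param path path to a FASTA file.
#' @param biofluid optional biofluid tag applied to every record.
#' @return A [protein_records] data frame.
#' @export
read_fasta <- function(path, biofluid = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  headers <- names(seqs)
  m <- regmatches(headers, regexec("^(sp|tr)\\|([^| ]+)\\|(\\S+)", headers))
  accession <- character(length(headers))
  name <- rep(NA_character_, length(headers))
  for (i in seq_along(headers)) {
    if (length(m[[i]]) == 4L) {
      accession[i] <- m[[i]][3]
      name[i] <- m[[i]][4]
    } else {
      accession[i] <- strsplit(trimws(headers[i]), "\\s+")[[1]][1]
    }
  }
  sequence <- toupper(as.character(seqs))
  sequence <- sub("\\*+$", "", sequence)
  protein_records(accession, sequence, biofluid = biofluid, name = name)
}

#' Write protein records to a FASTA file
#'
#' Records with a name are written with a UniProt-style `sp|ACC|NAME`
#' header so that [read_fasta] round-trips them exactly; records without a
#' name use the bare accession.
#'
#' @param records a [protein_records] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- ifelse(is.na(records$name), records$accession,
                    sprintf("sp|%s|%s", records$accession, records$name))
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Construct a collection of abundance records
#'
#' Holds, per protein, the LC-MS/MS abundance measured on the
#' nanoparticle-bound sample (`a_corona`) and in the biofluid-only control
#' (`a_biofluid`), in arbitrary but consistent units.
#'
#' @param accession character vector of identifiers.
#' @param a_corona nonnegative corona abundances.
#' @param a_biofluid nonnegative control abundances.
#' @param biofluid optional biofluid label per record.
#' @return A `data.frame` of class `abundance_records`.
#' @export
abundance_records <- function(accession, a_corona, a_biofluid,
                              biofluid = NA_character_) {
  accession <- as.character(accession)
  a_corona <- as.numeric(a_corona)
  a_biofluid <- as.numeric(a_biofluid)
  if (anyNA(a_corona) || anyNA(a_biofluid))
    stop("abundances must be numeric and non-missing (use 0 for undetected)")
  if (any(a_corona < 0) || any(a_biofluid < 0))
    stop("abundances must be nonnegative")
  biofluid <- check_biofluid(rep_len(as.character(biofluid), length(accession)))
  df <- data.frame(accession = accession, a_corona = a_corona,
                   a_biofluid = a_biofluid, biofluid = biofluid,
                   stringsAsFactors = FALSE)
  class(df) <- c("abundance_records", "data.frame")
  df
}

#' Read a quantitative protein abundance table
#'
#' Reads a delimited text table (comma by default; tab for `.tsv`/`.txt`
#' files) with one row per protein. Missing abundance cells are treated as
#' 0, i.e. the protein was not detected in that sample -- the usual
#' convention for label-free quantification exports.
#'
#' @param path path to the delimited file (header row required).
#' @param columns named list mapping the roles `accession`, `a_corona`,
#'   `a_biofluid` (and optionally `biofluid`) to column names in the file.
#' @param sep field separator; `NULL` picks by file extension.
#' @return An [abundance_records] data frame, rows in file order.
#' @export
read_abundance_table <- function(path,
                                 columns = list(accession = "accession",
                                                a_corona = "a_corona",
                                                a_biofluid = "a_biofluid",
                                                biofluid = "biofluid"),
                                 sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("accession", "a_corona", "a_biofluid")
  wanted <- unlist(columns[required])
  missing_cols <- wanted[!wanted %in% names(raw)]
  if (length(missing_cols))
    stop("abundance table is missing required column(s): ",
         paste(missing_cols, collapse = ", "),
         " (expected columns named: ", paste(wanted, collapse = ", "), ")")
  a_corona <- raw[[columns$a_corona]]
  a_biofluid <- raw[[columns$a_biofluid]]
  a_corona[is.na(a_corona)] <- 0
  a_biofluid[is.na(a_biofluid)] <- 0
  biofluid <- NA_character_
  if (!is.null(columns$biofluid) && columns$biofluid %in% names(raw))
    biofluid <- as.character(raw[[columns$biofluid]])
  abundance_records(raw[[columns$accession]], a_corona, a_biofluid, biofluid)
}

#' Write corona labels to CSV
#'
#' @param labels data frame from [assign_labels].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-residue solvent accessibility predictions (NetSurfP 2.0 CSV)
#'
#' Parses the CSV export of NetSurfP 2.0 and returns the per-residue
#' relative (RSA) and absolute (ASA) solvent accessibility grouped per
#' protein, with the exposed/buried call made by [classify_exposure].
#' Positions are 1-based and must be contiguous from 1 within each protein.
#'
#' @param path path to the CSV export.
#' @param columns named character vector mapping the roles `id`, `seq`,
#'   `n`, `rsa`, `asa` to header tokens in the file (defaults match the
#'   NetSurfP 2.0 CSV export).
#' @param rsa_cutoff RSA at or above which a residue is called exposed.
#' @return A named list (one element per accession) of `data.frame`s with
#'   columns `position`, `residue`, `rsa`, `asa`, `exposed`.
#' @export
read_netsurfp <- function(path,
                          columns = c(id = "id", seq = "seq", n = "n",
                                      rsa = "rsa", asa = "asa"),
                          rsa_cutoff = 0.25) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(raw) <- trimws(names(raw))
  missing_cols <- columns[!columns %in% names(raw)]
  if (length(missing_cols))
    stop("NetSurfP table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("NetSurfP file has no residue rows: ", path)
    return(list())
  }
  if (any(raw[[columns["rsa"]]] < 0 | raw[[columns["rsa"]]] > 1))
    stop("RSA values outside [0, 1] in ", path)
  out <- list()
  for (acc in unique(raw[[columns["id"]]])) {
    rows <- raw[raw[[columns["id"]]] == acc, , drop = FALSE]
    rows <- rows[order(rows[[columns["n"]]]), , drop = FALSE]
    pos <- rows[[columns["n"]]]
    if (!identical(as.integer(pos), seq_len(nrow(rows))))
      stop("residue positions for '", acc,
           "' are not contiguous from 1")
    res <- data.frame(position = as.integer(pos),
                      residue = toupper(as.character(rows[[columns["seq"]]])),
                      rsa = as.numeric(rows[[columns["rsa"]]]),
                      asa = as.numeric(rows[[columns["asa"]]]),
                      exposed = NA,
                      stringsAsFactors = FALSE)
    if (any(res$asa < 0)) stop("negative ASA values for '", acc, "'")
    out[[acc]] <- classify_exposure(res, rsa_cutoff = rsa_cutoff)
  }
  out
}

#' Write per-residue exposure calls in NetSurfP 2.0 CSV layout
#'
#' @param exposures named list of residue tables (as from [read_netsurfp]
#'   or [heuristic_exposure]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_netsurfp <- function(exposures, path) {
  rows <- lapply(names(exposures), function(acc) {
    e <- exposures[[acc]]
    data.frame(id = acc, seq = e$residue, n = e$position,
               rsa = e$rsa, asa = e$asa, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
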