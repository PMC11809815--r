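# Consensus epitope calling across interaction models, and chimeric
# antigen assembly.
#
# Each interaction model contributes a set of 1-based residue indices it
# predicts to be at the interface of a protein. Residues supported by at
# least `min_support` models form consensus intervals; short unsupported
# gaps are bridged. Consensus peptides are then combined into a single
# chimeric antigen, joined by lowercase GGGS linkers.

#' Evidence from one interaction model
#'
#' @param model_id model name (e.g. `"silico-1"`, `"music"`).
#' @param protein_id protein the residues belong to.
#' @param residues vector of 1-based residue indices (an interval can be
#'   given as `seq(start, end)`); an empty vector represents a model that
#'   predicts no interface residues for this protein.
#' @return list of class `model_evidence`.
#' @export
model_evidence <- function(model_id, protein_id, residues) {
  residues <- sort(unique(as.integer(residues)))
  if (any(residues < 1)) {
    stop_quantavax("residue indices are 1-based (>= 1)", "quantavax_value_error")
  }
  structure(list(model_id = model_id, protein_id = protein_id,
                 residues = residues),
            class = "model_evidence")
}

#' Read model evidence from JSON
#'
#' The JSON is a list of objects with `model_id`, `protein_id` and either
#' `residues` (index list) or `intervals` (list of `[start, end]` pairs).
#'
#' @param path JSON file.
#' @return list of `model_evidence`.
#' @export
read_evidence_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(entry) {
    residues <- if (!is.null(entry$residues)) {
      unlist(entry$residues)
    } else if (!is.null(entry$intervals)) {
      unlist(lapply(entry$intervals, function(iv) seq(iv[[1]], iv[[2]])))
    } else {
      stop_quantavax("evidence entry needs 'residues' or 'intervals'",
                     "quantavax_schema_error")
    }
    model_evidence(entry$model_id, entry$protein_id, residues)
  })
}

#' Per-residue support counts for one protein
#'
#' @param evidence list of `model_evidence` (all for `protein_id`).
#' @param protein_id protein to profile.
#' @return named integer vector: for residues 1..max observed, the number
#'   of models containing each residue.
#' @export
support_profile <- function(evidence, protein_id) {
  sets <- Filter(function(e) e$protein_id == protein_id, evidence)
  if (length(sets) == 0) {
    stop_quantavax(sprintf("no evidence for protein '%s'", protein_id),
                   "quantavax_input_error")
  }
  max_res <- max(c(0, unlist(lapply(sets, `[[`, "residues"))))
  counts <- integer(max_res)
  for (e in sets) counts[e$residues] <- counts[e$residues] + 1L
  stats::setNames(counts, seq_len(max_res))
}

#' Consensus intervals from a support profile
#'
#' Maximal runs of residues supported by at least `min_support` models;
#' runs separated by at most `merge_gap` unsupported residues are merged
#' into one interval.
#'
#' @param profile integer vector of per-residue support counts (index =
#'   residue number), e.g. from [support_profile()].
#' @param min_support minimum number of agreeing models (default 2).
#' @param merge_gap maximum bridged gap in residues (default 2).
#' @return data.frame with `start`, `end` (1-based inclusive), sorted by
#'   start; zero rows when nothing reaches `min_support`.
#' @export
consensus_intervals <- function(profile, min_support = 2, merge_gap = 2) {
  if (min_support < 1) {
    stop_quantavax("min_support must be >= 1", "quantavax_parameter_error")
  }
  supported <- which(profile >= min_support)
  if (length(supported) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  breaks <- which(diff(supported) > merge_gap + 1)
  out <- data.frame(start = supported[c(1, breaks + 1)],
                    end = supported[c(breaks, length(supported))])
  rownames(out) <- NULL
  out
}

#' Extract a consensus epitope peptide from a protein sequence
#'
#' @param protein_seq amino-acid string (or `Biostrings` string object).
#' @param interval length-2 vector `c(start, end)`, 1-based inclusive.
#' @param protein_id identifier carried into the result.
#' @param support optional per-residue support counts to record.
#' @return list of class `consensus_epitope` with `protein_id`, `start`,
#'   `end`, `sequence`, `support`.
#' @export
extract_epitope <- function(protein_seq, interval, protein_id = "protein",
                            support = NULL) {
  seq <- as.character(protein_seq)
  start <- as.integer(interval[1]); end <- as.integer(interval[2])
  if (start < 1 || end > nchar(seq) || start > end) {
    stop_quantavax(sprintf("interval [%d, %d] out of range for sequence of length %d",
                           start, end, nchar(seq)),
                   "quantavax_bounds_error")
  }
  structure(
    list(protein_id = protein_id, start = start, end = end,
         sequence = substr(seq, start, end),
         support = if (is.null(support)) NULL else support[start:end]),
    class = "consensus_epitope"
  )
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Assemble a chimeric antigen from epitope blocks
#'
#' Joins ordered uppercase amino-acid blocks with a lowercase linker
#' (default GGGS), so linker positions are recoverable from case.
#'
#' @param blocks named character vector or list of `(name, sequence)`
#'   amino-acid blocks (uppercase).
#' @param linker linker peptide (default `"GGGS"`).
#' @return list of class `chimera_design` with `blocks`, `linker` and
#'   `final_sequence` (linkers lowercase).
#' @export
assemble_chimera <- function(blocks, linker = "GGGS") {
  seqs <- vapply(blocks, function(b) {
    if (is.list(b)) as.character(b$sequence) else as.character(b)
  }, character(1))
  if (length(seqs) < 1) {
    stop_quantavax("at least one block is required", "quantavax_value_error")
  }
  for (s in c(seqs, linker)) {
    bad <- setdiff(strsplit(s, "")[[1]], AA_ALPHABET)
    if (length(bad) > 0) {
      stop_quantavax(sprintf("invalid amino-acid character(s): %s",
                             paste(unique(bad), collapse = "")),
                     "quantavax_alphabet_error")
    }
  }
  structure(
    list(blocks = seqs, linker = linker,
         final_sequence = paste(seqs, collapse = tolower(linker))),
    class = "chimera_design"
  )
}

#' Recover chimera blocks from a designed sequence
#'
#' Splits a chimera sequence on lowercase linker runs; inverse of
#' [assemble_chimera()].
#'
#' @param final_sequence chimera string with lowercase linkers.
#' @param linker linker peptide (default `"GGGS"`).
#' @return character vector of uppercase blocks.
#' @export
split_chimera <- function(final_sequence, linker = "GGGS") {
  strsplit(final_sequence, tolower(linker), fixed = TRUE)[[1]]
}

#' Verify a chimera design against a reference sequence
#'
#' @param design `chimera_design` (or a plain sequence string).
#' @param reference_sequence expected sequence (case-significant).
#' @return list with `exact_match`, `case_insensitive_match` and
#'   `first_mismatch` (position of the first differing character, NA on
#'   exact match).
#' @export
verify_chimera <- function(design, reference_sequence) {
  seq <- if (inherits(design, "chimera_design")) design$final_sequence
         else as.character(design)
  ref <- as.character(reference_sequence)
  if (nchar(seq) == 0 || nchar(ref) == 0) {
    stop_quantavax("both sequences must be non-empty", "quantavax_value_error")
  }
  exact <- identical(seq, ref)
  ci <- identical(toupper(seq), toupper(ref))
  first_mismatch <- NA_integer_
  if (!exact) {
    n <- min(nchar(seq), nchar(ref))
    a <- strsplit(seq, "")[[1]][seq_len(n)]
    b <- strsplit(ref, "")[[1]][seq_len(n)]
    diffs <- which(a != b)
    first_mismatch <- if (length(diffs) > 0) diffs[1] else n + 1L
  }
  list(exact_match = exact, case_insensitive_match = ci,
       first_mismatch = first_mismatch,
       length_design = nchar(seq), length_reference = nchar(ref))
}
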