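# Format readers and writers. Residue and interval coordinates are
# 1-based inclusive everywhere; FASTA handling preserves case because
# linker positions in chimera sequences are encoded by case.

#' Read a (multi-MODEL) PDB file into a trajectory
#'
#' Parses ATOM/HETATM records via `bio3d`; MODEL blocks become snapshots.
#' Chain IDs and residue sequence numbers are honored; the atom set must
#' be identical across models.
#'
#' @param path PDB file.
#' @param charges optional named numeric vector of partial charges keyed
#'   by atom_id (chain.resno.name); defaults to 0.
#' @param rmin_half,epsilon per-atom LJ parameters applied to all atoms,
#'   or named vectors keyed like `charges` (default NA).
#' @return list with `atoms` (`atom_sites`) and `traj` (list of
#'   coordinate matrices).
#' @export
read_pdb_models <- function(path, charges = NULL, rmin_half = NA_real_,
                            epsilon = NA_real_) {
  if (!file.exists(path)) {
    stop_quantavax(sprintf("PDB file not found: %s", path), "quantavax_io_error")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) {
      stop_quantavax(sprintf("malformed PDB file %s: %s", path, conditionMessage(e)),
                     "quantavax_parse_error")
    }
  )
  a <- pdb$atom
  atom_id <- sprintf("%s.%d.%s", a$chain, a$resno, a$elety)
  q <- if (is.null(charges)) rep(0, nrow(a)) else unname(charges[atom_id])
  rh <- if (length(rmin_half) > 1) unname(rmin_half[atom_id]) else rmin_half
  ep <- if (length(epsilon) > 1) unname(epsilon[atom_id]) else epsilon
  atoms <- atom_sites(atom_id = atom_id, chain = a$chain, res_index = a$resno,
                      charge = ifelse(is.na(q), 0, q),
                      rmin_half = rh, epsilon = ep)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(a)) {
    stop_quantavax("atom count mismatch across MODEL blocks", "quantavax_trajectory_error")
  }
  traj <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  list(atoms = atoms, traj = traj)
}

#' Write a trajectory as a multi-MODEL PDB file
#'
#' Fixed-width ATOM records wrapped in MODEL/ENDMDL blocks, one block per
#' snapshot. Atom names are synthesized as C1, C2, ... within each
#' residue.
#'
#' @param atoms `atom_sites` table.
#' @param traj list of coordinate matrices (n_atoms x 3).
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_pdb_models <- function(atoms, traj, path) {
  n <- nrow(atoms)
  name_within <- stats::ave(seq_len(n),
                            paste(atoms$chain, atoms$res_index),
                            FUN = seq_along)
  atom_name <- sprintf("C%d", name_within)
  lines <- character(0)
  for (m in seq_along(traj)) {
    xyz <- as.matrix(traj[[m]])
    if (nrow(xyz) != n) {
      stop_quantavax(sprintf("snapshot %d has %d atoms, expected %d",
                             m, nrow(xyz), n),
                     "quantavax_trajectory_error")
    }
    rec <- sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
                   seq_len(n), atom_name, "GLY", atoms$chain, atoms$res_index,
                   xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00)
    lines <- c(lines, sprintf("MODEL     %4d", m), rec, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write an atom parameter table as CSV
#'
#' Columns: atom_id, chain, res_index, charge, rmin_half, epsilon.
#'
#' @param atoms `atom_sites`.
#' @param path output CSV.
#' @return invisibly, the path.
#' @export
write_param_csv <- function(atoms, path) {
  utils::write.csv(as.data.frame(atoms), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an atom parameter table from CSV
#'
#' @param path CSV with columns atom_id, chain, res_index, charge and
#'   optionally rmin_half, epsilon.
#' @return `atom_sites`.
#' @export
read_param_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("atom_id", "chain", "res_index", "charge")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop_quantavax(sprintf("parameter CSV missing columns: %s",
                           paste(missing, collapse = ", ")),
                   "quantavax_schema_error")
  }
  atom_sites(df$atom_id, df$chain, df$res_index, df$charge,
             rmin_half = df$rmin_half %||% NA_real_,
             epsilon = df$epsilon %||% NA_real_)
}

#' Read FASTA preserving case
#'
#' Case is significant (chimera linkers are lowercase), so sequences are
#' read as raw B-strings.
#'
#' @param path FASTA file.
#' @param alphabet optional `"AA"` or `"DNA"`: validates characters
#'   (case-insensitively) against the amino-acid or nucleotide alphabet.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = NULL) {
  if (!file.exists(path)) {
    stop_quantavax(sprintf("FASTA file not found: %s", path), "quantavax_io_error")
  }
  set <- tryCatch(Biostrings::readBStringSet(path), error = function(e) {
    stop_quantavax(sprintf("cannot parse FASTA %s: %s", path, conditionMessage(e)),
                   "quantavax_format_error")
  })
  if (length(set) == 0) {
    stop_quantavax(sprintf("FASTA file %s contains no records", path),
                   "quantavax_format_error")
  }
  seqs <- stats::setNames(as.character(set),
                          vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1))
  seqs <- gsub("\\s", "", seqs)
  if (!is.null(alphabet)) {
    allowed <- if (alphabet == "AA") AA_ALPHABET else c("A", "C", "G", "T", "U")
    for (nm in names(seqs)) {
      bad <- setdiff(unique(strsplit(toupper(seqs[[nm]]), "")[[1]]), allowed)
      if (length(bad) > 0) {
        stop_quantavax(sprintf("record '%s' has illegal %s character(s): %s",
                               nm, alphabet, paste(bad, collapse = "")),
                       "quantavax_alphabet_error")
      }
    }
  }
  seqs
}

#' Write sequences as FASTA, preserving case
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width (default 60).
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
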