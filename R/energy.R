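# Residue-pair protein-protein interaction energies.
#
# For a two-chain complex the interaction energy is the sum over all
# inter-chain atom pairs of an electrostatic term, screened by a sigmoidal
# distance-dependent dielectric, and a 12-6 Lennard-Jones term. Atom-pair
# energies are attributed to residue pairs and averaged over structural
# snapshots; the per-residue marginals of the averaged matrix flag the
# regions most likely to be interacting.
#
# Units: distances in Angstrom, charges in elementary charge units,
# energies in kcal/mol. The Coulomb conversion factor is the AMBER
# convention k_e = 332.0637 kcal*A/(mol*e^2).

COULOMB_KCAL <- 332.0637

#' Sigmoidal distance-dependent dielectric model
#'
#' eps(r) = A + B / (1 + k * exp(-lambda * B * r)) with B = eps0 - A.
#' With the default constants eps(r) rises sigmoidally from ~1.35 at
#' contact to the bulk-water value 78.4 at long range.
#'
#' @param eps0 bulk dielectric limit (default 78.4, water).
#' @param a sigmoid offset A (default -8.5525).
#' @param lam rate constant lambda (default 0.003627).
#' @param k sigmoid constant (default 7.7839).
#' @return object of class `dielectric_model` with derived `b = eps0 - a`.
#' @export
dielectric_model <- function(eps0 = 78.4, a = -8.5525,
                             lam = 0.003627, k = 7.7839) {
  structure(list(eps0 = eps0, a = a, b = eps0 - a, lam = lam, k = k),
            class = "dielectric_model")
}

#' Evaluate the distance-dependent dielectric
#'
#' @param r distance(s) in Angstrom, >= 0.
#' @param model `dielectric_model` (default constants if omitted).
#' @return dielectric value(s), dimensionless.
#' @export
dielectric_eps <- function(r, model = dielectric_model()) {
  assert_finite_numeric(r, "r")
  if (any(r < 0)) {
    stop_quantavax("distance r must be non-negative", "quantavax_domain_error")
  }
  model$a + model$b / (1 + model$k * exp(-model$lam * model$b * r))
}

#' Screened electrostatic pair energy
#'
#' E_el = k_e * q_i * q_j / (eps(r) * r), kcal/mol.
#'
#' @param qi,qj partial charges (elementary charge units).
#' @param r inter-atomic distance in Angstrom, > 0.
#' @param model `dielectric_model`.
#' @return energy in kcal/mol.
#' @export
pair_electrostatic <- function(qi, qj, r, model = dielectric_model()) {
  assert_finite_numeric(r, "r")
  if (any(r <= 0)) {
    stop_quantavax("r must be positive (r = 0 is singular)", "quantavax_singularity_error")
  }
  COULOMB_KCAL * qi * qj / (dielectric_eps(r, model) * r)
}

#' 12-6 Lennard-Jones pair energy
#'
#' E_vdw = A_ij / r^12 - B_ij / r^6, kcal/mol.
#'
#' @param Aij repulsive coefficient (kcal*A^12/mol).
#' @param Bij dispersive coefficient (kcal*A^6/mol).
#' @param r distance in Angstrom, > 0.
#' @return energy in kcal/mol.
#' @export
pair_vdw <- function(Aij, Bij, r) {
  assert_finite_numeric(r, "r")
  if (any(r <= 0)) {
    stop_quantavax("r must be positive (r = 0 is singular)", "quantavax_singularity_error")
  }
  r6 <- r^6
  Aij / (r6 * r6) - Bij / r6
}

#' Combine per-atom Lennard-Jones parameters into pair coefficients
#'
#' Lorentz-Berthelot-style combination in the Rmin/epsilon convention:
#' Rmin_ij = rmin_half_i + rmin_half_j, eps_ij = sqrt(eps_i * eps_j),
#' A_ij = eps_ij * Rmin_ij^12, B_ij = 2 * eps_ij * Rmin_ij^6. The combined
#' pair potential has its minimum -eps_ij at r = Rmin_ij.
#'
#' @param lj_i,lj_j lists with `rmin_half` (Angstrom, > 0) and `epsilon`
#'   (kcal/mol, >= 0).
#' @return list with `Aij`, `Bij`.
#' @export
lj_pair_from_atoms <- function(lj_i, lj_j) {
  rh_i <- lj_i$rmin_half; rh_j <- lj_j$rmin_half
  e_i <- lj_i$epsilon; e_j <- lj_j$epsilon
  if (any(c(rh_i, rh_j) <= 0)) {
    stop_quantavax("rmin_half must be positive", "quantavax_parameter_error")
  }
  if (any(c(e_i, e_j) < 0)) {
    stop_quantavax("epsilon must be non-negative", "quantavax_parameter_error")
  }
  rmin <- rh_i + rh_j
  eps <- sqrt(e_i * e_j)
  list(Aij = eps * rmin^12, Bij = 2 * eps * rmin^6)
}

#' Atom-site table for a two-chain complex
#'
#' @param atom_id atom identifiers (unique).
#' @param chain chain labels; exactly two distinct values are required by
#'   the energy operations.
#' @param res_index 1-based residue numbers.
#' @param charge partial charges (e).
#' @param rmin_half,epsilon per-atom Lennard-Jones parameters (may be NA
#'   when a per-pair table is supplied downstream).
#' @return data.frame of class `atom_sites`.
#' @export
atom_sites <- function(atom_id, chain, res_index, charge,
                       rmin_half = NA_real_, epsilon = NA_real_) {
  df <- data.frame(atom_id = as.character(atom_id),
                   chain = as.character(chain),
                   res_index = as.integer(res_index),
                   charge = as.numeric(charge),
                   rmin_half = as.numeric(rmin_half),
                   epsilon = as.numeric(epsilon),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$atom_id)) {
    stop_quantavax("atom_id values must be unique", "quantavax_value_error")
  }
  if (any(df$res_index < 1)) {
    stop_quantavax("res_index must be >= 1", "quantavax_value_error")
  }
  class(df) <- c("atom_sites", class(df))
  df
}

check_two_chains <- function(atoms) {
  chains <- unique(atoms$chain)
  if (length(chains) != 2) {
    stop_quantavax(sprintf("exactly two chains are required, found %d (%s)",
                           length(chains), paste(chains, collapse = ", ")),
                   "quantavax_chain_error")
  }
  sort(chains)
}

#' Per-frame residue-pair interaction energy matrices
#'
#' Sums electrostatic and Lennard-Jones energies over all inter-chain atom
#' pairs (no distance cutoff unless `cutoff` is set) and attributes each
#' atom-pair energy to its residue pair. Intra-chain pairs never
#' contribute.
#'
#' @param coords numeric matrix (n_atoms x 3) of coordinates in Angstrom,
#'   rows in the order of `atoms`.
#' @param atoms `atom_sites` table describing the two chains.
#' @param model `dielectric_model`.
#' @param cutoff optional distance cutoff in Angstrom beyond which pairs
#'   are skipped (default `Inf`, i.e. all pairs, following the averaging
#'   protocol this scoring implements).
#' @return list of matrices `e_el`, `e_vdw`, `e_total` with chain-1
#'   residues as rows and chain-2 residues as columns (dimnames carry the
#'   residue numbers), chains ordered by sorted chain label.
#' @export
residue_pair_matrix <- function(coords, atoms, model = dielectric_model(),
                                cutoff = Inf) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(atoms) || ncol(coords) != 3) {
    stop_quantavax("coords must be an n_atoms x 3 matrix matching atoms",
                   "quantavax_value_error")
  }
  chains <- check_two_chains(atoms)
  i1 <- which(atoms$chain == chains[1])
  i2 <- which(atoms$chain == chains[2])
  res1 <- sort(unique(atoms$res_index[i1]))
  res2 <- sort(unique(atoms$res_index[i2]))

  # Pairwise distances between the two chains (n1 x n2).
  x1 <- coords[i1, , drop = FALSE]
  x2 <- coords[i2, , drop = FALSE]
  d2 <- outer(rowSums(x1^2), rep(1, nrow(x2))) +
    outer(rep(1, nrow(x1)), rowSums(x2^2)) - 2 * x1 %*% t(x2)
  d <- sqrt(pmax(d2, 0))
  if (any(d == 0)) {
    stop_quantavax("coincident atoms across chains (r = 0)", "quantavax_singularity_error")
  }

  q1 <- atoms$charge[i1]; q2 <- atoms$charge[i2]
  e_el_atom <- COULOMB_KCAL * outer(q1, q2) / (dielectric_eps(d, model) * d)

  rh1 <- atoms$rmin_half[i1]; rh2 <- atoms$rmin_half[i2]
  ep1 <- atoms$epsilon[i1]; ep2 <- atoms$epsilon[i2]
  if (any(is.na(rh1)) || any(is.na(rh2)) || any(is.na(ep1)) || any(is.na(ep2))) {
    stop_quantavax("per-atom LJ parameters (rmin_half, epsilon) are required",
                   "quantavax_parameter_error")
  }
  rmin <- outer(rh1, rh2, `+`)
  epsp <- sqrt(outer(ep1, ep2))
  sr6 <- (rmin / d)^6
  e_vdw_atom <- epsp * (sr6^2 - 2 * sr6)

  if (is.finite(cutoff)) {
    keep <- d <= cutoff
    e_el_atom <- e_el_atom * keep
    e_vdw_atom <- e_vdw_atom * keep
  }

  # Aggregate atom-pair energies into residue pairs.
  f1 <- factor(atoms$res_index[i1], levels = res1)
  f2 <- factor(atoms$res_index[i2], levels = res2)
  agg <- function(m) {
    by_row <- rowsum(m, group = f1, reorder = FALSE)
    t(rowsum(t(by_row), group = f2, reorder = FALSE))
  }
  e_el <- agg(e_el_atom)
  e_vdw <- agg(e_vdw_atom)
  dimnames(e_el) <- dimnames(e_vdw) <- list(as.character(res1), as.character(res2))
  list(chains = chains, e_el = e_el, e_vdw = e_vdw, e_total = e_el + e_vdw)
}

#' Average residue-pair energies over a snapshot ensemble
#'
#' @param traj list of coordinate matrices (each n_atoms x 3, identical
#'   atom order), e.g. from [read_pdb_models()] or [gen_complex()].
#' @param atoms `atom_sites` table.
#' @param model `dielectric_model`.
#' @param cutoff optional distance cutoff (see [residue_pair_matrix()]).
#' @return object of class `residue_pair_energy`: list with averaged
#'   matrices `e_el`, `e_vdw`, `e_total`, chain labels and `n_snapshots`.
#' @export
average_over_trajectory <- function(traj, atoms, model = dielectric_model(),
                                    cutoff = Inf) {
  if (length(traj) < 1) {
    stop_quantavax("at least one snapshot is required", "quantavax_trajectory_error")
  }
  n_atoms <- nrow(atoms)
  for (i in seq_along(traj)) {
    if (nrow(as.matrix(traj[[i]])) != n_atoms) {
      stop_quantavax(sprintf("snapshot %d has %d atoms, expected %d",
                             i, nrow(as.matrix(traj[[i]])), n_atoms),
                     "quantavax_trajectory_error")
    }
  }
  mats <- lapply(traj, residue_pair_matrix, atoms = atoms, model = model,
                 cutoff = cutoff)
  avg <- function(field) Reduce(`+`, lapply(mats, `[[`, field)) / length(mats)
  structure(
    list(chains = mats[[1]]$chains,
         e_el = avg("e_el"), e_vdw = avg("e_vdw"), e_total = avg("e_total"),
         n_snapshots = length(traj)),
    class = "residue_pair_energy"
  )
}

#' @export
print.residue_pair_energy <- function(x, ...) {
  cat(sprintf("Residue-pair interaction energies: %s (%d res) x %s (%d res), %d snapshot(s)\n",
              x$chains[1], nrow(x$e_total), x$chains[2], ncol(x$e_total),
              x$n_snapshots))
  cat(sprintf("  total inter-chain energy: %.3f kcal/mol\n", sum(x$e_total)))
  invisible(x)
}

#' Candidate interacting regions from a residue-pair energy matrix
#'
#' Scores each residue by its summed average interaction energy with the
#' partner chain. Residues scoring at or below mean - z_threshold * SD
#' (i.e. the most favourable tail) seed regions; seeds separated by at
#' most `merge_gap` residues are merged. Regions are ranked by mean
#' per-residue energy, most favourable first.
#'
#' @param energy `residue_pair_energy` object (or a per-frame list from
#'   [residue_pair_matrix()]).
#' @param z_threshold number of SDs below the mean a residue score must be
#'   to seed a region (default 1).
#' @param merge_gap maximum number of intervening residues bridged when
#'   merging seeds (default 2).
#' @return data.frame with columns `chain`, `start`, `end`, `mean_energy`,
#'   `rank`; zero rows (with attribute `zero_variance = TRUE`, plus a
#'   warning) when a chain's score vector has no variance.
#' @export
find_interaction_regions <- function(energy, z_threshold = 1, merge_gap = 2) {
  e_total <- energy$e_total
  if (length(e_total) == 0) {
    stop_quantavax("empty energy matrix", "quantavax_value_error")
  }
  per_chain <- list(
    list(chain = energy$chains[1],
         res = as.integer(rownames(e_total)), score = rowSums(e_total)),
    list(chain = energy$chains[2],
         res = as.integer(colnames(e_total)), score = colSums(e_total))
  )
  zero_var <- FALSE
  out <- list()
  for (pc in per_chain) {
    s <- pc$score
    if (stats::sd(s) == 0) {
      zero_var <- TRUE
      next
    }
    thr <- mean(s) - z_threshold * stats::sd(s)
    seeds <- pc$res[s <= thr]
    if (length(seeds) == 0) next
    seeds <- sort(seeds)
    breaks <- which(diff(seeds) > merge_gap + 1)
    starts <- seeds[c(1, breaks + 1)]
    ends <- seeds[c(breaks, length(seeds))]
    for (j in seq_along(starts)) {
      span <- pc$res >= starts[j] & pc$res <= ends[j]
      out[[length(out) + 1]] <- data.frame(
        chain = pc$chain, start = starts[j], end = ends[j],
        mean_energy = mean(s[span]), stringsAsFactors = FALSE)
    }
  }
  if (zero_var) {
    warning("zero-variance residue score vector; no regions reported for that chain")
  }
  if (length(out) == 0) {
    res <- data.frame(chain = character(), start = integer(), end = integer(),
                      mean_energy = numeric(), rank = integer(),
                      stringsAsFactors = FALSE)
    attr(res, "zero_variance") <- zero_var
    return(res)
  }
  res <- do.call(rbind, out)
  res$rank <- rank(res$mean_energy, ties.method = "first")
  res <- res[order(res$rank), ]
  rownames(res) <- NULL
  attr(res, "zero_variance") <- zero_var
  res
}

#' Write a residue-pair energy matrix as TSV
#'
#' Rows are chain-1 residues, columns chain-2 residues; the first column
#' holds the chain-1 residue number.
#'
#' @param energy `residue_pair_energy` object.
#' @param path output file.
#' @param field which matrix to write (default `"e_total"`).
#' @return invisibly, the path.
#' @export
write_energy_tsv <- function(energy, path, field = c("e_total", "e_el", "e_vdw")) {
  field <- match.arg(field)
  m <- energy[[field]]
  df <- data.frame(residue = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
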