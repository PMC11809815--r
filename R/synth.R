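# Seeded synthetic-data generators. Each generator takes an explicit seed
# and uses one local RNG stream, so outputs are bit-reproducible and do
# not disturb the caller's RNG state.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

rtruncnorm0 <- function(n, mean, sd) {
  # Normal truncated at zero by resampling; adequate for the mild
  # truncation of tick-fitness metrics (mean >> 0 relative to sd).
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  tries <- 0
  while (length(bad) > 0 && tries < 100) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < 0)
    tries <- tries + 1
  }
  x[x < 0] <- 0
  x
}

#' Generate a synthetic vaccination trial
#'
#' Per-animal tick-fitness metrics are drawn from zero-truncated normals
#' whose control means/SDs are configurable; vaccinated-group means are
#' the control means scaled by per-metric effect multipliers (1 = no
#' effect), with SDs scaled by the same factor. Tick counts are rounded
#' to integers.
#'
#' @param n_per_group animals per arm.
#' @param control_means,control_sds named numeric vectors with entries
#'   `nt`, `wt`, `pat`, `pplo`. Defaults follow the magnitudes typical of
#'   a pen trial with ~10,000-larvae challenges: 1459 +/- 206 engorged
#'   females, 273 +/- 17 mg/tick, 109 +/- 12 mg eggs/tick, fertility
#'   0.52 +/- 0.11.
#' @param effect_multipliers named list: one numeric vector (entries
#'   `nt`, `wt`, `pat`, `pplo`) per vaccinated group.
#' @param alpha significance level stored in the trial.
#' @param seed RNG seed (mandatory).
#' @return `trial_table`.
#' @export
gen_trial <- function(n_per_group = 3,
                      control_means = c(nt = 1459, wt = 273, pat = 109, pplo = 0.52),
                      control_sds = c(nt = 206, wt = 17, pat = 12, pplo = 0.11),
                      effect_multipliers = list(vaccinated = c(nt = 0.57, wt = 1,
                                                               pat = 1, pplo = 0.67)),
                      alpha = 0.05, seed) {
  if (missing(seed)) stop_quantavax("seed is required", "quantavax_parameter_error")
  metrics <- c("nt", "wt", "pat", "pplo")
  if (!all(metrics %in% names(control_means)) ||
      !all(metrics %in% names(control_sds))) {
    stop_quantavax("control_means/control_sds need nt, wt, pat, pplo",
                   "quantavax_parameter_error")
  }
  if (any(control_means[metrics] <= 0) || any(control_sds[metrics] < 0)) {
    stop_quantavax("means must be > 0 and SDs >= 0", "quantavax_parameter_error")
  }
  for (g in names(effect_multipliers)) {
    if (any(effect_multipliers[[g]][metrics] <= 0)) {
      stop_quantavax("effect multipliers must be > 0", "quantavax_parameter_error")
    }
  }
  with_seed(seed, {
    draw_group <- function(mult, prefix) {
      vals <- lapply(metrics, function(m) {
        x <- rtruncnorm0(n_per_group, control_means[[m]] * mult[[m]],
                         control_sds[[m]] * mult[[m]])
        if (m == "nt") round(x) else x
      })
      names(vals) <- metrics
      data.frame(animal_id = paste0(prefix, seq_len(n_per_group)),
                 nt = vals$nt, wt = vals$wt, pat = vals$pat, pplo = vals$pplo,
                 stringsAsFactors = FALSE)
    }
    control <- draw_group(c(nt = 1, wt = 1, pat = 1, pplo = 1), "c")
    groups <- lapply(names(effect_multipliers), function(g) {
      draw_group(effect_multipliers[[g]], substr(g, 1, 1))
    })
    names(groups) <- names(effect_multipliers)
    trial_table(control, groups, alpha = alpha)
  })
}

#' Generate a synthetic two-chain complex with a contact patch
#'
#' Builds a point-charge model of a two-chain complex: residues are laid
#' out on parallel lines 'background_separation' Angstrom apart, except
#' that the residues of the contact patch on chain 2 are moved opposite
#' the chain-1 patch at `separation` Angstrom. Patch atoms carry opposite
#' unit charges (+1 on chain 1, -1 on chain 2); all other atoms are
#' neutral. All atoms share mild Lennard-Jones parameters (rmin/2 =
#' 1.908 A, epsilon = 0.1094 kcal/mol). Snapshots add isotropic Gaussian
#' jitter to every coordinate.
#'
#' @param n_res residues per chain (each chain the same).
#' @param atoms_per_res atoms per residue (stacked 0.8 A apart in z).
#' @param patch1,patch2 1-based residue intervals `c(start, end)` of the
#'   contact patch on chains 1 and 2.
#' @param separation patch inter-chain distance (Angstrom).
#' @param background_separation distance between non-patch residues of
#'   the two chains (Angstrom; must exceed `separation`).
#' @param n_snapshots number of coordinate frames.
#' @param jitter_sd per-coordinate Gaussian jitter SD (Angstrom).
#' @param seed RNG seed (mandatory).
#' @return list with `atoms` (`atom_sites`), `traj` (list of coordinate
#'   matrices) and `spec` (the generating parameters).
#' @export
gen_complex <- function(n_res = 20, atoms_per_res = 2,
                        patch1 = c(5, 9), patch2 = c(10, 14),
                        separation = 4, background_separation = 30,
                        n_snapshots = 5, jitter_sd = 0.1, seed) {
  if (missing(seed)) stop_quantavax("seed is required", "quantavax_parameter_error")
  if (separation >= background_separation) {
    stop_quantavax("separation must be smaller than background_separation",
                   "quantavax_parameter_error")
  }
  for (iv in list(patch1, patch2)) {
    if (iv[1] < 1 || iv[2] > n_res || iv[1] > iv[2]) {
      stop_quantavax("patch interval out of chain range", "quantavax_parameter_error")
    }
  }
  res_spacing <- 5
  build_chain <- function(chain, y) {
    do.call(rbind, lapply(seq_len(n_res), function(i) {
      t(vapply(seq_len(atoms_per_res), function(a) {
        c(i * res_spacing, y, (a - 1) * 0.8)
      }, numeric(3)))
    }))
  }
  xyz1 <- build_chain("A", 0)
  xyz2 <- build_chain("B", background_separation)
  # Move the chain-2 patch opposite the chain-1 patch.
  for (k in seq(0, patch2[2] - patch2[1])) {
    res2 <- patch2[1] + k
    res1 <- min(patch1[1] + k, patch1[2])
    rows <- ((res2 - 1) * atoms_per_res + 1):(res2 * atoms_per_res)
    xyz2[rows, 1] <- res1 * res_spacing
    xyz2[rows, 2] <- separation
  }
  base <- rbind(xyz1, xyz2)
  res_index <- rep(rep(seq_len(n_res), each = atoms_per_res), 2)
  chain <- rep(c("A", "B"), each = n_res * atoms_per_res)
  in_patch <- (chain == "A" & res_index >= patch1[1] & res_index <= patch1[2]) |
              (chain == "B" & res_index >= patch2[1] & res_index <= patch2[2])
  charge <- ifelse(in_patch, ifelse(chain == "A", 1, -1), 0)
  atoms <- atom_sites(
    atom_id = sprintf("%s%d.%d", chain, res_index,
                      rep(rep(seq_len(atoms_per_res), n_res), 2)),
    chain = chain, res_index = res_index, charge = charge,
    rmin_half = 1.908, epsilon = 0.1094
  )
  with_seed(seed, {
    traj <- lapply(seq_len(n_snapshots), function(s) {
      frame <- base
      if (jitter_sd > 0) {
        attempts <- 0
        repeat {
          cand <- base + matrix(stats::rnorm(length(base), 0, jitter_sd),
                                ncol = 3)
          if (min(stats::dist(cand)) > 0) { frame <- cand; break }
          attempts <- attempts + 1
          if (attempts >= 100) {
            stop_quantavax("could not jitter atoms apart after 100 attempts",
                           "quantavax_internal_error")
          }
        }
      }
      frame
    })
    list(atoms = atoms, traj = traj,
         spec = list(n_res = n_res, atoms_per_res = atoms_per_res,
                     patch1 = patch1, patch2 = patch2,
                     separation = separation,
                     background_separation = background_separation,
                     n_snapshots = n_snapshots, jitter_sd = jitter_sd,
                     seed = seed))
  })
}

#' Generate a random coding sequence with periodic cysteine codons
#'
#' Random sense codons with TGC (Cys, the cadential codon of the default
#' sonification table) forced at every `cys_period`-th position, emulating
#' the recurrent cadence structure of real coding sequences.
#'
#' @param n_codons number of codons (>= 0).
#' @param cys_period insert TGC every this many codons (0 = never).
#' @param seed RNG seed (mandatory).
#' @return DNA string of length `3 * n_codons`.
#' @export
gen_codon_sequence <- function(n_codons, cys_period = 0, seed) {
  if (missing(seed)) stop_quantavax("seed is required", "quantavax_parameter_error")
  if (n_codons == 0) return("")
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  # Restrict the random draw to codons that are non-cadential under the
  # default table, so cadences land exactly at the forced TGC positions.
  table <- default_codon_table()
  cadential <- vapply(sense, function(cd) {
    rule <- table[[chartr("T", "U", cd)]]
    length(rule$tokens) == 1 && rule$durations[1] == 3
  }, logical(1))
  sense <- sense[!cadential]
  with_seed(seed, {
    codons <- sample(sense, n_codons, replace = TRUE)
    if (cys_period > 0) {
      codons[seq_along(codons) %% cys_period == 0] <- "TGC"
    }
    paste(codons, collapse = "")
  })
}

#' Generate synthetic per-model interface evidence
#'
#' Each model keeps each residue of the true interacting interval with
#' probability `retain_prob` and adds spurious residues outside it, each
#' outside position included with probability `spurious_rate`.
#'
#' @param true_interval `c(start, end)` of the true interface.
#' @param protein_id protein identifier.
#' @param n_models number of models (default 4).
#' @param retain_prob per-residue retention probability (default 0.8).
#' @param spurious_rate per-outside-residue inclusion probability
#'   (default 0.1).
#' @param protein_length length of the protein (defines the spurious
#'   candidate range; default `true_interval[2] + 20`).
#' @param seed RNG seed (mandatory).
#' @return list of `model_evidence`.
#' @export
gen_evidence <- function(true_interval, protein_id = "protein", n_models = 4,
                         retain_prob = 0.8, spurious_rate = 0.1,
                         protein_length = true_interval[2] + 20, seed) {
  if (missing(seed)) stop_quantavax("seed is required", "quantavax_parameter_error")
  if (retain_prob < 0 || retain_prob > 1 || spurious_rate < 0 || spurious_rate > 1) {
    stop_quantavax("probabilities must be in [0, 1]", "quantavax_parameter_error")
  }
  true_res <- seq(true_interval[1], true_interval[2])
  outside <- setdiff(seq_len(protein_length), true_res)
  with_seed(seed, {
    lapply(seq_len(n_models), function(m) {
      kept <- true_res[stats::runif(length(true_res)) < retain_prob]
      spur <- outside[stats::runif(length(outside)) < spurious_rate]
      model_evidence(paste0("model-", m), protein_id, sort(c(kept, spur)))
    })
  })
}
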