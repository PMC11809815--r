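# Umbrella pipeline: run selected stages from a single configuration and
# write their outputs plus a reproducibility manifest.

pipeline_stage_names <- c("efficacy", "energy", "sonify", "consensus")

#' Run the antigen-design pipeline
#'
#' Executes the requested stages in order and writes JSON/TSV artifacts
#' under `out_dir`, plus a `manifest.json` recording inputs, parameters,
#' seed, package version and output checksums.
#'
#' Config structure (list or YAML file path); unknown top-level keys are
#' rejected:
#' \describe{
#'   \item{stages}{character vector among efficacy, energy, sonify,
#'     consensus.}
#'   \item{seed}{integer seed used by any stage that simulates inputs.}
#'   \item{efficacy}{list: `trial_csv` (path), optional `alpha`, `sided`.}
#'   \item{energy}{list: either `pdb` + `params_csv` (paths) or
#'     `synthetic = TRUE` with optional generator overrides; optional
#'     `z_threshold`, `merge_gap`.}
#'   \item{sonify}{list: `fasta` (path) or `n_codons`/`cys_period` for a
#'     synthetic sequence; optional `format` (abc/musicxml/midi).}
#'   \item{consensus}{list: `evidence_json`, `protein_fasta` (named
#'     paths), optional `min_support`, `merge_gap`.}
#' }
#'
#' @param config list or path to a YAML file.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  known <- c("stages", "seed", pipeline_stage_names)
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop_quantavax(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
                   "quantavax_validation_error")
  }
  stages <- config$stages %||% intersect(pipeline_stage_names, names(config))
  bad <- setdiff(stages, pipeline_stage_names)
  if (length(bad) > 0) {
    stop_quantavax(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
                   "quantavax_validation_error")
  }
  stages <- pipeline_stage_names[pipeline_stage_names %in% stages]
  seed <- config$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)

  write_json_out <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <<- c(outputs, path)
    path
  }

  if ("efficacy" %in% stages) {
    cfg <- config$efficacy %||% list()
    trial <- read_trial_csv(cfg$trial_csv, alpha = cfg$alpha %||% 0.05)
    summaries <- lapply(names(trial$groups), function(g) {
      s <- vaccine_efficacy(trial, g, sided = cfg$sided %||% "one")
      list(group = g,
           effects = s$effects,
           crt = s$crt, cro = s$cro, crf = s$crf,
           efficacy_pct = s$efficacy_pct,
           efficacy_display = s$efficacy_display)
    })
    write_json_out(summaries, "efficacy_summary.json")
  }

  if ("energy" %in% stages) {
    cfg <- config$energy %||% list()
    if (isTRUE(cfg$synthetic) || is.null(cfg$pdb)) {
      cx <- gen_complex(
        n_res = cfg$n_res %||% 20,
        separation = cfg$separation %||% 4,
        background_separation = cfg$background_separation %||% 30,
        n_snapshots = cfg$n_snapshots %||% 5,
        seed = seed
      )
      atoms <- cx$atoms; traj <- cx$traj
    } else {
      atoms <- read_param_csv(cfg$params_csv)
      loaded <- read_pdb_models(cfg$pdb)
      traj <- loaded$traj
      if (nrow(loaded$atoms) != nrow(atoms)) {
        stop_quantavax("PDB and parameter table disagree on atom count",
                       "quantavax_data_error")
      }
    }
    energy <- average_over_trajectory(traj, atoms)
    tsv <- file.path(out_dir, "energy_matrix.tsv")
    write_energy_tsv(energy, tsv)
    outputs <- c(outputs, tsv)
    regions <- find_interaction_regions(energy,
                                        z_threshold = cfg$z_threshold %||% 1,
                                        merge_gap = cfg$merge_gap %||% 2)
    write_json_out(regions, "interaction_regions.json")
  }

  if ("sonify" %in% stages) {
    cfg <- config$sonify %||% list()
    if (!is.null(cfg$fasta)) {
      seqs <- read_fasta(cfg$fasta)
      seq <- seqs[[1]]
      source_id <- names(seqs)[1]
    } else {
      seq <- gen_codon_sequence(cfg$n_codons %||% 161,
                                cys_period = cfg$cys_period %||% 20,
                                seed = seed)
      source_id <- "synthetic_cds"
    }
    table <- if (!is.null(cfg$codon_table)) read_codon_table(cfg$codon_table)
             else default_codon_table()
    score <- sonify_sequence(seq, table, source_id = source_id)
    fmt <- cfg$format %||% "abc"
    ext <- c(abc = "abc", musicxml = "musicxml", midi = "mid")[[fmt]]
    score_path <- file.path(out_dir, paste0("score.", ext))
    export_score(score, score_path, format = fmt)
    outputs <- c(outputs, score_path)
    seg <- segment_by_cadence(score)
    write_json_out(list(source_id = score$source_id,
                        n_measures = length(score$measures),
                        boundaries = seg$boundaries,
                        segments = seg$segments),
                   "cadence_segments.json")
  }

  if ("consensus" %in% stages) {
    cfg <- config$consensus %||% list()
    evidence <- read_evidence_json(cfg$evidence_json)
    proteins <- read_fasta(cfg$protein_fasta)
    result <- lapply(names(proteins), function(pid) {
      prof <- support_profile(evidence, pid)
      ivs <- consensus_intervals(prof,
                                 min_support = cfg$min_support %||% 2,
                                 merge_gap = cfg$merge_gap %||% 2)
      peptides <- lapply(seq_len(nrow(ivs)), function(i) {
        ep <- extract_epitope(proteins[[pid]], c(ivs$start[i], ivs$end[i]),
                              protein_id = pid, support = prof)
        list(start = ep$start, end = ep$end, sequence = ep$sequence)
      })
      list(protein_id = pid, intervals = ivs, peptides = peptides)
    })
    write_json_out(result, "consensus_epitopes.json")
  }

  manifest <- list(
    package = "quantavax",
    version = as.character(utils::packageVersion("quantavax")),
    seed = seed,
    stages = stages,
    config = config,
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
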