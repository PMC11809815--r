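# Codon sonification: one 3/4 measure per codon.
#
# Each codon maps to a fixed melodic/rhythmic formula: a "base" of one or
# two pitches optionally followed by one or two more pitches, with beat
# durations always summing to exactly 3 quarter-note beats. A single-pitch
# base with no following notes fills the whole measure (a dotted half
# note) and acts as a cadence - a resting point used to segment the
# melodic line. Pitch tokens are the seven letter names C D E F G A B;
# solfege spellings (S = sol = G, L = la = A, R = re = D) are
# canonicalised on table load. "z" denotes a rest (used for stop codons).

SOLFEGE_MAP <- c(S = "G", L = "A", R = "D")
PITCH_TOKENS <- c("C", "D", "E", "F", "G", "A", "B", "z")

canonical_tokens <- function(tokens) {
  tokens <- as.character(tokens)
  mapped <- ifelse(tokens %in% names(SOLFEGE_MAP), SOLFEGE_MAP[tokens], tokens)
  bad <- setdiff(mapped, PITCH_TOKENS)
  if (length(bad) > 0) {
    stop_quantavax(sprintf("unknown pitch token(s): %s", paste(bad, collapse = ", ")),
                   "quantavax_value_error")
  }
  unname(mapped)
}

# The ten published codon formulas. n_base = how many tokens form the
# base; the rest are following notes.
printed_codon_rules <- function() {
  list(
    UGC = list(tokens = c("B"),                durations = 3,                      n_base = 1),
    CAA = list(tokens = c("E", "F"),           durations = c(2, 1),                n_base = 2),
    UCG = list(tokens = c("G", "D"),           durations = c(2, 1),                n_base = 1),
    UCC = list(tokens = c("G", "E", "D"),      durations = c(2, 0.5, 0.5),         n_base = 1),
    GCG = list(tokens = c("C", "D", "D"),      durations = c(1.5, 0.5, 1),         n_base = 2),
    GCC = list(tokens = c("C", "D", "E", "D"), durations = c(1.5, 0.5, 0.5, 0.5),  n_base = 2),
    GGA = list(tokens = c("S", "L"),           durations = c(2, 1),                n_base = 2),
    GGC = list(tokens = c("S", "L", "D", "R"), durations = c(1.5, 0.5, 0.5, 0.5),  n_base = 2),
    UCA = list(tokens = c("S"),                durations = 3,                      n_base = 1),
    UCU = list(tokens = c("S", "L"),           durations = c(1.5, 1.5),            n_base = 1)
  )
}

#' Default 64-codon sonification table
#'
#' The ten published codon formulas are fixed; the remaining 54 codons are
#' filled by a deterministic extrapolation that is NOT part of the
#' published model: each synonymous codon family (amino acid) receives a
#' base pitch from a fixed rotation of the seven letter names, and the
#' rhythmic pattern is chosen by the codon's third base (A: full-measure
#' base; G: half + quarter; C: half + two eighths; U: two dotted
#' quarters), with following pitches stepping upward through the letter
#' cycle. Stop codons map to a full-measure rest. Override any or all
#' entries via [read_codon_table()].
#'
#' @return named list of codon rules (class `codon_table`); each rule has
#'   `tokens` (canonical pitch letters), `durations` (beats, summing to
#'   3) and `n_base`.
#' @export
default_codon_table <- function() {
  letters7 <- c("C", "D", "E", "F", "G", "A", "B")
  gc <- Biostrings::GENETIC_CODE
  codons_dna <- names(gc)
  codons <- chartr("T", "U", codons_dna)
  aas <- unname(gc)
  aa_levels <- sort(unique(aas[aas != "*"]))
  base_for_aa <- stats::setNames(letters7[(seq_along(aa_levels) - 1) %% 7 + 1],
                                 aa_levels)
  step <- function(tok, by) {
    letters7[(match(tok, letters7) - 1 + by) %% 7 + 1]
  }
  table <- printed_codon_rules()
  for (i in seq_along(codons)) {
    codon <- codons[i]
    if (!is.null(table[[codon]])) next
    aa <- aas[i]
    if (aa == "*") {
      table[[codon]] <- list(tokens = "z", durations = 3, n_base = 1)
      next
    }
    base <- base_for_aa[[aa]]
    third <- substr(codon, 3, 3)
    rule <- switch(third,
      A = list(tokens = base, durations = 3, n_base = 1),
      G = list(tokens = c(base, step(base, 1)), durations = c(2, 1), n_base = 1),
      C = list(tokens = c(base, step(base, 1), step(base, 2)),
               durations = c(2, 0.5, 0.5), n_base = 1),
      U = list(tokens = c(base, step(base, 2)), durations = c(1.5, 1.5), n_base = 1)
    )
    table[[codon]] <- rule
  }
  table <- lapply(table, function(rule) {
    rule$tokens <- canonical_tokens(rule$tokens)
    rule
  })
  validate_codon_table(table)
}

validate_codon_table <- function(table) {
  for (codon in names(table)) {
    rule <- table[[codon]]
    if (abs(sum(rule$durations) - 3) > 1e-9) {
      stop_quantavax(sprintf("codon %s: durations sum to %g, not 3 beats",
                             codon, sum(rule$durations)),
                     "quantavax_value_error")
    }
    if (length(rule$tokens) != length(rule$durations)) {
      stop_quantavax(sprintf("codon %s: %d tokens but %d durations",
                             codon, length(rule$tokens), length(rule$durations)),
                     "quantavax_value_error")
    }
    if (is.null(rule$n_base) || rule$n_base < 1 || rule$n_base > length(rule$tokens)) {
      stop_quantavax(sprintf("codon %s: invalid n_base", codon), "quantavax_value_error")
    }
  }
  structure(table, class = "codon_table")
}

#' Read a codon sonification table from YAML
#'
#' The YAML maps each RNA codon to `tokens`, `durations` and `n_base`;
#' solfege tokens are canonicalised. Entries override the built-in
#' defaults when `merge_default = TRUE`.
#'
#' @param path YAML file.
#' @param merge_default start from [default_codon_table()] and override
#'   listed codons (default TRUE).
#' @return `codon_table`.
#' @export
read_codon_table <- function(path, merge_default = TRUE) {
  raw <- yaml::read_yaml(path)
  table <- if (merge_default) unclass(default_codon_table()) else list()
  for (codon in names(raw)) {
    entry <- raw[[codon]]
    table[[chartr("T", "U", toupper(codon))]] <- list(
      tokens = canonical_tokens(entry$tokens),
      durations = as.numeric(entry$durations),
      n_base = as.integer(entry$n_base %||% 1)
    )
  }
  validate_codon_table(table)
}

#' Write a codon table as YAML
#'
#' @param table `codon_table`.
#' @param path output YAML file.
#' @return invisibly, the path.
#' @export
write_codon_table <- function(table, path) {
  out <- lapply(unclass(table), function(rule) {
    list(tokens = as.list(rule$tokens),
         durations = as.list(rule$durations),
         n_base = rule$n_base)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Split a coding sequence into RNA codons
#'
#' @param seq DNA or RNA string (ACGT/ACGU, case-insensitive).
#' @param drop_stop drop a single trailing stop codon if present
#'   (default TRUE, so a CDS of N amino acids yields N codons).
#' @return character vector of RNA codons.
#' @export
transcribe_codons <- function(seq, drop_stop = TRUE) {
  seq <- toupper(gsub("\\s", "", seq))
  seq <- chartr("T", "U", seq)
  if (nchar(seq) == 0) return(character())
  bad <- gsub("[ACGU]", "", seq)
  if (nchar(bad) > 0) {
    stop_quantavax(sprintf("sequence contains non-ACGT/U characters: %s",
                           paste(unique(strsplit(bad, "")[[1]]), collapse = "")),
                   "quantavax_sequence_error")
  }
  if (nchar(seq) %% 3 != 0) {
    stop_quantavax(sprintf("sequence length %d is not a multiple of 3", nchar(seq)),
                   "quantavax_frame_error")
  }
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  if (drop_stop && length(codons) > 0 &&
      codons[length(codons)] %in% c("UAA", "UAG", "UGA")) {
    codons <- codons[-length(codons)]
  }
  codons
}

#' Map one codon to its measure
#'
#' @param codon RNA codon string.
#' @param table `codon_table`.
#' @return list with `tokens`, `durations`, `n_base` and `is_cadential`
#'   (TRUE when a single base token fills the full 3-beat measure).
#' @export
codon_to_measure <- function(codon, table = default_codon_table()) {
  rule <- table[[codon]]
  if (is.null(rule)) {
    stop_quantavax(sprintf("codon %s has no sonification rule", codon),
                   "quantavax_unmapped_codon")
  }
  list(codon = codon,
       tokens = rule$tokens,
       durations = rule$durations,
       n_base = rule$n_base,
       is_cadential = length(rule$tokens) == 1 && rule$durations[1] == 3)
}

#' Sonify a coding sequence
#'
#' One 3/4 measure per codon, in sequence order.
#'
#' @param seq DNA or RNA coding sequence.
#' @param table `codon_table`.
#' @param source_id identifier carried into the score.
#' @param drop_stop see [transcribe_codons()].
#' @return object of class `music_score`: list with `source_id` and
#'   `measures` (each as returned by [codon_to_measure()], plus `index`).
#' @export
sonify_sequence <- function(seq, table = default_codon_table(),
                            source_id = "seq", drop_stop = TRUE) {
  codons <- transcribe_codons(seq, drop_stop = drop_stop)
  measures <- lapply(seq_along(codons), function(i) {
    m <- codon_to_measure(codons[i], table)
    m$index <- i
    m
  })
  structure(list(source_id = source_id, measures = measures),
            class = "music_score")
}

#' @export
print.music_score <- function(x, ...) {
  n <- length(x$measures)
  n_cad <- sum(vapply(x$measures, `[[`, logical(1), "is_cadential"))
  cat(sprintf("Musical score '%s': Ms. %d (%d cadential measure(s))\n",
              x$source_id, n, n_cad))
  invisible(x)
}

#' Segment a score at its cadential measures
#'
#' Every cadential (full-measure single-note) measure closes a segment, so
#' a run of consecutive cadences yields one singleton segment per cadence
#' and segments always partition 1..N. Each segment reports its most
#' frequent pitch token (earliest-occurring token wins ties); rests are
#' ignored for the characteristic pitch unless a segment is all rests.
#'
#' @param score `music_score`.
#' @return object of class `cadence_segmentation`: list with `boundaries`
#'   (measure indices) and `segments` (data.frame: start, end,
#'   characteristic_pitch).
#' @export
segment_by_cadence <- function(score) {
  n <- length(score$measures)
  if (n == 0) {
    stop_quantavax("cannot segment an empty score", "quantavax_value_error")
  }
  boundaries <- which(vapply(score$measures, `[[`, logical(1), "is_cadential"))
  seg_starts <- c(1, boundaries[boundaries < n] + 1)
  seg_ends <- c(boundaries[boundaries < n], n)
  characteristic <- vapply(seq_along(seg_starts), function(i) {
    toks <- unlist(lapply(score$measures[seg_starts[i]:seg_ends[i]], `[[`, "tokens"))
    pitched <- toks[toks != "z"]
    if (length(pitched) == 0) pitched <- toks
    counts <- table(factor(pitched, levels = unique(pitched)))
    names(counts)[which.max(counts)]
  }, character(1))
  structure(
    list(boundaries = boundaries,
         segments = data.frame(start = seg_starts, end = seg_ends,
                               characteristic_pitch = characteristic,
                               stringsAsFactors = FALSE)),
    class = "cadence_segmentation"
  )
}
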