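# Score export: ABC notation (with a lossless reader), MusicXML and
# Standard MIDI File. Tokens are mapped to concrete pitches through a
# configurable map; the default places the seven letter names in the
# octave starting at middle C.

#' Default token-to-pitch map
#'
#' Maps the seven abstract pitch letters onto scientific pitches C4..B4.
#'
#' @return named character vector token -> scientific pitch.
#' @export
default_pitch_map <- function() {
  c(C = "C4", D = "D4", E = "E4", F = "F4", G = "G4", A = "A4", B = "B4")
}

pitch_to_midi <- function(pitch) {
  # Scientific pitch (naturals only) to MIDI note number; C4 = 60.
  letter <- substr(pitch, 1, 1)
  octave <- as.integer(substr(pitch, 2, nchar(pitch)))
  semis <- c(C = 0, D = 2, E = 4, F = 5, G = 7, A = 9, B = 11)
  12 * (octave + 1) + semis[[letter]]
}

abc_duration <- function(beats) {
  # Unit note length is a quarter (L:1/4).
  frac <- beats
  if (abs(frac - round(frac)) < 1e-9) {
    n <- round(frac)
    if (n == 1) "" else as.character(n)
  } else if (abs(frac - 0.5) < 1e-9) {
    "/2"
  } else if (abs(frac - 1.5) < 1e-9) {
    "3/2"
  } else {
    # Generic rational fallback in halves of a beat.
    sprintf("%d/2", round(frac * 2))
  }
}

lookup_pitch <- function(token, pitch_map) {
  if (!token %in% names(pitch_map)) {
    stop_quantavax(sprintf("token '%s' has no concrete pitch mapping", token),
                   "quantavax_export_error")
  }
  pitch_map[[token]]
}

abc_note <- function(token, beats, pitch_map) {
  if (token == "z") return(paste0("z", abc_duration(beats)))
  pitch <- lookup_pitch(token, pitch_map)
  letter <- substr(pitch, 1, 1)
  octave <- as.integer(substr(pitch, 2, nchar(pitch)))
  # ABC: C..B = octave 4 (below middle c convention with K:C, L:1/4);
  # c..b = octave 5; trailing , and ' shift further.
  core <- if (octave >= 5) {
    paste0(tolower(letter), strrep("'", octave - 5))
  } else {
    paste0(letter, strrep(",", 4 - octave))
  }
  paste0(core, abc_duration(beats))
}

#' Export a score as ABC notation
#'
#' One bar per measure in 3/4 with a quarter-note unit length. The
#' source id is kept in the T: header so re-import is lossless.
#'
#' @param score `music_score`.
#' @param path output file; when NULL the ABC text is returned invisibly
#'   without writing.
#' @param pitch_map token -> scientific pitch map.
#' @return the ABC text, invisibly when written to a file.
#' @export
export_abc <- function(score, path = NULL, pitch_map = default_pitch_map()) {
  bars <- vapply(score$measures, function(m) {
    paste(mapply(abc_note, m$tokens, m$durations,
                 MoreArgs = list(pitch_map = pitch_map)), collapse = " ")
  }, character(1))
  body <- if (length(bars) == 0) "" else paste0(paste(bars, collapse = " | "), " |]")
  text <- paste(
    "X:1",
    paste0("T:", score$source_id),
    "M:3/4",
    "L:1/4",
    "K:C",
    body,
    sep = "\n"
  )
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

parse_abc_note <- function(note, rev_map) {
  m <- regmatches(note, regexec("^([A-Ga-gz])([,']*)([0-9]*(?:/[0-9]+)?)$", note))[[1]]
  if (length(m) == 0) {
    stop_quantavax(sprintf("cannot parse ABC note '%s'", note), "quantavax_export_error")
  }
  letter <- m[2]; marks <- m[3]; durtxt <- m[4]
  beats <- if (durtxt == "") 1
           else if (grepl("/", durtxt)) {
             parts <- strsplit(durtxt, "/")[[1]]
             num <- if (parts[1] == "") 1 else as.numeric(parts[1])
             num / as.numeric(parts[2])
           } else as.numeric(durtxt)
  if (letter == "z") return(list(token = "z", beats = beats))
  octave <- if (letter %in% letters) 5 else 4
  octave <- octave + nchar(gsub("[^']", "", marks)) - nchar(gsub("[^,]", "", marks))
  pitch <- paste0(toupper(letter), octave)
  token <- rev_map[[pitch]]
  if (is.null(token)) {
    stop_quantavax(sprintf("pitch '%s' not present in the pitch map", pitch),
                   "quantavax_export_error")
  }
  list(token = token, beats = beats)
}

#' Import an ABC file written by [export_abc()]
#'
#' Supports the subset of ABC this package writes: naturals, 3/4 bars,
#' quarter-note unit length. Round-trips losslessly with [export_abc()].
#'
#' @param path ABC file (or a character scalar of ABC text).
#' @param pitch_map the token -> pitch map used at export.
#' @return `music_score` (codon identities are not recoverable; measures
#'   carry tokens, durations and the cadential flag).
#' @export
import_abc <- function(path, pitch_map = default_pitch_map()) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path)
           else strsplit(path, "\n")[[1]]
  rev_map <- as.list(stats::setNames(names(pitch_map), pitch_map))
  title <- sub("^T:", "", grep("^T:", lines, value = TRUE)[1])
  body <- paste(lines[!grepl("^[A-Za-z]:", lines)], collapse = " ")
  body <- gsub("\\|\\]", "", body)
  bars <- strsplit(body, "\\|")[[1]]
  bars <- trimws(bars)
  bars <- bars[bars != ""]
  measures <- lapply(seq_along(bars), function(i) {
    notes <- strsplit(bars[i], "\\s+")[[1]]
    parsed <- lapply(notes, parse_abc_note, rev_map = rev_map)
    tokens <- vapply(parsed, `[[`, character(1), "token")
    beats <- vapply(parsed, `[[`, numeric(1), "beats")
    list(codon = NA_character_, tokens = tokens, durations = beats,
         n_base = NA_integer_, index = i,
         is_cadential = length(tokens) == 1 && beats[1] == 3)
  })
  structure(list(source_id = if (is.na(title)) "abc" else title,
                 measures = measures),
            class = "music_score")
}

#' Export a score as MusicXML
#'
#' Minimal partwise MusicXML 3.1: one part, 3/4 time, quarter-note
#' divisions of 2 so eighth notes are representable.
#'
#' @param score `music_score`.
#' @param path output file.
#' @param pitch_map token -> scientific pitch map.
#' @return invisibly, the path.
#' @export
export_musicxml <- function(score, path, pitch_map = default_pitch_map()) {
  note_xml <- function(token, beats) {
    dur <- round(beats * 2)
    if (token == "z") {
      return(sprintf("<note><rest/><duration>%d</duration></note>", dur))
    }
    pitch <- lookup_pitch(token, pitch_map)
    sprintf(paste0("<note><pitch><step>%s</step><octave>%s</octave></pitch>",
                   "<duration>%d</duration></note>"),
            substr(pitch, 1, 1), substr(pitch, 2, nchar(pitch)), dur)
  }
  measures <- vapply(score$measures, function(m) {
    attrs <- if (m$index == 1) {
      paste0("<attributes><divisions>2</divisions>",
             "<time><beats>3</beats><beat-type>4</beat-type></time>",
             "</attributes>")
    } else ""
    notes <- paste(mapply(note_xml, m$tokens, m$durations), collapse = "")
    sprintf("<measure number=\"%d\">%s%s</measure>", m$index, attrs, notes)
  }, character(1))
  doc <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<score-partwise version=\"3.1\">",
    "<part-list><score-part id=\"P1\"><part-name>",
    score$source_id,
    "</part-name></score-part></part-list>",
    "<part id=\"P1\">", paste(measures, collapse = ""), "</part>",
    "</score-partwise>"
  )
  writeLines(doc, path)
  invisible(path)
}

midi_varlen <- function(n) {
  # MIDI variable-length quantity encoding.
  bytes <- n %% 128
  n <- n %/% 128
  while (n > 0) {
    bytes <- c(n %% 128 + 128, bytes)
    n <- n %/% 128
  }
  as.raw(bytes)
}

#' Export a score as a Standard MIDI File
#'
#' Format-0 SMF at 480 ticks per quarter note; rests advance time without
#' a note event.
#'
#' @param score `music_score`.
#' @param path output file.
#' @param pitch_map token -> scientific pitch map.
#' @param tempo_bpm quarter notes per minute (default 90).
#' @return invisibly, the path.
#' @export
export_midi <- function(score, path, pitch_map = default_pitch_map(),
                        tempo_bpm = 90) {
  tpq <- 480L
  events <- raw(0)
  pending_delta <- 0L
  usec_per_q <- round(60e6 / tempo_bpm)
  tempo_bytes <- as.raw(c(usec_per_q %/% 65536, (usec_per_q %/% 256) %% 256,
                          usec_per_q %% 256))
  events <- c(events, midi_varlen(0), as.raw(c(0xFF, 0x51, 0x03)), tempo_bytes)
  for (m in score$measures) {
    for (i in seq_along(m$tokens)) {
      ticks <- as.integer(round(m$durations[i] * tpq))
      tok <- m$tokens[i]
      if (tok == "z") {
        pending_delta <- pending_delta + ticks
        next
      }
      key <- pitch_to_midi(lookup_pitch(tok, pitch_map))
      events <- c(events,
                  midi_varlen(pending_delta), as.raw(c(0x90, key, 0x60)),
                  midi_varlen(ticks), as.raw(c(0x80, key, 0x40)))
      pending_delta <- 0L
    }
  }
  events <- c(events, midi_varlen(pending_delta), as.raw(c(0xFF, 0x2F, 0x00)))
  int_bytes <- function(n, width) {
    as.raw(rev((n %/% 256^(seq_len(width) - 1)) %% 256))
  }
  header <- c(charToRaw("MThd"), int_bytes(6, 4), int_bytes(0, 2),
              int_bytes(1, 2), int_bytes(tpq, 2))
  track <- c(charToRaw("MTrk"), int_bytes(length(events), 4), events)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, track), con)
  invisible(path)
}

#' Export a score
#'
#' Dispatcher over [export_abc()], [export_musicxml()] and
#' [export_midi()].
#'
#' @param score `music_score`.
#' @param path output file.
#' @param format `"abc"`, `"musicxml"` or `"midi"`.
#' @param pitch_map token -> scientific pitch map.
#' @return invisibly, the path.
#' @export
export_score <- function(score, path, format = c("abc", "musicxml", "midi"),
                         pitch_map = default_pitch_map()) {
  format <- match.arg(format)
  switch(format,
    abc = export_abc(score, path, pitch_map),
    musicxml = export_musicxml(score, path, pitch_map),
    midi = export_midi(score, path, pitch_map)
  )
  invisible(path)
}
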