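# Codon sonification: measures, cadences, exports.

test_that("the published codon formulas map exactly", {
  tab <- default_codon_table()
  ugc <- codon_to_measure("UGC", tab)
  expect_equal(ugc$tokens, "B")
  expect_equal(ugc$durations, 3)
  expect_true(ugc$is_cadential)

  ucc <- codon_to_measure("UCC", tab)
  expect_equal(ucc$tokens, c("G", "E", "D"))
  expect_equal(ucc$durations, c(2, 0.5, 0.5))
  expect_false(ucc$is_cadential)

  gcc <- codon_to_measure("GCC", tab)
  expect_equal(gcc$tokens, c("C", "D", "E", "D"))
  expect_equal(gcc$durations, c(1.5, 0.5, 0.5, 0.5))

  gcg <- codon_to_measure("GCG", tab)
  expect_equal(gcg$tokens, c("C", "D", "D"))
  expect_equal(gcg$durations, c(1.5, 0.5, 1))

  caa <- codon_to_measure("CAA", tab)
  expect_equal(caa$tokens, c("E", "F"))
  expect_equal(caa$durations, c(2, 1))

  # Solfege tokens are canonicalised (S -> G, L -> A, R -> D).
  gga <- codon_to_measure("GGA", tab)
  expect_equal(gga$tokens, c("G", "A"))
  ggc <- codon_to_measure("GGC", tab)
  expect_equal(ggc$tokens, c("G", "A", "D", "D"))
  uca <- codon_to_measure("UCA", tab)
  expect_true(uca$is_cadential)
  ucu <- codon_to_measure("UCU", tab)
  expect_equal(ucu$durations, c(1.5, 1.5))
})

test_that("every codon in the default table fills exactly 3 beats", {
  tab <- default_codon_table()
  expect_length(tab, 64)
  for (codon in names(tab)) {
    expect_equal(sum(tab[[codon]]$durations), 3, info = codon)
  }
  # Stop codons are full-measure rests.
  for (stop_codon in c("UAA", "UAG", "UGA")) {
    m <- codon_to_measure(stop_codon, tab)
    expect_equal(m$tokens, "z")
    expect_true(m$is_cadential)
  }
})

test_that("transcription validates frame and alphabet, and maps T to U", {
  expect_equal(transcribe_codons("TGC"), "UGC")
  expect_equal(transcribe_codons("tgcgca"), c("UGC", "GCA"))
  expect_error(transcribe_codons("TGCA"), class = "quantavax_frame_error")
  expect_error(transcribe_codons("TGN"), class = "quantavax_sequence_error")
  expect_equal(transcribe_codons("TGCTAA"), "UGC")
  expect_equal(transcribe_codons("TGCTAA", drop_stop = FALSE), c("UGC", "UAA"))
  expect_equal(transcribe_codons(""), character())
})

test_that("sonification is a pure one-measure-per-codon map", {
  expect_length(sonify_sequence("")$measures, 0)
  sc <- sonify_sequence(gen_codon_sequence(161, seed = 3))
  expect_length(sc$measures, 161)
  two <- sonify_sequence("UGCUGC")
  expect_equal(two$measures[[1]][c("tokens", "durations")],
               two$measures[[2]][c("tokens", "durations")])
  no_ugc <- default_codon_table()
  no_ugc[["UGC"]] <- NULL
  expect_error(sonify_sequence("UGC", table = no_ugc),
               class = "quantavax_unmapped_codon")
})

test_that("measure count and 3-beat bars hold on random sequences", {
  tab <- default_codon_table()
  for (seed in 1:25) {
    n <- 1 + (seed * 7) %% 60
    seq <- gen_codon_sequence(n, cys_period = ifelse(seed %% 2, 5, 0), seed = seed)
    sc <- sonify_sequence(seq, tab)
    expect_length(sc$measures, n)
    sums <- vapply(sc$measures, function(m) sum(m$durations), numeric(1))
    expect_equal(sums, rep(3, n))
    sc2 <- sonify_sequence(seq, tab)
    expect_identical(sc, sc2)
  }
})

test_that("cadence segmentation partitions the score at full-measure bars", {
  # 12 measures with cadences exactly at 5 and 10.
  codons <- rep("GCC", 12)
  codons[c(5, 10)] <- "UGC"
  sc <- sonify_sequence(paste(codons, collapse = ""))
  seg <- segment_by_cadence(sc)
  expect_equal(seg$boundaries, c(5, 10))
  expect_equal(seg$segments$start, c(1, 6, 11))
  expect_equal(seg$segments$end, c(5, 10, 12))

  none <- segment_by_cadence(sonify_sequence(strrep("GCC", 8)))
  expect_equal(nrow(none$segments), 1)
  expect_equal(c(none$segments$start, none$segments$end), c(1, 8))

  all_cad <- segment_by_cadence(sonify_sequence(strrep("UGC", 6)))
  expect_equal(nrow(all_cad$segments), 6)

  for (seed in 1:10) {
    sc <- sonify_sequence(gen_codon_sequence(40, cys_period = 7, seed = seed))
    seg <- segment_by_cadence(sc)
    expect_equal(seg$segments[c("start", "end")], naive_segments(sc),
                 ignore_attr = TRUE)
    # Segments partition 1..N.
    expect_equal(seg$segments$start[1], 1)
    expect_equal(seg$segments$end[nrow(seg$segments)], 40)
    expect_true(all(seg$segments$start[-1] == utils::head(seg$segments$end, -1) + 1))
  }
})

test_that("characteristic pitch is the modal token with earliest-first ties", {
  sc <- sonify_sequence("GGAGGAUCCUGC")  # G A / G A / G E D / B(cadence)
  seg <- segment_by_cadence(sc)
  expect_equal(seg$segments$characteristic_pitch, "G")
})

test_that("ABC export round-trips losslessly", {
  for (seed in c(2, 11, 23)) {
    sc <- sonify_sequence(gen_codon_sequence(30, cys_period = 6, seed = seed),
                          source_id = paste0("seq", seed))
    path <- withr::local_tempfile(fileext = ".abc")
    export_abc(sc, path)
    back <- import_abc(path)
    expect_equal(back$source_id, sc$source_id)
    expect_equal(lapply(back$measures, function(m) list(m$tokens, m$durations)),
                 lapply(sc$measures, function(m) list(m$tokens, m$durations)))
  }
  one <- sonify_sequence("UGC")
  txt <- export_abc(one)
  expect_match(txt, "B3")  # dotted half note on B
})

test_that("MIDI exports carry exactly 3 beats per measure", {
  for (n in c(1, 17)) {
    sc <- sonify_sequence(gen_codon_sequence(n, cys_period = 4, seed = n))
    path <- withr::local_tempfile(fileext = ".mid")
    export_midi(sc, path)
    expect_equal(midi_total_beats(path), 3 * n)
  }
  # Rests (stop codon retained) still advance time.
  sc <- sonify_sequence("GCCTAA", drop_stop = FALSE)
  path <- withr::local_tempfile(fileext = ".mid")
  export_midi(sc, path)
  expect_equal(midi_total_beats(path), 6)
})

test_that("MusicXML export is well-formed with one measure per codon", {
  skip_if_not_installed("xml2")
  sc <- sonify_sequence(gen_codon_sequence(9, cys_period = 3, seed = 8))
  path <- withr::local_tempfile(fileext = ".musicxml")
  export_musicxml(sc, path)
  doc <- xml2::read_xml(path)
  expect_length(xml2::xml_find_all(doc, "//measure"), 9)
  durs <- as.integer(xml2::xml_text(xml2::xml_find_all(doc, "//note/duration")))
  expect_equal(sum(durs), 9 * 6)  # divisions = 2 per quarter, 3 beats per bar
})

test_that("export fails clearly on unmapped tokens", {
  sc <- sonify_sequence("UGC")
  expect_error(export_abc(sc, pitch_map = c(C = "C4")),
               class = "quantavax_export_error")
})
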