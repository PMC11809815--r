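# Shared helpers: fixture paths and independent oracles used across tests.

fixture <- function(name) {
  path <- system.file("extdata", name, package = "quantavax")
  if (path == "") stop("missing fixture: ", name)
  path
}

table1_trial <- function() read_trial_csv(fixture("trial_table1.csv"))

# Independent brute-force oracle: total inter-chain energy of one frame by
# an explicit double loop over atom pairs (scalar closed forms only).
brute_force_total_energy <- function(coords, atoms, model = dielectric_model()) {
  chains <- sort(unique(atoms$chain))
  iA <- which(atoms$chain == chains[1])
  iB <- which(atoms$chain == chains[2])
  total <- 0
  for (i in iA) {
    for (j in iB) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      eps_r <- model$a + model$b / (1 + model$k * exp(-model$lam * model$b * d))
      e_el <- 332.0637 * atoms$charge[i] * atoms$charge[j] / (eps_r * d)
      rmin <- atoms$rmin_half[i] + atoms$rmin_half[j]
      epsp <- sqrt(atoms$epsilon[i] * atoms$epsilon[j])
      a_ij <- epsp * rmin^12
      b_ij <- 2 * epsp * rmin^6
      total <- total + e_el + a_ij / d^12 - b_ij / d^6
    }
  }
  total
}

# Naive segmentation scan: walk the measures, close a segment at every
# full-measure single-note bar.
naive_segments <- function(score) {
  n <- length(score$measures)
  starts <- integer(0); ends <- integer(0)
  cur <- 1
  for (i in seq_len(n)) {
    m <- score$measures[[i]]
    if (length(m$tokens) == 1 && m$durations[1] == 3) {
      starts <- c(starts, cur); ends <- c(ends, i); cur <- i + 1
    }
  }
  if (cur <= n) { starts <- c(starts, cur); ends <- c(ends, n) }
  data.frame(start = starts, end = ends)
}

# Brute-force consensus: residue-by-residue scan with explicit gap logic.
brute_force_consensus <- function(profile, min_support, merge_gap) {
  supported <- which(profile >= min_support)
  if (length(supported) == 0) return(data.frame(start = integer(), end = integer()))
  starts <- supported[1]; ends <- supported[1]
  for (r in supported[-1]) {
    if (r - ends[length(ends)] - 1 <= merge_gap) {
      ends[length(ends)] <- r
    } else {
      starts <- c(starts, r); ends <- c(ends, r)
    }
  }
  data.frame(start = starts, end = ends)
}

# Sum of all note/rest durations (in quarter-note beats) in a format-0
# MIDI file, read straight off the bytes: independent check of exports.
midi_total_beats <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  int_at <- function(i, w) sum(as.integer(bytes[i:(i + w - 1)]) * 256^((w - 1):0))
  stopifnot(rawToChar(bytes[1:4]) == "MThd")
  tpq <- int_at(13, 2)
  stopifnot(rawToChar(bytes[15:18]) == "MTrk")
  pos <- 23
  end <- 22 + int_at(19, 4)
  ticks <- 0
  while (pos <= end) {
    delta <- 0
    repeat {
      b <- as.integer(bytes[pos]); pos <- pos + 1
      delta <- delta * 128 + (b %% 128)
      if (b < 128) break
    }
    ticks <- ticks + delta
    status <- as.integer(bytes[pos])
    if (status == 0xFF) {
      len <- as.integer(bytes[pos + 2])
      pos <- pos + 3 + len
    } else {
      pos <- pos + 3  # note on/off: status + key + velocity
    }
  }
  ticks / tpq
}
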