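# Independent oracles used across tests.

# Dynamic-programming longest common subsequence length (token lists).
lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  d <- matrix(0L, na + 1, nb + 1)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    d[i + 1, j + 1] <- if (a[i] == b[j]) d[i, j] + 1L
                       else max(d[i, j + 1], d[i + 1, j])
  }
  d[na + 1, nb + 1]
}

# Brute-force Benjamini-Hochberg step-up adjusted values.
bh_stepup_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (k in rev(seq_len(m))) {
    running_min <- min(running_min, p[o[k]] * m / k)
    adj[o[k]] <- running_min
  }
  pmin(adj, 1)
}

# Minimal PCM16 mono WAV writer for round-trip tests of the reader.
write_wav_pcm16 <- function(samples, fs, path) {
  pcm <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")       # PCM
  writeBin(1L, con, size = 2, endian = "little")       # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# Long-format Praat TextGrid with one point tier, for reader tests.
write_textgrid_points_fixture <- function(times, tier, path) {
  lines <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"', "",
    "xmin = 0", paste0("xmax = ", max(times) + 1),
    "tiers? <exists>", "size = 1", "item []:",
    "    item [1]:",
    '        class = "TextTier"',
    paste0('        name = "', tier, '"'),
    "        xmin = 0", paste0("        xmax = ", max(times) + 1),
    paste0("        points: size = ", length(times)),
    unlist(lapply(seq_along(times), function(i) c(
      paste0("        points [", i, "]:"),
      paste0("            number = ", times[i]),
      '            mark = "syll"'))))
  writeLines(lines, path)
  invisible(path)
}

# All length-<=max_len strings over a small alphabet, as token lists.
enumerate_token_lists <- function(alphabet, max_len) {
  out <- list(character(0))
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len), stringsAsFactors = FALSE))
    out <- c(out, lapply(seq_len(nrow(grid)), function(i)
      as.character(unlist(grid[i, ]))))
  }
  out
}
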