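# Independent brute-force signal scanner used as an oracle. Implemented
# with run-length encoding, deliberately unlike the package's index-based
# scan, and replays the unique-site cap event by event.

oracle_scan_row <- function(row, min_gap, min_aligned) {
  ch <- strsplit(row, "", fixed = TRUE)[[1]]
  out <- data.frame(position = integer(0), side = character(0),
                    stringsAsFactors = FALSE)
  if (sum(ch != "-") < min_aligned) return(out)
  r <- rle(ch == "-")
  n <- length(r$values)
  if (r$values[1] && r$lengths[1] >= min_gap)
    out <- rbind(out, data.frame(position = r$lengths[1] + 1L,
                                 side = "N_TERMINAL", stringsAsFactors = FALSE))
  if (n > 1 && r$values[n] && r$lengths[n] >= min_gap)
    out <- rbind(out, data.frame(position = length(ch) - r$lengths[n],
                                 side = "C_TERMINAL", stringsAsFactors = FALSE))
  out
}

oracle_extract <- function(msa, params = signal_params()) {
  counts <- integer(0)   # named by position
  for (hit in msa$hits) {
    sig <- oracle_scan_row(hit$aligned, params$min_gap, params$min_aligned)
    for (r in seq_len(nrow(sig))) {
      p <- as.character(sig$position[r])
      counts[p] <- if (p %in% names(counts)) counts[[p]] + 1L else 1L
      if (length(counts) >= params$max_unique_sites) break
    }
    if (length(counts) >= params$max_unique_sites) break
  }
  pos <- as.integer(names(counts))
  o <- order(pos)
  data.frame(position = pos[o], multiplicity = unname(counts[o]))
}
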