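#' Signal-extraction parameters
#'
#' A domain boundary signal is a gap run starting at the N- or C-terminal end
#' of an MSA row that extends for at least `min_gap` residues, provided the
#' row retains at least `min_aligned` non-gap residues once all gaps are
#' removed. Rows are processed in order of increasing e-value and collection
#' halts once signals have been recorded at `max_unique_sites` distinct
#' residue positions. `near_tol` is the residue distance within which a
#' signal on a multi-domain chain counts as near a true boundary.
#'
#' @param min_gap Minimum terminal gap-run length, residues (default 45).
#' @param min_aligned Minimum non-gap residue count of the row (default 45).
#' @param max_unique_sites Cap on distinct signal positions per chain
#'   (default 35).
#' @param near_tol Near-boundary distance tolerance, residues (default 20).
#' @return An object of class `signal_params`.
#' @export
signal_params <- function(min_gap = 45L, min_aligned = 45L,
                          max_unique_sites = 35L, near_tol = 20L) {
  p <- list(min_gap = as.integer(min_gap),
            min_aligned = as.integer(min_aligned),
            max_unique_sites = as.integer(max_unique_sites),
            near_tol = as.integer(near_tol))
  if (any(vapply(p, function(v) is.na(v) || v <= 0L, logical(1))))
    stop("all signal parameters must be strictly positive integers")
  structure(p, class = "signal_params")
}

#' Scan one MSA row for terminal-gap boundary signals
#'
#' Emits an N-side signal when the row begins with at least `min_gap`
#' consecutive gaps and carries at least `min_aligned` non-gap residues in
#' total; the signal position is the first non-gap residue. The C-side rule
#' is the mirror image, positioned at the last non-gap residue. A single row
#' can emit zero, one or two signals; an all-gap row emits none.
#'
#' @param hit An [aligned_hit].
#' @param params [signal_params].
#' @return Data frame with columns `position`, `source_hit`, `side`
#'   (`"N_TERMINAL"`/`"C_TERMINAL"`); zero rows when no signal fires.
#' @export
scan_hit <- function(hit, params = signal_params()) {
  chars <- strsplit(hit$aligned, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  nongap <- which(chars != "-")
  empty <- data.frame(position = integer(0), source_hit = character(0),
                      side = character(0), stringsAsFactors = FALSE)
  if (length(nongap) < params$min_aligned) return(empty)
  first <- nongap[1L]
  last <- nongap[length(nongap)]
  out <- empty
  if (first - 1L >= params$min_gap)
    out <- rbind(out, data.frame(position = first, source_hit = hit$hit_id,
                                 side = "N_TERMINAL", stringsAsFactors = FALSE))
  if (L - last >= params$min_gap)
    out <- rbind(out, data.frame(position = last, source_hit = hit$hit_id,
                                 side = "C_TERMINAL", stringsAsFactors = FALSE))
  out
}

#' Extract boundary signal sites from an anchored MSA
#'
#' Processes hit rows in order of increasing e-value, recording every
#' terminal-gap signal event. Events at the same residue accumulate
#' multiplicity. Collection halts immediately once signals exist at
#' `max_unique_sites` distinct positions — mid-row, so the C-side signal of
#' a row may be skipped after its N-side signal hits the cap.
#'
#' @param msa An [anchored_msa] (hits already sorted by e-value).
#' @param params [signal_params].
#' @return List with `sites` (data frame `position`, `multiplicity`, sorted
#'   by position) and `events` (the raw per-hit signal log, in processing
#'   order).
#' @export
extract_signals <- function(msa, params = signal_params()) {
  events <- list()
  positions <- integer(0)
  halted <- FALSE
  for (hit in msa$hits) {
    sig <- scan_hit(hit, params)
    if (nrow(sig) == 0L) next
    for (r in seq_len(nrow(sig))) {
      events[[length(events) + 1L]] <- sig[r, , drop = FALSE]
      positions <- union(positions, sig$position[r])
      if (length(positions) >= params$max_unique_sites) {
        halted <- TRUE
        break
      }
    }
    if (halted) break
  }
  if (length(events) == 0L) {
    return(list(sites = data.frame(position = integer(0),
                                   multiplicity = integer(0)),
                events = data.frame(position = integer(0),
                                    source_hit = character(0),
                                    side = character(0),
                                    stringsAsFactors = FALSE)))
  }
  ev <- do.call(rbind, events)
  rownames(ev) <- NULL
  tab <- table(ev$position)
  sites <- data.frame(position = as.integer(names(tab)),
                      multiplicity = as.integer(tab))
  sites <- sites[order(sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  list(sites = sites, events = ev)
}

#' Boundary points of a domain definition
#'
#' Both flanks of every inter-domain transition: for each adjacent pair of
#' ranges, the end of the earlier range and the start of the later one. The
#' chain termini (first range's start, last range's end) are never included,
#' so a single-domain definition yields an empty set.
#'
#' @param def A [domain_definition].
#' @return Sorted integer vector of boundary residue indices.
#' @export
boundary_points <- function(def) {
  r <- def$ranges
  n <- nrow(r)
  if (n < 2L) return(integer(0))
  sort(unique(c(r$end[-n], r$start[-1L])))
}

#' Label signal sites against a domain definition
#'
#' Sites on a single-domain chain are all `FALSE_BOUNDARY`. On a multi-domain
#' chain a site is `NEAR` when its distance to the closest boundary point is
#' at most `near_tol` (inclusive), otherwise `AWAY`.
#'
#' @param sites Data frame with a `position` column (as from
#'   [extract_signals]).
#' @param def The chain's [domain_definition] (the truth).
#' @param params [signal_params] supplying `near_tol`.
#' @return Character vector of labels, one per site.
#' @export
label_sites <- function(sites, def, params = signal_params()) {
  if (nrow(sites) == 0L) return(character(0))
  if (!is_multi_domain(def))
    return(rep("FALSE_BOUNDARY", nrow(sites)))
  bp <- boundary_points(def)
  dmin <- vapply(sites$position, function(p) min(abs(p - bp)), numeric(1))
  ifelse(dmin <= params$near_tol, "NEAR", "AWAY")
}
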