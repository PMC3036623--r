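#' Feature-encoding parameters
#'
#' Each signal site is encoded from a window of `window` residues centered on
#' the site. Every window position contributes 21 sequence-profile features
#' (normalized frequencies of the 20 residues plus the gap over the MSA
#' column) and 5 structure indicators (helix, strand, loop, buried, exposed).
#' Appended are three signal-specific features — position from the N terminus
#' divided by `scale`, position from the C terminus divided by `scale`, and
#' the count of signal sites within `neighbor_radius` residues — one
#' protein-level feature (length divided by `scale`) and the signal-density
#' z-score at the site. At the defaults this gives 41 x 26 + 5 = 1071
#' features.
#'
#' @param window Window width in residues, odd (default 41).
#' @param density_radius Neighbourhood radius for the signal-density local
#'   sums, residues (default 5).
#' @param neighbor_radius Radius for the neighbouring-site count, residues
#'   (default 5).
#' @param scale Divisor for positional and length features (default 100).
#' @return An object of class `encoding_params` with an `n_features` field.
#' @export
encoding_params <- function(window = 41L, density_radius = 5L,
                            neighbor_radius = 5L, scale = 100) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer")
  structure(list(window = window,
                 density_radius = as.integer(density_radius),
                 neighbor_radius = as.integer(neighbor_radius),
                 scale = as.numeric(scale),
                 n_features = window * 26L + 5L),
            class = "encoding_params")
}

#' Feature names of the site encoding
#'
#' The frozen feature order: for each window offset (-(w-1)/2 .. +(w-1)/2),
#' 21 profile values (A..Y then gap) followed by ss.H, ss.E, ss.C, sa.b,
#' sa.e; then npos, cpos, nsites, len, zscore.
#'
#' @param params [encoding_params].
#' @return Character vector of length `params$n_features`.
#' @export
feature_names <- function(params = encoding_params()) {
  half <- (params$window - 1L) %/% 2L
  sym <- c(paste0("p.", c(AA_LETTERS, "gap")),
           paste0("ss.", SS_STATES), paste0("sa.", SA_STATES))
  per_pos <- unlist(lapply(seq(-half, half), function(o)
    paste0("w", o, ".", sym)))
  c(per_pos, "npos", "cpos", "nsites", "len", "zscore")
}

#' Hash of the feature schema
#'
#' MD5 digest of the ordered feature-name list; stored in trained models and
#' verified at prediction time so a model is never applied to features laid
#' out differently.
#'
#' @param params [encoding_params].
#' @return Hex digest string.
#' @export
feature_schema_hash <- function(params = encoding_params()) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(feature_names(params), f)
  unname(tools::md5sum(f))
}

# 21 x L matrix of per-column residue+gap frequencies over query + hit rows,
# each column normalized to sum 1. Ambiguity codes (B/Z/J/X) are spread
# uniformly over their member residues.
chain_profile <- function(msa) {
  seqs <- c(msa$query$sequence,
            vapply(msa$hits, `[[`, character(1), "aligned"))
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  L <- msa$query$length
  counts <- matrix(0, nrow = 21L, ncol = L,
                   dimnames = list(PROFILE_SYMBOLS, NULL))
  for (i in seq_along(PROFILE_SYMBOLS))
    counts[i, ] <- colSums(m == PROFILE_SYMBOLS[i])
  for (amb in names(AMBIGUITY_MAP)) {
    n_amb <- colSums(m == amb)
    if (any(n_amb > 0)) {
      members <- AMBIGUITY_MAP[[amb]]
      counts[members, ] <- sweep(counts[members, , drop = FALSE], 2,
                                 n_amb / length(members), `+`)
    }
  }
  sweep(counts, 2, colSums(counts), `/`)
}

#' Column profile at one position
#'
#' Normalized frequencies of the 20 residues plus the gap in one MSA column,
#' over the query row and all hit rows.
#'
#' @param msa An [anchored_msa].
#' @param position 1-based query residue index.
#' @return Named numeric vector of length 21 summing to 1.
#' @export
column_profile <- function(msa, position) {
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > msa$query$length)
    stop("position ", position, " outside 1..", msa$query$length)
  chain_profile(msa)[, position]
}

#' Per-residue signal-density z-scores
#'
#' For each residue the local sum of signal multiplicities within
#' `radius` residues, converted to z-scores over the whole chain (population
#' standard deviation). A flat profile (sd = 0) yields all zeros.
#'
#' @param sites Data frame with `position` and `multiplicity` columns.
#' @param query_length Chain length, residues.
#' @param radius Neighbourhood radius, residues (default 5).
#' @return Numeric vector of length `query_length`.
#' @export
signal_density_zscores <- function(sites, query_length, radius = 5L) {
  local <- numeric(query_length)
  if (nrow(sites) > 0L) {
    for (i in seq_len(nrow(sites))) {
      p <- sites$position[i]
      idx <- max(1L, p - radius):min(query_length, p + radius)
      local[idx] <- local[idx] + sites$multiplicity[i]
    }
  }
  mu <- mean(local)
  sd_pop <- sqrt(mean((local - mu)^2))
  if (sd_pop == 0) return(numeric(query_length))
  (local - mu) / sd_pop
}

# Encode all sites of one chain at once; profile/z-score work is shared.
encode_chain_sites <- function(msa, sites, ann, params = encoding_params(),
                               all_sites = sites) {
  L <- msa$query$length
  if (nchar(ann$ss) != L)
    stop("annotation length ", nchar(ann$ss), " != query length ", L)
  prof <- chain_profile(msa)
  ssc <- strsplit(ann$ss, "", fixed = TRUE)[[1L]]
  sac <- strsplit(ann$sa, "", fixed = TRUE)[[1L]]
  block <- rbind(prof,
                 ss.H = as.numeric(ssc == "H"),
                 ss.E = as.numeric(ssc == "E"),
                 ss.C = as.numeric(ssc == "C"),
                 sa.b = as.numeric(sac == "b"),
                 sa.e = as.numeric(sac == "e"))
  z <- signal_density_zscores(all_sites, L, params$density_radius)
  half <- (params$window - 1L) %/% 2L
  out <- matrix(0, nrow = nrow(sites), ncol = params$n_features)
  for (i in seq_len(nrow(sites))) {
    p <- sites$position[i]
    w <- (p - half):(p + half)
    ok <- w >= 1L & w <= L
    m <- matrix(0, nrow = 26L, ncol = params$window)
    m[, ok] <- block[, w[ok], drop = FALSE]
    nb <- sum(abs(all_sites$position - p) <= params$neighbor_radius)
    out[i, ] <- c(as.vector(m),
                  p / params$scale, (L - p) / params$scale, nb,
                  L / params$scale, z[p])
  }
  colnames(out) <- feature_names(params)
  out
}

#' Encode one signal site as a feature vector
#'
#' Concatenates, in the frozen order of [feature_names], the per-window
#' profile and structure features (window positions outside the chain
#' contribute all-zero 26-blocks), the signal-specific positional features,
#' the neighbouring-site count (self-inclusive), the scaled chain length and
#' the signal-density z-score at the site.
#'
#' @param msa An [anchored_msa].
#' @param site One-row data frame (or list) with `position` and
#'   `multiplicity`.
#' @param ann [structural_annotation] for the query.
#' @param all_sites All signal sites of the chain (data frame), used for the
#'   neighbour count and density z-scores; defaults to the site alone.
#' @param params [encoding_params].
#' @return Named numeric vector of length `params$n_features` (1071 at the
#'   defaults).
#' @export
encode_site <- function(msa, site, ann, all_sites = NULL,
                        params = encoding_params()) {
  site <- as.data.frame(site)
  if (is.null(all_sites)) all_sites <- site
  v <- encode_chain_sites(msa, site, ann, params, all_sites = all_sites)
  setNames(v[1L, ], colnames(v))
}

#' Encode a dataset of chains into a feature matrix
#'
#' @param chains List of per-chain lists with elements `msa`, `sites`, `ann`
#'   and optionally `labels` (character vector parallel to `sites`).
#' @param params [encoding_params].
#' @return List with `x` (row-per-site feature matrix, chains in input order,
#'   sites by position within chain; carries the schema hash as attribute
#'   `schema_hash`), `labels` (character vector or `NULL`) and `index`
#'   (data frame `chain_id`, `position`).
#' @export
encode_dataset <- function(chains, params = encoding_params()) {
  xs <- list(); idx <- list(); labs <- list()
  have_labels <- TRUE
  for (ch in chains) {
    if (is.null(ch$msa) || is.null(ch$sites) || is.null(ch$ann))
      stop("malformed chain entry",
           if (!is.null(ch$msa)) paste0(" for '", ch$msa$query$id, "'"))
    sites <- ch$sites[order(ch$sites$position), , drop = FALSE]
    if (nrow(sites) == 0L) next
    xs[[length(xs) + 1L]] <-
      encode_chain_sites(ch$msa, sites, ch$ann, params, all_sites = sites)
    idx[[length(idx) + 1L]] <-
      data.frame(chain_id = ch$msa$query$id, position = sites$position,
                 stringsAsFactors = FALSE)
    if (is.null(ch$labels)) have_labels <- FALSE
    else labs[[length(labs) + 1L]] <- ch$labels[order(ch$sites$position)]
  }
  x <- if (length(xs)) do.call(rbind, xs) else
    matrix(0, 0L, params$n_features, dimnames = list(NULL, feature_names(params)))
  attr(x, "schema_hash") <- feature_schema_hash(params)
  list(x = x,
       labels = if (have_labels && length(labs)) unlist(labs) else NULL,
       index = if (length(idx)) do.call(rbind, idx) else
         data.frame(chain_id = character(0), position = integer(0)))
}
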