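#' Query protein
#'
#' A query chain: an identifier plus an ungapped amino-acid sequence in the
#' 20-letter alphabet (ambiguity codes B/Z/J/X tolerated). All residue
#' coordinates in the package are 1-based and inclusive, anchored on this
#' sequence.
#'
#' @param id Chain identifier string.
#' @param sequence Amino-acid string; upper-cased on construction.
#' @return An object of class `query_protein` with fields `id`, `sequence`
#'   and `length`.
#' @export
query_protein <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(sequence) == 0L)
    stop("query '", id, "': empty sequence")
  bad <- gsub(paste0("[", paste(c(AA_LETTERS, names(AMBIGUITY_MAP)), collapse = ""), "]"),
              "", sequence)
  if (nchar(bad) > 0L)
    stop("query '", id, "': invalid residue character(s) '",
         substr(bad, 1L, 5L), "'")
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "query_protein")
}

#' Aligned homolog row in query coordinates
#'
#' One homologous sequence rendered in the coordinate system of the query:
#' a gapped string of exactly the query length, where `-` marks query
#' positions the homolog does not cover. Insertions relative to the query are
#' not represented.
#'
#' @param hit_id Identifier of the hit (one row per pairwise alignment).
#' @param e_value Non-negative e-value from the homology search.
#' @param aligned Gapped string of length equal to the query length.
#' @return An object of class `aligned_hit`.
#' @export
aligned_hit <- function(hit_id, e_value, aligned) {
  stopifnot(is.character(hit_id), length(hit_id) == 1L)
  e_value <- as.numeric(e_value)
  if (!is.finite(e_value) || e_value < 0)
    stop("hit '", hit_id, "': e-value must be a non-negative number")
  aligned <- toupper(gsub("[[:space:]]", "", aligned))
  bad <- gsub(paste0("[-", paste(c(AA_LETTERS, names(AMBIGUITY_MAP)), collapse = ""), "]"),
              "", aligned)
  if (nchar(bad) > 0L)
    stop("hit '", hit_id, "': invalid character(s) '", substr(bad, 1L, 5L), "'")
  structure(list(hit_id = hit_id, e_value = e_value, aligned = aligned),
            class = "aligned_hit")
}

#' Query-anchored multiple sequence alignment
#'
#' The query plus its aligned homolog rows, all in query coordinates. Hits
#' are stored sorted by increasing e-value; ties keep their input order.
#'
#' @param query A [query_protein].
#' @param hits List of [aligned_hit] rows (may be empty).
#' @return An object of class `anchored_msa`.
#' @export
anchored_msa <- function(query, hits = list()) {
  stopifnot(inherits(query, "query_protein"), is.list(hits))
  for (h in hits) {
    stopifnot(inherits(h, "aligned_hit"))
    if (nchar(h$aligned) != query$length)
      stop("hit '", h$hit_id, "': aligned length ", nchar(h$aligned),
           " != query length ", query$length)
  }
  if (length(hits) > 1L) {
    ev <- vapply(hits, `[[`, numeric(1), "e_value")
    hits <- hits[order(ev)]  # stable: ties keep report order
  }
  structure(list(query = query, hits = hits), class = "anchored_msa")
}

#' @export
print.anchored_msa <- function(x, ...) {
  cat("anchored MSA: query '", x$query$id, "' (", x$query$length,
      " aa), ", length(x$hits), " hit row(s)\n", sep = "")
  invisible(x)
}

#' Domain definition as ordered residue ranges
#'
#' @param chain_id Chain identifier.
#' @param ranges Two-column matrix or data frame of 1-based inclusive
#'   `(start, end)` pairs; sorted and checked for overlap.
#' @return An object of class `domain_definition` with a `ranges` data frame.
#' @export
domain_definition <- function(chain_id, ranges) {
  ranges <- as.data.frame(ranges)
  names(ranges) <- c("start", "end")
  ranges$start <- as.integer(ranges$start)
  ranges$end <- as.integer(ranges$end)
  if (nrow(ranges) == 0L)
    stop("chain '", chain_id, "': no domain ranges")
  if (any(ranges$start > ranges$end))
    stop("chain '", chain_id, "': inverted range (start > end)")
  ranges <- ranges[order(ranges$start), , drop = FALSE]
  rownames(ranges) <- NULL
  if (nrow(ranges) > 1L &&
      any(ranges$start[-1L] <= ranges$end[-nrow(ranges)]))
    stop("chain '", chain_id, "': overlapping domain ranges")
  structure(list(chain_id = chain_id, ranges = ranges),
            class = "domain_definition")
}

is_multi_domain <- function(def) nrow(def$ranges) > 1L

#' Per-residue structural annotation
#'
#' Predicted 3-state secondary structure (H/E/C) and 2-state relative solvent
#' accessibility (b = buried, e = exposed), as produced by an external
#' predictor, one character per query residue.
#'
#' @param ss Secondary-structure string over \{H, E, C\}.
#' @param sa Solvent-accessibility string over \{b, e\}.
#' @return An object of class `structural_annotation`.
#' @export
structural_annotation <- function(ss, sa) {
  ss <- gsub("[[:space:]]", "", ss)
  sa <- gsub("[[:space:]]", "", sa)
  if (nchar(gsub("[HEC]", "", ss)) > 0L)
    stop("secondary-structure string contains characters outside {H,E,C}")
  if (nchar(gsub("[be]", "", sa)) > 0L)
    stop("solvent-accessibility string contains characters outside {b,e}")
  if (nchar(ss) != nchar(sa))
    stop("ss length ", nchar(ss), " != sa length ", nchar(sa))
  structure(list(ss = ss, sa = sa), class = "structural_annotation")
}

# ---------------------------------------------------------------------------
# FASTA

#' Read query proteins from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return List of [query_protein], in file order; empty list for an empty
#'   file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(list())
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop("malformed FASTA in ", path, ": line ", nonblank[1L],
         " does not start a record ('>')")
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i)
    query_protein(ids[i], as.character(set[[i]])))
}

#' Write query proteins to FASTA
#'
#' @param proteins List of [query_protein].
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  seqs <- Biostrings::AAStringSet(vapply(proteins, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(proteins, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Aligned-FASTA dialect for anchored MSAs: first record is the (ungapped)
# query; each hit record carries its e-value in the description as "E=<float>".

#' Read a query-anchored MSA from aligned FASTA
#'
#' First record is the query (ungapped); every following record is a hit row
#' of the same length with the e-value given as `E=<float>` in its header.
#'
#' @param path Path to the aligned FASTA file.
#' @return An [anchored_msa].
#' @export
read_anchored_msa <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty anchored-MSA file: ", path)
  qname <- sub("\\s.*$", "", names(set)[1L])
  query <- query_protein(qname, as.character(set[[1L]]))
  hits <- list()
  if (length(set) > 1L) {
    hits <- lapply(2:length(set), function(i) {
      header <- names(set)[i]
      id <- sub("\\s.*$", "", header)
      m <- regmatches(header, regexpr("E=([0-9.eE+-]+)", header))
      if (length(m) == 0L)
        stop("hit '", id, "' in ", path, ": missing 'E=<float>' e-value tag")
      aligned_hit(id, as.numeric(sub("^E=", "", m)), as.character(set[[i]]))
    })
  }
  anchored_msa(query, hits)
}

#' Write a query-anchored MSA as aligned FASTA
#'
#' @param msa An [anchored_msa].
#' @param path Output path.
#' @export
write_anchored_msa <- function(msa, path) {
  seqs <- c(msa$query$sequence,
            vapply(msa$hits, `[[`, character(1), "aligned"))
  headers <- c(msa$query$id,
               vapply(msa$hits, function(h)
                 sprintf("%s E=%.6g", h$hit_id, h$e_value), character(1)))
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# PSI-BLAST XML (NCBI outfmt 5)

# Project one HSP onto query coordinates: hit residues facing query residues
# are placed at those positions; hit residues facing query gaps (insertions
# in the hit) are dropped; uncovered query positions stay '-'.
project_hsp <- function(qseq, hseq, qfrom, qto, qlen) {
  qc <- strsplit(qseq, "", fixed = TRUE)[[1L]]
  hc <- strsplit(hseq, "", fixed = TRUE)[[1L]]
  if (length(qc) != length(hc))
    stop("HSP query/hit alignment strings differ in length")
  row <- rep("-", qlen)
  qres <- qc != "-"
  pos <- qfrom - 1L + cumsum(qres)
  if (sum(qres) != qto - qfrom + 1L)
    stop("HSP query segment inconsistent with its coordinates")
  keep <- qres & hc != "-"
  row[pos[keep]] <- hc[keep]
  paste(row, collapse = "")
}

#' Build an anchored MSA from a PSI-BLAST XML report
#'
#' Parses an NCBI BLAST XML (outfmt 5) report and stacks every HSP of the
#' chosen iteration onto the query: each pairwise alignment becomes one row
#' in query coordinates (hit insertions relative to the query are dropped),
#' sorted by ascending e-value. Multiple HSPs from one database sequence
#' become separate rows with an ordinal suffix on the hit id.
#'
#' @param path Path to the BLAST XML report.
#' @param query The [query_protein] the report was generated for; its length
#'   must match the report's query length.
#' @param iteration Which search iteration to take hits from: `"last"`
#'   (default) or an iteration number.
#' @return An [anchored_msa]; zero hits yield an MSA with an empty hit list.
#' @export
anchor_psiblast <- function(path, query, iteration = "last") {
  doc <- xml2::read_xml(path)
  qlen <- as.integer(xml2::xml_text(
    xml2::xml_find_first(doc, ".//BlastOutput_query-len")))
  if (is.na(qlen) || qlen != query$length)
    stop("report query length (", qlen, ") does not match query '",
         query$id, "' (", query$length, ")")
  iters <- xml2::xml_find_all(doc, ".//Iteration")
  if (length(iters) == 0L) return(anchored_msa(query, list()))
  it <- if (identical(iteration, "last")) {
    iters[[length(iters)]]
  } else {
    k <- as.integer(iteration)
    if (is.na(k) || k < 1L || k > length(iters))
      stop("no iteration ", iteration, " in report (", length(iters), " present)")
    iters[[k]]
  }
  hits <- list()
  for (hit in xml2::xml_find_all(it, ".//Hit")) {
    hid <- xml2::xml_text(xml2::xml_find_first(hit, "./Hit_id"))
    hsps <- xml2::xml_find_all(hit, ".//Hsp")
    for (j in seq_along(hsps)) {
      hsp <- hsps[[j]]
      txt <- function(tag) xml2::xml_text(xml2::xml_find_first(hsp, paste0("./", tag)))
      row <- project_hsp(txt("Hsp_qseq"), txt("Hsp_hseq"),
                         as.integer(txt("Hsp_query-from")),
                         as.integer(txt("Hsp_query-to")), qlen)
      id <- if (length(hsps) > 1L) sprintf("%s/%d", hid, j) else hid
      hits[[length(hits) + 1L]] <- aligned_hit(id, as.numeric(txt("Hsp_evalue")), row)
    }
  }
  anchored_msa(query, hits)
}

# ---------------------------------------------------------------------------
# Domain-range TSV: "<chain_id><ws><start-end>, <start-end>, ..."

#' Read domain definitions from a range table
#'
#' One line per chain: the chain identifier, whitespace, then comma-separated
#' `start-end` residue ranges (1-based inclusive), e.g.
#' `T0529  7-339, 364-561`.
#'
#' @param path Path to the TSV/whitespace-separated file.
#' @return List of [domain_definition], one per non-comment line.
#' @export
read_domain_ranges <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(line) {
    m <- regmatches(line, regexpr("^\\S+", line))
    chain <- m
    rest <- trimws(sub("^\\S+", "", line))
    parts <- trimws(strsplit(rest, ",", fixed = TRUE)[[1L]])
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0L)
      stop("chain '", chain, "': no ranges on line")
    ok <- grepl("^[0-9]+\\s*-\\s*[0-9]+\\*?$", parts)
    if (!all(ok))
      stop("chain '", chain, "': malformed range '", parts[!ok][1L], "'")
    nums <- lapply(strsplit(sub("\\*$", "", parts), "-"), as.integer)
    ranges <- do.call(rbind, nums)
    domain_definition(chain, ranges)
  })
}

#' Write domain definitions in the range-table dialect
#'
#' @param defs List of [domain_definition].
#' @param path Output path.
#' @export
write_domain_ranges <- function(defs, path) {
  lines <- vapply(defs, function(d) {
    rng <- paste(sprintf("%d-%d", d$ranges$start, d$ranges$end), collapse = ", ")
    paste0(d$chain_id, "\t", rng)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SS/SA flat file: three lines (chain id, ss string, sa string)

#' Read a structural annotation file
#'
#' Three-line flat file: chain identifier, secondary-structure string over
#' \{H,E,C\}, solvent-accessibility string over \{b,e\}. Both strings are
#' length-checked against the query.
#'
#' @param path Path to the annotation file.
#' @param query The [query_protein] the annotation describes.
#' @return A [structural_annotation].
#' @export
read_annotation <- function(path, query) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L)
    stop("annotation file ", path, ": expected 3 lines (id, ss, sa)")
  ann <- structural_annotation(lines[2L], lines[3L])
  if (nchar(ann$ss) != query$length)
    stop("annotation for '", query$id, "': expected length ", query$length,
         ", found ", nchar(ann$ss))
  ann
}

#' Write a structural annotation file
#'
#' @param ann A [structural_annotation].
#' @param id Chain identifier for the first line.
#' @param path Output path.
#' @export
write_annotation <- function(ann, id, path) {
  writeLines(c(id, ann$ss, ann$sa), path)
  invisible(path)
}
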