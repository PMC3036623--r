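# Shared fixture builders; everything is generated in code at test time.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# row with g1 leading gaps, a aligned residues, g2 trailing gaps
segment_row <- function(g1, a, g2) {
  paste0(strrep("-", g1), rand_seq(a), strrep("-", g2))
}

toy_msa <- function(rows, evalues = seq_along(rows), qlen = nchar(rows[[1]])) {
  q <- query_protein("q", rand_seq(qlen))
  hits <- lapply(seq_along(rows), function(i)
    aligned_hit(sprintf("h%03d", i), evalues[i], rows[[i]]))
  anchored_msa(q, hits)
}

# random anchored MSA mixing terminal-segment rows and i.i.d.-gap rows
random_msa <- function(max_len = 300L, max_hits = 20L) {
  L <- sample(30:max_len, 1L)
  nh <- sample(0:max_hits, 1L)
  rows <- replicate(nh, {
    if (runif(1) < 0.6) {
      g1 <- sample(0:L, 1L)
      a <- sample(0:(L - g1), 1L)
      segment_row(g1, a, L - g1 - a)
    } else {
      paste(ifelse(runif(L) < 0.3, "-", sample(AA20, L, replace = TRUE)),
            collapse = "")
    }
  })
  toy_msa(as.list(rows), evalues = sort(runif(nh)), qlen = L)
}

rand_annotation <- function(L) {
  structural_annotation(
    paste(sample(c("H", "E", "C"), L, replace = TRUE), collapse = ""),
    paste(sample(c("b", "e"), L, replace = TRUE), collapse = ""))
}

# minimal NCBI BLAST XML (outfmt 5) report; hsps is a list of lists with
# fields hit_id, evalue, qfrom, qto, qseq, hseq, grouped per hit_id
blast_xml <- function(path, query_len, hsps, n_iterations = 1L,
                      final_only_hsps = TRUE) {
  hit_block <- function(hs) {
    ids <- unique(vapply(hs, `[[`, character(1), "hit_id"))
    paste(vapply(ids, function(id) {
      mine <- Filter(function(h) h$hit_id == id, hs)
      hsp_xml <- paste(vapply(mine, function(h) paste0(
        "<Hsp>",
        "<Hsp_evalue>", h$evalue, "</Hsp_evalue>",
        "<Hsp_query-from>", h$qfrom, "</Hsp_query-from>",
        "<Hsp_query-to>", h$qto, "</Hsp_query-to>",
        "<Hsp_qseq>", h$qseq, "</Hsp_qseq>",
        "<Hsp_hseq>", h$hseq, "</Hsp_hseq>",
        "</Hsp>"), character(1)), collapse = "")
      paste0("<Hit><Hit_id>", id, "</Hit_id><Hit_hsps>", hsp_xml,
             "</Hit_hsps></Hit>")
    }, character(1)), collapse = "")
  }
  iter_xml <- vapply(seq_len(n_iterations), function(i) {
    hs <- if (i == n_iterations || !final_only_hsps) hsps else list()
    paste0("<Iteration><Iteration_iter-num>", i, "</Iteration_iter-num>",
           "<Iteration_hits>", hit_block(hs), "</Iteration_hits></Iteration>")
  }, character(1))
  writeLines(paste0(
    "<?xml version=\"1.0\"?>\n<BlastOutput>",
    "<BlastOutput_query-def>q</BlastOutput_query-def>",
    "<BlastOutput_query-len>", query_len, "</BlastOutput_query-len>",
    "<BlastOutput_iterations>", paste(iter_xml, collapse = ""),
    "</BlastOutput_iterations></BlastOutput>"), path)
  path
}
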