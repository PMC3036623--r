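test_that("read_fasta parses records in file order and validates input", {
  f <- withr::local_tempfile(lines = ">q\nMKV")
  p <- read_fasta(f)
  expect_length(p, 1)
  expect_equal(p[[1]]$sequence, "MKV")
  expect_equal(p[[1]]$length, 3)

  empty <- withr::local_tempfile(lines = character(0))
  expect_equal(read_fasta(empty), list())

  two <- withr::local_tempfile(lines = c(">a", "MK", ">b", "ACDE"))
  p2 <- read_fasta(two)
  expect_equal(vapply(p2, `[[`, character(1), "id"), c("a", "b"))

  bad <- withr::local_tempfile(lines = c("MKV", ">a", "MK"))
  expect_error(read_fasta(bad), "line 1")
})

test_that("query and hit constructors enforce their invariants", {
  expect_error(query_protein("q", ""), "empty")
  expect_error(query_protein("q", "MK-V"), "invalid")
  expect_equal(query_protein("q", "mkv")$sequence, "MKV")
  expect_error(aligned_hit("h", -1, "MK"), "non-negative")
  expect_error(aligned_hit("h", 1, "M?"), "invalid")
  q <- query_protein("q", "MKVA")
  expect_error(anchored_msa(q, list(aligned_hit("h", 1, "MK"))), "length")
})

test_that("hits are sorted by e-value with ties kept in input order", {
  q <- query_protein("q", "MKVA")
  h <- function(id, e) aligned_hit(id, e, "MKVA")
  msa <- anchored_msa(q, list(h("c", 2), h("a", 1), h("b", 1)))
  expect_equal(vapply(msa$hits, `[[`, character(1), "hit_id"),
               c("a", "b", "c"))
})

test_that("domain range tables parse the printed dialect and validate", {
  f <- withr::local_tempfile(lines = c("T0529\t7-339, 364-561", "X\t1-90"))
  defs <- read_domain_ranges(f)
  expect_length(defs, 2)
  expect_equal(defs[[1]]$ranges$start, c(7L, 364L))
  expect_equal(defs[[1]]$ranges$end, c(339L, 561L))
  expect_equal(nrow(defs[[2]]$ranges), 1L)

  inv <- withr::local_tempfile(lines = "Y\t5-3")
  expect_error(read_domain_ranges(inv), "Y")
  ovl <- withr::local_tempfile(lines = "Z\t1-50, 40-80")
  expect_error(read_domain_ranges(ovl), "overlap")

  # round trip through the writer
  out <- withr::local_tempfile()
  write_domain_ranges(defs, out)
  again <- read_domain_ranges(out)
  expect_equal(again[[1]]$ranges, defs[[1]]$ranges)
})

test_that("annotation files are length- and alphabet-checked", {
  q <- query_protein("q", "MKVARG")
  ok <- withr::local_tempfile(lines = c("q", "HHHCCC", "bbbeee"))
  ann <- read_annotation(ok, q)
  expect_equal(ann$ss, "HHHCCC")

  short <- withr::local_tempfile(lines = c("q", "HHH", "bbb"))
  expect_error(read_annotation(short, q), "length 6")
  badchar <- withr::local_tempfile(lines = c("q", "HHHXCC", "bbbeee"))
  expect_error(read_annotation(badchar, q), "H,E,C")
})

test_that("PSI-BLAST HSPs are projected onto query coordinates", {
  set.seed(7)
  q <- query_protein("q", rand_seq(100))
  seg <- substr(q$sequence, 51, 100)
  f <- withr::local_tempfile()
  blast_xml(f, 100, list(list(hit_id = "h1", evalue = 1e-10,
                              qfrom = 51, qto = 100,
                              qseq = seg, hseq = seg)))
  msa <- anchor_psiblast(f, q)
  expect_length(msa$hits, 1)
  row <- msa$hits[[1]]$aligned
  expect_equal(nchar(row), 100)
  expect_equal(substr(row, 1, 50), strrep("-", 50))
  expect_equal(substr(row, 51, 100), seg)
})

test_that("hit insertions relative to the query are dropped", {
  set.seed(8)
  q <- query_protein("q", paste(sample(setdiff(AA20, "W"), 30, replace = TRUE),
                                collapse = ""))
  # hit inserts "WW" after query position 10
  qseq <- paste0(substr(q$sequence, 1, 10), "--", substr(q$sequence, 11, 30))
  hseq <- paste0(substr(q$sequence, 1, 10), "WW", substr(q$sequence, 11, 30))
  f <- withr::local_tempfile()
  blast_xml(f, 30, list(list(hit_id = "h1", evalue = 1, qfrom = 1, qto = 30,
                             qseq = qseq, hseq = hseq)))
  msa <- anchor_psiblast(f, q)
  row <- msa$hits[[1]]$aligned
  expect_equal(nchar(row), 30)
  expect_false(grepl("W", row))
  # projection conservation: non-gaps in the row never exceed hit residues
  expect_lte(sum(strsplit(row, "")[[1]] != "-"), nchar(gsub("-", "", hseq)))
})

test_that("multi-HSP hits, e-value sorting, and empty reports are handled", {
  set.seed(9)
  q <- query_protein("q", rand_seq(120))
  s1 <- substr(q$sequence, 1, 50)
  s2 <- substr(q$sequence, 71, 120)
  f <- withr::local_tempfile()
  blast_xml(f, 120, list(
    list(hit_id = "hA", evalue = 1e-3, qfrom = 1, qto = 50, qseq = s1, hseq = s1),
    list(hit_id = "hA", evalue = 1e-8, qfrom = 71, qto = 120, qseq = s2, hseq = s2)))
  msa <- anchor_psiblast(f, q)
  expect_equal(vapply(msa$hits, `[[`, character(1), "hit_id"),
               c("hA/2", "hA/1"))  # sorted by e-value ascending

  f0 <- withr::local_tempfile()
  blast_xml(f0, 120, list())
  expect_length(anchor_psiblast(f0, q)$hits, 0)

  expect_error(anchor_psiblast(f, query_protein("q", rand_seq(60))),
               "does not match")
})

test_that("only the requested PSI-BLAST iteration contributes hits", {
  set.seed(10)
  q <- query_protein("q", rand_seq(60))
  s <- substr(q$sequence, 1, 60)
  f <- withr::local_tempfile()
  blast_xml(f, 60, list(list(hit_id = "h1", evalue = 1, qfrom = 1, qto = 60,
                             qseq = s, hseq = s)),
            n_iterations = 3, final_only_hsps = TRUE)
  expect_length(anchor_psiblast(f, q)$hits, 1)       # default: last
  expect_length(anchor_psiblast(f, q, iteration = 1)$hits, 0)
  expect_error(anchor_psiblast(f, q, iteration = 9), "no iteration")
})

test_that("anchored-MSA aligned FASTA round-trips exactly", {
  set.seed(11)
  q <- query_protein("q1", rand_seq(80))
  hits <- list(aligned_hit("hitA", 1e-5, segment_row(50, 30, 0)),
               aligned_hit("hitB", 0.001, segment_row(0, 46, 34)))
  msa <- anchored_msa(q, hits)
  f <- withr::local_tempfile()
  write_anchored_msa(msa, f)
  again <- read_anchored_msa(f)
  expect_equal(again$query$sequence, msa$query$sequence)
  expect_equal(vapply(again$hits, `[[`, character(1), "hit_id"),
               vapply(msa$hits, `[[`, character(1), "hit_id"))
  expect_equal(vapply(again$hits, `[[`, character(1), "aligned"),
               vapply(msa$hits, `[[`, character(1), "aligned"))
  expect_equal(vapply(again$hits, `[[`, numeric(1), "e_value"),
               vapply(msa$hits, `[[`, numeric(1), "e_value"))
  # re-parse stability of the ordering
  f2 <- withr::local_tempfile()
  write_anchored_msa(again, f2)
  expect_identical(readLines(f), readLines(f2))
})
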