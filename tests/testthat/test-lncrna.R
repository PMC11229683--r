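# compact transcript-row constructor
tx <- function(id, start, end, strand = "+", exon_count = 2,
               length_bp = end - start + 1, read_count = 10,
               biotype = "novel", exon_starts = NULL, exon_ends = NULL) {
  row <- tibble::tibble(
    transcript_id = id, chrom = "chr1", start = start, end = end,
    strand = strand, exon_count = exon_count, length_bp = length_bp,
    read_count = read_count, biotype = biotype
  )
  if (!is.null(exon_starts)) {
    row$exon_starts <- list(exon_starts)
    row$exon_ends <- list(exon_ends)
  }
  row
}

all_noncoding <- function(ids) {
  tibble::tibble(transcript_id = ids, cpc_noncoding = TRUE,
                 cpat_noncoding = TRUE, pfam_no_domain = TRUE)
}

test_that("each cascade rule rejects exactly its planted violation", {
  ref <- dplyr::bind_rows(
    tx("mrna1", 1000, 3000, "+", biotype = "mRNA",
       exon_starts = c(1000, 2500), exon_ends = c(1500, 3000)),
    tx("rrna1", 50000, 50200, "+", biotype = "rRNA")
  )
  cands <- dplyr::bind_rows(
    tx("ok", 10000, 10500),                          # passes everything
    tx("short", 20000, 20149),                       # 150 bp
    tx("monoexonic", 30000, 30300, exon_count = 1),  # 1 exon
    tx("lowread", 40000, 40400, read_count = 2),     # < 3 reads
    tx("coding", 60000, 60400),                      # CPAT says coding
    tx("hits_mrna", 1400, 1700, "+"),                # same-strand exon overlap
    tx("hits_rrna", 50100, 50400, "-")               # structural, any strand
  )
  calls <- all_noncoding(cands$transcript_id)
  calls$cpat_noncoding[calls$transcript_id == "coding"] <- FALSE
  rep <- identify_lncrnas(cands, ref, calls)

  expect_setequal(rep$transcript_id[rep$retained], "ok")
  reasons <- setNames(rep$reason, rep$transcript_id)
  expect_identical(reasons[["short"]], "length")
  expect_identical(reasons[["monoexonic"]], "exons")
  expect_identical(reasons[["lowread"]], "reads")
  expect_identical(reasons[["coding"]], "coding")
  expect_identical(reasons[["hits_mrna"]], "overlap")
  expect_identical(reasons[["hits_rrna"]], "overlap")
  # retained + rejected cover the input disjointly
  expect_equal(sum(rep$retained) + sum(!is.na(rep$reason)), nrow(cands))
})

test_that("mRNA overlap exclusion is exonic and strand-aware", {
  ref <- tx("mrna1", 1000, 9000, "+", biotype = "mRNA",
            exon_starts = c(1000, 8000), exon_ends = c(1500, 9000))
  calls <- all_noncoding(c("intronic", "antisense", "exonic"))
  cands <- dplyr::bind_rows(
    tx("intronic", 2000, 2600, "+"),   # inside the intron: retained
    tx("antisense", 1200, 1800, "-"),  # exon overlap, wrong strand: retained
    tx("exonic", 1200, 1800, "+")      # same-strand exon overlap: excluded
  )
  rep <- identify_lncrnas(cands, ref, calls)
  expect_setequal(rep$transcript_id[rep$retained], c("intronic", "antisense"))
  expect_identical(rep$reason[rep$transcript_id == "exonic"], "overlap")
})

test_that("the consensus rule needs all three non-coding verdicts", {
  cands <- tx("cand", 1000, 1400)
  ref <- tx("far", 90000, 91000, biotype = "mRNA")
  for (col in c("cpc_noncoding", "cpat_noncoding", "pfam_no_domain")) {
    calls <- all_noncoding("cand")
    calls[[col]] <- FALSE
    rep <- identify_lncrnas(cands, ref, calls)
    expect_identical(rep$reason, "coding")
  }
  rep <- identify_lncrnas(cands, ref, all_noncoding("cand"))
  expect_true(rep$retained)
})

test_that("a candidate surviving structure but lacking verdicts is an error", {
  cands <- dplyr::bind_rows(tx("have_call", 1000, 1400),
                            tx("no_call", 5000, 5400))
  ref <- tx("far", 90000, 91000, biotype = "mRNA")
  expect_error(identify_lncrnas(cands, ref, all_noncoding("have_call")),
               "no_call")
  # a transcript already rejected structurally needs no verdict
  cands2 <- dplyr::bind_rows(tx("have_call", 1000, 1400),
                             tx("short_no_call", 5000, 5100))
  expect_no_error(identify_lncrnas(cands2, ref, all_noncoding("have_call")))
})

test_that("the first failing rule is reported but never changes the retained set", {
  # violates both length (rule 2) and coding (rule 5)
  cands <- tx("double", 1000, 1100)
  ref <- tx("far", 90000, 91000, biotype = "mRNA")
  calls <- all_noncoding("double")
  calls$cpc_noncoding <- FALSE
  rep <- identify_lncrnas(cands, ref, calls)
  expect_identical(rep$reason, "length")
  expect_false(rep$retained)
})

test_that("positional classes follow the standard definitions", {
  genes <- dplyr::bind_rows(
    tx("geneA", 1000, 9000, "+",
       exon_starts = c(1000, 8000), exon_ends = c(1500, 9000)),
    tx("geneB", 20000, 22000, "-",
       exon_starts = c(20000, 21500), exon_ends = c(20500, 22000))
  )
  lncs <- dplyr::bind_rows(
    tx("linc", 50000, 50800),          # intersects nothing
    tx("anti", 20100, 20700, "+"),     # only opposite-strand geneB
    tx("intr", 2000, 2600, "+"),       # inside geneA intron, same strand
    tx("sense", 1200, 2600, "+")       # same-strand exon overlap
  )
  expect_identical(classify_position(lncs, genes),
                   c("lincRNA", "antisense", "intronic", "sense_overlapping"))
})

test_that("transcript tables round-trip through GTF", {
  dir <- withr::local_tempdir()
  sim <- simulate_annotation(n_clean = 5, violations_per_rule = 2, seed = 21)
  path <- file.path(dir, "cand.gtf")
  write_transcripts_gtf(sim$candidates, path)
  back <- read_transcripts_gtf(path)
  ord <- match(sim$candidates$transcript_id, back$transcript_id)
  expect_false(anyNA(ord))
  back <- back[ord, ]
  for (col in c("chrom", "strand", "start", "end", "exon_count", "length_bp"))
    expect_equal(back[[col]], sim$candidates[[col]], ignore_attr = TRUE)
  expect_equal(back$exon_starts, sim$candidates$exon_starts,
               ignore_attr = TRUE)
})

test_that("filter counts on a planted annotation equal the planted design", {
  sim <- simulate_annotation(n_clean = 12, violations_per_rule = 4, seed = 8)
  rep <- identify_lncrnas(sim$candidates, sim$reference, sim$calls)
  counts <- filter_counts(rep)
  rules <- c("overlap", "length", "exons", "reads", "coding")
  expect_identical(unname(counts[rules]), rep(4L, 5))
  expect_identical(unname(counts[["retained"]]), 12L)
  expect_setequal(rep$transcript_id[rep$retained], sim$truth$clean_ids)
  # each planted violator is rejected for its planted reason
  for (rule in names(sim$truth$violations)) {
    expect_identical(
      sort(rep$transcript_id[!is.na(rep$reason) & rep$reason == rule]),
      sort(sim$truth$violations[[rule]])
    )
  }
})
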