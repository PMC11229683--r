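#' @importFrom rlang .data
NULL

STRUCTURAL_BIOTYPES <- c("rRNA", "tRNA", "snoRNA", "snRNA")
FILTER_RULES <- c("overlap", "length", "exons", "reads", "coding")

# Transcript-span GRanges from a transcript table.
transcript_granges <- function(transcripts) {
  GenomicRanges::GRanges(
    seqnames = transcripts$chrom,
    ranges = IRanges::IRanges(start = transcripts$start, end = transcripts$end),
    strand = transcripts$strand,
    transcript_id = transcripts$transcript_id
  )
}

# Exon GRanges: uses per-transcript exon coordinates when the table
# carries exon_starts/exon_ends list columns, otherwise falls back to the
# transcript span (a transcript with no recorded exon structure is
# treated as one exon covering its span).
exon_granges <- function(transcripts) {
  if (all(c("exon_starts", "exon_ends") %in% names(transcripts))) {
    n_ex <- lengths(transcripts$exon_starts)
    GenomicRanges::GRanges(
      seqnames = rep(transcripts$chrom, n_ex),
      ranges = IRanges::IRanges(start = unlist(transcripts$exon_starts),
                                end = unlist(transcripts$exon_ends)),
      strand = rep(transcripts$strand, n_ex),
      transcript_id = rep(transcripts$transcript_id, n_ex)
    )
  } else {
    transcript_granges(transcripts)
  }
}

#' Identify lncRNAs by the candidate filter cascade
#'
#' Applies, in fixed order, the five exclusion rules used to call long
#' non-coding RNAs among assembled transcripts:
#'
#' 1. `overlap` — the candidate span intersects an exon of a reference
#'    mRNA on the same strand, or the span of a reference structural RNA
#'    (rRNA, tRNA, snoRNA, snRNA) on either strand; a 1 bp intersection
#'    suffices. Opposite-strand mRNA overlap is retained (such
#'    transcripts are later classed antisense by [classify_position()]).
#' 2. `length` — summed exon length below `min_len` bp.
#' 3. `exons` — fewer than `min_exons` exons.
#' 4. `reads` — fewer than `min_reads` supporting reads.
#' 5. `coding` — retained only when all three coding-potential predictors
#'    (CPC, CPAT, Pfam domain scan) agree the transcript is non-coding.
#'
#' Each rejected transcript is reported with the FIRST rule it fails;
#' permuting the rule order can change the reported reason but never the
#' retained set.
#'
#' @param candidates Transcript table (one row per transcript) with
#'   columns `transcript_id`, `chrom`, `start`, `end`, `strand`,
#'   `exon_count`, `length_bp`, `read_count`.
#' @param reference Reference annotation table with the same coordinate
#'   columns plus `biotype` (`mRNA`, `rRNA`, `tRNA`, `snoRNA`, `snRNA`);
#'   optional `exon_starts`/`exon_ends` list columns give mRNA exon
#'   structure (otherwise spans are used).
#' @param calls Predictor verdicts: a data frame with columns
#'   `transcript_id`, `cpc_noncoding`, `cpat_noncoding`, `pfam_no_domain`
#'   (logical). Required for every candidate that survives rules 1-4.
#' @param min_len Minimum transcript length, bp.
#' @param min_exons Minimum exon count.
#' @param min_reads Minimum supporting read count.
#' @return An object of class `lnc_filter_report`: a tibble with columns
#'   `transcript_id`, `retained` (logical) and `reason` (first failed
#'   rule, `NA` when retained). Retained and rejected sets are disjoint
#'   and jointly cover the input.
#' @export
identify_lncrnas <- function(candidates, reference, calls,
                             min_len = 200, min_exons = 2, min_reads = 3) {
  stopifnot(is.data.frame(candidates), is.data.frame(reference))
  candidates <- tibble::as_tibble(candidates)
  n <- nrow(candidates)
  reason <- rep(NA_character_, n)

  # rule 1: overlap with reference features
  cand_gr <- transcript_granges(candidates)
  ref_mrna <- reference[reference$biotype == "mRNA", , drop = FALSE]
  ref_struct <- reference[reference$biotype %in% STRUCTURAL_BIOTYPES, , drop = FALSE]
  hit_mrna <- if (nrow(ref_mrna)) {
    IRanges::overlapsAny(cand_gr, exon_granges(ref_mrna), ignore.strand = FALSE)
  } else rep(FALSE, n)
  hit_struct <- if (nrow(ref_struct)) {
    IRanges::overlapsAny(cand_gr, transcript_granges(ref_struct),
                         ignore.strand = TRUE)
  } else rep(FALSE, n)
  reason[is.na(reason) & (hit_mrna | hit_struct)] <- "overlap"

  # rules 2-4: structural filters
  reason[is.na(reason) & candidates$length_bp < min_len] <- "length"
  reason[is.na(reason) & candidates$exon_count < min_exons] <- "exons"
  reason[is.na(reason) & candidates$read_count < min_reads] <- "reads"

  # rule 5: three-predictor non-coding consensus
  survivors <- candidates$transcript_id[is.na(reason)]
  calls <- tibble::as_tibble(calls)
  missing_ids <- setdiff(survivors, calls$transcript_id)
  if (length(missing_ids))
    stop("coding-potential calls missing for candidate(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  idx <- match(candidates$transcript_id, calls$transcript_id)
  noncoding <- calls$cpc_noncoding[idx] & calls$cpat_noncoding[idx] &
    calls$pfam_no_domain[idx]
  reason[is.na(reason) & !noncoding] <- "coding"

  report <- tibble::tibble(
    transcript_id = candidates$transcript_id,
    retained = is.na(reason),
    reason = reason
  )
  class(report) <- c("lnc_filter_report", class(report))
  report
}

#' Per-rule rejection counts of a filter report
#'
#' @param report An [identify_lncrnas()] report.
#' @return Named integer vector over the five rules plus `retained`.
#' @export
filter_counts <- function(report) {
  stopifnot(inherits(report, "lnc_filter_report"))
  counts <- vapply(FILTER_RULES,
                   function(r) sum(report$reason == r, na.rm = TRUE),
                   integer(1))
  c(counts, retained = sum(report$retained))
}

#' Positional classification of lncRNAs
#'
#' Assigns each lncRNA one of the four standard positional classes with
#' respect to a set of gene models:
#' * `lincRNA` — the span intersects no gene model on either strand;
#' * `antisense` — it intersects gene models only on the opposite strand;
#' * `intronic` — it lies fully inside a same-strand gene span without
#'   intersecting any of that strand's exons;
#' * `sense_overlapping` — any other same-strand overlap.
#'
#' @param lncrnas Transcript table of lncRNAs (rows that passed
#'   [identify_lncrnas()]).
#' @param gene_models Gene-model table with coordinate columns, `strand`
#'   and optional `exon_starts`/`exon_ends` list columns.
#' @return Character vector of classes, one per row of `lncrnas`.
#' @export
classify_position <- function(lncrnas, gene_models) {
  lnc_gr <- transcript_granges(lncrnas)
  gene_gr <- transcript_granges(gene_models)
  gene_ex <- exon_granges(gene_models)

  any_hit <- IRanges::overlapsAny(lnc_gr, gene_gr, ignore.strand = TRUE)
  sense_hit <- IRanges::overlapsAny(lnc_gr, gene_gr, ignore.strand = FALSE)
  sense_exon_hit <- IRanges::overlapsAny(lnc_gr, gene_ex, ignore.strand = FALSE)
  within_sense <- IRanges::overlapsAny(lnc_gr, gene_gr, type = "within",
                                       ignore.strand = FALSE)

  dplyr::case_when(
    !any_hit ~ "lincRNA",
    !sense_hit ~ "antisense",
    within_sense & !sense_exon_hit ~ "intronic",
    TRUE ~ "sense_overlapping"
  )
}

#' Read a transcript table from GTF
#'
#' Imports a GTF annotation and collapses its `exon` features into one
#' row per transcript: span coordinates, exon count, summed exon length
#' and (when present) the `transcript_biotype` attribute. Per-exon
#' coordinates are kept in `exon_starts`/`exon_ends` list columns for
#' strand-aware overlap work.
#'
#' @param path GTF file path (attributes `gene_id` and `transcript_id`;
#'   `exon` features required).
#' @return A transcript tibble as consumed by [identify_lncrnas()].
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("GTF has no exon features: ", path, call. = FALSE)
  key <- ex$transcript_id
  ord <- order(match(key, unique(key)), GenomicRanges::start(ex))
  ex <- ex[ord]
  key <- ex$transcript_id
  starts <- split(GenomicRanges::start(ex), factor(key, levels = unique(key)))
  ends <- split(GenomicRanges::end(ex), factor(key, levels = unique(key)))
  first <- !duplicated(key)
  tbl <- tibble::tibble(
    transcript_id = key[first],
    gene_id = ex$gene_id[first],
    chrom = as.character(GenomicRanges::seqnames(ex))[first],
    strand = as.character(GenomicRanges::strand(ex))[first],
    start = vapply(starts, min, numeric(1)),
    end = vapply(ends, max, numeric(1)),
    exon_count = lengths(starts),
    length_bp = vapply(seq_along(starts),
                       function(i) sum(ends[[i]] - starts[[i]] + 1), numeric(1)),
    exon_starts = unname(as.list(starts)),
    exon_ends = unname(as.list(ends))
  )
  if ("transcript_biotype" %in% names(S4Vectors::mcols(ex))) {
    tbl$biotype <- ex$transcript_biotype[first]
  } else {
    tbl$biotype <- "novel"
  }
  tbl
}

#' Write a transcript table as GTF
#'
#' Emits `transcript` and `exon` features with `gene_id`,
#' `transcript_id` and `transcript_biotype` attributes, suitable for
#' round-tripping through [read_transcripts_gtf()].
#'
#' @param transcripts Transcript table; if `exon_starts`/`exon_ends` are
#'   absent each transcript is written as a single exon.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_transcripts_gtf <- function(transcripts, path) {
  tbl <- tibble::as_tibble(transcripts)
  if (!"gene_id" %in% names(tbl)) tbl$gene_id <- paste0(tbl$transcript_id, ".g")
  if (!"biotype" %in% names(tbl)) tbl$biotype <- "novel"
  if (!all(c("exon_starts", "exon_ends") %in% names(tbl))) {
    tbl$exon_starts <- as.list(tbl$start)
    tbl$exon_ends <- as.list(tbl$end)
  }
  n_ex <- lengths(tbl$exon_starts)
  tx <- GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(tbl$start, tbl$end),
    strand = tbl$strand,
    type = "transcript", source = "hydrolnc",
    gene_id = tbl$gene_id, transcript_id = tbl$transcript_id,
    transcript_biotype = tbl$biotype
  )
  ex <- GenomicRanges::GRanges(
    seqnames = rep(tbl$chrom, n_ex),
    ranges = IRanges::IRanges(unlist(tbl$exon_starts), unlist(tbl$exon_ends)),
    strand = rep(tbl$strand, n_ex),
    type = "exon", source = "hydrolnc",
    gene_id = rep(tbl$gene_id, n_ex),
    transcript_id = rep(tbl$transcript_id, n_ex),
    transcript_biotype = rep(tbl$biotype, n_ex)
  )
  rtracklayer::export(c(tx, ex), path, format = "gtf")
  invisible(path)
}
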