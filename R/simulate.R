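#' Simulate an interval-censored germination experiment
#'
#' Draws a hydrotime germination experiment with daily (or other
#' interval) scoring and right censoring, mirroring a seven-day
#' germination trial. Each seed receives a base water potential
#' \eqn{\Psi_b \sim N(\Psi_b(50), \sigma^2)}; its latent germination time
#' at ambient potential \eqn{\Psi} is \eqn{\theta_H/(\Psi - \Psi_b)}
#' (infinite when \eqn{\Psi \le \Psi_b}). A seed is scored germinated at
#' the first inspection after its latent time, so events are binned to
#' the END of their observation interval, and seeds with latent times
#' beyond `censor_h` are never scored (right censoring).
#'
#' @param params Generating [hydrotime_params()].
#' @param psi_levels Water potentials (MPa) of the treatment arms.
#' @param n_seeds Seeds sown per water-potential level.
#' @param censor_h Censoring horizon in hours (a multiple of
#'   `interval_h`).
#' @param interval_h Scoring interval in hours (24 = daily scoring).
#' @param seed RNG seed; the seed plus this ledger reproduce the dataset
#'   exactly.
#' @return List with `observations` (tibble `psi`, `replicate`, `time_h`,
#'   `n_germ_cum`, `n_total` on the full inspection grid) and `truth`
#'   (generating parameters, design and seed).
#' @export
simulate_germination <- function(params, psi_levels = c(0, -0.5, -1.0),
                                 n_seeds = 500, censor_h = 168,
                                 interval_h = 24, seed = 1L) {
  stopifnot(inherits(params, "hydrotime_params"), n_seeds > 0)
  if (censor_h %% interval_h != 0)
    stop("`censor_h` must be a multiple of `interval_h`", call. = FALSE)
  grid <- seq(interval_h, censor_h, by = interval_h)
  obs <- with_seed_local(seed, {
    per_level <- lapply(psi_levels, function(psi) {
      psi_b <- stats::rnorm(n_seeds, params$psi_b50, params$sigma)
      t_lat <- seed_germination_time(params, psi_b, psi)
      # scored at the first inspection at or after the latent time; the
      # cumulative count at a grid time T is then #{latent <= T}
      tibble::tibble(
        psi = psi, replicate = "r1", time_h = grid,
        n_germ_cum = vapply(grid, function(tt) sum(t_lat <= tt), numeric(1)),
        n_total = n_seeds
      )
    })
    dplyr::bind_rows(per_level)
  })
  list(
    observations = obs,
    truth = list(
      generator = "simulate_germination",
      params = list(psi_b50 = params$psi_b50, sigma = params$sigma,
                    theta_h = params$theta_h),
      psi_levels = psi_levels, n_seeds = n_seeds,
      censor_h = censor_h, interval_h = interval_h, seed = seed
    )
  )
}

# The 42-sample germination time-course design: two cultivars, controls
# at 0/12/24/36 h and drought arms at 12/24/36 h (at 0 h the drought arm
# is indistinguishable from the control and is not sampled), three
# biological replicates.
expression_design <- function(n_replicates = 3) {
  arms <- dplyr::bind_rows(
    tidyr::expand_grid(condition = "control", time_h = c(0, 12, 24, 36)),
    tidyr::expand_grid(condition = "drought", time_h = c(12, 24, 36))
  )
  design <- tidyr::expand_grid(cultivar = c("WL", "SD"), arms,
                               replicate = seq_len(n_replicates))
  design$sample_id <- sprintf("%s_%s_%dh_r%d", design$cultivar,
                              design$condition, design$time_h,
                              design$replicate)
  design[, c("sample_id", "cultivar", "condition", "time_h", "replicate")]
}

#' Simulate expression matrices with planted structure
#'
#' Generates lncRNA and mRNA count matrices over the 42-sample design
#' (2 cultivars x control/drought time course x 3 replicates) with two
#' kinds of planted ground truth: correlated lncRNA-mRNA pairs and
#' drought-responsive differential expression.
#'
#' Condition responses live at the level of design cells
#' (cultivar x condition x time): each feature draws one latent value per
#' cell, shared by that cell's replicates, so replicate-to-replicate
#' variation is counting noise only — as in a well-behaved RNA-seq
#' experiment. A planted pair SHARES its cell-level latent factor with
#' loading `c`; unplanted features draw their own mild condition
#' response (`background_log2_sd`). Counts are negative binomial around
#' the exponentiated means, which attenuates the correlation, so the
#' loading is tuned analytically to make the EXPECTED Pearson
#' correlation of observed log2 expression equal `target_r`: with NB
#' log2-noise variance \eqn{v = (1/\mu + \phi)/\ln(2)^2} at the typical
#' mean \eqn{\mu}, the loading is \eqn{c = \sqrt{v\, r/(1-r)}}. Planted
#' differentially expressed lncRNAs are shifted by `true_lfc` log2 units
#' in all drought cells; they are chosen disjoint from planted-pair
#' lncRNAs so the shift does not dilute planted correlations.
#'
#' @param n_lnc,n_mrna Numbers of lncRNA and mRNA features.
#' @param n_planted_pairs Correlated pairs to plant (one-to-one; at most
#'   `min(n_lnc, n_mrna)`).
#' @param target_r Expected Pearson correlation of planted pairs, in
#'   (0, 1).
#' @param n_planted_de Drought-responsive lncRNAs to plant (at most
#'   `n_lnc - n_planted_pairs`).
#' @param true_lfc True log2 fold change of planted DE features
#'   (drought over control).
#' @param n_replicates Biological replicates per design cell.
#' @param nb_dispersion Negative-binomial dispersion of counts (0.1 is
#'   typical bulk RNA-seq overdispersion).
#' @param background_log2_sd Cell-to-cell log2 spread of unplanted
#'   features' condition response.
#' @param base_log2_mean,base_log2_sd Lognormal baseline of per-feature
#'   log2 mean counts.
#' @param seed RNG seed.
#' @return List with `lnc_counts`, `mrna_counts` (integer matrices,
#'   features x samples), `samples` (sample sheet tibble), `lengths`
#'   (named bp vector over all features) and `truth` (planted pairs with
#'   `target_r`, planted DE ids with `true_lfc`, generator settings,
#'   seed).
#' @export
simulate_expression <- function(n_lnc = 100, n_mrna = 300,
                                n_planted_pairs = 50, target_r = 0.95,
                                n_planted_de = 20, true_lfc = 4,
                                n_replicates = 3, nb_dispersion = 0.1,
                                background_log2_sd = 0.25,
                                base_log2_mean = 8, base_log2_sd = 1.5,
                                seed = 1L) {
  stopifnot(n_planted_pairs >= 0, target_r > 0, target_r < 1,
            n_planted_pairs <= min(n_lnc, n_mrna),
            n_planted_de >= 0, n_planted_de <= n_lnc - n_planted_pairs)
  samples <- expression_design(n_replicates)
  n_s <- nrow(samples)
  if (n_s <= 2) stop("design yields too few samples", call. = FALSE)
  cell <- paste(samples$cultivar, samples$condition, samples$time_h)
  cell_idx <- match(cell, unique(cell))
  n_cells <- max(cell_idx)
  lnc_ids <- sprintf("LNC%04d", seq_len(n_lnc))
  mrna_ids <- sprintf("MRNA%05d", seq_len(n_mrna))

  # latent-factor loading tuned so expected observed-log2 correlation of
  # a planted pair is target_r after NB noise attenuation
  mu_typ <- 2^base_log2_mean
  v_nb <- (1 / mu_typ + nb_dispersion) / log(2)^2
  loading <- sqrt(v_nb * target_r / (1 - target_r))

  out <- with_seed_local(seed, {
    pair_lnc <- sample(lnc_ids, n_planted_pairs)
    pair_mrna <- sample(mrna_ids, n_planted_pairs)
    de_ids <- sample(setdiff(lnc_ids, pair_lnc), n_planted_de)

    # background condition response: one mild latent value per design
    # cell, shared across its replicates (replicate scatter is counting
    # noise only); planted pairs instead share a per-sample latent
    # factor, the continuous co-regulation signal both partners track
    shared_z <- matrix(stats::rnorm(n_planted_pairs * n_s),
                       nrow = n_planted_pairs)
    signal_for <- function(ids, pair_members) {
      z <- matrix(stats::rnorm(length(ids) * n_cells), nrow = length(ids))
      sig <- (background_log2_sd * z)[, cell_idx, drop = FALSE]
      planted <- match(ids, pair_members)
      hit <- which(!is.na(planted))
      sig[hit, ] <- loading * shared_z[planted[hit], , drop = FALSE]
      sig
    }
    sig_lnc <- signal_for(lnc_ids, pair_lnc)
    sig_mrna <- signal_for(mrna_ids, pair_mrna)

    base_lnc <- stats::rnorm(n_lnc, base_log2_mean, base_log2_sd)
    base_mrna <- stats::rnorm(n_mrna, base_log2_mean, base_log2_sd)
    log2_mu_lnc <- base_lnc + sig_lnc
    log2_mu_mrna <- base_mrna + sig_mrna

    drought <- samples$condition == "drought"
    log2_mu_lnc[match(de_ids, lnc_ids), drought] <-
      log2_mu_lnc[match(de_ids, lnc_ids), drought, drop = FALSE] + true_lfc

    lib <- exp(stats::rnorm(n_s, 0, 0.05))  # mild library-size variation
    draw_counts <- function(log2_mu, ids) {
      mu <- sweep(2^log2_mu, 2, lib, "*")
      cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                   size = 1 / nb_dispersion),
                    nrow = nrow(mu),
                    dimnames = list(ids, samples$sample_id))
      cnt
    }
    list(
      lnc_counts = draw_counts(log2_mu_lnc, lnc_ids),
      mrna_counts = draw_counts(log2_mu_mrna, mrna_ids),
      lengths = stats::setNames(
        c(sample(200:2000, n_lnc, replace = TRUE),
          sample(500:3000, n_mrna, replace = TRUE)),
        c(lnc_ids, mrna_ids)),
      pair_lnc = pair_lnc, pair_mrna = pair_mrna, de_ids = de_ids
    )
  })
  list(
    lnc_counts = out$lnc_counts,
    mrna_counts = out$mrna_counts,
    samples = samples,
    lengths = out$lengths,
    truth = list(
      generator = "simulate_expression",
      planted_pairs = tibble::tibble(lnc_id = out$pair_lnc,
                                     mrna_id = out$pair_mrna,
                                     target_r = target_r),
      planted_de = tibble::tibble(feature_id = out$de_ids,
                                  true_lfc = true_lfc),
      nb_dispersion = nb_dispersion, loading = loading,
      background_log2_sd = background_log2_sd,
      base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
      n_replicates = n_replicates, seed = seed
    )
  )
}

#' Simulate an annotation set with planted filter violations
#'
#' Builds a small single-chromosome annotation: a reference set (mRNA
#' genes with exon structure plus one each of rRNA, tRNA, snoRNA and
#' snRNA) and a candidate set containing `n_clean` transcripts that pass
#' every lncRNA identification rule plus exactly `violations_per_rule`
#' transcripts violating each single rule (`overlap`, `length`, `exons`,
#' `reads`, `coding`) and no other. Features are laid out in disjoint
#' 10 kb slots so violations never compound.
#'
#' @param n_clean Clean candidates to plant.
#' @param violations_per_rule Planted single-rule violators per rule.
#' @param seed RNG seed.
#' @return List with `candidates` and `reference` (transcript tibbles
#'   with exon list columns), `calls` (predictor-verdict tibble) and
#'   `truth` (ids per rule, clean ids, seed).
#' @export
simulate_annotation <- function(n_clean = 20, violations_per_rule = 3,
                                seed = 1L) {
  stopifnot(n_clean >= 0, violations_per_rule >= 0)
  slot_w <- 10000
  next_slot <- local({i <- 0L; function() {i <<- i + 1L; (i - 1L) * slot_w}})

  make_tx <- function(id, offset, strand, exon_lens, gaps, biotype = "novel") {
    starts <- integer(length(exon_lens))
    ends <- integer(length(exon_lens))
    pos <- offset + 1L
    for (k in seq_along(exon_lens)) {
      starts[k] <- pos
      ends[k] <- pos + exon_lens[k] - 1L
      pos <- ends[k] + (if (k < length(exon_lens)) gaps[k] else 0L) + 1L
    }
    tibble::tibble(
      transcript_id = id, gene_id = paste0(id, ".g"), chrom = "chr1",
      start = starts[1], end = ends[length(ends)], strand = strand,
      exon_count = length(exon_lens), length_bp = sum(exon_lens),
      biotype = biotype,
      exon_starts = list(starts), exon_ends = list(ends)
    )
  }

  with_seed_local(seed, {
    # reference mRNA genes (one per overlap violator, at least 3) + the
    # four structural RNA types
    n_ref <- max(3, violations_per_rule)
    ref_mrna <- dplyr::bind_rows(lapply(seq_len(n_ref), function(i) {
      make_tx(sprintf("REFmRNA%03d", i), next_slot() + 1000L, "+",
              exon_lens = c(400L, 500L, 800L), gaps = c(600L, 700L),
              biotype = "mRNA")
    }))
    ref_struct <- dplyr::bind_rows(lapply(STRUCTURAL_BIOTYPES, function(bt) {
      make_tx(paste0("REF", bt), next_slot() + 1000L, "+",
              exon_lens = 150L, gaps = integer(0), biotype = bt)
    }))
    reference <- dplyr::bind_rows(ref_mrna, ref_struct)

    clean_structure <- function(id, offset, strand = sample(c("+", "-"), 1)) {
      n_ex <- sample(2:4, 1)
      make_tx(id, offset, strand,
              exon_lens = sample(150:500, n_ex, replace = TRUE),
              gaps = sample(50:500, max(n_ex - 1, 0), replace = TRUE))
    }

    clean <- dplyr::bind_rows(lapply(seq_len(n_clean), function(i) {
      clean_structure(sprintf("CAND_CLEAN%03d", i), next_slot() + 2000L)
    }))

    v <- violations_per_rule
    viol_overlap <- dplyr::bind_rows(lapply(seq_len(v), function(i) {
      # same-strand candidate whose span crosses exon 1 of reference
      # mRNA gene i; otherwise clean
      g <- ref_mrna[i, ]
      make_tx(sprintf("CAND_OVLP%03d", i), g$start - 100L, "+",
              exon_lens = c(250L, 200L), gaps = 300L)
    }))
    viol_length <- dplyr::bind_rows(lapply(seq_len(v), function(i) {
      make_tx(sprintf("CAND_SHORT%03d", i), next_slot() + 2000L,
              sample(c("+", "-"), 1), exon_lens = c(80L, 60L), gaps = 200L)
    }))
    viol_exons <- dplyr::bind_rows(lapply(seq_len(v), function(i) {
      make_tx(sprintf("CAND_MONOEX%03d", i), next_slot() + 2000L,
              sample(c("+", "-"), 1), exon_lens = 400L, gaps = integer(0))
    }))
    viol_reads <- dplyr::bind_rows(lapply(seq_len(v), function(i) {
      clean_structure(sprintf("CAND_LOWREAD%03d", i), next_slot() + 2000L)
    }))
    viol_coding <- dplyr::bind_rows(lapply(seq_len(v), function(i) {
      clean_structure(sprintf("CAND_CODING%03d", i), next_slot() + 2000L)
    }))

    tx_ids <- function(df) if (nrow(df)) df$transcript_id else character(0)
    candidates <- dplyr::bind_rows(clean, viol_overlap, viol_length,
                                   viol_exons, viol_reads, viol_coding)
    candidates$read_count <- sample(5:100, nrow(candidates), replace = TRUE)
    low <- candidates$transcript_id %in% tx_ids(viol_reads)
    candidates$read_count[low] <- sample(0:2, sum(low), replace = TRUE)

    calls <- tibble::tibble(
      transcript_id = candidates$transcript_id,
      cpc_noncoding = TRUE, cpat_noncoding = TRUE, pfam_no_domain = TRUE
    )
    coding_idx <- match(viol_coding$transcript_id, calls$transcript_id)
    for (i in coding_idx) {
      which_call <- sample(c("cpc_noncoding", "cpat_noncoding",
                             "pfam_no_domain"), 1)
      calls[[which_call]][i] <- FALSE
    }

    list(
      candidates = candidates,
      reference = reference,
      calls = calls,
      truth = list(
        generator = "simulate_annotation",
        clean_ids = tx_ids(clean),
        violations = list(
          overlap = tx_ids(viol_overlap),
          length = tx_ids(viol_length),
          exons = tx_ids(viol_exons),
          reads = tx_ids(viol_reads),
          coding = tx_ids(viol_coding)
        ),
        n_clean = n_clean, violations_per_rule = violations_per_rule,
        seed = seed
      )
    )
  })
}

#' Write a simulated germination dataset to disk
#'
#' Emits the scoring CSV consumed by [read_germination_csv()] /
#' [fit_hydrotime()] plus the ground-truth ledger JSON. Same seed, same
#' bytes.
#'
#' @param sim A [simulate_germination()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_germination_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obs <- dplyr::rename(sim$observations, psi_mpa = "psi")
  readr::write_csv(obs, file.path(dir, "germination.csv"))
  write_truth_ledger(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Write a simulated expression dataset to disk
#'
#' Emits counts TSVs (features x samples), a lengths TSV, the sample
#' sheet CSV and the ground-truth ledger JSON.
#'
#' @param sim A [simulate_expression()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_expression_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts <- function(m, path) {
    df <- tibble::as_tibble(m, rownames = "feature_id")
    readr::write_tsv(df, path)
  }
  write_counts(sim$lnc_counts, file.path(dir, "lnc_counts.tsv"))
  write_counts(sim$mrna_counts, file.path(dir, "mrna_counts.tsv"))
  readr::write_tsv(tibble::tibble(feature_id = names(sim$lengths),
                                  length_bp = unname(sim$lengths)),
                   file.path(dir, "lengths.tsv"))
  readr::write_csv(sim$samples, file.path(dir, "samples.csv"))
  write_truth_ledger(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Write a simulated annotation dataset to disk
#'
#' Emits candidate and reference GTFs, the read-count TSV, the
#' predictor-verdict TSV and the ground-truth ledger JSON.
#'
#' @param sim A [simulate_annotation()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_annotation_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_transcripts_gtf(sim$candidates, file.path(dir, "candidates.gtf"))
  write_transcripts_gtf(sim$reference, file.path(dir, "reference.gtf"))
  readr::write_tsv(sim$candidates[, c("transcript_id", "read_count")],
                   file.path(dir, "read_counts.tsv"))
  readr::write_tsv(sim$calls, file.path(dir, "predictor_calls.tsv"))
  write_truth_ledger(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
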