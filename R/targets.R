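#' Predict lncRNA target genes by expression correlation
#'
#' Tests every lncRNA x mRNA pair: Pearson correlation `r` across
#' samples on `log2(x + 1)`-transformed expression, a two-sided p-value
#' from the t transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with \eqn{n-2}
#' degrees of freedom, Benjamini-Hochberg adjustment over the full
#' tested-pair family, and selection of pairs with `|r| > r_threshold`
#' and `qvalue < q_threshold`. Pairs involving a zero-variance vector are
#' skipped (with a warning), not tested. When a table of externally
#' computed RNA-RNA interaction significances is supplied, a passing pair
#' must additionally have `interaction_score < q_threshold`.
#'
#' @param lnc_expr,mrna_expr Expression matrices (features x samples,
#'   dimnames required) with identical sample columns in the same order;
#'   typically FPKM.
#' @param r_threshold Minimum absolute correlation (exclusive).
#' @param q_threshold Maximum adjusted significance (exclusive).
#' @param interaction_scores Optional data frame `lnc_id`, `mrna_id`,
#'   `score` of per-pair interaction significances (e.g. RNA-RNA duplex
#'   FDR); pairs absent from the table fail the interaction filter.
#' @param log_transform Correlate `log2(x + 1)` values (default) or the
#'   raw matrix values.
#' @return Tibble of tested pairs: `lnc_id`, `mrna_id`, `r`, `pvalue`,
#'   `qvalue`, `passed` (plus `interaction_score` when supplied).
#' @export
predict_targets <- function(lnc_expr, mrna_expr, r_threshold = 0.9,
                            q_threshold = 0.05, interaction_scores = NULL,
                            log_transform = TRUE) {
  stopifnot(is.matrix(lnc_expr), is.matrix(mrna_expr),
            !is.null(rownames(lnc_expr)), !is.null(rownames(mrna_expr)))
  if (!identical(colnames(lnc_expr), colnames(mrna_expr)))
    stop("lnc and mRNA matrices must share identical sample columns in the ",
         "same order", call. = FALSE)
  n <- ncol(lnc_expr)
  if (n < 3L)
    stop("correlation testing needs at least 3 samples", call. = FALSE)
  x <- if (log_transform) log2(t(lnc_expr) + 1) else t(lnc_expr)
  y <- if (log_transform) log2(t(mrna_expr) + 1) else t(mrna_expr)

  const_x <- apply(x, 2, stats::var) == 0
  const_y <- apply(y, 2, stats::var) == 0
  if (any(const_x) || any(const_y)) {
    skipped <- c(colnames(x)[const_x], colnames(y)[const_y])
    warning("skipping zero-variance feature(s): ",
            paste(skipped, collapse = ", "), call. = FALSE)
    x <- x[, !const_x, drop = FALSE]
    y <- y[, !const_y, drop = FALSE]
  }
  if (ncol(x) == 0L || ncol(y) == 0L) {
    return(tibble::tibble(lnc_id = character(), mrna_id = character(),
                          r = numeric(), pvalue = numeric(),
                          qvalue = numeric(), passed = logical()))
  }
  r <- stats::cor(x, y)
  pairs <- tibble::tibble(
    lnc_id = rep(rownames(r), times = ncol(r)),
    mrna_id = rep(colnames(r), each = nrow(r)),
    r = as.vector(r)
  )
  # clamp |r| = 1 to the t-transform's limit (p = 0)
  r2 <- pmin(pairs$r^2, 1)
  tstat <- ifelse(r2 >= 1, Inf, abs(pairs$r) * sqrt((n - 2) / (1 - r2)))
  pairs$pvalue <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  pairs$qvalue <- bh_adjust(pairs$pvalue)
  pairs$passed <- abs(pairs$r) > r_threshold & pairs$qvalue < q_threshold

  if (!is.null(interaction_scores)) {
    stopifnot(all(c("lnc_id", "mrna_id", "score") %in% names(interaction_scores)))
    key <- paste(pairs$lnc_id, pairs$mrna_id, sep = "\r")
    skey <- paste(interaction_scores$lnc_id, interaction_scores$mrna_id,
                  sep = "\r")
    pairs$interaction_score <- interaction_scores$score[match(key, skey)]
    pairs$passed <- pairs$passed & !is.na(pairs$interaction_score) &
      pairs$interaction_score < q_threshold
  }
  pairs
}

#' Assemble the bipartite lncRNA-mRNA regulatory network
#'
#' Keeps only passing target pairs, removes duplicate (lncRNA, mRNA)
#' edges and builds a bipartite graph with per-node degrees. A hub
#' lncRNA regulating k genes has degree k on the lncRNA side.
#'
#' @param pairs Target-pair table from [predict_targets()] (columns
#'   `lnc_id`, `mrna_id`, optional `passed`; when `passed` is present
#'   only passing rows are used).
#' @return An object of class `regulatory_network`: list with `edges`
#'   (deduplicated tibble), `lnc_nodes`, `mrna_nodes`, `lnc_degree`,
#'   `mrna_degree` (named integer vectors) and `graph` (a bipartite
#'   [igraph::graph_from_data_frame()] object).
#' @export
build_network <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  edges <- tibble::as_tibble(pairs)
  if ("passed" %in% names(edges)) edges <- edges[edges$passed, , drop = FALSE]
  edges <- dplyr::distinct(edges, .data$lnc_id, .data$mrna_id,
                           .keep_all = TRUE)
  lnc_nodes <- unique(edges$lnc_id)
  mrna_nodes <- unique(edges$mrna_id)
  lnc_degree <- table(factor(edges$lnc_id, levels = lnc_nodes))
  mrna_degree <- table(factor(edges$mrna_id, levels = mrna_nodes))
  graph <- if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      edges[, c("lnc_id", "mrna_id")], directed = FALSE,
      vertices = data.frame(name = c(lnc_nodes, mrna_nodes),
                            type = rep(c(TRUE, FALSE),
                                       c(length(lnc_nodes), length(mrna_nodes))))
    )
  } else {
    igraph::make_empty_graph(directed = FALSE)
  }
  structure(
    list(edges = edges, lnc_nodes = lnc_nodes, mrna_nodes = mrna_nodes,
         lnc_degree = stats::setNames(as.integer(lnc_degree), lnc_nodes),
         mrna_degree = stats::setNames(as.integer(mrna_degree), mrna_nodes),
         graph = graph),
    class = "regulatory_network"
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("Bipartite lncRNA-mRNA regulatory network: %d lncRNAs, %d mRNAs, %d edges\n",
              length(x$lnc_nodes), length(x$mrna_nodes), nrow(x$edges)))
  if (length(x$lnc_degree)) {
    top <- sort(x$lnc_degree, decreasing = TRUE)[1]
    cat(sprintf("  top hub: %s regulating %d gene(s)\n", names(top), top))
  }
  invisible(x)
}
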