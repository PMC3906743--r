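#' Per-probe differential expression for one contrast
#'
#' For every probe, computes the two group means on the current analysis
#' scale, their standard errors (sd / sqrt(n)), the differential expression
#' `de = mean_a - mean_b`, the average abundance `(mean_a + mean_b) / 2`,
#' the fold change `2^de`, and the Phenotypic Impact Factor
#' `pif = avg_abund * de`. PIF up-weights abundant transcripts with modest
#' fold changes, which compensates for the higher relative noise of rare
#' transcripts.
#'
#' @param m An [expr_matrix()] (any scale; DE is a difference of means on
#'   whatever scale the data are in — run the normalization chain first for
#'   the standard analysis).
#' @param group_a,group_b Treatment-group labels to contrast (A minus B);
#'   each needs at least 2 samples.
#' @return A tibble with columns `probe_id`, `mean_a`, `se_a`, `mean_b`,
#'   `se_b`, `de`, `avg_abund`, `pif`, `fold`, in probe order.
#' @export
de_scores <- function(m, group_a, group_b) {
  stopifnot(inherits(m, "expr_matrix"))
  for (g in c(group_a, group_b)) {
    n_g <- sum(m$meta$group == g)
    if (n_g == 0L) abort(paste0("unknown group: ", g))
    if (n_g < 2L) abort(paste0("group ", g, " has fewer than 2 samples"))
  }
  a <- m$values[, m$meta$group == group_a, drop = FALSE]
  b <- m$values[, m$meta$group == group_b, drop = FALSE]
  mean_a <- unname(rowMeans(a))
  mean_b <- unname(rowMeans(b))
  se_a <- unname(apply(a, 1L, sd)) / sqrt(ncol(a))
  se_b <- unname(apply(b, 1L, sd)) / sqrt(ncol(b))
  out <- tibble(
    probe_id = rownames(m$values),
    mean_a = mean_a, se_a = se_a, mean_b = mean_b, se_b = se_b,
    de = mean_a - mean_b,
    avg_abund = (mean_a + mean_b) / 2
  )
  out$pif <- out$avg_abund * out$de
  out$fold <- 2^out$de
  out
}

#' Fill (or refresh) the PIF column of a contrast table
#'
#' `pif = avg_abund * de`, the product of a probe's average abundance and
#' its differential expression.
#'
#' @param contrast A tibble with columns `de` and `avg_abund` (as produced
#'   by [de_scores()]).
#' @return The tibble with its `pif` column (re)computed.
#' @export
pif_scores <- function(contrast) {
  if (!all(c("de", "avg_abund") %in% names(contrast))) {
    abort("`contrast` needs `de` and `avg_abund` columns")
  }
  dplyr::mutate(as_tibble(contrast), pif = .data$avg_abund * .data$de)
}

#' Fold change between two log2 expression levels
#'
#' @param log2_a,log2_b Log2 expression levels (vectorized).
#' @return `2^(log2_a - log2_b)`.
#' @export
fold_change <- function(log2_a, log2_b) {
  if (!all(is.finite(log2_a)) || !all(is.finite(log2_b))) {
    abort("inputs must be finite")
  }
  2^(log2_a - log2_b)
}

#' Correct a bulk fold change for transfection efficiency
#'
#' In a transient-transfection experiment only a fraction of cells take up
#' the construct; a bulk fold change of `f` measured over the whole culture
#' implies a per-transfected-cell fold change of `f / efficiency`.
#'
#' @param fold Bulk fold change(s).
#' @param efficiency Transfection efficiency as a proportion in `(0, 1]`.
#' @return The per-transfected-cell fold change.
#' @export
efficiency_correct <- function(fold, efficiency) {
  if (any(efficiency <= 0) || any(efficiency > 1)) {
    abort("`efficiency` must lie in (0, 1]")
  }
  fold / efficiency
}

#' Summarise a probe panel across a contrast
#'
#' Produces one row per panel probe with group means, standard errors and
#' fold change, plus panel-level counts: the number of distinct panel genes,
#' the number of genes with at least one probe at fold > 1, and the maximum
#' per-probe fold. Used, e.g., to ask whether an abundant gene panel (such
#' as the mitochondrially encoded protein genes) shows a coherent trend of
#' upregulation even when individual fold changes are modest.
#'
#' @param data Either an [expr_matrix()] (supply `annot`, `group_a`,
#'   `group_b`) or a pre-computed per-probe table with columns `gene`,
#'   `mean_a` and `mean_b` (e.g. published group means).
#' @param annot Optional probe annotation tibble with columns `probe_id`,
#'   `gene` and a logical panel-flag column named by `panel`.
#' @param panel Name of the logical flag column in `annot` marking panel
#'   membership (default `"panel"`).
#' @param group_a,group_b Contrast groups when `data` is an
#'   [expr_matrix()].
#' @return A list of class `panel_summary`: `probes` (per-probe tibble with
#'   `gene`, `mean_a`, `se_a`, `mean_b`, `se_b`, `de`, `fold`), `n_genes`,
#'   `n_genes_up`, `max_fold`.
#' @export
panel_summary <- function(data, annot = NULL, panel = "panel",
                          group_a = NULL, group_b = NULL) {
  if (inherits(data, "expr_matrix")) {
    if (is.null(annot) || !panel %in% names(annot)) {
      abort("supply `annot` with the panel flag column")
    }
    keep <- annot$probe_id[annot[[panel]] %in% TRUE]
    if (!length(keep)) abort("panel is empty")
    contrast <- de_scores(data, group_a, group_b)
    tab <- dplyr::inner_join(
      contrast[contrast$probe_id %in% keep, ],
      annot[, c("probe_id", "gene")], by = "probe_id"
    )
  } else {
    tab <- as_tibble(data)
    if (!all(c("gene", "mean_a", "mean_b") %in% names(tab))) {
      abort("per-probe input needs `gene`, `mean_a`, `mean_b` columns")
    }
    if (!nrow(tab)) abort("panel is empty")
    tab$de <- tab$mean_a - tab$mean_b
    tab$fold <- 2^tab$de
  }
  per_gene <- dplyr::summarise(dplyr::group_by(tab, .data$gene),
                               any_up = any(.data$fold > 1), .groups = "drop")
  structure(
    list(probes = tab,
         n_genes = nrow(per_gene),
         n_genes_up = sum(per_gene$any_up),
         max_fold = max(tab$fold)),
    class = "panel_summary"
  )
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf(
    "<panel_summary> %d probes, %d genes; %d gene(s) with >=1 probe fold > 1; max fold %.3g\n",
    nrow(x$probes), x$n_genes, x$n_genes_up, x$max_fold))
  print(x$probes, n = 5)
  invisible(x)
}

#' @rdname panel_summary
#' @param x A `panel_summary`.
#' @param ... Unused.
#' @method tidy panel_summary
#' @export
tidy.panel_summary <- function(x, ...) x$probes

#' @rdname panel_summary
#' @method glance panel_summary
#' @export
glance.panel_summary <- function(x, ...) {
  tibble(n_probes = nrow(x$probes), n_genes = x$n_genes,
         n_genes_up = x$n_genes_up, max_fold = x$max_fold)
}
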