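#' Build a probe-by-sample expression container
#'
#' `expr_matrix` is the container every pipeline stage consumes: a numeric
#' probe x sample matrix, optional per-cell detection p-values, a sample
#' metadata table mapping samples to treatment groups, and a scale flag that
#' tracks where the data sit in the normalization chain. The flag may only
#' move forward, `raw -> log2 -> standardized`; each transform checks it, so
#' applying a step out of order is an error rather than a silent corruption.
#'
#' @param values Numeric matrix, probes in rows, samples in columns. Row and
#'   column names are the probe and sample identifiers and must be unique.
#' @param meta Data frame with columns `sample_id` and `group`, one row per
#'   sample column of `values`.
#' @param detection_p Optional numeric matrix of the same shape as `values`
#'   with detection p-values in `[0, 1]` (the vendor's per-cell probability
#'   that a signal is indistinguishable from background).
#' @param scale One of `"raw"`, `"log2"`, `"standardized"`.
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, meta, detection_p = NULL, scale = "raw") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    abort("`values` must have at least one probe and one sample.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry probe rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    abort(paste0("duplicate probe id: ",
                 rownames(values)[duplicated(rownames(values))][1L]))
  }
  if (anyDuplicated(colnames(values))) {
    abort(paste0("duplicate sample id: ",
                 colnames(values)[duplicated(colnames(values))][1L]))
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    abort(paste0("missing value at probe ", rownames(values)[bad[[1L]]],
                 ", sample ", colnames(values)[bad[[2L]]],
                 "; missing values are not supported"))
  }
  meta <- as_tibble(meta)
  if (!all(c("sample_id", "group") %in% names(meta))) {
    abort("`meta` needs columns `sample_id` and `group`.")
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$group <- as.character(meta$group)
  if (!setequal(meta$sample_id, colnames(values)) ||
      nrow(meta) != ncol(values)) {
    abort("`meta$sample_id` must match the sample columns exactly.")
  }
  meta <- meta[match(colnames(values), meta$sample_id), ]
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(values))) {
      abort("`detection_p` must have the same shape as `values`.")
    }
    if (anyNA(detection_p) || any(detection_p < 0) || any(detection_p > 1)) {
      abort("`detection_p` entries must lie in [0, 1].")
    }
    dimnames(detection_p) <- dimnames(values)
  }
  scale <- match.arg(scale, c("raw", "log2", "standardized"))
  structure(
    list(values = values, detection_p = detection_p, meta = meta,
         scale = scale),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d probes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("groups:", paste(sprintf("%s (%d)", names(table(x$meta$group)),
                               table(x$meta$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Tidy an expression container into a long tibble
#'
#' @param x An [expr_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `probe_id`, `sample_id`, `group`, `value`
#'   and, when present, `detection_p`.
#' @method tidy expr_matrix
#' @export
tidy.expr_matrix <- function(x, ...) {
  out <- tibble(
    probe_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  if (!is.null(x$detection_p)) out$detection_p <- as.vector(x$detection_p)
  out$group <- x$meta$group[match(out$sample_id, x$meta$sample_id)]
  dplyr::relocate(out, "group", .after = "sample_id")
}

#' Read and write expression matrices as TSV
#'
#' The on-disk dialect is a tab-separated table with a `probe_id` header in
#' the first column and one column per sample; detection p-values travel in a
#' sibling file of identical shape, and sample metadata in a two-column
#' `sample_id<TAB>group` table. `read_expression()` flags the result `raw`
#' unless the expression file carries a `# scale: log2` comment header, which
#' `write_expression()` emits for non-raw data.
#'
#' @param path Expression TSV path.
#' @param meta_path Sample metadata TSV path.
#' @param detp_path Optional detection p-value TSV path.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, meta_path, detp_path = NULL) {
  first <- readLines(path, n = 1L)
  scale <- "raw"
  if (grepl("^# scale:", first)) {
    scale <- trimws(sub("^# scale:", "", first))
  }
  # read.delim parses doubles with strtod, so %.17g output round-trips
  # bit-for-bit; vroom's fast parser can be one ulp off
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "probe_id") {
    abort("expression TSV must start with a `probe_id` column")
  }
  dup <- names(tab)[duplicated(names(tab))]
  if (length(dup)) {
    abort(paste0("duplicated sample column: ", dup[1L]))
  }
  num <- as.data.frame(tab[-1L])
  bad <- !vapply(num, is.numeric, logical(1L))
  if (any(bad)) {
    abort(paste0("non-numeric cells in sample column ", names(num)[bad][1L]))
  }
  values <- as.matrix(num)
  rownames(values) <- as.character(tab$probe_id)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  detp <- NULL
  if (!is.null(detp_path)) {
    ptab <- utils::read.delim(detp_path, sep = "\t", comment.char = "#",
                              check.names = FALSE, stringsAsFactors = FALSE)
    detp <- as.matrix(as.data.frame(ptab[-1L]))
    rownames(detp) <- as.character(ptab$probe_id)
    detp <- detp[rownames(values), colnames(values), drop = FALSE]
  }
  expr_matrix(values, meta, detection_p = detp, scale = scale)
}

#' @rdname read_expression
#' @param m An [expr_matrix()] to write.
#' @param detp_path Optional path for the detection p-value table.
#' @export
write_expression <- function(m, path, meta_path = NULL, detp_path = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  # %.17g keeps doubles round-trippable so write/read is bit-identical
  write_mat <- function(x, path, header = NULL) {
    body <- cbind(probe_id = rownames(x),
                  matrix(sprintf("%.17g", x), nrow(x), ncol(x)))
    lines <- c(header,
               paste(c("probe_id", colnames(x)), collapse = "\t"),
               apply(body, 1L, paste, collapse = "\t"))
    writeLines(lines, path)
  }
  header <- if (m$scale != "raw") sprintf("# scale: %s", m$scale) else NULL
  write_mat(m$values, path, header)
  if (!is.null(meta_path)) {
    readr::write_tsv(m$meta, meta_path, progress = FALSE)
  }
  if (!is.null(detp_path) && !is.null(m$detection_p)) {
    write_mat(m$detection_p, detp_path)
  }
  invisible(path)
}

#' Keep probes detectable in at least one sample
#'
#' Retains exactly the probes whose detection p-value falls below `alpha` in
#' one or more samples, preserving probe order and leaving values untouched.
#' This is the standard first cleaning step for bead-array data: a probe that
#' never rises above background in any hybridization carries no signal.
#'
#' @param m An [expr_matrix()] with detection p-values.
#' @param alpha Detection threshold, default 0.01.
#' @return The filtered [expr_matrix()].
#' @export
detection_filter <- function(m, alpha = 0.01) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(m$detection_p)) {
    abort("detection_filter() needs detection p-values; none present.")
  }
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must lie in (0, 1).")
  keep <- rowSums(m$detection_p < alpha) >= 1L
  if (!any(keep)) {
    m$values <- m$values[keep, , drop = FALSE]
    m$detection_p <- m$detection_p[keep, , drop = FALSE]
    return(m)
  }
  m$values <- m$values[keep, , drop = FALSE]
  m$detection_p <- m$detection_p[keep, , drop = FALSE]
  m
}

#' Log2-transform raw expression values
#'
#' @param m A raw-scale [expr_matrix()] with strictly positive values.
#' @return The container with `log2` values and scale flag advanced.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "raw") {
    abort(sprintf("log2_transform() expects raw-scale data, got `%s`.",
                  m$scale))
  }
  if (any(m$values <= 0)) {
    bad <- which(m$values <= 0, arr.ind = TRUE)[1L, ]
    abort(paste0("non-positive value at probe ",
                 rownames(m$values)[bad[[1L]]], ", sample ",
                 colnames(m$values)[bad[[2L]]]))
  }
  m$values <- log2(m$values)
  m$scale <- "log2"
  m
}

#' Standardize each chip to mean 0, sd 1
#'
#' Within-chip normalization: every sample column has its mean subtracted and
#' is divided by its standard deviation (population convention, divide by n),
#' so arrays with different overall brightness or spread can be combined and
#' linear contrasts computed across them.
#'
#' @param m A log2-scale (or already standardized) [expr_matrix()].
#' @return The container with standardized values.
#' @export
standardize_chips <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!m$scale %in% c("log2", "standardized")) {
    abort("standardize_chips() expects log2-scale data; transform first.")
  }
  mu <- colMeans(m$values)
  sig <- apply(m$values, 2L, sd_pop)
  if (any(sig == 0)) {
    abort(paste0("constant chip: ", colnames(m$values)[sig == 0][1L]))
  }
  m$values <- sweep(sweep(m$values, 2L, mu, "-"), 2L, sig, "/")
  m$scale <- "standardized"
  m
}

#' Flag outlier samples by inter-sample correlation
#'
#' For each sample, computes its mean Pearson correlation to every other
#' sample; samples whose statistic lies more than `z_cut` standard deviations
#' below the across-sample mean of that statistic are flagged. This mirrors
#' the usual practice of dropping arrays that fail to cluster with their
#' replicates, but as an explicit, reproducible flagging step: nothing is
#' removed here — pass the flagged ids to [pool_controls()] to drop them.
#'
#' @param m A standardized [expr_matrix()] with at least 4 samples.
#' @param z_cut Flagging threshold in standard deviations, default 3.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
flag_outlier_samples <- function(m, z_cut = 3) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "standardized") {
    abort("flag_outlier_samples() expects standardized data.")
  }
  if (ncol(m$values) < 4L) abort("need at least 4 samples to flag outliers")
  r <- cor(m$values)
  diag(r) <- NA
  stat <- rowMeans(r, na.rm = TRUE)
  spread <- sd(stat)
  if (!is.finite(spread) || spread == 0) return(character(0L))
  z <- (mean(stat) - stat) / spread
  names(stat)[z > z_cut]
}

#' Pool control groups into a single control label
#'
#' Relabels every sample in the listed control groups to one `control`
#' group, first removing any samples in `drop` (e.g. arrays flagged by
#' [flag_outlier_samples()]). Expression values are untouched.
#'
#' @param m An [expr_matrix()].
#' @param control_groups Character vector of group labels to merge.
#' @param drop Sample ids to remove before pooling (default none).
#' @param label New label for the pooled group, default `"control"`.
#' @return The relabelled [expr_matrix()].
#' @export
pool_controls <- function(m, control_groups, drop = character(0L),
                          label = "control") {
  stopifnot(inherits(m, "expr_matrix"))
  missing_grp <- setdiff(control_groups, m$meta$group)
  if (length(missing_grp)) {
    abort(paste0("unknown group label: ", missing_grp[1L]))
  }
  missing_smp <- setdiff(drop, m$meta$sample_id)
  if (length(missing_smp)) {
    abort(paste0("unknown sample id in `drop`: ", missing_smp[1L]))
  }
  keep <- !(m$meta$sample_id %in% drop)
  meta <- m$meta[keep, ]
  is_ctrl <- meta$group %in% control_groups
  if (!any(is_ctrl)) abort("dropping removed every control sample")
  meta$group[is_ctrl] <- label
  m$values <- m$values[, keep, drop = FALSE]
  if (!is.null(m$detection_p)) {
    m$detection_p <- m$detection_p[, keep, drop = FALSE]
  }
  m$meta <- meta
  m
}
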