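#' Read gene sets from a GMT file
#'
#' GMT is the conventional gene-set exchange format: one set per line,
#' tab-separated as `set_name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return A named list of character vectors; descriptions attached as the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1L)) < 3L
  if (any(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", which(short)[1L]))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  attr(sets, "descriptions") <-
    setNames(vapply(parts, `[[`, character(1L), 2L), names(sets))
  sets
}

#' Hypergeometric over-representation test of a gene list
#'
#' For each gene set, tests whether the overlap between the hit list and the
#' set is larger than expected under sampling without replacement from the
#' background universe: `p = P(X >= k)` for `X ~ Hypergeometric(N = |bg|,
#' K = |set in bg|, n = |hits|)`, inclusive at the observed overlap. Sets
#' are first intersected with the background; genes in a set but absent
#' from the background are ignored (they could never have been hit).
#'
#' @param hits Character vector of called genes; must be a subset of
#'   `background`.
#' @param background Character vector: the gene universe (e.g. all genes on
#'   the array).
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param adjust Add a Benjamini-Hochberg adjusted column (default TRUE).
#' @return A tibble `set`, `set_size` (K, within background), `n_hits` (n),
#'   `overlap` (k), `p_value`, and `p_bh` when `adjust` is TRUE, sorted by
#'   `p_value`.
#' @export
hypergeom_enrich <- function(hits, background, sets, adjust = TRUE) {
  hits <- unique(hits)
  background <- unique(background)
  stray <- setdiff(hits, background)
  if (length(stray)) {
    abort(paste0("hit not in background: ", stray[1L]))
  }
  if (!length(sets) || is.null(names(sets))) {
    abort("`sets` must be a non-empty named list")
  }
  n_bg <- length(background)
  n_hit <- length(hits)
  rows <- purrr::map(names(sets), function(nm) {
    members <- intersect(sets[[nm]], background)
    k_set <- length(members)
    k_ov <- length(intersect(members, hits))
    p <- phyper(k_ov - 1L, k_set, n_bg - k_set, n_hit, lower.tail = FALSE)
    tibble(set = nm, set_size = k_set, n_hits = n_hit,
           overlap = k_ov, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  if (adjust) out$p_bh <- p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, .data$p_value, .data$set)
}
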