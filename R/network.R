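#' Pearson co-expression network from an expression matrix
#'
#' Computes the gene-by-gene Pearson correlation matrix across samples for a
#' chosen gene set. Correlations are taken on whatever scale the data are
#' in; the standard pipeline uses standardized log2 values.
#'
#' @param m An [expr_matrix()] with at least 3 samples.
#' @param genes Optional character vector of probe/gene ids to include
#'   (default: all).
#' @return An object of class `coexpr_network`: `genes`, `r` (symmetric,
#'   unit diagonal), `adjacency` (`NULL` until [pcit_filter()]).
#' @export
correlation_matrix <- function(m, genes = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 3L) abort("need at least 3 samples")
  x <- m$values
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(x))
    if (length(missing_g)) {
      abort(paste0("gene not in matrix: ", missing_g[1L]))
    }
    x <- x[genes, , drop = FALSE]
  }
  sds <- apply(x, 1L, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance gene: ", rownames(x)[sds == 0][1L]))
  }
  r <- cor(t(x))
  diag(r) <- 1
  structure(list(genes = rownames(x), r = r, adjacency = NULL),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  n <- length(x$genes)
  cat(sprintf("<coexpr_network> %d genes", n))
  if (!is.null(x$adjacency)) {
    kept <- sum(x$adjacency[upper.tri(x$adjacency)])
    cat(sprintf(", %d / %d edges kept by PCIT", kept, n * (n - 1) / 2))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a co-expression network into an edge table
#'
#' @param x A `coexpr_network`.
#' @param ... Unused.
#' @return A tibble with one row per unordered gene pair: `gene_a`,
#'   `gene_b`, `r` and, after [pcit_filter()], `kept`.
#' @method tidy coexpr_network
#' @export
tidy.coexpr_network <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  out <- tibble(gene_a = x$genes[idx[, 1L]], gene_b = x$genes[idx[, 2L]],
                r = x$r[idx])
  if (!is.null(x$adjacency)) out$kept <- x$adjacency[idx]
  out
}

#' PCIT edge filtering of a correlation network
#'
#' Partial Correlation and Information Theory (PCIT) scans every gene trio
#' (x, y, z). For a trio it computes the three first-order partial
#' correlations, e.g. `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 -
#' r_yz^2))`, and a trio-specific tolerance `eps` equal to the mean of the
#' three |partial / direct| ratios. The edge (x, y) is eliminated when some
#' third gene z explains it: `|r_xy| <= eps * |r_xz|` and
#' `|r_xy| <= eps * |r_yz|`. Surviving edges form the network adjacency.
#' Off-diagonal correlations at exactly +/-1 are clipped to `1 - 1e-12`
#' (with a warning) so the partials stay defined.
#'
#' @param net A `coexpr_network` from [correlation_matrix()] with at least
#'   3 genes.
#' @param max_genes Guard on the O(n^3) trio scan (default 2000); larger
#'   networks raise an error rather than silently running for hours.
#' @return The network with its `adjacency` slot filled (symmetric logical,
#'   `FALSE` diagonal).
#' @export
pcit_filter <- function(net, max_genes = 2000L) {
  stopifnot(inherits(net, "coexpr_network"))
  n <- length(net$genes)
  if (n < 3L) abort("PCIT needs at least 3 genes")
  if (n > max_genes) {
    abort(sprintf("%d genes exceeds the trio-scan cap of %d; raise `max_genes` deliberately if you mean it",
                  n, max_genes))
  }
  r <- net$r
  off <- abs(r) >= 1 & row(r) != col(r)
  if (any(off)) {
    warn("off-diagonal |r| = 1 clipped to 1 - 1e-12 for partial correlations")
    r[off] <- sign(r[off]) * (1 - 1e-12)
  }
  absr <- abs(r)
  keep <- matrix(TRUE, n, n)
  tiny <- .Machine$double.xmin
  ones <- rep(1, n)
  for (z in seq_len(n)) {
    rz <- r[, z]
    m1 <- outer(rz, ones)        # m1[x, y] = r_xz
    m2 <- outer(ones, rz)        # m2[x, y] = r_yz
    # the trio's three partial-to-direct ratios, each conditioning on the
    # third gene of its own pair: xy given z, xz given y, yz given x
    p_xy <- (r - m1 * m2) / sqrt((1 - m1^2) * (1 - m2^2))
    p_xz <- (m1 - r * m2) / sqrt((1 - r^2) * (1 - m2^2))
    p_yz <- (m2 - r * m1) / sqrt((1 - r^2) * (1 - m1^2))
    eps <- (abs(p_xy) / pmax(absr, tiny) +
              abs(p_xz) / pmax(abs(m1), tiny) +
              abs(p_yz) / pmax(abs(m2), tiny)) / 3
    elim <- absr <= eps * abs(m1) & absr <= eps * abs(m2)
    elim[z, ] <- FALSE           # trio genes must be distinct
    elim[, z] <- FALSE
    diag(elim) <- FALSE
    keep <- keep & !elim
  }
  diag(keep) <- FALSE
  net$adjacency <- keep
  net
}

#' Rank candidate regulators against a co-expression module
#'
#' Answers the question "which transcriptional regulator has the highest
#' absolute average correlation to all the genes in the module?". Each
#' regulator is scored by the mean of |r| to the module members; a
#' regulator that is itself a module member is excluded from its own
#' average. Ranking is descending by score with lexicographic gene-id
#' tie-break, so results are deterministic.
#'
#' @param net A `coexpr_network` (adjacency not required; scores use `r`).
#' @param module_genes Character vector of module member ids.
#' @param regulator_genes Character vector of candidate regulator ids.
#' @return A tibble `regulator`, `mean_abs_r`, `rank`.
#' @export
module_to_regulator <- function(net, module_genes, regulator_genes) {
  stopifnot(inherits(net, "coexpr_network"))
  module_genes <- intersect(module_genes, net$genes)
  regulator_genes <- intersect(regulator_genes, net$genes)
  if (!length(module_genes) || !length(regulator_genes)) {
    abort("module and regulator sets must intersect the network")
  }
  score <- vapply(regulator_genes, function(g) {
    mm <- setdiff(module_genes, g)
    if (!length(mm)) return(NA_real_)
    mean(abs(net$r[g, mm]))
  }, numeric(1L), USE.NAMES = FALSE)
  out <- tibble(regulator = regulator_genes, mean_abs_r = score)
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_abs_r), .data$regulator)
  out$rank <- seq_len(nrow(out))
  out
}

#' Regulatory Impact Factor scores across a two-condition contrast
#'
#' Scores each candidate regulator by how much its co-expression to a set of
#' DE genes changes between two conditions. With `r^A`, `r^B` the
#' regulator-to-DE-gene correlations in the two conditions, `pif_j` the
#' phenotypic impact factor of DE gene j, and `e_j` its mean expression per
#' condition:
#' \deqn{rif1_i = \frac{1}{n_{DE}} \sum_j pif_j (r_{ij}^A - r_{ij}^B)^2}
#' \deqn{rif2_i = \frac{1}{n_{DE}} \sum_j [(e_j^A r_{ij}^A)^2 -
#'   (e_j^B r_{ij}^B)^2]}
#' Both are z-standardized across regulators (if all raw scores are equal —
#' e.g. identical conditions give rif1 = 0 everywhere — the z-scores are
#' defined as 0). rif1 is invariant to swapping the conditions; rif2 changes
#' sign.
#'
#' @param m_a,m_b [expr_matrix()]s for the two conditions over the same
#'   genes, each with at least 10 samples.
#' @param regulators Candidate regulator ids.
#' @param de_genes DE gene ids (non-empty).
#' @param pif Named numeric vector of PIF values for `de_genes` (defaults
#'   to 1 for every DE gene, i.e. unweighted differential wiring).
#' @return A tibble `regulator`, `rif1`, `rif1_z`, `rif2`, `rif2_z`.
#'   Regulators with zero variance in either condition are excluded with a
#'   warning.
#' @export
rif_scores <- function(m_a, m_b, regulators, de_genes, pif = NULL) {
  stopifnot(inherits(m_a, "expr_matrix"), inherits(m_b, "expr_matrix"))
  if (!setequal(rownames(m_a$values), rownames(m_b$values))) {
    abort("both conditions must cover the same genes")
  }
  if (ncol(m_a$values) < 10L || ncol(m_b$values) < 10L) {
    abort("need >= 10 samples per condition")
  }
  if (!length(de_genes)) abort("`de_genes` must be non-empty")
  missing_g <- setdiff(c(regulators, de_genes), rownames(m_a$values))
  if (length(missing_g)) abort(paste0("gene not in matrix: ", missing_g[1L]))
  if (is.null(pif)) pif <- setNames(rep(1, length(de_genes)), de_genes)
  pif <- pif[de_genes]

  sd_a <- apply(m_a$values[regulators, , drop = FALSE], 1L, sd)
  sd_b <- apply(m_b$values[regulators, , drop = FALSE], 1L, sd)
  dead <- regulators[sd_a == 0 | sd_b == 0]
  if (length(dead)) {
    warn(paste0("excluding zero-variance regulator(s): ",
                paste(dead, collapse = ", ")))
    regulators <- setdiff(regulators, dead)
  }
  if (length(regulators) < 2L) abort("need >= 2 usable regulators")

  r_a <- cor(t(m_a$values[regulators, , drop = FALSE]),
             t(m_a$values[de_genes, , drop = FALSE]))
  r_b <- cor(t(m_b$values[regulators, , drop = FALSE]),
             t(m_b$values[de_genes, , drop = FALSE]))
  e_a <- rowMeans(m_a$values[de_genes, , drop = FALSE])
  e_b <- rowMeans(m_b$values[de_genes, , drop = FALSE])

  n_de <- length(de_genes)
  rif1 <- as.numeric((r_a - r_b)^2 %*% pif) / n_de
  rif2 <- as.numeric(sweep(r_a^2, 2L, e_a^2, "*") %*% rep(1, n_de) -
                       sweep(r_b^2, 2L, e_b^2, "*") %*% rep(1, n_de)) / n_de
  zstd <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  tibble(regulator = regulators, rif1 = rif1, rif1_z = zstd(rif1),
         rif2 = rif2, rif2_z = zstd(rif2))
}
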