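#' Read a qPCR Ct table from TSV
#'
#' Expected columns: `sample_id`, `primer`, `treatment`, `replicate`, `ct`
#' and optionally `censored` (logical; wells annotated as no-amplification).
#' Replicate indices must be unique within (sample, primer).
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_ct_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "primer", "treatment", "replicate", "ct")
  missing_c <- setdiff(need, names(tab))
  if (length(missing_c)) {
    abort(paste0("Ct table missing column: ", missing_c[1L]))
  }
  if (!"censored" %in% names(tab)) tab$censored <- FALSE
  if (any(tab$ct <= 0, na.rm = TRUE)) abort("Ct values must be positive")
  dup <- duplicated(tab[, c("sample_id", "primer", "replicate")])
  if (any(dup)) {
    abort(paste0("duplicate replicate index within sample/primer: row ",
                 which(dup)[1L]))
  }
  as_tibble(tab)
}

#' Fixed-effects ANOVA of qPCR Ct values
#'
#' Fits `Ct ~ primer + treatment + primer:treatment` by least squares on the
#' uncensored observations and returns least-square means per
#' primer-by-treatment cell (via \pkg{emmeans}), the model R-squared
#' (fraction of total Ct variation explained), and F-test p-values for the
#' two main effects and their interaction. In a balanced design the LSM of a
#' cell equals its arithmetic mean. Rows flagged `censored`, or with Ct at
#' or above `ct_ceiling`, are excluded and counted in the report; a cell
#' emptied by censoring appears in the grid with `lsm = NA`.
#'
#' Degenerate input with zero residual and zero model variation (all Cts
#' equal) returns `r_squared = NA`: 0/0 has no meaningful value and all
#' contrasts are 0 anyway.
#'
#' @param ct A Ct tibble as from [read_ct_table()] or [simulate_qpcr()].
#' @param ct_ceiling Cycles above which a well is treated as
#'   no-amplification (default 34).
#' @return An object of class `ct_anova`: `lsm` (tibble `primer`,
#'   `treatment`, `lsm`, `se`, `n`), `r_squared`, `anova` (tibble of
#'   F-tests), `n_censored`, `fit` (the underlying `lm`).
#' @export
fit_ct_anova <- function(ct, ct_ceiling = 34) {
  ct <- as_tibble(ct)
  if (!"censored" %in% names(ct)) ct$censored <- FALSE
  drop <- ct$censored | ct$ct >= ct_ceiling
  n_censored <- sum(drop)
  dat <- ct[!drop, ]
  if (length(unique(dat$primer)) < 2L || length(unique(dat$treatment)) < 2L) {
    abort("need >= 2 primers and >= 2 treatments after censoring")
  }
  dat$primer <- factor(dat$primer)
  dat$treatment <- factor(dat$treatment)
  fit <- lm(ct ~ primer * treatment, data = dat)
  sumfit <- summary(fit)
  tss <- sum((dat$ct - mean(dat$ct))^2)
  r2 <- if (tss == 0) NA_real_ else sumfit$r.squared

  emm <- suppressMessages(
    emmeans::emmeans(fit, ~ primer * treatment)
  )
  grid <- as.data.frame(emm)
  counts <- dplyr::count(dat, .data$primer, .data$treatment)
  lsm <- tibble(
    primer = as.character(grid$primer),
    treatment = as.character(grid$treatment),
    lsm = grid$emmean,
    se = grid$SE
  )
  lsm <- dplyr::left_join(
    lsm,
    dplyr::mutate(counts, primer = as.character(.data$primer),
                  treatment = as.character(.data$treatment)),
    by = c("primer", "treatment"))
  lsm$n <- dplyr::coalesce(lsm$n, 0L)
  lsm$lsm[lsm$n == 0L] <- NA_real_

  av <- anova(fit)
  atab <- tibble(
    term = rownames(av),
    df = av$Df, sum_sq = av$`Sum Sq`, f = av$`F value`,
    p_value = av$`Pr(>F)`
  )
  structure(
    list(lsm = lsm, r_squared = r2, anova = atab,
         n_censored = n_censored, fit = fit),
    class = "ct_anova"
  )
}

#' @export
print.ct_anova <- function(x, ...) {
  cat(sprintf("<ct_anova> R^2 = %s, %d censored well(s) excluded\n",
              ifelse(is.na(x$r_squared), "NA",
                     sprintf("%.4f", x$r_squared)), x$n_censored))
  print(x$lsm, n = 10)
  invisible(x)
}

#' @rdname fit_ct_anova
#' @param x A `ct_anova`.
#' @param ... Unused.
#' @method tidy ct_anova
#' @export
tidy.ct_anova <- function(x, ...) x$lsm

#' @rdname fit_ct_anova
#' @method glance ct_anova
#' @export
glance.ct_anova <- function(x, ...) {
  p <- setNames(x$anova$p_value, x$anova$term)
  tibble(r_squared = x$r_squared,
         p_primer = unname(p["primer"]),
         p_treatment = unname(p["treatment"]),
         p_interaction = unname(p["primer:treatment"]),
         n_censored = x$n_censored)
}

#' Reference-gene-normalized fold change from Ct least-square means
#'
#' The delta-delta-Ct contrast under perfect doubling:
#' \deqn{fold = 2^{(Ct_{target,control} - Ct_{ref,control}) -
#'   (Ct_{target,treatment} - Ct_{ref,treatment})}}
#' A lower Ct means more template, hence the sign convention: a target
#' amplifying 5 cycles earlier in the treatment than expected from the
#' reference gene gives a fold of 2^5 = 32.
#'
#' @param grid A `ct_anova` object or a tibble with columns `primer`,
#'   `treatment` and `lsm` (published LSM tables can be fed directly).
#' @param target,ref Target and reference primer names.
#' @param treatment,control Treatment levels to contrast.
#' @return The fold change (positive scalar).
#' @export
ddct_fold <- function(grid, target, ref, treatment, control) {
  if (inherits(grid, "ct_anova")) grid <- grid$lsm
  grid <- as_tibble(grid)
  cell <- function(p, t) {
    hit <- grid$lsm[grid$primer == p & grid$treatment == t]
    if (length(hit) != 1L || is.na(hit)) {
      abort(sprintf("missing LSM cell: primer %s, treatment %s", p, t))
    }
    hit
  }
  ddct <- (cell(target, control) - cell(ref, control)) -
    (cell(target, treatment) - cell(ref, treatment))
  2^ddct
}

#' Plot Ct least-square means per primer and treatment
#'
#' @param object A `ct_anova`.
#' @param ... Unused.
#' @return A ggplot object (Ct axis reversed: earlier amplification, i.e.
#'   more template, plots higher).
#' @method autoplot ct_anova
#' @export
autoplot.ct_anova <- function(object, ...) {
  ggplot2::ggplot(object$lsm,
                  ggplot2::aes(x = .data$treatment, y = .data$lsm,
                               colour = .data$primer,
                               group = .data$primer)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(y = "Ct (least-square mean)", x = NULL, colour = "primer") +
    ggplot2::theme_minimal()
}
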