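# Small builders shared across test files.

make_expr <- function(values, groups = NULL, detp = NULL, scale = "raw") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("p%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  if (is.null(groups)) groups <- rep("g", ncol(values))
  meta <- tibble::tibble(sample_id = colnames(values), group = groups)
  expr_matrix(values, meta, detection_p = detp, scale = scale)
}

extdata <- function(name) {
  system.file("extdata", name, package = "coexreg", mustWork = TRUE)
}

read_fixture <- function(name) {
  readr::read_tsv(extdata(name), show_col_types = FALSE, progress = FALSE)
}

mito_panel_table <- function() read_fixture("mito_panel_means.tsv")
probe_means_table <- function() read_fixture("rnf14_probe_means.tsv")
ct_lsm_table <- function() read_fixture("qpcr_ct_lsm.tsv")
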