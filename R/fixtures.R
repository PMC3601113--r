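# ---- bundled reference data -------------------------------------------------

#' Published editing-site base counts of the tea-tree chloroplast
#'
#' Per-site plus-strand base counts (A/C/G/U) at the 31 C-to-U RNA editing
#' sites detected in the *Camellia sinensis* var. *assamica* chloroplast
#' transcriptome, with each site's gene or region label, strand and, for
#' coding sites, the reported codon and amino-acid change.  Re-encoding
#' these rows as pileup columns and running [call_editing_sites()] at
#' default thresholds reproduces the published site list.
#'
#' @return Data frame with columns `gene`, `region`, `strand`, `pos`,
#'   `ref`, `A`, `C`, `G`, `U`, `codon_change`, `aa_change`.
#' @export
camellia_editing_sites <- function() {
  path <- system.file("extdata", "csa_editing_sites.tsv",
                      package = "plastoscope", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Pileup columns from a per-site count table
#'
#' Converts a table with `pos`, `ref`, `A`, `C`, `G`, `U` columns (such as
#' [camellia_editing_sites()]) into the pileup-column data frame consumed by
#' [call_editing_sites()].
#'
#' @param sites Data frame of per-site counts.
#' @return Pileup data frame with recomputed `depth`.
#' @export
sites_as_pileup <- function(sites) {
  data.frame(pos = sites$pos, ref = sites$ref, A = sites$A, C = sites$C,
             G = sites$G, U = sites$U,
             depth = sites$A + sites$C + sites$G + sites$U,
             mean_qual = NA_real_, stringsAsFactors = FALSE)
}
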