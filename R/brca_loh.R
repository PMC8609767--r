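#' Classify a SNP site for locus-specific loss of heterozygosity
#'
#' A site is informative when the control (germline) variant allele
#' fraction marks it heterozygous: control VAF in [0.35, 0.65]
#' (inclusive). An informative site is an LOH site when the tumor VAF has
#' drifted to homozygosity (strictly above 0.65 or strictly below 0.35),
#' and a non-LOH site when the tumor VAF also lies in [0.35, 0.65]. Sites
#' that are not heterozygous in the control are uninformative.
#'
#' @param control_vaf,tumor_vaf variant allele fractions in [0, 1]
#'   (vectorized).
#' @return character vector: `"LOH"`, `"non-LOH"` or `"uninformative"`.
#' @export
classify_snp <- function(control_vaf, tumor_vaf) {
  stopifnot(all(control_vaf >= 0 & control_vaf <= 1),
            all(tumor_vaf >= 0 & tumor_vaf <= 1))
  het_control <- control_vaf >= 0.35 & control_vaf <= 0.65
  hom_tumor <- tumor_vaf > 0.65 | tumor_vaf < 0.35
  ifelse(!het_control, "uninformative",
         ifelse(hom_tumor, "LOH", "non-LOH"))
}

#' Majority-vote gene-level LOH call
#'
#' The gene is called LOH when the number of LOH sites strictly exceeds the
#' number of non-LOH sites; a tie or minority yields no-LOH; with no
#' informative site the verdict is insufficient.
#'
#' @param sites data.frame with columns `control_vaf` and `tumor_vaf` (and
#'   optionally `gene`), or a character vector of pre-computed
#'   classifications from [classify_snp()].
#' @param gene optional gene name recorded in the call.
#' @return list of class `gene_loh_call` with fields `gene`, `n_loh`,
#'   `n_non_loh`, `n_uninformative`, `verdict` (`"LOH"`, `"no-LOH"` or
#'   `"insufficient"`).
#' @export
call_gene_loh <- function(sites, gene = NA_character_) {
  cls <- if (is.character(sites)) sites
  else classify_snp(sites$control_vaf, sites$tumor_vaf)
  if (is.data.frame(sites) && is.na(gene) && !is.null(sites$gene) &&
      length(unique(sites$gene)) == 1) {
    gene <- sites$gene[1]
  }
  n_loh <- sum(cls == "LOH")
  n_non <- sum(cls == "non-LOH")
  verdict <- if (n_loh + n_non == 0) "insufficient"
  else if (n_loh > n_non) "LOH" else "no-LOH"
  structure(list(gene = gene, n_loh = n_loh, n_non_loh = n_non,
                 n_uninformative = sum(cls == "uninformative"),
                 verdict = verdict),
            class = "gene_loh_call")
}

#' @export
print.gene_loh_call <- function(x, ...) {
  cat(sprintf("<gene_loh_call> %s: %s (%d LOH vs %d non-LOH, %d uninformative)\n",
              if (is.na(x$gene)) "?" else x$gene, x$verdict,
              x$n_loh, x$n_non_loh, x$n_uninformative))
  invisible(x)
}

#' Read a per-SNP variant-fraction table
#'
#' @param path tab-separated file with header
#'   `gene  pos  control_vaf  tumor_vaf`.
#' @return data.frame with those columns.
#' @export
read_snp_sites <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("gene", "pos", "control_vaf", "tumor_vaf")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("SNP table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}
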