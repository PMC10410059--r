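#' Read a protein domain table
#'
#' A domain table maps codon intervals of a protein to the labels used for
#' variant grouping: `TM` (transmembrane helix), `CY` (cytoplasmic segment)
#' or `other` (lumenal/extracellular; variants there are left unclassified).
#' Intervals are inclusive on both ends, non-overlapping and sorted.
#'
#' @param path delimited text file with columns `start_codon`, `end_codon`,
#'   `label` (and optionally `feature`); lines starting with `#` are treated
#'   as comments, and a leading `# provenance:` comment is kept as the
#'   table's provenance string.
#' @return data frame of class `domain_table` with attribute `"provenance"`.
#' @export
read_domain_table <- function(path) {
  first <- readLines(path, n = 1L)
  prov <- if (startsWith(first, "# provenance:"))
    trimws(sub("^# provenance:", "", first)) else NA_character_
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  domain_table(tab, provenance = prov)
}

#' Construct and validate a domain table
#'
#' @param x data frame with integer columns `start_codon`, `end_codon` and a
#'   character column `label` with values in `TM`, `CY`, `other`.
#' @param provenance free-text origin of the annotation.
#' @return validated `domain_table`.
#' @export
domain_table <- function(x, provenance = NA_character_) {
  need <- c("start_codon", "end_codon", "label")
  if (!all(need %in% names(x)))
    stop("domain table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  x$start_codon <- as.integer(x$start_codon)
  x$end_codon <- as.integer(x$end_codon)
  if (any(is.na(x$start_codon)) || any(is.na(x$end_codon)))
    stop("non-integer codon bounds in domain table", call. = FALSE)
  if (any(x$start_codon > x$end_codon))
    stop("domain table has start_codon > end_codon", call. = FALSE)
  if (!all(x$label %in% c("TM", "CY", "other")))
    stop("domain labels must be 'TM', 'CY' or 'other'", call. = FALSE)
  x <- x[order(x$start_codon), , drop = FALSE]
  if (nrow(x) > 1L && any(x$start_codon[-1L] <= x$end_codon[-nrow(x)]))
    stop("domain table intervals overlap", call. = FALSE)
  rownames(x) <- NULL
  structure(x, provenance = provenance, class = c("domain_table", "data.frame"))
}

#' Write a domain table as delimited text
#'
#' @param table a `domain_table`.
#' @param path output file.
#' @export
write_domain_table <- function(table, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  prov <- attr(table, "provenance")
  if (!is.na(prov)) writeLines(paste0("# provenance: ", prov), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged PSEN1 topology table
#'
#' The default codon-interval table for PSEN1 (UniProt P49768 membrane
#' topology: nine transmembrane helices; cytoplasmic N-terminus, short
#' cytoplasmic inter-helix segments and the large TM6-TM7 cytoplasmic loop).
#' Ships as a plain-text data file so an updated annotation can be swapped
#' in without code changes.
#'
#' @return a `domain_table`.
#' @export
psen1_domains <- function() {
  read_domain_table(system.file("extdata", "psen1_domains.csv",
                                package = "psen1traj", mustWork = TRUE))
}

#' Extract the affected codon from a protein-change string
#'
#' Parses strings such as `"A79V"` or `"p.M146L"` by the letters-digits-
#' letters pattern; unparseable entries give `NA` with a warning.
#'
#' @param variant character vector of protein-change notations (numeric
#'   input is passed through as codons).
#' @return integer vector of codons.
#' @export
parse_variant_codon <- function(variant) {
  if (is.numeric(variant)) return(as.integer(variant))
  codon <- rep(NA_integer_, length(variant))
  hit <- !is.na(variant) & grepl("^(p\\.)?[A-Za-z]+[0-9]+", variant)
  codon[hit] <- as.integer(sub("^(p\\.)?[A-Za-z]+([0-9]+).*$", "\\2", variant[hit]))
  if (any(!hit & !is.na(variant)))
    warning("unparseable variant string(s): ",
            paste(utils::head(variant[!hit & !is.na(variant)], 5L), collapse = ", "),
            "; left unclassified", call. = FALSE)
  codon
}

#' Classify variant codons into protein-domain groups
#'
#' Maps each affected codon to the label of the domain interval containing
#' it (`TM` or `CY`; codons in `other` intervals or outside every interval
#' are `unclassified`), and to the alternative pre-/post-codon-200 grouping.
#' "Before codon 200" is taken as codon < 200, so codon 200 itself is
#' `post200`; the boundary convention is documented rather than implied.
#'
#' @param codon integer vector of affected codons (or protein-change strings,
#'   parsed via [parse_variant_codon()]).
#' @param table a `domain_table`; defaults to [psen1_domains()].
#' @return data frame with columns `codon`, `group` (factor with levels
#'   `NC`, `CY`, `TM`, `unclassified`) and `codon_group` (factor `pre200`,
#'   `post200`; `NA` for missing codons).
#' @examples
#' classify_variant(c(79, 146, 280, 436))
#' @export
classify_variant <- function(codon, table = psen1_domains()) {
  codon <- parse_variant_codon(codon)
  if (any(!is.na(codon) & codon <= 0L))
    stop("codon positions must be >= 1", call. = FALSE)
  table <- domain_table(as.data.frame(table), attr(table, "provenance"))
  grp <- rep("unclassified", length(codon))
  for (i in seq_len(nrow(table))) {
    inside <- !is.na(codon) & codon >= table$start_codon[i] & codon <= table$end_codon[i]
    grp[inside] <- if (table$label[i] == "other") "unclassified" else table$label[i]
  }
  grp[is.na(codon)] <- "unclassified"
  cg <- ifelse(is.na(codon), NA_character_,
               ifelse(codon < 200L, "pre200", "post200"))
  data.frame(codon = codon,
             group = factor(grp, levels = c("NC", "CY", "TM", "unclassified")),
             codon_group = factor(cg, levels = c("pre200", "post200")))
}
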