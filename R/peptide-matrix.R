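#' Peptide-level abundance matrix with design
#'
#' The central container of the package: a peptides x samples matrix of
#' log2 abundances together with the peptide-to-protein mapping and the
#' sample-to-group design.  Missing measurements are stored as `NA` and are
#' never imputed.
#'
#' @param abundance numeric matrix (peptides x samples) of log2 intensities;
#'   rownames are peptide identifiers, colnames sample identifiers.
#' @param protein character vector, one protein accession per peptide row.
#' @param group factor or character vector, one group label per sample column.
#' @param allow_duplicates allow duplicate peptide identifiers (only sensible
#'   as input to [sum_duplicate_peptides]).
#' @return An object of class `peptide_matrix`: a list with elements
#'   `abundance`, `protein` (named by peptide), and `group` (factor named by
#'   sample).
#' @examples
#' m <- peptide_matrix(
#'   matrix(rnorm(12), 3, 4,
#'          dimnames = list(paste0("pep", 1:3), paste0("s", 1:4))),
#'   protein = c("P1", "P1", "P2"),
#'   group = c("A", "A", "B", "B"))
#' m
#' @export
peptide_matrix <- function(abundance, protein, group, allow_duplicates = FALSE) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (is.null(rownames(abundance)))
    rownames(abundance) <- paste0("peptide_", seq_len(nrow(abundance)))
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("sample_", seq_len(ncol(abundance)))
  if (!allow_duplicates && anyDuplicated(rownames(abundance)))
    stopf("duplicate peptide_id in abundance matrix")
  if (anyDuplicated(colnames(abundance)))
    stopf("duplicate sample_id in abundance matrix")
  if (length(protein) != nrow(abundance))
    stopf("length(protein) [%d] != number of peptides [%d]",
          length(protein), nrow(abundance))
  if (length(group) != ncol(abundance))
    stopf("length(group) [%d] != number of samples [%d]",
          length(group), ncol(abundance))
  if (any(is.infinite(abundance)))
    stopf("abundance values must be finite where present")
  protein <- as.character(protein)
  names(protein) <- rownames(abundance)
  group <- factor(group)
  names(group) <- colnames(abundance)
  structure(list(abundance = abundance, protein = protein, group = group),
            class = "peptide_matrix")
}

#' @export
print.peptide_matrix <- function(x, ...) {
  cat(sprintf("%s: %d peptides, %d proteins, %d samples\n",
              class(x)[1], nrow(x$abundance),
              length(unique(x$protein)), ncol(x$abundance)))
  tab <- table(x$group)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("missing values: %.1f%%\n", 100 * mean(is.na(x$abundance))))
  invisible(x)
}

#' @export
dim.peptide_matrix <- function(x) dim(x$abundance)

# protein_matrix shares the peptide_matrix layout with one row per protein
new_protein_matrix <- function(abundance, group) {
  m <- peptide_matrix(abundance, protein = rownames(abundance), group = group)
  class(m) <- c("protein_matrix", "peptide_matrix")
  m
}

#' Read a peptide quantification table and its design
#'
#' The table must have a header with columns `protein_id`, `peptide_id`
#' followed by one column per sample; the design file maps `sample_id` to
#' `group`.  Empty cells and `NA` become missing values.
#'
#' @param path peptide table, TSV (default) or CSV.
#' @param design_path two-column table `sample_id`, `group`.
#' @param log2 set `TRUE` if the table holds raw intensities to be
#'   log2-transformed on read (non-positive intensities become missing).
#' @param sep field separator; `"\t"` by default, use `","` for CSV.
#' @return A [peptide_matrix].
#' @export
read_peptide_table <- function(path, design_path, log2 = FALSE, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  need <- c("protein_id", "peptide_id")
  if (!all(need %in% colnames(tab)))
    stopf("peptide table must have columns 'protein_id' and 'peptide_id'")
  if (anyDuplicated(tab$peptide_id))
    stopf("duplicate peptide_id in %s: %s", path,
          paste(unique(tab$peptide_id[duplicated(tab$peptide_id)]),
                collapse = ", "))
  design <- utils::read.table(design_path, header = TRUE, sep = sep,
                              quote = "", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(design)))
    stopf("design must have columns 'sample_id' and 'group'")
  sample_cols <- setdiff(colnames(tab), need)
  unmapped <- setdiff(sample_cols, design$sample_id)
  if (length(unmapped))
    stopf("samples absent from design: %s", paste(unmapped, collapse = ", "))
  ab <- as.matrix(tab[, sample_cols, drop = FALSE])
  storage.mode(ab) <- "double"
  rownames(ab) <- tab$peptide_id
  if (log2) {
    ab[!is.na(ab) & ab <= 0] <- NA
    ab <- log2(ab)
  }
  grp <- design$group[match(sample_cols, design$sample_id)]
  peptide_matrix(ab, protein = tab$protein_id, group = grp)
}

#' Write a peptide matrix (and its design) back to TSV
#'
#' @param m a [peptide_matrix].
#' @param path output peptide table path.
#' @param design_path optional path for the two-column design table.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(m, path, design_path = NULL) {
  tab <- data.frame(protein_id = unname(m$protein),
                    peptide_id = rownames(m$abundance),
                    m$abundance, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design_path)) {
    utils::write.table(
      data.frame(sample_id = colnames(m$abundance),
                 group = as.character(m$group)),
      design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Restrict a peptide matrix to selected groups
#'
#' Used e.g. to drop an aberrant sample group before a two-group comparison.
#'
#' @param m a [peptide_matrix].
#' @param groups group labels to keep.
#' @return A [peptide_matrix] with only the selected samples; unused factor
#'   levels are dropped.
#' @export
select_groups <- function(m, groups) {
  miss <- setdiff(groups, levels(m$group))
  if (length(miss)) stopf("unknown group(s): %s", paste(miss, collapse = ", "))
  keep <- m$group %in% groups
  out <- peptide_matrix(m$abundance[, keep, drop = FALSE], m$protein,
                        droplevels(m$group[keep]))
  class(out) <- class(m)
  out
}

# error unless the matrix carries exactly two groups with >= 2 samples each
check_two_groups <- function(m) {
  lev <- levels(droplevels(m$group))
  if (length(lev) != 2L)
    stopf("a two-group design is required (found %d groups: %s); use select_groups()",
          length(lev), paste(lev, collapse = ", "))
  n <- table(droplevels(m$group))
  if (any(n < 2L))
    stopf("each group needs >= 2 samples (got %s)",
          paste(sprintf("%s=%d", names(n), n), collapse = ", "))
  invisible(lev)
}

#' Median-normalize sample columns
#'
#' Shifts each sample column additively (on the log2 scale) so that all
#' column medians over observed values coincide with the global median of the
#' pre-normalization column medians.  Centering to the global median rather
#' than to zero preserves the intensity magnitude.  Idempotent.
#'
#' @param m a [peptide_matrix].
#' @return The normalized [peptide_matrix].
#' @export
median_normalize <- function(m) {
  med <- apply(m$abundance, 2, stats::median, na.rm = TRUE)
  if (any(is.na(med)))
    stopf("column(s) with all values missing: %s",
          paste(colnames(m$abundance)[is.na(med)], collapse = ", "))
  target <- stats::median(med)
  out <- m
  out$abundance <- sweep(m$abundance, 2, med - target, "-")
  out
}

# intensity-scale (2^x) sum of log2 rows by a grouping key; NA absent from the
# sum, result NA only where all contributing values are NA
sum_rows_intensity <- function(ab, key) {
  key <- factor(key, levels = unique(key))
  lin <- 2^ab
  lin[is.na(lin)] <- 0
  summed <- rowsum(lin, key, reorder = FALSE)
  nobs <- rowsum((!is.na(ab)) + 0, key, reorder = FALSE)
  summed[nobs == 0] <- NA_real_
  log2(summed)
}

#' Roll peptides up to protein level by intensity summation
#'
#' Per protein and sample, observed peptide log2 values are unlogged, summed
#' on the intensity scale, and re-logged.  A protein value is missing only if
#' all of its peptides are missing in that sample.
#'
#' @param m a [peptide_matrix] of log2 abundances.
#' @return A `protein_matrix` (proteins x samples).
#' @export
rollup_sum <- function(m) {
  ab <- sum_rows_intensity(m$abundance, m$protein)
  rownames(ab) <- unique(unname(m$protein))
  out <- new_protein_matrix(ab, m$group)
  # carry annotated peptide counts for downstream reporting/filters
  attr(out, "n_peptides") <-
    as.integer(table(factor(m$protein, levels = rownames(ab))))
  out
}

#' Merge duplicate peptide rows by intensity summation
#'
#' Rows sharing the same (protein, peptide) key are summed on the intensity
#' scale, as when identical peptide sequences are quantified several times
#' across charge states or modifications.  Values missing in one duplicate
#' but observed in another contribute their observed part (union of observed
#' values).
#'
#' @param m a [peptide_matrix], possibly built with `allow_duplicates = TRUE`.
#' @param peptide_id,protein_id optional explicit keys overriding the ones
#'   stored in `m`.
#' @return A [peptide_matrix] with one row per (protein, peptide) key.
#' @export
sum_duplicate_peptides <- function(m, peptide_id = rownames(m$abundance),
                                   protein_id = m$protein) {
  key <- paste(protein_id, peptide_id, sep = "\r")
  if (!anyDuplicated(key)) return(m)
  ab <- sum_rows_intensity(m$abundance, key)
  first <- !duplicated(key)
  rownames(ab) <- peptide_id[first]
  peptide_matrix(ab, protein = protein_id[first], group = m$group)
}
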