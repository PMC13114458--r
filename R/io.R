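# Readers/writers for the external interchange formats: GMT gene sets,
# expression TSV (genes x samples), and the CSV tables (sample metadata,
# radiomic features, covariates).

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT dialect: one set per line,
#' `name <TAB> description <TAB> gene1 <TAB> gene2 ...`. The description
#' field is used to carry the set category (`hallmark`, `neftel`,
#' `ivygap_module`); unrecognised descriptions become category `"custom"`.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble with columns `set_name`, `category`, and a list-column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) {
    abort(sprintf("GMT line(s) %s have fewer than 3 fields.",
                  paste(which(bad), collapse = ", ")))
  }
  known <- c("hallmark", "neftel", "ivygap_module")
  tibble(
    set_name = vapply(fields, `[[`, character(1), 1),
    category = vapply(fields, function(f) {
      if (f[[2]] %in% known) f[[2]] else "custom"
    }, character(1)),
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  )
}

#' Write a gene-set collection to GMT
#'
#' @param gene_sets Tibble with `set_name`, `category`, list-column `genes`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  validate_gene_sets(gene_sets)
  lines <- purrr::pmap_chr(gene_sets, function(set_name, category, genes, ...) {
    paste(c(set_name, category, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read/write the expression matrix as TSV
#'
#' Genes are rows; the first column is `gene_id` and the remaining column
#' names are sample ids. Values are FPKM (non-negative).
#'
#' @param path File path.
#' @return A tibble (wide, `gene_id` + one column per sample).
#' @export
read_expression_tsv <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_expression(expr)
  expr
}

#' @rdname read_expression_tsv
#' @param expression Wide expression tibble.
#' @export
write_expression_tsv <- function(expression, path) {
  validate_expression(expression)
  readr::write_tsv(expression, path)
  invisible(path)
}

validate_expression <- function(expression) {
  if (!"gene_id" %in% names(expression)) {
    abort("Expression table must have a `gene_id` first column.")
  }
  if (anyDuplicated(expression$gene_id)) abort("Duplicate gene ids.")
  if (anyDuplicated(names(expression))) abort("Duplicate sample ids.")
  vals <- as.matrix(expression[setdiff(names(expression), "gene_id")])
  if (any(!is.finite(vals))) abort("Expression values must be finite.")
  if (any(vals < 0)) abort("FPKM expression values must be >= 0.")
  invisible(expression)
}

validate_gene_sets <- function(gene_sets, min_size = 2) {
  stopifnot(all(c("set_name", "category", "genes") %in% names(gene_sets)))
  if (anyDuplicated(gene_sets$set_name)) abort("Duplicate gene-set names.")
  sizes <- lengths(gene_sets$genes)
  if (any(sizes < min_size)) {
    abort(sprintf("Every gene set must contain >= %d gene(s).", min_size))
  }
  dup <- vapply(gene_sets$genes, anyDuplicated, integer(1)) > 0
  if (any(dup)) abort("Gene sets must not contain duplicate genes.")
  invisible(gene_sets)
}

# Feature columns of a radiomic table = everything except the id columns.
feature_columns <- function(radiomics) {
  setdiff(names(radiomics), c("patient_id", "subcompartment"))
}
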