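#' Construct an OTU count table
#'
#' The central container of the package: a non-negative integer count matrix
#' with samples as rows and OTUs as columns, plus one Greengenes-style
#' taxonomy string per OTU (\code{"k__Bacteria; p__Firmicutes; ..."}).
#'
#' @param counts integer matrix, samples x OTUs, with unique row and column
#'   names (sample ids / OTU ids).
#' @param taxonomy character vector of taxonomy strings, one per OTU, named by
#'   OTU id or in column order. Defaults to empty strings.
#' @return An object of class \code{otu_table}.
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  # zero-extent dimensions are legal (e.g. every OTU filtered away) and R
  # drops their dimnames to NULL, so only non-empty dimensions need names
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have sample ids as rownames and OTU ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ",
         rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU id: ", colnames(counts)[duplicated(colnames(counts))][1])
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "double"  # doubles hold integer counts exactly
  if (is.null(taxonomy)) {
    taxonomy <- setNames(rep("", ncol(counts)), colnames(counts))
  } else {
    if (is.null(names(taxonomy))) {
      if (length(taxonomy) != ncol(counts))
        stop("taxonomy length must match number of OTUs")
      names(taxonomy) <- colnames(counts)
    }
    taxonomy <- taxonomy[colnames(counts)]
    taxonomy[is.na(taxonomy)] <- ""
    names(taxonomy) <- colnames(counts)
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, %s reads total\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

sample_ids <- function(table) rownames(table$counts)
otu_ids <- function(table) colnames(table$counts)

subset_samples <- function(table, ids) {
  otu_table(table$counts[ids, , drop = FALSE], table$taxonomy)
}

subset_otus <- function(table, ids) {
  otu_table(table$counts[, ids, drop = FALSE], table$taxonomy[ids])
}

#' Read an OTU table from TSV or BIOM-style JSON
#'
#' The TSV layout is: one row per OTU; first column \code{otu_id}; one column
#' per sample; last column \code{taxonomy}. BIOM v1 ("JSON") files with dense
#' or sparse matrices are also accepted (observations are OTUs).
#'
#' @param path file path; files ending in \code{.json} or \code{.biom} are
#'   parsed as BIOM JSON, anything else as TSV.
#' @return An \code{\link{otu_table}}.
#' @export
read_otu_table <- function(path) {
  if (grepl("\\.(json|biom)$", path, ignore.case = TRUE))
    return(read_biom_json(path))
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"taxonomy" %in% names(df)) stop("TSV OTU table must have a 'taxonomy' column")
  otu_id_col <- names(df)[1]
  otus <- as.character(df[[otu_id_col]])
  if (anyDuplicated(otus))
    stop("duplicate OTU id in ", path, ": ", otus[duplicated(otus)][1])
  smp_cols <- setdiff(names(df), c(otu_id_col, "taxonomy"))
  if (anyDuplicated(smp_cols))
    stop("duplicate sample id in ", path, ": ", smp_cols[duplicated(smp_cols)][1])
  mat <- as.matrix(df[, smp_cols, drop = FALSE])
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("malformed count at data line %d (OTU %s, sample %s)",
                 bad[1, 1], otus[bad[1, 1]], smp_cols[bad[1, 2]]))
  counts <- t(mat)
  colnames(counts) <- otus
  otu_table(counts, setNames(as.character(df$taxonomy), otus))
}

# Minimal BIOM v1 JSON reader: rows = observations (OTUs), columns = samples,
# matrix_type "dense" or "sparse" ([row, col, value] triplets).
read_biom_json <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = FALSE)
  otus <- vapply(b$rows, function(r) r$id, character(1))
  smps <- vapply(b$columns, function(s) s$id, character(1))
  tax <- vapply(b$rows, function(r) {
    md <- r$metadata
    if (is.null(md) || is.null(md$taxonomy)) return("")
    paste(unlist(md$taxonomy), collapse = "; ")
  }, character(1))
  mat <- matrix(0, nrow = length(otus), ncol = length(smps))
  if (identical(b$matrix_type, "dense")) {
    for (i in seq_along(b$data))
      mat[i, ] <- as.numeric(unlist(b$data[[i]]))
  } else if (identical(b$matrix_type, "sparse")) {
    for (trip in b$data) {
      trip <- as.numeric(unlist(trip))
      mat[trip[1] + 1, trip[2] + 1] <- trip[3]  # BIOM indices are 0-based
    }
  } else {
    stop("unsupported BIOM matrix_type: ", b$matrix_type %||% "<missing>")
  }
  counts <- t(mat)
  rownames(counts) <- smps
  colnames(counts) <- otus
  otu_table(counts, setNames(tax, otus))
}

#' Write an OTU table as TSV
#'
#' Inverse of \code{\link{read_otu_table}}'s TSV branch; round-trips exactly.
#'
#' @param table an \code{otu_table}.
#' @param path output path.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(otu_id = otu_ids(table), t(table$counts),
                   taxonomy = unname(table$taxonomy),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("otu_id", sample_ids(table), "taxonomy")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample clinical metadata
#'
#' Expects a TSV with header containing at least \code{subject_id},
#' \code{sample_id}, \code{hbi}, \code{crp}, \code{fc}; recognised optional
#' columns (\code{days_since_antibiotics}, medication flags, \code{location},
#' \code{colectomy}, \code{age}) pass through untouched.
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("subject_id", "sample_id", "hbi", "crp", "fc")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id in ", path, ": ",
         df$sample_id[duplicated(df$sample_id)][1])
  df
}

#' @rdname read_metadata
#' @param meta metadata data.frame to write.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
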