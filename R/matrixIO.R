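## Plain-TSV readers/writers for expression matrices, sample sheets,
## probe-gene maps and count matrices.  "#"-prefixed lines are comments.
## Parsing is a thin validation layer (line-numbered errors, duplicate-id
## and numeric checks) over base field splitting.

.read_tsv_lines <- function(path) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    keep <- !startsWith(lines, "#") & nzchar(lines)
    list(lines = lines[keep], lineno = which(keep))
}

.split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

.check_rect <- function(fields, lineno, path) {
    n <- lengths(fields)
    if (length(unique(n)) > 1L) {
        bad <- lineno[which(n != n[1L])[1L]]
        stop(sprintf("ragged row in '%s' at line %d (expected %d fields)",
                     path, bad, n[1L]))
    }
}

#' Read a probe x sample expression matrix from TSV
#'
#' First column holds probe ids, header row holds sample ids; empty cells
#' or \code{NA} become missing values.  Comment lines starting with
#' \code{#} are ignored.
#'
#' @param path path to a UTF-8 tab-separated file.
#' @return Numeric matrix (probes x samples) with dimnames.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("probe_id\ts1\ts2", "p1\t1\t2", "p2\t3\t4"), f)
#' readExpressionMatrix(f)
#' @export
readExpressionMatrix <- function(path) {
    raw <- .read_tsv_lines(path)
    if (length(raw$lines) < 2L)
        stop(sprintf("'%s' has no data rows", path))
    fields <- .split_fields(raw$lines)
    .check_rect(fields, raw$lineno, path)
    header <- fields[[1L]]
    sample_ids <- header[-1L]
    if (anyDuplicated(sample_ids))
        stop(sprintf("duplicated sample id '%s' in '%s'",
                     sample_ids[duplicated(sample_ids)][1L], path))
    body <- fields[-1L]
    probe_ids <- vapply(body, `[[`, character(1), 1L)
    if (anyDuplicated(probe_ids)) {
        dup <- probe_ids[duplicated(probe_ids)][1L]
        stop(sprintf("duplicated probe id '%s' in '%s' (line %d)",
                     dup, path, raw$lineno[-1L][which(probe_ids == dup)[2L]]))
    }
    cells <- t(vapply(body, function(f) f[-1L],
                      character(length(sample_ids))))
    if (length(sample_ids) == 1L) cells <- matrix(cells, ncol = 1L)
    vals <- suppressWarnings(
        matrix(as.numeric(ifelse(cells == "" | cells == "NA",
                                 NA_character_, cells)),
               nrow = length(probe_ids)))
    bad <- which(is.na(vals) & !(cells == "" | cells == "NA"),
                 arr.ind = TRUE)
    if (nrow(bad)) {
        stop(sprintf(
            "non-numeric value '%s' in '%s' at line %d, column '%s'",
            cells[bad[1L, 1L], bad[1L, 2L]], path,
            raw$lineno[-1L][bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
    }
    dimnames(vals) <- list(probe_ids, sample_ids)
    vals
}

#' Write an expression matrix as TSV
#'
#' Values are formatted with 12 significant digits so that
#' write-then-read round-trips the matrix to well below 1e-9 relative
#' error, and identically formatted runs are byte-identical.
#'
#' @param mat numeric matrix with probe row names and sample column names.
#' @param path output path.
#' @param id_col header name for the id column.
#' @return Invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(mat, path, id_col = "probe_id") {
    fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.12g", v))
    header <- paste(c(id_col, colnames(mat)), collapse = "\t")
    rows <- vapply(seq_len(nrow(mat)), function(i)
        paste(c(rownames(mat)[i], fmt(mat[i, ])), collapse = "\t"),
        character(1))
    writeLines(c(header, rows), path)
    invisible(path)
}

#' Read and validate a sample sheet
#'
#' Expects columns \code{sample_id}, \code{group}, \code{etiology},
#' \code{tissue_type}.  Group labels are case-folded (\code{"Tumor"} is
#' accepted as \code{"tumor"}); etiology \code{""}/\code{"NA"} becomes
#' missing.  If \code{sample_ids} are given (e.g. the columns of the
#' expression matrix), every one of them must appear exactly once.
#'
#' @param path path to a TSV sample sheet.
#' @param sample_ids optional character vector the sheet must cover, or a
#'   matrix whose column names are used.
#' @return \code{data.frame} with validated columns.
#' @export
readSampleSheet <- function(path, sample_ids = NULL) {
    if (is.matrix(sample_ids)) sample_ids <- colnames(sample_ids)
    df <- utils::read.delim(path, comment.char = "#",
                            colClasses = "character", check.names = FALSE)
    need <- c("sample_id", "group", "etiology", "tissue_type")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop(sprintf("sample sheet '%s' lacks column(s): %s", path,
                     paste(miss, collapse = ", ")))
    df <- df[, need]
    df$group <- tolower(df$group)
    bad <- setdiff(unique(df$group), .SAMPLE_GROUPS)
    if (length(bad))
        stop(sprintf("unknown group value(s) in '%s': %s", path,
                     paste(bad, collapse = ", ")))
    if (anyDuplicated(df$sample_id))
        stop(sprintf("duplicated sample id '%s' in '%s'",
                     df$sample_id[duplicated(df$sample_id)][1L], path))
    df$etiology[df$etiology %in% c("", "NA")] <- NA_character_
    df$tissue_type[df$tissue_type %in% c("", "NA")] <- NA_character_
    no_tt <- df$group == "normal_tissue" & is.na(df$tissue_type)
    if (any(no_tt))
        stop(sprintf("normal_tissue sample(s) lacking tissue_type: %s",
                     paste(df$sample_id[no_tt], collapse = ", ")))
    if (!is.null(sample_ids)) {
        absent <- setdiff(sample_ids, df$sample_id)
        if (length(absent))
            stop(sprintf("sample(s) in matrix missing from sheet: %s",
                         paste(absent, collapse = ", ")))
    }
    df
}

#' Read a probe-to-gene map
#'
#' Two-column TSV (\code{probe_id}, \code{gene_symbol}); many probes may
#' map to one gene.  Gene symbols are case-folded to upper case so that
#' downstream set operations are deterministic.
#'
#' @param path path to the TSV map.
#' @param probe_ids optional probe universe that must be fully covered.
#' @return Named character vector, probe id to gene symbol.
#' @export
readProbeGeneMap <- function(path, probe_ids = NULL) {
    df <- utils::read.delim(path, comment.char = "#",
                            colClasses = "character", check.names = FALSE)
    if (!all(c("probe_id", "gene_symbol") %in% colnames(df)))
        stop(sprintf("'%s' must have columns probe_id and gene_symbol",
                     path))
    if (anyDuplicated(df$probe_id))
        stop(sprintf("duplicated probe id '%s' in '%s'",
                     df$probe_id[duplicated(df$probe_id)][1L], path))
    map <- setNames(toupper(df$gene_symbol), df$probe_id)
    if (!is.null(probe_ids)) {
        absent <- setdiff(probe_ids, names(map))
        if (length(absent))
            stop(sprintf("probe(s) missing from map '%s': %s", path,
                         paste(utils::head(absent, 5L), collapse = ", ")))
    }
    map
}

#' Read a gene x sample integer count matrix from TSV
#'
#' @param path path to a TSV with first column \code{gene_id} (or any id
#'   header) and integer cells.
#' @return Integer matrix with dimnames.
#' @export
readCountMatrix <- function(path) {
    mat <- readExpressionMatrix(path)
    if (anyNA(mat))
        stop(sprintf("missing values are not allowed in counts ('%s')",
                     path))
    if (any(mat < 0) || any(mat != round(mat))) {
        bad <- which(mat < 0 | mat != round(mat), arr.ind = TRUE)[1L, ]
        stop(sprintf(
            "count matrix '%s' has non-integer or negative value at %s/%s",
            path, rownames(mat)[bad[1L]], colnames(mat)[bad[2L]]))
    }
    storage.mode(mat) <- "integer"
    mat
}

#' @rdname readCountMatrix
#' @param mat integer matrix to serialize.
#' @param path output path.
#' @export
writeCountMatrix <- function(mat, path) {
    header <- paste(c("gene_id", colnames(mat)), collapse = "\t")
    rows <- vapply(seq_len(nrow(mat)), function(i)
        paste(c(rownames(mat)[i], format(mat[i, ], scientific = FALSE,
                                         trim = TRUE)), collapse = "\t"),
        character(1))
    writeLines(c(header, rows), path)
    invisible(path)
}

#' Write a data frame as plain TSV (no quoting, NA as "NA")
#'
#' @param df data frame.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Assemble an expression cohort experiment from its tabular parts
#'
#' Bundles a parsed expression matrix, sample sheet and probe map into the
#' same [SummarizedExperiment::SummarizedExperiment] layout that
#' [simulateExpressionCohort()] produces, so file-based and simulated
#' cohorts flow through the identical pipeline.
#'
#' @param mat probe x sample matrix from [readExpressionMatrix()].
#' @param sheet sample sheet from [readSampleSheet()].
#' @param map probe-to-gene map from [readProbeGeneMap()].
#' @return A \code{SummarizedExperiment} with assay \code{"exprs"}.
#' @export
makeCohortExperiment <- function(mat, sheet, map) {
    absent <- setdiff(rownames(mat), names(map))
    if (length(absent))
        stop(sprintf("probe(s) not in map: %s",
                     paste(utils::head(absent, 5L), collapse = ", ")))
    sheet <- sheet[match(colnames(mat), sheet$sample_id), ]
    SummarizedExperiment(
        assays = list(exprs = mat),
        rowData = DataFrame(probe_id = rownames(mat),
                            gene_symbol = unname(map[rownames(mat)]),
                            row.names = rownames(mat)),
        colData = DataFrame(sheet, row.names = sheet$sample_id))
}
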