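#' Read a count matrix from disk
#'
#' Supports the featureCounts output layout (columns `Geneid`, optionally
#' `Chr`/`Start`/`End`/`Strand` which are ignored, `Length`, then one column
#' per sample; lines starting with `#` are skipped) and a plain TSV layout
#' (gene ids in the first column, samples in the remaining columns, feature
#' lengths supplied separately).
#'
#' @param path path to a tab-delimited counts file.
#' @param dialect `"featurecounts"` (default) or `"plain_tsv"`.
#' @param lengths for `plain_tsv`: a single length applied to all genes, or a
#'   numeric vector named by gene id.
#' @param length_file for `plain_tsv`: a two-column TSV (gene id, length in
#'   bp) as an alternative to `lengths`.
#' @return a [count_matrix()]; column order is preserved as in the file.
#' @export
read_counts <- function(path, dialect = c("featurecounts", "plain_tsv"),
                        lengths = NULL, length_file = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (dialect == "featurecounts") {
    if (!all(c("Geneid", "Length") %in% names(tab)))
      stop("featureCounts dialect requires Geneid and Length columns",
           " (missing length or gene id column)")
    drop <- intersect(c("Chr", "Start", "End", "Strand"), names(tab))
    gid <- as.character(tab$Geneid)
    len <- tab$Length
    cnt <- tab[, setdiff(names(tab), c("Geneid", "Length", drop)), drop = FALSE]
  } else {
    gid <- as.character(tab[[1]])
    cnt <- tab[, -1, drop = FALSE]
    if (!is.null(length_file)) {
      lt <- utils::read.delim(length_file, header = FALSE, sep = "\t",
                              stringsAsFactors = FALSE)
      len <- stats::setNames(as.numeric(lt[[2]]), as.character(lt[[1]]))
      if (!all(gid %in% names(len)))
        stop("length file is missing length for some genes")
      len <- len[gid]
    } else if (!is.null(lengths)) {
      len <- if (length(lengths) == 1L) rep(as.numeric(lengths), length(gid))
             else lengths[gid]
      if (any(is.na(len))) stop("missing length for some genes")
    } else {
      stop("plain_tsv dialect requires lengths= or length_file= (missing length)")
    }
  }
  if (ncol(cnt) == 0L) stop("no sample columns found in ", path)
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  m <- as.matrix(cnt)
  if (!is.numeric(m)) stop("non-numeric count cell found in ", path)
  rownames(m) <- gid
  count_matrix(m, as.numeric(len))
}

#' Write a count matrix in featureCounts-style layout
#'
#' Writes `Geneid`, `Length` and one column per sample; [read_counts()] with
#' the default dialect reproduces the object exactly.
#'
#' @param cm a [count_matrix()]
#' @param path output path.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(Geneid = gene_ids(cm), Length = unname(cm$lengths),
                   cm$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation sheet
#'
#' A TSV with one row per sample; columns `sample_id` and `population` are
#' required, `patient` (donor / batch label), `age` and `sex` are optional.
#'
#' @param path path to the TSV.
#' @return a data.frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sheet <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
  .check_sheet(sheet)
}

#' Write a sample sheet
#' @param sheet data.frame with at least `sample_id` and `population`.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- .check_sheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated as
#' `set_name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' set are removed (with a message). Lines with fewer than three fields are a
#' format error.
#'
#' @param path path to a GMT file.
#' @return a named list of character vectors (class `gene_set_collection`),
#'   with set descriptions in attribute `description`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      message("GMT set ", f[1], ": duplicated genes removed")
      genes <- unique(genes)
    }
    if (!length(genes)) stop("GMT set ", f[1], " is empty")
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  structure(sets, description = desc, class = c("gene_set_collection", "list"))
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors (gene ids per set).
#' @param path output path.
#' @param description optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  if (is.null(description)) description <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Tab-separated, no quoting, stable column names; the standard output format
#' for every tabular result of the pipeline.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @export
write_results <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
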