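#' Genus-level count table for one sampling site
#'
#' Light S3 container around a samples x genera matrix of non-negative integer
#' counts, plus the site label and (optionally) semicolon-separated lineage
#' strings for each genus.
#'
#' @param counts integer matrix, samples in rows, genera in columns; must have
#'   unique, non-empty dimnames.
#' @param site sampling-site label (e.g. "caecum", "colon", "feces").
#' @param lineage optional character vector of lineage strings, one per genus.
#' @return an object of class `genus_count_table`.
#' @export
genus_count_table <- function(counts, site = "unknown", lineage = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must carry sample (row) and genus (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate genus ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite numbers")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', genus '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "double"
  if (!is.null(lineage) && length(lineage) != ncol(counts))
    stop("lineage must have one entry per genus")
  structure(list(counts = counts, site = site, lineage = lineage),
            class = "genus_count_table")
}

#' @export
print.genus_count_table <- function(x, ...) {
  cat(sprintf("genus_count_table: %d samples x %d genera (site: %s)\n",
              nrow(x$counts), ncol(x$counts), x$site))
  cat(sprintf("  total reads: %s; zero fraction: %.3f\n",
              format(sum(x$counts), big.mark = ","), mean(x$counts == 0)))
  invisible(x)
}

#' Read a genus count table from TSV/CSV
#'
#' Accepts samples-as-rows (default) or genera-as-rows layouts; the latter is
#' transposed on read so the in-memory object is always samples x genera.
#' A leading `#OTU ID` header cell (BIOM TSV dialect) is tolerated. Genus names
#' containing `;` are treated as lineage strings and the last field is used as
#' the genus id.
#'
#' @param path file path; delimiter inferred from extension (`.csv` vs other).
#' @param orientation "samples" (rows are samples) or "genera".
#' @param site site label to attach.
#' @return a [genus_count_table()].
#' @export
read_count_table <- function(path, orientation = c("samples", "genera"),
                             site = "unknown") {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#OTU ID")) {
    # BIOM TSV convention: features in rows regardless of caller default
    orientation <- "genera"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          row.names = 1L, comment.char = "",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!apply(df, 2, function(col) all(grepl("^\\s*-?[0-9.]+\\s*$", col))))
    stop("non-numeric cells in column(s): ",
         paste(colnames(df)[bad], collapse = ", "))
  }
  if (orientation == "genera") m <- t(m)
  lineage <- NULL
  if (any(grepl(";", colnames(m), fixed = TRUE))) {
    lineage <- colnames(m)
    last <- vapply(strsplit(colnames(m), ";", fixed = TRUE),
                   function(f) trimws(f[[length(f)]]), character(1))
    colnames(m) <- last
  }
  genus_count_table(m, site = site, lineage = lineage)
}

#' Write a genus count table to TSV (samples in rows)
#'
#' @param table a [genus_count_table()].
#' @param path output path.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "genus_count_table"))
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the sample metadata table
#'
#' Required columns: `sample_id`, `animal_id`, `treatment` (stress/control),
#' `litter`, `pen`, `site`.
#'
#' @param path TSV/CSV path.
#' @return data.frame with factors for treatment, litter, pen, site.
#' @export
read_metadata <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  need <- c("sample_id", "animal_id", "treatment", "litter", "pen", "site")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample ids in metadata")
  if (any(is.na(md$treatment)) || any(is.na(md$litter)))
    stop("treatment and litter must be non-missing")
  if (!all(md$treatment %in% c("stress", "control")))
    stop("treatment must be 'stress' or 'control'")
  dup <- duplicated(md[, c("animal_id", "site")])
  if (any(dup))
    stop("animal(s) with >1 sample at a site: ",
         paste(unique(md$animal_id[dup]), collapse = ", "))
  md$treatment <- factor(md$treatment, levels = c("stress", "control"))
  md$litter <- factor(md$litter)
  md$pen <- factor(md$pen)
  md$site <- factor(md$site)
  md
}

#' Align a count table with its metadata
#'
#' Reorders the metadata to the table's sample order and returns the factors
#' needed downstream; every table sample must be present in the metadata.
#'
#' @param table a [genus_count_table()].
#' @param metadata data.frame as from [read_metadata()].
#' @return list with `table`, aligned `metadata`, and factor vectors
#'   `treatment`, `litter`, `pen`, `animal_id`.
#' @export
join_metadata <- function(table, metadata) {
  stopifnot(inherits(table, "genus_count_table"))
  metadata <- validate_metadata(as.data.frame(metadata))
  ids <- rownames(table$counts)
  missing <- setdiff(ids, metadata$sample_id)
  if (length(missing))
    stop("sample id(s) absent from metadata: ", paste(missing, collapse = ", "))
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  rownames(md) <- NULL
  list(table = table, metadata = md,
       treatment = md$treatment, litter = md$litter, pen = md$pen,
       animal_id = md$animal_id)
}

#' Per-sample relative abundances
#'
#' Counts divided by the sample total; no rarefaction is applied.
#'
#' @param counts matrix samples x genera (or a [genus_count_table()]).
#' @return matrix of the same shape with rows summing to 1.
#' @export
relative_abundance <- function(counts) {
  if (inherits(counts, "genus_count_table")) counts <- counts$counts
  tot <- rowSums(counts)
  if (any(tot <= 0)) stop("sample(s) with zero total counts: ",
                          paste(rownames(counts)[tot <= 0], collapse = ", "))
  sweep(counts, 1, tot, "/")
}
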