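#' Construct an abundance table
#'
#' An abundance table holds a taxa x samples matrix of non-negative
#' abundances. Rows are taxa, columns are samples (the OTU-table
#' convention). Values may be raw counts or relative abundances; columns
#' that do not sum to 1 are flagged so that [normalize_relative()] is
#' called before any specificity computation.
#'
#' @param values numeric matrix, rows = taxa, columns = samples. All
#'   entries must be non-negative; absence is encoded as 0, not NA.
#' @param taxon_ids,sample_ids character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @return An object of class `ssd_table` with elements `values`
#'   (the named matrix) and `normalized` (logical flag).
#' @export
abundance_table <- function(values, taxon_ids = rownames(values),
                            sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  taxon_ids <- as.character(taxon_ids)
  sample_ids <- as.character(sample_ids)
  if (length(taxon_ids) != nrow(values))
    stop("length(taxon_ids) must equal nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) must equal ncol(values)")
  if (anyDuplicated(taxon_ids))
    stop("duplicate taxon ids: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(values)) stop("abundance values must not contain NA")
  if (any(values < 0)) stop("abundance values must be non-negative")
  dimnames(values) <- list(taxon_ids, sample_ids)
  obj <- structure(list(values = values,
                        normalized = .is_normalized(values)),
                   class = "ssd_table")
  obj
}

.is_normalized <- function(values, tol = 1e-9) {
  cs <- colSums(values)
  all(abs(cs[cs > 0] - 1) < tol)
}

#' @export
print.ssd_table <- function(x, ...) {
  cat(sprintf("ssd_table: %d taxa x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "relative abundances" else "needs normalization"))
  invisible(x)
}

#' @export
dim.ssd_table <- function(x) dim(x$values)

#' Taxon and sample identifiers of an abundance table
#' @param table an `ssd_table`
#' @return character vector of identifiers.
#' @export
taxon_ids <- function(table) rownames(table$values)

#' @rdname taxon_ids
#' @export
sample_ids <- function(table) colnames(table$values)

#' Read an abundance table from TSV or BIOM
#'
#' TSV dialect: tab-delimited, UTF-8, first column = taxon id, header row =
#' sample ids. BIOM input (JSON or HDF5) is parsed through the biomformat
#' package and oriented rows = observations (taxa), columns = samples.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"biom"`.
#' @param transpose logical; set TRUE if a TSV file is stored samples x
#'   taxa. Never applied to BIOM input, whose orientation is defined by the
#'   format itself.
#' @return an [abundance_table()]; check `$normalized` to see whether the
#'   columns are already relative abundances.
#' @export
read_abundance_table <- function(path, format = c("tsv", "biom"),
                                 transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, row.names = NULL,
                            colClasses = NA, comment.char = "",
                            quote = "", fileEncoding = "UTF-8")
    if (ncol(df) < 2) stop("TSV abundance table needs >= 1 sample column")
    ids <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(mat)) stop("non-numeric abundance values (ragged or malformed rows?)")
    rownames(mat) <- ids
    if (transpose) mat <- t(mat)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the 'biomformat' package is required for BIOM input")
    b <- biomformat::read_biom(path)
    mat <- as.matrix(biomformat::biom_data(b))
  }
  abundance_table(mat)
}

#' Write an abundance table as TSV
#' @param table an `ssd_table`.
#' @param path output path.
#' @param id_column name of the first (taxon id) column.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path, id_column = "taxon_id") {
  stopifnot(inherits(table, "ssd_table"))
  df <- data.frame(taxon_id = taxon_ids(table), table$values,
                   check.names = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize each sample to relative abundances
#'
#' Scales every nonzero column to sum to 1. All-zero columns are left
#' untouched and collected in the `zero_samples` attribute (a warning is
#' also emitted); they are degenerate, not an error. The operation is
#' idempotent and preserves the zero pattern.
#'
#' @param table an `ssd_table`.
#' @return a normalized `ssd_table`; `attr(, "zero_samples")` lists ids of
#'   all-zero samples.
#' @export
normalize_relative <- function(table) {
  stopifnot(inherits(table, "ssd_table"))
  v <- table$values
  cs <- colSums(v)
  zero <- cs == 0
  keep <- !zero
  v[, keep] <- sweep(v[, keep, drop = FALSE], 2, cs[keep], "/")
  out <- abundance_table(v)
  out$normalized <- TRUE
  attr(out, "zero_samples") <- colnames(v)[zero]
  if (any(zero))
    warning("all-zero sample(s) left unnormalized: ",
            paste(colnames(v)[zero], collapse = ", "))
  out
}

#' Construct a habitat map
#'
#' Assigns every sample to exactly one habitat label at a chosen level.
#' "Habitat" is any host grouping over which specificity is computed: a
#' host species, a host class or phylum, or a diet type. Habitat order is
#' lexicographic and fixed once, so downstream matrices and permutations
#' are reproducible.
#'
#' @param assignments named character vector, names = sample ids, values =
#'   habitat labels.
#' @param level one of `"host_species"`, `"class"`, `"phylum"`, `"diet"`.
#' @return object of class `habitat_map` with `assignments`, `level`,
#'   `habitats` (sorted unique labels).
#' @export
habitat_map <- function(assignments,
                        level = c("host_species", "class", "phylum", "diet")) {
  level <- match.arg(level)
  if (is.null(names(assignments)) || any(names(assignments) == ""))
    stop("assignments must be a named vector (names = sample ids)")
  if (anyDuplicated(names(assignments)))
    stop("duplicate sample ids in habitat assignments")
  assignments <- vapply(assignments, as.character, character(1))
  if (anyNA(assignments) || any(assignments == ""))
    stop("every sample needs a non-empty habitat label")
  structure(list(assignments = assignments,
                 level = level,
                 habitats = sort(unique(unname(assignments)))),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat(sprintf("habitat_map: %d samples, %d habitats at level '%s'\n",
              length(x$assignments), length(x$habitats), x$level))
  invisible(x)
}

#' Read sample metadata and derive a habitat map
#'
#' Metadata TSV columns: `sample_id` plus any of `host_species`, `class`,
#' `phylum`, `diet`.
#'
#' @param path metadata TSV path.
#' @return data.frame with a `sample_id` column.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          quote = "", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (!"sample_id" %in% names(df)) stop("metadata needs a 'sample_id' column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  df
}

#' @param metadata data.frame from [read_sample_metadata()].
#' @param level habitat level; must be a metadata column.
#' @rdname read_sample_metadata
#' @export
habitat_map_from_metadata <- function(metadata,
                                      level = c("host_species", "class",
                                                "phylum", "diet")) {
  level <- match.arg(level)
  if (!level %in% names(metadata))
    stop("metadata has no column '", level, "'")
  habitat_map(stats::setNames(as.character(metadata[[level]]),
                              metadata$sample_id),
              level = level)
}

#' Read a host phylogenetic-timeline table
#'
#' TSV with columns `host_species` and `pt_mya` (evolutionary age of the
#' host taxon, million years; larger = more ancient). All values must be
#' positive.
#'
#' @param path TSV path.
#' @return named numeric vector, names = host species ids.
#' @export
read_pt_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (!all(c("host_species", "pt_mya") %in% names(df)))
    stop("PT table needs columns 'host_species' and 'pt_mya'")
  pt <- as.numeric(df$pt_mya)
  if (anyNA(pt) || any(pt <= 0)) stop("PT values must be positive")
  if (anyDuplicated(df$host_species)) stop("duplicate host_species in PT table")
  stats::setNames(pt, df$host_species)
}

# Match a habitat map against a table; error on uncovered samples.
.check_map <- function(table, map) {
  stopifnot(inherits(table, "ssd_table"), inherits(map, "habitat_map"))
  miss <- setdiff(sample_ids(table), names(map$assignments))
  if (length(miss))
    stop("sample(s) without habitat label: ", paste(miss, collapse = ", "))
  labels <- map$assignments[sample_ids(table)]
  habitats <- sort(unique(unname(labels)))
  list(labels = labels, habitats = habitats)
}

#' Partition an abundance table by habitat
#'
#' Splits the sample columns into one sub-table per habitat, in the fixed
#' (lexicographic) habitat order. The sub-tables partition the columns: the
#' union of their sample ids equals the input's.
#'
#' @param table an `ssd_table`.
#' @param map a `habitat_map` covering all samples of `table`.
#' @return named list of `ssd_table`, one per habitat present.
#' @export
partition_by_habitat <- function(table, map) {
  chk <- .check_map(table, map)
  out <- lapply(chk$habitats, function(h) {
    sub <- table$values[, chk$labels == h, drop = FALSE]
    tab <- abundance_table(sub)
    tab$normalized <- table$normalized
    tab
  })
  names(out) <- chk$habitats
  out
}
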