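#' Read a proteome FASTA file
#'
#' Loads amino-acid sequences into a named character vector (the proteome
#' database used by all sequence-context operations). The record identifier
#' is the header token before the first whitespace; the description is
#' dropped. Sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector: protein ID -> sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate ID in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence in FASTA for: ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write a proteome FASTA file
#'
#' @param proteome Named character vector of amino-acid sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  set <- Biostrings::AAStringSet(proteome)
  names(set) <- names(proteome)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Define a table schema
#'
#' A schema names the required/optional columns of one of the tab-delimited
#' interchange tables and their types; [read_table()] validates against it.
#'
#' @param name Schema identifier.
#' @param columns Data frame with columns `name`, `type`
#'   (one of `"character"`, `"integer"`, `"numeric"`) and `required`
#'   (logical).
#' @return A `table_schema` object.
#' @export
table_schema <- function(name, columns) {
  stopifnot(is.data.frame(columns),
            all(c("name", "type", "required") %in% names(columns)))
  if (anyDuplicated(columns$name)) {
    stop("schema '", name, "': duplicate column names")
  }
  if (!all(columns$type %in% c("character", "integer", "numeric"))) {
    stop("schema '", name, "': unknown column type")
  }
  structure(list(name = name, columns = columns), class = "table_schema")
}

.schema_cols <- function(names, types, required) {
  data.frame(name = names, type = types, required = required)
}

#' Built-in schemas for the pipeline's interchange tables
#'
#' Returns the schemas for the site-level methylation quantification table,
#' the protein-abundance table, the phosphosite table, the somatic-mutation
#' table, the splice-event junction-count table and the event upstream
#' sequence table.
#'
#' @return Named list of [table_schema()] objects.
#' @export
methylomap_schemas <- function() {
  list(
    site_quant = table_schema("site_quant", .schema_cols(
      c("protein", "position", "methyl_type", "intensity_L", "intensity_H"),
      c("character", "integer", "character", "numeric", "numeric"),
      c(TRUE, TRUE, TRUE, TRUE, TRUE))),
    protein_quant = table_schema("protein_quant", .schema_cols(
      c("protein", "intensity_L", "intensity_H"),
      c("character", "numeric", "numeric"),
      c(TRUE, TRUE, TRUE))),
    phospho = table_schema("phospho", .schema_cols(
      c("protein", "position"),
      c("character", "integer"),
      c(TRUE, TRUE))),
    mutation = table_schema("mutation", .schema_cols(
      c("protein", "position", "count"),
      c("character", "integer", "integer"),
      c(TRUE, TRUE, FALSE))),
    splice_counts = table_schema("splice_counts", .schema_cols(
      c("event_id", "event_type", "condition", "inc_count", "skip_count",
        "inc_len", "skip_len"),
      c("character", "character", "character", "integer", "integer",
        "numeric", "numeric"),
      rep(TRUE, 7))),
    event_seq = table_schema("event_seq", .schema_cols(
      c("event_id", "upstream_sequence"),
      c("character", "character"),
      c(TRUE, TRUE)))
  )
}

#' Read a tab-delimited table against a schema
#'
#' Tables are UTF-8, tab-delimited, with a header row; lines starting with
#' `#` are comments. Empty numeric cells become `NA`, the explicit "absent"
#' marker that the abolished-site logic relies on (absent is distinct from
#' zero at the file level; the calling stage coerces zero intensities to
#' absent, see [compute_site_ratio()]).
#'
#' @param path Path to the table.
#' @param schema A [table_schema()].
#' @return Data frame with the schema's columns, typed.
#' @export
read_table <- function(path, schema) {
  stopifnot(inherits(schema, "table_schema"))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "#",
                           na.strings = NULL, check.names = FALSE,
                           fileEncoding = "UTF-8")
  cols <- schema$columns
  missing <- setdiff(cols$name[cols$required], names(raw))
  if (length(missing)) {
    stop("table '", path, "' does not match schema '", schema$name,
         "': missing required column(s) ", paste(missing, collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(cols))) {
    nm <- cols$name[i]
    if (!nm %in% names(raw)) next
    x <- raw[[nm]]
    if (cols$type[i] == "character") {
      out[[nm]] <- x
    } else {
      blank <- is.na(x) | x == "" | x == "NA"
      v <- suppressWarnings(as.numeric(x))
      bad <- which(!blank & is.na(v))
      if (length(bad)) {
        stop("table '", path, "', column '", nm, "': unparsable numeric ",
             "value '", x[bad[1]], "' at row ", bad[1])
      }
      v[blank] <- NA_real_
      out[[nm]] <- if (cols$type[i] == "integer") as.integer(round(v)) else v
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Write a tab-delimited table
#'
#' Counterpart of [read_table()]: tab-delimited UTF-8 with a header row.
#' Optional `comments` are written first as `#`-prefixed lines. `NA` is
#' written as an empty cell so absent measurements round-trip.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param comments Optional character vector of comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, comments = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' GMT dialect: one set per line, `name TAB description TAB member...`.
#' Members are deduplicated; a duplicate set name is an error; a set with no
#' members is kept (empty) with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (unique members per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(names_)) {
    stop("duplicate gene-set name in GMT: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- names_
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("GMT set(s) with no members: ",
            paste(names_[empty], collapse = ", "))
  }
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
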