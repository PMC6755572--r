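#' Chemical activity datasets
#'
#' A dataset is an ordinary `data.frame` with one row per chemical and the
#' columns
#' \describe{
#'   \item{`chem_id`}{unique chemical identifier (character);}
#'   \item{`smiles`}{SMILES structure string (may be `NA` when a precomputed
#'     similarity matrix is supplied downstream);}
#'   \item{one column per endpoint}{continuous activity score in `[0, 1]`,
#'     where 0 is inactive and 1 is active (the default endpoint column is
#'     `activity`);}
#'   \item{`n_sources`}{optional count of independent activity records;}
#'   \item{`source_calls`}{optional per-source binary active/inactive calls,
#'     encoded as a semicolon-joined string of 0/1 (e.g. `"1;1;0"`).}
#' }
#' Row order is meaningful: it is the deterministic tie-break used for
#' neighbor selection, so it is preserved by every operation.
#'
#' `validate_dataset()` checks this contract and returns the data invisibly.
#'
#' @param data data.frame to validate.
#' @param endpoint name of the activity column to check (default
#'   `"activity"`); use `NULL` to skip the score check.
#' @param require_structure if `TRUE`, every row must carry a SMILES string.
#' @return `data`, invisibly.
#' @export
validate_dataset <- function(data, endpoint = "activity",
                             require_structure = FALSE) {
  if (!is.data.frame(data))
    stop_gknn("dataset must be a data.frame", class = "gknn_schema_error")
  if (!"chem_id" %in% names(data))
    stop_gknn("dataset lacks required column 'chem_id'",
              class = "gknn_schema_error")
  if (anyDuplicated(data$chem_id))
    stop_gknn("duplicate chem_id values: ",
              paste(unique(data$chem_id[duplicated(data$chem_id)]),
                    collapse = ", "),
              class = "gknn_schema_error")
  if (!is.null(endpoint)) {
    if (!endpoint %in% names(data))
      stop_gknn("dataset lacks endpoint column '", endpoint, "'",
                class = "gknn_schema_error")
    if (nrow(data) > 0) check_scores(data[[endpoint]])
  }
  if (require_structure &&
      (!"smiles" %in% names(data) || anyNA(data$smiles)))
    stop_gknn("dataset rows lack SMILES structures",
              class = "gknn_schema_error")
  invisible(data)
}

#' Read a chemical dataset from CSV/TSV or SDF
#'
#' CSV files are read with a header row; column names are mapped onto the
#' canonical schema through the `columns` argument, so arbitrary headers
#' work. SDF files take the structure from the molecule block and the
#' activity from a named SD data tag.
#'
#' Rows whose structure fails to parse are skipped with a warning naming
#' them; they are never silently dropped. Structure parsing is only
#' attempted when `check_structures = TRUE` (the default for SDF; for CSV
#' the strings are validated lazily when fingerprints are computed).
#'
#' @param path input file.
#' @param format `"csv"` (comma- or tab-separated, autodetected) or `"sdf"`.
#' @param columns named character vector mapping canonical names
#'   (`chem_id`, `smiles`, `activity`, `n_sources`, `source_calls`) to the
#'   file's column headers. Unmapped canonical names default to themselves.
#' @param endpoint name the activity column receives in the returned data
#'   (default `"activity"`).
#' @param sdf_activity_tag SD tag holding the activity score (SDF only).
#' @param check_structures parse every SMILES now and drop unparsable rows
#'   with a warning.
#' @return data.frame in the canonical dataset schema (see
#'   [validate_dataset()]).
#' @export
read_dataset <- function(path, format = c("csv", "sdf"),
                         columns = character(),
                         endpoint = "activity",
                         sdf_activity_tag = "activity",
                         check_structures = (format == "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_gknn("input file not found: ", path, class = "gknn_io_error")
  if (format == "sdf") {
    ds <- read_dataset_sdf(path, endpoint, sdf_activity_tag)
  } else {
    ds <- read_dataset_csv(path, columns, endpoint)
  }
  if (isTRUE(check_structures) && nrow(ds) > 0 && "smiles" %in% names(ds)) {
    ok <- vapply(ds$smiles, function(s)
      !is.na(s) && !is.null(parse_smiles(s)), logical(1))
    if (any(!ok)) {
      warning(sprintf("skipping %d row(s) with unparsable structures: %s",
                      sum(!ok), paste(ds$chem_id[!ok], collapse = ", ")),
              call. = FALSE)
      ds <- ds[ok, , drop = FALSE]
      rownames(ds) <- NULL
    }
  }
  validate_dataset(ds, endpoint = if (endpoint %in% names(ds)) endpoint)
  ds
}

read_dataset_csv <- function(path, columns, endpoint) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8")
  canon <- c("chem_id", "smiles", "activity", "n_sources", "source_calls")
  map <- stats::setNames(canon, canon)
  map[names(columns)] <- columns
  if (!map[["chem_id"]] %in% names(raw))
    stop_gknn("configured column '", map[["chem_id"]],
              "' (chem_id) not found in ", path, class = "gknn_schema_error")
  ds <- data.frame(chem_id = raw[[map[["chem_id"]]]],
                   stringsAsFactors = FALSE)
  if (map[["smiles"]] %in% names(raw)) {
    smi <- raw[[map[["smiles"]]]]
    smi[is.na(smi) | !nzchar(smi)] <- NA_character_
    ds$smiles <- smi
  }
  if (map[["activity"]] %in% names(raw)) {
    ds[[endpoint]] <- as.numeric(raw[[map[["activity"]]]])
  } else if ("activity" %in% names(columns)) {
    stop_gknn("configured column '", map[["activity"]],
              "' (activity) not found in ", path,
              class = "gknn_schema_error")
  }
  if (map[["n_sources"]] %in% names(raw))
    ds$n_sources <- as.integer(raw[[map[["n_sources"]]]])
  if (map[["source_calls"]] %in% names(raw))
    ds$source_calls <- raw[[map[["source_calls"]]]]
  ds
}

read_dataset_sdf <- function(path, endpoint, tag) {
  sdfs <- ChemmineR::read.SDFset(path)
  ok <- ChemmineR::validSDF(sdfs)
  ids <- ChemmineR::sdfid(sdfs)
  if (any(!ok))
    warning(sprintf("skipping %d molecule(s) with invalid structures: %s",
                    sum(!ok), paste(ids[!ok], collapse = ", ")),
            call. = FALSE)
  sdfs <- sdfs[ok]
  ids <- ids[ok]
  smi <- as.character(ChemmineR::sdf2smiles(sdfs))
  act <- vapply(seq_along(sdfs), function(i) {
    db <- ChemmineR::datablock(sdfs[[i]])
    if (tag %in% names(db)) as.numeric(db[[tag]]) else NA_real_
  }, numeric(1))
  ds <- data.frame(chem_id = ids, smiles = smi, stringsAsFactors = FALSE)
  ds[[endpoint]] <- act
  ds
}

#' Write a chemical dataset to CSV
#'
#' Inverse of [read_dataset()] for the canonical CSV schema; a
#' write-then-read round trip reproduces all fields.
#'
#' @param data dataset data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Average activity records from multiple sources
#'
#' When a chemical carries several independent activity records for an
#' endpoint, its consensus score is their plain arithmetic mean.
#'
#' @param scores numeric vector of per-source activity scores in `[0, 1]`.
#' @return single activity score in `[0, 1]`.
#' @export
average_sources <- function(scores) {
  if (length(scores) == 0)
    stop_gknn("no activity records to average; exclude the chemical instead",
              class = "gknn_value_error")
  check_scores(scores)
  mean(scores)
}

#' Remove uncertain mid-range activities from a training set
#'
#' Chemicals whose activity falls strictly inside `(low, high)` are weak
#' signals most at risk of being assay false positives, and are dropped;
#' scores at or below `low` and at or above `high` are kept. The interval
#' is open, so the bounds themselves remain valid scores. The number of
#' removed chemicals is reported via `message()`.
#'
#' @param data dataset data.frame.
#' @param low,high removal interval bounds, `0 <= low < high <= 1`
#'   (defaults 0.01 and 0.1).
#' @param endpoint activity column to filter on.
#' @return filtered dataset, original row order preserved.
#' @export
curate_training <- function(data, low = 0.01, high = 0.1,
                            endpoint = "activity") {
  if (!(low >= 0 && low < high && high <= 1))
    stop_gknn("need 0 <= low < high <= 1", class = "gknn_value_error")
  validate_dataset(data, endpoint)
  if (nrow(data) == 0) return(data)
  keep <- data[[endpoint]] <= low | data[[endpoint]] >= high
  message(sprintf("curate_training: removed %d of %d chemicals with %s in (%g, %g)",
                  sum(!keep), nrow(data), endpoint, low, high))
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

parse_source_calls <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Restrict a dataset to chemicals with consistent activity sources
#'
#' Keeps chemicals with more than `min_sources` activity records whose
#' majority call (active or inactive) occurs in at least
#' `majority_frac` of the per-source calls. Raising either requirement
#' improves data quality and shrinks the set.
#'
#' @param data dataset data.frame carrying `n_sources` and `source_calls`.
#' @param min_sources keep chemicals with strictly more sources than this.
#' @param majority_frac required majority fraction, in `(0.5, 1]`
#'   (default 0.8).
#' @return filtered dataset, original row order preserved.
#' @export
consistency_subset <- function(data, min_sources, majority_frac = 0.8) {
  if (min_sources < 0)
    stop_gknn("min_sources must be >= 0", class = "gknn_value_error")
  if (!(majority_frac > 0.5 && majority_frac <= 1))
    stop_gknn("majority_frac must lie in (0.5, 1]",
              class = "gknn_value_error")
  validate_dataset(data, endpoint = NULL)
  if (nrow(data) == 0) return(data)
  if (!all(c("n_sources", "source_calls") %in% names(data)))
    stop_gknn("dataset lacks n_sources/source_calls columns",
              class = "gknn_data_error")
  keep <- vapply(seq_len(nrow(data)), function(i) {
    calls <- parse_source_calls(data$source_calls[i])
    if (length(calls) == 0)
      stop_gknn("chemical '", data$chem_id[i],
                "' has no source_calls; cannot apply consistency filter",
                class = "gknn_data_error")
    frac <- max(mean(calls == 1L), mean(calls == 0L))
    data$n_sources[i] > min_sources && frac >= majority_frac
  }, logical(1))
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
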