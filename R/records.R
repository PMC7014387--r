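#' Read incident records from CSV
#'
#' Reads a comma-separated table of categorical incident records, one row per
#' injury, and validates every cell against the node set. Cells equal to
#' `missing_token` become `NA`; columns absent from the file are added as
#' all-missing so downstream code always sees the full schema.
#'
#' @param path CSV file with a header row; column names must be node ids.
#' @param nodes Node-set tibble, e.g. [canonical_nodes()].
#' @param missing_token Sentinel string marking a missing cell (default "NA").
#' @return A tibble of character columns, one per node, in node-set order.
#' @export
read_records <- function(path, nodes = canonical_nodes(), missing_token = "NA") {
  validate_nodes(nodes)
  if (!file.exists(path)) {
    abort_escbn(sprintf("Records file not found: %s", path), "escbn_data_error")
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character(0))
  unknown <- setdiff(names(df), nodes$node_id)
  if (length(unknown)) {
    abort_escbn(
      sprintf("Unknown column(s) in records file: %s", paste(unknown, collapse = ", ")),
      "escbn_data_error"
    )
  }
  for (id in nodes$node_id) {
    if (!id %in% names(df)) {
      df[[id]] <- NA_character_
    } else {
      df[[id]][df[[id]] == missing_token] <- NA_character_
    }
  }
  out <- tibble::as_tibble(df[nodes$node_id])
  validate_records(out, nodes)
  out
}

#' Validate incident records against a node set
#'
#' Every non-missing cell must be a legal state of its column's node. The
#' error message reports the first offending row, column and value.
#'
#' @param data Tibble of character columns named by node ids; `NA` = missing.
#' @param nodes Node-set tibble.
#' @return `data`, invisibly, if valid.
#' @export
validate_records <- function(data, nodes = canonical_nodes()) {
  validate_nodes(nodes)
  unknown <- setdiff(names(data), nodes$node_id)
  if (length(unknown)) {
    abort_escbn(
      sprintf("Unknown column(s): %s", paste(unknown, collapse = ", ")),
      "escbn_data_error"
    )
  }
  for (id in names(data)) {
    st <- states_of(nodes, id)
    bad <- which(!is.na(data[[id]]) & !(data[[id]] %in% st))
    if (length(bad)) {
      abort_escbn(
        sprintf("Illegal state in column '%s', row %d: '%s'.",
                id, bad[1], data[[id]][bad[1]]),
        "escbn_data_error"
      )
    }
  }
  invisible(data)
}

#' Write incident records to CSV
#'
#' Round-trips with [read_records()]: missing cells are serialized as
#' `missing_token` and reading the file back yields the same tibble.
#'
#' @param data Validated records tibble.
#' @param path Output CSV path.
#' @param nodes Node-set tibble used for validation.
#' @param missing_token Sentinel written for missing cells.
#' @return `path`, invisibly.
#' @export
write_records <- function(data, path, nodes = canonical_nodes(), missing_token = "NA") {
  validate_records(data, nodes)
  out <- as.data.frame(data)
  for (j in seq_along(out)) {
    out[[j]][is.na(out[[j]])] <- missing_token
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    abort_escbn(sprintf("Could not write records to '%s'.", path), "escbn_data_error")
  }
  invisible(path)
}

#' Per-node missingness of a record set
#'
#' @param data Records tibble.
#' @return Tibble with `node_id` and the fraction of missing cells per node.
#' @export
missingness_summary <- function(data) {
  tibble::tibble(
    node_id = names(data),
    missing_fraction = vapply(data, function(x) mean(is.na(x)), numeric(1))
  )
}

# Convert a character record tibble to an integer state-index matrix
# (NA preserved). Columns ordered like `nodes`.
records_to_indices <- function(data, nodes) {
  m <- matrix(NA_integer_, nrow(data), nrow(nodes),
              dimnames = list(NULL, nodes$node_id))
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$node_id[[i]]
    if (id %in% names(data)) {
      m[, i] <- match(data[[id]], nodes$states[[i]])
    }
  }
  m
}

indices_to_records <- function(m, nodes) {
  out <- lapply(seq_len(nrow(nodes)), function(i) {
    nodes$states[[i]][m[, nodes$node_id[[i]]]]
  })
  names(out) <- nodes$node_id
  tibble::as_tibble(out)
}
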