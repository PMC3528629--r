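#' Read a compound bioactivity profile table
#'
#' Reads a delimited table whose first column holds compound identifiers and
#' whose header row names the features (for instance the cell lines of a
#' log(GI50) growth-inhibition panel). Empty cells, `"NA"` and `"nan"` are
#' parsed as missing values.
#'
#' @param path Path to the delimited file.
#' @param delimiter Field delimiter (default tab). No auto-detection is
#'   attempted.
#' @return A tibble of class `compound_profiles`: column `compound_id`
#'   followed by one numeric column per feature.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tA\tB\tC", "C1\t1\t2\t3", "C2\t3\t2\t1"), tf)
#' read_profiles(tf)
read_profiles <- function(path, delimiter = "\t") {
  stopifnot(file.exists(path))
  raw <- readr::read_delim(
    path,
    delim = delimiter,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(),
    progress = FALSE
  )
  if (ncol(raw) < 2) {
    abort("profile table needs a compound-id column plus at least one feature column")
  }
  ids <- as.character(raw[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate compound id(s): ", paste(dup, collapse = ", ")))
  }
  na_tokens <- c("", "NA", "nan", "NaN")
  feats <- raw[-1]
  for (j in seq_along(feats)) {
    cell <- feats[[j]]
    cell[cell %in% na_tokens] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf(
        "non-numeric value '%s' at row %d, column '%s'",
        cell[bad[1]], bad[1], names(feats)[j]
      ))
    }
    feats[[j]] <- num
  }
  out <- tibble::tibble(compound_id = ids)
  out <- dplyr::bind_cols(out, feats)
  class(out) <- c("compound_profiles", class(out))
  out
}

#' Read compound binary structural fingerprints
#'
#' Reads a two-column headerless delimited file: compound id, fingerprint.
#' Fingerprints may be given as bitstrings (`"1010..."`) or hexadecimal
#' strings (`"f0a3..."`); hex digits expand to four bits each,
#' most-significant-bit first. All fingerprints must have the same length.
#'
#' @param path Path to the fingerprint file.
#' @param format Either `"bitstring"` or `"hex"`.
#' @param delimiter Field delimiter (default tab).
#' @return A tibble of class `compound_fingerprints` with columns
#'   `compound_id` and `fingerprint` (binary string); attribute `bit_length`
#'   records the common fingerprint length.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("C1\t1100", "C2\t0110"), tf)
#' read_fingerprints(tf)
read_fingerprints <- function(path, format = c("bitstring", "hex"),
                              delimiter = "\t") {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty fingerprint file")
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2)) {
    abort(sprintf("malformed fingerprint line %d: expected 2 fields, got %d",
                  which(nf != 2)[1], nf[which(nf != 2)[1]]))
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  fps <- vapply(parts, `[[`, character(1), 2)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate compound id(s): ", paste(dup, collapse = ", ")))
  }
  if (format == "hex") {
    bad <- grepl("[^0-9a-fA-F]", fps)
    if (any(bad)) {
      abort(sprintf("non-hexadecimal character in fingerprint of '%s'", ids[which(bad)[1]]))
    }
    fps <- vapply(fps, hex_to_bits, character(1), USE.NAMES = FALSE)
  } else {
    bad <- grepl("[^01]", fps)
    if (any(bad)) {
      abort(sprintf("non-binary character in fingerprint of '%s'", ids[which(bad)[1]]))
    }
  }
  lens <- nchar(fps)
  if (length(unique(lens)) != 1) {
    abort(sprintf(
      "inconsistent fingerprint lengths: %s",
      paste(unique(lens), collapse = ", ")
    ))
  }
  out <- tibble::tibble(compound_id = ids, fingerprint = fps)
  attr(out, "bit_length") <- lens[1]
  class(out) <- c("compound_fingerprints", class(out))
  out
}

# expand a hex string to a binary string, MSB first per hex digit
hex_to_bits <- function(x) {
  digits <- strtoi(strsplit(tolower(x), "")[[1]], base = 16L)
  bits <- vapply(digits, function(d) {
    paste0(as.integer(bitwAnd(d, c(8L, 4L, 2L, 1L)) > 0L), collapse = "")
  }, character(1))
  paste0(bits, collapse = "")
}

#' Expand fingerprints into a binary matrix
#'
#' @param fps A `compound_fingerprints` tibble (see [read_fingerprints()]).
#' @return Integer 0/1 matrix, one row per compound, rownames = compound ids.
#' @export
fingerprint_matrix <- function(fps) {
  stopifnot(all(c("compound_id", "fingerprint") %in% names(fps)))
  bits <- do.call(rbind, lapply(strsplit(fps$fingerprint, ""), as.integer))
  rownames(bits) <- fps$compound_id
  bits
}

#' Read a compound-target interaction edge list
#'
#' Reads a headerless two-column delimited file of (compound id, target id)
#' pairs, e.g. a PubChem CID/GI dump. Duplicate edges are collapsed; the
#' compound and target universes are inferred from the file.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field delimiter (default tab).
#' @return A `bipartite_network` object (see [bipartite_network()]).
#' @export
read_edge_list <- function(path, delimiter = "\t") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    return(bipartite_network(tibble::tibble(
      compound_id = character(), target_id = character()
    )))
  }
  parts <- strsplit(lines[keep], delimiter, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2)) {
    bad <- which(keep)[which(nf != 2)[1]]
    abort(sprintf("malformed edge-list line %d: expected 2 fields", bad))
  }
  edges <- tibble::tibble(
    compound_id = vapply(parts, `[[`, character(1), 1),
    target_id = vapply(parts, `[[`, character(1), 2)
  )
  bipartite_network(dplyr::distinct(edges))
}

#' Construct a compound-target bipartite network
#'
#' @param edges Tibble/data frame with columns `compound_id` and `target_id`.
#' @param compound_ids,target_ids Optional id universes; defaults to the ids
#'   seen in `edges` (file/row order preserved). Compounds without any edge
#'   can be declared here so they survive the one-mode projection as
#'   degree-zero nodes.
#' @return Object of class `bipartite_network`: list with `compound_ids`,
#'   `target_ids` and the de-duplicated `edges` tibble.
#' @export
bipartite_network <- function(edges, compound_ids = NULL, target_ids = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("compound_id", "target_id") %in% names(edges)))
  edges <- dplyr::distinct(edges[c("compound_id", "target_id")])
  if (is.null(compound_ids)) compound_ids <- unique(edges$compound_id)
  if (is.null(target_ids)) target_ids <- unique(edges$target_id)
  missing_c <- setdiff(edges$compound_id, compound_ids)
  missing_t <- setdiff(edges$target_id, target_ids)
  if (length(missing_c) > 0 || length(missing_t) > 0) {
    abort(paste0(
      "edges reference undeclared ids: ",
      paste(c(missing_c, missing_t), collapse = ", ")
    ))
  }
  structure(
    list(compound_ids = compound_ids, target_ids = target_ids, edges = edges),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf(
    "<bipartite_network> %d compounds, %d targets, %d edges\n",
    length(x$compound_ids), length(x$target_ids), nrow(x$edges)
  ))
  invisible(x)
}

#' Write / read a labeled square matrix
#'
#' Tab-separated with row and column labels; numeric values round-trip
#' losslessly to at least 12 significant digits.
#'
#' @param m Numeric matrix with identical row and column label sets.
#' @param path Output file path.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("matrix must carry row and column labels")
  }
  fm <- matrix(formatC(m, digits = 17, format = "g"), nrow(m), ncol(m))
  lines <- c(
    paste(c("", colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], fm[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix
#' @return `read_matrix()` returns the labeled square numeric matrix.
#' @export
read_matrix <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m)) {
    abort(sprintf("matrix file is not square: %d x %d", nrow(m), ncol(m)))
  }
  storage.mode(m) <- "double"
  m
}

#' Write / read a flat run-configuration file
#'
#' Single flat JSON object carrying run parameters (eta, k, seed, tolerances,
#' linkage, ...).
#'
#' @param config Named list of scalar values.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @return `read_config()` returns the named list.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
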