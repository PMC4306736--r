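# Molecule and activity-table input, and the sparse fingerprint text format.
# SMILES and SDF parsing is delegated to OpenBabel (via ChemmineOB) with
# explicit-hydrogen expansion, and records are split with ChemmineR; this
# package only converts the resulting V2000 blocks into `molecule` graphs.

old_style_charge <- function(code) {
  # V2000 atom-block charge field: 1..3 -> +3..+1, 4 -> radical, 5..7 -> -1..-3
  ifelse(code >= 1 & code <= 3, 4L - as.integer(code),
         ifelse(code >= 5 & code <= 7, 4L - as.integer(code), 0L))
}

sdfset_to_molecules <- function(sdfset, provenance) {
  lapply(seq_along(ChemmineR::sdfid(sdfset)), function(k) {
    sdf <- sdfset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    charge <- if (ncol(ab) >= 5) old_style_charge(ab[, 5]) else
      rep(0L, nrow(ab))
    atoms <- data.frame(element = elements, charge = charge,
                        hcount = 0L, stringsAsFactors = FALSE)
    bonds <- if (length(bb) && nrow(bb)) {
      data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    } else empty_bonds()
    id <- ChemmineR::sdfid(sdf)
    meta <- as.list(ChemmineR::datablock(sdf))
    molecule(id, atoms, bonds, provenance = provenance, meta = meta)
  })
}

convert_with_explicit_h <- function(text, from) {
  ChemmineOB::convertFormat(
    from, "SDF", text,
    options = data.frame(names = "h", args = "", stringsAsFactors = FALSE))
}

parse_ob_sdf <- function(sdftext, provenance) {
  if (!nzchar(gsub("[[:space:]]", "", sdftext))) return(list())
  con <- textConnection(sdftext)
  on.exit(close(con))
  sdfset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(con),
                                   skipErrors = TRUE)
  sdfset <- sdfset[ChemmineR::validSDF(sdfset)]
  if (!length(sdfset)) return(list())
  sdfset_to_molecules(sdfset, provenance)
}

#' Read molecules from a SMILES file
#'
#' One record per line, `SMILES<whitespace>id`. Lines that cannot be parsed
#' (either malformed or rejected by the SMILES reader) are skipped with a
#' warning; the skip count is attached as attribute `skipped`.
#'
#' @param path path to the SMILES file.
#' @return List of [molecule] objects in file order, with attribute
#'   `skipped` (number of unparsable records).
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  well_formed <- vapply(fields, length, integer(1)) >= 2
  smi <- vapply(fields[well_formed], `[[`, character(1), 1)
  ids <- vapply(fields[well_formed], `[[`, character(1), 2)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate molecule id: %s", ids[duplicated(ids)][1]))
  # records are converted one at a time: a malformed SMILES then skips
  # only its own record instead of truncating the whole stream
  mols <- list()
  for (k in seq_along(smi)) {
    got <- tryCatch(
      parse_ob_sdf(convert_with_explicit_h(
        paste0(smi[k], "\t", ids[k], "\n"), "SMI"), "smiles"),
      error = function(e) list())
    if (length(got) == 1 && identical(got[[1]]$id, ids[k]))
      mols[[length(mols) + 1L]] <- got[[1]]
  }
  skipped <- length(lines) - length(mols)
  if (length(mols) == 0)
    stop(sprintf("no parsable SMILES records in %s", path))
  if (skipped > 0)
    warning(sprintf("skipped %d unparsable SMILES record(s)", skipped))
  attr(mols, "skipped") <- skipped
  mols
}

#' Read molecules from an SDF (V2000) file
#'
#' Records are passed through OpenBabel with explicit-hydrogen expansion and
#' parsed with ChemmineR. SDF property fields are retained in each
#' molecule's `meta` list. Truncated or otherwise unreadable records are
#' skipped and counted.
#'
#' @param path path to the SDF file.
#' @return List of [molecule] objects with attribute `skipped`.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- paste0(paste(readLines(path, warn = FALSE), collapse = "\n"), "\n")
  n_records <- length(gregexpr("\\$\\$\\$\\$", raw)[[1]])
  if (!grepl("\\$\\$\\$\\$", raw)) n_records <- 0L
  mols <- parse_ob_sdf(convert_with_explicit_h(raw, "SDF"), "sdf")
  if (length(mols) == 0) stop(sprintf("no parsable SDF records in %s", path))
  ids <- vapply(mols, `[[`, character(1), "id")
  blank <- !nzchar(ids)
  ids[blank] <- sprintf("mol%d", which(blank))
  for (k in which(blank)) mols[[k]]$id <- ids[k]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate molecule id: %s", ids[duplicated(ids)][1]))
  skipped <- max(0L, n_records - length(mols))
  if (skipped > 0)
    warning(sprintf("skipped %d unreadable SDF record(s)", skipped))
  attr(mols, "skipped") <- skipped
  mols
}

#' Read a per-compound activity table
#'
#' Tab-separated file with header `id<TAB>target1<TAB>...`. In `binary`
#' mode cells must be 0 or 1 and pass through unchanged. In `pki` mode
#' cells hold real pK_i values and a `cutoff` is required: a value greater
#' than or equal to the cutoff marks the compound active for that target
#' (the comparison is inclusive; a compound counts as inactive only when
#' its value lies strictly below the cutoff).
#'
#' @param path path to the TSV file.
#' @param mode `"binary"` or `"pki"`.
#' @param cutoff activity cutoff on the pK_i scale (required in pki mode;
#'   the protease protocol in this package uses 5.6, 6.1 and 6.6).
#' @return An object of class `activity_table` with fields `ids`, `targets`,
#'   `profiles` (binary matrix), `values` (raw numeric matrix), `mode`,
#'   `cutoff`.
#' @export
read_activity_table <- function(path, mode = c("binary", "pki"),
                                cutoff = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (mode == "pki" && is.null(cutoff))
    stop("pki mode requires a cutoff")
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("activity table needs an id column and >= 1 target")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate compound id: %s", ids[duplicated(ids)][1]))
  targets <- colnames(df)[-1]
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], c(1, 2),
                                              as.numeric))), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric activity value at row %d, column '%s'",
                 bad[1], targets[bad[2]]))
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric activity value at row %d, column '%s'",
                 bad[1], targets[bad[2]]))
  }
  if (mode == "binary") {
    if (!all(vals %in% c(0, 1))) {
      bad <- which(!(vals %in% c(0, 1)), arr.ind = FALSE)[1]
      rc <- arrayInd(bad, dim(vals))
      stop(sprintf("binary activity value outside {0,1} at row %d, column '%s'",
                   rc[1], targets[rc[2]]))
    }
    profiles <- vals
  } else {
    profiles <- (vals >= cutoff) * 1
  }
  storage.mode(profiles) <- "integer"
  rownames(profiles) <- ids
  rownames(vals) <- ids
  structure(list(ids = ids, targets = targets, profiles = profiles,
                 values = vals, mode = mode, cutoff = cutoff),
            class = "activity_table")
}

#' @exportS3Method base::print
print.activity_table <- function(x, ...) {
  cat(sprintf("<activity_table> %d compounds x %d targets (%s%s)\n",
              length(x$ids), length(x$targets), x$mode,
              if (!is.null(x$cutoff)) sprintf(", cutoff %.2f", x$cutoff)
              else ""))
  invisible(x)
}

#' Write / read sparse fingerprints in svmlight-style text format
#'
#' One record per line: `label index:value index:value ... # id`, with
#' 0-based, strictly increasing feature indices. Values are serialized at
#' full precision (17 significant digits), so a write followed by a read
#' reproduces the fingerprints bit-exactly. The trailing `# id` comment is
#' optional.
#'
#' @param fps list of [sparse_fp].
#' @param path output file path.
#' @param labels numeric labels, one per fingerprint (default 0).
#' @param ids optional character ids, written as trailing comments.
#' @return `write_sparse_fingerprints` returns `path` invisibly;
#'   `read_sparse_fingerprints` returns a list with elements `fps`,
#'   `labels`, `ids`, `dim`.
#' @export
write_sparse_fingerprints <- function(fps, path,
                                      labels = rep(0, length(fps)),
                                      ids = NULL) {
  stopifnot(length(labels) == length(fps))
  if (!is.null(ids)) stopifnot(length(ids) == length(fps))
  lines <- vapply(seq_along(fps), function(k) {
    f <- fps[[k]]
    feats <- if (length(f$index))
      paste(sprintf("%.0f:%.17g", f$index, f$value), collapse = " ")
    else ""
    line <- trimws(paste(format(labels[k], scientific = FALSE, trim = TRUE),
                         feats))
    if (!is.null(ids)) line <- paste(line, "#", ids[k])
    line
  }, character(1))
  dim_comment <- sprintf("# dim %s", format(fps[[1]]$dim,
                                            scientific = FALSE))
  writeLines(c(dim_comment, lines), path)
  invisible(path)
}

#' @rdname write_sparse_fingerprints
#' @param default_dim hash-space dimension assumed when the file carries no
#'   `# dim` header line.
#' @export
read_sparse_fingerprints <- function(path, default_dim = 2^20) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  dim <- default_dim
  if (length(lines) && grepl("^# dim ", lines[1])) {
    dim <- as.numeric(sub("^# dim ", "", lines[1]))
    lines <- lines[-1]
  }
  lines <- lines[nzchar(trimws(lines))]
  fps <- vector("list", length(lines))
  labels <- numeric(length(lines))
  ids <- rep(NA_character_, length(lines))
  for (k in seq_along(lines)) {
    line <- lines[k]
    hash_pos <- regexpr("#", line, fixed = TRUE)
    if (hash_pos > 0) {
      ids[k] <- trimws(substring(line, hash_pos + 1))
      line <- substring(line, 1, hash_pos - 1)
    }
    toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    labels[k] <- as.numeric(toks[1])
    if (is.na(labels[k]))
      stop(sprintf("line %d: malformed label", k))
    if (length(toks) > 1) {
      parts <- strsplit(toks[-1], ":", fixed = TRUE)
      idx <- as.numeric(vapply(parts, `[[`, character(1), 1))
      val <- as.numeric(vapply(parts, function(p) p[2], character(1)))
      if (anyNA(idx) || anyNA(val))
        stop(sprintf("line %d: malformed index:value pair", k))
      if (length(idx) > 1 && any(diff(idx) <= 0))
        stop(sprintf("line %d: unsorted or duplicate feature index", k))
      fps[[k]] <- sparse_fp(idx, val, dim = dim)
    } else {
      fps[[k]] <- sparse_fp(numeric(0), numeric(0), dim = dim)
    }
  }
  if (all(is.na(ids))) ids <- NULL
  list(fps = fps, labels = labels, ids = ids, dim = dim)
}
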