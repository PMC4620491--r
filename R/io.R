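#' Read a COLVAR-style CV table
#'
#' Whitespace-delimited numeric table whose first line is
#' `#! FIELDS <name> <name> ...`; later comment lines (starting `#`) are
#' skipped. Ragged or non-numeric rows raise an error naming the line.
#'
#' @param path File path.
#' @return Data.frame with the header's column names.
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^#!\\s*FIELDS\\s+", lines[1]))
    stop("missing '#! FIELDS' header in ", path)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", lines[1]), "\\s+")[[1]]
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  rows <- strsplit(trimws(lines[body_idx]), "\\s+")
  widths <- lengths(rows)
  if (any(widths != length(fields))) {
    bad <- body_idx[which(widths != length(fields))[1]]
    stop("line ", bad, " has ", widths[widths != length(fields)][1],
         " fields, expected ", length(fields))
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals) || any(!is.finite(vals))) {
    bad <- body_idx[ceiling(which(!is.finite(vals))[1] / length(fields))]
    stop("non-finite or non-numeric value at line ", bad)
  }
  df <- as.data.frame(matrix(vals, ncol = length(fields), byrow = TRUE))
  names(df) <- fields
  df
}

#' Write a COLVAR-style CV table
#'
#' @param df Data.frame of numeric columns (conventionally starting with
#'   `time`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_colvar <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(df), collapse = " ")), con)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column bias grid
#'
#' Plain text with two numeric columns, CV value and bias (kJ/mol);
#' comment lines starting `#` are ignored.
#'
#' @param path File path.
#' @return Data.frame with columns `cv_value`, `bias`.
#' @export
read_bias_grid <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("cv_value", "bias"))
  if (any(diff(df$cv_value) <= 0))
    stop("bias grid must be strictly increasing in cv_value: ", path)
  df
}

#' Write a two-column bias grid
#'
#' @param grid Data.frame with columns `cv_value`, `bias`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bias_grid <- function(grid, path) {
  utils::write.table(grid[, c("cv_value", "bias")], path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a peptide conformation from a PDB file
#'
#' Uses the first model of the file (with a warning if more are present),
#' rejects insertion codes, infers the one-letter sequence from residue
#' names, and renumbers residues contiguously from 1 (original numbers
#' kept as attribute `"orig_resno"`).
#'
#' @param path PDB file path.
#' @return A [conformation()].
#' @export
read_structure <- function(path) {
  if (any(grepl("^MODEL", readLines(path))))
    warning("multi-model PDB; using the first model")
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no ATOM records in ", path)
  if (any(!is.na(a$insert) & nzchar(a$insert)))
    stop("insertion codes are not supported")
  key <- paste(a$chain, a$resno)
  resmap <- match(key, unique(key))
  res3 <- a$resid[!duplicated(resmap)]
  seq1 <- .AA1[res3]
  if (anyNA(seq1))
    stop("unknown residue name(s): ",
         paste(unique(res3[is.na(seq1)]), collapse = ", "))
  atoms <- data.frame(resno = resmap, resid = a$resid, elety = a$elety,
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  conf <- conformation(unname(seq1), atoms,
                       chain = a$chain[1])
  attr(conf, "orig_resno") <- a$resno[!duplicated(resmap)]
  conf
}

#' Write a conformation as a PDB file
#'
#' Standard single-chain ATOM records with 1-based residue numbering.
#'
#' @param conf A [conformation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(conf, path) {
  a <- conf$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = rep(conf$chain, nrow(a)))
  invisible(path)
}
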