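# Reading/writing sequences, label manifests, PSSM profiles and feature
# tables. All formats are plain text; CRLF input is tolerated.

#' Construct a ProteinSet
#'
#' @param sequences An `AAStringSet`, or a named character vector of
#'   residue strings. Sequences are sanitized (see [sanitizeSequence]).
#' @param labels Optional character vector of class labels (parallel to
#'   `sequences`, or named by sequence identifier).
#' @param profiles Optional named list of L x 20 PSSM matrices.
#' @param classNames Optional explicit class ordering; defaults to the
#'   order of first appearance in `labels`.
#' @return A [ProteinSet].
#' @export
ProteinSet <- function(sequences, labels = NULL, profiles = list(),
                       classNames = NULL) {
  if (is(sequences, "XStringSet")) {
    seqs <- as.character(sequences)
    names(seqs) <- names(sequences)
  } else seqs <- sequences
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq_%04d", seq_along(seqs))
  seqs <- vapply(seqs, sanitizeSequence, character(1))
  if (is.null(labels)) {
    lab <- rep(NA_character_, length(seqs))
  } else if (!is.null(names(labels))) {
    lab <- unname(labels[names(seqs)])
    if (anyNA(lab) && !anyNA(labels))
      stop("label manifest is missing ids: ",
           paste(setdiff(names(seqs), names(labels)), collapse = ", "))
  } else {
    if (length(labels) != length(seqs))
      stop("labels must be parallel to sequences or named by id")
    lab <- as.character(labels)
  }
  if (is.null(classNames))
    classNames <- unique(lab[!is.na(lab)])
  new("ProteinSet",
      sequences = Biostrings::AAStringSet(seqs),
      labels = lab, classNames = classNames, profiles = profiles)
}

#' Sanitize a raw residue string
#'
#' Upper-cases and resolves non-standard residue codes: B -> D, Z -> E,
#' U -> C, O -> K; X and anything else outside the 20-letter alphabet is
#' removed. Errors if nothing remains.
#'
#' @param raw Non-empty character scalar.
#' @return Sanitized sequence over the 20-letter alphabet.
#' @export
sanitizeSequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw))
    stop("raw sequence must be a non-empty string")
  s <- strsplit(toupper(raw), "")[[1]]
  map <- c(B = "D", Z = "E", U = "C", O = "K")
  hit <- s %in% names(map)
  s[hit] <- map[s[hit]]
  s <- s[s %in% .aa_alphabet]
  if (!length(s))
    stop("invalid sequence: empty after removing non-standard residues")
  paste(s, collapse = "")
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A named `AAStringSet` (upper-cased, raw residues; apply
#'   [sanitizeSequence] / [ProteinSet] for alphabet cleanup). Identifiers
#'   are the first whitespace-delimited token of each header.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) {
    warning("empty FASTA file: ", path)
    return(Biostrings::AAStringSet())
  }
  if (!startsWith(trimws(lines[nonempty[1]]), ">"))
    stop("malformed FASTA: line ", nonempty[1],
         " holds sequence data before any '>' header")
  set <- Biostrings::readAAStringSet(path)
  names(set) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  set <- Biostrings::AAStringSet(toupper(as.character(set)))
  set
}

#' Write sequences as FASTA
#'
#' @param x A `ProteinSet` or `AAStringSet`.
#' @param path Output path.
#' @export
writeFasta <- function(x, path) {
  set <- if (is(x, "ProteinSet")) x@sequences else x
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a two-column label manifest (id TAB class)
#'
#' @param path Path to a TSV with columns `id` and `class` (no header
#'   required; a header line `id<TAB>class` is tolerated).
#' @return Named character vector label\[id\].
#' @export
readLabels <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, col.names = c("id", "class"),
                           colClasses = "character")
  if (nrow(tab) && tab$id[1] == "id" && tab$class[1] == "class")
    tab <- tab[-1, , drop = FALSE]
  stats::setNames(tab$class, tab$id)
}

#' Write a label manifest
#'
#' @param labels Named character vector (names = ids).
#' @param path Output path.
#' @export
writeLabels <- function(labels, path) {
  utils::write.table(data.frame(id = names(labels), class = unname(labels)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-Q` ASCII dialect: header lines, then one row per sequence
#' position carrying the position index, the residue, 20 integer log-odds
#' scores (the columns kept), 20 percentage columns and two trailing
#' floats. Trailing blank lines and footer statistics are ignored.
#'
#' @param path Path to the PSSM file.
#' @param id Identifier to attach; defaults to the file name without
#'   extension.
#' @return L x 20 numeric matrix (PSI-BLAST column order) with
#'   `attr(, "id")` and `attr(, "residues")`.
#' @export
readPssm <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  hdr <- grep("^\\s*A\\s+R\\s+N\\s+D\\s+C\\s", lines)
  if (!length(hdr))
    stop("missing PSSM header (amino-acid column labels) in ", path)
  rows <- grep("^\\s*\\d+\\s+[A-Za-z]\\s", lines)
  rows <- rows[rows > hdr[1]]
  if (!length(rows)) stop("no PSSM data rows found in ", path)
  scores <- matrix(0, nrow = length(rows), ncol = 20)
  residues <- character(length(rows))
  for (r in seq_along(rows)) {
    tok <- strsplit(trimws(lines[rows[r]]), "\\s+")[[1]]
    residues[r] <- tok[2]
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (length(tok) < 22 || anyNA(vals))
      stop("PSSM parse error at position ", tok[1], " in ", path,
           ": expected 20 numeric log-odds values")
    scores[r, ] <- vals
  }
  colnames(scores) <- .pssm_columns
  attr(scores, "id") <- id
  attr(scores, "residues") <- residues
  scores
}

#' Write a PSSM matrix in the PSI-BLAST ASCII layout
#'
#' Inverse of [readPssm] for fixtures and round-trips; only the 20
#' log-odds columns are meaningful (percentages are written as zeros).
#'
#' @param scores L x 20 numeric matrix.
#' @param path Output path.
#' @param residues Optional residue letters per row.
#' @export
writePssm <- function(scores, path, residues = NULL) {
  stopifnot(is.matrix(scores), ncol(scores) == 20)
  if (is.null(residues)) residues <- attr(scores, "residues")
  if (is.null(residues)) residues <- rep("X", nrow(scores))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
    "Last position-specific scoring matrix computed",
    paste0("            ", paste(sprintf("%3s", .pssm_columns), collapse = ""),
           "   ", paste(sprintf("%3s", .pssm_columns), collapse = ""))),
    con)
  for (i in seq_len(nrow(scores))) {
    writeLines(paste0(sprintf("%5d %s  ", i, residues[i]),
                      paste(sprintf("%4g", scores[i, ]), collapse = ""),
                      "  ", paste(rep("   0", 20), collapse = ""),
                      "  0.00 0.00"), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Write a FeatureMatrix as TSV
#'
#' Header `id label f1 ... fd`; values serialized with 12 significant
#' digits so a read/write round trip is lossless at working precision.
#' A leading `#params` comment line records lambda/omega/xi and the
#' block widths.
#'
#' @param fm A [FeatureMatrix].
#' @param path Output path.
#' @export
writeFeatureTable <- function(fm, path) {
  stopifnot(is(fm, "FeatureMatrix"))
  v <- fm@values
  p <- fm@params
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#params lambda=%s omega=%s xi=%s pseaac=%d psepssm=%d",
                     p$lambda, p$omega, p$xi,
                     length(fm@blocks$pseaac), length(fm@blocks$psepssm)),
             con)
  writeLines(paste(c("id", "label", paste0("f", seq_len(ncol(v)))),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i], fm@labels[i],
                       sprintf("%.12g", v[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' Read a feature table written by [writeFeatureTable]
#'
#' @param path Path to the TSV.
#' @return A [FeatureMatrix].
#' @export
readFeatureTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  params <- list(lambda = NA, omega = NA, xi = NA)
  blocks <- list()
  if (length(lines) && startsWith(lines[1], "#params")) {
    kv <- regmatches(lines[1], gregexpr("[a-z]+=[-0-9.eE]+", lines[1]))[[1]]
    vals <- stats::setNames(
      as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
    params <- list(lambda = unname(vals["lambda"]),
                   omega = unname(vals["omega"]),
                   xi = unname(vals["xi"]))
    if (!is.na(vals["pseaac"]))
      blocks <- list(
        pseaac = seq_len(as.integer(vals[["pseaac"]])),
        psepssm = as.integer(vals[["pseaac"]]) +
          seq_len(as.integer(vals[["psepssm"]])))
    lines <- lines[-1]
  }
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           check.names = FALSE, colClasses = "character")
  if (anyNA(tab$label) || any(!nzchar(tab$label)))
    stop("feature table has rows without labels")
  v <- as.matrix(vapply(tab[, -(1:2), drop = FALSE], as.numeric,
                        numeric(nrow(tab))))
  if (nrow(tab) == 1L) v <- matrix(v, nrow = 1)
  rownames(v) <- tab$id
  if (!length(blocks)) blocks <- list(all = seq_len(ncol(v)))
  new("FeatureMatrix", values = v, labels = tab$label,
      blocks = blocks, params = params)
}
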