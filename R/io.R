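# FASTA / Newick / TSV report I/O.

# Accept XStringSet or named character; return validated named character.
.as_seqvec <- function(x, moltype = c("aa", "nt"), gapped = FALSE) {
  moltype <- match.arg(moltype)
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (methods::is(x, "SeqAlignment")) x <- alignedSeqs(x)
  if (!is.character(x) || is.null(names(x))) {
    stop("sequences must be a named character vector or an XStringSet")
  }
  x <- toupper(x)
  x <- gsub(".", "-", x, fixed = TRUE)
  .validate_records(x, moltype, gapped = gapped)
  x
}

.validate_records <- function(seqs, moltype, gapped = FALSE, where = "input") {
  ids <- names(seqs)
  if (any(!nzchar(ids)) || anyNA(ids)) {
    stop(where, ": record with empty id")
  }
  if (anyDuplicated(ids)) {
    stop(where, ": duplicate id '", ids[duplicated(ids)][1], "'")
  }
  if (any(grepl("[[:space:]]", ids))) {
    stop(where, ": id contains whitespace")
  }
  if (any(!nzchar(seqs))) {
    stop(where, ": empty sequence for id '", ids[!nzchar(seqs)][1], "'")
  }
  alpha <- if (moltype == "aa") .aa_alphabet else .nt_alphabet
  if (gapped) alpha <- c(alpha, "-")
  rx <- paste0("[^", paste(alpha, collapse = ""), "]")
  hit <- regexpr(rx, seqs)
  bad <- which(hit > 0)
  if (length(bad)) {
    stop(where, ": illegal character '",
         substr(seqs[bad[1]], hit[bad[1]], hit[bad[1]]),
         "' in record '", ids[bad[1]], "' at position ", hit[bad[1]])
  }
  invisible(TRUE)
}

#' Read unaligned sequences from FASTA
#'
#' Reads a FASTA file ('>' headers, arbitrary line wrapping), uppercases the
#' residues, takes the first whitespace-delimited header token as the id,
#' and validates against the declared alphabet (20 amino acids plus 'X', or
#' ACGT plus 'N'). Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param moltype \code{"aa"} or \code{"nt"}.
#' @return A [Biostrings::AAStringSet] or [Biostrings::DNAStringSet].
#' @examples
#' tf <- tempfile(fileext = ".faa")
#' writeLines(c(">a", "MKC", "DEF", ">b", "ML"), tf)
#' readFasta(tf, "aa")
#' @export
readFasta <- function(path, moltype = c("aa", "nt")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("FASTA format error in '", path,
                                          "': ", conditionMessage(e)))
  if (length(ss) == 0L) stop("FASTA format error: '", path, "' is empty")
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, "", 1)
  .validate_records(seqs, moltype, where = path)
  if (moltype == "aa") Biostrings::AAStringSet(seqs) else
    Biostrings::DNAStringSet(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector, XStringSet, or [SeqAlignment-class].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return The path, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  if (methods::is(seqs, "SeqAlignment")) seqs <- alignedSeqs(seqs)
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' As [readFasta()] but requires equal-width rows (error reporting the first
#' offending row otherwise), allows '-' gaps (and normalizes '.' to '-'),
#' and stores a method label on the returned alignment.
#'
#' @inheritParams readFasta
#' @param methodLabel Label stored verbatim on the alignment.
#' @return A [SeqAlignment-class].
#' @export
readAlignment <- function(path, moltype = c("aa", "nt"), methodLabel = "") {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("alignment format error in '", path,
                                          "': ", conditionMessage(e)))
  if (length(ss) == 0L) stop("alignment format error: '", path, "' is empty")
  seqs <- toupper(as.character(ss))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  names(seqs) <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, "", 1)
  w <- nchar(seqs)
  if (length(unique(w)) > 1L) {
    off <- names(seqs)[which(w != w[1])[1]]
    stop("alignment format error: ragged rows in '", path,
         "' (row '", off, "' has length ", nchar(seqs[off]),
         ", expected ", w[1], ")")
  }
  .validate_records(seqs, moltype, gapped = TRUE, where = path)
  seqAlignment(seqs, moltype, methodLabel)
}

#' Read and validate a Newick tree
#'
#' Parses standard Newick (branch lengths, optional internal-node support
#' labels) into an \code{ape::phylo}, rejecting malformed strings and
#' negative branch lengths.
#'
#' @param x Path to a Newick file, or a Newick string.
#' @return An \code{ape::phylo}; numeric internal node labels are kept as
#'   support values in \code{node.label}.
#' @examples
#' readNewick("((a:1,b:1)0.95:1,c:2);")
#' @export
readNewick <- function(x) {
  txt <- if (length(x) == 1L && grepl("[(;]", x)) x else {
    if (!file.exists(x)) stop("file not found: ", x)
    paste(readLines(x, warn = FALSE), collapse = "")
  }
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("Newick parse error: ", substr(txt, 1, 60))
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("validation error: negative branch length in tree")
  }
  tr
}

#' Serialize a tree as Newick
#'
#' @param tree An \code{ape::phylo}.
#' @param path Optional output file; when NULL the string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when written to file).
#' @export
writeNewick <- function(tree, path = NULL, digits = 10L) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Write a report table as TSV
#'
#' Tab-separated, header row, UTF-8, deterministic row order (rows written
#' as given). Numeric cells are rendered at 6 significant digits so values
#' round-trip through text.
#'
#' @param table A data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeReportTable <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) {
        if (is.na(v)) NA_character_ else format(signif(v, 6), scientific = FALSE, trim = TRUE)
      }, "")
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV report table
#'
#' @param path Path written by [writeReportTable()].
#' @return A data.frame.
#' @export
readReportTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
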