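# Internal helpers: alphabets, genetic code tables, seeded RNG streams.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.NT4 <- c("A", "C", "G", "T")

.aa_alphabet <- c(.AA20, "X")
.nt_alphabet <- c(.NT4, "N")

# package-level cache for codon tables and eigen systems
.alnsens_cache <- new.env(parent = emptyenv())

#' @noRd
.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# 61 sense codons in lexicographic order, plus structural tables for the
# Goldman-Yang style codon process.
.codon_tables <- function() {
  if (!is.null(.alnsens_cache$codon)) return(.alnsens_cache$codon)
  gc <- .genetic_code()
  sense <- sort(names(gc)[gc != "*"])
  n <- length(sense)
  aa <- gc[sense]
  cm <- do.call(rbind, strsplit(sense, ""))
  ndiff <- matrix(0L, n, n)
  pos_diff <- matrix(0L, n, n)
  for (k in 1:3) {
    d <- outer(cm[, k], cm[, k], "!=")
    ndiff <- ndiff + d
    pos_diff[d & ndiff == 1L] <- k
  }
  single <- ndiff == 1L
  # transition (A<->G, C<->T) at the differing position
  is_ts <- matrix(FALSE, n, n)
  idx <- which(single, arr.ind = TRUE)
  if (nrow(idx)) {
    p <- pos_diff[idx]
    from <- cm[cbind(idx[, 1], p)]
    to <- cm[cbind(idx[, 2], p)]
    purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
    is_ts[idx] <- purine[from] == purine[to]
  }
  nonsyn <- outer(aa, aa, "!=")
  out <- list(sense = sense, aa = unname(aa), single = single,
              is_ts = is_ts & single, nonsyn = nonsyn & single)
  .alnsens_cache$codon <- out
  out
}

#' @noRd
.translate_codon <- function(codons) {
  gc <- .genetic_code()
  out <- rep(NA_character_, length(codons))
  out[codons == "---"] <- "-"
  known <- codons %in% names(gc)
  out[known] <- unname(gc[codons[known]])
  amb <- is.na(out)
  out[amb] <- "X"
  out
}

# Translate a gapped in-frame nucleotide string to a gapped aa string.
.translate_nt_row <- function(s) {
  if (nchar(s) %% 3 != 0) {
    stop("nucleotide row length not a multiple of 3: ", nchar(s))
  }
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  mixed <- grepl("-", codons) & codons != "---"
  if (any(mixed)) {
    stop("gap run not codon-aligned at codon ", which(mixed)[1])
  }
  paste(.translate_codon(codons), collapse = "")
}

# Deterministic child-stream seeding: every stochastic operation draws from
# a stream derived from (seed, stream name) so stages are independently
# reproducible. Kept below 2^31.
.derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_len(nchar(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + 17) %% 2147483587)
}

# Evaluate `expr` under a seeded local RNG without disturbing the caller's.
.with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(.derive_seed(seed, stream))
  expr
}

.is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == round(x)
}

.chr_mat <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(m) <- names(seqs)
  m
}
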