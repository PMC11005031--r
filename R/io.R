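# FASTA / FASTQ / TSV input-output. Parsing is delegated to Biostrings;
# this layer adds the circularity header tag, alphabet validation and
# the package's TSV report conventions (header row, '#' metadata lines,
# 1-based inclusive coordinates, +/- strands).

#' Read sequences from a FASTA file
#'
#' Records whose header carries the tag `circular=true` are returned as
#' [circular_sequence()] objects; set `circular = TRUE` to force it for
#' all records. Lowercase bases are uppercased (with a message).
#'
#' @param path FASTA file (gzip accepted).
#' @param circular treat every record as circular regardless of tag.
#' @return named list of `circular_sequence` (or, for linear records,
#'   plain character strings).
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(list())
  ss <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                 error = function(e)
                   stop("malformed FASTA '", path, "': ", conditionMessage(e),
                        call. = FALSE))
  if (length(ss) == 0L) return(list())
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  seqs <- unname(as.character(ss))
  lower <- grepl("[acgtn]", seqs)
  if (any(lower)) {
    message("uppercased lowercase bases in record(s): ",
            paste(ids[lower], collapse = ", "))
    seqs <- toupper(seqs)
  }
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    .assert_dna(seqs[i], ids[i])
    circ <- circular || grepl("circular=true", headers[i], fixed = TRUE)
    out[[i]] <- if (circ) circular_sequence(seqs[i], id = ids[i]) else seqs[i]
  }
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' `circular_sequence` records get a `circular=true` header tag so that
#' [read_fasta()] round-trips them.
#'
#' @param seqs named list of `circular_sequence` and/or character.
#' @param path output file.
#' @param wrap line width, 60 or 80.
#' @export
write_fasta <- function(seqs, path, wrap = 60L) {
  stopifnot(wrap %in% c(60L, 80L))
  con <- file(path, "w")
  on.exit(close(con))
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
  for (i in seq_along(seqs)) {
    x <- seqs[[i]]
    if (inherits(x, "circular_sequence")) {
      writeLines(paste0(">", x$id, " circular=true"), con)
      s <- x$seq
    } else {
      writeLines(paste0(">", nm[i]), con)
      s <- x
    }
    n <- nchar(s)
    starts <- seq(1L, n, by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, n)), con)
  }
  invisible(path)
}

#' Read long reads from FASTA or FASTQ
#'
#' Format is chosen by extension (`.fq`/`.fastq` vs anything else);
#' gzip is auto-detected by `.gz`. Qualities are not retained: every
#' downstream rule in the package is sequence-only.
#'
#' @param path reads file.
#' @return data.frame with columns `id`, `seq`, `length`.
#' @export
read_reads <- function(path) {
  fq <- grepl("\\.(fq|fastq)(\\.gz)?$", path)
  ss <- Biostrings::readBStringSet(path, format = if (fq) "fastq" else "fasta")
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(unname(as.character(ss)))
  data.frame(id = ids, seq = seqs, length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' Constant placeholder qualities (`I` = Q40) are emitted; output is
#' byte-deterministic. `.gz` extension triggers gzip compression.
#'
#' @param reads data.frame with `id` and `seq` columns.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads$seq),
                 function(n) strrep("I", n), character(1))
  writeLines(rbind(paste0("@", reads$id), reads$seq, "+", qual), con)
  invisible(path)
}

# TSV with '#' metadata lines and a header row.
write_tsv_report <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
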